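test_that("sharp two-band image is segmented exactly (IoU 1 against truth)", {
  img <- two_band_image(H = 90, W = 48, r1 = 30, r2 = 59)
  seg <- astar_segment(img)
  truth <- matrix(FALSE, 90, 48); truth[30:59, ] <- TRUE
  expect_equal(miou(seg$mask, truth), 1)
  expect_identical(seg$qc, "ok")
})

test_that("featureless images raise BoundaryNotFound", {
  expect_error(astar_segment(matrix(50, 64, 64)),
               class = "foveapit_boundary_error")
  expect_error(astar_segment(matrix(1, 10, 10)),
               class = "foveapit_shape_error")
})

test_that("A* path cost equals the exhaustive dynamic-programming minimum", {
  set.seed(301)
  for (i in 1:5) {
    H <- sample(32:64, 1); W <- sample(32:64, 1)
    cost <- matrix(runif(H * W), H, W)
    res <- foveapit:::astar_path_cpp(cost, 0.1, 5L)
    expect_equal(res$cost, dp_min_cost(cost, 0.1, 5L), tolerance = 1e-12)
    # returned path reproduces its own reported cost
    pc <- sum(cost[cbind(res$rows, seq_len(W))]) +
      0.1 * sum(abs(diff(res$rows)))
    expect_equal(pc, res$cost, tolerance = 1e-12)
  }
})

test_that("boundary traces extract correctly from masks, with interpolation flags", {
  m <- matrix(FALSE, 200, 40)
  m[100:187, ] <- TRUE
  ilm <- extract_ilm(m); rpe <- extract_rpe(m)
  expect_true(all(ilm$row == 100))
  expect_true(all(rpe$row == 187))
  expect_false(any(ilm$interpolated))

  # one empty column between tops at 100 and 102 -> interpolated 101, flagged
  m2 <- matrix(FALSE, 200, 3)
  m2[100:150, 1] <- TRUE; m2[102:150, 3] <- TRUE
  tr <- extract_ilm(m2)
  expect_equal(tr$row[2], 101)
  expect_true(tr$interpolated[2])
  expect_false(tr$valid[2])

  expect_error(extract_ilm(matrix(FALSE, 10, 10)),
               class = "foveapit_boundary_error")
  half <- matrix(FALSE, 10, 10); half[5, 1:4] <- TRUE
  expect_error(extract_ilm(half), class = "foveapit_boundary_error")
})

test_that("ILM trace never exceeds the RPE trace on segmented scans", {
  dc <- default_clean_scene()
  seg <- astar_segment(dc$bscan)
  expect_true(all(seg$ilm <= seg$rpe))
  expect_true(all(extract_ilm(seg)$row <= extract_rpe(seg)$row))
})

test_that("miou follows its set-count definition", {
  a <- matrix(FALSE, 30, 10); a[10:19, ] <- TRUE
  expect_equal(miou(a, a), 1)
  b <- matrix(FALSE, 30, 10); b[25:28, ] <- TRUE
  expect_equal(miou(a, b), 0)
  # truth band 100 rows thick, prediction dilated by one row -> 100/102
  t100 <- matrix(FALSE, 120, 8); t100[11:110, ] <- TRUE
  d100 <- matrix(FALSE, 120, 8); d100[10:111, ] <- TRUE
  expect_equal(miou(d100, t100), 100 / 102)
  expect_equal(miou(matrix(FALSE, 5, 5), matrix(FALSE, 5, 5)), 1)
})

test_that("segmentation at default noise stays within two rows of the truth", {
  sn <- generate_bscans(3, seed = 1)
  for (s in sn) {
    seg <- astar_segment(s$image)
    expect_lte(max(abs(seg$ilm - s$ilm)), 2)
    expect_lte(max(abs(seg$rpe - s$rpe)), 2)
    expect_gte(miou(seg$mask, s$mask), 0.97)
  }
})

test_that("lateral pit translation translates the traces (flat-rim scene)", {
  mk <- function(col) scene_truth(a_macula = 0, pit_center = c(64L, col),
                                  noise_sigma = 0, seed = 3)
  s1 <- mk(250L); s2 <- mk(262L)
  t1 <- astar_segment(render_bscan(s1, 64))
  t2 <- astar_segment(render_bscan(s2, 64))
  w <- 230:270
  expect_equal(t2$ilm[w + 12], t1$ilm[w], tolerance = 1e-8)
})

test_that("mean IoU is non-increasing in speckle level", {
  # scaled-down version of the 50-scan property (sampling error allowed)
  mean_iou_at <- function(sig) {
    sn <- generate_bscans(10, seed = 401, noise_sigma = sig)
    mean(vapply(sn, function(s) miou(astar_segment(s$image)$mask, s$mask),
                numeric(1)))
  }
  ious <- vapply(c(0.05, 0.25, 0.5), mean_iou_at, numeric(1))
  expect_true(all(diff(ious) <= 0.002)) # allow tiny sampling wiggle
})
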