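test_that("patch tiling covers the extent exactly once", {
  expect_equal(nrow(tile_patches(504, 504, 252)), 4L)
  expect_equal(nrow(tile_patches(252, 252, 252)), 1L)
  g <- tile_patches(600, 300, 252)
  expect_equal(sum(g$w * g$h), 600 * 300)
  # pairwise intersections are empty (half-open windows)
  for (i in seq_len(nrow(g) - 1)) for (j in (i + 1):nrow(g)) {
    ox <- min(g$x0[i] + g$w[i], g$x0[j] + g$w[j]) - max(g$x0[i], g$x0[j])
    oy <- min(g$y0[i] + g$h[i], g$y0[j] + g$h[j]) - max(g$y0[i], g$y0[j])
    expect_true(ox <= 0 || oy <= 0)
  }
  expect_error(tile_patches(10, 10, 0), class = "ki67cl_error_patch")
})

test_that("dot-to-density rendering is a peak-normalized Gaussian sum", {
  d <- dot_set(cbind(30, 20), "TUMOR_POS")
  g <- dots_to_density(d, c(40, 60), sigma = 3)
  expect_equal(which(g == max(g), arr.ind = TRUE)[1, ], c(row = 21, col = 31))
  expect_equal(max(g), 1)   # isolated dot peaks at exactly 1
  expect_equal(dots_to_density(dot_set(matrix(numeric(0), ncol = 2), "c"),
                               c(10, 10), 3),
               matrix(0, 10, 10))
  expect_error(dots_to_density(dot_set(cbind(100, 5), "c"), c(40, 60), 3),
               class = "ki67cl_error_dot_bounds")
  # linearity: two dots 4 sigma apart equal the sum of single-dot grids
  two <- dots_to_density(dot_set(rbind(c(20, 20), c(32, 20)), "c"), c(40, 60), 3)
  one_a <- dots_to_density(dot_set(cbind(20, 20), "c"), c(40, 60), 3)
  one_b <- dots_to_density(dot_set(cbind(32, 20), "c"), c(40, 60), 3)
  expect_equal(two, one_a + one_b, tolerance = 1e-12)
})

test_that("local maxima match an exhaustive neighborhood scan", {
  expect_equal(nrow(find_local_maxima(matrix(0, 30, 30))), 0L)
  one <- dots_to_density(dot_set(cbind(15, 12), "c"), c(30, 30), 3)
  fm <- find_local_maxima(one)
  expect_equal(nrow(fm), 1L)
  expect_equal(c(fm$x, fm$y), c(15, 12))

  centers <- rbind(c(20, 20), c(70, 25), c(45, 70))
  g <- dots_to_density(dot_set(centers, "c"), c(90, 90), 3)
  fm3 <- find_local_maxima(g, min_probability = 0.5, min_distance = 15)
  expect_equal(nrow(fm3), 3L)
  ord <- order(centers[, 1])
  expect_equal(fm3[order(fm3$x), c("x", "y")],
               data.frame(x = centers[ord, 1], y = centers[ord, 2]),
               ignore_attr = TRUE)
  # brute-force pixel scan oracle: each reported point beats its whole disk
  xx <- rep(0:89, each = 90); yy <- rep(0:89, 90)
  violations <- sum(vapply(seq_len(nrow(fm3)), function(k) {
    disk <- (xx - fm3$x[k])^2 + (yy - fm3$y[k])^2 <= 15^2
    sum(g[cbind(yy[disk] + 1, xx[disk] + 1)] > fm3$probability[k])
  }, numeric(1)))
  expect_equal(violations, 0)
})

test_that("plateaus yield the lowest-row, lowest-column representative", {
  g <- matrix(0, 20, 20)
  g[10:12, 10:12] <- 0.8
  fm <- find_local_maxima(g, min_probability = 0.5, min_distance = 5)
  expect_equal(nrow(fm), 1L)
  expect_equal(c(fm$x, fm$y), c(9, 9))  # 0-based lowest row then column
})

test_that("cross-channel merge keeps the strongest within 15 px", {
  per <- list(
    pos = data.frame(x = 0, y = 0, probability = 0.9),
    neg = data.frame(x = 10, y = 0, probability = 0.7))
  out <- merge_channels(per)
  expect_equal(nrow(out), 1L)
  expect_equal(out$channel, "pos")
  # 20 px apart: both survive; exactly 15 px: both survive (strict rule)
  per$neg$x <- 20
  expect_equal(nrow(merge_channels(per)), 2L)
  per$neg$x <- 15
  expect_equal(nrow(merge_channels(per)), 2L)

  # 5-detection chain at 10-px spacing vs brute-force greedy suppression
  chain <- data.frame(x = seq(0, 40, 10), y = 0,
                      probability = c(0.6, 0.9, 0.5, 0.8, 0.7))
  got <- merge_channels(list(c1 = chain))
  want <- oracle_suppress(transform(chain, chan_rank = 1), 15)
  expect_equal(got$x, want$x)
  expect_equal(got$probability, want$probability)

  # idempotence
  again <- merge_channels(split(got, got$channel))
  expect_equal(nrow(again), nrow(got))
})

test_that("dots -> density -> maxima round-trip recovers well-spaced dots", {
  withr::with_seed(9, {
    pts <- expand.grid(x = seq(30, 220, 48), y = seq(30, 220, 48))
    pts <- pts + matrix(sample(-5:5, nrow(pts) * 2, TRUE), ncol = 2)
    pm <- simulate_probability_map(list(dot_set(as.matrix(pts), "TUMOR_POS")),
                                   shape = c(256, 256), sigma = 3,
                                   noise_sd = 0.05, seed = 1)
    det <- detect_cells(pm)
    m <- match_detections(det[, c("x", "y")], as.matrix(pts), radius = 20)
    met <- detection_metrics(m, det$channel, rep("TUMOR_POS", nrow(pts)))
    expect_equal(met$f1, 1)
  })
})

test_that("noise-free simulated maps equal the density rendering", {
  d <- list(dot_set(rbind(c(10, 10), c(40, 40)), "TUMOR_NEG"))
  pm <- simulate_probability_map(d, c(60, 60), sigma = 3, noise_sd = 0)
  expect_equal(pm$channels$TUMOR_NEG,
               pmin(dots_to_density(d[[1]], c(60, 60), 3), 1))
  # empty dots + mild noise: nothing above the 0.5 threshold
  pm0 <- simulate_probability_map(
    list(dot_set(matrix(numeric(0), ncol = 2), "c")),
    c(64, 64), sigma = 3, noise_sd = 0.05, seed = 2)
  expect_equal(nrow(find_local_maxima(pm0$channels$c)), 0L)
})
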