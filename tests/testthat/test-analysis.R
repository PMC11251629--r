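# synthetic templates with controlled support
block_template <- function(rows, cols, value = 1, base = 0, T = 16,
                           n_r = 10, n_c = 32) {
  g <- array(base, c(n_r, n_c, T))
  g[rows, cols, ] <- value * sin(seq(0, 2 * pi, length.out = T))
  structure(list(grid = g, fs = 2048, cond = NULL), class = "muap_template")
}

test_that("cropping keeps the minimal bounding box of high-amplitude channels", {
  # uniform template: every channel is above 0.75 of the mean -> full grid
  uni <- block_template(1:10, 1:32, value = 1)
  expect_identical(dim(crop_muap(uni)$grid), dim(uni$grid))
  # single nonzero channel -> 1 x 1 crop at that channel
  single <- block_template(4, 7)
  cs <- crop_muap(single)
  expect_identical(dim(cs$grid)[1:2], c(1L, 1L))
  expect_identical(attr(cs, "rows"), 4L)
  expect_identical(attr(cs, "cols"), 7L)
  # a 3 x 4 high-amplitude block on a weak background -> exactly its box
  blk <- block_template(5:7, 10:13, value = 1, T = 16)
  blk$grid <- blk$grid + block_template(1:10, 1:32, value = 0.01)$grid
  cb <- crop_muap(blk)
  expect_identical(attr(cb, "rows"), 5:7)
  expect_identical(attr(cb, "cols"), 10:13)
  expect_error(crop_muap(block_template(1, 1, value = 0)), "all-zero")
})

test_that("cropping is idempotent", {
  tpl <- quick_muap(mid_cond(), sample_latent(2, 5), T = 64)
  c1 <- crop_muap(tpl)
  c2 <- crop_muap(c1)
  expect_identical(c2$grid, c1$grid)
  expect_identical(attr(c2, "rows"), attr(c1, "rows"))
})

test_that("NMSE matches its analytic cases", {
  a <- quick_muap(mid_cond(), sample_latent(1, 5), T = 64)
  expect_identical(nmse(a, a), 0)
  neg <- a; neg$grid <- -a$grid
  expect_equal(nmse(a, neg), 4, tolerance = 1e-12)
  zero <- a; zero$grid <- a$grid * 0
  expect_equal(nmse(a, zero), 2, tolerance = 1e-12)
  expect_error(nmse(zero, zero), "all-zero")
})

test_that("NMSE is symmetric, non-negative and scale invariant", {
  set.seed(13)
  for (i in 1:25) {
    ga <- array(rnorm(5 * 6 * 8), c(5, 6, 8))
    gb <- array(rnorm(5 * 6 * 8), c(5, 6, 8))
    v <- nmse(ga, gb)
    expect_gte(v, 0)
    expect_identical(nmse(gb, ga), v)
    al <- runif(1, 0.1, 10) * sample(c(-1, 1), 1)
    expect_equal(nmse(al * ga, al * gb), v, tolerance = 1e-12)
  }
  # zero iff identical on the support
  ga <- array(rnorm(240), c(5, 6, 8))
  expect_identical(nmse(ga, ga), 0)
})

test_that("similarity matrices separate distant territories", {
  lat <- sample_latent(3, 5)
  near1 <- quick_muap(mid_cond(ml_pos = 0.50), lat, T = 64)
  near2 <- quick_muap(mid_cond(ml_pos = 0.53, depth = 0.45), lat, T = 64)
  far1 <- quick_muap(mid_cond(ml_pos = 0.05), lat, T = 64)
  far2 <- quick_muap(mid_cond(ml_pos = 0.08, depth = 0.45), lat, T = 64)
  sim <- similarity_matrix(list(near1, near2, far1, far2),
                           labels = c("A", "A", "B", "B"))
  v <- sim$values
  expect_identical(v, t(v))
  expect_true(all(diag(v) == 0))
  within <- c(v[1, 2], v[3, 4])
  across <- c(v[1, 3], v[1, 4], v[2, 3], v[2, 4])
  expect_lt(max(within), min(across))
  expect_true(all(sim$threshold_map[v < 0.2]))
  # duplicated template -> all-zero matrix
  dup <- similarity_matrix(list(near1, near1))
  expect_true(all(dup$values == 0))
})

test_that("angle-similarity curves are zero at baseline and grow when morphing", {
  # all-ones trajectory: identically zero curve
  pt1 <- len2params(rep(1, 8), 1, time = seq(0, 1, length.out = 8),
                    config = cfg)
  sq1 <- morph_sequence(mid_cond(), pt1, 5, NULL, 2048, 96, cfg)
  expect_identical(angle_similarity_curve(sq1)$nmse, rep(0, 5))

  # monotone shortening: non-decreasing dissimilarity from the baseline
  pt2 <- len2params(seq(1, 0.7, length.out = 16), 1,
                    time = seq(0, 1, length.out = 16), config = cfg)
  sq2 <- morph_sequence(mid_cond(), pt2, 8, NULL, 2048, 96, cfg)
  curve <- angle_similarity_curve(sq2, baseline_index = 1)
  expect_identical(curve$nmse[1], 0)
  expect_true(all(diff(curve$nmse) >= -1e-12))

  # identical units give a zero variance band
  pool_curve <- pool_similarity_curve(list(sq2, sq2, sq2))
  expect_equal(pool_curve$var_nmse, rep(0, 8), tolerance = 1e-20)
  expect_equal(pool_curve$mean_nmse, curve$nmse, tolerance = 1e-12)
})

test_that("RMS features have the documented window arithmetic", {
  fs <- 2000
  const <- structure(list(values = matrix(-3, 2, 15 * fs), fs = fs,
                          channel_map = NULL, provenance = NULL),
                     class = "emg_recording")
  fe <- rms_features(const)
  # floor((15 - 0.2) / 0.15) + 1 windows for a 15-s record
  expect_identical(nrow(fe$values), 99L)
  expect_true(all(abs(fe$values - 3) < 1e-12))
  # alternative reading: 50-ms step
  fe50 <- rms_features(const, step_s = 0.050)
  expect_identical(nrow(fe50$values), as.integer(floor((15 - 0.2) / 0.05) + 1))
  expect_error(rms_features(structure(list(values = matrix(1, 1, 10),
                                           fs = fs),
                                      class = "emg_recording")),
               "window longer")
})

test_that("RMS of white noise concentrates around its standard deviation", {
  set.seed(99)
  fs <- 2000
  wn <- structure(list(values = matrix(rnorm(4 * 10 * fs), 4), fs = fs),
                  class = "emg_recording")
  fe <- rms_features(wn)
  # sampling-distribution oracle: RMS of n=400 draws has SE ~ 1/sqrt(2n)
  se <- 1 / sqrt(2 * 400)
  expect_true(all(abs(fe$values - 1) < 3.9 * se))
  expect_equal(mean(fe$values), 1, tolerance = 3 * se / sqrt(length(fe$values)))
})

test_that("window labels average the angle series within each window", {
  fs <- 2000
  emg <- structure(list(values = matrix(0.5, 1, 2 * fs), fs = fs),
                   class = "emg_recording")
  fe <- rms_features(emg)
  t40 <- seq(0, 2, by = 1 / 40)
  lab <- window_labels(fe, t40, 10 * t40)
  # mean angle in window k = 10 * (start + window/2)
  expect_equal(lab, 10 * (fe$window_starts + 0.1), tolerance = 0.05)
})

test_that("similarity matrices export as delimited text", {
  lat <- sample_latent(1, 2)
  sim <- similarity_matrix(list(quick_muap(mid_cond(), lat, T = 48),
                                quick_muap(mid_cond(depth = 0.7), lat,
                                           T = 48)),
                           labels = c("a", "b"))
  path <- scratch_file("sim.tsv")
  write_similarity_matrix(sim, path)
  back <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                      row.names = 1))
  expect_equal(unname(back), unname(sim$values), tolerance = 1e-9)
})
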