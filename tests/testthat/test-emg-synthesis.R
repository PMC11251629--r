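# small deterministic fixtures: static templates + hand-placed spike trains
fake_spikes <- function(trains, fs = 2048) {
  structure(list(fs = fs, trains = trains, drive = NULL,
                 muscle = "toy", model_kind = "classical"),
            class = "spike_train_set")
}

lat <- sample_latent(1, 99)
tpl_a <- quick_muap(mid_cond(), lat, T = 64)
tpl_b <- quick_muap(mid_cond(ml_pos = 0.25, depth = 0.3), lat, T = 64)

test_that("no spikes produce an all-zero recording", {
  emg <- synthesize(fake_spikes(list(numeric(0), numeric(0))),
                    list(static_sequence(tpl_a, 1), static_sequence(tpl_b, 1)),
                    2048, 1)
  expect_true(all(emg$values == 0))
  expect_identical(nrow(emg$values), 320L)
})

test_that("a single spike at zero reproduces the template", {
  emg <- synthesize(fake_spikes(list(0)), list(static_sequence(tpl_a, 1)),
                    2048, 1)
  expect_equal(emg$values[, 1:64], emgsim::flatten_muap(tpl_a),
               tolerance = 1e-14)
  expect_true(all(emg$values[, 65:2048] == 0))
})

test_that("overlapping and non-overlapping spikes superpose exactly", {
  fs <- 2048
  # separation > template length: two clean copies
  st <- fake_spikes(list(c(0.1, 0.5)))
  emg <- synthesize(st, list(static_sequence(tpl_a, 1)), fs, 1)
  flat <- emgsim::flatten_muap(tpl_a)
  i1 <- round(0.1 * fs) + 1
  i2 <- round(0.5 * fs) + 1
  expect_equal(emg$values[, i1:(i1 + 63)], flat, tolerance = 1e-14)
  expect_equal(emg$values[, i2:(i2 + 63)], flat, tolerance = 1e-14)
  # with overlap: equals the dense-convolution oracle
  st2 <- fake_spikes(list(c(0.1, 0.11)))
  emg2 <- synthesize(st2, list(static_sequence(tpl_a, 1)), fs, 1)
  expect_equal(emg2$values, oracle_emg(st2$trains,
                                       list(tpl_a), fs, 1),
               tolerance = 1e-12)
})

test_that("synthesis matches the dense oracle for multiple units", {
  set.seed(31)
  fs <- 2048
  trains <- lapply(1:3, function(k) sort(runif(15, 0, 0.9)))
  templates <- list(tpl_a, tpl_b, quick_muap(mid_cond(depth = 0.7), lat,
                                             T = 64))
  st <- fake_spikes(trains)
  emg <- synthesize(st, lapply(templates, static_sequence, duration = 1),
                    fs, 1)
  dense <- oracle_emg(trains, templates, fs, 1)
  peak <- max(abs(dense))
  expect_lt(max(abs(emg$values - dense)), 1e-10 * peak)
})

test_that("synthesis is linear and additive over disjoint spike sets", {
  fs <- 2048
  tr1 <- list(c(0.1, 0.3), numeric(0))
  tr2 <- list(numeric(0), c(0.2, 0.4))
  seqs <- list(static_sequence(tpl_a, 1), static_sequence(tpl_b, 1))
  e1 <- synthesize(fake_spikes(tr1), seqs, fs, 1)
  e2 <- synthesize(fake_spikes(tr2), seqs, fs, 1)
  e12 <- synthesize(fake_spikes(list(tr1[[1]], tr2[[2]])), seqs, fs, 1)
  expect_equal(e12$values, e1$values + e2$values, tolerance = 1e-14)
  # scalar homogeneity in the templates
  tpl_scaled <- tpl_a
  tpl_scaled$grid <- 2.5 * tpl_a$grid
  es <- synthesize(fake_spikes(tr1), list(static_sequence(tpl_scaled, 1),
                                          static_sequence(tpl_b, 1)), fs, 1)
  expect_equal(es$values, 2.5 * e1$values, tolerance = 1e-12)
})

test_that("morphing templates are interpolated at each spike time", {
  fs <- 2048
  sq <- structure(list(keyframe_times = c(0, 1),
                       templates = list(tpl_a, tpl_b), unit_id = 1),
                  class = "muap_sequence")
  emg <- synthesize(fake_spikes(list(0.5)), list(sq), fs, 1)
  i0 <- round(0.5 * fs) + 1
  mixed <- 0.5 * emgsim::flatten_muap(tpl_a) + 0.5 * emgsim::flatten_muap(tpl_b)
  expect_equal(emg$values[, i0:(i0 + 63)], mixed, tolerance = 1e-10)
  # nearest-keyframe mode snaps to the closer template
  emg_n <- synthesize(fake_spikes(list(0.9)), list(sq), fs, 1,
                      keyframe_mode = "nearest")
  i1 <- round(0.9 * fs) + 1
  expect_equal(emg_n$values[, i1:(i1 + 63)],
               emgsim::flatten_muap(tpl_b)[, 1:64], tolerance = 1e-14)
  # fs mismatch is an error
  expect_error(synthesize(fake_spikes(list(0.1), fs = 1000), list(sq),
                          1000, 1), "sampling rate")
})

test_that("regular firing with a static template yields a periodic record", {
  fs <- 2048
  period <- 0.125 # an integer number of samples at 2048 Hz
  st <- fake_spikes(list(seq(0, 1.8, by = period)))
  emg <- synthesize(st, list(static_sequence(tpl_a, 2)), fs, 2)
  ch <- which.max(apply(abs(emg$values), 1, max))
  x <- emg$values[ch, ]
  lag <- round(period * fs)
  # compare only samples whose lagged counterpart is inside the spiking span
  span <- 1:3328
  expect_equal(x[span + lag], x[span], tolerance = 1e-12)
})

test_that("additive noise hits the requested SNR and is reproducible", {
  fs <- 2048
  st <- fake_spikes(list(sort(runif(40, 0, 9.5))))
  emg <- synthesize(st, list(static_sequence(tpl_a, 10)), fs, 10)
  expect_identical(add_noise(emg, Inf)$values, emg$values)
  noisy <- add_noise(emg, 10, seed = 2)
  p_sig <- mean(emg$values^2)
  p_noise <- mean((noisy$values - emg$values)^2)
  measured <- 10 * log10(p_sig / p_noise)
  expect_equal(measured, 10, tolerance = 0.1)
  expect_identical(add_noise(emg, 10, seed = 2)$values, noisy$values)
  zero <- emg; zero$values[] <- 0
  expect_error(add_noise(zero, 10), "zero-power")
})

test_that("channel selection maps coordinates to nearest electrodes", {
  emg <- synthesize(fake_spikes(list(0.1)), list(static_sequence(tpl_a, 1)),
                    2048, 1)
  all_coords <- emg$channel_map[, c("row", "col")]
  ident <- select_channels(emg, all_coords)
  expect_equal(ident$values, emg$values)
  six <- select_channels(emg, data.frame(row = c(5, 5, 5, 6, 6, 6),
                                         col = c(1, 8, 16, 24, 32, 8)))
  expect_identical(nrow(six$values), 6L)
  expect_equal(six$values[2, ], emg$values[(5 - 1) * 32 + 8, ])
  # duplicates are duplicated; fractional coordinates snap; wrap circularly
  dup <- select_channels(emg, data.frame(row = c(5, 5), col = c(8, 8)))
  expect_equal(dup$values[1, ], dup$values[2, ])
  wrap <- select_channels(emg, data.frame(row = 5.4, col = 33))
  expect_equal(wrap$values[1, ], emg$values[(5 - 1) * 32 + 1, ])
  expect_error(select_channels(emg, data.frame(row = 40, col = 1)),
               "outside")
})

test_that("EMG text serialization round-trips small excerpts", {
  st <- fake_spikes(list(c(0.01, 0.02)))
  emg <- synthesize(st, list(static_sequence(tpl_a, 0.1)), 2048, 0.1)
  emg6 <- select_channels(emg, data.frame(row = rep(5, 3), col = c(1, 5, 9)))
  path <- scratch_file("emg.tsv")
  write_emg_text(emg6, path)
  back <- read_emg_text(path)
  expect_equal(back$values, emg6$values, tolerance = 1e-8)
  expect_equal(back$fs, emg6$fs)
})
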