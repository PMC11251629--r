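#' Generate paired (joint-angle, EMG) trials
#'
#' End-to-end synthetic trials of the two-DoF wrist / finger
#' (metacarpophalangeal, MCP) flexion-extension protocols: the movement is
#' defined by pose interpolation and sampled at 40 Hz, muscle activations
#' are estimated by static optimization and used as the neural drive to the
#' per-muscle motor unit pools (identity mapping), fibre-length changes are
#' tracked into conduction-velocity and depth trajectories, every unit's
#' MUAP sequence is morphed along the movement with a fixed latent, and the
#' surface EMG is synthesised at 2000 Hz, noise added, and six channels
#' selected at the electrode-grid positions nearest the instrumented
#' muscles.
#'
#' Motor-unit pools and MUAP sequences represent the (synthetic) subject and
#' are shared across trials of one call; trials differ by their drive jitter
#' (a slow multiplicative modulation of the common drive), their spike-train
#' realisations and their additive noise. The `"real_like"` regime emulates
#' an independently recorded counterpart of the same protocol: stronger
#' drive jitter, lower SNR, and a one-column electrode misplacement.
#'
#' @param protocol `"wrist_mcp_fe"` (both DoF groups move, default),
#'   `"wrist_fe"`, or `"mcp_fe"`.
#' @param n_trials number of trials.
#' @param seed integer root seed (also fixes the synthetic subject).
#' @param regime `"synthetic"` or `"real_like"`.
#' @param config configuration list.
#' @return list of trials; each is a list with `trial_id`, `time`
#'   (40 Hz angle grid), `wrist`, `mcp` (degrees), `emg` (six-channel
#'   `emg_recording` at 2000 Hz), `duration`, `protocol`, `regime`.
#' @export
generate_trials <- function(protocol = c("wrist_mcp_fe", "wrist_fe",
                                         "mcp_fe"),
                            n_trials = 1, seed = 1L,
                            regime = c("synthetic", "real_like"),
                            config = default_config()) {
  protocol <- match.arg(protocol)
  regime <- match.arg(regime)
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  ag <- config$augment
  poses <- switch(protocol,
    wrist_fe = c("default", "flex", "default", "ext",
                 "default", "flex", "default", "ext", "default"),
    mcp_fe = c("default", "grasp", "default", "open",
               "default", "grasp", "default", "open", "default"),
    wrist_mcp_fe = c("default", "flex", "default", "ext",
                     "default", "grasp", "default", "open", "default")
  )
  durations <- rep(ag$duration / (length(poses) - 1), length(poses) - 1)
  traj <- define_movement(poses, durations, ag$fs_motion, config)
  mcp_dofs <- paste0("mcp", 2:5, "_flexion")
  wrist <- traj$angles[, "wrist_flexion"]
  mcp <- rowMeans(traj$angles[, mcp_dofs, drop = FALSE])

  muscles <- muscle_set(config)
  act <- static_optimization_activations(muscles, traj, config = config)
  t_emg <- seq(0, ag$duration, by = 1 / ag$fs_emg)
  drive0 <- apply(act$activations, 2, function(a)
    stats::approx(traj$time, a, xout = t_emg, rule = 2)$y)
  drive0 <- pmin(pmax(drive0, 0), 1)

  # subject identity: pools + morphed MUAP sequences, shared across trials
  pools <- lapply(muscles, function(m)
    init_pool(m, "classical", config, seed = child_seed(seed, "pool", m$name)))
  muaps <- lapply(names(muscles), function(mn) {
    pool <- pools[[mn]]
    lt <- fibre_length(muscles[[mn]], traj, config)
    pt <- len2params(lt$fibre_length_norm, lt$fibre_length_norm[1],
                     time = traj$time, config = config)
    lapply(seq_len(nrow(pool$units)), function(k) {
      lat <- sample_latent(paste(mn, k), seed, config$muap$latent_dim)
      morph_sequence(unit_condition(pool, k, config), pt,
                     n_keyframes = ag$n_keyframes, latent = lat,
                     fs_muap = ag$fs_emg, T = ag$T, config = config,
                     unit_id = paste(mn, k))
    })
  })
  names(muaps) <- names(muscles)

  jit <- if (regime == "real_like") ag$real_like$drive_jitter else
    ag$drive_jitter
  snr <- if (regime == "real_like") ag$real_like$snr_db else ag$snr_db
  sel_coords <- channel_coordinates(ag$channels, config)

  trials <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    tseed <- child_seed(seed, regime, "trial", tr)
    total <- NULL
    for (mn in names(muscles)) {
      dmod <- with_seed(child_seed(tseed, mn, "jitter"), {
        f <- stats::runif(1, 0.1, 0.4)
        ph <- stats::runif(1, 0, 2 * pi)
        1 + jit * sin(2 * pi * f * t_emg + ph)
      })
      drv <- pmin(pmax(drive0[, mn] * dmod, 0), 1)
      if (all(drv == 0)) next
      spikes <- fuglevand_spikes(pools[[mn]], drv, ag$fs_emg,
                                 seed = child_seed(tseed, mn, "spikes"))
      rec <- synthesize(spikes, muaps[[mn]], ag$fs_emg, ag$duration)
      total <- if (is.null(total)) rec else {
        total$values <- total$values + rec$values
        total
      }
    }
    total$provenance <- list(seed = seed, trial = tr, regime = regime,
                             protocol = protocol)
    if (mean(total$values^2) > 0) total <- add_noise(total, snr, tseed)
    coords <- sel_coords
    if (regime == "real_like") {
      shift <- with_seed(child_seed(tseed, "shift"),
                         sample(c(-1, 1), nrow(coords), replace = TRUE)) *
        ag$real_like$channel_shift
      coords$col <- coords$col + shift
    }
    emg6 <- select_channels(total, coords)
    trials[[tr]] <- list(trial_id = tr, time = traj$time, wrist = wrist,
                         mcp = mcp, emg = emg6, duration = ag$duration,
                         protocol = protocol, regime = regime)
  }
  trials
}

# grid coordinates of the electrode nearest each named muscle's territory
channel_coordinates <- function(muscle_names, config = default_config()) {
  mc <- config$muap
  do.call(rbind, lapply(muscle_names, function(mn) {
    m <- get_muscle(mn, config)
    data.frame(muscle = mn, row = round((mc$n_rows + 1) / 2),
               col = round(m$ml_angle / 360 * mc$n_cols) + 1L)
  }))
}

#' RMS features and angle labels of a trial
#'
#' @param trial one element of [generate_trials()].
#' @param config configuration list.
#' @return list with `X` (windows x channels RMS matrix) and `Y`
#'   (windows x 2 matrix of wrist and MCP labels, mean angle per window).
#' @export
trial_features <- function(trial, config = default_config()) {
  ag <- config$augment
  feats <- rms_features(trial$emg, ag$rms_window, ag$rms_overlap)
  Y <- cbind(wrist = window_labels(feats, trial$time, trial$wrist),
             mcp = window_labels(feats, trial$time, trial$mcp))
  list(X = feats$values, Y = Y)
}

#' Ridge regression of joint angles on RMS features
#'
#' Closed-form ridge fit with standardised features, unpenalised intercept,
#' and one coefficient vector per target column.
#'
#' @param X feature matrix (windows x channels).
#' @param Y target matrix (windows x targets) or vector.
#' @param lambda ridge penalty.
#' @return an object of class `ridge_model`.
#' @export
train_ridge <- function(X, Y, lambda = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) < 2) stop("need at least two windows", call. = FALSE)
  xc <- colMeans(X)
  xs <- apply(X, 2, stats::sd)
  xs[xs == 0] <- 1
  Xs <- scale(X, xc, xs)
  yc <- colMeans(Y)
  Yc <- sweep(Y, 2, yc)
  p <- ncol(Xs)
  beta <- solve(crossprod(Xs) + lambda * diag(p), crossprod(Xs, Yc))
  structure(list(beta = beta, x_center = xc, x_scale = xs, y_center = yc,
                 lambda = lambda),
            class = "ridge_model")
}

#' @rdname train_ridge
#' @param model a `ridge_model`.
#' @export
predict_ridge <- function(model, X) {
  Xs <- scale(as.matrix(X), model$x_center, model$x_scale)
  sweep(Xs %*% model$beta, 2, model$y_center, "+")
}

# Pearson correlation with a defined-variance guard
pcc <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Evaluate a trained regressor on a trial
#'
#' Predicts the wrist and MCP angles of a trial from its RMS features and
#' reports the Pearson correlation coefficient (PCC) per target, together
#' with a shuffled-label null: the PCC between the predictions and randomly
#' permuted ground-truth labels, repeated `null_repeats` times. A one-sample
#' t-test compares the null draws against the observed PCC. Constant
#' predictions yield `NA` PCC with `degenerate = TRUE`.
#'
#' @param model a `ridge_model`.
#' @param trial a trial from [generate_trials()].
#' @param null_repeats number of label shuffles.
#' @param seed seed for the shuffles.
#' @param config configuration list.
#' @return list with `pcc` (named vector), `null_pccs`
#'   (`null_repeats` x 2), `p_value`, `predictions`, `truth`, `degenerate`.
#' @export
evaluate_regressor <- function(model, trial, null_repeats = 10, seed = 1L,
                               config = default_config()) {
  fe <- trial_features(trial, config)
  pred <- predict_ridge(model, fe$X)
  obs <- c(wrist = pcc(pred[, 1], fe$Y[, 1]),
           mcp = pcc(pred[, 2], fe$Y[, 2]))
  nulls <- with_seed(child_seed(seed, "null-shuffle", trial$trial_id), {
    t(vapply(seq_len(null_repeats), function(r) {
      idx <- sample(nrow(fe$Y))
      c(pcc(pred[, 1], fe$Y[idx, 1]), pcc(pred[, 2], fe$Y[idx, 2]))
    }, numeric(2)))
  })
  colnames(nulls) <- c("wrist", "mcp")
  pv <- vapply(1:2, function(k) {
    if (is.na(obs[k]) || stats::sd(nulls[, k]) == 0) return(NA_real_)
    stats::t.test(nulls[, k], mu = obs[k])$p.value
  }, 0)
  list(pcc = obs, null_pccs = nulls,
       p_value = stats::setNames(pv, c("wrist", "mcp")),
       predictions = pred, truth = fe$Y, degenerate = any(is.na(obs)))
}

#' Select the ridge penalty by leave-one-trial-out validation
#'
#' @param trials list of trials (>= 2).
#' @param grid candidate penalties.
#' @param config configuration list.
#' @return the penalty with the lowest held-out mean squared error.
#' @export
select_lambda <- function(trials, grid = 10^seq(-3, 2, by = 1),
                          config = default_config()) {
  stopifnot(length(trials) >= 2)
  fes <- lapply(trials, trial_features, config = config)
  err <- vapply(grid, function(lam) {
    mean(vapply(seq_along(fes), function(i) {
      Xtr <- do.call(rbind, lapply(fes[-i], `[[`, "X"))
      Ytr <- do.call(rbind, lapply(fes[-i], `[[`, "Y"))
      m <- train_ridge(Xtr, Ytr, lam)
      mean((predict_ridge(m, fes[[i]]$X) - fes[[i]]$Y)^2)
    }, 0))
  }, 0)
  grid[which.min(err)]
}

#' Data-augmentation experiment
#'
#' Repeatedly draws two "real-like" trials plus two synthetic trials as an
#' augmented training set, trains ridge regressors on the augmented set and
#' on the two real-like trials alone, and evaluates both on one held-out
#' real-like trial. Reports the per-repeat PCCs and their paired
#' comparison (paired and unpaired t-tests, per the ambiguity in how such
#' comparisons are paired across trials).
#'
#' @param real_like_trials list of >= 3 trials standing in for experimental
#'   recordings.
#' @param synthetic_trials list of >= 2 synthetic trials.
#' @param seed integer seed for the random selections.
#' @param n_repeats number of random train/test selections.
#' @param lambda ridge penalty; `NULL` selects it by leave-one-trial-out on
#'   the training trials of each repeat.
#' @param config configuration list.
#' @return list with `per_repeat` (data frame of augmented/baseline PCCs per
#'   target) and `summary` (mean difference, paired and unpaired p-values).
#' @export
augmentation_experiment <- function(real_like_trials, synthetic_trials,
                                    seed = 1L, n_repeats = 10,
                                    lambda = 1, config = default_config()) {
  if (length(real_like_trials) < 3) {
    stop("need at least 3 real-like trials", call. = FALSE)
  }
  if (length(synthetic_trials) < 2) {
    stop("need at least 2 synthetic trials", call. = FALSE)
  }
  fes_real <- lapply(real_like_trials, trial_features, config = config)
  fes_syn <- lapply(synthetic_trials, trial_features, config = config)
  rows <- with_seed(child_seed(seed, "augmentation"), {
    lapply(seq_len(n_repeats), function(r) {
      tr_real <- sample(length(fes_real), 2)
      test_i <- sample(setdiff(seq_along(fes_real), tr_real), 1)
      tr_syn <- sample(length(fes_syn), 2)
      Xr <- do.call(rbind, lapply(fes_real[tr_real], `[[`, "X"))
      Yr <- do.call(rbind, lapply(fes_real[tr_real], `[[`, "Y"))
      Xa <- rbind(Xr, do.call(rbind, lapply(fes_syn[tr_syn], `[[`, "X")))
      Ya <- rbind(Yr, do.call(rbind, lapply(fes_syn[tr_syn], `[[`, "Y")))
      lam <- if (is.null(lambda))
        select_lambda(real_like_trials[tr_real], config = config) else lambda
      mb <- train_ridge(Xr, Yr, lam)
      ma <- train_ridge(Xa, Ya, lam)
      fe_test <- fes_real[[test_i]]
      pb <- predict_ridge(mb, fe_test$X)
      pa <- predict_ridge(ma, fe_test$X)
      data.frame(repeat_i = r, test_trial = test_i,
                 aug_wrist = pcc(pa[, 1], fe_test$Y[, 1]),
                 aug_mcp = pcc(pa[, 2], fe_test$Y[, 2]),
                 base_wrist = pcc(pb[, 1], fe_test$Y[, 1]),
                 base_mcp = pcc(pb[, 2], fe_test$Y[, 2]))
    })
  })
  per_repeat <- do.call(rbind, rows)
  cmp <- function(a, b) {
    list(mean_diff = mean(a - b),
         p_paired = tryCatch(stats::t.test(a, b, paired = TRUE)$p.value,
                             error = function(e) NA_real_),
         p_unpaired = tryCatch(stats::t.test(a, b)$p.value,
                               error = function(e) NA_real_))
  }
  list(per_repeat = per_repeat,
       summary = list(wrist = cmp(per_repeat$aug_wrist,
                                  per_repeat$base_wrist),
                      mcp = cmp(per_repeat$aug_mcp, per_repeat$base_mcp)))
}
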