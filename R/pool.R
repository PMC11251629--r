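#' Twitch-force distribution across a motor unit pool
#'
#' Relative peak twitch forces of the `N` units, indexed by rank `j` (small
#' to large). Two laws are provided:
#'
#' * `"classical"`: the exponential distribution of the classical
#'   recruitment model, `ftw(j) = exp(ln(RP) * j / N)` with range-of-twitch
#'   parameter `RP` (default 100) — many weak units, few strong ones.
#' * `"lif"`: the linear-exponential law fitted to human forearm data used
#'   by the LIF cohort,
#'   `ftw(j) = 0.81 * (18.51 * (j/N) + 104.10 * (j/N)^4.83)`.
#'
#' Both are strictly increasing in rank. The units of the LIF law are
#' relative; its leading constant cancels in the fibre-count normalisation
#' of [allocate_sizes()] but is retained for fidelity to the published fit.
#'
#' @param model_kind `"classical"` or `"lif"`.
#' @param N number of motor units (>= 1).
#' @param RP twitch-force range for the classical law.
#' @return numeric vector of length `N`, strictly increasing.
#' @export
twitch_distribution <- function(model_kind = c("classical", "lif"), N,
                                RP = 100) {
  model_kind <- match.arg(model_kind)
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  j <- seq_len(N)
  switch(model_kind,
    classical = exp(log(RP) * j / N),
    lif = 0.81 * (18.51 * (j / N) + 104.10 * (j / N)^4.83)
  )
}

#' Allocate integer fibre counts to motor units
#'
#' Distributes the muscle's total fibre count over the units in proportion
#' to their twitch forces, `size_j = ftw(j) / sum(ftw) * N_f`, rounded by the
#' largest-remainder method so the sizes sum to `N_f` exactly. Every unit
#' receives at least one fibre (fibres are moved from the largest unit if a
#' quota rounds to zero).
#'
#' @param twitch_amp positive twitch amplitudes per unit.
#' @param N_f total fibre count, at least `length(twitch_amp)`.
#' @return integer vector of sizes summing exactly to `N_f`.
#' @export
allocate_sizes <- function(twitch_amp, N_f) {
  N <- length(twitch_amp)
  if (N_f < N) stop("N_f must be >= number of units", call. = FALSE)
  quota <- twitch_amp / sum(twitch_amp) * N_f
  sizes <- floor(quota)
  rem <- N_f - sum(sizes)
  if (rem > 0) {
    frac <- quota - sizes
    ord <- order(-frac, seq_len(N)) # ties broken toward lower rank
    sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1
  }
  while (any(sizes == 0)) {
    donor <- which.max(sizes)
    take <- which(sizes == 0)[1]
    sizes[donor] <- sizes[donor] - 1L
    sizes[take] <- 1L
  }
  as.integer(sizes)
}

#' Initialise a motor unit pool
#'
#' Draws the per-unit electrophysiological and geometric properties of one
#' muscle's motoneuron pool:
#'
#' * sizes from [twitch_distribution()] + [allocate_sizes()] so the sizes
#'   sum exactly to the muscle's fibre count;
#' * conduction velocity: classical model draws Normal(cv_mean, cv_sd) and
#'   sorts ascending so velocity pairs with ascending size; the LIF cohort
#'   maps normalised size through an increasing affine map onto
#'   `[cv_min, cv_max]`;
#' * depth and medial-lateral position uniform over the muscle's territory
#'   disk (cross-section);
#' * innervation-zone position and fibre length Normal, truncated to the
#'   configured ranges;
#' * recruitment thresholds exponentially spaced,
#'   `theta_j = exp(ln(RR) * j / N) / RR`, so the last unit recruits at
#'   normalised drive 1;
#' * peak firing rates linearly interpolated from `PFR_first` down to
#'   `PFR_last` with rank (onion-skin ordering);
#' * LIF membrane parameters affine in rank between configured endpoints.
#'
#' All draws come from per-unit child streams of the root seed
#' ([child_seed()]), so the pool is bit-reproducible and adding a unit never
#' perturbs the properties of the others.
#'
#' @param muscle a muscle model (see [get_muscle()]).
#' @param model_kind `"classical"` or `"lif"`.
#' @param config configuration list.
#' @param seed integer root seed.
#' @return an object of class `motor_unit_pool` with a `units` data frame
#'   (one row per unit, ranked) and pool-level parameters.
#' @export
init_pool <- function(muscle, model_kind = c("classical", "lif"),
                      config = default_config(), seed = 1L) {
  model_kind <- match.arg(model_kind)
  pp <- config$pool
  N <- muscle$n_units
  tw <- twitch_distribution(model_kind, N, RP = pp$RP)
  sizes <- allocate_sizes(tw, muscle$total_fibres)

  if (model_kind == "classical") {
    cv <- with_seed(child_seed(seed, muscle$name, "cv"),
                    stats::rnorm(N, pp$cv_mean, pp$cv_sd))
    cv <- sort(cv)
  } else {
    s <- (sizes - min(sizes)) / max(1e-12, diff(range(sizes)))
    cv <- pp$cv_min + s * (pp$cv_max - pp$cv_min)
  }
  cv <- cummax(cv) # guard: non-decreasing with rank

  trunc_norm <- function(n, mean, sd, lo, hi, sd_stream) {
    x <- with_seed(sd_stream, stats::rnorm(n, mean, sd))
    pmin(pmax(x, lo), hi)
  }
  pos <- with_seed(child_seed(seed, muscle$name, "pos"), {
    r <- muscle$territory_radius * sqrt(stats::runif(N))
    th <- stats::runif(N, 0, 2 * pi)
    cbind(depth_off = r * sin(th), ml_off = r * cos(th))
  })
  iz <- trunc_norm(N, pp$iz_mean, pp$iz_sd, pp$iz_range[1], pp$iz_range[2],
                   child_seed(seed, muscle$name, "iz"))
  flen <- trunc_norm(N, muscle$fibre_length_mm, pp$fibre_length_sd,
                     muscle$fibre_length_mm - pp$fibre_length_halfwidth,
                     muscle$fibre_length_mm + pp$fibre_length_halfwidth,
                     child_seed(seed, muscle$name, "flen"))

  j <- seq_len(N)
  thr <- exp(log(pp$RR) * j / N) / pp$RR
  pfr <- if (N == 1) pp$PFR_first else
    pp$PFR_first + (pp$PFR_last - pp$PFR_first) * (j - 1) / (N - 1)

  lp <- config$lif
  aff <- function(a, b) if (N == 1) a else a + (b - a) * (j - 1) / (N - 1)
  units <- data.frame(
    rank = j, size = sizes, twitch_amp = tw,
    recruitment_threshold = thr, pfr = pfr,
    cv = cv,
    depth = muscle$territory_centre_depth + pos[, "depth_off"],
    ml_pos = pos[, "ml_off"],
    iz_pos = iz, fibre_length = flen,
    latent_seed = vapply(j, function(k)
      child_seed(seed, muscle$name, "latent", k), 1L),
    lif_R = aff(lp$R_first, lp$R_last),
    lif_tau = aff(lp$tau_first, lp$tau_last),
    lif_v_th = rep(lp$v_th, N),
    lif_t_ref = aff(lp$t_ref_first, lp$t_ref_last)
  )
  structure(list(muscle = muscle$name, model_kind = model_kind,
                 units = units, RR = pp$RR, MFR = pp$MFR, gain = pp$gain,
                 isi_cv = pp$isi_cv, seed = seed),
            class = "motor_unit_pool")
}

#' @export
print.motor_unit_pool <- function(x, ...) {
  cat(sprintf("motor_unit_pool: %s, %s model, %d units, %d fibres\n",
              x$muscle, x$model_kind, nrow(x$units), sum(x$units$size)))
  invisible(x)
}
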