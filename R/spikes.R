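#' Built-in neural drive profiles
#'
#' Common normalised drive (excitation) profiles in `[0, 1]`: constant,
#' trapezoid (linear ramp up, plateau, ramp down), triangle, and sinusoid
#' (raised so it stays non-negative).
#'
#' @param kind profile type.
#' @param amplitude peak drive in `[0, 1]`.
#' @param duration total duration (s).
#' @param fs sampling rate (Hz).
#' @param ramp ramp duration for the trapezoid (s).
#' @param freq sinusoid frequency (Hz).
#' @return list with `time`, `values`, `fs`.
#' @export
drive_profile <- function(kind = c("constant", "trapezoid", "triangle",
                                   "sinusoid"),
                          amplitude = 0.5, duration = 5, fs = 2048,
                          ramp = duration / 4, freq = 0.5) {
  kind <- match.arg(kind)
  stopifnot(amplitude >= 0, amplitude <= 1, duration > 0, fs > 0)
  time <- seq(0, duration, by = 1 / fs)
  v <- switch(kind,
    constant = rep(amplitude, length(time)),
    trapezoid = amplitude * pmin(1, pmin(time, duration - time) / ramp),
    triangle = amplitude * (1 - abs(2 * time / duration - 1)),
    sinusoid = amplitude / 2 * (1 - cos(2 * pi * freq * time))
  )
  list(time = time, values = pmin(pmax(v, 0), 1), fs = fs)
}

new_spike_train_set <- function(trains, fs, drive, pool) {
  structure(list(fs = fs, trains = trains, drive = drive,
                 muscle = pool$muscle, model_kind = pool$model_kind),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  ns <- vapply(x$trains, length, 0L)
  cat(sprintf("spike_train_set: %s (%s), %d units, %d spikes, %d active\n",
              x$muscle, x$model_kind, length(ns), sum(ns), sum(ns > 0)))
  invisible(x)
}

#' Spike trains from the classical recruitment / rate-coding model
#'
#' Transforms a normalised drive series into per-unit spike trains. A unit
#' fires only while the drive is at or above its recruitment threshold; its
#' instantaneous rate is `MFR + gain * (E_units - theta_units)` clipped to
#' `[MFR, PFR_j]`, where excitation and thresholds are expressed in the
#' model's excitation units (normalised drive times the recruitment range
#' `RR`, so the last unit recruits at drive 1). Spikes are generated by
#' accumulating inter-spike intervals; each interval is the reciprocal rate
#' at emission time times `1 + isi_cv * z` with `z` standard Normal
#' truncated at +/- 3.9 so intervals stay positive. When the drive falls
#' below a unit's threshold the unit falls silent and re-recruits at the
#' next threshold crossing.
#'
#' @param pool a [init_pool()] result.
#' @param drive numeric series in `[0, 1]` or a [drive_profile()] list.
#' @param fs sampling rate of the drive (Hz), >= 1000.
#' @param seed integer root seed for the inter-spike-interval jitter.
#' @param isi_cv coefficient of variation of the intervals; defaults to the
#'   pool's configured value; 0 gives perfectly regular firing.
#' @return a `spike_train_set`.
#' @export
fuglevand_spikes <- function(pool, drive, fs = 2048, seed = 1L,
                             isi_cv = pool$isi_cv) {
  if (is.list(drive)) { fs <- drive$fs; drive <- drive$values }
  if (any(drive < 0 | drive > 1)) stop("drive must lie in [0,1]", call. = FALSE)
  if (fs < 1000) stop("fs must be >= 1000 Hz", call. = FALSE)
  n <- length(drive)
  duration <- (n - 1) / fs
  u <- pool$units
  eu <- drive * pool$RR # excitation units
  trains <- vector("list", nrow(u))
  for (k in seq_len(nrow(u))) {
    thr_u <- u$recruitment_threshold[k] * pool$RR
    rate <- pmin(pmax(pool$MFR + pool$gain * (eu - thr_u), pool$MFR),
                 u$pfr[k])
    rate[eu < thr_u - 1e-12] <- 0
    spikes <- numeric(0)
    rs <- child_seed(seed, pool$muscle, "isi", k)
    spikes <- with_seed(rs, {
      out <- numeric(0)
      idx <- which(rate > 0)
      if (length(idx)) {
        t <- (idx[1] - 1) / fs
        while (t <= duration) {
          i <- min(n, round(t * fs) + 1)
          if (rate[i] <= 0) {
            nxt <- idx[idx > i]
            if (!length(nxt)) break
            t <- (nxt[1] - 1) / fs
            next
          }
          out <- c(out, t)
          z <- if (isi_cv > 0) max(-3.9, min(3.9, stats::rnorm(1))) else 0
          t <- t + (1 / rate[i]) * (1 + isi_cv * z)
        }
      }
      out
    })
    trains[[k]] <- spikes
  }
  new_spike_train_set(trains, fs, drive, pool)
}

#' Spike trains from the leaky integrate-and-fire cohort
#'
#' Integrates one LIF membrane per motor unit with forward Euler:
#' `dV/dt = (R * I(t) - V) / tau`, with `I(t) = drive(t) * I_max_j` and
#' `I_max_j = v_th / (R_j * theta_j)` so that unit `j` reaches threshold in
#' steady state exactly when the drive exceeds its recruitment threshold
#' `theta_j` (sequential recruitment by rank). A spike is emitted when `V`
#' reaches `v_th`; the voltage is reset to zero and held there for the
#' absolute refractory period `t_ref`. Membrane time constants and
#' refractory periods increase along the rank axis, which yields
#' onion-skin-ordered firing rates. For a constant suprathreshold input the
#' inter-spike interval has the closed form
#' `t_ref + tau * log(RI / (RI - v_th))`.
#'
#' @param pool a [init_pool()] result (LIF parameters are carried by every
#'   pool).
#' @param drive numeric series in `[0, 1]` or a [drive_profile()] list.
#' @param fs integration rate (Hz); 10 kHz or more is recommended for
#'   accuracy, lower rates trigger a warning.
#' @param seed unused (integration is deterministic); kept for interface
#'   symmetry with [fuglevand_spikes()].
#' @return a `spike_train_set`.
#' @export
lif_spikes <- function(pool, drive, fs = 10000, seed = 1L) {
  if (is.list(drive)) { fs <- drive$fs; drive <- drive$values }
  if (any(drive < 0 | drive > 1)) stop("drive must lie in [0,1]", call. = FALSE)
  if (fs < 10000) warning("fs below 10 kHz: LIF integration accuracy degrades")
  u <- pool$units
  N <- nrow(u)
  n <- length(drive)
  dt <- 1 / fs
  tau <- u$lif_tau / 1000
  t_ref <- u$lif_t_ref / 1000
  v_th <- u$lif_v_th
  # R * I_max = v_th / theta_j; R itself cancels in the voltage dynamics
  ri_max <- v_th / u$recruitment_threshold
  V <- numeric(N)
  ref_until <- rep(-1, N)
  trains <- vector("list", N)
  for (k in seq_len(N)) trains[[k]] <- numeric(0)
  spike_buf <- vector("list", N)
  for (k in seq_len(N)) spike_buf[[k]] <- numeric(0)
  tvec <- (seq_len(n) - 1) * dt
  for (i in seq_len(n)) {
    t <- tvec[i]
    active <- t >= ref_until
    ri <- ri_max * drive[i]
    V[active] <- V[active] + dt * (ri[active] - V[active]) / tau[active]
    V[!active] <- 0
    fired <- which(active & V >= v_th)
    for (k in fired) {
      spike_buf[[k]] <- c(spike_buf[[k]], t)
      V[k] <- 0
      ref_until[k] <- t + t_ref[k]
    }
  }
  new_spike_train_set(spike_buf, fs, drive, pool)
}

#' Write / read spike trains as delimited text
#'
#' Two tab-separated columns (`unit_rank`, `spike_time_s`) plus a JSON
#' sidecar `<path>.json` with the pool metadata (muscle, model kind,
#' sampling rate, unit count).
#'
#' @param spikes a `spike_train_set`.
#' @param path output file.
#' @return `write_spike_trains` returns `path` invisibly;
#'   `read_spike_trains` returns a `spike_train_set` (without the drive).
#' @export
write_spike_trains <- function(spikes, path) {
  df <- do.call(rbind, lapply(seq_along(spikes$trains), function(k) {
    if (!length(spikes$trains[[k]])) return(NULL)
    data.frame(unit_rank = k, spike_time_s = spikes$trains[[k]])
  }))
  if (is.null(df)) df <- data.frame(unit_rank = integer(),
                                    spike_time_s = numeric())
  utils::write.table(format(df, digits = 15, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(muscle = spikes$muscle,
                            model_kind = spikes$model_kind,
                            fs = spikes$fs,
                            n_units = length(spikes$trains)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  trains <- lapply(seq_len(meta$n_units), function(k)
    sort(df$spike_time_s[df$unit_rank == k]))
  structure(list(fs = meta$fs, trains = trains, drive = NULL,
                 muscle = meta$muscle, model_kind = meta$model_kind),
            class = "spike_train_set")
}
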