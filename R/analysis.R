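#' Crop a MUAP to its high-amplitude subgrid
#'
#' Computes the per-channel maximum absolute amplitude, thresholds at 75% of
#' the mean of these maxima, and returns the minimal contiguous rectangular
#' subgrid (bounding box in rows and columns) containing every channel above
#' threshold. Degenerate templates with no channel above threshold return
#' the single peak channel, flagged via the `degenerate` attribute. The
#' operation is idempotent.
#'
#' @param muap a `muap_template`.
#' @return a `muap_template` whose `grid` is the cropped subgrid; attributes
#'   `rows` and `cols` record the retained indices.
#' @export
crop_muap <- function(muap) {
  if (all(muap$grid == 0)) {
    stop("cannot crop an all-zero template", call. = FALSE)
  }
  out <- muap
  degenerate <- FALSE
  # iterate the bounding-box rule to its fixpoint so the crop is idempotent:
  # re-cropping a cropped template leaves it unchanged
  repeat {
    g <- out$grid
    chan_max <- apply(abs(g), c(1, 2), max)
    thr <- 0.75 * mean(chan_max)
    keep <- chan_max >= thr
    if (!any(keep)) {
      degenerate <- TRUE
      pk <- which(chan_max == max(chan_max), arr.ind = TRUE)[1, ]
      rows <- pk[1]; cols <- pk[2]
    } else {
      rows <- range(which(apply(keep, 1, any)))
      cols <- range(which(apply(keep, 2, any)))
      rows <- rows[1]:rows[2]; cols <- cols[1]:cols[2]
    }
    prev_rows <- attr(out, "rows") %||% seq_len(dim(g)[1])
    prev_cols <- attr(out, "cols") %||% seq_len(dim(g)[2])
    done <- length(rows) == dim(g)[1] && length(cols) == dim(g)[2]
    out$grid <- g[rows, cols, , drop = FALSE]
    attr(out, "rows") <- prev_rows[rows]
    attr(out, "cols") <- prev_cols[cols]
    attr(out, "degenerate") <- degenerate
    if (done || degenerate) break
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalised mean square error between two MUAPs
#'
#' `nmse(a, b)` is the mean over all (channel, sample) of `(a - b)^2`
#' divided by the average of the two mean-square powers,
#' `(P_a + P_b) / 2`. Zero iff the inputs are identical on the compared
#' support; `nmse(a, -a) = 4` and `nmse(a, 0) = 2` analytically; invariant
#' to common rescaling. Inputs must share a common support (same shape);
#' use [pair_nmse()] to compare two templates with individual crops.
#'
#' @param a,b `muap_template`s or numeric arrays of identical shape.
#' @return non-negative scalar.
#' @export
nmse <- function(a, b) {
  ga <- if (inherits(a, "muap_template")) a$grid else a
  gb <- if (inherits(b, "muap_template")) b$grid else b
  stopifnot(all(dim(ga) == dim(gb)))
  pa <- mean(ga^2); pb <- mean(gb^2)
  if (pa == 0 && pb == 0) stop("both templates are all-zero", call. = FALSE)
  mean((ga - gb)^2) / ((pa + pb) / 2)
}

#' NMSE between two templates after amplitude-based cropping
#'
#' Each template is cropped with [crop_muap()]; both are then re-cropped to
#' the union bounding box of the two individual crops (the common support)
#' and compared with [nmse()].
#'
#' @param a,b full-grid `muap_template`s of identical shape.
#' @return non-negative scalar.
#' @export
pair_nmse <- function(a, b) {
  ca <- crop_muap(a); cb <- crop_muap(b)
  rows <- range(c(attr(ca, "rows"), attr(cb, "rows")))
  cols <- range(c(attr(ca, "cols"), attr(cb, "cols")))
  rows <- rows[1]:rows[2]; cols <- cols[1]:cols[2]
  nmse(a$grid[rows, cols, , drop = FALSE],
       b$grid[rows, cols, , drop = FALSE])
}

#' Pairwise MUAP similarity matrix
#'
#' All pairwise NMSE values between a set of templates, with the boolean
#' similarity map at the NMSE = 0.2 threshold (TRUE where NMSE < 0.2, i.e.
#' similar) and optional muscle grouping labels.
#'
#' @param muaps list of full-grid `muap_template`s (>= 2).
#' @param labels optional character vector of group (muscle) labels.
#' @param threshold similarity threshold on NMSE.
#' @return an object of class `similarity_matrix`: list with `values`
#'   (symmetric matrix, zero diagonal), `threshold_map`, `labels`.
#' @export
similarity_matrix <- function(muaps, labels = NULL, threshold = 0.2) {
  n <- length(muaps)
  stopifnot(n >= 2)
  v <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v[i, j] <- v[j, i] <- pair_nmse(muaps[[i]], muaps[[j]])
    }
  }
  if (!is.null(labels)) dimnames(v) <- list(labels, labels)
  structure(list(values = v, threshold_map = v < threshold,
                 threshold = threshold, labels = labels),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("similarity_matrix: %d templates, NMSE median %.3g, %d%% pairs below %.2g\n",
              nrow(x$values), stats::median(off),
              round(100 * mean(off < x$threshold)), x$threshold))
  invisible(x)
}

#' Export a similarity matrix as delimited text
#'
#' @param sim a `similarity_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(sim, path) {
  utils::write.table(format(as.data.frame(sim$values), digits = 10,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = !is.null(sim$labels))
  invisible(path)
}

#' Dissimilarity of morphed MUAPs from a baseline keyframe
#'
#' NMSE between each keyframe template of a morphed sequence and a baseline
#' keyframe (by default the one at zero joint excursion). All templates are
#' compared on the union of their individual crops so every keyframe uses
#' the same support; the curve is zero at the baseline and grows as the
#' templates morph away from it.
#'
#' @param seq a `muap_sequence`.
#' @param baseline_index index of the baseline keyframe.
#' @param angles optional normalised joint angles per keyframe (e.g. in
#'   `[-1, 1]`), carried into the result.
#' @return data frame with columns `keyframe`, `time`, `angle` (if given),
#'   `nmse`.
#' @export
angle_similarity_curve <- function(seq, baseline_index = 1, angles = NULL) {
  n <- length(seq$templates)
  stopifnot(baseline_index >= 1, baseline_index <= n)
  crops <- lapply(seq$templates, crop_muap)
  rows <- range(unlist(lapply(crops, attr, "rows")))
  cols <- range(unlist(lapply(crops, attr, "cols")))
  rows <- rows[1]:rows[2]; cols <- cols[1]:cols[2]
  base <- seq$templates[[baseline_index]]$grid[rows, cols, , drop = FALSE]
  vals <- vapply(seq$templates, function(tp)
    nmse(tp$grid[rows, cols, , drop = FALSE], base), 0)
  out <- data.frame(keyframe = seq_len(n), time = seq$keyframe_times,
                    nmse = vals)
  if (!is.null(angles)) out$angle <- angles
  out
}

#' Per-muscle mean and variance of angle-similarity curves
#'
#' Applies [angle_similarity_curve()] to every unit of a muscle and reduces
#' to the per-keyframe mean and variance, the form used to summarise how
#' consistently the MUAPs of one muscle morph during a movement.
#'
#' @param seqs list of `muap_sequence`s (same keyframe grid).
#' @param baseline_index baseline keyframe index.
#' @param angles optional normalised angles per keyframe.
#' @return data frame with `keyframe`, `time`, `angle` (if given),
#'   `mean_nmse`, `var_nmse`.
#' @export
pool_similarity_curve <- function(seqs, baseline_index = 1, angles = NULL) {
  curves <- vapply(seqs, function(s)
    angle_similarity_curve(s, baseline_index)$nmse,
    numeric(length(seqs[[1]]$templates)))
  curves <- matrix(curves, ncol = length(seqs))
  out <- data.frame(keyframe = seq_len(nrow(curves)),
                    time = seqs[[1]]$keyframe_times,
                    mean_nmse = rowMeans(curves),
                    var_nmse = apply(curves, 1, stats::var))
  if (!is.null(angles)) out$angle <- angles
  out
}

#' Windowed RMS features of an EMG recording
#'
#' Per-channel root-mean-square over sliding windows (default 200 ms with
#' 50 ms overlap between consecutive windows, i.e. a 150 ms step). Windows
#' that would extend past the end of the record are dropped. An alternative
#' reading of the overlap as the step size is available by passing `step_s`
#' directly.
#'
#' @param emg an `emg_recording`.
#' @param window_s window length (s).
#' @param overlap_s overlap between consecutive windows (s).
#' @param step_s window step (s); default `window_s - overlap_s`.
#' @return an object of class `rms_features`: list with `values`
#'   (n_windows x n_channels), `window_starts` (s), `window_s`, `step_s`.
#' @export
rms_features <- function(emg, window_s = 0.200, overlap_s = 0.050,
                         step_s = window_s - overlap_s) {
  n <- ncol(emg$values)
  wlen <- round(window_s * emg$fs)
  step <- round(step_s * emg$fs)
  if (wlen > n) stop("window longer than the record", call. = FALSE)
  starts <- seq(1L, n - wlen + 1L, by = step)
  vals <- t(vapply(starts, function(s0)
    sqrt(rowMeans(emg$values[, s0:(s0 + wlen - 1L), drop = FALSE]^2)),
    numeric(nrow(emg$values))))
  vals <- matrix(vals, nrow = length(starts))
  structure(list(values = vals, window_starts = (starts - 1L) / emg$fs,
                 window_s = window_s, step_s = step_s, fs = emg$fs),
            class = "rms_features")
}

#' Label RMS windows with joint angles
#'
#' Reduces an angle series to one label per RMS window (the mean angle
#' within the window).
#'
#' @param feats an [rms_features()] result.
#' @param time angle sample times (s).
#' @param angle angle series (same length as `time`).
#' @return numeric vector, one label per window.
#' @export
window_labels <- function(feats, time, angle) {
  vapply(feats$window_starts, function(s0) {
    sel <- time >= s0 - 1e-9 & time <= s0 + feats$window_s + 1e-9
    if (!any(sel)) angle[which.min(abs(time - s0))] else mean(angle[sel])
  }, 0)
}

# --- qualitative MUAP descriptors used in tests and reports ---------------

#' Scalar descriptors of a MUAP template
#'
#' `muap_amplitude`: global peak-to-peak amplitude. `muap_duration`: time
#' spanned by activity above 5% of the global peak on any channel.
#' `muap_spatial_spread`: amplitude-weighted circular standard deviation
#' (in columns) of the per-column peak amplitude profile.
#'
#' @param muap a `muap_template`.
#' @return scalar.
#' @export
muap_amplitude <- function(muap) {
  diff(range(muap$grid))
}

#' @rdname muap_amplitude
#' @export
muap_duration <- function(muap) {
  env <- apply(abs(muap$grid), 3, max)
  thr <- 0.05 * max(env)
  idx <- which(env >= thr)
  (max(idx) - min(idx)) / muap$fs
}

#' @rdname muap_amplitude
#' @export
muap_spatial_spread <- function(muap) {
  p <- apply(abs(muap$grid), 2, max)
  n_c <- length(p)
  ang <- (seq_len(n_c) - 1) * 2 * pi / n_c
  w <- p / sum(p)
  # circular spread: 1 - resultant length, monotone in dispersion
  r <- sqrt(sum(w * cos(ang))^2 + sum(w * sin(ang))^2)
  1 - r
}
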