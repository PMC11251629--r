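#' Synthesise multi-channel surface EMG from spike trains and dynamic MUAPs
#'
#' The interference EMG is the summation over all active motor units of the
#' convolution of each unit's spike train with its (time-varying) MUAP
#' template: for every spike at time `t_k`, the template in force at `t_k`
#' -- by default the linear interpolation of the two keyframe templates
#' bracketing the spike -- is added to the record starting at the sample
#' nearest `t_k`. Templates extending past the end of the record are
#' truncated.
#'
#' @param spikes a `spike_train_set` (see [fuglevand_spikes()]).
#' @param muaps list of `muap_sequence` objects, one per unit (by rank).
#'   Units with no spikes may have `NULL` entries.
#' @param fs output sampling rate (Hz); must equal the template rate.
#' @param duration record duration (s).
#' @param keyframe_mode `"interp"` (default) or `"nearest"`.
#' @return an object of class `emg_recording`: list with `values`
#'   (n_channels x n_samples), `fs`, `channel_map` (data frame channel ->
#'   row, col), `provenance`.
#' @export
synthesize <- function(spikes, muaps, fs, duration,
                       keyframe_mode = c("interp", "nearest")) {
  keyframe_mode <- match.arg(keyframe_mode)
  n <- round(duration * fs)
  shape <- NULL
  for (s in muaps) {
    if (is.null(s)) next
    d <- dim(s$templates[[1]]$grid)
    if (is.null(shape)) shape <- d else stopifnot(all(shape == d))
    if (abs(s$templates[[1]]$fs - fs) > 1e-9) {
      stop("MUAP sampling rate does not match the EMG rate", call. = FALSE)
    }
  }
  if (is.null(shape)) shape <- c(10, 32, 1)
  n_ch <- shape[1] * shape[2]
  Tt <- shape[3]
  values <- matrix(0, n_ch, n)
  for (k in seq_along(spikes$trains)) {
    st <- spikes$trains[[k]]
    if (!length(st)) next
    seq_k <- if (k <= length(muaps)) muaps[[k]] else NULL
    if (is.null(seq_k)) {
      stop("active unit ", k, " has no MUAP sequence", call. = FALSE)
    }
    st <- st[st >= 0 & st <= duration]
    kt <- seq_k$keyframe_times
    flat <- lapply(seq_k$templates, flatten_muap)
    for (t_k in st) {
      i0 <- round(t_k * fs) + 1L
      if (i0 > n) next
      len <- min(Tt, n - i0 + 1L)
      tmpl <- interp_template(flat, kt, t_k, keyframe_mode)
      values[, i0:(i0 + len - 1L)] <-
        values[, i0:(i0 + len - 1L)] + tmpl[, seq_len(len)]
    }
  }
  rows <- ((seq_len(n_ch) - 1L) %/% shape[2]) + 1L
  cols <- ((seq_len(n_ch) - 1L) %% shape[2]) + 1L
  structure(list(values = values, fs = fs,
                 channel_map = data.frame(channel = seq_len(n_ch),
                                          row = rows, col = cols),
                 provenance = list(muscle = spikes$muscle,
                                   model_kind = spikes$model_kind)),
            class = "emg_recording")
}

interp_template <- function(flat, kt, t_k, mode) {
  if (length(flat) == 1L) return(flat[[1]])
  t_k <- min(max(t_k, kt[1]), kt[length(kt)])
  i <- findInterval(t_k, kt, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(kt) - 1L)
  if (mode == "nearest") {
    j <- if (t_k - kt[i] > kt[i + 1] - t_k) i + 1L else i
    return(flat[[j]])
  }
  w <- (t_k - kt[i]) / (kt[i + 1] - kt[i])
  if (w <= 0) flat[[i]]
  else if (w >= 1) flat[[i + 1]]
  else flat[[i]] * (1 - w) + flat[[i + 1]] * w
}

#' Sum several EMG recordings
#'
#' Elementwise sum of recordings sharing grid and sampling rate, e.g. the
#' contributions of several muscles.
#'
#' @param recordings list of `emg_recording` objects.
#' @return an `emg_recording`.
#' @export
sum_emg <- function(recordings) {
  recordings <- Filter(Negate(is.null), recordings)
  stopifnot(length(recordings) >= 1)
  out <- recordings[[1]]
  for (r in recordings[-1]) {
    stopifnot(all(dim(r$values) == dim(out$values)), r$fs == out$fs)
    out$values <- out$values + r$values
  }
  out$provenance <- list(muscles = lapply(recordings, function(r)
    r$provenance$muscle))
  out
}

#' Add white Gaussian noise at a target SNR
#'
#' Per-channel additive white Gaussian noise scaled so that
#' `10*log10(P_signal / P_noise) = snr_db`, with signal power measured over
#' all channels and samples. `snr_db = Inf` returns the input unchanged.
#'
#' @param emg an `emg_recording` with nonzero power.
#' @param snr_db target signal-to-noise ratio (dB).
#' @param seed integer seed for the noise stream.
#' @return an `emg_recording`.
#' @export
add_noise <- function(emg, snr_db, seed = 1L) {
  if (is.infinite(snr_db) && snr_db > 0) return(emg)
  p_sig <- mean(emg$values^2)
  if (p_sig == 0) stop("zero-power input", call. = FALSE)
  sd_n <- sqrt(p_sig / 10^(snr_db / 10))
  noise <- with_seed(child_seed(seed, "emg-noise"),
                     matrix(stats::rnorm(length(emg$values), 0, sd_n),
                            nrow(emg$values)))
  emg$values <- emg$values + noise
  emg$provenance$snr_db <- snr_db
  emg
}

#' Select channels by grid coordinates
#'
#' Subsets a recording to the channels nearest the requested grid
#' coordinates (order preserved; duplicates yield duplicated channels). The
#' mapping is recorded in the result's `channel_map`.
#'
#' @param emg an `emg_recording`.
#' @param coords data frame or matrix with columns `row`, `col` (grid
#'   coordinates; fractional values snap to the nearest electrode,
#'   circularly in the column direction).
#' @return an `emg_recording` with the selected channels.
#' @export
select_channels <- function(emg, coords) {
  coords <- as.data.frame(coords)
  n_r <- max(emg$channel_map$row)
  n_c <- max(emg$channel_map$col)
  if (any(coords$row < 0.5 | coords$row > n_r + 0.5)) {
    stop("row coordinate outside the grid", call. = FALSE)
  }
  rows <- pmin(pmax(round(coords$row), 1L), n_r)
  cols <- ((round(coords$col) - 1L) %% n_c) + 1L
  idx <- (rows - 1L) * n_c + cols
  emg$values <- emg$values[idx, , drop = FALSE]
  emg$channel_map <- data.frame(channel = seq_along(idx), row = rows,
                                col = cols, source_channel = idx)
  emg
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("emg_recording: %d channels x %d samples (%.3g s at %g Hz), rms %.3g\n",
              nrow(x$values), ncol(x$values), ncol(x$values) / x$fs, x$fs,
              sqrt(mean(x$values^2))))
  invisible(x)
}

#' Write / read an EMG recording as delimited text
#'
#' Tab-delimited matrix (samples x channels) with a `time` column, plus a
#' JSON sidecar with sampling rate, channel map and provenance. Intended
#' for small excerpts; large runs are better kept in R's native
#' serialization.
#'
#' @param emg an `emg_recording`.
#' @param path output file.
#' @return `write_emg_text` returns `path` invisibly; `read_emg_text` an
#'   `emg_recording`.
#' @export
write_emg_text <- function(emg, path) {
  df <- data.frame(time = (seq_len(ncol(emg$values)) - 1) / emg$fs,
                   t(emg$values))
  names(df) <- c("time", paste0("ch", seq_len(nrow(emg$values))))
  utils::write.table(format(df, digits = 10, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(fs = emg$fs, channel_map = emg$channel_map,
                            provenance = emg$provenance),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_emg_text
#' @export
read_emg_text <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  structure(list(values = unname(t(as.matrix(df[, -1, drop = FALSE]))),
                 fs = meta$fs, channel_map = meta$channel_map,
                 provenance = meta$provenance),
            class = "emg_recording")
}

#' Hierarchical on-disk store for MUAP sequences
#'
#' Directory-tree container mirroring a hierarchical `/muscle/unit/keyframe`
#' layout: each keyframe template is one delimited text file
#' (channels x samples) and each unit carries a JSON attribute file with the
#' keyframe times and conditions. The same layout can be produced by
#' external tools and read back.
#'
#' @param muaps named list (by muscle) of lists of `muap_sequence`.
#' @param dir store directory.
#' @return `write_muap_store` returns `dir` invisibly; `read_muap_store` the
#'   nested list.
#' @export
write_muap_store <- function(muaps, dir) {
  for (mus in names(muaps)) {
    for (k in seq_along(muaps[[mus]])) {
      sq <- muaps[[mus]][[k]]
      ud <- file.path(dir, mus, sprintf("unit%03d", k))
      dir.create(ud, recursive = TRUE, showWarnings = FALSE)
      for (i in seq_along(sq$templates)) {
        utils::write.table(flatten_muap(sq$templates[[i]]),
                           file.path(ud, sprintf("keyframe%03d.txt", i)),
                           sep = "\t", quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
      }
      jsonlite::write_json(
        list(keyframe_times = sq$keyframe_times, unit_id = sq$unit_id,
             fs = sq$templates[[1]]$fs,
             shape = dim(sq$templates[[1]]$grid),
             conds = lapply(sq$templates, function(tp)
               as.list(unclass(tp$cond)))),
        file.path(ud, "attributes.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(dir)
}

#' @rdname write_muap_store
#' @export
read_muap_store <- function(dir) {
  out <- list()
  for (mus in list.dirs(dir, recursive = FALSE, full.names = FALSE)) {
    seqs <- list()
    for (ud in list.dirs(file.path(dir, mus), recursive = FALSE)) {
      at <- jsonlite::read_json(file.path(ud, "attributes.json"),
                                simplifyVector = TRUE)
      files <- sort(list.files(ud, pattern = "^keyframe", full.names = TRUE))
      templates <- lapply(seq_along(files), function(i) {
        m <- as.matrix(utils::read.table(files[i], sep = "\t"))
        g <- array(0, at$shape)
        for (r in seq_len(at$shape[1])) {
          g[r, , ] <- m[(r - 1) * at$shape[2] + seq_len(at$shape[2]), ]
        }
        cond <- if (is.data.frame(at$conds) || is.matrix(at$conds)) {
          as.list(as.data.frame(at$conds)[i, ])
        } else {
          as.list(at$conds[[i]])
        }
        structure(list(grid = g, fs = at$fs,
                       cond = do.call(condition_vector, cond)),
                  class = "muap_template")
      })
      seqs[[length(seqs) + 1L]] <- structure(
        list(keyframe_times = at$keyframe_times, templates = templates,
             unit_id = at$unit_id), class = "muap_sequence")
    }
    out[[mus]] <- seqs
  }
  out
}
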