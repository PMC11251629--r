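#' Joint-angle trajectory container
#'
#' A `joint_trajectory` holds uniformly sampled joint angles (degrees) for
#' every DoF of the schema.
#'
#' @param time numeric vector of sample times (s), uniform grid.
#' @param angles numeric matrix, `length(time)` rows, one column per DoF.
#' @param fs_motion sampling rate (Hz).
#' @param dof_names column names.
#' @return an object of class `joint_trajectory`.
#' @export
joint_trajectory <- function(time, angles, fs_motion,
                             dof_names = colnames(angles)) {
  angles <- as.matrix(angles)
  stopifnot(nrow(angles) == length(time), fs_motion > 0)
  if (length(time) > 1) {
    dt <- diff(time)
    stopifnot(all(dt > 0),
              max(abs(dt - dt[1])) < 1e-9 * max(dt[1], 1))
  }
  colnames(angles) <- dof_names
  structure(list(time = time, angles = angles, fs_motion = fs_motion,
                 dof_names = dof_names),
            class = "joint_trajectory")
}

#' @export
print.joint_trajectory <- function(x, ...) {
  cat(sprintf("joint_trajectory: %d samples, %d DoFs, %.4g s at %g Hz\n",
              length(x$time), ncol(x$angles),
              if (length(x$time)) max(x$time) else 0, x$fs_motion))
  moved <- colnames(x$angles)[apply(x$angles, 2, function(a) any(a != 0))]
  if (length(moved)) cat("  active DoFs:", paste(moved, collapse = ", "), "\n")
  invisible(x)
}

#' Define a movement by interpolating between poses
#'
#' Builds a joint trajectory by holding one pose at each stage and
#' interpolating over the given transition durations on a uniform time grid.
#' By default a cosine-eased (smoothstep) interpolant is used so angular
#' velocity is zero at each keyframe, avoiding abrupt fibre-length changes at
#' stage boundaries; linear interpolation is available with
#' `interp = "linear"`. Endpoint samples reproduce the pose angle maps
#' exactly.
#'
#' @param pose_sequence character vector of pose names (combinations with
#'   `+` allowed).
#' @param durations numeric vector of transition durations (s), one fewer
#'   than poses.
#' @param fs_motion motion sampling rate (Hz).
#' @param config configuration list.
#' @param interp `"cosine"` (default, from config) or `"linear"`.
#' @return a [joint_trajectory()].
#' @export
define_movement <- function(pose_sequence, durations, fs_motion,
                            config = default_config(),
                            interp = config$kinematics$interp) {
  stopifnot(length(durations) == length(pose_sequence) - 1L)
  if (any(durations <= 0)) stop("durations must be positive", call. = FALSE)
  stopifnot(fs_motion > 0)
  lib <- load_pose_library(config)
  key <- t(vapply(pose_sequence, resolve_pose, numeric(length(config$dof$names)),
                  library = lib, config = config))
  key_t <- c(0, cumsum(durations))
  n <- round(key_t[length(key_t)] * fs_motion) + 1L
  time <- (seq_len(n) - 1L) / fs_motion
  angles <- matrix(0, n, ncol(key), dimnames = list(NULL, config$dof$names))
  seg <- pmin(findInterval(time, key_t, rightmost.closed = TRUE),
              length(durations))
  u <- (time - key_t[seg]) / durations[seg]
  u <- pmin(pmax(u, 0), 1)
  w <- if (identical(interp, "linear")) u else (1 - cos(pi * u)) / 2
  angles <- key[seg, , drop = FALSE] * (1 - w) +
    key[seg + 1L, , drop = FALSE] * w
  # keyframe samples that fall exactly on the grid reproduce the pose maps
  on_key <- which(abs(time - key_t[seg]) < 1e-12)
  if (length(on_key)) angles[on_key, ] <- key[seg[on_key], , drop = FALSE]
  angles[n, ] <- key[nrow(key), ]
  dimnames(angles) <- list(NULL, config$dof$names)
  joint_trajectory(time, angles, fs_motion, config$dof$names)
}

#' Check a trajectory against the declared joint ranges
#'
#' Reports every (DoF, sample) pair whose angle falls outside the declared
#' closed-interval range. Reporting, not raising: a compliant trajectory
#' yields a zero-row report and values exactly at a range limit are
#' compliant.
#'
#' @param traj a [joint_trajectory()].
#' @param config configuration list.
#' @return data frame with columns `dof`, `sample`, `angle`, `lower`,
#'   `upper`.
#' @export
check_joint_ranges <- function(traj, config = default_config()) {
  rng <- config$dof$ranges
  out <- list()
  for (d in intersect(colnames(traj$angles), rng$dof)) {
    r <- rng[rng$dof == d, ]
    a <- traj$angles[, d]
    bad <- which(a < r$lower | a > r$upper)
    if (length(bad)) {
      out[[d]] <- data.frame(dof = d, sample = bad, angle = a[bad],
                             lower = r$lower, upper = r$upper,
                             stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
  else data.frame(dof = character(), sample = integer(), angle = numeric(),
                  lower = numeric(), upper = numeric(),
                  stringsAsFactors = FALSE)
}

#' Write / read OpenSim-style .mot motion files
#'
#' Tab-delimited motion files with the conventional header (`name`,
#' `datacolumns`, `datarows`, `inDegrees=yes`, `endheader`), first body
#' column `time`, remaining columns the joint angles in degrees. A
#' write-then-read round trip is lossless to better than 1e-9.
#'
#' @param traj a [joint_trajectory()].
#' @param path output file.
#' @param name motion name written in the header.
#' @return `write_mot` returns `path` invisibly; `read_mot` returns a
#'   [joint_trajectory()].
#' @export
write_mot <- function(traj, path, name = "movement") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(name,
               sprintf("datacolumns %d", ncol(traj$angles) + 1L),
               sprintf("datarows %d", length(traj$time)),
               "inDegrees=yes",
               "endheader",
               paste(c("time", colnames(traj$angles)), collapse = "\t")),
             con)
  body <- cbind(traj$time, traj$angles)
  writeLines(apply(body, 1, function(r)
    paste(sprintf("%.12g", r), collapse = "\t")), con)
  invisible(path)
}

#' @rdname write_mot
#' @export
read_mot <- function(path) {
  lines <- readLines(path)
  end <- match("endheader", trimws(lines))
  if (is.na(end)) stop("not a .mot file: no endheader line", call. = FALSE)
  header <- strsplit(trimws(lines[end + 1L]), "\t")[[1]]
  stopifnot(header[1] == "time")
  body <- utils::read.table(text = lines[-seq_len(end + 1L)], sep = "\t",
                            col.names = header, check.names = FALSE)
  time <- body$time
  angles <- as.matrix(body[, -1, drop = FALSE])
  fs <- if (length(time) > 1) 1 / mean(diff(time)) else 1
  joint_trajectory(time, angles, fs, header[-1])
}
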