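#' Physiological parameter trajectories from fibre length
#'
#' Converts a normalised fibre-length series into conduction-velocity and
#' motor-unit-depth scaling trajectories under the assumption that muscle
#' volume is constant during a movement. With constant volume the muscle
#' cross-sectional area scales as the reciprocal of the relative fibre
#' length `l_s(t) = fibre_length_norm(t) / rest_length_norm`, so the
#' cross-section *radius* (and with it both the fibre diameter that sets
#' conduction velocity and the radial position of a motor unit that sets its
#' depth) scales as `l_s^(-1/2)`. The exponents are configurable
#' (`cv_exponent`, `depth_exponent`, default -0.5 each) so alternative
#' scaling laws, e.g. velocity proportional to area (exponent -1), are a
#' one-line change.
#'
#' All three scales equal 1 whenever the fibre is at its rest length;
#' shortening (`l_s < 1`) increases both the conduction-velocity and the
#' depth scale.
#'
#' @param fibre_length_norm positive numeric series of normalised fibre
#'   lengths.
#' @param rest_length_norm positive scalar, the rest (baseline) normalised
#'   length.
#' @param time optional time vector (s) carried through.
#' @param config configuration list (exponents).
#' @return an object of class `parameter_trajectory`: list with `time`,
#'   `fibre_length_scale`, `cv_scale`, `depth_scale`.
#' @export
len2params <- function(fibre_length_norm, rest_length_norm = 1,
                       time = NULL, config = default_config()) {
  if (any(fibre_length_norm <= 0) || rest_length_norm <= 0) {
    stop("fibre lengths must be positive", call. = FALSE)
  }
  ls <- fibre_length_norm / rest_length_norm
  structure(list(
    time = if (is.null(time)) seq_along(ls) - 1 else time,
    fibre_length_scale = ls,
    cv_scale = ls^config$kinematics$cv_exponent,
    depth_scale = ls^config$kinematics$depth_exponent
  ), class = "parameter_trajectory")
}

#' @export
print.parameter_trajectory <- function(x, ...) {
  cat(sprintf("parameter_trajectory: %d samples, length scale [%.3f, %.3f], cv scale [%.3f, %.3f]\n",
              length(x$time), min(x$fibre_length_scale),
              max(x$fibre_length_scale), min(x$cv_scale), max(x$cv_scale)))
  invisible(x)
}

#' Write / read a parameter trajectory as delimited text
#'
#' Columns `time`, `length_scale`, `cv_scale`, `depth_scale`, tab-delimited
#' with a header row.
#'
#' @param ptraj a `parameter_trajectory`.
#' @param path file path.
#' @return `write_param_trajectory` returns `path` invisibly;
#'   `read_param_trajectory` returns a `parameter_trajectory`.
#' @export
write_param_trajectory <- function(ptraj, path) {
  df <- data.frame(time = ptraj$time,
                   length_scale = ptraj$fibre_length_scale,
                   cv_scale = ptraj$cv_scale,
                   depth_scale = ptraj$depth_scale)
  utils::write.table(format(df, digits = 15, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_param_trajectory
#' @export
read_param_trajectory <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  structure(list(time = df$time, fibre_length_scale = df$length_scale,
                 cv_scale = df$cv_scale, depth_scale = df$depth_scale),
            class = "parameter_trajectory")
}
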