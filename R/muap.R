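#' Seven-parameter condition vector for MUAP generation
#'
#' The MUAP generator is conditioned on seven physiological parameters, each
#' expressed on a relative scale in `(0, 1]`: fat-layer conductivity, fibre
#' number, motor-unit depth, medial-lateral position, innervation-zone
#' position, conduction velocity, and fibre length. Physical values map to
#' the relative scale through the affine ranges in `config$muap$maps`
#' (depth in mm, conduction velocity in m/s, fibre length in mm); the
#' medial-lateral position maps the full circumference to `(0, 1]` and the
#' innervation zone is already a fraction of fibre length.
#'
#' @param fat_conductivity,fibre_number,depth,ml_pos,iz_pos,cv,fibre_length
#'   relative values in `(0, 1]`.
#' @return an object of class `condition_vector` (named numeric of length 7).
#' @export
condition_vector <- function(fat_conductivity, fibre_number, depth, ml_pos,
                             iz_pos, cv, fibre_length) {
  x <- c(fat_conductivity = fat_conductivity, fibre_number = fibre_number,
         depth = depth, ml_pos = ml_pos, iz_pos = iz_pos, cv = cv,
         fibre_length = fibre_length)
  if (length(x) != 7 || any(!is.finite(x)) || any(x <= 0) || any(x > 1)) {
    stop("all seven condition parameters must lie in (0, 1]", call. = FALSE)
  }
  structure(x, class = "condition_vector")
}

# physical <-> relative affine maps
rel_to_phys <- function(rel, range) range[1] + rel * (range[2] - range[1])
phys_to_rel <- function(x, range, rel_min = 0.02) {
  pmin(pmax((x - range[1]) / (range[2] - range[1]), rel_min), 1)
}

#' Condition vector for one motor unit of a pool
#'
#' Maps the physical unit properties drawn by [init_pool()] (depth and
#' medial-lateral offset in the muscle territory, innervation zone,
#' conduction velocity, fibre length, fibre count) onto the relative
#' condition scale.
#'
#' @param pool a [init_pool()] result.
#' @param rank unit rank.
#' @param config configuration list.
#' @param fat relative fat-layer conductivity shared by the simulation.
#' @return a [condition_vector()].
#' @export
unit_condition <- function(pool, rank, config = default_config(),
                           fat = config$muap$fat_default) {
  u <- pool$units[rank, ]
  mus <- get_muscle(pool$muscle, config)
  maps <- config$muap$maps
  rmin <- config$muap$rel_min
  ang <- (mus$ml_angle * pi / 180 + u$ml_pos / config$muap$radius_mm) %%
    (2 * pi)
  condition_vector(
    fat_conductivity = fat,
    fibre_number = pmin(pmax(u$size / max(pool$units$size), rmin), 1),
    depth = phys_to_rel(u$depth, maps$depth_mm, rmin),
    ml_pos = max(ang / (2 * pi), rmin),
    iz_pos = pmin(pmax(u$iz_pos, rmin), 1),
    cv = phys_to_rel(u$cv, maps$cv_ms, rmin),
    fibre_length = phys_to_rel(u$fibre_length, maps$fibre_length_mm, rmin)
  )
}

#' Fixed per-unit latent vector
#'
#' Standard-Normal latent representation of the morphological identity of
#' one motor unit, a pure function of `(unit_id, root_seed)`. The latent is
#' sampled once per unit and held fixed for the whole movement, so the
#' generated MUAPs change only through the physiological parameters.
#'
#' @param unit_id identifier (integer or string) of the unit.
#' @param root_seed integer root seed.
#' @param dim latent dimension.
#' @return numeric vector of length `dim`.
#' @export
sample_latent <- function(unit_id, root_seed,
                          dim = default_config()$muap$latent_dim) {
  with_seed(child_seed(root_seed, "latent-stream", unit_id),
            stats::rnorm(dim))
}

#' Generate one MUAP template on the electrode grid
#'
#' Analytical line-source volume-conductor model on a cylindrical limb:
#' two intracellular action-potential sources (spatial profile: first
#' derivative of a Gaussian, i.e. a travelling dipole) depart from the
#' innervation zone and propagate toward the two fibre ends at the
#' conduction velocity, extinguishing progressively as the profile passes a
#' fibre end. Each electrode of the 10 x 32 grid (10 axial rows, 32
#' circumferential columns on a cylinder) sees the sum over source
#' quadrature points of `A / (sigma_eff * d)`, with `d` the 3-D distance
#' from the source point to the electrode. Source amplitude is proportional
#' to the relative fibre number; the fat-layer conductivity scales the
#' effective conductivity and sets a circumferential smoothing width
#' (thicker/less conductive fat blurs the potential). The fixed per-unit
#' latent perturbs the two pole amplitudes and the innervation-zone position
#' by bounded (+/- 10% and +/- 2% of fibre length) deterministic amounts.
#'
#' The output is deterministic: identical (condition, latent, fs, T) give a
#' bit-identical template.
#'
#' @param cond a [condition_vector()].
#' @param latent latent vector from [sample_latent()]; `NULL` for the
#'   unperturbed template.
#' @param fs_muap template sampling rate (Hz).
#' @param T number of time samples.
#' @param config configuration list.
#' @return an object of class `muap_template`: list with `grid` (array
#'   10 x 32 x T), `fs`, `cond`.
#' @export
generate_muap <- function(cond, latent = NULL,
                          fs_muap = default_config()$muap$fs_muap,
                          T = default_config()$muap$T,
                          config = default_config()) {
  if (!inherits(cond, "condition_vector")) cond <- do.call(condition_vector,
                                                           as.list(cond))
  mc <- config$muap
  n_r <- mc$n_rows; n_c <- mc$n_cols
  Rc <- mc$radius_mm
  z_rows <- (seq_len(n_r) - (n_r + 1) / 2) * mc$ied_mm
  th_cols <- (seq_len(n_c) - 1) * 2 * pi / n_c

  depth_mm <- rel_to_phys(cond[["depth"]], mc$maps$depth_mm)
  v <- rel_to_phys(cond[["cv"]], mc$maps$cv_ms) * 1000 # mm/s
  L <- rel_to_phys(cond[["fibre_length"]], mc$maps$fibre_length_mm)
  phi <- cond[["ml_pos"]] * 2 * pi
  r_f <- Rc - depth_mm

  amp_pos <- 1; amp_neg <- 1; iz <- cond[["iz_pos"]]
  if (!is.null(latent)) {
    amp_pos <- 1 + mc$latent_amp_frac * tanh(latent[1])
    amp_neg <- 1 + mc$latent_amp_frac * tanh(latent[2])
    iz <- min(max(iz + mc$latent_iz_frac * tanh(latent[3]), 0.05), 0.95)
  }
  z0 <- -L / 2
  z_iz <- z0 + iz * L

  w <- mc$ap_width_mm
  Q <- mc$quad_points
  u_q <- seq(-3 * w, 3 * w, length.out = Q)
  du <- u_q[2] - u_q[1]
  psi <- -u_q / w^2 * exp(-u_q^2 / (2 * w^2)) * du # travelling dipole

  tvec <- (seq_len(T) - 1) / fs_muap
  amp0 <- cond[["fibre_number"]] * cond[["fat_conductivity"]] / mc$sigma0
  # source positions and weights: dims (Q, 2 dirs, T)
  zc_pos <- z_iz + v * tvec
  zc_neg <- z_iz - v * tvec
  z_src <- c(vapply(seq_len(T), function(i)
    c(zc_pos[i] + u_q, zc_neg[i] - u_q), numeric(2 * Q)))
  w_src <- rep(c(psi * amp_pos * amp0, -psi * amp_neg * amp0), T)
  inside <- z_src >= z0 & z_src <= z0 + L
  w_src <- w_src * inside

  rho <- sqrt(Rc^2 + r_f^2 - 2 * Rc * r_f * cos(th_cols - phi))
  z_e <- rep(z_rows, times = n_c)   # electrode order: row fastest
  rho_e <- rep(rho, each = n_r)
  d <- sqrt(outer(z_e, z_src, "-")^2 + rho_e^2)
  contrib <- sweep(1 / d, 2, w_src, "*")
  arr <- array(contrib, c(n_r * n_c, 2 * Q, T))
  phi_e <- colSums(aperm(arr, c(2, 1, 3)))  # (320, T)
  grid <- array(phi_e, c(n_r, n_c, T))

  sdc <- mc$smooth_sd_base + mc$smooth_sd_fat * (1 - cond[["fat_conductivity"]])
  grid <- smooth_columns(grid, sdc)
  structure(list(grid = grid, fs = fs_muap, cond = cond),
            class = "muap_template")
}

# circular Gaussian smoothing across the circumferential (column) axis
smooth_columns <- function(grid, sd_cols) {
  n_c <- dim(grid)[2]
  off <- seq(-floor(n_c / 2), floor(n_c / 2) - 1)
  k <- exp(-off^2 / (2 * sd_cols^2))
  k <- k / sum(k)
  K <- matrix(0, n_c, n_c)
  for (c0 in seq_len(n_c)) {
    K[c0, ((c0 - 1 + off) %% n_c) + 1] <- k
  }
  d <- dim(grid)
  m <- aperm(grid, c(2, 1, 3))
  dim(m) <- c(n_c, d[1] * d[3])
  m <- K %*% m
  dim(m) <- c(n_c, d[1], d[3])
  aperm(m, c(2, 1, 3))
}

#' @export
print.muap_template <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("muap_template: %d x %d grid, %d samples at %g Hz, peak %.3g\n",
              d[1], d[2], d[3], x$fs, max(abs(x$grid))))
  invisible(x)
}

#' Flatten a template grid to channel-major form
#'
#' Channel index is row-major over the grid: channel `c` (1-based) maps to
#' row `(c - 1) %/% 32 + 1`, column `(c - 1) %% 32 + 1`.
#'
#' @param muap a `muap_template`.
#' @return numeric matrix (n_channels x T).
#' @export
flatten_muap <- function(muap) {
  d <- dim(muap$grid)
  m <- aperm(muap$grid, c(2, 1, 3)) # column fastest within a row block
  dim(m) <- c(d[1] * d[2], d[3])
  m
}

#' Morph a MUAP template sequence along a parameter trajectory
#'
#' Generates one template per keyframe, with the unit's depth, conduction
#' velocity and fibre length multiplied by the trajectory scales at the
#' keyframe time (clamped to the valid relative range) and the latent held
#' fixed, so consecutive templates differ only through the physiological
#' parameters. Keyframe times are evenly spaced over the trajectory.
#'
#' @param base_cond baseline [condition_vector()].
#' @param param_traj a [len2params()] result covering the movement.
#' @param n_keyframes number of keyframes (>= 2).
#' @param latent fixed latent vector (or `NULL`).
#' @param fs_muap,T template sampling parameters.
#' @param config configuration list.
#' @param unit_id identifier carried through.
#' @return an object of class `muap_sequence`: list with `keyframe_times`,
#'   `templates`, `unit_id`.
#' @export
morph_sequence <- function(base_cond, param_traj, n_keyframes = 16,
                           latent = NULL,
                           fs_muap = default_config()$muap$fs_muap,
                           T = default_config()$muap$T,
                           config = default_config(), unit_id = NA) {
  if (n_keyframes < 2) stop("n_keyframes must be >= 2", call. = FALSE)
  rmin <- config$muap$rel_min
  kt <- seq(min(param_traj$time), max(param_traj$time),
            length.out = n_keyframes)
  interp <- function(y) stats::approx(param_traj$time, y, xout = kt,
                                      rule = 2)$y
  ls <- interp(param_traj$fibre_length_scale)
  cs <- interp(param_traj$cv_scale)
  ds <- interp(param_traj$depth_scale)
  clamp <- function(x) pmin(pmax(x, rmin), 1)
  templates <- lapply(seq_len(n_keyframes), function(k) {
    cond_k <- base_cond
    cond_k[["fibre_length"]] <- clamp(base_cond[["fibre_length"]] * ls[k])
    cond_k[["cv"]] <- clamp(base_cond[["cv"]] * cs[k])
    cond_k[["depth"]] <- clamp(base_cond[["depth"]] * ds[k])
    generate_muap(cond_k, latent, fs_muap, T, config)
  })
  structure(list(keyframe_times = kt, templates = templates,
                 unit_id = unit_id),
            class = "muap_sequence")
}

#' @export
print.muap_sequence <- function(x, ...) {
  cat(sprintf("muap_sequence: unit %s, %d keyframes over [%.3g, %.3g] s\n",
              as.character(x$unit_id), length(x$templates),
              min(x$keyframe_times), max(x$keyframe_times)))
  invisible(x)
}

#' Static single-template sequence
#'
#' Convenience wrapper producing a two-keyframe sequence whose templates are
#' identical, for synthesising EMG with non-morphing MUAPs.
#'
#' @param muap a `muap_template`.
#' @param duration movement duration (s).
#' @param unit_id identifier carried through.
#' @return a `muap_sequence`.
#' @export
static_sequence <- function(muap, duration, unit_id = NA) {
  structure(list(keyframe_times = c(0, duration),
                 templates = list(muap, muap), unit_id = unit_id),
            class = "muap_sequence")
}
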