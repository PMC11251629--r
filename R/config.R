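#' Default simulator configuration
#'
#' Returns the full nested configuration used across the simulator: the
#' 24-DoF joint schema with closed-interval ranges (degrees), the default
#' superficial forearm muscle set with constant moment arms and territory
#' geometry, motor-unit-pool parameters for the classical recruitment model
#' and the leaky integrate-and-fire (LIF) cohort, the volume-conductor and
#' electrode-grid geometry of the MUAP model, the single-DoF rigid-body
#' dynamics used by the torque helper, and the settings of the
#' data-augmentation demonstration.
#'
#' All values are plain numbers in the stated units so a configuration can be
#' round-tripped through YAML with [read_config()] / [write_config()] and
#' edited field-wise.
#'
#' The moment arms, slack lengths and maximal forces are a documented
#' surrogate for a full musculoskeletal model: constant, signed moment arms
#' chosen so that flexor fibres shorten during wrist/finger flexion and
#' extensor fibres lengthen, which preserves the qualitative fibre-length
#' patterns a forward musculoskeletal simulation produces without requiring
#' one at run time.
#'
#' @return a named list with components `dof`, `muscles`, `pool`, `lif`,
#'   `muap`, `dynamics`, `kinematics`, `emg`, `augment`.
#' @export
default_config <- function() {
  dof_names <- c(
    "pronation_supination", "wrist_flexion", "wrist_deviation",
    "cmc1_flexion", "cmc1_abduction", "cmc1_rotation",
    "mp1_flexion", "ip1_flexion",
    paste0(rep(c("mcp", "mcpab", "pip", "dip"), times = 4),
           rep(2:5, each = 4), "_flexion")
  )
  # closed-interval ranges, degrees
  lo <- c(-90, -70, -25, -30, -30, -45, -20, -20,
          rep(c(-40, -25, -15, -15), times = 4))
  hi <- c(90, 70, 35, 60, 60, 45, 80, 90,
          rep(c(90, 25, 110, 90), times = 4))
  ranges <- data.frame(dof = dof_names, lower = lo, upper = hi,
                       stringsAsFactors = FALSE)

  mcp_flex <- paste0("mcp", 2:5, "_flexion")

  muscle <- function(name, lopt, slack, fmax, arms, depth, radius, ml_angle,
                     n_units, total_fibres, fibre_length_mm) {
    list(name = name, optimal_fibre_length = lopt,
         tendon_slack_length = slack, max_isometric_force = fmax,
         moment_arms = arms, territory_centre_depth = depth,
         territory_radius = radius, ml_angle = ml_angle,
         n_units = n_units, total_fibres = total_fibres,
         fibre_length_mm = fibre_length_mm)
  }
  ed_arms <- c(list(wrist_flexion = -0.010),
               stats::setNames(as.list(rep(-0.008, 4)), mcp_flex))
  fds_arms <- c(list(wrist_flexion = 0.010),
                stats::setNames(as.list(rep(0.008, 4)), mcp_flex))
  muscles <- list(
    ECRB  = muscle("ECRB", 0.059, 0.222, 337,
                   list(wrist_flexion = -0.014, wrist_deviation = -0.010),
                   8, 5, 22.5, 16, 25000, 59),
    ECRL  = muscle("ECRL", 0.081, 0.244, 304,
                   list(wrist_flexion = -0.012, wrist_deviation = -0.012),
                   7, 5, 45.0, 16, 22000, 81),
    ED    = muscle("ED", 0.070, 0.322, 260, ed_arms,
                   8, 6, 67.5, 16, 20000, 70),
    ECU   = muscle("ECU", 0.062, 0.228, 192,
                   list(wrist_flexion = -0.012, wrist_deviation = 0.012),
                   7, 5, 101.25, 16, 18000, 62),
    FCU_u = muscle("FCU_u", 0.051, 0.265, 479,
                   list(wrist_flexion = 0.016, wrist_deviation = 0.010),
                   8, 5, 236.25, 16, 30000, 51),
    FCU_h = muscle("FCU_h", 0.051, 0.265, 479,
                   list(wrist_flexion = 0.016, wrist_deviation = 0.012),
                   9, 5, 225.0, 16, 30000, 51),
    FDS   = muscle("FDS", 0.084, 0.275, 406, fds_arms,
                   10, 6, 270.0, 16, 28000, 84),
    PL    = muscle("PL", 0.064, 0.269, 101,
                   list(wrist_flexion = 0.012),
                   6, 4, 292.5, 16, 9000, 64),
    FCR   = muscle("FCR", 0.063, 0.244, 407,
                   list(wrist_flexion = 0.015, wrist_deviation = -0.008),
                   8, 5, 315.0, 16, 26000, 63)
  )

  list(
    dof = list(names = dof_names, ranges = ranges),
    muscles = muscles,
    kinematics = list(
      interp = "cosine",            # zero angular velocity at keyframes
      fibre_length_band = c(0.5, 1.5),
      force_length_width = 0.45,    # Gaussian force-length factor width
      cv_exponent = -0.5,           # scaling laws for len2params
      depth_exponent = -0.5
    ),
    pool = list(
      RR = 30, RP = 100, MFR = 8, gain = 1,
      PFR_first = 35, PFR_last = 25, isi_cv = 0.2,
      cv_mean = 4.0, cv_sd = 0.35, cv_min = 3.2, cv_max = 4.8,
      iz_mean = 0.5, iz_sd = 0.05, iz_range = c(0.3, 0.7),
      fibre_length_sd = 5, fibre_length_halfwidth = 10
    ),
    lif = list(
      R_first = 12, R_last = 4,       # MOhm (metadata; cancels in RI product)
      tau_first = 10, tau_last = 10,  # ms
      v_th = 20,                      # mV
      t_ref_first = 25, t_ref_last = 33  # ms -> max rates ~40 down to ~30 Hz
    ),
    muap = list(
      n_rows = 10, n_cols = 32, radius_mm = 40, ied_mm = 10,
      fs_muap = 2048, T = 128, latent_dim = 16,
      sigma0 = 1, quad_points = 15, ap_width_mm = 4,
      latent_amp_frac = 0.10, latent_iz_frac = 0.02,
      fat_default = 0.5,
      smooth_sd_base = 0.5, smooth_sd_fat = 1.5,
      maps = list(depth_mm = c(1, 25), cv_ms = c(2, 6),
                  fibre_length_mm = c(40, 160)),
      rel_min = 0.02,
      n_keyframes = 16
    ),
    dynamics = list(
      # single-DoF rigid-body torque helper: tau = I*qddot + b*qdot + k*q
      wrist = list(inertia = 0.004, damping = 0.05, stiffness = 3.0),
      mcp   = list(inertia = 0.0003, damping = 0.005, stiffness = 0.8),
      default = list(inertia = 0.002, damping = 0.02, stiffness = 1.0)
    ),
    emg = list(fs = 2048, snr_db = Inf),
    augment = list(
      fs_motion = 40, fs_emg = 2000, duration = 15,
      channels = c("FCR", "FDS", "FCU_u", "ECU", "ED", "ECRL"),
      n_keyframes = 8, T = 96,
      drive_jitter = 0.05, snr_db = 20,
      real_like = list(drive_jitter = 0.12, snr_db = 14, channel_shift = 1),
      rms_window = 0.200, rms_overlap = 0.050,
      null_repeats = 10
    )
  )
}

#' Read / write a configuration as YAML
#'
#' @param path file path.
#' @return `read_config` returns a configuration list (fields absent from the
#'   file fall back to [default_config()]); `write_config` returns `path`
#'   invisibly.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (!is.null(user$dof$ranges)) {
    user$dof$ranges <- as.data.frame(user$dof$ranges, stringsAsFactors = FALSE)
  }
  modifyList(default_config(), user)
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  cfg <- config
  cfg$dof$ranges <- as.list(cfg$dof$ranges)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# dynamics parameters for one DoF
dof_dynamics <- function(dof, config) {
  dyn <- config$dynamics
  if (grepl("^wrist", dof)) dyn$wrist
  else if (grepl("^(mcp|pip|dip|mp1|ip1)", dof)) dyn$mcp
  else dyn$default
}
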