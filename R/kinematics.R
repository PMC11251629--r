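#' Muscle model accessors
#'
#' The default muscle set covers the superficial forearm muscles (ECRB,
#' ECRL, ED, ECU, FCU ulnar and humeral heads, FDS, PL, FCR) with constant
#' signed moment arms, rigid-tendon lengths and cylindrical territory
#' geometry. See [default_config()] for the values.
#'
#' @param config configuration list.
#' @return `muscle_set` returns the named list of muscle models;
#'   `get_muscle` one muscle by name.
#' @export
muscle_set <- function(config = default_config()) config$muscles

#' @rdname muscle_set
#' @param name muscle name.
#' @export
get_muscle <- function(name, config = default_config()) {
  m <- config$muscles[[name]]
  if (is.null(m)) stop("unknown muscle: '", name, "'", call. = FALSE)
  m
}

#' Normalised muscle fibre length during a movement
#'
#' Deduces the fibre-length trajectory of one muscle under the rigid-tendon
#' assumption: with constant moment arms the musculotendon length is affine
#' in the joint angles,
#' `L_mt(t) = L_mt0 - sum_d r_d * (q_d(t) - q0_d)` (angles in radians inside
#' the sum), and the fibre length is the musculotendon length minus the
#' constant tendon slack length. At the neutral posture
#' `L_mt0 = tendon_slack_length + optimal_fibre_length`, so the neutral
#' normalised length is 1. The result is clipped to a physiological band
#' (default `[0.5, 1.5]`); any sample whose unclipped fibre length is
#' non-positive triggers a warning.
#'
#' @param muscle a muscle model (see [get_muscle()]).
#' @param traj a [joint_trajectory()].
#' @param config configuration list.
#' @return a list of class `muscle_trajectory` with fields `muscle`, `time`,
#'   `fibre_length_norm`, and `activation` (NULL until estimated).
#' @export
fibre_length <- function(muscle, traj, config = default_config()) {
  arms <- muscle$moment_arms
  lmt0 <- muscle$tendon_slack_length + muscle$optimal_fibre_length
  dev <- numeric(length(traj$time))
  for (d in names(arms)) {
    if (!d %in% colnames(traj$angles)) next
    q <- traj$angles[, d] * pi / 180 # q0 = 0 at neutral
    dev <- dev + arms[[d]] * q
  }
  lmt <- lmt0 - dev
  lf <- (lmt - muscle$tendon_slack_length) / muscle$optimal_fibre_length
  if (any(lf <= 0)) {
    warning(sprintf("muscle %s: non-positive fibre length at %d sample(s) before clipping",
                    muscle$name, sum(lf <= 0)))
  }
  band <- config$kinematics$fibre_length_band
  lf <- pmin(pmax(lf, band[1]), band[2])
  structure(list(muscle = muscle$name, time = traj$time,
                 fibre_length_norm = lf, activation = NULL),
            class = "muscle_trajectory")
}

# Gaussian force-length factor at normalised fibre length
force_length_factor <- function(lnorm, width) exp(-((lnorm - 1) / width)^2)

#' Joint torque demand from a single-DoF rigid-body model
#'
#' Helper that converts the angle series of one DoF into a torque demand
#' `tau = I*qddot + b*qdot + k*q` (angles in radians). The elastic term `k*q`
#' stands in for the passive/postural load the muscles must hold against, so
#' that slow movements still demand agonist activity in proportion to the
#' joint excursion; inertial and viscous terms dominate only for fast
#' movements. Derivatives use central differences.
#'
#' @param traj a [joint_trajectory()].
#' @param dof DoF name.
#' @param config configuration list.
#' @return numeric torque series (N m) on the trajectory's grid.
#' @export
joint_torque_demand <- function(traj, dof, config = default_config()) {
  par <- dof_dynamics(dof, config)
  q <- traj$angles[, dof] * pi / 180
  n <- length(q)
  if (n < 3) return(par$stiffness * q)
  dt <- 1 / traj$fs_motion
  qd <- c(0, (q[3:n] - q[1:(n - 2)]) / (2 * dt), 0)
  qdd <- c(0, (q[3:n] - 2 * q[2:(n - 1)] + q[1:(n - 2)]) / dt^2, 0)
  par$inertia * qdd + par$damping * qd + par$stiffness * q
}

# Minimise ||a||^2 subject to C a = b, 0 <= a <= 1, via the smooth concave
# dual g(lambda) = lambda'b - sum_i psi(c_i'lambda); a_i = clip(c_i'lambda/2).
solve_min_activation <- function(C, b) {
  n <- ncol(C)
  a_of <- function(lam) pmin(pmax(drop(crossprod(C, lam)) / 2, 0), 1)
  negg <- function(lam) {
    a <- a_of(lam)
    -(sum(lam * b) + sum(a^2 - drop(crossprod(C, lam)) * a))
  }
  grneg <- function(lam) -(b - drop(C %*% a_of(lam)))
  fit <- stats::optim(rep(0, nrow(C)), negg, grneg, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-15))
  a <- a_of(fit$par)
  resid <- drop(C %*% a) - b
  feasible <- max(abs(resid)) <= 1e-6 * max(1, max(abs(b)))
  if (!feasible) {
    # least-squares-closest feasible point within the box
    ls <- stats::optim(a, function(x) sum((drop(C %*% x) - b)^2),
                       function(x) drop(2 * crossprod(C, drop(C %*% x) - b)),
                       method = "L-BFGS-B", lower = 0, upper = 1,
                       control = list(maxit = 500, factr = 1e4))
    a <- ls$par
  }
  list(a = a, feasible = feasible)
}

#' Muscle activations by static optimization
#'
#' At each sample solves the standard static-optimization problem: minimise
#' the sum of squared activations subject to the demanded joint torques being
#' produced, `sum_i a_i * F_max_i * f_L(lnorm_i) * r_id = tau_d` for every
#' demanded DoF `d`, with `0 <= a_i <= 1`. `f_L` is a Gaussian force-length
#' factor `exp(-((lnorm - 1)/w)^2)` with configurable width `w` (default
#' 0.45). Samples whose demand exceeds the muscles' capacity are flagged and
#' return the least-squares-closest feasible activation vector.
#'
#' @param muscles list of muscle models.
#' @param traj a [joint_trajectory()].
#' @param torque_demand named list: DoF name -> torque series (N m) on the
#'   trajectory grid. Defaults to [joint_torque_demand()] on every DoF some
#'   muscle spans and the trajectory moves.
#' @param config configuration list.
#' @return list with `activations` (matrix samples x muscles), `feasible`
#'   (logical per sample) and `dofs` used.
#' @export
static_optimization_activations <- function(muscles, traj,
                                            torque_demand = NULL,
                                            config = default_config()) {
  mnames <- vapply(muscles, `[[`, "", "name")
  spanned <- unique(unlist(lapply(muscles, function(m) names(m$moment_arms))))
  if (is.null(torque_demand)) {
    moved <- colnames(traj$angles)[apply(traj$angles, 2,
                                         function(a) any(a != 0))]
    dofs <- intersect(spanned, moved)
    torque_demand <- lapply(stats::setNames(dofs, dofs), function(d)
      joint_torque_demand(traj, d, config))
  }
  dofs <- names(torque_demand)
  if (!length(dofs)) {
    return(list(activations = matrix(0, length(traj$time), length(muscles),
                                     dimnames = list(NULL, mnames)),
                feasible = rep(TRUE, length(traj$time)), dofs = character()))
  }
  for (d in dofs) {
    if (!any(vapply(muscles, function(m) !is.null(m$moment_arms[[d]]) &&
                      m$moment_arms[[d]] != 0, TRUE))) {
      stop("no muscle spans demanded DoF '", d, "'", call. = FALSE)
    }
  }
  w <- config$kinematics$force_length_width
  lnorm <- vapply(muscles, function(m)
    fibre_length(m, traj, config)$fibre_length_norm,
    numeric(length(traj$time)))
  lnorm <- matrix(lnorm, nrow = length(traj$time))
  arms <- vapply(muscles, function(m) {
    vapply(dofs, function(d) {
      r <- m$moment_arms[[d]]; if (is.null(r)) 0 else r
    }, 0)
  }, numeric(length(dofs)))
  arms <- matrix(arms, nrow = length(dofs),
                 dimnames = list(dofs, mnames))
  fmax <- vapply(muscles, `[[`, 0, "max_isometric_force")
  n <- length(traj$time)
  act <- matrix(0, n, length(muscles), dimnames = list(NULL, mnames))
  feas <- logical(n)
  tau <- do.call(cbind, torque_demand)
  for (t in seq_len(n)) {
    fl <- force_length_factor(lnorm[t, ], w)
    C <- arms * rep(fmax * fl, each = length(dofs))
    sol <- solve_min_activation(C, tau[t, ])
    act[t, ] <- sol$a
    feas[t] <- sol$feasible
  }
  list(activations = act, feasible = feas, dofs = dofs)
}
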