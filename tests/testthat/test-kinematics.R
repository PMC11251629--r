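test_that("pose library has eight poses plus an all-zero neutral", {
  lib <- load_pose_library(cfg)
  expect_length(setdiff(names(lib), "default"), 8)
  expect_true("default" %in% names(lib))
  expect_length(lib$default$angle_map, 0)
  neutral <- resolve_pose("default", lib, cfg)
  expect_true(all(neutral == 0))
  # every pose touches only DoFs in the schema
  for (p in lib) expect_true(all(names(p$angle_map) %in% cfg$dof$names))
})

test_that("combined poses sum their angle maps key-wise", {
  lib <- load_pose_library(cfg)
  comb <- resolve_pose("open+flex", lib, cfg)
  manual <- resolve_pose("open", lib, cfg) + resolve_pose("flex", lib, cfg)
  expect_identical(comb, manual)
  expect_equal(comb[["wrist_flexion"]], 60)
  expect_equal(comb[["mcp2_flexion"]], -30)
  expect_error(resolve_pose("open+nosuch", lib, cfg), "unknown pose")
})

test_that("define_movement interpolates on a uniform grid with exact endpoints", {
  traj <- define_movement(c("default", "flex", "default"), c(1, 1), 50, cfg)
  expect_length(traj$time, 101)
  expect_equal(diff(traj$time), rep(1 / 50, 100))
  wf <- traj$angles[, "wrist_flexion"]
  expect_identical(wf[1], 0)
  expect_identical(wf[51], 60)
  expect_identical(wf[101], 0)
  expect_true(all(diff(wf[1:51]) >= 0))
  expect_true(all(diff(wf[51:101]) <= 0))
  # untouched DoFs stay identically zero
  expect_true(all(traj$angles[, "mcp2_flexion"] == 0))
})

test_that("define_movement between identical poses is constant", {
  traj <- define_movement(c("default", "default"), 2.0, 50, cfg)
  expect_true(all(traj$angles == 0))
  expect_length(traj$time, 101)
})

test_that("open-to-grasp moves finger DoFs, not the wrist", {
  traj <- define_movement(c("open", "grasp"), 1.0, 50, cfg)
  mcp <- traj$angles[, "mcp3_flexion"]
  expect_equal(mcp[1], -30)
  expect_equal(mcp[51], 70)
  # cosine easing: midpoint of the transition is the midpoint of the values
  expect_equal(mcp[26], (70 - 30) / 2, tolerance = 1e-12)
  expect_true(all(traj$angles[, "wrist_flexion"] == 0))
  # linear mode hits the same midpoint and matches direct evaluation
  lin <- define_movement(c("open", "grasp"), 1.0, 50, cfg, interp = "linear")
  expect_equal(lin$angles[, "mcp3_flexion"],
               -30 + (0:50) / 50 * 100, tolerance = 1e-12)
})

test_that("joint-range check reports violations and honours closed intervals", {
  traj <- define_movement(c("default", "flex", "default"), c(1, 1), 50, cfg)
  expect_identical(nrow(check_joint_ranges(traj, cfg)), 0L)
  bad <- traj
  bad$angles[10, "wrist_flexion"] <- 999
  rep <- check_joint_ranges(bad, cfg)
  expect_identical(nrow(rep), 1L)
  expect_identical(rep$dof, "wrist_flexion")
  expect_identical(rep$sample, 10L)
  # boundary value exactly at the limit is compliant
  edge <- flat_traj(set = list(wrist_flexion = 70))
  expect_identical(nrow(check_joint_ranges(edge, cfg)), 0L)
  over <- flat_traj(set = list(wrist_flexion = 70.0001))
  expect_identical(nrow(check_joint_ranges(over, cfg)), 5L)
})

test_that("fibre length is constant at neutral and affine in joint angle", {
  m <- get_muscle("FCU_u", cfg)
  neutral <- flat_traj(n = 20)
  lt <- fibre_length(m, neutral, cfg)
  expect_true(all(lt$fibre_length_norm == lt$fibre_length_norm[1]))
  expect_equal(lt$fibre_length_norm[1], 1)

  # flexor (positive moment arm) shortens monotonically during flexion
  traj <- define_movement(c("default", "flex"), 1, 50, cfg)
  lf <- fibre_length(m, traj, cfg)$fibre_length_norm
  expect_true(all(diff(lf) <= 0))
  expect_lt(lf[51], 1)
  # extensor lengthens, but clipped to the physiological band
  ext <- fibre_length(get_muscle("ECRB", cfg), traj, cfg)$fibre_length_norm
  expect_true(all(diff(ext) >= 0))
  expect_true(all(ext <= cfg$kinematics$fibre_length_band[2]))

  # linearity: doubling the moment arm doubles the deviation from rest
  m2 <- m
  m2$moment_arms$wrist_flexion <- 2 * m$moment_arms$wrist_flexion
  wide <- cfg
  wide$kinematics$fibre_length_band <- c(0.01, 3)
  lf1 <- fibre_length(m, traj, wide)$fibre_length_norm
  lf2 <- fibre_length(m2, traj, wide)$fibre_length_norm
  expect_equal(lf2 - 1, 2 * (lf1 - 1), tolerance = 1e-12)

  # superposition across DoFs
  t_a <- flat_traj(set = list(wrist_flexion = 30))
  t_b <- flat_traj(set = list(wrist_deviation = 20))
  t_ab <- flat_traj(set = list(wrist_flexion = 30, wrist_deviation = 20))
  dev <- function(tr) fibre_length(m, tr, wide)$fibre_length_norm[1] - 1
  expect_equal(dev(t_ab), dev(t_a) + dev(t_b), tolerance = 1e-12)
})

test_that("static optimization solves the activation-sharing problem", {
  m1 <- toy_muscle("m1", r = 0.02)
  traj <- flat_traj(n = 3)

  # zero torque demand -> all activations zero
  sol0 <- static_optimization_activations(list(m1), traj,
    torque_demand = list(wrist_flexion = rep(0, 3)), config = cfg)
  expect_true(all(sol0$activations == 0))
  expect_true(all(sol0$feasible))

  # one muscle, one DoF: closed form a = tau / (F * fL * r)
  tau <- 2.0
  sol1 <- static_optimization_activations(list(m1), traj,
    torque_demand = list(wrist_flexion = rep(tau, 3)), config = cfg)
  a_exp <- tau / (300 * exp(0) * 0.02) # lnorm = 1 at neutral -> fL = 1
  expect_equal(unname(sol1$activations[1, 1]), a_exp, tolerance = 1e-6)

  # two identical muscles share the load equally
  sol2 <- static_optimization_activations(list(m1, toy_muscle("m2", 0.02)),
    traj, torque_demand = list(wrist_flexion = rep(tau, 3)), config = cfg)
  expect_equal(unname(sol2$activations[1, 1]), unname(sol2$activations[1, 2]),
               tolerance = 1e-8)
  expect_equal(unname(sol2$activations[1, 1]), a_exp / 2, tolerance = 1e-6)

  # bounds respected; infeasible demand flagged and saturated
  solx <- static_optimization_activations(list(m1), traj,
    torque_demand = list(wrist_flexion = rep(100, 3)), config = cfg)
  expect_true(all(solx$activations >= 0 & solx$activations <= 1))
  expect_false(any(solx$feasible))
  expect_equal(unname(solx$activations[1, 1]), 1, tolerance = 1e-6)

  expect_error(static_optimization_activations(list(m1), traj,
    torque_demand = list(mcp2_flexion = rep(1, 3)), config = cfg),
    "no muscle spans")
})

test_that("static optimization beats a dense grid search on a 2-muscle problem", {
  mA <- toy_muscle("A", r = 0.015, fmax = 250)
  mB <- toy_muscle("B", r = 0.025, fmax = 350)
  traj <- flat_traj(n = 1)
  tau <- 3.0
  sol <- static_optimization_activations(list(mA, mB), traj,
    torque_demand = list(wrist_flexion = tau), config = cfg)
  cA <- 250 * 0.015; cB <- 350 * 0.025
  # dense grid over feasible (a1, a2) pairs on the constraint line
  a1 <- seq(0, 1, by = 1e-4)
  a2 <- (tau - cA * a1) / cB
  ok <- a2 >= 0 & a2 <= 1
  best <- min(a1[ok]^2 + a2[ok]^2)
  obj <- sum(sol$activations[1, ]^2)
  expect_lte(obj, best + 1e-8)
  expect_equal(unname(cA * sol$activations[1, 1] + cB * sol$activations[1, 2]), tau,
               tolerance = 1e-6)
})

test_that("torque helper combines inertial, viscous and elastic terms", {
  traj <- define_movement(c("default", "flex"), 1, 100, cfg)
  tau <- joint_torque_demand(traj, "wrist_flexion", cfg)
  par <- cfg$dynamics$wrist
  # at the end of the transition velocity and acceleration vanish:
  # torque reduces to the elastic term
  expect_equal(tau[length(tau)], par$stiffness * 60 * pi / 180,
               tolerance = 0.05)
  expect_equal(tau[1], 0, tolerance = 1e-6)
})
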