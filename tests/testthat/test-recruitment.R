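test_that("net joint moments equal the wrench summation and respect symmetry", {
  subj <- mean_male()
  chain <- build_chain(subj, parameter_set("male_base"))
  po <- pose_chain(chain, posture())
  nm <- net_joint_moments(po)
  expect_equal(nm$mx, rep(0, 6), tolerance = 1e-9)
  expect_equal(nm$mz, rep(0, 6), tolerance = 1e-9)

  tp <- task_posture("T10", subj)
  po2 <- pose_chain(chain, tp$posture, tp$load)
  nm2 <- net_joint_moments(po2)
  for (k in seq_len(6)) {
    joint <- nm2$joint[k]
    oracle <- gravity_moment(po2, joint) + hand_load_moment(po2$hand_load, po2, joint)
    expect_equal(as.numeric(nm2[k, c("mx", "my", "mz")]), oracle, tolerance = 1e-9)
  }

  # hand contribution is linear in the load mass
  po5 <- pose_chain(chain, tp$posture, hand_load(5, "bilateral_box"))
  po10 <- pose_chain(chain, tp$posture, hand_load(10, "bilateral_box"))
  h5 <- hand_load_moment(po5$hand_load, po5, "L5-S1")
  h10 <- hand_load_moment(po10$hand_load, po10, "L5-S1")
  expect_equal(h10, 2 * h5, tolerance = 1e-9)
})

test_that("two identical extensors share the demand equally", {
  pr <- single_joint_problem(arms = c(0.05, 0.05), strengths = c(500, 500), demand = 30)
  sol <- solve_recruitment(pr)
  expect_true(sol$feasible)
  expect_equal(sol$forces$force, rep(30 / (2 * 0.05), 2), tolerance = 1e-4)
})

test_that("the cubic objective recruits in proportion to strength^(3/2) and arm^(1/2)", {
  # equal arms, strengths 4:1 -> force ratio 8
  pr <- single_joint_problem(arms = c(0.05, 0.05), strengths = c(800, 200), demand = 20)
  sol <- solve_recruitment(pr)
  f <- sol$forces$force
  expect_equal(f[1] / f[2], 8, tolerance = 1e-3)

  # different arms: f_i proportional to N_i^{3/2} r_i^{1/2}
  arms <- c(0.06, 0.035); strengths <- c(700, 450)
  pr2 <- single_joint_problem(arms, strengths, demand = 25)
  sol2 <- solve_recruitment(pr2)
  f2 <- sol2$forces$force
  pred <- strengths^1.5 * arms^0.5
  expect_equal(f2[1] / f2[2], pred[1] / pred[2], tolerance = 1e-3)
})

test_that("random single-joint problems match the grid-search oracle", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(2:4, 1)
    arms <- runif(n, 0.02, 0.08)
    strengths <- runif(n, 200, 900)
    capacity <- sum(arms * strengths)
    demand <- runif(1, 0.1, 0.8) * capacity
    pr <- single_joint_problem(arms, strengths, demand)
    sol <- solve_recruitment(pr)
    expect_true(sol$feasible)
    oracle <- grid_oracle(arms, strengths, demand, grid_n = if (n <= 3) 201 else 41)
    expect_lte(sol$objective, oracle * 1.001)
    # equality within solver tolerance
    expect_lt(max(sol$residuals$norm), 1e-6 * max(1, demand))
  }
})

test_that("demand beyond total capacity is reported infeasible with the violated joint", {
  pr <- single_joint_problem(arms = c(0.05, 0.04), strengths = c(500, 300), demand = 100)
  sol <- solve_recruitment(pr)
  expect_false(sol$feasible)
  expect_match(sol$infeasibility, "L5-S1")
  expect_match(sol$infeasibility, "flexion")
})

test_that("solving is deterministic", {
  subj <- mean_female()
  chain <- build_chain(subj, parameter_set("female_base"))
  tp <- task_posture("T9", subj)
  po <- pose_chain(chain, tp$posture, tp$load)
  pr <- recruitment_problem(po)
  s1 <- solve_recruitment(pr)
  s2 <- solve_recruitment(pr)
  expect_identical(s1$forces$force, s2$forces$force)
  expect_identical(s1$iap_kpa, s2$iap_kpa)
})

test_that("L5-S1 loads reduce to the static column when no muscle acts", {
  subj <- mean_male()
  chain <- build_chain(subj, parameter_set("male_base"))
  po <- pose_chain(chain, posture())
  pr <- recruitment_problem(po)
  sol <- solve_recruitment(pr)

  # fake a solution with zero muscle forces
  sol0 <- sol
  sol0$forces$force <- rep(0, nrow(sol0$forces))
  loads0 <- l5s1_loads(sol0, po)
  above <- po$bodies[po$bodies$above_joint <= 6, ]
  W <- sum(above$mass) * 9.81
  expect_equal(loads0$compression, W, tolerance = 1e-9)
  expect_equal(loads0$resultant_shear, 0, tolerance = 1e-9)

  # one purely axial extensor force adds collinearly
  sol1 <- sol0
  i <- match("longissimus_pars_lumborum_left", sol1$forces$fascicle)
  sol1$forces$force[i] <- 100
  loads1 <- l5s1_loads(sol1, po)
  # the fascicle is near-vertical: compression rises by almost the full force
  expect_gt(loads1$compression - W, 95)
  expect_lte(loads1$compression - W, 100 + 1e-9)

  # symmetric task: mediolateral shear vanishes, resultant equals |AP|
  tp <- task_posture("T7", subj)
  po7 <- pose_chain(chain, tp$posture, tp$load)
  res7 <- solve_posed(po7)
  expect_lt(abs(res7$loads$ml_shear), 1e-6)
  expect_equal(res7$loads$resultant_shear, abs(res7$loads$ap_shear), tolerance = 1e-9)
})

test_that("body-weight normalization is exact", {
  expect_equal(normalize_bw(77.3 * 9.81, 77.3), 100)
  expect_equal(normalize_bw(0, 60), 0)
  expect_equal(normalize_bw(758.3, 77.3), 100, tolerance = 1e-4)
  expect_error(normalize_bw(100, 0), "positive")
})

test_that("compression grows with hand mass and anterior offset at fixed posture", {
  subj <- mean_male()
  chain <- build_chain(subj, parameter_set("male_base"))
  p <- posture(trunk_rotation = c(20, 0, 0),
               hand_positions = rbind(c(0.3, 0.15, -0.1), c(0.3, -0.15, -0.1)))
  comps_mass <- vapply(c(0, 5, 10, 15), function(m) {
    po <- pose_chain(chain, p, if (m > 0) hand_load(m, "bilateral_box"))
    solve_posed(po)$loads$compression
  }, numeric(1))
  expect_true(all(diff(comps_mass) > 0))

  comps_offset <- vapply(c(0.15, 0.25, 0.35, 0.45), function(ant) {
    p2 <- posture(trunk_rotation = c(20, 0, 0),
                  hand_positions = rbind(c(ant, 0.15, -0.1), c(ant, -0.15, -0.1)))
    po <- pose_chain(chain, p2, hand_load(10, "bilateral_box"))
    solve_posed(po)$loads$compression
  }, numeric(1))
  expect_true(all(diff(comps_offset) > 0))
})

test_that("female-specific parameters lower compression in flexed symmetric tasks", {
  subj <- mean_female()
  scale <- length_mass_fat_scale(subj)
  for (task in c("T2", "T10")) {
    tp <- task_posture(task, subj)
    base <- solve_posed(pose_chain(build_chain(subj, parameter_set("female_base", strength_scale = scale)),
                                   tp$posture, tp$load))
    spec <- solve_posed(pose_chain(build_chain(subj, parameter_set("female_specific", strength_scale = scale)),
                                   tp$posture, tp$load))
    expect_true(base$solution$feasible && spec$solution$feasible)
    expect_lt(spec$loads$compression, base$loads$compression)
  }
})
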