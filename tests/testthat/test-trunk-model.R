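test_that("the chain scales with stature and carries the variant masses", {
  subj <- mean_male()
  chain <- build_chain(subj, parameter_set("male_base"))
  geo <- load_geometry()

  lumbar_len <- sum(chain$segments$length[chain$segments$name != "thorax"])
  expect_equal(lumbar_len, geo$segments$lumbar_total_length * subj$stature, tolerance = 1e-12)

  expect_equal(nrow(chain$segments), 6)           # L5..L1 + thorax: 6 internal joints
  expect_equal(length(LUMBAR_JOINTS <- c("T12-L1", "L1-L2", "L2-L3", "L3-L4", "L4-L5", "L5-S1")), 6)

  masses <- segment_masses(load_mass_distribution("male_base"), subj$mass)
  expect_equal(sum(chain$segments$mass[chain$segments$name != "thorax"]),
               masses$mass[masses$segment == "lumbar"], tolerance = 1e-12)
  expect_equal(chain$head_mass, masses$mass[masses$segment == "head"])
  expect_true(all(chain$fascicles$strength > 0))
})

test_that("neutral posing reproduces configuration offsets; posing is deterministic", {
  subj <- mean_male()
  chain <- build_chain(subj, parameter_set("male_base"))
  po <- pose_chain(chain, posture())
  # joint centres stack vertically from the origin in neutral posture
  expect_equal(unname(po$joint_centers["L5-S1", ]), c(0, 0, 0))
  expect_equal(unname(po$joint_centers["T12-L1", 3]), 5 * chain$vert_len, tolerance = 1e-12)
  expect_equal(unname(po$joint_centers["T12-L1", 1:2]), c(0, 0), tolerance = 1e-12)

  po2 <- pose_chain(chain, posture())
  expect_identical(po$bodies, po2$bodies)
  expect_identical(po$fascicles$path_world, po2$fascicles$path_world)
})

test_that("a single-joint 90 degree flexion rotates the distal chain as computed by hand", {
  subj <- mean_male()
  chain <- build_chain(subj, parameter_set("male_base"))
  jr <- distribute_lumbar_rotation(c(0, 0, 0))
  jr$flexion[jr$joint == "L5-S1"] <- 90
  p <- posture(trunk_rotation = c(90, 0, 0), joint_rotations = jr)
  po <- pose_chain(chain, p)
  # everything above L5-S1 rotates 90 deg about y: +z offsets become +x
  expect_equal(unname(po$joint_centers["L4-L5", ]), c(chain$vert_len, 0, 0), tolerance = 1e-9)
  expect_equal(unname(po$joint_centers["T12-L1", ]), c(5 * chain$vert_len, 0, 0), tolerance = 1e-9)
})

test_that("posing round-trips every joint rotation through the posed frames", {
  subj <- mean_male()
  chain <- build_chain(subj, parameter_set("male_base"))
  seg_parent <- c(L5 = "pelvis", L4 = "L5", L3 = "L4", L2 = "L3", L1 = "L2", thorax = "L1")
  joint_of <- c(L5 = "L5-S1", L4 = "L4-L5", L3 = "L3-L4", L2 = "L2-L3",
                L1 = "L1-L2", thorax = "T12-L1")
  for (tr in list(c(30, 0, 0), c(20, 8, -10))) {
    p <- posture(trunk_rotation = tr, pelvis_rotation = c(12, 0, 0))
    po <- pose_chain(chain, p)
    for (seg in names(seg_parent)) {
      R_rel <- t(po$frames[[seg_parent[[seg]]]]) %*% po$frames[[seg]]
      rec <- matrix_to_euler(R_rel)
      jr <- p$joint_rotations
      k <- match(joint_of[[seg]], jr$joint)
      expect_equal(rec, as.numeric(jr[k, c("flexion", "lateral", "axial")]),
                   tolerance = 1e-9)
    }
    # single-plane totals also round-trip through the thorax frame
    if (tr[2] == 0 && tr[3] == 0) {
      rec_tot <- trunk_pelvis_rotation(po$frames$thorax, po$frames$pelvis)
      expect_equal(rec_tot$flexion, tr[1], tolerance = 1e-9)
    }
  }
})

test_that("moment arms match the tendon-excursion finite-difference oracle", {
  subj <- mean_male()
  chain <- build_chain(subj, parameter_set("male_base"))
  postures <- list(
    posture(),
    posture(trunk_rotation = c(30, 0, 0), pelvis_rotation = c(20, 0, 0)),
    posture(trunk_rotation = c(10, 8, -10))
  )
  for (p in postures) {
    po <- pose_chain(chain, p)
    for (joint in c("L5-S1", "L3-L4", "T12-L1")) {
      R <- moment_arm_matrix(po, joint)
      jr <- p$joint_rotations
      k <- match(joint, jr$joint)
      ki <- match(joint, rownames(po$joint_centers))
      # world axes of the joint's intrinsic flexion/lateral/axial rotations
      seg_above <- chain$segments$name[7 - ki]
      below <- c(pelvis = "pelvis", L5 = "pelvis", L4 = "L5", L3 = "L4", L2 = "L3",
                 L1 = "L2", thorax = "L1")[[seg_above]]
      R_par <- po$frames[[below]]
      ang <- as.numeric(jr[k, c("flexion", "lateral", "axial")])
      axes <- list(
        R_par %*% c(0, 1, 0),
        R_par %*% spineload:::rot_y(ang[1]) %*% c(1, 0, 0),
        R_par %*% spineload:::rot_y(ang[1]) %*% spineload:::rot_x(ang[2]) %*% c(0, 0, 1)
      )
      for (fid in c("multifidus_L3_left", "longissimus_pars_thoracis_right",
                    "rectus_abdominis_left", "internal_oblique_anterior_right")) {
        i <- match(fid, po$fascicles$fascicle)
        if (all(R[i, ] == 0)) next
        for (axis in 1:3) {
          oracle <- excursion_arm(chain, p, NULL, fid, joint, axis)
          expect_equal(sum(R[i, ] * axes[[axis]]), oracle, tolerance = 1e-4)
        }
      }
    }
  }
})

test_that("gravity moments match a brute-force summation oracle and scale linearly", {
  subj <- mean_male()
  chain <- build_chain(subj, parameter_set("male_base"))
  p <- posture(trunk_rotation = c(35, 5, 0), pelvis_rotation = c(25, 0, 0))
  po <- pose_chain(chain, p)
  for (joint in c("L5-S1", "L2-L3")) {
    k <- match(joint, rownames(po$joint_centers))
    c_j <- po$joint_centers[k, ]
    above <- po$bodies[po$bodies$above_joint <= k, ]
    oracle <- c(0, 0, 0)
    for (i in seq_len(nrow(above))) {
      r <- c(above$x[i], above$y[i], above$z[i]) - c_j
      f <- c(0, 0, -9.81 * above$mass[i])
      oracle <- oracle + c(r[2] * f[3] - r[3] * f[2], r[3] * f[1] - r[1] * f[3],
                           r[1] * f[2] - r[2] * f[1])
    }
    expect_equal(gravity_moment(po, joint), oracle, tolerance = 1e-9)
  }
  # linear in g via masses: a chain at double body mass doubles the moment
  subj2 <- subj
  subj2$mass <- subj$mass * 2
  chain2 <- build_chain(subj2, parameter_set("male_base"))
  po2 <- pose_chain(chain2, p)
  expect_equal(gravity_moment(po2, "L5-S1"), 2 * gravity_moment(po, "L5-S1"),
               tolerance = 1e-9)
})

test_that("hand-load moments follow the cross product and split conventions", {
  subj <- mean_male()
  chain <- build_chain(subj, parameter_set("male_base"))
  # load directly above the joint: no moment
  p0 <- posture(hand_positions = rbind(c(0, 0.1, 0.3), c(0, -0.1, 0.3)))
  po0 <- pose_chain(chain, p0, hand_load(10, "bilateral_box"))
  expect_equal(hand_load_moment(po0$hand_load, po0, "L5-S1")[2], 0, tolerance = 1e-9)

  # 10 kg at 0.40 m anterior: 39.24 N*m flexion
  p1 <- posture(hand_positions = rbind(c(0.40, 0.1, 0.1), c(0.40, -0.1, 0.1)))
  po1 <- pose_chain(chain, p1, hand_load(10, "bilateral_box"))
  expect_equal(hand_load_moment(po1$hand_load, po1, "L5-S1")[2], 10 * 9.81 * 0.40,
               tolerance = 1e-9)

  # unilateral 10 kg at 0.20 m lateral: pure lateral-bend moment, cross-product oracle
  p2 <- posture(hand_positions = rbind(c(0, 0.5, 0.1), c(0, -0.20, 0.1)))
  po2 <- pose_chain(chain, p2, hand_load(10, "unilateral", side = "right"))
  m <- hand_load_moment(po2$hand_load, po2, "L5-S1")
  oracle <- c((-0.20) * (-10 * 9.81), 0.1 * 0 - 0 * 0, 0) # r x (0,0,-mg)
  expect_equal(m[1], oracle[1], tolerance = 1e-9)
  expect_equal(abs(m[1]), 19.62, tolerance = 1e-9)
  expect_equal(m[2], 0, tolerance = 1e-9)
})

test_that("intra-abdominal pressure moment is capped at 26.6 kPa", {
  cfg <- list(max_pressure_kpa = 26.6, effective_area = 0.01, lever_arm = 0.05)
  expect_equal(iap_extensor_moment(0, cfg), 0)
  expect_equal(iap_extensor_moment(10, cfg), 5.0)
  expect_equal(iap_extensor_moment(40, cfg), iap_extensor_moment(26.6, cfg))
  expect_error(iap_extensor_moment(-1, cfg), "nonnegative")
})

test_that("passive joint moments are linear and oppose rotation", {
  expect_equal(passive_joint_moment(c(0, 0, 0), c(1, 1, 1)), c(0, 0, 0))
  m1 <- passive_joint_moment(c(10, 0, 0), c(0.5, 0.5, 0.5))
  expect_equal(m1[1], -5)
  expect_equal(passive_joint_moment(c(20, 0, 0), c(0.5, 0.5, 0.5))[1], 2 * m1[1])
  expect_error(passive_joint_moment(c(1, 1, 1), c(-1, 0, 0)), "nonnegative")
})

test_that("symmetric posture and load leave no out-of-plane moments", {
  subj <- mean_male()
  chain <- build_chain(subj, parameter_set("male_base"))
  tp <- task_posture("T6", subj)
  po <- pose_chain(chain, tp$posture, tp$load)
  for (joint in c("T12-L1", "L3-L4", "L5-S1")) {
    m <- gravity_moment(po, joint) + hand_load_moment(po$hand_load, po, joint)
    expect_lt(abs(m[1]), 1e-9)
    expect_lt(abs(m[3]), 1e-9)
  }
})
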