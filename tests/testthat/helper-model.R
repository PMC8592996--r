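# shared fixture builders (all generated in code, nothing stored on disk)

mean_male <- function() {
  dplyr::bind_cols(tibble::tibble(id = "m_ref"),
                   subject_profile("male", 1.769, 77.3, 33))
}

mean_female <- function() {
  dplyr::bind_cols(tibble::tibble(id = "f_ref"),
                   subject_profile("female", 1.685, 56.4, 31.9))
}

sine_ts <- function(freq, rate, duration = 4, amplitude = 1) {
  t <- seq(0, duration, by = 1 / rate)
  timeseries(data.frame(x = amplitude * sin(2 * pi * freq * t)), rate)
}

# mid-section amplitude of a channel (avoids filter edge transients)
mid_amplitude <- function(x) {
  n <- length(x)
  idx <- seq(floor(n / 4), ceiling(3 * n / 4))
  (max(x[idx]) - min(x[idx])) / 2
}

# a single-joint recruitment problem embedded in the full 18-row layout:
# all moment arms act about the flexion (y) axis of L5-S1
single_joint_problem <- function(arms, strengths, demand) {
  n <- length(arms)
  stopifnot(length(strengths) == n)
  B <- matrix(0, 18, n + 1)
  B[17, 1:n] <- arms * strengths
  b <- numeric(18)
  b[17] <- demand
  structure(
    list(B = B, b = b,
         fascicles = tibble::tibble(
           fascicle = paste0("m", seq_len(n)), muscle = paste0("m", seq_len(n)),
           source = "test", group = "local", side = "left", strength = strengths),
         strengths = strengths, iap_max = 0, iap_col_unit = 0, external = NULL),
    class = c("spineload_problem", "list"))
}

# exhaustive grid-search oracle for a single-joint problem: grid over the
# first n-1 activities, solve the last one from the equality exactly
grid_oracle <- function(arms, strengths, demand, grid_n = 41) {
  n <- length(arms)
  r <- arms * strengths
  if (n == 1) {
    a <- demand / r
    if (a < -1e-9 || a > 1 + 1e-9) return(Inf)
    return(a^3)
  }
  g <- seq(0, 1, length.out = grid_n)
  grid <- as.matrix(expand.grid(rep(list(g), n - 1)))
  a_last <- (demand - grid %*% r[-n]) / r[n]
  ok <- a_last >= -1e-12 & a_last <= 1 + 1e-12
  if (!any(ok)) return(Inf)
  obj <- rowSums(grid[ok, , drop = FALSE]^3) + pmax(a_last[ok], 0)^3
  min(obj)
}

# tendon-excursion oracle: moment arm about world axis e at a joint equals
# -dL/dtheta for a rotation of everything above the joint about e
excursion_arm <- function(chain, posture_obj, load, fascicle_id, joint, axis, h = 1e-5) {
  path_len <- function(delta) {
    jr <- posture_obj$joint_rotations
    k <- match(joint, jr$joint)
    jr2 <- jr
    plane <- c("flexion", "lateral", "axial")[axis]
    jr2[[plane]][k] <- jr2[[plane]][k] + delta
    tr <- posture_obj$trunk_rotation
    tr[axis] <- tr[axis] + delta
    p2 <- posture(trunk_rotation = tr, pelvis_rotation = posture_obj$pelvis_rotation,
                  joint_rotations = jr2, hand_positions = posture_obj$hand_positions)
    po <- pose_chain(chain, p2, load)
    w <- po$fascicles$path_world[[match(fascicle_id, po$fascicles$fascicle)]]
    sum(sqrt(rowSums(diff(w)^2)))
  }
  -(path_len(h) - path_len(-h)) / (2 * h) * 180 / pi
}
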