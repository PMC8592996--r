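# Rigid-body trunk chain: pelvis, L5..L1, thorax (7 bodies, 6 spherical
# joints), with head and arms carried as massed appendages of the thorax.
# Coordinates: x anterior, y left, z superior; origin at the L5-S1 joint.
#
# Fascicles are piecewise-straight paths of segment-anchored points.
# Spine-following fascicles (erector spinae, multifidus, quadratus lumborum,
# psoas) carry one via point per intermediate vertebra so that their moment
# arms track the curving spine instead of collapsing onto the pelvis-thorax
# chord in flexed postures. Via points are rigidly segment-fixed (no sliding).

LUMBAR_JOINTS <- c("T12-L1", "L1-L2", "L2-L3", "L3-L4", "L4-L5", "L5-S1")
LUMBAR_SEGMENTS <- c("L5", "L4", "L3", "L2", "L1")
SEGMENT_LEVEL <- c(pelvis = 0, L5 = 1, L4 = 2, L3 = 3, L2 = 4, L1 = 5, thorax = 6)

# Table-row muscle group feeding each fascicle
FASCICLE_SOURCE <- c(
  multifidus = "multifidus",
  rotatores = "multifidus",
  longissimus_pars_lumborum = "erector_spinae",
  iliocostalis_pars_lumborum = "erector_spinae",
  quadratus_lumborum = "quadratus_lumborum",
  psoas_major = "psoas_major",
  iliocostalis_pars_thoracis = "erector_spinae",
  longissimus_pars_thoracis = "erector_spinae",
  rectus_abdominis = "rectus_abdominis",
  external_oblique = "external_oblique",
  internal_oblique = "internal_oblique"
)

anchor_vec <- function(a, stature, default_z = NA_real_) {
  z <- if (is.null(a$z)) default_z else a$z * stature
  c(a$x * stature, a$y * stature, z)
}

# one named fascicle (possibly fanned per superior level), both sides
build_one_fascicle <- function(nm, fan_tag, cfg, src, frac, params,
                               pcsa_of, stature, vert_len) {
  levels <- if (!is.null(cfg$levels)) cfg$levels else
    setNames(list(1), cfg$superior_segment %||%
               abort(paste0("fascicle '", nm, "' lacks superior_segment or levels")))
  purrr::map_dfr(names(levels), function(lvl) {
    pcsa <- pcsa_of(src) * frac * (cfg$source_fraction %||% 1) * levels[[lvl]]
    cfg_lvl <- cfg
    cfg_lvl$superior_segment <- lvl
    if (isTRUE(cfg$one_level)) {
      # segmental muscle: spans exactly the joint below its superior level
      cfg_lvl$inferior_segment <- names(SEGMENT_LEVEL)[SEGMENT_LEVEL[[lvl]]]
      if (cfg_lvl$inferior_segment != "pelvis") cfg_lvl$inferior$z <- NULL
    }
    lvl_tag <- if (length(levels) > 1) paste0("_", lvl) else ""
    purrr::map_dfr(c("left", "right"), function(side) {
      mirror <- if (side == "left") 1 else -1
      path <- fascicle_path(cfg_lvl, stature, vert_len, mirror)
      tibble::tibble(
        fascicle = paste0(nm, fan_tag, lvl_tag, "_", side),
        muscle = nm, source = src,
        group = cfg$group, side = side,
        pcsa = pcsa,
        strength = muscle_strength(pcsa, params$specific_tension, params$strength_scale),
        sup_segment = lvl,
        crosses_from = 7 - SEGMENT_LEVEL[[lvl]],
        path = list(path)
      )
    })
  })
}

# build the local-coordinates path (segment, x, y, z) of one fascicle side
fascicle_path <- function(cfg, stature, vert_len, mirror) {
  inf_seg <- cfg$inferior_segment %||% "pelvis"
  inf_default_z <- if (inf_seg == "pelvis") NA_real_ else vert_len / 2
  inf <- anchor_vec(cfg$inferior, stature, default_z = inf_default_z)
  sup_seg <- cfg$superior_segment
  sup_level <- SEGMENT_LEVEL[[sup_seg]]
  inf_level <- SEGMENT_LEVEL[[inf_seg]]
  sup <- anchor_vec(cfg$superior, stature, default_z = vert_len / 2)
  pts <- list(list(segment = inf_seg, p = inf))
  if (isTRUE(cfg$follow_spine) && sup_level - inf_level > 1) {
    n_span <- sup_level - inf_level
    for (lvl in seq_len(n_span - 1)) {
      frac <- lvl / n_span
      xy <- inf[1:2] + frac * (sup[1:2] - inf[1:2])
      pts[[length(pts) + 1]] <- list(segment = names(SEGMENT_LEVEL)[inf_level + lvl + 1],
                                     p = c(xy, vert_len / 2))
    }
  }
  pts[[length(pts) + 1]] <- list(segment = sup_seg, p = sup)
  purrr::map_dfr(pts, function(q) tibble::tibble(
    segment = q$segment, x = q$p[1], y = mirror * q$p[2], z = q$p[3]
  ))
}

#' Build the rigid-body trunk chain for one subject and parameter set
#'
#' Scales segment lengths by stature, assigns segment masses from the
#' variant's mass-fraction table (the lumbar mass is split equally over the
#' five lumbar vertebrae), and instantiates the bilateral fascicle set with
#' strengths `pcsa * specific_tension * strength_scale`. The erector spinae
#' PCSA is divided over its four fascicles by the configured split.
#'
#' @param subject One-row subject tibble from [subject_profile()].
#' @param params Parameter set from [parameter_set()].
#' @param geometry Geometry config from [load_geometry()].
#' @return A `spineload_chain` list.
#' @export
build_chain <- function(subject, params, geometry = load_geometry()) {
  stopifnot(inherits(params, "spineload_parameter_set"))
  stature <- subject$stature[1]
  seg_cfg <- geometry$segments
  lumbar_len <- seg_cfg$lumbar_total_length * stature
  vert_len <- lumbar_len / 5
  thorax_len <- seg_cfg$thorax_length * stature

  masses <- segment_masses(params$mass_table, subject$mass[1])
  mass_of <- function(s) masses$mass[masses$segment == s]

  segments <- tibble::tibble(
    name = c(LUMBAR_SEGMENTS, "thorax"),
    length = c(rep(vert_len, 5), thorax_len),
    mass = c(rep(mass_of("lumbar") / 5, 5), mass_of("thorax")),
    com_x = c(rep(seg_cfg$lumbar_com$x * stature, 5), seg_cfg$thorax_com$x * stature),
    com_z = c(rep(vert_len / 2, 5), seg_cfg$thorax_com$z_frac_of_length * thorax_len)
  )

  pcsa_of <- function(muscle) params$pcsa_table$pcsa[params$pcsa_table$muscle == muscle]
  fas_names <- names(geometry$fascicles)
  missing <- setdiff(fas_names, names(FASCICLE_SOURCE))
  if (length(missing) > 0) {
    abort(paste0("geometry defines unknown fascicle(s): ", paste(missing, collapse = ", ")))
  }

  fascicles <- purrr::map_dfr(fas_names, function(nm) {
    cfg0 <- geometry$fascicles[[nm]]
    src <- FASCICLE_SOURCE[[nm]]
    es_frac <- if (src == "erector_spinae") params$es_split[[nm]] %||% 0.25 else 1
    # broad sheet muscles may fan into sub-fascicles with their own anchors
    fans <- if (!is.null(cfg0$fans)) cfg0$fans else list(main = list(fraction = 1))
    purrr::map_dfr(names(fans), function(fan_nm) {
      fan <- fans[[fan_nm]]
      cfg <- cfg0
      cfg$fans <- NULL
      for (field in c("inferior", "superior", "superior_segment", "levels", "follow_spine")) {
        if (!is.null(fan[[field]])) cfg[[field]] <- fan[[field]]
      }
      fan_frac <- fan$fraction %||% 1
      fan_tag <- if (length(fans) > 1) paste0("_", fan_nm) else ""
      build_one_fascicle(nm, fan_tag, cfg, src, es_frac * fan_frac, params,
                         pcsa_of, stature, vert_len)
    })
  })
  if (any(fascicles$strength <= 0)) abort("all fascicle strengths must be positive")

  iap <- list(
    max_pressure_kpa = geometry$iap$max_pressure_kpa,
    effective_area = geometry$iap$effective_area_frac * stature^2,
    lever_arm = geometry$iap$lever_arm_frac * stature
  )

  structure(
    list(
      subject = subject, params = params, geometry = geometry,
      stature = stature, segments = segments, fascicles = fascicles,
      vert_len = vert_len, thorax_len = thorax_len,
      head_mass = mass_of("head"),
      arm_masses = c(
        upper_arms = mass_of("upper_arms") / 2,
        lower_arms = mass_of("lower_arms") / 2,
        hands = mass_of("hands") / 2
      ),
      shoulder_half_width = seg_cfg$shoulder_half_width * stature,
      head_com_above = seg_cfg$head_com_above_thorax * stature,
      head_com_x = seg_cfg$head_com$x * stature,
      iap = iap,
      stiffness = geometry$joint_stiffness,
      arm_com_fractions = geometry$arm_com_fractions
    ),
    class = c("spineload_chain", "list")
  )
}

#' Construct a posture
#'
#' @param trunk_rotation Length-3 trunk-pelvis rotation (flexion, lateral,
#'   axial) in degrees.
#' @param pelvis_rotation Length-3 pelvis orientation in degrees (same
#'   convention).
#' @param joint_rotations Optional per-joint rotation tibble (from
#'   [distribute_lumbar_rotation()]); derived from `trunk_rotation` and the
#'   default rhythm when omitted.
#' @param hand_positions 2x3 matrix of left/right hand positions (m) in the
#'   pelvis frame, or `NULL`.
#' @param arm_elevation,arm_abduction Arm posture metadata in degrees.
#' @param rhythm Rhythm coefficients used when `joint_rotations` is omitted.
#' @return A `spineload_posture` list.
#' @export
posture <- function(trunk_rotation = c(0, 0, 0), pelvis_rotation = c(0, 0, 0),
                    joint_rotations = NULL, hand_positions = NULL,
                    arm_elevation = 0, arm_abduction = 0,
                    rhythm = lumbar_rhythm_coefficients()) {
  stopifnot(all(is.finite(trunk_rotation)), all(is.finite(pelvis_rotation)))
  if (is.null(joint_rotations)) {
    joint_rotations <- distribute_lumbar_rotation(trunk_rotation, rhythm)
  }
  for (plane in c("flexion", "lateral", "axial")) {
    tot <- trunk_rotation[match(plane, c("flexion", "lateral", "axial"))]
    if (abs(sum(joint_rotations[[plane]]) - tot) > 1e-9) {
      abort("per-plane joint rotations must sum to the total trunk-pelvis rotation")
    }
  }
  if (!is.null(hand_positions)) {
    hand_positions <- matrix(as.numeric(hand_positions), ncol = 3)
  }
  structure(
    list(trunk_rotation = trunk_rotation, pelvis_rotation = pelvis_rotation,
         joint_rotations = joint_rotations, hand_positions = hand_positions,
         arm_elevation = arm_elevation, arm_abduction = arm_abduction),
    class = c("spineload_posture", "list")
  )
}

#' Pose the chain: forward kinematics
#'
#' Composes segment frames by successive intrinsic rotations about the joint
#' centres (caudal to cranial), places fascicle path points, segment centres
#' of mass, head, arms and hand loads in world coordinates. In the neutral
#' posture world positions equal the cumulative configuration offsets.
#'
#' @param chain A `spineload_chain` from [build_chain()].
#' @param posture A `spineload_posture`.
#' @param hand_load Optional [hand_load()] carried in the posture.
#' @return A `spineload_posed` list.
#' @export
pose_chain <- function(chain, posture, hand_load = NULL) {
  stopifnot(inherits(chain, "spineload_chain"), inherits(posture, "spineload_posture"))
  R_pelvis <- euler_to_matrix(posture$pelvis_rotation)

  # joint rotations caudal-to-cranial (L5-S1 first), matching segments L5..thorax
  jr <- posture$joint_rotations
  jr <- jr[match(rev(LUMBAR_JOINTS), jr$joint), ]

  frames <- vector("list", 7)
  names(frames) <- names(SEGMENT_LEVEL)
  frames[["pelvis"]] <- R_pelvis
  origins <- list(pelvis = c(0, 0, 0))
  centers <- matrix(0, 6, 3)
  R_par <- R_pelvis
  c_cur <- c(0, 0, 0)
  for (k in 1:6) {
    centers[k, ] <- c_cur
    seg <- chain$segments$name[k]
    Rk <- R_par %*% euler_to_matrix(as.numeric(jr[k, c("flexion", "lateral", "axial")]))
    frames[[seg]] <- Rk
    origins[[seg]] <- c_cur
    if (k < 6) c_cur <- as.numeric(c_cur + Rk %*% c(0, 0, chain$segments$length[k]))
    R_par <- Rk
  }
  R_thorax <- frames[["thorax"]]
  thorax_origin <- origins[["thorax"]]

  to_world <- function(segment, p_local) {
    as.numeric(origins[[segment]] + frames[[segment]] %*% p_local)
  }

  # segment COMs
  seg_com <- t(vapply(1:6, function(k) {
    to_world(chain$segments$name[k],
             c(chain$segments$com_x[k], 0, chain$segments$com_z[k]))
  }, numeric(3)))
  bodies <- tibble::tibble(
    body = chain$segments$name, mass = chain$segments$mass,
    x = seg_com[, 1], y = seg_com[, 2], z = seg_com[, 3],
    # most cranial joint this body loads (1 = T12-L1 ... 6 = L5-S1)
    above_joint = 7 - (1:6)
  )

  # head
  head_com <- to_world("thorax", c(chain$head_com_x, 0, chain$thorax_len + chain$head_com_above))
  bodies <- dplyr::bind_rows(bodies, tibble::tibble(
    body = "head", mass = chain$head_mass,
    x = head_com[1], y = head_com[2], z = head_com[3], above_joint = 1
  ))

  # hands / arms
  shoulders <- list(
    left = to_world("thorax", c(0, chain$shoulder_half_width, chain$thorax_len)),
    right = to_world("thorax", c(0, -chain$shoulder_half_width, chain$thorax_len))
  )
  hp <- posture$hand_positions
  if (is.null(hp)) {
    # arms hanging: hands straight below the shoulders at 0.33 stature
    hp <- rbind(shoulders$left - c(0, 0, 0.33 * chain$stature),
                shoulders$right - c(0, 0, 0.33 * chain$stature))
  } else {
    hp <- t(apply(hp, 1, function(p) as.numeric(R_pelvis %*% p)))  # pelvis frame -> world
  }
  hands_world <- list(left = hp[1, ], right = hp[2, ])
  arm_frac <- chain$arm_com_fractions
  for (side in c("left", "right")) {
    sh <- shoulders[[side]]
    hd <- hands_world[[side]]
    for (part in c("upper_arms", "lower_arms", "hands")) {
      p <- sh + (hd - sh) * arm_frac[[part]]
      bodies <- dplyr::bind_rows(bodies, tibble::tibble(
        body = paste(part, side, sep = "_"), mass = chain$arm_masses[[part]],
        x = p[1], y = p[2], z = p[3], above_joint = 1
      ))
    }
  }

  # fascicle path points in world coordinates
  fw <- chain$fascicles
  fw$path_world <- lapply(fw$path, function(pa) {
    w <- t(vapply(seq_len(nrow(pa)), function(i) {
      to_world(pa$segment[i], c(pa$x[i], pa$y[i], pa$z[i]))
    }, numeric(3)))
    colnames(w) <- c("x", "y", "z")
    w
  })
  fw$path_level <- lapply(fw$path, function(pa) unname(SEGMENT_LEVEL[pa$segment]))

  joint_centers <- centers[rev(seq_len(6)), , drop = FALSE]
  rownames(joint_centers) <- LUMBAR_JOINTS

  structure(
    list(chain = chain, posture = posture, hand_load = hand_load,
         frames = frames, joint_centers = joint_centers, bodies = bodies,
         fascicles = fw, shoulders = shoulders, hands = hands_world,
         gravity = c(0, 0, -GRAVITY), R_pelvis = R_pelvis,
         iap = chain$iap),
    class = c("spineload_posed", "list")
  )
}

#' Define a hand-held load
#'
#' @param mass Load mass in kg (>= 0).
#' @param attachment `"bilateral_box"`, `"bilateral_dumbbells"` or
#'   `"unilateral"`. Bilateral attachments split the weight 50/50 between the
#'   hands (dumbbells are one per hand); a unilateral load is carried fully
#'   by one hand.
#' @param side For unilateral loads, `"left"` or `"right"`.
#' @return A `spineload_hand_load` list.
#' @export
hand_load <- function(mass, attachment = c("bilateral_box", "bilateral_dumbbells", "unilateral"),
                      side = "right") {
  attachment <- match.arg(attachment)
  if (!is.finite(mass) || mass < 0) abort("hand load mass must be nonnegative")
  structure(list(mass = mass, attachment = attachment, side = side),
            class = c("spineload_hand_load", "list"))
}

# per-hand point masses of a load in a posed model
hand_load_points <- function(load, posed) {
  if (is.null(load) || load$mass == 0) return(NULL)
  if (load$attachment == "unilateral") {
    list(list(mass = load$mass, pos = posed$hands[[load$side]]))
  } else {
    list(list(mass = load$mass / 2, pos = posed$hands$left),
         list(mass = load$mass / 2, pos = posed$hands$right))
  }
}

joint_index <- function(joint) {
  k <- match(joint, LUMBAR_JOINTS)
  if (is.na(k)) abort(paste0("unknown joint '", joint, "'"))
  k
}

# the straight path span of fascicle i crossing joint with cranial index k:
# the consecutive point pair whose levels straddle the joint. Returns NULL
# if the fascicle does not cross the joint.
crossing_span <- function(posed, i, k) {
  lev <- posed$fascicles$path_level[[i]]
  below_level <- 6 - k
  idx <- which(lev <= below_level)
  if (length(idx) == 0) return(NULL)
  a <- max(idx)
  if (a == length(lev)) return(NULL)
  if (lev[a + 1] <= below_level) return(NULL)
  w <- posed$fascicles$path_world[[i]]
  list(lower = w[a, ], upper = w[a + 1, ])
}

#' Gravity moment of the superincumbent bodies about a joint
#'
#' Sum over all segments above the joint (lumbar vertebrae, thorax, head,
#' arm segments) of `(com - joint_center) x m g`. Hand loads are handled by
#' [hand_load_moment()].
#'
#' @param posed A `spineload_posed` model.
#' @param joint Joint name, e.g. `"L5-S1"`.
#' @return Length-3 moment vector, N*m.
#' @export
gravity_moment <- function(posed, joint) {
  k <- joint_index(joint)
  c_j <- posed$joint_centers[k, ]
  above <- posed$bodies[posed$bodies$above_joint <= k, ]
  m <- c(0, 0, 0)
  g <- posed$gravity
  for (i in seq_len(nrow(above))) {
    r <- c(above$x[i], above$y[i], above$z[i]) - c_j
    m <- m + cross3(r, above$mass[i] * g)
  }
  m
}

#' Moment of a hand-held load about a joint
#'
#' @param load A [hand_load()] (a unilateral load must resolve to one hand).
#' @param posed A `spineload_posed` model.
#' @param joint Joint name.
#' @return Length-3 moment vector, N*m.
#' @export
hand_load_moment <- function(load, posed, joint) {
  k <- joint_index(joint)
  c_j <- posed$joint_centers[k, ]
  pts <- hand_load_points(load, posed)
  m <- c(0, 0, 0)
  for (p in pts %||% list()) {
    m <- m + cross3(p$pos - c_j, p$mass * posed$gravity)
  }
  m
}

#' Extension moment generated by intra-abdominal pressure
#'
#' `min(pressure, cap) * effective_area * lever_arm`, with the 26.6 kPa cap
#' always enforced.
#'
#' @param pressure_kpa Abdominal pressure, kPa (>= 0).
#' @param cfg List with `max_pressure_kpa`, `effective_area` (m^2) and
#'   `lever_arm` (m).
#' @return Extension moment magnitude, N*m.
#' @export
iap_extensor_moment <- function(pressure_kpa, cfg) {
  if (!is.finite(pressure_kpa) || pressure_kpa < 0) abort("pressure must be nonnegative")
  min(pressure_kpa, cfg$max_pressure_kpa) * 1000 * cfg$effective_area * cfg$lever_arm
}

#' Linear passive joint moment
#'
#' Per-plane moment `-stiffness * rotation`, opposing the rotation.
#'
#' @param rotation Length-3 joint rotation (flexion, lateral, axial), deg.
#' @param stiffness Length-3 or named stiffness (N*m/deg per plane, >= 0).
#' @return Length-3 moment in plane order (flexion, lateral, axial), N*m.
#' @export
passive_joint_moment <- function(rotation, stiffness) {
  s <- if (is.list(stiffness)) c(stiffness$flexion, stiffness$lateral, stiffness$axial)
       else as.numeric(stiffness)
  if (any(s < 0)) abort("stiffness must be nonnegative")
  -s * rotation
}

#' Fascicle moment-arm matrix at a joint
#'
#' The row of fascicle i is `(upper_point - joint_center) x unit_line`, the
#' moment per newton of fascicle force, where the line is the straight path
#' span crossing the joint (for two-point fascicles, the whole line of
#' action). Fascicles not crossing the joint get zero rows.
#'
#' @param posed A `spineload_posed` model.
#' @param joint Joint name.
#' @return Matrix (fascicles x 3), metres; rownames are fascicle ids.
#' @export
moment_arm_matrix <- function(posed, joint) {
  k <- joint_index(joint)
  c_j <- posed$joint_centers[k, ]
  f <- posed$fascicles
  out <- matrix(0, nrow(f), 3, dimnames = list(f$fascicle, c("x", "y", "z")))
  for (i in seq_len(nrow(f))) {
    span <- crossing_span(posed, i, k)
    if (is.null(span)) next
    d <- span$lower - span$upper
    len <- sqrt(sum(d^2))
    if (len < 1e-9) abort(paste0("degenerate zero-length fascicle span: ", f$fascicle[i]))
    out[i, ] <- cross3(span$upper - c_j, d / len)
  }
  out
}
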