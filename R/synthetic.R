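# Synthetic study generator: subjects from the study's demographic
# distributions, task postures for the twelve static holds, and static
# GRF/EMG recordings with known ground truth, so the whole pipeline can be
# exercised and checked without any recorded data.

# Demographic distributions (mean, sd): stature cm, mass kg, age years.
SUBJECT_DISTRIBUTIONS <- list(
  female = list(stature = c(168.5, 3.5), mass = c(56.4, 4.5), age = c(31.9, 7.6)),
  male = list(stature = c(176.9, 8.8), mass = c(77.3, 9.8), age = c(33.0, 7.4))
)

rtruncnorm3 <- function(n, mean, sd) {
  # normal truncated at +/- 3 sd, by rejection
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[abs(x - mean) <= 3 * sd])
  }
  out[seq_len(n)]
}

#' Sample synthetic subjects
#'
#' Draws stature, mass and age from per-sex truncated normal distributions
#' (truncation at 3 sd) matching the study population, and derives BMI and
#' body-fat fraction.
#'
#' @param n Number of subjects (>= 0).
#' @param sex `"male"` or `"female"`.
#' @param seed Integer seed; same seed gives identical subjects.
#' @param defaults Package defaults list.
#' @return Subject tibble with an `id` column.
#' @export
sample_subjects <- function(n, sex, seed = 1, defaults = spineload_defaults()) {
  if (!sex %in% names(SUBJECT_DISTRIBUTIONS)) abort("sex must be 'male' or 'female'")
  if (n == 0) {
    return(tibble::tibble(id = character(), sex = character(), stature = numeric(),
                          mass = numeric(), age = numeric(), bmi = numeric(),
                          fat_fraction = numeric()))
  }
  d <- SUBJECT_DISTRIBUTIONS[[sex]]
  with_seed(substream_seed(seed, if (sex == "female") 2 else 1), {
    stature <- rtruncnorm3(n, d$stature[1], d$stature[2]) / 100
    mass <- rtruncnorm3(n, d$mass[1], d$mass[2])
    age <- rtruncnorm3(n, d$age[1], d$age[2])
    dplyr::bind_cols(
      tibble::tibble(id = sprintf("%s%02d", substr(sex, 1, 1), seq_len(n))),
      subject_profile(sex, stature, mass, age, defaults = defaults)
    )
  })
}

#' The twelve static load-handling task definitions
#'
#' Reads the shipped task configuration: hand-load spec and quantitative
#' posture template for tasks T1-T12 (upright reference, full flexion,
#' dumbbell holds at three arm positions, box holds at four heights and
#' reaches, one-handed hold, and the twisted hold).
#'
#' @param path Optional alternative YAML task config.
#' @return Tibble of 12 rows; hand-height fractions and the L5-S1 height
#'   fraction are carried in attributes `hand_heights`, `l5s1_height`.
#' @export
task_definitions <- function(path = NULL) {
  cfg <- read_yaml_strict(path %||% spineload_extdata("tasks.yaml"))
  tasks <- purrr::map_dfr(cfg$tasks, function(t) {
    tibble::tibble(
      id = t$id, label = t$label, load_kg = t$load_kg, load_type = t$load_type,
      unilateral = isTRUE(t$unilateral),
      unilateral_side = t$unilateral_side %||% NA_character_,
      trunk_flexion = t$trunk_flexion, trunk_lateral = t$trunk_lateral,
      trunk_axial = t$trunk_axial, pelvis_flexion = t$pelvis_flexion,
      pelvis_lateral = t$pelvis_lateral %||% 0, pelvis_axial = t$pelvis_axial %||% 0,
      arm_elevation = t$arm_elevation, arm_abduction = t$arm_abduction,
      hand_height = t$hand_height, hand_anterior = t$hand_anterior,
      hand_lateral = t$hand_lateral, elbows_extended = isTRUE(t$elbows_extended)
    )
  })
  expected <- paste0("T", 1:12)
  if (!identical(tasks$id, expected)) abort("task config must define exactly tasks T1..T12 in order")
  attr(tasks, "hand_heights") <- cfg$hand_heights
  attr(tasks, "l5s1_height") <- cfg$l5s1_height
  tasks
}

task_row <- function(tasks, id) {
  row <- tasks[tasks$id == id, ]
  if (nrow(row) != 1) abort(paste0("unknown task id '", id, "'"))
  row
}

#' Instantiate a task posture for a subject
#'
#' Fills the task's posture template with the configured angles and places
#' the hands at the task's height class scaled by the subject's stature.
#' Hand targets are defined in world coordinates relative to the L5-S1
#' joint, rotated by the trunk axial rotation (the hands follow the twisted
#' trunk), then stored in the pelvis frame.
#'
#' @param task Task id (e.g. `"T5"`) or a one-row task tibble.
#' @param subject One-row subject tibble.
#' @param tasks Task table from [task_definitions()].
#' @param rhythm Lumbar rhythm coefficients.
#' @return List with elements `posture` ([posture()]), `load`
#'   ([hand_load()] or `NULL`) and `task` (the task row).
#' @export
task_posture <- function(task, subject, tasks = task_definitions(),
                         rhythm = lumbar_rhythm_coefficients()) {
  t <- if (is.character(task)) task_row(tasks, task) else task
  stature <- subject$stature[1]
  heights <- attr(tasks, "hand_heights")
  z_off <- (heights[[t$hand_height]] - attr(tasks, "l5s1_height")) * stature

  lat <- t$hand_lateral * stature
  ant <- t$hand_anterior * stature
  if (t$unilateral) {
    side <- t$unilateral_side
    loaded <- c(ant, lat, z_off)
    free <- c(0.02 * stature, sign(-lat) * 0.10 * stature,
              (heights$thigh - attr(tasks, "l5s1_height")) * stature)
    hp <- if (side == "right") rbind(free, loaded) else rbind(loaded, free)
  } else {
    hp <- rbind(c(ant, abs(lat), z_off), c(ant, -abs(lat), z_off))
  }
  # hands follow the total (pelvis + trunk) axial rotation
  total_axial <- t$trunk_axial + (t$pelvis_axial %||% 0)
  if (abs(total_axial) > 1e-12) {
    Rz <- rot_z(total_axial)
    hp <- t(apply(hp, 1, function(p) as.numeric(Rz %*% p)))
  }
  pelvis_rot <- c(t$pelvis_flexion, t$pelvis_lateral %||% 0, t$pelvis_axial %||% 0)
  R_pelvis <- euler_to_matrix(pelvis_rot)
  hp_pelvis <- t(apply(hp, 1, function(p) as.numeric(t(R_pelvis) %*% p)))

  load <- switch(t$load_type,
    none = NULL,
    dumbbells = hand_load(t$load_kg, "bilateral_dumbbells"),
    box = if (t$unilateral) hand_load(t$load_kg, "unilateral", side = t$unilateral_side)
          else hand_load(t$load_kg, "bilateral_box"),
    abort(paste0("unknown load type '", t$load_type, "'"))
  )
  list(
    posture = posture(
      trunk_rotation = c(t$trunk_flexion, t$trunk_lateral, t$trunk_axial),
      pelvis_rotation = pelvis_rot,
      hand_positions = hp_pelvis,
      arm_elevation = t$arm_elevation, arm_abduction = t$arm_abduction,
      rhythm = rhythm
    ),
    load = load,
    task = t
  )
}

#' Default noise configuration for synthetic trials
#'
#' @param tremor_deg Posture tremor SD, degrees.
#' @param grf_n GRF sensor noise SD, N.
#' @param emg_frac Additive EMG noise SD as a fraction of each channel's
#'   clean-signal RMS.
#' @param mvc_amp MVC-level EMG carrier amplitude (arbitrary units).
#' @return Named list.
#' @export
noise_config <- function(tremor_deg = 0.2, grf_n = 5, emg_frac = 0.05, mvc_amp = 1) {
  list(tremor_deg = tremor_deg, grf_n = grf_n, emg_frac = emg_frac, mvc_amp = mvc_amp)
}

band_carrier <- function(n, rate, defaults) {
  cfg <- defaults$emg
  bf <- signal::butter(cfg$filter_order, cfg$bandpass / (rate / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, rnorm(n)))
}

#' Generate one synthetic static trial with known ground truth
#'
#' Solves the model for the subject and task to obtain ground-truth muscle
#' forces, activities and L5-S1 loads, then emits a 3-s static recording:
#' quasi-constant posture channels (constant plus tremor), ground reaction
#' forces whose vertical sum is the supported weight plus sensor noise, and
#' per-site raw EMG built as a 30-450 Hz band-limited carrier whose
#' amplitude is the site's ground-truth activity times the MVC amplitude,
#' plus additive noise proportional to the clean-signal RMS. MVC trials are
#' generated at activity 1.
#'
#' @param subject One-row subject tibble.
#' @param task Task id or row.
#' @param params Parameter set; defaults to the base variant for the
#'   subject's sex.
#' @param noise Noise configuration from [noise_config()].
#' @param seed Integer seed; trials are bit-identical for identical seeds.
#' @param duration Hold duration, s.
#' @param pad Extra recording time before and after the hold, s (absorbs
#'   zero-lag filter edge transients in downstream processing).
#' @param tasks Task table.
#' @param defaults Package defaults.
#' @return A `spineload_trial` list with `posture_ts`, `grf`, `emg`, `mvc`,
#'   `ground_truth` and the inputs.
#' @export
synth_trial <- function(subject, task, params = NULL, noise = noise_config(),
                        seed = 1, duration = 3, pad = 0.5,
                        tasks = task_definitions(),
                        defaults = spineload_defaults()) {
  t <- if (is.character(task)) task_row(tasks, task) else task
  if (is.null(params)) {
    params <- parameter_set(if (subject$sex[1] == "male") "male_base" else "female_base",
                            defaults = defaults)
  }
  tp <- task_posture(t, subject, tasks)
  chain <- build_chain(subject, params)
  posed <- pose_chain(chain, tp$posture, tp$load)
  res <- solve_posed(posed)
  if (!res$solution$feasible) {
    abort(paste0("task ", t$id, " infeasible for this subject: ",
                 res$solution$infeasibility))
  }
  site_act <- predicted_site_activity(res$solution, defaults = defaults)
  task_idx <- match(t$id, paste0("T", 1:12))

  # posture channels (200 Hz); recordings extend pad s beyond the hold
  total <- duration + 2 * pad
  rate_p <- 200
  n_p <- round(rate_p * total) + 1
  ang <- c(trunk_flexion = t$trunk_flexion, trunk_lateral = t$trunk_lateral,
           trunk_axial = t$trunk_axial, pelvis_flexion = t$pelvis_flexion,
           pelvis_lateral = t$pelvis_lateral %||% 0, pelvis_axial = t$pelvis_axial %||% 0)
  hp <- tp$posture$hand_positions
  hand_ch <- c(hand_left_x = hp[1, 1], hand_left_y = hp[1, 2], hand_left_z = hp[1, 3],
               hand_right_x = hp[2, 1], hand_right_y = hp[2, 2], hand_right_z = hp[2, 3])
  posture_ts <- with_seed(substream_seed(seed, task_idx, 1), {
    m <- cbind(
      sapply(ang, function(a) a + rnorm(n_p, 0, noise$tremor_deg)),
      sapply(hand_ch, function(h) rep(h, n_p))
    )
    timeseries(m, rate_p, labels = c(names(ang), names(hand_ch)))
  })

  # ground reaction forces (1000 Hz): vertical sum = supported weight
  rate_g <- 1000
  n_g <- round(rate_g * total) + 1
  w_total <- (subject$mass[1] + (tp$load$mass %||% 0)) * GRAVITY
  grf <- with_seed(substream_seed(seed, task_idx, 2), {
    m <- cbind(fx = rnorm(n_g, 0, noise$grf_n), fy = rnorm(n_g, 0, noise$grf_n),
               fz = w_total + rnorm(n_g, 0, noise$grf_n))
    timeseries(m, rate_g)
  })

  # raw EMG (2000 Hz): activity-modulated band-limited carrier + noise
  rate_e <- 2000
  n_e <- round(rate_e * total) + 1
  emg <- with_seed(substream_seed(seed, task_idx, 3), {
    m <- sapply(seq_len(nrow(site_act)), function(i) {
      carrier <- band_carrier(n_e, rate_e, defaults)
      clean <- site_act$activity[i] * noise$mvc_amp * carrier / max(sd(carrier), 1e-12)
      clean + rnorm(n_e, 0, noise$emg_frac * sd(clean))
    })
    timeseries(m, rate_e, labels = site_act$site)
  })

  # MVC trials: one recording with every site at activity 1
  mvc <- with_seed(substream_seed(seed, task_idx, 4), {
    m <- sapply(seq_len(nrow(site_act)), function(i) {
      carrier <- band_carrier(n_e, rate_e, defaults)
      noise$mvc_amp * carrier / max(sd(carrier), 1e-12)
    })
    timeseries(m, rate_e, labels = site_act$site)
  })

  structure(
    list(subject = subject, task = t, params_variant = params$variant,
         posture = tp$posture, load = tp$load,
         posture_ts = posture_ts, grf = grf, emg = emg, mvc = mvc,
         ground_truth = list(solution = res$solution, loads = res$loads,
                             site_activity = site_act),
         seed = seed, noise = noise, duration = duration, pad = pad),
    class = c("spineload_trial", "list")
  )
}

#' Run the estimation pipeline on one synthetic trial
#'
#' The inverse path: average the static hold of the posture channels,
#' rebuild the posture and hand placement, pose the model, solve the
#' recruitment, extract L5-S1 loads; process the raw EMG to MVC-normalized
#' envelope means over the hold and report the vertical-GRF consistency
#' check.
#'
#' @param trial A `spineload_trial`.
#' @param params Parameter set (defaults to the variant used to generate).
#' @param defaults Package defaults.
#' @return List with `loads`, `solution`, `posture`, `emg_site_means`,
#'   `predicted_activity`, `grf_residual_n`.
#' @export
process_trial <- function(trial, params = NULL, defaults = spineload_defaults()) {
  if (is.null(params)) params <- parameter_set(trial$params_variant, defaults = defaults)
  pad <- trial$pad %||% 0
  hold <- static_phase_average(trial$posture_ts, pad, trial$duration)
  hp <- rbind(c(hold$hand_left_x, hold$hand_left_y, hold$hand_left_z),
              c(hold$hand_right_x, hold$hand_right_y, hold$hand_right_z))
  post <- posture(
    trunk_rotation = c(hold$trunk_flexion, hold$trunk_lateral, hold$trunk_axial),
    pelvis_rotation = c(hold$pelvis_flexion, hold$pelvis_lateral, hold$pelvis_axial),
    hand_positions = hp,
    arm_elevation = trial$task$arm_elevation, arm_abduction = trial$task$arm_abduction
  )
  chain <- build_chain(trial$subject, params)
  posed <- pose_chain(chain, post, trial$load)
  res <- solve_posed(posed)

  grf_lp <- zero_lag_lowpass(trial$grf, 20)
  grf_mean <- static_phase_average(grf_lp, pad, trial$duration)
  w_total <- (trial$subject$mass[1] + (trial$load$mass %||% 0)) * GRAVITY
  grf_residual <- abs(grf_mean$fz - w_total)

  peaks <- mvc_peaks(trial$mvc, defaults = defaults)
  env <- emg_envelope(trial$emg, peaks, defaults = defaults)
  site_means <- static_phase_average(env, pad, trial$duration) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "site", values_to = "envelope_mean")

  list(loads = res$loads, solution = res$solution, posture = post,
       emg_site_means = site_means,
       predicted_activity = predicted_site_activity(res$solution, defaults = defaults),
       grf_residual_n = grf_residual)
}

#' Write a synthetic trial to a directory
#'
#' Emits `posture.csv`, `grf.csv`, `emg.csv`, `mvc.csv` (rate-headed CSVs),
#' `ground_truth.json` and `manifest.yaml`.
#'
#' @param trial A `spineload_trial`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_series_csv(trial$posture_ts, file.path(dir, "posture.csv"))
  write_series_csv(trial$grf, file.path(dir, "grf.csv"))
  write_series_csv(trial$emg, file.path(dir, "emg.csv"))
  write_series_csv(trial$mvc, file.path(dir, "mvc.csv"))
  gt <- trial$ground_truth
  jsonlite::write_json(list(
    loads = as.list(gt$loads),
    iap_kpa = gt$solution$iap_kpa,
    objective = gt$solution$objective,
    forces = gt$solution$forces,
    site_activity = gt$site_activity
  ), file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(list(
    task = trial$task$id, subject = as.list(trial$subject[1, ]),
    variant = trial$params_variant, seed = trial$seed,
    duration = trial$duration, noise = trial$noise,
    package_version = as.character(utils::packageVersion("spineload"))
  ), file.path(dir, "manifest.yaml"))
  invisible(dir)
}
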