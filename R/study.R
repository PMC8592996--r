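# Study battery: every model variant x task, load aggregation and the
# group comparisons (unpaired male vs female-base, paired female base vs
# specific), plus the per-site EMG correlation table.

#' Run the model battery over subjects, variants and tasks
#'
#' One simulation per model (subject x applicable variant) and task: male
#' subjects run under `male_base`, female subjects under both `female_base`
#' and `female_specific` (same posture and body mass in both, so the paired
#' comparison isolates the parameter tables). Ten male + ten female subjects
#' over the twelve tasks give 360 rows. Infeasible runs are flagged, never
#' dropped.
#'
#' @param subjects Subject tibble with `id` (e.g. from [sample_subjects()]).
#' @param variants Character vector of variants to run.
#' @param tasks Task table from [task_definitions()].
#' @param seed Integer seed recorded with the result (the battery itself is
#'   deterministic).
#' @param scale_strength Apply the length-mass-fat strength scale per
#'   subject (default TRUE).
#' @param defaults Package defaults.
#' @return A `spineload_battery` tibble: one row per model x task with
#'   L5-S1 loads (N and %BW) and per-muscle forces (%BW, mean of sides).
#' @export
run_battery <- function(subjects,
                        variants = c("male_base", "female_base", "female_specific"),
                        tasks = task_definitions(), seed = 1,
                        scale_strength = TRUE,
                        defaults = spineload_defaults()) {
  variants <- vapply(variants, match_variant, character(1))
  rhythm <- lumbar_rhythm_coefficients(defaults = defaults)
  rows <- list()
  for (si in seq_len(nrow(subjects))) {
    subj <- subjects[si, ]
    subj_variants <- if (subj$sex == "male") intersect(variants, "male_base")
                     else intersect(variants, c("female_base", "female_specific"))
    if (length(subj_variants) == 0) next
    postures <- lapply(tasks$id, function(id) task_posture(id, subj, tasks, rhythm = rhythm))
    names(postures) <- tasks$id
    for (variant in subj_variants) {
      scale <- if (scale_strength) length_mass_fat_scale(subj, defaults = defaults) else 1
      params <- parameter_set(variant, strength_scale = scale, defaults = defaults)
      chain <- build_chain(subj, params)
      for (id in tasks$id) {
        tp <- postures[[id]]
        posed <- pose_chain(chain, tp$posture, tp$load)
        res <- solve_posed(posed)
        sol <- res$solution
        muscle_bw <- sol$forces |>
          dplyr::summarise(force = mean(.data$force), .by = "muscle") |>
          tidyr::pivot_wider(names_from = "muscle", values_from = "force",
                             names_prefix = "force_bw_")
        muscle_bw[] <- lapply(muscle_bw, normalize_bw, body_mass = subj$mass)
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          tibble::tibble(
            model_id = paste(subj$id, variant, sep = "/"), subject_id = subj$id,
            sex = subj$sex, variant = variant, task = id,
            body_mass = subj$mass, stature = subj$stature,
            feasible = sol$feasible,
            note = sol$infeasibility %||% NA_character_
          ),
          res$loads, tibble::tibble(iap_kpa = sol$iap_kpa,
                                    max_residual = max(sol$residuals$norm),
                                    max_rel_residual = max(sol$residuals$rel)),
          muscle_bw
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "seed") <- seed
  class(out) <- c("spineload_battery", class(out))
  out
}

check_sample <- function(x, min_n = 2) {
  if (length(x) < min_n || anyNA(x)) abort("samples must have length >= 2 and no missing values")
}

#' Unpaired two-sample Student t-test
#'
#' Pooled-variance t with `df = n1 + n2 - 2` and a two-sided p value,
#' computed from the closed form.
#'
#' @param a,b Numeric samples (length >= 2 each).
#' @return One-row tibble with `t`, `p`, `df`.
#' @export
unpaired_ttest <- function(a, b) {
  check_sample(a); check_sample(b)
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  if (sp2 <= 0) abort("t undefined: zero pooled variance", class = "spineload_undefined")
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  tibble::tibble(t = tstat, p = 2 * pt(-abs(tstat), df), df = df)
}

#' Paired Student t-test
#'
#' One-sample t on the paired differences, two-sided p value.
#'
#' @param a,b Numeric samples of equal length >= 2, paired by position.
#' @return One-row tibble with `t`, `p`, `df`.
#' @export
paired_ttest <- function(a, b) {
  check_sample(a); check_sample(b)
  if (length(a) != length(b)) abort("paired samples must have equal length")
  d <- a - b
  if (sd(d) == 0) abort("t undefined: zero difference variance", class = "spineload_undefined")
  n <- length(d)
  tstat <- mean(d) / (sd(d) / sqrt(n))
  tibble::tibble(t = tstat, p = 2 * pt(-abs(tstat), n - 1), df = n - 1)
}

pct_diff_both <- function(x, y) {
  # percent difference of x vs y under both denominator conventions
  tibble::tibble(
    pct_of_smaller = 100 * (max(x, y) - min(x, y)) / min(x, y) * sign(x - y),
    pct_of_larger = 100 * (max(x, y) - min(x, y)) / max(x, y) * sign(x - y)
  )
}

#' Group comparisons over a battery result
#'
#' Per task and across tasks (equal task weighting): male vs female-base
#' unpaired t, female base vs specific paired t (same subjects under both
#' variants), and mean percent differences of group means under both
#' denominator conventions (labelled; no multiple-testing correction is
#' applied).
#'
#' @param table A `spineload_battery` tibble containing both sexes and both
#'   female variants.
#' @param measure Load column to compare (default `"compression"`).
#' @return A `spineload_comparison` list of tibbles: `per_task`, `overall`.
#' @export
summarize_differences <- function(table, measure = "compression") {
  needed <- c("male_base", "female_base", "female_specific")
  if (!all(needed %in% unique(table$variant))) {
    abort("battery must contain male_base, female_base and female_specific rows")
  }
  tab <- table[table$feasible, ]
  get <- function(task, variant) {
    rows <- tab$task == task & tab$variant == variant
    x <- tab[[measure]][rows]
    names(x) <- tab$subject_id[rows]
    x
  }
  per_task <- purrr::map_dfr(unique(tab$task), function(tk) {
    m <- get(tk, "male_base"); fb <- get(tk, "female_base"); fs <- get(tk, "female_specific")
    fs <- fs[names(fb)]   # identical subject ordering in both paired arms
    ut <- tryCatch(unpaired_ttest(m, fb), spineload_undefined = function(e) tibble::tibble(t = NA, p = NA, df = NA))
    pt_ <- tryCatch(paired_ttest(fb, fs), spineload_undefined = function(e) tibble::tibble(t = NA, p = NA, df = NA))
    dplyr::bind_cols(
      tibble::tibble(task = tk, mean_male = mean(m), mean_female_base = mean(fb),
                     mean_female_specific = mean(fs),
                     t_male_vs_female_base = ut$t, p_male_vs_female_base = ut$p,
                     t_base_vs_specific = pt_$t, p_base_vs_specific = pt_$p),
      pct_diff_both(mean(m), mean(fb)) |>
        dplyr::rename(male_vs_base_pct_of_smaller = "pct_of_smaller",
                      male_vs_base_pct_of_larger = "pct_of_larger"),
      pct_diff_both(mean(fb), mean(fs)) |>
        dplyr::rename(base_vs_specific_pct_of_smaller = "pct_of_smaller",
                      base_vs_specific_pct_of_larger = "pct_of_larger")
    )
  })
  overall <- per_task |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric) & !dplyr::starts_with("t_") &
                                     !dplyr::starts_with("p_"), mean))
  structure(list(per_task = per_task, overall = overall, measure = measure,
                 note = "no multiple-testing correction applied"),
            class = c("spineload_comparison", "list"))
}

#' Per-site EMG correlation table
#'
#' Pearson correlation, per electrode site, between measured envelope means
#' and model-predicted activities across the task battery (one value per
#' task, matching the per-muscle design of the study's comparison).
#'
#' @param measured Tibble with columns `site`, `task`, `envelope_mean`.
#' @param predicted Tibble with columns `site`, `task`, `activity`.
#' @return Tibble with `site`, `r`, `p`, `n`; sites whose predicted
#'   activities have zero variance across tasks are returned with `NA`
#'   (correlation undefined).
#' @export
emg_correlation_table <- function(measured, predicted) {
  joined <- dplyr::inner_join(measured, predicted, by = c("site", "task"))
  joined |>
    dplyr::summarise(
      res = list(tryCatch(pearson_r(.data$envelope_mean, .data$activity),
                          spineload_undefined = function(e)
                            tibble::tibble(r = NA_real_, p = NA_real_, n = dplyr::n()))),
      .by = "site"
    ) |>
    tidyr::unnest("res")
}
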