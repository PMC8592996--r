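#' Create subject profiles
#'
#' Builds a tibble of subject profiles with derived BMI and, unless supplied,
#' a body-fat fraction from the configured BMI regression for the subject's
#' sex.
#'
#' @param sex Character vector, `"male"` or `"female"`.
#' @param stature Stature in metres (> 0).
#' @param mass Body mass in kg (> 0).
#' @param age Age in years.
#' @param fat_fraction Optional body-fat fraction in `[0, 1)`; computed from
#'   BMI when `NULL`.
#' @param defaults Package defaults list, see [spineload_defaults()].
#' @return Tibble with columns `sex`, `stature`, `mass`, `age`, `bmi`,
#'   `fat_fraction`.
#' @examples
#' subject_profile("female", 1.685, 56.4, 32)
#' @export
subject_profile <- function(sex, stature, mass, age, fat_fraction = NULL,
                            defaults = spineload_defaults()) {
  if (!all(sex %in% c("male", "female"))) abort("sex must be 'male' or 'female'")
  if (any(!is.finite(stature) | stature <= 0)) abort("stature must be positive")
  if (any(!is.finite(mass) | mass <= 0)) abort("mass must be positive")
  out <- tibble::tibble(sex = sex, stature = stature, mass = mass, age = age) |>
    dplyr::mutate(bmi = .data$mass / .data$stature^2)
  if (is.null(fat_fraction)) {
    out$fat_fraction <- purrr::map2_dbl(out$bmi, out$sex, function(b, s) {
      body_fat_fraction(b, sex = s, defaults = defaults)
    })
  } else {
    if (any(fat_fraction < 0 | fat_fraction >= 1)) abort("fat_fraction must be in [0, 1)")
    out$fat_fraction <- fat_fraction
  }
  out
}

#' Trunk muscle PCSA table for a model variant
#'
#' Returns the physiological cross-sectional areas (cm^2) of the seven trunk
#' muscle groups for one model variant. The male and female base models share
#' one column; the female-specific variant carries female PCSAs (smaller back
#' muscles, slightly larger obliques).
#'
#' @param variant One of `"male_base"`, `"female_base"`, `"female_specific"`.
#' @param path Optional path to an alternative CSV mirroring the shipped
#'   layout (`muscle,base,female_specific`).
#' @return Tibble with columns `muscle`, `pcsa`.
#' @export
load_pcsa_table <- function(variant = c("male_base", "female_base", "female_specific"),
                            path = NULL) {
  variant <- match_variant(variant)
  tab <- readr::read_csv(path %||% spineload_extdata("pcsa_trunk_muscles.csv"),
                         show_col_types = FALSE)
  expected <- c("multifidus", "erector_spinae", "quadratus_lumborum", "psoas_major",
                "internal_oblique", "external_oblique", "rectus_abdominis")
  if (!setequal(tab$muscle, expected) || nrow(tab) != 7) {
    abort("PCSA table must contain exactly the seven trunk muscle groups")
  }
  col <- if (variant == "female_specific") "female_specific" else "base"
  out <- tibble::tibble(muscle = tab$muscle, pcsa = tab[[col]])
  if (any(out$pcsa <= 0)) abort("PCSA values must be strictly positive")
  out[match(expected, out$muscle), ]
}

#' Segment mass-fraction table for a model variant
#'
#' Returns each body segment's share of total body mass (percent of body
#' weight). Fractions in each variant column sum to 100 up to rounding of the
#' shipped values.
#'
#' @inheritParams load_pcsa_table
#' @return Tibble with columns `segment`, `fraction` (percent of body mass).
#' @export
load_mass_distribution <- function(variant = c("male_base", "female_base", "female_specific"),
                                   path = NULL) {
  variant <- match_variant(variant)
  tab <- readr::read_csv(path %||% spineload_extdata("segment_mass_fractions.csv"),
                         show_col_types = FALSE)
  expected <- c("head", "thorax", "lumbar", "pelvis", "thighs", "shanks", "feet",
                "upper_arms", "lower_arms", "hands")
  if (!setequal(tab$segment, expected) || nrow(tab) != 10) {
    abort("mass-fraction table must contain exactly the ten body segments")
  }
  col <- if (variant == "female_specific") "female_specific" else "base"
  out <- tibble::tibble(segment = tab$segment, fraction = tab[[col]])
  if (any(out$fraction <= 0)) abort("mass fractions must be strictly positive")
  if (abs(sum(out$fraction) - 100) > 0.05) {
    abort("mass fractions must sum to 100 (+/- 0.05 rounding)")
  }
  out[match(expected, out$segment), ]
}

match_variant <- function(variant) {
  choices <- c("male_base", "female_base", "female_specific")
  if (length(variant) > 1 && identical(variant, choices)) variant <- variant[1]
  if (length(variant) != 1 || !variant %in% choices) {
    abort(paste0("unknown model variant '", paste(variant, collapse = ","),
                 "'; must be one of ", paste(choices, collapse = ", ")))
  }
  variant
}

#' Absolute segment masses for a subject
#'
#' @param table Mass-fraction tibble from [load_mass_distribution()].
#' @param body_mass Total body mass in kg (>= 0).
#' @return Tibble with columns `segment`, `mass` (kg); masses sum to
#'   `body_mass` up to rounding of the fractions.
#' @export
segment_masses <- function(table, body_mass) {
  if (!is.finite(body_mass) || body_mass < 0) abort("body_mass must be nonnegative")
  tibble::tibble(segment = table$segment, mass = table$fraction / 100 * body_mass)
}

#' Body-fat fraction from BMI
#'
#' Evaluates a linear regression of body-fat fraction on BMI with per-sex
#' coefficients. BMI outside the configured validity window triggers a
#' warning and is clamped to the window before evaluation; the output is
#' clamped to `[0, 0.75]`.
#'
#' @param bmi Body mass index, kg/m^2.
#' @param sex `"male"` or `"female"` (selects the default coefficients).
#' @param coefficients Optional list with elements `slope` and `intercept`
#'   (fraction units), overriding the configured per-sex values.
#' @param defaults Package defaults list.
#' @return Body-fat fraction in `[0, 0.75]`.
#' @export
body_fat_fraction <- function(bmi, sex = "female", coefficients = NULL,
                              defaults = spineload_defaults()) {
  if (is.null(coefficients)) {
    if (!sex %in% c("male", "female")) abort("sex must be 'male' or 'female'")
    coefficients <- defaults$fat_regression[[sex]]
  }
  window <- as.numeric(defaults$fat_bmi_window %||% c(15, 40))
  if (any(bmi < window[1] | bmi > window[2])) {
    warn(paste0("BMI outside validity window [", window[1], ", ", window[2],
                "]; clamped before evaluating the fat regression"))
  }
  bmi <- pmin(pmax(bmi, window[1]), window[2])
  pmin(pmax(coefficients$slope * bmi + coefficients$intercept, 0), 0.75)
}

#' Length-mass-fat muscle strength scale
#'
#' Strength scale relating a subject to the reference subject:
#' `(lean mass ratio)^a / (stature ratio)^b` with configurable exponents
#' (defaults a = b = 1). Lean mass is `mass * (1 - fat_fraction)`. The scale
#' is exactly 1 when subject and reference coincide and is homogeneous of
#' degree `a` in lean mass at fixed stature.
#'
#' @param subject One-row subject tibble (see [subject_profile()]).
#' @param reference One-row reference subject tibble; defaults to the
#'   configured reference (75 kg, 1.75 m male).
#' @param exponents List with `lean_mass_exponent` and `stature_exponent`.
#' @param defaults Package defaults list.
#' @return Dimensionless strength scale (> 0).
#' @export
length_mass_fat_scale <- function(subject, reference = NULL, exponents = NULL,
                                  defaults = spineload_defaults()) {
  if (is.null(reference)) {
    r <- defaults$reference_subject
    reference <- subject_profile(r$sex, r$stature, r$mass, r$age, defaults = defaults)
  }
  exponents <- exponents %||% defaults$strength_scaling
  lean_s <- subject$mass[1] * (1 - subject$fat_fraction[1])
  lean_r <- reference$mass[1] * (1 - reference$fat_fraction[1])
  if (!is.finite(lean_r) || lean_r <= 0 || !is.finite(lean_s) || lean_s <= 0) {
    abort("lean mass must be positive for both subject and reference")
  }
  (lean_s / lean_r)^exponents$lean_mass_exponent /
    (subject$stature[1] / reference$stature[1])^exponents$stature_exponent
}

#' Maximal muscle force from PCSA
#'
#' @param pcsa Physiological cross-sectional area, cm^2 (>= 0).
#' @param specific_tension Maximal stress, N/cm^2 (>= 0).
#' @param scale Dimensionless strength scale (>= 0).
#' @return Maximal force in N (`pcsa * specific_tension * scale`).
#' @export
muscle_strength <- function(pcsa, specific_tension, scale = 1) {
  if (any(pcsa < 0) || any(specific_tension < 0) || any(scale < 0)) {
    abort("pcsa, specific_tension and scale must all be nonnegative")
  }
  pcsa * specific_tension * scale
}

#' Bundle the parameters of one model variant
#'
#' Collects the variant's PCSA table, mass-fraction table, specific tension
#' and a subject strength scale into one list used by [build_chain()].
#'
#' @param variant Model variant name.
#' @param specific_tension N/cm^2; defaults to the configured value.
#' @param strength_scale Dimensionless; typically from
#'   [length_mass_fat_scale()].
#' @param defaults Package defaults list.
#' @return List with class `spineload_parameter_set`.
#' @export
parameter_set <- function(variant = c("male_base", "female_base", "female_specific"),
                          specific_tension = NULL, strength_scale = 1,
                          defaults = spineload_defaults()) {
  variant <- match_variant(variant)
  specific_tension <- specific_tension %||% defaults$specific_tension
  if (specific_tension <= 0) abort("specific_tension must be positive")
  structure(
    list(
      variant = variant,
      pcsa_table = load_pcsa_table(variant),
      mass_table = load_mass_distribution(variant),
      specific_tension = specific_tension,
      strength_scale = strength_scale,
      es_split = defaults$erector_spinae_split,
      pcsa_per_side = isTRUE(defaults$pcsa_per_side)
    ),
    class = c("spineload_parameter_set", "list")
  )
}
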