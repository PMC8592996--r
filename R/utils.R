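#' Locate a shipped configuration or data file
#'
#' @param file File name under the package's `extdata` directory.
#' @return Absolute path to the file.
#' @keywords internal
spineload_extdata <- function(file) {
  path <- system.file("extdata", file, package = "spineload")
  if (!nzchar(path)) abort(paste0("shipped file not found: ", file))
  path
}

#' Package default parameters
#'
#' Reads the shipped `defaults.yaml`: specific tension, body-fat regression
#' coefficients, strength-scaling exponents, the reference subject, lumbar
#' rhythm coefficients, the erector spinae fascicle split and EMG settings.
#'
#' @param path Optional path to an alternative YAML file.
#' @return A named list.
#' @export
spineload_defaults <- function(path = NULL) {
  read_yaml_strict(path %||% spineload_extdata("defaults.yaml"))
}

# read YAML without the 1.1 rule that bare y/n keys are booleans
read_yaml_strict <- function(path) {
  yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(x) if (tolower(x) %in% c("y", "yes")) x else TRUE,
    "bool#no" = function(x) if (tolower(x) %in% c("n", "no")) x else FALSE
  ))
}

#' Model geometry configuration
#'
#' Reads the shipped `geometry.yaml`: segment proportions (fractions of
#' stature), fascicle anchor coordinates, intra-abdominal pressure actuator
#' parameters and intervertebral stiffness. The schema is validated on load.
#'
#' @param path Optional path to an alternative YAML file.
#' @return A named list with class `spineload_geometry`.
#' @export
load_geometry <- function(path = NULL) {
  geo <- read_yaml_strict(path %||% spineload_extdata("geometry.yaml"))
  required <- c("segments", "fascicles", "iap", "joint_stiffness", "arm_com_fractions")
  missing <- setdiff(required, names(geo))
  if (length(missing) > 0) {
    abort(paste0("geometry config missing section(s): ", paste(missing, collapse = ", ")))
  }
  for (nm in names(geo$fascicles)) {
    fas <- geo$fascicles[[nm]]
    parts <- if (!is.null(fas$fans)) fas$fans else list(fas)
    for (part in parts) {
      inf <- part$inferior %||% fas$inferior
      sup <- part$superior %||% fas$superior
      seg <- part$superior_segment %||% fas$superior_segment %||% part$levels %||% fas$levels
      if (is.null(inf) || is.null(sup) || is.null(seg)) {
        abort(paste0("geometry config: fascicle '", nm, "' lacks an anchor or superior segment"))
      }
    }
    if (!fas$group %in% c("local", "global")) {
      abort(paste0("geometry config: fascicle '", nm, "' group must be local or global"))
    }
  }
  structure(geo, class = c("spineload_geometry", "list"))
}

# ---- rotations ------------------------------------------------------------

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

rot_x <- function(deg) {
  a <- deg2rad(deg); c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

rot_y <- function(deg) {
  a <- deg2rad(deg); c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

rot_z <- function(deg) {
  a <- deg2rad(deg); c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Compose a rotation from flexion / lateral-bend / axial angles
#'
#' Intrinsic sequence: flexion about y (forward positive), then lateral bend
#' about x (rightward positive), then axial rotation about z (leftward
#' positive, right-hand rule).
#'
#' @param angles Numeric length-3 vector in degrees (flexion, lateral, axial).
#' @return 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(angles) {
  stopifnot(length(angles) == 3, all(is.finite(angles)))
  rot_y(angles[1]) %*% rot_x(angles[2]) %*% rot_z(angles[3])
}

is_rotation_matrix <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' Decompose a rotation matrix into flexion / lateral-bend / axial angles
#'
#' Inverse of [euler_to_matrix()] (y-x-z intrinsic sequence).
#'
#' @param R 3x3 rotation matrix.
#' @return Numeric length-3 vector in degrees (flexion, lateral, axial).
#' @export
matrix_to_euler <- function(R) {
  if (!is_rotation_matrix(R)) abort("input is not a valid rotation matrix (orthonormal, det +1)")
  lat <- asin(max(-1, min(1, -R[2, 3])))
  if (abs(cos(lat)) < 1e-12) {
    # gimbal: flexion and axial share an axis; attribute everything to flexion
    flex <- atan2(R[1, 2] * sign(-R[2, 3]), R[1, 1])
    ax <- 0
  } else {
    flex <- atan2(R[1, 3], R[3, 3])
    ax <- atan2(R[2, 1], R[2, 2])
  }
  rad2deg(c(flex, lat, ax))
}

#' Relative trunk-pelvis rotation angles
#'
#' Decomposes the rotation carrying the pelvis frame onto the thorax frame
#' into flexion, lateral bending and axial rotation (y-x-z intrinsic).
#'
#' @param thorax_frame,pelvis_frame 3x3 rotation matrices (columns = frame
#'   axes in world coordinates).
#' @return Tibble with columns `flexion`, `lateral`, `axial` (degrees).
#' @export
trunk_pelvis_rotation <- function(thorax_frame, pelvis_frame) {
  if (!is_rotation_matrix(thorax_frame)) abort("thorax_frame is not a valid rotation matrix")
  if (!is_rotation_matrix(pelvis_frame)) abort("pelvis_frame is not a valid rotation matrix")
  ang <- matrix_to_euler(t(pelvis_frame) %*% thorax_frame)
  tibble::tibble(flexion = ang[1], lateral = ang[2], axial = ang[3])
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# ---- seeding --------------------------------------------------------------

#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one master seed; substreams for
#' subjects, tasks and channels are derived with this splitter so that trials
#' are independent yet bit-reproducible.
#'
#' @param seed Master integer seed.
#' @param ... Further integer indices (subject, task, channel, ...).
#' @return An integer < 2^31 usable with [set.seed()].
#' @export
substream_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483629
  for (k in seq_along(idx)) {
    s <- (s * 48271 + as.double(idx[k]) * 16807 + k) %% 2147483629
  }
  as.integer(s)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}
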