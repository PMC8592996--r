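# Muscle recruitment by cubic-stress minimization.
#
# minimize   sum_i (f_i / N_i)^3
# subject to sum_i r_ij x f_i + IAP_j + passive_j + external_j = 0  (each joint j,
#            all three moment components), 0 <= f_i <= N_i, 0 <= p <= p_max.
#
# In activities a_i = f_i / N_i the objective sum a_i^3 is strictly convex on
# the interior of [0, 1]^n and the constraints are linear, so the optimum is
# unique whenever any fascicle is active; no tie-breaking is needed.

#' Net external moments at every intervertebral joint
#'
#' Top-down static moments from gravity of the superincumbent bodies and the
#' hand load, per joint, in world axes.
#'
#' @param posed A `spineload_posed` model.
#' @return Tibble with columns `joint`, `mx`, `my`, `mz` (N*m).
#' @export
net_joint_moments <- function(posed) {
  purrr::map_dfr(LUMBAR_JOINTS, function(j) {
    m <- gravity_moment(posed, j) + hand_load_moment(posed$hand_load, posed, j)
    tibble::tibble(joint = j, mx = m[1], my = m[2], mz = m[3])
  })
}

#' Assemble the recruitment problem for a posed model
#'
#' Builds the stacked (6 joints x 3 axes) equality system in scaled variables
#' (muscle activities and intra-abdominal pressure): columns are fascicle
#' moment-arm rows times strengths, plus the IAP actuator column (extension
#' moment per kPa at every joint it spans); the right-hand side balances the
#' external (gravity + hand) and passive moments.
#'
#' @param posed A `spineload_posed` model.
#' @return A `spineload_problem` list.
#' @export
recruitment_problem <- function(posed) {
  f <- posed$fascicles
  nf <- nrow(f)
  external <- net_joint_moments(posed)

  B <- matrix(0, 18, nf + 1)
  b <- numeric(18)
  jr <- posed$posture$joint_rotations
  stiff <- posed$chain$stiffness
  iap_col_unit <- posed$iap$effective_area * posed$iap$lever_arm * 1000  # N*m per kPa
  for (k in 1:6) {
    rows <- (3 * (k - 1) + 1):(3 * k)
    R <- moment_arm_matrix(posed, LUMBAR_JOINTS[k])
    B[rows, 1:nf] <- t(R) %*% diag(f$strength, nf)
    B[rows, nf + 1] <- c(0, -iap_col_unit, 0)  # extension = -y
    rot <- as.numeric(jr[jr$joint == LUMBAR_JOINTS[k], c("flexion", "lateral", "axial")])
    pas_plane <- passive_joint_moment(rot, stiff)
    pas_world <- c(pas_plane[2], pas_plane[1], pas_plane[3])  # planes -> x,y,z axes
    ext <- as.numeric(external[k, c("mx", "my", "mz")])
    b[rows] <- -(ext + pas_world)
  }
  structure(
    list(B = B, b = b, fascicles = f, strengths = f$strength,
         iap_max = posed$iap$max_pressure_kpa, iap_col_unit = iap_col_unit,
         external = external),
    class = c("spineload_problem", "list")
  )
}

# augmented-Lagrangian inner objective and gradient over x = (a, p)
al_fn <- function(x, B, b, lambda, mu, nf) {
  r <- as.numeric(B %*% x) - b
  sum(x[1:nf]^3) + sum(lambda * r) + mu / 2 * sum(r^2)
}
al_gr <- function(x, B, b, lambda, mu, nf) {
  r <- as.numeric(B %*% x) - b
  g <- c(3 * x[1:nf]^2, 0)
  g + as.numeric(crossprod(B, lambda + mu * r))
}

# Newton polish on the free variables with fixed active set: solves the KKT
# system of the equality-constrained problem to drive the residual to
# machine precision. Returns NULL if the active set is inconsistent.
kkt_polish <- function(x, B, b, nf, lower, upper, iter = 40, tol = 1e-12) {
  n <- length(x)
  for (it in seq_len(iter)) {
    free <- which(x > lower + 1e-9 & x < upper - 1e-9)
    if (length(free) == 0) return(NULL)
    Bf <- B[, free, drop = FALSE]
    g <- c(3 * x[1:nf]^2, 0)[free]
    h <- c(6 * x[1:nf], 0)[free] + 1e-9
    r <- as.numeric(B %*% x) - b
    m <- nrow(B)
    K <- rbind(cbind(diag(h, length(free)), t(Bf)),
               cbind(Bf, matrix(0, m, m)))
    rhs <- c(-g, -r)
    sol <- tryCatch(solve(K + diag(1e-12, nrow(K)), rhs), error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    dx <- sol[seq_along(free)]
    nu <- sol[-seq_along(free)]
    # step with bound clipping
    step <- 1
    xf <- x[free]
    hit_lo <- dx < 0 & xf + dx < lower[free]
    hit_hi <- dx > 0 & xf + dx > upper[free]
    if (any(hit_lo)) step <- min(step, min((lower[free][hit_lo] - xf[hit_lo]) / dx[hit_lo]))
    if (any(hit_hi)) step <- min(step, min((upper[free][hit_hi] - xf[hit_hi]) / dx[hit_hi]))
    x[free] <- xf + step * dx
    x <- pmin(pmax(x, lower), upper)
    r <- as.numeric(B %*% x) - b
    grad_lag <- c(3 * x[1:nf]^2, 0) + as.numeric(crossprod(B, nu))
    at_lo <- x <= lower + 1e-9
    at_hi <- x >= upper - 1e-9
    stat <- grad_lag
    stat[at_lo] <- pmin(stat[at_lo], 0)   # at lower bound, gradient may be positive
    stat[at_hi] <- pmax(stat[at_hi], 0)
    if (max(abs(r)) < tol && max(abs(stat)) < 1e-6 && step == 1) {
      return(list(x = x, nu = nu, residual = r))
    }
  }
  r <- as.numeric(B %*% x) - b
  if (max(abs(r)) < 1e-9) return(list(x = x, nu = nu, residual = r))
  NULL
}

#' Solve the muscle recruitment problem
#'
#' Minimizes the sum of cubed muscle stresses subject to three-component
#' moment equilibrium at all six intervertebral joints and force bounds,
#' using an augmented-Lagrangian method (bound-constrained L-BFGS-B inner
#' solves) followed by a KKT Newton polish on the active set. Infeasible
#' demand is detected by a bound-constrained least-squares certificate and
#' reported with the most violated joint and plane.
#'
#' @param problem A `spineload_problem` from [recruitment_problem()].
#' @param control List of solver controls: `constraint_tol` (default 1e-8,
#'   relative to `max(1, |b|)` per joint), `outer_iter`, `mu0`.
#' @return A `spineload_recruitment` list: `forces` tibble (fascicle forces
#'   and activities), `iap_kpa`, `residuals` per joint, `objective`,
#'   `feasible`, `converged`.
#' @export
solve_recruitment <- function(problem, control = list()) {
  B <- problem$B; b <- problem$b
  nf <- length(problem$strengths)
  n <- nf + 1
  tol <- control$constraint_tol %||% 1e-8
  outer_iter <- control$outer_iter %||% 40
  mu <- control$mu0 %||% 30
  inner_maxit <- control$inner_maxit %||% 200
  lower <- rep(0, n)
  upper <- c(rep(1, nf), problem$iap_max)

  scale_b <- pmax(1, abs(b))
  x <- c(rep(0.02, nf), min(1, problem$iap_max))
  lambda <- numeric(length(b))
  converged <- FALSE
  for (it in seq_len(outer_iter)) {
    opt <- optim(x, al_fn, al_gr, B = B, b = b, lambda = lambda, mu = mu, nf = nf,
                 method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = inner_maxit, factr = 1e1, pgtol = 1e-12))
    x <- opt$par
    r <- as.numeric(B %*% x) - b
    if (max(abs(r) / scale_b) < tol) { converged <- TRUE; break }
    if (max(abs(r) / scale_b) < 1e-3) {
      # close enough for the active-set Newton polish to finish the job
      pol <- kkt_polish(x, B, b, nf, lower, upper)
      if (!is.null(pol) && max(abs(pol$residual) / scale_b) < tol) {
        x <- pol$x; converged <- TRUE; break
      }
    }
    lambda <- lambda + mu * r
    mu <- min(mu * 6, 1e9)
  }

  if (!converged) {
    pol <- kkt_polish(x, B, b, nf, lower, upper)
    if (!is.null(pol)) { x <- pol$x; converged <- TRUE }
  }
  r <- as.numeric(B %*% x) - b

  feasible <- TRUE
  infeasibility <- NULL
  if (max(abs(r) / scale_b) > 1e-6) {
    # certificate: minimum attainable violation under the bounds
    ls <- optim(x, function(z) sum((as.numeric(B %*% z) - b)^2),
                function(z) 2 * as.numeric(crossprod(B, as.numeric(B %*% z) - b)),
                method = "L-BFGS-B", lower = lower, upper = upper,
                control = list(maxit = 2000, factr = 1e1))
    r_ls <- as.numeric(B %*% ls$par) - b
    if (max(abs(r_ls) / scale_b) > 1e-6) {
      feasible <- FALSE
      worst <- which.max(abs(r_ls) / scale_b)
      joint <- LUMBAR_JOINTS[ceiling(worst / 3)]
      plane <- c("x (lateral axis)", "y (flexion axis)", "z (axial)")[(worst - 1) %% 3 + 1]
      infeasibility <- paste0("demand infeasible at joint ", joint, ", moment component ",
                              plane, " (violation ", signif(abs(r_ls[worst]), 3), " N*m)")
    } else {
      converged <- FALSE
    }
  }

  a <- x[1:nf]
  f <- problem$fascicles
  res_tbl <- tibble::tibble(
    joint = LUMBAR_JOINTS,
    mx = r[seq(1, 16, 3)], my = r[seq(2, 17, 3)], mz = r[seq(3, 18, 3)],
    net_norm = vapply(1:6, function(k) sqrt(sum(b[(3 * k - 2):(3 * k)]^2)), numeric(1))
  ) |>
    dplyr::mutate(norm = sqrt(.data$mx^2 + .data$my^2 + .data$mz^2),
                  rel = .data$norm / pmax(1, .data$net_norm))

  structure(
    list(
      forces = tibble::tibble(
        fascicle = f$fascicle, muscle = f$muscle, source = f$source,
        group = f$group, side = f$side, strength = f$strength,
        force = a * f$strength, activity = a
      ),
      iap_kpa = x[n],
      residuals = res_tbl,
      objective = sum(a^3),
      feasible = feasible,
      converged = converged,
      infeasibility = infeasibility,
      problem = problem
    ),
    class = c("spineload_recruitment", "list")
  )
}

#' L5-S1 joint reaction loads from a recruitment solution
#'
#' The joint reaction balances the weight of all superincumbent bodies, the
#' hand load and the pull of every fascicle crossing L5-S1. Compression is
#' the component along the superior axis of the S1 endplate frame (the
#' pelvis frame); anteroposterior and mediolateral shears are the in-plane
#' components and the resultant shear their Euclidean norm.
#'
#' @param solution A `spineload_recruitment`.
#' @param posed The `spineload_posed` model the solution was computed for.
#' @return One-row tibble: `compression`, `ap_shear`, `ml_shear`,
#'   `resultant_shear` (N) and the same normalized to body weight (%BW).
#' @export
l5s1_loads <- function(solution, posed) {
  k <- joint_index("L5-S1")
  above <- posed$bodies[posed$bodies$above_joint <= k, ]
  F_grav <- posed$gravity * sum(above$mass)
  for (p in hand_load_points(posed$hand_load, posed) %||% list()) {
    F_grav <- F_grav + p$mass * posed$gravity
  }
  f <- posed$fascicles
  F_mus <- c(0, 0, 0)
  for (i in seq_len(nrow(f))) {
    span <- crossing_span(posed, i, k)
    if (is.null(span)) next
    d <- span$lower - span$upper
    u <- d / sqrt(sum(d^2))
    F_mus <- F_mus + solution$forces$force[i] * u
  }
  R <- -(F_grav + F_mus)   # force on L5 from the sacrum
  Rp <- as.numeric(t(posed$R_pelvis) %*% R)  # into the S1 endplate frame
  comp <- Rp[3]; ap <- Rp[1]; ml <- Rp[2]
  bw <- posed$chain$subject$mass[1]
  tibble::tibble(
    compression = comp, ap_shear = ap, ml_shear = ml,
    resultant_shear = sqrt(ap^2 + ml^2),
    compression_bw = normalize_bw(comp, bw),
    ap_shear_bw = normalize_bw(ap, bw),
    ml_shear_bw = normalize_bw(ml, bw),
    resultant_shear_bw = normalize_bw(sqrt(ap^2 + ml^2), bw)
  )
}

#' Normalize a force to body weight
#'
#' @param force Force in N.
#' @param body_mass Body mass in kg (> 0).
#' @return Force as a percentage of body weight (`100 * force / (m * 9.81)`).
#' @export
normalize_bw <- function(force, body_mass) {
  if (any(!is.finite(body_mass)) || any(body_mass <= 0)) abort("body_mass must be positive")
  100 * force / (body_mass * GRAVITY)
}

#' Solve a posed model end to end
#'
#' Convenience wrapper: assembles the recruitment problem, solves it and
#' extracts L5-S1 loads.
#'
#' @param posed A `spineload_posed` model.
#' @param control Solver controls passed to [solve_recruitment()].
#' @return List with `solution` and `loads`.
#' @export
solve_posed <- function(posed, control = list()) {
  sol <- solve_recruitment(recruitment_problem(posed), control)
  loads <- if (sol$feasible) l5s1_loads(sol, posed) else
    tibble::tibble(compression = NA_real_, ap_shear = NA_real_, ml_shear = NA_real_,
                   resultant_shear = NA_real_, compression_bw = NA_real_,
                   ap_shear_bw = NA_real_, ml_shear_bw = NA_real_,
                   resultant_shear_bw = NA_real_)
  list(solution = sol, loads = loads)
}
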