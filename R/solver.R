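#' Solver options
#'
#' @param tol Absolute tolerance on the scaled equality-constraint residual
#'   used to declare a frame optimal (rows are comparably conditioned after
#'   scaling; see `char_lever`).
#' @param char_lever Characteristic lever arm (m). Moment rows are divided by
#'   this value before solving so that force rows (dimensionless direction
#'   components) and moment rows (meters) are comparably scaled; residuals
#'   are reported unscaled.
#' @param max_iter Iteration cap for the cubic-objective SQP loop.
#' @param lp_max_iter Iteration cap for the simplex solver.
#' @param step_tol Relative step-norm convergence threshold of the SQP loop.
#' @return A list of class `solver_options`.
#' @export
solver_options <- function(tol = 1e-8, char_lever = 0.05, max_iter = 60L,
                           lp_max_iter = 1000L, step_tol = 1e-10) {
  stopifnot(tol > 0, char_lever > 0, max_iter >= 1, step_tol > 0)
  structure(list(tol = tol, char_lever = char_lever,
                 max_iter = as.integer(max_iter),
                 lp_max_iter = as.integer(lp_max_iter),
                 step_tol = step_tol),
            class = "solver_options")
}

# scaled copies of A and b (moment rows divided by the characteristic lever)
scale_system <- function(system, options) {
  A <- system$A
  b <- system$b
  if (length(system$moment_rows) > 0L) {
    A[system$moment_rows, ] <- A[system$moment_rows, , drop = FALSE] /
      options$char_lever
    b[system$moment_rows] <- b[system$moment_rows] / options$char_lever
  }
  list(A = A, b = b)
}

# boot::simplex requires nonnegative right-hand sides; equality rows are
# sign-flipped as needed. Returns list(x, solved) with solved in {1, 0, -1}.
lp_solve <- function(cc, Aeq, beq, A_ineq = NULL, b_ineq = NULL,
                     upper = NULL, n_iter = 1000L) {
  n <- length(cc)
  s <- ifelse(beq < 0, -1, 1)
  A3 <- Aeq * s
  b3 <- beq * s
  A1 <- diag(n)[seq_along(upper), , drop = FALSE]
  b1 <- upper
  if (!is.null(A_ineq)) {
    A1 <- rbind(A1, A_ineq)
    b1 <- c(b1, b_ineq)
  }
  res <- boot::simplex(a = cc, A1 = A1, b1 = b1, A3 = A3, b3 = b3,
                       maxi = FALSE, n.iter = n_iter)
  list(x = unname(res$soln[seq_len(n)]), solved = res$solved)
}

# one equality + bounds QP through quadprog; ridge keeps the Hessian PD.
# Returns list(x, ok).
qp_solve <- function(Hdiag, d, Aeq, beq, lower, upper) {
  ridge <- 1e-9 * max(Hdiag, 1)
  Hdiag[Hdiag <= 0] <- ridge
  res <- tryCatch(
    pracma::quadprog(C = diag(Hdiag, length(Hdiag)), d = d,
                     Aeq = Aeq, beq = beq, lb = lower, ub = upper),
    error = function(e) NULL
  )
  if (is.null(res)) list(x = NULL, ok = FALSE)
  else list(x = as.numeric(res$xmin), ok = TRUE)
}

# minimum-norm point of the optimal face: min ||x||^2 subject to the
# equalities, the bounds, and (near-)optimality of the primary objective
# expressed as extra inequality rows. Linear and minimax criteria leave the
# objective-free variables (ligaments, contacts) degenerate; this secondary
# criterion makes the reported forces deterministic and keeps arbitrary
# internal preloads (ligaments pulling against contacts at zero objective
# cost) out of the solution.
polish_min_norm <- function(Ahat, bhat, lower, upper, A_extra, b_extra,
                            fallback) {
  n <- ncol(Ahat)
  res <- tryCatch(
    pracma::quadprog(C = diag(2, n), d = rep(0, n),
                     A = A_extra, b = b_extra,
                     Aeq = Ahat, beq = bhat, lb = lower, ub = upper),
    error = function(e) NULL
  )
  if (is.null(res)) fallback else as.numeric(res$xmin)
}

# bounded least-squares point closest to satisfying the equalities; used to
# report a residual when a frame is infeasible.
ls_closest_feasible <- function(Ahat, bhat, lower, upper) {
  n <- ncol(Ahat)
  C <- 2 * crossprod(Ahat)
  C <- C + diag(1e-10 * max(diag(C), 1), n)
  res <- tryCatch(
    pracma::quadprog(C = C, d = as.numeric(-2 * crossprod(Ahat, bhat)),
                     lb = lower, ub = upper),
    error = function(e) NULL
  )
  if (is.null(res)) pmin(pmax(rep(0, n), lower), upper)
  else as.numeric(res$xmin)
}

#' Solve one force-distribution program
#'
#' The numerical kernel behind [solve_frame()]: minimizes
#' `sum((w_i x_i)^power)` (power 1, 2 or 3) or `max(w_i x_i)` subject to
#' `A x = b` and `lower <= x <= upper`. Linear programs go through the
#' simplex method with a minimum-norm polish over the optimal face; minimax
#' programs through the epigraph reformulation plus the same polish;
#' quadratic programs through a single QP; cubic programs through a
#' feasible-descent SQP with analytic derivatives and an Armijo line search.
#' A vanishing quadratic regularizer (1e-9 on the quadratic/cubic paths)
#' keeps the minimizer unique along directions the objective leaves flat.
#'
#' @param A Equality-constraint matrix (m x n).
#' @param b Right-hand side (length m).
#' @param lower,upper Variable bounds (length n).
#' @param weights Nonnegative objective weights `w_i` (0 for variables that
#'   do not enter the objective).
#' @param form `"power"` or `"maximum"`.
#' @param power Exponent for the power form (1, 2 or 3).
#' @param options A [solver_options()].
#' @param warm_start Optional starting point (length n), used by the cubic
#'   path.
#' @return List: `x` (solution, length n), `status` (`"optimal"`,
#'   `"infeasible"`, `"max_iter"`), `objective_value`, `iterations`.
#' @export
#' @examples
#' # two muscles, moment arms 0.04 and 0.02 m, required moment 2 N*m
#' A <- matrix(c(0.04, 0.02), 1)
#' solve_program(A, 2, c(0, 0), c(5000, 5000), c(1, 1), "power", 2)$x
solve_program <- function(A, b, lower, upper, weights,
                          form = c("power", "maximum"), power = 1,
                          options = solver_options(), warm_start = NULL) {
  form <- match.arg(form)
  A <- as.matrix(A)
  n <- ncol(A)
  stopifnot(length(b) == nrow(A), length(lower) == n, length(upper) == n,
            length(weights) == n, all(weights >= 0))
  x <- NULL
  status <- "optimal"
  iterations <- 0L

  if (form == "maximum") {
    widx <- which(weights > 0)
    Aepi <- matrix(0, length(widx), n + 1L)
    for (r in seq_along(widx)) Aepi[r, widx[r]] <- weights[widx[r]]
    Aepi[, n + 1L] <- -1
    r <- lp_solve(cc = c(rep(0, n), 1),
                  Aeq = cbind(A, 0), beq = b,
                  A_ineq = Aepi, b_ineq = rep(0, length(widx)),
                  upper = upper, n_iter = options$lp_max_iter)
    if (r$solved == 1L) {
      tstar <- r$x[n + 1L]
      slack <- 1e-7 * max(1, abs(tstar))
      x <- polish_min_norm(A, b, lower, upper,
                           A_extra = Aepi[, seq_len(n), drop = FALSE],
                           b_extra = rep(tstar + slack, length(widx)),
                           fallback = r$x[seq_len(n)])
    } else status <- if (r$solved == 0L) "max_iter" else "infeasible"
  } else if (power == 1) {
    r <- lp_solve(cc = weights, Aeq = A, beq = b,
                  upper = upper, n_iter = options$lp_max_iter)
    if (r$solved == 1L) {
      fstar <- sum(weights * r$x)
      slack <- 1e-7 * max(1, abs(fstar))
      x <- polish_min_norm(A, b, lower, upper,
                           A_extra = matrix(weights, 1L),
                           b_extra = fstar + slack, fallback = r$x)
    } else status <- if (r$solved == 0L) "max_iter" else "infeasible"
  } else if (power == 2) {
    r <- qp_solve(Hdiag = 2 * weights^2, d = rep(0, n), Aeq = A, beq = b,
                  lower = lower, upper = upper)
    if (r$ok) x <- r$x else status <- "infeasible"
  } else if (power == 3) {
    r <- sqp_cubic(A, b, lower, upper, weights, options, warm_start)
    x <- r$x
    status <- r$status
    iterations <- r$iterations
  } else stop("power must be 1, 2 or 3")

  if (is.null(x)) {
    x <- ls_closest_feasible(A, b, lower, upper)
    if (status == "optimal") status <- "infeasible"
  }
  x <- pmin(pmax(x, lower), upper)  # remove QP-level bound violations (~1e-8)
  value <- if (form == "maximum") max(weights * pmax(x, 0))
           else sum((weights * pmax(x, 0))^power)
  list(x = x, status = status, objective_value = value,
       iterations = iterations)
}

# feasible-descent SQP for min sum((w x)^3), s.t. Ax=b, bounds. The eps
# regularizer keeps the Hessian positive and the minimizer unique along
# directions the cubic objective leaves flat; its effect on the objective
# value is far below reporting precision.
sqp_cubic <- function(A, b, lower, upper, weights, options, warm_start) {
  n <- ncol(A)
  m <- nrow(A)
  w <- weights^3
  eps <- 1e-9

  fval <- function(x) sum(w * pmax(x, 0)^3) + eps * sum(x^2)
  grad <- function(x) 3 * w * pmax(x, 0)^2 + 2 * eps * x

  # feasible start: projection of the warm start (or origin) onto {Ax=b}
  x0 <- rep(0, n)
  if (!is.null(warm_start) && length(warm_start) == n &&
      !any(is.na(warm_start))) {
    x0 <- pmin(pmax(as.numeric(warm_start), lower), upper)
  }
  pr <- qp_solve(Hdiag = rep(2, n), d = -2 * x0, Aeq = A, beq = b,
                 lower = lower, upper = upper)
  if (!pr$ok) return(list(x = NULL, status = "infeasible", iterations = 0L))
  x <- pr$x

  status <- "max_iter"
  k <- 0L
  while (k < options$max_iter) {
    k <- k + 1L
    g <- grad(x)
    Hd <- 6 * w * pmax(x, 0) + 2 * eps
    st <- qp_solve(Hdiag = Hd, d = g, Aeq = A, beq = rep(0, m),
                   lower = lower - x, upper = upper - x)
    if (!st$ok) break
    p <- st$x
    if (max(abs(p)) <= options$step_tol * (1 + max(abs(x)))) {
      status <- "optimal"
      break
    }
    dd <- sum(g * p)
    if (dd > -1e-14 * (1 + abs(fval(x)))) {
      status <- "optimal"
      break
    }
    alpha <- 1
    f0 <- fval(x)
    while (fval(x + alpha * p) > f0 + 1e-4 * alpha * dd && alpha > 1e-12) {
      alpha <- alpha / 2
    }
    x <- x + alpha * p
  }
  list(x = x, status = status, iterations = k)
}

#' Solve the force-distribution problem for one frame
#'
#' Minimizes the selected criterion subject to the frame's equipollence
#' equalities and the nonnegativity/upper bounds, via [solve_program()] on
#' the row-scaled system. For minimax criteria the epigraph auxiliary
#' variable is stripped from the reported forces. An infeasible frame is
#' reported as such together with the residual of the bounded least-squares
#' point closest to satisfying the equalities; it is never silently relaxed.
#'
#' @param system A [assemble_equipollence()] constraint system.
#' @param spec An [objective_spec()].
#' @param props A [muscle_properties()] (PCSAs for stress criteria).
#' @param options A [solver_options()].
#' @param warm_start Optional named force vector (e.g. the previous frame's
#'   solution) used as the starting point of the cubic SQP loop.
#' @return An object of class `frame_solution`: `forces` (named, N),
#'   `objective_value` (NA when infeasible), `status` (`"optimal"`,
#'   `"infeasible"` or `"max_iter"`), `residual_force` (3-vector N for RFML,
#'   `NULL` otherwise), `residual_moment` (3-vector N*m), `iterations`.
#' @export
solve_frame <- function(system, spec, props = muscle_properties(),
                        options = solver_options(), warm_start = NULL) {
  if (!inherits(system, "constraint_system")) {
    stop("system must be created with assemble_equipollence()")
  }
  if (!inherits(spec, "objective_spec")) {
    stop("spec must be created with objective_spec()")
  }
  n <- ncol(system$A)
  muscle_idx <- which(system$kinds == "muscle")
  sc <- scale_system(system, options)
  coeffs <- objective_coefficients(spec, props)
  weights <- rep(0, n)
  weights[muscle_idx] <- coeffs[seq_along(muscle_idx)]

  ws <- NULL
  if (!is.null(warm_start)) {
    v <- warm_start[system$labels]
    if (!any(is.na(v))) ws <- as.numeric(v)
  }
  r <- solve_program(sc$A, sc$b, system$lower, system$upper, weights,
                     form = if (spec$form == "maximum") "maximum" else "power",
                     power = if (spec$form == "maximum") 1 else spec$power,
                     options = options, warm_start = ws)
  x <- r$x
  status <- r$status

  # declare optimality only if the scaled equality residual is tight
  rhat <- as.numeric(sc$A %*% x - sc$b)
  if (status == "optimal" &&
      max(abs(rhat)) > options$tol * max(1, max(abs(sc$b)))) {
    status <- "max_iter"
  }

  resid <- as.numeric(system$A %*% x - system$b)
  forces <- stats::setNames(x, system$labels)
  structure(
    list(
      forces = forces,
      objective_value = if (status == "infeasible") NA_real_ else
        evaluate_objective(pmax(forces[muscle_idx], 0), props, spec),
      status = status,
      residual_force = if (length(system$force_rows) > 0L)
        resid[system$force_rows] else NULL,
      residual_moment = resid[system$moment_rows],
      formulation = system$formulation,
      objective_id = spec$id,
      iterations = r$iterations
    ),
    class = "frame_solution"
  )
}

#' @export
print.frame_solution <- function(x, ...) {
  cat(sprintf("<frame_solution %s x %s: status %s, objective %s>\n",
              x$formulation, x$objective_id, x$status,
              format(x$objective_value)))
  invisible(x)
}

#' Solve a whole gait trial for one formulation and one criterion
#'
#' Runs an independent [solve_frame()] at every sampled instant of the gait
#' cycle, warm-starting each frame from the previous frame's solution
#' (continuity across the cycle). Failed frames carry a non-optimal status
#' and are never dropped.
#'
#' @param trial A [gen_trial()] gait trial (or any object with the same
#'   `frame_pct`, `loads` and `geometry` fields).
#' @param formulation A [formulation()].
#' @param spec An [objective_spec()].
#' @param props A [muscle_properties()].
#' @param options A [solver_options()].
#' @param contact_upper_bound Passed to [assemble_equipollence()].
#' @return An object of class `cycle_solution`: `frame_pct`, `forces`
#'   (frames x variables matrix, N), `objective_values`, `statuses`,
#'   `residual_force` (frames x 3, RFML only, otherwise `NULL`),
#'   `residual_moment` (frames x 3), `formulation`, `objective_id`,
#'   `metadata` (options and the count of non-optimal frames).
#' @export
solve_cycle <- function(trial, formulation, spec,
                        props = muscle_properties(),
                        options = solver_options(),
                        contact_upper_bound = 10000) {
  stopifnot(inherits(formulation, "formulation"),
            inherits(spec, "objective_spec"))
  grid <- trial$frame_pct
  nf <- length(grid)
  geom_by_frame <- split_geometry(trial$geometry, grid)

  n <- formulation$n_vars
  forces <- matrix(NA_real_, nf, n,
                   dimnames = list(NULL, formulation$variables))
  objective_values <- rep(NA_real_, nf)
  statuses <- character(nf)
  res_f <- if (formulation$has_force_rows) matrix(NA_real_, nf, 3L) else NULL
  res_m <- matrix(NA_real_, nf, 3L)

  warm <- NULL
  for (i in seq_len(nf)) {
    load <- resultant_load(
      force = as.numeric(trial$loads[i, c("Rx", "Ry", "Rz")]),
      moment = as.numeric(trial$loads[i, c("Mx", "My", "Mz")])
    )
    system <- assemble_equipollence(geom_by_frame[[i]], load, formulation,
                                    props, contact_upper_bound)
    sol <- solve_frame(system, spec, props, options, warm_start = warm)
    forces[i, ] <- sol$forces
    objective_values[i] <- sol$objective_value
    statuses[i] <- sol$status
    if (!is.null(res_f)) res_f[i, ] <- sol$residual_force
    res_m[i, ] <- sol$residual_moment
    if (sol$status == "optimal") warm <- sol$forces
  }

  structure(
    list(frame_pct = grid, forces = forces,
         objective_values = objective_values, statuses = statuses,
         residual_force = res_f, residual_moment = res_m,
         formulation = formulation$tag, objective_id = spec$id,
         metadata = list(options = options,
                         contact_upper_bound = contact_upper_bound,
                         n_not_optimal = sum(statuses != "optimal"))),
    class = "cycle_solution"
  )
}

#' @export
print.cycle_solution <- function(x, ...) {
  cat(sprintf(
    "<cycle_solution %s x %s: %d frames, %d non-optimal>\n",
    x$formulation, x$objective_id, length(x$frame_pct),
    x$metadata$n_not_optimal))
  invisible(x)
}

# split a long geometry table into one data.frame per frame, in grid order
split_geometry <- function(geometry, grid) {
  check_frame_geometry_df(geometry)
  if (!"frame_pct" %in% names(geometry)) {
    stop("trial geometry must carry a frame_pct column")
  }
  idx <- match(geometry$frame_pct, grid)
  if (any(is.na(idx))) stop("geometry contains frames outside the trial grid")
  out <- split(geometry, factor(idx, levels = seq_along(grid)))
  unname(out)
}
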