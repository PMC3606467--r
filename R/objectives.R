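#' The eight optimization criteria
#'
#' `objective_spec()` describes one of the eight criteria minimized when
#' distributing the joint load: sums of linear, quadratic or cubic muscle
#' forces (J1, J2, J3), the maximum muscle force (J4), and the same four
#' forms applied to muscle stresses, i.e. force divided by PCSA (J5, J6, J7,
#' J8). Only the twelve muscle variables enter any objective; ligament and
#' contact forces are free of objective cost in every criterion.
#'
#' @param id One of `"J1"` .. `"J8"`.
#' @return An object of class `objective_spec` with fields `id`, `basis`
#'   (`"force"` or `"stress"`), `form` (`"power"` or `"maximum"`) and `power`
#'   (1, 2, 3, or NA for the minimax criteria).
#' @export
#' @examples
#' objective_spec("J6")
objective_spec <- function(id) {
  id <- match.arg(id, paste0("J", 1:8))
  k <- match(id, paste0("J", 1:8))
  basis <- if (k <= 4) "force" else "stress"
  within_basis <- ((k - 1) %% 4) + 1
  if (within_basis == 4) {
    form <- "maximum"; power <- NA_real_
  } else {
    form <- "power"; power <- within_basis
  }
  structure(list(id = id, basis = basis, form = form, power = power),
            class = "objective_spec")
}

#' @export
print.objective_spec <- function(x, ...) {
  what <- if (x$form == "maximum") "maximum" else
    c("sum", "sum of quadratic", "sum of cubic")[x$power]
  cat(sprintf("<objective %s: %s of muscle %s>\n", x$id, what,
              if (x$basis == "force") "forces" else "stresses"))
  invisible(x)
}

#' All eight criterion ids
#' @return Character vector `"J1"` .. `"J8"`.
#' @export
objective_ids <- function() paste0("J", 1:8)

# per-muscle coefficients c_i such that the objective is
# sum((c_i F_i)^p) or max(c_i F_i); stress basis uses 1/PCSA (N/cm^2).
objective_coefficients <- function(spec, props) {
  if (spec$basis == "force") {
    rep(1, 12L)
  } else {
    if (is.null(props) || !inherits(props, "muscle_properties")) {
      stop("PCSA (muscle_properties) required for stress-based objective ",
           spec$id)
    }
    unname(1 / props$pcsa)
  }
}

#' Evaluate an optimization criterion on a vector of muscle forces
#'
#' @param muscle_forces Numeric vector of the 12 muscle force magnitudes (N),
#'   in canonical muscle order; must be nonnegative (tolerance 1e-9 N).
#' @param props A [muscle_properties()]; required for stress-based criteria.
#' @param spec An [objective_spec()].
#' @return Scalar objective value (N, N^2, N^3, or the stress analogues in
#'   N/cm^2 units).
#' @export
#' @examples
#' f <- c(3, 4, rep(0, 10))
#' evaluate_objective(f, muscle_properties(), objective_spec("J2"))  # 25
evaluate_objective <- function(muscle_forces, props, spec) {
  if (!inherits(spec, "objective_spec")) {
    stop("spec must be created with objective_spec()")
  }
  muscle_forces <- as.numeric(muscle_forces)
  if (length(muscle_forces) != 12L) {
    stop("muscle_forces must have length 12 (one per muscle)")
  }
  if (any(muscle_forces < -1e-9)) {
    stop("muscle forces must be nonnegative")
  }
  cf <- objective_coefficients(spec, props) * pmax(muscle_forces, 0)
  if (spec$form == "maximum") max(cf) else sum(cf^spec$power)
}

#' Epigraph reformulation of a minimax criterion
#'
#' Rewrites `min max_i(c_i F_i)` as the smooth problem `min t` subject to
#' `c_i F_i - t <= 0` for each muscle, by appending one auxiliary variable
#' `t` after the existing variables. The augmented problem's optimum equals
#' the minimax optimum.
#'
#' @param spec An [objective_spec()] with `form == "maximum"`.
#' @param n_vars Number of variables in the problem before augmentation.
#' @param props A [muscle_properties()]; required for `J8`.
#' @param muscle_idx Indices of the 12 muscle variables among the `n_vars`
#'   (default the first 12).
#' @return A list: `objective` (length `n_vars + 1` linear cost, all zero
#'   except 1 on `t`), `A_ineq` (12 x (`n_vars` + 1) rows `c_i F_i - t <= 0`),
#'   `b_ineq` (zeros), and `t_index = n_vars + 1`.
#' @export
epigraph_reformulate <- function(spec, n_vars, props = NULL,
                                 muscle_idx = 1:12) {
  if (!inherits(spec, "objective_spec") || spec$form != "maximum") {
    stop("epigraph_reformulate() applies only to maximum-form objectives")
  }
  if (n_vars < max(muscle_idx)) {
    stop("n_vars smaller than the largest muscle index")
  }
  coeffs <- objective_coefficients(spec, props)
  A <- matrix(0, length(muscle_idx), n_vars + 1L)
  for (r in seq_along(muscle_idx)) A[r, muscle_idx[r]] <- coeffs[r]
  A[, n_vars + 1L] <- -1
  list(objective = c(rep(0, n_vars), 1), A_ineq = A,
       b_ineq = rep(0, length(muscle_idx)), t_index = n_vars + 1L)
}
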