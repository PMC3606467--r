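#' Problem formulation: which variables and which equipollence equations
#'
#' Three formulations are compared throughout the package:
#' \describe{
#'   \item{RM}{muscle and contact force magnitudes (14 variables), moment
#'     equipollence only (3 equations);}
#'   \item{RML}{muscle, ligament and contact force magnitudes (18 variables),
#'     moment equipollence only (3 equations);}
#'   \item{RFML}{the same 18 variables, simultaneous force and moment
#'     equipollence (6 equations).}
#' }
#'
#' @param tag One of `"RM"`, `"RML"`, `"RFML"`.
#' @return An object of class `formulation` with fields `tag`, `variables`
#'   (structure names in canonical order), `n_vars`, `has_force_rows` and
#'   `n_constraints`.
#' @export
#' @examples
#' formulation("RFML")$n_constraints  # 6
formulation <- function(tag) {
  tag <- match.arg(tag, c("RM", "RML", "RFML"))
  s <- knee_structures()
  vars <- if (tag == "RM") {
    s$structure[s$kind != "ligament"]
  } else {
    s$structure
  }
  structure(
    list(tag = tag, variables = vars, n_vars = length(vars),
         has_force_rows = (tag == "RFML"),
         n_constraints = if (tag == "RFML") 6L else 3L),
    class = "formulation"
  )
}

#' @export
print.formulation <- function(x, ...) {
  cat(sprintf("<formulation %s: %d variables, %d equipollence equations%s>\n",
              x$tag, x$n_vars, x$n_constraints,
              if (x$has_force_rows) " (force + moment)" else " (moment only)"))
  invisible(x)
}

#' Assemble the equipollence constraint system for one frame
#'
#' Builds the linear equality system `A x = b` whose unknowns `x` are the
#' nonnegative force magnitudes of the formulation's structures. Force rows
#' (RFML only) hold the unit direction components of each structure; moment
#' rows hold the components of `lever_arm x direction`. The right-hand side
#' is the resultant force `R` and/or moment `M`. Muscles and ligaments are
#' bounded above by `props$force_upper_bound`; contacts, which must absorb
#' the summed compressive load of all muscles, get their own (larger) bound.
#'
#' @param geometry Frame-geometry data.frame (see
#'   [validate_frame_geometry()]) covering at least the formulation's
#'   structures.
#' @param load A [resultant_load()].
#' @param formulation A [formulation()].
#' @param props A [muscle_properties()].
#' @param contact_upper_bound Upper bound in N on each contact force
#'   magnitude (default 10000 N).
#' @return An object of class `constraint_system`: `A` (matrix,
#'   `n_constraints` x `n_vars`), `b`, `lower`, `upper`, `labels` (column
#'   structure names), `kinds`, `formulation` tag, and `force_rows` /
#'   `moment_rows` row indices into `A` (`force_rows` empty for RM/RML).
#' @export
assemble_equipollence <- function(geometry, load, formulation, props,
                                  contact_upper_bound = 10000) {
  check_frame_geometry_df(geometry)
  if (!inherits(load, "resultant_load")) stop("load must be a resultant_load")
  if (!inherits(formulation, "formulation")) {
    stop("formulation must be created with formulation()")
  }
  if (!inherits(props, "muscle_properties")) {
    stop("props must be created with muscle_properties()")
  }
  if (!is.finite(contact_upper_bound) || contact_upper_bound <= 0) {
    stop("contact_upper_bound must be finite and > 0")
  }

  vars <- formulation$variables
  missing <- setdiff(vars, geometry$structure)
  if (length(missing) > 0L) {
    stop("missing geometry for structure(s): ", paste(missing, collapse = ", "))
  }
  idx <- match(vars, geometry$structure)

  n <- length(vars)
  Af <- matrix(0, 3L, n)  # force rows: direction components
  Am <- matrix(0, 3L, n)  # moment rows: lever x direction
  kinds <- geometry$kind[idx]
  for (j in seq_len(n)) {
    g <- line_of_action(
      direction = as.numeric(geometry[idx[j], c("lx", "ly", "lz")]),
      lever_arm = as.numeric(geometry[idx[j], c("dx", "dy", "dz")])
    )
    Af[, j] <- g$direction
    Am[, j] <- moment_contribution(g)
  }

  if (formulation$has_force_rows) {
    A <- rbind(Af, Am)
    b <- c(load$force, load$moment)
    force_rows <- 1:3
    moment_rows <- 4:6
  } else {
    A <- Am
    b <- load$moment
    force_rows <- integer(0)
    moment_rows <- 1:3
  }
  dimnames(A) <- list(NULL, vars)

  upper <- ifelse(kinds == "contact", contact_upper_bound,
                  props$force_upper_bound)
  structure(
    list(A = A, b = b, lower = rep(0, n), upper = upper,
         labels = vars, kinds = kinds, formulation = formulation$tag,
         force_rows = force_rows, moment_rows = moment_rows),
    class = "constraint_system"
  )
}

#' @export
print.constraint_system <- function(x, ...) {
  cat(sprintf("<constraint_system %s: %d equations x %d variables>\n",
              x$formulation, nrow(x$A), ncol(x$A)))
  invisible(x)
}
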