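#' Unbalanced force vector of a moment-only solution
#'
#' When only moment equipollence is enforced (RM, RML), the solved forces
#' need not satisfy force equipollence; the unbalanced force vector
#' `e = sum(F_i * l_i) - R` over the formulation's structures measures that
#' error. For RFML solutions it equals the solver's force-row residual and
#' is near zero on optimal frames (useful for verification).
#'
#' @param solution A [solve_frame()] result.
#' @param geometry The same frame-geometry data.frame the solution was
#'   assembled from.
#' @param load The frame's [resultant_load()].
#' @return Numeric length-3 vector, N.
#' @export
unbalanced_force <- function(solution, geometry, load) {
  stopifnot(inherits(solution, "frame_solution"),
            inherits(load, "resultant_load"))
  check_frame_geometry_df(geometry)
  vars <- names(solution$forces)
  idx <- match(vars, geometry$structure)
  if (any(is.na(idx))) {
    stop("geometry does not cover the solution's structures: ",
         paste(vars[is.na(idx)], collapse = ", "))
  }
  L <- as.matrix(geometry[idx, c("lx", "ly", "lz")])
  as.numeric(crossprod(L, solution$forces)) - load$force
}

#' Total ligament force vector
#'
#' The vector sum of the four ligament force contributions
#' `L = sum(F_j * l_j)` in the tibia frame, defined for formulations that
#' carry ligament variables (RML, RFML).
#'
#' @param solution A [solve_frame()] result from an RML or RFML problem.
#' @param geometry The frame-geometry data.frame.
#' @return Numeric length-3 vector, N.
#' @export
total_ligament_force <- function(solution, geometry) {
  stopifnot(inherits(solution, "frame_solution"))
  check_frame_geometry_df(geometry)
  ligs <- ligament_names()
  if (!all(ligs %in% names(solution$forces))) {
    stop("total ligament force is undefined for formulation ",
         solution$formulation, " (no ligament variables)")
  }
  idx <- match(ligs, geometry$structure)
  if (any(is.na(idx))) stop("geometry lacks ligament rows")
  L <- as.matrix(geometry[idx, c("lx", "ly", "lz")])
  as.numeric(crossprod(L, solution$forces[ligs]))
}

# cycle-level wrappers -------------------------------------------------------

#' Per-frame unbalanced force vectors over a cycle
#'
#' @param cycle A [solve_cycle()] result (RM or RML; RFML allowed for
#'   verification).
#' @param trial The gait trial the cycle was solved on.
#' @return Matrix, frames x 3 (columns x, y, z), N.
#' @export
unbalanced_forces_cycle <- function(cycle, trial) {
  stopifnot(inherits(cycle, "cycle_solution"))
  geom_by_frame <- split_geometry(trial$geometry, trial$frame_pct)
  out <- matrix(NA_real_, length(trial$frame_pct), 3L,
                dimnames = list(NULL, c("x", "y", "z")))
  for (i in seq_along(trial$frame_pct)) {
    g <- geom_by_frame[[i]]
    idx <- match(colnames(cycle$forces), g$structure)
    L <- as.matrix(g[idx, c("lx", "ly", "lz")])
    R <- as.numeric(trial$loads[i, c("Rx", "Ry", "Rz")])
    out[i, ] <- as.numeric(crossprod(L, cycle$forces[i, ])) - R
  }
  out
}

#' Per-frame total ligament force vectors over a cycle
#'
#' @inheritParams unbalanced_forces_cycle
#' @return Matrix, frames x 3, N.
#' @export
ligament_forces_cycle <- function(cycle, trial) {
  stopifnot(inherits(cycle, "cycle_solution"))
  ligs <- ligament_names()
  if (!all(ligs %in% colnames(cycle$forces))) {
    stop("formulation ", cycle$formulation, " carries no ligament variables")
  }
  geom_by_frame <- split_geometry(trial$geometry, trial$frame_pct)
  out <- matrix(NA_real_, length(trial$frame_pct), 3L,
                dimnames = list(NULL, c("x", "y", "z")))
  for (i in seq_along(trial$frame_pct)) {
    g <- geom_by_frame[[i]]
    idx <- match(ligs, g$structure)
    L <- as.matrix(g[idx, c("lx", "ly", "lz")])
    out[i, ] <- as.numeric(crossprod(L, cycle$forces[i, ligs]))
  }
  out
}

#' Summed contact force magnitude per frame
#'
#' The knee contact force reported by the package is the sum of the medial
#' and lateral contact magnitudes; the compartment split stays available in
#' the solution itself.
#'
#' @param cycle A [solve_cycle()] result.
#' @return Numeric vector, one value per frame, N.
#' @export
contact_force_total <- function(cycle) {
  stopifnot(inherits(cycle, "cycle_solution"))
  rowSums(cycle$forces[, contact_names(), drop = FALSE])
}

# scalar summaries -----------------------------------------------------------

#' Per-axis RMS of a per-frame vector series
#'
#' For each axis, `sqrt(mean(component^2))` over all frames of the cycle.
#'
#' @param series Matrix (frames x axes) or numeric vector (one axis).
#' @return Numeric vector of per-axis RMS values (same units as the input).
#' @export
#' @examples
#' rms_over_cycle(cbind(x = c(3, 4), y = c(0, 0)))  # sqrt(12.5), 0
rms_over_cycle <- function(series) {
  if (is.null(dim(series))) series <- matrix(series, ncol = 1L)
  if (nrow(series) < 1L) stop("rms_over_cycle() needs at least one frame")
  if (any(!is.finite(series))) stop("series contains non-finite values")
  sqrt(colMeans(series^2))
}

#' Convert forces from newtons to body weights
#'
#' @param values Numeric forces in N (any shape).
#' @param body_weight Body weight in N (mass times gravitational
#'   acceleration); must be > 0.
#' @return `values / body_weight`, in BW.
#' @export
to_bw <- function(values, body_weight) {
  if (!is.numeric(body_weight) || length(body_weight) != 1L ||
      !is.finite(body_weight) || body_weight <= 0) {
    stop("body_weight must be a single positive number (N)")
  }
  values / body_weight
}

#' Default gait-cycle windows for contact-force peak extraction
#'
#' First-peak, second-peak and swing windows in percent gait cycle. The
#' defaults bracket the typical early-stance (about 10% GC) and late-stance
#' (about 40% GC) contact-force peaks, with the stance-swing transition taken
#' at 62% GC.
#'
#' @param first,second,swing Length-2 numeric ranges within 0-100.
#' @return Named list of the three windows.
#' @export
peak_windows <- function(first = c(0, 30), second = c(30, 62),
                         swing = c(62, 100)) {
  w <- list(first = first, second = second, swing = swing)
  for (nm in names(w)) {
    r <- w[[nm]]
    if (length(r) != 2L || any(r < 0) || any(r > 100) || r[1] >= r[2]) {
      stop("window '", nm, "' must be an increasing range within 0-100% GC")
    }
  }
  w
}

#' Contact-force peak metrics over the gait cycle
#'
#' Maxima of the total contact force within the first-peak, second-peak and
#' swing windows, plus their locations in percent gait cycle.
#'
#' @param contact_total Numeric per-frame total contact force (any unit; BW
#'   if already normalized).
#' @param frame_pct Percent-gait-cycle grid, same length.
#' @param windows A [peak_windows()] list.
#' @return List: `first_peak`, `first_peak_pct`, `second_peak`,
#'   `second_peak_pct`, `swing_max`, `swing_max_pct`.
#' @export
extract_contact_peaks <- function(contact_total, frame_pct,
                                  windows = peak_windows()) {
  if (length(contact_total) != length(frame_pct)) {
    stop("contact_total and frame_pct must have the same length")
  }
  windows <- peak_windows(windows$first, windows$second, windows$swing)
  window_max <- function(rng) {
    sel <- frame_pct >= rng[1] & frame_pct <= rng[2]
    if (!any(sel)) stop("no frames inside window [", rng[1], ", ", rng[2], "]")
    i <- which(sel)[which.max(contact_total[sel])]
    c(value = contact_total[i], pct = frame_pct[i])
  }
  f <- window_max(windows$first)
  s <- window_max(windows$second)
  w <- window_max(windows$swing)
  list(first_peak = unname(f["value"]), first_peak_pct = unname(f["pct"]),
       second_peak = unname(s["value"]), second_peak_pct = unname(s["pct"]),
       swing_max = unname(w["value"]), swing_max_pct = unname(w["pct"]))
}

# study-style tables ----------------------------------------------------------

#' Per-axis RMS table of unbalanced and ligament-force errors
#'
#' Builds the summary matrix comparing formulations across all criteria:
#' per-axis RMS over the gait cycle of (i) the unbalanced force vector of RM,
#' (ii) the unbalanced force vector of RML, and (iii) the componentwise
#' difference between the total ligament force under RML and under RFML.
#' Values are expressed in body weights.
#'
#' @param solutions Nested list of [solve_cycle()] results indexed as
#'   `solutions[[formulation]][[objective_id]]`, covering RM, RML and RFML
#'   for every requested objective.
#' @param trial The gait trial the solutions were computed on.
#' @param objectives Character vector of objective ids (columns).
#' @return A data.frame with columns `quantity` (`e_RM`, `e_RML`,
#'   `L_RML_minus_L_RFML`), `axis` (x, y, z) and one column per objective
#'   (RMS in BW).
#' @export
rms_summary_table <- function(solutions, trial,
                              objectives = objective_ids()) {
  bw <- trial$body_weight
  rows <- expand.grid(axis = c("x", "y", "z"),
                      quantity = c("e_RM", "e_RML", "L_RML_minus_L_RFML"),
                      stringsAsFactors = FALSE)[, 2:1]
  out <- rows
  for (obj in objectives) {
    e_rm <- unbalanced_forces_cycle(solutions[["RM"]][[obj]], trial)
    e_rml <- unbalanced_forces_cycle(solutions[["RML"]][[obj]], trial)
    dL <- ligament_forces_cycle(solutions[["RML"]][[obj]], trial) -
      ligament_forces_cycle(solutions[["RFML"]][[obj]], trial)
    vals <- c(rms_over_cycle(to_bw(e_rm, bw)),
              rms_over_cycle(to_bw(e_rml, bw)),
              rms_over_cycle(to_bw(dL, bw)))
    out[[obj]] <- unname(vals)
  }
  out
}

#' Contact-force peak table per formulation and criterion
#'
#' @inheritParams rms_summary_table
#' @param windows A [peak_windows()] list.
#' @return A data.frame with one row per formulation x objective:
#'   `first_peak_bw`, `first_peak_pct`, `second_peak_bw`, `second_peak_pct`,
#'   `swing_max_bw`, `swing_max_pct`, `n_not_optimal`.
#' @export
contact_peak_table <- function(solutions, trial,
                               objectives = objective_ids(),
                               windows = peak_windows()) {
  bw <- trial$body_weight
  rows <- list()
  for (form in names(solutions)) {
    for (obj in objectives) {
      cyc <- solutions[[form]][[obj]]
      pk <- extract_contact_peaks(to_bw(contact_force_total(cyc), bw),
                                  cyc$frame_pct, windows)
      rows[[length(rows) + 1L]] <- data.frame(
        formulation = form, objective = obj,
        first_peak_bw = pk$first_peak, first_peak_pct = pk$first_peak_pct,
        second_peak_bw = pk$second_peak, second_peak_pct = pk$second_peak_pct,
        swing_max_bw = pk$swing_max, swing_max_pct = pk$swing_max_pct,
        n_not_optimal = cyc$metadata$n_not_optimal,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
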