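# CSV/YAML interfaces. All numeric cells are written with 17 significant
# digits so files round-trip to full double precision and reruns are
# byte-identical.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}

write_numeric_csv <- function(df, path, units_comment = NULL) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(units_comment)) writeLines(paste0("# ", units_comment), con)
  utils::write.table(out, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_csv_checked <- function(path, required_cols, numeric_cols, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0L) {
    stop(what, " file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !(df[[col]] %in% c("NA", "")))
    if (length(bad) > 0L) {
      stop(what, " file ", path, ": non-numeric value in column '", col,
           "', row ", bad[1], " ('", df[[col]][bad[1]], "')")
    }
    df[[col]] <- v
  }
  df
}

#' Write / read a resultant-load series
#'
#' Schema: columns `frame_pct`, `Rx`, `Ry`, `Rz` (N), `Mx`, `My`, `Mz`
#' (N*m), one row per frame, plus a leading `#` units comment. The reader
#' validates the schema, rejects duplicate frames, names any non-numeric
#' cell, and sorts (with a warning) if rows arrive shuffled.
#'
#' @param loads Data.frame in the schema above.
#' @param path File path.
#' @return `read_loads_csv()`: the validated, frame-ordered data.frame.
#' @export
write_loads_csv <- function(loads, path) {
  need <- c("frame_pct", "Rx", "Ry", "Rz", "Mx", "My", "Mz")
  stopifnot(all(need %in% names(loads)))
  write_numeric_csv(loads[need], path,
                    "units: frame_pct %GC; Rx,Ry,Rz N; Mx,My,Mz N.m")
}

#' @rdname write_loads_csv
#' @export
read_loads_csv <- function(path) {
  need <- c("frame_pct", "Rx", "Ry", "Rz", "Mx", "My", "Mz")
  df <- read_csv_checked(path, need, need, "loads")
  if (anyDuplicated(df$frame_pct)) {
    stop("loads file ", path, ": duplicate frame_pct value ",
         df$frame_pct[duplicated(df$frame_pct)][1])
  }
  if (is.unsorted(df$frame_pct)) {
    warning("loads file ", path, ": rows not ordered by frame_pct; sorting")
    df <- df[order(df$frame_pct), , drop = FALSE]
    rownames(df) <- NULL
  }
  df[need]
}

#' Write / read a per-frame structure geometry table
#'
#' Long-format schema: `frame_pct`, `structure`, `kind` (muscle, ligament or
#' contact), unit direction `lx`, `ly`, `lz`, and lever arm `dx`, `dy`, `dz`
#' (m). The reader checks structure names against the model's structure set,
#' verifies completeness (every required structure present at every frame),
#' and validates unit norms and lever-arm bounds, naming the offending frame
#' and structure.
#'
#' @param geometry Long-format geometry data.frame.
#' @param path File path.
#' @param structure_set Data.frame of valid structures ([knee_structures()]).
#' @param required Character vector of structures that must be present at
#'   every frame (default: all of `structure_set`; pass
#'   `formulation(...)$variables` to check a single formulation's needs).
#' @return `read_geometry_csv()`: the validated geometry data.frame.
#' @export
write_geometry_csv <- function(geometry, path) {
  need <- c("frame_pct", "structure", "kind",
            "lx", "ly", "lz", "dx", "dy", "dz")
  stopifnot(all(need %in% names(geometry)))
  write_numeric_csv(geometry[need], path,
                    "units: frame_pct %GC; lx..lz unit direction; dx..dz m")
}

#' @rdname write_geometry_csv
#' @export
read_geometry_csv <- function(path, structure_set = knee_structures(),
                              required = structure_set$structure) {
  need <- c("frame_pct", "structure", "kind",
            "lx", "ly", "lz", "dx", "dy", "dz")
  df <- read_csv_checked(path, need,
                         c("frame_pct", "lx", "ly", "lz", "dx", "dy", "dz"),
                         "geometry")
  unknown <- setdiff(unique(df$structure), structure_set$structure)
  if (length(unknown) > 0L) {
    stop("geometry file ", path, ": unknown structure(s): ",
         paste(unknown, collapse = ", "))
  }
  frames <- sort(unique(df$frame_pct))
  key <- paste(df$frame_pct, df$structure)
  want <- expand.grid(frame_pct = frames, structure = required,
                      stringsAsFactors = FALSE)
  gap <- !(paste(want$frame_pct, want$structure) %in% key)
  if (any(gap)) {
    miss <- want[gap, , drop = FALSE]
    stop("geometry file ", path, ": missing (frame, structure) pair(s): ",
         paste(utils::head(paste0(miss$frame_pct, "%/", miss$structure), 10L),
               collapse = ", "),
         if (sum(gap) > 10L) sprintf(" and %d more", sum(gap) - 10L) else "")
  }
  for (f in frames) {
    viol <- validate_frame_geometry(df[df$frame_pct == f, , drop = FALSE])
    if (nrow(viol) > 0L) {
      stop("geometry file ", path, ": frame ", f, "%, structure ",
           viol$structure[1], ": ", viol$problem[1])
    }
  }
  df <- df[order(df$frame_pct, match(df$structure,
                                     structure_set$structure)), , drop = FALSE]
  rownames(df) <- NULL
  df[need]
}

#' Write / read a PCSA table (YAML map, muscle name to cm^2)
#'
#' @param pcsa Named numeric vector of PCSAs in cm^2.
#' @param path File path.
#' @return `read_pcsa_yaml()`: named numeric vector.
#' @export
write_pcsa_yaml <- function(pcsa, path) {
  yaml::write_yaml(as.list(pcsa), path, precision = 15L)
  invisible(path)
}

#' @rdname write_pcsa_yaml
#' @export
read_pcsa_yaml <- function(path) {
  if (!file.exists(path)) stop("PCSA file not found: ", path)
  v <- unlist(yaml::read_yaml(path))
  if (!is.numeric(v)) stop("PCSA file ", path, " must map names to numbers")
  v
}

#' Write / read a full synthetic trial directory
#'
#' Writes `loads.csv`, `geometry.csv`, `flexion.csv` and `trial.yaml`
#' (body mass, body weight, seed) so a trial round-trips through the
#' package's own readers.
#'
#' @param trial A [gen_trial()] object.
#' @param dir Output directory (created if needed).
#' @return `read_trial()`: the reconstructed `gait_trial`.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "gait_trial"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_loads_csv(trial$loads, file.path(dir, "loads.csv"))
  write_geometry_csv(trial$geometry, file.path(dir, "geometry.csv"))
  write_numeric_csv(data.frame(frame_pct = trial$frame_pct,
                               flexion_deg = trial$flexion_deg),
                    file.path(dir, "flexion.csv"),
                    "units: frame_pct %GC; flexion_deg degrees")
  yaml::write_yaml(list(body_mass_kg = trial$body_mass,
                        body_weight_n = trial$body_weight,
                        seed = trial$seed),
                   file.path(dir, "trial.yaml"), precision = 15L)
  invisible(dir)
}

#' @rdname write_trial
#' @export
read_trial <- function(dir) {
  loads <- read_loads_csv(file.path(dir, "loads.csv"))
  geometry <- read_geometry_csv(file.path(dir, "geometry.csv"))
  flex <- read_csv_checked(file.path(dir, "flexion.csv"),
                           c("frame_pct", "flexion_deg"),
                           c("frame_pct", "flexion_deg"), "flexion")
  meta <- yaml::read_yaml(file.path(dir, "trial.yaml"))
  structure(
    list(frame_pct = loads$frame_pct, flexion_deg = flex$flexion_deg,
         loads = loads, geometry = geometry,
         body_mass = meta$body_mass_kg, body_weight = meta$body_weight_n,
         seed = as.integer(meta$seed)),
    class = "gait_trial"
  )
}

#' Write a cycle solution as CSV
#'
#' Schema: `frame_pct`, one force column per structure (N),
#' `objective_value`, `status`.
#'
#' @param cycle A [solve_cycle()] result.
#' @param path File path.
#' @return `read_solution_csv()`: the solution table as a data.frame.
#' @export
write_solution_csv <- function(cycle, path) {
  stopifnot(inherits(cycle, "cycle_solution"))
  df <- data.frame(frame_pct = cycle$frame_pct, check.names = FALSE)
  df <- cbind(df, as.data.frame(cycle$forces))
  df$objective_value <- cycle$objective_values
  df$status <- cycle$statuses
  write_numeric_csv(df, path,
                    sprintf("formulation %s, objective %s; forces N",
                            cycle$formulation, cycle$objective_id))
}

#' @rdname write_solution_csv
#' @export
read_solution_csv <- function(path) {
  if (!file.exists(path)) stop("solution file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (!all(c("frame_pct", "status") %in% names(df))) {
    stop("solution file ", path, " lacks the frame_pct/status columns")
  }
  df
}
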