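#' Gaussian-bump waveform parameters
#'
#' Load and flexion waveforms are mixtures of Gaussian bumps over the
#' percent-gait-cycle axis plus a constant baseline: bumps give direct,
#' testable control over peak counts, locations and widths.
#'
#' @param bumps Data.frame (or NULL for none) with columns `amp`, `center`
#'   (% GC, within 0-100) and `width` (% GC, > 0).
#' @param baseline Constant offset.
#' @param noise_sd Standard deviation of optional additive Gaussian noise
#'   (same unit as the waveform); 0 keeps the waveform deterministic.
#' @return A list of class `waveform_params`.
#' @export
waveform_params <- function(bumps = NULL, baseline = 0, noise_sd = 0) {
  if (is.null(bumps)) {
    bumps <- data.frame(amp = numeric(), center = numeric(),
                        width = numeric())
  }
  stopifnot(is.data.frame(bumps),
            all(c("amp", "center", "width") %in% names(bumps)))
  if (any(bumps$width <= 0)) stop("bump widths must be > 0")
  if (any(bumps$center < 0 | bumps$center > 100)) {
    stop("bump centers must lie within 0-100% GC")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(bumps = bumps, baseline = baseline, noise_sd = noise_sd),
            class = "waveform_params")
}

bumps_df <- function(...) {
  m <- matrix(c(...), ncol = 3L, byrow = TRUE)
  data.frame(amp = m[, 1], center = m[, 2], width = m[, 3])
}

# deterministic part of a waveform on the grid
eval_waveform <- function(params, grid) {
  y <- rep(params$baseline, length(grid))
  b <- params$bumps
  for (k in seq_len(nrow(b))) {
    y <- y + b$amp[k] * exp(-0.5 * ((grid - b$center[k]) / b$width[k])^2)
  }
  y
}

# run code with a private RNG stream, restoring the caller's RNG state
with_private_rng <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Default knee flexion waveform parameters
#'
#' A small stance flexion wave (about 20 degrees near 15% GC) and the swing
#' flexion peak (about 60 degrees near 72% GC) over a few degrees of
#' baseline flexion.
#'
#' @return A [waveform_params()] object (degrees).
#' @export
default_flexion_params <- function() {
  waveform_params(bumps_df(17, 15, 8,
                           57, 72, 9),
                  baseline = 3)
}

#' Generate the knee flexion angle over the gait cycle
#'
#' @param params A [waveform_params()] (degrees).
#' @param grid Percent-gait-cycle sample grid.
#' @return Numeric vector of flexion angles (degrees), one per grid point.
#' @export
gen_flexion_angle <- function(params = default_flexion_params(),
                              grid = seq(0, 100, length.out = 101)) {
  check_grid(grid)
  eval_waveform(params, grid)
}

#' Default resultant-load waveform parameters
#'
#' One [waveform_params()] per load component, emulating the canonical
#' intersegmental knee load patterns of level walking: a compressive
#' (inferior, negative y) force with a two-peak stance pattern on the order
#' of one body weight and small swing values; anterior/posterior and
#' medial/lateral force components an order of magnitude smaller; a biphasic
#' extensor/flexor moment about z; and a two-peaked frontal-plane moment
#' about x whose sign (negative under the x-anterior/y-superior/z-right
#' axes with structure-side moments) loads the medial compartment.
#'
#' @param body_weight Body weight in N (scales the force components).
#' @param noise_sd Common noise standard deviation applied to every
#'   component (forces in N, moments in N*m); default 0.
#' @return Named list of [waveform_params()] for `Rx`, `Ry`, `Rz` (N) and
#'   `Mx`, `My`, `Mz` (N*m).
#' @export
default_load_params <- function(body_weight, noise_sd = 0) {
  W <- body_weight
  list(
    Rx = waveform_params(bumps_df(0.05 * W, 10, 6,
                                  -0.04 * W, 50, 8), 0, noise_sd),
    Ry = waveform_params(bumps_df(-0.90 * W, 15, 7,
                                  -1.00 * W, 45, 7), -0.08 * W, noise_sd),
    Rz = waveform_params(bumps_df(0.01 * W, 30, 15), 0, noise_sd),
    Mx = waveform_params(bumps_df(-24, 15, 8,
                                  -27, 45, 8), 0, noise_sd),
    My = waveform_params(bumps_df(-0.5, 15, 8,
                                  0.8, 45, 10), 0, noise_sd),
    Mz = waveform_params(bumps_df(22, 14, 7,
                                  -16, 45, 8,
                                  -4, 74, 8), 0, noise_sd)
  )
}

#' Load parameters that are mechanically inconsistent with the geometry
#'
#' A deliberately infeasible variant of [default_load_params()]: a lateral
#' (z) force of several body weights that exceeds what the model's nearly
#' sagittal lines of action can supply even at their force bounds. Used to
#' exercise the solver's infeasibility reporting.
#'
#' @inheritParams default_load_params
#' @return Named list of [waveform_params()].
#' @export
inconsistent_load_params <- function(body_weight, noise_sd = 0) {
  p <- default_load_params(body_weight, noise_sd)
  p$Rz <- waveform_params(bumps_df(5 * body_weight, 40, 25),
                          1.5 * body_weight, noise_sd)
  p
}

#' Generate per-frame resultant loads
#'
#' @param params Named list of [waveform_params()] for `Rx`, `Ry`, `Rz`,
#'   `Mx`, `My`, `Mz` (see [default_load_params()]).
#' @param grid Percent-gait-cycle grid.
#' @param seed Integer seed for the optional noise (used only when some
#'   `noise_sd > 0`); identical seeds give identical series.
#' @return Data.frame: `frame_pct`, `Rx`, `Ry`, `Rz` (N), `Mx`, `My`, `Mz`
#'   (N*m).
#' @export
gen_resultant_loads <- function(params, grid = seq(0, 100, length.out = 101),
                                seed = 0L) {
  check_grid(grid)
  comp <- c("Rx", "Ry", "Rz", "Mx", "My", "Mz")
  if (!all(comp %in% names(params))) {
    stop("params must contain waveform_params for: ",
         paste(comp, collapse = ", "))
  }
  out <- data.frame(frame_pct = grid)
  noisy <- any(vapply(params[comp], function(p) p$noise_sd > 0, logical(1)))
  gen_one <- function(p) {
    y <- eval_waveform(p, grid)
    if (p$noise_sd > 0) y <- y + stats::rnorm(length(grid), 0, p$noise_sd)
    y
  }
  if (noisy) {
    out[comp] <- with_private_rng(seed, lapply(params[comp], gen_one))
  } else {
    out[comp] <- lapply(params[comp], gen_one)
  }
  out
}

# closed-form geometry template ----------------------------------------------

#' Default geometry-template parameters
#'
#' One row per structure: the lever-arm vector `dx, dy, dz` (m, from the
#' joint center), the sagittal direction angle at full extension `phi0`
#' (degrees from the +y axis toward +x) with its per-degree-of-flexion slope
#' `dphi`, the out-of-sagittal direction component `zdir0` with slope
#' `dzdir`, and `ysign` (+1 for structures pulling the shank superiorly,
#' -1 for the contacts, along which the femur pushes the tibia inferiorly).
#' The quadriceps act through a patellar tendon whose direction rotates
#' posteriorly with flexion (extensor moment arm about 0.04 m near full
#' extension); hamstrings and gastrocnemius carry flexor moment arms of
#' 0.02-0.03 m. The passive structures are pure force elements with, at
#' most, a frontal-plane (varus-valgus) moment arm, which is their
#' physiological restraint role: the cruciates (posterior-superior ACL,
#' anterior-superior PCL) cross through the joint center -- their lever arm
#' lies along the line of action (`d_along`), so they carry
#' anterior/posterior force but no moment; the collaterals are vertical in
#' the sagittal plane with medial/lateral lever offsets, giving frontal
#' moment arms comparable to the contacts; the contacts act along -y (the
#' femur pressing the tibia inferiorly) at plateau points offset 0.025 m
#' medially/laterally. Passive structures with sagittal or transverse
#' moment arms would act as objective-cost-free moment generators and
#' produce unphysiological internal preloads under every criterion.
#'
#' @return Data.frame of per-structure template constants (`d_along` > 0
#'   marks a lever arm of that length directed along the line of action).
#' @export
default_geometry_params <- function() {
  s <- knee_structures()
  p <- data.frame(
    structure = s$structure, kind = s$kind,
    dx = c( 0.035, -0.0245, -0.0250, -0.0255, -0.0262, -0.0300, -0.0300,
            0.035,  0.035,  0.035,  0.040,  0.040,
            0.000,  0.000,  0.000,  0.000,
            0.000,  0.000),
    dy = c(-0.030, -0.030, -0.028, -0.026, -0.026, -0.008, -0.008,
           -0.030, -0.030, -0.030, -0.025, -0.025,
            0.000,  0.000, -0.010, -0.010,
           -0.004, -0.004),
    dz = c( 0.000, -0.018, -0.025,  0.028,  0.024, -0.020,  0.020,
            0.000, -0.024,  0.024,  0.012,  0.012,
            0.000,  0.000, -0.030,  0.028,
           -0.025,  0.025),
    d_along = c(rep(0, 12L), 0.015, 0.014, 0, 0, 0, 0),
    phi0 = c(15, -12, -12, -12, -10, -12, -12, 15, 15, 15, -3, 3,
             -50, 52, 0, 0, 0, 0),
    dphi = c(-0.35, -0.25, -0.25, -0.25, -0.25, -0.25, -0.25,
             -0.35, -0.35, -0.35, -0.05, -0.05,
             -0.15, -0.10, 0, 0, 0, 0),
    zdir0 = c(0.00, -0.03, -0.018, 0.018, 0.03, -0.024, 0.024,
              0.00, -0.006, 0.006, -0.01, -0.01,
              0.10, -0.08, 0.25, -0.25, 0.00, 0.00),
    dzdir = rep(0, 18L),
    ysign = c(rep(1, 16L), -1, -1),
    stringsAsFactors = FALSE
  )
  p
}

#' Evaluate the closed-form geometry template at one flexion angle
#'
#' Directions rotate smoothly with flexion in the sagittal plane (angle
#' `phi0 + dphi * flexion` from the +y axis), carry an out-of-sagittal
#' component `zdir0 + dzdir * flexion`, and are normalized to unit length.
#' Lever arms are the template constants, except where `d_along > 0`
#' (cruciates): there the lever arm is `-d_along` times the current unit
#' direction, i.e. the structure's line of action passes through the joint
#' center at every flexion angle.
#'
#' @param flexion_deg Knee flexion angle in degrees, within 0-90.
#' @param params A [default_geometry_params()] table.
#' @return Frame-geometry data.frame (`structure`, `kind`, `lx`..`dz`).
#' @export
geometry_template <- function(flexion_deg, params = default_geometry_params()) {
  if (!is.finite(flexion_deg) || flexion_deg < 0 || flexion_deg > 90) {
    stop("flexion angle must lie within the template's 0-90 degree range; got ",
         format(flexion_deg))
  }
  phi <- (params$phi0 + params$dphi * flexion_deg) * pi / 180
  z <- params$zdir0 + params$dzdir * flexion_deg
  lx <- sin(phi)
  ly <- params$ysign * cos(phi)
  nrm <- sqrt(lx^2 + ly^2 + z^2)
  lx <- lx / nrm
  ly <- ly / nrm
  lz <- z / nrm
  dx <- params$dx
  dy <- params$dy
  dz <- params$dz
  along <- params$d_along > 0
  dx[along] <- -params$d_along[along] * lx[along]
  dy[along] <- -params$d_along[along] * ly[along]
  dz[along] <- -params$d_along[along] * lz[along]
  data.frame(
    structure = params$structure, kind = params$kind,
    lx = lx, ly = ly, lz = lz,
    dx = dx, dy = dy, dz = dz,
    stringsAsFactors = FALSE
  )
}

#' Generate flexion-dependent geometry for a whole trial
#'
#' @param flexion_deg Per-frame flexion angles (degrees, 0-90).
#' @param grid Percent-gait-cycle grid, same length.
#' @param params Template constants, see [default_geometry_params()].
#' @return Long data.frame: `frame_pct`, `structure`, `kind`, `lx`, `ly`,
#'   `lz`, `dx`, `dy`, `dz`.
#' @export
gen_geometry <- function(flexion_deg, grid = seq(0, 100, length.out = 101),
                         params = default_geometry_params()) {
  check_grid(grid)
  if (length(flexion_deg) != length(grid)) {
    stop("flexion_deg and grid must have the same length")
  }
  pieces <- lapply(seq_along(grid), function(i) {
    g <- geometry_template(flexion_deg[i], params)
    cbind(frame_pct = grid[i], g)
  })
  do.call(rbind, pieces)
}

#' Generate a synthetic gait trial
#'
#' Bundles the flexion waveform, the resultant-load waveforms and the
#' flexion-dependent structure geometry into one time-normalized trial.
#' Trials are pure functions of their parameters and seed.
#'
#' @param n_frames Number of samples on the 0-100% GC grid (default 101).
#' @param body_mass Subject mass in kg (default 56.4).
#' @param g Gravitational acceleration, m/s^2 (default 9.81); body weight is
#'   `body_mass * g`.
#' @param seed Integer seed (only consumed when load noise is enabled).
#' @param load_params Named list of [waveform_params()]; default
#'   [default_load_params()] at this body weight.
#' @param flexion_params A [waveform_params()] for the flexion angle.
#' @param geom_params Geometry template constants.
#' @return An object of class `gait_trial`: `frame_pct`, `flexion_deg`,
#'   `loads` (data.frame), `geometry` (long data.frame), `body_mass`,
#'   `body_weight`, `seed`.
#' @export
#' @examples
#' trial <- gen_trial(n_frames = 11)
#' nrow(trial$loads)
gen_trial <- function(n_frames = 101, body_mass = 56.4, g = 9.81, seed = 0L,
                      load_params = NULL,
                      flexion_params = default_flexion_params(),
                      geom_params = default_geometry_params()) {
  if (n_frames < 2) stop("a trial needs at least 2 frames")
  grid <- seq(0, 100, length.out = n_frames)
  body_weight <- body_mass * g
  if (is.null(load_params)) load_params <- default_load_params(body_weight)
  flexion <- gen_flexion_angle(flexion_params, grid)
  loads <- gen_resultant_loads(load_params, grid, seed)
  geometry <- gen_geometry(flexion, grid, geom_params)
  structure(
    list(frame_pct = grid, flexion_deg = flexion, loads = loads,
         geometry = geometry, body_mass = body_mass,
         body_weight = body_weight, seed = as.integer(seed)),
    class = "gait_trial"
  )
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf(
    "<gait_trial: %d frames, body mass %.1f kg (BW %.1f N), seed %d>\n",
    length(x$frame_pct), x$body_mass, x$body_weight, x$seed))
  invisible(x)
}

check_grid <- function(grid) {
  if (length(grid) < 2L || any(!is.finite(grid)) ||
      any(diff(grid) <= 0) ||
      abs(grid[1]) > 1e-9 || abs(grid[length(grid)] - 100) > 1e-9) {
    stop("grid must be strictly increasing and cover 0 to 100% GC")
  }
  invisible(grid)
}
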