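#' Force-bearing structures of the knee model
#'
#' The model distributes the knee joint resultant load among 18 structures:
#' twelve muscles crossing the knee (the quadriceps acting through the
#' patellar tendon, the hamstrings, the two gastrocnemius heads, and the
#' gluteus maximus and tensor fasciae latae acting through the iliotibial
#' tract), the four major ligaments, and the medial and lateral tibiofemoral
#' contacts. The row order of this table is the canonical variable (column)
#' order used by every constraint system and solution in the package:
#' muscles first, then ligaments, then contacts.
#'
#' @return A data.frame with columns `structure` (name) and `kind`
#'   (`"muscle"`, `"ligament"` or `"contact"`), 18 rows, fixed order.
#' @export
#' @examples
#' knee_structures()
knee_structures <- function() {
  data.frame(
    structure = c(
      "rectus_femoris", "semitendinosus", "semimembranosus",
      "biceps_femoris_long", "biceps_femoris_short",
      "gastrocnemius_medialis", "gastrocnemius_lateralis",
      "vastus_intermedius", "vastus_medialis", "vastus_lateralis",
      "gluteus_maximus_itb", "tensor_fasciae_latae_itb",
      "ACL", "PCL", "MCL", "LCL",
      "contact_medial", "contact_lateral"
    ),
    kind = c(rep("muscle", 12L), rep("ligament", 4L), rep("contact", 2L)),
    stringsAsFactors = FALSE
  )
}

#' Names of the twelve knee-crossing muscles, in canonical order
#' @return Character vector of length 12.
#' @export
muscle_names <- function() {
  s <- knee_structures()
  s$structure[s$kind == "muscle"]
}

#' Names of the four knee ligaments, in canonical order
#' @return Character vector of length 4.
#' @export
ligament_names <- function() {
  s <- knee_structures()
  s$structure[s$kind == "ligament"]
}

#' Names of the two tibiofemoral contacts, in canonical order
#' @return Character vector of length 2.
#' @export
contact_names <- function() {
  s <- knee_structures()
  s$structure[s$kind == "contact"]
}

#' Default physiological cross-sectional areas (cm^2)
#'
#' A configurable table in the range of published anatomical PCSA data for
#' the twelve modeled muscles. Muscle stress is force divided by PCSA, so
#' these values drive the stress-based criteria (J5-J8); they are defaults,
#' not a claim about any particular cadaver study.
#'
#' @return Named numeric vector, one entry per muscle, cm^2.
#' @export
default_pcsa <- function() {
  c(
    rectus_femoris = 12.7,
    semitendinosus = 5.4,
    semimembranosus = 16.9,
    biceps_femoris_long = 11.8,
    biceps_femoris_short = 5.1,
    gastrocnemius_medialis = 21.1,
    gastrocnemius_lateralis = 9.7,
    vastus_intermedius = 16.7,
    vastus_medialis = 21.1,
    vastus_lateralis = 30.6,
    gluteus_maximus_itb = 18.0,  # only the ITB-transmitted fraction
    tensor_fasciae_latae_itb = 8.0
  )
}

#' Muscle properties: PCSA table and the common force upper bound
#'
#' @param pcsa Named numeric vector of PCSAs in cm^2; must cover all twelve
#'   muscles of [muscle_names()] with positive values.
#' @param force_upper_bound Upper bound in N applied to every muscle and
#'   ligament force magnitude in the optimization (default 5000 N, a loose
#'   bound that lets unphysiological predictions reveal themselves rather
#'   than clipping them).
#' @return An object of class `muscle_properties`.
#' @export
muscle_properties <- function(pcsa = default_pcsa(), force_upper_bound = 5000) {
  m <- muscle_names()
  if (!all(m %in% names(pcsa))) {
    stop("PCSA missing for muscle(s): ",
         paste(setdiff(m, names(pcsa)), collapse = ", "))
  }
  pcsa <- pcsa[m]
  if (any(!is.finite(pcsa)) || any(pcsa <= 0)) {
    stop("all PCSA values must be finite and > 0")
  }
  if (!is.finite(force_upper_bound) || force_upper_bound <= 0) {
    stop("force_upper_bound must be finite and > 0")
  }
  structure(list(pcsa = pcsa, force_upper_bound = force_upper_bound),
            class = "muscle_properties")
}

#' Line of action of one force-bearing structure
#'
#' A structure applies a force of unknown magnitude to the shank along a unit
#' direction, at a point located by a lever-arm vector from the knee joint
#' center (midpoint of the inter-condylar line). Directions express the force
#' applied TO the shank: muscle and ligament directions point from the tibial
#' insertion toward the femoral attachment (tension), contact directions
#' point the way the femur pushes the tibia (compression), so all force
#' magnitudes are nonnegative.
#'
#' @param direction Numeric length-3 unit vector (tibia frame: x anterior,
#'   y superior, z to the right), unit norm to 1e-9.
#' @param lever_arm Numeric length-3 vector in meters from the joint center
#'   to the point of application; must be finite with norm < 0.5 m.
#' @return An object of class `line_of_action` with fields `direction` and
#'   `lever_arm`.
#' @export
#' @examples
#' line_of_action(c(0, 1, 0), c(0.05, 0, 0))
line_of_action <- function(direction, lever_arm) {
  direction <- as.numeric(direction)
  lever_arm <- as.numeric(lever_arm)
  if (length(direction) != 3L || length(lever_arm) != 3L) {
    stop("direction and lever_arm must be length-3 numeric vectors")
  }
  if (any(!is.finite(direction)) || any(!is.finite(lever_arm))) {
    stop("direction and lever_arm components must be finite")
  }
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-9) {
    stop("direction must have unit norm (within 1e-9); got norm ",
         format(sqrt(sum(direction^2))))
  }
  if (sqrt(sum(lever_arm^2)) >= 0.5) {
    stop("lever_arm norm must be < 0.5 m; got ",
         format(sqrt(sum(lever_arm^2))), " m")
  }
  structure(list(direction = direction, lever_arm = lever_arm),
            class = "line_of_action")
}

#' Moment about the joint center per unit force magnitude
#'
#' Returns the cross product `lever_arm x direction`: the moment (N*m per N
#' of force, i.e. meters) that one newton transmitted along the structure's
#' line of action produces about the knee joint center. These are the
#' per-structure coefficients of the moment equipollence rows.
#'
#' @param geometry A [line_of_action()].
#' @return Numeric length-3 vector in meters.
#' @export
#' @examples
#' moment_contribution(line_of_action(c(0, 1, 0), c(0.05, 0, 0)))
moment_contribution <- function(geometry) {
  if (!inherits(geometry, "line_of_action")) {
    geometry <- line_of_action(geometry$direction, geometry$lever_arm)
  }
  cross3(geometry$lever_arm, geometry$direction)
}

# plain 3-vector cross product (a x b)
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Resultant intersegmental load at the knee joint center
#'
#' The net force and moment that the force-bearing structures must jointly
#' supply at one instant, expressed in the tibia-embedded frame (x anterior,
#' y superior, z to the right), moments taken about the joint center.
#'
#' @param force Numeric length-3, N.
#' @param moment Numeric length-3, N*m.
#' @return An object of class `resultant_load` with fields `force`, `moment`
#'   and the axis `convention` string.
#' @export
resultant_load <- function(force, moment) {
  force <- as.numeric(force)
  moment <- as.numeric(moment)
  if (length(force) != 3L || length(moment) != 3L) {
    stop("force and moment must be length-3 numeric vectors")
  }
  if (any(!is.finite(force)) || any(!is.finite(moment))) {
    stop("force and moment components must be finite")
  }
  structure(
    list(force = force, moment = moment,
         convention = "x-anterior, y-superior, z-right"),
    class = "resultant_load"
  )
}

#' Validate the geometry of one frame
#'
#' Checks every structure's direction for unit norm (1e-9) and every lever
#' arm for finiteness and the 0.5 m sanity bound, without throwing: returns a
#' report, one row per violation. An empty report means the frame is valid.
#'
#' @param geometry A frame-geometry data.frame with columns `structure`,
#'   `kind`, `lx`, `ly`, `lz` (direction) and `dx`, `dy`, `dz` (lever arm, m).
#' @return A data.frame with columns `structure` and `problem`; zero rows if
#'   and only if all structures are valid.
#' @export
validate_frame_geometry <- function(geometry) {
  check_frame_geometry_df(geometry)
  viol <- data.frame(structure = character(), problem = character(),
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(geometry))) {
    l <- as.numeric(geometry[i, c("lx", "ly", "lz")])
    d <- as.numeric(geometry[i, c("dx", "dy", "dz")])
    nm <- geometry$structure[i]
    if (any(!is.finite(l)) || abs(sqrt(sum(l^2)) - 1) > 1e-9) {
      viol <- rbind(viol, data.frame(structure = nm,
                                     problem = "direction not unit norm"))
    }
    if (any(!is.finite(d)) || sqrt(sum(d^2)) >= 0.5) {
      viol <- rbind(viol, data.frame(structure = nm,
                                     problem = "lever arm outside sanity bound"))
    }
  }
  viol
}

check_frame_geometry_df <- function(geometry) {
  need <- c("structure", "kind", "lx", "ly", "lz", "dx", "dy", "dz")
  if (!is.data.frame(geometry) || !all(need %in% names(geometry))) {
    stop("frame geometry must be a data.frame with columns ",
         paste(need, collapse = ", "))
  }
  invisible(geometry)
}
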