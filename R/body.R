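#' Construct a planar body model
#'
#' Defines the seven-segment planar skeleton: one HAT (head-arms-trunk)
#' segment and, per leg, a thigh, shank and foot. Segments articulate at pin
#' joints (hip, knee, ankle) with linear viscous elements and one-sided
#' range-of-motion lock springs; the heel and toe of each foot interact with
#' the ground through a linear spring-damper contact.
#'
#' Segment parameters default to values reconstructed from the anthropometric
#' literature this class of model is built on (roughly a 70 kg, 1.7 m adult);
#' they are editable defaults, not measured data.
#'
#' @param mass named or positional numeric length 7: HAT, thigh/shank/foot
#'   left, thigh/shank/foot right (kg).
#' @param inertia segment moments of inertia about the COM, same order
#'   (kg m^2).
#' @param com_hat HAT COM height above the hip (m).
#' @param l_thigh,l_shank segment lengths (m), shared left/right.
#' @param com_thigh,com_shank COM distance from the proximal joint (m).
#' @param foot_geom numeric length 5: heel offset behind the ankle, toe offset
#'   ahead of the ankle, sole depth below the ankle, foot COM forward offset,
#'   foot COM depth (m).
#' @param joint_viscosity hip, knee, ankle viscous coefficients (N m s/rad).
#' @param rom_hip,rom_knee,rom_ankle allowed joint ranges (rad); outside the
#'   range a stiff one-sided lock spring engages.
#' @param lock lock spring stiffness (N m/rad) and damping (N m s/rad).
#' @param contact ground contact coefficients: horizontal stiffness (N/m) and
#'   damping (N s/m), vertical stiffness and damping.
#' @param g gravitational acceleration (m/s^2).
#' @return an object of class `cpgwalk_body`.
#' @export
body_model <- function(mass = c(48.0, 7.3, 3.0, 1.0, 7.3, 3.0, 1.0),
                       inertia = c(2.7, 0.15, 0.05, 0.007, 0.15, 0.05, 0.007),
                       com_hat = 0.35,
                       l_thigh = 0.45, com_thigh = 0.20,
                       l_shank = 0.45, com_shank = 0.20,
                       foot_geom = c(0.07, 0.18, 0.07, 0.05, 0.03),
                       joint_viscosity = c(1.09, 3.17, 0.943),
                       rom_hip = c(-0.7, 2.0),
                       rom_knee = c(-0.05, 2.4),
                       rom_ankle = c(-0.9, 0.9),
                       lock = c(1000, 50),
                       contact = c(5.0e3, 1.0e3, 2.5e4, 5.0e2),
                       g = 9.81) {
  body <- list(
    mass = as.numeric(mass), inertia = as.numeric(inertia),
    com_hat = com_hat, l_thigh = l_thigh, com_thigh = com_thigh,
    l_shank = l_shank, com_shank = com_shank,
    foot_geom = as.numeric(foot_geom),
    joint_viscosity = as.numeric(joint_viscosity),
    rom_hip = as.numeric(rom_hip), rom_knee = as.numeric(rom_knee),
    rom_ankle = as.numeric(rom_ankle),
    lock = as.numeric(lock), contact = as.numeric(contact),
    pros_side = -1L, pros_ankle_k = 0.0,
    removed_muscles = character(0),
    g = g)
  class(body) <- "cpgwalk_body"
  validate_body(body)
  body
}

validate_body <- function(body) {
  stopifnot(length(body$mass) == 7, length(body$inertia) == 7)
  if (any(body$mass <= 0)) stop("all segment masses must be positive")
  if (any(body$inertia <= 0)) stop("all segment inertias must be positive")
  if (any(c(body$l_thigh, body$l_shank, body$com_hat) <= 0))
    stop("segment lengths must be positive")
  if (any(body$contact < 0)) stop("contact coefficients must be non-negative")
  if (any(body$joint_viscosity < 0)) stop("joint viscosities must be non-negative")
  stopifnot(body$rom_hip[1] < body$rom_hip[2],
            body$rom_knee[1] < body$rom_knee[2],
            body$rom_ankle[1] < body$rom_ankle[2])
  invisible(body)
}

#' Total body mass
#' @param body a `cpgwalk_body`.
#' @return total mass (kg), the sum of segment masses.
#' @export
total_mass <- function(body) sum(body$mass)

#' Standing hip height of a body model
#' @param body a `cpgwalk_body`.
#' @return hip height above the ground with straight legs and flat feet (m).
#' @export
standing_height <- function(body) body$l_thigh + body$l_shank + body$foot_geom[3]

#' Apply a unilateral transtibial prosthesis to one leg
#'
#' Replaces the shank + foot complex of one side with a prosthesis: the
#' segment masses are scaled to 65%, the moments of inertia to 40%, the
#' ankle receives a passive rotational stiffness of 400 Nm/rad, and the three
#' muscles crossing the amputated ankle (TA, SO, GC) are marked for removal
#' on that side (enforced when the muscle set is assembled for simulation).
#'
#' @param body a `cpgwalk_body` in the normal configuration.
#' @param side `"left"` or `"right"`.
#' @param mass_scale,inertia_scale,ankle_stiffness prosthesis parameters;
#'   defaults are the transtibial prosthesis values used throughout.
#' @return a modified copy of `body`.
#' @export
apply_prosthesis <- function(body, side, mass_scale = 0.65,
                             inertia_scale = 0.40, ankle_stiffness = 400) {
  if (!side %in% c("left", "right"))
    stop("unknown side identifier: ", side, " (use 'left' or 'right')")
  s <- if (side == "left") 0L else 1L
  idx <- c(3, 4) + 3L * s  # shank, foot rows in the 7-segment order
  body$mass[idx] <- body$mass[idx] * mass_scale
  body$inertia[idx] <- body$inertia[idx] * inertia_scale
  body$pros_side <- s
  body$pros_ankle_k <- ankle_stiffness
  body$removed_muscles <- paste0(c("TA", "SO", "GC"), "_", side)
  validate_body(body)
  body
}

#' @export
print.cpgwalk_body <- function(x, ...) {
  cat("<cpgwalk_body> 7-segment planar biped\n")
  cat(sprintf("  total mass %.1f kg, standing hip height %.2f m\n",
              total_mass(x), standing_height(x)))
  cat(sprintf("  joint viscosity (hip/knee/ankle): %s Nms/rad\n",
              paste(x$joint_viscosity, collapse = "/")))
  if (x$pros_side >= 0)
    cat(sprintf("  prosthesis: %s side, ankle stiffness %g Nm/rad, removed: %s\n",
                c("left", "right")[x$pros_side + 1], x$pros_ankle_k,
                paste(x$removed_muscles, collapse = ", ")))
  invisible(x)
}

# flatten for the C++ core
body_params <- function(body) {
  list(mass = body$mass, inertia = body$inertia, com_hat = body$com_hat,
       l_thigh = body$l_thigh, com_thigh = body$com_thigh,
       l_shank = body$l_shank, com_shank = body$com_shank,
       foot_geom = body$foot_geom, joint_viscosity = body$joint_viscosity,
       rom_hip = body$rom_hip, rom_knee = body$rom_knee,
       rom_ankle = body$rom_ankle, lock = body$lock, contact = body$contact,
       pros_side = as.integer(body$pros_side),
       pros_ankle_k = body$pros_ankle_k, g = body$g)
}
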