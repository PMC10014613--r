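#' Ground contact force at a single point
#'
#' Linear spring-damper contact. While penetrating, the vertical force is
#' `k_v * depth + c_v * (-vy)`, floored at zero (no adhesion), and the
#' horizontal force is a spring-damper on the horizontal displacement since
#' touchdown, active only while the point is loaded. Above ground the force
#' is zero.
#'
#' @param depth penetration depth (m, positive = below ground).
#' @param velocity contact point velocity `c(vx, vy)` (m/s).
#' @param coeffs contact coefficients `c(k_h, c_h, k_v, c_v)`; defaults to
#'   the package's standard values.
#' @param horizontal_disp horizontal displacement since touchdown (m).
#' @return named force vector `c(fx, fy)` (N); `fy >= 0` always.
#' @export
contact_force <- function(depth, velocity = c(0, 0),
                          coeffs = c(5.0e3, 1.0e3, 2.5e4, 5.0e2),
                          horizontal_disp = 0) {
  stopifnot(all(coeffs >= 0))
  contactForceC(-depth, velocity[1], velocity[2], horizontal_disp,
                coeffs[1], coeffs[2], coeffs[3], coeffs[4])
}

#' Passive joint moment
#'
#' The sum of a linear viscous moment `-b * theta_dot`, a stiff one-sided
#' lock spring-damper engaged outside the allowed range of motion (the
#' knee/ankle "lock" against hyperextension and hyperflexion), and for a
#' prosthetic ankle an elastic return `-k_pros * theta` to neutral.
#'
#' @param joint `"hip"`, `"knee"` or `"ankle"`.
#' @param theta,theta_dot joint angle (rad) and rate (rad/s); conventions:
#'   hip flexion, knee flexion, ankle dorsiflexion positive.
#' @param body a `cpgwalk_body`.
#' @param side `"left"` or `"right"` (decides whether the prosthetic ankle
#'   stiffness applies).
#' @return passive moment (Nm).
#' @export
joint_passive_moment <- function(joint, theta, theta_dot, body,
                                 side = "left") {
  if (!joint %in% c("hip", "knee", "ankle"))
    stop("unknown joint id: ", joint)
  if (!side %in% c("left", "right")) stop("unknown side: ", side)
  i <- match(joint, c("hip", "knee", "ankle"))
  rom <- switch(joint, hip = body$rom_hip, knee = body$rom_knee,
                ankle = body$rom_ankle)
  pros <- if (joint == "ankle" &&
              body$pros_side == (if (side == "left") 0 else 1))
    body$pros_ankle_k else 0
  jointPassiveMomentC(theta, theta_dot, body$joint_viscosity[i],
                      rom[1], rom[2], body$lock[1], body$lock[2], pros)
}

#' Generalized coordinate names
#' @return names of the 9 minimal coordinates: hip position and the 7
#'   absolute segment angles.
#' @export
coord_names <- function() {
  c("x", "y", "th_hat", "th_thigh_l", "th_shank_l", "th_foot_l",
    "th_thigh_r", "th_shank_r", "th_foot_r")
}

#' Equations of motion of the 7-link biped
#'
#' Newton-Euler dynamics of the planar articulated chain in minimal
#' coordinates (hip x, y + 7 absolute segment angles) under gravity, the six
#' net joint torques and external forces at the four heel/toe points.
#'
#' @param q,qd generalized coordinates and velocities (length 9, see
#'   [coord_names()]).
#' @param joint_torques net torques at hip/knee/ankle left then right
#'   (length 6, Nm); positive = flexion (dorsiflexion at the ankle).
#' @param contact_forces 4 x 2 matrix of world-frame forces (N) at heel_l,
#'   toe_l, heel_r, toe_r.
#' @param body a `cpgwalk_body`.
#' @return generalized accelerations (length 9).
#' @export
equations_of_motion <- function(q, qd, joint_torques = rep(0, 6),
                                contact_forces = matrix(0, 4, 2),
                                body = body_model()) {
  stopifnot(length(q) == 9, length(qd) == 9, length(joint_torques) == 6,
            all(dim(contact_forces) == c(4, 2)))
  acc <- eomC(body_params(body), as.numeric(q), as.numeric(qd),
              as.numeric(joint_torques), contact_forces)
  setNames(acc, coord_names())
}

#' One classical fourth-order Runge-Kutta step
#'
#' @param y state vector.
#' @param f derivative function `f(t, y)` returning `dy/dt`.
#' @param dt step size (s); `dt = 0` returns `y` unchanged.
#' @param t current time.
#' @return the state advanced by `dt`.
#' @export
rk4_step <- function(y, f, dt, t = 0) {
  stopifnot(dt >= 0)
  if (dt == 0) return(y)
  k1 <- f(t, y)
  if (any(!is.finite(k1))) stop("non-finite derivative: numerical blow-up")
  k2 <- f(t + dt / 2, y + dt / 2 * k1)
  k3 <- f(t + dt / 2, y + dt / 2 * k2)
  k4 <- f(t + dt, y + dt * k3)
  if (any(!is.finite(k4))) stop("non-finite derivative: numerical blow-up")
  y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Landmark and COM positions of the skeleton
#'
#' @param body a `cpgwalk_body`.
#' @param q,qd generalized coordinates and velocities.
#' @return matrix with rows hip, knee/ankle/heel/toe per side, segment COMs
#'   and the whole-body COM; columns `x`, `y`, `vx`, `vy`.
#' @export
body_points <- function(body, q, qd = rep(0, 9)) {
  m <- bodyPointsC(body_params(body), as.numeric(q), as.numeric(qd))
  dimnames(m) <- list(
    c("hip", "knee_l", "ankle_l", "heel_l", "toe_l",
      "knee_r", "ankle_r", "heel_r", "toe_r",
      "com_hat", "com_thigh_l", "com_shank_l", "com_foot_l",
      "com_thigh_r", "com_shank_r", "com_foot_r", "com"),
    c("x", "y", "vx", "vy"))
  m
}

#' Total mechanical energy of the skeleton
#'
#' Kinetic plus gravitational potential energy; useful for checking that the
#' passive dynamics only dissipate.
#'
#' @param body a `cpgwalk_body`.
#' @param q,qd generalized coordinates and velocities.
#' @return energy (J).
#' @export
mechanical_energy <- function(body, q, qd) {
  mechanicalEnergyC(body_params(body), as.numeric(q), as.numeric(qd))
}
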