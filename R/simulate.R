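#' Default initial condition for a walking trial
#'
#' A standing configuration with straight legs and flat feet, the hip lowered
#' by the static contact penetration, a slight forward trunk pitch, a small
#' forward push, and an asymmetric CPG seed (left hip flexor / right hip
#' extensor units pre-charged) so the legs break symmetry into antiphase.
#'
#' @param body a `cpgwalk_body`.
#' @param push forward hip velocity (m/s).
#' @param lean initial trunk pitch (rad; negative = forward with the
#'   counter-clockwise-positive convention).
#' @return list with `q0`, `qd0`, `cpg_u`, `cpg_v`.
#' @export
default_init <- function(body, push = 0.5, lean = -0.08) {
  pen <- total_mass(body) * body$g / (4 * body$contact[3])
  q0 <- c(0, standing_height(body) - pen, lean, rep(0, 6))
  qd0 <- c(push, rep(0, 8))
  u <- rep(0.01, 12)
  names(u) <- cpg_unit_names()
  u["hipF_L"] <- 0.6
  u["hipE_R"] <- 0.6
  list(q0 = q0, qd0 = qd0, cpg_u = unname(u), cpg_v = rep(0, 12))
}

trial_log_names <- function() {
  mn <- as.vector(outer(muscle_order(), c("l", "r"), paste, sep = "_"))
  c("t", coord_names(), paste0("d_", coord_names()),
    "grf_l", "grf_r", "grfx_l", "grfx_r",
    "heel_l_x", "heel_l_y", "toe_l_x", "toe_l_y",
    "heel_r_x", "heel_r_y", "toe_r_x", "toe_r_y",
    paste0("alpha_", tolower(mn)), paste0("edot_", tolower(mn)))
}

#' Run one forward-dynamics walking trial
#'
#' Integrates the coupled mechanical (9 DOF), muscular (18 Hill muscles) and
#' neural (12-unit CPG) state with classical RK4 at a fixed step (default
#' 0.1 ms). The trial is aborted and flagged as a fall when the hip drops
#' below a fraction of standing height, the trunk pitches past a limit, a
#' knee approaches the ground, or the state becomes non-finite (numerical
#' blow-up under aggressive controller gains).
#'
#' @param body a `cpgwalk_body`.
#' @param controller a `cpgwalk_controller`.
#' @param muscles muscle table; muscles flagged removed in `body` are
#'   deactivated automatically.
#' @param duration trial length (s).
#' @param dt integration step (s).
#' @param log_every keep every n-th sample in the returned log (default 10,
#'   i.e. 1 ms sampling); `0` disables logging (used inside the GA).
#' @param init initial condition, see [default_init()].
#' @param ground,controller_on,fall_check switches used by tests of the
#'   passive dynamics; `controller_on = FALSE` removes the whole muscle
#'   apparatus (active and passive elements), leaving the bare skeleton with
#'   its viscous joints.
#' @param fall_height_frac,fall_pitch,knee_clearance fall detection
#'   thresholds.
#' @return object of class `cpgwalk_trial`: the sampled log (data.frame),
#'   walked distance `distance` (m), `fell` flag, end time `t_end` (s), the
#'   time-integrated metabolic energy `energy` (J), mean speed, body mass
#'   and the final state vector.
#' @export
run_trial <- function(body, controller, muscles = default_muscles(body),
                      duration = 10, dt = 1e-4, log_every = 10L,
                      init = default_init(body), ground = TRUE,
                      controller_on = TRUE, fall_check = TRUE,
                      fall_height_frac = 0.55, fall_pitch = 1.0,
                      knee_clearance = 0.05) {
  stopifnot(inherits(body, "cpgwalk_body"),
            inherits(controller, "cpgwalk_controller"),
            duration > 0, dt > 0)
  if (length(body$removed_muscles))
    muscles$active[rownames(muscles) %in% body$removed_muscles] <- FALSE
  opts <- list(duration = duration, dt = dt, log_every = as.integer(log_every),
               ground = ground, controller_on = controller_on,
               fall_check = fall_check, fall_height_frac = fall_height_frac,
               fall_pitch = fall_pitch, knee_clearance = knee_clearance,
               q0 = init$q0, qd0 = init$qd0,
               cpg_u = init$cpg_u, cpg_v = init$cpg_v)
  res <- simulateTrialC(body_params(body), muscle_matrix(muscles),
                        controller_params(controller), opts)
  log <- NULL
  if (log_every > 0 && res$n_logged > 0) {
    log <- as.data.frame(res$log[seq_len(res$n_logged), , drop = FALSE])
    names(log) <- trial_log_names()
  }
  t_end <- max(res$t_end, dt)
  out <- list(log = log, distance = res$distance, fell = res$fell,
              t_end = res$t_end, energy = res$energy,
              speed = res$distance / t_end, mass = total_mass(body),
              duration = duration, dt = dt, final_state = res$final_state)
  class(out) <- "cpgwalk_trial"
  out
}

#' @export
print.cpgwalk_trial <- function(x, ...) {
  cat("<cpgwalk_trial>\n")
  cat(sprintf("  %s after %.2f s; distance %.2f m (%.2f m/s); energy %.0f J\n",
              if (x$fell) "fell" else "completed", x$t_end, x$distance,
              x$speed, x$energy))
  invisible(x)
}
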