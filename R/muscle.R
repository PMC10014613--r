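#' Default muscle specification table
#'
#' Nine Hill-type muscles per leg: gluteus maximus (GM), iliopsoas (IL),
#' biceps femoris long head (BFL), rectus femoris (RF), biceps femoris short
#' head (BFS), vastus (VA), gastrocnemius (GC), soleus (SO) and tibialis
#' anterior (TA). BFL, RF and GC are bi-articular; the rest span one joint.
#'
#' The muscle path model is linear: constant signed moment arms about each
#' spanned joint, calibrated so every muscle is at its optimum length in the
#' standing reference posture (all joint angles zero). Moment arm sign
#' convention: joint angles are hip flexion (+), knee flexion (+) and ankle
#' dorsiflexion (+); a muscle that shortens as an angle increases has a
#' negative moment arm there, and tension produces joint torque
#' `-r * F` about that angle.
#'
#' Strength and path constants are reconstructed, physiologically plausible
#' defaults in the tradition of the lumped planar walking models this package
#' follows; they are editable defaults, not measured experimental values.
#'
#' @param body optional `cpgwalk_body`; muscles listed in
#'   `body$removed_muscles` are returned with `active = FALSE`.
#' @return a data.frame with one row per muscle (18 rows): name, side,
#'   maximum contractile tension `f_ce` (N), optimum length `l_bar` (m),
#'   maximum contraction velocity `ldot_bar` (m/s), damping `c_pd` (Ns/m),
#'   passive-elastic coefficient `k_pe` (N), signed moment arms (m) about
#'   hip/knee/ankle, primary joint, role (+1 extensor-like, -1 flexor-like)
#'   and `active` flag.
#' @export
default_muscles <- function(body = NULL) {
  base <- data.frame(
    name = c("GM", "IL", "BFL", "RF", "BFS", "VA", "GC", "SO", "TA"),
    f_ce = c(1500, 1000, 1200, 1000, 600, 2500, 1200, 3000, 800),
    l_bar = c(0.28, 0.25, 0.40, 0.40, 0.20, 0.22, 0.42, 0.25, 0.26),
    ldot_bar = c(1.12, 1.00, 1.60, 1.60, 0.80, 0.88, 1.68, 1.00, 1.04),
    c_pd = c(30, 20, 24, 20, 12, 50, 24, 60, 16),
    k_pe = c(150, 100, 120, 100, 60, 250, 120, 300, 80),
    r_hip = c(0.07, -0.07, 0.05, -0.05, 0, 0, 0, 0, 0),
    r_knee = c(0, 0, -0.03, 0.04, -0.03, 0.04, -0.03, 0, 0),
    r_ankle = c(0, 0, 0, 0, 0, 0, 0.05, 0.05, -0.04),
    joint = c("hip", "hip", "hip", "knee", "knee", "knee",
              "ankle", "ankle", "ankle"),
    role = c(1, -1, 1, 1, -1, 1, 1, 1, -1),
    stringsAsFactors = FALSE)
  m <- rbind(transform(base, side = "left"), transform(base, side = "right"))
  m$active <- TRUE
  rownames(m) <- paste0(m$name, "_", m$side)
  if (!is.null(body) && length(body$removed_muscles))
    m$active[rownames(m) %in% body$removed_muscles] <- FALSE
  m
}

# numeric 18 x 13 matrix handed to the C++ core; column order is fixed there
muscle_matrix <- function(muscles) {
  joint_idx <- match(muscles$joint, c("hip", "knee", "ankle")) - 1L
  dm_idx <- match(muscles$name,
                  c("GM", "IL", "BFL", "RF", "BFS", "VA", "GC", "SO", "TA")) - 1L
  m <- cbind(side = ifelse(muscles$side == "left", 0, 1),
             f_ce = muscles$f_ce, l_bar = muscles$l_bar,
             ldot_bar = muscles$ldot_bar, c_pd = muscles$c_pd,
             k_pe = muscles$k_pe, r_hip = muscles$r_hip,
             r_knee = muscles$r_knee, r_ankle = muscles$r_ankle,
             active = as.numeric(muscles$active),
             joint = joint_idx, role = muscles$role, dm = dm_idx)
  storage.mode(m) <- "double"
  m
}

#' Force-length gain of the contractile element
#'
#' `k(xi) = 0.32 + 0.71 exp(-1.112 (xi - 1)) sin(3.722 (xi - 0.656))`,
#' floored at zero outside the physiological range. `xi` is muscle length
#' normalized by optimum length; the gain peaks near `xi = 1`.
#'
#' @param xi normalized muscle length (dimensionless), `> 0`.
#' @return gain value(s) in `[0, ~1]`.
#' @export
force_length <- function(xi) {
  stopifnot(all(xi > 0))
  vapply(xi, flGainC, numeric(1))
}

#' Force-velocity gain of the contractile element
#'
#' `h(eta) = 1 + tanh(3 eta)`, bounded in (0, 2) with `h(0) = 1`. `eta` is
#' contraction velocity normalized by maximum contraction velocity; by the
#' package default (`fv_sign = 1`) positive `eta` means lengthening, so the
#' gain exceeds 1 during eccentric contraction.
#'
#' @param eta normalized contraction velocity (dimensionless).
#' @return gain value(s) in (0, 2).
#' @export
force_velocity <- function(eta) {
  vapply(eta, fvGainC, numeric(1))
}

#' Hill-type muscle tension
#'
#' Total tension `F = F_ce k(xi) h(eta) alpha + F_pd + F_pe` with damping
#' `F_pd = c_pd * Ldot` (opposing stretch) and passive-elastic
#' `F_pe = k_pe (exp(15 (L - l_bar)) - 1)` active only in stretch.
#'
#' @param spec one muscle specification (a one-row data.frame or list with
#'   `f_ce`, `l_bar`, `ldot_bar`, `c_pd`, `k_pe`).
#' @param L,L_dot muscle length (m) and lengthening velocity (m/s).
#' @param alpha activation in `[0, 1]`.
#' @param fv_sign sign convention of the normalized velocity entering the
#'   force-velocity gain (`1`: positive = lengthening, the default).
#' @return named vector: total tension `F` and components `F_ce`, `F_pd`,
#'   `F_pe` (N).
#' @export
muscle_tension <- function(spec, L, L_dot, alpha, fv_sign = 1) {
  stopifnot(alpha >= 0, alpha <= 1)
  hillTensionC(spec$f_ce, spec$l_bar, spec$ldot_bar, spec$c_pd, spec$k_pe,
               L, L_dot, alpha, fv_sign)
}

#' Muscle path kinematics and torque contributions
#'
#' Linear path model: `L = l_bar + sum_j r_j * theta_j` over the spanned
#' joints (constant moment arms, reference posture at zero joint angles) and
#' `L_dot = sum_j r_j * theta_dot_j`. Tension `F` produces torque `-r_j F`
#' about joint `j`.
#'
#' @param joint_angles named numeric with `hip`, `knee`, `ankle` (rad).
#' @param spec one muscle specification row (needs `l_bar`, `r_hip`,
#'   `r_knee`, `r_ankle`).
#' @param joint_rates named numeric like `joint_angles` (rad/s); defaults to
#'   zeros.
#' @param tension optional muscle tension (N) to scale torques by; default 1
#'   returns torque per unit tension.
#' @return list with `L`, `L_dot` and named `torque` (Nm about hip, knee,
#'   ankle).
#' @export
muscle_kinematics <- function(joint_angles, spec,
                              joint_rates = c(hip = 0, knee = 0, ankle = 0),
                              tension = 1) {
  need <- c("hip", "knee", "ankle")
  if (!all(need %in% names(joint_angles)))
    stop("joint_angles must name hip, knee and ankle")
  r <- c(hip = spec$r_hip, knee = spec$r_knee, ankle = spec$r_ankle)
  L <- spec$l_bar + sum(r * joint_angles[need])
  L_dot <- sum(r * joint_rates[need])
  list(L = L, L_dot = L_dot, moment_arms = r, torque = -r * tension)
}

#' Per-muscle metabolic rate
#'
#' A three-term muscle energetics model: activation/maintenance heat
#' proportional to `F_ce_max * l_bar * alpha`, shortening heat proportional
#' to `F_ce_max * alpha` times shortening speed, and the positive mechanical
#' work rate of the contractile element. Inactive or removed muscles consume
#' nothing; there is no basal term.
#'
#' @param muscles muscle table (as from [default_muscles()]).
#' @param alpha activations in `[0,1]`, one per row.
#' @param L,L_dot muscle lengths (m) and lengthening velocities (m/s).
#' @param fv_sign force-velocity sign convention flag.
#' @return metabolic rate per muscle (W), all `>= 0`.
#' @export
metabolic_rate <- function(muscles, alpha, L, L_dot, fv_sign = 1) {
  stopifnot(length(alpha) == nrow(muscles), length(L) == nrow(muscles),
            length(L_dot) == nrow(muscles))
  setNames(metabolicRateC(muscle_matrix(muscles), alpha, L, L_dot, fv_sign),
           rownames(muscles))
}
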