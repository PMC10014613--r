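#' CPG unit names
#'
#' The 12 internal units are organized as flexor/extensor pairs for the hip,
#' knee and ankle oscillators of each leg.
#' @return character vector of length 12.
#' @export
cpg_unit_names <- function() {
  as.vector(outer(c("hipF", "hipE", "kneeF", "kneeE", "ankF", "ankE"),
                  c("L", "R"), paste, sep = "_"))
}

muscle_order <- function() c("GM", "IL", "BFL", "RF", "BFS", "VA", "GC", "SO", "TA")

#' Construct a Matsuoka-style CPG network
#'
#' Each unit `i` obeys
#' `tau_i du_i/dt = -u_i + sum_j w_ij y_j - beta v_i + u0 + Feed_i`,
#' `tau'_i dv_i/dt = -v_i + y_i`, `y_i = max(0, u_i)`:
#' a rectified leaky integrator with self-inhibitory adaptation. Mutual
#' inhibition between paired units yields sustained alternation.
#'
#' @param n number of units (12 for the walker; 2 for a bare oscillator).
#' @param tau,taup membrane and adaptation time constants (s); recycled to
#'   length `n`.
#' @param beta adaptation coefficient.
#' @param w `n x n` connection matrix (inhibitory entries negative).
#' @param u0 tonic external input.
#' @param u,v initial internal and adaptation states.
#' @return object of class `cpgwalk_cpg` with fields `u`, `v`, `y` and the
#'   parameters.
#' @export
cpg_network <- function(n = 12, tau = 0.08, taup = 0.16, beta = 2.5,
                        w = matrix(0, n, n), u0 = 1,
                        u = rep(0, n), v = rep(0, n)) {
  stopifnot(all(tau > 0), all(taup > 0), nrow(w) == n, ncol(w) == n,
            length(u) == n, length(v) == n)
  net <- list(n = n, tau = rep_len(tau, n), taup = rep_len(taup, n),
              beta = beta, w = w, u0 = u0,
              u = as.numeric(u), v = as.numeric(v), y = pmax(0, u))
  class(net) <- "cpgwalk_cpg"
  net
}

#' CPG state derivatives
#'
#' @param net a `cpgwalk_cpg`.
#' @param feed feedback vector (length `net$n`; zero-padded where a unit
#'   receives none). Defaults to zeros.
#' @return list with `ud`, `vd` and the rectified outputs `y`.
#' @export
cpg_derivatives <- function(net, feed = rep(0, net$n)) {
  stopifnot(length(feed) == net$n, all(is.finite(net$u)), all(is.finite(feed)))
  cpgDerivC(net$u, net$v, net$w, net$beta, net$tau, net$taup, net$u0, feed)
}

#' Advance a CPG network by one RK4 step
#' @param net a `cpgwalk_cpg`.
#' @param dt step size (s).
#' @param feed feedback vector held constant over the step.
#' @return the updated network.
#' @export
cpg_step <- function(net, dt, feed = rep(0, net$n)) {
  y <- c(net$u, net$v)
  f <- function(t, s) {
    d <- cpgDerivC(s[seq_len(net$n)], s[net$n + seq_len(net$n)], net$w,
                   net$beta, net$tau, net$taup, net$u0, feed)
    c(d$ud, d$vd)
  }
  y2 <- rk4_step(y, f, dt)
  net$u <- y2[seq_len(net$n)]
  net$v <- y2[net$n + seq_len(net$n)]
  net$y <- pmax(0, net$u)
  net
}

# 12x12 walker connection matrix from 11 named symmetric coupling strengths.
# Applied identically to both legs; the two hip pairs are additionally coupled
# across the body so the legs settle into antiphase.
build_wcpg <- function(cpl) {
  need <- c("hip_pair", "knee_pair", "ankle_pair", "contra_hipF", "contra_hipE",
            "hipF_kneeF", "hipF_kneeE", "hipE_kneeE", "kneeF_ankF",
            "kneeF_ankE", "kneeE_ankE")
  stopifnot(all(need %in% names(cpl)))
  un <- cpg_unit_names()
  w <- matrix(0, 12, 12, dimnames = list(un, un))
  for (lg in c("L", "R")) {
    cg <- if (lg == "L") "R" else "L"
    u <- function(nm) paste0(nm, "_", lg)
    # mutual inhibition within each flexor-extensor pair
    w[u("hipF"), u("hipE")] <- w[u("hipE"), u("hipF")] <- cpl[["hip_pair"]]
    w[u("kneeF"), u("kneeE")] <- w[u("kneeE"), u("kneeF")] <- cpl[["knee_pair"]]
    w[u("ankF"), u("ankE")] <- w[u("ankE"), u("ankF")] <- cpl[["ankle_pair"]]
    # contralateral hip coupling (antiphase of the legs)
    w[u("hipF"), paste0("hipF_", cg)] <- cpl[["contra_hipF"]]
    w[u("hipE"), paste0("hipE_", cg)] <- cpl[["contra_hipE"]]
    # descending intra-leg coupling
    w[u("kneeF"), u("hipF")] <- cpl[["hipF_kneeF"]]
    w[u("kneeE"), u("hipF")] <- cpl[["hipF_kneeE"]]
    w[u("kneeE"), u("hipE")] <- cpl[["hipE_kneeE"]]
    w[u("ankF"), u("kneeF")] <- cpl[["kneeF_ankF"]]
    w[u("ankE"), u("kneeF")] <- cpl[["kneeF_ankE"]]
    w[u("ankE"), u("kneeE")] <- cpl[["kneeE_ankE"]]
  }
  w
}

# default motoneuron mixing map: each muscle is driven by its flexor/extensor
# oscillator unit(s); bi-articular muscles get a half-weight secondary drive
default_walpha <- function() {
  un <- cpg_unit_names()
  mn <- as.vector(outer(muscle_order(), c("L", "R"), paste, sep = "_"))
  w <- matrix(0, 18, 12, dimnames = list(mn, un))
  for (lg in c("L", "R")) {
    u <- function(nm) paste0(nm, "_", lg)
    m <- function(nm) paste0(nm, "_", lg)
    w[m("GM"), u("hipE")] <- 1
    w[m("IL"), u("hipF")] <- 1
    w[m("BFL"), u("hipE")] <- 1; w[m("BFL"), u("kneeF")] <- 0.5
    w[m("RF"), u("hipF")] <- 1; w[m("RF"), u("kneeE")] <- 0.5
    w[m("BFS"), u("kneeF")] <- 1
    w[m("VA"), u("kneeE")] <- 1
    w[m("GC"), u("ankE")] <- 1; w[m("GC"), u("kneeF")] <- 0.5
    w[m("SO"), u("ankE")] <- 1
    w[m("TA"), u("ankF")] <- 1
  }
  w
}

default_couplings <- function() {
  c(hip_pair = -2.0, knee_pair = -2.0, ankle_pair = -2.0,
    contra_hipF = -1.0, contra_hipE = -1.0,
    hipF_kneeF = 0.5, hipF_kneeE = -0.5, hipE_kneeE = 0.5,
    kneeF_ankF = 0.5, kneeF_ankE = -0.5, kneeE_ankE = 0.5)
}

#' Construct the full controller weight set
#'
#' Bundles everything the neural controller needs: Matsuoka time constants
#' and adaptation, the 12x12 CPG connection matrix, the 16-per-leg sensory
#' feedback weights, the 23 posture-reflex coefficients, the 18x12
#' motoneuron mixing map and the force-velocity sign flag. The feedback and
#' posture weights default to zero (they are what the genetic algorithm
#' searches); the structural parts default to a reconstructed, editable
#' wiring in the tradition of Matsuoka-oscillator walking controllers.
#'
#' @param u0 tonic CPG input.
#' @param tau,taup membrane / adaptation time constants (s).
#' @param beta adaptation coefficient.
#' @param couplings named vector of 11 CPG coupling strengths (see
#'   [build_wcpg]).
#' @param w_feed 2 x 16 matrix of per-leg feedback weights (rows left,
#'   right).
#' @param w_pos numeric length 23, posture-reflex coefficients.
#' @param w_alpha 18 x 12 motoneuron mixing matrix.
#' @param fv_sign force-velocity sign convention (`1`: positive normalized
#'   velocity = lengthening).
#' @param grf_thresh vertical GRF threshold (N) above which a foot counts as
#'   in contact for feedback gating.
#' @return object of class `cpgwalk_controller`.
#' @export
controller_weights <- function(u0 = 1.2, tau = 0.08, taup = 0.16, beta = 2.5,
                               couplings = default_couplings(),
                               w_feed = matrix(0, 2, 16,
                                               dimnames = list(c("left", "right"), NULL)),
                               w_pos = rep(0, 23),
                               w_alpha = default_walpha(),
                               fv_sign = 1, grf_thresh = 10) {
  stopifnot(nrow(w_feed) == 2, ncol(w_feed) == 16, length(w_pos) == 23,
            nrow(w_alpha) == 18, ncol(w_alpha) == 12, tau > 0, taup > 0)
  ctrl <- list(u0 = u0, tau = rep(tau, 12), taup = rep(taup, 12), beta = beta,
               couplings = couplings, w_cpg = build_wcpg(couplings),
               w_feed = w_feed, w_pos = as.numeric(w_pos), w_alpha = w_alpha,
               fv_sign = fv_sign, grf_thresh = grf_thresh)
  class(ctrl) <- "cpgwalk_controller"
  ctrl
}

#' @export
print.cpgwalk_controller <- function(x, ...) {
  cat("<cpgwalk_controller>\n")
  cat(sprintf("  u0 = %.3f, tau = %.3f s, tau' = %.3f s, beta = %.2f\n",
              x$u0, x$tau[1], x$taup[1], x$beta))
  cat(sprintf("  |w_feed| left/right: %.3f / %.3f; fv_sign = %+d\n",
              sum(abs(x$w_feed[1, ])), sum(abs(x$w_feed[2, ])),
              as.integer(x$fv_sign)))
  invisible(x)
}

# flatten for the C++ core
controller_params <- function(ctrl) {
  list(tau = ctrl$tau, taup = ctrl$taup, beta = ctrl$beta, u0 = ctrl$u0,
       w_cpg = unname(ctrl$w_cpg), w_feed = unname(ctrl$w_feed),
       w_pos = ctrl$w_pos, w_alpha = unname(ctrl$w_alpha),
       fv_sign = ctrl$fv_sign, grf_thresh = ctrl$grf_thresh)
}

#' Sensory feedback signals to the CPG
#'
#' Each CPG unit receives a linear combination of segment-angle signals and
#' contact-gated, body-weight-normalized vertical GRFs, with 16 weighted
#' slots per leg. The slot-to-sensor wiring is fixed (documented in the
#' methods vignette): slots 1-8 feed the hip pair from the ipsilateral and
#' contralateral thigh angles, the HAT angle and the ipsilateral GRF; slots
#' 9-12 feed the knee pair from the shank angle and the GRF; slots 13-16
#' feed the ankle pair from the foot angle and the ipsi-/contralateral GRF.
#'
#' @param sensors list with `seg_angles` (named numeric length 7: `hat`,
#'   `thigh_l`, `shank_l`, `foot_l`, `thigh_r`, `shank_r`, `foot_r`, rad)
#'   and `grf` (length 2, left/right vertical GRF in N, `>= 0`).
#' @param w_feed 2 x 16 weight matrix (rows left, right).
#' @param body_weight body weight (N) used to normalize GRFs.
#' @param grf_thresh contact gating threshold (N).
#' @return named feedback vector of length 12 (one per CPG unit).
#' @export
compute_feedback <- function(sensors, w_feed, body_weight,
                             grf_thresh = 10) {
  th <- sensors$seg_angles
  need <- c("hat", "thigh_l", "shank_l", "foot_l", "thigh_r", "shank_r", "foot_r")
  if (!all(need %in% names(th)))
    stop("seg_angles must name: ", paste(need, collapse = ", "))
  if (any(sensors$grf < 0)) stop("GRF must be non-negative")
  f <- feedSignalsC(as.numeric(th[need]), as.numeric(sensors$grf),
                    unname(w_feed), body_weight, grf_thresh)
  setNames(f, cpg_unit_names())
}

#' Alpha-motoneuron outputs
#'
#' `alpha_m = clamp(2 / (1 + exp(-0.25 (sum_i w_mi y_i + P_m))) - 1, 0, 1)`:
#' an increasing sigmoid of the summed oscillator drive plus the posture
#' correction, clamped to the admissible activation range. Muscles flagged
#' inactive (removed with the prosthesis) output zero.
#'
#' @param y CPG outputs (length 12, `>= 0`).
#' @param posture posture corrections `P_m` (length 18).
#' @param w_alpha 18 x 12 mixing matrix.
#' @param active logical/numeric length 18 muscle availability.
#' @return activation vector in `[0, 1]^18`.
#' @export
motoneuron_output <- function(y, posture = rep(0, 18),
                              w_alpha = default_walpha(),
                              active = rep(TRUE, 18)) {
  stopifnot(all(y >= 0), length(posture) == nrow(w_alpha))
  motoneuronC(as.numeric(y), as.numeric(posture), unname(w_alpha),
              as.numeric(active))
}

#' Posture-reflex corrections
#'
#' Stance-gated proportional-derivative corrections on HAT pitch and the
#' stance leg's joint angles, distributed to the 18 muscles through the
#' 23-coefficient posture weight vector: per-muscle-group P and D weights on
#' the group's primary-joint error (18), plus HAT-pitch P/D weights routed
#' to the hip, knee and ankle groups (5). The correction is strictly linear
#' in the coefficients, role-signed (extensors and flexors receive opposite
#' corrections), vanishes in the reference posture, and muscles of a leg not
#' in ground contact receive zero.
#'
#' @param sensors list with `joint_angles` and `joint_rates` (length 6 each:
#'   hip/knee/ankle left then right, rad and rad/s), `hat_pitch`,
#'   `hat_pitch_rate`, and `grf` (length 2, N).
#' @param w_pos numeric length 23.
#' @param muscles muscle table (for side/joint/role metadata).
#' @param body_weight body weight (N).
#' @param grf_thresh contact gating threshold (N).
#' @return named posture correction vector (length 18).
#' @export
posture_control <- function(sensors, w_pos, muscles = default_muscles(),
                            body_weight = 70 * 9.81, grf_thresh = 10) {
  p <- postureSignalsC(as.numeric(sensors$joint_angles),
                       as.numeric(sensors$joint_rates),
                       sensors$hat_pitch, sensors$hat_pitch_rate,
                       as.numeric(sensors$grf), as.numeric(w_pos),
                       muscle_matrix(muscles), body_weight, grf_thresh)
  setNames(p, rownames(muscles))
}
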