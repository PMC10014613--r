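# reference two-unit oscillator used in several tests
two_unit <- function(u = c(0.1, 0), tau = 0.08, taup = 0.16, beta = 2.5,
                     a = -2.0, u0 = 1)
  cpg_network(n = 2, tau = tau, taup = taup, beta = beta,
              w = matrix(c(0, a, a, 0), 2, 2), u0 = u0, u = u)

settle <- function(net, T, dt = 1e-3, trace = FALSE) {
  n <- round(T / dt)
  y1 <- if (trace) numeric(n) else NULL
  for (i in seq_len(n)) {
    net <- cpg_step(net, dt)
    if (trace) y1[i] <- net$y[1] - net$y[2]
  }
  if (trace) y1 else net
}

test_that("uncoupled neuron settles on the closed-form fixed point u* = u0/(1+beta)", {
  net <- cpg_network(n = 1, tau = 0.05, taup = 0.1, beta = 1,
                     w = matrix(0, 1, 1), u0 = 1, u = 0.2)
  # derivative vanishes exactly at the closed-form fixed point
  net$u <- 0.5; net$v <- 0.5
  d <- cpg_derivatives(net)
  expect_equal(d$ud, 0); expect_equal(d$vd, 0)
  # and the dynamics converge to it
  net$u <- 0.0; net$v <- 0.0
  net <- settle(net, 3)
  expect_equal(net$u, 0.5, tolerance = 1e-4)
  # rectification: y = max(0, u)
  net$u <- -0.3
  expect_equal(cpg_derivatives(net)$y, 0)
})

test_that("mutually inhibitory pair sustains alternation with IC-invariant period", {
  period_amp <- function(u_init) {
    y <- settle(two_unit(u = u_init), 20, trace = TRUE)
    s <- y[(length(y) / 2):length(y)]           # discard transient
    expect_gt(max(s), 0.05); expect_lt(min(s), -0.05)  # sustained alternation
    cr <- which(diff(sign(s)) == 2)
    expect_gt(length(cr), 3)                     # no fixed point
    mean(diff(cr)) * 1e-3
  }
  p1 <- period_amp(c(0.1, 0))
  p2 <- period_amp(c(2, -1))
  p3 <- period_amp(c(0.5, 0.4))
  expect_lt(abs(p1 - p2) / p1, 0.01)
  expect_lt(abs(p1 - p3) / p1, 0.01)
})

test_that("feedback is linear in the weights and swaps with the legs", {
  set.seed(11)
  bw <- 70 * 9.81
  snap <- list(seg_angles = c(hat = 0.1, thigh_l = 0.2, shank_l = -0.1,
                              foot_l = 0.05, thigh_r = -0.3, shank_r = 0.15,
                              foot_r = -0.05),
               grf = c(400, 250))
  w <- matrix(rnorm(32), 2, 16)
  expect_true(all(compute_feedback(snap, matrix(0, 2, 16), bw) == 0))
  f1 <- compute_feedback(snap, w, bw)
  expect_equal(unname(compute_feedback(snap, 3 * w, bw)), unname(3 * f1))
  # left/right interchange: swapped snapshot + swapped weight blocks give
  # the leg-swapped feedback vector
  snap_sw <- list(seg_angles = c(hat = 0.1, thigh_l = -0.3, shank_l = 0.15,
                                 foot_l = -0.05, thigh_r = 0.2, shank_r = -0.1,
                                 foot_r = 0.05),
                  grf = c(250, 400))
  f2 <- compute_feedback(snap_sw, w[2:1, ], bw)
  expect_equal(unname(f2), unname(f1[c(7:12, 1:6)]))
  # contact gating: GRF below threshold contributes nothing
  snap0 <- snap; snap0$grf <- c(5, 5)
  wg <- matrix(0, 2, 16); wg[, 7] <- 1  # a GRF slot
  expect_true(all(compute_feedback(snap0, wg, bw) == 0))
  expect_error(compute_feedback(list(seg_angles = c(hat = 1), grf = c(0, 0)),
                                w, bw))
})

test_that("motoneuron output is the clamped increasing sigmoid on [0,1]", {
  y <- rep(0, 12)
  expect_true(all(motoneuron_output(y) == 0))
  # hand-inverted sigmoid: drive with 0.25*drive = ln 3 gives alpha = 0.5
  w <- matrix(0, 18, 12); w[, 1] <- 1
  drive <- 4 * log(3)
  y1 <- c(drive, rep(0, 11))
  expect_equal(motoneuron_output(y1, w_alpha = w)[1], 0.5, tolerance = 1e-12)
  expect_equal(motoneuron_output(c(1e4, rep(0, 11)), w_alpha = w)[1], 1)
  # negative net drive clamps at 0, removed muscles forced to 0
  expect_equal(motoneuron_output(y1, posture = rep(-100, 18), w_alpha = w)[1], 0)
  act <- rep(TRUE, 18); act[c(3, 10)] <- FALSE
  out <- motoneuron_output(c(5, rep(1, 11)), w_alpha = matrix(1, 18, 12),
                           active = act)
  expect_true(all(out[c(3, 10)] == 0) && all(out[-c(3, 10)] > 0))
  # clamp contract holds over random inputs
  set.seed(4)
  for (i in 1:20) {
    a <- motoneuron_output(runif(12, 0, 3), rnorm(18, 0, 10),
                           matrix(rnorm(18 * 12), 18, 12))
    expect_true(all(a >= 0 & a <= 1))
  }
})

test_that("posture reflex: zero at reference, linear in weights, stance-gated", {
  mus <- default_muscles()
  mks <- function(grf) list(joint_angles = rep(0, 6), joint_rates = rep(0, 6),
                            hat_pitch = 0, hat_pitch_rate = 0, grf = grf)
  set.seed(2)
  w <- runif(23, -2, 2)
  expect_true(all(posture_control(mks(c(400, 400)), w, mus) == 0))
  s2 <- list(joint_angles = runif(6, -0.3, 0.3), joint_rates = runif(6, -1, 1),
             hat_pitch = 0.12, hat_pitch_rate = -0.4, grf = c(400, 300))
  p1 <- posture_control(s2, w, mus)
  expect_equal(unname(posture_control(s2, 2 * w, mus)), unname(2 * p1))
  # swing-leg muscles receive no correction
  s3 <- s2; s3$grf <- c(400, 0)
  p <- posture_control(s3, w, mus)
  expect_true(all(p[mus$side == "right"] == 0))
  expect_true(any(p[mus$side == "left"] != 0))
})

test_that("controller evaluation is pure: same inputs give same outputs", {
  set.seed(9)
  snap <- list(seg_angles = setNames(rnorm(7, 0, 0.2),
                                     c("hat", "thigh_l", "shank_l", "foot_l",
                                       "thigh_r", "shank_r", "foot_r")),
               grf = c(500, 100))
  w <- matrix(rnorm(32), 2, 16)
  expect_identical(compute_feedback(snap, w, 700),
                   compute_feedback(snap, w, 700))
  net <- two_unit()
  expect_identical(cpg_derivatives(net, rep(0.3, 2)),
                   cpg_derivatives(net, rep(0.3, 2)))
})
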