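# independent closed-form oracles, written out here rather than calling the
# package, so the implementation is checked against a second derivation
oracle_fl <- function(xi)
  pmax(0, 0.32 + 0.71 * exp(-1.112 * (xi - 1.0)) * sin(3.722 * (xi - 0.656)))
oracle_fv <- function(eta) 1 + tanh(3.0 * eta)

test_that("force-length gain matches the closed form and peaks at optimum length", {
  expect_identical(force_length(0.656), 0.32)
  grid <- seq(0.4, 1.8, by = 0.007)
  expect_equal(force_length(grid), oracle_fl(grid), tolerance = 1e-12)
  expect_equal(force_length(1.0), 1.0, tolerance = 0.01)
  # derivative ~ 0 at the optimum, and the maximum sits at xi = 1 +/- 0.01
  h <- 1e-6
  expect_lt(abs((force_length(1 + h) - force_length(1 - h)) / (2 * h)), 1e-3)
  fine <- seq(0.6, 1.4, by = 1e-4)
  expect_lt(abs(fine[which.max(force_length(fine))] - 1.0), 0.01)
  expect_true(all(force_length(seq(0.05, 3, by = 0.01)) >= 0))
  expect_error(force_length(-0.1))
})

test_that("force-velocity gain is the bounded tanh form, monotone, h(0) = 1", {
  expect_identical(force_velocity(0), 1.0)
  expect_equal(force_velocity(0.5), 1 + tanh(1.5), tolerance = 1e-12)
  eta <- seq(-5, 5, by = 0.01)
  h <- force_velocity(eta)
  expect_equal(h, oracle_fv(eta), tolerance = 1e-12)
  expect_true(all(h > 0 & h < 2))
  expect_true(all(diff(h) >= 0))
  expect_equal(force_velocity(50), 2, tolerance = 1e-8)
  expect_equal(force_velocity(-50), 0, tolerance = 1e-8)
})

test_that("muscle tension combines CE, PD and PE terms as specified", {
  spec <- default_muscles()[1, ]  # GM
  # every term vanishes at rest
  expect_equal(unname(muscle_tension(spec, spec$l_bar, 0, 0)[["F"]]), 0)
  # full activation at optimum length, isometric: F ~ F_ce_max
  F1 <- muscle_tension(spec, spec$l_bar, 0, 1)
  expect_equal(unname(F1[["F"]]), spec$f_ce, tolerance = 0.01)
  # passive elastic term: hand arithmetic on the exponential form
  Fpe <- muscle_tension(spec, spec$l_bar + 0.01, 0, 0)
  expect_equal(unname(Fpe[["F_pe"]]), spec$k_pe * (exp(0.15) - 1),
               tolerance = 1e-12)
  # PE inactive in shortening
  expect_equal(unname(muscle_tension(spec, spec$l_bar - 0.05, 0, 0)[["F_pe"]]), 0)
  # PD opposes stretch: lengthening adds tension, shortening subtracts
  expect_gt(muscle_tension(spec, spec$l_bar, 0.1, 0)[["F_pd"]], 0)
  expect_lt(muscle_tension(spec, spec$l_bar, -0.1, 0)[["F_pd"]], 0)
  # CE tension non-decreasing in activation at fixed kinematics
  alphas <- seq(0, 1, by = 0.1)
  Fs <- vapply(alphas, function(a)
    muscle_tension(spec, spec$l_bar * 1.05, 0.02, a)[["F_ce"]], numeric(1))
  expect_true(all(diff(Fs) >= 0))
})

test_that("path model: reference posture, anatomy signs, bi-articular partials", {
  m <- default_muscles()
  ref <- c(hip = 0, knee = 0, ankle = 0)
  for (i in seq_len(nrow(m)))
    expect_equal(muscle_kinematics(ref, m[i, ])$L, m$l_bar[i])
  # mono-articular VA: positive tension extends the knee (negative torque in
  # the flexion-positive convention)
  va <- m["VA_left", ]
  expect_lt(muscle_kinematics(ref, va, tension = 100)$torque[["knee"]], 0)
  # bi-articular RF stretches with hip extension and knee flexion
  rf <- m["RF_left", ]
  h <- 1e-6
  dL_dhip <- (muscle_kinematics(c(hip = h, knee = 0, ankle = 0), rf)$L -
              muscle_kinematics(c(hip = -h, knee = 0, ankle = 0), rf)$L) / (2 * h)
  dL_dknee <- (muscle_kinematics(c(hip = 0, knee = h, ankle = 0), rf)$L -
               muscle_kinematics(c(hip = 0, knee = -h, ankle = 0), rf)$L) / (2 * h)
  expect_lt(dL_dhip, 0)   # hip extension = decreasing flexion angle -> dL > 0
  expect_gt(dL_dknee, 0)
  # left/right specs are mirrored copies: identical tension for mirrored states
  left <- m[m$side == "left", ]; right <- m[m$side == "right", ]
  for (i in seq_len(nrow(left)))
    expect_identical(muscle_tension(left[i, ], left$l_bar[i] + 0.01, 0.05, 0.7),
                     muscle_tension(right[i, ], right$l_bar[i] + 0.01, 0.05, 0.7))
})

test_that("metabolic rate is non-negative, zero when inactive, monotone in activation", {
  m <- default_muscles()
  n <- nrow(m)
  expect_true(all(metabolic_rate(m, rep(0, n), m$l_bar, rep(0, n)) == 0))
  e1 <- metabolic_rate(m, rep(0.3, n), m$l_bar, rep(0, n))
  e2 <- metabolic_rate(m, rep(0.6, n), m$l_bar, rep(0, n))
  expect_true(all(e1 >= 0) && all(e2 >= e1))
  # shortening adds heat and work terms over isometric at the same activation
  e_iso <- metabolic_rate(m, rep(0.5, n), m$l_bar, rep(0, n))
  e_short <- metabolic_rate(m, rep(0.5, n), m$l_bar, rep(-0.1, n))
  expect_true(all(e_short > e_iso))
  # removed muscles consume nothing
  utta <- apply_prosthesis(body_model(), "right")
  mu <- default_muscles(utta)
  er <- metabolic_rate(mu, rep(1, n), mu$l_bar, rep(-0.1, n))
  expect_true(all(er[!mu$active] == 0))
  expect_true(all(er[mu$active] > 0))
})
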