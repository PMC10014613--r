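test_that("default body satisfies its invariants", {
  b <- body_model()
  expect_equal(b$joint_viscosity, c(1.09, 3.17, 0.943))
  expect_equal(b$contact, c(5.0e3, 1.0e3, 2.5e4, 5.0e2))
  expect_equal(total_mass(b), sum(b$mass))
  expect_true(all(b$mass > 0) && all(b$inertia > 0))
  expect_error(body_model(mass = c(-1, rep(1, 6))), "positive")
})

test_that("prosthesis operator scales the shank/foot complex and removes ankle muscles", {
  b <- body_model()
  p <- apply_prosthesis(b, "right")
  # shank: 3.0 kg -> 1.95 kg; inertia 0.05 -> 0.02
  expect_equal(p$mass[6], 1.95)
  expect_equal(p$inertia[6], 0.02)
  expect_equal(p$mass[7], b$mass[7] * 0.65)
  expect_equal(p$inertia[7], b$inertia[7] * 0.40)
  expect_equal(p$pros_ankle_k, 400)
  expect_setequal(p$removed_muscles, c("TA_right", "SO_right", "GC_right"))
  # everything else untouched
  expect_identical(p$mass[1:5], b$mass[1:5])
  expect_identical(p$inertia[1:5], b$inertia[1:5])
  expect_identical(p$contact, b$contact)
  expect_identical(p$joint_viscosity, b$joint_viscosity)
  # left side removal and the muscle table honour the flags
  pl <- apply_prosthesis(b, "left")
  mu <- default_muscles(pl)
  expect_false(any(mu$active[rownames(mu) %in% c("TA_left", "SO_left", "GC_left")]))
  expect_true(all(mu$active[mu$side == "right"]))
  expect_error(apply_prosthesis(b, "rigth"), "unknown side")
})

test_that("contact force arithmetic: spring-damper with non-adhesion clamp", {
  expect_equal(unname(contact_force(0)), c(0, 0))
  expect_equal(unname(contact_force(-0.02, c(0, -1))), c(0, 0))  # above ground
  f <- contact_force(0.01)
  expect_equal(unname(f[["fy"]]), 250)  # 2.5e4 * 0.01
  f2 <- contact_force(0.002, horizontal_disp = 0.002)
  expect_equal(unname(f2[["fx"]]), -10)  # restoring, magnitude 5e3 * 0.002
  # separating fast: damper would pull down, clamped at zero
  expect_equal(unname(contact_force(0.001, c(0, 10))[["fy"]]), 0)
  expect_true(all(vapply(seq(-0.01, 0.03, by = 0.001), function(d)
    contact_force(d, c(0.3, runif(1, -2, 2)))[["fy"]], numeric(1)) >= 0))
})

test_that("passive joint moment: viscosity, one-sided lock, prosthetic ankle", {
  b <- body_model()
  expect_equal(joint_passive_moment("hip", 0.2, 0, b), 0)
  expect_equal(joint_passive_moment("hip", 0, 1.0, b), -1.09)
  expect_equal(joint_passive_moment("knee", 0, 1.0, b), -3.17)
  expect_equal(joint_passive_moment("ankle", 0, 1.0, b), -0.943)
  # knee 0.05 rad beyond hyperextension: restoring (positive) moment
  expect_gt(joint_passive_moment("knee", b$rom_knee[1] - 0.05, 0, b), 0)
  expect_lt(joint_passive_moment("knee", b$rom_knee[2] + 0.05, 0, b), 0)
  # prosthetic ankle: additional -400 * theta on the prosthetic side only
  p <- apply_prosthesis(b, "right")
  th <- 0.1
  expect_equal(joint_passive_moment("ankle", th, 0, p, side = "right"),
               -400 * th)
  expect_equal(joint_passive_moment("ankle", th, 0, p, side = "left"), 0)
  expect_error(joint_passive_moment("elbow", 0, 0, b), "unknown joint")
})

test_that("equations of motion: free fall, static equilibrium, scale invariance, mirror symmetry", {
  b <- body_model()
  # airborne, zero torques: COM falls at -g (finite-difference on the COM path)
  st <- random_state(b, 42)
  st$q[2] <- 5; st$qd <- rep(0, 9)
  f <- function(t, s) c(s[10:18], equations_of_motion(s[1:9], s[10:18], body = b))
  dt <- 1e-3
  s0 <- c(st$q, st$qd)
  s1 <- rk4_step(s0, f, dt); s2 <- rk4_step(s1, f, dt)
  com_y <- function(s) body_points(b, s[1:9], s[10:18])["com", "y"]
  acc <- (com_y(s2) - 2 * com_y(s1) + com_y(s0)) / dt^2
  expect_equal(acc, -9.81, tolerance = 1e-6)

  # hand-derived static standing equilibrium forces give ~zero accelerations
  stand <- standing_state(b)
  Fc <- standing_contact_forces(b)
  acc0 <- equations_of_motion(stand$q, stand$qd, contact_forces = Fc, body = b)
  expect_lt(max(abs(acc0)), 1e-9)

  # doubling every mass/inertia and every applied force/torque leaves
  # accelerations unchanged (gravity scales with mass automatically)
  b2 <- body_model(mass = b$mass * 2, inertia = b$inertia * 2)
  st <- random_state(b, 7)
  tau <- runif(6, -20, 20)
  Fc <- matrix(runif(8, -50, 200), 4, 2)
  a1 <- equations_of_motion(st$q, st$qd, tau, Fc, b)
  a2 <- equations_of_motion(st$q, st$qd, 2 * tau, 2 * Fc, b2)
  expect_equal(a1, a2, tolerance = 1e-10)

  # side symmetry of the normal body: exchanging the left and right leg
  # states, torques and forces exchanges the leg accelerations
  for (seed in 1:3) {
    st <- random_state(b, seed)
    tau <- runif(6, -10, 10)
    Fc <- matrix(runif(8, -20, 100), 4, 2)
    swap_q <- function(q) c(q[1:3], q[7:9], q[4:6])
    a <- equations_of_motion(st$q, st$qd, tau, Fc, b)
    as_ <- equations_of_motion(swap_q(st$q), swap_q(st$qd),
                               tau[c(4:6, 1:3)], Fc[c(3, 4, 1, 2), ], b)
    expect_equal(unname(as_), unname(swap_q(a)), tolerance = 1e-9)
  }
  # full sagittal mirror (x negated, angles negated, legs swapped) is exact
  # once the foot geometry is fore-aft symmetric
  bs <- body_model(foot_geom = c(0.12, 0.12, 0.07, 0, 0.03))
  for (seed in 4:6) {
    st <- random_state(bs, seed)
    tau <- runif(6, -10, 10)
    Fc <- matrix(runif(8, -20, 100), 4, 2)
    a <- equations_of_motion(st$q, st$qd, tau, Fc, bs)
    am <- equations_of_motion(mirror_q(st$q), mirror_q(st$qd),
                              mirror_joint6(tau), mirror_forces(Fc), bs)
    expect_equal(unname(am), unname(mirror_q(a)), tolerance = 1e-9)
  }
  expect_error(equations_of_motion(stand$q, stand$qd,
                                   body = body_model(inertia = rep(1e-30, 7),
                                                     mass = rep(1e-30, 7) + 1e-30)))
})

test_that("RK4 integrator: identity at dt=0, 5th-order local error, 4th-order convergence", {
  y0 <- c(1, 2)
  expect_identical(rk4_step(y0, function(t, y) y, 0), y0)
  # scalar exponential: one step matches exp(lambda dt) to O(dt^5)
  lam <- -2.3
  for (dt in c(1e-2, 5e-3)) {
    err <- abs(rk4_step(1, function(t, y) lam * y, dt) - exp(lam * dt))
    expect_lt(err, 10 * abs(lam * dt)^5 / 120)
  }
  # harmonic oscillator: halving dt shrinks the global error ~16x
  f <- function(t, y) c(y[2], -y[1])
  integrate_to <- function(dt, T = 2) {
    y <- c(1, 0)
    for (i in seq_len(round(T / dt))) y <- rk4_step(y, f, dt)
    y
  }
  exact <- c(cos(2), -sin(2))
  e1 <- max(abs(integrate_to(0.02) - exact))
  e2 <- max(abs(integrate_to(0.01) - exact))
  expect_gt(e1 / e2, 12)
  expect_lt(e1 / e2, 20)
  expect_error(rk4_step(1, function(t, y) NaN, 0.1), "non-finite")
})

test_that("passive dynamics only dissipate: mechanical energy decays without ground or muscles", {
  b <- body_model()
  init <- default_init(b, push = 0)
  init$q0[2] <- 3                       # airborne
  # joint angles stay inside the range-of-motion limits for the whole trial,
  # so no lock-spring potential energy enters the balance
  init$q0[3:9] <- c(0.1, 0.3, 0.1, 0.05, 0.3, 0.1, 0)
  init$qd0 <- c(0, 0, 0.3, 0.5, 0.1, 0, 0.4, 0.05, -0.1)
  tr <- run_trial(b, controller_weights(), duration = 0.3, log_every = 50L,
                  init = init, ground = FALSE, controller_on = FALSE,
                  fall_check = FALSE)
  E <- apply(tr$log, 1, function(r)
    mechanical_energy(b, as.numeric(r[2:10]), as.numeric(r[11:19])))
  expect_true(all(diff(E) <= 1e-8))
  expect_lt(E[length(E)], E[1])
})
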