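# shared helpers: small state constructors used across the dynamics tests

standing_state <- function(body) {
  list(q = c(0, standing_height(body), 0, rep(0, 6)), qd = rep(0, 9))
}

# random but physically sane state within joint ranges
random_state <- function(body, seed = 1) {
  set.seed(seed)
  q <- c(runif(1, -0.5, 0.5), runif(1, 0.8, 1.2), runif(7, -0.3, 0.3))
  qd <- runif(9, -0.5, 0.5)
  list(q = q, qd = qd)
}

# sagittal mirror: reverse the walking direction and swap the legs.
# x -> -x, all absolute segment angles negate, left/right leg blocks swap.
mirror_q <- function(q) c(-q[1], q[2], -q[3], -q[7:9], -q[4:6])

# joint-level quantities (hip/knee/ankle per side) negate and swap sides
mirror_joint6 <- function(v) c(-v[4:6], -v[1:3])

# contact-point forces under the sagittal mirror: legs swap, heel and toe
# exchange roles (valid for a fore-aft symmetric foot), horizontal negates
mirror_forces <- function(f) {
  f2 <- f[c(4, 3, 2, 1), , drop = FALSE]
  f2[, 1] <- -f2[, 1]
  f2
}

# hand-computed static standing contact forces (per-leg vertical balance and
# moment balance about the ankle), used as the equilibrium oracle
standing_contact_forces <- function(body) {
  fg <- body$foot_geom
  M <- total_mass(body)
  mF <- body$mass[4]
  A <- rbind(c(1, 1), c(-fg[1], fg[2]))
  sol <- solve(A, c(M * body$g / 2, mF * body$g * fg[4]))
  Fc <- matrix(0, 4, 2)
  Fc[, 2] <- sol[c(1, 2, 1, 2)]
  Fc
}
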