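test_that("fitness function implements the distance/penalty/economy branches", {
  expect_equal(ga_fitness(2.0, fell = TRUE), -1.0)
  expect_equal(ga_fitness(5.0, fell = FALSE, cot = 10), 11.0)
  expect_equal(ga_fitness(5.0, fell = TRUE, cot = 10), 8.0)
  # monotone decreasing in cost of transport
  expect_gt(ga_fitness(5, FALSE, 5), ga_fitness(5, FALSE, 10))
  # below 3 m the economy term is absent even with a valid CoT
  expect_equal(ga_fitness(2.9, FALSE, 1), 2.9)
  expect_error(ga_fitness(4, FALSE, cot = 0), "cost of transport")
  expect_error(ga_fitness(4, FALSE, cot = NA), "cost of transport")
  # a non-faller strictly outscores any faller at equal distance
  set.seed(5)
  for (i in 1:20) {
    D <- runif(1, 0, 8); C <- runif(1, 1, 20)
    expect_gt(ga_fitness(D, FALSE, C), ga_fitness(D, TRUE, C))
  }
})

test_that("scenario genomes have the stated sizes and decode correctly", {
  expect_equal(genome_spec("normal")$length, 51)
  expect_equal(genome_spec("utta_symmetric")$length, 17)
  expect_equal(genome_spec("utta_asymmetric")$length, 33)
  set.seed(8)
  # symmetric scenarios tie the left/right feedback blocks exactly
  for (sc in c("normal", "utta_symmetric")) {
    spec <- genome_spec(sc)
    g <- runif(spec$length, spec$bounds["lo", ], spec$bounds["hi", ])
    ctrl <- decode_genome(g, spec)
    expect_identical(unname(ctrl$w_feed[1, ]), unname(ctrl$w_feed[2, ]))
  }
  spec <- genome_spec("utta_asymmetric")
  g <- runif(spec$length, spec$bounds["lo", ], spec$bounds["hi", ])
  ctrl <- decode_genome(g, spec)
  expect_false(identical(unname(ctrl$w_feed[1, ]), unname(ctrl$w_feed[2, ])))
  expect_equal(unname(ctrl$w_feed[1, ]), unname(g[2:17]))
  expect_equal(unname(ctrl$w_feed[2, ]), unname(g[18:33]))
  # UTTA decode freezes everything else at the base (normal) controller
  nspec <- genome_spec("normal")
  ng <- runif(nspec$length, nspec$bounds["lo", ], nspec$bounds["hi", ])
  base <- decode_genome(ng, nspec)
  sctrl <- decode_genome(runif(17, -1, 1), genome_spec("utta_symmetric"), base)
  expect_identical(sctrl$w_cpg, base$w_cpg)
  expect_identical(sctrl$w_pos, base$w_pos)
  expect_error(decode_genome(rep(0, 10), nspec), "length")
})

test_that("GA: elitism monotonicity, reproducibility, bound clipping, sphere convergence", {
  sphere <- function(x) -sum((x - 0.3)^2)
  bounds <- rbind(lo = rep(-1, 5), hi = rep(1, 5))
  colnames(bounds) <- paste0("g", 1:5)
  r1 <- run_ga(sphere, bounds, pop_size = 32, generations = 60, seed = 2)
  r2 <- run_ga(sphere, bounds, pop_size = 32, generations = 60, seed = 2)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best, r2$best)
  r3 <- run_ga(sphere, bounds, pop_size = 32, generations = 60, seed = 3)
  expect_false(identical(r1$best, r3$best))
  # elitism makes best-of-generation non-decreasing
  expect_true(all(diff(r1$history$best) >= 0))
  # bounds respected after variation
  expect_true(all(r1$population >= -1 & r1$population <= 1))
  # converges near the optimum
  expect_gt(r1$best_fitness, -1e-2)
  # a throwing fitness is fault-isolated, not fatal
  flaky <- function(x) if (x[1] > 0) stop("boom") else sphere(x)
  expect_silent(rf <- run_ga(flaky, bounds, pop_size = 8, generations = 3,
                             seed = 1))
  expect_true(all(is.finite(rf$fitness)))
})

test_that("warm start freezes non-scenario genes and projects the normal genome", {
  nspec <- genome_spec("normal")
  set.seed(21)
  ng <- runif(nspec$length, nspec$bounds["lo", ], nspec$bounds["hi", ])
  names(ng) <- nspec$names
  sspec <- genome_spec("utta_symmetric")
  pop <- warm_start_utta(ng, sspec, pop_size = 6, noise_frac = 0)
  expect_equal(dim(pop), c(6, 17))
  # zero exploration noise: every row is the exact projection
  expect_true(all(apply(pop, 1, identical, y = pop[1, ])))
  expect_equal(unname(pop[1, ]), unname(c(ng["u0"], ng[paste0("w_feed", 1:16)])))
  aspec <- genome_spec("utta_asymmetric")
  popa <- warm_start_utta(ng, aspec, pop_size = 4, noise_frac = 0.1)
  expect_equal(dim(popa), c(4, 33))
  expect_equal(unname(popa[1, 2:17]), unname(popa[1, 18:33]))  # projection is symmetric
  expect_true(all(popa >= rep(aspec$bounds["lo", ], each = 4) &
                  popa <= rep(aspec$bounds["hi", ], each = 4)))
  expect_error(warm_start_utta(ng[1:10], sspec), "length")
  expect_error(warm_start_utta(ng, nspec), "UTTA")
})

test_that("genome evaluation is deterministic and a dead controller falls", {
  body <- body_model()
  spec <- genome_spec("normal")
  g0 <- rep(0, 51)
  r1 <- evaluate_genome(g0, spec, body, duration = 3)
  r2 <- evaluate_genome(g0, spec, body, duration = 3)
  expect_identical(unclass(r1), unclass(r2))
  expect_true(r1$fell)
  expect_lt(r1$fitness, 0)
  expect_lt(r1$distance, 3)
})
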