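#' Genome layout for a control scenario
#'
#' Three scenarios are searched:
#' \describe{
#'   \item{normal}{51 free genes: the tonic CPG input `u0`, 16 feedback
#'     weights applied identically to both legs, 11 CPG coupling strengths
#'     and the 23 posture-reflex coefficients.}
#'   \item{utta_symmetric}{17 genes: `u0` plus the 16 feedback weights, still
#'     tied across legs; everything else frozen at the normal solution.}
#'   \item{utta_asymmetric}{33 genes: `u0` plus 16 feedback weights per leg,
#'     searched independently; everything else frozen.}
#' }
#'
#' @param scenario one of `"normal"`, `"utta_symmetric"`,
#'   `"utta_asymmetric"`.
#' @return object of class `cpgwalk_genome_spec` with gene `names`, a
#'   2-row `bounds` matrix (`lo`, `hi`) and the scenario id.
#' @export
genome_spec <- function(scenario = c("normal", "utta_symmetric",
                                     "utta_asymmetric")) {
  scenario <- match.arg(scenario)
  feed_nm <- paste0("w_feed", 1:16)
  cpl_nm <- names(default_couplings())
  pos_nm <- paste0("w_pos", 1:23)
  b <- function(nm, lo, hi) data.frame(name = nm, lo = lo, hi = hi)
  u0_b <- b("u0", 0, 3)
  feed_b <- b(feed_nm, -3, 3)
  cpl_b <- rbind(b(cpl_nm[1:5], -3, 0),    # inhibitory couplings
                 b(cpl_nm[6:11], -2, 2))
  pos_b <- b(pos_nm, -5, 5)  # linear output weights on the posture features
  tab <- switch(scenario,
    normal = rbind(u0_b, feed_b, cpl_b, pos_b),
    utta_symmetric = rbind(u0_b, feed_b),
    utta_asymmetric = rbind(u0_b,
                            b(paste0(feed_nm, "_l"), -3, 3),
                            b(paste0(feed_nm, "_r"), -3, 3)))
  spec <- list(scenario = scenario, names = tab$name,
               bounds = rbind(lo = tab$lo, hi = tab$hi),
               length = nrow(tab))
  colnames(spec$bounds) <- tab$name
  class(spec) <- "cpgwalk_genome_spec"
  spec
}

#' Decode a genome into a controller
#'
#' @param genome numeric vector matching `spec$length`.
#' @param spec a `cpgwalk_genome_spec`.
#' @param base controller supplying the frozen parameters. Required for the
#'   UTTA scenarios (the normal solution); for the normal scenario it
#'   supplies structure (time constants, motoneuron map).
#' @return a `cpgwalk_controller`.
#' @export
decode_genome <- function(genome, spec, base = controller_weights()) {
  if (length(genome) != spec$length)
    stop(sprintf("genome length %d does not match scenario %s (expects %d)",
                 length(genome), spec$scenario, spec$length))
  g <- setNames(as.numeric(genome), spec$names)
  ctrl <- base
  ctrl$u0 <- g[["u0"]]
  if (spec$scenario == "normal") {
    wf <- g[paste0("w_feed", 1:16)]
    ctrl$w_feed <- rbind(left = wf, right = wf)
    ctrl$couplings <- g[names(default_couplings())]
    ctrl$w_cpg <- build_wcpg(ctrl$couplings)
    ctrl$w_pos <- unname(g[paste0("w_pos", 1:23)])
  } else if (spec$scenario == "utta_symmetric") {
    wf <- g[paste0("w_feed", 1:16)]
    ctrl$w_feed <- rbind(left = wf, right = wf)
  } else {
    ctrl$w_feed <- rbind(left = unname(g[paste0("w_feed", 1:16, "_l")]),
                         right = unname(g[paste0("w_feed", 1:16, "_r")]))
  }
  ctrl
}

#' Fitness of a trial record
#'
#' `J = D + P` when the walked distance `D` is below 3 m, and
#' `J = D + P + 60/C` once the model covers at least 3 m, where `C` is the
#' gross metabolic cost of transport and the fall penalty `P` is -3 if the
#' model fell, else 0. A non-faller always outscores a faller at equal
#' distance.
#'
#' @param distance walked distance `D` (m).
#' @param fell logical fall flag.
#' @param cot cost of transport `C` (J/kg/m); required (and `> 0`) when
#'   `distance >= 3`.
#' @param penalty fall penalty (default -3).
#' @return fitness value `J`.
#' @export
ga_fitness <- function(distance, fell, cot = NA_real_, penalty = -3.0) {
  P <- if (isTRUE(fell)) penalty else 0.0
  if (distance < 3) return(distance + P)
  if (!is.finite(cot) || cot <= 0)
    stop("invalid cost of transport for a trial with D >= 3 m")
  distance + P + 60 / cot
}

#' Evaluate one genome with a full forward trial
#'
#' Decodes the genome, runs a single trial from the standard initial posture
#' and scores it. Deterministic: the simulator has no internal randomness.
#' The cost of transport is evaluated over the full trial
#' (`C = E / (M D)`, equivalent to the time-normalized definition with
#' `V = D/T`).
#'
#' @param genome numeric parameter vector.
#' @param spec a `cpgwalk_genome_spec`.
#' @param body a `cpgwalk_body` matching the scenario.
#' @param base base controller (see [decode_genome()]).
#' @param duration trial length (s).
#' @param dt integration step (s).
#' @param ... passed to [run_trial()].
#' @return object of class `cpgwalk_fitness`: `distance`, `fell`, `cot`,
#'   `fitness`, `speed`, `t_end`.
#' @export
evaluate_genome <- function(genome, spec, body, base = controller_weights(),
                            duration = 10, dt = 1e-4, ...) {
  ctrl <- decode_genome(genome, spec, base)
  tr <- run_trial(body, ctrl, duration = duration, dt = dt, log_every = 0L, ...)
  cot <- if (tr$distance > 0) tr$energy / (tr$mass * tr$distance) else NA_real_
  rec <- list(distance = tr$distance, fell = tr$fell, cot = cot,
              speed = tr$speed, t_end = tr$t_end,
              fitness = ga_fitness(tr$distance, tr$fell, cot))
  class(rec) <- "cpgwalk_fitness"
  rec
}

clip_bounds <- function(x, bounds) pmin(pmax(x, bounds["lo", ]), bounds["hi", ])

#' Generational genetic algorithm over a bounded real genome
#'
#' Standard real-coded GA: tournament selection, blend (BLX-alpha)
#' crossover, Gaussian mutation with per-gene standard deviation
#' proportional to the gene range, elitism, and clipping to bounds after
#' every variation. Evaluations go through a pluggable `map_fn` (serial
#' `lapply` by default); an evaluation that throws is fault-isolated and
#' scored as a fall at zero distance, so one crashed trial never kills a
#' run.
#'
#' @param fitness_fn function(genome) returning a finite scalar to maximise
#'   (or an object with a `$fitness` element, e.g. [evaluate_genome()]
#'   output).
#' @param bounds 2 x n matrix with rows `lo`, `hi`.
#' @param pop_size population size (>= 2).
#' @param generations number of generations (>= 1).
#' @param seed RNG seed; the run is reproducible given (seed, config).
#' @param tournament tournament size.
#' @param p_cross crossover probability per pairing.
#' @param blend_alpha BLX-alpha exploration parameter.
#' @param mut_sd_frac mutation SD as a fraction of each gene's range.
#' @param p_mut per-gene mutation probability.
#' @param elitism number of best genomes carried over unchanged (makes the
#'   best-of-generation fitness non-decreasing).
#' @param init_pop optional matrix (rows = genomes) seeding the initial
#'   population; missing rows are drawn uniformly within bounds.
#' @param map_fn list-returning map used for fitness evaluation.
#' @param fallback_fitness score assigned to a failed evaluation.
#' @return list with `best` genome, `best_fitness`, `history` (data.frame:
#'   generation, best, mean), final `population` and `fitness` values.
#' @export
run_ga <- function(fitness_fn, bounds, pop_size = 100, generations = 50,
                   seed = 1, tournament = 3, p_cross = 0.8,
                   blend_alpha = 0.5, mut_sd_frac = 0.05, p_mut = 0.15,
                   elitism = 2, init_pop = NULL, map_fn = lapply,
                   fallback_fitness = -3.0) {
  stopifnot(pop_size >= 2, generations >= 1, nrow(bounds) == 2)
  n <- ncol(bounds)
  rng <- bounds["hi", ] - bounds["lo", ]
  set.seed(seed)

  pop <- matrix(runif(pop_size * n, bounds["lo", ], bounds["hi", ]),
                nrow = pop_size, ncol = n, byrow = TRUE)
  if (!is.null(init_pop)) {
    k <- min(nrow(init_pop), pop_size)
    pop[seq_len(k), ] <- t(apply(init_pop[seq_len(k), , drop = FALSE], 1,
                                 clip_bounds, bounds = bounds))
  }

  score <- function(P) {
    vals <- map_fn(seq_len(nrow(P)), function(i) {
      tryCatch({
        f <- fitness_fn(P[i, ])
        if (is.list(f)) f <- f$fitness
        if (!is.finite(f)) fallback_fitness else f
      }, error = function(e) fallback_fitness)
    })
    unlist(vals)
  }

  fit <- score(pop)
  history <- data.frame(generation = 0, best = max(fit), mean = mean(fit))

  for (gen in seq_len(generations)) {
    ord <- order(fit, decreasing = TRUE)
    newpop <- matrix(NA_real_, pop_size, n)
    n_elite <- min(elitism, pop_size)
    newpop[seq_len(n_elite), ] <- pop[ord[seq_len(n_elite)], , drop = FALSE]
    pick <- function() {
      cand <- sample.int(pop_size, tournament, replace = TRUE)
      cand[which.max(fit[cand])]
    }
    for (i in seq(n_elite + 1, pop_size)) {
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      child <- if (runif(1) < p_cross) {
        # BLX-alpha: sample uniformly in the per-gene interval extended by alpha
        lo <- pmin(p1, p2) - blend_alpha * abs(p1 - p2)
        hi <- pmax(p1, p2) + blend_alpha * abs(p1 - p2)
        runif(n, lo, hi)
      } else p1
      mut <- runif(n) < p_mut
      child[mut] <- child[mut] + rnorm(sum(mut), 0, mut_sd_frac * rng[mut])
      newpop[i, ] <- clip_bounds(child, bounds)
    }
    pop <- newpop
    fit <- score(pop)
    history <- rbind(history,
                     data.frame(generation = gen, best = max(fit),
                                mean = mean(fit)))
  }
  best_i <- which.max(fit)
  list(best = setNames(pop[best_i, ], colnames(bounds)),
       best_fitness = fit[best_i], history = history,
       population = pop, fitness = fit)
}

#' Warm-start population for a UTTA re-search
#'
#' The UTTA scenarios freeze every parameter not in the scenario genome at
#' the normal model's values and re-search only the scenario's free genes,
#' initialized at the normal solution's values plus Gaussian exploration
#' noise (clipped to bounds). The first individual is the exact projection
#' of the normal genome.
#'
#' @param normal_genome the best genome of the normal scenario (length 51).
#' @param spec the UTTA scenario's `cpgwalk_genome_spec`.
#' @param pop_size number of rows to generate.
#' @param noise_frac exploration noise SD as a fraction of each gene range;
#'   `0` reproduces the normal genome verbatim in every row.
#' @return `pop_size` x `spec$length` matrix of initial genomes.
#' @export
warm_start_utta <- function(normal_genome, spec, pop_size = 100,
                            noise_frac = 0.1) {
  normal_spec <- genome_spec("normal")
  if (length(normal_genome) != normal_spec$length)
    stop("normal genome must have length ", normal_spec$length)
  g <- setNames(as.numeric(normal_genome), normal_spec$names)
  center <- switch(spec$scenario,
    utta_symmetric = c(g[["u0"]], g[paste0("w_feed", 1:16)]),
    utta_asymmetric = c(g[["u0"]], g[paste0("w_feed", 1:16)],
                        g[paste0("w_feed", 1:16)]),
    stop("warm start applies to the UTTA scenarios, not ", spec$scenario))
  rng <- spec$bounds["hi", ] - spec$bounds["lo", ]
  pop <- matrix(rep(center, each = pop_size), nrow = pop_size)
  if (pop_size > 1 && noise_frac > 0) {
    noise <- matrix(rnorm((pop_size - 1) * spec$length, 0, noise_frac) *
                      rep(rng, each = pop_size - 1),
                    nrow = pop_size - 1)
    pop[-1, ] <- pop[-1, , drop = FALSE] + noise
  }
  pop <- t(apply(pop, 1, clip_bounds, bounds = spec$bounds))
  colnames(pop) <- spec$names
  pop
}
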