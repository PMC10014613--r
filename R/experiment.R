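#' Scenario configuration
#'
#' Bundles everything one experimental scenario needs: which control
#' scenario is searched, the prosthesis side for the UTTA conditions, trial
#' and GA settings, the stride analysis window and the replication seeds.
#'
#' @param scenario `"normal"`, `"utta_symmetric"` or `"utta_asymmetric"`.
#' @param pros_side prosthesis side for the UTTA scenarios.
#' @param duration trial duration (s).
#' @param dt integration step (s).
#' @param stride_window strides used for gait metrics.
#' @param seeds replication seeds (the replication protocol runs five).
#' @param ga named list of [run_ga()] settings (`pop_size`, `generations`,
#'   operator rates, ...).
#' @return object of class `cpgwalk_scenario`.
#' @export
scenario_config <- function(scenario = c("normal", "utta_symmetric",
                                         "utta_asymmetric"),
                            pros_side = "right", duration = 10, dt = 1e-4,
                            stride_window = c(3, 8), seeds = 1:5,
                            ga = list(pop_size = 100, generations = 2000)) {
  scenario <- match.arg(scenario)
  if (!length(seeds)) stop("seeds list must be non-empty")
  if (scenario != "normal" && !pros_side %in% c("left", "right"))
    stop("UTTA scenarios must reference a prosthesis side")
  cfg <- list(scenario = scenario, pros_side = pros_side, duration = duration,
              dt = dt, stride_window = stride_window, seeds = seeds, ga = ga)
  class(cfg) <- "cpgwalk_scenario"
  cfg
}

scenario_body <- function(cfg, body = body_model()) {
  if (cfg$scenario == "normal") body else apply_prosthesis(body, cfg$pros_side)
}

#' Run a full scenario experiment
#'
#' For each seed: run the GA search for the scenario's genome, evaluate the
#' best genome with full logging, and write the result bundle (GA history
#' CSV, best genome CSV, trial log CSV, metrics JSON, configs and a
#' manifest). The UTTA scenarios require the normal scenario's best genome
#' and warm-start their populations from it.
#'
#' @param cfg a `cpgwalk_scenario`.
#' @param out_dir output directory (created if missing).
#' @param body the normal body model.
#' @param normal_best best genome of the normal scenario (length 51);
#'   required for UTTA scenarios.
#' @param map_fn pluggable parallel map for fitness evaluation (serial
#'   `lapply` by default).
#' @param base_controller structural controller defaults.
#' @return list with one element per seed: the GA result, the evaluated best
#'   trial, metrics (or NULL when the best genome does not walk far enough
#'   to yield the stride window) and the file manifest.
#' @export
run_experiment <- function(cfg, out_dir, body = body_model(),
                           normal_best = NULL, map_fn = lapply,
                           base_controller = controller_weights()) {
  stopifnot(inherits(cfg, "cpgwalk_scenario"))
  if (cfg$scenario != "normal" && is.null(normal_best))
    stop("UTTA scenarios require the normal scenario's best genome")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sbody <- scenario_body(cfg, body)
  spec <- genome_spec(cfg$scenario)
  if (!is.null(normal_best) && cfg$scenario != "normal")
    base_controller <- decode_genome(normal_best, genome_spec("normal"),
                                     base_controller)

  results <- lapply(cfg$seeds, function(seed) {
    ga_args <- cfg$ga
    ga_args$fitness_fn <- function(g)
      evaluate_genome(g, spec, sbody, base_controller,
                      duration = cfg$duration, dt = cfg$dt)
    ga_args$bounds <- spec$bounds
    ga_args$seed <- seed
    ga_args$map_fn <- map_fn
    if (cfg$scenario != "normal") {
      set.seed(seed)
      ga_args$init_pop <- warm_start_utta(normal_best, spec,
                                          ga_args$pop_size %||% 100)
    }
    ga <- do.call(run_ga, ga_args)

    ctrl <- decode_genome(ga$best, spec, base_controller)
    trial <- run_trial(sbody, ctrl, duration = cfg$duration, dt = cfg$dt)
    metrics <- tryCatch(
      summarize_trial(trial, cfg$stride_window),
      error = function(e) NULL, warning = function(w) {
        tryCatch(suppressWarnings(summarize_trial(trial, cfg$stride_window)),
                 error = function(e) NULL)
      })

    tag <- sprintf("%s_seed%d", cfg$scenario, seed)
    files <- c(history = file.path(out_dir, paste0(tag, "_history.csv")),
               genome = file.path(out_dir, paste0(tag, "_genome.csv")),
               trial = file.path(out_dir, paste0(tag, "_trial.csv")),
               metrics = file.path(out_dir, paste0(tag, "_metrics.json")),
               body = file.path(out_dir, paste0(tag, "_body.yaml")),
               controller = file.path(out_dir, paste0(tag, "_controller.yaml")))
    utils::write.csv(ga$history, files["history"], row.names = FALSE)
    utils::write.csv(data.frame(name = spec$names, value = ga$best),
                     files["genome"], row.names = FALSE)
    if (!is.null(trial$log)) write_trial_csv(trial, files["trial"])
    summary_out <- if (!is.null(metrics)) metrics else
      list(distance = trial$distance, fell = trial$fell, speed = trial$speed)
    write_metrics_json(summary_out, files["metrics"])
    write_body_yaml(sbody, files["body"])
    write_controller_yaml(ctrl, files["controller"])
    manifest <- file.path(out_dir, paste0(tag, "_manifest.json"))
    jsonlite::write_json(list(scenario = cfg$scenario, seed = seed,
                              complete = !is.null(metrics),
                              files = as.list(basename(files))),
                         manifest, auto_unbox = TRUE, pretty = TRUE)
    list(seed = seed, ga = ga, trial = trial, metrics = metrics,
         files = c(files, manifest = manifest))
  })
  names(results) <- paste0("seed", cfg$seeds)
  invisible(results)
}

# synthetic periodic trial with known stance times and step lengths; used by
# the metric tests so they never depend on a simulation
synthetic_trial <- function(stance_l = rep(0.6, 10), stance_r = rep(0.6, 10),
                            period = 1.0, offset = 0.5, stride_len = 0.5,
                            edot_total = 100, speed = stride_len / period,
                            mass = 70, dt = 0.005, grf_amp = 700) {
  n_str <- min(length(stance_l), length(stance_r))
  t_max <- (n_str + 1) * period + offset
  t <- seq(0, t_max, by = dt)
  square <- function(strikes, stance) {
    g <- numeric(length(t))
    for (i in seq_along(strikes))
      g[t >= strikes[i] & t < strikes[i] + stance[i]] <- grf_amp
    g
  }
  strikes_l <- (seq_len(n_str) - 1) * period
  strikes_r <- strikes_l + offset
  placement <- function(strikes) {
    # heel advances to a new placement instantaneously at each strike
    pos <- numeric(length(t))
    p <- stride_len * (seq_along(strikes) - 1)
    idx <- findInterval(t, strikes)
    pos[idx > 0] <- p[idx[idx > 0]]
    pos
  }
  heel_l <- placement(strikes_l)
  heel_r <- placement(strikes_r) + stride_len * offset / period
  log <- data.frame(t = t, x = speed * t,
                    grf_l = square(strikes_l, stance_l),
                    grf_r = square(strikes_r, stance_r),
                    heel_l_x = heel_l, heel_r_x = heel_r)
  for (nm in trial_log_names()[!trial_log_names() %in% names(log)])
    log[[nm]] <- 0
  ed <- grep("^edot_", names(log))
  log[, ed] <- edot_total / length(ed)
  log <- log[, trial_log_names()]
  out <- list(log = log, distance = speed * t_max, fell = FALSE,
              t_end = t_max, energy = edot_total * t_max, speed = speed,
              mass = mass, duration = t_max, dt = dt)
  class(out) <- "cpgwalk_trial"
  out
}

#' Generate test fixtures
#'
#' Deterministic synthetic inputs for the test suite: no simulation is run.
#'
#' @param kind one of `"toy-grf"` (square-wave GRF traces with known stance
#'   times), `"periodic-trial"` (a synthetic trial object with known stance
#'   times and step lengths), `"controller-weights"` (random bounded
#'   controller; pass `symmetric = TRUE` to tie the leg blocks) or
#'   `"body-configs"` (the normal and UTTA body models).
#' @param seed RNG seed for the randomized kinds.
#' @param ... kind-specific options (e.g. `stance_l`, `stance_r`,
#'   `stride_len` for the periodic trial; `symmetric`, `pros_side`).
#' @return the fixture object (see details per kind).
#' @export
make_fixtures <- function(kind, seed = 1, ...) {
  args <- list(...)
  set.seed(seed)
  switch(kind,
    "toy-grf" = {
      tr <- do.call(synthetic_trial, args[names(args) %in%
                      names(formals(synthetic_trial))])
      tr$log[, c("t", "grf_l", "grf_r")]
    },
    "periodic-trial" = do.call(synthetic_trial, args[names(args) %in%
                                 names(formals(synthetic_trial))]),
    "controller-weights" = {
      sym <- isTRUE(args$symmetric)
      wf <- matrix(runif(32, -1, 1), 2, 16,
                   dimnames = list(c("left", "right"), NULL))
      if (sym) wf[2, ] <- wf[1, ]
      controller_weights(u0 = runif(1, 0.5, 2), w_feed = wf,
                         w_pos = runif(23, -0.5, 0.5))
    },
    "body-configs" = {
      side <- args$pros_side %||% "right"
      list(normal = body_model(), utta = apply_prosthesis(body_model(), side))
    },
    stop("unknown fixture kind: ", kind))
}
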