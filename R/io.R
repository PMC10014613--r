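#' Write / read a body model as YAML
#' @param body a `cpgwalk_body`.
#' @param path file path.
#' @return `read_body_yaml` returns a `cpgwalk_body`; the writer returns
#'   `path` invisibly.
#' @export
write_body_yaml <- function(body, path) {
  yaml::write_yaml(unclass(body), path, precision = 15)
  invisible(path)
}

#' @rdname write_body_yaml
#' @export
read_body_yaml <- function(path) {
  b <- yaml::read_yaml(path)
  body <- body_model(mass = b$mass, inertia = b$inertia, com_hat = b$com_hat,
                     l_thigh = b$l_thigh, com_thigh = b$com_thigh,
                     l_shank = b$l_shank, com_shank = b$com_shank,
                     foot_geom = b$foot_geom,
                     joint_viscosity = b$joint_viscosity,
                     rom_hip = b$rom_hip, rom_knee = b$rom_knee,
                     rom_ankle = b$rom_ankle, lock = b$lock,
                     contact = b$contact, g = b$g)
  body$pros_side <- as.integer(b$pros_side)
  body$pros_ankle_k <- b$pros_ankle_k
  body$removed_muscles <- as.character(b$removed_muscles %||% character(0))
  body
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read controller weights as YAML
#'
#' The file holds named blocks (`u0`, `tau`, `beta`, `couplings`,
#' `w_feed` left/right, `w_pos`, `w_alpha`, flags) with a schema version.
#' @param ctrl a `cpgwalk_controller`.
#' @param path file path.
#' @return the reader returns a `cpgwalk_controller`; the writer returns
#'   `path` invisibly.
#' @export
write_controller_yaml <- function(ctrl, path) {
  yaml::write_yaml(list(
    schema = "cpgwalk-controller-1",
    u0 = ctrl$u0, tau = ctrl$tau[1], taup = ctrl$taup[1], beta = ctrl$beta,
    couplings = as.list(ctrl$couplings),
    w_feed_left = as.numeric(ctrl$w_feed[1, ]),
    w_feed_right = as.numeric(ctrl$w_feed[2, ]),
    w_pos = ctrl$w_pos,
    w_alpha = as.numeric(ctrl$w_alpha),
    fv_sign = ctrl$fv_sign, grf_thresh = ctrl$grf_thresh), path, precision = 15)
  invisible(path)
}

#' @rdname write_controller_yaml
#' @export
read_controller_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!identical(y$schema, "cpgwalk-controller-1"))
    stop("unrecognized controller file schema")
  controller_weights(
    u0 = y$u0, tau = y$tau, taup = y$taup, beta = y$beta,
    couplings = unlist(y$couplings),
    w_feed = rbind(left = y$w_feed_left, right = y$w_feed_right),
    w_pos = y$w_pos,
    w_alpha = matrix(y$w_alpha, 18, 12,
                     dimnames = dimnames(default_walpha())),
    fv_sign = y$fv_sign, grf_thresh = y$grf_thresh)
}

#' Write a trial log as CSV
#' @param trial a `cpgwalk_trial` with a log.
#' @param path file path.
#' @export
write_trial_csv <- function(trial, path) {
  if (is.null(trial$log)) stop("trial has no log")
  utils::write.csv(trial$log, path, row.names = FALSE)
  invisible(path)
}

#' Write a gait summary as JSON
#' @param summary a `cpgwalk_gait_summary` (or plain named list).
#' @param path file path.
#' @export
write_metrics_json <- function(summary, path) {
  x <- unclass(summary)
  x$per_stride <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
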