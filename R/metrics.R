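trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Detect gait events from a vertical GRF trace
#'
#' Foot strike is an upward crossing of the force threshold, toe-off a
#' downward crossing. Contact or flight intervals shorter than the debounce
#' window are treated as contact-model chatter and merged into their
#' neighbours before events are extracted. Stance time is toe-off minus the
#' preceding strike.
#'
#' @param grf vertical GRF samples of one limb (N), uniformly sampled.
#' @param time sample times (s), same length.
#' @param threshold contact threshold (N), `> 0`.
#' @param debounce minimum event duration (s).
#' @return list with `strike` and `off` times (s) and `stance` durations (s)
#'   for the completed stance phases.
#' @export
detect_gait_events <- function(grf, time, threshold = 10, debounce = 0.02) {
  stopifnot(length(grf) == length(time), threshold > 0)
  dt <- stats::median(diff(time))
  deb_n <- max(1L, as.integer(round(debounce / dt)))
  contact <- grf > threshold
  # merge interior runs shorter than the debounce window
  repeat {
    r <- rle(contact)
    if (length(r$lengths) < 3) break
    short <- which(r$lengths < deb_n)
    short <- short[short > 1 & short < length(r$lengths)]
    if (!length(short)) break
    r$values[short[1]] <- !r$values[short[1]]
    contact <- inverse.rle(r)
  }
  d <- diff(contact)
  strike <- time[which(d == 1) + 1L]
  off <- time[which(d == -1) + 1L]
  if (contact[1]) strike <- c(time[1], strike)  # trial starts in stance
  if (!length(strike) || !any(contact))
    stop("no gait events detected: not a walking trial")
  # pair each strike with the next toe-off
  stance <- vapply(strike, function(s) {
    nxt <- off[off > s]
    if (length(nxt)) nxt[1] - s else NA_real_
  }, numeric(1))
  list(strike = strike, off = off, stance = stance[!is.na(stance)])
}

#' Gross metabolic cost of transport
#'
#' `C = 1/(T M V) * integral of total muscle metabolic rate`, with the
#' integral taken by the trapezoid rule on the logged sampling grid
#' (J/kg/m).
#'
#' @param edot per-sample total metabolic rate (W), or a matrix with one
#'   column per muscle (columns are summed).
#' @param time sample times (s).
#' @param mass body mass (kg), `> 0`.
#' @param speed mean walking speed (m/s), `> 0`.
#' @return cost of transport (J/kg/m).
#' @export
cost_of_transport <- function(edot, time, mass, speed) {
  if (is.matrix(edot) || is.data.frame(edot)) edot <- rowSums(edot)
  T_ <- time[length(time)] - time[1]
  if (!(T_ > 0)) stop("trial duration must be positive")
  if (!(mass > 0)) stop("body mass must be positive")
  if (!(speed > 0)) stop("walking speed must be positive: failed trial")
  trapz(time, edot) / (T_ * mass * speed)
}

#' Symmetry index of a spatiotemporal gait parameter
#'
#' `ASI = 2 (R - L) / (R + L) * 100` (percent). The signed value is
#' returned; take `abs()` for the absolute symmetry index. Antisymmetric in
#' its arguments and bounded in `[-200, 200]`.
#'
#' @param right,left the parameter (stance time in s or step length in m)
#'   of the right and left limb; non-negative, not both zero.
#' @return signed symmetry index (percent).
#' @export
asi <- function(right, left) {
  stopifnot(all(right >= 0), all(left >= 0))
  if (any(right + left == 0)) stop("ASI undefined: R + L = 0")
  2 * (right - left) / (right + left) * 100
}

#' Spatiotemporal and energetic summary of a walking trial
#'
#' Detects gait events per limb, computes stance times and step lengths
#' (anterior distance between the striking heel and the contralateral heel
#' at each strike), restricts to the stride analysis window, and reports
#' per-side means and SDs, signed and absolute symmetry indices, cost of
#' transport over the window and mean speed.
#'
#' @param trial a `cpgwalk_trial` with a log.
#' @param stride_window strides used for analysis, inclusive (default 3 to
#'   8). Trials with fewer strides than the upper bound are summarized over
#'   what is available, with a warning; trials with fewer strides than the
#'   lower bound are an error.
#' @param threshold,debounce event detection parameters, see
#'   [detect_gait_events()].
#' @return object of class `cpgwalk_gait_summary`: per-side stance time and
#'   step length statistics, `asi_stance`/`asi_step` (signed; `abs_` for
#'   magnitudes), `cot`, `speed`, the per-stride table and the window used.
#' @export
summarize_trial <- function(trial, stride_window = c(3, 8), threshold = 10,
                            debounce = 0.02) {
  if (is.null(trial$log)) stop("trial has no log; rerun with log_every > 0")
  log <- trial$log
  ev <- list(left = detect_gait_events(log$grf_l, log$t, threshold, debounce),
             right = detect_gait_events(log$grf_r, log$t, threshold, debounce))
  lo <- stride_window[1]; hi <- stride_window[2]
  n_strides <- min(length(ev$left$stance), length(ev$right$stance))
  if (n_strides < lo)
    stop(sprintf("only %d strides detected; need at least %d for the window",
                 n_strides, lo))
  if (n_strides < hi) {
    warning(sprintf("only %d strides; truncating analysis window [%d, %d]",
                    n_strides, lo, hi))
    hi <- n_strides
  }
  idx <- lo:hi
  heel_x <- list(left = log$heel_l_x, right = log$heel_r_x)
  step_len <- function(side) {
    contra <- if (side == "left") "right" else "left"
    vapply(ev[[side]]$strike, function(ts) {
      i <- which.min(abs(log$t - ts))
      heel_x[[side]][i] - heel_x[[contra]][i]
    }, numeric(1))
  }
  per_stride <- do.call(rbind, lapply(c("left", "right"), function(side) {
    st <- ev[[side]]$stance
    sl <- step_len(side)
    n <- min(length(st), length(sl))
    data.frame(side = side, stride = seq_len(n), stance_time = st[seq_len(n)],
               step_length = sl[seq_len(n)])
  }))
  win <- per_stride[per_stride$stride %in% idx, ]
  stat <- function(side, var) {
    v <- win[[var]][win$side == side]
    c(mean = mean(v), sd = stats::sd(v))
  }
  stance_l <- stat("left", "stance_time"); stance_r <- stat("right", "stance_time")
  step_l <- stat("left", "step_length"); step_r <- stat("right", "step_length")

  t0 <- min(ev$left$strike[lo], ev$right$strike[lo])
  t1 <- max(ev$left$strike[hi] + ev$left$stance[hi],
            ev$right$strike[hi] + ev$right$stance[hi])
  sub <- log[log$t >= t0 & log$t <= t1, ]
  edot <- rowSums(sub[, grep("^edot_", names(sub)), drop = FALSE])
  dist <- sub$x[nrow(sub)] - sub$x[1]
  speed <- dist / (sub$t[nrow(sub)] - sub$t[1])
  cot <- cost_of_transport(edot, sub$t, trial$mass, speed)

  out <- list(
    stance_time = rbind(left = stance_l, right = stance_r),
    step_length = rbind(left = step_l, right = step_r),
    asi_stance = asi(stance_r[["mean"]], stance_l[["mean"]]),
    asi_step = asi(step_r[["mean"]], step_l[["mean"]]),
    cot = cot, speed = speed, n_strides = n_strides,
    stride_window = c(lo, hi), per_stride = per_stride)
  out$abs_asi_stance <- abs(out$asi_stance)
  out$abs_asi_step <- abs(out$asi_step)
  class(out) <- "cpgwalk_gait_summary"
  out
}

#' @export
print.cpgwalk_gait_summary <- function(x, ...) {
  cat("<cpgwalk_gait_summary>\n")
  cat(sprintf("  strides %d-%d of %d; speed %.2f m/s; CoT %.2f J/kg/m\n",
              x$stride_window[1], x$stride_window[2], x$n_strides, x$speed,
              x$cot))
  cat(sprintf("  stance time  L %.3f+/-%.3f s, R %.3f+/-%.3f s (ASI %+.1f%%)\n",
              x$stance_time["left", "mean"], x$stance_time["left", "sd"],
              x$stance_time["right", "mean"], x$stance_time["right", "sd"],
              x$asi_stance))
  cat(sprintf("  step length  L %.3f+/-%.3f m, R %.3f+/-%.3f m (ASI %+.1f%%)\n",
              x$step_length["left", "mean"], x$step_length["left", "sd"],
              x$step_length["right", "mean"], x$step_length["right", "sd"],
              x$asi_step))
  invisible(x)
}
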