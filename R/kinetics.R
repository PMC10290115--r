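#' Segment a tongue trace into illumination phases
#'
#' Splits a trace at the schedule's switch instants. Each segment's time
#' axis is re-zeroed to its phase onset; a frame landing exactly on a
#' switch belongs to the later phase.
#'
#' @param trace a \code{tongue_trace} (columns \code{time_s},
#'   \code{position_um}).
#' @param schedule an \code{\link{illum_schedule}} covering the trace.
#' @return A list of segments; each is a data frame \code{(time_s,
#'   position_um)} with attributes \code{"phase"} (channel),
#'   \code{"onset_s"} and \code{"duration_s"}.
#' @export
segment_cycles <- function(trace, schedule) {
  stopifnot(inherits(schedule, "illum_schedule"),
            all(c("time_s", "position_um") %in% names(trace)))
  idx <- schedule_interval_index(schedule, trace$time_s)
  if (all(is.na(idx)))
    stop("trace and schedule do not overlap in time")
  segs <- lapply(sort(unique(idx[!is.na(idx)])), function(i) {
    sel <- !is.na(idx) & idx == i
    if ("ok" %in% names(trace)) sel <- sel & trace$ok
    seg <- data.frame(time_s = trace$time_s[sel] - schedule$t_start[i],
                      position_um = trace$position_um[sel])
    attr(seg, "phase") <- schedule$channel[i]
    attr(seg, "onset_s") <- schedule$t_start[i]
    attr(seg, "duration_s") <- schedule$t_end[i] - schedule$t_start[i]
    attr(seg, "intensity") <- schedule$intensity[i]
    seg
  })
  segs
}

#' Synchronize and average illumination cycles
#'
#' Groups consecutive UV+VIS phase pairs into cycles, aligns every cycle on
#' its UV onset, linearly interpolates each onto a common time grid, and
#' returns the pointwise mean and standard deviation — the cycle-averaged
#' trace that the relaxation fits are usually run on.
#'
#' @param segments output of \code{\link{segment_cycles}} (alternating
#'   UV/VIS phases).
#' @param grid_dt common grid spacing (s); defaults to the median sampling
#'   interval of the first cycle.
#' @param tol relative tolerance on equal cycle durations.
#' @return A list of class \code{"cycle_average"}: \code{time_s},
#'   \code{mean_um}, \code{sd_um}, \code{n_cycles}, \code{uv_duration_s}.
#' @export
average_cycles <- function(segments, grid_dt = NULL, tol = 0.05) {
  phases <- vapply(segments, attr, character(1), "phase")
  uv_idx <- which(phases == "UV")
  uv_idx <- uv_idx[uv_idx < length(segments) &
                     phases[pmin(uv_idx + 1, length(segments))] == "VIS"]
  if (length(uv_idx) < 1) stop("no complete UV+VIS cycle found")
  durations <- vapply(uv_idx, function(i)
    attr(segments[[i]], "duration_s") + attr(segments[[i + 1]], "duration_s"),
    numeric(1))
  ref_dur <- stats::median(durations)
  bad <- which(abs(durations - ref_dur) > tol * ref_dur)
  if (length(bad) > 0)
    stop("cycles of unequal duration: ",
         paste(sprintf("cycle %d (%.3g s vs %.3g s)", bad, durations[bad],
                       ref_dur), collapse = ", "))
  cycles <- lapply(uv_idx, function(i) {
    uv <- segments[[i]]; vis <- segments[[i + 1]]
    data.frame(time_s = c(uv$time_s,
                          vis$time_s + attr(uv, "duration_s")),
               position_um = c(uv$position_um, vis$position_um))
  })
  if (is.null(grid_dt))
    grid_dt <- stats::median(diff(cycles[[1]]$time_s))
  grid <- seq(0, ref_dur, by = grid_dt)
  mat <- vapply(cycles, function(cy)
    stats::approx(cy$time_s, cy$position_um, xout = grid, rule = 2)$y,
    numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  structure(list(time_s = grid,
                 mean_um = rowMeans(mat),
                 sd_um = apply(mat, 1, stats::sd),
                 n_cycles = length(cycles),
                 uv_duration_s = attr(segments[[uv_idx[1]]], "duration_s")),
            class = "cycle_average")
}

#' @export
print.cycle_average <- function(x, ...) {
  cat(sprintf("cycle average over %d cycles, grid 0..%.3g s (%d points)\n",
              x$n_cycles, max(x$time_s), length(x$time_s)))
  invisible(x)
}

#' Fit an exponential relaxation to a phase segment
#'
#' Fits the relaxation model y(t) = a + b exp(-t / tau) to the interface
#' position within one illumination phase by nonlinear least squares
#' (Levenberg-Marquardt), with initial values a0 = last position,
#' b0 = first - last, tau0 = duration / 5, and tau bounded in
#' (0, 10 x duration]. The characteristic switching time is \code{tau}.
#' A segment with no resolvable amplitude (|b| below noise) is flagged
#' unidentifiable rather than silently returned.
#'
#' @param segment a data frame \code{(time_s, position_um)}, e.g. from
#'   \code{\link{segment_cycles}}, or a \code{cycle_average} restricted to
#'   one phase.
#' @param phase optional phase label; defaults to the segment's
#'   \code{"phase"} attribute.
#' @return An object of class \code{"relaxation_fit"}: coefficients
#'   \code{a} (um), \code{b} (um), \code{tau} (s); \code{rmse};
#'   \code{n_points}; flags \code{converged} and \code{identifiable};
#'   the data and fitted values.
#' @examples
#' seg <- data.frame(time_s = seq(0, 2, 0.075),
#'                   position_um = 1 - 0.5 * exp(-seq(0, 2, 0.075) / 0.24))
#' fit_relaxation(seg)
#' @export
fit_relaxation <- function(segment, phase = NULL) {
  stopifnot(all(c("time_s", "position_um") %in% names(segment)))
  t <- segment$time_s - min(segment$time_s)
  y <- segment$position_um
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  if (length(t) < 5) stop("need at least 5 points to fit a relaxation")
  if (is.null(phase)) phase <- attr(segment, "phase")
  dur <- max(t)
  a0 <- y[length(y)]
  b0 <- y[1] - a0
  tau0 <- dur / 5
  out <- list(phase = phase, n_points = length(t),
              data = data.frame(time_s = t, position_um = y))
  spread <- stats::sd(y)
  if (spread == 0 || abs(b0) < 1e-12) {
    out <- c(out, list(a = mean(y), b = 0, tau = NA_real_, rmse = spread,
                       fitted = rep(mean(y), length(t)),
                       converged = TRUE, identifiable = FALSE))
    class(out) <- "relaxation_fit"
    return(out)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a + b * exp(-t / tau),
                      start = list(a = a0, b = b0, tau = tau0),
                      lower = c(-Inf, -Inf, 1e-6),
                      upper = c(Inf, Inf, 10 * dur),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- c(out, list(a = NA_real_, b = NA_real_, tau = NA_real_,
                       rmse = NA_real_, fitted = rep(NA_real_, length(t)),
                       converged = FALSE, identifiable = FALSE,
                       message = conditionMessage(fit)))
    class(out) <- "relaxation_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  resid <- y - stats::fitted(fit)
  # amplitude below the residual noise level: tau is not identified
  identifiable <- abs(cf[["b"]]) > 2 * stats::sd(resid) / sqrt(length(t))
  out <- c(out, list(a = cf[["a"]], b = cf[["b"]], tau = cf[["tau"]],
                     rmse = sqrt(mean(resid^2)),
                     fitted = as.numeric(stats::fitted(fit)),
                     converged = TRUE, identifiable = identifiable))
  class(out) <- "relaxation_fit"
  out
}

#' @export
print.relaxation_fit <- function(x, ...) {
  ph <- if (is.null(x$phase)) "?" else x$phase
  if (!x$converged) {
    cat(sprintf("relaxation fit (%s): DID NOT CONVERGE (%s)\n", ph,
                x$message))
  } else if (!x$identifiable) {
    cat(sprintf("relaxation fit (%s): amplitude unresolved, tau %s\n", ph,
                "unidentifiable"))
  } else {
    cat(sprintf(
      "relaxation fit (%s): tau = %.4g s, a = %.4g um, b = %.4g um, rmse = %.3g um (n = %d)\n",
      ph, x$tau, x$a, x$b, x$rmse, x$n_points))
  }
  invisible(x)
}

#' @export
coef.relaxation_fit <- function(object, ...)
  c(a = object$a, b = object$b, tau = object$tau)

#' @export
predict.relaxation_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time_s else newdata$time_s
  if (!object$identifiable || is.na(object$tau))
    return(rep(object$a, length(t)))
  object$a + object$b * exp(-t / object$tau)
}

#' @export
residuals.relaxation_fit <- function(object, ...)
  object$data$position_um - object$fitted

#' @export
summary.relaxation_fit <- function(object, ...) {
  print(object)
  if (object$converged && object$identifiable)
    cat(sprintf("  residual sd %.3g um over %d points\n",
                stats::sd(residuals(object)), object$n_points))
  invisible(object)
}

#' Fit both relaxations of a cycle average
#'
#' Splits a \code{cycle_average} at the UV/VIS boundary and fits the
#' relaxation model to each phase, mirroring the per-phase exponential fits
#' of the averaged switching trace.
#'
#' @param ca a \code{cycle_average}.
#' @return A list with elements \code{uv} and \code{vis}, each a
#'   \code{relaxation_fit}.
#' @export
fit_cycle_average <- function(ca) {
  stopifnot(inherits(ca, "cycle_average"))
  uv_sel <- ca$time_s < ca$uv_duration_s
  seg_uv <- data.frame(time_s = ca$time_s[uv_sel],
                       position_um = ca$mean_um[uv_sel])
  seg_vis <- data.frame(time_s = ca$time_s[!uv_sel] - ca$uv_duration_s,
                        position_um = ca$mean_um[!uv_sel])
  list(uv = fit_relaxation(seg_uv, phase = "UV"),
       vis = fit_relaxation(seg_vis, phase = "VIS"))
}

#' Relaxation time versus irradiation intensity
#'
#' Fits the empirical saturation trend tau(I) = tau_plateau + c exp(-I / I0)
#' to per-experiment (intensity, tau) pairs and reports whether tau
#' decreases with intensity. The trend is descriptive (a guide to the eye);
#' the scientifically meaningful outputs are the plateau value and the
#' monotone-decrease flag.
#'
#' @param fits data frame with columns \code{intensity} (fraction, 0-1) and
#'   \code{tau} (s); at least 4 distinct intensity levels.
#' @return A list of class \code{"intensity_trend"}: \code{tau_plateau},
#'   \code{c}, \code{I0}, \code{monotone_decreasing}, \code{converged}.
#' @export
intensity_response <- function(fits) {
  stopifnot(all(c("intensity", "tau") %in% names(fits)))
  if (length(unique(fits$intensity)) < 4)
    stop("need at least 4 intensity levels")
  I <- fits$intensity
  tau <- fits$tau
  ord <- order(I)
  if (stats::sd(tau) == 0) {
    # flat response: plateau equals the common tau, no intensity dependence
    out <- list(tau_plateau = tau[1], c = 0, I0 = NA_real_,
                monotone_decreasing = FALSE, converged = TRUE,
                fitted = tau)
    class(out) <- "intensity_trend"
    return(out)
  }
  monotone <- stats::cor(I, tau, method = "kendall") < 0
  plateau0 <- min(tau)
  c0 <- max(tau) - min(tau)
  I0_0 <- max(diff(range(I)) / 3, 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(tau ~ p + cc * exp(-I / I0),
                      start = list(p = plateau0, cc = c0, I0 = I0_0),
                      lower = c(0, 0, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- list(tau_plateau = NA_real_, c = NA_real_, I0 = NA_real_,
                monotone_decreasing = monotone, converged = FALSE,
                message = conditionMessage(fit))
  } else {
    cf <- stats::coef(fit)
    out <- list(tau_plateau = cf[["p"]], c = cf[["cc"]], I0 = cf[["I0"]],
                monotone_decreasing = monotone, converged = TRUE,
                fitted = stats::fitted(fit)[order(ord)])
  }
  class(out) <- "intensity_trend"
  out
}

#' @export
print.intensity_trend <- function(x, ...) {
  if (x$converged)
    cat(sprintf(
      "intensity trend: tau_plateau = %.4g s, c = %.4g s, I0 = %.4g; tau %s with intensity\n",
      x$tau_plateau, x$c, x$I0,
      if (x$monotone_decreasing) "decreases" else "does not decrease"))
  else cat("intensity trend: fit did not converge\n")
  invisible(x)
}
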