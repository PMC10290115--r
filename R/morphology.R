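#' Frame-to-first-frame autocorrelation of an image stack
#'
#' Correlates the first frame with every subsequent frame over an ROI:
#' entry t is the Pearson correlation (zero-mean, unit-variance normalized
#' scalar product) of the pixel vectors of frame 1 and frame t, so entry 1
#' is exactly 1. Sharp phase-locked drops report illumination-driven shape
#' change; the slow baseline decay reports focus drift and intracellular
#' motion. The stack should be drift-corrected
#' (\code{\link{stabilize_stack}}) first.
#'
#' @param stack an \code{\link{image_stack}}.
#' @param roi optional \code{\link{roi_spec}} cropped around the moving
#'   membrane; default uses the full frame.
#' @return A data frame \code{(time_s, raw)}; frames with zero pixel
#'   variance get \code{NA} with a warning.
#' @export
autocorrelate_stack <- function(stack, roi = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  crop <- function(frame) {
    if (is.null(roi)) as.vector(frame)
    else as.vector(frame[roi$row:(roi$row + roi$width - 1),
                         roi$col:(roi$col + roi$length - 1)])
  }
  v0 <- crop(stack_frame(stack, 1))
  if (stats::sd(v0) == 0) {
    warning("reference frame has zero variance; correlation undefined")
    return(data.frame(time_s = stack_times(stack),
                      raw = rep(NA_real_, length(stack))))
  }
  raw <- vapply(seq_len(length(stack)), function(i) {
    vi <- crop(stack_frame(stack, i))
    if (stats::sd(vi) == 0) return(NA_real_)
    stats::cor(v0, vi)
  }, numeric(1))
  if (anyNA(raw[-1])) warning("zero-variance frame(s): correlation NA")
  data.frame(time_s = stack_times(stack), raw = raw)
}

#' Fit and remove the slow decay of an autocorrelation trace
#'
#' Fits y(t) = a exp(-t / tau) + b to the raw autocorrelation by nonlinear
#' least squares and subtracts the fitted decay, leaving the phase-locked
#' excursions caused by illumination switches. The decay models gradual
#' decorrelation (focus drift, intracellular movement); its coefficients
#' are unrelated to the membrane relaxation time constants.
#'
#' @param trace data frame \code{(time_s, raw)} from
#'   \code{\link{autocorrelate_stack}}; at least 10 finite points.
#' @return An object of class \code{"autocorr_decay_fit"} with coefficients
#'   \code{a}, \code{b}, \code{tau}, the \code{trace} extended by columns
#'   \code{fit} and \code{corrected}, and a \code{converged} flag (if the
#'   fit fails, \code{corrected} is not produced).
#' @export
fit_autocorr_decay <- function(trace) {
  stopifnot(all(c("time_s", "raw") %in% names(trace)))
  ok <- is.finite(trace$raw)
  if (sum(ok) < 10) stop("need at least 10 finite autocorrelation points")
  t <- trace$time_s[ok]
  y <- trace$raw[ok]
  dur <- max(t) - min(t)
  if (stats::sd(y) < 1e-12) {
    # already flat: nothing to remove
    out <- list(trace = trace, converged = TRUE,
                a = 0, b = mean(y), tau = dur)
    out$trace$fit <- rep(mean(y), nrow(trace))
    out$trace$corrected <- trace$raw - mean(y)
    class(out) <- "autocorr_decay_fit"
    return(out)
  }
  b0 <- min(y)
  a0 <- max(y) - b0
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-t / tau) + b,
                      start = list(a = a0, b = b0, tau = max(dur / 3, 1e-3)),
                      lower = c(-Inf, -Inf, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) e)
  out <- list(trace = trace, converged = !inherits(fit, "error"))
  if (!out$converged) {
    out$message <- conditionMessage(fit)
    class(out) <- "autocorr_decay_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  out$a <- cf[["a"]]; out$b <- cf[["b"]]; out$tau <- cf[["tau"]]
  out$trace$fit <- out$a * exp(-trace$time_s / out$tau) + out$b
  out$trace$corrected <- out$trace$raw - out$trace$fit
  class(out) <- "autocorr_decay_fit"
  out
}

#' @export
print.autocorr_decay_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf(
      "autocorrelation decay: a = %.4g, b = %.4g, tau = %.4g s (%d frames)\n",
      x$a, x$b, x$tau, nrow(x$trace)))
  else cat("autocorrelation decay: fit did not converge:", x$message, "\n")
  invisible(x)
}

#' @export
coef.autocorr_decay_fit <- function(object, ...) {
  if (!object$converged) return(c(a = NA_real_, b = NA_real_, tau = NA_real_))
  c(a = object$a, b = object$b, tau = object$tau)
}

#' Count schedule-aligned excursions in a corrected autocorrelation
#'
#' An excursion is an illumination interval during which the decay-corrected
#' autocorrelation departs from its same-phase baseline — the square-wave
#' signature of a reversible shape change. The reference phase is the one
#' containing frame 1; an interval of the opposite phase counts as an
#' excursion when its mean corrected value differs from the reference-phase
#' mean by more than \code{threshold}.
#'
#' @param fit an \code{\link{fit_autocorr_decay}} result with a
#'   \code{corrected} column.
#' @param schedule the \code{\link{illum_schedule}} of the movie.
#' @param threshold minimum mean departure (correlation units).
#' @return Integer count of excursion intervals.
#' @export
count_excursions <- function(fit, schedule, threshold = 0.05) {
  stopifnot(inherits(fit, "autocorr_decay_fit"), fit$converged)
  tr <- fit$trace
  idx <- schedule_interval_index(schedule, tr$time_s)
  ref_phase <- schedule$channel[idx[1]]
  ref_mean <- mean(tr$corrected[schedule$channel[idx] == ref_phase],
                   na.rm = TRUE)
  opp <- which(schedule$channel != ref_phase)
  sum(vapply(opp, function(i) {
    v <- tr$corrected[idx == i]
    length(v) > 0 && abs(mean(v, na.rm = TRUE) - ref_mean) > threshold
  }, logical(1)))
}

#' Roughness score of a cell image
#'
#' The standard deviation (population form: divisor n) of all pixel values
#' whose centres fall strictly inside a circle drawn within the cell,
#' avoiding the cell boundary. Spiculated (echinocyte) cells have an
#' inhomogeneous interior and score high; smooth discocyte-like cells score
#' low.
#'
#' @param image numeric intensity matrix.
#' @param center length-2 vector (row, col) of the circle centre (px).
#' @param radius circle radius (px).
#' @return A list of class \code{"roughness_score"}: \code{score},
#'   \code{n_pixels}, \code{center}, \code{radius}.
#' @export
roughness_score <- function(image, center, radius) {
  stopifnot(is.matrix(image), length(center) == 2, radius > 0)
  if (center[1] - radius < 1 || center[1] + radius > nrow(image) ||
      center[2] - radius < 1 || center[2] + radius > ncol(image))
    stop("circle extends outside the image")
  g <- expand.grid(r = seq_len(nrow(image)), c = seq_len(ncol(image)))
  sel <- (g$r - center[1])^2 + (g$c - center[2])^2 < radius^2
  v <- image[cbind(g$r[sel], g$c[sel])]
  structure(list(score = sqrt(mean((v - mean(v))^2)),
                 n_pixels = length(v), center = center, radius = radius),
            class = "roughness_score")
}

#' @export
print.roughness_score <- function(x, ...) {
  cat(sprintf("roughness: sd = %.4g over %d px (r = %.3g px)\n",
              x$score, x$n_pixels, x$radius))
  invisible(x)
}

#' Two-sample comparison of roughness scores
#'
#' Classical Student's independent two-sample t test (pooled variance by
#' default; Welch by flag) on two groups of roughness scores, with the
#' conventional significance stars (*** for p < 0.001).
#'
#' @param scores_A,scores_B numeric vectors (n >= 2 each) of roughness
#'   scores, or lists of \code{roughness_score} objects.
#' @param var_equal pooled-variance test if \code{TRUE} (default), Welch
#'   otherwise.
#' @return A list: \code{t}, \code{df}, \code{p}, \code{stars},
#'   \code{method}.
#' @export
compare_roughness <- function(scores_A, scores_B, var_equal = TRUE) {
  as_num <- function(s) {
    if (is.list(s) && !is.data.frame(s))
      vapply(s, function(x)
        if (inherits(x, "roughness_score")) x$score else as.numeric(x),
        numeric(1))
    else as.numeric(s)
  }
  a <- as_num(scores_A); b <- as_num(scores_B)
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 scores")
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b))
    return(list(t = 0, df = length(a) + length(b) - 2, p = 1, stars = "ns",
                method = "degenerate: identical constant groups"))
  if (stats::sd(c(a - mean(a), b - mean(b))) == 0)
    stop("zero within-group variance; t test undefined")
  ht <- stats::t.test(a, b, var.equal = var_equal)
  p <- ht$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "ns"
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = p,
       stars = stars, method = ht$method)
}
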