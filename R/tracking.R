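#' Region of interest along the pipette
#'
#' A rectangular ROI whose long side runs along the pipette axis (image
#' columns) and whose short side spans roughly half the pipette width — wide
#' enough to average out noise, narrow enough to stay inside the corridor.
#'
#' @param row,col top-left corner (1-based px).
#' @param length extent along the pipette axis (columns, px).
#' @param width extent across the pipette (rows, px).
#' @return A list of class \code{"roi_spec"}.
#' @export
roi_spec <- function(row, col, length, width) {
  stopifnot(row >= 1, col >= 1, length >= 5, width >= 1)
  structure(list(row = as.integer(row), col = as.integer(col),
                 length = as.integer(length), width = as.integer(width)),
            class = "roi_spec")
}

#' Average an ROI across the pipette into a 1-D axial intensity profile
#'
#' @param frame numeric intensity matrix.
#' @param roi an \code{\link{roi_spec}}.
#' @return Numeric vector of length \code{roi$length}: entry i is the mean
#'   intensity over the ROI width at axial offset i.
#' @export
reduce_roi <- function(frame, roi) {
  stopifnot(inherits(roi, "roi_spec"))
  if (roi$row + roi$width - 1 > nrow(frame) ||
      roi$col + roi$length - 1 > ncol(frame))
    stop("ROI exceeds frame bounds")
  block <- frame[roi$row:(roi$row + roi$width - 1),
                 roi$col:(roi$col + roi$length - 1), drop = FALSE]
  colMeans(block)
}

# sub-pixel extremum of a discrete series by a 3-point quadratic vertex fit;
# returns NA at boundaries or zero curvature
quadratic_vertex <- function(y, i) {
  if (i <= 1 || i >= length(y)) return(NA_real_)
  y0 <- y[i - 1]; y1 <- y[i]; y2 <- y[i + 1]
  denom <- y0 - 2 * y1 + y2
  if (denom == 0) return(NA_real_)
  i + 0.5 * (y0 - y2) / denom
}

# Gaussian smoothing by direct convolution; ends are NA (kernel support
# incomplete there), which callers must mask
gaussian_smooth <- function(p, sigma) {
  if (sigma <= 0) return(p)
  h <- ceiling(3 * sigma)
  k <- stats::dnorm(-h:h, sd = sigma)
  k <- k / sum(k)
  as.numeric(stats::filter(p, k, sides = 2))
}

# 5-point least-squares quadratic vertex (optional wider stencil)
quadratic_vertex5 <- function(y, i) {
  if (i <= 2 || i >= length(y) - 1) return(quadratic_vertex(y, i))
  x <- -2:2
  yy <- y[(i - 2):(i + 2)]
  fit <- stats::lm.fit(cbind(1, x, x^2), yy)
  b <- fit$coefficients
  if (b[3] == 0) return(NA_real_)
  i - b[2] / (2 * b[3])
}

#' Track the membrane interface with sub-pixel resolution
#'
#' For every frame the ROI is averaged across the pipette into an axial
#' intensity profile, the first difference of the profile is taken (assigned
#' to the midpoint between samples), the extremum of the requested polarity
#' is located, and a second-order polynomial through the extremum and its
#' two neighbours gives the sub-pixel interface position as the parabola
#' vertex. Positions increase into the pipette. Frames whose extremum falls
#' on the profile boundary or whose parabola has zero curvature are flagged
#' \code{ok = FALSE}.
#'
#' @param stack an \code{\link{image_stack}}.
#' @param roi an \code{\link{roi_spec}}.
#' @param polarity \code{"min"} (default; dark tongue interior gives a
#'   derivative minimum at the interface) or \code{"max"}.
#' @param stencil 3 (default) or 5 points for the vertex fit.
#' @param smooth_sigma Gaussian smoothing of the reduced axial profile (px)
#'   before differentiation — the axial counterpart of the across-width
#'   averaging, acting as a matched filter against pixel noise. 0 disables.
#'   The default 1.5 px is of the order of the optical edge width; smoothing
#'   a symmetric edge does not shift it, so the sub-pixel position is
#'   unbiased while the noise on the derivative is strongly suppressed.
#' @param track_window optional half-width (px): search the extremum only
#'   within this distance of the previous frame's position instead of
#'   globally over the ROI.
#' @return A data frame of class \code{"tongue_trace"} with columns
#'   \code{time_s}, \code{position_um}, \code{position_px} (frame column
#'   coordinates) and \code{ok}.
#' @export
track_interface <- function(stack, roi, polarity = c("min", "max"),
                            stencil = 3, smooth_sigma = 1.5,
                            track_window = NULL) {
  stopifnot(inherits(stack, "image_stack"), inherits(roi, "roi_spec"))
  polarity <- match.arg(polarity)
  stopifnot(stencil %in% c(3, 5), smooth_sigma >= 0)
  n <- length(stack)
  pos_px <- rep(NA_real_, n)
  ok <- rep(FALSE, n)
  prev <- NA_real_
  for (i in seq_len(n)) {
    profile <- reduce_roi(stack_frame(stack, i), roi)
    profile <- gaussian_smooth(profile, smooth_sigma)
    d <- diff(profile)
    if (polarity == "max") d <- -d
    finite_d <- is.finite(d)
    search <- which(finite_d)
    if (length(search) == 0) next
    if (!is.null(track_window) && !is.na(prev)) {
      ctr <- prev - roi$col + 1 - 0.5  # previous position in d-index coords
      inwin <- search[abs(search - ctr) <= track_window]
      if (length(inwin) > 0) search <- inwin
    }
    j <- search[which.min(d[search])]
    # extremum on the (finite) profile boundary cannot be vertex-fitted
    if (j <= 1 || j >= length(d) ||
        !finite_d[j - 1] || !finite_d[j + 1]) next
    v <- if (stencil == 3) quadratic_vertex(d, j) else quadratic_vertex5(d, j)
    if (!is.na(v)) {
      # d[k] sits at the midpoint k + 0.5 of the profile; profile index 1 is
      # frame column roi$col
      pos_px[i] <- v + 0.5 + roi$col - 1
      ok[i] <- TRUE
      prev <- pos_px[i]
    }
  }
  out <- data.frame(time_s = stack_times(stack),
                    position_um = pos_px * stack$pixel_size,
                    position_px = pos_px, ok = ok)
  class(out) <- c("tongue_trace", "data.frame")
  out
}

#' Stabilize an image stack against in-plane drift
#'
#' Registers every frame to frame 1 by whole-pixel translation, found as the
#' peak of the FFT cross-correlation; optionally refined to sub-pixel by a
#' 3-point parabola through the correlation peak. Shifted-in borders are
#' padded by edge replication. Featureless (uniform) frames produce a
#' warning and zero shift.
#'
#' @param stack an \code{\link{image_stack}} with >= 2 frames.
#' @param subpixel logical; refine the shift estimate below one pixel
#'   (the correction itself stays whole-pixel).
#' @return A list with elements \code{stack} (stabilized) and \code{shifts}
#'   (n x 2 matrix of applied (row, col) shifts).
#' @export
stabilize_stack <- function(stack, subpixel = FALSE) {
  stopifnot(inherits(stack, "image_stack"), length(stack) >= 2)
  n <- length(stack)
  ref <- stack_frame(stack, 1)
  nr <- nrow(ref); nc <- ncol(ref)
  # zero-pad to double size: the correlation is then linear, not circular,
  # so shifts up to the full frame size are unambiguous
  pr <- 2 * nr; pc <- 2 * nc
  pad <- function(m) {
    out <- matrix(0, pr, pc)
    out[seq_len(nr), seq_len(nc)] <- m - mean(m)
    out
  }
  F_ref <- stats::fft(pad(ref))
  shifts <- matrix(0, n, 2, dimnames = list(NULL, c("row", "col")))
  out <- stack$frames
  for (i in 2:n) {
    fr <- stack_frame(stack, i)
    if (stats::sd(fr) == 0) {
      warning(sprintf("frame %d is featureless; zero shift applied", i))
      next
    }
    cc <- Re(stats::fft(F_ref * Conj(stats::fft(pad(fr))), inverse = TRUE))
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    dr <- pk[1] - 1; dc <- pk[2] - 1
    if (dr > pr / 2) dr <- dr - pr
    if (dc > pc / 2) dc <- dc - pc
    if (subpixel) {
      wrap <- function(k, m) ((k - 1) %% m) + 1
      sub1 <- function(axis) {
        if (axis == 1)
          y <- cc[wrap(pk[1] + (-1:1), pr), pk[2]]
        else
          y <- cc[pk[1], wrap(pk[2] + (-1:1), pc)]
        denom <- y[1] - 2 * y[2] + y[3]
        if (denom == 0) 0 else 0.5 * (y[1] - y[3]) / denom
      }
      dr <- dr + sub1(1)
      dc <- dc + sub1(2)
    }
    shifts[i, ] <- c(dr, dc)
    out[, , i] <- shift_matrix(fr, round(dr), round(dc))
  }
  list(stack = image_stack(out, stack$pixel_size, stack$frame_interval),
       shifts = shifts)
}

# whole-pixel translate with edge replication; shifting by (dr, dc) moves
# content so that a scene displaced by (-dr, -dc) is brought back
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  src_r <- pmin(pmax(seq_len(nr) - dr, 1), nr)
  src_c <- pmin(pmax(seq_len(nc) - dc, 1), nc)
  m[src_r, src_c, drop = FALSE]
}

#' Write / read a tongue trace as CSV
#'
#' Columns carry units in the header: \code{time_s, position_um,
#' position_px, ok}.
#'
#' @param trace a \code{tongue_trace}.
#' @param path CSV file path.
#' @return \code{path} (write) or the trace (read).
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("tongue_trace", "data.frame")
  out
}
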