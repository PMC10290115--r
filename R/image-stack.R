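#' Image stack container
#'
#' A time-lapse image stack: a numeric 3-D array \code{[row, col, frame]}
#' carrying the pixel size (micrometre per pixel) and the frame interval
#' (seconds). This is the raw observable consumed by interface tracking,
#' autocorrelation and roughness scoring.
#'
#' @param frames numeric 3-D array \code{[row, col, frame]}, or a list of
#'   equally sized matrices.
#' @param pixel_size pixel size in micrometre per pixel.
#' @param frame_interval frame interval in seconds.
#' @return An object of class \code{"image_stack"}.
#' @export
image_stack <- function(frames, pixel_size, frame_interval) {
  if (is.list(frames))
    frames <- array(unlist(frames),
                    dim = c(dim(frames[[1]]), length(frames)))
  stopifnot(is.array(frames), length(dim(frames)) == 3,
            is.numeric(pixel_size), pixel_size > 0,
            is.numeric(frame_interval), frame_interval > 0)
  structure(list(frames = frames,
                 pixel_size = as.numeric(pixel_size),
                 frame_interval = as.numeric(frame_interval)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_stack: %d frames of %d x %d px, %.4g um/px, dt = %.4g s\n",
              d[3], d[1], d[2], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' @export
length.image_stack <- function(x) dim(x$frames)[3]

stack_frame <- function(stack, i) stack$frames[, , i]

stack_times <- function(stack)
  (seq_len(dim(stack$frames)[3]) - 1) * stack$frame_interval

#' Write an image stack as a multi-page TIFF with a JSON sidecar
#'
#' Frames are stored as 16-bit grayscale TIFF pages; pixel size, frame
#' interval, and any ground-truth annotations (e.g. simulated interface
#' positions) go into \code{<path>.json}. Intensities are scaled to the
#' 16-bit range by \code{scale_max}.
#'
#' @param stack an \code{\link{image_stack}}.
#' @param path output TIFF path.
#' @param scale_max intensity mapped to the top of the 16-bit range.
#' @param extra named list of extra sidecar fields (e.g. ground truth).
#' @return \code{path}, invisibly.
#' @export
write_image_stack <- function(stack, path, scale_max = 65535, extra = list()) {
  stopifnot(inherits(stack, "image_stack"))
  n <- length(stack)
  pages <- lapply(seq_len(n), function(i) {
    m <- stack_frame(stack, i) / scale_max
    m[m < 0] <- 0
    m[m > 1] <- 1
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- c(list(pixel_size_um = stack$pixel_size,
                    frame_interval_s = stack$frame_interval,
                    n_frames = n,
                    scale_max = scale_max), extra)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack from a multi-page TIFF
#'
#' Pixel size and frame interval come from the \code{<path>.json} sidecar
#' when present; explicit arguments override the sidecar. RGB pages are
#' converted to grayscale with a warning.
#'
#' @param path TIFF file path.
#' @param pixel_size,frame_interval metadata overrides (micrometre per px, s).
#' @return An \code{\link{image_stack}}; sidecar extras are attached as the
#'   \code{"sidecar"} attribute.
#' @export
read_image_stack <- function(path, pixel_size = NULL, frame_interval = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) {
      warning("RGB input converted to grayscale (channel mean)")
      p <- apply(p, c(1, 2), mean)
    }
    p
  })
  sidecar <- NULL
  scale_max <- 65535
  sc_path <- paste0(path, ".json")
  if (file.exists(sc_path)) {
    sidecar <- jsonlite::fromJSON(sc_path)
    if (!is.null(sidecar$n_frames) && sidecar$n_frames != length(pages))
      stop(sprintf("sidecar declares %d frames but TIFF has %d",
                   sidecar$n_frames, length(pages)))
    if (!is.null(sidecar$scale_max)) scale_max <- sidecar$scale_max
    if (is.null(pixel_size)) pixel_size <- sidecar$pixel_size_um
    if (is.null(frame_interval)) frame_interval <- sidecar$frame_interval_s
  }
  if (is.null(pixel_size))
    stop("pixel size unknown: no sidecar; supply pixel_size=")
  if (is.null(frame_interval))
    stop("frame interval unknown: no sidecar; supply frame_interval=")
  frames <- array(unlist(pages) * scale_max,
                  dim = c(dim(pages[[1]])[1:2], length(pages)))
  out <- image_stack(frames, pixel_size, frame_interval)
  attr(out, "sidecar") <- sidecar
  out
}
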