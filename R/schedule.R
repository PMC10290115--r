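#' Illumination schedule
#'
#' An illumination schedule is an ordered set of non-overlapping time
#' intervals, each with a light channel (\code{"UV"}, \code{"VIS"} or
#' \code{"dark"}) and a relative irradiation intensity in \code{[0, 1]}.
#' It drives both the synthetic generators and the cycle segmentation of
#' measured tongue traces.
#'
#' @param t_start,t_end numeric vectors of interval start/end times (s).
#' @param channel character vector, each \code{"UV"}, \code{"VIS"} or
#'   \code{"dark"}.
#' @param intensity relative intensity per interval, in \code{[0, 1]};
#'   recycled if length 1.
#'
#' @return A data frame of class \code{"illum_schedule"} with columns
#'   \code{t_start}, \code{t_end}, \code{channel}, \code{intensity}.
#' @examples
#' illum_schedule(c(0, 2), c(2, 4), c("UV", "VIS"))
#' @export
illum_schedule <- function(t_start, t_end, channel, intensity = 1) {
  stopifnot(length(t_start) == length(t_end),
            length(channel) == length(t_start))
  if (length(channel) > 0) {
    channel <- match.arg(toupper(channel), c("UV", "VIS", "DARK"),
                         several.ok = TRUE)
    channel[channel == "DARK"] <- "dark"
  }
  intensity <- rep_len(intensity, length(t_start))
  if (any(intensity < 0 | intensity > 1))
    stop("intensity must lie in [0, 1]")
  sched <- data.frame(t_start = as.numeric(t_start),
                      t_end = as.numeric(t_end),
                      channel = channel,
                      intensity = intensity,
                      stringsAsFactors = FALSE)
  if (nrow(sched) > 0) {
    sched <- sched[order(sched$t_start), , drop = FALSE]
    rownames(sched) <- NULL
    if (any(sched$t_end <= sched$t_start))
      stop("each interval must satisfy t_end > t_start")
    if (nrow(sched) > 1 &&
        any(sched$t_start[-1] < sched$t_end[-nrow(sched)] - 1e-12))
      stop("schedule intervals overlap")
  }
  class(sched) <- c("illum_schedule", "data.frame")
  sched
}

#' Alternating UV/VIS cycle schedule
#'
#' Convenience constructor for the standard cyclic protocol: \code{n_cycles}
#' repetitions of a UV phase followed by a VIS phase, as used in aspiration
#' switching experiments. The default phase duration of 1.95 s is 26 frames
#' of the 75 ms camera clock: illumination switches are synchronized to
#' frame acquisition, so cycle onsets always coincide with a frame and
#' cycle averaging needs no interpolation across switch instants.
#'
#' @param n_cycles number of UV+VIS cycles.
#' @param uv_duration,vis_duration phase durations (s).
#' @param uv_intensity,vis_intensity relative intensities in \code{[0, 1]}.
#' @param t0 start time of the first UV phase (s).
#' @return An \code{\link{illum_schedule}} with \code{2 * n_cycles} intervals.
#' @examples
#' cycle_schedule(10, 2, 2)
#' @export
cycle_schedule <- function(n_cycles, uv_duration = 1.95, vis_duration = 1.95,
                           uv_intensity = 1, vis_intensity = 1, t0 = 0) {
  stopifnot(n_cycles >= 1, uv_duration > 0, vis_duration > 0)
  period <- uv_duration + vis_duration
  starts_uv <- t0 + (seq_len(n_cycles) - 1) * period
  illum_schedule(
    t_start = as.vector(rbind(starts_uv, starts_uv + uv_duration)),
    t_end = as.vector(rbind(starts_uv + uv_duration, starts_uv + period)),
    channel = rep(c("UV", "VIS"), n_cycles),
    intensity = rep(c(uv_intensity, vis_intensity), n_cycles)
  )
}

#' Read / write illumination schedules as JSON
#'
#' @param path file path.
#' @return \code{read_schedule} returns an \code{\link{illum_schedule}};
#'   \code{write_schedule} returns \code{path} invisibly.
#' @export
read_schedule <- function(path) {
  x <- jsonlite::fromJSON(path)
  illum_schedule(x$t_start, x$t_end, x$channel, x$intensity)
}

#' @rdname read_schedule
#' @param schedule an \code{\link{illum_schedule}}.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "illum_schedule"))
  jsonlite::write_json(unclass(schedule), path, auto_unbox = FALSE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

# interval index for each time point; points exactly on a switch belong to
# the later interval
schedule_interval_index <- function(schedule, times) {
  idx <- rep(NA_integer_, length(times))
  for (i in seq_len(nrow(schedule))) {
    sel <- times >= schedule$t_start[i] - 1e-12 &
      times < schedule$t_end[i] - 1e-12
    idx[sel] <- i
  }
  # points at the very end of the schedule close the last interval
  last <- nrow(schedule)
  if (last > 0)
    idx[is.na(idx) & abs(times - schedule$t_end[last]) < 1e-9] <- last
  idx
}
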