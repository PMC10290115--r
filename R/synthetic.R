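#' Photoswitch relaxation kinetics parameters
#'
#' Relaxation time constants and amplitude of the membrane response to
#' illumination switches. Defaults are the cohort means measured on
#' aspirated red blood cells: the UV-triggered retraction relaxes with
#' tau_uv = 0.24 s, the VIS-triggered extension with tau_vis = 0.49 s, and
#' the plateau-to-plateau tongue displacement is 0.82 um. The Z isomer
#' relaxes thermally back to E in the dark with a half-life of 64 h.
#'
#' @param tau_uv,tau_vis relaxation time constants (s), strictly positive.
#' @param amplitude plateau-to-plateau tongue displacement (um).
#' @param thermal_halflife dark Z-to-E half-life (hours).
#' @return A list of class \code{"switch_kinetics"}.
#' @export
switch_kinetics <- function(tau_uv = 0.24, tau_vis = 0.49,
                            amplitude = 0.82, thermal_halflife = 64) {
  stopifnot(tau_uv > 0, is.finite(tau_uv),
            tau_vis > 0, is.finite(tau_vis),
            amplitude >= 0, thermal_halflife > 0)
  structure(list(tau_uv = tau_uv, tau_vis = tau_vis,
                 amplitude = amplitude,
                 thermal_halflife = thermal_halflife),
            class = "switch_kinetics")
}

#' Two-state photoisomer population under an illumination schedule
#'
#' First-order two-state model of the E/Z photoswitch population: under each
#' illumination interval the E-isomer fraction relaxes exponentially toward
#' the channel's photostationary plateau with rate
#' \code{intensity / tau_channel}; in dark intervals it relaxes toward pure E
#' (fraction 1) with the slow thermal rate \code{log(2) / thermal_halflife}.
#'
#' @param schedule an \code{\link{illum_schedule}} (non-overlapping, ordered).
#' @param kinetics a \code{\link{switch_kinetics}}.
#' @param dt output sampling interval (s), > 0.
#' @param start initial E fraction in \code{[0, 1]}.
#' @param pss_uv,pss_vis photostationary E-fraction plateaus of the two
#'   channels. The measured photostationary compositions are not pinned
#'   down by the aspiration data; 0.1/0.9 are used as generic strongly
#'   switching defaults.
#' @return A data frame with columns \code{time} (s) and \code{e_fraction}.
#' @examples
#' s <- illum_schedule(0, 5, "UV")
#' simulate_switch_state(s, switch_kinetics(), dt = 0.1)
#' @export
simulate_switch_state <- function(schedule, kinetics, dt,
                                  start = 1, pss_uv = 0.1, pss_vis = 0.9) {
  stopifnot(inherits(schedule, "illum_schedule"), dt > 0,
            start >= 0, start <= 1)
  if (nrow(schedule) == 0)
    return(data.frame(time = numeric(0), e_fraction = numeric(0)))
  rate_of <- function(i) switch(schedule$channel[i],
    UV = schedule$intensity[i] / kinetics$tau_uv,
    VIS = schedule$intensity[i] / kinetics$tau_vis,
    dark = log(2) / (kinetics$thermal_halflife * 3600))
  plateau_of <- function(i) switch(schedule$channel[i],
                                   UV = pss_uv, VIS = pss_vis, dark = 1)
  # E fraction entering each interval, propagated analytically (exact,
  # independent of the sampling grid)
  entry <- numeric(nrow(schedule))
  entry[1] <- start
  if (nrow(schedule) > 1) {
    for (i in 2:nrow(schedule)) {
      dur <- schedule$t_end[i - 1] - schedule$t_start[i - 1]
      p <- plateau_of(i - 1)
      entry[i] <- p + (entry[i - 1] - p) * exp(-rate_of(i - 1) * dur)
    }
  }
  times <- seq(schedule$t_start[1], schedule$t_end[nrow(schedule)], by = dt)
  idx <- schedule_interval_index(schedule, times)
  times <- times[!is.na(idx)]
  idx <- idx[!is.na(idx)]
  frac <- vapply(seq_along(times), function(j) {
    i <- idx[j]
    p <- plateau_of(i)
    p + (entry[i] - p) * exp(-rate_of(i) * (times[j] - schedule$t_start[i]))
  }, numeric(1))
  data.frame(time = times, e_fraction = frac)
}

#' Simulate a tongue-position trace under cyclic illumination
#'
#' Generates the membrane-interface position inside the micropipette as a
#' piecewise exponential: at each illumination switch the position relaxes
#' toward the new phase's plateau with that channel's time constant
#' (\code{tau_uv} after UV onset, \code{tau_vis} after VIS onset). The
#' E-intercalated (VIS) state has the larger membrane area, hence the deeper
#' plateau \code{baseline + amplitude}; the UV state plateau is
#' \code{baseline}. Additive Gaussian noise models tracking/readout noise.
#'
#' @param schedule an \code{\link{illum_schedule}} of alternating UV/VIS
#'   phases.
#' @param kinetics a \code{\link{switch_kinetics}}.
#' @param noise_sd Gaussian noise standard deviation (um), >= 0.
#' @param seed integer RNG seed; fixed seed gives bit-identical traces.
#' @param dt frame interval (s); default 0.075 s camera frame rate.
#' @param baseline UV-state plateau position (um, measured into the pipette).
#' @return A data frame of class \code{"tongue_trace"} with columns
#'   \code{time_s}, \code{position_um}, \code{ok}; the noise-free model
#'   positions are kept in attribute \code{"truth_um"}.
#' @export
simulate_tongue_trace <- function(schedule, kinetics, noise_sd = 0.02,
                                  seed = 1, dt = 0.075, baseline = 6) {
  stopifnot(inherits(schedule, "illum_schedule"), nrow(schedule) >= 1)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  plateau_of <- function(ch)
    if (ch == "VIS") baseline + kinetics$amplitude else baseline
  tau_of <- function(ch) if (ch == "VIS") kinetics$tau_vis else kinetics$tau_uv
  times <- seq(schedule$t_start[1], schedule$t_end[nrow(schedule)], by = dt)
  idx <- schedule_interval_index(schedule, times)
  times <- times[!is.na(idx)]
  idx <- idx[!is.na(idx)]
  # entry position at the start of each interval, propagated analytically
  entry <- numeric(nrow(schedule))
  entry[1] <- plateau_of(if (schedule$channel[1] == "VIS") "UV" else "VIS")
  if (nrow(schedule) > 1) {
    for (i in 2:nrow(schedule)) {
      ch <- schedule$channel[i - 1]
      dur <- schedule$t_end[i - 1] - schedule$t_start[i - 1]
      entry[i] <- plateau_of(ch) +
        (entry[i - 1] - plateau_of(ch)) * exp(-dur / tau_of(ch))
    }
  }
  pos <- vapply(seq_along(times), function(j) {
    i <- idx[j]
    ch <- schedule$channel[i]
    plateau_of(ch) + (entry[i] - plateau_of(ch)) *
      exp(-(times[j] - schedule$t_start[i]) / tau_of(ch))
  }, numeric(1))
  noisy <- pos
  if (noise_sd > 0) {
    set.seed(seed)
    noisy <- pos + stats::rnorm(length(pos), sd = noise_sd)
  }
  out <- data.frame(time_s = times, position_um = noisy,
                    ok = rep(TRUE, length(times)))
  attr(out, "truth_um") <- pos
  class(out) <- c("tongue_trace", "data.frame")
  out
}

#' Aspiration scene rendering configuration
#'
#' Geometry and noise parameters of the synthetic aspiration movie: a bright
#' background, a darker-walled pipette corridor running along the image
#' columns, and inside the corridor a sigmoidal bright-to-dark interface at
#' the tongue position. The pixel size default (0.1 um/px) is an arbitrary
#' plausible magnification; the frame interval default is the 75 ms camera
#' frame rate.
#'
#' @param pipette_radius pipette inner radius (um).
#' @param pipette_axis corridor centre row (px).
#' @param n_rows,n_cols field size (px).
#' @param edge_width intrinsic interface softness (px).
#' @param psf_sigma Gaussian optical blur (px).
#' @param noise_sd additive Gaussian intensity noise (counts), >= 0.
#' @param drift_per_frame uniform lateral (row) drift (px/frame).
#' @param pixel_size um per px.
#' @param frame_interval s per frame.
#' @param bright,dark background / tongue-interior intensities (counts).
#' @param seed integer RNG seed.
#' @return A list of class \code{"aspiration_scene_config"}.
#' @export
aspiration_scene_config <- function(pipette_radius = 1.05, pipette_axis = 20,
                                    n_rows = 40, n_cols = 120,
                                    edge_width = 1.5, psf_sigma = 1,
                                    noise_sd = 8, drift_per_frame = 0,
                                    pixel_size = 0.1, frame_interval = 0.075,
                                    bright = 1000, dark = 200, seed = 1) {
  stopifnot(pipette_radius > 0, frame_interval > 0, noise_sd >= 0,
            pixel_size > 0, bright > dark)
  structure(list(pipette_radius = pipette_radius, pipette_axis = pipette_axis,
                 n_rows = n_rows, n_cols = n_cols, edge_width = edge_width,
                 psf_sigma = psf_sigma, noise_sd = noise_sd,
                 drift_per_frame = drift_per_frame, pixel_size = pixel_size,
                 frame_interval = frame_interval, bright = bright,
                 dark = dark, seed = seed),
            class = "aspiration_scene_config")
}

#' Render a synthetic micropipette aspiration stack
#'
#' Turns a tongue trace into a brightfield-like image stack: each frame has a
#' bright background, a pipette corridor bounded by dark walls, and inside
#' the corridor a sigmoidal bright-to-dark interface whose midpoint sits at
#' the trace position (converted um to px). The interface edge is an
#' integrated Gaussian (erf) profile with effective width
#' \code{sqrt(edge_width^2 + psf_sigma^2)}, so the optical blur is applied
#' analytically and the ground-truth edge midpoint is exact. Columns are the
#' pipette axis; position increases with column index, i.e. deeper into the
#' pipette, and the tongue interior (beyond the interface) is darker than
#' the background, so the axial intensity derivative has a minimum at the
#' interface.
#'
#' @param trace a \code{tongue_trace} (positions in um).
#' @param cfg an \code{\link{aspiration_scene_config}}.
#' @return An \code{\link{image_stack}} with attributes
#'   \code{"truth_px"} (ground-truth interface column per frame, px),
#'   \code{"truth_um"}, and \code{"drift_rows"} (applied row drift per
#'   frame).
#' @export
render_aspiration_stack <- function(trace, cfg = aspiration_scene_config()) {
  stopifnot(inherits(trace, "tongue_trace"))
  pos_px <- trace$position_um / cfg$pixel_size
  if (any(pos_px < 3 | pos_px > cfg$n_cols - 3))
    stop("trace positions fall outside the rendered field")
  n <- nrow(trace)
  sigma_eff <- sqrt(cfg$edge_width^2 + cfg$psf_sigma^2)
  radius_px <- cfg$pipette_radius / cfg$pixel_size
  rows <- seq_len(cfg$n_rows)
  cols <- seq_len(cfg$n_cols)
  set.seed(cfg$seed)
  frames <- array(0, dim = c(cfg$n_rows, cfg$n_cols, n))
  wall_sigma <- max(cfg$psf_sigma, 0.5)
  for (i in seq_len(n)) {
    axis_row <- cfg$pipette_axis + cfg$drift_per_frame * (i - 1)
    # bright -> dark along the axis; midpoint at the interface position
    axial <- cfg$dark + (cfg$bright - cfg$dark) *
      stats::pnorm((pos_px[i] - cols) / sigma_eff)
    inside <- abs(rows - axis_row) <= radius_px
    frame <- matrix(cfg$bright, cfg$n_rows, cfg$n_cols)
    frame[inside, ] <- matrix(axial, sum(inside), cfg$n_cols, byrow = TRUE)
    # dark pipette walls just outside the corridor (blurred lines)
    wall <- exp(-((abs(rows - axis_row) - radius_px - 1)^2) /
                  (2 * wall_sigma^2))
    frame <- frame - 0.6 * cfg$bright * matrix(wall, cfg$n_rows, cfg$n_cols)
    if (cfg$noise_sd > 0)
      frame <- frame + matrix(stats::rnorm(length(frame), sd = cfg$noise_sd),
                              cfg$n_rows, cfg$n_cols)
    frames[, , i] <- pmax(frame, 0)  # camera counts are non-negative
  }
  out <- image_stack(frames, cfg$pixel_size, cfg$frame_interval)
  attr(out, "truth_px") <- pos_px
  attr(out, "truth_um") <- trace$position_um
  attr(out, "drift_rows") <- cfg$drift_per_frame * (seq_len(n) - 1)
  out
}

#' Render a synthetic adherent-cell movie for autocorrelation analysis
#'
#' A textured disc whose boundary band shifts radially on every illumination
#' switch, on top of a slowly evolving intracellular texture. The texture is
#' a per-pixel AR(1) process in time with autocorrelation
#' \code{exp(-dt / decay_tau)}, so the similarity between frame 0 and frame t
#' decays exponentially with time constant \code{decay_tau} — emulating
#' focus drift and intracellular motion — while the boundary displacement
#' produces sharp phase-locked drops.
#'
#' @param schedule an \code{\link{illum_schedule}}; frames in VIS intervals
#'   show the expanded boundary.
#' @param displacement_px radial boundary displacement on switches (px),
#'   >= 0.
#' @param decay_tau texture decorrelation time constant (s); \code{Inf} for
#'   a frozen texture.
#' @param n_px field edge length (px).
#' @param disc_radius disc radius (px).
#' @param texture_sd texture intensity standard deviation (counts).
#' @param background,contrast background level and disc contrast (counts).
#' @param frame_interval s per frame.
#' @param seed integer RNG seed.
#' @return An \code{\link{image_stack}} (pixel size fixed at 0.1 um/px) with
#'   the schedule attached as attribute \code{"schedule"}.
#' @export
render_cell_movie <- function(schedule, displacement_px = 2, decay_tau = 30,
                              n_px = 96, disc_radius = 36, texture_sd = 60,
                              background = 500, contrast = 200,
                              frame_interval = 0.075, seed = 1) {
  stopifnot(inherits(schedule, "illum_schedule"), displacement_px >= 0,
            decay_tau > 0)
  times <- seq(schedule$t_start[1], schedule$t_end[nrow(schedule)],
               by = frame_interval)
  idx <- schedule_interval_index(schedule, times)
  times <- times[!is.na(idx)]
  idx <- idx[!is.na(idx)]
  n <- length(times)
  ctr <- (n_px + 1) / 2
  g <- expand.grid(r = seq_len(n_px), c = seq_len(n_px))
  rho <- sqrt((g$r - ctr)^2 + (g$c - ctr)^2)
  inside <- rho <= disc_radius
  phi <- if (is.finite(decay_tau)) exp(-frame_interval / decay_tau) else 1
  set.seed(seed)
  tex <- stats::rnorm(sum(inside), sd = texture_sd)
  frames <- array(0, dim = c(n_px, n_px, n))
  for (i in seq_len(n)) {
    expanded <- schedule$channel[idx[i]] == "VIS"
    R <- disc_radius + if (expanded) displacement_px else 0
    # soft disc with a dark boundary band at radius R
    body <- -contrast * stats::pnorm((R - rho) / 1.5)
    band <- -contrast * 0.8 * exp(-(rho - R)^2 / (2 * 1.5^2))
    frame_v <- background + body + band
    frame_v[inside] <- frame_v[inside] + tex
    frames[, , i] <- matrix(frame_v, n_px, n_px)
    if (i < n && phi < 1)
      tex <- phi * tex +
        sqrt(1 - phi^2) * stats::rnorm(sum(inside), sd = texture_sd)
  }
  out <- image_stack(frames, 0.1, frame_interval)
  attr(out, "schedule") <- schedule
  attr(out, "times") <- times
  out
}

#' Free-floating cell morphology rendering configuration
#'
#' @param cell_radius cell radius (px); 0 renders pure background.
#' @param n_spicules number of membrane spicules around the perimeter, >= 0.
#' @param spicule_amplitude radial spicule modulation as a fraction of the
#'   radius, in \code{[0, 1)}.
#' @param texture_contrast intensity contrast of the cell relief (counts).
#' @param n_px field edge length (px).
#' @param background background intensity (counts).
#' @param noise_sd additive Gaussian noise (counts); 0 gives a clean
#'   analytic render.
#' @param seed integer RNG seed (spicule phase and noise).
#' @return A list of class \code{"morphology_config"}.
#' @export
morphology_config <- function(cell_radius = 40, n_spicules = 12,
                              spicule_amplitude = 0.25,
                              texture_contrast = 150, n_px = 128,
                              background = 500, noise_sd = 0, seed = 1) {
  stopifnot(n_spicules >= 0, cell_radius >= 0, noise_sd >= 0)
  if (spicule_amplitude < 0 || spicule_amplitude >= 1)
    stop("spicule_amplitude must lie in [0, 1)")
  structure(list(cell_radius = cell_radius, n_spicules = n_spicules,
                 spicule_amplitude = spicule_amplitude,
                 texture_contrast = texture_contrast, n_px = n_px,
                 background = background, noise_sd = noise_sd, seed = seed),
            class = "morphology_config")
}

#' Render a single free-floating red blood cell image
#'
#' Discocytes are rendered with a smooth radial relief (dark rim, lighter
#' centre). Echinocytes use the same relief but with the cell radius
#' modulated by \code{n_spicules} sinusoidal lobes of relative amplitude
#' \code{spicule_amplitude}, and the spicules additionally imprint an
#' angular intensity ripple across the cell interior (in brightfield the
#' membrane protrusions shadow the cell face) — the inhomogeneous texture
#' that raises the pixel-standard-deviation roughness score. With
#' \code{spicule_amplitude = 0} the echinocyte render is identical to the
#' discocyte.
#'
#' @param kind \code{"discocyte"} or \code{"echinocyte"}.
#' @param cfg a \code{\link{morphology_config}}.
#' @return A numeric intensity matrix.
#' @export
render_rbc_morphology <- function(kind = c("discocyte", "echinocyte"),
                                  cfg = morphology_config()) {
  kind <- match.arg(kind)
  stopifnot(inherits(cfg, "morphology_config"))
  if (cfg$cell_radius > (cfg$n_px - 2) / 2)
    stop("cell does not fit in the field")
  set.seed(cfg$seed)
  phase <- stats::runif(1, 0, 2 * pi)
  ctr <- (cfg$n_px + 1) / 2
  g <- expand.grid(r = seq_len(cfg$n_px), c = seq_len(cfg$n_px))
  img_v <- rep(cfg$background, nrow(g))
  if (cfg$cell_radius > 0) {
    rho <- sqrt((g$r - ctr)^2 + (g$c - ctr)^2)
    theta <- atan2(g$r - ctr, g$c - ctr)
    amp <- if (kind == "echinocyte") cfg$spicule_amplitude else 0
    R <- cfg$cell_radius * (1 + amp * cos(cfg$n_spicules * theta + phase))
    u <- rho / R
    # dark rim near u = 0.85, partial recovery toward the centre
    relief <- exp(-((u - 0.85) / 0.18)^2) - 0.35 * exp(-(u / 0.45)^2)
    # spicule shadows ripple across the interior
    relief <- relief + amp * cos(cfg$n_spicules * theta + phase) *
      sin(pi * pmin(u, 1))
    relief[u > 1.15] <- 0
    img_v <- img_v - cfg$texture_contrast * relief
  }
  if (cfg$noise_sd > 0)
    img_v <- img_v + stats::rnorm(length(img_v), sd = cfg$noise_sd)
  matrix(img_v, cfg$n_px, cfg$n_px)
}

#' Simulate a shake-flask partitioning experiment
#'
#' For each octanol/aqueous volume pair the total amount of solute is
#' partitioned so that the octanol:aqueous concentration ratio equals
#' \code{10^logP_true}; each phase is then read out as an absorbance through
#' its linear Beer-Lambert calibration, with additive Gaussian noise.
#'
#' @param logP_true true decimal-log partition coefficient.
#' @param volume_pairs data frame with columns \code{v_oct}, \code{v_aq}
#'   (mL); defaults to six compositions spanning 3:7 to 7:3 volume ratios.
#' @param cal_oct,cal_aq \code{\link{calibration}} objects of the two phases.
#' @param stock_uM total-solute concentration of the combined sample (uM).
#' @param noise_sd absorbance noise standard deviation.
#' @param seed integer RNG seed.
#' @return A data frame with one row per sample: volumes, true
#'   concentrations, and noisy absorbances \code{A_oct}, \code{A_aq}.
#' @export
simulate_shake_flask <- function(logP_true,
                                 volume_pairs = data.frame(
                                   v_oct = c(5, 4, 6, 3, 7, 5),
                                   v_aq = c(5, 6, 4, 7, 3, 5)),
                                 cal_oct = calibration(0.01, 0, "octanol"),
                                 cal_aq = calibration(0.01, 0, "aqueous"),
                                 stock_uM = 200, noise_sd = 0, seed = 1) {
  stopifnot(all(volume_pairs$v_oct > 0), all(volume_pairs$v_aq > 0),
            cal_oct$slope > 0, cal_aq$slope > 0, noise_sd >= 0)
  P <- 10^logP_true
  v_o <- volume_pairs$v_oct
  v_a <- volume_pairs$v_aq
  amount <- stock_uM * (v_o + v_a)           # nmol
  c_aq <- amount / (P * v_o + v_a)           # uM
  c_oct <- P * c_aq
  set.seed(seed)
  noise <- function(n) if (noise_sd > 0) stats::rnorm(n, sd = noise_sd) else 0
  data.frame(sample = seq_along(v_o), v_oct = v_o, v_aq = v_a,
             c_oct_true = c_oct, c_aq_true = c_aq,
             A_oct = cal_oct$slope * c_oct + cal_oct$intercept + noise(length(v_o)),
             A_aq = cal_aq$slope * c_aq + cal_aq$intercept + noise(length(v_o)))
}
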