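#' Linear Beer-Lambert calibration
#'
#' Absorbance A = slope x concentration + intercept for one solvent phase.
#'
#' @param slope absorbance per uM, > 0.
#' @param intercept absorbance offset.
#' @param phase label (e.g. "octanol", "aqueous").
#' @return A list of class \code{"calibration"}.
#' @export
calibration <- function(slope, intercept = 0, phase = "") {
  stopifnot(slope > 0)
  structure(list(slope = slope, intercept = intercept, phase = phase),
            class = "calibration")
}

#' Concentration from absorbance via a linear calibration
#'
#' @param absorbance measured absorbance (vector allowed).
#' @param cal a \code{\link{calibration}}.
#' @return Concentration in uM; physically impossible negative results are
#'   kept but flagged with a warning.
#' @examples
#' concentration_from_absorbance(1.47, calibration(0.01))  # 147 uM
#' @export
concentration_from_absorbance <- function(absorbance, cal) {
  stopifnot(inherits(cal, "calibration"))
  conc <- (absorbance - cal$intercept) / cal$slope
  if (any(conc < 0))
    warning("negative concentration(s) from calibration; check blank/intercept")
  conc
}

#' Octanol-water partition coefficient
#'
#' @param c_oct,c_aq concentrations in the octanol and aqueous phases
#'   (same units), > 0.
#' @return A data frame with columns \code{P_ow} = c_oct / c_aq and
#'   \code{logP} = log10(P_ow).
#' @examples
#' partition_coefficient(8.02, 1)
#' @export
partition_coefficient <- function(c_oct, c_aq) {
  if (any(c_oct <= 0) || any(c_aq <= 0))
    stop("concentrations must be strictly positive")
  P <- c_oct / c_aq
  data.frame(P_ow = P, logP = log10(P))
}

#' Aggregate a shake-flask cohort
#'
#' Computes per-sample partition coefficients and the cohort mean and
#' standard deviation, after removing explicitly listed outlier samples
#' (exclusion is always recorded in the result, never silent). The cohort
#' log P is reported both as the mean of per-sample log10 values (default
#' headline number) and as log10 of the mean P.
#'
#' @param samples data frame with columns \code{sample}, \code{c_oct},
#'   \code{c_aq}.
#' @param exclusions sample ids to exclude (e.g. visually identified
#'   outliers), or an empty vector.
#' @param auto_exclude logical; additionally drop samples whose P is more
#'   than \code{auto_k} standard deviations from the cohort median
#'   (off by default).
#' @param auto_k threshold for \code{auto_exclude}.
#' @return A list of class \code{"partition_result"}: per-sample table,
#'   \code{mean_P}, \code{sd_P}, \code{mean_logP} (mean of logs),
#'   \code{sd_logP}, \code{logP_of_mean}, \code{excluded}, \code{n}.
#' @export
aggregate_partition <- function(samples, exclusions = integer(0),
                                auto_exclude = FALSE, auto_k = 2) {
  stopifnot(all(c("sample", "c_oct", "c_aq") %in% names(samples)))
  per <- cbind(samples[c("sample", "c_oct", "c_aq")],
               partition_coefficient(samples$c_oct, samples$c_aq))
  excluded <- intersect(per$sample, exclusions)
  keep <- !(per$sample %in% excluded)
  if (auto_exclude) {
    med <- stats::median(per$P_ow[keep])
    s <- stats::sd(per$P_ow[keep])
    if (is.finite(s) && s > 0) {
      auto <- per$sample[keep][abs(per$P_ow[keep] - med) > auto_k * s]
      excluded <- union(excluded, auto)
      keep <- !(per$sample %in% excluded)
    }
  }
  if (sum(keep) < 2)
    stop("fewer than 2 samples retained after exclusions")
  P <- per$P_ow[keep]
  lp <- per$logP[keep]
  structure(list(samples = per,
                 mean_P = mean(P), sd_P = stats::sd(P),
                 mean_logP = mean(lp), sd_logP = stats::sd(lp),
                 logP_of_mean = log10(mean(P)),
                 excluded = excluded, n = sum(keep)),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf(
    "partition cohort (n = %d%s): P_ow = %.3g +/- %.3g, log P = %.3g +/- %.3g (mean of logs)\n",
    x$n,
    if (length(x$excluded)) paste0(", excluded: ",
                                   paste(x$excluded, collapse = ",")) else "",
    x$mean_P, x$sd_P, x$mean_logP, x$sd_logP))
  invisible(x)
}

#' Membrane-bound fraction from a depletion assay
#'
#' Fraction of solute lost from solution after incubation with cells and
#' their removal — the membrane-bound share of the photoswitch.
#'
#' @param c_initial concentration before cell addition, > 0.
#' @param c_after concentration after cell removal.
#' @return Loss in percent: 100 (c_initial - c_after) / c_initial. Values
#'   of \code{c_after} above \code{c_initial} (possible under measurement
#'   noise) give a negative loss with a warning, not an error.
#' @examples
#' membrane_bound_fraction(147, 55.86)  # 62 percent
#' @export
membrane_bound_fraction <- function(c_initial, c_after) {
  if (any(c_initial <= 0)) stop("c_initial must be > 0")
  if (any(c_after < 0)) stop("c_after must be >= 0")
  if (any(c_after > c_initial))
    warning("c_after exceeds c_initial (negative loss); measurement noise?")
  100 * (c_initial - c_after) / c_initial
}

#' Potential of mean force from a density profile
#'
#' Inverse-Boltzmann transform of a number-density profile along the
#' membrane normal: PMF(z) = -ln rho(z), in units of kT (the k_B T factor
#' is taken out). Grid points with non-positive density are masked to NA,
#' since the free energy is undefined there. The additive constant is
#' arbitrary until a reference alignment is chosen (see
#' \code{\link{partition_ratio_from_pmf}}).
#'
#' @param profile data frame with columns \code{z} (nm) and \code{rho}
#'   (number density, arbitrary units).
#' @return A data frame with columns \code{z} and \code{pmf} (kT units).
#' @examples
#' z <- seq(-2, 2, 0.1)
#' pmf_from_density(data.frame(z = z, rho = exp(-z^2 / 2)))
#' @export
pmf_from_density <- function(profile) {
  stopifnot(all(c("z", "rho") %in% names(profile)))
  if (any(profile$rho < 0)) stop("densities must be non-negative")
  pmf <- ifelse(profile$rho > 0, -log(profile$rho), NA_real_)
  data.frame(z = profile$z, pmf = pmf)
}

# trapezoidal quadrature on an irregular grid
trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)

#' Partition ratio of two species from their PMF profiles
#'
#' Computes the ratio of Boltzmann-weighted populations of two
#' potential-of-mean-force profiles: integral of exp(-PMF_A) over the
#' common support divided by the same integral for profile B, by
#' trapezoidal quadrature after interpolating both onto the common grid.
#' PMFs are in kT units, so exp(-PMF) is the spatial distribution
#' exp(-beta W). If \code{align_at} is given, each profile is first shifted
#' so that its value at that position is zero — the convention of pinning
#' both profiles to a common reference (e.g. the lipid head-group
#' position), after which the ratio reflects only the shape difference
#' inside the membrane. Without alignment the profiles are compared as
#' given, so a constant offset dW between them yields the ratio
#' exp(-dW).
#'
#' @param pmf_A,pmf_B data frames with columns \code{z} and \code{pmf}
#'   (kT units), e.g. from \code{\link{pmf_from_density}}.
#' @param align_at optional z position at which the two profiles are forced
#'   to agree (both shifted to zero there); \code{NULL} (default) uses the
#'   profiles as given.
#' @return The scalar ratio integral_A / integral_B.
#' @examples
#' z <- seq(-2, 2, 0.05)
#' w <- data.frame(z = z, pmf = z^2)
#' partition_ratio_from_pmf(transform(w, pmf = pmf + 0.4), w)  # exp(-0.4)
#' @export
partition_ratio_from_pmf <- function(pmf_A, pmf_B, align_at = NULL) {
  stopifnot(all(c("z", "pmf") %in% names(pmf_A)),
            all(c("z", "pmf") %in% names(pmf_B)))
  ok_A <- is.finite(pmf_A$pmf); ok_B <- is.finite(pmf_B$pmf)
  zlo <- max(min(pmf_A$z[ok_A]), min(pmf_B$z[ok_B]))
  zhi <- min(max(pmf_A$z[ok_A]), max(pmf_B$z[ok_B]))
  if (zhi <= zlo) stop("PMF profiles have no overlapping support")
  grid <- sort(unique(c(pmf_A$z[ok_A], pmf_B$z[ok_B])))
  grid <- grid[grid >= zlo & grid <= zhi]
  wA <- stats::approx(pmf_A$z[ok_A], pmf_A$pmf[ok_A], xout = grid)$y
  wB <- stats::approx(pmf_B$z[ok_B], pmf_B$pmf[ok_B], xout = grid)$y
  if (!is.null(align_at)) {
    if (align_at < zlo || align_at > zhi)
      stop("profiles do not overlap at align_at")
    wA <- wA - stats::approx(pmf_A$z[ok_A], pmf_A$pmf[ok_A],
                             xout = align_at)$y
    wB <- wB - stats::approx(pmf_B$z[ok_B], pmf_B$pmf[ok_B],
                             xout = align_at)$y
  }
  trapz(grid, exp(-wA)) / trapz(grid, exp(-wB))
}

#' Read a two-column profile CSV
#'
#' Density or PMF profiles are exchanged as two-column CSV files with a
#' header row (first column the coordinate, second the value).
#'
#' @param path CSV path.
#' @param names column names to assign, default \code{c("z", "rho")}.
#' @return A data frame.
#' @export
read_profile <- function(path, names = c("z", "rho")) {
  x <- utils::read.csv(path)
  stopifnot(ncol(x) >= 2)
  stats::setNames(x[, 1:2], names)
}
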