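# Size-exclusion chromatography sizing: profile normalization, standards
# calibration, size-class mass ratios, peak calling, and gel-ladder sizing.

#' SEC elution profile
#'
#' Per-fraction hyaluronan amounts from a size-exclusion chromatography run
#' (conventionally 30 fractions of 200 microliters). Larger molecules elute
#' earlier, so molecular weight decreases with fraction index.
#'
#' @param concentration Non-negative amount of HA per fraction (ng, or % of
#'   total after normalization).
#' @param fraction_volume_ul Volume per fraction (default 200).
#' @param normalized Whether the values are already percentages of total.
#' @return An object of class `elution_profile`.
#' @export
elution_profile <- function(concentration, fraction_volume_ul = 200,
                            normalized = FALSE) {
  if (!is.numeric(concentration) || length(concentration) < 1L) {
    stop("'concentration' must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(concentration) || any(concentration < 0)) {
    stop("concentrations must be non-negative and non-missing", call. = FALSE)
  }
  structure(
    list(fraction_index = seq_along(concentration),
         fraction_volume_ul = fraction_volume_ul,
         concentration = as.numeric(concentration),
         normalized = isTRUE(normalized)),
    class = "elution_profile"
  )
}

#' @export
print.elution_profile <- function(x, ...) {
  cat(sprintf("elution_profile: %d fractions of %g ul%s, total %.4g\n",
              length(x$concentration), x$fraction_volume_ul,
              if (x$normalized) " (normalized %)" else "",
              sum(x$concentration)))
  invisible(x)
}

#' Normalize an elution profile to percent of total HA recovered
#'
#' @param profile An [elution_profile()] with at least one positive fraction.
#' @return The profile with concentrations summing to 100 and the
#'   `normalized` flag set. Idempotent.
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "elution_profile"))
  total <- sum(profile$concentration)
  if (total <= 0) stop("cannot normalize an all-zero profile", call. = FALSE)
  profile$concentration <- 100 * profile$concentration / total
  profile$normalized <- TRUE
  profile
}

#' Fit a molecular-weight calibration from standards
#'
#' Piecewise-linear interpolation of log10(MW) against position (fraction
#' index for SEC, migration distance for gels), through the anchor points of
#' standards of known size. MW must be strictly decreasing in position, as
#' it is for both SEC (large molecules elute first) and gels (large
#' molecules migrate least); any other ordering is rejected.
#' Queries outside the anchor range are clamped to the terminal anchor values
#' and flagged, never extrapolated without bound.
#'
#' @param anchors Data frame with columns `mw_kda` and `position`.
#' @return An object of class `size_calibration`.
#' @examples
#' cal <- fit_calibration(data.frame(mw_kda = c(2500, 500, 150),
#'                                   position = c(8, 14, 20)))
#' mw_at(11, cal)  # 1118.03 kDa, log-midpoint of the first segment
#' @export
fit_calibration <- function(anchors) {
  if (!is.data.frame(anchors) || !all(c("mw_kda", "position") %in% names(anchors))) {
    stop("'anchors' must be a data frame with columns mw_kda, position",
         call. = FALSE)
  }
  if (nrow(anchors) < 2L) stop("need at least 2 anchors", call. = FALSE)
  if (any(anchors$mw_kda <= 0)) stop("anchor MW must be positive", call. = FALSE)
  anchors <- anchors[order(anchors$position), , drop = FALSE]
  if (anyDuplicated(anchors$position)) {
    stop("anchor positions must be distinct", call. = FALSE)
  }
  d <- diff(anchors$mw_kda)
  if (!all(d < 0)) {
    stop("anchor MW must decrease strictly with position (larger molecules ",
         "elute/migrate first)", call. = FALSE)
  }
  structure(
    list(anchors = data.frame(mw_kda = anchors$mw_kda,
                              position = anchors$position),
         log10_mw = log10(anchors$mw_kda),
         decreasing = TRUE),
    class = "size_calibration"
  )
}

#' @export
print.size_calibration <- function(x, ...) {
  cat(sprintf("size_calibration: %d anchors, %s - %s kDa, MW %s with position\n",
              nrow(x$anchors), format(min(x$anchors$mw_kda)),
              format(max(x$anchors$mw_kda)),
              if (x$decreasing) "decreasing" else "increasing"))
  invisible(x)
}

#' Molecular weight at a position, and position of a molecular weight
#'
#' Mutually inverse lookups on a [fit_calibration()] map. Queries outside
#' the anchor range are clamped to the nearest anchor, a warning is issued
#' and the returned vector carries an `out_of_range` logical attribute.
#'
#' @param position Numeric position(s) (fraction index or migration
#'   distance).
#' @param mw_kda Molecular weight(s) in kDa.
#' @param calibration A `size_calibration`.
#' @return Numeric vector of kDa (for `mw_at`) or positions (for
#'   `position_of`), with attribute `out_of_range`.
#' @export
mw_at <- function(position, calibration) {
  stopifnot(inherits(calibration, "size_calibration"))
  rng <- range(calibration$anchors$position)
  tol <- 1e-9 * max(1, abs(rng))
  oor <- position < rng[1] - tol | position > rng[2] + tol
  if (any(oor)) warning("position(s) outside the calibrated range; clamped")
  y <- stats::approx(calibration$anchors$position, calibration$log10_mw,
                     xout = pmin(pmax(position, rng[1]), rng[2]),
                     method = "linear", ties = "ordered")$y
  structure(10^y, out_of_range = oor)
}

#' @rdname mw_at
#' @export
position_of <- function(mw_kda, calibration) {
  stopifnot(inherits(calibration, "size_calibration"))
  if (any(mw_kda <= 0)) stop("'mw_kda' must be positive", call. = FALSE)
  lm <- log10(mw_kda)
  rng <- range(calibration$log10_mw)
  tol <- 1e-9 * max(1, abs(rng))
  oor <- lm < rng[1] - tol | lm > rng[2] + tol
  if (any(oor)) warning("MW(s) outside the calibrated range; clamped")
  # invert the piecewise-linear map (log10 MW is monotone in position);
  # re-sort ascending in log10 MW for approx()
  o <- order(calibration$log10_mw)
  y <- stats::approx(calibration$log10_mw[o], calibration$anchors$position[o],
                     xout = pmin(pmax(lm, rng[1]), rng[2]),
                     method = "linear", ties = "ordered")$y
  structure(y, out_of_range = oor)
}

#' Size-class mass summary of an elution profile
#'
#' Splits the normalized profile mass into high (> `hi` kDa), mid
#' (`lo`-`hi` kDa) and low (< `lo` kDa) molecular-weight classes, using the
#' calibration to place the class boundaries on the fraction axis. A
#' fraction is assigned by the MW at its center; a fraction whose position
#' interval (center +/- 0.5) straddles a boundary is split linearly in
#' position. The headline quantity is the HMW/LMW mass ratio.
#'
#' @param profile A normalized [elution_profile()] (see
#'   [normalize_profile()]).
#' @param calibration A `size_calibration` covering `hi` and `lo`.
#' @param hi,lo Class bounds in kDa (defaults 500 and 150; `hi > lo`).
#' @return A list of class `size_class_summary`: `pct_hmw`, `pct_mid`,
#'   `pct_lmw` (summing to 100), `hmw_lmw_ratio` (`Inf` with
#'   `lmw_zero = TRUE` when no LMW mass), `hi`, `lo`.
#' @export
size_class_summary <- function(profile, calibration, hi = 500, lo = 150) {
  stopifnot(inherits(profile, "elution_profile"),
            inherits(calibration, "size_calibration"))
  if (!profile$normalized) {
    stop("profile must be normalized first (see normalize_profile())",
         call. = FALSE)
  }
  if (hi <= lo) stop("'hi' must exceed 'lo'", call. = FALSE)
  pos_hi <- suppressWarnings(as.numeric(position_of(hi, calibration)))
  pos_lo <- suppressWarnings(as.numeric(position_of(lo, calibration)))
  # MW decreases with position, so the > hi class occupies positions below
  # pos_hi and the < lo class positions above pos_lo
  centers <- profile$fraction_index
  lower <- centers - 0.5
  upper <- centers + 0.5
  # share of each fraction's position interval lying before a boundary
  share_before <- function(b) pmin(pmax((b - lower) / (upper - lower), 0), 1)
  s_hi <- share_before(pos_hi)   # fraction of interval in the HMW class
  s_lo <- share_before(pos_lo)   # fraction of interval in HMW + mid classes
  conc <- profile$concentration
  pct_hmw <- sum(conc * s_hi)
  pct_lmw <- sum(conc * (1 - s_lo))
  pct_mid <- sum(conc * (s_lo - s_hi))
  lmw_zero <- pct_lmw <= 0
  structure(
    list(pct_hmw = pct_hmw, pct_mid = pct_mid, pct_lmw = pct_lmw,
         hmw_lmw_ratio = if (lmw_zero) Inf else pct_hmw / pct_lmw,
         lmw_zero = lmw_zero, hi = hi, lo = lo),
    class = "size_class_summary"
  )
}

#' @export
print.size_class_summary <- function(x, ...) {
  cat(sprintf("size classes: %.1f%% > %g kDa | %.1f%% mid | %.1f%% < %g kDa; HMW/LMW = %s\n",
              x$pct_hmw, x$hi, x$pct_mid, x$pct_lmw, x$lo,
              if (is.infinite(x$hmw_lmw_ratio)) "Inf (no LMW mass)"
              else sprintf("%.3f", x$hmw_lmw_ratio)))
  invisible(x)
}

#' Peak molecular weight of an elution profile
#'
#' MW at the modal fraction. Ties are broken toward the earlier-eluting
#' (larger-MW) fraction and flagged.
#'
#' @param profile A normalized [elution_profile()].
#' @param calibration A `size_calibration`.
#' @return Numeric kDa with attributes `fraction` (modal index) and `tie`.
#' @export
peak_mw <- function(profile, calibration) {
  stopifnot(inherits(profile, "elution_profile"))
  conc <- profile$concentration
  if (all(conc == 0)) stop("all-zero profile has no peak", call. = FALSE)
  mx <- max(conc)
  at <- which(conc == mx)
  idx <- at[1]  # earlier fraction = larger MW under SEC orientation
  mw <- suppressWarnings(as.numeric(mw_at(idx, calibration)))
  structure(mw, fraction = idx, tie = length(at) > 1L)
}

#' Size a gel band against a molecular-weight ladder
#'
#' Log-linear interpolation of MW against migration distance through ladder
#' bands of known size (e.g. 200, 400, 1260, 2500, 3900 kDa). Migrations
#' outside the ladder are clamped and flagged.
#'
#' @param migration Migration distance(s) of the band(s).
#' @param ladder Data frame with columns `mw_kda` and `position` (migration
#'   distance of each ladder band).
#' @return Numeric kDa with attribute `out_of_range`.
#' @export
gel_band_size <- function(migration, ladder) {
  cal <- fit_calibration(ladder)
  mw_at(migration, cal)
}
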