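# HA quantification: standard-curve interpolation, dry-weight
# normalization, and the study's group comparisons.

#' Interpolate concentrations from an assay standard curve
#'
#' Monotone piecewise-linear inverse mapping from assay signal to
#' concentration, through the standards of an ELISA-like HA assay. Signals
#' outside the standards' range are returned as `NA` and flagged, never
#' extrapolated — out-of-range wells need dilution or a new curve, not a
#' guess.
#'
#' @param signals Numeric assay readouts.
#' @param standards Data frame with columns `concentration` and `signal`;
#'   signal must be strictly monotone in concentration.
#' @return Numeric concentrations with attribute `out_of_range` (logical).
#' @export
standard_curve_interpolate <- function(signals, standards) {
  if (!is.data.frame(standards) ||
      !all(c("concentration", "signal") %in% names(standards))) {
    stop("'standards' needs columns concentration, signal", call. = FALSE)
  }
  if (nrow(standards) < 2L) stop("need at least 2 standards", call. = FALSE)
  standards <- standards[order(standards$concentration), , drop = FALSE]
  d <- diff(standards$signal)
  if (!(all(d > 0) || all(d < 0))) {
    stop("standard signals must be strictly monotone in concentration",
         call. = FALSE)
  }
  rng <- range(standards$signal)
  oor <- signals < rng[1] | signals > rng[2]
  conc <- stats::approx(standards$signal, standards$concentration,
                        xout = signals, method = "linear",
                        ties = "ordered")$y
  conc[oor] <- NA_real_
  structure(conc, out_of_range = oor)
}

#' Tissue HA content per gram dry weight
#'
#' @param ha_ug HA mass in micrograms.
#' @param dry_mass_g Dry tissue mass in grams (> 0).
#' @return HA content in micrograms per gram dry weight.
#' @examples
#' tissue_content(1.5, 0.01)  # 150 ug/g, a renal-medulla magnitude
#' @export
tissue_content <- function(ha_ug, dry_mass_g) {
  if (any(dry_mass_g <= 0)) stop("'dry_mass_g' must be positive", call. = FALSE)
  if (any(ha_ug < 0)) stop("'ha_ug' must be non-negative", call. = FALSE)
  ha_ug / dry_mass_g
}

#' Holm-Sidak step-down adjustment of p-values
#'
#' Step-down Sidak procedure: with the raw p-values sorted ascending, the
#' i-th is adjusted to `1 - (1 - p_(i))^(m - i + 1)`, then running maxima
#' enforce monotonicity and values are capped at 1. Uniformly no larger than
#' Holm's (and hence Bonferroni's) adjustment.
#'
#' @param p Raw p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
holm_sidak_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("'p' must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Group comparisons for HA quantification data
#'
#' Runs the comparison design used for HA contents and serum levels:
#' \describe{
#'   \item{`two_group`}{Welch's t-test (or pooled-variance Student with
#'     `var_equal = TRUE`) between two species within one stratum.}
#'   \item{`one_way`}{One-way ANOVA across groups followed by all pairwise
#'     t-tests adjusted by Holm-Sidak (default) or Bonferroni.}
#'   \item{`two_way`}{Two-way ANOVA `value ~ species * tissue`: main-effect
#'     and interaction F and p.}
#' }
#'
#' @param records Data frame with columns `species`, `tissue`, `value`
#'   (see [simulate_quant_dataset()] for the layout).
#' @param design `"two_group"`, `"one_way"` or `"two_way"`.
#' @param group_by Factor column defining groups for `two_group`/`one_way`
#'   (default `"species"`).
#' @param adjust Pairwise adjustment for `one_way`: `"holm_sidak"` or
#'   `"bonferroni"`.
#' @param var_equal Pooled-variance t-tests instead of Welch.
#' @return For `two_group`: list with `statistic`, `p_value`, `df`. For
#'   `one_way`: list with `F`, `p_value`, and data.frame `pairwise`
#'   (`group_1`, `group_2`, `p_raw`, `p_adjusted`). For `two_way`: data.frame
#'   `effects` (`term`, `F`, `p_value`).
#' @export
compare_groups <- function(records,
                           design = c("two_group", "one_way", "two_way"),
                           group_by = "species",
                           adjust = c("holm_sidak", "bonferroni"),
                           var_equal = FALSE) {
  design <- match.arg(design)
  adjust <- match.arg(adjust)
  if (!is.data.frame(records) || !"value" %in% names(records)) {
    stop("'records' must be a data frame with a 'value' column", call. = FALSE)
  }
  if (design %in% c("two_group", "one_way")) {
    g <- factor(records[[group_by]])
    if (any(table(g) < 2L)) stop("need >= 2 records per group", call. = FALSE)
    if (design == "two_group") {
      if (nlevels(g) != 2L) stop("'two_group' needs exactly 2 groups", call. = FALSE)
      sp <- split(records$value, g)
      return(.welch_t(sp[[1]], sp[[2]], var_equal = var_equal))
    }
    fit <- stats::aov(value ~ g, data = data.frame(value = records$value, g = g))
    tab <- summary(fit)[[1]]
    pairs <- utils::combn(levels(g), 2)
    p_raw <- apply(pairs, 2, function(pr) {
      .welch_t(records$value[g == pr[1]], records$value[g == pr[2]],
               var_equal = var_equal)$p_value
    })
    p_adj <- if (adjust == "holm_sidak") holm_sidak_adjust(p_raw)
             else stats::p.adjust(p_raw, method = "bonferroni")
    return(list(
      F = tab[["F value"]][1], p_value = tab[["Pr(>F)"]][1],
      pairwise = data.frame(group_1 = pairs[1, ], group_2 = pairs[2, ],
                            p_raw = p_raw, p_adjusted = p_adj,
                            adjust = adjust, stringsAsFactors = FALSE)
    ))
  }
  # two-way: species x tissue with interaction
  if (!all(c("species", "tissue") %in% names(records))) {
    stop("'two_way' needs species and tissue columns", call. = FALSE)
  }
  cells <- table(records$species, records$tissue)
  if (any(cells == 0L)) stop("empty cells in the species x tissue design", call. = FALSE)
  if (any(cells < 2L)) stop("need >= 2 records per design cell", call. = FALSE)
  df <- data.frame(value = records$value,
                   species = factor(records$species),
                   tissue = factor(records$tissue))
  fit <- stats::aov(value ~ species * tissue, data = df)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  keep <- terms != "Residuals"
  list(effects = data.frame(term = terms[keep],
                            F = tab[["F value"]][keep],
                            p_value = tab[["Pr(>F)"]][keep],
                            stringsAsFactors = FALSE))
}
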