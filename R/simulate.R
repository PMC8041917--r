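# Synthetic-data generators. Every downstream stage (cross-tissue
# aggregation, RPKM tables, SEC sizing, quantification tests) can be
# exercised against known ground truth without any external download.

#' Configuration for the cross-tissue differential-expression simulator
#'
#' Describes a genes x tissues grid in which most genes are null (uniform
#' p-values, random fold-change signs) and a minority of "signal" genes show
#' consistently signed fold changes with small p-values in every tissue —
#' the structure the sign-weighted Fisher statistic is designed to detect.
#' The defaults mirror a cross-species comparison of roughly 9,600 homologous
#' genes measured in 11 tissues.
#'
#' @param n_genes,n_tissues,n_signal_genes Grid dimensions and number of
#'   planted signal genes (`n_signal_genes <= n_genes`).
#' @param signal_p_law Per-tissue p-value law for signal genes: either
#'   `list(type = "fixed", value = p0)` (point mass, the default: clean
#'   recovery tests) or `list(type = "beta", shape1 = a, shape2 = b)`
#'   (skewed toward 0 for graded power curves).
#' @param signal_sign +1 or -1, recycled per signal gene: the consistent
#'   direction of its fold change across tissues.
#' @param null_logfc_sd Standard deviation of the Normal(0, sd) null log
#'   fold-changes; signs are then +/-1 equiprobable and magnitudes exist for
#'   volcano plumbing (only the sign enters the statistic).
#' @param seed Integer master seed.
#' @return A list of class `cross_tissue_sim_config`.
#' @export
cross_tissue_sim_config <- function(n_genes = 9600L, n_tissues = 11L,
                                    n_signal_genes = 0L,
                                    signal_p_law = list(type = "fixed",
                                                        value = 1e-3),
                                    signal_sign = 1L,
                                    null_logfc_sd = 1,
                                    seed = 1L) {
  n_genes <- .check_count(n_genes, "n_genes")
  n_tissues <- .check_count(n_tissues, "n_tissues")
  n_signal_genes <- .check_count(n_signal_genes, "n_signal_genes", min = 0L)
  if (n_signal_genes > n_genes) {
    stop("'n_signal_genes' cannot exceed 'n_genes'", call. = FALSE)
  }
  if (!is.list(signal_p_law) || is.null(signal_p_law$type) ||
      !signal_p_law$type %in% c("fixed", "beta")) {
    stop("'signal_p_law' must be list(type = 'fixed', value=) or list(type = 'beta', shape1=, shape2=)",
         call. = FALSE)
  }
  if (signal_p_law$type == "fixed") .check_prob(signal_p_law$value, "signal_p_law$value")
  if (!all(signal_sign %in% c(-1L, 1L))) {
    stop("'signal_sign' entries must be +1 or -1", call. = FALSE)
  }
  if (!is.numeric(null_logfc_sd) || null_logfc_sd <= 0) {
    stop("'null_logfc_sd' must be positive", call. = FALSE)
  }
  structure(
    list(n_genes = n_genes, n_tissues = n_tissues,
         n_signal_genes = n_signal_genes, signal_p_law = signal_p_law,
         signal_sign = rep_len(as.integer(signal_sign),
                               max(n_signal_genes, 1L))[seq_len(max(n_signal_genes, 0L))],
         null_logfc_sd = null_logfc_sd, seed = .check_count(seed, "seed", 0L)),
    class = "cross_tissue_sim_config"
  )
}

#' Simulate a cross-tissue differential-expression table
#'
#' Null genes get per-tissue p ~ Uniform(0, 1] and logFC ~ Normal(0, sd)
#' (signs +/-1 equiprobable); signal genes get p drawn from the configured
#' law and a fixed fold-change direction in every tissue. The first
#' `n_signal_genes` rows are the signal genes.
#'
#' @param config A [cross_tissue_sim_config()].
#' @return A list: `matrix` (a [cross_tissue_matrix()]) and `truth`
#'   (data.frame gene_id, is_signal, signal_sign).
#' @export
simulate_cross_tissue_table <- function(config) {
  stopifnot(inherits(config, "cross_tissue_sim_config"))
  ng <- config$n_genes; nt <- config$n_tissues; ns <- config$n_signal_genes
  res <- with_seed(derive_seed(config$seed, "cross_tissue_table"), {
    # runif is in [0,1); map to (0,1] to respect the open-at-zero domain
    p <- matrix(1 - stats::runif(ng * nt), nrow = ng, ncol = nt)
    lfc <- matrix(stats::rnorm(ng * nt, 0, config$null_logfc_sd),
                  nrow = ng, ncol = nt)
    if (ns > 0L) {
      law <- config$signal_p_law
      p[seq_len(ns), ] <- if (law$type == "fixed") {
        law$value
      } else {
        matrix(stats::rbeta(ns * nt, law$shape1, law$shape2), nrow = ns)
      }
      lfc[seq_len(ns), ] <- abs(lfc[seq_len(ns), , drop = FALSE]) *
        config$signal_sign
    }
    list(p = p, lfc = lfc)
  })
  gene_ids <- sprintf("gene_%05d", seq_len(ng))
  truth <- data.frame(
    gene_id = gene_ids,
    is_signal = seq_len(ng) <= ns,
    signal_sign = c(if (ns > 0L) config$signal_sign else integer(0),
                    rep(NA_integer_, ng - ns)),
    stringsAsFactors = FALSE
  )
  list(matrix = cross_tissue_matrix(res$p, res$lfc, gene_ids = gene_ids),
       truth = truth)
}

#' Simulate a count matrix for RPKM plumbing
#'
#' Negative-binomial counts (Poisson when `dispersion = 0`) per gene and
#' sample, with per-gene expected counts and gene lengths supplied by the
#' caller. Library sizes are the realized column sums.
#'
#' @param mu Per-gene expected counts (length `n_genes`), recycled across
#'   samples.
#' @param dispersion Per-gene negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson.
#' @param group_sizes Integer vector of samples per group; groups are labeled
#'   `group_1`, `group_2`, ...
#' @param gene_lengths_kb Transcript lengths in kilobases (> 0).
#' @param seed Integer seed.
#' @return List: `counts` (genes x samples integer matrix), `gene_lengths_kb`,
#'   `library_sizes`, `groups` (per-sample label).
#' @export
simulate_expression_counts <- function(mu, dispersion = 0, group_sizes = c(4L, 3L),
                                       gene_lengths_kb = rep(1, length(mu)),
                                       seed = 1L) {
  if (any(group_sizes < 1L)) stop("each group needs >= 1 sample", call. = FALSE)
  if (any(gene_lengths_kb <= 0)) stop("gene lengths must be positive", call. = FALSE)
  if (any(mu < 0)) stop("'mu' must be non-negative", call. = FALSE)
  dispersion <- rep_len(dispersion, length(mu))
  n_samples <- sum(group_sizes)
  counts <- with_seed(derive_seed(seed, "expression_counts"), {
    m <- matrix(0L, nrow = length(mu), ncol = n_samples)
    for (g in seq_along(mu)) {
      m[g, ] <- if (dispersion[g] > 0) {
        stats::rnbinom(n_samples, mu = mu[g], size = 1 / dispersion[g])
      } else {
        stats::rpois(n_samples, mu[g])
      }
    }
    m
  })
  groups <- rep(sprintf("group_%d", seq_along(group_sizes)), group_sizes)
  colnames(counts) <- sprintf("%s_s%02d", groups, seq_len(n_samples))
  rownames(counts) <- sprintf("gene_%05d", seq_along(mu))
  list(counts = counts, gene_lengths_kb = gene_lengths_kb,
       library_sizes = colSums(counts), groups = groups)
}

#' Configuration for the SEC elution-profile simulator
#'
#' A hyaluronan sample is modelled as a mixture of lognormal molecular-weight
#' components; the simulator pushes the mixture through a size calibration to
#' obtain per-fraction masses, optionally perturbed by multiplicative noise.
#'
#' @param components Data frame with columns `mean_log10_mw` (log10 kDa),
#'   `sd_log10_mw`, `mass_fraction` (must sum to 1).
#' @param n_fractions Number of collected fractions (default 30).
#' @param fraction_volume_ul Volume per fraction in microliters (default 200).
#' @param total_mass Total HA mass recovered, in arbitrary units (default
#'   100, so noise-free fraction values are percentages).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise per fraction (0 = noise-free).
#' @param calibration A [fit_calibration()] object mapping MW to fraction
#'   position; must cover the components' MW range (clamping allowed).
#' @param seed Integer seed.
#' @return A list of class `elution_sim_config`.
#' @export
elution_sim_config <- function(components, calibration,
                               n_fractions = 30L, fraction_volume_ul = 200,
                               total_mass = 100, noise_cv = 0, seed = 1L) {
  if (!is.data.frame(components) || nrow(components) == 0L) {
    stop("'components' must be a non-empty data frame", call. = FALSE)
  }
  need <- c("mean_log10_mw", "sd_log10_mw", "mass_fraction")
  if (!all(need %in% names(components))) {
    stop("'components' needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (abs(sum(components$mass_fraction) - 1) > 1e-8) {
    stop("component mass fractions must sum to 1", call. = FALSE)
  }
  if (any(components$sd_log10_mw < 0)) {
    stop("'sd_log10_mw' must be non-negative", call. = FALSE)
  }
  n_fractions <- .check_count(n_fractions, "n_fractions", min = 3L)
  if (noise_cv < 0) stop("'noise_cv' must be >= 0", call. = FALSE)
  stopifnot(inherits(calibration, "size_calibration"))
  structure(
    list(components = components, calibration = calibration,
         n_fractions = n_fractions, fraction_volume_ul = fraction_volume_ul,
         total_mass = total_mass, noise_cv = noise_cv,
         seed = .check_count(seed, "seed", 0L)),
    class = "elution_sim_config"
  )
}

#' Simulate an SEC elution profile with known size-class truth
#'
#' Each fraction's mass is the probability mass of the continuous
#' molecular-weight mixture falling in that fraction's position interval
#' under the calibration, times the total mass, times (1 + multiplicative
#' noise). The returned true size-class summary is computed from the
#' continuous mixture itself (not the discretized profile), so recovery
#' tests can quantify pure discretization error.
#'
#' @param config An [elution_sim_config()].
#' @param hi,lo Size-class boundaries in kDa for the truth summary
#'   (defaults 500 and 150).
#' @return List: `profile` (an [elution_profile()]), `truth` (list with
#'   `pct_hmw`, `pct_mid`, `pct_lmw`, `hmw_lmw_ratio` from the continuous
#'   mixture).
#' @export
simulate_elution_profile <- function(config, hi = 500, lo = 150) {
  stopifnot(inherits(config, "elution_sim_config"))
  comp <- config$components
  nf <- config$n_fractions
  # P(MW > x) for the lognormal (base-10) mixture
  surv <- function(x) {
    sum(comp$mass_fraction *
          stats::pnorm(log10(x), mean = comp$mean_log10_mw,
                       sd = pmax(comp$sd_log10_mw, 1e-12),
                       lower.tail = FALSE))
  }
  # mass in fraction i = P(position in [i - 0.5, i + 0.5]); positions grow as
  # MW falls, so that's P(MW in (mw_at(i+0.5), mw_at(i-0.5)])
  edges <- seq(0.5, nf + 0.5, by = 1)
  mw_edges <- suppressWarnings(mw_at(edges, config$calibration))
  mass <- vapply(seq_len(nf), function(i) {
    surv(mw_edges[i + 1]) - surv(mw_edges[i])
  }, numeric(1))
  # mass beyond the collected window elutes in the terminal fractions:
  # MW above the first edge before fraction 1, MW below the last edge after
  # fraction nf
  mass[1] <- mass[1] + surv(mw_edges[1])
  mass[nf] <- mass[nf] + (1 - surv(mw_edges[nf + 1]))
  conc <- config$total_mass * mass
  if (config$noise_cv > 0) {
    s <- sqrt(log(1 + config$noise_cv^2))
    conc <- conc * with_seed(derive_seed(config$seed, "elution_noise"),
                             stats::rlnorm(nf, meanlog = -s^2 / 2, sdlog = s))
  }
  pct_hmw <- 100 * surv(hi)
  pct_lmw <- 100 * (1 - surv(lo))
  truth <- list(
    pct_hmw = pct_hmw,
    pct_mid = 100 - pct_hmw - pct_lmw,
    pct_lmw = pct_lmw,
    hmw_lmw_ratio = if (pct_lmw > 0) pct_hmw / pct_lmw else Inf
  )
  list(profile = elution_profile(conc,
                                 fraction_volume_ul = config$fraction_volume_ul),
       truth = truth)
}

#' Simulate an HA quantification dataset
#'
#' Positive-valued measurements (lognormal, with the requested mean and
#' coefficient of variation per group cell) for two-group, one-way or
#' two-way comparisons. A zero CV yields values exactly at the group mean.
#'
#' @param design Data frame with one row per group cell: columns `species`,
#'   `tissue`, `mean` (> = 0), `cv` (>= 0), `n` (>= 2).
#' @param seed Integer seed.
#' @return Data frame of records: `sample_id`, `species`, `tissue`, `value`.
#' @export
simulate_quant_dataset <- function(design, seed = 1L) {
  need <- c("species", "tissue", "mean", "cv", "n")
  if (!is.data.frame(design) || !all(need %in% names(design))) {
    stop("'design' needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(design$mean < 0)) stop("group means must be non-negative", call. = FALSE)
  if (any(design$cv < 0)) stop("group CVs must be non-negative", call. = FALSE)
  if (any(design$n < 2L)) stop("need n >= 2 per group", call. = FALSE)
  values <- with_seed(derive_seed(seed, "quant_dataset"), {
    lapply(seq_len(nrow(design)), function(i) {
      m <- design$mean[i]; cv <- design$cv[i]; n <- design$n[i]
      if (cv == 0 || m == 0) return(rep(m, n))
      s <- sqrt(log(1 + cv^2))
      stats::rlnorm(n, meanlog = log(m) - s^2 / 2, sdlog = s)
    })
  })
  out <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    data.frame(species = design$species[i], tissue = design$tissue[i],
               value = values[[i]], stringsAsFactors = FALSE)
  }))
  out$sample_id <- sprintf("s%03d", seq_len(nrow(out)))
  out[, c("sample_id", "species", "tissue", "value")]
}
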