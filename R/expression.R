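# Expression tables: RPKM normalization, group fold changes, per-gene
# tests, and volcano-table export.

#' RPKM normalization of a count matrix
#'
#' Reads (fragments) per kilobase of transcript per million mapped
#' fragments: `rpkm[g, s] = counts[g, s] / (length_kb[g] * library_size[s] / 1e6)`.
#' Invariant under joint rescaling of all counts and library sizes.
#'
#' @param counts Non-negative genes x samples matrix.
#' @param gene_lengths_kb Transcript lengths in kilobases, one per gene (> 0).
#' @param library_sizes Mapped fragments per sample (> 0); defaults to the
#'   column sums of `counts`.
#' @return Numeric matrix of RPKM values, same dimnames as `counts`.
#' @examples
#' rpkm_from_counts(matrix(10), gene_lengths_kb = 2, library_sizes = 1e6)  # 5
#' @export
rpkm_from_counts <- function(counts, gene_lengths_kb,
                             library_sizes = colSums(counts)) {
  if (!is.matrix(counts) || any(counts < 0)) {
    stop("'counts' must be a non-negative matrix", call. = FALSE)
  }
  if (length(gene_lengths_kb) != nrow(counts) || any(gene_lengths_kb <= 0)) {
    stop("'gene_lengths_kb' must be positive, one per gene", call. = FALSE)
  }
  if (length(library_sizes) != ncol(counts) || any(library_sizes <= 0)) {
    stop("'library_sizes' must be positive, one per sample", call. = FALSE)
  }
  sweep(counts / gene_lengths_kb, 2, library_sizes / 1e6, "/")
}

#' Fold change between two group means
#'
#' Ratio-scale fold change `(mean_A + pseudocount) / (mean_B + pseudocount)`
#' with its log2. The default pseudocount is 0: a zero denominator is an
#' error that advises adding one, because silently shifting means hides
#' upstream problems.
#'
#' @param mean_A,mean_B Group mean expressions (e.g. RPKM), vectorized.
#' @param pseudocount Non-negative constant added to both means.
#' @return Data frame: `mean_A`, `mean_B`, `fold_change`, `log2_fc`.
#' @examples
#' fold_change_from_means(36.86, 0.64)  # 57.59-fold, the Tnfaip6 magnitude
#' @export
fold_change_from_means <- function(mean_A, mean_B, pseudocount = 0) {
  if (pseudocount < 0) stop("'pseudocount' must be >= 0", call. = FALSE)
  if (any(mean_A < 0) || any(mean_B < 0)) {
    stop("means must be non-negative", call. = FALSE)
  }
  den <- mean_B + pseudocount
  if (any(den == 0)) {
    stop("zero denominator mean; supply a positive 'pseudocount'",
         call. = FALSE)
  }
  fc <- (mean_A + pseudocount) / den
  data.frame(mean_A = mean_A, mean_B = mean_B, fold_change = fc,
             log2_fc = log2(fc))
}

#' Per-gene fold changes between two sample groups of an expression matrix
#'
#' @param rpkm Genes x samples expression matrix (RPKM).
#' @param group_A,group_B Column names (or indices) of the two groups; the
#'   fold change is A over B.
#' @param pseudocount See [fold_change_from_means()].
#' @return Data frame with `gene_id`, `mean_A`, `mean_B`, `fold_change`,
#'   `log2_fc`.
#' @export
group_fold_change <- function(rpkm, group_A, group_B, pseudocount = 0) {
  if (length(group_A) == 0L || length(group_B) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  mA <- rowMeans(rpkm[, group_A, drop = FALSE])
  mB <- rowMeans(rpkm[, group_B, drop = FALSE])
  out <- fold_change_from_means(mA, mB, pseudocount)
  cbind(data.frame(gene_id = rownames(rpkm) %||%
                     sprintf("gene_%05d", seq_len(nrow(rpkm))),
                   stringsAsFactors = FALSE),
        out)
}

# Welch (or pooled) t-test robust to zero-variance degeneracies.
# Identical constant groups -> t = 0, p = 1; constant but different -> the
# smallest representable p with a warning.
.welch_t <- function(x, y, var_equal = FALSE) {
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(statistic = 0, p_value = 1, df = length(x) + length(y) - 2))
    }
    warning("zero within-group variance with unequal means; p floored")
    return(list(statistic = Inf, p_value = .Machine$double.xmin,
                df = length(x) + length(y) - 2))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Per-gene two-group differential-expression test
#'
#' Welch's two-sample t-test on `log2(RPKM + 1)` per gene (unequal variances
#' by default, matching unequal group sizes), two-sided.
#'
#' @param rpkm Genes x samples RPKM matrix.
#' @param group_A,group_B Column names/indices; each group needs >= 2
#'   samples.
#' @param var_equal Use the pooled-variance (classical Student) form.
#' @return Data frame: `gene_id`, `statistic`, `p_value`.
#' @export
per_gene_test <- function(rpkm, group_A, group_B, var_equal = FALSE) {
  if (length(group_A) < 2L || length(group_B) < 2L) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  lx <- log2(rpkm[, group_A, drop = FALSE] + 1)
  ly <- log2(rpkm[, group_B, drop = FALSE] + 1)
  res <- lapply(seq_len(nrow(rpkm)), function(g) {
    .welch_t(lx[g, ], ly[g, ], var_equal = var_equal)
  })
  data.frame(
    gene_id = rownames(rpkm) %||% sprintf("gene_%05d", seq_len(nrow(rpkm))),
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE
  )
}

#' Volcano table: fold change vs significance, with gene highlighting
#'
#' One row per gene with `log2_fc` and `-log10(p)`, plus a highlight flag
#' for a nominated gene list (e.g. the HA-family genes). Highlight ids
#' absent from the input produce a warning, not a row.
#'
#' @param summaries Data frame with columns `gene_id`, `log2_fc`, `p_value`
#'   (e.g. a join of [group_fold_change()] and [per_gene_test()]).
#' @param highlight Character vector of gene ids to flag.
#' @return Data frame: `gene_id`, `log2_fc`, `neg_log10_p`, `highlight`.
#' @export
volcano_table <- function(summaries, highlight = character(0)) {
  need <- c("gene_id", "log2_fc", "p_value")
  if (!is.data.frame(summaries) || nrow(summaries) == 0L ||
      !all(need %in% names(summaries))) {
    stop("'summaries' must be a non-empty data frame with columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  .check_prob(summaries$p_value, "p_value")
  missing_ids <- setdiff(highlight, summaries$gene_id)
  if (length(missing_ids)) {
    warning("highlight ids not in input: ",
            paste(missing_ids, collapse = ", "))
  }
  data.frame(
    gene_id = summaries$gene_id,
    log2_fc = summaries$log2_fc,
    neg_log10_p = -log10(summaries$p_value),
    highlight = summaries$gene_id %in% highlight,
    stringsAsFactors = FALSE
  )
}

#' Hyaluronan-family gene list
#'
#' Gene symbols for proteins with HA-synthase, hyaluronidase or HA-binding
#' roles (synthases Has1-3, hyaluronidases Hyal1-3 and Cemip/Cemip2,
#' receptors and binding proteins such as Cd44, Lyve1, Hmmr, Stab2, the
#' inter-alpha-trypsin-inhibitor heavy chains, Tnfaip6/Tsg6, and associated
#' signalling genes), as used to highlight HA metabolism genes in volcano
#' plots.
#'
#' @return Character vector of gene symbols.
#' @export
ha_family_genes <- function() {
  path <- system.file("extdata", "ha_family_genes.txt", package = "hamet",
                      mustWork = TRUE)
  readLines(path)
}

#' Lymph-node RPKM summary for the HA synthase/hyaluronidase panel
#'
#' Published group summaries (mean and SD of RPKM) for eight HA-family genes
#' in naked mole-rat (n = 4) versus mouse (n = 3) lymph nodes, shipped as a
#' worked example for [fold_change_from_means()]: Tnfaip6 and Hyal3 are
#' massively overexpressed in the naked mole-rat, Has2/Hyal1/Hyal2 mildly
#' higher in mouse.
#'
#' @return Data frame: `gene_id`, `nmr_mean`, `nmr_sd`, `mouse_mean`,
#'   `mouse_sd`, with attributes `n_nmr = 4`, `n_mouse = 3`.
#' @export
lymph_node_rpkm <- function() {
  path <- system.file("extdata", "lymph_node_rpkm_summary.tsv",
                      package = "hamet", mustWork = TRUE)
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  attr(out, "n_nmr") <- 4L
  attr(out, "n_mouse") <- 3L
  out
}
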