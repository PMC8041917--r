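#' Cross-tissue matrix of differential-expression summaries
#'
#' Container for a genes x tissues grid of per-tissue differential-expression
#' results: a p-value and a log fold-change per cell. Cells where a gene was
#' not measured in a tissue are `NA` in both matrices. This is the substrate
#' of the sign-weighted Fisher statistic ([weighted_fisher_statistic()]) and
#' its resampled null ([build_empirical_null()]).
#'
#' @param p Numeric matrix (genes x tissues) of p-values in (0, 1]; `NA`
#'   marks a missing cell.
#' @param logfc Numeric matrix of the same shape with log fold-changes
#'   (any base: only the sign is ever used by the statistic); `NA` pattern
#'   must match `p`.
#' @param gene_ids,tissue_ids Character vectors naming rows and columns;
#'   default to the dimnames of `p` or generated ids.
#'
#' @return An object of class `cross_tissue_matrix` with elements `p`,
#'   `logfc`, `gene_ids`, `tissue_ids`.
#' @export
cross_tissue_matrix <- function(p, logfc, gene_ids = NULL, tissue_ids = NULL) {
  if (!is.matrix(p) || !is.matrix(logfc)) {
    stop("'p' and 'logfc' must be matrices", call. = FALSE)
  }
  if (!identical(dim(p), dim(logfc))) {
    stop("'p' and 'logfc' must have identical dimensions", call. = FALSE)
  }
  if (ncol(p) < 1L) stop("at least one tissue is required", call. = FALSE)
  if (!identical(is.na(p), is.na(logfc))) {
    stop("missing-value patterns of 'p' and 'logfc' must match", call. = FALSE)
  }
  pv <- p[!is.na(p)]
  if (length(pv) && (any(pv <= 0) || any(pv > 1))) {
    stop("all non-missing p-values must lie in (0, 1]", call. = FALSE)
  }
  if (any(!is.finite(logfc[!is.na(logfc)]))) {
    stop("all non-missing logFC values must be finite", call. = FALSE)
  }
  gene_ids <- gene_ids %||% rownames(p) %||% sprintf("gene_%05d", seq_len(nrow(p)))
  tissue_ids <- tissue_ids %||% colnames(p) %||% sprintf("tissue_%02d", seq_len(ncol(p)))
  if (length(gene_ids) != nrow(p) || length(tissue_ids) != ncol(p)) {
    stop("id lengths must match matrix dimensions", call. = FALSE)
  }
  dimnames(p) <- dimnames(logfc) <- list(gene_ids, tissue_ids)
  structure(
    list(p = p, logfc = logfc,
         gene_ids = as.character(gene_ids),
         tissue_ids = as.character(tissue_ids)),
    class = "cross_tissue_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cross_tissue_matrix <- function(x, ...) {
  cat(sprintf("cross_tissue_matrix: %d genes x %d tissues (%d missing cells)\n",
              nrow(x$p), ncol(x$p), sum(is.na(x$p))))
  invisible(x)
}

#' Sign-weighted Fisher statistic for one gene across tissues
#'
#' Combines per-tissue differential-expression p-values into a single
#' cross-tissue statistic that is large only when small p-values share a
#' fold-change direction:
#' \deqn{F = \left| \sum_t \ln(p_t) \, \mathrm{sgn}(\mathrm{logFC}_t) \right|}
#' Opposite-signed evidence cancels, so a gene must be consistently up- or
#' down-regulated across tissues to score highly. A zero log fold-change has
#' sign 0 and contributes nothing.
#'
#' @param pvals Numeric vector of p-values in (0, 1] (one per tissue; remove
#'   missing cells before calling).
#' @param logfcs Numeric vector of log fold-changes, same length as `pvals`.
#'
#' @return A single non-negative number.
#' @examples
#' weighted_fisher_statistic(c(0.01, 0.04, 0.5), c(1.2, 0.3, -0.2))
#' @export
weighted_fisher_statistic <- function(pvals, logfcs) {
  if (length(pvals) != length(logfcs)) {
    stop("'pvals' and 'logfcs' must have the same length", call. = FALSE)
  }
  if (length(pvals) == 0L) {
    stop("need at least one (p, logFC) pair", call. = FALSE)
  }
  if (anyNA(pvals) || anyNA(logfcs)) {
    stop("missing values must be removed before calling", call. = FALSE)
  }
  .check_prob(pvals, "pvals")
  abs(sum(log(pvals) * sign(logfcs)))
}

#' Empirical null distribution of the cross-tissue statistic
#'
#' Estimates the distribution of the sign-weighted Fisher statistic under no
#' cross-tissue consistency, by resampling from the observed background of
#' all genes. In each round, `l` (p, logFC) cell pairs are drawn uniformly
#' with replacement from the pooled non-missing cells of the matrix
#' (preserving the marginal distributions of p and of the fold-change sign
#' while destroying within-gene consistency) and the statistic is recomputed.
#' An alternative scheme resamples each tissue column independently
#' (row-permutation within columns), which preserves per-tissue marginals.
#'
#' @param matrix A [cross_tissue_matrix()].
#' @param n_rounds Number of resampling rounds (the reference analysis used
#'   100,000).
#' @param seed Integer seed; the null is reproducible bit-for-bit.
#' @param scheme `"pooled"` (default) or `"per_tissue"`.
#' @param l Number of tissues per resampled pseudo-gene; defaults to the
#'   matrix's full tissue count.
#'
#' @return An object of class `null_distribution`: sorted `samples`,
#'   `n_rounds`, `l`, `seed`, `scheme`.
#' @export
build_empirical_null <- function(matrix, n_rounds = 100000L, seed = 1L,
                                 scheme = c("pooled", "per_tissue"),
                                 l = NULL) {
  stopifnot(inherits(matrix, "cross_tissue_matrix"))
  scheme <- match.arg(scheme)
  n_rounds <- .check_count(n_rounds, "n_rounds")
  l <- if (is.null(l)) ncol(matrix$p) else .check_count(l, "l")
  keep <- !is.na(matrix$p)
  if (!any(keep)) stop("matrix has no non-missing cells", call. = FALSE)

  samples <- with_seed(derive_seed(seed, "empirical_null"), {
    if (scheme == "pooled") {
      # signed log contribution of every observed cell, pooled
      s <- log(matrix$p[keep]) * sign(matrix$logfc[keep])
      idx <- sample.int(length(s), n_rounds * l, replace = TRUE)
      abs(rowSums(base::matrix(s[idx], nrow = n_rounds, ncol = l)))
    } else {
      cols <- lapply(seq_len(ncol(matrix$p)), function(j) {
        ok <- keep[, j]
        log(matrix$p[ok, j]) * sign(matrix$logfc[ok, j])
      })
      cols <- cols[lengths(cols) > 0]
      if (length(cols) < l) {
        stop("fewer tissues with data than requested 'l'", call. = FALSE)
      }
      acc <- base::matrix(0, nrow = n_rounds, ncol = l)
      for (j in seq_len(l)) {
        acc[, j] <- cols[[j]][sample.int(length(cols[[j]]), n_rounds,
                                         replace = TRUE)]
      }
      abs(rowSums(acc))
    }
  })
  structure(
    list(samples = sort(samples), n_rounds = n_rounds, l = l,
         seed = as.integer(seed), scheme = scheme),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null_distribution: %d rounds, l = %d, scheme = %s, median F = %.3f\n",
              x$n_rounds, x$l, x$scheme, stats::median(x$samples)))
  invisible(x)
}

#' Empirical cross-tissue p-value from a resampled null
#'
#' Converts an observed statistic to a p-value by its upper-tail rank in the
#' resampled null, with the add-one correction
#' \eqn{\rho = (1 + \#\{F_{null} \ge F\}) / (1 + n_{rounds})} so the result
#' is never 0 and its logarithm stays finite for gene-set aggregation.
#'
#' @param F Observed statistic(s), non-negative; vectorized.
#' @param null A `null_distribution` from [build_empirical_null()].
#'
#' @return p-value(s) in `[1/(n_rounds+1), 1]`.
#' @export
empirical_pvalue <- function(F, null) {
  stopifnot(inherits(null, "null_distribution"))
  if (anyNA(F) || any(F < 0)) {
    stop("'F' must be non-negative and non-missing", call. = FALSE)
  }
  n <- null$n_rounds
  # samples are sorted; count of samples >= F via rank of F with left-open
  # intervals (ties on F count into the tail)
  n_ge <- n - findInterval(F, null$samples, left.open = TRUE)
  (1 + n_ge) / (1 + n)
}

#' Unweighted Fisher aggregation over a gene set
#'
#' Combines the per-gene cross-tissue p-values of a gene set with Fisher's
#' method: \eqn{\mathcal{F} = \sum_g \ln(\rho_g)}, and converts
#' \eqn{-2\mathcal{F}} to a combined p-value via the chi-square distribution
#' with \eqn{2k} degrees of freedom (treating each \eqn{\rho} as uniform
#' under the null).
#'
#' @param rhos Per-gene p-values in (0, 1].
#' @param gene_ids Optional gene names for the result.
#'
#' @return A list of class `geneset_result`: `gene_ids`, `script_F` (the sum
#'   of logs, always <= 0), `p_geneset`, `k`, `method`.
#' @examples
#' aggregate_geneset(c(0.5, 0.5))  # p = 0.596
#' @export
aggregate_geneset <- function(rhos, gene_ids = NULL) {
  .check_prob(rhos, "rhos")
  k <- length(rhos)
  script_F <- sum(log(rhos))
  p <- stats::pchisq(-2 * script_F, df = 2 * k, lower.tail = FALSE)
  structure(
    list(gene_ids = gene_ids, script_F = script_F,
         p_geneset = max(p, .Machine$double.xmin), k = k,
         method = "fisher_chisq"),
    class = "geneset_result"
  )
}

#' @export
print.geneset_result <- function(x, ...) {
  cat(sprintf("geneset_result: k = %d, sum(ln rho) = %.4f, p = %.4g\n",
              x$k, x$script_F, x$p_geneset))
  invisible(x)
}

#' Full cross-tissue differential-expression aggregation
#'
#' Runs the whole per-gene pipeline on a cross-tissue matrix: the
#' sign-weighted Fisher statistic per gene over its non-missing tissues, one
#' shared empirical null resampled from the full matrix, an empirical
#' cross-tissue p-value per gene, significance calls at `alpha`, and the
#' unweighted Fisher aggregate over a nominated gene set.
#'
#' The shared null is built at the full tissue count; for genes with missing
#' tissues, `per_gene_null = TRUE` instead builds one null per distinct
#' tissue count so each gene is ranked against pseudo-genes of its own size.
#'
#' @param matrix A [cross_tissue_matrix()].
#' @param geneset Character vector of gene ids to aggregate (must all be in
#'   the matrix); `NULL` skips the gene-set step.
#' @param alpha Per-gene significance threshold on the empirical p-value
#'   (default 0.01).
#' @param n_rounds Resampling rounds for the null (default 100,000).
#' @param seed Integer seed.
#' @param scheme Resampling scheme, see [build_empirical_null()].
#' @param per_gene_null Build a separate null for each distinct number of
#'   tissues observed (default `FALSE`: one full-width null).
#'
#' @return A list of class `cross_tissue_result`: `genes` (data.frame with
#'   gene_id, F, rho, n_tissues_used, significant), `geneset`
#'   (a `geneset_result` or `NULL`), `null`, `alpha`.
#' @export
run_cross_tissue_analysis <- function(matrix, geneset = NULL, alpha = 0.01,
                                      n_rounds = 100000L, seed = 1L,
                                      scheme = c("pooled", "per_tissue"),
                                      per_gene_null = FALSE) {
  stopifnot(inherits(matrix, "cross_tissue_matrix"))
  scheme <- match.arg(scheme)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be a single number in (0, 1)", call. = FALSE)
  }
  if (!is.null(geneset)) {
    unknown <- setdiff(geneset, matrix$gene_ids)
    if (length(unknown)) {
      stop("gene ids not in matrix: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }

  keep <- !is.na(matrix$p)
  n_used <- rowSums(keep)
  if (any(n_used == 0L)) {
    stop("genes with no measured tissue: ",
         paste(utils::head(matrix$gene_ids[n_used == 0L], 5), collapse = ", "),
         call. = FALSE)
  }
  signed <- log(matrix$p) * sign(matrix$logfc)
  signed[!keep] <- 0
  F_obs <- abs(rowSums(signed))

  if (per_gene_null) {
    rho <- numeric(length(F_obs))
    for (li in sort(unique(n_used))) {
      null_l <- build_empirical_null(matrix, n_rounds = n_rounds, seed = seed,
                                     scheme = scheme, l = li)
      sel <- n_used == li
      rho[sel] <- empirical_pvalue(F_obs[sel], null_l)
    }
    null <- build_empirical_null(matrix, n_rounds = n_rounds, seed = seed,
                                 scheme = scheme)
  } else {
    null <- build_empirical_null(matrix, n_rounds = n_rounds, seed = seed,
                                 scheme = scheme)
    rho <- empirical_pvalue(F_obs, null)
  }

  genes <- data.frame(
    gene_id = matrix$gene_ids,
    F = unname(F_obs),
    rho = unname(rho),
    n_tissues_used = unname(as.integer(n_used)),
    significant = unname(rho < alpha),
    stringsAsFactors = FALSE
  )
  gs <- NULL
  if (!is.null(geneset)) {
    sel <- match(geneset, genes$gene_id)
    gs <- aggregate_geneset(genes$rho[sel], gene_ids = geneset)
  }
  structure(list(genes = genes, geneset = gs, null = null, alpha = alpha),
            class = "cross_tissue_result")
}

#' @export
print.cross_tissue_result <- function(x, ...) {
  cat(sprintf("cross_tissue_result: %d genes, %d significant at alpha = %g\n",
              nrow(x$genes), sum(x$genes$significant), x$alpha))
  if (!is.null(x$geneset)) print(x$geneset)
  invisible(x)
}
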