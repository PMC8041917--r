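# Plain-text interchange: long-format TSV for cross-tissue tables, CSV for
# elution profiles, calibrations and quantification records, YAML/JSON for
# configs, and JSON provenance records for pipeline runs.

#' Read and write cross-tissue tables as long-format TSV
#'
#' The canonical interchange format is long (one row per gene x tissue cell:
#' `gene_id`, `tissue_id`, `pvalue`, `logfc`), which represents missing
#' cells simply by absent rows.
#'
#' @param path File path.
#' @param matrix A [cross_tissue_matrix()].
#' @return `read_cross_tissue_tsv` returns a `cross_tissue_matrix`;
#'   `write_cross_tissue_tsv` returns `path` invisibly.
#' @export
read_cross_tissue_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "tissue_id", "pvalue", "logfc")
  if (!all(need %in% names(df))) {
    stop("expected columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  genes <- unique(df$gene_id)
  tissues <- unique(df$tissue_id)
  p <- matrix(NA_real_, length(genes), length(tissues),
              dimnames = list(genes, tissues))
  lfc <- p
  gi <- match(df$gene_id, genes)
  ti <- match(df$tissue_id, tissues)
  p[cbind(gi, ti)] <- df$pvalue
  lfc[cbind(gi, ti)] <- df$logfc
  cross_tissue_matrix(p, lfc, gene_ids = genes, tissue_ids = tissues)
}

#' @rdname read_cross_tissue_tsv
#' @export
write_cross_tissue_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "cross_tissue_matrix"))
  keep <- !is.na(matrix$p)
  idx <- which(keep, arr.ind = TRUE)
  df <- data.frame(
    gene_id = matrix$gene_ids[idx[, 1]],
    tissue_id = matrix$tissue_ids[idx[, 2]],
    pvalue = matrix$p[keep],
    logfc = matrix$logfc[keep],
    stringsAsFactors = FALSE
  )
  df <- df[order(match(df$gene_id, matrix$gene_ids),
                 match(df$tissue_id, matrix$tissue_ids)), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write SEC elution profiles as CSV
#'
#' Columns: `fraction_index`, `volume_ul`, `concentration`.
#'
#' @param path File path.
#' @param profile An [elution_profile()].
#' @return `read_elution_csv` returns an `elution_profile`;
#'   `write_elution_csv` returns `path` invisibly.
#' @export
read_elution_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fraction_index", "volume_ul", "concentration")
  if (!all(need %in% names(df))) {
    stop("expected columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  df <- df[order(df$fraction_index), ]
  elution_profile(df$concentration,
                  fraction_volume_ul = df$volume_ul[1])
}

#' @rdname read_elution_csv
#' @export
write_elution_csv <- function(profile, path) {
  stopifnot(inherits(profile, "elution_profile"))
  utils::write.csv(
    data.frame(fraction_index = profile$fraction_index,
               volume_ul = profile$fraction_volume_ul,
               concentration = profile$concentration),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a simulation/run configuration from YAML or JSON
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml, .yml or .json", call. = FALSE)
  }
}

#' Write a JSON provenance record for a pipeline step
#'
#' Records the inputs, parameters, seed and package version that produced a
#' set of artifacts, so any output directory can be reproduced bit-for-bit.
#'
#' @param path Output JSON path.
#' @param step Name of the pipeline step.
#' @param params Named list of parameters (including the seed).
#' @param inputs,outputs Character vectors of file paths.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, step, params = list(),
                             inputs = character(0), outputs = character(0)) {
  rec <- list(
    step = step,
    params = params,
    inputs = inputs,
    outputs = outputs,
    package = "hamet",
    version = as.character(utils::packageVersion("hamet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
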