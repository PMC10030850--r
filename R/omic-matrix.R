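#' Omic feature matrix
#'
#' A samples-by-features numeric matrix tagged with its omic kind. The four
#' kinds mirror the pipeline's factors: `F1_mrna` (FPKM-like mRNA, >= 0),
#' `F2_mirna` (RPKM-like miRNA, >= 0), `F3_methylation` (beta values in
#' \[0, 1\], possibly missing), `F4_protein` (real-valued RPPA, possibly
#' missing). Missing entries are `NA`.
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   features in columns (colnames = feature ids)
#' @param kind one of `"F1_mrna"`, `"F2_mirna"`, `"F3_methylation"`,
#'   `"F4_protein"`
#' @return an `omic_matrix` object
#' @export
omic_matrix <- function(values,
                        kind = c("F1_mrna", "F2_mirna", "F3_methylation",
                                 "F4_protein")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop_omics("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_omics("values must carry sample rownames and feature colnames")
  if (anyDuplicated(rownames(values)))
    stop_omics("duplicate sample ids")
  if (anyDuplicated(colnames(values)))
    stop_omics("duplicate feature ids")
  obs <- values[!is.na(values)]
  if (kind %in% c("F1_mrna", "F2_mirna") && any(obs < 0))
    stop_omics("%s values must be non-negative", kind)
  if (kind == "F3_methylation" && any(obs < 0 | obs > 1))
    stop_omics("methylation beta values must lie in [0, 1]")
  structure(list(values = values, kind = kind), class = "omic_matrix")
}

#' @export
print.omic_matrix <- function(x, ...) {
  cat(sprintf("<omic_matrix %s: %d samples x %d features, %.1f%% missing>\n",
              x$kind, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.omic_matrix <- function(x) dim(x$values)

sample_ids <- function(m) rownames(m$values)
feature_ids <- function(m) colnames(m$values)

#' Read an omic matrix from delimited text
#'
#' @param path TSV/CSV path (first column sample id, header = feature ids,
#'   missing entries empty or "NA")
#' @param kind omic kind, see [omic_matrix()]
#' @param sep field separator
#' @return an `omic_matrix`
#' @export
read_omic_matrix <- function(path, kind, sep = "\t") {
  omic_matrix(read_matrix_tsv(path, sep = sep), kind = kind)
}
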