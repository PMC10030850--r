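#' @useDynLib omicsubtyper, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats kmeans prcomp sd var fisher.test p.adjust pf ptukey
#'   pchisq runif rnorm rexp rbinom quantile predict glm binomial plogis
#'   coef median aggregate
#' @importFrom utils head modifyList read.delim write.table
NULL

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded internals do not
#' perturb the global random stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministic, stage-independent streams: a small string hash of the stage
#' name is folded into the master seed modulo 2^31 - 1.
#'
#' @param master integer master seed
#' @param stage character stage name
#' @return integer seed in `[1, 2^31 - 1]`
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 131 + cp) %% 2147483647
  as.integer((abs(master) %% 2147483647 + h * 2654435 + 12345) %% 2147483646 + 1)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples.
#'
#' @param a,b label vectors of equal length
#' @return ARI in `[-1, 1]`; 1 for identical partitions (up to relabeling)
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(0)
  (sum_ij - expected) / (maxidx - expected)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_omics <- function(...) stop(sprintf(...), call. = FALSE)

#' Read a delimited samples-in-rows matrix
#'
#' First column holds sample identifiers, header row holds feature
#' identifiers; empty strings and "NA" are missing.
#'
#' @param path TSV/CSV file path
#' @param sep field separator (default tab)
#' @return numeric matrix with sample rownames and feature colnames
#' @export
read_matrix_tsv <- function(path, sep = "\t") {
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   na.strings = c("", "NA"), stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a samples-in-rows matrix as TSV
#'
#' @param m matrix with rownames
#' @param path output path
#' @param id_col name of the identifier column
#' @return `path`, invisibly
#' @export
write_matrix_tsv <- function(m, path, id_col = "sample_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
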