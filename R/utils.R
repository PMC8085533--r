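#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic entry points funnel
# through this so nothing in the package touches global RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from a master seed; keeps every derived
# seed inside 32-bit integer range.
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 1000003L * seq_len(n)) %% .Machine$integer.max
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items.
#' Used to compare detected co-expression modules with planted ground
#' truth; label 0 (unassigned) is treated as an ordinary class.
#'
#' @param a,b integer or factor vectors of equal length.
#' @return A scalar in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Read and write tab-separated tables
#'
#' Thin wrappers fixing the conventions used throughout the pipeline:
#' tab-separated, header row, no quoting, no row names. Expression
#' matrices carry their gene ids in the first column.
#'
#' @param path file path.
#' @param x data.frame to write.
#' @return `read_tsv_table` returns a data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an expression matrix as TSV
#'
#' @param mat numeric matrix, genes in rows (rownames), samples in columns.
#' @param path file path.
#' @return `read_expression_tsv` returns a numeric matrix with dimnames.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_table(df, path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv_table(path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  mat
}

# Pearson correlation p-value via the t approximation,
# t = r * sqrt(n - 2) / sqrt(1 - r^2), two-sided.
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt(pmax(n - 2, 0)) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tt), df = n - 2)
}
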