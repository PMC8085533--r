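#' Observed module preservation statistics
#'
#' For each reference module, computes a reduced battery capturing the two
#' aspects of preservation: density (mean intramodular adjacency of the
#' module's genes in the test network) and connectivity pattern
#' (correlation of intramodular connectivities kIM between datasets, and
#' correlation of the vectorized intramodular correlation matrices).
#'
#' @param ref_expr,test_expr genes x samples matrices (reference and test
#'   dataset); genes matched by rowname.
#' @param labels named integer module labels from the reference network
#'   (0 ignored).
#' @param beta soft power used to form adjacencies in both datasets.
#' @param min_size modules with fewer than this many genes shared between
#'   the datasets are skipped with a warning.
#' @return data.frame: module, n_genes, density, cor_kim, cor_cor.
#' @export
preservation_stats <- function(ref_expr, test_expr, labels, beta = 14,
                               min_size = 10L) {
  mods <- sort(unique(labels[labels > 0L]))
  common <- intersect(rownames(ref_expr), rownames(test_expr))
  rows <- lapply(mods, function(m) {
    genes <- intersect(names(labels)[labels == m], common)
    if (length(genes) < min_size) {
      warning("module ", m, " has fewer than ", min_size,
              " genes present in both datasets; skipped")
      return(NULL)
    }
    st <- module_pres_stats(ref_expr[genes, , drop = FALSE],
                            test_expr[genes, , drop = FALSE], beta)
    data.frame(module = m, n_genes = length(genes), density = st["density"],
               cor_kim = st["cor_kim"], cor_cor = st["cor_cor"],
               row.names = NULL)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

# Density and connectivity statistics for one gene set.
module_pres_stats <- function(ref_sub, test_sub, beta) {
  cr <- stats::cor(t(ref_sub))
  ct <- stats::cor(t(test_sub))
  ar <- abs(cr)^beta; diag(ar) <- 1
  at <- abs(ct)^beta; diag(at) <- 1
  off <- upper.tri(at)
  density <- mean(at[off])
  kim_ref <- colSums(ar) - 1
  kim_test <- colSums(at) - 1
  c(density = density,
    cor_kim = stats::cor(kim_ref, kim_test),
    cor_cor = stats::cor(cr[off], ct[off]))
}

#' Permutation Z statistics and median rank for module preservation
#'
#' For each module, `n_perm` random gene sets of identical size are drawn
#' uniformly from the genes shared by both datasets, the preservation
#' statistics are recomputed on each, and each observed statistic is
#' standardized against its permutation distribution:
#' Z = (observed - mean_perm) / sd_perm. Z_density is the density Z;
#' Z_connectivity is the median of the two connectivity Zs; Zsummary is
#' their mean. Values above 10 are conventionally read as strong evidence
#' of preservation, 2-10 as moderate. medianRank is the median, across the
#' three statistics, of the module's rank among all modules (rank 1 = most
#' preserved); unlike Zsummary it is largely insensitive to module size.
#'
#' @inheritParams preservation_stats
#' @param n_perm number of permutations (minimum 30 enforced).
#' @param seed integer seed for the permutation draws.
#' @return object of class `preservation_report`: data.frame with module,
#'   n_genes, observed statistics, Z_density, Z_connectivity, Zsummary,
#'   medianRank, and an `n_perm` attribute.
#' @export
module_preservation <- function(ref_expr, test_expr, labels, beta = 14,
                                n_perm = 200L, seed = 1L, min_size = 10L) {
  if (n_perm < 30L) stop("n_perm must be at least 30")
  obs <- preservation_stats(ref_expr, test_expr, labels, beta, min_size)
  if (is.null(obs) || nrow(obs) == 0L) stop("no scorable modules")
  common <- intersect(rownames(ref_expr), rownames(test_expr))
  stat_names <- c("density", "cor_kim", "cor_cor")

  zmat <- matrix(NA_real_, nrow(obs), 3L,
                 dimnames = list(NULL, stat_names))
  with_seed(seed, {
    for (i in seq_len(nrow(obs))) {
      sz <- obs$n_genes[i]
      perm <- matrix(NA_real_, n_perm, 3L)
      for (p in seq_len(n_perm)) {
        genes <- sample(common, sz)
        perm[p, ] <- module_pres_stats(ref_expr[genes, , drop = FALSE],
                                       test_expr[genes, , drop = FALSE],
                                       beta)
      }
      mu <- colMeans(perm)
      sdev <- apply(perm, 2L, stats::sd)
      z <- (as.numeric(obs[i, stat_names]) - mu) / sdev
      if (any(sdev == 0)) {
        warning("zero permutation sd for module ", obs$module[i],
                "; Z set to 0")
        z[sdev == 0] <- 0
      }
      zmat[i, ] <- z
    }
  })
  ranks <- apply(-as.matrix(obs[, stat_names]), 2L, rank,
                 ties.method = "average")
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = 1L)
  out <- obs
  out$Z_density <- zmat[, "density"]
  out$Z_connectivity <- apply(zmat[, c("cor_kim", "cor_cor"), drop = FALSE],
                              1L, stats::median)
  out$Zsummary <- (out$Z_density + out$Z_connectivity) / 2
  out$medianRank <- apply(ranks, 1L, stats::median)
  attr(out, "n_perm") <- n_perm
  class(out) <- c("preservation_report", class(out))
  out
}
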