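#' Network construction parameters
#'
#' Bundles the tunable knobs of the weighted co-expression stage. The
#' defaults mirror a standard microarray analysis: unsigned soft power 14,
#' minimum module size 30, deep-split 2, eigengene merge cut height 0.2,
#' and a variance filter keeping the top 25% most variable genes.
#'
#' @param soft_power soft-threshold exponent beta (positive integer); set
#'   to `NA` to let [build_network()] choose it by scale-free fit.
#' @param min_module_size smallest allowed module (>= 3).
#' @param deep_split integer 1-4 controlling how finely the dendrogram is
#'   cut: the static cut height is the (65 - 5 * deep_split)-th percentile
#'   of the merge heights.
#' @param merge_cut_height eigengene dissimilarity below which modules are
#'   merged, in (0, 1).
#' @param variance_quantile quantile of per-gene variance below which
#'   genes are discarded (0.75 keeps the top 25%; 0 disables filtering).
#' @param rsq_target minimum signed scale-free fit R^2 sought by the
#'   soft-power scan.
#' @return an object of class `network_params` (named list).
#' @export
network_params <- function(soft_power = 14L, min_module_size = 30L,
                           deep_split = 2L, merge_cut_height = 0.2,
                           variance_quantile = 0.75, rsq_target = 0.9) {
  stopifnot(is.na(soft_power) || soft_power >= 1,
            min_module_size >= 3L,
            deep_split >= 1L, deep_split <= 4L,
            merge_cut_height > 0, merge_cut_height < 1,
            variance_quantile >= 0, variance_quantile < 1)
  structure(list(soft_power = soft_power,
                 min_module_size = as.integer(min_module_size),
                 deep_split = as.integer(deep_split),
                 merge_cut_height = merge_cut_height,
                 variance_quantile = variance_quantile,
                 rsq_target = rsq_target),
            class = "network_params")
}

#' Keep the most variable genes
#'
#' @param mat genes x samples matrix.
#' @param quantile variance quantile defining the cut; genes with variance
#'   greater than or equal to the cut are retained, so ties at the
#'   threshold all survive. 0 disables filtering.
#' @return the filtered matrix.
#' @export
variance_filter <- function(mat, quantile = 0.75) {
  if (quantile <= 0) return(mat)
  stopifnot(nrow(mat) >= 4L)
  v <- apply(mat, 1L, stats::var)
  cut <- stats::quantile(v, quantile, names = FALSE)
  mat[v >= cut, , drop = FALSE]
}

#' Unsigned weighted adjacency
#'
#' a_ij = |cor(x_i, x_j)|^beta with unit diagonal.
#'
#' @param mat genes x samples matrix.
#' @param beta soft-threshold power (>= 1).
#' @return symmetric adjacency matrix with entries in \[0, 1\].
#' @export
adjacency_matrix <- function(mat, beta) {
  stopifnot(beta >= 1)
  v <- apply(mat, 1L, stats::var)
  if (any(v == 0)) {
    stop("zero-variance gene(s): ",
         paste(rownames(mat)[v == 0], collapse = ", "))
  }
  a <- abs(stats::cor(t(mat)))^beta
  diag(a) <- 1
  a
}

#' Signed scale-free topology fit
#'
#' Bins the connectivities k_i = sum_j a_ij (diagonal excluded) into
#' `n_bins` equal-width bins, regresses log10(frequency) on log10(mean k)
#' over non-empty bins, and returns -sign(slope) * R^2, so a decaying
#' power-law degree distribution scores near +1.
#'
#' @param a adjacency matrix.
#' @param n_bins number of connectivity bins.
#' @return signed R^2 scalar (0, with a warning, if all k are equal).
#' @export
scale_free_fit <- function(a, n_bins = 10L) {
  k <- colSums(a) - diag(a)
  if (max(k) - min(k) < .Machine$double.eps^0.5) {
    warning("all connectivities equal; scale-free fit undefined")
    return(0)
  }
  bins <- cut(k, breaks = n_bins, include.lowest = TRUE)
  dk <- tapply(k, bins, mean)
  pk <- tapply(k, bins, length) / length(k)
  ok <- !is.na(dk) & dk > 0
  dk <- dk[ok]; pk <- pk[ok]
  if (length(dk) < 3L) {
    warning("too few occupied bins for a scale-free fit")
    return(0)
  }
  fit <- stats::lm(log10(pk) ~ log10(dk))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2L]
  -sign(slope) * r2
}

#' Choose the soft-threshold power by scale-free fit
#'
#' Returns the smallest candidate power whose signed fit exceeds
#' `rsq_target`; when none reaches it, the argmax power is returned with a
#' warning (as done in practice when a cohort tops out below the target).
#'
#' @param mat genes x samples matrix.
#' @param candidates candidate powers, scanned in order.
#' @param rsq_target signed R^2 threshold.
#' @param n_bins bins for [scale_free_fit()].
#' @return list with `power`, `fit_table` (data.frame power / rsq /
#'   mean_k), and `reached_target`.
#' @export
pick_soft_power <- function(mat, candidates = 1:20, rsq_target = 0.9,
                            n_bins = 10L) {
  stopifnot(length(candidates) >= 1L)
  cors <- abs(stats::cor(t(mat)))
  rsq <- numeric(length(candidates))
  mean_k <- numeric(length(candidates))
  chosen <- NA_integer_
  for (i in seq_along(candidates)) {
    a <- cors^candidates[i]
    diag(a) <- 1
    rsq[i] <- suppressWarnings(scale_free_fit(a, n_bins = n_bins))
    mean_k[i] <- mean(colSums(a) - 1)
    if (is.na(chosen) && rsq[i] > rsq_target) chosen <- candidates[i]
  }
  reached <- !is.na(chosen)
  if (!reached) {
    chosen <- candidates[which.max(rsq)]
    warning(sprintf(
      "no candidate power reached signed R^2 > %.2f; using %d (R^2 = %.2f)",
      rsq_target, chosen, max(rsq)))
  }
  list(power = chosen,
       fit_table = data.frame(power = candidates, rsq = rsq,
                              mean_k = mean_k),
       reached_target = reached)
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) /
#' (min(k_i, k_j) + 1 - a_ij), with k the connectivity excluding the
#' diagonal; TOM_ii = 1. The clustering dissimilarity is 1 - TOM.
#'
#' @param a symmetric adjacency with unit diagonal.
#' @return TOM similarity matrix.
#' @export
tom_similarity <- function(a) {
  k <- colSums(a) - diag(a)
  num <- a %*% a - 2 * a + a  # sum_{u != i,j} a_iu a_uj + a_ij (diag = 1)
  kmin <- outer(k, k, pmin)
  tom <- num / (kmin + 1 - a)
  diag(tom) <- 1
  tom
}

#' Detect modules by average-linkage clustering of the TOM dissimilarity
#'
#' Genes are clustered by average linkage on `1 - TOM` and the tree is cut
#' at a static height anchored at the (65 - 5 * deep_split)-th percentile
#' of the merge heights and snapped upward to the first wide gap in the
#' sorted heights (a gap at least ten times the median merge-height gap).
#' Within-module merges happen low in the tree and noise chaining high;
#' the percentile anchor places the cut in the module region regardless
#' of how the soft power compresses all heights toward 1, and the
#' gap-snapping moves it to the module/noise boundary, so complete
#' modules are not split by an arbitrary quantile (when no wide gap
#' exists, as in structureless data, the plain percentile is used and the
#' resulting splinters fall below the size floor). Higher `deep_split`
#' lowers the anchor and so splits more finely. Clusters smaller than
#' `min_module_size` get label 0 (unassigned); surviving modules are
#' renumbered by decreasing size, so module 1 is always the largest.
#'
#' @param diss_tom dissimilarity matrix (1 - TOM), entries in \[0, 1\].
#' @param params a [network_params()] object.
#' @return named integer vector of module labels (0 = unassigned).
#' @export
detect_modules <- function(diss_tom, params = network_params()) {
  n <- nrow(diss_tom)
  ids <- rownames(diss_tom)
  if (is.null(ids)) ids <- sprintf("g%d", seq_len(n))
  if (n < params$min_module_size) {
    return(stats::setNames(integer(n), ids))
  }
  tree <- stats::hclust(stats::as.dist(diss_tom), method = "average")
  h <- sort(tree$height)
  anchor <- stats::quantile(h, (65 - 5 * params$deep_split) / 100,
                            names = FALSE)
  cut_h <- snap_to_gap(h, anchor)
  raw <- stats::cutree(tree, h = cut_h)
  relabel_by_size(raw, params$min_module_size, ids)
}

# First wide gap (>= 10x the median gap) in the sorted heights at or
# above `anchor`; returns its midpoint, or `anchor` when none exists.
snap_to_gap <- function(h, anchor, factor = 10) {
  gaps <- diff(h)
  if (length(gaps) == 0L) return(anchor)
  wide <- stats::median(gaps) * factor
  for (i in seq_along(gaps)) {
    if (h[i] >= anchor && gaps[i] >= wide) {
      return((h[i] + h[i + 1L]) / 2)
    }
  }
  anchor
}

# Renumber cluster labels by decreasing size, zeroing clusters below the
# minimum size; ties broken by the smaller original label.
relabel_by_size <- function(raw, min_size, ids = names(raw)) {
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  out <- integer(length(raw))
  if (length(keep)) {
    ord <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(ord)) out[raw == as.integer(ord[i])] <- i
  }
  stats::setNames(out, ids)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' gene-standardized expression, scaled to unit variance across samples
#' and sign-oriented so that the mean correlation of member genes with the
#' eigengene is non-negative (ties resolved toward positive correlation
#' with the module's first gene).
#'
#' @param mat genes x samples matrix.
#' @param labels integer module labels aligned to rows (0 ignored).
#' @return samples x modules matrix; column names `ME1`, `ME2`, ...
#' @export
module_eigengenes <- function(mat, labels) {
  mods <- sort(unique(labels[labels > 0L]))
  if (length(mods) == 0L) stop("no modules to summarize")
  me <- sapply(mods, function(m) {
    x <- mat[labels == m, , drop = FALSE]
    if (nrow(x) < 2L) stop("module ", m, " has fewer than 2 genes")
    xs <- t(scale(t(x)))  # standardize each gene across samples
    if (any(!is.finite(xs))) {
      stop("module ", m, " contains constant gene(s)")
    }
    sv <- svd(xs, nu = 0L, nv = 1L)
    v <- sv$v[, 1L]
    v <- v / stats::sd(v)
    mm <- stats::cor(t(x), v)
    s <- mean(mm)
    if (s < 0 || (s == 0 && mm[1L] < 0)) v <- -v
    v
  })
  rownames(me) <- colnames(mat)
  colnames(me) <- paste0("ME", mods)
  me
}

#' Merge modules with similar eigengenes
#'
#' Iteratively clusters eigengenes by average linkage on 1 - cor(ME) and
#' merges modules joined below `cut`, recomputing eigengenes until the
#' module count stabilizes. Labels are renumbered by decreasing size after
#' each pass.
#'
#' @param mat genes x samples matrix.
#' @param labels integer module labels (0 = unassigned, untouched).
#' @param cut eigengene dissimilarity threshold; 0 disables merging.
#' @return merged label vector.
#' @export
merge_similar_modules <- function(mat, labels, cut = 0.2) {
  if (cut <= 0) return(labels)
  repeat {
    mods <- sort(unique(labels[labels > 0L]))
    if (length(mods) < 2L) return(labels)
    me <- module_eigengenes(mat, labels)
    diss <- 1 - stats::cor(me)
    tree <- stats::hclust(stats::as.dist(diss), method = "average")
    grp <- stats::cutree(tree, h = cut)
    if (max(grp) == length(mods)) return(labels)
    new_labels <- labels
    for (g in unique(grp)) {
      members <- mods[grp == g]
      new_labels[labels %in% members] <- min(members)
    }
    # renumber by size, keeping every merged module (size floor 1 here:
    # merging never unassigns genes)
    new_labels <- relabel_by_size(new_labels, 1L, names(labels))
    labels <- new_labels
  }
}

#' Module membership and gene significance
#'
#' MM_gm is the Pearson correlation of gene g with module m's eigengene
#' (kME); GS_g is the correlation of gene g with the binary trait,
#' reported both signed and in absolute value.
#'
#' @param mat genes x samples matrix.
#' @param me eigengene matrix from [module_eigengenes()].
#' @param trait 0/1 vector aligned to samples.
#' @return list with `mm` (genes x modules matrix), `gs` (absolute
#'   correlations) and `gs_signed`.
#' @export
membership_and_significance <- function(mat, me, trait) {
  if (stats::sd(trait) == 0) stop("trait has zero variance")
  mm <- stats::cor(t(mat), me)
  gs_signed <- drop(stats::cor(t(mat), trait))
  names(gs_signed) <- rownames(mat)
  list(mm = mm, gs = abs(gs_signed), gs_signed = gs_signed)
}

#' Module-trait association
#'
#' Pearson correlation of each eigengene with each trait column, with
#' two-sided p-values from t = r * sqrt(n - 2) / sqrt(1 - r^2).
#'
#' @param me eigengene matrix (samples x modules).
#' @param traits numeric vector or samples x traits matrix/data.frame.
#' @return data.frame: module, trait, r, p.
#' @export
module_trait_association <- function(me, traits) {
  if (is.null(dim(traits))) traits <- matrix(traits, ncol = 1L,
                                             dimnames = list(NULL, "trait"))
  traits <- as.matrix(traits)
  stopifnot(nrow(traits) == nrow(me), nrow(me) >= 4L)
  n <- nrow(me)
  r <- stats::cor(me, traits)
  out <- expand.grid(module = as.integer(sub("^ME", "", colnames(me))),
                     trait = colnames(traits), stringsAsFactors = FALSE)
  out$r <- as.vector(r)
  out$p <- as.vector(cor_pvalue(r, n))
  out
}

#' Build the full weighted co-expression network
#'
#' Runs the whole stage: variance filter, soft-power choice (if
#' `params$soft_power` is `NA`), adjacency, TOM, module detection,
#' eigengene merging, eigengenes, module membership, gene significance,
#' and module-trait association.
#'
#' @param mat genes x samples matrix.
#' @param trait 0/1 disease status aligned to samples.
#' @param params a [network_params()] object.
#' @param keep_matrices retain adjacency and TOM in the result (set
#'   `FALSE` to save memory in resampling loops).
#' @return object of class `coexnet`: list with genes, params, power,
#'   fit_table, labels, me, mm, gs, gs_signed, trait_table, connectivity,
#'   and (optionally) adjacency / tom.
#' @export
build_network <- function(mat, trait, params = network_params(),
                          keep_matrices = TRUE) {
  stopifnot(length(trait) == ncol(mat))
  mat <- variance_filter(mat, params$variance_quantile)
  power <- params$soft_power
  fit_table <- NULL
  if (is.na(power)) {
    pick <- pick_soft_power(mat, rsq_target = params$rsq_target)
    power <- pick$power
    fit_table <- pick$fit_table
  }
  a <- adjacency_matrix(mat, power)
  tom <- tom_similarity(a)
  labels <- detect_modules(1 - tom, params)
  labels <- merge_similar_modules(mat, labels, params$merge_cut_height)
  n_mod <- max(labels)
  if (n_mod == 0L) {
    warning("no modules detected")
    me <- NULL; mmgs <- list(mm = NULL, gs = NULL, gs_signed = NULL)
    tt <- NULL
  } else {
    me <- module_eigengenes(mat, labels)
    mmgs <- membership_and_significance(mat, me, trait)
    tt <- module_trait_association(me, trait)
  }
  out <- list(genes = rownames(mat), params = params, power = power,
              fit_table = fit_table, labels = labels, me = me,
              mm = mmgs$mm, gs = mmgs$gs, gs_signed = mmgs$gs_signed,
              trait_table = tt, trait = trait,
              connectivity = colSums(a) - 1, expr = mat)
  if (keep_matrices) {
    out$adjacency <- a
    out$tom <- tom
  }
  structure(out, class = "coexnet")
}

#' @export
print.coexnet <- function(x, ...) {
  n_mod <- max(x$labels)
  cat("Weighted co-expression network\n")
  cat(sprintf("  genes: %d   soft power: %s   modules: %d (unassigned: %d)\n",
              length(x$genes), x$power, n_mod, sum(x$labels == 0L)))
  if (!is.null(x$trait_table)) {
    top <- x$trait_table[which.max(abs(x$trait_table$r)), ]
    cat(sprintf("  top trait module: %d (r = %.3f, p = %.3g)\n",
                top$module, top$r, top$p))
  }
  invisible(x)
}
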