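#' ROC curve and AUC for a single marker
#'
#' AUC is computed by the Mann-Whitney formulation (probability that a
#' random case scores above a random control; ties get half credit),
#' which equals the trapezoidal area under the empirical ROC curve. The
#' full sensitivity/specificity curve is returned, and the operating
#' point is chosen by Youden's J = sensitivity + specificity - 1.
#'
#' @param values numeric marker values, one per sample.
#' @param labels 0/1 (or logical) class labels; 1 = positive/case.
#'   Higher values are assumed to indicate the positive class.
#' @return object of class `roc_result`: list with `auc`, `curve`
#'   (data.frame threshold / sensitivity / specificity), and
#'   `operating_point` (row of `curve` maximizing Youden's J).
#' @export
roc_auc <- function(values, labels) {
  labels <- as.integer(labels)
  stopifnot(length(values) == length(labels), all(labels %in% 0:1))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(values)  # midranks handle ties with half credit
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  # empirical curve: predict positive when value >= threshold
  thresholds <- c(sort(unique(values)), Inf)
  sens <- vapply(thresholds,
                 function(t) sum(values >= t & labels == 1L) / n_pos,
                 numeric(1))
  spec <- vapply(thresholds,
                 function(t) sum(values < t & labels == 0L) / n_neg,
                 numeric(1))
  curve <- data.frame(threshold = thresholds, sensitivity = sens,
                      specificity = spec)
  j <- sens + spec - 1
  op <- curve[which.max(j), ]
  structure(list(auc = auc, curve = curve, operating_point = op),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f; Youden point: threshold %.3g (sens %.2f, spec %.2f)\n",
              x$auc, x$operating_point$threshold,
              x$operating_point$sensitivity, x$operating_point$specificity))
  invisible(x)
}

#' Relative quantification by the 2^-ddCt method
#'
#' Replicate Ct values are averaged per (sample, gene); the target gene's
#' delta-Ct subtracts the reference gene's Ct in the same sample;
#' delta-delta-Ct subtracts the mean control-group delta-Ct; and the fold
#' change is 2^-ddCt, so control samples average approximately 1. Samples
#' missing a reference Ct are dropped with a warning.
#'
#' @param ct data.frame with columns sample_id, group, gene, ct and a
#'   logical is_reference column (or pass `reference_gene`).
#' @param reference_gene name of the normalizer gene (e.g. "GAPDH");
#'   defaults to the gene flagged by `is_reference`.
#' @param control_group value of `group` identifying control samples.
#' @return list with `per_sample` (data.frame: sample_id, group, gene,
#'   delta_ct, ddct, fold) and `per_group` (gene x group mean and sd of
#'   folds).
#' @export
ddct_fold_change <- function(ct, reference_gene = NULL,
                             control_group = "control") {
  need <- c("sample_id", "group", "gene", "ct")
  stopifnot(all(need %in% names(ct)))
  if (is.null(reference_gene)) {
    if (!"is_reference" %in% names(ct) || !any(ct$is_reference)) {
      stop("no reference gene flagged and none named")
    }
    reference_gene <- unique(ct$gene[ct$is_reference])
    stopifnot(length(reference_gene) == 1L)
  }
  if (!any(ct$group == control_group)) stop("control group is empty")

  # mean of replicate Cts per (sample, gene)
  agg <- stats::aggregate(ct ~ sample_id + group + gene, data = ct, FUN = mean)
  ref <- agg[agg$gene == reference_gene, c("sample_id", "ct")]
  tgt <- agg[agg$gene != reference_gene, , drop = FALSE]
  tgt$ref_ct <- ref$ct[match(tgt$sample_id, ref$sample_id)]
  if (any(is.na(tgt$ref_ct))) {
    bad <- unique(tgt$sample_id[is.na(tgt$ref_ct)])
    warning("dropping sample(s) without reference Ct: ",
            paste(bad, collapse = ", "))
    tgt <- tgt[!is.na(tgt$ref_ct), , drop = FALSE]
  }
  tgt$delta_ct <- tgt$ct - tgt$ref_ct
  ctrl_mean <- tapply(tgt$delta_ct[tgt$group == control_group],
                      tgt$gene[tgt$group == control_group], mean)
  tgt$ddct <- tgt$delta_ct - ctrl_mean[tgt$gene]
  tgt$fold <- 2^(-tgt$ddct)
  per_sample <- tgt[, c("sample_id", "group", "gene", "delta_ct",
                        "ddct", "fold")]
  rownames(per_sample) <- NULL
  per_group <- do.call(rbind, lapply(split(per_sample,
      list(per_sample$gene, per_sample$group), drop = TRUE),
    function(d) data.frame(gene = d$gene[1L], group = d$group[1L],
                           mean_fold = mean(d$fold),
                           sd_fold = stats::sd(d$fold),
                           stringsAsFactors = FALSE)))
  rownames(per_group) <- NULL
  list(per_sample = per_sample, per_group = per_group)
}
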