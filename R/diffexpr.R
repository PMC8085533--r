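#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as input, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  adj
}

# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); used to moment-match the prior degrees of freedom.
trigamma_inverse <- function(x, tol = 1e-8, max_iter = 100L) {
  if (x <= 0) return(Inf)
  # initial value from the asymptotic expansion trigamma(y) ~ 1/y
  y <- 0.5 + 1 / x
  for (i in seq_len(max_iter)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (-dif / y < tol) break
  }
  y
}

#' Two-sample Student's t-test
#'
#' Pooled-variance two-sided t by default; Welch optional. Returns t = 0,
#' p = 1 when both groups are constant and equal.
#'
#' @param x,y numeric vectors, each with at least 2 values.
#' @param pooled use the pooled-variance statistic (default); otherwise
#'   Welch's unequal-variance form.
#' @return list with `t`, `df`, `p`.
#' @export
student_t_test <- function(x, y, pooled = TRUE) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  n1 <- length(x); n2 <- length(y)
  d <- mean(x) - mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (se == 0) {
    if (d == 0) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(d) * Inf, df = df, p = 0))
  }
  tt <- d / se
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df = df))
}

#' Empirical-Bayes moderated t-test for two-group differential expression
#'
#' Per gene, the two-group linear model gives a residual variance s_g^2
#' with d = n1 + n2 - 2 degrees of freedom. A scaled inverse-chi-square
#' prior (d0, s0^2) is estimated from all genes by moment-matching the
#' log-variances (the mean and variance of log s_g^2 identify log s0^2 and
#' d0 via digamma/trigamma; d0 is found by Newton inversion of the
#' trigamma function). The posterior variance
#' s~_g^2 = (d0 s0^2 + d s_g^2) / (d0 + d) replaces s_g^2 in the t
#' statistic, which is referred to a t distribution with d0 + d degrees of
#' freedom; p-values are Benjamini-Hochberg adjusted.
#'
#' @param mat numeric matrix, genes x samples.
#' @param groups data.frame with columns `sample_id` and `status`
#'   (1 = case, 0 = control), or a 0/1 vector aligned to columns.
#' @param alpha significance level applied to the adjusted p (default
#'   0.05).
#' @param biotype optional named character vector of biotypes per gene.
#' @return data.frame: gene_id, biotype, log2_fold_change (case minus
#'   control mean), t_moderated, p_value, p_adjusted, is_DE; plus
#'   attributes `d0` and `s0_2`.
#' @export
moderated_t_test <- function(mat, groups, alpha = 0.05, biotype = NULL) {
  status <- if (is.data.frame(groups)) {
    groups$status[match(colnames(mat), groups$sample_id)]
  } else {
    groups
  }
  stopifnot(length(status) == ncol(mat), all(status %in% c(0, 1)))
  case <- status == 1
  n1 <- sum(case); n2 <- sum(!case)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 samples per group")

  m1 <- rowMeans(mat[, case, drop = FALSE])
  m2 <- rowMeans(mat[, !case, drop = FALSE])
  delta <- m1 - m2
  ss <- rowSums((mat[, case, drop = FALSE] - m1)^2) +
    rowSums((mat[, !case, drop = FALSE] - m2)^2)
  d <- n1 + n2 - 2
  s2 <- ss / d
  se_unit <- sqrt(1 / n1 + 1 / n2)

  pos <- s2 > 0
  if (!any(pos)) {
    warning("all genes have zero residual variance; ",
            "falling back to ordinary t on raw variances")
    d0 <- 0; s0_2 <- NA_real_
    s2_post <- s2
    df_total <- d
  } else {
    z <- log(s2[pos])
    e <- z - digamma(d / 2) + log(d / 2)
    evar <- stats::var(e) - trigamma(d / 2)
    if (!is.na(evar) && stats::var(z) < 1e-12) {
      # literally identical variances: the prior collapses onto the
      # common value and moderation is a no-op
      d0 <- Inf
      s0_2 <- exp(mean(z))
    } else if (is.na(evar) || evar <= 0) {
      d0 <- Inf
      s0_2 <- exp(mean(e))
    } else {
      d0 <- 2 * trigamma_inverse(evar)
      s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    }
    s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2)) else {
      (d0 * s0_2 + d * s2) / (d0 + d)
    }
    df_total <- d0 + d
  }

  tt <- delta / (sqrt(s2_post) * se_unit)
  tt[s2_post == 0 & delta == 0] <- 0
  p <- 2 * stats::pt(-abs(tt), df = df_total)
  p[is.infinite(tt)] <- 0
  padj <- bh_adjust(p)

  ids <- rownames(mat)
  if (is.null(ids)) ids <- sprintf("gene_%d", seq_len(nrow(mat)))
  bio <- if (is.null(biotype)) rep(NA_character_, length(ids)) else {
    unname(biotype[ids])
  }
  out <- data.frame(gene_id = ids, biotype = bio,
                    log2_fold_change = unname(delta),
                    t_moderated = unname(tt),
                    p_value = unname(p), p_adjusted = unname(padj),
                    is_DE = unname(padj < alpha),
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  out
}
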