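test_that("design invariants are enforced", {
  expect_error(synthetic_design(n_genes = 100, module_sizes = c(60, 60)),
               "exceeds")
  expect_error(synthetic_design(loading_range = c(0, 0.5)))
  expect_error(synthetic_design(trait_coupling = 1.2))
})

test_that("generation is deterministic given the seed and leaves RNG alone", {
  a <- generate_expression(synthetic_design(seed = 5L))
  set.seed(123); before <- .Random.seed
  b <- generate_expression(synthetic_design(seed = 5L))
  expect_identical(before, .Random.seed)
  expect_identical(a$expr, b$expr)
  expect_identical(a$truth, b$truth)
  c <- generate_expression(synthetic_design(seed = 6L))
  expect_false(identical(a$expr, c$expr))
})

test_that("background-only design yields uncorrelated genes", {
  d <- synthetic_design(n_genes = 40L, module_sizes = integer(0),
                        n_samples_case = 30L, n_samples_control = 30L,
                        trait_coupling = 0, seed = 2L)
  sim <- generate_expression(d)
  cm <- cor(t(sim$expr))
  off <- abs(cm[upper.tri(cm)])
  # |r| < 3/sqrt(n) for the bulk of null correlations
  expect_lt(median(off), 3 / sqrt(ncol(sim$expr)))
  expect_lt(mean(off > 3 / sqrt(ncol(sim$expr))), 0.05)
})

test_that("degenerate loading with c = 1 ties the gene to the trait", {
  d <- synthetic_design(n_genes = 5L, module_sizes = 2L,
                        loading_range = c(1, 1), trait_coupling = 1,
                        n_samples_case = 10L, n_samples_control = 10L,
                        seed = 3L)
  sim <- generate_expression(d)
  g <- names(sim$truth$module)[sim$truth$module == 1L][1]
  expect_equal(abs(cor(sim$expr[g, ], sim$samples$status)), 1,
               tolerance = 1e-12)
})

test_that("factor model: correlations match the closed form w_i * w_j", {
  # within-module mean |r| beats between-module, and empirical r converges
  # to the loading product at large n
  d <- synthetic_design(n_genes = 250L, module_sizes = rep(50L, 5L),
                        n_samples_case = 1000L, n_samples_control = 1000L,
                        loading_range = c(0.6, 0.95), seed = 4L)
  sim <- generate_expression(d)
  cm <- cor(t(sim$expr))
  lab <- sim$truth$module
  w <- sim$truth$loadings
  within <- between <- c()
  err <- c()
  for (i in 1:20) {
    for (j in (i + 1):60) {
      if (lab[i] == lab[j]) {
        within <- c(within, abs(cm[i, j]))
        err <- c(err, abs(cm[i, j] - w[i] * w[j]))
      } else {
        between <- c(between, abs(cm[i, j]))
      }
    }
  }
  expect_gt(mean(within), mean(between))
  # convergence at n = 2000: sampling error of r-hat has sd ~ 0.02, so
  # the +-0.05 band holds for (at least) 95% of pairs and on average
  expect_lt(mean(err), 0.02)
  expect_lt(quantile(err, 0.95), 0.05)
})

test_that("trait coupling plants a mean shift only in the disease module", {
  sim <- default_sim()
  expect_true(all(sim$truth$true_diff[sim$truth$module != 1L] == 0))
  expect_true(all(sim$truth$true_diff[sim$truth$module == 1L] > 0))
  # planted hubs are disease-module lncRNAs
  expect_true(all(sim$truth$module[sim$truth$hubs] == 1L))
  expect_true(all(sim$truth$biotype[sim$truth$hubs] == "lncRNA"))
})

test_that("alignment fixture plants exactly the advertised violations", {
  fx <- generate_alignment_fixture(seed = 1L)
  h <- fx$hits
  # at least one imperfect identity, one imperfect coverage, one boundary E
  expect_true(any(h$percent_identity < 100))
  expect_true(any(h$query_coverage < 100))
  expect_true(any(h$e_value == 2e-6))
  # a multi-target probe and an under-covered transcript exist
  perfect <- h[h$percent_identity == 100 & h$query_coverage == 100 &
                 h$e_value < 2e-6, ]
  n_tx <- tapply(perfect$transcript_id, perfect$probe_id,
                 function(x) length(unique(x)))
  expect_true(any(n_tx > 1))
  dedup <- perfect[!duplicated(perfect[c("probe_id", "transcript_id")]), ]
  singles <- dedup[!(dedup$probe_id %in% names(n_tx)[n_tx > 1]), ]
  per_tx <- tapply(singles$probe_id, singles$transcript_id,
                   function(x) length(unique(x)))
  expect_true(any(per_tx < 3))
})

test_that("interactome sharing counts are exact by construction", {
  lnc <- sprintf("L%02d", 1:6)
  mrna <- sprintf("M%02d", 1:10)
  inter <- generate_interactome(lnc, mrna, n_planted = 4L, n_mirna = 120L,
                                sharing_high = 8L, sharing_low = 1L,
                                seed = 9L)
  sets <- inter$db$sets
  for (i in 1:4) {
    expect_length(intersect(sets[[lnc[i]]], sets[[mrna[i]]]), 8L)
  }
  # decoy pairs share exactly sharing_low
  expect_length(intersect(sets[["L05"]], sets[["M06"]]), 1L)
  # planted x decoy pairs share nothing
  expect_length(intersect(sets[[lnc[1]]], sets[["M07"]]), 0L)
  expect_error(
    generate_interactome(lnc, mrna, n_planted = 4L, n_mirna = 10L),
    "impossible sharing")
})

test_that("ct fixture encodes folds as exact delta-Ct offsets", {
  ct <- generate_ct_fixture(c(2, 0.5, 4), seed = 1L)
  # fold 2 <=> case delta-Ct exactly one cycle below control
  mean_ct <- function(g, grp) mean(ct$ct[ct$gene == g & ct$group == grp])
  ref_case <- mean_ct("REF", "case"); ref_ctrl <- mean_ct("REF", "control")
  d_case <- mean_ct("TGT1", "case") - ref_case
  d_ctrl <- mean_ct("TGT1", "control") - ref_ctrl
  expect_equal(d_ctrl - d_case, 1)
  # fold 1 would mean ddCt 0; fold 0.5 means one cycle above
  expect_equal((mean_ct("TGT2", "case") - ref_case) - d_ctrl, 1)
})
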