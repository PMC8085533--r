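mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(probe_id = r[[1]], probeset_id = r[[2]],
               transcript_id = r[[3]],
               percent_identity = as.numeric(r[[4]]),
               query_coverage = as.numeric(r[[5]]),
               e_value = as.numeric(r[[6]]), stringsAsFactors = FALSE)
  }))
}

test_that("perfect-hit filter enforces all three thresholds, E strictly", {
  h <- mk_hits(list("p1", "ps1", "t1", 100, 100, 1e-9),
               list("p2", "ps1", "t1", 99.9, 100, 1e-9),
               list("p3", "ps1", "t1", 100, 99, 1e-9),
               list("p4", "ps1", "t1", 100, 100, 2e-6),
               list("p5", "ps1", "t1", 100, 100, 1.999e-6))
  out <- filter_perfect_hits(h)
  expect_setequal(out$probe_id, c("p1", "p5"))
  expect_error(filter_perfect_hits(h[, -6]), "missing columns")
})

test_that("multi-target probes are removed, duplicates deduplicate", {
  h <- mk_hits(list("p1", "ps1", "t1", 100, 100, 1e-9),
               list("p1", "ps1", "t2", 100, 100, 1e-9),  # ambiguous
               list("p2", "ps1", "t1", 100, 100, 1e-9),
               list("p2", "ps1", "t1", 100, 100, 1e-8))  # duplicate
  out <- drop_multitarget_probes(h)
  expect_identical(out$probe_id, "p2")
  expect_equal(nrow(out), 1L)
  # all single-hit: identity transformation (modulo row names)
  single <- mk_hits(list("p1", "ps1", "t1", 100, 100, 1e-9),
                    list("p2", "ps1", "t1", 100, 100, 1e-9))
  expect_equal(drop_multitarget_probes(single), single)
})

test_that("under-supported transcripts go; exactly-3-probe ones stay", {
  h <- mk_hits(list("p1", "ps1", "t1", 100, 100, 1e-9),
               list("p2", "ps1", "t1", 100, 100, 1e-9),
               list("p3", "ps1", "t1", 100, 100, 1e-9),
               list("p4", "ps2", "t2", 100, 100, 1e-9),
               list("p5", "ps2", "t2", 100, 100, 1e-9))
  out <- drop_undersupported_transcripts(h)
  expect_setequal(unique(out$transcript_id), "t1")
  expect_equal(nrow(out), 3L)
  empty <- h[0, ]
  expect_equal(nrow(drop_undersupported_transcripts(empty)), 0L)
})

test_that("probeset map drops gene-ambiguous probesets and flags missing annotation", {
  h <- mk_hits(list("p1", "ps1", "t1", 100, 100, 1e-9),
               list("p2", "ps1", "t2", 100, 100, 1e-9),
               list("p3", "ps2", "t3", 100, 100, 1e-9))
  annot <- data.frame(transcript_id = c("t1", "t2", "t3"),
                      gene_id = c("gA", "gB", "gC"),
                      gene_symbol = c("A", "B", "C"),
                      biotype = c("lncRNA", "protein_coding", "lncRNA"),
                      stringsAsFactors = FALSE)
  expect_warning(map <- build_probeset_map(h, annot), "multiple genes")
  expect_identical(map$probeset_id, "ps2")
  expect_identical(map$biotype, "lncRNA")
  expect_error(build_probeset_map(h, annot[1:2, ]), "absent from annotation")
})

test_that("filter chain reproduces the fixture's expected map exactly,
           independent of row order", {
  fx <- generate_alignment_fixture(seed = 42L)
  got <- reannotate(fx$hits, fx$annot)
  expect_equal(got, fx$expected_map)
  # permuting rows changes nothing
  perm <- fx$hits[rev(seq_len(nrow(fx$hits))), ]
  expect_equal(reannotate(perm, fx$annot), fx$expected_map)
})

test_that("tightening thresholds never retains more rows (monotonicity)", {
  fx <- generate_alignment_fixture(n_clean = 6L, seed = 8L)
  h1 <- filter_perfect_hits(fx$hits, e_max = 2e-6)
  h2 <- filter_perfect_hits(fx$hits, e_max = 1e-10)
  expect_lte(nrow(h2), nrow(h1))
  base <- drop_multitarget_probes(h1)
  expect_lte(nrow(drop_undersupported_transcripts(base, 4L)),
             nrow(drop_undersupported_transcripts(base, 3L)))
})

test_that("relabel_expression collapses multi-probeset genes by highest mean", {
  map <- data.frame(probeset_id = c("ps1", "ps2", "ps3"),
                    gene_id = c("gA", "gA", "gB"),
                    gene_symbol = c("A", "A", "B"),
                    biotype = c("lncRNA", "lncRNA", "protein_coding"),
                    n_supporting_probes = c(4L, 4L, 3L),
                    stringsAsFactors = FALSE)
  mat <- rbind(ps1 = c(5, 5), ps2 = c(7, 7), ps3 = c(1, 2),
               ps_unmapped = c(9, 9))
  colnames(mat) <- c("s1", "s2")
  expect_message(out <- relabel_expression(mat, map), "unmapped")
  expect_equal(out["gA", ], c(s1 = 7, s2 = 7))  # the mean-7 probeset wins
  expect_identical(attr(out, "biotype")[["gA"]], "lncRNA")
  expect_error(relabel_expression(mat[4, , drop = FALSE], map),
               "none of the matrix rows")
})
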