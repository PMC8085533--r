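#' Specify a synthetic expression design with planted module structure
#'
#' The generator follows a single-latent-factor-per-module model: each
#' module m has one factor f_m per sample, and a member gene g with
#' loading w_g is w_g * f_m + sqrt(1 - w_g^2) * noise, so every gene has
#' unit variance and the expected correlation between two genes of one
#' module is the product of their loadings. The designated disease module
#' (always module 1) has its factor coupled to the binary trait with
#' strength `trait_coupling`: f_1 = c * z(trait) + sqrt(1 - c^2) * noise,
#' where z(trait) is the standardized 0/1 status. Genes not assigned to a
#' module are independent standard normal background.
#'
#' Defaults describe the standard test world: five modules of 50 genes
#' plus 250 background genes, 20 case and 8 control samples (mirroring the
#' small unbalanced cardiomyopathy cohorts this design emulates), loadings
#' uniform in \[0.6, 0.95\] and trait coupling 0.8.
#'
#' @param n_genes total number of genes.
#' @param n_samples_case,n_samples_control samples per group.
#' @param module_sizes integer vector of planted module sizes; their sum
#'   must not exceed `n_genes`.
#' @param loading_range length-2 interval in (0, 1] from which per-gene
#'   loadings are drawn uniformly.
#' @param trait_coupling scalar c in \[0, 1\]: correlation between the
#'   disease module's factor and the standardized trait.
#' @param lnc_fraction fraction of genes labeled `lncRNA` (rest
#'   `protein_coding`).
#' @param hub_loading loadings at or above this value define the planted
#'   hub set (disease-module lncRNAs only).
#' @param seed integer seed; the design is fully deterministic given it.
#' @return An object of class `synthetic_design` (a named list).
#' @export
synthetic_design <- function(n_genes = 500L,
                             n_samples_case = 20L,
                             n_samples_control = 8L,
                             module_sizes = rep(50L, 5L),
                             loading_range = c(0.6, 0.95),
                             trait_coupling = 0.8,
                             lnc_fraction = 0.3,
                             hub_loading = 0.75,
                             seed = 1L) {
  stopifnot(length(loading_range) == 2L,
            loading_range[1] <= loading_range[2],
            loading_range[1] > 0, loading_range[2] <= 1,
            trait_coupling >= 0, trait_coupling <= 1,
            lnc_fraction >= 0, lnc_fraction <= 1,
            n_samples_case >= 2L, n_samples_control >= 2L)
  if (sum(module_sizes) > n_genes) {
    stop("sum(module_sizes) exceeds n_genes")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_samples_case = as.integer(n_samples_case),
                 n_samples_control = as.integer(n_samples_control),
                 module_sizes = as.integer(module_sizes),
                 loading_range = as.numeric(loading_range),
                 trait_coupling = as.numeric(trait_coupling),
                 lnc_fraction = as.numeric(lnc_fraction),
                 hub_loading = as.numeric(hub_loading),
                 seed = as.integer(seed)),
            class = "synthetic_design")
}

#' A tight, strongly trait-coupled variant of the default design
#'
#' Used for stability protocols where the planted answer should be
#' unambiguous: loadings in \[0.85, 0.98\] and trait coupling 0.9.
#'
#' @param ... overrides passed on to [synthetic_design()].
#' @export
strong_design <- function(...) {
  args <- list(...)
  defaults <- list(loading_range = c(0.85, 0.98), trait_coupling = 0.9)
  do.call(synthetic_design, utils::modifyList(defaults, args))
}

#' Generate a synthetic expression matrix with planted co-expression modules
#'
#' Draws from the latent-factor model described in [synthetic_design()].
#' Gene ids are `G0001`, ...; lncRNA-labeled genes keep their id with an
#' `lncRNA` biotype. The returned truth records everything a downstream
#' stage should recover: module labels, the disease module id, the planted
#' hub lncRNAs (disease-module lncRNAs with loading >= `hub_loading`), and
#' each gene's expected case-minus-control mean difference.
#'
#' Gene-level randomness (loadings, biotype labels) is driven by the
#' design seed alone, while sample-level randomness (factors and noise)
#' uses `sample_seed`, so two calls sharing a design but differing in
#' `sample_seed` are independent cohorts measuring the same genes — the
#' setting module preservation and cross-cohort validation assume.
#'
#' @param design a [synthetic_design()] object.
#' @param sample_seed seed for the sample-level draws; defaults to the
#'   design seed.
#' @return A list with `expr` (genes x samples matrix), `samples`
#'   (data.frame: sample_id, group, status with 1 = case), `truth` (list:
#'   module labels, disease_module, hubs, loadings, biotype, factors,
#'   true_diff), and `gene_info` (data.frame: gene_id, biotype, module).
#' @export
generate_expression <- function(design, sample_seed = design$seed) {
  stopifnot(inherits(design, "synthetic_design"))
  d <- design
  n_case <- d$n_samples_case
  n_ctrl <- d$n_samples_control
  n <- n_case + n_ctrl
  status <- c(rep(1L, n_case), rep(0L, n_ctrl))
  z_trait <- as.numeric(scale(status))  # standardized 0/1 status
  gene_ids <- sprintf("G%04d", seq_len(d$n_genes))

  n_mod <- length(d$module_sizes)
  labels <- integer(d$n_genes)
  idx <- 1L
  for (m in seq_len(n_mod)) {
    labels[idx:(idx + d$module_sizes[m] - 1L)] <- m
    idx <- idx + d$module_sizes[m]
  }
  in_mod <- labels > 0L

  # gene-level attributes: fixed by the design seed
  gene_attrs <- with_seed(d$seed, {
    loadings <- numeric(d$n_genes)
    loadings[in_mod] <- stats::runif(sum(in_mod),
                                     d$loading_range[1], d$loading_range[2])
    biotype <- rep("protein_coding", d$n_genes)
    biotype[sample.int(d$n_genes, round(d$lnc_fraction * d$n_genes))] <-
      "lncRNA"
    list(loadings = loadings, biotype = biotype)
  })
  loadings <- gene_attrs$loadings
  biotype <- stats::setNames(gene_attrs$biotype, gene_ids)

  # sample-level draws: latent factors and gene noise
  cc <- d$trait_coupling
  expr_parts <- with_seed(sample_seed, {
    factors <- matrix(stats::rnorm(n * max(n_mod, 1L)), nrow = n)
    if (n_mod >= 1L) {
      # disease module factor tied to the trait
      factors[, 1L] <- cc * z_trait + sqrt(1 - cc^2) * factors[, 1L]
    }
    expr <- matrix(stats::rnorm(d$n_genes * n), nrow = d$n_genes)
    list(factors = factors, expr = expr)
  })
  factors <- expr_parts$factors
  expr <- expr_parts$expr
  for (g in which(in_mod)) {
    w <- loadings[g]
    expr[g, ] <- w * factors[, labels[g]] + sqrt(1 - w^2) * expr[g, ]
  }

  rownames(expr) <- gene_ids
  sample_ids <- c(sprintf("case_%02d", seq_len(n_case)),
                  sprintf("ctrl_%02d", seq_len(n_ctrl)))
  colnames(expr) <- sample_ids

  # expected case-minus-control mean shift under the factor model:
  # E[x_g | case] - E[x_g | control] = w_g * c * (z_case - z_ctrl)
  z_diff <- z_trait[1L] - z_trait[n]
  true_diff <- ifelse(labels == 1L, loadings * cc * z_diff, 0)
  names(true_diff) <- gene_ids

  hubs <- gene_ids[labels == 1L & biotype == "lncRNA" &
                     loadings >= d$hub_loading]
  names(labels) <- names(loadings) <- gene_ids

  samples <- data.frame(sample_id = sample_ids,
                        group = ifelse(status == 1L, "case", "control"),
                        status = status,
                        stringsAsFactors = FALSE)
  truth <- list(module = labels,
                disease_module = if (n_mod >= 1L) 1L else NA_integer_,
                hubs = hubs, loadings = loadings, biotype = biotype,
                factors = factors, true_diff = true_diff)
  gene_info <- data.frame(gene_id = gene_ids, biotype = unname(biotype),
                          module = unname(labels),
                          stringsAsFactors = FALSE)
  list(expr = expr, samples = samples, truth = truth,
       gene_info = gene_info, design = d)
}

#' Generate a probe alignment fixture with known filter outcome
#'
#' Builds a small BLAST-tabular-style alignment table that, by
#' construction, contains: clean probesets whose probes each perfectly hit
#' one transcript at least three times; a probe perfectly hitting two
#' distinct transcripts (ambiguous, must go); a transcript supported by
#' fewer than three probes (under-covered, must go); imperfect hits
#' (identity or coverage below 100, or E-value at/above threshold); and a
#' duplicated probe-transcript row that must deduplicate, not count as
#' multi-target. The expected post-filter probeset map is returned
#' alongside so the filter chain can be checked exactly.
#'
#' @param n_clean number of clean probesets (each: 4 probes, 1 transcript).
#' @param seed integer seed (jitters E-values only).
#' @return list with `hits` (ProbeAlignmentTable data.frame), `annot`
#'   (TranscriptAnnotation data.frame) and `expected_map` (the
#'   ProbesetMap the filter chain must reproduce).
#' @export
generate_alignment_fixture <- function(n_clean = 4L, seed = 1L) {
  with_seed(seed, {
    stopifnot(n_clean >= 1L)
    rows <- list()
    add <- function(probe, pset, tx, ident = 100, cov = 100, e = NULL) {
      if (is.null(e)) e <- 10^stats::runif(1, -12, -8)
      rows[[length(rows) + 1L]] <<- data.frame(
        probe_id = probe, probeset_id = pset, transcript_id = tx,
        percent_identity = ident, query_coverage = cov, e_value = e,
        stringsAsFactors = FALSE)
    }

    n_tx <- n_clean + 4L
    tx_ids <- sprintf("TX%03d", seq_len(n_tx))
    biotypes <- rep(c("lncRNA", "protein_coding"), length.out = n_tx)
    annot <- data.frame(transcript_id = tx_ids,
                        gene_id = sprintf("GENE%03d", seq_len(n_tx)),
                        gene_symbol = sprintf("SYM%03d", seq_len(n_tx)),
                        biotype = biotypes, stringsAsFactors = FALSE)

    # clean probesets: 4 distinct probes, one transcript each
    for (i in seq_len(n_clean)) {
      pset <- sprintf("PS%03d", i)
      for (p in 1:4) add(sprintf("%s_p%d", pset, p), pset, tx_ids[i])
    }
    # duplicated hit to ONE transcript: dedups, still counts once;
    # transcript keeps >= 3 distinct probes so the probeset survives
    dup_tx <- tx_ids[n_clean + 1L]
    pset_dup <- "PS_DUP"
    for (p in 1:3) add(sprintf("PS_DUP_p%d", p), pset_dup, dup_tx)
    add("PS_DUP_p1", pset_dup, dup_tx)  # exact duplicate row

    # ambiguous probeset: every probe perfectly hits two transcripts
    amb_tx <- tx_ids[n_clean + 2L]
    for (p in 1:3) {
      add(sprintf("PS_AMB_p%d", p), "PS_AMB", amb_tx)
      add(sprintf("PS_AMB_p%d", p), "PS_AMB", tx_ids[1L])
    }
    # under-covered transcript: only two probes
    thin_tx <- tx_ids[n_clean + 3L]
    for (p in 1:2) add(sprintf("PS_THIN_p%d", p), "PS_THIN", thin_tx)
    # imperfect hits only: identity < 100, coverage < 100, E at threshold
    bad_tx <- tx_ids[n_clean + 4L]
    add("PS_BAD_p1", "PS_BAD", bad_tx, ident = 99.5)
    add("PS_BAD_p2", "PS_BAD", bad_tx, cov = 95)
    add("PS_BAD_p3", "PS_BAD", bad_tx, e = 2e-6)  # boundary: must be dropped

    hits <- do.call(rbind, rows)
    keep_ps <- c(sprintf("PS%03d", seq_len(n_clean)), pset_dup)
    keep_tx <- c(tx_ids[seq_len(n_clean)], dup_tx)
    expected_map <- data.frame(
      probeset_id = keep_ps,
      gene_id = annot$gene_id[match(keep_tx, annot$transcript_id)],
      gene_symbol = annot$gene_symbol[match(keep_tx, annot$transcript_id)],
      biotype = annot$biotype[match(keep_tx, annot$transcript_id)],
      n_supporting_probes = c(rep(4L, n_clean), 3L),
      stringsAsFactors = FALSE)
    expected_map <- expected_map[order(expected_map$probeset_id), ]
    rownames(expected_map) <- NULL
    list(hits = hits, annot = annot, expected_map = expected_map)
  })
}

#' Generate a miRNA interactome with planted high-sharing ceRNA pairs
#'
#' Overlaps are constructed exactly, not left to chance. Each planted pair
#' (one lncRNA, one mRNA) receives a dedicated block of `sharing_high`
#' shared miRNAs plus `n_private` private ones per gene, so the pair's
#' overlap is exactly `sharing_high`. Every decoy gene receives
#' `sharing_low` miRNAs from one small promiscuous pool shared by all
#' decoys plus `decoy_set_size - sharing_low` private miRNAs, so any decoy
#' pair shares exactly `sharing_low` and planted-vs-decoy pairs share
#' none. Planted pairs therefore carry a tiny upper-tail hypergeometric p
#' while no other pair does. The universe must be large enough to host all
#' the disjoint blocks; otherwise an error is raised.
#'
#' @param lnc_ids,mrna_ids character vectors of gene ids by biotype.
#' @param n_planted number of planted pairs, pairing `lnc_ids[i]` with
#'   `mrna_ids[i]`; must not exceed the length of either vector.
#' @param n_mirna miRNA universe size.
#' @param sharing_high shared-miRNA count planted into each true pair.
#' @param sharing_low exact shared-miRNA count of every decoy pair
#'   (must be < `sharing_high` and < `decoy_set_size`).
#' @param decoy_set_size target-set size of non-planted genes.
#' @param n_private private miRNAs per planted gene.
#' @param seed integer seed.
#' @return list with `db` (a `mirna_db` object, see [mirna_db()]),
#'   `planted_pairs` (data.frame: lncRNA, mRNA, n_shared).
#' @export
generate_interactome <- function(lnc_ids, mrna_ids, n_planted = 8L,
                                 n_mirna = 300L, sharing_high = 10L,
                                 sharing_low = 1L, decoy_set_size = 5L,
                                 n_private = 2L, seed = 1L) {
  stopifnot(sharing_high > sharing_low, n_mirna >= sharing_high,
            sharing_low < decoy_set_size,
            n_planted <= length(lnc_ids), n_planted <= length(mrna_ids))
  decoys <- setdiff(c(lnc_ids, mrna_ids),
                    c(lnc_ids[seq_len(n_planted)],
                      mrna_ids[seq_len(n_planted)]))
  needed <- n_planted * (sharing_high + 2L * n_private) + sharing_low +
    length(decoys) * (decoy_set_size - sharing_low)
  if (needed > n_mirna) {
    stop("impossible sharing counts: need ", needed,
         " distinct miRNAs but n_mirna = ", n_mirna)
  }
  with_seed(seed, {
    mirnas <- sample(sprintf("miR-%03d", seq_len(n_mirna)))  # shuffled pool
    take <- local({
      used <- 0L
      function(k) {
        out <- mirnas[used + seq_len(k)]
        used <<- used + k
        out
      }
    })
    targets <- list()  # per-gene miRNA sets
    planted <- data.frame(lncRNA = character(0), mRNA = character(0),
                          n_shared = integer(0), stringsAsFactors = FALSE)
    for (i in seq_len(n_planted)) {
      shared <- take(sharing_high)
      targets[[lnc_ids[i]]] <- c(shared, take(n_private))
      targets[[mrna_ids[i]]] <- c(shared, take(n_private))
      planted <- rbind(planted, data.frame(
        lncRNA = lnc_ids[i], mRNA = mrna_ids[i],
        n_shared = sharing_high, stringsAsFactors = FALSE))
    }
    common <- take(sharing_low)
    for (g in decoys) {
      targets[[g]] <- c(common, take(decoy_set_size - sharing_low))
    }

    biotype <- c(stats::setNames(rep("lncRNA", length(lnc_ids)), lnc_ids),
                 stats::setNames(rep("protein_coding", length(mrna_ids)),
                                 mrna_ids))
    pairs <- do.call(rbind, lapply(names(targets), function(g) {
      data.frame(miRNA_id = targets[[g]], target_id = g,
                 target_type = unname(biotype[g]), stringsAsFactors = FALSE)
    }))
    list(db = mirna_db(pairs), planted_pairs = planted)
  })
}

#' Generate a triplicate Ct fixture with known fold changes
#'
#' Builds a Ct table (target gene + reference gene, triplicates) in which
#' each case sample's delta-Ct sits exactly log2(fold) cycles below the
#' control mean delta-Ct, so noiseless relative quantification by
#' 2^-ddCt recovers `true_folds` exactly. Each fold gets its own target
#' gene (`TGT1`, `TGT2`, ...); the reference gene is `REF`.
#'
#' @param true_folds positive numeric vector of planted case/control folds.
#' @param n_case,n_control samples per group.
#' @param noise_sd standard deviation of per-replicate Ct noise, cycles
#'   (default 0 = noiseless).
#' @param seed integer seed (only matters when `noise_sd > 0`).
#' @return data.frame with columns sample_id, group, gene, replicate, ct,
#'   is_reference.
#' @export
generate_ct_fixture <- function(true_folds, n_case = 3L, n_control = 3L,
                                noise_sd = 0, seed = 1L) {
  stopifnot(all(true_folds > 0))
  with_seed(seed, {
    samples <- data.frame(
      sample_id = c(sprintf("case_%d", seq_len(n_case)),
                    sprintf("ctrl_%d", seq_len(n_control))),
      group = c(rep("case", n_case), rep("control", n_control)),
      stringsAsFactors = FALSE)
    ref_ct <- 18
    base_dct <- 5  # control-group delta-Ct for every target gene
    rows <- list()
    genes <- sprintf("TGT%d", seq_along(true_folds))
    for (i in seq_len(nrow(samples))) {
      for (rep_i in 1:3) {
        noise <- function() if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = samples$sample_id[i], group = samples$group[i],
          gene = "REF", replicate = rep_i, ct = ref_ct + noise(),
          is_reference = TRUE, stringsAsFactors = FALSE)
        for (k in seq_along(true_folds)) {
          dct <- if (samples$group[i] == "case") {
            base_dct - log2(true_folds[k])
          } else {
            base_dct
          }
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = samples$sample_id[i], group = samples$group[i],
            gene = genes[k], replicate = rep_i, ct = ref_ct + dct + noise(),
            is_reference = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}
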