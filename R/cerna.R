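#' miRNA interaction database
#'
#' Wraps a long-format interaction table (miRNA_id, target_id,
#' target_type) into per-gene miRNA target sets plus the miRNA universe
#' (all distinct miRNAs with at least one interaction), the population
#' against which shared-miRNA enrichment is tested.
#'
#' @param pairs data.frame with columns miRNA_id, target_id, target_type
#'   (`lncRNA` or `protein_coding`/`mRNA`).
#' @return object of class `mirna_db`: list with `sets` (named list of
#'   miRNA character vectors per gene), `type` (named vector), `universe`
#'   (character vector of miRNAs), `n_universe`.
#' @export
mirna_db <- function(pairs) {
  need <- c("miRNA_id", "target_id", "target_type")
  if (!all(need %in% names(pairs))) {
    stop("interaction table needs columns: ", paste(need, collapse = ", "))
  }
  pairs <- unique(pairs[need])
  sets <- split(pairs$miRNA_id, pairs$target_id)
  sets <- lapply(sets, unique)
  type <- vapply(split(pairs$target_type, pairs$target_id),
                 function(x) x[1L], character(1))
  universe <- sort(unique(pairs$miRNA_id))
  structure(list(sets = sets, type = type, universe = universe,
                 n_universe = length(universe)),
            class = "mirna_db")
}

#' Hypergeometric shared-miRNA test
#'
#' Upper-tail probability that two genes share at least the observed
#' number of targeting miRNAs, drawing without replacement from a universe
#' of `n_universe` miRNAs: with K = |lncRNA set| successes and
#' n = |mRNA set| draws, p = P(X >= k) where k is the observed overlap.
#'
#' @param lnc_targets,mrna_targets character vectors of miRNA ids.
#' @param n_universe miRNA universe size N (>= the union of both sets).
#' @return list with `k_shared` and `p`. Empty target sets give p = 1
#'   with a warning.
#' @export
shared_mirna_test <- function(lnc_targets, mrna_targets, n_universe) {
  lnc_targets <- unique(lnc_targets)
  mrna_targets <- unique(mrna_targets)
  if (length(lnc_targets) == 0L || length(mrna_targets) == 0L) {
    warning("empty target set; p set to 1")
    return(list(k_shared = 0L, p = 1))
  }
  if (n_universe < length(union(lnc_targets, mrna_targets))) {
    stop("universe smaller than the union of the two target sets")
  }
  k <- length(intersect(lnc_targets, mrna_targets))
  p <- stats::phyper(k - 1, length(lnc_targets),
                     n_universe - length(lnc_targets),
                     length(mrna_targets), lower.tail = FALSE)
  list(k_shared = k, p = min(p, 1))
}

#' Build a ceRNA network within a module
#'
#' Every lncRNA x mRNA pair among `module_genes` with both genes present
#' in the interaction database is tested on two criteria: the pair must
#' share a significant number of miRNAs (hypergeometric upper-tail
#' p < `p_max`, no multiplicity correction) and be positively co-expressed
#' (Pearson r > `r_min` with correlation p < `corp_max`, t approximation,
#' all samples pooled). Genes absent from the database are skipped.
#'
#' @param module_genes character vector of gene ids in the module.
#' @param mat genes x samples expression matrix covering those genes.
#' @param db a [mirna_db()] object.
#' @param biotype named biotype vector for `module_genes`.
#' @param p_max hypergeometric p threshold (default 0.01).
#' @param r_min Pearson correlation threshold (default 0.7, strict >).
#' @param corp_max correlation p threshold (default 0.01).
#' @return object of class `cerna_network`: list with `pairs` (data.frame
#'   of all tested pairs: lncRNA, mRNA, k_shared, hyper_p, r, cor_p,
#'   passes), `edges` (passing pairs only), `nodes`, `n_skipped` (genes
#'   without DB entry).
#' @export
build_cerna_network <- function(module_genes, mat, db, biotype,
                                p_max = 0.01, r_min = 0.7,
                                corp_max = 0.01) {
  stopifnot(inherits(db, "mirna_db"))
  module_genes <- intersect(module_genes, rownames(mat))
  lnc <- module_genes[biotype[module_genes] == "lncRNA"]
  mrna <- module_genes[biotype[module_genes] != "lncRNA"]
  in_db <- names(db$sets)
  n_skipped <- sum(!c(lnc, mrna) %in% in_db)
  lnc <- intersect(lnc, in_db)
  mrna <- intersect(mrna, in_db)
  empty <- data.frame(lncRNA = character(0), mRNA = character(0),
                      k_shared = integer(0), hyper_p = numeric(0),
                      r = numeric(0), cor_p = numeric(0),
                      passes = logical(0), stringsAsFactors = FALSE)
  if (length(lnc) == 0L || length(mrna) == 0L) {
    return(structure(list(pairs = empty, edges = empty,
                          nodes = empty[0, 1:2], n_skipped = n_skipped),
                     class = "cerna_network"))
  }
  n <- ncol(mat)
  grid <- expand.grid(lncRNA = lnc, mRNA = mrna,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    l <- grid$lncRNA[i]; m <- grid$mRNA[i]
    ht <- shared_mirna_test(db$sets[[l]], db$sets[[m]], db$n_universe)
    r <- stats::cor(mat[l, ], mat[m, ])
    data.frame(lncRNA = l, mRNA = m, k_shared = ht$k_shared,
               hyper_p = ht$p, r = r, cor_p = cor_pvalue(r, n),
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, res)
  pairs$passes <- pairs$hyper_p < p_max & pairs$r > r_min &
    pairs$cor_p < corp_max
  edges <- pairs[pairs$passes, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- data.frame(
    id = c(unique(edges$lncRNA), unique(edges$mRNA)),
    type = c(rep("lncRNA", length(unique(edges$lncRNA))),
             rep("mRNA", length(unique(edges$mRNA)))),
    stringsAsFactors = FALSE)
  structure(list(pairs = pairs, edges = edges, nodes = nodes,
                 n_skipped = n_skipped),
            class = "cerna_network")
}

#' Extract per-hub sub-networks
#'
#' @param net a `cerna_network`.
#' @param hubs character vector of hub lncRNA ids.
#' @return named list (one entry per hub) of lists with `nodes` and
#'   `edges`; hubs absent from the network yield empty sub-networks (a
#'   message is emitted).
#' @export
extract_hub_subnetworks <- function(net, hubs) {
  stopifnot(inherits(net, "cerna_network"))
  out <- lapply(hubs, function(h) {
    e <- net$edges[net$edges$lncRNA == h, , drop = FALSE]
    if (nrow(e) == 0L) {
      message("hub ", h, " not present in the ceRNA network")
      return(list(nodes = character(0), edges = e))
    }
    list(nodes = c(h, e$mRNA), edges = e)
  })
  names(out) <- hubs
  out
}

#' Edge overlap between two ceRNA networks
#'
#' @param net_a,net_b `cerna_network` objects sharing one id space.
#' @return list with `n_shared` (shared lncRNA-mRNA pairs) and
#'   `fraction_of_a` (shared / edges of `net_a`; 0 when `net_a` is empty).
#' @export
network_overlap <- function(net_a, net_b) {
  key <- function(net) paste(net$edges$lncRNA, net$edges$mRNA, sep = "\t")
  shared <- length(intersect(key(net_a), key(net_b)))
  n_a <- nrow(net_a$edges)
  list(n_shared = shared,
       fraction_of_a = if (n_a == 0L) 0 else shared / n_a)
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf(
    "ceRNA network: %d edge(s) among %d lncRNA(s) and %d mRNA(s) (%d pair(s) tested)\n",
    nrow(x$edges), sum(x$nodes$type == "lncRNA"),
    sum(x$nodes$type == "mRNA"), nrow(x$pairs)))
  invisible(x)
}
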