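#' Probe re-annotation: from alignment hits to a probeset-gene map
#'
#' Microarray probes designed against an old transcriptome are re-annotated
#' by aligning their sequences to a current lncRNA/mRNA catalog and keeping
#' only unambiguous, well-supported matches. Three filters are applied in
#' order: (1) a probe must perfectly hit a transcript (E-value below
#' `e_max`, query coverage 100, identity 100); (2) any probe perfectly
#' hitting more than one distinct transcript is eliminated; (3) transcripts
#' matched by fewer than `min_probes` probes are discarded. The retained
#' hits map each probeset to one gene and biotype, and the expression
#' matrix is relabeled accordingly.
#'
#' @name reannotation
NULL

check_hit_columns <- function(hits) {
  need <- c("probe_id", "probeset_id", "transcript_id",
            "percent_identity", "query_coverage", "e_value")
  missing <- setdiff(need, names(hits))
  if (length(missing)) {
    stop("alignment table is missing columns: ",
         paste(missing, collapse = ", "))
  }
  invisible(hits)
}

#' Keep only perfect alignment hits
#'
#' @param hits ProbeAlignmentTable data.frame with columns probe_id,
#'   probeset_id, transcript_id, percent_identity, query_coverage, e_value.
#' @param e_max E-value threshold; rows with `e_value < e_max` (strict)
#'   are kept. Identity and coverage must equal 100 exactly.
#' @return the filtered data.frame.
#' @export
filter_perfect_hits <- function(hits, e_max = 2e-6) {
  check_hit_columns(hits)
  keep <- hits$e_value < e_max &
    hits$query_coverage == 100 &
    hits$percent_identity == 100
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove probes that perfectly hit multiple targets
#'
#' Ambiguity is judged at the transcript level: a probe hitting more than
#' one distinct transcript id is removed entirely; duplicate rows for the
#' same (probe, transcript) collapse to one and do not count as
#' multi-target.
#'
#' @param hits perfect-hit-filtered ProbeAlignmentTable.
#' @return data.frame in which every probe maps to exactly one transcript.
#' @export
drop_multitarget_probes <- function(hits) {
  check_hit_columns(hits)
  hits <- hits[!duplicated(hits[c("probe_id", "transcript_id")]), ,
               drop = FALSE]
  n_targets <- tapply(hits$transcript_id, hits$probe_id,
                      function(x) length(unique(x)))
  bad <- names(n_targets)[n_targets > 1L]
  out <- hits[!(hits$probe_id %in% bad), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Discard transcripts supported by too few probes
#'
#' @param hits ProbeAlignmentTable after multi-target removal.
#' @param min_probes minimum number of distinct supporting probes;
#'   transcripts with fewer are dropped (a transcript with exactly
#'   `min_probes` probes is kept).
#' @return the filtered data.frame.
#' @export
drop_undersupported_transcripts <- function(hits, min_probes = 3L) {
  check_hit_columns(hits)
  if (nrow(hits) == 0L) return(hits)
  n_probes <- tapply(hits$probe_id, hits$transcript_id,
                     function(x) length(unique(x)))
  keep_tx <- names(n_probes)[n_probes >= min_probes]
  out <- hits[hits$transcript_id %in% keep_tx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the probeset-to-gene map from filtered hits
#'
#' Each probeset inherits the gene and biotype of the transcript(s) its
#' probes match. Probesets whose probes map to transcripts of different
#' genes are ambiguous at the gene level and are dropped with a warning.
#' Multiple transcripts of one gene are not distinguished.
#'
#' @param hits fully filtered ProbeAlignmentTable.
#' @param annot TranscriptAnnotation data.frame with columns transcript_id,
#'   gene_id, gene_symbol, biotype.
#' @return ProbesetMap data.frame: probeset_id, gene_id, gene_symbol,
#'   biotype, n_supporting_probes; sorted by probeset_id.
#' @export
build_probeset_map <- function(hits, annot) {
  check_hit_columns(hits)
  missing_tx <- setdiff(unique(hits$transcript_id), annot$transcript_id)
  if (length(missing_tx)) {
    stop("transcripts absent from annotation: ",
         paste(missing_tx, collapse = ", "))
  }
  hits$gene_id <- annot$gene_id[match(hits$transcript_id,
                                      annot$transcript_id)]
  split_ps <- split(hits, hits$probeset_id)
  rows <- lapply(split_ps, function(h) {
    genes <- unique(h$gene_id)
    if (length(genes) > 1L) return(NULL)
    tx1 <- h$transcript_id[1L]
    i <- match(tx1, annot$transcript_id)
    data.frame(probeset_id = h$probeset_id[1L],
               gene_id = genes,
               gene_symbol = annot$gene_symbol[i],
               biotype = annot$biotype[i],
               n_supporting_probes = length(unique(h$probe_id)),
               stringsAsFactors = FALSE)
  })
  dropped <- names(split_ps)[vapply(rows, is.null, logical(1))]
  if (length(dropped)) {
    warning(length(dropped), " probeset(s) span multiple genes, dropped: ",
            paste(dropped, collapse = ", "))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(probeset_id = character(0), gene_id = character(0),
                      gene_symbol = character(0), biotype = character(0),
                      n_supporting_probes = integer(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$probeset_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full re-annotation filter chain
#'
#' Convenience wrapper applying [filter_perfect_hits()],
#' [drop_multitarget_probes()], [drop_undersupported_transcripts()] and
#' [build_probeset_map()] in order.
#'
#' @inheritParams filter_perfect_hits
#' @inheritParams drop_undersupported_transcripts
#' @inheritParams build_probeset_map
#' @return ProbesetMap data.frame (see [build_probeset_map()]).
#' @export
reannotate <- function(hits, annot, e_max = 2e-6, min_probes = 3L) {
  hits <- filter_perfect_hits(hits, e_max = e_max)
  hits <- drop_multitarget_probes(hits)
  hits <- drop_undersupported_transcripts(hits, min_probes = min_probes)
  build_probeset_map(hits, annot)
}

#' Relabel a probeset-level expression matrix to gene level
#'
#' Probesets without a map entry are excluded (count reported via
#' message). When several probesets map to one gene, one row is chosen by
#' `collapse`: `"max_mean"` keeps the probeset with the highest mean
#' intensity (common microarray practice); `"median"` takes the
#' per-sample median across the gene's probesets.
#'
#' @param mat numeric matrix, probesets in rows (rownames = probeset ids).
#' @param map ProbesetMap from [build_probeset_map()].
#' @param collapse `"max_mean"` (default) or `"median"`.
#' @return gene-level matrix with a `biotype` attribute (named character
#'   vector aligned to rows).
#' @export
relabel_expression <- function(mat, map, collapse = c("max_mean", "median")) {
  collapse <- match.arg(collapse)
  mapped <- intersect(rownames(mat), map$probeset_id)
  if (length(mapped) == 0L) {
    stop("none of the matrix rows appear in the probeset map")
  }
  n_unmapped <- nrow(mat) - length(mapped)
  if (n_unmapped > 0L) {
    message(n_unmapped, " unmapped probeset(s) excluded")
  }
  sub <- mat[mapped, , drop = FALSE]
  gene <- map$gene_id[match(mapped, map$probeset_id)]
  out <- switch(collapse,
    max_mean = {
      means <- rowMeans(sub)
      best <- tapply(seq_along(gene), gene, function(ii) {
        ii[which.max(means[ii])]
      })
      res <- sub[unlist(best), , drop = FALSE]
      rownames(res) <- names(best)
      res
    },
    median = {
      res <- do.call(rbind, lapply(split(seq_along(gene), gene),
        function(ii) apply(sub[ii, , drop = FALSE], 2, stats::median)))
      res
    })
  out <- out[order(rownames(out)), , drop = FALSE]
  bio <- map$biotype[match(rownames(out), map$gene_id)]
  names(bio) <- rownames(out)
  attr(out, "biotype") <- bio
  out
}

#' Read a BLAST tabular (outfmt 6) alignment file as a ProbeAlignmentTable
#'
#' Expects the standard 12 outfmt-6 columns with the probeset id carried
#' inside the query id (`<probeset><sep><probe>`; default separator
#' `"|"`). Query coverage is not part of outfmt 6; a 13th column is
#' expected to carry it (as from `-outfmt "6 std qcovs"`).
#'
#' @param path file path.
#' @param sep_id separator between probeset id and probe id in the query.
#' @return ProbeAlignmentTable data.frame.
#' @export
read_blast_hits <- function(path, sep_id = "|") {
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 13L) {
    stop("expected 13 columns (outfmt 6 std + qcovs), got ", ncol(raw))
  }
  qid <- raw[[1]]
  split_at <- regexpr(sep_id, qid, fixed = TRUE)
  if (any(split_at < 0L)) {
    stop("query ids lack the probeset separator '", sep_id, "'")
  }
  data.frame(
    probe_id = qid,
    probeset_id = substr(qid, 1L, split_at - 1L),
    transcript_id = raw[[2]],
    percent_identity = raw[[3]],
    query_coverage = raw[[13]],
    e_value = raw[[11]],
    stringsAsFactors = FALSE)
}
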