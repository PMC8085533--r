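#' Hub screening criteria
#'
#' @param mm_threshold module-membership cutoff; hubs require |MM|
#'   strictly above it (default 0.75).
#' @param require_de additionally require the gene to be differentially
#'   expressed (needs a DE table when screening).
#' @return object of class `hub_criteria`.
#' @export
hub_criteria <- function(mm_threshold = 0.75, require_de = FALSE) {
  stopifnot(mm_threshold > 0, mm_threshold < 1)
  structure(list(mm_threshold = mm_threshold, require_de = require_de),
            class = "hub_criteria")
}

#' Screen hub lncRNAs in the most trait-associated module
#'
#' A hub lncRNA (1) belongs to the module with the largest |module-trait
#' correlation| and (2) has |MM| to that module's eigengene strictly above
#' the threshold.
#'
#' @param net a `coexnet` object from [build_network()].
#' @param biotype named character vector (`lncRNA` / `protein_coding`)
#'   covering the network's genes.
#' @param criteria a [hub_criteria()] object.
#' @param de optional DE table (from [moderated_t_test()]) used when
#'   `criteria$require_de` is `TRUE`.
#' @return character vector of hub lncRNA ids (possibly empty); the
#'   selected module id is attached as attribute `module`.
#' @export
screen_hubs <- function(net, biotype, criteria = hub_criteria(), de = NULL) {
  if (is.null(net$trait_table) || nrow(net$trait_table) == 0L) {
    return(structure(character(0), module = NA_integer_))
  }
  top <- net$trait_table$module[which.max(abs(net$trait_table$r))]
  in_top <- names(net$labels)[net$labels == top]
  lnc <- in_top[biotype[in_top] == "lncRNA"]
  mm_col <- paste0("ME", top)
  mm <- net$mm[lnc, mm_col]
  hubs <- lnc[abs(mm) > criteria$mm_threshold]
  if (criteria$require_de) {
    if (is.null(de)) stop("require_de = TRUE but no DE table supplied")
    hubs <- intersect(hubs, de$gene_id[de$is_DE])
  }
  structure(hubs, module = top)
}

#' Bootstrap hub stability over the input gene set
#'
#' The candidate hubs are fixed by a baseline run on the full (variance
#' filtered) gene set. Each iteration then resamples `fraction` of those
#' genes without replacement, rebuilds the network with the same
#' parameters, re-screens hubs, and records for every candidate whether it
#' was called a hub. Candidates missing from a resample count as non-hub
#' in that iteration, keeping the candidate x iteration denominator fixed.
#'
#' @param mat genes x samples matrix (pre variance filter).
#' @param trait 0/1 status aligned to samples.
#' @param params [network_params()]; `soft_power` must be fixed (not NA).
#' @param biotype named biotype vector.
#' @param criteria [hub_criteria()].
#' @param fraction fraction of genes resampled per iteration, in (0, 1].
#' @param n_iter number of iterations.
#' @param seed master seed; per-iteration seeds are derived from it.
#' @return object of class `bootstrap_report`: list with `hub_matrix`
#'   (candidate x iteration logical), `candidates`, `per_gene` consistency,
#'   `rate` (overall), `meta` (data.frame of iteration seeds).
#' @export
bootstrap_genes <- function(mat, trait, params = network_params(),
                            biotype, criteria = hub_criteria(),
                            fraction = 0.9, n_iter = 100L, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1, n_iter >= 1L,
            !is.na(params$soft_power))
  base_mat <- variance_filter(mat, params$variance_quantile)
  inner <- params
  inner$variance_quantile <- 0  # resample from the already-filtered set
  base_net <- build_network(base_mat, trait, inner, keep_matrices = FALSE)
  candidates <- as.character(screen_hubs(base_net, biotype, criteria))
  if (length(candidates) == 0L) {
    stop("baseline run produced no candidate hubs")
  }
  genes <- rownames(base_mat)
  n_take <- floor(fraction * length(genes))
  seeds <- derive_seeds(seed, n_iter)
  hub_matrix <- matrix(FALSE, length(candidates), n_iter,
                       dimnames = list(candidates, NULL))
  for (it in seq_len(n_iter)) {
    take <- with_seed(seeds[it], sample(genes, n_take))
    net_it <- build_network(base_mat[take, , drop = FALSE], trait, inner,
                            keep_matrices = FALSE)
    hubs_it <- screen_hubs(net_it, biotype, criteria)
    hub_matrix[, it] <- candidates %in% hubs_it
  }
  meta <- data.frame(iteration = seq_len(n_iter), seed = seeds,
                     fraction = fraction)
  new_bootstrap_report(hub_matrix, meta)
}

new_bootstrap_report <- function(hub_matrix, meta) {
  structure(list(hub_matrix = hub_matrix,
                 candidates = rownames(hub_matrix),
                 per_gene = rowMeans(hub_matrix),
                 rate = mean(hub_matrix),
                 meta = meta),
            class = "bootstrap_report")
}

#' Overall consistency rate of a stability report
#'
#' The fraction of "hub" cells in the candidate x iteration matrix (the
#' shaded-cell ratio of a bootstrap consistency plot).
#'
#' @param report a `bootstrap_report` (or its hub matrix).
#' @return scalar in \[0, 1\].
#' @export
consistency_rate <- function(report) {
  m <- if (inherits(report, "bootstrap_report")) report$hub_matrix else report
  if (length(m) == 0L) stop("empty candidate x iteration matrix")
  sum(m) / length(m)
}

#' Round half up (0.5 always rounds away from zero toward +Inf)
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' Sweep network parameters around a baseline
#'
#' Each of soft_power, min_module_size, deep_split and merge_cut_height is
#' varied over `n_steps` equally spaced multipliers in \[lo, hi\] of its
#' baseline value (others held at baseline). Integer parameters are
#' rounded half-up and deduplicated. Hubs are re-screened at every
#' setting; the candidate set is the baseline run's hubs.
#'
#' @inheritParams bootstrap_genes
#' @param baseline baseline [network_params()] (soft_power fixed).
#' @param lo,hi multiplier range (default 0.5 to 1.5).
#' @param n_steps number of multipliers, endpoints included.
#' @return named list of `bootstrap_report`s, one per swept parameter;
#'   each report's `meta` records the parameter values evaluated. The
#'   pooled consistency rate over all settings is attached as attribute
#'   `pooled_rate`, and the evaluated grids as attribute `grids`.
#' @export
parameter_sweep <- function(mat, trait, baseline = network_params(),
                            biotype, criteria = hub_criteria(),
                            lo = 0.5, hi = 1.5, n_steps = 5L) {
  stopifnot(!is.na(baseline$soft_power), lo <= hi, n_steps >= 1L)
  grids <- sweep_grids(baseline, lo, hi, n_steps)
  base_mat <- variance_filter(mat, baseline$variance_quantile)
  inner <- baseline
  inner$variance_quantile <- 0
  base_net <- build_network(base_mat, trait, inner, keep_matrices = FALSE)
  candidates <- as.character(screen_hubs(base_net, biotype, criteria))
  if (length(candidates) == 0L) stop("baseline run produced no hubs")

  reports <- lapply(names(grids), function(par) {
    values <- grids[[par]]
    hub_matrix <- matrix(FALSE, length(candidates), length(values),
                         dimnames = list(candidates, NULL))
    for (i in seq_along(values)) {
      p_i <- inner
      p_i[[par]] <- values[i]
      net_i <- suppressWarnings(
        build_network(base_mat, trait, p_i, keep_matrices = FALSE))
      if (max(net_i$labels) == 0L) {
        # setting yields zero modules: all candidates non-hub, flagged
        warning("sweep setting ", par, " = ", values[i],
                " produced no modules")
        next
      }
      hubs_i <- screen_hubs(net_i, biotype, criteria)
      hub_matrix[, i] <- candidates %in% hubs_i
    }
    meta <- data.frame(iteration = seq_along(values), parameter = par,
                       value = values)
    new_bootstrap_report(hub_matrix, meta)
  })
  names(reports) <- names(grids)
  attr(reports, "pooled_rate") <-
    mean(unlist(lapply(reports, function(r) as.vector(r$hub_matrix))))
  attr(reports, "grids") <- grids
  reports
}

#' Parameter grids for [parameter_sweep()]
#'
#' @inheritParams parameter_sweep
#' @return named list of numeric vectors (soft_power, min_module_size,
#'   deep_split, merge_cut_height).
#' @export
sweep_grids <- function(baseline = network_params(), lo = 0.5, hi = 1.5,
                        n_steps = 5L) {
  mult <- seq(lo, hi, length.out = n_steps)
  list(
    soft_power = unique(round_half_up(baseline$soft_power * mult)),
    min_module_size = unique(round_half_up(baseline$min_module_size * mult)),
    deep_split = unique(pmin(4L, pmax(1L,
      round_half_up(baseline$deep_split * mult)))),
    merge_cut_height = unique(baseline$merge_cut_height * mult))
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat(sprintf(
    "Hub stability report: %d candidate(s) x %d iteration(s); rate = %.1f%%\n",
    nrow(x$hub_matrix), ncol(x$hub_matrix), 100 * x$rate))
  invisible(x)
}
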