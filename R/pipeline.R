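#' Assemble a pipeline run configuration
#'
#' Collects every input and threshold of the full analysis in one object.
#' Inputs may be given as file paths (TSV, read on demand) or as in-memory
#' objects; every threshold used downstream traces back to a field here.
#'
#' @param expr expression matrix (genes x samples) or TSV path (first
#'   column gene ids).
#' @param samples sample table (sample_id, group, status with 1 = case) or
#'   TSV path.
#' @param biotype named biotype vector, or `NULL` when `hits`/`annot` are
#'   given (re-annotation then supplies biotypes).
#' @param hits,annot optional probe alignment table and transcript
#'   annotation (objects or TSV paths); when present the expression matrix
#'   is treated as probeset-level and re-annotated first.
#' @param interactions optional miRNA interaction table (object, TSV path
#'   or [mirna_db()]); when absent the ceRNA stage is skipped.
#' @param params [network_params()].
#' @param criteria [hub_criteria()].
#' @param alpha adjusted-p cutoff for differential expression.
#' @param cerna_p_max,cerna_r_min,cerna_corp_max ceRNA thresholds.
#' @param e_max,min_probes re-annotation thresholds.
#' @param seed master seed recorded in the report.
#' @param out_dir optional directory; when set, every stage's output is
#'   persisted as TSV there.
#' @return object of class `run_config`.
#' @export
run_config <- function(expr, samples, biotype = NULL, hits = NULL,
                       annot = NULL, interactions = NULL,
                       params = network_params(),
                       criteria = hub_criteria(), alpha = 0.05,
                       cerna_p_max = 0.01, cerna_r_min = 0.7,
                       cerna_corp_max = 0.01, e_max = 2e-6,
                       min_probes = 3L, seed = 1L, out_dir = NULL) {
  cfg <- list(expr = expr, samples = samples, biotype = biotype,
              hits = hits, annot = annot, interactions = interactions,
              params = params, criteria = criteria, alpha = alpha,
              cerna_p_max = cerna_p_max, cerna_r_min = cerna_r_min,
              cerna_corp_max = cerna_corp_max, e_max = e_max,
              min_probes = min_probes, seed = as.integer(seed),
              out_dir = out_dir)
  for (f in c("expr", "samples", "hits", "annot", "interactions")) {
    if (is.character(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("config file not found for '", f, "': ", cfg[[f]])
    }
  }
  structure(cfg, class = "run_config")
}

load_input <- function(x, reader = read_tsv_table) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

persist <- function(out_dir, stage, name, obj) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir <- file.path(out_dir, stage)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, name)
  if (is.matrix(obj)) write_expression_tsv(obj, path)
  else write_tsv_table(obj, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: probe re-annotation (when alignment inputs are
#' present), moderated-t differential expression, co-expression network
#' construction with module detection and trait association, hub lncRNA
#' screening, ceRNA network inference within the top trait module (when an
#' interaction table is present), and per-hub ROC diagnostics. Every
#' intermediate is persisted as TSV under `out_dir` when configured, and
#' the report records parameters and counts at each stage.
#'
#' @param config a [run_config()].
#' @return object of class `run_report`: list with `counts`, `de`, `net`,
#'   `hubs`, `hub_module`, `cerna`, `roc` (per-hub AUC table), `biotype`,
#'   `expr`, `samples`, `config_summary`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_stage <- function(stage, msg) {
    message(sprintf("[%s] %s (%.1fs)", stage, msg,
                    as.numeric(Sys.time() - t0, units = "secs")))
  }
  expr <- load_input(config$expr, read_expression_tsv)
  samples <- load_input(config$samples)
  stopifnot(all(c("sample_id", "status") %in% names(samples)))
  samples <- samples[match(colnames(expr), samples$sample_id), ]
  if (any(is.na(samples$sample_id))) {
    stop("stage 'input': samples table does not cover all expression columns")
  }
  trait <- samples$status
  counts <- list(genes_in = nrow(expr), samples = ncol(expr))

  biotype <- config$biotype
  if (!is.null(config$hits)) {
    hits <- load_input(config$hits)
    annot <- load_input(config$annot)
    if (is.null(annot)) stop("stage 'reannotation': annotation missing")
    map <- reannotate(hits, annot, e_max = config$e_max,
                      min_probes = config$min_probes)
    expr <- relabel_expression(expr, map)
    biotype <- attr(expr, "biotype")
    persist(config$out_dir, "01_reannotation", "probeset_map.tsv", map)
    persist(config$out_dir, "01_reannotation", "expr_gene.tsv", expr)
    counts$genes_mapped <- nrow(expr)
    log_stage("reannotation", paste(nrow(expr), "genes mapped"))
  }
  if (is.null(biotype)) stop("no biotype information available")

  de <- moderated_t_test(expr, samples, alpha = config$alpha,
                         biotype = biotype)
  persist(config$out_dir, "02_diffexpr", "de.tsv", de)
  counts$n_de <- sum(de$is_DE)
  log_stage("diffexpr", paste(counts$n_de, "DE genes at adjusted p <",
                              config$alpha))

  net <- build_network(expr, trait, config$params, keep_matrices = FALSE)
  counts$genes_network <- length(net$genes)
  counts$modules <- max(net$labels)
  mod_table <- data.frame(gene_id = names(net$labels),
                          module = unname(net$labels))
  if (!is.null(net$mm)) {
    mod_table$gs <- unname(net$gs[mod_table$gene_id])
  }
  persist(config$out_dir, "03_network", "modules.tsv", mod_table)
  if (!is.null(net$me)) {
    persist(config$out_dir, "03_network", "eigengenes.tsv",
            data.frame(sample_id = rownames(net$me), net$me))
    persist(config$out_dir, "03_network", "module_trait.tsv",
            net$trait_table)
  }
  if (!is.null(net$fit_table)) {
    persist(config$out_dir, "03_network", "soft_power_fit.tsv",
            net$fit_table)
  }
  log_stage("network", paste(counts$modules, "modules at power",
                             net$power))

  hubs <- screen_hubs(net, biotype, config$criteria, de = de)
  hub_module <- attr(hubs, "module")
  counts$hubs <- length(hubs)
  persist(config$out_dir, "04_hubs", "hubs.tsv",
          data.frame(gene_id = as.character(hubs)))
  log_stage("hubs", paste(counts$hubs, "hub lncRNA(s) in module",
                          hub_module))

  cerna <- NULL
  if (!is.null(config$interactions)) {
    db <- load_input(config$interactions)
    if (!inherits(db, "mirna_db")) db <- mirna_db(db)
    module_genes <- names(net$labels)[net$labels == hub_module]
    cerna <- build_cerna_network(module_genes, expr, db, biotype,
                                 p_max = config$cerna_p_max,
                                 r_min = config$cerna_r_min,
                                 corp_max = config$cerna_corp_max)
    counts$cerna_edges <- nrow(cerna$edges)
    persist(config$out_dir, "05_cerna", "edges.tsv", cerna$edges)
    log_stage("cerna", paste(counts$cerna_edges, "edges"))
  } else {
    message("[cerna] no interaction table configured; stage skipped")
  }

  roc <- NULL
  if (length(hubs)) {
    roc <- do.call(rbind, lapply(as.character(hubs), function(h) {
      rr <- roc_auc(expr[h, ], trait)
      data.frame(gene_id = h, auc = rr$auc,
                 sensitivity = rr$operating_point$sensitivity,
                 specificity = rr$operating_point$specificity,
                 stringsAsFactors = FALSE)
    }))
    persist(config$out_dir, "06_diagnostics", "hub_roc.tsv", roc)
  }

  report <- structure(list(counts = counts, de = de, net = net,
                           hubs = as.character(hubs),
                           hub_module = hub_module, cerna = cerna,
                           roc = roc, biotype = biotype, expr = expr,
                           samples = samples,
                           config_summary = summarize_config(config)),
                      class = "run_report")
  if (!is.null(config$out_dir)) {
    jsonlite::write_json(
      c(report$counts, report$config_summary),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, pretty = TRUE)
  }
  report
}

summarize_config <- function(config) {
  list(soft_power = config$params$soft_power,
       min_module_size = config$params$min_module_size,
       deep_split = config$params$deep_split,
       merge_cut_height = config$params$merge_cut_height,
       variance_quantile = config$params$variance_quantile,
       mm_threshold = config$criteria$mm_threshold,
       alpha = config$alpha, cerna_p_max = config$cerna_p_max,
       cerna_r_min = config$cerna_r_min,
       cerna_corp_max = config$cerna_corp_max,
       e_max = config$e_max, min_probes = config$min_probes,
       seed = config$seed)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-14s %s\n", nm, x$counts[[nm]]))
  }
  if (length(x$hubs)) {
    cat("  hub lncRNAs:  ", paste(x$hubs, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Cross-cohort validation report
#'
#' The machine form of a test-vs-validation comparison: which hub lncRNAs
#' of the first (test) cohort replicate in the second (validation)
#' cohort. For each test-cohort hub the report records: differential
#' expression in the validation cohort (unpaired two-sided t at
#' `alpha`), ROC AUC in the validation cohort, and hub status there
#' (membership in the validation run's top trait module with |MM| above
#' threshold). Module preservation of the test cohort's top module in the
#' validation expression is scored by [module_preservation()], and the
#' two ceRNA networks are compared by edge overlap.
#'
#' @param report_test,report_validation `run_report` objects from
#'   [run_pipeline()].
#' @param alpha significance level for the per-hub t-test.
#' @param n_perm permutations for the preservation stage.
#' @param seed seed for the preservation permutations.
#' @return list with `hub_grid` (per-hub Yes/No data.frame), `preservation`
#'   (report row for the test cohort's hub module), `cerna_overlap`.
#' @export
validate_cohort <- function(report_test, report_validation, alpha = 0.05,
                            n_perm = 100L, seed = 1L) {
  a <- report_test; b <- report_validation
  shared_genes <- intersect(rownames(a$expr), rownames(b$expr))
  if (length(shared_genes) == 0L) stop("no shared gene ids between cohorts")

  hub_grid <- do.call(rbind, lapply(a$hubs, function(h) {
    present <- h %in% rownames(b$expr)
    de_p <- auc <- NA_real_
    is_hub_b <- FALSE
    if (present) {
      x <- b$expr[h, b$samples$status == 1]
      y <- b$expr[h, b$samples$status == 0]
      de_p <- student_t_test(x, y)$p
      auc <- roc_auc(b$expr[h, ], b$samples$status)$auc
      is_hub_b <- h %in% b$hubs
    }
    data.frame(gene_id = h, in_validation = present,
               de_validation = isTRUE(de_p < alpha), de_p = de_p,
               auc_validation = auc, hub_validation = is_hub_b,
               stringsAsFactors = FALSE)
  }))

  pres <- NULL
  if (!is.na(a$hub_module)) {
    labels <- a$net$labels
    pres_all <- module_preservation(
      a$expr[intersect(a$net$genes, shared_genes), , drop = FALSE],
      b$expr[intersect(a$net$genes, shared_genes), , drop = FALSE],
      labels, beta = a$net$power, n_perm = n_perm, seed = seed)
    pres <- pres_all[pres_all$module == a$hub_module, , drop = FALSE]
  }

  overlap <- if (!is.null(a$cerna) && !is.null(b$cerna)) {
    network_overlap(a$cerna, b$cerna)
  } else {
    NULL
  }
  list(hub_grid = hub_grid, preservation = pres, cerna_overlap = overlap)
}
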