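# Shared fixtures (memoised: each is generated once per test run) and
# independent brute-force oracles used across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, make(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# default world: 5 modules x 50 genes + 250 noise, 28 samples, c = 0.8
default_sim <- function() {
  cached("default_sim", function() {
    generate_expression(synthetic_design(seed = 7L))
  })
}

# tight world for stability protocols: loadings 0.85-0.98, c = 0.9
strong_sim <- function() {
  cached("strong_sim", function() {
    generate_expression(strong_design(seed = 11L))
  })
}

# single tight module + planted interactome for ceRNA recovery
cerna_fixture <- function() {
  cached("cerna_fixture", function() {
    d <- synthetic_design(n_genes = 60L, module_sizes = 30L,
                          n_samples_case = 24L, n_samples_control = 16L,
                          loading_range = c(0.9, 0.99),
                          lnc_fraction = 0.35, seed = 31L)
    sim <- generate_expression(d)
    mod <- names(sim$truth$module)[sim$truth$module == 1L]
    lnc <- mod[sim$truth$biotype[mod] == "lncRNA"]
    mrna <- mod[sim$truth$biotype[mod] != "lncRNA"]
    inter <- generate_interactome(lnc, mrna, n_planted = 8L, seed = 32L)
    c(sim, inter, list(module_genes = mod))
  })
}

default_net <- function() {
  cached("default_net", function() {
    sim <- default_sim()
    suppressWarnings(build_network(sim$expr, sim$samples$status,
                                   network_params(variance_quantile = 0)))
  })
}

strong_net <- function() {
  cached("strong_net", function() {
    sim <- strong_sim()
    build_network(sim$expr, sim$samples$status,
                  network_params(variance_quantile = 0),
                  keep_matrices = FALSE)
  })
}

# ---- brute-force oracles ------------------------------------------------

oracle_bh <- function(p) {
  # direct definition: adj_i = min over j with p_(j) >= p_(i) of
  # p_(j) * m / j, computed by explicit loops
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

oracle_adjacency <- function(mat, beta) {
  n <- nrow(mat)
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a[i, j] <- if (i == j) 1 else abs(cor(mat[i, ], mat[j, ]))^beta
    }
  }
  a
}

oracle_tom <- function(a) {
  n <- nrow(a)
  k <- colSums(a) - diag(a)
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      s <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) s <- s + a[i, u] * a[u, j]
      }
      tom[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}

oracle_hyper_upper <- function(k, K, n, N) {
  # exact combinatorial sum P(X >= k)
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

oracle_auc_trapezoid <- function(values, labels) {
  # trapezoidal area under the empirical ROC curve
  ths <- c(-Inf, sort(unique(values)), Inf)
  sens <- sapply(ths, function(t) mean(values[labels == 1] >= t))
  fpr <- sapply(ths, function(t) mean(values[labels == 0] >= t))
  o <- order(fpr, sens)
  sum(diff(fpr[o]) * (head(sens[o], -1) + tail(sens[o], -1)) / 2)
}

edge_keys <- function(df) paste(df$lncRNA, df$mRNA, sep = "\t")
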