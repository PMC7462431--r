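# Shared fixtures, built in code. The medium cohort used by several test
# files is generated once per test run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small deterministic parcellation for unit tests
tiny_parcellation <- function(n = 8, seed = 42) make_parcellation(n, seed)

# a 68-ROI cohort of SC matrices (no time series), shared across tests
fixture_sc_cohort <- function() {
  cached("sc_cohort", {
    parc <- make_parcellation(68, seed = 1)
    scs <- make_subject_scs(parc, n_subjects = 20, seed = 7)
    cons <- consensus_sc(scs, parc)
    list(parc = parc, scs = scs, cons = cons,
         si = search_information(cons))
  })
}

# brute-force search-information oracle: enumerate all simple paths,
# pick the shortest by summed 1/weight, multiply per-node transition
# probabilities. Independent of the igraph-based implementation.
si_oracle <- function(w, s, t) {
  n <- nrow(w)
  strength <- rowSums(w)
  best <- list(len = Inf, path = NULL)
  walk <- function(path, len) {
    v <- path[length(path)]
    if (v == t) {
      if (len < best$len) best <<- list(len = len, path = path)
      return()
    }
    for (u in which(w[v, ] > 0)) {
      if (u %in% path) next
      walk(c(path, u), len + 1 / w[v, u])
    }
  }
  walk(s, 0)
  if (is.null(best$path)) return(Inf)
  p <- 1
  vp <- best$path
  for (i in seq_len(length(vp) - 1L)) {
    p <- p * w[vp[i], vp[i + 1L]] / strength[vp[i]]
  }
  -log2(p)
}

# random connected weighted graph on n nodes
random_connected_graph <- function(n, p_edge = 0.5) {
  repeat {
    w <- matrix(0, n, n)
    ut <- upper.tri(w)
    on <- ut & matrix(runif(n * n) < p_edge, n, n)
    w[on] <- runif(sum(on), 0.2, 5)
    w <- w + t(w)
    if (connsmooth:::connected_adj(w)) return(w)
  }
}
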