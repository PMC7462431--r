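# Group-consensus SC, filter-graph variants, degree-preserving nulls, and
# search information.

pair_class <- function(parc) {
  intra <- outer(parc$hemisphere, parc$hemisphere, "==")
  intra
}

support_densities <- function(weights, parc) {
  ut <- upper.tri(weights)
  intra <- pair_class(parc)
  present <- weights > 0
  list(overall = mean(present[ut]),
       intra = mean(present[ut & intra]),
       inter = mean(present[ut & !intra]))
}

#' Construct a structural connectome object
#' @param weights N x N nonnegative symmetric matrix (average fiber count),
#'   zero diagonal.
#' @param parc a [parcellation()].
#' @return object of class `structural_connectome` with densities recorded.
#' @export
structural_connectome <- function(weights, parc) {
  stopifnot(isSymmetric(unname(weights)), all(diag(weights) == 0),
            all(weights >= 0))
  d <- support_densities(weights, parc)
  structure(list(weights = weights, parcellation = parc,
                 density_overall = d$overall, density_intra = d$intra,
                 density_inter = d$inter),
            class = "structural_connectome")
}

#' @export
print.structural_connectome <- function(x, ...) {
  cat(sprintf(
    "<structural_connectome> %d ROIs, density %.1f%% (%.1f%% intra, %.1f%% inter)\n",
    nrow(x$weights), 100 * x$density_overall, 100 * x$density_intra,
    100 * x$density_inter))
  invisible(x)
}

#' Distance-binned group-consensus structural connectome
#'
#' Builds a group-representative SC that preserves the intra- and
#' interhemispheric connection densities seen in single subjects, instead of
#' the interhemisphere-starved result a single global threshold produces.
#' Edges are split into intra-/interhemispheric classes; within each class
#' the Euclidean-distance range is split into equal-count bins; within each
#' bin the most consistently present edges are retained until the class
#' matches the average single-subject density. Retained edges must addition-
#' ally recur in at least `recurrence_min` of subjects; their weight is the
#' mean fiber count over the subjects that have them.
#'
#' @param subject_scs list of N x N symmetric nonnegative matrices.
#' @param parc a [parcellation()].
#' @param recurrence_min minimum fraction of subjects an edge must appear in.
#' @param target_intra_density optional override for the intrahemispheric
#'   density (interhemispheric density scales with it); `NULL` = match the
#'   single-subject average.
#' @param n_bins number of equal-count distance bins per class; default
#'   `ceiling(sqrt(E))` with E the class's candidate edge count.
#' @return a [structural_connectome()].
#' @export
consensus_sc <- function(subject_scs, parc, recurrence_min = 0.3,
                         target_intra_density = NULL, n_bins = NULL) {
  if (length(subject_scs) < 2) stop("need >= 2 subjects", call. = FALSE)
  stopifnot(recurrence_min > 0, recurrence_min <= 1)
  n_sub <- length(subject_scs)
  ed <- roi_distances(parc)
  n <- nrow(ed)
  ut <- which(upper.tri(ed))
  intra <- pair_class(parc)[upper.tri(ed)]
  pres <- sapply(subject_scs, function(m) m[ut] > 0)      # pairs x subjects
  wsum <- Reduce(`+`, lapply(subject_scs, function(m) m[ut]))
  recurrence <- rowMeans(pres)
  n_present <- rowSums(pres)
  mean_w <- ifelse(n_present > 0, wsum / n_present, 0)
  keep <- logical(length(ut))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(intra == cls)
    if (!length(idx)) next
    # average single-subject edge count in this class
    target_density <- if (cls && !is.null(target_intra_density))
      target_intra_density else mean(colMeans(pres[idx, , drop = FALSE]))
    k_class <- round(target_density * length(idx))
    cand <- idx[recurrence[idx] >= recurrence_min]
    if (!length(cand)) next
    nb <- if (is.null(n_bins)) ceiling(sqrt(length(cand))) else n_bins
    nb <- max(1L, min(nb, length(cand)))
    # equal-count distance bins over the candidate edges
    br <- quantile(ed[ut][cand], probs = seq(0, 1, length.out = nb + 1))
    bin <- cut(ed[ut][cand], breaks = unique(br), include.lowest = TRUE)
    # per-bin retention quota proportional to the single-subject edge mass
    per_bin <- tapply(seq_along(cand), bin, identity)
    subj_counts_bin <- vapply(per_bin, function(ii)
      mean(colSums(pres[cand[ii], , drop = FALSE])), numeric(1))
    quota <- round(k_class * subj_counts_bin / max(sum(subj_counts_bin), 1))
    for (b in seq_along(per_bin)) {
      ii <- cand[per_bin[[b]]]
      if (!length(ii) || quota[b] == 0) next
      # most consistent first; ties broken by mean weight then pair order
      ord <- order(-recurrence[ii], -mean_w[ii], ii)
      keep[ii[head(ord, quota[b])]] <- TRUE
    }
  }
  if (!any(keep)) stop("consensus is empty", call. = FALSE)
  w <- matrix(0, n, n, dimnames = dimnames(ed))
  w[ut[keep]] <- mean_w[keep]
  w <- w + t(w)
  structural_connectome(w, parc)
}

#' Degree-preserving connected rewiring (Maslov-Sneppen)
#'
#' Randomly rewires the graph while exactly preserving the binary degree
#' sequence and the edge count, carrying edge weights along and rejecting
#' swaps that would disconnect the graph.
#'
#' @param sc a [structural_connectome()].
#' @param n_iter_per_edge approximate number of times each edge is rewired.
#' @param seed integer seed.
#' @return a rewired [structural_connectome()].
#' @export
rewire_degree_preserving <- function(sc, n_iter_per_edge = 100, seed = 1L) {
  w <- sc$weights
  n <- nrow(w)
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
  if (!igraph::is_connected(g)) stop("graph must be connected", call. = FALSE)
  if (n_iter_per_edge == 0) return(sc)
  edges <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  withr::with_seed(seed, {
    n_attempts <- n_iter_per_edge * nrow(edges)
    for (it in seq_len(n_attempts)) {
      sel <- sample.int(nrow(edges), 2L)
      a <- edges[sel[1], 1]; b <- edges[sel[1], 2]
      c_ <- edges[sel[2], 1]; d <- edges[sel[2], 2]
      if (runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
      if (a == c_ || a == d || b == c_ || b == d) next
      if (w[a, d] > 0 || w[c_, b] > 0) next
      wab <- w[a, b]; wcd <- w[c_, d]
      w[a, b] <- w[b, a] <- 0; w[c_, d] <- w[d, c_] <- 0
      w[a, d] <- w[d, a] <- wab; w[c_, b] <- w[b, c_] <- wcd
      # only the endpoints of the removed edges can lose their connection
      if (connected_pair(w, a, b) && connected_pair(w, c_, d)) {
        edges[sel[1], ] <- c(min(a, d), max(a, d))
        edges[sel[2], ] <- c(min(c_, b), max(c_, b))
      } else { # revert
        w[a, d] <- w[d, a] <- 0; w[c_, b] <- w[b, c_] <- 0
        w[a, b] <- w[b, a] <- wab; w[c_, d] <- w[d, c_] <- wcd
      }
    }
  })
  structural_connectome(w, sc$parcellation)
}

connected_pair <- function(w, from, to) {
  n <- nrow(w)
  seen <- logical(n)
  stack <- from
  seen[from] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- which(w[v, ] > 0 & !seen)
    if (to %in% nb) return(TRUE)
    seen[nb] <- TRUE
    stack <- c(stack, nb)
  }
  FALSE
}

connected_adj <- function(w) {
  n <- nrow(w)
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- which(w[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    stack <- c(stack, nb)
  }
  all(seen)
}

#' Build a filter graph for smoothing
#'
#' The four variants used for graph filtering, plus a degree-preserving
#' randomized control:
#' \describe{
#'   \item{`sc`}{the consensus fiber counts themselves.}
#'   \item{`ed_full`}{dense `exp(-k ED)` between all ROI pairs.}
#'   \item{`ed_match`}{`exp(-k ED)` restricted to the SC support (same
#'     present/absent edges as `sc`).}
#'   \item{`ed_dens`}{`exp(-k ED)` on the shortest-distance pairs up to the
#'     SC's connection density.}
#'   \item{`randomized`}{the consensus SC rewired degree-preservingly.}
#' }
#' With `k = "auto"`, k is set so that the median off-diagonal `ed_full`
#' weight equals the median nonzero weight of the max-normalized SC, which
#' puts the filter weights G on a comparable scale across variants.
#'
#' @param variant one of `"sc"`, `"ed_full"`, `"ed_match"`, `"ed_dens"`,
#'   `"randomized"`.
#' @param sc a [structural_connectome()] (required for all variants in auto-k
#'   mode, and for `sc`, `ed_match`, `ed_dens`, `randomized`).
#' @param parc a [parcellation()].
#' @param k exponential distance scale (1/mm), or `"auto"`.
#' @param normalization `"max1"` (divide by the maximum weight) or `"none"`.
#' @param seed seed for the `randomized` variant.
#' @return object of class `filter_graph`.
#' @export
build_filter_graph <- function(variant, sc = NULL, parc, k = "auto",
                               normalization = c("max1", "none"), seed = 1L) {
  normalization <- match.arg(normalization)
  if (!variant %in% c("sc", "ed_full", "ed_match", "ed_dens", "randomized"))
    stop("unknown filter-graph variant: ", variant, call. = FALSE)
  ed <- roi_distances(parc)
  n <- nrow(ed)
  ut <- upper.tri(ed)
  if (identical(k, "auto")) {
    if (is.null(sc)) stop("k = 'auto' needs the consensus SC", call. = FALSE)
    wmax <- sc$weights / max(sc$weights)
    med_w <- median(wmax[ut & wmax > 0])
    med_ed <- median(ed[ut])
    k <- -log(med_w) / med_ed
  }
  w <- switch(variant,
    sc = sc$weights,
    randomized = rewire_degree_preserving(sc, seed = seed)$weights,
    ed_full = {
      m <- exp(-k * ed); diag(m) <- 0; m
    },
    ed_match = {
      m <- exp(-k * ed) * (sc$weights > 0); diag(m) <- 0; m
    },
    ed_dens = {
      n_edges <- sum(sc$weights[ut] > 0)
      ord <- order(ed[ut], row(ed)[ut], col(ed)[ut])  # deterministic ties
      sel <- which(ut)[ord[seq_len(n_edges)]]
      m <- matrix(0, n, n, dimnames = dimnames(ed))
      m[sel] <- exp(-k * ed[sel])
      m + t(m)
    })
  if (normalization == "max1" && max(w) > 0) w <- w / max(w)
  dimnames(w) <- dimnames(ed)
  structure(list(weights = w, variant = variant,
                 normalization = normalization, k = k),
            class = "filter_graph")
}

#' Search information on a weighted connectome
#'
#' For each ordered pair (s, t), the probability that a naive random walker
#' follows the shortest path from s to t is the product, over the nodes i of
#' the path sequence (t excluded), of the path's outgoing edge weight at i
#' divided by i's node strength. Search information is `-log2` of that
#' probability: high when the shortest path is hidden among many
#' alternatives, and roughly inversely related to fiber count. Shortest
#' paths are computed on edge lengths `1/weight` (or `-log(w/max(w))`).
#'
#' @param sc a [structural_connectome()] or nonnegative symmetric matrix.
#' @param symmetrize average the directed matrix with its transpose
#'   (recommended when using the result as a dense pairwise predictor).
#' @param edge_length `"inverse"` (1/w) or `"neglog"` (-log of the
#'   max-normalized weight).
#' @return object of class `search_information` with fields `si` (N x N,
#'   zero diagonal; `Inf` for disconnected pairs) and `symmetrized`.
#' @export
search_information <- function(sc, symmetrize = TRUE,
                               edge_length = c("inverse", "neglog")) {
  edge_length <- match.arg(edge_length)
  w <- if (inherits(sc, "structural_connectome")) sc$weights else sc
  n <- nrow(w)
  strength <- rowSums(w)
  lengths_of <- function(wts) switch(edge_length,
    inverse = 1 / wts,
    neglog = -log(wts / max(wts)) + 1e-12)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  len <- lengths_of(igraph::E(g)$weight)
  si <- matrix(0, n, n, dimnames = dimnames(w))
  disconnected <- FALSE
  for (s in seq_len(n)) {
    paths <- suppressWarnings(
      igraph::shortest_paths(g, from = s, to = seq_len(n), weights = len,
                             output = "vpath")$vpath)
    for (t in seq_len(n)) {
      if (t == s) next
      vp <- as.integer(paths[[t]])
      if (length(vp) < 2) {
        si[s, t] <- Inf
        disconnected <- TRUE
        next
      }
      steps <- w[cbind(vp[-length(vp)], vp[-1])]
      si[s, t] <- -sum(log2(steps / strength[vp[-length(vp)]]))
    }
  }
  if (disconnected)
    warning("disconnected node pairs: search information set to Inf",
            call. = FALSE)
  if (symmetrize) si <- (si + t(si)) / 2
  structure(list(si = si, symmetrized = symmetrize,
                 edge_length = edge_length),
            class = "search_information")
}
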