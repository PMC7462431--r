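# Repeated-Louvain co-assignment ("community") matrices, cross-FC community
# agreement, and the (resolution, filter-weight) sweep.

#' Repeated-Louvain co-assignment matrix
#'
#' Runs Louvain community detection `n_reps` times with random node orders
#' (one independent seeded stream per repetition) at resolution `gamma` and
#' records, for each ROI pair, the fraction of repetitions that assigned
#' both ROIs to the same community — an estimate of the probability that
#' the pair shares a community. Rows of the result are the ROIs'
#' "community profiles".
#'
#' @param fc an `fc_matrix` or plain symmetric matrix.
#' @param gamma resolution parameter (> 0); larger values give more and
#'   smaller communities.
#' @param n_reps number of Louvain repetitions.
#' @param neg_mode `"asym"` (signed modularity with asymmetric negative
#'   contribution) or `"zero"` (negative weights zeroed).
#' @param seed integer seed; repetition k uses substream `seed + k`.
#' @return object of class `community_matrix`: `coassign` (N x N in
#'   \[0,1\], unit diagonal, entries multiples of 1/n_reps),
#'   `n_communities` per repetition and its mean, plus the settings.
#' @export
louvain_coassignment <- function(fc, gamma = 1, n_reps = 200,
                                 neg_mode = c("asym", "zero"), seed = 1L) {
  neg_mode <- match.arg(neg_mode)
  stopifnot(gamma > 0, n_reps >= 1)
  W <- if (inherits(fc, "fc_matrix")) fc$values else fc
  n <- nrow(W)
  if (n < 3) stop("need at least 3 ROIs", call. = FALSE)
  if (all(W == 0)) stop("all-zero matrix", call. = FALSE)
  counts <- matrix(0L, n, n)
  n_comm <- integer(n_reps)
  memberships <- matrix(0L, n_reps, n)
  for (k in seq_len(n_reps)) {
    res <- withr::with_seed(seed + k, louvain_once(W, gamma, neg_mode))
    same <- outer(res$membership, res$membership, "==")
    counts <- counts + same
    n_comm[k] <- res$n_communities
    memberships[k, ] <- res$membership
  }
  coassign <- counts / n_reps
  dimnames(coassign) <- dimnames(W)
  structure(list(coassign = coassign, n_communities = n_comm,
                 n_communities_mean = mean(n_comm), memberships = memberships,
                 gamma = gamma, n_reps = n_reps, neg_mode = neg_mode,
                 seed = seed),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("<community_matrix> %d ROIs, gamma = %g, %d reps, mean %0.1f communities\n",
              nrow(x$coassign), x$gamma, x$n_reps, x$n_communities_mean))
  invisible(x)
}

#' Agreement between two community matrices
#'
#' For each ROI, the Spearman correlation between its co-assignment profile
#' (its row, diagonal entry excluded) in the two matrices; the mean over
#' ROIs summarizes how similar the two community structures are. ROIs with
#' a constant profile in either matrix are excluded with a warning.
#'
#' @param cm_a,cm_b `community_matrix` objects (or plain matrices) with the
#'   same N and ROI order.
#' @return list with `per_roi` (named vector, NA where undefined) and
#'   `mean` (over defined ROIs).
#' @export
community_agreement <- function(cm_a, cm_b) {
  a <- if (inherits(cm_a, "community_matrix")) cm_a$coassign else cm_a
  b <- if (inherits(cm_b, "community_matrix")) cm_b$coassign else cm_b
  stopifnot(nrow(a) == nrow(b))
  n <- nrow(a)
  per_roi <- vapply(seq_len(n), function(i) {
    pa <- a[i, -i]
    pb <- b[i, -i]
    if (sd(pa) == 0 || sd(pb) == 0) return(NA_real_)
    cor(pa, pb, method = "spearman")
  }, numeric(1))
  names(per_roi) <- rownames(a)
  if (anyNA(per_roi))
    warning(sum(is.na(per_roi)),
            " ROI(s) with constant profile excluded from agreement",
            call. = FALSE)
  list(per_roi = per_roi, mean = mean(per_roi, na.rm = TRUE))
}

#' Community-agreement sweep over resolution and filter weight
#'
#' For every (gamma, G): a co-assignment matrix of the filtered group-mean
#' FC, its agreement with the reference community matrix at the same gamma,
#' and the mean community count. Per gamma, the G maximizing agreement is
#' reported, and rows on the agreement-versus-community-count Pareto front
#' are flagged.
#'
#' @param fc_by_G named list (by G) of group-mean FC matrices.
#' @param reference_fc reference FC matrix (its community matrix is computed
#'   per gamma with the same settings), or a precomputed
#'   `community_matrix` list indexed like `gamma_grid`.
#' @param gamma_grid resolution parameters.
#' @param n_reps Louvain repetitions per condition.
#' @param neg_mode negative-weight mode, see [louvain_coassignment()].
#' @param seed integer base seed; each (gamma, G) cell uses the
#'   deterministic substream reported in the output table.
#' @param keep_matrices also return the co-assignment matrices.
#' @return object of class `community_sweep`: `table` (gamma, G, agreement,
#'   n_communities, reference n_communities, cell seed, pareto flag),
#'   `best_G` per gamma, optionally `matrices`.
#' @export
community_sweep <- function(fc_by_G, reference_fc, gamma_grid,
                            n_reps = 200, neg_mode = c("asym", "zero"),
                            seed = 1L, keep_matrices = FALSE) {
  neg_mode <- match.arg(neg_mode)
  stopifnot(length(fc_by_G) > 0, length(gamma_grid) > 0)
  rows <- list()
  mats <- list()
  for (gi in seq_along(gamma_grid)) {
    gamma <- gamma_grid[gi]
    ref_seed <- seed + 100000L * gi
    ref_cm <- if (inherits(reference_fc, "community_matrix") ||
                  (is.list(reference_fc) && !is.matrix(reference_fc)))
      reference_fc[[gi]]
    else louvain_coassignment(reference_fc, gamma = gamma, n_reps = n_reps,
                              neg_mode = neg_mode, seed = ref_seed)
    for (Gi in seq_along(fc_by_G)) {
      cell_seed <- seed + 100000L * gi + 1000L * Gi
      cm <- louvain_coassignment(fc_by_G[[Gi]], gamma = gamma,
                                 n_reps = n_reps, neg_mode = neg_mode,
                                 seed = cell_seed)
      agr <- suppressWarnings(community_agreement(cm, ref_cm))
      rows[[length(rows) + 1L]] <- data.frame(
        gamma = gamma, G = as.numeric(names(fc_by_G)[Gi]),
        agreement = agr$mean, n_communities = cm$n_communities_mean,
        n_communities_ref = ref_cm$n_communities_mean, seed = cell_seed)
      if (keep_matrices)
        mats[[sprintf("gamma%g_G%s", gamma, names(fc_by_G)[Gi])]] <- cm
    }
  }
  tab <- do.call(rbind, rows)
  # Pareto front: maximal agreement, minimal community count
  tab$pareto <- vapply(seq_len(nrow(tab)), function(i) {
    !any(tab$agreement >= tab$agreement[i] &
           tab$n_communities <= tab$n_communities[i] &
           (tab$agreement > tab$agreement[i] |
              tab$n_communities < tab$n_communities[i]))
  }, logical(1))
  best_G <- do.call(rbind, lapply(split(tab, tab$gamma), function(d) {
    i <- which.max(d$agreement)
    data.frame(gamma = d$gamma[1], G_best = d$G[i],
               agreement = d$agreement[i],
               n_communities = d$n_communities[i])
  }))
  rownames(best_G) <- NULL
  out <- list(table = tab, best_G = best_G)
  if (keep_matrices) out$matrices <- mats
  structure(out, class = "community_sweep")
}
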