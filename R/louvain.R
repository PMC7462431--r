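# Louvain community detection on (possibly signed) association matrices,
# with a resolution parameter and the standard asymmetric treatment of
# negative weights: positive and negative modularity contributions are
# weighted by their share of total weight, so negative within-community
# weight is penalized without letting it dominate. Written against the
# dense-matrix formulation used throughout network neuroscience; for
# purely positive graphs it optimizes ordinary Newman-Girvan modularity
# (cross-checked against igraph in the tests).

signed_modularity_matrix <- function(W, gamma, neg_mode) {
  W0 <- pmax(W, 0)
  W1 <- pmax(-W, 0)
  s0 <- sum(W0)
  s1 <- sum(W1)
  if (s0 == 0) stop("no positive weight in matrix", call. = FALSE)
  B <- (W0 - gamma * outer(rowSums(W0), rowSums(W0)) / s0) / s0
  if (neg_mode == "asym" && s1 > 0) {
    B1 <- (W1 - gamma * outer(rowSums(W1), rowSums(W1)) / s1)
    B <- B - B1 / (s0 + s1)
  }
  (B + t(B)) / 2
}

louvain_once <- function(W, gamma = 1, neg_mode = "asym") {
  n <- nrow(W)
  diag(W) <- 0
  B <- signed_modularity_matrix(W, gamma, neg_mode)
  membership <- seq_len(n)
  repeat {
    nB <- nrow(B)
    comm <- seq_len(nB)
    H <- B                     # H[i, c] = sum of B[i, members of c]
    moved_any <- FALSE
    repeat {
      moved <- FALSE
      for (i in sample.int(nB)) {
        ci <- comm[i]
        conn <- H[i, ]
        conn[ci] <- conn[ci] - B[i, i]
        gains <- conn - (H[i, ci] - B[i, i])
        gains[ci] <- 0
        best <- which.max(gains)
        if (gains[best] > 1e-12) {
          H[, ci] <- H[, ci] - B[, i]
          H[, best] <- H[, best] + B[, i]
          comm[i] <- best
          moved <- TRUE
          moved_any <- TRUE
        }
      }
      if (!moved) break
    }
    if (!moved_any) break
    # aggregate communities into super-nodes
    keep <- sort(unique(comm))
    relabel <- match(comm, keep)
    M <- matrix(0, nB, length(keep))
    M[cbind(seq_len(nB), relabel)] <- 1
    B <- t(M) %*% B %*% M
    membership <- relabel[membership]
    if (length(keep) == nB) break
  }
  relabel <- match(membership, sort(unique(membership)))
  list(membership = relabel, n_communities = max(relabel), q = sum(diag(B)))
}
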