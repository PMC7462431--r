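# One-hop low-pass filtering of ROI signals on a filter graph:
# x_hat = (I + G * C) x, applied columnwise over time. Linear, zero-lag,
# no temporal mixing, no renormalization (correlation-based FC is invariant
# to per-ROI scale).

#' Smooth a source epoch on a graph
#'
#' Applies \eqn{\hat x_i(t) = x_i(t) + G \sum_j c_{ij} x_j(t)} at every
#' sample. `G = 0` returns the input untouched.
#'
#' @param epoch a [source_epoch()].
#' @param graph a [filter_graph()][build_filter_graph] (or plain matrix).
#' @param G nonnegative scalar filter weight.
#' @return the filtered [source_epoch()].
#' @export
graph_smooth <- function(epoch, graph, G) {
  stopifnot(G >= 0)
  if (G == 0) return(epoch)
  C <- if (inherits(graph, "filter_graph")) graph$weights else graph
  if (nrow(C) != nrow(epoch$data))
    stop("graph dimension (", nrow(C), ") does not match epoch (",
         nrow(epoch$data), ")", call. = FALSE)
  if (!all(is.finite(epoch$data)))
    stop("non-finite values in epoch", call. = FALSE)
  out <- epoch
  out$data <- epoch$data + G * (C %*% epoch$data)
  dimnames(out$data) <- dimnames(epoch$data)
  out
}

#' Smooth a whole study over a grid of filter weights
#'
#' Filters every interval of every subject independently at every G.
#'
#' @param epochs list (by subject) of lists of [source_epoch()]s.
#' @param graph a [filter_graph()][build_filter_graph].
#' @param G_grid vector of nonnegative filter weights.
#' @return named list over G (names are the G values) of per-subject epoch
#'   lists; identical to calling [graph_smooth()] per epoch.
#' @export
smooth_study <- function(epochs, graph, G_grid) {
  out <- lapply(G_grid, function(G) {
    lapply(epochs, function(subj) lapply(subj, graph_smooth, graph = graph,
                                         G = G))
  })
  names(out) <- as.character(G_grid)
  out
}
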