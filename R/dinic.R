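#' Residual graph of a flow network
#'
#' Builds the standard paired-arc residual representation: every original arc
#' gets a companion reverse arc of capacity 0, and pushing flow on an arc
#' increases the residual of its pair.  All of Dinic's phases operate on this
#' object.
#'
#' @param network a [build_flow_network()] result, or any list with fields
#'   `n`, `s`, `t`, `from`, `to`, `cap` (1-based vertex indices).
#' @return An object of class `residual_graph` with arc vectors `from`, `to`,
#'   residuals `res`, pairing index `pair`, original capacities `orig_cap`
#'   (NA on reverse arcs) and `n_orig`, the number of original arcs.
#' @export
residual_graph <- function(network) {
  m <- length(network$from)
  stopifnot(length(network$to) == m, length(network$cap) == m)
  if (any(!is.finite(network$cap)) || any(network$cap < 0))
    stop("capacities must be finite and nonnegative")
  structure(list(
    n = network$n, s = network$s, t = network$t,
    from = c(network$from, network$to),
    to = c(network$to, network$from),
    res = c(network$cap, rep(0, m)),
    pair = c(seq_len(m) + m, seq_len(m)),
    orig_cap = c(network$cap, rep(NA_real_, m)),
    n_orig = m
  ), class = "residual_graph")
}

#' BFS level assignment of a residual graph
#'
#' Breadth-first distances (in arcs) from `s` through positive-residual arcs:
#' the level graph of one Dinic phase keeps only arcs that step from level
#' `i` to level `i + 1`.  Unreachable vertices get `NA`; `t` unreachable
#' signals termination of the algorithm.
#'
#' @param residual a [residual_graph()].
#' @param s source vertex (default: the graph's source).
#' @param tol residual capacities at or below `tol` count as saturated
#'   (default 1e-9).
#' @return Integer vector of levels (`level[s] == 0`), `NA` = unreachable.
#' @export
bfs_levels <- function(residual, s = residual$s, tol = 1e-9) {
  lev <- cpp_bfs_levels(residual$n, residual$from - 1L, residual$to - 1L,
                        residual$res, s - 1L, tol)
  lev[lev < 0] <- NA_integer_
  lev
}

#' Blocking flow in the level graph
#'
#' Depth-first augmentation (current-arc rule, explicit stack) until every
#' s-t path in the level graph contains a saturated arc.  Called with `t`
#' unreachable it is a no-op returning increment 0.
#'
#' @param residual a [residual_graph()].
#' @param levels level assignment from [bfs_levels()].
#' @param s,t terminals (defaults: the graph's).
#' @param tol saturation tolerance.
#' @return List: `residual` (updated) and `increment` (flow added, >= 0).
#' @export
blocking_flow <- function(residual, levels, s = residual$s, t = residual$t,
                          tol = 1e-9) {
  lev <- levels
  lev[is.na(lev)] <- -1L
  out <- cpp_blocking_flow(residual$n, residual$from - 1L, residual$to - 1L,
                           residual$pair - 1L, residual$res,
                           as.integer(lev), s - 1L, t - 1L, tol)
  residual$res <- out$res
  list(residual = residual, increment = out$increment)
}

#' Maximum s-t flow by Dinic's algorithm
#'
#' Repeats BFS level-graph construction and DFS blocking flow until the sink
#' is unreachable in the residual graph.  By the max-flow/min-cut theorem the
#' total flow equals the capacity of the minimum s-t cut, which is how the
#' segmentation is read off afterwards.
#'
#' @param network a [build_flow_network()] result (or compatible arc list).
#' @param tol saturation tolerance for residual capacities (default 1e-9).
#' @return An object of class `max_flow_result`: `flow` (total value),
#'   `residual` (the converged [residual_graph()]), and `phase_levels`, the
#'   BFS distance of `t` at each phase (strictly increasing — the classical
#'   Dinic progress guarantee).
#' @export
max_flow <- function(network, tol = 1e-9) {
  rg <- if (inherits(network, "residual_graph")) network else residual_graph(network)
  out <- cpp_dinic(rg$n, rg$from - 1L, rg$to - 1L, rg$pair - 1L, rg$res,
                   rg$s - 1L, rg$t - 1L, tol)
  rg$res <- out$res
  structure(list(flow = out$flow, residual = rg, phase_levels = out$t_levels),
            class = "max_flow_result")
}

#' @export
print.max_flow_result <- function(x, ...) {
  cat(sprintf("max_flow_result: flow = %.6g after %d Dinic phases\n",
              x$flow, length(x$phase_levels)))
  invisible(x)
}

#' Minimum s-t cut from a converged residual graph
#'
#' `S` is the set of vertices reachable from `s` through positive-residual
#' arcs; `T` is the rest.  The capacity of the cut (sum of original
#' capacities of arcs from `S` to `T`) equals the maximum flow.  Pixels in
#' `S` form the segmented object.
#'
#' @param residual the converged [residual_graph()] from [max_flow()] (or a
#'   `max_flow_result`).
#' @param s source vertex.
#' @param tol saturation tolerance.
#' @return List with logical membership vector `in_S`, vertex index sets `S`
#'   and `T`, and `cut_capacity`.
#' @export
min_cut_partition <- function(residual, s = NULL, tol = 1e-9) {
  if (inherits(residual, "max_flow_result")) residual <- residual$residual
  if (is.null(s)) s <- residual$s
  reach <- cpp_reachable(residual$n, residual$from - 1L, residual$to - 1L,
                         residual$res, s - 1L, tol)
  if (reach[residual$t])
    stop("residual graph is not converged: t is still reachable from s")
  orig <- seq_len(residual$n_orig)
  crossing <- reach[residual$from[orig]] & !reach[residual$to[orig]]
  list(in_S = reach,
       S = which(reach), T = which(!reach),
       cut_capacity = sum(residual$orig_cap[orig][crossing]))
}

# Raw segmentation mask (ROI-shaped 0/1 matrix) from a solved network.
cut_to_mask <- function(network, partition) {
  in_obj <- partition$in_S[seq_len(network$n_pixels)]
  # pixel vertex ids are row-major; fill by row
  matrix(as.integer(in_obj), network$height, network$width, byrow = TRUE)
}
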