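# Seeded force-directed layout.  A small Fruchterman-Reingold-style loop:
# every node pair repels with magnitude proportional to `repulsion`, every
# edge attracts with magnitude proportional to distance^2 / `attraction`,
# displacement is capped by a geometrically cooling temperature.  Fully
# deterministic given the layout seed (only the initial scatter is random).

#' Compute node coordinates for a network
#'
#' Force-directed placement of the network nodes.  The `repulsion` and
#' `attraction` parameters of the [NetworkConfig-class] (defaults 160 and
#' 80) scale the repulsive and attractive force terms; larger repulsion
#' spreads the graph, larger attraction loosens edges (the attractive force
#' divides by it).  Repeated calls with the same `layoutSeed` give
#' identical coordinates.  A single node is placed at the origin.
#'
#' @param network a [CorrelationNetwork-class].
#' @param config a [NetworkConfig-class].
#' @param iterations number of force iterations.
#' @return numeric matrix with one row per node (rownames = node IDs) and
#'   columns `x`, `y`; all coordinates finite.
#' @export
layoutNetwork <- function(network, config = networkConfig(),
                          iterations = 150L) {
  stopifnot(is(network, "CorrelationNetwork"), is(config, "NetworkConfig"))
  ids <- networkNodes(network)$id
  n <- length(ids)
  if (n == 0L) stop("cannot lay out an empty network")
  if (n == 1L) {
    pos <- matrix(0, 1L, 2L, dimnames = list(ids, c("x", "y")))
    return(pos)
  }
  pos <- .withSeed(config@layoutSeed,
                   matrix(stats::runif(2L * n, -1, 1), n, 2L))
  dimnames(pos) <- list(ids, c("x", "y"))

  e <- networkEdges(network)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(e)) {
    A[cbind(e$from, e$to)] <- 1
    A[cbind(e$to, e$from)] <- 1
  }
  kRep <- config@repulsion * 0.01
  kAtt <- config@attraction * 0.1
  eps <- 1e-9
  temp <- 1
  for (it in seq_len(iterations)) {
    dx <- outer(pos[, 1L], pos[, 1L], "-")
    dy <- outer(pos[, 2L], pos[, 2L], "-")
    d <- sqrt(dx * dx + dy * dy)
    d[d < eps] <- eps
    # repulsion ~ kRep / d, applied along the unit direction
    fr <- kRep / (d * d)
    diag(fr) <- 0
    dispx <- rowSums(dx * fr)
    dispy <- rowSums(dy * fr)
    # attraction ~ d^2 / kAtt along edges
    fa <- A * d / kAtt
    dispx <- dispx - rowSums(dx * fa)
    dispy <- dispy - rowSums(dy * fa)
    len <- sqrt(dispx^2 + dispy^2)
    len[len < eps] <- eps
    scale <- pmin(len, temp) / len
    pos[, 1L] <- pos[, 1L] + dispx * scale
    pos[, 2L] <- pos[, 2L] + dispy * scale
    temp <- temp * 0.97
  }
  stopifnot(all(is.finite(pos)))
  pos
}
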