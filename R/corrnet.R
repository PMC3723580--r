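# Correlation networking: PCC matrix, thresholded graph construction,
# cluster extraction and ranking.

#' Pearson correlation matrix across omics layers
#'
#' Stacks one to three omics tables that share an identical condition-label
#' sequence and computes the Pearson correlation coefficient between every
#' pair of molecules, using pairwise-complete observations.  A pair is
#' *undefined* (`NA`, never 0) when fewer than `minSharedObs` conditions are
#' jointly observed or when either profile has zero variance over the shared
#' conditions; undefined pairs produce no network edge.
#'
#' @param tables an [OmicsTable-class] or list of 1-3 of them (distinct
#'   layers) with identical condition labels in identical order.
#' @param minSharedObs minimum pairwise complete observations (default 3).
#' @return symmetric numeric matrix with unit diagonal and attribute
#'   `layers` (named layer code per molecule).
#' @examples
#' m <- matrix(c(1, 2, 3, 3, 2, 1), 2, 3, byrow = TRUE,
#'             dimnames = list(c("10", "20"), c("c1", "c2", "c3")))
#' correlationMatrix(omicsTable(m, "T"))
#' @export
correlationMatrix <- function(tables, minSharedObs = 3) {
  if (is(tables, "OmicsTable")) tables <- list(tables)
  stopifnot(length(tables) >= 1L, length(tables) <= 3L,
            all(vapply(tables, is, logical(1L), "OmicsTable")))
  conds <- lapply(tables, conditionLabels)
  ref <- conds[[1L]]
  for (i in seq_along(conds)[-1L]) {
    if (!identical(conds[[i]], ref)) {
      onlyA <- setdiff(ref, conds[[i]])
      onlyB <- setdiff(conds[[i]], ref)
      stop("condition labels differ across tables",
           if (length(onlyA)) paste0("; only in table 1: ",
                                     paste(onlyA, collapse = ", ")) else "",
           if (length(onlyB)) paste0("; only in table ", i, ": ",
                                     paste(onlyB, collapse = ", ")) else "",
           if (!length(onlyA) && !length(onlyB)) " (same labels, different order)"
           else "")
    }
  }
  layers <- vapply(tables, omicsLayer, character(1L))
  if (anyDuplicated(layers)) stop("tables must come from distinct layers")
  X <- do.call(rbind, lapply(tables, omicsValues))
  if (anyDuplicated(rownames(X)))
    stop("molecule IDs collide across layers: ",
         paste(unique(rownames(X)[duplicated(rownames(X))]), collapse = ", "))
  nodeLayers <- rep(layers, vapply(tables, function(t) nrow(omicsValues(t)),
                                   integer(1L)))
  names(nodeLayers) <- rownames(X)

  cc <- suppressWarnings(stats::cor(t(X), use = "pairwise.complete.obs"))
  # pairwise complete observation counts
  obs <- crossprod(t(!is.na(X)))
  cc[obs < minSharedObs] <- NA_real_
  diag(cc) <- 1
  attr(cc, "layers") <- nodeLayers
  cc
}

.canonicalEdges <- function(a, b) {
  swap <- a > b
  data.frame(from = ifelse(swap, b, a), to = ifelse(swap, a, b))
}

#' Build the correlation network
#'
#' Thresholds the PCC matrix into an undirected graph: a solid correlation
#' edge joins molecules whose correlation is strictly greater than
#' `pccThreshold` (or whose absolute correlation is, when `useAbsolute`),
#' and dotted literature edges join each bridged molecule of the missing
#' layer to the measured molecules it co-occurs with in a relation triple.
#' Measured molecules that end up with no edge stay in the node table (they
#' are drawn) but never enter a cluster.
#'
#' @param mat correlation matrix from [correlationMatrix()].
#' @param config a [NetworkConfig-class]; `networkConfig()` gives the
#'   defaults (threshold 0.9).
#' @param bridged optional output of [bridgeMissingLayer()].
#' @return a [CorrelationNetwork-class] (clusters not yet computed; see
#'   [findClusters()]).
#' @export
buildNetwork <- function(mat, config = networkConfig(), bridged = NULL) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat),
            is(config, "NetworkConfig"))
  validObject(config)
  layers <- attr(mat, "layers")
  if (is.null(layers))
    stop("correlation matrix must carry the 'layers' attribute ",
         "(build it with correlationMatrix())")
  ids <- rownames(mat)
  nodes <- data.frame(id = ids, layer = unname(layers[ids]),
                      origin = "measured", row.names = NULL)

  thr <- config@pccThreshold
  ut <- upper.tri(mat)
  w <- mat[ut]
  pass <- if (config@useAbsolute) !is.na(w) & abs(w) > thr
          else !is.na(w) & w > thr
  idx <- which(ut, arr.ind = TRUE)[pass, , drop = FALSE]
  edges <- if (nrow(idx)) {
    ce <- .canonicalEdges(ids[idx[, 1L]], ids[idx[, 2L]])
    data.frame(ce, weight = w[pass], kind = "correlation")
  } else {
    data.frame(from = character(), to = character(),
               weight = numeric(), kind = character())
  }

  if (!is.null(bridged) && nrow(bridged)) {
    bn <- data.frame(id = bridged$id, layer = bridged$layer,
                     origin = "literature", row.names = NULL)
    nodes <- rbind(nodes, bn[!bn$id %in% nodes$id, , drop = FALSE])
    le <- do.call(rbind, lapply(seq_len(nrow(bridged)), function(i) {
      linked <- bridged$linked[[i]]
      ce <- .canonicalEdges(rep(bridged$id[i], length(linked)), linked)
      data.frame(ce, weight = NA_real_, kind = "literature")
    }))
    le <- le[!duplicated(le[, c("from", "to")]), , drop = FALSE]
    edges <- rbind(edges, le)
  }
  edges <- edges[order(edges$kind, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  new("CorrelationNetwork", nodes = nodes, edges = edges, clusters = list())
}

#' Extract and rank network clusters
#'
#' Clusters are the connected components of the network with at least two
#' members (singletons are drawn but not ranked).  By default both
#' correlation and literature edges connect; set
#' `includeLiteratureEdges = FALSE` to cluster on measured correlations
#' only.  Components are ordered by decreasing size, ties broken by the
#' lexicographically smallest member ID; members are sorted within each
#' cluster.
#'
#' @param network a [CorrelationNetwork-class].
#' @param includeLiteratureEdges logical.
#' @return the network with its `clusters` slot filled.
#' @seealso [clusterSummary()]
#' @export
findClusters <- function(network, includeLiteratureEdges = TRUE) {
  stopifnot(is(network, "CorrelationNetwork"))
  e <- networkEdges(network)
  if (!includeLiteratureEdges)
    e <- e[e$kind == "correlation", , drop = FALSE]
  if (nrow(e) == 0L) {
    network@clusters <- list()
    return(network)
  }
  g <- igraph::graph_from_data_frame(e[, c("from", "to")], directed = FALSE,
                                     vertices = networkNodes(network)$id)
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  groups <- groups[lengths(groups) >= 2L]
  groups <- lapply(groups, sort)
  ord <- order(-lengths(groups),
               vapply(groups, `[`, character(1L), 1L))
  network@clusters <- unname(groups[ord])
  validObject(network)
  network
}

#' Cluster summary table
#'
#' @param network a [CorrelationNetwork-class] with clusters computed.
#' @return `data.frame` with columns `rank`, `size` and `;`-joined
#'   `members`, ranked by descending size.
#' @export
clusterSummary <- function(network) {
  cl <- networkClusters(network)
  data.frame(rank = seq_along(cl), size = lengths(cl),
             members = vapply(cl, paste, character(1L), collapse = ";"),
             row.names = NULL)
}
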