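# Coexpression profiling: hierarchical clustering of the stacked omics
# matrix by Euclidean distance, and a deterministic SVG heatmap with
# cyan-to-pink colorization and per-row omics colour codes.

#' Coexpression clustering of one to three omics tables
#'
#' Stacks the tables (identical condition labels required), drops rows with
#' any missing value (with a warning), then clusters rows and columns by
#' agglomerative hierarchical clustering on Euclidean distances.  The
#' colour matrix maps the global minimum to 0 (cyan) and the global maximum
#' to 1 (pink); a constant matrix maps everything to 0.5.  No scaling is
#' applied by default — cells are coloured by the input expression value —
#' but `scale = "row_z"` standardises each row to mean 0, variance 1 first
#' (constant rows are dropped, since a z-score is undefined for them).
#'
#' @param tables an [OmicsTable-class] or list of 1-3 of them.
#' @param scale `"none"` (default) or `"row_z"`.
#' @param linkage agglomeration rule: `"complete"` (default), `"single"`
#'   or `"average"`.
#' @return a [CoexpressionResult-class].
#' @examples
#' m <- matrix(rnorm(12), 4, 3,
#'             dimnames = list(as.character(1:4), c("a", "b", "c")))
#' coexpression(omicsTable(m, "T"))
#' @export
coexpression <- function(tables, scale = c("none", "row_z"),
                         linkage = c("complete", "single", "average")) {
  scale <- match.arg(scale)
  linkage <- match.arg(linkage)
  if (is(tables, "OmicsTable")) tables <- list(tables)
  stopifnot(length(tables) >= 1L, length(tables) <= 3L,
            all(vapply(tables, is, logical(1L), "OmicsTable")))
  ref <- conditionLabels(tables[[1L]])
  for (t in tables[-1L])
    if (!identical(conditionLabels(t), ref))
      stop("condition labels differ across tables")
  X <- do.call(rbind, lapply(tables, omicsValues))
  rowTypes <- rep(vapply(tables, omicsLayer, character(1L)),
                  vapply(tables, function(t) nrow(omicsValues(t)), integer(1L)))
  if (anyDuplicated(rownames(X)))
    stop("molecule IDs collide across layers: ",
         paste(unique(rownames(X)[duplicated(rownames(X))]), collapse = ", "))

  hasNA <- rowSums(is.na(X)) > 0L
  if (any(hasNA)) {
    warning(sum(hasNA), " row(s) with missing values dropped: ",
            paste(utils::head(rownames(X)[hasNA], 5L), collapse = ", "),
            if (sum(hasNA) > 5L) ", ..." else "")
    X <- X[!hasNA, , drop = FALSE]
    rowTypes <- rowTypes[!hasNA]
  }
  if (scale == "row_z") {
    sds <- apply(X, 1L, stats::sd)
    flat <- sds == 0
    if (any(flat)) {
      warning(sum(flat), " constant row(s) dropped under row_z scaling: ",
              paste(utils::head(rownames(X)[flat], 5L), collapse = ", "))
      X <- X[!flat, , drop = FALSE]
      rowTypes <- rowTypes[!flat]
      sds <- sds[!flat]
    }
    X <- (X - rowMeans(X)) / sds
  }
  if (nrow(X) < 2L || ncol(X) < 2L)
    stop("need at least 2 rows and 2 columns to build dendrograms (have ",
         nrow(X), " x ", ncol(X), ")")

  rowTree <- stats::hclust(stats::dist(X), method = linkage)
  colTree <- stats::hclust(stats::dist(t(X)), method = linkage)
  rng <- range(X)
  colorMatrix <- if (rng[1L] == rng[2L])
    matrix(0.5, nrow(X), ncol(X), dimnames = dimnames(X))
  else (X - rng[1L]) / (rng[2L] - rng[1L])

  new("CoexpressionResult", values = X,
      rowOrder = as.integer(rowTree$order),
      colOrder = as.integer(colTree$order),
      rowTree = rowTree, colTree = colTree,
      colorMatrix = colorMatrix, rowTypes = rowTypes)
}

# cyan (lowest) -> pink (highest)
.heatColor <- function(v) {
  lo <- c(0, 255, 255); hi <- c(255, 192, 203)
  rgb <- round(lo + v * (hi - lo))
  sprintf("#%02X%02X%02X", rgb[1L], rgb[2L], rgb[3L])
}

# dendrogram segments for an hclust tree, in (leaf position, height) space
.dendroSegments <- function(hc) {
  n <- length(hc$order)
  leafX <- numeric(n)
  leafX[hc$order] <- seq_len(n)
  posX <- numeric(nrow(hc$merge))
  posH <- numeric(nrow(hc$merge))
  segs <- NULL
  childXH <- function(ch)
    if (ch < 0) c(leafX[-ch], 0) else c(posX[ch], posH[ch])
  for (i in seq_len(nrow(hc$merge))) {
    a <- childXH(hc$merge[i, 1L])
    b <- childXH(hc$merge[i, 2L])
    xs <- c(a[1L], b[1L])
    hs <- c(a[2L], b[2L])
    h <- hc$height[i]
    posX[i] <- mean(xs)
    posH[i] <- h
    segs <- rbind(segs,
                  c(xs[1L], hs[1L], xs[1L], h),   # riser left child
                  c(xs[2L], hs[2L], xs[2L], h),   # riser right child
                  c(xs[1L], h, xs[2L], h))        # crossbar
  }
  colnames(segs) <- c("x1", "y1", "x2", "y2")
  segs
}

#' Render a coexpression heatmap as SVG
#'
#' Cells are laid out in dendrogram leaf order (rows and columns), each
#' drawn as a `rect` of class `cell` coloured cyan (lowest) to pink
#' (highest).  Row and column dendrograms are drawn to the left and on top;
#' a colour strip along the rows encodes the omics source of each row
#' (green = transcriptomics, red = proteomics, blue = metabolomics).
#' Output bytes depend only on the result object, so identical inputs give
#' identical files.
#'
#' @param result a [CoexpressionResult-class].
#' @param path output SVG path.
#' @param cell cell size in pixels.
#' @return `path`, invisibly.
#' @export
renderHeatmap <- function(result, path, cell = 18L) {
  stopifnot(is(result, "CoexpressionResult"))
  cm <- result@colorMatrix
  ro <- result@rowOrder
  co <- result@colOrder
  nr <- nrow(cm); nc <- ncol(cm)
  dendW <- 70; strip <- 10; labW <- 60; labH <- 46
  x0 <- dendW + strip + 2
  y0 <- dendW + 2
  width <- as.integer(x0 + nc * cell + labW)
  height <- as.integer(y0 + nr * cell + labH)
  out <- .svgHeader(width, height)

  scaleH <- function(h, hmax) if (hmax > 0) h / hmax * (dendW - 6) else 0
  rs <- .dendroSegments(result@rowTree)
  hmax <- max(result@rowTree$height, 0)
  for (i in seq_len(nrow(rs)))
    out <- c(out, sprintf(
      "<line class=\"rowdend\" x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"#333333\" stroke-width=\"1\"/>",
      .fmtCoord(dendW - scaleH(rs[i, "y1"], hmax)),
      .fmtCoord(y0 + (rs[i, "x1"] - 0.5) * cell),
      .fmtCoord(dendW - scaleH(rs[i, "y2"], hmax)),
      .fmtCoord(y0 + (rs[i, "x2"] - 0.5) * cell)))
  cs <- .dendroSegments(result@colTree)
  hmaxC <- max(result@colTree$height, 0)
  for (i in seq_len(nrow(cs)))
    out <- c(out, sprintf(
      "<line class=\"coldend\" x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"#333333\" stroke-width=\"1\"/>",
      .fmtCoord(x0 + (cs[i, "x1"] - 0.5) * cell),
      .fmtCoord(dendW - scaleH(cs[i, "y1"], hmaxC)),
      .fmtCoord(x0 + (cs[i, "x2"] - 0.5) * cell),
      .fmtCoord(dendW - scaleH(cs[i, "y2"], hmaxC))))

  for (ri in seq_len(nr)) {
    r <- ro[ri]
    out <- c(out, sprintf(
      "<rect class=\"rowtype\" x=\"%s\" y=\"%s\" width=\"%d\" height=\"%d\" fill=\"%s\"/>",
      .fmtCoord(dendW + 1), .fmtCoord(y0 + (ri - 1) * cell),
      strip, cell, .LAYER_COLOR[[result@rowTypes[r]]]))
    for (ci in seq_len(nc)) {
      cidx <- co[ci]
      out <- c(out, sprintf(
        "<rect class=\"cell\" x=\"%s\" y=\"%s\" width=\"%d\" height=\"%d\" fill=\"%s\"/>",
        .fmtCoord(x0 + (ci - 1) * cell), .fmtCoord(y0 + (ri - 1) * cell),
        cell, cell, .heatColor(cm[r, cidx])))
    }
    out <- c(out, sprintf(
      "<text x=\"%s\" y=\"%s\" font-size=\"9\" font-family=\"sans-serif\">%s</text>",
      .fmtCoord(x0 + nc * cell + 4), .fmtCoord(y0 + (ri - 0.35) * cell),
      rownames(cm)[r]))
  }
  for (ci in seq_len(nc))
    out <- c(out, sprintf(
      "<text x=\"%s\" y=\"%s\" font-size=\"9\" font-family=\"sans-serif\" transform=\"rotate(90 %s %s)\">%s</text>",
      .fmtCoord(x0 + (ci - 0.65) * cell), .fmtCoord(y0 + nr * cell + 6),
      .fmtCoord(x0 + (ci - 0.65) * cell), .fmtCoord(y0 + nr * cell + 6),
      colnames(cm)[co[ci]]))

  out <- c(out, "</svg>")
  con <- tryCatch(file(path, "w"), error = function(err)
    stop("cannot write SVG file: ", path))
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}
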