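# Network export: SIF for Cytoscape import, SVG and PNG scenes.

.LAYER_COLOR <- c(T = "#2ca02c", P = "#d62728", M = "#1f77b4")

#' Export a network in SIF format
#'
#' One tab-separated line per edge, `source<TAB>relation<TAB>target`, with
#' relation `cor` for correlation edges and `lit` for literature edges.
#' Lines are sorted lexicographically so the file is canonical; an empty
#' network yields an empty (zero-line) file.  SIF files import directly
#' into Cytoscape and similar editors.
#'
#' @param network a [CorrelationNetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [readSIF()]
#' @export
exportSIF <- function(network, path) {
  stopifnot(is(network, "CorrelationNetwork"))
  e <- networkEdges(network)
  rel <- c(correlation = "cor", literature = "lit")[e$kind]
  lines <- sprintf("%s\t%s\t%s", e$from, rel, e$to)
  con <- tryCatch(file(path, "w"), error = function(err)
    stop("cannot write SIF file: ", path))
  on.exit(close(con))
  writeLines(sort(lines), con)
  invisible(path)
}

#' Read a SIF file back into an edge table
#'
#' @param path a SIF file written by [exportSIF()] (or any 3-column SIF).
#' @return `data.frame` with columns `from`, `relation`, `to`.
#' @export
readSIF <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(from = character(), relation = character(),
                      to = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("malformed SIF line: ", lines[which(lengths(parts) != 3L)[1L]])
  data.frame(from = vapply(parts, `[`, character(1L), 1L),
             relation = vapply(parts, `[`, character(1L), 2L),
             to = vapply(parts, `[`, character(1L), 3L))
}

.svgHeader <- function(w, h)
  c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<svg xmlns=\"http://www.w3.org/2000/svg\" version=\"1.1\" width=\"%d\" height=\"%d\" viewBox=\"0 0 %d %d\">",
            w, h, w, h))

.fmtCoord <- function(x) sprintf("%.2f", x)

#' Export a network scene as SVG
#'
#' Draws the laid-out network with the field's node-shape conventions:
#' squares for transcripts, triangles for proteins, circles for
#' metabolites, coloured green/red/blue respectively.  Correlation edges
#' are solid lines; literature-derived edges are dotted.  Output is
#' deterministic for a fixed layout.
#'
#' @param network a [CorrelationNetwork-class].
#' @param coords coordinate matrix from [layoutNetwork()].
#' @param path output path.
#' @param size canvas size in pixels.
#' @param labels draw node ID labels.
#' @return `path`, invisibly.
#' @export
exportNetworkSVG <- function(network, coords, path, size = 640L,
                             labels = TRUE) {
  stopifnot(is(network, "CorrelationNetwork"), is.matrix(coords))
  nodes <- networkNodes(network)
  stopifnot(all(nodes$id %in% rownames(coords)))
  pad <- 40
  xy <- coords[nodes$id, , drop = FALSE]
  rng <- apply(xy, 2L, range)
  span <- pmax(rng[2L, ] - rng[1L, ], 1e-6)
  sx <- pad + (xy[, 1L] - rng[1L, 1L]) / span[1L] * (size - 2 * pad)
  sy <- pad + (xy[, 2L] - rng[1L, 2L]) / span[2L] * (size - 2 * pad)
  names(sx) <- names(sy) <- nodes$id

  out <- .svgHeader(size, size)
  e <- networkEdges(network)
  for (i in seq_len(nrow(e))) {
    dash <- if (e$kind[i] == "literature")
      " stroke-dasharray=\"5,4\"" else ""
    out <- c(out, sprintf(
      "<line class=\"edge %s\" x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"#777777\" stroke-width=\"1.2\"%s/>",
      e$kind[i], .fmtCoord(sx[e$from[i]]), .fmtCoord(sy[e$from[i]]),
      .fmtCoord(sx[e$to[i]]), .fmtCoord(sy[e$to[i]]), dash))
  }
  r <- 7
  for (i in seq_len(nrow(nodes))) {
    x <- sx[nodes$id[i]]; y <- sy[nodes$id[i]]
    col <- .LAYER_COLOR[[nodes$layer[i]]]
    shape <- switch(nodes$layer[i],
      T = sprintf("<rect class=\"node\" x=\"%s\" y=\"%s\" width=\"%d\" height=\"%d\" fill=\"%s\"/>",
                  .fmtCoord(x - r), .fmtCoord(y - r), 2L * r, 2L * r, col),
      P = sprintf("<polygon class=\"node\" points=\"%s,%s %s,%s %s,%s\" fill=\"%s\"/>",
                  .fmtCoord(x), .fmtCoord(y - r),
                  .fmtCoord(x - r), .fmtCoord(y + r),
                  .fmtCoord(x + r), .fmtCoord(y + r), col),
      M = sprintf("<circle class=\"node\" cx=\"%s\" cy=\"%s\" r=\"%d\" fill=\"%s\"/>",
                  .fmtCoord(x), .fmtCoord(y), r, col))
    out <- c(out, shape)
    if (labels)
      out <- c(out, sprintf(
        "<text x=\"%s\" y=\"%s\" font-size=\"9\" font-family=\"sans-serif\">%s</text>",
        .fmtCoord(x + r + 2), .fmtCoord(y + 3), nodes$id[i]))
  }
  out <- c(out, "</svg>")
  con <- tryCatch(file(path, "w"), error = function(err)
    stop("cannot write SVG file: ", path))
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Export a network scene as PNG
#'
#' Raster rendering of the same scene as [exportNetworkSVG()] through the
#' base graphics device.  Requires PNG support in the R build; if absent,
#' the function warns and writes nothing.
#'
#' @inheritParams exportNetworkSVG
#' @param width,height raster size in pixels.
#' @return `path` invisibly, or `NULL` when PNG support is unavailable.
#' @export
exportNetworkPNG <- function(network, coords, path, width = 800L,
                             height = 800L) {
  if (!capabilities("png")) {
    warning("this R build has no PNG device; skipping ", path)
    return(invisible(NULL))
  }
  nodes <- networkNodes(network)
  e <- networkEdges(network)
  xy <- coords[nodes$id, , drop = FALSE]
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::plot(xy, type = "n", axes = FALSE, xlab = "", ylab = "", asp = 1)
  if (nrow(e)) {
    lit <- e$kind == "literature"
    graphics::segments(xy[e$from, 1L], xy[e$from, 2L],
                       xy[e$to, 1L], xy[e$to, 2L],
                       col = "grey50", lty = ifelse(lit, 3L, 1L))
  }
  pch <- c(T = 15L, P = 17L, M = 16L)[nodes$layer]
  graphics::points(xy, pch = pch, col = .LAYER_COLOR[nodes$layer], cex = 1.6)
  graphics::text(xy[, 1L], xy[, 2L], nodes$id, pos = 4L, cex = 0.6)
  invisible(path)
}
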