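# The analysis-availability matrix: which of the five analyses each
# combination of uploaded omics layers supports, and which missing layer is
# bridged from the literature in two-layer modes.

.ANALYSES <- c("correlation", "coexpression", "phenotype",
               "pathway_enrichment", "go_enrichment")

.MODES <- list("T-P-M" = c("T", "P", "M"), "T-P" = c("T", "P"),
               "P-M" = c("P", "M"), "T-M" = c("T", "M"),
               "T" = "T", "P" = "P", "M" = "M")

#' Normalise a set of omics layers into an analysis mode
#'
#' @param layers character vector, subset of `c("T", "P", "M")`.
#' @return the mode label, one of `"T-P-M"`, `"T-P"`, `"P-M"`, `"T-M"`,
#'   `"T"`, `"P"`, `"M"`.
#' @examples
#' analysisMode(c("M", "T"))
#' @export
analysisMode <- function(layers) {
  layers <- unique(as.character(layers))
  if (length(layers) == 0L || !all(layers %in% c("T", "P", "M")))
    stop("layers must be a non-empty subset of T, P, M")
  paste(c("T", "P", "M")[c("T", "P", "M") %in% layers], collapse = "-")
}

#' The capability matrix of analysis availability
#'
#' One row per analysis mode (the seven layer combinations), one column per
#' analysis, each cell the availability statement: `"Yes"`, `"No"`, or for
#' correlation analysis in a two-layer mode the bridging annotation
#' `"Yes, <layer> is derived from the literature."`.  Correlation and
#' coexpression are available in every mode; phenotype mapping needs
#' transcripts or proteins (not metabolites alone); pathway enrichment
#' needs metabolomics data; GO enrichment needs transcriptomics data.
#'
#' @return `data.frame` with columns `mode`, the five analysis columns,
#'   and `bridged_layer` (`NA` outside two-layer modes).
#' @export
capabilityMatrix <- function() {
  modes <- names(.MODES)
  rows <- lapply(modes, function(md) {
    ly <- .MODES[[md]]
    bridged <- if (length(ly) == 2L) setdiff(c("T", "P", "M"), ly)
               else NA_character_
    data.frame(
      mode = md,
      correlation = if (!is.na(bridged))
        sprintf("Yes, %s is derived from the literature.", bridged)
      else "Yes",
      coexpression = "Yes",
      phenotype = if (identical(ly, "M")) "No" else "Yes",
      pathway_enrichment = if ("M" %in% ly) "Yes" else "No",
      go_enrichment = if ("T" %in% ly) "Yes" else "No",
      bridged_layer = bridged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.analysisAllowed <- function(mode, analysis) {
  cm <- capabilityMatrix()
  cell <- cm[cm$mode == mode, analysis]
  startsWith(cell, "Yes")
}

#' Plan an analysis run against the capability matrix
#'
#' Validates the requested analyses for the given layer combination.  An
#' explicitly requested analysis that the mode does not support fails fast
#' with the capability rule; `analyses = "all"` expands to everything the
#' mode supports.  In a two-layer mode with correlation analysis planned,
#' the plan records the missing layer to be bridged from the literature.
#'
#' @param layers character vector of available layers (or a mode label such
#'   as `"T-P"`).
#' @param analyses `"all"` or a character vector from
#'   `correlation`, `coexpression`, `phenotype`, `pathway_enrichment`,
#'   `go_enrichment`.
#' @return a list of class `omicsAnalysisPlan` with elements `mode`,
#'   `layers`, `analyses` and `bridgedLayer` (`NA` if no bridging).
#' @examples
#' planAnalyses(c("T", "P"))                      # bridges M
#' try(planAnalyses("M", "phenotype"))            # capability error
#' @export
planAnalyses <- function(layers, analyses = "all") {
  mode <- if (length(layers) == 1L && grepl("-", layers)) {
    if (!layers %in% names(.MODES)) stop("unknown mode label: ", layers)
    layers
  } else analysisMode(layers)
  ly <- .MODES[[mode]]
  cm <- capabilityMatrix()
  row <- cm[cm$mode == mode, ]

  if (identical(analyses, "all")) {
    analyses <- .ANALYSES[vapply(.ANALYSES, function(a)
      .analysisAllowed(mode, a), logical(1L))]
  } else {
    bad <- setdiff(analyses, .ANALYSES)
    if (length(bad)) stop("unknown analysis type(s): ",
                          paste(bad, collapse = ", "))
    for (a in analyses)
      if (!.analysisAllowed(mode, a))
        stop(sprintf(
          "analysis '%s' is not available in mode %s (capability matrix: \"%s\")",
          a, mode, row[[a]]))
  }
  bridged <- if ("correlation" %in% analyses) row$bridged_layer
             else NA_character_
  structure(list(mode = mode, layers = ly, analyses = analyses,
                 bridgedLayer = bridged),
            class = "omicsAnalysisPlan")
}

#' @export
print.omicsAnalysisPlan <- function(x, ...) {
  cat("Analysis plan for mode", x$mode, "\n")
  cat("  analyses:", paste(x$analyses, collapse = ", "), "\n")
  if (!is.na(x$bridgedLayer))
    cat("  bridging:", x$bridgedLayer, "is derived from the literature\n")
  invisible(x)
}
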