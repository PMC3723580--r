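#' @import methods
NULL

# Layer codes <-> identifier namespaces.  One omics layer carries exactly one
# identifier type: transcripts are Entrez Gene IDs (digits), proteins are
# UniProtKB accessions, metabolites are PubChem CIDs (digits).
.LAYERS <- c("T", "P", "M")
.LAYER_NAMESPACE <- c(T = "gene", P = "protein", M = "metabolite")
.NAMESPACE_LAYER <- c(gene = "T", protein = "P", metabolite = "M")

#' Validate molecule identifiers for a namespace
#'
#' Entrez Gene IDs and PubChem CIDs are strings of digits; UniProtKB
#' accessions start with a letter and contain only alphanumerics, dots,
#' underscores or dashes.  All identifiers must be non-empty and free of
#' whitespace and commas.
#'
#' @param ids character vector of identifiers.
#' @param namespace one of `"gene"`, `"protein"`, `"metabolite"`.
#' @return logical vector, `TRUE` where the identifier is well-formed.
#' @examples
#' validMoleculeId(c("1234", "12x"), "gene")
#' validMoleculeId("Q15788", "protein")
#' @export
validMoleculeId <- function(ids, namespace = c("gene", "protein", "metabolite")) {
  namespace <- match.arg(namespace)
  ids <- as.character(ids)
  ok <- nzchar(ids) & !grepl("[[:space:],]", ids)
  pat <- switch(namespace,
    gene       = "^[0-9]+$",
    metabolite = "^[0-9]+$",
    protein    = "^[A-Za-z][A-Za-z0-9._-]*$")
  ok & grepl(pat, ids)
}

#' OmicsTable: one omics layer of measurements
#'
#' An `OmicsTable` holds one omics layer: a numeric matrix with one row per
#' molecule (rownames are the molecule identifiers) and one column per
#' experimental condition or time point (colnames are the condition labels,
#' kept in upload order).  `layer` is `"T"` (transcriptomics, Entrez Gene
#' IDs), `"P"` (proteomics, UniProtKB accessions) or `"M"` (metabolomics,
#' PubChem CIDs).  Entries may be `NA` (missing measurement).
#'
#' @slot layer single character, one of `"T"`, `"P"`, `"M"`.
#' @slot values numeric matrix; rownames are molecule IDs, colnames are
#'   condition labels.
#' @seealso [readOmicsCSV()], [omicsTable()], [correlationMatrix()]
#' @export
setClass("OmicsTable", representation(layer = "character", values = "matrix"))

setValidity("OmicsTable", function(object) {
  msg <- character()
  if (length(object@layer) != 1L || !object@layer %in% .LAYERS)
    msg <- c(msg, "'layer' must be one of \"T\", \"P\", \"M\"")
  v <- object@values
  if (!is.numeric(v))
    msg <- c(msg, "'values' must be a numeric matrix")
  if (nrow(v) < 1L)
    msg <- c(msg, "table must contain at least one molecule row")
  if (ncol(v) < 2L)
    msg <- c(msg, "at least 2 condition columns are required")
  ids <- rownames(v)
  if (is.null(ids) || is.null(colnames(v))) {
    msg <- c(msg, "'values' must carry molecule IDs as rownames and condition labels as colnames")
  } else {
    if (anyDuplicated(ids)) {
      dup <- unique(ids[duplicated(ids)])
      msg <- c(msg, sprintf("duplicate molecule ID(s): %s",
                            paste(dup, collapse = ", ")))
    }
    if (length(object@layer) == 1L && object@layer %in% .LAYERS) {
      ns <- .LAYER_NAMESPACE[[object@layer]]
      bad <- ids[!validMoleculeId(ids, ns)]
      if (length(bad))
        msg <- c(msg, sprintf("ID(s) not valid for namespace '%s': %s",
                              ns, paste(utils::head(bad, 5L), collapse = ", ")))
    }
    if (anyDuplicated(colnames(v)))
      msg <- c(msg, "condition labels must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsTable from a numeric matrix
#'
#' @param values numeric matrix with molecule IDs as rownames and condition
#'   labels as colnames.
#' @param layer `"T"`, `"P"` or `"M"`.
#' @return a validated [OmicsTable-class] object.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("10", "20"), c("c1", "c2", "c3")))
#' omicsTable(m, "T")
#' @export
omicsTable <- function(values, layer = c("T", "P", "M")) {
  layer <- match.arg(layer)
  storage.mode(values) <- "double"
  new("OmicsTable", layer = layer, values = values)
}

#' @describeIn OmicsTable-class molecule identifiers (row order)
#' @param object,x an `OmicsTable`.
#' @export
setGeneric("moleculeIds", function(x) standardGeneric("moleculeIds"))

#' @export
setMethod("moleculeIds", "OmicsTable", function(x) rownames(x@values))

#' @describeIn OmicsTable-class condition labels (column order)
#' @export
setGeneric("conditionLabels", function(x) standardGeneric("conditionLabels"))

#' @export
setMethod("conditionLabels", "OmicsTable", function(x) colnames(x@values))

#' @describeIn OmicsTable-class the omics layer code
#' @export
setGeneric("omicsLayer", function(x) standardGeneric("omicsLayer"))

#' @export
setMethod("omicsLayer", "OmicsTable", function(x) x@layer)

#' @describeIn OmicsTable-class the numeric value matrix
#' @export
setGeneric("omicsValues", function(x) standardGeneric("omicsValues"))

#' @export
setMethod("omicsValues", "OmicsTable", function(x) x@values)

setMethod("show", "OmicsTable", function(object) {
  cat(sprintf("OmicsTable [layer %s, %s]: %d molecules x %d conditions\n",
              object@layer, .LAYER_NAMESPACE[[object@layer]],
              nrow(object@values), ncol(object@values)))
  cat("  conditions:", paste(colnames(object@values), collapse = ", "), "\n")
  n <- min(3L, nrow(object@values))
  print(object@values[seq_len(n), , drop = FALSE])
  if (nrow(object@values) > n) cat("  ...\n")
  invisible(NULL)
})

#' KnowledgeBase: local reference annotation
#'
#' Bundles the five flat annotation tables the analyses draw on:
#' transcript-protein-metabolite relation triples (literature bridging),
#' metabolite pathway sets (KEGG-like / HumanCyc-like), GO term annotations,
#' OMIM-style phenotype records, and a name-to-identifier synonym map.
#' Missing optional tables switch off the corresponding analyses via
#' `capabilities`.
#'
#' @slot triples data.frame with columns `gene`, `protein`, `metabolite`
#'   (`NA` = absent slot; at least two present per row) and `evidence`.
#' @slot pathways data.frame with columns `pathway_id`, `name`, `source`
#'   and list-column `members` (metabolite CIDs).
#' @slot goTerms data.frame with columns `term_id`, `term_name`, `ontology`
#'   (`BP`/`CC`/`MF`) and list-column `genes`.
#' @slot phenotypes data.frame with columns `phenotype_id`, `phenotype_name`
#'   and list-column `genes`.
#' @slot nameMap data.frame with columns `name`, `namespace`, `id`.
#' @slot capabilities named logical: which tables were present on load.
#' @seealso [loadKnowledgeBase()], [generateKnowledgeBaseFixture()]
#' @export
setClass("KnowledgeBase", representation(
  triples = "data.frame", pathways = "data.frame", goTerms = "data.frame",
  phenotypes = "data.frame", nameMap = "data.frame",
  capabilities = "logical"))

setValidity("KnowledgeBase", function(object) {
  msg <- character()
  need <- function(df, cols, what)
    if (nrow(df) && !all(cols %in% names(df)))
      sprintf("%s table must have columns: %s", what, paste(cols, collapse = ", "))
  msg <- c(msg,
    need(object@triples, c("gene", "protein", "metabolite", "evidence"), "triples"),
    need(object@pathways, c("pathway_id", "name", "source", "members"), "pathways"),
    need(object@goTerms, c("term_id", "term_name", "ontology", "genes"), "GO"),
    need(object@phenotypes, c("phenotype_id", "phenotype_name", "genes"), "phenotypes"),
    need(object@nameMap, c("name", "namespace", "id"), "name map"))
  want <- c("triples", "pathways", "go", "phenotypes", "names")
  if (!all(want %in% names(object@capabilities)))
    msg <- c(msg, "capabilities must be named logicals for triples/pathways/go/phenotypes/names")
  if (nrow(object@triples)) {
    present <- (!is.na(object@triples$gene)) + (!is.na(object@triples$protein)) +
      (!is.na(object@triples$metabolite))
    if (any(present < 2L))
      msg <- c(msg, "every relation triple must fill at least two of gene/protein/metabolite")
  }
  if (nrow(object@pathways) && anyDuplicated(object@pathways$pathway_id))
    msg <- c(msg, "pathway_id values must be unique")
  msg <- msg[!vapply(msg, is.null, logical(1L))]
  if (length(msg)) unlist(msg) else TRUE
})

setMethod("show", "KnowledgeBase", function(object) {
  cat("KnowledgeBase\n")
  cat(sprintf("  relation triples : %d\n", nrow(object@triples)))
  cat(sprintf("  pathways         : %d\n", nrow(object@pathways)))
  cat(sprintf("  GO terms         : %d\n", nrow(object@goTerms)))
  cat(sprintf("  phenotypes       : %d\n", nrow(object@phenotypes)))
  cat(sprintf("  name synonyms    : %d\n", nrow(object@nameMap)))
  off <- names(object@capabilities)[!object@capabilities]
  if (length(off)) cat("  disabled tables  :", paste(off, collapse = ", "), "\n")
  invisible(NULL)
})

#' NetworkConfig: correlation-network parameters
#'
#' Holds the tunable parameters of the correlation network.  Defaults follow
#' the original tool: PCC threshold 0.9, layout repulsion 160 and attraction
#' 80.  Edges require a correlation strictly above the threshold; with
#' `useAbsolute = TRUE` the absolute correlation is thresholded instead so
#' strong anti-correlations also connect.  `minSharedObs` is the minimum
#' number of pairwise complete observations for a correlation to be defined.
#'
#' @slot pccThreshold numeric in (0, 1].
#' @slot useAbsolute logical.
#' @slot repulsion positive numeric; scales the repulsive layout force.
#' @slot attraction positive numeric; scales the attractive layout force.
#' @slot minSharedObs integer >= 3.
#' @slot layoutSeed integer seed for the layout initialisation.
#' @export
setClass("NetworkConfig", representation(
  pccThreshold = "numeric", useAbsolute = "logical",
  repulsion = "numeric", attraction = "numeric",
  minSharedObs = "numeric", layoutSeed = "numeric"),
  prototype(pccThreshold = 0.9, useAbsolute = FALSE,
            repulsion = 160, attraction = 80,
            minSharedObs = 3, layoutSeed = 1))

setValidity("NetworkConfig", function(object) {
  msg <- character()
  if (!(length(object@pccThreshold) == 1L &&
        object@pccThreshold > 0 && object@pccThreshold <= 1))
    msg <- c(msg, "pccThreshold must lie in (0, 1]")
  if (object@repulsion <= 0 || object@attraction <= 0)
    msg <- c(msg, "repulsion and attraction must be positive")
  if (object@minSharedObs < 3)
    msg <- c(msg, "minSharedObs must be >= 3")
  if (length(msg)) msg else TRUE
})

#' @rdname NetworkConfig-class
#' @param pccThreshold,useAbsolute,repulsion,attraction,minSharedObs,layoutSeed
#'   see slot documentation.
#' @return a `NetworkConfig`.
#' @examples
#' networkConfig()                  # the defaults: 0.9 / 160 / 80
#' networkConfig(pccThreshold = 0.95, useAbsolute = TRUE)
#' @export
networkConfig <- function(pccThreshold = 0.9, useAbsolute = FALSE,
                          repulsion = 160, attraction = 80,
                          minSharedObs = 3, layoutSeed = 1) {
  new("NetworkConfig", pccThreshold = pccThreshold, useAbsolute = useAbsolute,
      repulsion = repulsion, attraction = attraction,
      minSharedObs = minSharedObs, layoutSeed = layoutSeed)
}

#' CorrelationNetwork: thresholded molecule graph
#'
#' Nodes are molecules (measured, or literature-bridged from the missing
#' layer); undirected edges are either `correlation` edges carrying the PCC
#' that passed the threshold (drawn solid) or `literature` edges from
#' curated relation triples (drawn dotted, no weight).  Each edge is stored
#' once with `from < to` in lexicographic ID order.  `clusters` holds the
#' connected components of size >= 2, ranked by decreasing size.
#'
#' @slot nodes data.frame with columns `id`, `layer`, `origin`
#'   (`measured`/`literature`).
#' @slot edges data.frame with columns `from`, `to`, `weight` (`NA` for
#'   literature edges) and `kind` (`correlation`/`literature`).
#' @slot clusters list of character vectors of node IDs.
#' @seealso [buildNetwork()], [findClusters()], [exportSIF()]
#' @export
setClass("CorrelationNetwork", representation(
  nodes = "data.frame", edges = "data.frame", clusters = "list"))

setValidity("CorrelationNetwork", function(object) {
  msg <- character()
  if (nrow(object@nodes) && !all(c("id", "layer", "origin") %in% names(object@nodes)))
    msg <- c(msg, "nodes need columns id/layer/origin")
  e <- object@edges
  if (nrow(e)) {
    if (!all(c("from", "to", "weight", "kind") %in% names(e)))
      msg <- c(msg, "edges need columns from/to/weight/kind")
    else {
      if (any(e$from >= e$to))
        msg <- c(msg, "edges must be stored once with from < to")
      cw <- e$weight[e$kind == "correlation"]
      if (any(is.na(cw)) || any(abs(cw) > 1))
        msg <- c(msg, "correlation edges must carry a weight with |weight| <= 1")
      if (any(!is.na(e$weight[e$kind == "literature"])))
        msg <- c(msg, "literature edges carry no weight")
    }
  }
  if (length(object@clusters)) {
    sz <- lengths(object@clusters)
    if (any(sz < 2L)) msg <- c(msg, "clusters must have size >= 2")
    if (is.unsorted(rev(sz))) msg <- c(msg, "clusters must be ordered by non-increasing size")
    if (anyDuplicated(unlist(object@clusters)))
      msg <- c(msg, "clusters must be disjoint")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CorrelationNetwork", function(object) {
  kinds <- table(factor(object@edges$kind, c("correlation", "literature")))
  cat(sprintf("CorrelationNetwork: %d nodes (%d literature-bridged), %d edges (%d correlation, %d literature)\n",
              nrow(object@nodes), sum(object@nodes$origin == "literature"),
              nrow(object@edges), kinds[["correlation"]], kinds[["literature"]]))
  if (length(object@clusters))
    cat(sprintf("  %d clusters; largest has %d molecules\n",
                length(object@clusters), length(object@clusters[[1L]])))
  invisible(NULL)
})

#' @describeIn CorrelationNetwork-class node table
#' @param x a `CorrelationNetwork`.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @export
setMethod("networkNodes", "CorrelationNetwork", function(x) x@nodes)

#' @describeIn CorrelationNetwork-class edge table
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @export
setMethod("networkEdges", "CorrelationNetwork", function(x) x@edges)

#' @describeIn CorrelationNetwork-class ranked cluster list
#' @export
setGeneric("networkClusters", function(x) standardGeneric("networkClusters"))

#' @export
setMethod("networkClusters", "CorrelationNetwork", function(x) x@clusters)

#' CoexpressionResult: clustered heatmap data
#'
#' Output of [coexpression()]: hierarchical row and column clustering of the
#' stacked omics matrix by Euclidean distance, with dendrogram leaf orders,
#' the cyan-to-pink colour intensities in [0, 1], and the omics layer of each
#' row (for the green/red/blue row edge colour codes).
#'
#' @slot values the numeric matrix that was clustered (after any scaling).
#' @slot rowOrder,colOrder integer permutations (dendrogram leaf order).
#' @slot rowTree,colTree `hclust` merge trees.
#' @slot colorMatrix numeric matrix in [0, 1]; 0 = cyan (lowest value),
#'   1 = pink (highest value).
#' @slot rowTypes character layer code (`T`/`P`/`M`) per row.
#' @export
setClass("CoexpressionResult", representation(
  values = "matrix", rowOrder = "integer", colOrder = "integer",
  rowTree = "ANY", colTree = "ANY", colorMatrix = "matrix",
  rowTypes = "character"))

setValidity("CoexpressionResult", function(object) {
  msg <- character()
  if (!identical(sort(object@rowOrder), seq_len(nrow(object@values))))
    msg <- c(msg, "rowOrder must be a permutation of the rows")
  if (!identical(sort(object@colOrder), seq_len(ncol(object@values))))
    msg <- c(msg, "colOrder must be a permutation of the columns")
  cm <- object@colorMatrix[!is.na(object@colorMatrix)]
  if (length(cm) && (min(cm) < 0 || max(cm) > 1))
    msg <- c(msg, "colorMatrix entries must lie in [0, 1]")
  if (length(object@rowTypes) != nrow(object@values))
    msg <- c(msg, "rowTypes must label every row")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CoexpressionResult", function(object) {
  cat(sprintf("CoexpressionResult: %d rows x %d columns (layers: %s)\n",
              nrow(object@values), ncol(object@values),
              paste(unique(object@rowTypes), collapse = ", ")))
  cat("  row leaf order :", paste(utils::head(rownames(object@values)[object@rowOrder], 8L),
                                  collapse = ", "),
      if (nrow(object@values) > 8L) "..." else "", "\n")
  invisible(NULL)
})
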