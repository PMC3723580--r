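# Phenotype mapping: join input transcripts/proteins to OMIM-style
# phenotype records.  Proteins reach gene space through relation triples.

#' Map input molecules to phenotype records
#'
#' Joins the input transcript and/or protein tables against the OMIM-style
#' phenotype table of the knowledgebase.  Transcripts match by gene
#' identity; proteins are first translated to genes through the relation
#' triples (a protein with no gene relation is skipped with a warning).
#' Metabolomics-only input is rejected: phenotype records relate genes to
#' phenotypes, so the analysis is not available for metabolite data alone.
#' One row is returned per phenotype matched by at least one input
#' molecule, with all matches aggregated, sorted by phenotype ID; each row
#' carries an external-reference string for the phenotype entry.
#'
#' @param tables an [OmicsTable-class] or list of them; at least one must
#'   be layer `T` or `P`.
#' @param kb a [KnowledgeBase-class] with a phenotype table.
#' @return `data.frame` with columns `phenotype_id`, `phenotype_name`,
#'   `genes` (matched genes, `;`-joined), `matched_inputs` (input molecule
#'   IDs, `;`-joined) and `external_ref`.
#' @export
phenotypeMap <- function(tables, kb) {
  stopifnot(is(kb, "KnowledgeBase"))
  if (is(tables, "OmicsTable")) tables <- list(tables)
  stopifnot(all(vapply(tables, is, logical(1L), "OmicsTable")))
  layers <- vapply(tables, omicsLayer, character(1L))
  if (!any(layers %in% c("T", "P")))
    stop("phenotype analysis is not available for metabolomics data alone ",
         "(capability matrix: mode {M} has no phenotype analysis)")
  if (!kbCapabilities(kb)[["phenotypes"]])
    stop("this knowledgebase has no phenotype table; phenotype analysis is disabled")

  # input molecule -> gene(s) it resolves to
  geneOf <- list()
  for (i in seq_along(tables)) {
    ids <- moleculeIds(tables[[i]])
    if (layers[i] == "T") {
      for (g in ids) geneOf[[g]] <- union(geneOf[[g]], g)
    } else if (layers[i] == "P") {
      tr <- kbTriples(kb)
      rel <- tr[!is.na(tr$protein) & !is.na(tr$gene), , drop = FALSE]
      for (p in ids) {
        gs <- unique(rel$gene[rel$protein == p])
        if (length(gs) == 0L) {
          warning("protein ", p, " has no gene relation; skipped")
        } else {
          geneOf[[p]] <- union(geneOf[[p]], gs)
        }
      }
    }
  }
  empty <- data.frame(phenotype_id = character(), phenotype_name = character(),
                      genes = character(), matched_inputs = character(),
                      external_ref = character())
  if (length(geneOf) == 0L) return(empty)

  ph <- kbPhenotypes(kb)
  if (nrow(ph) == 0L) return(empty)
  rows <- lapply(seq_len(nrow(ph)), function(i) {
    recGenes <- ph$genes[[i]]
    matchedInputs <- names(geneOf)[vapply(geneOf, function(gs)
      any(gs %in% recGenes), logical(1L))]
    if (length(matchedInputs) == 0L) return(NULL)
    matchedGenes <- sort(unique(unlist(geneOf[matchedInputs])))
    matchedGenes <- intersect(recGenes, matchedGenes)
    data.frame(phenotype_id = ph$phenotype_id[i],
               phenotype_name = ph$phenotype_name[i],
               genes = paste(sort(matchedGenes), collapse = ";"),
               matched_inputs = paste(sort(matchedInputs), collapse = ";"),
               external_ref = sprintf("https://omim.org/entry/%s",
                                      ph$phenotype_id[i]))
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$phenotype_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
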