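# Local reference annotation: flat-file loaders, a seeded fixture generator,
# and literature bridging of the missing omics layer.
#
# Flat-file schema (TSV with a header row, UTF-8):
#   triples.tsv    gene_id  protein_id  metabolite_id  evidence   (empty = absent)
#   pathways.tsv   pathway_id  name  source  members    (members ;-joined CIDs)
#   go.tsv         term_id  term_name  ontology  genes  (genes ;-joined Entrez)
#   phenotypes.tsv phenotype_id  phenotype_name  genes
#   names.tsv      name  namespace  id

.KB_FILES <- c(triples = "triples.tsv", pathways = "pathways.tsv",
               go = "go.tsv", phenotypes = "phenotypes.tsv",
               names = "names.tsv")

.readTSV <- function(path) {
  utils::read.delim(path, colClasses = "character", check.names = FALSE,
                    na.strings = NULL, quote = "")
}

.kbStop <- function(file, line, msg) {
  stop(sprintf("%s, line %d: %s", file, line, msg), call. = FALSE)
}

.splitMembers <- function(s) {
  out <- strsplit(s, ";", fixed = TRUE)
  lapply(out, function(x) x[nzchar(x)])
}

.checkIds <- function(ids, namespace, file, lines) {
  ok <- validMoleculeId(ids, namespace)
  if (any(!ok))
    .kbStop(file, lines[which(!ok)[1L]],
            sprintf("'%s' is not a valid %s identifier",
                    ids[!ok][1L], namespace))
}

#' Load a knowledgebase from a directory of flat files
#'
#' Reads whichever of the five annotation tables (`triples.tsv`,
#' `pathways.tsv`, `go.tsv`, `phenotypes.tsv`, `names.tsv`) are present in
#' `dir` and cross-validates them: pathway members must be PubChem CIDs,
#' GO and phenotype gene sets must be Entrez IDs and non-empty, relation
#' triples must fill at least two of their three slots.  A missing file is
#' not an error; it switches off the corresponding analyses through the
#' capability flags (see [kbCapabilities()]).  A malformed line is an error
#' naming the file and line number.
#'
#' @param dir directory containing the TSV files.
#' @return a [KnowledgeBase-class].
#' @seealso [generateKnowledgeBaseFixture()] for a seeded offline fixture.
#' @export
loadKnowledgeBase <- function(dir) {
  if (!dir.exists(dir)) stop("knowledgebase directory not found: ", dir)
  paths <- file.path(dir, .KB_FILES)
  names(paths) <- names(.KB_FILES)
  have <- file.exists(paths)
  names(have) <- names(paths)

  triples <- data.frame(gene = character(), protein = character(),
                        metabolite = character(), evidence = character())
  if (have[["triples"]]) {
    f <- .KB_FILES[["triples"]]
    raw <- .readTSV(paths[["triples"]])
    if (ncol(raw) != 4L) .kbStop(f, 1L, "expected 4 tab-separated columns")
    lines <- seq_len(nrow(raw)) + 1L
    g <- ifelse(nzchar(raw[[1L]]), raw[[1L]], NA_character_)
    p <- ifelse(nzchar(raw[[2L]]), raw[[2L]], NA_character_)
    m <- ifelse(nzchar(raw[[3L]]), raw[[3L]], NA_character_)
    npresent <- (!is.na(g)) + (!is.na(p)) + (!is.na(m))
    if (any(npresent < 2L))
      .kbStop(f, lines[which(npresent < 2L)[1L]],
              "a relation triple must fill at least two slots")
    .checkIds(g[!is.na(g)], "gene", f, lines[!is.na(g)])
    .checkIds(p[!is.na(p)], "protein", f, lines[!is.na(p)])
    .checkIds(m[!is.na(m)], "metabolite", f, lines[!is.na(m)])
    triples <- data.frame(gene = g, protein = p, metabolite = m,
                          evidence = raw[[4L]])
  }

  pathways <- data.frame(pathway_id = character(), name = character(),
                         source = character(), members = I(list()))
  if (have[["pathways"]]) {
    f <- .KB_FILES[["pathways"]]
    raw <- .readTSV(paths[["pathways"]])
    if (ncol(raw) != 4L) .kbStop(f, 1L, "expected 4 tab-separated columns")
    lines <- seq_len(nrow(raw)) + 1L
    if (anyDuplicated(raw[[1L]]))
      .kbStop(f, lines[which(duplicated(raw[[1L]]))[1L]],
              sprintf("duplicate pathway_id '%s'",
                      raw[[1L]][duplicated(raw[[1L]])][1L]))
    bad <- !raw[[3L]] %in% c("kegg-like", "humancyc-like")
    if (any(bad))
      .kbStop(f, lines[which(bad)[1L]],
              "source must be 'kegg-like' or 'humancyc-like'")
    members <- .splitMembers(raw[[4L]])
    if (any(lengths(members) == 0L))
      .kbStop(f, lines[which(lengths(members) == 0L)[1L]],
              "pathway member list must be non-empty")
    for (i in seq_along(members))
      .checkIds(members[[i]], "metabolite", f, rep(lines[i], length(members[[i]])))
    pathways <- data.frame(pathway_id = raw[[1L]], name = raw[[2L]],
                           source = raw[[3L]], members = I(members))
  }

  goTerms <- data.frame(term_id = character(), term_name = character(),
                        ontology = character(), genes = I(list()))
  if (have[["go"]]) {
    f <- .KB_FILES[["go"]]
    raw <- .readTSV(paths[["go"]])
    if (ncol(raw) != 4L) .kbStop(f, 1L, "expected 4 tab-separated columns")
    lines <- seq_len(nrow(raw)) + 1L
    bad <- !raw[[3L]] %in% c("BP", "CC", "MF")
    if (any(bad))
      .kbStop(f, lines[which(bad)[1L]], "ontology must be BP, CC or MF")
    genes <- .splitMembers(raw[[4L]])
    if (any(lengths(genes) == 0L))
      .kbStop(f, lines[which(lengths(genes) == 0L)[1L]],
              "GO gene list must be non-empty")
    for (i in seq_along(genes))
      .checkIds(genes[[i]], "gene", f, rep(lines[i], length(genes[[i]])))
    goTerms <- data.frame(term_id = raw[[1L]], term_name = raw[[2L]],
                          ontology = raw[[3L]], genes = I(genes))
  }

  phenotypes <- data.frame(phenotype_id = character(),
                           phenotype_name = character(), genes = I(list()))
  if (have[["phenotypes"]]) {
    f <- .KB_FILES[["phenotypes"]]
    raw <- .readTSV(paths[["phenotypes"]])
    if (ncol(raw) != 3L) .kbStop(f, 1L, "expected 3 tab-separated columns")
    lines <- seq_len(nrow(raw)) + 1L
    genes <- .splitMembers(raw[[3L]])
    if (any(lengths(genes) == 0L))
      .kbStop(f, lines[which(lengths(genes) == 0L)[1L]],
              "phenotype gene list must be non-empty")
    for (i in seq_along(genes))
      .checkIds(genes[[i]], "gene", f, rep(lines[i], length(genes[[i]])))
    phenotypes <- data.frame(phenotype_id = raw[[1L]],
                             phenotype_name = raw[[2L]], genes = I(genes))
  }

  nameMap <- data.frame(name = character(), namespace = character(),
                        id = character())
  if (have[["names"]]) {
    f <- .KB_FILES[["names"]]
    raw <- .readTSV(paths[["names"]])
    if (ncol(raw) != 3L) .kbStop(f, 1L, "expected 3 tab-separated columns")
    lines <- seq_len(nrow(raw)) + 1L
    bad <- !raw[[2L]] %in% c("gene", "protein", "metabolite")
    if (any(bad))
      .kbStop(f, lines[which(bad)[1L]],
              "namespace must be gene, protein or metabolite")
    for (ns in c("gene", "protein", "metabolite")) {
      sel <- raw[[2L]] == ns
      if (any(sel)) .checkIds(raw[[3L]][sel], ns, f, lines[sel])
    }
    nameMap <- data.frame(name = raw[[1L]], namespace = raw[[2L]],
                          id = raw[[3L]])
  }

  new("KnowledgeBase", triples = triples, pathways = pathways,
      goTerms = goTerms, phenotypes = phenotypes, nameMap = nameMap,
      capabilities = have)
}

#' @describeIn KnowledgeBase-class relation-triple table
#' @param x a `KnowledgeBase`.
#' @export
setGeneric("kbTriples", function(x) standardGeneric("kbTriples"))
#' @export
setMethod("kbTriples", "KnowledgeBase", function(x) x@triples)

#' @describeIn KnowledgeBase-class pathway-set table
#' @export
setGeneric("kbPathways", function(x) standardGeneric("kbPathways"))
#' @export
setMethod("kbPathways", "KnowledgeBase", function(x) x@pathways)

#' @describeIn KnowledgeBase-class GO annotation table
#' @export
setGeneric("kbGoTerms", function(x) standardGeneric("kbGoTerms"))
#' @export
setMethod("kbGoTerms", "KnowledgeBase", function(x) x@goTerms)

#' @describeIn KnowledgeBase-class phenotype-record table
#' @export
setGeneric("kbPhenotypes", function(x) standardGeneric("kbPhenotypes"))
#' @export
setMethod("kbPhenotypes", "KnowledgeBase", function(x) x@phenotypes)

#' @describeIn KnowledgeBase-class name-synonym table
#' @export
setGeneric("kbNameMap", function(x) standardGeneric("kbNameMap"))
#' @export
setMethod("kbNameMap", "KnowledgeBase", function(x) x@nameMap)

#' @describeIn KnowledgeBase-class which annotation tables were present
#' @export
setGeneric("kbCapabilities", function(x) standardGeneric("kbCapabilities"))
#' @export
setMethod("kbCapabilities", "KnowledgeBase", function(x) x@capabilities)

#' Bridge the missing omics layer from relation triples
#'
#' Given measured tables for exactly two of the three layers, scans the
#' knowledgebase relation triples for molecules of the absent third layer
#' that co-occur in a triple with at least one input molecule.  These
#' bridged molecules carry no expression vector; in the correlation network
#' they appear as literature nodes joined by dotted (unweighted) edges to
#' the input molecules they link to.
#'
#' @param tables list of exactly two [OmicsTable-class] objects with
#'   distinct layers.
#' @param kb a [KnowledgeBase-class] with a loaded triples table.
#' @return a `data.frame` sorted by bridged ID: `id` (bridged molecule),
#'   `layer` (the missing layer code), list-column `linked` (input molecule
#'   IDs it connects to) and `evidence` (`;`-joined provenance tags).
#'   Zero rows when nothing bridges.
#' @examples
#' kbdir <- generateKnowledgeBaseFixture(tempfile(), seed = 1)
#' kb <- loadKnowledgeBase(kbdir)
#' tr <- kbTriples(kb)[1, ]
#' tabs <- list(
#'   omicsTable(matrix(1:3, 1, 3, dimnames = list(tr$gene, c("a","b","c"))), "T"),
#'   omicsTable(matrix(1:3, 1, 3, dimnames = list(tr$protein, c("a","b","c"))), "P"))
#' bridgeMissingLayer(tabs, kb)
#' @export
bridgeMissingLayer <- function(tables, kb) {
  stopifnot(is(kb, "KnowledgeBase"))
  if (!is.list(tables) || length(tables) != 2L ||
      !all(vapply(tables, is, logical(1L), "OmicsTable")))
    stop("bridging requires exactly two OmicsTable inputs")
  present <- vapply(tables, omicsLayer, character(1L))
  if (anyDuplicated(present))
    stop("the two input tables must come from distinct omics layers")
  missingLayer <- setdiff(.LAYERS, present)
  inputIds <- lapply(tables, moleculeIds)
  names(inputIds) <- present

  tr <- kbTriples(kb)
  out <- data.frame(id = character(), layer = character(),
                    linked = I(list()), evidence = character())
  if (nrow(tr) == 0L) return(out)
  slotOf <- c(T = "gene", P = "protein", M = "metabolite")
  bridgeCol <- tr[[slotOf[[missingLayer]]]]
  hits <- list()
  for (i in seq_len(nrow(tr))) {
    bid <- bridgeCol[i]
    if (is.na(bid)) next
    linked <- character()
    for (ly in present) {
      v <- tr[[slotOf[[ly]]]][i]
      if (!is.na(v) && v %in% inputIds[[ly]]) linked <- c(linked, v)
    }
    if (length(linked) == 0L) next
    prev <- hits[[bid]]
    hits[[bid]] <- list(linked = union(if (is.null(prev)) character() else prev$linked,
                                       linked),
                        evidence = union(if (is.null(prev)) character() else prev$evidence,
                                         tr$evidence[i]))
  }
  if (length(hits) == 0L) return(out)
  ids <- sort(names(hits))
  data.frame(id = ids, layer = missingLayer,
             linked = I(lapply(hits[ids], function(h) sort(h$linked))),
             evidence = vapply(hits[ids], function(h)
               paste(sort(h$evidence), collapse = ";"), character(1L)),
             row.names = NULL)
}

# -- seeded fixture generation ------------------------------------------------

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate a deterministic synthetic knowledgebase fixture
#'
#' Writes the five flat annotation tables to `dir`, generated from a seeded
#' RNG so that repeated calls with the same seed are byte-identical.  The
#' fixture plants one "enriched" pathway and one "enriched" GO term whose
#' member identifiers are recorded in `manifest.json`, so recovery tests can
#' read their own ground truth.  All identifiers are synthetic (numeric
#' Entrez-style gene IDs, `P`-prefixed accessions, numeric CIDs); the
#' fixture mimics the shape of KEGG/HumanCyc/OMIM-derived tables, not their
#' content.
#'
#' @param dir output directory (created if needed).
#' @param seed integer RNG seed.
#' @param sizes named list overriding table sizes: `nGenes`, `nProteins`,
#'   `nMetabolites` (identifier pools), `nTriples`, `nPathways`, `nGoTerms`,
#'   `nPhenotypes`, `nNames`.
#' @return `dir`, invisibly annotated with attribute `manifest` (the parsed
#'   manifest list).
#' @examples
#' d <- generateKnowledgeBaseFixture(tempfile(), seed = 7)
#' loadKnowledgeBase(d)
#' @export
generateKnowledgeBaseFixture <- function(dir, seed = 1L, sizes = list()) {
  sz <- utils::modifyList(list(
    nGenes = 60L, nProteins = 60L, nMetabolites = 80L,
    nTriples = 50L, nPathways = 20L, nGoTerms = 30L,
    nPhenotypes = 15L, nNames = 30L), sizes)
  stopifnot(all(unlist(sz) > 0))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  genes <- as.character(1000L + seq_len(sz$nGenes))
  proteins <- sprintf("P%05d", seq_len(sz$nProteins))
  metabolites <- as.character(5000L + seq_len(sz$nMetabolites))

  .withSeed(seed, {
    # relation triples: mostly full, some with one empty slot (still pairs)
    g <- sample(genes, sz$nTriples, replace = TRUE)
    p <- sample(proteins, sz$nTriples, replace = TRUE)
    m <- sample(metabolites, sz$nTriples, replace = TRUE)
    dropSlot <- sample(c(0L, 1L, 2L, 3L), sz$nTriples, replace = TRUE,
                       prob = c(0.55, 0.15, 0.15, 0.15))
    g[dropSlot == 1L] <- ""
    p[dropSlot == 2L] <- ""
    m[dropSlot == 3L] <- ""
    triples <- data.frame(gene_id = g, protein_id = p, metabolite_id = m,
                          evidence = "literature")

    # pathways: 6-10 metabolites each; one planted pathway of 10 members
    pwIds <- sprintf("PW%03d", seq_len(sz$nPathways))
    plantedIdx <- sample(sz$nPathways, 1L)
    pwSource <- sample(c("kegg-like", "humancyc-like"), sz$nPathways,
                       replace = TRUE)
    pwMembers <- lapply(seq_len(sz$nPathways), function(i)
      sort(sample(metabolites, if (i == plantedIdx) 10L else sample(6:10, 1L))))
    pathways <- data.frame(
      pathway_id = pwIds,
      name = sprintf("synthetic pathway %03d", seq_len(sz$nPathways)),
      source = pwSource,
      members = vapply(pwMembers, paste, character(1L), collapse = ";"))

    # GO terms: balanced across the three ontologies; one planted BP term
    ont <- rep(c("BP", "CC", "MF"), length.out = sz$nGoTerms)
    goIds <- sprintf("GO:%07d", seq_len(sz$nGoTerms))
    plantedGoIdx <- which(ont == "BP")[1L]
    goGenes <- lapply(seq_len(sz$nGoTerms), function(i)
      sort(sample(genes, if (i == plantedGoIdx) 8L else sample(3:12, 1L))))
    goTab <- data.frame(
      term_id = goIds,
      term_name = sprintf("synthetic term %03d", seq_len(sz$nGoTerms)),
      ontology = ont,
      genes = vapply(goGenes, paste, character(1L), collapse = ";"))

    # phenotypes: OMIM-style 6-digit ids, 1-4 genes each
    phIds <- as.character(600000L + seq_len(sz$nPhenotypes))
    phGenes <- lapply(seq_len(sz$nPhenotypes), function(i)
      sort(sample(genes, sample(1:4, 1L))))
    phenotypes <- data.frame(
      phenotype_id = phIds,
      phenotype_name = sprintf("synthetic phenotype %03d", seq_len(sz$nPhenotypes)),
      genes = vapply(phGenes, paste, character(1L), collapse = ";"))

    # name synonyms; the last one is deliberately ambiguous (two gene ids)
    nmGenes <- sample(genes, min(sz$nNames, sz$nGenes))
    nameMap <- data.frame(
      name = sprintf("gene_%s", nmGenes),
      namespace = "gene", id = nmGenes)
    nameMap <- rbind(nameMap,
                     data.frame(name = "shared_alias", namespace = "gene",
                                id = sort(sample(genes, 2L))))

    writeTab <- function(df, file)
      utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    writeTab(triples, "triples.tsv")
    writeTab(pathways, "pathways.tsv")
    writeTab(goTab, "go.tsv")
    writeTab(phenotypes, "phenotypes.tsv")
    writeTab(nameMap, "names.tsv")

    manifest <- list(
      seed = seed, sizes = sz,
      pools = list(genes = genes, proteins = proteins,
                   metabolites = metabolites),
      planted_pathway = list(id = pwIds[plantedIdx],
                             members = pwMembers[[plantedIdx]]),
      planted_go_term = list(id = goIds[plantedGoIdx],
                             genes = goGenes[[plantedGoIdx]]))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })
  invisible(structure(dir,
    manifest = jsonlite::read_json(file.path(dir, "manifest.json"),
                                   simplifyVector = TRUE)))
}

#' Read the ground-truth manifest written by the fixture generator
#'
#' @param dir fixture directory.
#' @return the parsed manifest list.
#' @export
readFixtureManifest <- function(dir) {
  jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
}
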