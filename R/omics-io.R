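# Reading/writing omics CSV tables and the name-to-ID converter.

# Shortest decimal representation that survives a read/write round trip.
.formatNumber <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- sprintf("%.15g", v)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    s
  }, character(1L))
}

#' Read one omics layer from a CSV file
#'
#' Parses a comma-separated table whose first column holds molecule
#' identifiers (Entrez Gene ID, UniProtKB accession or PubChem CID,
#' depending on `layer`) and whose remaining columns hold numeric
#' measurements per experimental condition or time point.  The header row
#' names the ID column and the condition labels; condition order is taken
#' from column order and never parsed from the labels.
#'
#' Empty cells and the token `NA` are treated as missing measurements.  Any
#' other non-numeric cell is an error naming the offending row and column.
#' Duplicate molecule IDs are an error naming the ID and the file rows on
#' which it appears.
#'
#' @param path path to the CSV file.
#' @param layer omics layer of the file: `"T"`, `"P"` or `"M"`.
#' @return an [OmicsTable-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("ID,t0,t1", "10,1.5,2.5", "20,0.5,NA"), f)
#' readOmicsCSV(f, "T")
#' @export
readOmicsCSV <- function(path, layer = c("T", "P", "M")) {
  layer <- match.arg(layer)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL, strip.white = TRUE)
  if (nrow(raw) == 0L) stop("empty omics file (no data rows): ", path)
  if (ncol(raw) < 3L)
    stop("at least 2 condition columns are required, found ", ncol(raw) - 1L)
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    where <- vapply(dup, function(d)
      paste(which(ids == d) + 1L, collapse = ", "), character(1L))
    stop("duplicate molecule ID(s): ",
         paste(sprintf("'%s' (file rows %s)", dup, where), collapse = "; "))
  }
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  missing <- vals == "" | vals == "NA"
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !missing, arr.ind = TRUE)
  if (nrow(bad)) {
    b <- bad[1L, ]
    stop(sprintf("non-numeric value '%s' at file row %d, column '%s'",
                 vals[b[1L], b[2L]], b[1L] + 1L, colnames(vals)[b[2L]]))
  }
  num[missing] <- NA_real_
  dimnames(num) <- list(ids, colnames(raw)[-1L])
  omicsTable(num, layer)
}

#' Write an OmicsTable back to CSV
#'
#' Inverse of [readOmicsCSV()]: writes the ID column followed by one column
#' per condition, preserving row and column order.  Finite values round-trip
#' bit-identically; missing values are written as `NA`.
#'
#' @param x an [OmicsTable-class].
#' @param path output file path.
#' @param idHeader header label for the identifier column.
#' @return `path`, invisibly.
#' @export
writeOmicsCSV <- function(x, path, idHeader = "ID") {
  stopifnot(is(x, "OmicsTable"))
  v <- omicsValues(x)
  lines <- c(paste(c(idHeader, colnames(v)), collapse = ","),
             vapply(seq_len(nrow(v)), function(i)
               paste(c(rownames(v)[i], .formatNumber(v[i, ])), collapse = ","),
               character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' Convert molecule names to database identifiers
#'
#' Case-insensitive exact lookup of gene/protein/metabolite names against a
#' synonym table.  A name mapping to several identifiers is reported as
#' `ambiguous` with every candidate preserved; nothing is silently resolved
#' and no fuzzy matching is attempted.
#'
#' @param names character vector of molecule names to convert.
#' @param map a name-synonym `data.frame` with columns `name`, `namespace`
#'   and `id` (the `nameMap` table of a [KnowledgeBase-class], see
#'   [kbNameMap()]).
#' @param namespace optional filter: restrict matches to `"gene"`,
#'   `"protein"` or `"metabolite"`.
#' @return a `data.frame` with one row per input name: `name`, `status`
#'   (`unique`/`ambiguous`/`unmapped`) and list-column `ids` holding the
#'   matched identifiers (empty when unmapped).
#' @examples
#' map <- data.frame(name = c("alanine", "ALA"), namespace = "metabolite",
#'                   id = c("5950", "5950"))
#' convertNames(c("Alanine", "unknown"), map)
#' @export
convertNames <- function(names, map, namespace = NULL) {
  stopifnot(is.data.frame(map),
            all(c("name", "namespace", "id") %in% colnames(map)))
  if (!is.null(namespace)) {
    namespace <- match.arg(namespace, c("gene", "protein", "metabolite"))
    map <- map[map$namespace == namespace, , drop = FALSE]
  }
  key <- tolower(map$name)
  hits <- lapply(tolower(as.character(names)), function(nm)
    sort(unique(map$id[key == nm])))
  status <- vapply(hits, function(h)
    if (length(h) == 0L) "unmapped" else if (length(h) == 1L) "unique"
    else "ambiguous", character(1L))
  data.frame(name = as.character(names), status = status,
             ids = I(hits), row.names = NULL)
}
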