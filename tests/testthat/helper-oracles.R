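# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately avoid the code paths they check: exact integer
# arithmetic instead of log-space sums, boolean matrix closure instead of
# graph libraries, naive agglomeration instead of stats::hclust.

# Exact lower-tail hypergeometric by integer-arithmetic summation.  For
# N <= 25 every binomial coefficient (and every product of two of them) is
# below 2^53, so the double-precision integers are exact and the only
# rounding is the final division and sum (~1e-16 per term).
oracleHyperLower <- function(N, m, n, x) {
  tot <- choose(N, n)
  s <- 0
  for (i in 0:x) s <- s + choose(m, i) * choose(N - m, n - i)
  s / tot
}

oracleHyperUpper <- function(N, m, n, x) {
  tot <- choose(N, n)
  hi <- min(n, m)
  if (x > hi) return(0)
  s <- 0
  for (i in x:hi) s <- s + choose(m, i) * choose(N - m, n - i)
  s / tot
}

# One-sided (greater) Fisher's exact p for a 2x2 table with fixed margins:
# enumerate every admissible table and sum the hypergeometric weights of
# those at least as extreme as the observed cell.
oracleFisherGreater <- function(k, nQuery, K, nBg) {
  lo <- max(0, nQuery + K - nBg)
  hi <- min(nQuery, K)
  tot <- choose(nBg, nQuery)
  s <- 0
  for (i in lo:hi)
    if (i >= k) s <- s + choose(K, i) * choose(nBg - K, nQuery - i)
  s / tot
}

# Connected components by boolean transitive closure (Warshall).
oracleComponents <- function(ids, from, to) {
  n <- length(ids)
  R <- diag(TRUE, n)
  dimnames(R) <- list(ids, ids)
  if (length(from)) {
    R[cbind(from, to)] <- TRUE
    R[cbind(to, from)] <- TRUE
  }
  for (k in seq_len(n)) R <- R | (outer(R[, k], R[k, ], "&"))
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[R[i, ]] <- cid
    }
  }
  split(ids, comp)
}

# Naive agglomerative clustering returning the cophenetic distance matrix.
oracleCophenetic <- function(X, method = c("complete", "single", "average")) {
  method <- match.arg(method)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  coph <- matrix(0, n, n)
  work <- D
  diag(work) <- Inf
  for (step in seq_len(n - 1L)) {
    idx <- which(work == min(work), arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    i <- idx[1L, 1L]; j <- idx[1L, 2L]
    h <- work[i, j]
    for (a in members[[i]]) for (b in members[[j]])
      coph[a, b] <- coph[b, a] <- h
    # linkage update into slot i
    for (k in which(active)) {
      if (k == i || k == j) next
      work[i, k] <- work[k, i] <- switch(method,
        complete = max(work[i, k], work[j, k]),
        single = min(work[i, k], work[j, k]),
        average = (length(members[[i]]) * work[i, k] +
                   length(members[[j]]) * work[j, k]) /
                  (length(members[[i]]) + length(members[[j]])))
    }
    members[[i]] <- c(members[[i]], members[[j]])
    active[j] <- FALSE
    work[j, ] <- work[, j] <- Inf
  }
  rownames(coph) <- colnames(coph) <- rownames(X)
  coph
}

# in-memory KnowledgeBase with a single GO table (fast path for the
# many-instance Fisher checks; skips file round-trips)
makeGoKB <- function(termGenes, ontology = "BP") {
  go <- data.frame(term_id = sprintf("GO:%07d", seq_along(termGenes)),
                   term_name = sprintf("term %d", seq_along(termGenes)),
                   ontology = ontology, genes = I(termGenes))
  methods::new("KnowledgeBase",
    triples = data.frame(gene = character(), protein = character(),
                         metabolite = character(), evidence = character()),
    pathways = data.frame(pathway_id = character(), name = character(),
                          source = character(), members = I(list())),
    goTerms = go,
    phenotypes = data.frame(phenotype_id = character(),
                            phenotype_name = character(), genes = I(list())),
    nameMap = data.frame(name = character(), namespace = character(),
                         id = character()),
    capabilities = c(triples = FALSE, pathways = FALSE, go = TRUE,
                     phenotypes = FALSE, names = FALSE))
}

# quick numeric OmicsTable
makeOmics <- function(values, layer = "T", ids = NULL, conds = NULL) {
  if (is.null(ids))
    ids <- switch(layer,
                  T = as.character(1000L + seq_len(nrow(values))),
                  P = sprintf("P%05d", seq_len(nrow(values))),
                  M = as.character(5000L + seq_len(nrow(values))))
  if (is.null(conds)) conds <- sprintf("c%d", seq_len(ncol(values)))
  dimnames(values) <- list(ids, conds)
  omicsTable(values, layer)
}

# a tiny hand-built knowledgebase directory
writeMiniKB <- function(dir,
                        triples = NULL, pathways = NULL, go = NULL,
                        phenotypes = NULL, names = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, file) if (!is.null(df))
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  w(triples, "triples.tsv")
  w(pathways, "pathways.tsv")
  w(go, "go.tsv")
  w(phenotypes, "phenotypes.tsv")
  w(names, "names.tsv")
  dir
}
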