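# Enrichment statistics: hypergeometric tails (authored here, in log space),
# pathway enrichment over metabolite sets, and GO over-representation via a
# one-sided Fisher's exact test with the EASE modification.

.checkHyperArgs <- function(N, m, n, x) {
  args <- c(N = N, m = m, n = n, x = x)
  if (any(is.na(args)) || any(args != round(args)))
    stop("N, m, n, x must be integers")
  if (N < 0 || m < 0 || m > N || n < 0 || n > N)
    stop("require 0 <= m <= N and 0 <= n <= N")
  if (x < 0 || x > n)
    stop("require 0 <= x <= n")
}

# log-sum-exp over hypergeometric log-PMF terms for i in `idx`
.hyperLogSum <- function(N, m, n, idx) {
  if (length(idx) == 0L) return(0)
  lt <- lchoose(m, idx) + lchoose(N - m, n - idx) - lchoose(N, n)
  lt <- lt[is.finite(lt)]
  if (length(lt) == 0L) return(0)
  mx <- max(lt)
  min(exp(mx + log(sum(exp(lt - mx)))), 1)
}

#' Lower-tail cumulative hypergeometric probability
#'
#' Probability that `x` or fewer of the `n` molecules in the significant set
#' fall inside a pathway containing `m` of the `N` molecules of the overall
#' set, when the significant set is drawn without replacement:
#' \deqn{P(X \le x) = \sum_{i=0}^{x} \binom{m}{i}\binom{N-m}{n-i} / \binom{N}{n}.}
#' This is the "probability" by which enriched pathways are ranked
#' (descending) in enrichment mode.  Computed by log-space summation of the
#' PMF (via `lchoose`), stable up to population sizes of about 1e5.
#'
#' @param N population size (overall set).
#' @param m number of population members in the category (pathway).
#' @param n sample size (significant set).
#' @param x observed category count in the sample.
#' @return `P(X <= x)` in [0, 1].
#' @examples
#' hypergeomLowerTail(10, 4, 5, 2)
#' hypergeomLowerTail(10, 0, 5, 0)   # degenerate: X is identically 0
#' @seealso [hypergeomUpperTail()], [pathwayEnrichment()]
#' @export
hypergeomLowerTail <- function(N, m, n, x) {
  .checkHyperArgs(N, m, n, x)
  if (x >= min(n, m)) return(1)
  .hyperLogSum(N, m, n, 0:x)
}

#' Upper-tail cumulative hypergeometric probability
#'
#' `P(X >= x)` for the same distribution as [hypergeomLowerTail()]; this is
#' the conventional over-representation p-value (and, applied to a 2x2
#' table, the one-sided "greater" Fisher's exact test).
#'
#' @inheritParams hypergeomLowerTail
#' @return `P(X >= x)` in [0, 1].
#' @export
hypergeomUpperTail <- function(N, m, n, x) {
  .checkHyperArgs(N, m, n, x)
  if (x <= max(0, n + m - N)) return(1)
  .hyperLogSum(N, m, n, x:min(n, m))
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjustment of raw p-values to FDR q-values; output order matches
#' input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values, same length and order.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03))
#' @export
bhFdr <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pathway enrichment analysis over metabolite sets
#'
#' Two modes, mirroring the original tool.  `normal` mode is simple
#' membership mapping: every pathway sharing at least one metabolite with
#' the overall set is listed with its mapped members, ranked by the mapped
#' count `m` (descending).  `enrichment` mode takes an overall metabolite
#' set (size `N`) and a significantly-changed subset (size `n`) and
#' computes, per pathway with `m` overall members and `x` significant
#' members, the cumulative hypergeometric probability `P(X <= x)`; pathways
#' are ranked by that probability, descending.  The conventional upper-tail
#' p-value `P(X >= x)` is reported alongside.  Pathways with `m = 0` are
#' omitted; ranking ties break by `pathway_id`.
#'
#' @param overall character vector of PubChem CIDs (the overall set).
#' @param kb a [KnowledgeBase-class] with a pathway table.
#' @param significant character vector of CIDs, required in `enrichment`
#'   mode; must be a subset of `overall`.
#' @param mode `"normal"` or `"enrichment"`.
#' @param source restrict to `"kegg-like"` or `"humancyc-like"` pathways,
#'   or `"all"`.
#' @return a ranked `data.frame`; in enrichment mode with columns
#'   `pathway_id`, `name`, `source`, `N`, `m`, `n`, `x`, `probability`,
#'   `upper_tail_p` and `;`-joined `mapped` / `mapped_significant` members.
#' @examples
#' d <- generateKnowledgeBaseFixture(tempfile(), seed = 2)
#' kb <- loadKnowledgeBase(d)
#' pool <- readFixtureManifest(d)$pools$metabolites
#' pathwayEnrichment(pool, kb, mode = "normal")[1:3, 1:5]
#' @export
pathwayEnrichment <- function(overall, kb, significant = NULL,
                              mode = c("normal", "enrichment"),
                              source = c("all", "kegg-like", "humancyc-like")) {
  mode <- match.arg(mode)
  source <- match.arg(source)
  stopifnot(is(kb, "KnowledgeBase"))
  if (!kbCapabilities(kb)[["pathways"]])
    stop("this knowledgebase has no pathway table; pathway enrichment is disabled")
  overall <- unique(as.character(overall))
  if (length(overall) == 0L) stop("overall metabolite set is empty")
  pw <- kbPathways(kb)
  if (source != "all") pw <- pw[pw$source == source, , drop = FALSE]

  mapped <- lapply(pw$members, intersect, x = overall)
  m <- lengths(mapped)
  keep <- m > 0L
  pw <- pw[keep, , drop = FALSE]
  mapped <- mapped[keep]
  m <- m[keep]
  joined <- vapply(mapped, function(x) paste(sort(x), collapse = ";"),
                   character(1L))

  if (mode == "normal") {
    out <- data.frame(pathway_id = pw$pathway_id, name = pw$name,
                      source = pw$source,
                      N = rep(length(overall), nrow(pw)), m = m,
                      mapped = joined, row.names = NULL)
    ord <- order(-out$m, out$pathway_id)
    return(out[ord, , drop = FALSE])
  }

  if (is.null(significant))
    stop("enrichment mode requires the significantly-changed metabolite set")
  significant <- unique(as.character(significant))
  extra <- setdiff(significant, overall)
  if (length(extra))
    stop("significant set must be a subset of the overall set; offenders: ",
         paste(extra, collapse = ", "))
  N <- length(overall)
  n <- length(significant)
  if (n < 1L) stop("significant set is empty")

  mappedSig <- lapply(pw$members, intersect, x = significant)
  x <- lengths(mappedSig)
  prob <- mapply(hypergeomLowerTail, m = m, x = x,
                 MoreArgs = list(N = N, n = n))
  pUp <- mapply(hypergeomUpperTail, m = m, x = x,
                MoreArgs = list(N = N, n = n))
  out <- data.frame(pathway_id = pw$pathway_id, name = pw$name,
                    source = pw$source, N = rep(N, nrow(pw)), m = m,
                    n = rep(n, nrow(pw)), x = x,
                    probability = as.numeric(prob),
                    upper_tail_p = as.numeric(pUp),
                    mapped = joined,
                    mapped_significant = vapply(mappedSig, function(z)
                      paste(sort(z), collapse = ";"), character(1L)),
                    row.names = NULL)
  ord <- order(-out$probability, out$pathway_id)
  out[ord, , drop = FALSE]
}

#' GO over-representation with Fisher's exact test or the EASE score
#'
#' One-sided (greater) Fisher's exact test per GO term on the 2x2 table
#' (query genes in term, query genes not in term, background genes in term
#' not in query, remaining background).  With `method = "ease"` (the
#' default, matching DAVID's modified Fisher's exact test) one observed
#' success is removed — `k` is replaced by `max(k - 1, 0)` — before the
#' p-value is computed, which penalises terms supported by a single gene.
#' Benjamini-Hochberg FDR is computed within each ontology (BP/CC/MF), and
#' terms with `p < alpha` form the display set.
#'
#' @param query character vector of Entrez gene IDs (the study set).
#' @param kb a [KnowledgeBase-class] with a GO table.
#' @param background character vector of Entrez gene IDs; defaults to every
#'   gene annotated in the knowledgebase.  `query` must be a subset.
#' @param method `"ease"` or `"fisher"`.
#' @param alpha display threshold on the raw p-value (default 0.05).
#' @return named list with one `data.frame` per ontology (`BP`, `CC`,
#'   `MF`), each ranked by p-value with columns `term_id`, `term_name`,
#'   `k`, `K`, `n_query`, `n_background`, `p_value`, `fdr`, `significant`
#'   (p < alpha) and `;`-joined mapped query `genes`.
#' @examples
#' d <- generateKnowledgeBaseFixture(tempfile(), seed = 3)
#' kb <- loadKnowledgeBase(d)
#' planted <- readFixtureManifest(d)$planted_go_term
#' res <- goEnrichment(planted$genes, kb, method = "fisher")
#' res$BP[1, c("term_id", "p_value", "fdr")]
#' @export
goEnrichment <- function(query, kb, background = NULL,
                         method = c("ease", "fisher"), alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(is(kb, "KnowledgeBase"))
  if (!kbCapabilities(kb)[["go"]])
    stop("this knowledgebase has no GO table; GO enrichment is disabled")
  go <- kbGoTerms(kb)
  if (is.null(background))
    background <- sort(unique(unlist(go$genes)))
  background <- unique(as.character(background))
  query <- unique(as.character(query))
  outside <- setdiff(query, background)
  if (length(outside))
    stop("query gene(s) absent from the background: ",
         paste(outside, collapse = ", "))
  nBg <- length(background)
  nQ <- length(query)

  res <- lapply(c(BP = "BP", CC = "CC", MF = "MF"), function(ont) {
    sub <- go[go$ontology == ont, , drop = FALSE]
    termBg <- lapply(sub$genes, intersect, x = background)
    K <- lengths(termBg)
    keep <- K > 0L
    sub <- sub[keep, , drop = FALSE]
    termBg <- termBg[keep]
    K <- K[keep]
    hit <- lapply(termBg, intersect, x = query)
    k <- lengths(hit)
    kAdj <- if (method == "ease") pmax(k - 1L, 0L) else k
    p <- as.numeric(mapply(hypergeomUpperTail, m = K, x = kAdj,
                           MoreArgs = list(N = nBg, n = nQ)))
    nT <- nrow(sub)
    out <- data.frame(term_id = sub$term_id, term_name = sub$term_name,
                      ontology = rep(ont, nT), k = k, K = K,
                      n_query = rep(nQ, nT), n_background = rep(nBg, nT),
                      p_value = p, fdr = bhFdr(p),
                      significant = p < alpha,
                      genes = vapply(hit, function(g)
                        paste(sort(g), collapse = ";"), character(1L)),
                      row.names = NULL)
    out[order(out$p_value, out$term_id), , drop = FALSE]
  })
  res
}
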