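# Hypergeometric tails, pathway enrichment modes, GO Fisher/EASE, BH FDR.

test_that("hypergeometric tails match exact arithmetic on hand cases", {
  # P = [C(4,0)C(6,5) + C(4,1)C(6,4) + C(4,2)C(6,3)] / C(10,5) = 186/252
  expect_equal(hypergeomLowerTail(10, 4, 5, 2), 31 / 42, tolerance = 1e-14)
  expect_identical(hypergeomLowerTail(10, 4, 5, 4), 1)  # x = min(n, m)
  expect_identical(hypergeomLowerTail(10, 0, 5, 0), 1)  # X identically 0
  expect_identical(hypergeomUpperTail(10, 4, 5, 0), 1)
  expect_equal(hypergeomUpperTail(10, 4, 5, 3) + hypergeomLowerTail(10, 4, 5, 2),
               1, tolerance = 1e-12)
})

test_that("argument validation rejects out-of-range counts", {
  expect_error(hypergeomLowerTail(10, 11, 5, 2), "m <= N")
  expect_error(hypergeomLowerTail(10, 4, 5, 6), "x <= n")
  expect_error(hypergeomLowerTail(10, 4, 5, -1), "x")
  expect_error(hypergeomLowerTail(10.5, 4, 5, 2), "integers")
})

test_that("lower tail is non-decreasing in x and agrees with stats::phyper", {
  set.seed(31)
  for (rep in 1:20) {
    N <- sample(5:200, 1L)
    m <- sample(0:N, 1L)
    n <- sample(1:N, 1L)
    ps <- vapply(0:n, function(x) hypergeomLowerTail(N, m, n, x), numeric(1L))
    expect_true(all(diff(ps) >= -1e-15))
    x <- sample(0:n, 1L)
    expect_equal(hypergeomLowerTail(N, m, n, x),
                 stats::phyper(x, m, N - m, n), tolerance = 1e-12)
  }
})

test_that("BH FDR follows the step-up definition", {
  expect_identical(bhFdr(0.04), 0.04)
  p <- c(0.01, 0.02, 0.03)
  # definitional step-up, evaluated directly
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  expected <- numeric(n)
  running <- Inf
  for (i in seq_along(o)) {
    rank <- n - i + 1L
    running <- min(running, p[o[i]] * n / rank)
    expected[o[i]] <- running
  }
  expect_equal(bhFdr(p), expected, tolerance = 1e-15)
  expect_equal(bhFdr(p), c(0.03, 0.03, 0.03), tolerance = 1e-15)
  expect_identical(bhFdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bhFdr(c(0.5, 1.2)), "0, 1")
  expect_identical(bhFdr(numeric()), numeric())
})

test_that("pathway enrichment ranks by descending probability with id tie-break", {
  d <- writeMiniKB(tempfile(), pathways = data.frame(
    pathway_id = c("PWa", "PWb", "PWc", "PWd"),
    name = c("A", "B", "C", "D"),
    source = c("kegg-like", "kegg-like", "humancyc-like", "kegg-like"),
    members = c("1;2;3;4", "5;6;7;8", "1;5;9", "100;101")))
  kb <- loadKnowledgeBase(d)
  overall <- as.character(1:9)
  sig <- c("1", "2", "3", "5")
  res <- pathwayEnrichment(overall, kb, significant = sig, mode = "enrichment")
  # PWd shares no member with the overall set -> omitted
  expect_false("PWd" %in% res$pathway_id)
  expect_identical(res$N, rep(9L, 3L))
  expect_identical(res$n, rep(4L, 3L))
  # oracle probabilities decide the ranking
  oracle <- vapply(seq_len(nrow(res)), function(i)
    oracleHyperLower(res$N[i], res$m[i], res$n[i], res$x[i]), numeric(1L))
  expect_equal(res$probability, oracle, tolerance = 1e-12)
  expect_true(all(diff(res$probability) <= 1e-15))
  # complementarity of the two reported tails: P(X<=x) + P(X>x) = 1
  upper_strict <- vapply(seq_len(nrow(res)), function(i)
    oracleHyperUpper(res$N[i], res$m[i], res$n[i], res$x[i] + 1L), numeric(1L))
  expect_equal(res$probability + upper_strict, rep(1, nrow(res)),
               tolerance = 1e-12)
})

test_that("pathway enrichment edge rules: modes, subsets, degenerate inputs", {
  d <- writeMiniKB(tempfile(), pathways = data.frame(
    pathway_id = c("PW1", "PW2"), name = c("one", "two"),
    source = "kegg-like", members = c("1;2;3", "2;9")))
  kb <- loadKnowledgeBase(d)
  norm <- pathwayEnrichment(as.character(1:3), kb, mode = "normal")
  expect_identical(norm$pathway_id, c("PW1", "PW2"))  # ranked by m desc
  expect_identical(norm$m, c(3L, 1L))
  expect_identical(norm$mapped, c("1;2;3", "2"))

  expect_error(pathwayEnrichment(as.character(1:3), kb,
                                 significant = c("2", "77"),
                                 mode = "enrichment"), "77")

  # significant = overall forces x = m and probability 1 everywhere
  res <- pathwayEnrichment(as.character(1:3), kb,
                           significant = as.character(1:3),
                           mode = "enrichment")
  expect_identical(res$x, res$m)
  expect_identical(res$probability, rep(1, 2L))

  # source filter
  only <- pathwayEnrichment(as.character(1:3), kb, mode = "normal",
                            source = "humancyc-like")
  expect_identical(nrow(only), 0L)
})

test_that("planted fixture pathway attains the top probability rank", {
  d <- generateKnowledgeBaseFixture(tempfile(), seed = 8)
  kb <- loadKnowledgeBase(d)
  man <- readFixtureManifest(d)
  overall <- man$pools$metabolites
  sig <- c(man$planted_pathway$members[1:8],
           setdiff(overall, man$planted_pathway$members)[1:4])
  res <- pathwayEnrichment(overall, kb, significant = sig, mode = "enrichment")
  oracle <- vapply(seq_len(nrow(res)), function(i)
    oracleHyperLower(res$N[i], res$m[i], res$n[i], res$x[i]), numeric(1L))
  expect_equal(res$probability, oracle, tolerance = 1e-10)
  expect_identical(res$pathway_id[1L], man$planted_pathway$id)
})

test_that("GO p-values equal enumeration and independent fisher.test", {
  d <- writeMiniKB(tempfile(), go = data.frame(
    term_id = c("GO:1", "GO:2", "GO:3"),
    term_name = c("a", "b", "c"), ontology = "BP",
    genes = c("1;2;3", "4;5;6;7;8", paste(1:10, collapse = ";"))))
  kb <- loadKnowledgeBase(d)
  query <- c("1", "2", "4")
  res <- goEnrichment(query, kb, method = "fisher")$BP
  for (i in seq_len(nrow(res))) {
    k <- res$k[i]; K <- res$K[i]
    expect_equal(res$p_value[i],
                 oracleFisherGreater(k, 3L, K, 10L), tolerance = 1e-12)
    tab <- matrix(c(k, 3L - k, K - k, 10L - 3L - K + k), 2L)
    expect_equal(res$p_value[i],
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
  # the term annotating the entire background is never enriched
  expect_identical(res$p_value[res$term_id == "GO:3"], 1)
})

test_that("EASE deflates single-gene support to p = 1", {
  d <- writeMiniKB(tempfile(), go = data.frame(
    term_id = c("GO:1", "GO:2"), term_name = c("a", "bg"), ontology = "MF",
    genes = c("1;2", paste(1:12, collapse = ";"))))
  kb <- loadKnowledgeBase(d)
  res <- goEnrichment(c("1", "5"), kb, method = "ease")$MF
  expect_identical(res$p_value[res$term_id == "GO:1"], 1)  # k=1 -> k'=0
  fish <- goEnrichment(c("1", "5"), kb, method = "fisher")$MF
  expect_lt(fish$p_value[fish$term_id == "GO:1"], 1)
  # EASE is uniformly conservative relative to plain Fisher
  expect_true(all(res$p_value >= fish$p_value - 1e-15))
})

test_that("GO output contracts: background checks, FDR per ontology, display set", {
  d <- generateKnowledgeBaseFixture(tempfile(), seed = 4)
  kb <- loadKnowledgeBase(d)
  man <- readFixtureManifest(d)
  bg <- sort(unique(unlist(kbGoTerms(kb)$genes)))
  expect_error(goEnrichment(c(bg[1], "999999"), kb), "999999")

  res <- goEnrichment(man$planted_go_term$genes, kb, method = "fisher")
  expect_named(res, c("BP", "CC", "MF"))
  for (ont in names(res)) {
    df <- res[[ont]]
    expect_true(all(df$ontology == ont))
    expect_equal(df$fdr, bhFdr(df$p_value), tolerance = 1e-15)
    expect_true(all(df$fdr >= df$p_value - 1e-15))  # within-rank monotone BH
    expect_true(!is.unsorted(df$p_value))
    expect_identical(df$significant, df$p_value < 0.05)
    expect_true(all(df$k <= pmin(length(man$planted_go_term$genes), df$K)))
  }
  expect_identical(res$BP$term_id[1L], man$planted_go_term$id)
})
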