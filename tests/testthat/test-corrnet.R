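# Correlation matrix, network thresholding, cluster ranking, layout, export.

test_that("correlation matrix reproduces closed-form PCC values", {
  m <- rbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(1, 2, 4))
  tab <- makeOmics(m, "T", ids = c("1", "2", "3"))
  cc <- correlationMatrix(tab)
  expect_identical(diag(cc), c(`1` = 1, `2` = 1, `3` = 1))
  expect_equal(cc["1", "2"], -1)
  # cor((1,2,3),(1,2,4)) = (3/2) / sqrt(1 * 7/3) = sqrt(27/28), exactly
  expect_equal(cc["1", "3"], sqrt(27 / 28), tolerance = 1e-12)
  expect_identical(cc, t(cc))
})

test_that("undefined pairs are NA, not zero", {
  m <- rbind(c(1, 2, 3, 4), c(5, 5, 5, 5), c(2, 1, NA, NA), c(1, NA, NA, 2))
  tab <- makeOmics(m, "M")
  cc <- correlationMatrix(tab, minSharedObs = 3)
  expect_true(is.na(cc[1, 2]))            # zero variance partner
  expect_true(is.na(cc[1, 3]))            # only 2 shared observations
  expect_true(is.na(cc[3, 4]))
  expect_identical(diag(cc), stats::setNames(rep(1, 4), moleculeIds(tab)))
  # undefined pairs never become edges
  net <- buildNetwork(cc, networkConfig(pccThreshold = 0.01))
  expect_false(any(is.na(networkEdges(net)$weight)))
})

test_that("mismatched condition labels across layers are an error", {
  tT <- makeOmics(matrix(1:6, 2), "T", conds = c("a", "b", "c"))
  tP <- makeOmics(matrix(1:6, 2), "P", conds = c("a", "b", "d"))
  expect_error(correlationMatrix(list(tT, tP)), "only in table 2: d")
  tP2 <- makeOmics(matrix(1:6, 2), "P", conds = c("b", "a", "c"))
  expect_error(correlationMatrix(list(tT, tP2)), "different order")
})

test_that("PCC is invariant to row order and positive affine transforms", {
  set.seed(7)
  m <- matrix(stats::rnorm(40), 8L, 5L)
  tab <- makeOmics(m, "T")
  cc <- correlationMatrix(tab)
  perm <- sample(nrow(m))
  tabP <- makeOmics(m[perm, ], "T", ids = moleculeIds(tab)[perm])
  ccP <- correlationMatrix(tabP)
  expect_equal(ccP[moleculeIds(tab), moleculeIds(tab)],
               cc[moleculeIds(tab), moleculeIds(tab)],
               tolerance = 1e-12, ignore_attr = TRUE)
  # y -> 3y + 10 leaves PCC untouched
  m2 <- m
  m2[3, ] <- 3 * m2[3, ] + 10
  cc2 <- correlationMatrix(makeOmics(m2, "T"))
  expect_equal(cc2, cc, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("edges obey the strict threshold rule, signed by default", {
  cc <- diag(4)
  dimnames(cc) <- list(as.character(1:4), as.character(1:4))
  cc[1, 2] <- cc[2, 1] <- 0.95
  cc[1, 3] <- cc[3, 1] <- 0.9          # exactly at threshold: excluded
  cc[2, 4] <- cc[4, 2] <- -0.97        # negative: excluded unless absolute
  attr(cc, "layers") <- stats::setNames(rep("T", 4), rownames(cc))
  net <- buildNetwork(cc, networkConfig())
  e <- networkEdges(net)
  expect_identical(nrow(e), 1L)
  expect_identical(c(e$from, e$to), c("1", "2"))
  expect_identical(e$weight, 0.95)

  netAbs <- buildNetwork(cc, networkConfig(useAbsolute = TRUE))
  expect_identical(nrow(networkEdges(netAbs)), 2L)

  netTop <- buildNetwork(cc, networkConfig(pccThreshold = 1))
  expect_identical(nrow(networkEdges(netTop)), 0L)

  expect_error(networkConfig(pccThreshold = 1.2), "0, 1")
  expect_error(networkConfig(pccThreshold = 0), "0, 1")
})

test_that("edge set equals a brute-force pair scan and is monotone in threshold", {
  set.seed(21)
  for (rep in 1:5) {
    m <- matrix(stats::rnorm(6 * 5), 6L, 5L)
    tab <- makeOmics(m, "T")
    cc <- correlationMatrix(tab)
    thr <- stats::runif(1, 0.2, 0.95)
    net <- buildNetwork(cc, networkConfig(pccThreshold = thr))
    got <- networkEdges(net)[, c("from", "to")]
    exp <- NULL
    ids <- rownames(cc)
    for (i in 1:5) for (j in (i + 1):6)
      if (!is.na(cc[i, j]) && cc[i, j] > thr)
        exp <- rbind(exp, sort(c(ids[i], ids[j])))
    nexp <- if (is.null(exp)) 0L else nrow(exp)
    expect_identical(nrow(got), nexp)
    if (nexp > 0) {
      ord <- order(exp[, 1L], exp[, 2L])
      expect_identical(got$from, exp[ord, 1L])
      expect_identical(got$to, exp[ord, 2L])
    }
    # monotone edge counts over an increasing threshold ladder
    counts <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9, 1.0), function(t)
      nrow(networkEdges(buildNetwork(cc, networkConfig(pccThreshold = t)))),
      integer(1L))
    expect_true(all(diff(counts) <= 0L))
  }
})

test_that("clusters are ranked components with deterministic tie-breaks", {
  cc <- diag(6)
  ids <- c("a1", "a2", "b1", "b2", "c1", "z9")
  dimnames(cc) <- list(ids, ids)
  # two 2-clusters (tie on size -> smallest member first), one singleton pair
  cc["b1", "b2"] <- cc["b2", "b1"] <- 0.99
  cc["a1", "a2"] <- cc["a2", "a1"] <- 0.95
  attr(cc, "layers") <- stats::setNames(rep("P", 6), ids)
  # protein ids must look like accessions; relabel
  ids2 <- c("Pa1", "Pa2", "Pb1", "Pb2", "Pc1", "Pz9")
  dimnames(cc) <- list(ids2, ids2)
  attr(cc, "layers") <- stats::setNames(rep("P", 6), ids2)
  net <- findClusters(buildNetwork(cc, networkConfig()))
  cl <- networkClusters(net)
  expect_identical(cl, list(c("Pa1", "Pa2"), c("Pb1", "Pb2")))
  # isolated nodes stay in the node table but not in clusters
  expect_identical(nrow(networkNodes(net)), 6L)
  summ <- clusterSummary(net)
  expect_identical(summ$rank, 1:2)
  expect_identical(summ$size, c(2L, 2L))
})

test_that("components equal brute-force reachability on random graphs", {
  set.seed(33)
  for (rep in 1:10) {
    n <- 12L
    ids <- sprintf("P%05d", seq_len(n))
    cc <- diag(n)
    dimnames(cc) <- list(ids, ids)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      cc[i, j] <- cc[j, i] <- stats::runif(1, -1, 1)
    attr(cc, "layers") <- stats::setNames(rep("P", n), ids)
    net <- findClusters(buildNetwork(cc, networkConfig(pccThreshold = 0.8)))
    e <- networkEdges(net)
    comps <- oracleComponents(ids, e$from, e$to)
    comps <- Filter(function(x) length(x) >= 2L, comps)
    comps <- lapply(comps, sort)
    comps <- comps[order(-lengths(comps),
                         vapply(comps, `[`, character(1L), 1L))]
    expect_identical(networkClusters(net), unname(comps))
  }
})

test_that("literature edges connect clusters unless excluded", {
  cc <- diag(2)
  dimnames(cc) <- list(c("1001", "1002"), c("1001", "1002"))
  attr(cc, "layers") <- c("1001" = "T", "1002" = "T")
  bridged <- data.frame(id = "5001", layer = "M",
                        linked = I(list(c("1001", "1002"))),
                        evidence = "literature")
  net <- buildNetwork(cc, networkConfig(), bridged)
  expect_identical(sum(networkNodes(net)$origin == "literature"), 1L)
  e <- networkEdges(net)
  expect_identical(sum(e$kind == "literature"), 2L)
  expect_true(all(is.na(e$weight[e$kind == "literature"])))
  withLit <- findClusters(net)
  expect_identical(networkClusters(withLit),
                   list(c("1001", "1002", "5001")))
  noLit <- findClusters(net, includeLiteratureEdges = FALSE)
  expect_identical(networkClusters(noLit), list())
})

test_that("layout is seeded, finite, and repulsion-driven", {
  cc <- diag(2)
  dimnames(cc) <- list(c("1001", "1002"), c("1001", "1002"))
  attr(cc, "layers") <- c("1001" = "T", "1002" = "T")
  net <- buildNetwork(cc, networkConfig())
  p1 <- layoutNetwork(net, networkConfig(layoutSeed = 4))
  p2 <- layoutNetwork(net, networkConfig(layoutSeed = 4))
  expect_identical(p1, p2)
  expect_true(all(is.finite(p1)))
  # two disconnected nodes drift apart under pure repulsion
  init <- OmicsBridge:::.withSeed(4, matrix(stats::runif(4, -1, 1), 2L, 2L))
  d0 <- sqrt(sum((init[1, ] - init[2, ])^2))
  d1 <- sqrt(sum((p1[1, ] - p1[2, ])^2))
  expect_gt(d1, d0)

  one <- buildNetwork(cc[1, 1, drop = FALSE] |>
                        (\(m) { attr(m, "layers") <- c("1001" = "T"); m })(),
                      networkConfig())
  expect_identical(layoutNetwork(one)["1001", ], c(x = 0, y = 0))
})

test_that("SIF export writes canonical lines and round-trips edges", {
  cc <- diag(2)
  dimnames(cc) <- list(c("1001", "1002"), c("1001", "1002"))
  cc[1, 2] <- cc[2, 1] <- 0.99
  attr(cc, "layers") <- c("1001" = "T", "1002" = "T")
  bridged <- data.frame(id = "5001", layer = "M",
                        linked = I(list("1001")), evidence = "literature")
  net <- buildNetwork(cc, networkConfig(), bridged)
  f <- tempfile(fileext = ".sif")
  exportSIF(net, f)
  lines <- readLines(f)
  expect_identical(lines, c("1001\tcor\t1002", "1001\tlit\t5001"))
  back <- readSIF(f)
  expect_identical(back$relation, c("cor", "lit"))

  emptyNet <- buildNetwork(
    (\(m) { dimnames(m) <- list("1001", "1001")
            attr(m, "layers") <- c("1001" = "T"); m })(diag(1)),
    networkConfig())
  f2 <- tempfile(fileext = ".sif")
  exportSIF(emptyNet, f2)
  expect_identical(length(readLines(f2)), 0L)
})

test_that("SVG scene uses layer shapes and dotted literature strokes", {
  tT <- makeOmics(matrix(c(1, 2, 3, 1.1, 2, 3.2), 2L, 3L, byrow = TRUE), "T")
  tP <- makeOmics(matrix(c(1, 2, 3, 3, 2, 1), 2L, 3L, byrow = TRUE), "P")
  cc <- correlationMatrix(list(tT, tP))
  bridged <- data.frame(id = "5001", layer = "M",
                        linked = I(list(moleculeIds(tT)[1L])),
                        evidence = "literature")
  net <- buildNetwork(cc, networkConfig(pccThreshold = 0.5), bridged)
  svg <- tempfile(fileext = ".svg")
  exportNetworkSVG(net, layoutNetwork(net), svg)
  txt <- readLines(svg)
  expect_identical(sum(grepl("<rect class=\"node\"", txt)), 2L)     # transcripts
  expect_identical(sum(grepl("<polygon class=\"node\"", txt)), 2L)  # proteins
  expect_identical(sum(grepl("<circle class=\"node\"", txt)), 1L)   # metabolite
  expect_identical(sum(grepl("stroke-dasharray", txt)),
                   sum(networkEdges(net)$kind == "literature"))
})
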