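# Hierarchical coexpression clustering and the heatmap renderer.

test_that("identical rows merge at height zero and sit adjacent", {
  m <- rbind(c(1, 2, 3), c(1, 2, 3), c(9, 9, 0), c(5, 1, 2))
  res <- coexpression(makeOmics(m, "T"))
  hc <- res@rowTree
  first <- hc$merge[1L, ]
  expect_identical(sort(-first), c(1L, 2L))
  expect_identical(hc$height[1L], 0)
  pos <- match(c(1L, 2L), res@rowOrder)
  expect_identical(abs(diff(pos)), 1L)
})

test_that("merge structure equals brute-force agglomeration (cophenetic)", {
  # tiny hand-checkable case first
  m <- rbind(a = c(0, 0), b = c(1, 0), c = c(5, 0))
  res <- coexpression(makeOmics(cbind(m, 0), "T", ids = c("1", "2", "3")))
  coph <- as.matrix(stats::cophenetic(res@rowTree))
  # a,b merge at 1; c joins at complete-linkage distance max(5,4)=5
  expect_equal(coph["1", "2"], 1)
  expect_equal(coph["1", "3"], 5)
  expect_equal(coph["2", "3"], 5)

  set.seed(11)
  for (linkage in c("complete", "single", "average")) {
    for (rep in 1:4) {
      X <- matrix(stats::rnorm(7 * 4), 7L, 4L)
      tab <- makeOmics(X, "M")
      res2 <- coexpression(tab, linkage = linkage)
      got <- as.matrix(stats::cophenetic(res2@rowTree))
      exp <- oracleCophenetic(omicsValues(tab), linkage)
      expect_equal(got[rownames(exp), rownames(exp)], exp, tolerance = 1e-10)
    }
  }
})

test_that("merge heights are monotone and leaves span contiguous blocks", {
  set.seed(5)
  res <- coexpression(makeOmics(matrix(stats::rnorm(36), 9L, 4L), "T"))
  expect_true(!is.unsorted(res@rowTree$height))
  expect_true(!is.unsorted(res@colTree$height))
  # every subtree occupies a contiguous stretch of the leaf order
  contiguous <- function(hc) {
    n <- length(hc$order)
    leafPos <- match(seq_len(n), hc$order)
    members <- vector("list", nrow(hc$merge))
    ok <- TRUE
    for (i in seq_len(nrow(hc$merge))) {
      ch <- hc$merge[i, ]
      mem <- unlist(lapply(ch, function(c)
        if (c < 0) -c else members[[c]]))
      members[[i]] <- mem
      pos <- sort(leafPos[mem])
      ok <- ok && all(diff(pos) == 1L)
    }
    ok
  }
  expect_true(contiguous(res@rowTree))
  expect_true(contiguous(res@colTree))
})

test_that("Euclidean distances satisfy the metric axioms", {
  set.seed(13)
  X <- matrix(stats::rnorm(8 * 5), 8L, 5L)
  D <- as.matrix(stats::dist(X))
  direct <- sqrt(outer(rowSums(X^2), rowSums(X^2), "+") - 2 * X %*% t(X))
  expect_equal(D, direct, tolerance = 1e-8, ignore_attr = TRUE)
  expect_identical(diag(D), stats::setNames(rep(0, 8), rownames(D)))
  expect_equal(D, t(D))
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
})

test_that("clustering is invariant to input row permutation", {
  set.seed(19)
  X <- matrix(stats::rnorm(6 * 4), 6L, 4L)
  tab <- makeOmics(X, "T")
  res <- coexpression(tab)
  perm <- sample(6L)
  tabP <- makeOmics(X[perm, ], "T", ids = moleculeIds(tab)[perm])
  resP <- coexpression(tabP)
  ids <- moleculeIds(tab)
  c1 <- as.matrix(stats::cophenetic(res@rowTree))[ids, ids]
  c2 <- as.matrix(stats::cophenetic(resP@rowTree))[ids, ids]
  expect_equal(c1, c2, tolerance = 1e-12)
})

test_that("colour scale maps min to 0, max to 1, degenerate to 0.5", {
  m <- rbind(c(0, 10), c(5, 2.5))
  res <- coexpression(makeOmics(m, "M"))
  expect_identical(min(res@colorMatrix), 0)
  expect_identical(max(res@colorMatrix), 1)
  expect_identical(res@colorMatrix[1L, 2L], 1)

  flat <- coexpression(makeOmics(matrix(3, 2L, 2L), "M"))
  expect_true(all(flat@colorMatrix == 0.5))
})

test_that("row_z scaling standardises every retained row", {
  set.seed(23)
  m <- rbind(matrix(stats::rnorm(12), 3L, 4L), c(2, 2, 2, 2))
  expect_warning(res <- coexpression(makeOmics(m, "T"), scale = "row_z"),
                 "constant row")
  expect_identical(nrow(res@values), 3L)
  expect_true(all(abs(rowMeans(res@values)) < 1e-9))
  expect_true(all(abs(apply(res@values, 1L, stats::var) - 1) < 1e-9))
})

test_that("missing-value rows are dropped with a warning; degenerate sizes error", {
  m <- rbind(c(1, 2, 3), c(NA, 2, 3), c(4, 5, 6))
  expect_warning(res <- coexpression(makeOmics(m, "T")), "dropped")
  expect_identical(nrow(res@values), 2L)
  expect_error(suppressWarnings(
    coexpression(makeOmics(rbind(c(1, 2), c(NA, 1)), "T"))),
    "at least 2 rows")
})

test_that("row colour codes follow the omics source of each row", {
  tT <- makeOmics(matrix(c(1, 2, 3, 2, 3, 4), 2L, 3L, byrow = TRUE), "T")
  tM <- makeOmics(matrix(c(9, 1, 2, 8, 2, 1), 2L, 3L, byrow = TRUE), "M")
  res <- coexpression(list(tT, tM))
  expect_identical(res@rowTypes, c("T", "T", "M", "M"))
  svg <- tempfile(fileext = ".svg")
  renderHeatmap(res, svg)
  txt <- readLines(svg)
  strips <- grep("class=\"rowtype\"", txt, value = TRUE)
  expect_identical(sum(grepl("#2ca02c", strips)), 2L)  # green transcript rows
  expect_identical(sum(grepl("#1f77b4", strips)), 2L)  # blue metabolite rows
})

test_that("heatmap SVG is deterministic and cell layout follows leaf order", {
  m <- rbind(c(1, 2), c(3, 4))
  res <- coexpression(makeOmics(m, "T"))
  f1 <- tempfile(fileext = ".svg")
  f2 <- tempfile(fileext = ".svg")
  renderHeatmap(res, f1)
  renderHeatmap(res, f2)
  expect_identical(readLines(f1), readLines(f2))
  cells <- grep("class=\"cell\"", readLines(f1), value = TRUE)
  expect_identical(length(cells), 4L)

  # reversing the row order mirrors the vertical cell placement
  resRev <- res
  resRev@rowOrder <- rev(res@rowOrder)
  fRev <- tempfile(fileext = ".svg")
  renderHeatmap(resRev, fRev)
  rowsOf <- function(f) {
    cl <- grep("class=\"cell\"", readLines(f), value = TRUE)
    y <- as.numeric(sub('.* y="([0-9.]+)".*', "\\1", cl))
    fill <- sub('.*fill="([^"]+)".*', "\\1", cl)
    lapply(sort(unique(y)), function(yy) sort(fill[y == yy]))
  }
  r1 <- rowsOf(f1); r2 <- rowsOf(fRev)
  expect_identical(r1, rev(r2))
  expect_false(identical(r1, r2))
})
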