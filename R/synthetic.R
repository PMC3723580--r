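# Seeded synthetic omics tables with planted block structure, so network
# and coexpression analyses have a recoverable ground truth.

#' Describe a synthetic omics design
#'
#' A design is a set of molecule blocks, each tied to a latent condition
#' profile: every molecule in a block is its block's profile plus i.i.d.
#' Gaussian noise.  Profiles are drawn once per design from a standard
#' normal over the conditions (and, by default, orthogonalised so distinct
#' blocks are uncorrelated at the population level, which keeps
#' between-block correlations controllable).  With the default profile
#' scale of 1, `noiseSd = 0.05` gives within-block correlations of about
#' 1/(1 + noiseSd^2) — far above the 0.9 network threshold.
#'
#' @param nConditions number of conditions (>= 3; a Pearson correlation
#'   needs at least three points).
#' @param blocks `data.frame` with columns `layer` (`T`/`P`/`M`), `size`
#'   (>= 2) and `profile` (positive integer profile id).
#' @param noiseSd noise standard deviation (>= 0; 0 gives exact copies of
#'   the profile, hence within-block correlations of exactly 1).
#' @param seed integer RNG seed.
#' @param orthogonalize orthogonalise the latent profiles (default TRUE).
#' @return a list of class `syntheticDesign`.
#' @examples
#' syntheticDesign(8, data.frame(layer = c("T", "T"), size = c(10, 10),
#'                               profile = c(1, 2)))
#' @export
syntheticDesign <- function(nConditions,
                            blocks = data.frame(layer = c("T", "P"),
                                                size = c(10L, 10L),
                                                profile = c(1L, 2L)),
                            noiseSd = 0.05, seed = 1L,
                            orthogonalize = TRUE) {
  if (nConditions < 3L)
    stop("nConditions must be >= 3 (a correlation needs at least 3 points)")
  stopifnot(is.data.frame(blocks),
            all(c("layer", "size", "profile") %in% names(blocks)),
            all(blocks$layer %in% c("T", "P", "M")),
            all(blocks$size >= 2L),
            all(blocks$profile >= 1L), noiseSd >= 0)
  if (orthogonalize && max(blocks$profile) > nConditions - 1L)
    stop("cannot orthogonalise more than nConditions - 1 profiles")
  structure(list(nConditions = as.integer(nConditions), blocks = blocks,
                 noiseSd = noiseSd, seed = as.integer(seed),
                 orthogonalize = orthogonalize),
            class = "syntheticDesign")
}

#' Simulate omics tables from a synthetic design
#'
#' Deterministic under the design's seed.  Returns one [OmicsTable-class]
#' per layer used in the design plus a truth manifest recording which block
#' (and latent profile) each molecule belongs to.  Optionally writes the
#' tables as standard omics CSVs and the truth as `truth.json` to `dir`.
#'
#' @param design a [syntheticDesign()].
#' @param dir optional output directory for CSVs + `truth.json`.
#' @return list with `tables` (named by layer), `truth` (`data.frame` with
#'   `id`, `layer`, `block`, `profile`) and `profiles` (matrix, one row per
#'   latent profile).
#' @export
simulateOmics <- function(design, dir = NULL) {
  stopifnot(inherits(design, "syntheticDesign"))
  nc <- design$nConditions
  conds <- sprintf("c%d", seq_len(nc))
  nProf <- max(design$blocks$profile)

  .withSeed(design$seed, {
    P <- matrix(stats::rnorm(nProf * nc), nProf, nc)
    P <- P - rowMeans(P)
    if (design$orthogonalize && nProf > 1L) {
      for (i in 2:nProf) {
        for (j in 1:(i - 1L))
          P[i, ] <- P[i, ] - sum(P[i, ] * P[j, ]) / sum(P[j, ]^2) * P[j, ]
        P[i, ] <- P[i, ] - mean(P[i, ])
      }
    }
    # unit variance per profile
    P <- P / apply(P, 1L, stats::sd)

    counters <- c(T = 0L, P = 0L, M = 0L)
    truth <- NULL
    rowsByLayer <- list()
    for (b in seq_len(nrow(design$blocks))) {
      ly <- design$blocks$layer[b]
      sz <- design$blocks$size[b]
      idx <- counters[[ly]] + seq_len(sz)
      counters[[ly]] <- counters[[ly]] + sz
      ids <- switch(ly, T = as.character(1000L + idx),
                    P = sprintf("P%05d", idx),
                    M = as.character(5000L + idx))
      vals <- matrix(rep(P[design$blocks$profile[b], ], each = sz), sz, nc) +
        matrix(stats::rnorm(sz * nc, sd = design$noiseSd), sz, nc)
      dimnames(vals) <- list(ids, conds)
      rowsByLayer[[ly]] <- rbind(rowsByLayer[[ly]], vals)
      truth <- rbind(truth, data.frame(id = ids, layer = ly, block = b,
                                       profile = design$blocks$profile[b]))
    }
    tables <- lapply(names(rowsByLayer), function(ly)
      omicsTable(rowsByLayer[[ly]], ly))
    names(tables) <- names(rowsByLayer)

    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      for (ly in names(tables))
        writeOmicsCSV(tables[[ly]], file.path(dir, sprintf("%s.csv", ly)))
      jsonlite::write_json(list(seed = design$seed,
                                noise_sd = design$noiseSd,
                                blocks = truth),
                           file.path(dir, "truth.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
    list(tables = tables, truth = truth, profiles = P)
  })
}
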