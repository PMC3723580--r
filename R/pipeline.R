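# One-command orchestration: bridge -> correlation -> clusters ->
# coexpression -> enrichments -> phenotype, with every table and image
# written to an output directory plus a manifest.

.writeCSV <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# bar chart of enriched GO terms, bar length ~ -log10(p)
.goBarChartSVG <- function(goRes, path, alpha = 0.05) {
  rows <- do.call(rbind, lapply(goRes, function(df)
    df[df$significant, c("term_id", "term_name", "ontology", "p_value"),
       drop = FALSE]))
  bar <- 16L; gap <- 6L; left <- 260L; width <- 640L
  n <- if (is.null(rows)) 0L else nrow(rows)
  height <- max(60L, 30L + n * (bar + gap))
  out <- .svgHeader(width, height)
  out <- c(out, sprintf(
    "<text x=\"10\" y=\"18\" font-size=\"12\" font-family=\"sans-serif\">Enriched GO terms (p &lt; %s)</text>",
    format(alpha)))
  if (n) {
    score <- -log10(pmax(rows$p_value, 1e-300))
    smax <- max(score)
    for (i in seq_len(n)) {
      y <- 30L + (i - 1L) * (bar + gap)
      out <- c(out,
        sprintf("<text x=\"10\" y=\"%d\" font-size=\"10\" font-family=\"sans-serif\">%s [%s] %s</text>",
                y + 12L, rows$term_id[i], rows$ontology[i],
                substr(rows$term_name[i], 1L, 28L)),
        sprintf("<rect class=\"bar\" x=\"%d\" y=\"%d\" width=\"%s\" height=\"%d\" fill=\"%s\"/>",
                left, y, .fmtCoord((width - left - 20L) * score[i] / smax),
                bar, c(BP = "#1b9e77", CC = "#d95f02", MF = "#7570b3")[[rows$ontology[i]]]))
    }
  }
  out <- c(out, "</svg>")
  writeLines(out, path)
  invisible(path)
}

#' Run the full integrated analysis
#'
#' Executes the planned analyses over the uploaded omics tables in a fixed
#' stage order — literature bridging, correlation network, cluster ranking,
#' coexpression heatmap, pathway and GO enrichment, phenotype mapping —
#' and writes every result table (CSV), network file (SIF) and image (SVG,
#' optionally PNG) into `outdir`, together with `manifest.json` listing
#' parameters and outputs.  With fixed seeds the manifest and every CSV/SVG
#' are reproduced identically.  Input files are never copied into `outdir`
#' unless `keepInputs = TRUE` (uploads are transient by design).  A failing
#' stage aborts with an error naming the stage.
#'
#' @param tables list of 1-3 [OmicsTable-class] objects (distinct layers).
#' @param kb a [KnowledgeBase-class].
#' @param outdir output directory, created if needed.
#' @param analyses `"all"` or a subset; see [planAnalyses()].
#' @param config a [NetworkConfig-class].
#' @param significantMetabolites optional vector of CIDs (subset of the
#'   metabolomics table) switching pathway enrichment from normal to
#'   enrichment mode.
#' @param linkage,scale coexpression options, see [coexpression()].
#' @param goMethod,alpha GO options, see [goEnrichment()].
#' @param seed integer; seeds the network layout.
#' @param keepInputs copy the input tables into `outdir`.
#' @param writePng additionally render the network as PNG.
#' @return the manifest, invisibly (list).
#' @export
runPipeline <- function(tables, kb, outdir, analyses = "all",
                        config = networkConfig(),
                        significantMetabolites = NULL,
                        linkage = "complete", scale = "none",
                        goMethod = "ease", alpha = 0.05,
                        seed = 1L, keepInputs = FALSE, writePng = FALSE) {
  if (is(tables, "OmicsTable")) tables <- list(tables)
  stopifnot(all(vapply(tables, is, logical(1L), "OmicsTable")),
            is(kb, "KnowledgeBase"))
  layers <- vapply(tables, omicsLayer, character(1L))
  names(tables) <- layers
  plan <- planAnalyses(layers, analyses)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  config@layoutSeed <- seed

  logFile <- file.path(outdir, "run.log")
  cat(sprintf("mode=%s analyses=%s\n", plan$mode,
              paste(plan$analyses, collapse = ",")), file = logFile)
  outputs <- character()
  stages <- character()
  t0 <- Sys.time()
  stage <- function(name, expr) {
    message("[", name, "] running")
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    cat(sprintf("%-14s ok (%.2fs)\n", name,
                as.numeric(Sys.time() - t0, units = "secs")),
        file = logFile, append = TRUE)
    stages <<- c(stages, name)
    res
  }
  emit <- function(file) outputs <<- c(outputs, file)

  if (keepInputs)
    for (ly in layers) {
      f <- sprintf("input_%s.csv", ly)
      writeOmicsCSV(tables[[ly]], file.path(outdir, f))
      emit(f)
    }

  bridged <- NULL
  if (!is.na(plan$bridgedLayer))
    bridged <- stage("bridge", {
      b <- bridgeMissingLayer(tables, kb)
      f <- "bridged_molecules.csv"
      .writeCSV(data.frame(id = b$id, layer = b$layer,
                           linked = vapply(b$linked, paste, character(1L),
                                           collapse = ";"),
                           evidence = b$evidence), file.path(outdir, f))
      emit(f)
      b
    })

  if ("correlation" %in% plan$analyses) {
    net <- stage("correlation", {
      cc <- correlationMatrix(tables, config@minSharedObs)
      buildNetwork(cc, config, bridged)
    })
    net <- stage("clusters", {
      n2 <- findClusters(net)
      .writeCSV(clusterSummary(n2), file.path(outdir, "clusters.csv"))
      emit("clusters.csv")
      n2
    })
    stage("network_export", {
      exportSIF(net, file.path(outdir, "network.sif"))
      emit("network.sif")
      .writeCSV(networkEdges(net), file.path(outdir, "network_edges.csv"))
      emit("network_edges.csv")
      if (nrow(networkNodes(net))) {
        coords <- layoutNetwork(net, config)
        exportNetworkSVG(net, coords, file.path(outdir, "network.svg"))
        emit("network.svg")
        if (writePng &&
            !is.null(exportNetworkPNG(net, coords,
                                      file.path(outdir, "network.png"))))
          emit("network.png")
      }
    })
  }

  if ("coexpression" %in% plan$analyses)
    stage("coexpression", {
      cx <- coexpression(tables, scale = scale, linkage = linkage)
      renderHeatmap(cx, file.path(outdir, "coexpression.svg"))
      emit("coexpression.svg")
      .writeCSV(data.frame(position = seq_along(cx@rowOrder),
                           molecule = rownames(cx@values)[cx@rowOrder],
                           layer = cx@rowTypes[cx@rowOrder]),
                file.path(outdir, "coexpression_row_order.csv"))
      emit("coexpression_row_order.csv")
      .writeCSV(data.frame(position = seq_along(cx@colOrder),
                           condition = colnames(cx@values)[cx@colOrder]),
                file.path(outdir, "coexpression_col_order.csv"))
      emit("coexpression_col_order.csv")
    })

  if ("pathway_enrichment" %in% plan$analyses)
    stage("pathway_enrichment", {
      overall <- moleculeIds(tables[["M"]])
      res <- if (is.null(significantMetabolites))
        pathwayEnrichment(overall, kb, mode = "normal")
      else pathwayEnrichment(overall, kb,
                             significant = significantMetabolites,
                             mode = "enrichment")
      .writeCSV(res, file.path(outdir, "pathway_enrichment.csv"))
      emit("pathway_enrichment.csv")
    })

  if ("go_enrichment" %in% plan$analyses)
    stage("go_enrichment", {
      background <- sort(unique(unlist(kbGoTerms(kb)$genes)))
      query <- intersect(moleculeIds(tables[["T"]]), background)
      dropped <- length(moleculeIds(tables[["T"]])) - length(query)
      if (dropped > 0L)
        message(dropped, " input gene(s) not annotated in the knowledgebase; ",
                "excluded from GO enrichment")
      if (length(query) == 0L)
        stop("no input gene is annotated in the knowledgebase GO table")
      res <- goEnrichment(query, kb, background = background,
                          method = goMethod, alpha = alpha)
      .writeCSV(do.call(rbind, c(res, make.row.names = FALSE)),
                file.path(outdir, "go_enrichment.csv"))
      emit("go_enrichment.csv")
      .goBarChartSVG(res, file.path(outdir, "go_enrichment.svg"), alpha)
      emit("go_enrichment.svg")
    })

  if ("phenotype" %in% plan$analyses)
    stage("phenotype", {
      .writeCSV(phenotypeMap(tables, kb),
                file.path(outdir, "phenotypes.csv"))
      emit("phenotypes.csv")
    })

  manifest <- list(
    mode = plan$mode,
    analyses = plan$analyses,
    bridged_layer = if (is.na(plan$bridgedLayer)) NULL else plan$bridgedLayer,
    parameters = list(pcc_threshold = config@pccThreshold,
                      use_absolute = config@useAbsolute,
                      repulsion = config@repulsion,
                      attraction = config@attraction,
                      min_shared_obs = config@minSharedObs,
                      linkage = linkage, scale = scale,
                      go_method = goMethod, alpha = alpha, seed = seed),
    stages_completed = stages,
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
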