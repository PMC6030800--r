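#' Assemble a pipeline run configuration
#'
#' @param transactions Path to the transaction table.
#' @param annotations Path to the herb annotation table (may be
#'   \code{NULL}; the enrichment stage then aborts after the earlier
#'   stages have written their outputs).
#' @param outDir Output directory (created if needed).
#' @param route Route filter applied before mining
#'   (\code{"internal"} by default).
#' @param ruleLen Integer vector of rule lengths to mine (subset of
#'   \code{c(2, 3)}).
#' @param minSupport,minConfidence Rule thresholds.
#' @param topK Number of rules shown per table in the report.
#' @param resolution Louvain resolution gamma.
#' @param louvainSeed,permSeed The two named seeds through which all
#'   randomness flows.
#' @param nPerm Permutations for the enrichment test.
#' @param alpha FDR threshold for direction calls.
#' @return A named list of class \code{"herbnetRunConfig"}.
#' @export
runConfig <- function(transactions, annotations = NULL, outDir,
                      route = "internal", ruleLen = c(2L, 3L),
                      minSupport = 0, minConfidence = 0, topK = 10L,
                      resolution = 1, louvainSeed = 1L, nPerm = 10000L,
                      permSeed = 1L, alpha = 0.05) {
  stopifnot(all(ruleLen %in% c(2L, 3L)))
  .checkRoute(route)
  structure(list(transactions = transactions, annotations = annotations,
                 outDir = outDir, route = route,
                 ruleLen = as.integer(ruleLen),
                 minSupport = minSupport, minConfidence = minConfidence,
                 topK = as.integer(topK), resolution = resolution,
                 louvainSeed = as.integer(louvainSeed),
                 nPerm = as.integer(nPerm),
                 permSeed = as.integer(permSeed), alpha = alpha),
            class = "herbnetRunConfig")
}

.stage <- function(name, logCon, expr) {
  tryCatch(expr, error = function(e) {
    msg <- paste0("stage '", name, "' failed: ", conditionMessage(e))
    .logLine(logCon, msg)
    stop(msg, call. = FALSE)
  })
}

.logLine <- function(logCon, ...) {
  line <- paste0(...)
  message(line)
  if (!is.null(logCon)) writeLines(line, logCon)
}

#' Run the full mining / network / enrichment pipeline
#'
#' Executes, on the route-filtered corpus: association rule mining for
#' the configured rule lengths, co-occurrence network construction and
#' export (GraphML + GEXF), Louvain module detection, and the
#' meridian-enrichment permutation test. Stage outputs are written
#' eagerly, so a late-stage failure preserves earlier results. Given
#' identical configuration and seeds the output files are reproduced
#' bit for bit (log lines carry no timestamps).
#'
#' Files written to \code{outDir}: \code{rules_len2.tsv} /
#' \code{rules_len3.tsv} (full precision), \code{network.graphml},
#' \code{network.gexf}, \code{partition.tsv}, \code{enrichment.tsv},
#' \code{manifest.json}, \code{run.log}.
#'
#' @param config A configuration from \code{\link{runConfig}}.
#' @return Invisibly, a list with the in-memory artifacts
#'   (\code{corpus}, \code{rules}, \code{network}, \code{partition},
#'   \code{enrichment}, \code{manifest}).
#' @seealso \code{\link{summarizeRun}}
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "herbnetRunConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(config$outDir, "run.log")
  logCon <- file(logPath, open = "wt")
  on.exit(close(logCon), add = TRUE)

  manifest <- config[setdiff(names(config), "outDir")]
  artifacts <- list()

  corpus <- .stage("read", logCon, {
    corp <- readTransactions(config$transactions)
    .logLine(logCon, "read: N = ", nPrescriptions(corp), ", herbs = ",
             length(herbUniverse(corp)))
    corp
  })
  corpus <- .stage("filter", logCon, {
    corp <- filterByRoute(corpus, config$route)
    .logLine(logCon, "filter: route = ", config$route, ", N = ",
             nPrescriptions(corp))
    corp
  })
  manifest$N <- nPrescriptions(corpus)
  manifest$nHerbs <- length(unique(unlist(herbSets(corpus),
                                          use.names = FALSE)))
  artifacts$corpus <- corpus

  rules <- .stage("mine", logCon, {
    counts <- countItemsets(corpus, maxLen = max(config$ruleLen))
    out <- list()
    for (len in config$ruleLen) {
      r <- mineRules(corpus, ruleLen = len,
                     minSupport = config$minSupport,
                     minConfidence = config$minConfidence,
                     counts = counts)
      path <- file.path(config$outDir, sprintf("rules_len%d.tsv", len))
      writeRules(r, path)
      .logLine(logCon, "mine: len ", len, " -> ", nrow(r), " rule(s)")
      out[[as.character(len)]] <- r
    }
    out
  })
  artifacts$rules <- rules

  ann <- NULL
  annAvailable <- !is.null(config$annotations)
  if (annAvailable) {
    ann <- tryCatch(readAnnotations(config$annotations),
                    error = function(e) NULL)
    annAvailable <- !is.null(ann)
  }

  network <- .stage("network", logCon, {
    net <- buildCooccurrenceNetwork(corpus)
    .logLine(logCon, "network: ", length(networkNodes(net)),
             " node(s), ", nrow(edgeTable(net)), " edge(s), ",
             length(isolatedHerbs(net)), " isolated")
    net
  })
  manifest$nEdges <- nrow(edgeTable(network))
  artifacts$network <- network

  partition <- .stage("modularity", logCon, {
    p <- louvainPartition(network, resolution = config$resolution,
                          seed = config$louvainSeed)
    .logLine(logCon, "modularity: ", length(moduleSizes(p)),
             " module(s), sizes ",
             paste(moduleSizes(p), collapse = "/"),
             sprintf(", Q = %.6f", modularityScore(p)))
    ptab <- data.frame(herb_id = names(moduleAssignment(p)),
                       module = unname(moduleAssignment(p)),
                       stringsAsFactors = FALSE)
    utils::write.table(ptab, file.path(config$outDir, "partition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    exportGraphML(network, file.path(config$outDir, "network.graphml"),
                  partition = p, annotations = ann)
    exportGEXF(network, file.path(config$outDir, "network.gexf"),
               partition = p, annotations = ann)
    p
  })
  manifest$moduleSizes <- unname(moduleSizes(partition))
  manifest$Q <- modularityScore(partition)
  artifacts$partition <- partition
  .writeManifest(manifest, config$outDir)

  enrichment <- .stage("enrichment", logCon, {
    if (!annAvailable)
      stop("annotation table unavailable (",
           if (is.null(config$annotations)) "not configured"
           else config$annotations, ")")
    en <- permutationTest(partition, ann, nPerm = config$nPerm,
                          seed = config$permSeed, alpha = config$alpha)
    writeEnrichment(en, file.path(config$outDir, "enrichment.tsv"))
    sig <- sum(enrichmentTable(en)$direction != "none")
    .logLine(logCon, "enrichment: ", sig, " significant call(s) at q < ",
             config$alpha)
    en
  })
  artifacts$enrichment <- enrichment
  artifacts$manifest <- manifest
  .logLine(logCon, "done")
  invisible(artifacts)
}

.writeManifest <- function(manifest, outDir) {
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

#' Render a human-readable report of a pipeline run
#'
#' @param outDir A completed run directory written by
#'   \code{\link{runPipeline}}.
#' @param topK Rules shown per table (default: the run's configured
#'   value). Metric columns are rounded to 3 decimals; the machine
#'   tables on disk keep full precision.
#' @return Character vector of report lines, invisibly; the report is
#'   also printed.
#' @export
summarizeRun <- function(outDir, topK = NULL) {
  manifestPath <- file.path(outDir, "manifest.json")
  if (!file.exists(manifestPath))
    stop("incomplete run directory: missing manifest.json", call. = FALSE)
  manifest <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
  if (is.null(topK)) topK <- manifest$topK
  lines <- c("herbnet pipeline run",
             paste0("  route: ", manifest$route,
                    " | N = ", manifest$N,
                    " | herbs = ", manifest$nHerbs,
                    " | edges = ", manifest$nEdges),
             paste0("  seeds: louvain = ", manifest$louvainSeed,
                    ", permutation = ", manifest$permSeed,
                    " | resolution = ", manifest$resolution,
                    " | nPerm = ", manifest$nPerm))
  for (len in manifest$ruleLen) {
    path <- file.path(outDir, sprintf("rules_len%d.tsv", len))
    if (!file.exists(path))
      stop("incomplete run directory: missing ", basename(path),
           call. = FALSE)
    r <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    r <- topRules(r, topK)
    for (col in c("support", "confidence", "lift"))
      r[[col]] <- sprintf("%.3f", r[[col]])
    lines <- c(lines, "",
               sprintf("Top %d association rules (herb set size %d):",
                       nrow(r), len),
               paste0("  ", r$antecedent, " -> ", r$consequent,
                      "  support ", r$support,
                      "  confidence ", r$confidence,
                      "  lift ", r$lift,
                      "  frequency ", r$frequency))
  }
  partPath <- file.path(outDir, "partition.tsv")
  if (!file.exists(partPath))
    stop("incomplete run directory: missing partition.tsv", call. = FALSE)
  sizes <- manifest$moduleSizes
  lines <- c(lines, "",
             sprintf("Modules: %d (sizes %s; %d herbs), Q = %.3f",
                     length(sizes), paste(sizes, collapse = ", "),
                     sum(sizes), manifest$Q))
  enPath <- file.path(outDir, "enrichment.tsv")
  if (file.exists(enPath)) {
    en <- utils::read.table(enPath, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    sig <- en[en$direction != "none", , drop = FALSE]
    lines <- c(lines, "", "Significant meridian enrichment:")
    if (nrow(sig)) {
      lines <- c(lines, sprintf(
        "  module %s %s: %s (ratio %.3f, q = %.4g)",
        sig$module, sig$meridian, sig$direction, sig$observed_ratio,
        ifelse(sig$direction == "high", sig$q_high, sig$q_low)))
    } else {
      lines <- c(lines, "  none")
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
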