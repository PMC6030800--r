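# Accessor generics and show methods for the package classes.

#' Number of prescriptions in a corpus
#' @param x A \code{\linkS4class{HerbCorpus}}.
#' @return Integer.
#' @export
setGeneric("nPrescriptions", function(x) standardGeneric("nPrescriptions"))

#' @rdname nPrescriptions
#' @export
setMethod("nPrescriptions", "HerbCorpus",
          function(x) length(x@prescriptions))

#' Per-prescription herb sets
#' @param x A \code{\linkS4class{HerbCorpus}}.
#' @return Named list of character vectors.
#' @export
setGeneric("herbSets", function(x) standardGeneric("herbSets"))

#' @rdname herbSets
#' @export
setMethod("herbSets", "HerbCorpus", function(x) x@prescriptions)

#' Herb universe of a corpus
#' @param x A \code{\linkS4class{HerbCorpus}}.
#' @return Character vector of herb ids.
#' @export
setGeneric("herbUniverse", function(x) standardGeneric("herbUniverse"))

#' @rdname herbUniverse
#' @export
setMethod("herbUniverse", "HerbCorpus", function(x) x@herbs)

#' Administration route of each prescription
#' @param x A \code{\linkS4class{HerbCorpus}}.
#' @return Named character vector ("internal"/"external").
#' @export
setGeneric("prescriptionRoutes",
           function(x) standardGeneric("prescriptionRoutes"))

#' @rdname prescriptionRoutes
#' @export
setMethod("prescriptionRoutes", "HerbCorpus", function(x) x@route)

#' Herb annotation table of a corpus
#' @param x A \code{\linkS4class{HerbCorpus}}.
#' @return \code{data.frame} (possibly with zero rows) with columns
#'   \code{herb_id}, \code{latin_name}, \code{category} and one logical
#'   column per meridian code.
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname annotations
#' @export
setMethod("annotations", "HerbCorpus", function(x) x@annotations)

#' Replace the annotation table of a corpus
#' @param x A \code{\linkS4class{HerbCorpus}}.
#' @param value Annotation \code{data.frame}.
#' @export
setGeneric("annotations<-", function(x, value) standardGeneric("annotations<-"))

#' @rdname annotations-set
#' @export
setMethod("annotations<-", "HerbCorpus", function(x, value) {
  x@annotations <- .checkAnnotations(value)
  x@herbs <- sort(union(x@herbs, value$herb_id))
  validObject(x)
  x
})

setMethod("show", "HerbCorpus", function(object) {
  n <- nPrescriptions(object)
  cat("HerbCorpus with", n, "prescription(s) over",
      length(object@herbs), "herb(s)\n")
  if (n) {
    tab <- table(factor(object@route, levels = .ROUTES))
    cat("  routes: internal =", tab[["internal"]],
        "| external =", tab[["external"]], "\n")
    sizes <- lengths(object@prescriptions)
    cat("  herbs per prescription:", min(sizes), "-", max(sizes), "\n")
  }
  cat("  annotated herbs:", nrow(object@annotations), "\n")
})

#' Edge table of a co-occurrence network
#' @param x A \code{\linkS4class{CooccurrenceNetwork}}.
#' @return \code{data.frame} with columns \code{from}, \code{to},
#'   \code{weight}.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "CooccurrenceNetwork", function(x) x@edges)

#' Connected nodes of a co-occurrence network
#' @param x A \code{\linkS4class{CooccurrenceNetwork}}.
#' @return Character vector of herb ids.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname networkNodes
#' @export
setMethod("networkNodes", "CooccurrenceNetwork", function(x) x@nodes)

#' Herbs with no co-occurrence edge
#' @param x A \code{\linkS4class{CooccurrenceNetwork}}.
#' @return Character vector of herb ids.
#' @export
setGeneric("isolatedHerbs", function(x) standardGeneric("isolatedHerbs"))

#' @rdname isolatedHerbs
#' @export
setMethod("isolatedHerbs", "CooccurrenceNetwork", function(x) x@isolated)

setMethod("show", "CooccurrenceNetwork", function(object) {
  cat("CooccurrenceNetwork:", length(object@nodes), "node(s),",
      nrow(object@edges), "edge(s),",
      length(object@isolated), "isolated herb(s)\n")
  if (nrow(object@edges))
    cat("  total edge weight:", sum(object@edges$weight), "\n")
})

#' Module assignment of a partition
#' @param x A \code{\linkS4class{ModulePartition}}.
#' @return Named integer vector (herb id -> module label).
#' @export
setGeneric("moduleAssignment", function(x) standardGeneric("moduleAssignment"))

#' @rdname moduleAssignment
#' @export
setMethod("moduleAssignment", "ModulePartition", function(x) x@assignment)

#' Modularity score of a partition
#' @param x A \code{\linkS4class{ModulePartition}}.
#' @return Numeric Q.
#' @export
setGeneric("modularityScore", function(x) standardGeneric("modularityScore"))

#' @rdname modularityScore
#' @export
setMethod("modularityScore", "ModulePartition", function(x) x@Q)

#' Module sizes of a partition
#' @param x A \code{\linkS4class{ModulePartition}}.
#' @return Named integer vector of member counts, by module label.
#' @export
setGeneric("moduleSizes", function(x) standardGeneric("moduleSizes"))

#' @rdname moduleSizes
#' @export
setMethod("moduleSizes", "ModulePartition", function(x) {
  tab <- table(x@assignment)
  setNames(as.integer(tab), names(tab))
})

setMethod("show", "ModulePartition", function(object) {
  sizes <- moduleSizes(object)
  cat("ModulePartition:", length(sizes), "module(s) over",
      length(object@assignment), "herb(s)\n")
  cat("  sizes:", paste(sizes, collapse = ", "), "\n")
  cat(sprintf("  Q = %.4f at resolution %.2f\n", object@Q, object@resolution))
})

#' Count of one itemset
#'
#' @param x An \code{\linkS4class{ItemsetCounts}} object.
#' @param items Character vector of herb ids (order irrelevant).
#' @return Integer count (0 when the itemset occurs in no transaction).
#' @export
setGeneric("itemsetCount", function(x, items) standardGeneric("itemsetCount"))

#' @rdname itemsetCount
#' @export
setMethod("itemsetCount", "ItemsetCounts", function(x, items) {
  cnt <- x@counts[.itemKey(items)]
  if (is.na(cnt)) 0L else unname(cnt)
})

#' All counted itemsets as a data.frame
#' @param x An \code{\linkS4class{ItemsetCounts}} object.
#' @return \code{data.frame} with columns \code{itemset} (members joined
#'   by \code{" + "}), \code{size}, \code{count}.
#' @export
setGeneric("itemsetTable", function(x) standardGeneric("itemsetTable"))

#' @rdname itemsetTable
#' @export
setMethod("itemsetTable", "ItemsetCounts", function(x) {
  items <- .keyItems(names(x@counts))
  data.frame(itemset = vapply(items, .itemLabel, ""),
             size = x@sizes, count = unname(x@counts),
             stringsAsFactors = FALSE)
})

setMethod("show", "ItemsetCounts", function(object) {
  cat("ItemsetCounts over", object@nTransactions, "transaction(s)\n")
  for (k in seq_len(object@maxLen))
    cat("  size", k, ":", sum(object@sizes == k), "itemset(s)\n")
})

#' Result table of a meridian enrichment test
#' @param x A \code{\linkS4class{MeridianEnrichment}} object.
#' @return \code{data.frame}, one row per (module, meridian).
#' @export
setGeneric("enrichmentTable", function(x) standardGeneric("enrichmentTable"))

#' @rdname enrichmentTable
#' @export
setMethod("enrichmentTable", "MeridianEnrichment", function(x) x@table)

setMethod("show", "MeridianEnrichment", function(object) {
  tab <- object@table
  cat("MeridianEnrichment:", length(unique(tab$module)), "module(s) x",
      length(unique(tab$meridian)), "meridian(s),",
      object@nPerm, "permutation(s), alpha =", object@alpha, "\n")
  sig <- tab[tab$direction != "none", , drop = FALSE]
  if (nrow(sig)) {
    cat("  significant calls:\n")
    for (i in seq_len(nrow(sig)))
      cat(sprintf("    module %s %s: %s (ratio %.3f, q = %.4g)\n",
                  sig$module[i], sig$meridian[i], sig$direction[i],
                  sig$observed_ratio[i],
                  ifelse(sig$direction[i] == "high",
                         sig$q_high[i], sig$q_low[i])))
  } else cat("  significant calls: none\n")
})

#' Planted module labels of a synthetic corpus
#' @param x A \code{\linkS4class{GroundTruth}} object.
#' @return Named integer vector.
#' @export
setGeneric("plantedModules", function(x) standardGeneric("plantedModules"))

#' @rdname plantedModules
#' @export
setMethod("plantedModules", "GroundTruth", function(x) x@moduleLabels)

#' Planted meridian sets of a synthetic corpus
#' @param x A \code{\linkS4class{GroundTruth}} object.
#' @return Named list of character vectors.
#' @export
setGeneric("plantedMeridians", function(x) standardGeneric("plantedMeridians"))

#' @rdname plantedMeridians
#' @export
setMethod("plantedMeridians", "GroundTruth", function(x) x@meridians)
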