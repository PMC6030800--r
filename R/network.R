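#' Build the weighted herb co-occurrence network
#'
#' Two herbs are linked if at least one prescription contains both; the
#' edge weight is the number of prescriptions containing both (dose and
#' within-prescription repetition are never considered). Herbs that
#' appear only in single-herb prescriptions, or never co-occur, have no
#' edge and are reported as isolated.
#'
#' @param corpus A non-empty \code{\linkS4class{HerbCorpus}}.
#' @return A \code{\linkS4class{CooccurrenceNetwork}}.
#' @examples
#' corp <- herbCorpus(list(p1 = c("A","B"), p2 = c("A","B"), p3 = c("A","C")))
#' edgeTable(buildCooccurrenceNetwork(corp))
#' @export
buildCooccurrenceNetwork <- function(corpus) {
  stopifnot(is(corpus, "HerbCorpus"))
  if (nPrescriptions(corpus) == 0L) stop("corpus is empty", call. = FALSE)
  M <- .incidenceMatrix(corpus)
  herbs <- colnames(M)
  P <- Matrix::crossprod(M * 1)           # herb x herb joint counts
  trip <- Matrix::summary(methods::as(P, "TsparseMatrix"))
  up <- trip[trip$i < trip$j & trip$x > 0, , drop = FALSE]
  edges <- data.frame(from = herbs[up$i], to = herbs[up$j],
                      weight = as.integer(up$x), stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  connected <- unique(c(edges$from, edges$to))
  new("CooccurrenceNetwork",
      nodes = sort(connected),
      edges = edges,
      isolated = sort(setdiff(herbs, connected)))
}

# Modularity from raw edge vectors: labels indexed by node position.
# selfw[i] holds twice the node's internal (self-loop) weight.
.modularityFromEdges <- function(ei, ej, w, labels, gamma, m,
                                 selfw = NULL) {
  n <- length(labels)
  if (is.null(selfw)) selfw <- numeric(n)
  k <- selfw
  kw <- rowsum(c(w, w), c(ei, ej))
  k[as.integer(rownames(kw))] <- k[as.integer(rownames(kw))] + kw[, 1]
  sin <- rowsum(c(2 * w * (labels[ei] == labels[ej]), selfw),
                c(labels[ei], labels))
  tot <- rowsum(k, labels)
  cc <- sort(unique(labels))
  sinFull <- setNames(numeric(length(cc)), cc)
  sinFull[rownames(sin)] <- sin[, 1]
  sum(sinFull / (2 * m) - gamma * (tot[, 1] / (2 * m))^2)
}

#' Modularity of a module assignment
#'
#' Computes
#' \deqn{Q = \frac{1}{2m} \sum_{ij} \left[A_{ij} -
#'   \gamma \frac{k_i k_j}{2m}\right] \delta(c_i, c_j)}
#' over the weighted adjacency \eqn{A}, with \eqn{k} the weighted
#' degrees, \eqn{m} the total edge weight and \eqn{\gamma} the
#' resolution.
#'
#' @param network A \code{\linkS4class{CooccurrenceNetwork}} with at
#'   least one edge.
#' @param assignment Named integer vector covering every non-isolated
#'   node, or a \code{\linkS4class{ModulePartition}}.
#' @param resolution Resolution \eqn{\gamma} (default 1).
#' @return Numeric Q.
#' @examples
#' corp <- herbCorpus(list(p1 = c("A","B"), p2 = c("C","D")))
#' net <- buildCooccurrenceNetwork(corp)
#' networkModularity(net, c(A = 1, B = 1, C = 2, D = 2))  # 0.5
#' @export
networkModularity <- function(network, assignment, resolution = 1) {
  stopifnot(is(network, "CooccurrenceNetwork"))
  if (is(assignment, "ModulePartition"))
    assignment <- moduleAssignment(assignment)
  e <- edgeTable(network)
  if (nrow(e) == 0L)
    stop("modularity undefined: network has no edges", call. = FALSE)
  nodes <- networkNodes(network)
  if (!all(nodes %in% names(assignment)))
    stop("assignment must cover every non-isolated node", call. = FALSE)
  labels <- as.integer(assignment[nodes])
  ei <- match(e$from, nodes)
  ej <- match(e$to, nodes)
  .modularityFromEdges(ei, ej, e$weight, labels, resolution,
                       m = sum(e$weight))
}

# One Louvain level: greedy local moving on the current (aggregated)
# graph. Returns the community vector and whether any node moved.
.louvainLevel <- function(n, ei, ej, w, selfw, m, gamma,
                          maxPass = 50L) {
  nb <- vector("list", n)
  nbw <- vector("list", n)
  for (idx in seq_along(ei)) {
    a <- ei[idx]; b <- ej[idx]
    nb[[a]] <- c(nb[[a]], b); nbw[[a]] <- c(nbw[[a]], w[idx])
    nb[[b]] <- c(nb[[b]], a); nbw[[b]] <- c(nbw[[b]], w[idx])
  }
  k <- selfw + vapply(seq_len(n), function(i) sum(nbw[[i]]), 0)
  comm <- seq_len(n)
  tot <- k
  movedAny <- FALSE
  for (pass in seq_len(maxPass)) {
    moves <- 0L
    for (i in sample.int(n)) {
      ci <- comm[i]
      tot[ci] <- tot[ci] - k[i]
      if (length(nb[[i]])) {
        lc <- rowsum(nbw[[i]], comm[nb[[i]]])
        cand <- as.integer(rownames(lc))
        link <- lc[, 1]
      } else {
        cand <- integer(0); link <- numeric(0)
      }
      if (!ci %in% cand) { cand <- c(cand, ci); link <- c(link, 0) }
      gain <- link / m - gamma * k[i] * tot[cand] / (2 * m * m)
      best <- gain >= max(gain) - 1e-12
      target <- min(cand[best])      # equal gain: smaller community id
      tot[target] <- tot[target] + k[i]
      if (target != ci) { comm[i] <- target; moves <- moves + 1L }
    }
    if (moves == 0L) break
    movedAny <- TRUE
  }
  list(comm = comm, moved = movedAny)
}

#' Louvain module detection on the co-occurrence network
#'
#' Standard two-phase Louvain modularity maximisation: greedy local
#' moving of nodes to the neighbouring community with the largest
#' modularity gain (equal gains resolved in favour of the smaller
#' community id), followed by aggregation of communities into
#' super-nodes, repeated until no move improves Q. Edge weights are
#' used throughout; the node sweep order is shuffled from \code{seed},
#' making runs reproducible. Isolated herbs are excluded before
#' optimisation.
#'
#' @param network A \code{\linkS4class{CooccurrenceNetwork}} with at
#'   least one edge.
#' @param resolution Resolution \eqn{\gamma} scaling the null term
#'   (default 1).
#' @param seed Integer seed for the sweep order.
#' @return A \code{\linkS4class{ModulePartition}} with canonical labels
#'   (see \code{\link{canonicalizeLabels}}) and the achieved Q.
#' @export
louvainPartition <- function(network, resolution = 1, seed = 1L) {
  stopifnot(is(network, "CooccurrenceNetwork"))
  e <- edgeTable(network)
  if (nrow(e) == 0L)
    stop("modularity undefined: network has no edges", call. = FALSE)
  nodes <- networkNodes(network)
  n <- length(nodes)
  m <- sum(e$weight)
  assign0 <- withr::with_seed(as.integer(seed), {
    cur <- seq_len(n)                     # original node -> current node
    ei <- match(e$from, nodes); ej <- match(e$to, nodes)
    w <- as.numeric(e$weight)
    selfw <- numeric(n)
    nCur <- n
    repeat {
      lev <- .louvainLevel(nCur, ei, ej, w, selfw, m, resolution)
      if (!lev$moved) break
      # newId[i]: canonical community id of current node i
      newId <- match(lev$comm, sort(unique(lev$comm)))
      cur <- newId[cur]
      # aggregate graph
      nNew <- max(newId)
      ci <- newId[ei]; cj <- newId[ej]
      selfNew <- numeric(nNew)
      sAgg <- rowsum(selfw, newId)
      selfNew[as.integer(rownames(sAgg))] <- sAgg[, 1]
      internal <- ci == cj
      if (any(internal)) {
        iAgg <- rowsum(2 * w[internal], ci[internal])
        selfNew[as.integer(rownames(iAgg))] <-
          selfNew[as.integer(rownames(iAgg))] + iAgg[, 1]
      }
      if (any(!internal)) {
        a <- pmin(ci[!internal], cj[!internal])
        b <- pmax(ci[!internal], cj[!internal])
        key <- paste(a, b)
        wAgg <- rowsum(w[!internal], key)
        parts <- strsplit(rownames(wAgg), " ", fixed = TRUE)
        ei <- vapply(parts, function(p) as.integer(p[1]), 0L)
        ej <- vapply(parts, function(p) as.integer(p[2]), 0L)
        w <- wAgg[, 1]
      } else {
        ei <- integer(0); ej <- integer(0); w <- numeric(0)
      }
      selfw <- selfNew
      nCur <- nNew
      if (nCur == 1L) break
    }
    cur
  })
  assignment <- setNames(as.integer(match(assign0, sort(unique(assign0)))),
                         nodes)
  Q <- networkModularity(network, assignment, resolution)
  canonicalizeLabels(new("ModulePartition", assignment = assignment,
                         Q = Q, resolution = resolution,
                         seed = as.integer(seed)))
}

#' Canonical module labels
#'
#' Renumbers module labels 1..k by descending member count; equal-size
#' modules are ordered by their lexicographically smallest member herb
#' id. Assignment content is unchanged and the operation is idempotent.
#'
#' @param partition A \code{\linkS4class{ModulePartition}}.
#' @return A \code{\linkS4class{ModulePartition}} with canonical labels.
#' @export
canonicalizeLabels <- function(partition) {
  stopifnot(is(partition, "ModulePartition"))
  a <- partition@assignment
  labs <- sort(unique(a))
  size <- vapply(labs, function(l) sum(a == l), 0L)
  minMember <- vapply(labs, function(l) min(names(a)[a == l]), "")
  ord <- labs[order(-size, minMember)]
  newA <- setNames(as.integer(match(a, ord)), names(a))
  methods::initialize(partition, assignment = newA)
}

#' Convert to an igraph graph
#'
#' Builds an \pkg{igraph} graph from the network, with edge attribute
#' \code{weight} and node attributes \code{module} (0 when
#' unassigned/isolated), \code{meridians} (codes joined by \code{"|"})
#' and \code{category} where a partition/annotations are supplied.
#' Isolated herbs are included as degree-zero vertices.
#'
#' @param network A \code{\linkS4class{CooccurrenceNetwork}}.
#' @param partition Optional \code{\linkS4class{ModulePartition}}.
#' @param annotations Optional annotation \code{data.frame}.
#' @return An \pkg{igraph} graph.
#' @export
toIgraph <- function(network, partition = NULL, annotations = NULL) {
  stopifnot(is(network, "CooccurrenceNetwork"))
  allNodes <- c(networkNodes(network), isolatedHerbs(network))
  v <- data.frame(name = allNodes, stringsAsFactors = FALSE)
  if (!is.null(partition)) {
    a <- moduleAssignment(partition)
    v$module <- ifelse(allNodes %in% names(a),
                       unname(a[allNodes]), 0L)
  }
  if (!is.null(annotations) && nrow(annotations)) {
    ann <- .checkAnnotations(annotations)
    idx <- match(allNodes, ann$herb_id)
    mm <- .meridianMatrix(ann)
    v$meridians <- vapply(idx, function(i) {
      if (is.na(i)) "" else paste(MERIDIANS[mm[i, ]], collapse = "|")
    }, "")
    v$category <- ifelse(is.na(idx), NA_integer_, ann$category[idx])
  }
  igraph::graph_from_data_frame(edgeTable(network), directed = FALSE,
                                vertices = v)
}

#' Export the network as GraphML
#'
#' @inheritParams toIgraph
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
exportGraphML <- function(network, path, partition = NULL,
                          annotations = NULL) {
  g <- toIgraph(network, partition, annotations)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Export the network as GEXF
#'
#' Writes a static GEXF 1.2 file with the edge \code{weight} and the
#' node attributes described in \code{\link{toIgraph}} — loadable by
#' standard graph viewers.
#'
#' @inheritParams exportGraphML
#' @return \code{path}, invisibly.
#' @export
exportGEXF <- function(network, path, partition = NULL,
                       annotations = NULL) {
  stopifnot(is(network, "CooccurrenceNetwork"))
  allNodes <- c(networkNodes(network), isolatedHerbs(network))
  a <- if (is.null(partition)) NULL else moduleAssignment(partition)
  ann <- if (is.null(annotations) || !nrow(annotations)) NULL
         else .checkAnnotations(annotations)
  mm <- if (is.null(ann)) NULL else .meridianMatrix(ann)

  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<gexf xmlns=\"http://www.gexf.net/1.2draft\" version=\"1.2\">",
    "  <graph mode=\"static\" defaultedgetype=\"undirected\">",
    "    <attributes class=\"node\">",
    "      <attribute id=\"0\" title=\"module\" type=\"integer\"/>",
    "      <attribute id=\"1\" title=\"meridians\" type=\"string\"/>",
    "      <attribute id=\"2\" title=\"category\" type=\"integer\"/>",
    "    </attributes>",
    "    <nodes>")
  for (nd in allNodes) {
    mod <- if (!is.null(a) && nd %in% names(a)) a[[nd]] else 0L
    mer <- ""; cate <- ""
    if (!is.null(ann)) {
      i <- match(nd, ann$herb_id)
      if (!is.na(i)) {
        mer <- paste(MERIDIANS[mm[i, ]], collapse = "|")
        cate <- ann$category[i]
      }
    }
    lines <- c(lines, sprintf(
      paste0("      <node id=\"%s\" label=\"%s\">",
             "<attvalues>",
             "<attvalue for=\"0\" value=\"%s\"/>",
             "<attvalue for=\"1\" value=\"%s\"/>",
             "<attvalue for=\"2\" value=\"%s\"/>",
             "</attvalues></node>"),
      .xmlEscape(nd), .xmlEscape(nd), mod, .xmlEscape(mer), cate))
  }
  e <- edgeTable(network)
  lines <- c(lines, "    </nodes>", "    <edges>")
  if (nrow(e))
    lines <- c(lines, sprintf(
      "      <edge id=\"%d\" source=\"%s\" target=\"%s\" weight=\"%d\"/>",
      seq_len(nrow(e)), .xmlEscape(e$from), .xmlEscape(e$to), e$weight))
  lines <- c(lines, "    </edges>", "  </graph>", "</gexf>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
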