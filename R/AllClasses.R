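#' HerbCorpus: a set of herb prescriptions with annotations
#'
#' Container for a prescription corpus. Each prescription is a set of
#' herb identifiers (duplicates collapse; dose is never represented),
#' carries an administration route (\code{"internal"} or
#' \code{"external"}), and the corpus optionally carries a herb
#' annotation table (Latin name, pharmacological category 1-20, and
#' presence flags for the twelve organ meridians, see
#' \code{\link{MERIDIANS}}).
#'
#' @slot prescriptions Named list of character vectors; element names are
#'   prescription identifiers, values are the herb sets.
#' @slot route Named character vector parallel to \code{prescriptions},
#'   values \code{"internal"} or \code{"external"}.
#' @slot annotations \code{data.frame} with columns \code{herb_id},
#'   \code{latin_name}, \code{category} and one logical column per
#'   meridian code.
#' @slot herbs Character vector: the herb universe (union of herbs
#'   appearing in prescriptions and annotated herbs).
#'
#' @seealso \code{\link{readTransactions}}, \code{\link{filterByRoute}},
#'   \code{\link{generateCorpus}}, \code{\link{buildFixtureCorpus}}
#' @export
setClass("HerbCorpus",
  representation(prescriptions = "list",
                 route = "character",
                 annotations = "data.frame",
                 herbs = "character"),
  prototype(prescriptions = list(), route = character(0),
            herbs = character(0)))

setValidity("HerbCorpus", function(object) {
  p <- object@prescriptions
  msgs <- character(0)
  if (length(p)) {
    if (is.null(names(p)) || anyDuplicated(names(p)))
      msgs <- c(msgs, "prescriptions must be uniquely named")
    if (any(lengths(p) == 0L))
      msgs <- c(msgs, "every prescription must contain at least one herb")
    if (any(vapply(p, anyDuplicated, 0L) > 0L))
      msgs <- c(msgs, "duplicate herb within a prescription")
  }
  if (length(object@route) != length(p))
    msgs <- c(msgs, "route must be parallel to prescriptions")
  if (length(object@route) && !all(object@route %in% .ROUTES))
    msgs <- c(msgs, "route values must be 'internal' or 'external'")
  used <- unique(unlist(p, use.names = FALSE))
  if (!all(used %in% object@herbs))
    msgs <- c(msgs, "herb universe must contain every herb used")
  if (length(msgs)) msgs else TRUE
})

#' CountSpec: exact occurrence counts a fixture corpus must realise
#'
#' Encodes marginal herb occurrence counts and joint co-occurrence
#' counts (for herb pairs and triples) that
#' \code{\link{buildFixtureCorpus}} turns into a concrete corpus.
#' Used to reconstruct corpora whose mining statistics match published
#' frequency tables exactly.
#'
#' @slot N Integer: total number of transactions.
#' @slot marginals Named integer vector: required occurrence count per
#'   herb.
#' @slot joints List of character vectors (each of size 2 or 3): the
#'   itemsets with constrained joint counts.
#' @slot jointCounts Integer vector parallel to \code{joints}.
#'
#' @seealso \code{\link{countSpec}}, \code{\link{buildFixtureCorpus}}
#' @export
setClass("CountSpec",
  representation(N = "integer", marginals = "integer",
                 joints = "list", jointCounts = "integer"))

setValidity("CountSpec", function(object) {
  msgs <- character(0)
  if (length(object@N) != 1L || is.na(object@N) || object@N < 1L)
    msgs <- c(msgs, "N must be a single positive integer")
  if (any(object@marginals < 0L, na.rm = TRUE) ||
      any(object@jointCounts < 0L, na.rm = TRUE))
    msgs <- c(msgs, "counts must be non-negative")
  if (length(object@marginals) && any(object@marginals > object@N))
    msgs <- c(msgs, "marginal counts cannot exceed N")
  if (length(object@joints) != length(object@jointCounts))
    msgs <- c(msgs, "joints and jointCounts must be parallel")
  sizes <- lengths(object@joints)
  if (length(sizes) && (any(sizes < 2L) || any(sizes > 3L)))
    msgs <- c(msgs, "joint itemsets must have size 2 or 3")
  if (length(msgs)) msgs else TRUE
})

#' SyntheticConfig: parameters of the planted-structure corpus generator
#'
#' Describes a generative model for prescription corpora: herbs are
#' partitioned into modules; each prescription picks a home module
#' (probability proportional to module size), draws its size uniformly
#' from a range, and draws each member herb from the home module with
#' probability \code{pWithin}, otherwise uniformly from the whole herb
#' universe. Meridian flags are Bernoulli draws, with per-module
#' enrichment overriding a baseline probability.
#'
#' @slot nHerbs,nPrescriptions,nModules Integers.
#' @slot moduleSizes Integer vector summing to \code{nHerbs}.
#' @slot herbsPerPrescription Integer vector \code{c(min, max)}.
#' @slot pWithin Probability of drawing a herb from the home module.
#' @slot pBetween Probability of the uniform-mixing path
#'   (\code{1 - pWithin}).
#' @slot meridianEnrichment Named list: one element per enriched module
#'   (name = module index), each a named numeric vector of per-meridian
#'   flag probabilities.
#' @slot baselineMeridianProb Flag probability for unenriched
#'   (module, meridian) combinations.
#' @slot seed Integer RNG seed; fully determines the generated corpus.
#'
#' @seealso \code{\link{syntheticConfig}}, \code{\link{generateCorpus}}
#' @export
setClass("SyntheticConfig",
  representation(nHerbs = "integer", nPrescriptions = "integer",
                 nModules = "integer", moduleSizes = "integer",
                 herbsPerPrescription = "integer",
                 pWithin = "numeric", pBetween = "numeric",
                 meridianEnrichment = "list",
                 baselineMeridianProb = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msgs <- character(0)
  if (object@nHerbs < 1L || object@nPrescriptions < 1L || object@nModules < 1L)
    msgs <- c(msgs, "nHerbs, nPrescriptions and nModules must be positive")
  if (length(object@moduleSizes) != object@nModules)
    msgs <- c(msgs, "moduleSizes must have one entry per module")
  if (any(object@moduleSizes < 1L))
    msgs <- c(msgs, "module sizes must be positive")
  if (sum(object@moduleSizes) != object@nHerbs)
    msgs <- c(msgs, "moduleSizes must sum to nHerbs")
  hp <- object@herbsPerPrescription
  if (length(hp) != 2L || hp[1] < 1L || hp[2] < hp[1] || hp[2] > object@nHerbs)
    msgs <- c(msgs, "herbsPerPrescription must be c(min, max) with 1 <= min <= max <= nHerbs")
  probs <- c(object@pWithin, object@pBetween, object@baselineMeridianProb,
             unlist(object@meridianEnrichment, use.names = FALSE))
  if (any(probs < 0 | probs > 1, na.rm = TRUE))
    msgs <- c(msgs, "all probabilities must lie in [0, 1]")
  if (abs(object@pWithin + object@pBetween - 1) > 1e-12)
    msgs <- c(msgs, "pWithin + pBetween must equal 1")
  en <- object@meridianEnrichment
  if (length(en)) {
    mod <- suppressWarnings(as.integer(names(en)))
    if (any(is.na(mod)) || any(mod < 1L) || any(mod > object@nModules))
      msgs <- c(msgs, "meridianEnrichment names must be module indices")
    mer <- unlist(lapply(en, names), use.names = FALSE)
    if (!all(mer %in% MERIDIANS))
      msgs <- c(msgs, "meridianEnrichment meridians must be canonical codes")
  }
  if (length(object@seed) != 1L || is.na(object@seed))
    msgs <- c(msgs, "seed must be a single integer")
  if (length(msgs)) msgs else TRUE
})

#' GroundTruth: planted structure of a synthetic corpus
#'
#' @slot moduleLabels Named integer vector: planted module per herb.
#' @slot meridians Named list: planted meridian set per herb.
#' @export
setClass("GroundTruth",
  representation(moduleLabels = "integer", meridians = "list"))

#' ItemsetCounts: exact transaction counts of herb itemsets
#'
#' Result of level-wise apriori counting: for every itemset of size up
#' to \code{maxLen} occurring in at least \code{minCount} transactions,
#' the exact number of transactions containing all of its members.
#'
#' @slot counts Named integer vector; names are canonical itemset keys.
#' @slot sizes Integer vector parallel to \code{counts}: itemset sizes.
#' @slot nTransactions Integer: corpus size N.
#' @slot maxLen,minCount Integers: counting parameters used.
#' @seealso \code{\link{countItemsets}}, \code{\link{itemsetCount}}
#' @export
setClass("ItemsetCounts",
  representation(counts = "integer", sizes = "integer",
                 nTransactions = "integer", maxLen = "integer",
                 minCount = "integer"))

#' CooccurrenceNetwork: weighted herb co-occurrence graph
#'
#' Undirected graph over the herbs of a corpus: two herbs are joined by
#' an edge if at least one prescription contains both, with weight the
#' number of prescriptions containing both (dose is never considered).
#' Herbs that never co-occur with another herb are kept in
#' \code{isolated} and carry no edges.
#'
#' @slot nodes Character vector of herb ids with at least one edge.
#' @slot edges \code{data.frame} with columns \code{from}, \code{to}
#'   (herb ids, \code{from < to} lexicographically) and integer
#'   \code{weight}.
#' @slot isolated Character vector of edge-less herbs.
#' @seealso \code{\link{buildCooccurrenceNetwork}},
#'   \code{\link{louvainPartition}}
#' @export
setClass("CooccurrenceNetwork",
  representation(nodes = "character", edges = "data.frame",
                 isolated = "character"))

setValidity("CooccurrenceNetwork", function(object) {
  msgs <- character(0)
  e <- object@edges
  if (!all(c("from", "to", "weight") %in% names(e)))
    msgs <- c(msgs, "edges must have columns from, to, weight")
  else if (nrow(e)) {
    if (any(e$weight < 1)) msgs <- c(msgs, "edge weights must be >= 1")
    if (any(e$from == e$to)) msgs <- c(msgs, "self-edges are not allowed")
    if (!all(c(e$from, e$to) %in% object@nodes))
      msgs <- c(msgs, "edge endpoints must be nodes")
  }
  if (length(intersect(object@nodes, object@isolated)))
    msgs <- c(msgs, "nodes and isolated must be disjoint")
  if (length(msgs)) msgs else TRUE
})

#' ModulePartition: a module assignment with its modularity
#'
#' @slot assignment Named integer vector: module label per
#'   (non-isolated) herb.
#' @slot Q Numeric: modularity of the assignment at \code{resolution}.
#' @slot resolution Numeric: resolution parameter gamma.
#' @slot seed Integer: RNG seed used by the optimiser (NA when the
#'   partition was supplied, not optimised).
#' @seealso \code{\link{louvainPartition}},
#'   \code{\link{canonicalizeLabels}}
#' @export
setClass("ModulePartition",
  representation(assignment = "integer", Q = "numeric",
                 resolution = "numeric", seed = "integer"))

setValidity("ModulePartition", function(object) {
  msgs <- character(0)
  if (is.null(names(object@assignment)) || anyDuplicated(names(object@assignment)))
    msgs <- c(msgs, "assignment must be uniquely named by herb id")
  if (length(object@Q) != 1L || object@Q < -1 - 1e-9 || object@Q > 1 + 1e-9)
    msgs <- c(msgs, "Q must be a single value in [-1, 1]")
  if (length(msgs)) msgs else TRUE
})

#' MeridianEnrichment: permutation-test results per (module, meridian)
#'
#' One row per (module, meridian) pair: the observed within-module
#' occurrence ratio of the meridian, the permutation-null mean, add-one
#' one-sided empirical p-values for excess (\code{p_high}) and deficit
#' (\code{p_low}), Benjamini-Hochberg q-values adjusted per module and
#' per tail, and the resulting direction call.
#'
#' @slot table \code{data.frame} with columns \code{module},
#'   \code{meridian}, \code{observed_ratio}, \code{null_mean},
#'   \code{p_high}, \code{p_low}, \code{q_high}, \code{q_low},
#'   \code{direction}.
#' @slot nPerm,seed Integers: permutation count and RNG seed.
#' @slot alpha Numeric: FDR threshold used for direction calls.
#' @seealso \code{\link{permutationTest}}
#' @export
setClass("MeridianEnrichment",
  representation(table = "data.frame", nPerm = "integer",
                 seed = "integer", alpha = "numeric"))
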