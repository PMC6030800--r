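#' Specify exact occurrence counts for a fixture corpus
#'
#' @param N Total number of transactions.
#' @param marginals Named numeric/integer vector: required occurrence
#'   count per herb (may be empty).
#' @param joints Named numeric/integer vector of joint co-occurrence
#'   counts; names are itemsets with members joined by \code{"+"}
#'   (e.g. \code{c("A+B" = 120)}), sizes 2 or 3. Alternatively a list of
#'   \code{list(items =, count =)} entries.
#' @return A \code{\linkS4class{CountSpec}}.
#' @examples
#' spec <- countSpec(312, c(Angelica = 171, Polygonum = 175),
#'                   c("Angelica+Polygonum" = 120))
#' @export
countSpec <- function(N, marginals = integer(0), joints = integer(0)) {
  if (is.list(joints)) {
    items <- lapply(joints, `[[`, "items")
    cnts <- vapply(joints, function(j) as.integer(j$count), 0L)
  } else if (length(joints)) {
    items <- strsplit(names(joints), "+", fixed = TRUE)
    cnts <- as.integer(joints)
  } else {
    items <- list(); cnts <- integer(0)
  }
  m <- as.integer(round(marginals)); names(m) <- names(marginals)
  if (any(is.na(m)) || any(is.na(cnts)))
    stop("counts must be non-missing integers", call. = FALSE)
  if (any(m < 0L) || any(cnts < 0L))
    stop("negative counts are not allowed", call. = FALSE)
  obj <- new("CountSpec", N = as.integer(N), marginals = m,
             joints = items, jointCounts = cnts)
  # feasibility versus stated marginals
  for (i in seq_along(items)) {
    have <- intersect(items[[i]], names(m))
    if (length(have) && cnts[i] > min(m[have]))
      stop("infeasible spec: joint count for {",
           paste(items[[i]], collapse = ", "),
           "} exceeds a member's marginal", call. = FALSE)
  }
  obj
}

#' Build a corpus realising exact marginal and joint counts
#'
#' Deterministically constructs a corpus of exactly \code{N}
#' transactions in which every herb named in the spec's marginals
#' occurs exactly the requested number of times and every specified
#' itemset co-occurs exactly the requested number of times. The
#' construction is greedy from the largest itemsets down: for a triple
#' constraint \code{fABC} transactions \{A,B,C\} are emitted, a
#' contained pair constraint \code{fAB} is then topped up with
#' \code{fAB - fABC} transactions \{A,B\}, marginals are topped up with
#' singletons, and the remaining transactions are padding so that the
#' corpus reaches \code{N} without perturbing any specified count.
#'
#' This makes corpora whose mining statistics (support, confidence,
#' lift) reproduce published frequency tables exactly, without access
#' to the undeposited raw prescriptions.
#'
#' @param spec A \code{\linkS4class{CountSpec}} (or arguments for
#'   \code{\link{countSpec}} via \code{...}).
#' @param fillerPolicy \code{"dummy_herb"} (default): each padding
#'   transaction is a fresh singleton dummy herb; \code{"empty_pad"}:
#'   all padding transactions share one reserved placebo herb.
#'   Either way prescriptions stay non-empty and padding never touches
#'   a specified count.
#' @param route Route label for all generated prescriptions.
#' @return A \code{\linkS4class{HerbCorpus}} with exactly \code{spec@N}
#'   prescriptions.
#' @examples
#' corp <- buildFixtureCorpus(countSpec(312,
#'   c(Angelica = 171, Polygonum = 175), c("Angelica+Polygonum" = 120)))
#' nPrescriptions(corp)
#' @export
buildFixtureCorpus <- function(spec,
                               fillerPolicy = c("dummy_herb", "empty_pad"),
                               route = "internal") {
  stopifnot(is(spec, "CountSpec"))
  fillerPolicy <- match.arg(fillerPolicy)
  validObject(spec)

  keys <- vapply(spec@joints, .itemKey, "")
  if (anyDuplicated(keys))
    stop("duplicate joint itemset in spec", call. = FALSE)
  remJoint <- setNames(spec@jointCounts, keys)
  remMarg <- spec@marginals

  sets <- list()
  emit <- function(items, times) {
    if (times > 0L)
      sets[length(sets) + seq_len(times)] <<- rep(list(sort(items)), times)
  }
  # largest itemsets first; emitting a set decrements every contained
  # specified joint and every member marginal
  ord <- order(-lengths(spec@joints))
  for (i in ord) {
    items <- spec@joints[[i]]
    t <- remJoint[[.itemKey(items)]]
    if (t < 0L)
      stop("infeasible spec: itemset {", paste(items, collapse = ", "),
           "} is over-covered by larger itemsets", call. = FALSE)
    emit(items, t)
    remJoint[[.itemKey(items)]] <- 0L
    for (j in seq_along(spec@joints)) {
      other <- spec@joints[[j]]
      if (length(other) < length(items) && all(other %in% items))
        remJoint[[.itemKey(other)]] <- remJoint[[.itemKey(other)]] - t
    }
    inMarg <- intersect(items, names(remMarg))
    remMarg[inMarg] <- remMarg[inMarg] - t
  }
  if (any(remJoint != 0L))
    stop("internal error: joint counts not realised", call. = FALSE)
  if (any(remMarg < 0L))
    stop("infeasible spec: a joint count exceeds a member's marginal",
         call. = FALSE)
  for (h in names(remMarg)) emit(h, remMarg[[h]])

  if (length(sets) > spec@N)
    stop("infeasible spec: ", length(sets),
         " transactions required but N = ", spec@N, call. = FALSE)
  nPad <- spec@N - length(sets)
  if (nPad > 0L) {
    pads <- if (fillerPolicy == "dummy_herb")
      as.list(sprintf("DUMMY_%04d", seq_len(nPad)))
    else rep(list("PLACEBO"), nPad)
    sets <- c(sets, pads)
  }
  names(sets) <- sprintf("fx%04d", seq_along(sets))
  herbCorpus(sets, route = route)
}
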