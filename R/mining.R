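#' Level-wise apriori itemset counting
#'
#' Counts, for every herb itemset of size up to \code{maxLen} that
#' occurs in at least \code{minCount} transactions, the exact number of
#' transactions containing all of its members. Counting proceeds
#' level-wise: singletons are tabulated first, then each level's
#' candidate itemsets are drawn from transactions restricted to
#' frequent items and accepted only if every (k-1)-subset was frequent
#' at the previous level (anti-monotone pruning). The result is
#' independent of transaction order.
#'
#' @param corpus A non-empty \code{\linkS4class{HerbCorpus}}.
#' @param maxLen Maximum itemset size, 1, 2 or 3.
#' @param minCount Minimum transaction count for an itemset to be kept
#'   (default 1, i.e. every occurring itemset).
#' @return An \code{\linkS4class{ItemsetCounts}} object.
#' @examples
#' corp <- herbCorpus(list(p1 = c("A", "B"), p2 = c("A", "B"), p3 = c("A", "C")))
#' cnt <- countItemsets(corp, maxLen = 2)
#' itemsetCount(cnt, c("A", "B"))  # 2
#' @export
countItemsets <- function(corpus, maxLen = 3L, minCount = 1L) {
  stopifnot(is(corpus, "HerbCorpus"))
  maxLen <- as.integer(maxLen)
  minCount <- max(1L, as.integer(minCount))
  if (length(maxLen) != 1L || is.na(maxLen) || maxLen < 1L || maxLen > 3L)
    stop("maxLen must be 1, 2 or 3", call. = FALSE)
  sets <- herbSets(corpus)
  if (length(sets) == 0L) stop("corpus is empty", call. = FALSE)

  tab1 <- table(unlist(sets, use.names = FALSE))
  counts <- setNames(as.integer(tab1), names(tab1))
  counts <- counts[counts >= minCount]
  sizes <- rep(1L, length(counts))
  freqItems <- names(counts)
  freqPrev <- names(counts)  # keys of frequent (k-1)-sets

  for (k in 2:3) {
    if (k > maxLen || length(freqPrev) == 0L) break
    combos <- unlist(lapply(sets, function(t) {
      t <- sort(t[t %in% freqItems])
      if (length(t) < k) return(NULL)
      combn(t, k, FUN = paste, collapse = .KEY_SEP)
    }), use.names = FALSE)
    if (is.null(combos) || length(combos) == 0L) break
    tabk <- table(combos)
    keys <- names(tabk)
    # anti-monotone candidate acceptance: all (k-1)-subsets frequent
    ok <- vapply(.keyItems(keys), function(it) {
      all(combn(it, k - 1L, FUN = paste, collapse = .KEY_SEP) %in% freqPrev)
    }, NA)
    cnts <- setNames(as.integer(tabk), keys)[ok]
    cnts <- cnts[cnts >= minCount]
    counts <- c(counts, cnts)
    sizes <- c(sizes, rep(k, length(cnts)))
    freqPrev <- names(cnts)
  }
  new("ItemsetCounts", counts = counts, sizes = as.integer(sizes),
      nTransactions = length(sets), maxLen = maxLen,
      minCount = minCount)
}

#' Support, confidence, lift and frequency of one rule
#'
#' For a rule X -> Y over disjoint itemsets:
#' \deqn{support = count(X \cup Y) / N}
#' \deqn{confidence = count(X \cup Y) / count(X)}
#' \deqn{lift = confidence / (count(Y) / N)}
#'
#' @param counts An \code{\linkS4class{ItemsetCounts}} covering
#'   \code{X}, \code{Y} and their union.
#' @param X,Y Character vectors of herb ids; must be disjoint.
#' @return List with elements \code{support}, \code{confidence},
#'   \code{lift}, \code{frequency}.
#' @examples
#' corp <- buildFixtureCorpus(countSpec(312,
#'   c(Angelica = 171, Polygonum = 175), c("Angelica+Polygonum" = 120)))
#' cnt <- countItemsets(corp, 2)
#' ruleMetrics(cnt, "Angelica", "Polygonum")
#' @export
ruleMetrics <- function(counts, X, Y) {
  stopifnot(is(counts, "ItemsetCounts"))
  if (length(intersect(X, Y)))
    stop("antecedent and consequent must be disjoint", call. = FALSE)
  N <- counts@nTransactions
  cX <- itemsetCount(counts, X)
  cY <- itemsetCount(counts, Y)
  cXY <- itemsetCount(counts, union(X, Y))
  if (cX == 0L)
    stop("confidence undefined: antecedent never occurs", call. = FALSE)
  if (cY == 0L)
    stop("lift undefined: consequent never occurs", call. = FALSE)
  conf <- cXY / cX
  list(support = cXY / N, confidence = conf,
       lift = conf / (cY / N), frequency = cXY)
}

#' Mine ranked two- or three-herb association rules
#'
#' For \code{ruleLen = 2}, each co-occurring unordered pair yields one
#' rule, reported in the orientation with the higher confidence (the
#' lower-count herb as antecedent; equal counts break lexicographically
#' with the smaller herb id as antecedent). For \code{ruleLen = 3},
#' each co-occurring triple yields one rule in the pair-to-singleton
#' partition with the highest confidence (the lowest-count pair as
#' antecedent; ties pick the lexicographically smallest consequent).
#' Rules below the thresholds are dropped; the ranking is support
#' descending, then confidence descending, then lexicographic itemset
#' order — stable across runs.
#'
#' @param corpus A non-empty \code{\linkS4class{HerbCorpus}}.
#' @param ruleLen Size of the herb set a rule covers: 2 or 3.
#' @param minSupport,minConfidence Thresholds in [0, 1]; rules with
#'   support/confidence strictly below are dropped. Defaults 0 keep
#'   every co-occurring combination.
#' @param counts Optional precomputed \code{\linkS4class{ItemsetCounts}}
#'   (must cover size \code{ruleLen}).
#' @return \code{data.frame} with columns \code{antecedent},
#'   \code{consequent} (herb ids joined by \code{" + "}),
#'   \code{support}, \code{confidence}, \code{lift}, \code{frequency},
#'   ranked as described, at full numeric precision.
#' @seealso \code{\link{topRules}}, \code{\link{writeRules}}
#' @export
mineRules <- function(corpus, ruleLen = 2L, minSupport = 0,
                      minConfidence = 0, counts = NULL) {
  ruleLen <- as.integer(ruleLen)
  if (length(ruleLen) != 1L || is.na(ruleLen) || !ruleLen %in% c(2L, 3L))
    stop("ruleLen must be 2 or 3", call. = FALSE)
  stopifnot(minSupport >= 0, minSupport <= 1,
            minConfidence >= 0, minConfidence <= 1)
  if (is.null(counts)) counts <- countItemsets(corpus, maxLen = ruleLen)
  stopifnot(counts@maxLen >= ruleLen)
  N <- counts@nTransactions

  keys <- names(counts@counts)[counts@sizes == ruleLen]
  rows <- lapply(.keyItems(keys), function(items) {
    if (ruleLen == 2L) {
      cA <- itemsetCount(counts, items[1])
      cB <- itemsetCount(counts, items[2])
      # lower-count antecedent maximises confidence; items are sorted so
      # the tie falls to the lexicographically smaller herb
      ante <- if (cB < cA) items[2] else items[1]
      cons <- setdiff(items, ante)
    } else {
      pairCnt <- vapply(items, function(cons)
        itemsetCount(counts, setdiff(items, cons)), 0L)
      # consequents sorted (items sorted): ties pick the smallest consequent
      cons <- items[which.min(pairCnt)]
      ante <- setdiff(items, cons)
    }
    m <- ruleMetrics(counts, ante, cons)
    data.frame(antecedent = .itemLabel(ante), consequent = cons,
               support = m$support, confidence = m$confidence,
               lift = m$lift, frequency = m$frequency,
               stringsAsFactors = FALSE)
  })
  rules <- if (length(rows)) do.call(rbind, rows) else
    data.frame(antecedent = character(0), consequent = character(0),
               support = numeric(0), confidence = numeric(0),
               lift = numeric(0), frequency = integer(0),
               stringsAsFactors = FALSE)
  rules <- rules[rules$support >= minSupport &
                   rules$confidence >= minConfidence, , drop = FALSE]
  ord <- order(-rules$support, -rules$confidence,
               rules$antecedent, rules$consequent)
  rules <- rules[ord, , drop = FALSE]
  rownames(rules) <- NULL
  rules
}

#' First k rules of a ranked rule table
#'
#' @param rules Rule \code{data.frame} from \code{\link{mineRules}}.
#' @param k Positive integer.
#' @return The first \code{k} rows (fewer if fewer exist), order
#'   preserved.
#' @export
topRules <- function(rules, k) {
  stopifnot(k >= 1)
  utils::head(rules, k)
}

#' Write a rule table as delimited text
#'
#' @param rules Rule \code{data.frame}.
#' @param path Output path.
#' @param sep Field delimiter (default tab).
#' @param digits Optional rounding for the metric columns (e.g. 3 for a
#'   publication-style table); \code{NULL} writes full precision.
#' @return \code{path}, invisibly.
#' @export
writeRules <- function(rules, path, sep = "\t", digits = NULL) {
  if (!is.null(digits))
    for (col in c("support", "confidence", "lift"))
      rules[[col]] <- round(rules[[col]], digits)
  utils::write.table(rules, path, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
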