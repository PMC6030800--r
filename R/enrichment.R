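#' Within-module occurrence ratio of a meridian
#'
#' The fraction of a module's herbs whose meridian set contains the
#' given meridian. Every herb counts once, regardless of how many
#' prescriptions use it; herbs with an empty meridian set stay in the
#' denominator.
#'
#' @param assignment Named integer vector (herb -> module label) or a
#'   \code{\linkS4class{ModulePartition}}.
#' @param annotations Annotation \code{data.frame} covering the
#'   assigned herbs.
#' @param module Module label.
#' @param meridian One of \code{\link{MERIDIANS}}.
#' @return Fraction in [0, 1].
#' @export
meridianRatio <- function(assignment, annotations, module, meridian) {
  if (is(assignment, "ModulePartition"))
    assignment <- moduleAssignment(assignment)
  stopifnot(meridian %in% MERIDIANS)
  ann <- .checkAnnotations(annotations)
  members <- names(assignment)[assignment == module]
  if (length(members) == 0L)
    stop("module '", module, "' is empty", call. = FALSE)
  missing <- setdiff(members, ann$herb_id)
  if (length(missing))
    stop("herbs lacking annotations: ", paste(missing, collapse = ", "),
         call. = FALSE)
  flags <- ann[[meridian]][match(members, ann$herb_id)]
  mean(flags)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: p-values are sorted ascending, the i-th becomes
#' \eqn{\min_{j \ge i} m p_{(j)} / j} capped at 1, and results are
#' mapped back to input order. Delegates to
#' \code{stats::p.adjust(method = "BH")} after validating that every
#' input lies in (0, 1] (the add-one permutation estimator can never
#' produce 0).
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same order as the input.
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
fdrAdjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Module-label permutation test for meridian enrichment
#'
#' For every (module, meridian) pair, compares the observed
#' within-module occurrence ratio with a null distribution obtained by
#' randomly permuting module labels across herbs (module sizes are
#' preserved; each herb's meridian set rides with the herb),
#' \code{nPerm} times. One-sided add-one empirical p-values are
#' computed for both tails,
#' \deqn{p_{high} = \frac{1 + \#\{r^* \ge r_{obs}\}}{1 + n_{perm}},
#'   \qquad p_{low} = \frac{1 + \#\{r^* \le r_{obs}\}}{1 + n_{perm}},}
#' and each module's 12 meridian tests are FDR-adjusted per tail
#' (Benjamini-Hochberg). A pair is called \code{"high"} if
#' \code{q_high < alpha}, else \code{"low"} if \code{q_low < alpha},
#' else \code{"none"}. Results are deterministic given \code{seed}.
#'
#' An optional \code{weights} vector (e.g. per-herb prescription
#' frequencies) switches the ratio to a weighted form
#' \eqn{\sum w_i f_i / \sum w_i} over the module's herbs; the default
#' counts each herb once.
#'
#' @param assignment Named integer vector (herb -> module label) or a
#'   \code{\linkS4class{ModulePartition}}.
#' @param annotations Annotation \code{data.frame}; must cover every
#'   assigned herb.
#' @param nPerm Number of permutations (default 10000).
#' @param seed Integer RNG seed.
#' @param alpha FDR threshold for direction calls (default 0.05).
#' @param weights Optional named non-negative numeric vector per herb.
#' @return A \code{\linkS4class{MeridianEnrichment}} object.
#' @export
permutationTest <- function(assignment, annotations, nPerm = 10000L,
                            seed = 1L, alpha = 0.05, weights = NULL) {
  if (is(assignment, "ModulePartition"))
    assignment <- moduleAssignment(assignment)
  nPerm <- as.integer(nPerm)
  stopifnot(nPerm >= 1L, alpha > 0, alpha < 1)
  ann <- .checkAnnotations(annotations)
  herbs <- names(assignment)
  missing <- setdiff(herbs, ann$herb_id)
  if (length(missing))
    stop("herbs present in assignment but absent from annotations: ",
         paste(missing, collapse = ", "), call. = FALSE)
  flags <- .meridianMatrix(ann)[herbs, , drop = FALSE]
  storage.mode(flags) <- "double"
  if (!is.null(weights)) {
    stopifnot(all(herbs %in% names(weights)), all(weights >= 0))
    wts <- as.numeric(weights[herbs])
    flags <- flags * wts
    base <- wts
  } else {
    base <- rep(1, length(herbs))
  }
  labels <- as.integer(assignment)
  mods <- sort(unique(labels))
  labFac <- factor(labels, levels = mods)

  weighted <- !is.null(weights)
  denom <- rowsum(base, labFac)[, 1]
  obs <- rowsum(flags, labFac) / denom

  nMod <- length(mods)
  geq <- matrix(0L, nMod, ncol(flags))
  leq <- matrix(0L, nMod, ncol(flags))
  rsum <- matrix(0, nMod, ncol(flags))
  n <- length(labels)
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(nPerm)) {
      perm <- sample.int(n)
      permFac <- labFac[perm]
      # module sizes are preserved; with herb weights the permuted
      # module's weight total changes, so recompute the denominator
      d <- if (weighted) rowsum(base, permFac)[, 1] else denom
      r <- rowsum(flags, permFac) / d
      geq <- geq + (r >= obs - 1e-12)
      leq <- leq + (r <= obs + 1e-12)
      rsum <- rsum + r
    }
  })
  nullMean <- rsum / nPerm
  pHigh <- (1 + geq) / (1 + nPerm)
  pLow <- (1 + leq) / (1 + nPerm)

  tab <- data.frame(
    module = rep(mods, times = ncol(flags)),
    meridian = rep(colnames(flags), each = nMod),
    observed_ratio = as.vector(obs),
    null_mean = as.vector(nullMean),
    p_high = as.vector(pHigh),
    p_low = as.vector(pLow),
    stringsAsFactors = FALSE)
  tab$q_high <- NA_real_
  tab$q_low <- NA_real_
  for (mod in mods) {
    rows <- tab$module == mod
    tab$q_high[rows] <- fdrAdjust(tab$p_high[rows])
    tab$q_low[rows] <- fdrAdjust(tab$p_low[rows])
  }
  tab$direction <- ifelse(tab$q_high < alpha, "high",
                          ifelse(tab$q_low < alpha, "low", "none"))
  tab <- tab[order(tab$module, match(tab$meridian, MERIDIANS)), ,
             drop = FALSE]
  rownames(tab) <- NULL
  new("MeridianEnrichment", table = tab, nPerm = nPerm,
      seed = as.integer(seed), alpha = alpha)
}

#' Write an enrichment table as delimited text
#'
#' @param enrichment A \code{\linkS4class{MeridianEnrichment}}.
#' @param path Output path.
#' @param sep Field delimiter (default tab).
#' @return \code{path}, invisibly.
#' @export
writeEnrichment <- function(enrichment, path, sep = "\t") {
  stopifnot(is(enrichment, "MeridianEnrichment"))
  utils::write.table(enrichmentTable(enrichment), path, sep = sep,
                     quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
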