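#' Configure the planted-structure corpus generator
#'
#' Defaults mirror a corpus of 312 internal prescriptions over 258
#' herbs organised in three co-prescription modules, with module 1
#' enriched for the Liver/Kidney meridians and module 3 for the
#' Stomach/Spleen meridians — the structure the downstream network and
#' enrichment stages are designed to detect.
#'
#' @param nHerbs Number of herbs in the universe.
#' @param nPrescriptions Number of prescriptions (transactions).
#' @param nModules Number of planted modules.
#' @param moduleSizes Integer vector summing to \code{nHerbs}; default
#'   splits proportionally to 58/86/114.
#' @param herbsPerPrescription \code{c(min, max)} herbs per
#'   prescription, drawn uniformly.
#' @param pWithin Probability each herb of a prescription is drawn from
#'   the prescription's home module (the complement \code{pBetween}
#'   draws uniformly from all herbs).
#' @param meridianEnrichment Named list: per-module named vectors of
#'   elevated meridian-flag probabilities (names are module indices).
#' @param baselineMeridianProb Flag probability for unenriched
#'   (module, meridian) pairs.
#' @param seed Integer seed; same config + seed gives a byte-identical
#'   corpus.
#' @return A \code{\linkS4class{SyntheticConfig}}.
#' @export
syntheticConfig <- function(nHerbs = 258L, nPrescriptions = 312L,
                            nModules = 3L, moduleSizes = NULL,
                            herbsPerPrescription = c(4L, 12L),
                            pWithin = 0.7,
                            meridianEnrichment = list(
                              "1" = c(LR = 0.8, KI = 0.7),
                              "3" = c(ST = 0.7, SP = 0.6)),
                            baselineMeridianProb = 0.25,
                            seed = 1L) {
  if (is.null(moduleSizes)) {
    base <- c(58, 86, 114) / 258
    if (nModules == 3L) {
      moduleSizes <- floor(base * nHerbs)
    } else {
      moduleSizes <- rep(nHerbs %/% nModules, nModules)
    }
    moduleSizes[nModules] <- nHerbs - sum(moduleSizes[-nModules])
  }
  en <- if (is.null(meridianEnrichment)) list() else meridianEnrichment
  en <- en[as.integer(names(en)) <= nModules]
  new("SyntheticConfig",
      nHerbs = as.integer(nHerbs),
      nPrescriptions = as.integer(nPrescriptions),
      nModules = as.integer(nModules),
      moduleSizes = as.integer(moduleSizes),
      herbsPerPrescription = as.integer(herbsPerPrescription),
      pWithin = pWithin, pBetween = 1 - pWithin,
      meridianEnrichment = en,
      baselineMeridianProb = baselineMeridianProb,
      seed = as.integer(seed))
}

#' Generate a corpus with planted modules and meridian enrichment
#'
#' Each prescription picks a home module with probability proportional
#' to module size, draws its size uniformly from the configured range,
#' and fills its herb set one draw at a time: with probability
#' \code{pWithin} a uniform herb of the home module, otherwise a
#' uniform herb of the whole universe; draws repeat until the set holds
#' the target number of distinct herbs. Meridian flags are independent
#' Bernoulli draws per (herb, meridian) with the enriched probability
#' for the herb's module where configured, the baseline otherwise.
#' Everything is determined by \code{config@seed}.
#'
#' @param config A \code{\linkS4class{SyntheticConfig}}.
#' @return List with elements \code{corpus}
#'   (\code{\linkS4class{HerbCorpus}}, annotations attached) and
#'   \code{truth} (\code{\linkS4class{GroundTruth}}).
#' @examples
#' sim <- generateCorpus(syntheticConfig(nHerbs = 30, nPrescriptions = 40,
#'   nModules = 2, moduleSizes = c(15, 15), seed = 7))
#' nPrescriptions(sim$corpus)
#' @export
generateCorpus <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  withr::with_seed(config@seed, .generateCorpusImpl(config))
}

.generateCorpusImpl <- function(config) {
  nH <- config@nHerbs
  herbs <- sprintf("herb%03d", seq_len(nH))
  labels <- rep.int(seq_len(config@nModules), config@moduleSizes)
  names(labels) <- herbs
  byModule <- split(herbs, labels)

  lo <- config@herbsPerPrescription[1]
  hi <- config@herbsPerPrescription[2]
  sets <- vector("list", config@nPrescriptions)
  homes <- sample.int(config@nModules, config@nPrescriptions,
                      replace = TRUE,
                      prob = config@moduleSizes / nH)
  sizes <- lo + floor(stats::runif(config@nPrescriptions) * (hi - lo + 1L))
  for (i in seq_len(config@nPrescriptions)) {
    pool <- byModule[[homes[i]]]
    drawn <- character(0)
    while (length(drawn) < sizes[i]) {
      h <- if (stats::runif(1) < config@pWithin)
        pool[sample.int(length(pool), 1L)]
      else herbs[sample.int(nH, 1L)]
      if (!h %in% drawn) drawn <- c(drawn, h)
    }
    sets[[i]] <- drawn
  }
  names(sets) <- sprintf("rx%04d", seq_len(config@nPrescriptions))

  flagProb <- matrix(config@baselineMeridianProb, nrow = nH,
                     ncol = length(MERIDIANS),
                     dimnames = list(herbs, MERIDIANS))
  for (mod in names(config@meridianEnrichment)) {
    en <- config@meridianEnrichment[[mod]]
    rows <- labels == as.integer(mod)
    for (mer in names(en)) flagProb[rows, mer] <- en[[mer]]
  }
  flags <- matrix(stats::runif(length(flagProb)) < flagProb,
                  nrow = nH, dimnames = dimnames(flagProb))

  ann <- data.frame(herb_id = herbs,
                    latin_name = paste("Herba synthetica", seq_len(nH)),
                    category = sample.int(20L, nH, replace = TRUE),
                    stringsAsFactors = FALSE)
  for (m in MERIDIANS) ann[[m]] <- unname(flags[, m])

  corpus <- herbCorpus(sets, route = "internal", annotations = ann)
  meridianSets <- lapply(seq_len(nH), function(i) MERIDIANS[flags[i, ]])
  names(meridianSets) <- herbs
  truth <- new("GroundTruth", moduleLabels = labels,
               meridians = meridianSets)
  list(corpus = corpus, truth = truth)
}

#' Generate structure-free meridian annotations for a corpus
#'
#' Every (herb, meridian) flag is an independent Bernoulli draw with a
#' common probability, so flags carry no module information. Feeding
#' these annotations to \code{\link{permutationTest}} yields a null in
#' which any significant call is a false positive — the basis of the
#' type-I error calibration of the permutation machinery.
#'
#' @param corpus A non-empty \code{\linkS4class{HerbCorpus}}.
#' @param baselineMeridianProb Common flag probability.
#' @param seed Integer seed.
#' @return Annotation \code{data.frame} covering the corpus herb
#'   universe.
#' @export
generateNullAnnotations <- function(corpus, baselineMeridianProb = 0.25,
                                    seed = 1L) {
  stopifnot(is(corpus, "HerbCorpus"))
  if (nPrescriptions(corpus) == 0L)
    stop("corpus is empty", call. = FALSE)
  stopifnot(baselineMeridianProb >= 0, baselineMeridianProb <= 1)
  herbs <- herbUniverse(corpus)
  withr::with_seed(as.integer(seed), {
    flags <- matrix(stats::runif(length(herbs) * length(MERIDIANS)) <
                      baselineMeridianProb,
                    nrow = length(herbs),
                    dimnames = list(herbs, MERIDIANS))
    ann <- data.frame(herb_id = herbs,
                      latin_name = paste("Herba synthetica", seq_along(herbs)),
                      category = sample.int(20L, length(herbs),
                                            replace = TRUE),
                      stringsAsFactors = FALSE)
    for (m in MERIDIANS) ann[[m]] <- unname(flags[, m])
    ann
  })
}
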