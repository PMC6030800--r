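#' Construct a HerbCorpus from parts
#'
#' @param prescriptions Named list of character vectors (herb sets); names
#'   are prescription identifiers.
#' @param route Character vector, one of \code{"internal"}/\code{"external"}
#'   per prescription; a single value is recycled.
#' @param annotations Optional annotation \code{data.frame} (see
#'   \code{\link{readAnnotations}} for the expected columns).
#' @return A \code{\linkS4class{HerbCorpus}}.
#' @examples
#' corp <- herbCorpus(list(p1 = c("A", "B"), p2 = "A"), route = "internal")
#' nPrescriptions(corp)
#' @export
herbCorpus <- function(prescriptions, route = "internal",
                       annotations = NULL) {
  if (length(route) == 1L) route <- rep(route, length(prescriptions))
  names(route) <- names(prescriptions)
  prescriptions <- lapply(prescriptions, function(h) sort(unique(h)))
  ann <- if (is.null(annotations)) .emptyAnnotations()
         else .checkAnnotations(annotations)
  herbs <- sort(union(unique(unlist(prescriptions, use.names = FALSE)),
                      ann$herb_id))
  new("HerbCorpus", prescriptions = prescriptions, route = route,
      annotations = ann, herbs = herbs)
}

# Autodetect tab vs comma from the header line unless a delimiter is given.
.detectSep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path, call. = FALSE)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a prescription-herb transaction table
#'
#' Reads a delimited text file with one row per prescription-herb
#' occurrence (header columns \code{prescription_id}, \code{herb_id},
#' \code{route}) into a \code{\linkS4class{HerbCorpus}}. Herb sets use
#' set semantics: a herb listed twice in the same prescription collapses
#' to one occurrence (with a warning), since dose and repetition carry
#' no weight in the analysis. Row order never affects the result.
#'
#' @param path Path to a CSV or TSV file (UTF-8, header required).
#' @param sep Field delimiter; \code{NULL} (default) autodetects tab
#'   versus comma from the header line.
#' @param annotations Optional annotation table to attach.
#' @return A \code{\linkS4class{HerbCorpus}}.
#' @seealso \code{\link{writeTransactions}}, \code{\link{readAnnotations}}
#' @export
readTransactions <- function(path, sep = NULL, annotations = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- .detectSep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          quote = "\"", comment.char = "",
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("prescription_id", "herb_id", "route")
  if (!all(need %in% names(df)))
    stop("transaction file must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) stop("empty transaction file: ", path, call. = FALSE)
  bad <- which(!df$route %in% .ROUTES)
  if (length(bad))
    stop("unknown route '", df$route[bad[1]], "' at data row ", bad[1],
         call. = FALSE)
  df$prescription_id <- as.character(df$prescription_id)
  df$herb_id <- as.character(df$herb_id)
  routes <- tapply(df$route, df$prescription_id,
                   function(r) unique(r), simplify = FALSE)
  multi <- names(routes)[lengths(routes) > 1L]
  if (length(multi))
    stop("prescription(s) with conflicting route values: ",
         paste(multi, collapse = ", "), call. = FALSE)
  sets <- split(df$herb_id, df$prescription_id)
  ndup <- sum(vapply(sets, function(h) length(h) - length(unique(h)), 0L))
  if (ndup > 0L)
    warning(ndup, " duplicate herb occurrence(s) collapsed ",
            "(transactions are sets)", call. = FALSE)
  herbCorpus(sets, route = unlist(lapply(routes, `[[`, 1L))[names(sets)],
             annotations = annotations)
}

#' Write a corpus as a transaction table
#'
#' Inverse of \code{\link{readTransactions}}: one row per
#' prescription-herb occurrence, deterministic row order (prescriptions
#' by id, herbs sorted within prescription).
#'
#' @param corpus A \code{\linkS4class{HerbCorpus}}.
#' @param path Output file path.
#' @param sep Field delimiter (default tab).
#' @return \code{path}, invisibly.
#' @export
writeTransactions <- function(corpus, path, sep = "\t") {
  sets <- herbSets(corpus)
  ord <- order(names(sets))
  sets <- sets[ord]
  df <- data.frame(
    prescription_id = rep(names(sets), lengths(sets)),
    herb_id = unlist(sets, use.names = FALSE),
    route = rep(unname(prescriptionRoutes(corpus)[names(sets)]),
                lengths(sets)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

.TRUTHY <- c("Y", "y", "1", "TRUE", "true", "T")
.FALSY <- c("", "N", "n", "0", "FALSE", "false", "F", NA)

#' Read a herb annotation table
#'
#' Reads a delimited text file with one row per herb: columns
#' \code{herb_id}, \code{latin_name}, \code{category} (integer 1-20,
#' the twenty traditional pharmacological classes) and one presence-flag
#' column per meridian code (\code{LR}, \code{HT}, \code{PC}, \code{SP},
#' \code{LU}, \code{KI}, \code{GB}, \code{SI}, \code{TE}, \code{ST},
#' \code{LI}, \code{BL}). Flags accept \code{Y}/\code{1}/\code{true}
#' (case-insensitive) as present and empty/\code{N}/\code{0}/\code{false}
#' as absent. A herb may carry no meridian flag at all.
#'
#' @param path Path to a CSV or TSV file (UTF-8, header required).
#' @param sep Field delimiter; \code{NULL} autodetects.
#' @return \code{data.frame} keyed by \code{herb_id} with logical
#'   meridian columns.
#' @seealso \code{\link{writeAnnotations}}, \code{\link{MERIDIANS}}
#' @export
readAnnotations <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- .detectSep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE,
                          colClasses = "character", encoding = "UTF-8")
  need <- c("herb_id", "latin_name", "category")
  if (!all(need %in% names(df)))
    stop("annotation file must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(df), c(need, MERIDIANS))
  if (length(extra))
    stop("unknown meridian column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  for (m in intersect(MERIDIANS, names(df))) {
    v <- df[[m]]
    known <- v %in% .TRUTHY | v %in% .FALSY
    if (!all(known))
      stop("unparseable flag value '", v[!known][1], "' in column ", m,
           call. = FALSE)
    df[[m]] <- v %in% .TRUTHY
  }
  for (m in setdiff(MERIDIANS, names(df))) df[[m]] <- FALSE
  df$category <- as.integer(df$category)
  .checkAnnotations(df)
}

#' Write a herb annotation table
#'
#' @param annotations Annotation \code{data.frame}.
#' @param path Output file path.
#' @param sep Field delimiter (default tab).
#' @return \code{path}, invisibly.
#' @export
writeAnnotations <- function(annotations, path, sep = "\t") {
  ann <- .checkAnnotations(annotations)
  for (m in MERIDIANS) ann[[m]] <- ifelse(ann[[m]], "Y", "")
  ann <- ann[order(ann$herb_id), , drop = FALSE]
  utils::write.table(ann, path, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Restrict a corpus to one administration route
#'
#' Analyses of internally administered formulas are routinely kept apart
#' from external applications because the mechanism of action differs by
#' route; this filter implements that restriction. Per-prescription herb
#' sets and the annotation table are untouched.
#'
#' @param corpus A \code{\linkS4class{HerbCorpus}}.
#' @param route \code{"internal"} or \code{"external"}.
#' @return A \code{\linkS4class{HerbCorpus}} containing exactly the
#'   prescriptions with that route (possibly zero).
#' @export
filterByRoute <- function(corpus, route) {
  .checkRoute(route)
  keep <- prescriptionRoutes(corpus) == route
  new("HerbCorpus",
      prescriptions = herbSets(corpus)[keep],
      route = prescriptionRoutes(corpus)[keep],
      annotations = annotations(corpus),
      herbs = herbUniverse(corpus))
}
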