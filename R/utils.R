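# Internal helpers shared across modules.

# Canonical key for an itemset: members sorted, joined on a separator that
# cannot occur in sane herb identifiers (unit separator).
.KEY_SEP <- "\x1f"

.itemKey <- function(items) paste(sort(items), collapse = .KEY_SEP)

.keyItems <- function(key) strsplit(key, .KEY_SEP, fixed = TRUE)

# Display form used in rule tables and reports.
.itemLabel <- function(items) paste(sort(items), collapse = " + ")

.ROUTES <- c("internal", "external")

.checkRoute <- function(route) {
  if (length(route) != 1L || !route %in% .ROUTES) {
    stop("route must be one of: ", paste(.ROUTES, collapse = ", "),
         " (got '", paste(route, collapse = ","), "')", call. = FALSE)
  }
  route
}

# Logical herb x meridian flag matrix from an annotation table.
.meridianMatrix <- function(annotations) {
  stopifnot(all(MERIDIANS %in% names(annotations)))
  m <- as.matrix(annotations[, MERIDIANS, drop = FALSE])
  storage.mode(m) <- "logical"
  rownames(m) <- annotations$herb_id
  m
}

# Sparse prescriptions x herbs incidence matrix (logical pattern matrix).
.incidenceMatrix <- function(corpus) {
  herbs <- sort(unique(unlist(herbSets(corpus), use.names = FALSE)))
  sets <- herbSets(corpus)
  ii <- rep.int(seq_along(sets), lengths(sets))
  jj <- match(unlist(sets, use.names = FALSE), herbs)
  Matrix::sparseMatrix(i = ii, j = jj,
                       dims = c(length(sets), length(herbs)),
                       dimnames = list(names(sets), herbs))
}

.emptyAnnotations <- function() {
  ann <- data.frame(herb_id = character(0), latin_name = character(0),
                    category = integer(0), stringsAsFactors = FALSE)
  for (m in MERIDIANS) ann[[m]] <- logical(0)
  ann
}

# Validate an annotation data.frame; returns it with canonical column order.
.checkAnnotations <- function(annotations) {
  need <- c("herb_id", "latin_name", "category", MERIDIANS)
  missing <- setdiff(need, names(annotations))
  if (length(missing)) {
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(annotations$herb_id)) {
    dup <- unique(annotations$herb_id[duplicated(annotations$herb_id)])
    stop("duplicate herb_id in annotation table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  bad <- !is.na(annotations$category) &
    (annotations$category < 1L | annotations$category > 20L)
  if (any(bad)) {
    stop("category outside 1-20 for herb(s): ",
         paste(annotations$herb_id[bad], collapse = ", "), call. = FALSE)
  }
  annotations[, need, drop = FALSE]
}
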