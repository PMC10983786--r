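#' Conformations and ensemble sets
#'
#' A `conformation` is a labelled n x 3 matrix of C-alpha coordinates
#' (Angstrom) with a presence mask marking alignment positions that carry a
#' coordinate. An `ensemble_set` groups conformations into named ensembles
#' (for example, all X-ray chains of one enzyme); after complete-case
#' filtering every member shares the same atom count n.
#'
#' @param id Conformation identifier, e.g. `"1pq2A"`.
#' @param coords n x 3 numeric matrix, Angstrom. Rows at masked-absent
#'   positions may be `NA`.
#' @param present Logical length-n mask; defaults to rows with all-finite
#'   coordinates.
#' @return `conformation()` returns a `conformation`; `ensemble_set()` an
#'   `ensemble_set`.
#' @examples
#' c1 <- conformation("a1", matrix(rnorm(12), 4))
#' es <- ensemble_set(list(e1 = list(c1)))
#' es$n_atoms
#' @export
conformation <- function(id, coords, present = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stopf("coords must have 3 columns")
  n <- nrow(coords)
  if (is.null(present)) present <- apply(is.finite(coords), 1L, all)
  present <- as.logical(present)
  if (length(present) != n) stopf("present mask length must equal nrow(coords)")
  if (any(!is.finite(coords[present, , drop = FALSE])))
    stopf("conformation '%s': non-finite coordinates at present positions", id)
  structure(list(id = as.character(id), coords = coords, present = present),
            class = "conformation")
}

#' @rdname conformation
#' @param ensembles Named list; each element a list of `conformation`s
#'   belonging to one ensemble.
#' @export
ensemble_set <- function(ensembles) {
  if (length(ensembles) < 1L) stopf("at least one ensemble is required")
  ids <- names(ensembles)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    stopf("ensembles must be a uniquely named list")
  for (e in ensembles) {
    if (length(e) < 1L) stopf("every ensemble needs at least one member")
    for (cf in e) if (!inherits(cf, "conformation"))
      stopf("ensemble members must be conformation objects")
  }
  ns <- unique(unlist(lapply(ensembles, function(e)
    vapply(e, function(cf) nrow(cf$coords), integer(1)))))
  if (length(ns) != 1L)
    stopf("all conformations must share one atom count (found: %s)",
          paste(ns, collapse = ", "))
  structure(list(
    ensembles = ensembles,
    n_atoms = ns,
    n_ensembles = length(ensembles),
    sizes = vapply(ensembles, length, integer(1))
  ), class = "ensemble_set")
}

#' @export
print.ensemble_set <- function(x, ...) {
  cat("Ensemble set:", x$n_ensembles, "ensemble(s),",
      sum(x$sizes), "conformations,", x$n_atoms, "atoms\n")
  sz <- x$sizes
  cat("  sizes:", paste(sprintf("%s=%d", names(sz), sz), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.conformation <- function(x, ...) {
  cat("Conformation", x$id, "-", nrow(x$coords), "atoms,",
      sum(x$present), "present\n")
  invisible(x)
}

# Flatten an ensemble_set into parallel lists used by the fitters.
set_members <- function(set) {
  out <- list(coords = list(), conf_id = character(), ens_id = character(),
              ens_index = integer())
  k <- 0L
  for (i in seq_along(set$ensembles)) {
    eid <- names(set$ensembles)[i]
    for (cf in set$ensembles[[i]]) {
      k <- k + 1L
      out$coords[[k]] <- cf$coords
      out$conf_id[k] <- cf$id
      out$ens_id[k] <- eid
      out$ens_index[k] <- i
    }
  }
  out
}

#' Read and write plain-text coordinate tables
#'
#' The coordinate-table dialect stores one conformation as a header line
#' `#n=<n> id=<id> ensemble=<eid>` followed by n whitespace-separated
#' `x y z` rows (Angstrom); a file concatenates any number of conformations.
#' The format is line-diffable, which makes fixtures and round-trip checks
#' easy to audit.
#'
#' @param set An [ensemble_set()].
#' @param path File path.
#' @return `read_coord_table()` returns an `ensemble_set`;
#'   `write_coord_table()` returns `path` invisibly.
#' @export
write_coord_table <- function(set, path) {
  con <- file(path, "w")
  on.exit(close(con))
  mem <- set_members(set)
  for (k in seq_along(mem$coords)) {
    X <- mem$coords[[k]]
    writeLines(sprintf("#n=%d id=%s ensemble=%s", nrow(X),
                       mem$conf_id[k], mem$ens_id[k]), con)
    writeLines(sprintf("%.6f %.6f %.6f", X[, 1], X[, 2], X[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_coord_table
#' @export
read_coord_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  ens <- list()
  i <- 1L
  while (i <= length(lines)) {
    h <- lines[i]
    m <- regmatches(h, regexec("^#n=(\\d+) id=(\\S+) ensemble=(\\S+)", h))[[1]]
    if (length(m) != 4L) stopf("malformed coordinate-table header: '%s'", h)
    n <- as.integer(m[2]); id <- m[3]; eid <- m[4]
    if (i + n > length(lines)) stopf("truncated block for conformation '%s'", id)
    rows <- lines[(i + 1L):(i + n)]
    X <- matrix(as.numeric(unlist(strsplit(trimws(rows), "\\s+"))),
                ncol = 3L, byrow = TRUE)
    if (nrow(X) != n) stopf("conformation '%s': expected %d rows", id, n)
    ens[[eid]] <- c(ens[[eid]], list(conformation(id, X)))
    i <- i + n + 1L
  }
  ensemble_set(ens)
}
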