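#' Read C-alpha coordinates of one chain from a PDB or mmCIF file
#'
#' Extracts one C-alpha coordinate per residue of the requested chain.
#' Residues that have atoms but no C-alpha record are kept as masked-absent
#' positions, so downstream alignment and complete-case filtering see them.
#' Insertion codes are treated as distinct residues. Parsing is delegated to
#' \pkg{bio3d} (`read.pdb` / `read.cif` by file extension).
#'
#' @param path PDB (`.pdb`, `.ent`) or mmCIF (`.cif`) file.
#' @param chain Chain identifier to extract.
#' @param altloc_policy How to resolve alternate locations of a C-alpha:
#'   `"first"` (default) keeps the first record in file order; `"occupancy"`
#'   keeps the highest-occupancy record.
#' @param id Conformation id; default `<basename><chain>`.
#' @return A [conformation()] with an attached `resno` attribute (author
#'   residue numbering, insertion codes appended) used by
#'   [apply_alignment()].
#' @export
read_pdb_calpha <- function(path, chain,
                            altloc_policy = c("first", "occupancy"),
                            id = NULL) {
  altloc_policy <- match.arg(altloc_policy)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext == "cif") bio3d::read.cif(path, rm.alt = FALSE)
         else bio3d::read.pdb(path, rm.alt = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  chains <- unique(at$chain)
  if (!chain %in% chains)
    stopf("chain '%s' not found in %s (available: %s)",
          chain, path, paste(sort(chains), collapse = ", "))
  at <- at[at$chain == chain, , drop = FALSE]
  ins <- ifelse(is.na(at$insert) | at$insert == "", "", at$insert)
  reskey <- paste0(at$resno, ins)
  residues <- unique(reskey)          # file order
  ca <- at[at$elety == "CA", , drop = FALSE]
  ca_key <- reskey[at$elety == "CA"]
  if (nrow(ca) == 0L)
    stopf("no C-alpha atoms found for chain '%s' in %s", chain, path)

  n <- length(residues)
  coords <- matrix(NA_real_, n, 3L)
  present <- logical(n)
  for (r in seq_len(n)) {
    idx <- which(ca_key == residues[r])
    if (length(idx) == 0L) next
    if (length(idx) > 1L && altloc_policy == "occupancy")
      idx <- idx[order(-ca$o[idx])]
    rec <- ca[idx[1L], ]
    coords[r, ] <- c(rec$x, rec$y, rec$z)
    present[r] <- TRUE
  }
  if (is.null(id))
    id <- paste0(tools::file_path_sans_ext(basename(path)), chain)
  cf <- conformation(id, coords, present)
  attr(cf, "resno") <- residues
  cf
}

#' Residue-alignment maps
#'
#' An alignment map assigns each chain's author residue numbers to 0-based
#' common alignment columns. It stands in for an upstream multiple sequence
#' alignment, consumed as a three-column TSV (`chain_key`, `source_resnum`,
#' `column`) with a header line.
#'
#' @param path TSV file with columns `chain_key`, `source_resnum`, `column`.
#' @return A data frame with those three columns.
#' @export
read_alignment_map <- function(path) {
  map <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "character", "integer"))
  need <- c("chain_key", "source_resnum", "column")
  if (!all(need %in% names(map)))
    stopf("alignment map must have columns: %s", paste(need, collapse = ", "))
  map
}

#' Re-index a conformation onto common alignment columns
#'
#' @param conf A [conformation()]; its residue labels are taken from the
#'   `resno` attribute set by [read_pdb_calpha()] (default `1..n`).
#' @param map Alignment map data frame (see [read_alignment_map()]).
#' @param n_total Total number of alignment columns.
#' @param chain_key Key selecting this conformation's rows of the map;
#'   defaults to the conformation id.
#' @return A [conformation()] with `n_total` rows; columns that received no
#'   residue (or a masked-absent residue) are masked absent. The operation
#'   never invents coordinates.
#' @export
apply_alignment <- function(conf, map, n_total, chain_key = conf$id) {
  rows <- map[map$chain_key == chain_key, , drop = FALSE]
  if (nrow(rows) == 0L)
    stopf("alignment map has no entries for chain_key '%s'", chain_key)
  if (anyDuplicated(rows$column))
    stopf("alignment map assigns chain '%s' twice to a column", chain_key)
  if (any(rows$column < 0L | rows$column >= n_total))
    stopf("alignment columns out of range [0, %d)", n_total)
  resno <- attr(conf, "resno")
  if (is.null(resno)) resno <- as.character(seq_len(nrow(conf$coords)))
  coords <- matrix(NA_real_, n_total, 3L)
  present <- logical(n_total)
  src <- match(rows$source_resnum, resno)
  keep <- !is.na(src)
  tgt <- rows$column[keep] + 1L
  coords[tgt, ] <- conf$coords[src[keep], , drop = FALSE]
  present[tgt] <- conf$present[src[keep]]
  coords[!present, ] <- NA_real_
  out <- conformation(conf$id, coords, present)
  attr(out, "resno") <- as.character(seq_len(n_total) - 1L)
  out
}

#' Complete-case filtering of a multi-ensemble dataset
#'
#' Builds a complete-case dataset in three steps: (1) drop conformations
#' whose fraction of masked-absent positions exceeds
#' `max_missing_frac_conf`; (2) drop alignment columns absent in any
#' surviving conformation (so every survivor is complete); (3) drop
#' explicitly excluded conformation ids (manual outliers). Ensembles left
#' empty are removed.
#'
#' @param set An [ensemble_set()] (members may have masked positions but
#'   must share a common length).
#' @param max_missing_frac_conf Missing-fraction threshold in `[0, 1]`
#'   (default 0.5).
#' @param drop_any_missing_residue If `TRUE` (default), step 2 enforces
#'   strict per-column completeness; if `FALSE` the column step is skipped
#'   and masked positions may remain.
#' @param exclude_ids Conformation ids to drop after filtering.
#' @return A list of class `filter_result`: `set` (the filtered
#'   [ensemble_set()]) and `report`, a one-row tibble of counts dropped at
#'   each step.
#' @export
complete_case_filter <- function(set, max_missing_frac_conf = 0.5,
                                 drop_any_missing_residue = TRUE,
                                 exclude_ids = character()) {
  stopifnot(max_missing_frac_conf >= 0, max_missing_frac_conf <= 1)
  n <- set$n_atoms

  # step 1: conformations lacking too many residues
  dropped_conf <- 0L
  ens1 <- lapply(set$ensembles, function(e) {
    Filter(function(cf) {
      ok <- mean(!cf$present) <= max_missing_frac_conf
      if (!ok) dropped_conf <<- dropped_conf + 1L
      ok
    }, e)
  })
  ens1 <- ens1[vapply(ens1, length, integer(1)) > 0L]
  if (length(ens1) == 0L) stopf("no complete cases survive filtering")

  # step 2: columns absent in any surviving conformation
  dropped_cols <- 0L
  if (drop_any_missing_residue) {
    keep_col <- rep(TRUE, n)
    for (e in ens1) for (cf in e) keep_col <- keep_col & cf$present
    dropped_cols <- sum(!keep_col)
    ens1 <- lapply(ens1, function(e) lapply(e, function(cf) {
      conformation(cf$id, cf$coords[keep_col, , drop = FALSE],
                   cf$present[keep_col])
    }))
  }

  # step 3: manual outlier exclusion
  dropped_excl <- 0L
  if (length(exclude_ids)) {
    ens1 <- lapply(ens1, function(e) {
      Filter(function(cf) {
        ok <- !(cf$id %in% exclude_ids)
        if (!ok) dropped_excl <<- dropped_excl + 1L
        ok
      }, e)
    })
    ens1 <- ens1[vapply(ens1, length, integer(1)) > 0L]
  }
  if (length(ens1) == 0L || sum(vapply(ens1, length, integer(1))) == 0L)
    stopf("no complete cases survive filtering")

  out <- ensemble_set(ens1)
  if (drop_any_missing_residue && out$n_atoms == 0L)
    stopf("no complete cases survive filtering")
  report <- tibble::tibble(
    conformations_in = sum(set$sizes),
    dropped_incomplete_conformations = dropped_conf,
    dropped_columns = dropped_cols,
    dropped_excluded = dropped_excl,
    conformations_out = sum(out$sizes),
    atoms_out = out$n_atoms
  )
  structure(list(set = out, report = report), class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("Complete-case filter:\n")
  print(x$report)
  invisible(x)
}

#' Write superposed conformations as a multi-MODEL PDB file
#'
#' Applies each rigid transform (`Y = (X - 1 t^T) R`) and writes every
#' conformation as one MODEL of a single PDB file, one C-alpha per residue.
#' Coordinates survive a read round trip to the fixed-width PDB precision of
#' 1e-3 Angstrom.
#'
#' @param confs List of [conformation()]s.
#' @param transforms List of [rigid_transform()]s, same length (identity
#'   transforms write the raw coordinates).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_superposed_pdb <- function(confs, transforms, path) {
  if (length(confs) != length(transforms))
    stopf("confs and transforms must have the same length")
  con <- tryCatch(file(path, "w"), error = function(e)
    stopf("cannot open '%s' for writing", path))
  on.exit(close(con))
  for (k in seq_along(confs)) {
    cf <- confs[[k]]
    Y <- apply_transform(cf$coords, transforms[[k]])
    writeLines(sprintf("MODEL     %4d", k), con)
    idx <- which(cf$present)
    writeLines(sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_along(idx), idx, Y[idx, 1], Y[idx, 2], Y[idx, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Build a complete-case dataset from a manifest and an alignment map
#'
#' Drives the full import path: read each chain listed in the manifest,
#' re-index it onto the common alignment columns, group chains into
#' ensembles and apply [complete_case_filter()].
#'
#' @param manifest_path TSV with header columns `ensemble_id`,
#'   `conformation_id`, `path`, `chain`.
#' @param alignment_path Alignment-map TSV (see [read_alignment_map()]);
#'   `chain_key` must match `conformation_id`.
#' @param n_total Number of alignment columns; default `max(column) + 1`.
#' @param ... Passed to [complete_case_filter()].
#' @return A `filter_result` (filtered set plus report).
#' @export
build_dataset <- function(manifest_path, alignment_path, n_total = NULL, ...) {
  man <- utils::read.table(manifest_path, header = TRUE, sep = "\t",
                           colClasses = "character")
  need <- c("ensemble_id", "conformation_id", "path", "chain")
  if (!all(need %in% names(man)))
    stopf("manifest must have columns: %s", paste(need, collapse = ", "))
  map <- read_alignment_map(alignment_path)
  if (is.null(n_total)) n_total <- max(map$column) + 1L
  ens <- list()
  for (r in seq_len(nrow(man))) {
    if (!file.exists(man$path[r]))
      stopf("manifest entry '%s': file not found: %s",
            man$conformation_id[r], man$path[r])
    cf <- read_pdb_calpha(man$path[r], man$chain[r], id = man$conformation_id[r])
    cf <- apply_alignment(cf, map, n_total, chain_key = man$conformation_id[r])
    eid <- man$ensemble_id[r]
    ens[[eid]] <- c(ens[[eid]], list(cf))
  }
  complete_case_filter(ensemble_set(ens), ...)
}
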