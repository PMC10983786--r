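#' Write and read covariance matrices as plain text
#'
#' A 3n x 3n covariance matrix is stored as a whitespace-separated dense
#' text matrix together with a one-line JSON-style sidecar header (`#` line)
#' recording the atom count, the index convention and provenance tags. Plain
#' text keeps the containers diffable and portable.
#'
#' @param C 3n x 3n matrix.
#' @param path Output file.
#' @param method,divisor Optional provenance tags stored in the header.
#' @return `path` invisibly; `read_covariance_matrix()` returns the matrix
#'   with the header fields as attributes.
#' @export
write_covariance_matrix <- function(C, path, method = NA, divisor = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    '#{"n": %d, "index": "3*(atom-1)+axis, vec(t(Y))", "method": "%s", "divisor": "%s"}',
    nrow(C) / 3L, method, divisor), con)
  utils::write.table(format(C, digits = 17, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_covariance_matrix
#' @export
read_covariance_matrix <- function(path) {
  header <- readLines(path, n = 1L)
  C <- as.matrix(utils::read.table(path, skip = 1L))
  dimnames(C) <- NULL
  attr(C, "header") <- sub("^#", "", header)
  C
}

#' Write the artifacts of a fitted model to a directory
#'
#' Writes the mean structure (PDB), the estimated covariance matrices
#' (plain-text containers), the per-conformation transform table (TSV with
#' the translation and the row-major rotation matrix) and, when present, the
#' log-likelihood trace (CSV).
#'
#' @param fit A [rem_fit()], [ts_fit()], [spe_fit()] or `single_fit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit_artifacts <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  method <- fit$method %||% class(fit)[1]
  write_superposed_pdb(list(conformation("mean", fit$M_hat)),
                       list(rigid_transform()),
                       file.path(dir, "mean.pdb"))
  covs <- fit_covariances(fit)
  for (nm in names(covs)) if (!is.null(covs[[nm]]))
    write_covariance_matrix(covs[[nm]], file.path(dir, paste0(nm, ".txt")),
                            method = method)
  keep <- !vapply(fit$transforms, is.null, logical(1))
  tab <- do.call(rbind, lapply(which(keep), function(k) {
    tr <- fit$transforms[[k]]
    data.frame(id = fit$conf_ids[k] %||% as.character(k),
               t1 = tr$t[1], t2 = tr$t[2], t3 = tr$t[3],
               matrix(as.numeric(t(tr$R)), 1,
                      dimnames = list(NULL, paste0("r", 1:9))))
  }))
  utils::write.table(tab, file.path(dir, "transforms.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(fit$loglik_trace))
    utils::write.table(
      data.frame(iteration = seq_along(fit$loglik_trace) - 1L,
                 loglik = fit$loglik_trace),
      file.path(dir, "loglik_trace.csv"), sep = ",", row.names = FALSE,
      quote = FALSE)
  invisible(dir)
}
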