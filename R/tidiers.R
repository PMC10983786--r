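#' Broom-style tidiers for fitted superposition models
#'
#' `tidy()` returns one row per atom with the fitted per-atom standard
#' deviations (square root of the mean diagonal of each 3 x 3 atom block);
#' `glance()` returns a one-row model summary.
#'
#' @param x A fitted model object.
#' @param ... Unused.
#' @return A tibble.
#' @name remsuper-tidiers
NULL

#' @rdname remsuper-tidiers
#' @method tidy rem_fit
#' @export
tidy.rem_fit <- function(x, ...) {
  tibble::tibble(
    atom = seq_len(nrow(x$M_hat)),
    sd_W = sqrt(atom_variances(x$W_hat)),
    sd_Sigma = sqrt(atom_variances(x$Sigma_hat))
  )
}

#' @rdname remsuper-tidiers
#' @method glance rem_fit
#' @export
glance.rem_fit <- function(x, ...) {
  tibble::tibble(
    n_atoms = nrow(x$M_hat), n_ensembles = length(x$sizes),
    n_conformations = length(x$transforms),
    n_iter = x$n_iter, converged = x$converged,
    loglik = x$loglik_trace[length(x$loglik_trace)],
    tr_W = sum(diag(x$W_hat)), tr_Sigma = sum(diag(x$Sigma_hat))
  )
}

#' @rdname remsuper-tidiers
#' @method tidy ts_fit
#' @export
tidy.ts_fit <- function(x, ...) {
  tibble::tibble(
    atom = seq_len(nrow(x$M_hat)),
    sd_W = sqrt(atom_variances(x$W_hat)),
    sd_Sigma = sqrt(atom_variances(x$Sigma_pooled))
  )
}

#' @rdname remsuper-tidiers
#' @method glance ts_fit
#' @export
glance.ts_fit <- function(x, ...) {
  tibble::tibble(
    n_atoms = nrow(x$M_hat), n_ensembles = nrow(x$flags),
    n_failed = sum(x$flags$failed), method = x$method,
    tr_W = sum(diag(x$W_hat)), tr_Sigma = sum(diag(x$Sigma_pooled))
  )
}

#' @rdname remsuper-tidiers
#' @method tidy spe_fit
#' @export
tidy.spe_fit <- function(x, ...) {
  tibble::tibble(
    atom = seq_len(nrow(x$M_hat)),
    sd_Delta = sqrt(atom_variances(x$Delta_hat))
  )
}

#' @rdname remsuper-tidiers
#' @method glance spe_fit
#' @export
glance.spe_fit <- function(x, ...) {
  tibble::tibble(
    n_atoms = nrow(x$M_hat), n_conformations = length(x$transforms),
    converged = x$converged, tr_Delta = sum(diag(x$Delta_hat))
  )
}

#' @rdname remsuper-tidiers
#' @method tidy single_fit
#' @export
tidy.single_fit <- function(x, ...) {
  tibble::tibble(
    atom = seq_len(nrow(x$M_hat)),
    sd = sqrt(atom_variances(x$Sigma_hat)),
    weight = x$weights
  )
}

#' @rdname remsuper-tidiers
#' @method glance single_fit
#' @export
glance.single_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, n_conformations = length(x$transforms),
    n_atoms = nrow(x$M_hat), n_iter = x$n_iter, converged = x$converged,
    objective = x$objective_trace[length(x$objective_trace)]
  )
}

#' @rdname remsuper-tidiers
#' @method tidy covariance_pca
#' @export
tidy.covariance_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$K),
    eigenvalue = x$values,
    prop_variance = x$values / max(x$trace, .Machine$double.eps)
  )
}

#' @rdname remsuper-tidiers
#' @method tidy recovery_report
#' @export
tidy.recovery_report <- function(x, ...) x$results

#' @rdname remsuper-tidiers
#' @method glance recovery_report
#' @export
glance.recovery_report <- function(x, ...) x$summary

#' Plots for PCA models and recovery reports
#'
#' `autoplot.covariance_pca()` draws the eigenvalue spectrum (scree plot);
#' `autoplot.recovery_report()` draws the accuracy curves (MAE of
#' per-coordinate standard deviations against ensemble size, one panel per
#' ensemble count, one colour per method). `plot_pc_scores()` scatters
#' conformations in the PC1-PC2 plane coloured by ensemble, and
#' `plot_displacement_profile()` draws a per-residue displacement profile.
#'
#' @param object Object to plot.
#' @param metric Column of the recovery summary to plot
#'   (default `"mae_W"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot covariance_pca
#' @export
autoplot.covariance_pca <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$eigenvalue)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Principal component",
                  y = expression("Eigenvalue (" * ring(A)^2 * ")"),
                  title = paste("Spectrum of", object$source)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.covariance_pca
#' @method autoplot recovery_report
#' @export
autoplot.recovery_report <- function(object, metric = "mae_W", ...) {
  d <- object$summary
  ggplot2::ggplot(d, ggplot2::aes(x = .data$m, y = .data[[metric]],
                                  colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~nu, labeller = ggplot2::label_both) +
    ggplot2::scale_x_log10(breaks = unique(d$m)) +
    ggplot2::labs(x = "Ensemble size m", y = metric) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.covariance_pca
#' @param scores Tibble from [project_structures()].
#' @export
plot_pc_scores <- function(scores, ...) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                       colour = .data$ensemble)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "PC1 (Å)", y = "PC2 (Å)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.covariance_pca
#' @param profile Numeric per-residue displacement vector from
#'   [per_residue_displacement()].
#' @export
plot_displacement_profile <- function(profile, ...) {
  d <- tibble::tibble(residue = seq_along(profile), displacement = profile)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$residue, y = .data$displacement)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Residue (alignment column)",
                  y = "RMS displacement (Å)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
NULL
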