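#' Tidy a block-model fit
#'
#' One row per unordered cluster pair with the fitted connectivity
#' parameters: `pi` for the bernoulli family, `mu` (and the regression
#' coefficients, one column per covariate) for the valued families.
#'
#' @param x A `blockmodel_fit`.
#' @param ... Unused.
#' @return A tibble with columns `q`, `l`, and the parameter columns.
#' @exportS3Method generics::tidy
tidy.blockmodel_fit <- function(x, ...) {
  pairs <- tidyr::expand_grid(q = seq_len(x$Q), l = seq_len(x$Q)) %>%
    filter(.data$q <= .data$l)
  out <- pairs
  if (x$family == "bernoulli") {
    out$pi <- x$pi[cbind(pairs$q, pairs$l)]
  } else {
    out$mu <- x$mu[cbind(pairs$q, pairs$l)]
    if (x$d > 0) {
      for (k in seq_len(x$d)) {
        out[[paste0("beta", k)]] <-
          x$beta[k, , ][cbind(pairs$q, pairs$l)]
      }
    }
  }
  out
}

#' Glance at a block-model fit
#'
#' @param x A `blockmodel_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `family`, `Q`, `d`, `n`, `J`, `icl`,
#'   `n_params`, `sigma2`, `converged`.
#' @exportS3Method generics::glance
glance.blockmodel_fit <- function(x, ...) {
  tibble(family = x$family, Q = x$Q, d = x$d, n = x$n, J = x$J,
         icl = x$icl, n_params = x$n_params,
         sigma2 = if (is.null(x$sigma2)) NA_real_ else x$sigma2,
         converged = x$converged)
}

#' Cluster memberships of a block-model fit
#'
#' @param fit A `blockmodel_fit`.
#' @return A tibble `protein`, `cluster` (MAP assignment),
#'   `posterior` (its posterior probability).
#' @export
cluster_memberships <- function(fit) {
  stopifnot(inherits(fit, "blockmodel_fit"))
  tibble(protein = fit$proteins,
         cluster = unname(fit$labels),
         posterior = fit$tau[cbind(seq_len(fit$n), fit$labels)])
}

#' Heatmap of the fitted connectivity matrix
#'
#' Tile plot of the per-cluster-pair interaction probabilities
#' (bernoulli) or mean interaction likelihoods (valued families), the
#' cluster-scale summary of the network topology.
#'
#' @param object A `blockmodel_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.blockmodel_fit <- function(object, ...) {
  M <- if (object$family == "bernoulli") object$pi else object$mu
  value_lab <- if (object$family == "bernoulli") "pi" else "mu"
  df <- tidyr::expand_grid(q = seq_len(object$Q), l = seq_len(object$Q)) %>%
    mutate(value = M[cbind(.data$q, .data$l)])
  sizes <- tabulate(object$labels, object$Q)
  ggplot(df, aes(x = factor(.data$l), y = factor(.data$q),
                 fill = .data$value)) +
    geom_tile() +
    geom_text(aes(label = formatC(.data$value, format = "g", digits = 3)),
              colour = "white") +
    scale_y_discrete(limits = rev,
                     labels = function(q) sprintf("C%s (n=%d)", q,
                                                  sizes[as.integer(q)])) +
    labs(x = "cluster", y = "cluster", fill = value_lab,
         title = sprintf("%s block model, Q = %d", object$family, object$Q))
}

#' ICL profile of a model scan
#'
#' @param object A `blockmodel_scan`.
#' @param ... Unused.
#' @return A ggplot object: ICL against Q, the best model marked.
#' @exportS3Method ggplot2::autoplot
autoplot.blockmodel_scan <- function(object, ...) {
  df <- as_tibble(object)[, c("Q", "icl", "best")]
  ggplot(df, aes(x = .data$Q, y = .data$icl)) +
    geom_line() +
    geom_point(aes(colour = .data$best), size = 2, show.legend = FALSE) +
    scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "black")) +
    labs(x = "number of clusters Q", y = "ICL")
}
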