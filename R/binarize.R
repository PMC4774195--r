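#' Fit a Gaussian mixture to the HIS3 optical-density ratios
#'
#' The HIS3 reporter produces a ratio of optical densities whose empirical
#' distribution is well described by a Gaussian mixture; the published
#' analysis retained three components selected by BIC, the upper component
#' gathering the growing (interacting) yeasts.  Fitting is delegated to
#' \pkg{mclust} (unequal-variance univariate models, BIC selection), the
#' standard tool for this step.
#'
#' @param ratios Numeric vector of OD ratios (at least 10 finite values).
#' @param k_range Component counts to scan, a subset of 1:6.
#' @return An object of class `od_mixture`: list with `K`, `weights`,
#'   `means`, `variances` (components sorted by mean), `bic` (the selected
#'   model's BIC, \pkg{mclust} convention, higher is better), `loglik`,
#'   `data` (the fitted sample).
#' @examples
#' set.seed(1)
#' z <- c(rnorm(300, 0.12, 0.03), rnorm(300, 0.45, 0.05), rnorm(300, 1, 0.15))
#' fit_od_mixture(z)
#' @export
fit_od_mixture <- function(ratios, k_range = 1:6) {
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) < 10) abort("need at least 10 finite OD ratios")
  if (!all(k_range %in% 1:6)) abort("k_range must be a subset of 1:6")
  if (stats::sd(ratios) < .Machine$double.eps^0.5) {
    abort("degenerate OD ratio sample: all values (numerically) identical")
  }
  fit <- mclust::Mclust(ratios, G = k_range, modelNames = "V",
                        verbose = FALSE)
  if (is.null(fit)) abort("mixture estimation failed for all component counts")
  p <- fit$parameters
  sigma2 <- p$variance$sigmasq
  if (length(sigma2) == 1) sigma2 <- rep(sigma2, fit$G)
  ord <- order(p$mean)
  structure(list(K = fit$G,
                 weights = unname(p$pro[ord]),
                 means = unname(p$mean[ord]),
                 variances = unname(sigma2[ord]),
                 bic = unname(fit$bic),
                 loglik = unname(fit$loglik),
                 data = ratios),
            class = "od_mixture")
}

#' @export
print.od_mixture <- function(x, ...) {
  cat("Gaussian mixture on OD ratios: K = ", x$K,
      " (BIC = ", format(x$bic), ")\n", sep = "")
  print(tibble(component = seq_len(x$K), weight = x$weights,
               mean = x$means, sd = sqrt(x$variances)))
  invisible(x)
}

#' Posterior-equality boundaries between successive mixture components
#'
#' The limit between two successive components is the ratio value at which
#' their posterior probabilities are equal, i.e. where
#' \eqn{\alpha_k f_k(z) = \alpha_{k+1} f_{k+1}(z)}; it is located by root
#' bracketing between the two component means.
#'
#' @param m An [fit_od_mixture()] result (components sorted by mean).
#' @return Numeric vector of length `K - 1`; `NA` (with a warning) where no
#'   sign change exists between the adjacent means.
#' @export
component_boundaries <- function(m) {
  stopifnot(inherits(m, "od_mixture"))
  if (m$K < 2) return(numeric(0))
  vapply(seq_len(m$K - 1), function(k) {
    f <- function(z) {
      log(m$weights[k]) + dnorm(z, m$means[k], sqrt(m$variances[k]), log = TRUE) -
        log(m$weights[k + 1]) -
        dnorm(z, m$means[k + 1], sqrt(m$variances[k + 1]), log = TRUE)
    }
    lo <- m$means[k]; hi <- m$means[k + 1]
    if (!is.finite(f(lo)) || !is.finite(f(hi)) || f(lo) * f(hi) > 0) {
      warn(sprintf("no posterior-equality boundary between components %d and %d",
                   k, k + 1))
      return(NA_real_)
    }
    uniroot(f, c(lo, hi), tol = 1e-10)$root
  }, numeric(1))
}

resolve_xgal_threshold <- function(threshold, scale = ordinal_scale()) {
  if (is.character(threshold)) mark_to_code(threshold, scale) else
    as.integer(threshold)
}

#' Threshold the two reporters for one or more test records
#'
#' A test is positive when its output reaches the threshold: marks at or
#' above `'+'` for X-Gal (the published cut between `'+?'` and `'+'`) and
#' OD ratios at or above 0.45 for HIS3.  Missing HIS3 values are treated
#' as negative (conservative).
#'
#' @param xgal Integer mark codes.
#' @param his3 Numeric OD ratios (may be `NA`).
#' @param xgal_threshold Mark (label or code) from which X-Gal is positive;
#'   default `"+"`.
#' @param his3_threshold Ratio from which HIS3 is positive; default 0.45
#'   (the published threshold; 0.3 and 0.65 were tested as alternatives).
#' @param scale Ordinal scale for resolving a mark label.
#' @return A tibble with logical columns `xgal_pos`, `his3_pos`.
#' @examples
#' binarize_tests(mark_to_code("+?"), 1.19)  # X-Gal negative, HIS3 positive
#' @export
binarize_tests <- function(xgal, his3, xgal_threshold = "+",
                           his3_threshold = 0.45, scale = ordinal_scale()) {
  thr <- resolve_xgal_threshold(xgal_threshold, scale)
  tibble(xgal_pos = !is.na(xgal) & xgal >= thr,
         his3_pos = !is.na(his3) & his3 >= his3_threshold)
}

#' Classify the four-test configuration of an unordered pair
#'
#' Each unordered protein pair is tested in two orientations (ways), each
#' with two reporters, giving four boolean test outcomes.  Configurations:
#' \describe{
#'   \item{1}{all four tests positive;}
#'   \item{2}{exactly three positive;}
#'   \item{3}{exactly two positive, both in the same way;}
#'   \item{4}{exactly two positive, one reporter in each way (different
#'     reporters);}
#'   \item{5}{exactly two positive, the same reporter in both ways —
#'     judged unreliable and discarded when building the binary network;}
#'   \item{none}{at most one positive.}
#' }
#'
#' @param xgal_way1,his3_way1 Logical: reporter outcomes with `i` as bait.
#' @param xgal_way2,his3_way2 Logical: reporter outcomes with `j` as bait.
#' @return Character vector in `c("1","2","3","4","5","none")`.
#' @examples
#' classify_configuration(TRUE, TRUE, TRUE, FALSE)  # "2"
#' @export
classify_configuration <- function(xgal_way1, his3_way1, xgal_way2, his3_way2) {
  s <- xgal_way1 + his3_way1 + xgal_way2 + his3_way2
  same_way <- (xgal_way1 & his3_way1) | (xgal_way2 & his3_way2)
  same_reporter <- (xgal_way1 & xgal_way2) | (his3_way1 & his3_way2)
  dplyr::case_when(
    s == 4 ~ "1",
    s == 3 ~ "2",
    s == 2 & same_way ~ "3",
    s == 2 & same_reporter ~ "5",
    s == 2 ~ "4",
    TRUE ~ "none"
  )
}

#' Build the binary interaction network from thresholded tests
#'
#' Applies the reporter thresholds to both orientations of every unordered
#' pair, classifies the four-test configuration, and declares an edge for
#' configurations 1-4 (configuration 5 is discarded as unreliable; at most
#' one positive test means no interaction).  A missing orientation counts
#' as two negative tests (with a warning).  Homodimer (diagonal) pairs have
#' a single orientation, used for both ways; they are classified and stored
#' on the diagonal but excluded from block-model fitting.
#'
#' @param data A `y2h_data` object.
#' @inheritParams binarize_tests
#' @return An object of class `binary_network`: list with `roster`, `Z`
#'   (symmetric logical matrix with protein dimnames), `configuration`
#'   (character matrix of configuration labels) and `thresholds`.
#' @export
build_binary_network <- function(data, xgal_threshold = "+",
                                 his3_threshold = 0.45) {
  stopifnot(inherits(data, "y2h_data"))
  ids <- data$roster$protein
  n <- length(ids)
  thr <- resolve_xgal_threshold(xgal_threshold, data$scale)
  xp <- hp <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  seen <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  bi <- match(data$records$bait, ids)
  pj <- match(data$records$prey, ids)
  pos <- binarize_tests(data$records$xgal, data$records$his3,
                        thr, his3_threshold, data$scale)
  xp[cbind(bi, pj)] <- pos$xgal_pos
  hp[cbind(bi, pj)] <- pos$his3_pos
  seen[cbind(bi, pj)] <- TRUE
  # duplicate the single homodimer orientation as both ways
  miss <- 0L
  config <- matrix("none", n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in i:n) {
    o1 <- c(i, j); o2 <- c(j, i)
    if (i == j) o2 <- o1
    if (!seen[o1[1], o1[2]] && !seen[o2[1], o2[2]] && i != j) next
    if (i != j && (!seen[o1[1], o1[2]] || !seen[o2[1], o2[2]])) miss <- miss + 1L
    cfg <- classify_configuration(xp[o1[1], o1[2]], hp[o1[1], o1[2]],
                                  xp[o2[1], o2[2]], hp[o2[1], o2[2]])
    config[i, j] <- cfg
    config[j, i] <- cfg
  }
  if (miss > 0) {
    warn(sprintf("%d unordered pair(s) missing one orientation; its tests treated as negative",
                 miss))
  }
  Z <- matrix(config %in% as.character(1:4), n, n, dimnames = list(ids, ids))
  structure(list(roster = data$roster, Z = Z, configuration = config,
                 thresholds = list(xgal = thr, his3 = his3_threshold)),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  n <- nrow(x$Z)
  ut <- upper.tri(x$Z)
  cat("Binary Y2H network: ", n, " proteins, ", sum(x$Z[ut]),
      " edges (of ", sum(ut), " pairs), ", sum(diag(x$Z)),
      " homodimers\n", sep = "")
  invisible(x)
}

#' Export a binary network
#'
#' Writes the symmetric 0/1 matrix as a TSV with a protein header and the
#' edge list (`protein_a`, `protein_b`, unordered pairs, diagonal included
#' for homodimers) as a second TSV.
#'
#' @param net A `binary_network`.
#' @param matrix_path,edges_path Output file paths (either may be `NULL`
#'   to skip).
#' @return Invisibly, the edge-list tibble.
#' @export
write_binary_network <- function(net, matrix_path = NULL, edges_path = NULL) {
  stopifnot(inherits(net, "binary_network"))
  ids <- rownames(net$Z)
  if (!is.null(matrix_path)) {
    tab <- as_tibble(net$Z * 1L)
    readr::write_tsv(dplyr::bind_cols(tibble(protein = ids), tab),
                     matrix_path, progress = FALSE)
  }
  idx <- which(net$Z & upper.tri(net$Z, diag = TRUE), arr.ind = TRUE)
  edges <- tibble(protein_a = ids[idx[, 1]], protein_b = ids[idx[, 2]]) %>%
    arrange(.data$protein_a, .data$protein_b)
  if (!is.null(edges_path)) readr::write_tsv(edges, edges_path, progress = FALSE)
  invisible(edges)
}

#' Density view of an OD-ratio mixture
#'
#' Histogram of the fitted sample with the weighted component densities and
#' their posterior-equality boundaries overlaid.
#'
#' @param object An `od_mixture`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.od_mixture <- function(object, ...) {
  grid <- seq(min(object$data), max(object$data), length.out = 400)
  dens <- purrr::map_dfr(seq_len(object$K), function(k) {
    tibble(component = factor(k), z = grid,
           density = object$weights[k] *
             dnorm(grid, object$means[k], sqrt(object$variances[k])))
  })
  bounds <- suppressWarnings(component_boundaries(object))
  p <- ggplot(tibble(z = object$data), aes(x = .data$z)) +
    geom_histogram(aes(y = after_stat(density)), bins = 50,
                   fill = "grey85", colour = "grey60") +
    geom_line(data = dens,
              aes(y = .data$density, colour = .data$component)) +
    labs(x = "OD ratio (HIS3)", y = "density",
         title = sprintf("%d-component Gaussian mixture on OD ratios", object$K))
  if (any(is.finite(bounds))) {
    p <- p + geom_vline(xintercept = bounds[is.finite(bounds)],
                        linetype = "dashed")
  }
  p
}
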