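#' Mid-ranks of a sample with ties
#'
#' Observed distances on an ordinal (or ratio) scale are replaced by their
#' ranks; tied values share the mean of the ranks they span,
#' \deqn{Rank(y) = 1/2 + \sum_{n < y} f_n + f_y / 2,}
#' where \eqn{f_n} is the frequency of level \eqn{n}.  Ranks therefore sum
#' to \eqn{M(M+1)/2} for a sample of size \eqn{M}.
#'
#' @param sample Numeric vector (ordinal codes or reals), all finite.
#' @return A tibble with columns `value` and `rank`; attribute `M` holds
#'   the sample size.
#' @examples
#' mid_ranks(c(0, 0, 1))  # ranks 1.5, 1.5, 3
#' @export
mid_ranks <- function(sample) {
  if (!length(sample)) abort("empty sample")
  if (!all(is.finite(sample))) abort("sample must be finite")
  u <- sort(unique(sample))
  f <- tabulate(match(sample, u), length(u))
  below <- cumsum(f) - f
  r <- (0.5 + below + f / 2)[match(sample, u)]
  structure(tibble(value = sample, rank = r), M = length(sample))
}

#' Weighting presets for combining the two reporters
#'
#' The standardized interaction distance mixes the X-Gal and HIS3 rank
#' terms with weights summing to 1.  The study's presets:
#' `XGal-only` (1, 0), `A` (0.75, 0.25), `B` (0.5, 0.5) — the balanced
#' weighting, `C` (0.25, 0.75), `HIS3-only` (0, 1).
#'
#' @return Named list of length-2 numeric vectors `c(xgal = , his3 = )`.
#' @examples
#' weight_presets()$A
#' @export
weight_presets <- function() {
  list(`XGal-only` = c(xgal = 1, his3 = 0),
       A = c(xgal = 0.75, his3 = 0.25),
       B = c(xgal = 0.5, his3 = 0.5),
       C = c(xgal = 0.25, his3 = 0.75),
       `HIS3-only` = c(xgal = 0, his3 = 1))
}

resolve_weights <- function(weights) {
  if (is.character(weights)) {
    presets <- weight_presets()
    if (!weights %in% names(presets)) {
      abort(paste0("unknown weight preset '", weights, "'; choose one of ",
                   paste(names(presets), collapse = ", ")))
    }
    weights <- presets[[weights]]
  }
  weights <- as.numeric(weights)
  if (length(weights) != 2 || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    abort("weights must be two non-negative numbers summing to 1")
  }
  setNames(weights, c("xgal", "his3"))
}

# rank matrix for one test: pools all observed ordered pairs (diagonal
# included) into a single marginal, mid-ranks ties
rank_matrix <- function(V) {
  obs <- !is.na(V)
  R <- matrix(NA_real_, nrow(V), ncol(V), dimnames = dimnames(V))
  if (any(obs)) R[obs] <- mid_ranks(V[obs])$rank
  list(R = R, M = sum(obs))
}

#' Standardized interaction-distance matrix (the valued network)
#'
#' Converts the two reporter outputs to mid-ranks over a single pooled
#' marginal per test (all ordered pairs, both orientations, diagonal
#' included) and combines the two orientations of each pair into the
#' weighted standardized distance
#' \deqn{x_{ij} = w_{XGal} \frac{Rank(y_{ij}) + Rank(y_{ji})}{1 + M_{XGal}}
#'            + w_{HIS3} \frac{Rank(z_{ij}) + Rank(z_{ji})}{1 + M_{HIS3}},}
#' where \eqn{M} is the number of observed values for the test
#' (\eqn{N^2} when nothing is missing).  A missing directed term is
#' dropped and its companion renormalized by \eqn{(1 + M)/2}; a test with
#' both directions missing drops out and the weights renormalize over the
#' available tests; an entry with both tests fully missing is `NA`.
#' With no missing values the mean of \eqn{x} over all ordered pairs is
#' exactly 1.
#'
#' @param data A `y2h_data` object.
#' @param weights Either a preset name (see [weight_presets()]) or a
#'   length-2 non-negative vector `(w_XGal, w_HIS3)` summing to 1.
#' @return An object of class `valued_network`: list with `roster`, `X`
#'   (symmetric matrix of standardized distances, protein dimnames),
#'   `weights`, and `M` (observed sample sizes per test).
#' @export
standardized_distance_matrix <- function(data, weights = "A") {
  stopifnot(inherits(data, "y2h_data"))
  w <- resolve_weights(weights)
  ids <- data$roster$protein
  n <- length(ids)
  Y <- Z <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  bi <- match(data$records$bait, ids)
  pj <- match(data$records$prey, ids)
  Y[cbind(bi, pj)] <- data$records$xgal
  Z[cbind(bi, pj)] <- data$records$his3
  ry <- rank_matrix(Y)
  rz <- rank_matrix(Z)
  term <- function(rk) {
    # per-direction normalizer (1 + M)/2; present directions averaged,
    # so both-present reduces to (R_ij + R_ji) / (1 + M)
    S <- rk$R / ((1 + rk$M) / 2)
    cnt <- (!is.na(S)) + t(!is.na(S))
    S[is.na(S)] <- 0
    tot <- S + t(S)
    out <- ifelse(cnt > 0, tot / pmax(cnt, 1), NA_real_)
    out
  }
  Tx <- term(ry)
  Th <- term(rz)
  avail_x <- !is.na(Tx)
  avail_h <- !is.na(Th)
  Tx[!avail_x] <- 0
  Th[!avail_h] <- 0
  denom <- w[["xgal"]] * avail_x + w[["his3"]] * avail_h
  X <- ifelse(denom > 0, (w[["xgal"]] * Tx + w[["his3"]] * Th) / denom,
              NA_real_)
  dimnames(X) <- list(ids, ids)
  structure(list(roster = data$roster, X = X, weights = w,
                 M = c(xgal = ry$M, his3 = rz$M)),
            class = "valued_network")
}

#' @export
print.valued_network <- function(x, ...) {
  cat("Valued Y2H network: ", nrow(x$X), " proteins, weights (X-Gal, HIS3) = (",
      x$weights[["xgal"]], ", ", x$weights[["his3"]], ")\n", sep = "")
  cat("standardized distances: mean ", format(mean(x$X, na.rm = TRUE)),
      ", range [", format(min(x$X, na.rm = TRUE)), ", ",
      format(max(x$X, na.rm = TRUE)), "]\n", sep = "")
  invisible(x)
}

#' Export a valued network
#'
#' Writes the full symmetric matrix as TSV (protein header row and column)
#' and the weights (plus observed sample sizes) as a JSON sidecar.
#'
#' @param net A `valued_network`.
#' @param matrix_path Output TSV path.
#' @param weights_path Optional JSON sidecar path.
#' @return `matrix_path`, invisibly.
#' @export
write_valued_network <- function(net, matrix_path, weights_path = NULL) {
  stopifnot(inherits(net, "valued_network"))
  ids <- rownames(net$X)
  readr::write_tsv(dplyr::bind_cols(tibble(protein = ids), as_tibble(net$X)),
                   matrix_path, progress = FALSE)
  if (!is.null(weights_path)) {
    jsonlite::write_json(list(weights = as.list(net$weights),
                              M = as.list(net$M)),
                         weights_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(matrix_path)
}

#' Separation of standardized distances by binary interaction status
#'
#' Reproduces the diagnostic used to choose the reporter weighting: the
#' empirical distributions of the standardized distances for pairs called
#' interacting vs non-interacting in the binary network.  A good weighting
#' concentrates the non-interacting mass at small distances, away from the
#' interacting mass.
#'
#' @param valued A `valued_network`.
#' @param binary A `binary_network` over the same roster.
#' @return A ggplot object (densities coloured by status).
#' @export
plot_distance_separation <- function(valued, binary) {
  stopifnot(inherits(valued, "valued_network"),
            inherits(binary, "binary_network"),
            identical(rownames(valued$X), rownames(binary$Z)))
  ut <- upper.tri(valued$X)
  df <- tibble(x = valued$X[ut],
               status = ifelse(binary$Z[ut], "interaction", "no interaction"))
  df <- df[!is.na(df$x), ]
  ggplot(df, aes(x = .data$x, fill = .data$status)) +
    geom_density(alpha = 0.5) +
    scale_fill_manual(values = c(interaction = "darkgreen",
                                 `no interaction` = "firebrick")) +
    labs(x = "standardized interaction distance", y = "density",
         fill = NULL)
}
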