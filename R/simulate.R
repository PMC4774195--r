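#' Simulation configuration
#'
#' Bundles the ground-truth parameters for the simulators.  Defaults mirror
#' the study conditions: 46 proteins in three biological groups (ARF+,
#' ARF-, Aux/IAA) with strong ARF+/Aux-IAA connectivity, a 7-level ordinal
#' X-Gal emission, and a 3-component OD-ratio mixture whose upper component
#' carries the interacting pairs.
#'
#' @param n Vertex (protein) count.
#' @param Q True cluster count.
#' @param alpha Cluster weights (sum 1).
#' @param family Edge-law family (`"gaussian"`, `"gaussian_regression"`,
#'   `"bernoulli"`).
#' @param mu Q x Q matrix of mean edge weights (valued families) —
#'   defaults to 0.9 within / 0.3 between — or `NULL`.
#' @param pi Q x Q matrix of interaction probabilities (bernoulli family
#'   and the planted Y2H network).  Defaults to the study-like pattern.
#' @param beta Regression coefficients: a `d x Q x Q` array, a Q x Q
#'   matrix (d = 1) or `NULL` (d = 0).
#' @param sigma Edge-weight noise standard deviation.
#' @param covariate_within,covariate_between Mean sequence distance for
#'   within- / between-cluster pairs.
#' @param covariate_jitter Covariate noise standard deviation.
#' @param fp_rate,fn_rate Per-orientation false-positive / false-negative
#'   rates for the Y2H emissions.
#' @param missing_rate Probability that a HIS3 value is missing.
#' @param seed Integer seed; all randomness in a simulation call flows
#'   through it (RNG state is restored afterwards).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n = 46, Q = 3, alpha = NULL,
                       family = c("gaussian", "gaussian_regression",
                                  "bernoulli"),
                       mu = NULL, pi = NULL, beta = NULL, sigma = 0.1,
                       covariate_within = 0.3, covariate_between = 0.7,
                       covariate_jitter = 0.1,
                       fp_rate = 0, fn_rate = 0, missing_rate = 0,
                       seed = NULL) {
  family <- match.arg(family)
  if (is.null(alpha)) {
    alpha <- if (Q == 3) c(6, 12, 28) / 46 else rep(1 / Q, Q)
  }
  stopifnot(length(alpha) == Q, abs(sum(alpha) - 1) < 1e-8,
            all(alpha >= 0), sigma >= 0,
            all(c(fp_rate, fn_rate, missing_rate) >= 0),
            all(c(fp_rate, fn_rate, missing_rate) <= 1))
  if (is.null(mu)) mu <- block_means(Q)
  if (is.null(pi)) pi <- default_pi(Q)
  if (!is.null(beta) && is.matrix(beta)) beta <- array(beta, c(1, Q, Q))
  structure(list(n = n, Q = Q, alpha = alpha, family = family, mu = mu,
                 pi = pi, beta = beta, sigma = sigma,
                 covariate_within = covariate_within,
                 covariate_between = covariate_between,
                 covariate_jitter = covariate_jitter,
                 fp_rate = fp_rate, fn_rate = fn_rate,
                 missing_rate = missing_rate, seed = seed),
            class = "sim_config")
}

#' Planted block mean / probability matrices
#'
#' `block_means()` gives a Q x Q matrix with `within` on the diagonal and
#' `between` off it.  `default_pi()` gives the study-like interaction
#' probabilities: for Q = 3 (ARF+, ARF-, Aux/IAA) strong ARF+/Aux-IAA
#' connectivity, moderate within-ARF+ and within-Aux/IAA, sparse
#' elsewhere; otherwise 0.7 within / 0.1 between.
#'
#' @param Q Cluster count.
#' @param within,between Diagonal / off-diagonal values.
#' @return A Q x Q symmetric matrix.
#' @export
block_means <- function(Q, within = 0.9, between = 0.3) {
  M <- matrix(between, Q, Q)
  diag(M) <- within
  M
}

#' @rdname block_means
#' @export
default_pi <- function(Q) {
  if (Q == 3) {
    matrix(c(0.6, 0.1, 0.8,
             0.1, 0.1, 0.1,
             0.8, 0.1, 0.3), 3, 3)
  } else {
    block_means(Q, within = 0.7, between = 0.1)
  }
}

sym_from_upper <- function(n, draw) {
  M <- matrix(0, n, n)
  ut <- upper.tri(M, diag = FALSE)
  M[ut] <- draw(sum(ut))
  M + t(M)
}

#' Simulate symmetric sequence-distance covariates
#'
#' Entries are Gaussian around a mean chosen by whether the pair lies
#' within or between the true clusters, clipped at 0; zero diagonal.
#'
#' @param labels Integer vector of true cluster labels.
#' @param within_mean,between_mean Pair-type means (non-negative).
#' @param jitter Noise standard deviation.
#' @param d Number of covariate matrices to draw.
#' @param names Optional names for the matrices.
#' @param seed Optional integer seed.
#' @return A `covariate_set`.
#' @export
simulate_covariates <- function(labels, within_mean = 0.3,
                                between_mean = 0.7, jitter = 0.1,
                                d = 1, names = NULL, seed = NULL) {
  stopifnot(within_mean >= 0, between_mean >= 0, jitter >= 0)
  n <- length(labels)
  ids <- if (!is.null(names(labels))) names(labels) else
    sprintf("P%02d", seq_len(n))
  same <- outer(labels, labels, "==")
  mean_mat <- ifelse(same, within_mean, between_mean)
  run <- function() {
    lapply(seq_len(d), function(k) {
      M <- sym_from_upper(n, function(m) rnorm(m))
      M <- pmax(mean_mat + jitter * M, 0)
      M <- (M + t(M)) / 2
      diag(M) <- 0
      dimnames(M) <- list(ids, ids)
      M
    })
  }
  Ys <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  names(Ys) <- if (!is.null(names)) names else paste0("Y", seq_len(d))
  align_covariates(Ys, ids)
}

#' Simulate a graph from a planted block model
#'
#' Labels are drawn from the categorical distribution with weights
#' `alpha`; covariates (when `beta` is given) from
#' [simulate_covariates()]; edges from the family's conditional law.
#' Output is symmetric with an empty (NA) diagonal and reproducible per
#' seed.
#'
#' @param cfg A [sim_config()].
#' @return List with `network` (a `valued_network`-shaped or
#'   `binary_network`-shaped object), `labels` (named integer vector) and
#'   `covariates` (a `covariate_set`, or `NULL`).
#' @export
simulate_blockmodel_graph <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  run <- function() {
    n <- cfg$n
    ids <- sprintf("P%02d", seq_len(n))
    labels <- setNames(sample.int(cfg$Q, n, replace = TRUE, prob = cfg$alpha),
                       ids)
    d <- if (is.null(cfg$beta)) 0 else dim(cfg$beta)[1]
    covariates <- if (d > 0) {
      simulate_covariates(labels, cfg$covariate_within,
                          cfg$covariate_between, cfg$covariate_jitter,
                          d = d)
    } else NULL
    roster <- tibble(protein = ids, family = NA_character_)
    if (cfg$family == "bernoulli") {
      P <- cfg$pi[labels, labels]
      Z <- matrix(FALSE, n, n)
      ut <- upper.tri(Z)
      Z[ut] <- runif(sum(ut)) < P[ut]
      Z <- Z | t(Z)
      dimnames(Z) <- list(ids, ids)
      net <- structure(list(roster = roster, Z = Z,
                            configuration = NULL, thresholds = NULL),
                       class = "binary_network")
    } else {
      M <- cfg$mu[labels, labels]
      if (d > 0) {
        for (k in seq_len(d)) {
          B <- matrix(cfg$beta[k, , ][cbind(rep(labels, n),
                                            rep(labels, each = n))],
                      n, n)
          M <- M + B * covariates$matrices[[k]]
        }
      }
      X <- M + sym_from_upper(n, function(m) rnorm(m, sd = cfg$sigma))
      X <- (X + t(X)) / 2
      diag(X) <- NA_real_
      dimnames(X) <- list(ids, ids)
      net <- structure(list(roster = roster, X = X,
                            weights = NULL, M = NULL),
                       class = "valued_network")
    }
    list(network = net, labels = labels, covariates = covariates)
  }
  if (is.null(cfg$seed)) run() else withr::with_seed(cfg$seed, run())
}

# emission distributions for the Y2H simulator; supports on the correct
# side of the default thresholds so the zero-noise round trip is exact
xgal_emission <- function(interacting) {
  if (interacting) list(codes = 4:6, prob = c(0.35, 0.4, 0.25))
  else list(codes = 0:3, prob = c(0.5, 0.2, 0.15, 0.15))
}

draw_his3 <- function(m, interacting) {
  # 3-component OD-ratio mixture: two lower components (non-growing) and
  # an upper component enriched for interacting pairs
  if (interacting) {
    repeat_draw(m, function(k) rnorm(k, 1.0, 0.2), function(v) v >= 0.45)
  } else {
    comp <- sample.int(2, m, replace = TRUE, prob = c(0.7, 0.3))
    v <- numeric(m)
    v[comp == 1] <- repeat_draw(sum(comp == 1),
                                function(k) rnorm(k, 0.12, 0.03),
                                function(x) x >= 0 & x < 0.45)
    v[comp == 2] <- repeat_draw(sum(comp == 2),
                                function(k) rnorm(k, 0.3, 0.06),
                                function(x) x >= 0 & x < 0.45)
    v
  }
}

repeat_draw <- function(m, rfun, ok) {
  if (m == 0) return(numeric(0))
  v <- rfun(m)
  bad <- !ok(v)
  while (any(bad)) {
    v[bad] <- rfun(sum(bad))
    bad <- !ok(v)
  }
  v
}

#' Simulate a two-way two-reporter Y2H dataset with planted structure
#'
#' Draws true cluster labels, a planted binary interaction network from
#' the cluster-pair probabilities `cfg$pi`, and then per-orientation test
#' outputs: X-Gal marks from interaction-conditional ordinal
#' distributions (interacting pairs at `'+'` or above) and HIS3 OD ratios
#' from a 3-component Gaussian mixture whose upper component carries the
#' interacting pairs.  Status flips (`fp_rate`, `fn_rate`) are applied
#' independently per orientation before emission; HIS3 values go missing
#' with `missing_rate`.  With all rates at 0,
#' [build_binary_network()] recovers the planted network exactly.
#'
#' @param cfg A [sim_config()].
#' @return List with `data` (a `y2h_data`), `truth` (symmetric logical
#'   matrix of planted interactions, homodimers on the diagonal) and
#'   `labels`.
#' @export
simulate_y2h_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  run <- function() {
    n <- cfg$n
    ids <- sprintf("P%02d", seq_len(n))
    labels <- setNames(sample.int(cfg$Q, n, replace = TRUE, prob = cfg$alpha),
                       ids)
    P <- cfg$pi[labels, labels]
    truth <- matrix(FALSE, n, n, dimnames = list(ids, ids))
    ut <- upper.tri(truth, diag = TRUE)
    truth[ut] <- runif(sum(ut)) < P[ut]
    truth[lower.tri(truth)] <- t(truth)[lower.tri(truth)]
    # all n^2 ordered pairs: both orientations off-diagonal, homodimers once
    ord <- which(matrix(TRUE, n, n), arr.ind = TRUE)
    status <- truth[ord]
    flip_to_pos <- runif(nrow(ord)) < cfg$fp_rate
    flip_to_neg <- runif(nrow(ord)) < cfg$fn_rate
    status <- ifelse(status, !flip_to_neg, flip_to_pos)
    xgal <- integer(nrow(ord))
    for (s in c(TRUE, FALSE)) {
      em <- xgal_emission(s)
      idx <- which(status == s)
      xgal[idx] <- sample(em$codes, length(idx), replace = TRUE,
                          prob = em$prob)
    }
    his3 <- numeric(nrow(ord))
    his3[status] <- draw_his3(sum(status), TRUE)
    his3[!status] <- draw_his3(sum(!status), FALSE)
    his3[runif(nrow(ord)) < cfg$missing_rate] <- NA_real_
    records <- tibble(bait = ids[ord[, 1]], prey = ids[ord[, 2]],
                      xgal = xgal, his3 = his3)
    data <- new_y2h_data(tibble(protein = ids, family = NA_character_),
                         records)
    list(data = data, truth = truth, labels = labels)
  }
  if (is.null(cfg$seed)) run() else withr::with_seed(cfg$seed, run())
}
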