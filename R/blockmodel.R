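#' @name blockmodel
#' @title Mixture models for random graphs (stochastic block models)
#'
#' @description
#' The package's statistical core clusters the vertices of an undirected
#' graph by their connectivity profiles.  Every vertex belongs to one of
#' `Q` latent clusters with prior weights \eqn{\alpha_q}; conditionally on
#' the memberships, edges are independent with a law that depends only on
#' the endpoint clusters:
#' \describe{
#'   \item{bernoulli}{binary adjacency,
#'     \eqn{Z_{ij} \sim B(\pi_{q\ell})};}
#'   \item{gaussian}{valued adjacency,
#'     \eqn{X_{ij} \sim N(\mu_{q\ell}, \sigma^2)};}
#'   \item{gaussian_regression}{valued adjacency with edge covariates
#'     (sequence dissimilarities),
#'     \eqn{X_{ij} \sim N(\mu_{q\ell} + Y_{ij}^\top b_{q\ell}, \sigma^2)}.}
#' }
#' The variance \eqn{\sigma^2} is a single scalar shared by all cluster
#' pairs.  The diagonal is excluded: all edge sums run over unordered
#' pairs \eqn{i < j}.  Estimation is by variational EM: the E-step
#' approximates the membership posterior \eqn{\tau_{iq}} with the
#' fixed-point formula
#' \eqn{\tau_{iq} \propto \alpha_q \prod_{j \ne i} \prod_\ell
#' (\phi_{ij}^{q\ell})^{\tau_{j\ell}}}, and each EM step increases a lower
#' bound \eqn{J} of the observed-data log-likelihood.  The number of
#' clusters is chosen with the ICL criterion (see [icl_score()]).
NULL

as_adjacency <- function(x) {
  if (inherits(x, "valued_network")) A <- x$X
  else if (inherits(x, "binary_network")) A <- x$Z * 1
  else if (is.matrix(x)) A <- x * 1
  else abort("x must be a valued_network, binary_network or symmetric matrix")
  if (nrow(A) != ncol(A)) abort("adjacency must be square")
  offd <- A[upper.tri(A)] - t(A)[upper.tri(A)]
  if (any(is.na(offd)) ||
      any(is.na(A[upper.tri(A)]))) abort("off-diagonal adjacency entries must be observed")
  if (max(abs(offd)) > 1e-8) abort("adjacency must be symmetric")
  A <- (A + t(A)) / 2
  if (is.null(rownames(A))) {
    dimnames(A) <- list(paste0("V", seq_len(nrow(A))),
                        paste0("V", seq_len(nrow(A))))
  }
  A
}

as_covariate_list <- function(covariates, A) {
  if (is.null(covariates)) return(list())
  Ys <- if (inherits(covariates, "covariate_set")) covariates$matrices
        else if (is.matrix(covariates)) list(Y = covariates)
        else covariates
  lapply(Ys, function(Y) {
    if (!all(dim(Y) == dim(A))) abort("covariate dimensions must match adjacency")
    (Y + t(Y)) / 2
  })
}

# n x n x Q x Q array of log edge densities, diagonal zeroed so matrix
# products over j automatically exclude j = i
logphi_array <- function(A, Ylist, params) {
  n <- nrow(A)
  Q <- length(params$alpha)
  L <- array(0, c(n, n, Q, Q))
  for (q in seq_len(Q)) for (l in seq_len(Q)) {
    if (params$family == "bernoulli") {
      p <- params$pi[q, l]
      M <- A * log(p) + (1 - A) * log(1 - p)
    } else {
      mean_ql <- matrix(params$mu[q, l], n, n)
      if (length(Ylist)) {
        for (k in seq_along(Ylist)) {
          mean_ql <- mean_ql + params$beta[k, q, l] * Ylist[[k]]
        }
      }
      M <- dnorm(A, mean_ql, sqrt(params$sigma2), log = TRUE)
    }
    diag(M) <- 0
    if (any(!is.finite(M))) {
      bad <- which(!is.finite(M), arr.ind = TRUE)[1, ]
      abort(sprintf("non-finite log-density at pair (%d, %d), clusters (%d, %d)",
                    bad[1], bad[2], q, l))
    }
    L[, , q, l] <- M
  }
  L
}

e_step_core <- function(L, log_alpha, tau, max_sweeps = 100, tol = 1e-6) {
  n <- dim(L)[1]
  Q <- length(log_alpha)
  prev_delta <- Inf
  for (sweep in seq_len(max_sweeps)) {
    S <- matrix(0, n, Q)
    for (q in seq_len(Q)) {
      acc <- numeric(n)
      for (l in seq_len(Q)) acc <- acc + L[, , q, l] %*% tau[, l]
      S[, q] <- acc
    }
    logt <- sweep(S, 2, log_alpha, "+")
    logt <- logt - apply(logt, 1, max)
    tau_new <- exp(logt)
    tau_new <- tau_new / rowSums(tau_new)
    delta <- max(abs(tau_new - tau))
    if (delta > prev_delta) tau_new <- (tau_new + tau) / 2  # damp oscillation
    tau <- tau_new
    if (delta < tol) break
    prev_delta <- delta
  }
  tau
}

#' Variational E-step: fixed-point membership posteriors
#'
#' Iterates the mean-field fixed point
#' \eqn{\tau_{iq} \propto \alpha_q \prod_{j \ne i} \prod_\ell
#' (\phi_{ij}^{q\ell})^{\tau_{j\ell}}} in the log domain, renormalizing
#' each row per sweep, until the largest change is below `tol` or
#' `max_sweeps` sweeps.  A damping factor of 1/2 is applied when the
#' update starts oscillating.
#'
#' @param x Adjacency: a `valued_network`, `binary_network` or symmetric
#'   matrix (diagonal ignored).
#' @param covariates Optional `covariate_set` (or list of matrices) for
#'   the regression family.
#' @param params Parameter list as returned by [m_step()].
#' @param tau N x Q matrix of initial posteriors (rows summing to 1).
#' @param max_sweeps,tol Fixed-point controls.
#' @return N x Q matrix of posteriors, rows summing to 1.
#' @export
e_step <- function(x, covariates = NULL, params, tau,
                   max_sweeps = 100, tol = 1e-6) {
  A <- as_adjacency(x)
  Ylist <- as_covariate_list(covariates, A)
  L <- logphi_array(A, Ylist, params)
  out <- e_step_core(L, log(pmax(params$alpha, 1e-300)), tau,
                     max_sweeps, tol)
  dimnames(out) <- list(rownames(A), NULL)
  out
}

m_step_core <- function(A, Ylist, tau, family, ridge = 1e-8) {
  n <- nrow(A)
  Q <- ncol(tau)
  d <- length(Ylist)
  ut <- which(upper.tri(A), arr.ind = TRUE)
  ii <- ut[, 1]; jj <- ut[, 2]
  xv <- A[ut]
  alpha <- colMeans(tau)
  alpha <- pmax(alpha, 1e-12); alpha <- alpha / sum(alpha)
  if (family == "bernoulli") {
    pi_ <- matrix(NA_real_, Q, Q)
    for (q in seq_len(Q)) for (l in q:Q) {
      w <- tau[ii, q] * tau[jj, l]
      if (l > q) w <- w + tau[ii, l] * tau[jj, q]
      sw <- sum(w)
      p <- if (sw > 0) sum(w * xv) / sw else 0.5
      pi_[q, l] <- pi_[l, q] <- min(max(p, 1e-10), 1 - 1e-10)
    }
    return(list(family = family, alpha = alpha, pi = pi_))
  }
  Xd <- matrix(1, length(xv), 1)
  if (d > 0) Xd <- cbind(Xd, do.call(cbind, lapply(Ylist, function(Y) Y[ut])))
  p <- d + 1
  mu <- matrix(NA_real_, Q, Q)
  beta <- if (d > 0) array(NA_real_, c(d, Q, Q)) else NULL
  SS <- 0; W <- 0
  low_weight <- FALSE
  for (q in seq_len(Q)) for (l in q:Q) {
    w <- tau[ii, q] * tau[jj, l]
    if (l > q) w <- w + tau[ii, l] * tau[jj, q]
    sw <- sum(w)
    if (sw < p * 1e-8) low_weight <- TRUE
    XtWX <- crossprod(Xd, w * Xd) + diag(ridge, p)
    coef <- drop(solve(XtWX, crossprod(Xd, w * xv)))
    mu[q, l] <- mu[l, q] <- coef[1]
    if (d > 0) beta[, q, l] <- beta[, l, q] <- coef[-1]
    r <- xv - drop(Xd %*% coef)
    SS <- SS + sum(w * r^2)
    W <- W + sw
  }
  list(family = family, alpha = alpha, mu = mu, beta = beta,
       sigma2 = max(SS / W, 1e-12), low_weight = low_weight)
}

#' M-step: weighted maximum-likelihood parameter updates
#'
#' Given posteriors `tau`, updates the cluster weights
#' (\eqn{\alpha_q = \sum_i \tau_{iq} / n}) and, for every unordered
#' cluster pair, the \eqn{\tau_{iq}\tau_{j\ell}}-weighted least-squares
#' regression of edge weights on covariates over pairs \eqn{i < j}
#' (intercept only for the gaussian family).  The variance is pooled over
#' all pairs and cluster pairs.  For the bernoulli family,
#' \eqn{\pi_{q\ell}} is the weighted mean of the binary edges.  A cluster
#' pair with (near-)zero total weight is stabilized with a small ridge.
#'
#' @inheritParams e_step
#' @param family One of `"bernoulli"`, `"gaussian"`,
#'   `"gaussian_regression"`.
#' @return Parameter list: `family`, `alpha`, and `pi` (bernoulli) or
#'   `mu`, `beta` (`d x Q x Q` array or `NULL`), `sigma2`.
#' @export
m_step <- function(x, covariates = NULL, tau,
                   family = c("gaussian", "gaussian_regression", "bernoulli")) {
  family <- match.arg(family)
  A <- as_adjacency(x)
  Ylist <- as_covariate_list(covariates, A)
  if (family == "bernoulli" && length(Ylist)) {
    abort("the bernoulli family does not take covariates")
  }
  if (family == "gaussian") Ylist <- list()
  if (max(abs(rowSums(tau) - 1)) > 1e-6) abort("tau rows must sum to 1")
  m_step_core(A, Ylist, tau, family)
}

lower_bound_core <- function(A, Ylist, params, tau) {
  L <- logphi_array(A, Ylist, params)
  Q <- length(params$alpha)
  J1 <- sum(sweep(tau, 2, log(pmax(params$alpha, 1e-300)), "*"))
  J2 <- 0
  for (q in seq_len(Q)) for (l in seq_len(Q)) {
    J2 <- J2 + sum(tau[, q] * (L[, , q, l] %*% tau[, l]))
  }
  tl <- tau * log(tau)
  tl[tau == 0] <- 0
  J1 + J2 / 2 - sum(tl)
}

#' Variational lower bound of the log-likelihood
#'
#' \deqn{J = \sum_{iq} \tau_{iq} \log \alpha_q
#'   + \sum_{i<j} \sum_{q\ell} \tau_{iq}\tau_{j\ell} \log \phi_{ij}^{q\ell}
#'   - \sum_{iq} \tau_{iq} \log \tau_{iq},}
#' with \eqn{0 \log 0 = 0}.  For hard (0/1) posteriors this is the
#' complete-data log-likelihood of the partition.
#'
#' @inheritParams e_step
#' @return The scalar bound `J`.
#' @export
lower_bound <- function(x, covariates = NULL, params, tau) {
  A <- as_adjacency(x)
  Ylist <- as_covariate_list(covariates, A)
  lower_bound_core(A, Ylist, params, tau)
}

#' Number of independent parameters of a block model
#'
#' \eqn{(Q-1)} membership probabilities plus \eqn{Q^2} constants and
#' \eqn{dQ^2} regression coefficients: \eqn{(Q-1) + Q^2(d+1)}.
#'
#' @param Q Cluster count.
#' @param d Covariate count (0 for bernoulli/gaussian).
#' @return Integer parameter count.
#' @examples
#' blockmodel_param_count(4, 1)  # 35
#' @export
blockmodel_param_count <- function(Q, d = 0) {
  (Q - 1) + Q^2 * (d + 1)
}

#' Integrated completed likelihood (ICL) criterion
#'
#' A clustering-tailored penalized criterion with a double penalty: the
#' \eqn{Q-1} membership probabilities are penalized against the \eqn{n}
#' vertices and the \eqn{Q^2(d+1)} edge parameters against the
#' \eqn{n(n-1)/2} edges:
#' \deqn{ICL = J - \frac{Q-1}{2}\log n
#'   - \frac{Q^2(d+1)}{2}\log\frac{n(n-1)}{2}.}
#'
#' @param J Variational lower bound at convergence.
#' @param n Vertex count (at least 2).
#' @param Q Cluster count.
#' @param d Covariate count.
#' @return The ICL score.
#' @seealso [jeffreys_icl_threshold()] for the rule-of-thumb gap.
#' @export
icl_score <- function(J, n, Q, d = 0) {
  stopifnot(n >= 2)
  J - (Q - 1) / 2 * log(n) - Q^2 * (d + 1) / 2 * log(n * (n - 1) / 2)
}

#' Jeffreys' rule-of-thumb ICL gap
#'
#' A difference of ICL of at least \eqn{\log(100) = 4.6} is needed to deem
#' the model with the higher ICL substantially better.
#'
#' @return `log(100)`.
#' @export
jeffreys_icl_threshold <- function() log(100)

init_tau <- function(A, Q, kind = c("ward", "random"), soft = 0.95) {
  n <- nrow(A)
  kind <- match.arg(kind)
  if (Q == 1) return(matrix(1, n, 1))
  if (kind == "ward") {
    A0 <- A; diag(A0) <- 0
    cl <- cutree(hclust(dist(A0), method = "ward.D2"), Q)
  } else {
    cl <- sample.int(Q, n, replace = TRUE)
  }
  tau <- matrix((1 - soft) / (Q - 1), n, Q)
  tau[cbind(seq_len(n), cl)] <- soft
  # random starts additionally jittered to escape symmetric fixed points
  if (kind == "random") {
    tau <- tau * matrix(stats::rexp(n * Q), n, Q)
    tau <- tau / rowSums(tau)
  }
  tau
}

fit_one_start <- function(A, Ylist, family, tau, max_iter = 500,
                          tol = 1e-8) {
  J_old <- -Inf
  params <- NULL
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    params <- m_step_core(A, Ylist, tau, family)
    L <- logphi_array(A, Ylist, params)
    tau <- e_step_core(L, log(pmax(params$alpha, 1e-300)), tau)
    J <- lower_bound_core(A, Ylist, params, tau)
    if (is.finite(J_old) && abs(J - J_old) < tol * (abs(J_old) + 1)) {
      converged <- TRUE
      J_old <- J
      break
    }
    J_old <- J
  }
  list(params = params, tau = tau, J = J_old, converged = converged,
       n_iter = iter)
}

#' Fit a block model by variational EM
#'
#' Alternates [m_step()] and [e_step()] until the relative change of the
#' lower bound `J` falls below `1e-8` (or 500 iterations), from several
#' initializations: one hierarchical (Ward clustering of the adjacency
#' rows) plus `n_restarts - 1` random soft starts.  The restart with the
#' best final `J` is returned.  Deterministic given `seed`.
#'
#' @inheritParams m_step
#' @param Q Number of clusters (`n >= Q`).
#' @param n_restarts Total number of initializations (default 5).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return An object of class `blockmodel_fit`: list with `family`, `Q`,
#'   `d`, `n`, `alpha`, `pi` or (`mu`, `beta`, `sigma2`), `tau` (rows are
#'   proteins), `labels` (MAP assignment), `J`, `icl`, `n_params`,
#'   `converged`, `n_iter`, `proteins`.
#' @examples
#' sim <- simulate_blockmodel_graph(sim_config(n = 30, Q = 2, seed = 1))
#' fit <- fit_blockmodel(sim$network, family = "gaussian", Q = 2, seed = 1)
#' glance(fit)
#' @export
fit_blockmodel <- function(x, covariates = NULL,
                           family = c("gaussian", "gaussian_regression",
                                      "bernoulli"),
                           Q, n_restarts = 5, seed = NULL) {
  family <- match.arg(family)
  A <- as_adjacency(x)
  Ylist <- as_covariate_list(covariates, A)
  if (family == "bernoulli" && length(Ylist)) {
    abort("the bernoulli family does not take covariates")
  }
  if (family == "gaussian") Ylist <- list()
  if (family == "gaussian_regression" && !length(Ylist)) {
    abort("gaussian_regression requires at least one covariate matrix")
  }
  n <- nrow(A)
  if (n < Q) abort("need n >= Q")
  runs <- function() {
    starts <- c(list(init_tau(A, Q, "ward")),
                purrr::map(seq_len(max(n_restarts - 1, 0)),
                           ~init_tau(A, Q, "random")))
    purrr::map(starts, function(tau0) {
      tryCatch(fit_one_start(A, Ylist, family, tau0),
               error = function(e) NULL)
    })
  }
  fits <- if (is.null(seed)) runs() else withr::with_seed(seed, runs())
  fits <- purrr::compact(fits)
  if (!length(fits)) abort("all EM restarts failed")
  best <- fits[[which.max(purrr::map_dbl(fits, "J"))]]
  d <- length(Ylist)
  tau <- best$tau
  dimnames(tau) <- list(rownames(A), NULL)
  out <- list(family = family, Q = Q, d = d, n = n,
              alpha = best$params$alpha,
              pi = best$params$pi,
              mu = best$params$mu,
              beta = best$params$beta,
              sigma2 = best$params$sigma2,
              tau = tau,
              labels = setNames(max.col(tau), rownames(A)),
              J = best$J,
              icl = icl_score(best$J, n, Q, d),
              n_params = blockmodel_param_count(Q, d),
              converged = best$converged,
              n_iter = best$n_iter,
              proteins = rownames(A),
              seed = seed)
  class(out) <- "blockmodel_fit"
  out
}

#' @export
print.blockmodel_fit <- function(x, ...) {
  cat("Block model fit (", x$family, "): n = ", x$n, ", Q = ", x$Q,
      if (x$d > 0) paste0(", d = ", x$d) else "", "\n", sep = "")
  cat("J = ", format(x$J), ", ICL = ", format(x$icl),
      " (", x$n_params, " parameters)\n", sep = "")
  cat("cluster sizes:", paste(tabulate(x$labels, x$Q), collapse = ", "), "\n")
  invisible(x)
}

#' Scan cluster counts and compare models by ICL
#'
#' Fits the model for every `Q` in `Q_range`, reports the ICL, and turns
#' the ICL values into posterior model probabilities by exp-normalization
#' (softmax) over the scanned models.  A fit failure for one `Q` is
#' reported and the scan continues.
#'
#' @inheritParams fit_blockmodel
#' @param Q_range Integer vector of cluster counts (e.g. `1:7`).
#' @return A tibble of class `blockmodel_scan` with columns `family`, `Q`,
#'   `J`, `icl`, `n_params`, `converged`, `post_prob`, `best` and a `fit`
#'   list-column; attribute `jeffreys_substantial` says whether the best
#'   model beats the runner-up by at least `log(100)`.
#' @export
model_scan <- function(x, covariates = NULL,
                       family = c("gaussian", "gaussian_regression",
                                  "bernoulli"),
                       Q_range = 1:7, n_restarts = 5, seed = NULL) {
  family <- match.arg(family)
  if (!length(Q_range)) abort("Q_range must be non-empty")
  rows <- purrr::map(Q_range, function(Q) {
    fit <- tryCatch(
      fit_blockmodel(x, covariates, family, Q, n_restarts,
                     seed = if (is.null(seed)) NULL else seed + Q),
      error = function(e) {
        warn(sprintf("fit failed for Q = %d: %s", Q, conditionMessage(e)))
        NULL
      })
    tibble(family = family, Q = as.integer(Q),
           J = if (is.null(fit)) NA_real_ else fit$J,
           icl = if (is.null(fit)) NA_real_ else fit$icl,
           n_params = blockmodel_param_count(Q, if (is.null(fit)) 0 else fit$d),
           converged = if (is.null(fit)) NA else fit$converged,
           fit = list(fit))
  })
  tab <- bind_rows(rows)
  w <- exp(tab$icl - max(tab$icl, na.rm = TRUE))
  w[is.na(w)] <- 0
  tab$post_prob <- w / sum(w)
  tab$best <- !is.na(tab$icl) & tab$icl == max(tab$icl, na.rm = TRUE)
  icl_sorted <- sort(tab$icl[!is.na(tab$icl)], decreasing = TRUE)
  attr(tab, "jeffreys_substantial") <-
    length(icl_sorted) >= 2 &&
    (icl_sorted[1] - icl_sorted[2]) >= jeffreys_icl_threshold()
  class(tab) <- c("blockmodel_scan", class(tab))
  tab
}

#' Write a model-scan table
#'
#' TSV mirroring the reported scan layout: family, Q, ICL and posterior
#' model probability.
#'
#' @param scan A `blockmodel_scan`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(scan, path) {
  readr::write_tsv(select(as_tibble(scan), -"fit"), path, progress = FALSE)
  invisible(path)
}

#' Bootstrap reporting intervals for regression coefficients
#'
#' The study reports only coefficients "significantly different from
#' zero"; no test is specified there, so this package's own convention is
#' a nonparametric bootstrap over vertices: holding the MAP cluster labels
#' fixed, vertices are resampled with replacement and the per-cluster-pair
#' weighted least squares is recomputed; a coefficient is flagged when its
#' percentile interval excludes 0.
#'
#' @param fit A `blockmodel_fit` from the regression family.
#' @inheritParams fit_blockmodel
#' @param n_boot Number of resamples (default 200).
#' @param level Interval coverage (default 0.95).
#' @return A tibble with `term`, `q`, `l`, `estimate`, `lower`, `upper`,
#'   `significant`.
#' @export
coefficient_significance <- function(fit, x, covariates, n_boot = 200,
                                     level = 0.95, seed = NULL) {
  stopifnot(inherits(fit, "blockmodel_fit"), fit$d >= 1)
  A <- as_adjacency(x)
  Ylist <- as_covariate_list(covariates, A)
  n <- fit$n; Q <- fit$Q; d <- fit$d
  z <- fit$labels
  hard_beta <- function(idx) {
    Ab <- A[idx, idx]
    zb <- z[idx]
    if (length(unique(zb)) < Q) return(NULL)
    keep <- outer(idx, idx, "!=")  # drop duplicated-vertex self pairs
    ut <- which(upper.tri(Ab) & keep, arr.ind = TRUE)
    if (!nrow(ut)) return(NULL)
    xv <- Ab[ut]
    Xd <- cbind(1, do.call(cbind, lapply(Ylist, function(Y) Y[idx, idx][ut])))
    out <- array(NA_real_, c(d, Q, Q))
    for (q in seq_len(Q)) for (l in q:Q) {
      sel <- (zb[ut[, 1]] == q & zb[ut[, 2]] == l) |
             (zb[ut[, 1]] == l & zb[ut[, 2]] == q)
      if (sum(sel) < d + 2) return(NULL)
      coef <- drop(solve(crossprod(Xd[sel, , drop = FALSE]) + diag(1e-8, d + 1),
                         crossprod(Xd[sel, , drop = FALSE], xv[sel])))
      out[, q, l] <- out[, l, q] <- coef[-1]
    }
    out
  }
  boot <- function() {
    res <- vector("list", n_boot)
    b <- 0
    tries <- 0
    while (b < n_boot && tries < n_boot * 20) {
      tries <- tries + 1
      bb <- hard_beta(sample.int(n, n, replace = TRUE))
      if (!is.null(bb)) { b <- b + 1; res[[b]] <- bb }
    }
    res[seq_len(b)]
  }
  draws <- if (is.null(seed)) boot() else withr::with_seed(seed, boot())
  if (!length(draws)) abort("all bootstrap resamples degenerate")
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  terms <- if (!is.null(names(Ylist))) names(Ylist) else paste0("Y", seq_len(d))
  purrr::map_dfr(seq_len(d), function(k) {
    purrr::map_dfr(seq_len(Q), function(q) {
      purrr::map_dfr(q:Q, function(l) {
        vals <- purrr::map_dbl(draws, ~.x[k, q, l])
        ci <- stats::quantile(vals, probs, names = FALSE)
        tibble(term = terms[k], q = q, l = l,
               estimate = fit$beta[k, q, l],
               lower = ci[1], upper = ci[2],
               significant = ci[1] > 0 | ci[2] < 0)
      })
    })
  })
}
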