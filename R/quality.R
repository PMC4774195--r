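#' Connectivity-profile distances between proteins
#'
#' The distance between two proteins is the mean absolute difference of
#' their adjacency rows (their connectivity profiles),
#' \eqn{D(i,j) = \sum_k |x_{ik} - x_{jk}| / N}.  For a binary adjacency
#' matrix this is the Sokal-Michener distance: the proportion of
#' mismatching columns.  The sum runs over all `N` columns; by the
#' package's convention the diagonal is set to 0 first (homodimer entries
#' are outside the model) and missing entries count as 0.
#'
#' @param x A `valued_network`, `binary_network` or symmetric matrix.
#' @return An N x N symmetric distance matrix (a pseudo-metric).
#' @export
profile_distance_matrix <- function(x) {
  A <- if (inherits(x, "valued_network")) x$X
       else if (inherits(x, "binary_network")) x$Z * 1
       else x * 1
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  A[is.na(A)] <- 0
  diag(A) <- 0
  as.matrix(dist(A, method = "manhattan")) / nrow(A)
}

#' Protein-to-cluster profile distances
#'
#' Soft-assignment distance between protein `i` and cluster `q`:
#' \deqn{D(i,q) = \frac{\sum_{j \ne i} \tau_{jq} \sum_k |x_{ik} - x_{jk}|}
#'   {\{\sum_{j \ne i} \tau_{jq}\} N}.}
#' With hard (0/1) posteriors this reduces to averaging over the
#' \eqn{n_q - 1} other members (for `i` in `q`) or the \eqn{n_q} members
#' (for `i` outside `q`).  A cluster with zero soft mass for some protein
#' gives `NA` and is flagged via the `"flagged"` attribute.
#'
#' @param D An N x N profile distance matrix from
#'   [profile_distance_matrix()].
#' @param tau N x Q posterior matrix (rows summing to 1; a hard partition
#'   may be supplied as a 0/1 matrix).
#' @return N x Q matrix of distances `D(i, q)`.
#' @export
protein_cluster_distances <- function(D, tau) {
  stopifnot(nrow(D) == nrow(tau))
  # left-to-right accumulation over j (rowSums) so that hard 0/1 posteriors
  # reproduce the partition formulas bit-for-bit; D_ii = 0, so j = i drops out
  num <- vapply(seq_len(ncol(tau)),
                function(q) rowSums(sweep(D, 2, tau[, q], "*")),
                numeric(nrow(D)))
  den <- matrix(colSums(tau), nrow(tau), ncol(tau), byrow = TRUE) - tau
  out <- ifelse(den > 1e-12, num / den, NA_real_)
  rownames(out) <- rownames(D)
  attr(out, "flagged") <- which(is.na(out), arr.ind = TRUE)
  out
}

hard_tau <- function(labels, Q = max(labels)) {
  tau <- matrix(0, length(labels), Q)
  tau[cbind(seq_along(labels), labels)] <- 1
  tau
}

#' Cluster-scale distance diagnostics
#'
#' Within- and between-cluster summaries of the connectivity-profile
#' distances:
#' \eqn{D(q,q)} averages over within-cluster unordered pairs (denominator
#' \eqn{n_q(n_q-1)}), \eqn{D(q,\ell)} over cross pairs (denominator
#' \eqn{n_q n_\ell}), and \eqn{D_{between}(q)} over pairs with exactly one
#' endpoint in `q` (denominator \eqn{n_q(N - n_q)}); all profile sums are
#' divided by `N`.  Clusters are "strongly defined" when the diagonal of
#' \eqn{D(q,\ell)} is smaller than its off-diagonal entries.  Soft
#' posteriors generalize the formulas with \eqn{\tau}-weights and reduce
#' to them exactly for 0/1 posteriors.  Singleton (or zero-mass) clusters
#' have an undefined within distance (`NA`, flagged).
#'
#' @inheritParams protein_cluster_distances
#' @return An object of class `cluster_diagnostics`: list with
#'   `protein_cluster` (N x Q), `cluster_cluster` (Q x Q symmetric),
#'   `within` (length Q), `between` (length Q), `n_q` (MAP cluster
#'   sizes), `flagged` (clusters with undefined within distance).
#' @export
cluster_distance_matrix <- function(D, tau) {
  stopifnot(nrow(D) == nrow(tau))
  Q <- ncol(tau)
  cc <- matrix(NA_real_, Q, Q)
  for (q in seq_len(Q)) for (l in q:Q) {
    num <- drop(crossprod(tau[, q], D %*% tau[, l]))
    if (l == q) {
      den <- sum(tau[, q])^2 - sum(tau[, q]^2)
    } else {
      num <- num  # i = j term vanishes since D_ii = 0
      den <- sum(tau[, q]) * sum(tau[, l]) - sum(tau[, q] * tau[, l])
    }
    cc[q, l] <- cc[l, q] <- if (den > 1e-12) num / den else NA_real_
  }
  between <- vapply(seq_len(Q), function(q) {
    w2 <- 1 - tau[, q]
    num <- drop(crossprod(tau[, q], D %*% w2))
    den <- sum(tau[, q]) * sum(w2) - sum(tau[, q] * w2)
    if (den > 1e-12) num / den else NA_real_
  }, numeric(1))
  n_q <- tabulate(max.col(tau), Q)
  structure(list(protein_cluster = protein_cluster_distances(D, tau),
                 cluster_cluster = cc,
                 within = diag(cc),
                 between = between,
                 n_q = n_q,
                 flagged = which(is.na(diag(cc)))),
            class = "cluster_diagnostics")
}

#' @export
print.cluster_diagnostics <- function(x, ...) {
  cat("Cluster diagnostics over", length(x$n_q), "clusters (sizes:",
      paste(x$n_q, collapse = ", "), ")\n")
  cat("D(q, l):\n")
  print(round(x$cluster_cluster, 4))
  invisible(x)
}

#' Cluster membership table sorted by centrality
#'
#' One row per protein with its cluster and its distance to that cluster,
#' members sorted most-central first within each cluster, mirroring the
#' study's cluster-composition tables.
#'
#' @param fit A `blockmodel_fit`.
#' @param x The network the fit was computed on (for profile distances).
#' @return A tibble `cluster`, `protein`, `D_iq`.
#' @export
cluster_table <- function(fit, x) {
  D <- profile_distance_matrix(x)
  Diq <- protein_cluster_distances(D, fit$tau)
  tibble(protein = fit$proteins,
         cluster = unname(fit$labels),
         D_iq = Diq[cbind(seq_len(fit$n), fit$labels)]) %>%
    arrange(.data$cluster, .data$D_iq)
}

match_count <- function(conf) {
  # exact optimal injective matching by enumeration (small Q)
  nr <- nrow(conf); nc <- ncol(conf)
  if (nr > nc) return(match_count(t(conf)))
  best <- 0
  rec <- function(row, used, acc) {
    if (row > nr) { best <<- max(best, acc); return() }
    for (col in which(!used)) {
      used[col] <- TRUE
      rec(row + 1, used, acc + conf[row, col])
      used[col] <- FALSE
    }
  }
  rec(1, rep(FALSE, nc), 0)
  best
}

#' Agreement between two partitions by optimal label matching
#'
#' Counts the maximum number of proteins on which two partitions of the
#' same roster agree, over all injective matchings of the cluster labels
#' (an optimal assignment on the confusion matrix; cluster counts may
#' differ).
#'
#' @param p1,p2 Cluster label vectors over the same roster (named vectors
#'   are matched by name), or `blockmodel_fit` objects.
#' @return A tibble with `percent` (rounded to integer), `count`, `n`.
#' @examples
#' partition_match(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 100% despite relabel
#' @export
partition_match <- function(p1, p2) {
  lab <- function(p) if (inherits(p, "blockmodel_fit")) p$labels else p
  p1 <- lab(p1); p2 <- lab(p2)
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!setequal(names(p1), names(p2))) abort("partitions cover different rosters")
    p2 <- p2[names(p1)]
  } else if (length(p1) != length(p2)) {
    abort("partitions cover different rosters")
  }
  conf <- table(p1, p2)
  count <- match_count(unclass(conf))
  tibble(percent = round(100 * count / length(p1)),
         count = as.integer(count),
         n = length(p1))
}

#' Pairwise partition-match matrix for several fitted models
#'
#' @param fits Named list of `blockmodel_fit` objects (or label vectors)
#'   over the same roster.
#' @return A tibble in long-but-wide form: one row per model, one column
#'   per model, entries `"percent% (count)"`, with a 100% diagonal.
#' @export
partition_match_matrix <- function(fits) {
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("model", seq_along(fits))
  cells <- outer(seq_along(fits), seq_along(fits),
                 Vectorize(function(i, j) {
                   m <- partition_match(fits[[i]], fits[[j]])
                   sprintf("%d%% (%d)", m$percent, m$count)
                 }))
  dimnames(cells) <- list(nm, nm)
  dplyr::bind_cols(tibble(model = nm), as_tibble(cells))
}
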