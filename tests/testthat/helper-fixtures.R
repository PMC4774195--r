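# Shared fixture builders: everything is generated in code at test time.

write_y2h_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("# Y2H fixture", "bait\tprey\txgal\this3", rows), path)
  path
}

# seeded random symmetric matrix with zero diagonal
rand_sym <- function(n, seed = 1, labels = sprintf("P%02d", seq_len(n))) {
  withr::with_seed(seed, {
    M <- matrix(runif(n * n), n, n)
    M <- (M + t(M)) / 2
    diag(M) <- 0
    dimnames(M) <- list(labels, labels)
    M
  })
}

# seeded random y2h data over n proteins, complete table, no missing values
random_y2h <- function(n, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("P%02d", seq_len(n))
    ord <- expand.grid(bait = ids, prey = ids, stringsAsFactors = FALSE)
    tibble::tibble(bait = ord$bait, prey = ord$prey,
                   xgal = sample(0:6, n^2, replace = TRUE),
                   his3 = round(runif(n^2, 0, 1.7), 3))
  }) |>
    (\(rec) auxnet:::new_y2h_data(
      tibble::tibble(protein = sprintf("P%02d", seq_len(n)),
                     family = NA_character_), rec))()
}

hard_tau <- function(labels, Q = max(labels)) {
  tau <- matrix(0, length(labels), Q)
  tau[cbind(seq_along(labels), labels)] <- 1
  tau
}

# complete-data log-likelihood of a hard labelling under ML parameters,
# computed directly (independent of the EM path)
complete_loglik <- function(A, Ylist, labels, Q, family = "gaussian") {
  tau <- hard_tau(labels, Q)
  params <- auxnet:::m_step_core(A, Ylist, tau, family)
  auxnet:::lower_bound_core(A, Ylist, params, tau)
}
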