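test_that("profile distances: identity, mismatch proportion, pseudo-metric", {
  A <- matrix(0, 4, 4)
  A[1, 3] <- A[3, 1] <- 1; A[2, 3] <- A[3, 2] <- 1
  A[1, 4] <- A[4, 1] <- 1; A[2, 4] <- A[4, 2] <- 1
  D <- profile_distance_matrix(A)
  expect_equal(D[1, 2], 0)                         # identical profiles
  expect_identical(D, t(D))
  # binary rows differing in exactly k columns -> k / N
  B <- matrix(0, 4, 4)
  B[1, 3] <- B[3, 1] <- 1                          # rows 1 and 2 differ in col 3
  expect_equal(profile_distance_matrix(B)[1, 2], 1 / 4)
  # binary network: equals the valued formula on the 0/1 matrix
  Z <- rand_sym(8, seed = 2) > 0.5
  diag(Z) <- FALSE
  expect_equal(profile_distance_matrix(Z * 1), profile_distance_matrix(Z))
  # triangle inequality on random matrices
  M <- rand_sym(10, seed = 5)
  Dm <- profile_distance_matrix(M)
  for (i in 1:10) for (j in 1:10) for (k in 1:10) {
    expect_lte(Dm[i, j], Dm[i, k] + Dm[k, j] + 1e-12)
  }
})

test_that("soft and hard protein-to-cluster distances coincide for 0/1 tau", {
  M <- rand_sym(9, seed = 6)
  D <- profile_distance_matrix(M)
  labs <- c(1, 1, 1, 2, 2, 2, 3, 3, 3)
  tau <- hard_tau(labs)
  soft <- protein_cluster_distances(D, tau)
  # hard formulas evaluated directly from the partition
  for (i in 1:9) for (q in 1:3) {
    members <- setdiff(which(labs == q), i)
    expect_equal(unname(soft[i, q]), mean(D[i, members]))
  }
  # all identical profiles -> zero everywhere defined
  C <- matrix(0, 6, 6)
  Dc <- profile_distance_matrix(C)
  sc <- protein_cluster_distances(Dc, hard_tau(rep(1:2, each = 3)))
  expect_true(all(sc == 0))
  # singleton cluster: distance to own cluster undefined and flagged
  t1 <- hard_tau(c(1, 2, 2, 2), Q = 2)
  out <- protein_cluster_distances(profile_distance_matrix(rand_sym(4, 7)), t1)
  expect_true(is.na(out[1, 1]))
  expect_true(nrow(attr(out, "flagged")) >= 1)
})

test_that("cluster-scale distances use the printed denominators", {
  M <- rand_sym(8, seed = 8)
  D <- profile_distance_matrix(M)
  labs <- rep(1:2, each = 4)
  cd <- cluster_distance_matrix(D, hard_tau(labs))
  in1 <- which(labs == 1); in2 <- which(labs == 2)
  # D(q, q): within unordered pairs, denominator n_q (n_q - 1)
  expect_equal(cd$cluster_cluster[1, 1],
               sum(D[in1, in1]) / (4 * 3))
  # D(q, l): cross pairs, denominator n_q n_l
  expect_equal(cd$cluster_cluster[1, 2], sum(D[in1, in2]) / (4 * 4))
  expect_identical(cd$cluster_cluster, t(cd$cluster_cluster))
  expect_equal(cd$within, diag(cd$cluster_cluster))
  # D_between(q) is the n_l-weighted mean of D(q, l) over l != q
  expect_equal(cd$between[1], cd$cluster_cluster[1, 2])
  labs3 <- c(1, 1, 1, 2, 2, 3, 3, 3)
  cd3 <- cluster_distance_matrix(D, hard_tau(labs3))
  n_l <- cd3$n_q
  expect_equal(cd3$between[1],
               sum(n_l[2:3] * cd3$cluster_cluster[1, 2:3]) / sum(n_l[2:3]))
  # two blocks of identical profiles: zero within, positive between
  A <- matrix(0, 6, 6)
  A[1:3, 4:6] <- 1; A <- pmax(A, t(A)); diag(A) <- 0
  Da <- profile_distance_matrix(A)
  cda <- cluster_distance_matrix(Da, hard_tau(rep(1:2, each = 3)))
  expect_equal(unname(cda$within), c(0, 0))
  expect_gt(cda$cluster_cluster[1, 2], 0)
})

test_that("well-separated planted clusters are strongly defined", {
  sim <- simulate_blockmodel_graph(sim_config(n = 30, Q = 3,
      alpha = rep(1/3, 3), mu = block_means(3, 0.9, 0.2), sigma = 0.05,
      seed = 16))
  D <- profile_distance_matrix(sim$network)
  cd <- cluster_distance_matrix(D, hard_tau(unname(sim$labels)))
  for (q in 1:3) for (l in setdiff(1:3, q)) {
    expect_lt(cd$cluster_cluster[q, q], cd$cluster_cluster[q, l])
  }
})

test_that("partition matching maximizes agreement over label matchings", {
  expect_equal(partition_match(rep(1:4, each = 5), rep(1:4, each = 5))$percent,
               100)
  p46 <- rep(1:4, c(9, 11, 19, 7))
  m <- partition_match(p46, p46)
  expect_equal(m$percent, 100); expect_equal(m$count, 46L)
  # one protein moved, N = 10 -> 90% (9)
  a <- rep(1:2, each = 5); b <- a; b[1] <- 2
  m2 <- partition_match(a, b)
  expect_equal(m2$percent, 90); expect_equal(m2$count, 9L)
  # invariance under relabelling and symmetry in arguments
  expect_equal(partition_match(c(1, 1, 2, 2), c(2, 2, 1, 1))$percent, 100)
  for (s in 1:5) {
    p1 <- withr::with_seed(s, sample(1:3, 12, replace = TRUE))
    p2 <- withr::with_seed(s + 50, sample(1:4, 12, replace = TRUE))
    expect_identical(partition_match(p1, p2), partition_match(p2, p1))
    # optimal matching is at least any fixed injective labelling's agreement
    conf <- unclass(table(factor(p1, 1:3), factor(p2, 1:4)))
    perms <- expand.grid(rep(list(1:4), 3))
    perms <- perms[apply(perms, 1, function(z) !anyDuplicated(z)), ]
    brute <- max(apply(perms, 1, function(z)
      sum(conf[cbind(1:3, unlist(z))])))
    expect_equal(partition_match(p1, p2)$count, brute)
  }
  expect_error(partition_match(c(1, 2), c(1, 2, 3)), "roster")
})
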