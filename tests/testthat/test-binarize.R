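test_that("BIC selects the generating component count for the OD mixture", {
  z1 <- withr::with_seed(1, rnorm(500, 0.1, 0.01))
  expect_equal(fit_od_mixture(z1)$K, 1L)

  z3 <- withr::with_seed(1, c(rnorm(300, 0.1, 0.02),
                              rnorm(300, 0.45, 0.05),
                              rnorm(300, 1.0, 0.15)))
  m <- fit_od_mixture(z3)
  expect_equal(m$K, 3L)
  expect_lt(max(abs(m$means - c(0.1, 0.45, 1.0))), 0.05)
  expect_equal(sum(m$weights), 1, tolerance = 1e-9)
  expect_true(all(m$variances > 0))

  expect_error(fit_od_mixture(rep(0.5, 50)), "degenerate")
  expect_error(fit_od_mixture(c(0.1, 0.2)), "at least 10")
})

test_that("component boundaries equalize posteriors", {
  # equal-weight, equal-variance pair: boundary at the midpoint
  m <- structure(list(K = 2L, weights = c(0.5, 0.5), means = c(0, 2),
                      variances = c(1, 1)), class = "od_mixture")
  expect_equal(component_boundaries(m), 1.0, tolerance = 1e-8)

  m1 <- structure(list(K = 1L, weights = 1, means = 0.3, variances = 0.01),
                  class = "od_mixture")
  expect_identical(component_boundaries(m1), numeric(0))

  # numeric root agrees with a dense-grid oracle on a fitted 3-component mix
  z3 <- withr::with_seed(1, c(rnorm(300, 0.1, 0.02),
                              rnorm(300, 0.45, 0.05),
                              rnorm(300, 1.0, 0.15)))
  fit <- fit_od_mixture(z3)
  b <- component_boundaries(fit)
  post <- function(z) {
    u <- sapply(seq_len(fit$K), function(k) {
      fit$weights[k] * dnorm(z, fit$means[k], sqrt(fit$variances[k]))
    })
    if (is.null(dim(u))) u <- matrix(u, nrow = 1)
    u / rowSums(u)
  }
  for (k in seq_len(fit$K - 1)) {
    grid <- seq(fit$means[k], fit$means[k + 1], length.out = 200001)
    pg <- post(grid)
    oracle <- grid[which.min(abs(pg[, k] - pg[, k + 1]))]
    expect_equal(b[k], oracle, tolerance = 1e-4)
    pb <- post(b[k])
    expect_equal(pb[1, k], pb[1, k + 1], tolerance = 1e-8)
  }
})

test_that("reporter thresholding follows the published cuts", {
  # Table-style rows: '+?' at 119% and '++' at 90%
  r1 <- binarize_tests(mark_to_code("+?"), 1.19)
  expect_false(r1$xgal_pos); expect_true(r1$his3_pos)
  r2 <- binarize_tests(mark_to_code("++"), 0.90)
  expect_true(r2$xgal_pos); expect_true(r2$his3_pos)
  r3 <- binarize_tests(mark_to_code("-"), NA_real_)
  expect_false(r3$xgal_pos); expect_false(r3$his3_pos)
})

test_that("configuration classifier matches the exhaustive truth table", {
  # hand-built truth table over all 16 patterns (x1, h1, x2, h2):
  # 4 positives -> 1; 3 -> 2; 2 in one way -> 3; one reporter per way -> 4;
  # same reporter both ways -> 5; <= 1 positive -> none
  patterns <- expand.grid(x1 = c(FALSE, TRUE), h1 = c(FALSE, TRUE),
                          x2 = c(FALSE, TRUE), h2 = c(FALSE, TRUE))
  truth <- apply(patterns, 1, function(p) {
    s <- sum(p)
    if (s == 4) "1"
    else if (s == 3) "2"
    else if (s <= 1) "none"
    else if ((p["x1"] && p["h1"]) || (p["x2"] && p["h2"])) "3"
    else if ((p["x1"] && p["x2"]) || (p["h1"] && p["h2"])) "5"
    else "4"
  })
  got <- classify_configuration(patterns$x1, patterns$h1,
                                patterns$x2, patterns$h2)
  expect_identical(got, unname(truth))
  # every pattern maps to exactly one configuration
  expect_equal(sum(table(got)), 16)
  # way swap fixes every configuration class
  swapped <- classify_configuration(patterns$x2, patterns$h2,
                                    patterns$x1, patterns$h1)
  expect_identical(got, swapped)
  expect_identical(classify_configuration(TRUE, TRUE, TRUE, TRUE), "1")
  expect_identical(classify_configuration(TRUE, FALSE, TRUE, FALSE), "5")
})

test_that("binary network keeps configurations 1-4 and discards 5", {
  rows <- c("A\tB\t++\t1.0",  "B\tA\t+\t0.9",   # config 1 -> edge
            "A\tC\t++\t1.0",  "C\tA\t++\t0.1",  # config 2 -> edge
            "B\tC\t++\t0.2",  "C\tB\t++\t0.3",  # X-Gal both ways only -> 5
            "A\tA\t+++\t1.2",                    # homodimer, config 1
            "B\tB\t-\t0.1",   "C\tC\t-\t")
  dat <- parse_y2h_table(write_y2h_fixture(rows))
  net <- build_binary_network(dat)
  expect_true(net$Z["A", "B"] && net$Z["B", "A"])
  expect_true(net$Z["A", "C"])
  expect_false(net$Z["B", "C"])
  expect_identical(net$configuration["B", "C"], "5")
  expect_true(net$Z["A", "A"])   # homodimer on the diagonal
  expect_false(net$Z["B", "B"])
  expect_identical(net$Z, t(net$Z))

  empty <- auxnet:::new_y2h_data(
    tibble::tibble(protein = c("A", "B"), family = NA_character_),
    tibble::tibble(bait = character(), prey = character(),
                   xgal = integer(), his3 = numeric()))
  expect_equal(sum(build_binary_network(empty)$Z), 0)
})

test_that("raising the HIS3 threshold never creates an edge", {
  dat <- random_y2h(12, seed = 8)
  thresholds <- c(0.3, 0.45, 0.65)
  nets <- lapply(thresholds, function(t)
    build_binary_network(dat, his3_threshold = t)$Z)
  for (k in 2:3) {
    expect_true(all(nets[[k]] <= nets[[k - 1]]))
  }
})
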