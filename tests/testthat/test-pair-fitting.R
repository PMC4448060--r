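test_that("fit_pair solves exact and boundary cases", {
  rho1 <- c(1, 2, 0.5)
  prof <- clique_profile(3 * rho1, "c", 1L)
  fit <- fit_pair(prof, rho1, c(0.3, 0.1, 2))
  expect_equal(fit$alpha[1] * rho1, fit$fitted, tolerance = 1e-9)
  expect_equal(fit$psi_pair, 1, tolerance = 1e-12)

  ortho <- fit_pair(clique_profile(c(3, 4), "c", 1L), c(1, 0), c(0, 1))
  expect_equal(ortho$alpha, c(3, 4))
  expect_equal(ortho$psi_pair, 1)

  # unconstrained alpha1 < 0: boundary solution on rho2 alone
  e <- clique_profile(c(0, 1), "c", 1L)
  bound <- fit_pair(e, c(1, 0), c(1, 1) / sqrt(2))
  expect_equal(bound$alpha[1], 0)
  expect_equal(bound$psi_pair, 1 / sqrt(2), tolerance = 1e-9)
  oracle <- grid_min_quad2(0, 1 / sqrt(2), 1, 1, 1 / sqrt(2), 1)
  expect_lte(bound$objective, oracle + 1e-6)

  # collinear profiles are handled as boundary problems
  coll <- fit_pair(clique_profile(c(2, 2), "c", 1L), c(1, 1), c(2, 2))
  expect_equal(coll$psi_pair, 1, tolerance = 1e-12)

  expect_error(fit_pair(clique_profile(c(0, 0), "z", 1L), c(1, 0), c(0, 1)),
               "zero")
})

test_that("fit_pair satisfies KKT conditions on random instances", {
  set.seed(77)
  for (i in 1:50) {
    n <- 8
    e <- clique_profile(rexp(n), "c", 1L)
    rho1 <- rexp(n) * sample(c(0, 1), n, replace = TRUE, prob = c(0.3, 0.7))
    rho2 <- rexp(n) * sample(c(0, 1), n, replace = TRUE, prob = c(0.3, 0.7))
    if (all(rho1 == 0) && all(rho2 == 0)) next
    fit <- fit_pair(e, rho1, rho2)
    expect_true(all(fit$alpha >= 0))
    # gradient of ||e - a1 r1 - a2 r2||^2
    resid <- e$values - fit$fitted
    g <- -2 * c(sum(resid * rho1), sum(resid * rho2))
    scale <- max(sum(e$values^2), 1)
    for (j in 1:2) {
      if (fit$alpha[j] > 1e-12) {
        expect_lt(abs(g[j]), 1e-6 * scale)
      } else {
        expect_gte(g[j], -1e-6 * scale)
      }
    }
  }
})

test_that("distance minimization yields the cone-optimal cosine", {
  # maximizing the cosine over the nonnegative span equals the cosine of
  # the least-squares point; checked against a 1-D angular grid search
  set.seed(55)
  for (i in 1:20) {
    n <- 6
    e <- clique_profile(rexp(n), "c", 1L)
    rho1 <- rexp(n)
    rho2 <- rexp(n)
    fit <- fit_pair(e, rho1, rho2)
    theta <- seq(0, pi / 2, length.out = 20001)
    best_angular <- max(vapply(theta, function(th) {
      v <- cos(th) * rho1 + sin(th) * rho2
      cosine_similarity(v, e$values)
    }, numeric(1)))
    expect_equal(fit$psi_pair, best_angular, tolerance = 1e-6)
  }
})

test_that("pair matrix is symmetric, dominant, and matches a grid oracle", {
  set.seed(14)
  field <- density_field(matrix(rexp(12 * 3), 12, 3), c("a", "b", "c"))
  prof <- clique_profile(rexp(12), "c", 2L)
  pm <- pair_similarity_matrix(prof, field)
  expect_equal(pm, t(pm))
  single <- diag(pm)
  for (t in 1:3) {
    expect_equal(single[t],
                 cosine_similarity(prof$values, field$values[, t]),
                 ignore_attr = TRUE)
  }
  for (i in 1:2) {
    for (j in (i + 1):3) {
      expect_gte(pm[i, j], max(single[i], single[j]) - 1e-9)
      # full per-pair oracle via the exact lattice search
      fit <- fit_pair(prof, field$values[, i], field$values[, j])
      oracle <- grid_min_quad2(sum(prof$values * field$values[, i]),
                               sum(prof$values * field$values[, j]),
                               sum(field$values[, i]^2),
                               sum(field$values[, j]^2),
                               sum(field$values[, i] * field$values[, j]),
                               sum(prof$values^2), upper = 3)
      expect_lte(fit$objective, oracle + 1e-6)
      expect_equal(pm[i, j], fit$psi_pair, tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("better_pairs applies the strict improvement rule", {
  pm <- matrix(c(1, 0.5, 0.5, 0.2), 2, 2)
  expect_equal(nrow(better_pairs(pm)), 0)   # nothing beats psi = 1

  pm2 <- matrix(0, 3, 3)
  pm2[1, 2] <- pm2[2, 1] <- 0.4
  bp <- better_pairs(pm2)
  expect_equal(nrow(bp), 1)
  expect_equal(c(bp$t1, bp$t2), c(1L, 2L))

  # fractions as reported: 62/2016 and 66/2016
  expect_equal(round(100 * 62 / 2016, 2), 3.08)
  expect_equal(round(100 * 66 / 2016, 2), 3.27)
})

test_that("pair_significance counts strictly-lower draws", {
  atlas <- toy_atlas(matrix(c(1, 2, 3), 3, 1), gene_ids = "g1")
  field <- density_field(cbind(a = c(1, 2, 3), b = c(0, 0, 1)),
                         c("a", "b"))
  prof <- sum_expression(atlas, gene_clique("c", "g1"))
  pairs <- data.frame(t1 = 1L, t2 = 2L)
  # pool of one gene: every draw ties the observation, strict rule gives 0
  res <- pair_significance(atlas, field, pairs, 1,
                           monte_carlo_config(30, seed = 1),
                           profile = prof)
  expect_equal(res$P_R, 0)
  expect_equal(res$psi_pair, 1, tolerance = 1e-12)

  # observed 1, no draw reaches it -> P_R = 1
  atlas2 <- random_atlas(10, 6, seed = 21)
  set.seed(22)
  field2 <- density_field(matrix(rexp(20), 10, 2), c("a", "b"))
  pairs2 <- data.frame(t1 = 1L, t2 = 2L)
  res2 <- pair_significance(atlas2, field2, pairs2, 2,
                            monte_carlo_config(100, seed = 3),
                            observed = 1 + 1e-9)
  expect_equal(res2$P_R, 1)
})

test_that("pair_significance agrees with exhaustive enumeration", {
  atlas <- random_atlas(15, 10, seed = 23)
  set.seed(24)
  field <- density_field(matrix(rexp(30), 15, 2), c("a", "b"))
  prof_genes <- sample(atlas$gene_ids, 3)
  prof <- sum_expression(atlas, gene_clique("c", prof_genes))
  pairs <- data.frame(t1 = 1L, t2 = 2L)
  obs <- fit_pair(prof, field$values[, 1], field$values[, 2])$psi_pair

  sets <- utils::combn(10, 3)
  exact_vals <- vapply(seq_len(ncol(sets)), function(i) {
    p <- clique_profile(rowSums(atlas$values[, sets[, i], drop = FALSE]),
                        "e", 3L)
    fit_pair(p, field$values[, 1], field$values[, 2])$psi_pair
  }, numeric(1))
  p_exact <- mean(exact_vals < obs)

  res <- pair_significance(atlas, field, pairs, 3,
                           monte_carlo_config(4000, seed = 25),
                           profile = prof)
  expect_lt(abs(res$P_R - p_exact), 0.05)
})

test_that("occurrence histogram counts both members of each pair", {
  pairs <- data.frame(t1 = c(1L, 1L), t2 = c(2L, 3L))
  counts <- pair_occurrence_histogram(pairs, 4)
  expect_equal(unname(counts), c(2L, 1L, 1L, 0L))
  expect_equal(sum(counts), 2 * nrow(pairs))
  expect_equal(sum(pair_occurrence_histogram(pairs[0, ], 4)), 0)
})
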