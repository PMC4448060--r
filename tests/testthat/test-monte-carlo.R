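test_that("Hoeffding bound and sample size match closed forms", {
  # reference values: bound at R = 26,500, tau = 0.01 is 2*exp(-5.3)
  expect_equal(hoeffding_bound(26500, 0.01), 2 * exp(-5.3))
  expect_lte(hoeffding_bound(26500, 0.01), 0.01)

  # smallest R with 2*exp(-2 R tau^2) <= delta
  expect_equal(hoeffding_sample_size(0.01, 0.01), 26492L)
  expect_equal(hoeffding_sample_size(0.1, 0.05), 185L)
  for (case in list(c(0.02, 0.1), c(0.05, 0.01))) {
    R <- hoeffding_sample_size(case[1], case[2])
    expect_lte(hoeffding_bound(R, case[1]), case[2])
    expect_gt(hoeffding_bound(R - 1, case[1]), case[2])
  }
  expect_error(hoeffding_sample_size(0, 0.5), "tolerance")
  expect_error(hoeffding_bound(26500, 1.5), "tolerance")
})

test_that("draw_random_cliques is uniform, seeded, and bounded", {
  pool <- sprintf("g%d", 1:10)
  full <- draw_random_cliques(pool, 10, 5, seed = 1)
  for (i in 1:5) expect_setequal(draw_clique(full, i)$gene_ids, pool)

  a <- draw_random_cliques(pool, 3, 100, seed = 42)
  b <- draw_random_cliques(pool, 3, 100, seed = 42)
  expect_identical(unclass(a)[seq_along(a)], unclass(b)[seq_along(b)])

  expect_error(draw_random_cliques(pool, 11, 5), "exceeds")

  # single-gene draws from 10 genes: each frequency within 4 sigma of 0.1
  d <- draw_random_cliques(pool, 1, 10000, seed = 7)
  freq <- tabulate(d[, 1], nbins = 10) / 10000
  sigma <- sqrt(0.1 * 0.9 / 10000)
  expect_true(all(abs(freq - 0.1) < 4 * sigma))
})

test_that("simulate_null degenerate cases and Gram shortcut are exact", {
  # pool of one gene whose column equals the density column: all samples 1
  atlas <- toy_atlas(matrix(c(1, 2, 3), 3, 1), gene_ids = "g1")
  field <- density_field(cbind(t1 = c(1, 2, 3)), "t1")
  null <- simulate_null(atlas, field, 1, monte_carlo_config(50, seed = 1))
  expect_equal(unname(null$samples[, 1]), rep(1, 50))

  # orthogonal supports: all samples 0
  atlas2 <- toy_atlas(matrix(c(1, 0, 2, 0), 2, 2))
  field2 <- density_field(cbind(t1 = c(0, 1)), "t1")
  null2 <- simulate_null(atlas2, field2, 2, monte_carlo_config(20, seed = 2))
  expect_true(all(null2$samples == 0))

  # the algebraic shortcut equals the direct voxel-space computation
  atlas3 <- random_atlas(15, 8, seed = 3)
  set.seed(33)
  field3 <- density_field(matrix(rexp(15 * 3), 15, 3), c("a", "b", "c"))
  draws <- draw_random_cliques(atlas3$gene_ids, 3, 40, seed = 4)
  null3 <- simulate_null(atlas3, field3, 3, draws = draws)
  direct <- direct_null_samples(atlas3, field3, draws)
  expect_equal(null3$samples, apply(direct, 2, sort), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("significance counts strictly-lower samples and ranks types", {
  null <- structure(list(samples = cbind(t1 = c(0.1, 0.2, 0.3, 0.4)),
                         clique_size = 2L, seed = 1L, type_labels = "t1"),
                    class = "null_distribution")
  expect_equal(significance(0.25, null)$P_R, 0.5)
  expect_equal(significance(0.9, null)$P_R, 1)    # above all samples
  expect_equal(significance(0.1, null)$P_R, 0)    # ties are not lower
  expect_equal(significance(0.05, null)$P_R, 0)

  # monotonicity: adding a sample below the observation cannot lower P_R
  null2 <- null
  null2$samples <- cbind(t1 = sort(c(null$samples[, 1], 0.01)))
  expect_gte(significance(0.25, null2)$P_R, 0.4)

  # ranking: descending P_R, ties by descending psi then index
  null3 <- structure(list(samples = cbind(a = c(0, 0.5), b = c(0, 0.5),
                                          c = c(0, 0.9)),
                          clique_size = 1L, seed = 1L,
                          type_labels = c("a", "b", "c")),
                     class = "null_distribution")
  sig <- significance(c(0.6, 0.7, 0.2), null3)
  expect_equal(sig$type_index, c(2L, 1L, 3L))
  expect_equal(sig$rank, 1:3)
  expect_error(significance(c(0.5, 0.5), null3), "types")
})

test_that("empirical P_R matches full enumeration on a tiny pool", {
  # 12-gene pool, k = 3: 220 enumerable cliques; moderate R here, the
  # full R = 26,500 version runs in the acceptance suite
  atlas <- random_atlas(20, 12, seed = 8)
  set.seed(88)
  field <- density_field(matrix(rexp(20 * 2), 20, 2), c("a", "b"))
  exact <- enumerate_null(atlas, field, 3)
  null <- simulate_null(atlas, field, 3, monte_carlo_config(5000, seed = 9))
  for (t in 1:2) {
    obs <- stats::quantile(exact[, t], 0.7, names = FALSE)
    p_exact <- mean(exact[, t] < obs)
    p_emp <- significance(rep(obs, 2), null)$P_R[
      match(t, significance(rep(obs, 2), null)$type_index)]
    expect_lt(abs(p_emp - p_exact), 0.05)
  }
})

test_that("shared draws leave each type's marginal P_R correct", {
  atlas <- random_atlas(20, 12, seed = 10)
  set.seed(101)
  field <- density_field(matrix(rexp(20 * 3), 20, 3), c("a", "b", "c"))
  exact <- enumerate_null(atlas, field, 3)
  obs <- apply(exact, 2, stats::quantile, 0.6, names = FALSE)
  p_exact <- vapply(1:3, function(t) mean(exact[, t] < obs[t]), numeric(1))

  R <- hoeffding_sample_size(0.05, 0.05)   # 738 draws
  shared <- simulate_null(atlas, field, 3, monte_carlo_config(R, seed = 5))
  sig_shared <- significance(obs, shared)
  p_shared <- sig_shared$P_R[order(sig_shared$type_index)]

  # per-type independent draws agree with the shared sequence within the
  # Hoeffding tolerance on each marginal
  for (t in 1:3) {
    ind <- simulate_null(atlas, field, 3,
                         monte_carlo_config(R, seed = 100 + t))
    sig_ind <- significance(obs, ind)
    p_ind <- sig_ind$P_R[order(sig_ind$type_index)][t]
    expect_lt(abs(p_shared[t] - p_exact[t]), 0.1)
    expect_lt(abs(p_ind - p_exact[t]), 0.1)
  }
})

test_that("Hoeffding-sized runs hit the promised accuracy rate", {
  atlas <- random_atlas(20, 12, seed = 13)
  set.seed(131)
  field <- density_field(matrix(rexp(20 * 1), 20, 1), "a")
  exact <- enumerate_null(atlas, field, 3)[, 1]
  obs <- stats::quantile(exact, 0.65, names = FALSE)
  p_exact <- mean(exact < obs)

  R <- hoeffding_sample_size(0.05, 0.05)
  hits <- vapply(1:100, function(s) {
    null <- simulate_null(atlas, field, 3, monte_carlo_config(R, seed = s))
    abs(significance(obs, null)$P_R - p_exact) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
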