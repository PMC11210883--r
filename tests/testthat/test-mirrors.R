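test_that("split_and_fit partitions subjects deterministically by seed", {
  cl <- linear_collection(n_subjects = 5L, T_len = 16L, seed = 1)
  cfg <- boosting_config(n_iterations = 30L)
  sp <- split_and_fit(cl, cfg, P = 1L, Q = 1L, seed = 42L)
  expect_length(intersect(sp$subjects1, sp$subjects2), 0L)
  expect_setequal(c(sp$subjects1, sp$subjects2), cl$subjects)
  expect_setequal(c(length(sp$subjects1), length(sp$subjects2)), c(2L, 3L))
  sp2 <- split_and_fit(cl, cfg, P = 1L, Q = 1L, seed = 42L)
  expect_identical(sp$subjects1, sp2$subjects1)
  expect_identical(sp$m1$beta, sp2$m1$beta)
  cl2 <- subset_subjects(cl, cl$subjects[1:2])
  sp3 <- split_and_fit(cl2, cfg, P = 1L, Q = 1L, seed = 7L)
  expect_length(sp3$subjects1, 1L)
  expect_error(split_and_fit(subset_subjects(cl, "s01"), cfg, 1L, 1L), "2 subjects")
})

test_that("pd_effect has the linear closed form, including isolated pulses", {
  cl <- linear_collection(n_subjects = 4L, T_len = 16L, seed = 5)
  d <- tile_windows(cl, P = 1L, Q = 2L)
  m <- fit_transfer(d, config = boosting_config(n_iterations = 200L))
  blk <- tfmicro:::intervention_block(m)
  cw <- colSums(m$beta[blk, , drop = FALSE])        # sum of intervention coefs
  pd <- pd_effect(m, d)
  expect_equal(unname(pd), unname(cw), tolerance = 1e-10)
  # isolated pulse at lag 1 picks out the single lag-1 coefficient
  pulse <- matrix(c(0, 1), 1L, 2L)
  pd_pulse <- pd_effect(m, d, W_on = pulse)
  expect_equal(unname(pd_pulse), unname(m$beta[blk[2L], ]), tolerance = 1e-10)
  expect_equal(unname(pd_effect(m, d, W_on = matrix(0, 1, 2))), rep(0, 3L))
})

test_that("mirror statistics follow the signed-agreement formula and its symmetries", {
  expect_equal(mirror_statistics(0.5, 0.3), 0.8)
  expect_equal(mirror_statistics(0.5, -0.3), -0.8)
  expect_equal(mirror_statistics(0, 0.7), 0)
  set.seed(8)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(mirror_statistics(a, b), mirror_statistics(b, a))
  expect_equal(mirror_statistics(-a, b), -mirror_statistics(a, b))
  expect_equal(mirror_statistics(a, -b), -mirror_statistics(a, b))
})

test_that("fdr_hat counts tails as printed, with the empty-denominator convention", {
  M <- c(4, 3, 2, -1.5, 0.5)
  expect_equal(fdr_hat(M, 1.0), 1 / 3)
  expect_equal(fdr_hat(abs(M), 0.1), 0)
  expect_equal(fdr_hat(-abs(M), 0.1), Inf)
  expect_error(fdr_hat(M, 0), "t must be")
})

test_that("select_taxa matches the worked example and the exhaustive-scan oracle", {
  M <- c(4, 3, 2, -1.5, 0.5)
  res <- select_taxa(M, q = 0.2)
  expect_equal(res$threshold, 1.5)
  expect_equal(res$selected, c(1L, 2L, 3L))
  expect_equal(select_taxa(c(-1, -2, 0), q = 0.2)$selected, integer(0))
  # all-positive M: smallest candidate qualifies, strict rule drops the minimum
  Mp <- c(3, 1, 2)
  rp <- select_taxa(Mp, q = 0.01)
  expect_equal(rp$threshold, 1)
  expect_equal(sort(rp$selected), c(1L, 3L))

  oracle <- function(M, q) {
    cand <- sort(unique(abs(M[M != 0])))
    for (t in cand) {
      num <- sum(M < -t); den <- sum(M > t)
      fdr <- if (den == 0) (if (num == 0) 0 else Inf) else num / den
      if (fdr <= q) return(list(t = t, sel = which(M > t)))
    }
    list(t = Inf, sel = integer(0))
  }
  set.seed(99)
  for (i in 1:200) {
    M <- round(rnorm(sample(3:12, 1L)), 2)
    q <- runif(1, 0.05, 0.5)
    got <- select_taxa(M, q)
    want <- oracle(M, q)
    expect_equal(got$threshold, want$t)
    expect_equal(got$selected, want$sel)
  }
})

test_that("multi-split aggregation reduces to the single split and ranks by inclusion", {
  cl <- linear_collection(n_subjects = 8L, T_len = 18L, J = 4L,
                          beta_w = c(3, 0, 0, 0), noise_sd = 0.05, seed = 13)
  cfg <- boosting_config(n_iterations = 150L)
  one <- multi_split_select(cl, cfg, P = 1L, Q = 1L, q = 0.2, n_splits = 1L, seed = 3L)
  expect_equal(one$selected, one$splits[[1L]]$selected)
  multi <- multi_split_select(cl, cfg, P = 1L, Q = 1L, q = 0.2, n_splits = 8L, seed = 3L)
  ever <- sort(unique(unlist(lapply(multi$splits, `[[`, "selected"))))
  never <- setdiff(seq_len(4L), ever)
  if (length(ever) && length(never))
    expect_gte(min(multi$inclusion_rates[ever]), max(multi$inclusion_rates[never]))
  # the strongly driven taxon dominates the inclusion ranking
  expect_equal(which.max(multi$inclusion_rates), c(tax1 = 1L))
})

test_that("inclusion-rate aggregation drops the largest low-rate prefix under q", {
  sels <- list(c(1L, 2L), c(1L, 2L), c(1L, 3L), 1L)
  agg <- tfmicro:::aggregate_inclusion(sels, J = 4L, q = 0.2)
  # rates: 1 -> (.5+.5+.5+1)/4 = .625, 2 -> .25, 3 -> .125, 4 -> 0
  expect_equal(unname(agg$inclusion_rates), c(0.625, 0.25, 0.125, 0))
  # ascending: 0 (tax4), .125 (tax3) cumsum .125 <= .2, then .25 exceeds
  expect_equal(agg$selected, c(1L, 2L))
  none <- tfmicro:::aggregate_inclusion(list(integer(0), integer(0)), J = 3L, q = 0.2)
  expect_equal(none$selected, integer(0))
})

test_that("lagged mirrors at h_max = 1 agree with the unlagged pipeline", {
  cl <- linear_collection(n_subjects = 6L, T_len = 16L, J = 3L,
                          beta_w = c(2.5, 0, 0), noise_sd = 0.05, seed = 17)
  cfg <- boosting_config(n_iterations = 150L)
  lag1 <- lagged_mirrors(cl, cfg, P = 1L, Q = 1L, q = 0.2, h_max = 1L,
                         n_splits = 3L, seed = 5L)
  flat <- multi_split_select(cl, cfg, P = 1L, Q = 1L, q = 0.2,
                             n_splits = 3L, seed = 5L)
  expect_equal(lag1$per_lag[[1L]]$selected, flat$selected)
  expect_equal(unname(lag1$per_lag[[1L]]$M), unname(flat$M), tolerance = 1e-9)
})

test_that("a null model yields near-zero lagged mirrors and empty selections", {
  cl <- linear_collection(n_subjects = 6L, T_len = 16L, J = 3L,
                          beta_w = c(0, 0, 0), noise_sd = 0.3, seed = 23)
  cfg <- boosting_config(n_iterations = 0L)   # intercept-only: zero PD exactly
  res <- lagged_mirrors(cl, cfg, P = 1L, Q = 1L, q = 0.2, h_max = 2L,
                        n_splits = 2L, seed = 9L)
  for (h in 1:2) {
    expect_lt(max(abs(res$per_lag[[h]]$M)), 1e-12)
    expect_length(res$per_lag[[h]]$selected, 0L)
  }
})

test_that("strongly-affected taxa are recovered by the aggregate selection", {
  # 3 of 60 taxa carry an intervention effect of 3 latent sd (effect >> unit
  # noise); all three should appear in the 25-split aggregate selection in
  # >= 90% of 20 replicate simulated runs
  hits <- 0L
  for (r in 1:20) {
    p <- generate_params(J = 60L, pi_nonnull = 0.05, signal_strength = 1,
                         alpha = 10, lambda = 10, phi = 5, seed = 1000L + r)
    set.seed(1050L + r)
    for (q in seq_along(p$B))
      p$B[[q]][p$nonnull, ] <- 3 * sample(c(-1, 1), length(p$nonnull), replace = TRUE)
    sim <- simulate_dataset(p, n_subjects = 12L, T_len = 30L, seed = 1100L + r)
    cl <- suppressWarnings(apply_normalization(
      sim$collection, normalization_spec("size_factor_asinh")))
    res <- multi_split_select(cl, boosting_config(), P = 2L, Q = 2L, q = 0.2,
                              n_splits = 25L, seed = 1200L + r)
    if (all(p$nonnull %in% res$selected)) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("mirror signs are roughly balanced under the null (fair-coin check)", {
  # small-scale version of the null-symmetry property: one DGM draw with
  # B = C = 0 and moderate taxa
  p <- generate_params(J = 64L, pi_nonnull = 0, signal_strength = 0,
                       alpha = 10, lambda = 10, phi = 5, seed = 41L)
  sim <- simulate_dataset(p, n_subjects = 10L, T_len = 24L, seed = 42L)
  cl <- suppressWarnings(apply_normalization(
    sim$collection, normalization_spec("size_factor_asinh")))
  sp <- split_and_fit(cl, boosting_config(n_iterations = 200L), P = 1L, Q = 1L,
                      seed = 43L)
  M <- mirror_statistics(pd_effect(sp$m1, sp$d1), pd_effect(sp$m2, sp$d2))
  signs <- sign(M[M != 0])
  bt <- binom.test(sum(signs > 0), length(signs))
  expect_gt(bt$p.value, 0.001)
})
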