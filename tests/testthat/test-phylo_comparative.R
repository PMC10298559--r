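test_that("Pearson correlations reproduce the reference class values", {
  gt <- noctuid_genome_table()
  line <- pearson_correlation(gt$genome_size_mb, gt$LINE_pct)
  expect_equal(round(line$r, 2), 0.83)
  dna <- pearson_correlation(gt$genome_size_mb, gt$DTE_pct)
  expect_equal(round(dna$r, 2), 0.81)
  expect_lt(line$p_value, 0.01)
  perfect <- pearson_correlation(1:10, 1:10 * 2 + 3)
  expect_equal(perfect$r, 1)
  expect_lt(perfect$p_value, 1e-12)
})

test_that("lambda endpoints tie out against BM and star-tree limits", {
  tr <- make_ultra_tree(16, seed = 5)
  z <- simulate_trait(tr, "BM", list(sigma2 = 2, z0 = 1), seed = 6)
  tt <- trait_tree(tr, z)
  bm <- fit_continuous(tt, "BM")
  lam <- pagel_lambda(tt)
  # likelihood at lambda = 1 equals the BM likelihood
  g1 <- tehorizon:::.gls_profile(tehorizon:::.lambda_cov(tt$vcv, 1),
                                 tt$trait)
  expect_equal(g1$logL, bm$logL, tolerance = 1e-10)
  expect_true(lam$logL >= g1$logL - 1e-8)

  # star tree: flat likelihood, degenerate flag
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  zs <- stats::setNames(c(0.1, 2, -1, 0.5), c("A", "B", "C", "D"))
  res <- pagel_lambda(trait_tree(star, zs))
  expect_true(res$degenerate)
})

test_that("signal statistics agree with an independent implementation", {
  skip_if_not_installed("phytools")
  tr <- make_ultra_tree(32, seed = 9)
  z <- simulate_trait(tr, "BM", list(sigma2 = 1, z0 = 0), seed = 10)
  tt <- trait_tree(tr, z)
  lam <- pagel_lambda(tt)
  ps <- phytools::phylosig(tr, z, method = "lambda")
  expect_equal(lam$estimate, ps$lambda, tolerance = 1e-3)
  K <- blomberg_k(tt, n_perm = 0)
  pk <- phytools::phylosig(tr, z, method = "K")
  expect_equal(K$estimate, as.numeric(pk), tolerance = 1e-8)
})

test_that("BM simulations carry strong signal; permuted traits lose it", {
  tr <- make_ultra_tree(64, seed = 2)
  z <- simulate_trait(tr, "BM", list(sigma2 = 1, z0 = 0), seed = 3)
  tt <- trait_tree(tr, z)
  expect_gte(pagel_lambda(tt)$estimate, 0.9)
  set.seed(4)
  zp <- stats::setNames(sample(z), names(z))
  expect_lt(pagel_lambda(trait_tree(tr, zp))$estimate, 0.2)
  Kp <- blomberg_k(trait_tree(tr, zp), n_perm = 199, seed = 8)
  expect_lt(Kp$estimate, blomberg_k(tt, n_perm = 0)$estimate)
  expect_gt(Kp$p_value, 0.05)
})

test_that("model fits: EB limit, WN closed form, AICc bookkeeping", {
  tr <- make_ultra_tree(24, seed = 13)
  z <- simulate_trait(tr, "BM", list(sigma2 = 1.5, z0 = -2), seed = 14)
  tt <- trait_tree(tr, z)
  bm <- fit_continuous(tt, "BM")
  # EB covariance with a -> 0- reproduces the BM likelihood
  g <- tehorizon:::.gls_profile(
    tehorizon:::.model_cov(tt$vcv, tt$height, "EB", -1e-9), tt$trait)
  expect_equal(g$logL, bm$logL, tolerance = 1e-6)

  wn <- fit_continuous(tt, "WN")
  n <- tt$n
  s2 <- mean((z - mean(z))^2)
  logL_iid <- -n / 2 * log(2 * pi * s2) - n / 2
  expect_equal(wn$logL, logL_iid, tolerance = 1e-8)
  expect_equal(wn$AICc, -2 * wn$logL + 4 + 12 / (n - 3))

  # AICc ordering invariant under affine trait rescaling (BM/EB/WN)
  zt <- stats::setNames(3.7 * z + 11, names(z))
  tt2 <- trait_tree(tr, zt)
  for (m in c("BM", "EB", "WN")) {
    d <- fit_continuous(tt, m)$AICc - fit_continuous(tt, "BM")$AICc
    d2 <- fit_continuous(tt2, m)$AICc - fit_continuous(tt2, "BM")$AICc
    expect_equal(d, d2, tolerance = 1e-5)
  }

  # OU with tiny attraction approaches BM
  ou <- fit_continuous(tt, "OU")
  expect_gte(ou$logL, bm$logL - 1e-4)
})

test_that("ancestral states match closed-form GLS and label directions", {
  # 2-tip symmetric tree: root is the midpoint
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  z2 <- c(A = 0, B = 10)
  a2 <- ancestral_ml(trait_tree(tr2, z2))
  expect_equal(unname(a2$node_states), 5)

  # 3-tip tree against the conditional-mean oracle
  tr3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  z3 <- c(A = 0, B = 0, C = 3)
  a3 <- ancestral_ml(trait_tree(tr3, z3))
  oracle <- oracle_gls_anc(tr3, z3)
  expect_equal(a3$node_states, oracle, tolerance = 1e-10)

  # random trees against the oracle
  for (s in 1:3) {
    tr <- make_ultra_tree(8, seed = 20 + s)
    z <- simulate_trait(tr, "BM", list(sigma2 = 1, z0 = 0), seed = 30 + s)
    a <- ancestral_ml(trait_tree(tr, z))
    expect_equal(a$node_states, oracle_gls_anc(tr, z), tolerance = 1e-8)
  }

  # constant trait: every node equal, all branches "no_change"
  zc <- stats::setNames(rep(4.2, 8), tr$tip.label)
  ac <- ancestral_ml(trait_tree(tr, zc))
  expect_true(all(abs(ac$node_states - 4.2) < 1e-10))
  expect_true(all(ac$branches$direction == "no_change"))

  # root state equals the phylogenetically corrected mean used by K
  tt <- trait_tree(tr, z)
  Cinv <- solve(tt$vcv)
  abar <- drop(rep(1, 8) %*% Cinv %*% tt$trait) /
    drop(rep(1, 8) %*% Cinv %*% rep(1, 8))
  root <- as.character(length(tr$tip.label) + 1L)
  expect_equal(unname(ancestral_ml(tt)$node_states[root]), abar,
               tolerance = 1e-10)
})

test_that("ancestral reconstruction under an EB fit uses the rescaled tree", {
  skip_if_not_installed("phytools")
  tr <- make_ultra_tree(16, seed = 44)
  z <- simulate_trait(tr, "EB", list(sigma2 = 1, z0 = 0,
                                     a = -0.5 / max(ape::vcv(tr))),
                      seed = 45)
  tt <- trait_tree(tr, z)
  eb <- fit_continuous(tt, "EB")
  anc <- ancestral_ml(tt, eb)
  resc <- eb_rescale_tree(tr, eb$a)
  fa <- phytools::fastAnc(resc, z)
  expect_equal(unname(anc$node_states), as.numeric(fa), tolerance = 1e-6)
})

test_that("trait simulation covariance converges to the model covariance", {
  tr <- make_ultra_tree(12, seed = 50)
  C <- ape::vcv.phylo(tr)
  set.seed(51)
  reps <- vapply(1:500, function(i)
    simulate_trait(tr, "BM", list(sigma2 = 2, z0 = 0)), numeric(12))
  Chat <- reps %*% t(reps) / 500
  expect_lt(norm(Chat - 2 * C, "F") / norm(2 * C, "F"), 0.15)
  expect_equal(unname(simulate_trait(tr, "WN", list(sigma2 = 0, z0 = 7))),
               rep(7, 12))
})
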