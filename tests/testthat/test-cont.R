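test_that("bm_loglik equals the dense multivariate-normal density", {
  set.seed(301)
  for (i in 1:8) {
    tr <- sim_bd_tree(1, 0, ntips = 6)
    x <- sim_bm(tr, sig2 = 2, a = 1)
    s2 <- runif(1, 0.5, 3); a <- rnorm(1)
    C <- phylo_vcv(tr)
    xi <- x[rownames(C)]
    dense <- -3 * log(2 * pi) - 0.5 * determinant(s2 * C)$modulus[1] -
      0.5 * t(xi - a) %*% solve(s2 * C) %*% (xi - a)
    expect_equal(bm_loglik(tr, x, s2, a), as.numeric(dense), tolerance = 1e-8)
    ## shift invariance
    expect_equal(bm_loglik(tr, x + 5, s2, a + 5), bm_loglik(tr, x, s2, a),
                 tolerance = 1e-8)
  }
  ## 2-tip closed form: independent normals
  tr <- parse_tree("(A:1,B:1);")
  x <- c(A = 0.3, B = -0.2)
  expect_equal(bm_loglik(tr, x, 1.5, 0),
               sum(dnorm(x, 0, sqrt(1.5), log = TRUE)), tolerance = 1e-10)
})

test_that("Blomberg's K reproduces the eel body-size analysis", {
  tr <- ape::as.phylo(load_phytools_data("eel.tree"))
  dat <- load_phytools_data("eel.data")
  x <- setNames(log(dat$Max_TL_cm), rownames(dat))
  K <- blomberg_k(tr, x, nperm = 1000, seed = 11)
  expect_equal(K$value, 0.362879, tolerance = 0.001 / 0.36)
  expect_lt(abs(K$p_value - 0.036), 0.02)
  ## affine invariance
  K2 <- blomberg_k(tr, 3 * x + 7, nperm = 0)
  expect_equal(K2$value, K$value, tolerance = 1e-10)
  expect_error(blomberg_k(tr, setNames(rep(1, length(x)), names(x))),
               "constant")
})

test_that("Pagel's lambda reproduces the eel analysis and its LR test", {
  tr <- ape::as.phylo(load_phytools_data("eel.tree"))
  dat <- load_phytools_data("eel.data")
  x <- setNames(log(dat$Max_TL_cm), rownames(dat))
  lam <- pagel_lambda(tr, x, profile = TRUE)
  expect_equal(lam$value, 0.673729, tolerance = 0.005 / 0.67)
  expect_equal(lam$loglik, -54.3016, tolerance = 0.001)
  expect_equal(lam$LR, 5.18173, tolerance = 0.05 / 5.2)
  expect_equal(lam$p_value, 0.0228256, tolerance = 1e-3)
  ## profile behaviour
  expect_gte(lam$loglik, max(lam$profile$logLik) - 1e-6)
  expect_gte(lam$loglik, lam$loglik0)
})

test_that("lambda recovers the generating transform on simulated data", {
  set.seed(313)
  lam_hat <- replicate(12, {
    tr <- sim_bd_tree(1, 0, ntips = 300)
    C <- phylo_vcv(tr)
    Cl <- C * 0.5
    diag(Cl) <- diag(C)
    L <- chol(Cl)
    x <- setNames(as.numeric(t(L) %*% rnorm(300)), rownames(C))
    pagel_lambda(tr, x)$value
  })
  expect_lt(abs(stats::median(lam_hat) - 0.5), 0.15)
})

test_that("fast_anc matches the GLS closed form and the re-rooting oracle", {
  ## 2-tip symmetry
  tr <- parse_tree("(A:1,B:1);")
  fa <- fast_anc(tr, c(A = 2, B = 4))
  expect_equal(fa$estimate, 3)

  ## vertebrate mass reconstruction, back-transformed at the root
  vtr <- load_phytools_data("vertebrate.tree")
  vdat <- load_phytools_data("vertebrate.data")
  x <- setNames(log(vdat$Mass), rownames(vdat))
  fa <- fast_anc(vtr, x)
  expect_equal(exp(fa$estimate[fa$node == 12]), 25.571594, tolerance = 1e-4)

  ## root equals the GLS phylogenetic mean
  C <- phylo_vcv(vtr)
  Ci <- solve(C)
  expect_equal(fa$estimate[fa$node == 12],
               sum(Ci %*% x[rownames(C)]) / sum(Ci), tolerance = 1e-10)

  ## re-rooting oracle on random trees: each node's estimate equals the
  ## phylogenetic mean after re-rooting the tree at that node
  set.seed(41)
  for (i in 1:10) {
    tr <- sim_bd_tree(1, 0, ntips = 12)
    x <- sim_bm(tr, 1, 0)
    fa <- fast_anc(tr, x)
    nodes <- sample(fa$node[-1], 3)   # root checked against GLS above
    for (v in nodes) {
      rt <- ape::root(tr, node = v, resolve.root = FALSE)
      Cr <- ape::vcv.phylo(rt)
      Cri <- solve(Cr)
      est <- sum(Cri %*% x[rownames(Cr)]) / sum(Cri)
      expect_equal(fa$estimate[fa$node == v], est, tolerance = 1e-8)
    }
  }
})

test_that("sim_bm has the Brownian mean-variance structure", {
  tr <- parse_tree("(A:1,(B:0.5,C:0.5):0.5);")
  expect_equal(unname(sim_bm(tr, sig2 = 0, a = 2)), rep(2, 3))
  set.seed(42)
  reps <- 4000
  sims <- replicate(reps, sim_bm(tr, sig2 = 2, a = 0))
  v <- apply(sims, 1, var)
  expect_lt(max(abs(v - 2)), 0.05 * 2 * 4)                # tip height 1
  cv <- stats::cov(sims["B", ], sims["C", ])
  expect_lt(abs(cv - 2 * 0.5), 0.1 * 1 * 3)               # shared height 0.5
  expect_lt(abs(stats::cov(sims["A", ], sims["B", ])), 0.1)
})

test_that("the ancestral-state MCMC matches its bookkeeping and the ML states", {
  set.seed(77)
  tr <- sim_bd_tree(1, 0, ntips = 30)
  x <- sim_bm(tr, sig2 = 0.5, a = 0)
  mc <- anc_bayes(tr, x, ngen = 200000, seed = 5)
  expect_equal(nrow(mc$chain), 200000 / 100 + 1)
  expect_equal(mc$chain$gen[1], 0)
  s <- summary(mc)
  expect_equal(nrow(s), tr$Nnode)
  ## posterior means track the ML reconstruction under diffuse priors
  fa <- fast_anc(tr, x)
  expect_lt(max(abs(s$estimate - fa$estimate)), 0.25)
  expect_gt(stats::cor(s$estimate, fa$estimate), 0.98)
  ## sampler is neither stuck nor degenerate
  expect_gt(mc$accept, 0.05)
  expect_lt(mc$accept, 0.95)
  expect_error(anc_bayes(tr, x, ngen = 1000, control = list(prop = -1)),
               "positive")
  expect_error(anc_bayes(tr, x, ngen = 1001), "divide")
})

test_that("MCMC posterior of sig2 is calibrated on simulated data", {
  set.seed(99)
  tr <- sim_bd_tree(1, 0, ntips = 200)
  tr$edge.length <- tr$edge.length / tree_height(tr)
  x <- sim_bm(tr, sig2 = 1.5, a = 0)
  mc <- anc_bayes(tr, x, ngen = 120000, seed = 6)
  g <- glance(mc)
  expect_lt(abs(g$sig2_mean - 1.5) / 1.5, 0.35)
})
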