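test_that("evolvcv_lite reproduces the tropidurid habit analysis", {
  tt <- load_phytools_data("tropidurid.tree")
  dat <- load_phytools_data("tropidurid.data")
  mt <- as_mapped_phylo(ape::as.phylo(tt), tt$maps)
  fits <- evolvcv_lite(mt, dat, seed = 1)
  ll <- vapply(fits, `[[`, 0, "loglik")
  df <- vapply(fits, `[[`, 0, "df")
  expect_equal(unname(df), c(5, 7, 6, 8))
  expect_equal(unname(ll), c(52.3056, 54.3968, 55.1105, 56.2877),
               tolerance = 0.05 / 55)
  ## regime-specific covariances of the best model
  R12 <- vapply(fits$model3$R, function(R) R[1, 2], 0)
  expect_equal(unname(R12["n_rock"]), 0.0394, tolerance = 0.02)
  expect_equal(unname(R12["rock"]), -0.0354, tolerance = 0.02)
  ## nesting order
  expect_gte(ll[4], ll[2] - 1e-4)
  expect_gte(ll[2], ll[1] - 1e-4)
  expect_gte(ll[4], ll[3] - 1e-4)
  expect_gte(ll[3], ll[1] - 1e-4)
})

test_that("a single-regime map reduces model 1 to ordinary bivariate BM", {
  set.seed(17)
  tr <- sim_bd_tree(1, 0, ntips = 40)
  maps <- lapply(seq_len(nrow(tr$edge)), function(e)
    setNames(tr$edge.length[e], "one"))
  mt <- as_mapped_phylo(tr, maps)
  X <- cbind(a = sim_bm(tr, 1), b = sim_bm(tr, 2))
  f <- evolvcv_lite(mt, X, models = 1, seed = 2)
  ## dense GLS oracle
  C <- phylo_vcv(tr)
  Ci <- solve(C)
  a <- colSums(Ci %*% X[rownames(C), ]) / sum(Ci)
  Xc <- sweep(X[rownames(C), ], 2, a)
  Rhat <- t(Xc) %*% Ci %*% Xc / 40
  n <- 40
  dense_ll <- -n * log(2 * pi) - n / 2 * log(det(Rhat)) -
    determinant(C)$modulus[1] - n
  expect_equal(f$model1$loglik, as.numeric(dense_ll), tolerance = 1e-4)
  expect_equal(unname(f$model1$R[[1]]), unname(Rhat), tolerance = 0.01)
})

test_that("variable-rate BM reproduces the primate skull-length fit", {
  tr <- ape::as.phylo(load_phytools_data("primate.tree"))
  dat <- load_phytools_data("primate.data")
  x <- setNames(log(dat$Skull_length), rownames(dat))
  fit <- multirate_bm(tr, x, lambda_pen = 1)
  expect_equal(fit$loglik_penalized, -267.108, tolerance = 0.1 / 267)
  expect_true(all(fit$rates$sig2 > 0))
})

test_that("a huge penalty collapses to the single-rate ML solution", {
  set.seed(23)
  tr <- sim_bd_tree(1, 0, ntips = 40)
  x <- sim_bm(tr, sig2 = 1.3, a = 0)
  fit <- multirate_bm(tr, x, lambda_pen = 1e6)
  s2_single <- phycomp:::single_rate_ml(tr, x)
  expect_lt(max(abs(fit$rates$sig2 / s2_single - 1)), 0.01)
})

test_that("the penalty only tightens the objective at the flat-rate point", {
  set.seed(29)
  tr <- sim_bd_tree(1, 0, ntips = 25)
  x <- sim_bm(tr, 1, 0)
  n <- ape::Ntip(tr)
  tp <- phycomp:::tree_postorder(tr)
  s2 <- phycomp:::single_rate_ml(tr, x)
  ls <- rep(log(s2), n + tr$Nnode)
  obj <- function(lam) {
    lld <- phycomp:::bm_peel_loglik(tp$edge, n, tr$Nnode, x[tr$tip.label],
                                    tp$len * s2)
    llp <- phycomp:::bm_peel_full(tp$edge, n, ls, tp$len)
    lld + lam * llp
  }
  vals <- vapply(c(0.1, 1, 10, 100), obj, 0)
  expect_true(all(diff(vals) <= 0))
})

test_that("rate shifts are detected robustly across penalty strengths", {
  set.seed(37)
  hits <- 0
  reps <- 10
  for (r in seq_len(reps)) {
    tr <- sim_bd_tree(1, 0, ntips = 50)
    tr$edge.length <- tr$edge.length / tree_height(tr)
    ## pick an internal clade of 8-20 tips and inflate its rate 10x
    h <- node_heights(tr)
    sizes <- vapply(51:99, function(v)
      length(phycomp:::clade_tips(tr, v)), 0L)
    cand <- (51:99)[sizes >= 8 & sizes <= 20]
    v <- cand[which.max(h[cand])]
    clade <- phycomp:::clade_tips(tr, v)
    scale <- ifelse(tr$edge[, 2] %in% c(clade, phycomp:::clade_nodes(tr, v)),
                    10, 1)
    tr2 <- tr
    tr2$edge.length <- tr$edge.length * scale
    x <- sim_bm(tr2, 1, 0)
    ok <- vapply(c(0.1, 1, 10), function(lam) {
      fit <- multirate_bm(tr, x, lambda_pen = lam)
      in_rank <- rank(fit$rates$sig2)[clade]
      mean(in_rank) > (ape::Ntip(tr) + tr$Nnode) / 2
    }, TRUE)
    if (all(ok)) hits <- hits + 1
  }
  expect_gte(hits, reps - 2)
})

test_that("phylogenetic PCA reproduces the anole shape analysis", {
  tt <- load_phytools_data("anoletree")
  dat <- load_phytools_data("anole.data")
  pc <- phyl_pca(ape::as.phylo(tt), dat, mode = "corr")
  expect_equal(unname(pc$sdev),
               c(2.2896942, 0.6674345, 0.4381067, 0.2997973, 0.1395612,
                 0.1026573), tolerance = 1e-5)
  expect_equal(abs(pc$loadings["SVL", "PC1"]), 0.9782776, tolerance = 1e-5)
  expect_true(all(abs(pc$loadings) <= 1 + 1e-8))
  ## C-weighted score covariance is diagonal with entries sdev^2
  C <- phylo_vcv(ape::as.phylo(tt))
  S <- as.matrix(pc$scores[, -1])
  Ci <- solve(C)
  V <- t(S) %*% Ci %*% S / (nrow(S) - 1)
  expect_equal(unname(diag(V)), unname(pc$sdev^2), tolerance = 1e-8)
  expect_lt(max(abs(V[row(V) != col(V)])), 1e-8)
})

test_that("on a star tree phylogenetic PCA equals ordinary PCA", {
  set.seed(43)
  star <- ape::stree(30, "star")
  star$edge.length <- rep(1, 30)
  star$tip.label <- paste0("t", 1:30)
  X <- matrix(rnorm(90), 30, 3, dimnames = list(star$tip.label, c("u", "v", "w")))
  pc <- phyl_pca(star, X, mode = "cov")
  ord <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  expect_equal(unname(pc$sdev), unname(ord$sdev), tolerance = 1e-8)
  expect_equal(abs(unname(as.matrix(pc$scores[, -1]))),
               abs(unname(ord$x)), tolerance = 1e-6)
})
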