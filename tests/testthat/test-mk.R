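test_that("design matrices implement ER, SYM, ARD and explicit templates", {
  expect_equal(unclass(build_design(c("a", "b"), "ER")),
               matrix(c(0L, 1L, 1L, 0L), 2, 2,
                      dimnames = list(c("a", "b"), c("a", "b"))))
  irr <- build_design(c("a", "b"), matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE))
  expect_equal(sum(irr > 0), 1)
  expect_equal(unname(irr["a", "b"]), 1L)
  expect_equal(max(build_design(letters[1:3], "ARD")), 6L)
  expect_equal(max(build_design(letters[1:3], "SYM")), 3L)
  expect_error(build_design("a"), "at least 2")
  expect_error(build_design(c("a", "b"), matrix(-1, 2, 2)), ">= 0")
})

test_that("mk_loglik matches closed forms and ambiguity conventions", {
  tr <- parse_tree("(A:1,B:1);")
  lv <- c("s1", "s2")
  Q0 <- design_to_q(build_design(lv, "ER"), 1e-12)
  ll <- mk_loglik(tr, setNames(c("s1", "s1"), c("A", "B")), Q0)
  expect_equal(exp(ll), 0.5, tolerance = 1e-8)

  Q <- design_to_q(build_design(lv, "ER"), 0.5)
  ll <- mk_loglik(tr, setNames(c("s1", "s2"), c("A", "B")), Q)
  expect_equal(exp(ll), (1 + exp(-1)) * (1 - exp(-1)) / 4, tolerance = 1e-10)

  ## a fully ambiguous tip integrates to the one-tip likelihood
  llNA <- mk_loglik(tr, setNames(c("s1", NA), c("A", "B")), Q)
  expect_equal(exp(llNA), 0.5, tolerance = 1e-10)
})

test_that("pruning equals brute-force enumeration on 4-tip shapes", {
  set.seed(4)
  for (shape in four_tip_shapes()) {
    tr <- parse_tree(shape)
    for (k in 2:3) {
      for (r in 1:12) {
        Q <- random_q(k)
        ts <- sample(1:k, 4, replace = TRUE)
        x <- setNames(letters[1:k][ts], tr$tip.label)
        expect_equal(mk_loglik(tr, x, Q),
                     brute_mk_loglik(tr, ts, Q, rep(1 / k, k)),
                     tolerance = 1e-9)
        ## FitzJohn prior: weights are the normalized root partials
        ll_fj <- mk_loglik(tr, x, Q, prior = "fitzjohn")
        expect_true(is.finite(ll_fj))
      }
    }
  }
})

test_that("transition probabilities are proper stochastic matrices", {
  set.seed(5)
  Q <- random_q(3)
  tm <- trait_levels <- letters[1:3]
  for (t in c(0, 1e-3, 0.5, 3, 100)) {
    tr <- parse_tree(sprintf("(A:%g,B:%g);", max(t, 1e-12), max(t, 1e-12)))
    x <- setNames(c("a", "a"), c("A", "B"))
    expect_true(is.finite(mk_loglik(tr, x, Q)))
  }
  P <- as.matrix(Matrix::expm(Q * 0))
  expect_equal(P, diag(3), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("mk_loglik is invariant to tip order and child rotation", {
  set.seed(6)
  Q <- random_q(2)
  x <- setNames(c("a", "b", "a", "b"), LETTERS[1:4])
  t1 <- parse_tree("((A:1,B:2):1.5,(C:0.7,D:1):2);")
  t2 <- parse_tree("((C:0.7,D:1):2,(B:2,A:1):1.5);")   # rotated children
  expect_equal(mk_loglik(t1, x, Q), mk_loglik(t2, x, Q), tolerance = 1e-10)
  expect_equal(mk_loglik(t1, x, Q), mk_loglik(t1, x[c(3, 1, 4, 2)], Q),
               tolerance = 1e-12)
})

test_that("fit_mk reproduces the centrarchid feeding-mode model table", {
  tr <- ape::as.phylo(load_phytools_data("sunfish.tree"))
  dat <- load_phytools_data("sunfish.data")
  x <- setNames(dat$feeding.mode, rownames(dat))
  er <- fit_mk(tr, x, "ER")
  ard <- fit_mk(tr, x, "ARD")
  irr1 <- fit_mk(tr, x, matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE))
  irr2 <- fit_mk(tr, x, matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE))
  expect_equal(er$loglik, -13.07453, tolerance = 0.01 / 13)
  expect_equal(ard$loglik, -12.86494, tolerance = 0.01 / 13)
  expect_equal(ard$df, 2L)
  expect_equal(er$AIC, 2 * er$df - 2 * er$loglik, tolerance = 1e-8)
  tab <- compare_models(er, irr1, irr2, ard)
  expect_equal(tab$weight, c(0.3486479, 0.3800846, 0.1130998, 0.1581677),
               tolerance = 0.005)
  ## nesting: ER is a special case of ARD
  expect_gte(ard$loglik, er$loglik - 1e-6)
})

test_that("fit_mk recovers the generating rate from simulated data", {
  set.seed(91)
  tr <- sim_bd_tree(1, 0, ntips = 500)
  tr$edge.length <- tr$edge.length / tree_height(tr) * 5
  Q <- design_to_q(build_design(c("a", "b"), "ER"), 1)
  qhat <- replicate(10, {
    x <- sim_mk(tr, Q)
    fit_mk(tr, x, "ER")$rates
  })
  expect_lt(abs(stats::median(qhat) - 1), 0.25)
})

test_that("model weights behave like Akaike weights", {
  f1 <- structure(list(loglik = -10, df = 1), class = "ll_df")
  f2 <- structure(list(loglik = -10, df = 1), class = "ll_df")
  tab <- compare_models(f1, f2)
  expect_equal(tab$weight, c(0.5, 0.5))
  expect_equal(sum(tab$weight), 1, tolerance = 1e-10)
  single <- compare_models(only = f1)
  expect_equal(single$weight, 1)
  ## invariance to a constant shift in logL at fixed df
  f3 <- structure(list(loglik = -4, df = 1), class = "ll_df")
  f4 <- structure(list(loglik = -6, df = 2), class = "ll_df")
  t1 <- compare_models(f3, f4)
  f3$loglik <- f3$loglik + 7; f4$loglik <- f4$loglik + 7
  t2 <- compare_models(f3, f4)
  expect_equal(t1$weight, t2$weight, tolerance = 1e-12)
  ## weight ordering is inverse to AIC ordering
  expect_equal(order(t1$AIC), order(-t1$weight))
})

test_that("marginal reconstruction matches enumeration and sums to one", {
  set.seed(14)
  for (shape in four_tip_shapes()[1:2]) {
    tr <- parse_tree(shape)
    for (k in 2:3) {
      Q <- random_q(k)
      ts <- sample(1:k, 4, replace = TRUE)
      x <- setNames(letters[1:k][ts], tr$tip.label)
      fit <- fit_mk(tr, x, "ER", levels = letters[1:k])
      fit$Q <- Q  # evaluate reconstruction at a fixed, known Q
      fit$rates <- NULL
      marg <- ancr(fit, tips = TRUE)
      M <- as.matrix(as.data.frame(marg)[, -1])
      expect_equal(unname(rowSums(M)), rep(1, nrow(M)), tolerance = 1e-8)
      oracle <- brute_mk_marginals(tr, ts, Q, rep(1 / k, k))
      expect_equal(unname(M), unname(oracle), tolerance = 1e-8)
    }
  }
})

test_that("model-averaged reconstruction with degenerate weights equals single-model", {
  tr <- ape::as.phylo(load_phytools_data("sunfish.tree"))
  dat <- load_phytools_data("sunfish.data")
  x <- setNames(dat$feeding.mode, rownames(dat))
  er <- fit_mk(tr, x, "ER")
  ard <- fit_mk(tr, x, "ARD")
  tab <- compare_models(er, ard)
  tab$weight <- c(1, 0)
  avg <- ancr(tab)
  single <- ancr(er)
  expect_equal(as.data.frame(avg), as.data.frame(single), tolerance = 1e-12)
})

test_that("joint reconstruction is deterministic and respects tip data", {
  tr <- ape::as.phylo(load_phytools_data("sunfish.tree"))
  dat <- load_phytools_data("sunfish.data")
  x <- setNames(dat$feeding.mode, rownames(dat))
  er <- fit_mk(tr, x, "ER")
  j1 <- ancr(er, method = "joint")
  j2 <- ancr(er, method = "joint")
  expect_identical(j1, j2)
  expect_identical(unname(j1[seq_len(28)]), as.character(x[tr$tip.label]))
})

test_that("sim_mk follows the generating process", {
  tr <- parse_tree("(A:1,B:1);")
  Q0 <- design_to_q(build_design(c("a", "b"), "ER"), 1e-12)
  x <- sim_mk(tr, Q0, root_state = "b", seed = 1)
  expect_equal(as.character(x), c("b", "b"))

  ## stationary frequency ~ 1/2 for long branches under ER
  set.seed(55)
  star <- ape::stree(2000, "star")
  star$edge.length <- rep(5, 2000)
  Q <- design_to_q(build_design(c("a", "b"), "ER"), 10)
  x <- sim_mk(star, Q, root_state = "a")
  p <- mean(x == "a")
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 2000))

  ## transition counts per unit length approximate the rate on one long edge
  long <- parse_tree("(A:500,B:0);")
  h <- sim_mk(long, Q / 10, history = TRUE, seed = 9)  # q = 1
  eA <- which(long$edge[, 2] == 1)
  nchanges <- length(h$tree$maps[[eA]]) - 1
  expect_lt(abs(nchanges / 500 - 1), 0.2)
})
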