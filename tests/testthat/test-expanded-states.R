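test_that("polymorphic state spaces have the right states and rate classes", {
  sp <- build_poly_space(c("a", "b"))
  expect_equal(sp$states, c("a", "b", "a+b"))
  expect_equal(max(sp$design), 1L)
  expect_equal(sum(sp$design > 0), 4)   # a<->a+b, b<->a+b

  spu <- build_poly_space(c("forest", "fringe", "open"), model = "ARD")
  expect_equal(spu$states,
               c("forest", "fringe", "open", "forest+fringe", "forest+open",
                 "fringe+open", "forest+fringe+open"))
  expect_equal(max(spu$design), 18L)

  spo <- build_poly_space(c("forest", "fringe", "open"), ordered = TRUE,
                          order = c("forest", "fringe", "open"), model = "ARD")
  expect_equal(max(spo$design), 12L)
  expect_false("forest+open" %in% spo$states)
  expect_true("forest+fringe+open" %in% spo$states)

  tr2 <- build_poly_space(c("a", "b", "c"), model = "transient")
  expect_equal(max(tr2$design), 2L)
  ## gains carry class 1, losses class 2
  expect_equal(unname(tr2$design["a", "a+b"]), 1L)
  expect_equal(unname(tr2$design["a+b", "a"]), 2L)
})

test_that("polymorphic fits reproduce the butterfly habitat models", {
  tr <- ape::as.phylo(load_phytools_data("butterfly.tree"))
  dat <- load_phytools_data("butterfly.data")
  x <- setNames(dat$habitat, rownames(dat))
  er_u <- fit_polymk(tr, x, model = "ER", nstarts = 3, seed = 1)
  expect_equal(er_u$loglik, -355.8122, tolerance = 0.01 / 355)
  expect_equal(er_u$df, 1L)
  ard_o <- fit_polymk(tr, x, model = "ARD", ordered = TRUE,
                      order = c("forest", "fringe", "open"),
                      nstarts = 10, seed = 2)
  expect_equal(ard_o$loglik, -297.7376, tolerance = 0.05 / 298)
  expect_equal(ard_o$df, 12L)
  expect_equal(ard_o$AIC, 619.4753, tolerance = 0.2 / 619)
})

test_that("transient model is nested in ARD", {
  set.seed(33)
  tr <- sim_bd_tree(1, 0, ntips = 60)
  sp <- build_poly_space(c("a", "b"), model = "ARD")
  Q <- design_to_q(sp$design, rexp(max(sp$design)))
  x <- sim_mk(tr, Q)
  f_tr <- fit_polymk(tr, x, model = "transient", nstarts = 5, seed = 3)
  f_ard <- fit_polymk(tr, x, model = "ARD", nstarts = 5, seed = 4)
  expect_lte(f_tr$loglik, f_ard$loglik + 1e-6)
})

test_that("polymorphic conditions are canonicalized order-insensitively", {
  set.seed(44)
  tr <- sim_bd_tree(1, 0, ntips = 40)
  sp <- build_poly_space(c("a", "b"), model = "ER")
  Q <- design_to_q(sp$design, 0.6)
  x <- as.character(sim_mk(tr, Q))
  names(x) <- tr$tip.label
  x2 <- sub("^a\\+b$", "b+a", x)
  f1 <- fit_polymk(tr, x, model = "ER", nstarts = 2, seed = 5)
  f2 <- fit_polymk(tr, x2, model = "ER", nstarts = 2, seed = 5)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(f1$rates, f2$rates, tolerance = 1e-6)
})

test_that("hidden-rates state spaces match the printed design conventions", {
  sp <- build_hrm_space(c("O", "V"), ncat = 2, umbral = TRUE)
  expect_equal(sp$states, c("O", "O*", "V", "V*"))
  expect_equal(unclass(sp$design),
               matrix(c(0L, 1L, 2L, 0L,
                        3L, 0L, 0L, 0L,
                        4L, 0L, 0L, 5L,
                        0L, 0L, 6L, 0L), 4, 4, byrow = TRUE,
                      dimnames = list(sp$states, sp$states)))
  full <- build_hrm_space(c("O", "V"), ncat = 2, umbral = FALSE)
  expect_equal(max(full$design), 8L)
  plain <- build_hrm_space(c("O", "V"), ncat = 1)
  expect_equal(unclass(plain$design),
               unclass(build_design(c("O", "V"), "ARD")))
})

test_that("expanded-space likelihoods equal enumeration through the shared engine", {
  set.seed(71)
  tr <- parse_tree(four_tip_shapes()[1])
  ## polymorphic binary space: 3 states
  sp <- build_poly_space(c("a", "b"), model = "ER")
  Q <- design_to_q(sp$design, 0.8)
  ts <- c(1, 3, 2, 3)
  x <- setNames(sp$states[ts], tr$tip.label)
  ll <- mk_loglik(tr, x, Q)
  expect_equal(ll, brute_mk_loglik(tr, ts, Q, rep(1 / 3, 3)), tolerance = 1e-9)

  ## HRM space: observed tip spreads over its hidden levels
  hs <- build_hrm_space(c("O", "V"), ncat = 2, umbral = TRUE)
  Qh <- design_to_q(hs$design, rexp(6))
  tipL <- matrix(0, 4, 4, dimnames = list(tr$tip.label, hs$states))
  obs <- c("O", "V", "O", "V")
  for (i in 1:4) tipL[i, hs$level_of == obs[i]] <- 1
  ll <- mk_loglik(tr, tipL, Qh)
  ## oracle: enumerate over hidden tip assignments too
  base <- ifelse(obs == "O", 1, 3)
  combos <- expand.grid(lapply(base, function(b) b + 0:1))
  tot <- 0
  for (g in seq_len(nrow(combos)))
    tot <- tot + exp(brute_mk_loglik(tr, as.integer(combos[g, ]), Qh, rep(1 / 4, 4)))
  expect_equal(ll, log(tot), tolerance = 1e-9)
})

test_that("hidden-rates fits reproduce the liolaemid parity analysis", {
  tr <- ape::as.phylo(load_phytools_data("liolaemid.tree"))
  dat <- load_phytools_data("liolaemid.data")
  x <- setNames(dat$parity_mode, rownames(dat))
  mk1 <- fit_hrm(tr, x, ncat = 1, prior = "fitzjohn", nstarts = 4, seed = 1)
  expect_equal(mk1$loglik, -64.27046, tolerance = 0.01 / 64)
  expect_equal(mk1$df, 2L)
})

test_that("hidden-rate simulations separate labile from inert categories", {
  set.seed(81)
  sp <- build_hrm_space(c("A", "B"), ncat = 2, umbral = TRUE)
  ## labile observed-state rates fast, hidden-category rates slow
  true_rates <- c(0.1, 1.5, 0.1, 1.5, 0.1, 0.1)
  Qh <- design_to_q(sp$design, true_rates)
  hits <- 0
  reps <- 8
  for (r in seq_len(reps)) {
    tr <- sim_bd_tree(1, 0, ntips = 300)
    tr$edge.length <- tr$edge.length / tree_height(tr) * 3
    full <- sim_mk(tr, Qh)
    obs <- setNames(sub("\\*$", "", as.character(full)), names(full))
    fit <- fit_hrm(tr, obs, ncat = 2, umbral = TRUE, nstarts = 5, seed = r)
    ## the between-state (labile) rates should dominate the O->O* style moves
    labile <- mean(fit$rates[c(2, 4)])
    inert <- mean(fit$rates[c(1, 3)])
    if (labile > inert) hits <- hits + 1
  }
  expect_gte(hits, reps - 2)
})
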