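## Continuous-trait core: Brownian likelihood, phylogenetic signal, ML and
## Bayesian ancestral states, BM simulation.

## GLS phylogenetic mean given the inverse covariance
gls_mean <- function(Cinv, x) sum(Cinv %*% x) / sum(Cinv)

#' Brownian-motion log-likelihood of tip data
#'
#' Multivariate-normal log density of the tip values with mean `a` and
#' covariance `sig2 * C`, where C is the phylogenetic covariance matrix
#' ([phylo_vcv()]).
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param x Named numeric tip vector.
#' @param sig2 Brownian rate (squared trait units per branch-length unit).
#' @param a Root (ancestral mean) state.
#' @return Log-likelihood (scalar).
#' @export
bm_loglik <- function(tree, x, sig2, a) {
  if (sig2 <= 0) stop("sig2 must be > 0")
  C <- phylo_vcv(tree)
  x <- x[rownames(C)]
  n <- length(x)
  cd <- chol(C)
  logdet <- 2 * sum(log(diag(cd)))
  z <- backsolve(cd, x - a, transpose = TRUE)
  -n / 2 * log(2 * pi) - n / 2 * log(sig2) - logdet / 2 - sum(z^2) / (2 * sig2)
}

#' Blomberg's K with a permutation test
#'
#' K compares the observed ratio of the mean squared error of tip data
#' around the phylogenetic (GLS) mean to the phylogenetically corrected mean
#' squared error, against the value of that ratio expected under Brownian
#' motion; K = 1 is the Brownian expectation, K < 1 less signal, K > 1
#' more. The p-value is the upper-tail share of K values obtained by
#' permuting trait values across tips (plus-one convention).
#'
#' @param tree A `phylo`.
#' @param x Named numeric tip vector (non-constant).
#' @param nperm Number of permutations (default 1000); 0 skips the test.
#' @param seed Optional seed.
#' @return Object of class `"phylo_signal"`: `statistic = "K"`, `value`,
#'   `p_value`, `null` (permutation sample).
#' @export
blomberg_k <- function(tree, x, nperm = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  C <- phylo_vcv(tree)
  x <- x[rownames(C)]
  if (length(x) < 3) stop("need at least 3 tips")
  if (stats::sd(x) == 0) stop("K is undefined for a constant trait")
  n <- length(x)
  Cinv <- solve(C)
  expected <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
  Kof <- function(v) {
    a <- gls_mean(Cinv, v)
    mse0 <- sum((v - a)^2)
    mse <- as.numeric(t(v - a) %*% Cinv %*% (v - a))
    (mse0 / mse) / expected
  }
  K <- Kof(x)
  null <- numeric(0); p <- NA_real_
  if (nperm > 0) {
    null <- vapply(seq_len(nperm), function(i) Kof(sample(x)), 0)
    p <- (sum(null >= K) + 1) / (nperm + 1)
  }
  structure(list(statistic = "K", value = K, p_value = p, null = null,
                 nperm = nperm),
            class = "phylo_signal")
}

#' Pagel's lambda with a likelihood-ratio test
#'
#' Lambda multiplies the off-diagonal entries of the phylogenetic covariance
#' (the correlations of related taxa); it is estimated by maximum likelihood
#' (profiling out sigma^2 and the root state) and tested against lambda = 0
#' with a likelihood ratio referred to chi-square with 1 df. The upper bound
#' is the largest lambda keeping C(lambda) positive definite.
#'
#' @param tree A `phylo`.
#' @param x Named numeric tip vector.
#' @param profile Return the likelihood profile as a tibble (`lambda`,
#'   `logLik`) in element `profile`.
#' @return Object of class `"phylo_signal"`: `statistic = "lambda"`,
#'   `value`, `loglik`, `loglik0`, `LR`, `p_value`.
#' @export
pagel_lambda <- function(tree, x, profile = FALSE) {
  C <- phylo_vcv(tree)
  x <- x[rownames(C)]
  n <- length(x)
  transform <- function(lam) {
    Cl <- C * lam
    diag(Cl) <- diag(C)
    Cl
  }
  prof <- function(lam) {
    Cl <- transform(lam)
    cd <- tryCatch(chol(Cl), error = function(e) NULL)
    if (is.null(cd)) return(-Inf)
    Cli <- chol2inv(cd)
    a <- gls_mean(Cli, x)
    s2 <- as.numeric(t(x - a) %*% Cli %*% (x - a)) / n
    -n / 2 * log(2 * pi) - n / 2 * log(s2) - sum(log(diag(cd))) - n / 2
  }
  ## largest feasible lambda (C(lambda) positive definite), by bisection
  lam_max <- 1
  if (is.finite(prof(1.5))) {
    lo <- 1; hi <- 2
    while (is.finite(prof(hi)) && hi < 64) { lo <- hi; hi <- 2 * hi }
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if (is.finite(prof(mid))) lo <- mid else hi <- mid
    }
    lam_max <- lo
  }
  opt <- optimize(prof, c(0, lam_max), maximum = TRUE, tol = 1e-8)
  ll0 <- prof(0)
  ## guard the boundary: lambda = 0 may beat the interior optimum
  lam_hat <- opt$maximum; ll <- opt$objective
  if (ll0 > ll) { lam_hat <- 0; ll <- ll0 }
  LR <- 2 * (ll - ll0)
  out <- list(statistic = "lambda", value = lam_hat, loglik = ll,
              loglik0 = ll0, LR = LR,
              p_value = stats::pchisq(LR, df = 1, lower.tail = FALSE),
              lambda_max = lam_max)
  if (profile) {
    grid <- seq(0, lam_max, length.out = 101)
    out$profile <- tibble::tibble(lambda = grid,
                                  logLik = vapply(grid, prof, 0))
  }
  structure(out, class = "phylo_signal")
}

#' @export
print.phylo_signal <- function(x, ...) {
  if (x$statistic == "K") {
    cat(sprintf("Phylogenetic signal K: %.6f\n", x$value))
    if (!is.na(x$p_value))
      cat(sprintf("P-value (based on %d randomizations): %g\n", x$nperm, x$p_value))
  } else {
    cat(sprintf("Phylogenetic signal lambda: %.6f\n", x$value))
    cat(sprintf("logL(lambda): %.4f\n", x$loglik))
    cat(sprintf("LR(lambda=0): %.5f\n", x$LR))
    cat(sprintf("P-value (based on LR test): %g\n", x$p_value))
  }
  invisible(x)
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Point estimates are the conditional-normal (GLS) values: the root takes
#' the phylogenetic mean, and every other internal node the conditional
#' expectation of its state given the tips (equivalent to the phylogenetic
#' mean of the tree re-rooted at that node). Variances and 95% CIs use the
#' ML rate estimate and account for uncertainty in the mean.
#'
#' @param tree A `phylo`.
#' @param x Named numeric tip vector.
#' @param ci Also return variances and 95% intervals.
#' @return A tibble: `node`, `estimate` and, with `ci`, `var`, `lower`,
#'   `upper`.
#' @export
fast_anc <- function(tree, x, ci = FALSE) {
  n <- ape::Ntip(tree)
  C <- phylo_vcv(tree)
  x <- x[rownames(C)]
  Cinv <- solve(C)
  a <- gls_mean(Cinv, x)
  Cfull <- vcv_with_ancestors(tree)
  anc_ids <- (n + 2):(n + tree$Nnode)  # root handled separately
  est <- c(a, if (tree$Nnode > 1)
    as.numeric(Cfull[anc_ids, seq_len(n)] %*% Cinv %*% (x - a)) + a)
  nodes <- (n + 1):(n + tree$Nnode)
  out <- tibble::tibble(node = as.integer(nodes), estimate = est)
  if (ci) {
    s2 <- as.numeric(t(x - a) %*% Cinv %*% (x - a)) / n  # ML rate
    one <- rep(1, n)
    vars <- vapply(nodes, function(v) {
      if (v == n + 1) return(s2 / sum(Cinv))
      cv <- Cfull[v, seq_len(n)]
      w <- 1 - sum(Cinv %*% cv)
      s2 * (Cfull[v, v] - as.numeric(t(cv) %*% Cinv %*% cv) + w^2 / sum(Cinv))
    }, 0)
    out$var <- vars
    out$lower <- est - 1.959964 * sqrt(vars)
    out$upper <- est + 1.959964 * sqrt(vars)
  }
  out
}

## covariance (shared path length) matrix including internal nodes (root has
## zero row/column and is included for indexing convenience)
vcv_with_ancestors <- function(tree) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  h <- node_heights(tree)
  anc <- ancestor_list(tree)
  C <- matrix(0, nn, nn)
  for (i in seq_len(nn)) {
    ai <- c(anc[[i]], i)
    for (j in seq_len(nn)) {
      if (j < i) next
      aj <- c(anc[[j]], j)
      common <- intersect(ai, aj)
      hm <- max(h[common])
      C[i, j] <- hm; C[j, i] <- hm
    }
  }
  diag(C) <- h
  C
}

ancestor_list <- function(tree) {
  nn <- ape::Ntip(tree) + tree$Nnode
  parent <- integer(nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  lapply(seq_len(nn), function(v) {
    out <- integer(0)
    while (parent[v] != 0L) { v <- parent[v]; out <- c(out, v) }
    out
  })
}

#' Simulate Brownian motion on a tree
#'
#' Gaussian increments with variance `sig2 * t` along each edge.
#'
#' @param tree A `phylo`.
#' @param sig2 Brownian rate (>= 0).
#' @param a Root state.
#' @param internal Also return internal-node values.
#' @param seed Optional seed.
#' @return Named numeric vector of tip values (plus node values when
#'   `internal = TRUE`, named by node id).
#' @export
sim_bm <- function(tree, sig2 = 1, a = 0, internal = FALSE, seed = NULL) {
  if (sig2 < 0) stop("sig2 must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  nn <- ape::Ntip(tree) + tree$Nnode
  vals <- numeric(nn)
  vals[ape::Ntip(tree) + 1L] <- a
  eo <- rev(ape::postorder(tree))
  inc <- rnorm(nrow(tree$edge), 0, sqrt(sig2 * tree$edge.length))
  for (e in eo) vals[tree$edge[e, 2]] <- vals[tree$edge[e, 1]] + inc[e]
  tips <- setNames(vals[seq_len(ape::Ntip(tree))], tree$tip.label)
  if (!internal) return(tips)
  c(tips, setNames(vals[(ape::Ntip(tree) + 1):nn], (ape::Ntip(tree) + 1):nn))
}

#' Bayesian MCMC ancestral state estimation under Brownian motion
#'
#' Metropolis-Hastings sampling of the Brownian rate sigma^2, the root state
#' a, and all internal-node states, with Gaussian one-parameter-at-a-time
#' random-walk proposals cycled in order (sigma^2 proposals reflected at 0).
#' The likelihood is the joint Brownian density of node-to-node changes
#' along every edge. Default priors are diffuse: sigma^2 ~ N(1000, 1e6)
#' truncated at 0, node states ~ N(0, 1e3). The chain is sampled every
#' `sample` generations, including generation 0, so a run of `ngen` yields
#' `ngen/sample + 1` rows.
#'
#' @param tree A `phylo`.
#' @param x Named numeric tip vector.
#' @param ngen Number of MCMC generations.
#' @param control Optional list overriding `sig2` (initial rate), `a`
#'   (initial root), `y` (initial node states), `pr.mean`, `pr.var`
#'   (prior means/variances: sigma^2 first, then root and nodes), `prop`
#'   (proposal variances), `sample` (sampling interval).
#' @param burnin Fraction of samples discarded by [summary()] (default 0.2).
#' @param seed Optional seed.
#' @return Object of class `"anc_mcmc"`: `chain` (tibble: `gen`, `sig2`,
#'   node columns, `logLik`), `burnin`, `accept` (acceptance rate), `tree`.
#' @export
anc_bayes <- function(tree, x, ngen = 10000, control = list(), burnin = 0.2,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)
  x <- x[tree$tip.label]
  nnode <- tree$Nnode
  nodes <- (n + 1):(n + nnode)
  ## initial values: rate from mean squared independent contrasts, states at
  ## the GLS phylogenetic mean
  pic <- ape::pic(x, tree)
  sig2 <- if (!is.null(control$sig2)) control$sig2 else mean(pic^2)
  C <- phylo_vcv(tree)
  a0 <- gls_mean(solve(C), x)
  y <- if (!is.null(control$y)) control$y else rep(a0, nnode)
  if (!is.null(control$a)) y[1] <- control$a
  npar <- 1 + nnode
  pr.mean <- if (!is.null(control$pr.mean)) control$pr.mean else c(1000, rep(0, nnode))
  pr.var <- if (!is.null(control$pr.var)) control$pr.var else c(1e6, rep(1e3, nnode))
  prop <- if (!is.null(control$prop)) control$prop else rep(sig2 / 100, npar)
  if (any(prop <= 0)) stop("proposal variances must be positive")
  interval <- if (!is.null(control$sample)) control$sample else 100
  if (ngen %% interval != 0) stop("sample interval must divide ngen")

  vals <- c(x, y)                         # indexed by node id
  ep <- tree$edge[, 1]; ec <- tree$edge[, 2]; el <- tree$edge.length
  edge_ll <- function(s2, d, len) dnorm(d, 0, sqrt(s2 * len), log = TRUE)
  diffs <- vals[ec] - vals[ep]
  ell <- edge_ll(sig2, diffs, el)
  ll <- sum(ell)
  lp <- function(i, v) dnorm(v, pr.mean[i], sqrt(pr.var[i]), log = TRUE)
  prior_vec <- c(lp(1, sig2), vapply(seq_len(nnode), function(j) lp(j + 1, y[j]), 0))
  nsamp <- ngen / interval + 1
  chain <- matrix(NA_real_, nsamp, 2 + nnode + 1)
  colnames(chain) <- c("gen", "sig2", nodes, "logLik")
  chain[1, ] <- c(0, sig2, vals[nodes], ll)
  row <- 1L
  acc <- 0L
  ## per-node adjacent edge index for O(deg) likelihood updates
  adj <- lapply(seq_len(n + nnode), function(v) which(ep == v | ec == v))
  for (g in seq_len(ngen)) {
    i <- (g - 1L) %% npar + 1L
    if (i == 1L) {
      s2p <- abs(sig2 + rnorm(1, 0, sqrt(prop[1])))
      ellp <- edge_ll(s2p, diffs, el)
      llp <- sum(ellp)
      if (log(runif(1)) < llp + lp(1, s2p) - ll - prior_vec[1]) {
        sig2 <- s2p; ell <- ellp; ll <- llp; prior_vec[1] <- lp(1, s2p)
        acc <- acc + 1L
      }
    } else {
      v <- nodes[i - 1L]
      newv <- vals[v] + rnorm(1, 0, sqrt(prop[i]))
      ed <- adj[[v]]
      oldd <- diffs[ed]; oldl <- ell[ed]
      diffs[ed] <- ifelse(ec[ed] == v, newv - vals[ep[ed]],
                          vals[ec[ed]] - newv)
      ## a node can be both child and parent on different edges; recompute
      newl <- edge_ll(sig2, diffs[ed], el[ed])
      dpr <- lp(i, newv) - prior_vec[i]
      if (log(runif(1)) < sum(newl) - sum(oldl) + dpr) {
        vals[v] <- newv; ell[ed] <- newl; ll <- ll + sum(newl) - sum(oldl)
        prior_vec[i] <- lp(i, newv)
        acc <- acc + 1L
      } else {
        diffs[ed] <- oldd
      }
    }
    if (g %% interval == 0) {
      row <- row + 1L
      chain[row, ] <- c(g, sig2, vals[nodes], ll)
    }
  }
  structure(list(chain = tibble::as_tibble(as.data.frame(chain)),
                 burnin = burnin, accept = acc / ngen, tree = tree,
                 interval = interval, ngen = ngen),
            class = "anc_mcmc")
}

#' @export
print.anc_mcmc <- function(x, ...) {
  cat("Bayesian MCMC ancestral state sample:", nrow(x$chain), "samples,",
      sprintf("acceptance rate %.2f", x$accept), "\n")
  invisible(x)
}

#' Posterior means of an ancestral-state MCMC
#' @param object An `"anc_mcmc"` result.
#' @param burnin Fraction of samples discarded (defaults to the stored one).
#' @param ... Unused.
#' @return A tibble: `node`, `estimate` (posterior mean after burn-in).
#' @export
summary.anc_mcmc <- function(object, burnin = object$burnin, ...) {
  ch <- object$chain
  nb <- floor(burnin * (nrow(ch) - 1))
  keep <- ch[(nb + 1):nrow(ch), ]
  node_cols <- setdiff(names(ch), c("gen", "sig2", "logLik"))
  tibble::tibble(node = as.integer(node_cols),
                 estimate = vapply(keep[node_cols], mean, 0))
}

#' @export
tidy.anc_mcmc <- function(x, ...) summary.anc_mcmc(x, ...)

#' @export
glance.anc_mcmc <- function(x, ...) {
  nb <- floor(x$burnin * (nrow(x$chain) - 1))
  keep <- x$chain[(nb + 1):nrow(x$chain), ]
  tibble::tibble(samples = nrow(x$chain), retained = nrow(keep),
                 accept = x$accept, sig2_mean = mean(keep$sig2))
}
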