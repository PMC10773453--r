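## Multi-regime multivariate Brownian motion, penalized-likelihood
## variable-rate BM, and phylogenetic PCA.

## Per-regime shared-path-length matrices from a mapped tree: C_r[i, j] is
## the time spent in regime r along the root -> MRCA(i, j) path.
regime_vcv <- function(tree) {
  validate_mapped(tree)
  states <- sort(unique(unlist(lapply(tree$maps, names))))
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  ## cumulative time in each regime from the root to each node
  cum <- matrix(0, nn, length(states), dimnames = list(NULL, states))
  eo <- rev(ape::postorder(tree))
  for (e in eo) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    m <- tree$maps[[e]]
    cum[ch, ] <- cum[p, ]
    for (s in seq_along(m)) cum[ch, names(m)[s]] <- cum[ch, names(m)[s]] + m[s]
  }
  ## MRCA matrix via postorder tip-set merge (as in phylo_vcv)
  desc <- vector("list", nn)
  for (i in seq_len(n)) desc[[i]] <- i
  mrca <- matrix(0L, n, n)
  po <- ape::postorder(tree)
  for (e in po) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    prev <- desc[[p]]
    if (!is.null(prev)) {
      mrca[prev, desc[[ch]]] <- p
      mrca[desc[[ch]], prev] <- p
    }
    desc[[p]] <- c(prev, desc[[ch]])
  }
  diag(mrca) <- seq_len(n)
  out <- lapply(states, function(s) {
    M <- matrix(cum[mrca, s], n, n,
                dimnames = list(tree$tip.label, tree$tip.label))
    diag(M) <- cum[seq_len(n), s]
    M
  })
  names(out) <- states
  out
}

#' Multi-regime multivariate Brownian motion (two traits)
#'
#' Fits, by maximum likelihood, a hierarchy of bivariate Brownian models on
#' a tree with mapped regimes: (1) common rates and correlation across
#' regimes; (2) regime-specific rates, common correlation; (3) common rates,
#' regime-specific correlations; (4) a free rate/covariance matrix R per
#' regime. Root means are profiled by GLS. The covariance of the stacked
#' trait vector is `sum_r R_r (x) C_r` with C_r the time spent in regime r
#' on shared paths.
#'
#' @param tree A `mapped_phylo` with at least one regime.
#' @param X An n x 2 matrix/data frame of traits, rownames = tip labels.
#' @param models Integer subset of 1:4 (default all).
#' @param nstarts Optimization restarts per model.
#' @param seed Optional seed.
#' @return A list of class `"evolvcv_fit"`, one element per model: `model`,
#'   `R` (list per regime), `a`, `loglik`, `df`, `AIC`, `converged`.
#' @export
evolvcv_lite <- function(tree, X, models = 1:4, nstarts = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  if (ncol(X) != 2) stop("exactly 2 traits required")
  X <- X[tree$tip.label, , drop = FALSE]
  if (qr(stats::cov(X))$rank < 2) stop("rank-deficient trait table")
  Cs <- regime_vcv(tree)
  regimes <- names(Cs)
  nr <- length(regimes)
  n <- nrow(X)
  y <- as.numeric(X)                       # trait-major stacking
  W <- kronecker(diag(2), rep(1, n))
  build_R <- function(s1, s2, r) {
    cv <- r * s1 * s2
    matrix(c(s1^2, cv, cv, s2^2), 2, 2)
  }
  ## par -> list of R per regime, per model
  par_to_R <- function(model, par) {
    switch(as.character(model),
      "1" = { R <- build_R(exp(par[1]), exp(par[2]), tanh(par[3]))
              rep(list(R), nr) },
      "2" = { r <- tanh(par[2 * nr + 1])
              lapply(seq_len(nr), function(i)
                build_R(exp(par[2 * i - 1]), exp(par[2 * i]), r)) },
      "3" = { s1 <- exp(par[1]); s2 <- exp(par[2])
              lapply(seq_len(nr), function(i) build_R(s1, s2, tanh(par[2 + i]))) },
      "4" = lapply(seq_len(nr), function(i)
              build_R(exp(par[3 * i - 2]), exp(par[3 * i - 1]), tanh(par[3 * i]))))
  }
  npar <- c("1" = 3, "2" = 2 * nr + 1, "3" = 2 + nr, "4" = 3 * nr)
  loglik_R <- function(Rs) {
    V <- matrix(0, 2 * n, 2 * n)
    for (i in seq_len(nr)) V <- V + kronecker(Rs[[i]], Cs[[i]])
    cd <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cd)) return(list(ll = -Inf))
    Vi_y <- backsolve(cd, backsolve(cd, y, transpose = TRUE))
    Vi_W <- backsolve(cd, backsolve(cd, W, transpose = TRUE))
    a <- solve(t(W) %*% Vi_W, t(W) %*% Vi_y)
    resid <- y - W %*% a
    z <- backsolve(cd, resid, transpose = TRUE)
    ll <- -n * log(2 * pi) - sum(log(diag(cd))) - sum(z^2) / 2
    list(ll = ll, a = as.numeric(a))
  }
  ## starting values from the pooled single-regime ML
  Ctot <- Reduce(`+`, Cs)
  Ci <- solve(Ctot)
  a0 <- colSums(Ci %*% X) / sum(Ci)
  Xc <- sweep(X, 2, a0)
  R0 <- t(Xc) %*% Ci %*% Xc / n
  s0 <- log(sqrt(diag(R0)))
  r0 <- atanh(max(min(stats::cov2cor(R0)[1, 2], 0.99), -0.99))
  start_for <- function(model) {
    switch(as.character(model),
      "1" = c(s0, r0),
      "2" = c(rep(s0, nr), r0),
      "3" = c(s0, rep(r0, nr)),
      "4" = rep(c(s0, r0), nr))
  }
  fits <- lapply(models, function(model) {
    nll <- function(par) {
      out <- loglik_R(par_to_R(model, par))
      if (!is.finite(out$ll)) 1e10 else -out$ll
    }
    best <- NULL
    for (s in seq_len(nstarts)) {
      st <- start_for(model)
      if (s > 1) st <- st + rnorm(length(st), 0, 0.5)
      opt <- tryCatch(nlminb(st, nll, control = list(iter.max = 2000)),
                      error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$objective < best$objective))
        best <- opt
    }
    Rs <- par_to_R(model, best$par)
    names(Rs) <- regimes
    out <- loglik_R(Rs)
    df <- unname(npar[as.character(model)]) + 2   # + 2 root means
    list(model = model, R = Rs, a = out$a, loglik = out$ll, df = df,
         AIC = 2 * df - 2 * out$ll, converged = best$convergence == 0)
  })
  names(fits) <- paste0("model", models)
  structure(fits, class = "evolvcv_fit", regimes = regimes)
}

#' @export
print.evolvcv_fit <- function(x, ...) {
  lab <- c("common rates, common correlation",
           "different rates, common correlation",
           "common rates, different correlation", "no common structure")
  for (f in x) {
    cat(sprintf("Model %d: %s\n", f$model, lab[f$model]))
    for (r in names(f$R)) {
      R <- f$R[[r]]
      cat(sprintf("  %s  R[1,1]=%.4f R[1,2]=%.4f R[2,2]=%.4f\n",
                  r, R[1, 1], R[1, 2], R[2, 2]))
    }
    cat(sprintf("  k=%d log(L)=%.4f AIC=%.4f\n", f$df, f$loglik, f$AIC))
  }
  invisible(x)
}

#' @export
tidy.evolvcv_fit <- function(x, ...) {
  purrr::map_dfr(x, function(f)
    purrr::map_dfr(names(f$R), function(r)
      tibble::tibble(model = f$model, regime = r,
                     R11 = f$R[[r]][1, 1], R12 = f$R[[r]][1, 2],
                     R22 = f$R[[r]][2, 2], logLik = f$loglik,
                     df = f$df, AIC = f$AIC)))
}

#' Compare the models of an `evolvcv_fit`
#' @param fits An `evolvcv_fit`.
#' @return A [compare_models()] table.
#' @export
compare_evolvcv <- function(fits) {
  wrapped <- lapply(fits, function(f)
    structure(list(loglik = f$loglik, df = f$df), class = "ll_df"))
  names(wrapped) <- paste("model", vapply(fits, `[[`, 0, "model"))
  compare_models(wrapped)
}

#' @export
logLik.ll_df <- function(object, ...)
  structure(object$loglik, df = object$df, class = "logLik")

## ---------------------------------------------------------------------------

## O(n) Brownian ML log-likelihood by postorder peeling, with the root mean
## profiled out (full ML). Returns -Inf for degenerate contrast variances.
bm_peel_loglik <- function(edge_po, ntip, nnode, x, elen) {
  nn <- ntip + nnode
  mu <- numeric(nn); vv <- numeric(nn)
  mu[seq_len(ntip)] <- x
  first <- rep(TRUE, nn)
  ll <- 0
  for (e in seq_len(nrow(edge_po))) {
    p <- edge_po[e, 1]; ch <- edge_po[e, 2]
    v_ch <- vv[ch] + elen[e]
    if (first[p]) { mu[p] <- mu[ch]; vv[p] <- v_ch; first[p] <- FALSE; next }
    vt <- vv[p] + v_ch
    if (vt <= 0) return(-Inf)
    ll <- ll - 0.5 * (log(2 * pi * vt) + (mu[p] - mu[ch])^2 / vt)
    mu[p] <- (mu[p] * v_ch + mu[ch] * vv[p]) / vt
    vv[p] <- vv[p] * v_ch / vt
  }
  root <- ntip + 1L
  if (vv[root] <= 0) return(-Inf)
  ## profiled root mean: the root factor keeps only its normalizing constant
  ll - 0.5 * log(2 * pi * vv[root])
}

#' Variable-rate Brownian motion by penalized likelihood
#'
#' The trait evolves by Brownian motion whose rate sigma^2 itself evolves by
#' geometric Brownian motion (Brownian on the log scale). The objective is
#' the data log-likelihood (edge lengths scaled by edge rates, each edge
#' rate the logarithmic mean of the rates at its two ends -- the exact time
#' average of a rate varying log-linearly along the edge) plus `lambda_pen`
#' times the Brownian log-density of the node ln-rates on the tree (the
#' rate-process scale is absorbed by the penalty coefficient). The data-
#' process root mean is profiled; the rate-process root value is a free
#' parameter.
#'
#' @param tree A `phylo`.
#' @param x Named numeric tip vector.
#' @param lambda_pen Penalty (smoothing) coefficient, > 0; large values
#'   force a near-constant rate.
#' @param seed Unused placeholder for interface symmetry.
#' @return Object of class `"multirate_bm_fit"`: `rates` (tibble: node,
#'   sig2), `lambda_pen`, `loglik_penalized`, `loglik_data`, `converged`.
#' @export
multirate_bm <- function(tree, x, lambda_pen = 1, seed = NULL) {
  if (lambda_pen <= 0) stop("lambda_pen must be > 0")
  n <- ape::Ntip(tree)
  x <- x[tree$tip.label]
  nn <- n + tree$Nnode
  tp <- tree_postorder(tree)
  ## single-rate ML as the starting point
  s2_hat <- single_rate_ml(tree, x)
  objective <- function(ls) {
    rates <- exp(ls)
    escale <- log_mean(rates[tp$edge[, 1]], rates[tp$edge[, 2]])
    ll_data <- bm_peel_loglik(tp$edge, n, tree$Nnode, x, tp$len * escale)
    ll_pen <- bm_peel_full(tp$edge, n, ls, tp$len)
    if (!is.finite(ll_data) || !is.finite(ll_pen)) return(1e10)
    -(ll_data + lambda_pen * ll_pen)
  }
  start <- rep(log(s2_hat), nn)
  opt <- optim(start, objective, method = "L-BFGS-B",
               lower = rep(log(1e-12), nn), upper = rep(log(1e12), nn),
               control = list(maxit = 2000, factr = 1e7))
  ls <- opt$par
  rates <- exp(ls)
  escale <- log_mean(rates[tp$edge[, 1]], rates[tp$edge[, 2]])
  ll_data <- bm_peel_loglik(tp$edge, n, tree$Nnode, x, tp$len * escale)
  structure(list(rates = tibble::tibble(node = seq_len(nn), sig2 = rates),
                 lambda_pen = lambda_pen,
                 loglik_penalized = -opt$value,
                 loglik_data = ll_data,
                 converged = opt$convergence == 0,
                 tree = tree),
            class = "multirate_bm_fit")
}

## logarithmic mean: time-average of a rate varying log-linearly from a to b
log_mean <- function(a, b) {
  out <- (a - b) / (log(a) - log(b))
  eq <- abs(log(a) - log(b)) < 1e-12
  out[eq] <- a[eq]
  out
}

## Brownian log-density of values observed at EVERY node (tips + internals):
## just the product of edge-increment densities; the root value is free.
bm_peel_full <- function(edge_po, ntip, vals, elen) {
  d <- vals[edge_po[, 2]] - vals[edge_po[, 1]]
  sum(dnorm(d, 0, sqrt(elen), log = TRUE))
}

single_rate_ml <- function(tree, x) {
  C <- phylo_vcv(tree)
  x <- x[rownames(C)]
  Ci <- solve(C)
  a <- gls_mean(Ci, x)
  as.numeric(t(x - a) %*% Ci %*% (x - a)) / length(x)
}

#' @export
print.multirate_bm_fit <- function(x, ...) {
  cat(sprintf("Variable-rate BM fit (lambda = %g)\n", x$lambda_pen))
  cat(sprintf("Penalized log-likelihood: %.4f\n", x$loglik_penalized))
  rng <- range(x$rates$sig2)
  cat(sprintf("sig2 range across nodes: [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Phylogenetic principal components analysis
#'
#' Eigen-decomposition of the phylogenetic trait covariance (or correlation):
#' traits are centred on their GLS phylogenetic means and weighted by the
#' inverse phylogenetic covariance. In `"corr"` mode loadings are the
#' correlations between traits and components (all within [-1, 1]).
#'
#' @param tree A `phylo` (a mapped tree is accepted; the mapping is ignored).
#' @param X n x m trait matrix/data frame (n > m >= 2), rownames = tips.
#' @param mode `"cov"` or `"corr"`.
#' @return Object of class `"phyl_pca"`: `sdev` (singular values), `loadings`
#'   (m x m), `scores` (tibble with tip + PC columns), `mode`.
#' @export
phyl_pca <- function(tree, X, mode = c("cov", "corr")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X)
  if (n <= m) stop("need more tips than traits")
  C <- phylo_vcv(tree)
  X <- X[rownames(C), , drop = FALSE]
  Ci <- solve(C)
  a <- colSums(Ci %*% X) / sum(Ci)
  Xc <- sweep(X, 2, a)
  V <- t(Xc) %*% Ci %*% Xc / (n - 1)
  if (min(eigen(V, symmetric = TRUE, only.values = TRUE)$values) < 1e-12)
    stop("singular trait covariance")
  if (mode == "corr") {
    D <- diag(1 / sqrt(diag(V)), m)
    V <- D %*% V %*% D
    Xc <- Xc %*% D
  }
  e <- eigen(V, symmetric = TRUE)
  sdev <- sqrt(pmax(e$values, 0))
  loadings <- e$vectors %*% diag(sdev, m)
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(m)))
  scores <- Xc %*% e$vectors
  colnames(scores) <- paste0("PC", seq_len(m))
  scores_tbl <- dplyr::bind_cols(tibble::tibble(tip = rownames(X)),
                                 tibble::as_tibble(as.data.frame(scores)))
  structure(list(sdev = setNames(sdev, paste0("PC", seq_len(m))),
                 loadings = loadings, scores = scores_tbl, mode = mode),
            class = "phyl_pca")
}

#' @export
print.phyl_pca <- function(x, digits = 7, ...) {
  cat("Phylogenetic pca\nStandard deviations:\n")
  print(round(x$sdev, digits))
  cat("Loads:\n")
  print(round(x$loadings, digits))
  invisible(x)
}
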