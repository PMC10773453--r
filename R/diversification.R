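## Lineage-through-time curves, the gamma statistic, the MCCR test, and
## Yule / birth-death maximum likelihood with an incomplete sampling
## fraction.

#' Lineage-through-time curve
#'
#' Number of reconstructed lineages at each event time (node heights above
#' the root). For an ultrametric extant-only tree the count starts at 2 at
#' the root and jumps by one at every internal node height.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @return Object of class `"ltt_result"`: `curve` (tibble: `time`, `count`,
#'   right-continuous step function), `gamma`, `gamma_p` (two-tailed normal
#'   p), `tree`.
#' @export
ltt_curve <- function(tree) {
  n <- ape::Ntip(tree)
  h <- node_heights(tree)
  internal <- sort(h[(n + 1):(n + tree$Nnode)])
  counts <- 1 + seq_along(internal)
  curve <- tibble::tibble(time = c(internal, max(h)),
                          count = c(counts, n))
  g <- tryCatch(gamma_test(tree), error = function(e) NULL)
  structure(list(curve = curve,
                 gamma = if (!is.null(g)) g$gamma else NA_real_,
                 gamma_p = if (!is.null(g)) g$p_value else NA_real_,
                 tree = tree),
            class = "ltt_result")
}

#' @export
print.ltt_result <- function(x, ...) {
  cat("Lineage-through-time curve for a tree with",
      ape::Ntip(x$tree), "tips\n")
  if (!is.na(x$gamma))
    cat(sprintf("gamma = %.4f, p-value = %.4g\n", x$gamma, x$gamma_p))
  invisible(x)
}

#' Plot a lineage-through-time curve
#' @param object An `"ltt_result"`.
#' @param ... Unused.
#' @export
autoplot.ltt_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$time, y = .data$count)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time since root", y = "lineages") +
    ggplot2::theme_minimal()
}

#' The gamma statistic of lineage accumulation
#'
#' Standardized summary of internode intervals: gamma ~ N(0, 1) under a
#' completely sampled pure-birth process; negative values indicate early
#' lineage accumulation (or missing recent taxa), positive values a pull
#' toward the present.
#'
#' @param tree An ultrametric `phylo` with >= 3 tips.
#' @param tol Ultrametricity tolerance (relative).
#' @return List of class `"gamma_result"`: `gamma`, `p_value` (two-tailed,
#'   `2 * pnorm(-|gamma|)`).
#' @export
gamma_test <- function(tree, tol = 1e-6) {
  n <- ape::Ntip(tree)
  if (n < 3) stop("need at least 3 tips")
  h <- node_heights(tree)
  H <- max(h)
  if (any(abs(h[seq_len(n)] - H) > tol * H)) stop("tree must be ultrametric")
  node_h <- sort(h[(n + 1):(n + tree$Nnode)])
  ## g[k]: duration with k lineages, k = 2..n
  bounds <- c(node_h, H)
  g <- diff(bounds)            # g[k] for k = 2..n (length n-1)
  kk <- 2:n
  T_tot <- sum(kk * g)
  cum <- cumsum(kk * g)        # sum_{k=2}^{i} k g_k at i = 2..n
  num <- sum(cum[1:(n - 2)]) / (n - 2) - T_tot / 2
  gamma <- num / (T_tot * sqrt(1 / (12 * (n - 2))))
  structure(list(gamma = gamma, p_value = 2 * pnorm(-abs(gamma))),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("gamma = %.4f, p-value = %.4g\n", x$gamma, x$p_value))
  invisible(x)
}

#' Monte Carlo constant-rates (MCCR) test of gamma with incomplete sampling
#'
#' Simulates pure-birth trees with `round(n_obs / rho)` tips, randomly prunes
#' them to the observed richness, and uses the resulting gamma values as the
#' null distribution. The two-tailed p is twice the smaller empirical tail
#' (plus-one convention), capped at 1.
#'
#' @param tree An ultrametric `phylo` (the observed tree).
#' @param rho Sampling fraction in (0, 1].
#' @param nsim Number of null simulations (>= 100 recommended).
#' @param seed Optional seed.
#' @return Object of class `"mccr_result"`: `gamma` (observed), `p_value`,
#'   `null` (simulated gamma values).
#' @export
mccr_test <- function(tree, rho = 1, nsim = 1000, seed = NULL) {
  if (rho <= 0 || rho > 1) stop("rho must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n_obs <- ape::Ntip(tree)
  g_obs <- gamma_test(tree)$gamma
  n_full <- max(round(n_obs / rho), n_obs)
  null <- vapply(seq_len(nsim), function(i) {
    tr <- sim_bd_tree(birth = 1, death = 0, ntips = n_full)
    if (n_full > n_obs)
      tr <- drop_tips(tr, sample(tr$tip.label, n_full - n_obs))
    gamma_test(tr)$gamma
  }, 0)
  lower <- (sum(null <= g_obs) + 1) / (nsim + 1)
  upper <- (sum(null >= g_obs) + 1) / (nsim + 1)
  p <- min(1, 2 * min(lower, upper))
  structure(list(gamma = g_obs, p_value = p, null = null, rho = rho),
            class = "mccr_result")
}

#' @export
print.mccr_result <- function(x, ...) {
  cat(sprintf("MCCR test: gamma = %.4f, two-tailed p = %.4g (rho = %g, %d simulations)\n",
              x$gamma, x$p_value, x$rho, length(x$null)))
  invisible(x)
}

## Birth-death log-likelihood of an ultrametric reconstructed tree with
## sampling fraction rho, conditioned on the crown age and survival of both
## crown lineages; includes the (n-1)! labelled-histories constant.
bd_loglik_factory <- function(tree, rho) {
  n <- ape::Ntip(tree)
  h <- node_heights(tree)
  H <- max(h)
  ages <- sort(H - h[(n + 1):(n + tree$Nnode)], decreasing = TRUE)  # from present
  crown <- ages[1]
  other <- ages[-1]
  const <- lfactorial(n - 1)
  function(theta) {
    b <- theta[1]; d <- theta[2]
    if (b <= 0 || d < 0 || b <= d) return(NaN)
    r <- b - d
    denom <- function(t) rho * b + (b * (1 - rho) - d) * exp(-r * t)
    p0 <- function(t) 1 - rho * r / denom(t)
    p1 <- function(t) rho * r^2 * exp(-r * t) / denom(t)^2
    if (any(!is.finite(p1(c(crown, other)))) || any(p1(c(crown, other)) <= 0))
      return(NaN)
    const + sum(log(b * p1(other))) + 2 * log(p1(crown)) - 2 * log(1 - p0(crown))
  }
}

#' Fit a birth-death model to a reconstructed tree
#'
#' Joint maximum likelihood of speciation (b) and extinction (d) rates under
#' the reconstructed-process likelihood with sampling fraction `rho`,
#' conditioned on the crown age and survival of both crown lineages. The
#' fitted object exports the likelihood function (`lik`, callable on
#' `c(b, d)`).
#'
#' @param tree An ultrametric `phylo`.
#' @param rho Sampling fraction in (0, 1].
#' @return Object of class `"bd_fit"`: `b`, `d`, `rho`, `loglik`, `df`,
#'   `AIC`, `lik`, `converged`.
#' @export
fit_bd <- function(tree, rho = 1) {
  if (rho <= 0 || rho > 1) stop("rho must be in (0, 1]")
  lik <- bd_loglik_factory(tree, rho)
  ## optimize over (log(b - d), logit-ish d/b) to avoid the boundary ridge
  nll <- function(par) {
    r <- exp(par[1]); eps <- stats::plogis(par[2])
    b <- r / (1 - eps); d <- b * eps
    v <- lik(c(b, d))
    if (!is.finite(v)) 1e10 else -v
  }
  ## initial growth rate from the Yule estimate
  b0 <- fit_yule(tree, rho)$b
  best <- NULL
  for (st in list(c(log(b0), stats::qlogis(0.05)),
                  c(log(b0 * 0.5), stats::qlogis(0.5)),
                  c(log(b0 * 0.8), stats::qlogis(0.2)))) {
    opt <- tryCatch(optim(st, nll, method = "Nelder-Mead",
                          control = list(maxit = 5000, reltol = 1e-12)),
                    error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  r <- exp(best$par[1]); eps <- stats::plogis(best$par[2])
  b <- r / (1 - eps); d <- b * eps
  ll <- lik(c(b, d))
  structure(list(b = b, d = d, rho = rho, loglik = ll, df = 2L,
                 AIC = 4 - 2 * ll, lik = lik,
                 converged = best$convergence == 0),
            class = "bd_fit")
}

#' Fit a Yule (pure-birth) model to a reconstructed tree
#'
#' Same likelihood as [fit_bd()] constrained to d = 0.
#'
#' @inheritParams fit_bd
#' @return A `"bd_fit"` with `d = 0` and `df = 1`.
#' @export
fit_yule <- function(tree, rho = 1) {
  if (rho <= 0 || rho > 1) stop("rho must be in (0, 1]")
  lik <- bd_loglik_factory(tree, rho)
  f <- function(logb) {
    v <- lik(c(exp(logb), 0))
    if (!is.finite(v)) -1e10 else v
  }
  opt <- optimize(f, c(log(1e-6), log(100)), maximum = TRUE, tol = 1e-10)
  b <- exp(opt$maximum)
  ll <- lik(c(b, 0))
  structure(list(b = b, d = 0, rho = rho, loglik = ll, df = 1L,
                 AIC = 2 - 2 * ll, lik = lik, converged = TRUE),
            class = "bd_fit")
}

#' @export
print.bd_fit <- function(x, ...) {
  cat("Fitted", if (x$df == 1) "Yule" else "birth-death", "model:\n")
  cat(sprintf("ML(b/lambda) = %.4f\n", x$b))
  if (x$df == 2) cat(sprintf("ML(d/mu) = %.4f\n", x$d))
  cat(sprintf("log(L) = %.4f\n", x$loglik))
  cat(sprintf("Assumed sampling fraction (rho) = %.4f\n", x$rho))
  invisible(x)
}

#' @export
logLik.bd_fit <- function(object, ...)
  structure(object$loglik, df = object$df, class = "logLik")

#' @export
glance.bd_fit <- function(x, ...)
  tibble::tibble(b = x$b, d = x$d, rho = x$rho, logLik = x$loglik,
                 df = x$df, AIC = x$AIC)
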