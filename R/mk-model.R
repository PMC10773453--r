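#' Build a design matrix for an extended Mk model
#'
#' A design matrix is a k x k integer template over the trait levels: zeros
#' mark forbidden transitions and equal positive integers tie the
#' corresponding off-diagonal rates of Q into one shared rate class.
#'
#' @param levels Character vector of trait levels (k >= 2).
#' @param model `"ER"` (one shared rate), `"SYM"` (one class per unordered
#'   pair), `"ARD"` (one class per ordered pair), or an explicit k x k
#'   integer matrix with zero diagonal.
#' @return An integer matrix of class `"mk_design"` with level dimnames.
#' @export
#' @examples
#' build_design(c("a", "b"), "ER")
#' build_design(c("a", "b"), matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE))
build_design <- function(levels, model = "ER") {
  k <- length(levels)
  if (k < 2) stop("need at least 2 levels")
  if (is.matrix(model)) {
    if (nrow(model) != k || ncol(model) != k) stop("design matrix must be k x k")
    if (any(model < 0)) stop("design matrix entries must be >= 0")
    D <- model
    diag(D) <- 0L
    ## renumber rate classes to 1..m without gaps
    cls <- sort(unique(D[D > 0]))
    D[D > 0] <- match(D[D > 0], cls)
  } else {
    model <- match.arg(model, c("ER", "SYM", "ARD"))
    D <- matrix(0L, k, k)
    off <- which(row(D) != col(D))
    if (model == "ER") D[off] <- 1L
    else if (model == "ARD") {
      ## classes numbered row-major (reading the matrix row by row)
      m <- 0L
      for (i in 1:k) for (j in 1:k) if (i != j) { m <- m + 1L; D[i, j] <- m }
    } else {
      m <- 0L
      for (i in 1:(k - 1)) for (j in (i + 1):k) {
        m <- m + 1L
        D[i, j] <- m; D[j, i] <- m
      }
    }
  }
  storage.mode(D) <- "integer"
  dimnames(D) <- list(levels, levels)
  structure(D, class = c("mk_design", "matrix"))
}

n_rate_classes <- function(design) if (any(design > 0)) max(design) else 0L

#' Assemble a transition-rate matrix Q from a design and rates
#'
#' @param design An `mk_design` (or integer matrix with level dimnames).
#' @param rates Numeric vector, one rate per rate class.
#' @return A k x k rate matrix whose rows sum to zero.
#' @export
design_to_q <- function(design, rates) {
  m <- n_rate_classes(design)
  if (length(rates) != m) stop("need ", m, " rates")
  Q <- matrix(0, nrow(design), ncol(design), dimnames = dimnames(design))
  pos <- design > 0
  Q[pos] <- rates[design[pos]]
  diag(Q) <- -rowSums(Q)
  Q
}

## --- trait handling ---------------------------------------------------------

## Normalise a tip trait into a list(levels, tipL) where tipL is the n x k
## matrix of tip partial likelihoods in the tree's tip order. `x` may be a
## named factor/character vector; NA or "a+b"-style multi-level entries (when
## `ambiguous_plus` is TRUE) put likelihood 1 on every allowed level.
trait_matrix <- function(tree, x, levels = NULL, ambiguous_plus = FALSE) {
  if (is.matrix(x)) {  # already a tip likelihood matrix
    if (is.null(levels)) levels <- colnames(x)
    tipL <- x[tree$tip.label, , drop = FALSE]
    return(list(levels = levels, tipL = unname(tipL)))
  }
  if (is.null(names(x))) stop("trait vector must be named by tip label")
  miss <- setdiff(tree$tip.label, names(x))
  if (length(miss)) stop("trait missing for tips: ", paste(head(miss, 5), collapse = ", "))
  x <- x[tree$tip.label]
  vals <- as.character(x)
  if (is.null(levels)) {
    lv <- if (is.factor(x)) levels(x) else sort(unique(vals[!is.na(vals)]))
    if (ambiguous_plus) lv <- sort(unique(unlist(strsplit(lv, "+", fixed = TRUE))))
    levels <- lv
  }
  k <- length(levels)
  tipL <- matrix(0, length(vals), k)
  for (i in seq_along(vals)) {
    v <- vals[i]
    if (is.na(v)) { tipL[i, ] <- 1; next }
    states <- if (ambiguous_plus) strsplit(v, "+", fixed = TRUE)[[1]] else v
    idx <- match(states, levels)
    if (anyNA(idx)) stop("tip state '", v, "' not among levels: ", paste(levels, collapse = ", "))
    tipL[i, idx] <- 1
  }
  list(levels = levels, tipL = tipL)
}

resolve_prior <- function(prior, k) {
  if (is.numeric(prior)) {
    if (length(prior) != k) stop("fixed root prior must have length k")
    if (any(prior < 0) || abs(sum(prior) - 1) > 1e-10)
      stop("fixed root prior must be non-negative and sum to 1")
    return(list(kind = "fixed", pi = prior, fitzjohn = FALSE))
  }
  prior <- match.arg(prior, c("equal", "fitzjohn"))
  if (prior == "equal") list(kind = "equal", pi = rep(1 / k, k), fitzjohn = FALSE)
  else list(kind = "fitzjohn", pi = rep(1 / k, k), fitzjohn = TRUE)
}

## postorder edge matrix + lengths, cached pieces used by the pruning engine
tree_postorder <- function(tree) {
  po <- ape::postorder(tree)
  list(edge = tree$edge[po, , drop = FALSE], len = tree$edge.length[po])
}

mk_prune <- function(tree, tipL, Q, prior, want_extras = FALSE) {
  tp <- tree_postorder(tree)
  mk_pruning_cpp(tp$edge, tp$len, ape::Ntip(tree), tipL, Q,
                 prior$pi, prior$fitzjohn, want_extras)
}

#' Log-likelihood of a discrete trait under an Mk model
#'
#' Computes the phylogenetic likelihood by Felsenstein's pruning algorithm,
#' with per-edge transition probabilities `expm(Q t)`. The FitzJohn root
#' prior weights each root state by its share of the conditional likelihood
#' at the root (the root state treated as a nuisance parameter).
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param x Named tip-state vector (factor or character); entries like
#'   `"a+b"` are *not* interpreted here (see [fit_polymk()]); `NA` marks a
#'   missing state (all levels allowed). Alternatively an n x k tip
#'   likelihood matrix with level colnames and tip rownames.
#' @param Q k x k transition-rate matrix with level dimnames.
#' @param prior `"equal"`, `"fitzjohn"`, or a fixed probability vector.
#' @return The log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, x, Q, prior = "equal") {
  lv <- colnames(Q)
  if (is.null(lv)) stop("Q needs level dimnames")
  if (any(!is.finite(Q))) stop("Q must be finite")
  tm <- trait_matrix(tree, x, levels = lv)
  pr <- resolve_prior(prior, length(lv))
  mk_prune(tree, tm$tipL, Q, pr)$loglik
}

## --- ML fitting --------------------------------------------------------------

#' Fit an extended Mk model by maximum likelihood
#'
#' Rates are optimized on the log scale inside the box `[1e-12, 1e3]`, from
#' `nstarts` starting points (the first at a parsimony-informed guess, the
#' rest drawn around it), keeping the best optimum.
#'
#' @inheritParams mk_loglik
#' @param design An `mk_design`, one of `"ER"/"SYM"/"ARD"`, or an explicit
#'   integer matrix (see [build_design()]).
#' @param prior Root prior (see [mk_loglik()]). The flat (`"equal"`) prior is
#'   the default.
#' @param nstarts Number of optimization starts (default 1).
#' @param seed Optional seed for the random restarts.
#' @param levels Optional explicit level set (inferred from `x` otherwise).
#' @return An object of class `"mk_fit"` with elements `design`, `rates`,
#'   `Q`, `prior`, `pi`, `loglik`, `df`, `AIC`, `converged`, plus the tree
#'   and tip data used.
#' @export
#' @examples
#' tr <- parse_tree("((A:1,B:1):1,(C:1,D:1):1);")
#' x <- setNames(c("a", "a", "b", "b"), c("A", "B", "C", "D"))
#' fit <- fit_mk(tr, x, design = "ER")
#' fit$loglik
fit_mk <- function(tree, x, design = "ER", prior = "equal", nstarts = 1,
                   seed = NULL, levels = NULL) {
  tm <- trait_matrix(tree, x, levels = levels)
  lv <- tm$levels
  if (is.character(design) || (is.matrix(design) && !inherits(design, "mk_design")))
    design <- build_design(lv, design)
  if (!identical(rownames(design), lv))
    design <- structure(unclass(design)[lv, lv], class = c("mk_design", "matrix"))
  k <- length(lv)
  m <- n_rate_classes(design)
  if (m == 0L) stop("design allows no transitions")
  pr <- resolve_prior(prior, k)
  if (!is.null(seed)) set.seed(seed)

  nll <- function(logr) {
    Q <- design_to_q(design, exp(logr))
    ll <- mk_prune(tree, tm$tipL, Q, pr)$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }
  ## parsimony-informed rate guess: changes per unit total branch length
  q0 <- max(fitch_score(tree, tm$tipL), 1) / sum(tree$edge.length)
  lb <- log(1e-12); ub <- log(1e3)
  best <- NULL
  ok <- FALSE
  for (s in seq_len(max(1, nstarts))) {
    start <- if (s == 1) rep(log(q0), m) else log(pmin(pmax(rexp(m, 1 / q0), 1e-10), 9e2))
    opt <- tryCatch(
      nlminb(start, nll, lower = lb, upper = ub,
             control = list(iter.max = 2000, eval.max = 4000)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$objective < best$objective) {
      best <- opt
      ok <- opt$convergence == 0
    }
  }
  if (is.null(best)) stop("optimization failed at every start")
  rates <- exp(best$par)
  Q <- design_to_q(design, rates)
  ex <- mk_prune(tree, tm$tipL, Q, pr, want_extras = TRUE)
  loglik <- ex$loglik
  structure(list(design = design, rates = rates, Q = Q,
                 prior = pr$kind, pi = setNames(as.numeric(ex$pi), lv),
                 loglik = loglik, df = m, AIC = 2 * m - 2 * loglik,
                 converged = ok, levels = lv,
                 tree = tree, tipL = tm$tipL, data = x),
            class = "mk_fit")
}

## Fitch parsimony score on possibly ambiguous tip sets (rough rate guess and
## a cheap sanity statistic; ties resolved implicitly by set intersection).
fitch_score <- function(tree, tipL) {
  nn <- ape::Ntip(tree) + tree$Nnode
  k <- ncol(tipL)
  S <- matrix(FALSE, nn, k)
  S[seq_len(nrow(tipL)), ] <- tipL > 0
  score <- 0L
  tp <- tree_postorder(tree)
  first <- rep(TRUE, nn)
  for (e in seq_len(nrow(tp$edge))) {
    p <- tp$edge[e, 1]; ch <- tp$edge[e, 2]
    if (first[p]) { S[p, ] <- S[ch, ]; first[p] <- FALSE; next }
    inter <- S[p, ] & S[ch, ]
    if (any(inter)) S[p, ] <- inter
    else { S[p, ] <- S[p, ] | S[ch, ]; score <- score + 1L }
  }
  score
}

#' @export
logLik.mk_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, class = "logLik")
}

#' @export
print.mk_fit <- function(x, digits = 6, ...) {
  cat("Extended Mk model fit\n")
  cat("Levels: [", paste(x$levels, collapse = ", "), "]\n")
  cat("Fitted Q:\n")
  print(round(x$Q, digits))
  cat("Root prior:", x$prior, "(",
      paste(round(x$pi, 4), collapse = ", "), ")\n")
  cat(sprintf("Log-likelihood: %.*f   d.f.: %d   AIC: %.*f\n",
              digits, x$loglik, x$df, digits, x$AIC))
  if (!x$converged) cat("warning: optimizer did not report convergence\n")
  invisible(x)
}

#' Tidy the fitted rates of an Mk model
#' @param x An `mk_fit`.
#' @param ... Unused.
#' @return A tibble with one row per allowed transition: `from`, `to`,
#'   `rate_class`, `rate`.
#' @export
tidy.mk_fit <- function(x, ...) {
  idx <- which(x$design > 0, arr.ind = TRUE)
  tibble::tibble(from = x$levels[idx[, 1]], to = x$levels[idx[, 2]],
                 rate_class = as.integer(x$design[idx]),
                 rate = x$rates[x$design[idx]]) |>
    dplyr::arrange(.data$rate_class)
}

#' @export
glance.mk_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, df = x$df, AIC = x$AIC,
                 converged = x$converged)
}

#' Compare fitted models by AIC and Akaike weight
#'
#' Accepts any fitted objects exposing `logLik()` with a `df` attribute
#' (Mk fits, polymorphic/hidden-rate fits, birth-death fits, ...). The
#' Akaike weight of model i is `exp(-dAIC_i/2) / sum_j exp(-dAIC_j/2)`.
#'
#' @param ... Fitted model objects (or a single list of them).
#' @return A tibble of class `"model_table"` with columns `model`, `logLik`,
#'   `df`, `AIC`, `weight`; the fits travel along as attribute `"fits"`.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !is.object(fits[[1]]))
    fits <- fits[[1]]
  nm <- names(fits)
  if (is.null(nm) || any(!nzchar(nm))) {
    cl <- match.call(expand.dots = FALSE)$...
    nm2 <- vapply(cl, function(e) paste(deparse(e), collapse = ""), "")
    if (length(nm2) == length(fits)) nm <- nm2 else nm <- paste0("model", seq_along(fits))
  }
  ll <- vapply(fits, function(f) as.numeric(logLik(f)), 0)
  df <- vapply(fits, function(f) attr(logLik(f), "df"), 0)
  aic <- 2 * df - 2 * ll
  d <- aic - min(aic)
  w <- exp(-d / 2); w <- w / sum(w)
  out <- tibble::tibble(model = nm, logLik = unname(ll),
                        df = as.integer(unname(df)),
                        AIC = unname(aic), weight = unname(w))
  attr(out, "fits") <- setNames(fits, nm)
  class(out) <- c("model_table", class(out))
  out
}

#' @export
print.model_table <- function(x, ...) {
  df <- as.data.frame(x)
  colnames(df) <- c("", "log(L)", "d.f.", "AIC", "weight")
  print(df, row.names = FALSE)
  invisible(x)
}
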