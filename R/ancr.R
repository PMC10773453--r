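#' Ancestral state reconstruction under fitted Mk-type models
#'
#' Marginal reconstruction gives, for each node, the probability of each
#' state conditioned on all tip data (the standard two-pass algorithm:
#' postorder conditional likelihoods, then a preorder "outside" pass). Joint
#' reconstruction returns the single most probable assignment of states to
#' all nodes (max-product with traceback; ties broken toward the lowest
#' state index). Passing a [compare_models()] table whose fits share the
#' tree and trait yields model-averaged marginals, weighted by Akaike
#' weight.
#'
#' @param fit An `mk_fit`, or a `model_table` carrying Mk-type fits.
#' @param method `"marginal"` or `"joint"`.
#' @param tips Also return rows for the tips (marginal only).
#' @return For `"marginal"`, an object of class `"ancr"`: a tibble with
#'   `node` plus one probability column per state (rows sum to 1). For
#'   `"joint"`, a named character vector of states indexed by node id.
#' @export
ancr <- function(fit, method = c("marginal", "joint"), tips = FALSE) {
  method <- match.arg(method)
  if (inherits(fit, "model_table")) {
    fits <- attr(fit, "fits")
    if (method == "joint") stop("joint reconstruction requires a single model")
    lv <- fits[[1]]$levels
    tr <- fits[[1]]$tree
    for (f in fits) {
      if (!identical(f$levels, lv) || !identical(f$tree$edge, tr$edge))
        stop("model averaging requires fits on the same tree and state space")
    }
    margs <- lapply(fits, ancr_marginal, tips = tips)
    P <- Reduce(`+`, Map(function(m, w) w * m, margs, fit$weight))
    return(ancr_table(P, lv, fits[[1]], tips))
  }
  if (!inherits(fit, "mk_fit")) stop("fit must be an mk_fit or model_table")
  if (method == "joint") return(ancr_joint(fit))
  ancr_table(ancr_marginal(fit, tips = tips), fit$levels, fit, tips)
}

ancr_table <- function(P, lv, fit, tips) {
  n <- ape::Ntip(fit$tree)
  nodes <- if (tips) seq_len(nrow(P)) else (n + 1):(n + fit$tree$Nnode)
  out <- tibble::as_tibble(as.data.frame(P[nodes, , drop = FALSE]))
  names(out) <- lv
  out <- dplyr::bind_cols(tibble::tibble(node = as.integer(nodes)), out)
  structure(out, class = c("ancr", class(out)), levels = lv,
            loglik = fit$loglik)
}

## marginal probabilities for all nodes (matrix (2n-1) x k, rows sum to 1)
ancr_marginal <- function(fit, tips = FALSE) {
  tree <- fit$tree
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  k <- length(fit$levels)
  pr <- resolve_prior(if (fit$prior == "fixed") fit$pi else fit$prior, k)
  ex <- mk_prune(tree, fit$tipL, fit$Q, pr, want_extras = TRUE)
  L <- ex$partials
  P <- ex$P
  pi <- as.numeric(ex$pi)  # fitzjohn prior resolved at the fit
  tp <- tree_postorder(tree)
  nedge <- nrow(tp$edge)
  ## downward messages per (postordered) edge
  msg <- matrix(0, nedge, k)
  for (e in seq_len(nedge)) msg[e, ] <- P[, , e] %*% L[tp$edge[e, 2], ]
  kids <- split(seq_len(nedge), tp$edge[, 1])
  U <- matrix(0, nn, k)
  U[ntip + 1, ] <- pi
  for (e in rev(seq_len(nedge))) {   # preorder
    p <- tp$edge[e, 1]; ch <- tp$edge[e, 2]
    sib <- setdiff(kids[[as.character(p)]], e)
    other <- U[p, ]
    for (s in sib) other <- other * msg[s, ]
    if (sum(other) > 0) other <- other / sum(other)
    u <- as.numeric(t(P[, , e]) %*% other)
    if (sum(u) > 0) u <- u / sum(u)
    U[ch, ] <- u
  }
  M <- U * L
  rs <- rowSums(M)
  rs[rs == 0] <- 1
  M <- M / rs
  colnames(M) <- fit$levels
  M
}

ancr_joint <- function(fit) {
  tree <- fit$tree
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  k <- length(fit$levels)
  pr <- resolve_prior(if (fit$prior == "fixed") fit$pi else fit$prior, k)
  ex <- mk_prune(tree, fit$tipL, fit$Q, pr, want_extras = TRUE)
  P <- ex$P
  pi <- as.numeric(ex$pi)
  tp <- tree_postorder(tree)
  nedge <- nrow(tp$edge)
  ## D[v, i]: log of best subtree likelihood below v given state i at v
  D <- matrix(0, nn, k)
  D[seq_len(ntip), ] <- log(fit$tipL)
  back <- vector("list", nedge)  # best child state given parent state
  Medge <- matrix(0, nedge, k)   # max-message to parent
  for (e in seq_len(nedge)) {
    p <- tp$edge[e, 1]; ch <- tp$edge[e, 2]
    W <- log(P[, , e]) + matrix(D[ch, ], k, k, byrow = TRUE)  # W[j, i]
    bi <- apply(W, 1, which.max)                              # lowest index on ties
    back[[e]] <- bi
    Medge[e, ] <- W[cbind(seq_len(k), bi)]
    D[p, ] <- D[p, ] + Medge[e, ]
  }
  root <- ntip + 1L
  state <- integer(nn)
  state[root] <- which.max(log(pi) + D[root, ])
  for (e in rev(seq_len(nedge)))
    state[tp$edge[e, 2]] <- back[[e]][state[tp$edge[e, 1]]]
  setNames(fit$levels[state], seq_len(nn))
}

#' @export
print.ancr <- function(x, printlen = 10, ...) {
  cat("Marginal ancestral state estimates:\n")
  print(as.data.frame(head(x, printlen)), row.names = FALSE, digits = 6)
  if (nrow(x) > printlen) cat("...\n")
  ll <- attr(x, "loglik")
  if (!is.null(ll)) cat(sprintf("\nLog-likelihood = %f\n", ll))
  invisible(x)
}

#' Simulate a discrete character along a tree
#'
#' Forward simulation of the continuous-time Markov chain defined by `Q`
#' down every edge.
#'
#' @param tree A `phylo` with branch lengths.
#' @param Q Transition-rate matrix with level dimnames.
#' @param root_state Optional fixed root state (label); otherwise the root is
#'   drawn from `root_prior`.
#' @param root_prior Probability vector over levels (default uniform).
#' @param history If `TRUE`, also return the full realized history as a
#'   `mapped_phylo` (element `tree` of the result).
#' @param seed Optional seed.
#' @return A named factor of tip states; with `history = TRUE`, a list with
#'   elements `states` and `tree`.
#' @export
sim_mk <- function(tree, Q, root_state = NULL, root_prior = NULL,
                   history = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lv <- colnames(Q)
  k <- length(lv)
  nn <- ape::Ntip(tree) + tree$Nnode
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  root <- ape::Ntip(tree) + 1L
  st <- integer(nn)
  st[root] <- if (!is.null(root_state)) match(root_state, lv)
              else sample.int(k, 1, prob = root_prior)
  maps <- vector("list", nrow(tree$edge))
  eo <- rev(ape::postorder(tree))
  for (e in eo) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    sim <- sim_ctmc_path(st[p], Q, tree$edge.length[e])
    st[ch] <- sim$end
    maps[[e]] <- setNames(sim$dur, lv[sim$states])
  }
  states <- factor(lv[st[seq_len(ape::Ntip(tree))]], levels = lv)
  names(states) <- tree$tip.label
  if (!history) return(states)
  list(states = states, tree = as_mapped_phylo(tree, maps))
}

## unconditional CTMC path of duration t from state a (indices)
sim_ctmc_path <- function(a, Q, t) {
  states <- a; dur <- numeric(0)
  cur <- a; left <- t
  repeat {
    rate <- -Q[cur, cur]
    if (rate <= 0) { dur <- c(dur, left); break }
    w <- rexp(1, rate)
    if (w >= left) { dur <- c(dur, left); break }
    dur <- c(dur, w); left <- left - w
    p <- Q[cur, ]; p[cur] <- 0
    cur <- sample.int(length(p), 1, prob = p)
    states <- c(states, cur)
  }
  if (t == 0) { states <- a; dur <- 0 }
  list(states = states, dur = dur, end = cur)
}
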