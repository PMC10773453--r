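## Shared fixtures and independent oracles.

## Brute-force Mk likelihood: sum over every internal-node state assignment,
## with transition probabilities from Matrix::expm (independent of the
## package's pruning engine and of its own matrix exponential).
brute_mk_loglik <- function(tree, tipstates, Q, pi) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  k <- nrow(Q)
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(Q * tree$edge.length[e])))
  ints <- (n + 1):nn
  grid <- as.matrix(expand.grid(rep(list(1:k), length(ints))))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    st <- integer(nn)
    st[ints] <- grid[g, ]
    st[1:n] <- tipstates
    pr <- pi[st[n + 1]]
    for (e in seq_len(nrow(tree$edge)))
      pr <- pr * P[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
    tot <- tot + pr
  }
  log(tot)
}

## Brute-force marginal probabilities at every node, same enumeration.
brute_mk_marginals <- function(tree, tipstates, Q, pi) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  k <- nrow(Q)
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(Q * tree$edge.length[e])))
  ints <- (n + 1):nn
  grid <- as.matrix(expand.grid(rep(list(1:k), length(ints))))
  M <- matrix(0, nn, k)
  for (g in seq_len(nrow(grid))) {
    st <- integer(nn)
    st[ints] <- grid[g, ]
    st[1:n] <- tipstates
    pr <- pi[st[n + 1]]
    for (e in seq_len(nrow(tree$edge)))
      pr <- pr * P[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
    M[cbind(seq_len(nn), st)] <- M[cbind(seq_len(nn), st)] + pr
  }
  M / rowSums(M)
}

random_q <- function(k, scale = 1) {
  Q <- matrix(rexp(k * k, 1 / scale), k, k)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(letters[1:k], letters[1:k])
  Q
}

four_tip_shapes <- function() c(
  "((A:1,B:2):1.5,(C:0.7,D:1):2);",
  "(((A:1,B:1):1,C:2):1,D:3);",
  "(A:2,(B:1,(C:0.5,D:0.5):0.5):1);")

## patristic distances by explicit root-to-tip path sums
path_patristic <- function(tree) {
  h <- node_heights(tree)
  C <- phylo_vcv(tree)
  outer(diag(C), diag(C), "+") - 2 * C
}

load_phytools_data <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "phytools", envir = e)
  get(name, envir = e)
}
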