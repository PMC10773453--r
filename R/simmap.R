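#' Sample stochastic character maps under fitted Mk-type models
#'
#' Draws full character histories consistent with the tip data: node states
#' are sampled from their joint conditional distribution (root from the
#' prior times the root conditional likelihoods, then preorder conditional
#' on the sampled parent), and each edge's path is simulated conditioned on
#' its endpoint states (forward rejection sampling with a retry cap, falling
#' back to uniformization). Passing a [compare_models()] table samples the
#' generating model for each replicate in proportion to its Akaike weight,
#' integrating over model-selection uncertainty.
#'
#' @param fit An `mk_fit` or a `model_table` of Mk-type fits sharing one
#'   tree and trait.
#' @param nsim Number of maps (default 100).
#' @param weighted With a `model_table`: sample models by weight (`TRUE`,
#'   default) or use only the best model.
#' @param seed Optional seed.
#' @return An object of class `"map_set"`: list with `maps` (list of
#'   `mapped_phylo`), `models` (tibble: replicate, model), `levels`, `tree`.
#' @export
sample_maps <- function(fit, nsim = 100, weighted = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(fit, "model_table")) {
    fits <- attr(fit, "fits")
    w <- if (weighted) fit$weight else as.numeric(fit$AIC == min(fit$AIC))
    pick <- sample.int(length(fits), nsim, replace = TRUE, prob = w)
    model_names <- fit$model[pick]
  } else {
    fits <- list(fit)
    pick <- rep(1L, nsim)
    model_names <- rep("model", nsim)
  }
  lv <- fits[[1]]$levels
  tree <- fits[[1]]$tree
  ## per-model pruning artifacts, computed once
  arts <- lapply(fits, function(f) {
    pr <- resolve_prior(if (f$prior == "fixed") f$pi else f$prior, length(lv))
    ex <- mk_prune(f$tree, f$tipL, f$Q, pr, want_extras = TRUE)
    tp <- tree_postorder(f$tree)
    list(Q = f$Q, L = ex$partials, P = ex$P, pi = as.numeric(ex$pi), tp = tp)
  })
  maps <- vector("list", nsim)
  for (s in seq_len(nsim)) maps[[s]] <- draw_one_map(tree, arts[[pick[s]]], lv)
  structure(list(maps = maps,
                 models = tibble::tibble(replicate = seq_len(nsim),
                                         model = model_names),
                 levels = lv, tree = tree, seed = seed),
            class = "map_set")
}

#' @export
print.map_set <- function(x, ...) {
  cat(length(x$maps), "phylogenetic trees with mapped discrete characters\n")
  invisible(x)
}

draw_one_map <- function(tree, art, lv) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  k <- length(lv)
  tp <- art$tp
  st <- integer(nn)
  root <- ntip + 1L
  p0 <- art$pi * art$L[root, ]
  st[root] <- sample.int(k, 1, prob = p0)
  nedge <- nrow(tp$edge)
  for (e in rev(seq_len(nedge))) {  # preorder
    pnode <- tp$edge[e, 1]; ch <- tp$edge[e, 2]
    pr <- art$P[st[pnode], , e] * art$L[ch, ]
    st[ch] <- sample.int(k, 1, prob = pr)
  }
  ## endpoint-conditioned paths, in the tree's own edge order
  maps <- vector("list", nrow(tree$edge))
  eidx <- match(paste(tree$edge[, 1], tree$edge[, 2]),
                paste(tp$edge[, 1], tp$edge[, 2]))
  for (r in seq_len(nrow(tree$edge))) {
    a <- st[tree$edge[r, 1]]; b <- st[tree$edge[r, 2]]
    path <- sample_conditioned_path(a, b, art$Q, tree$edge.length[r])
    maps[[r]] <- setNames(path$dur, lv[path$states])
  }
  as_mapped_phylo(tree, maps)
}

## CTMC path from a to b over duration t: rejection sampling (retry cap),
## then uniformization.
sample_conditioned_path <- function(a, b, Q, t, retry = 1000) {
  if (t <= 0) return(list(states = b, dur = t))
  for (i in seq_len(retry)) {
    sim <- sim_ctmc_path(a, Q, t)
    if (sim$end == b) return(sim)
  }
  uniformization_path(a, b, Q, t)
}

uniformization_path <- function(a, b, Q, t) {
  k <- nrow(Q)
  mu <- max(-diag(Q))
  if (mu <= 0) return(list(states = b, dur = t))
  R <- diag(k) + Q / mu
  ## transition probability for normalization
  Pt <- as.matrix(Matrix_expm(Q * t))
  pb <- Pt[a, b]
  ## sample number of virtual jumps m | endpoints
  u <- runif(1)
  cum <- 0
  Rpow <- diag(k)
  m <- 0
  repeat {
    pm <- stats::dpois(m, mu * t) * Rpow[a, b] / pb
    cum <- cum + pm
    if (u <= cum || m > 10000) break
    m <- m + 1
    Rpow <- Rpow %*% R
  }
  if (m == 0) return(list(states = b, dur = t))
  ## jump times uniform; intermediate states by forward-backward sampling
  times <- sort(runif(m, 0, t))
  Rpows <- vector("list", m + 1)
  Rpows[[1]] <- diag(k)
  for (i in seq_len(m)) Rpows[[i + 1]] <- Rpows[[i]] %*% R
  states <- integer(m)
  cur <- a
  for (l in seq_len(m)) {
    w <- R[cur, ] * Rpows[[m - l + 1]][, b]
    states[l] <- sample.int(k, 1, prob = w)
    cur <- states[l]
  }
  ## collapse virtual (self) jumps
  seq_states <- c(a, states)
  seq_times <- c(0, times, t)
  keep <- c(TRUE, diff(seq_states) != 0)
  ss <- seq_states[keep]
  tt <- seq_times[c(keep, TRUE)]
  dur <- diff(tt)
  list(states = ss, dur = dur, end = ss[length(ss)])
}

## small local expm (series/scaling) to avoid a hard Matrix dependency
Matrix_expm <- function(A) {
  e <- eigen(A)
  if (any(abs(Im(e$values)) > 0) || rcond_ok(e$vectors)) {
    V <- e$vectors
    out <- V %*% diag(exp(e$values), nrow(A)) %*% solve(V)
    return(Re(out))
  }
  ## fallback: scaling and squaring with Taylor series
  n <- nrow(A)
  j <- max(0, ceiling(log2(max(1e-16, norm(A, "1")))))
  As <- A / 2^j
  X <- diag(n); term <- diag(n)
  for (i in 1:20) { term <- term %*% As / i; X <- X + term }
  for (i in seq_len(j)) X <- X %*% X
  X
}
rcond_ok <- function(V) {
  rc <- tryCatch(rcond(V), error = function(e) 0)
  is.finite(rc) && rc > 1e-10
}

#' Summarize a set of stochastic maps
#'
#' @param maps A `map_set`.
#' @return A list of class `"map_summary"`: `node_freq` (tibble: node plus
#'   per-state frequency columns, rows summing to 1), `mean_changes`
#'   (tibble: from, to, mean count per map), `n_maps`.
#' @export
summarize_maps <- function(maps) {
  stopifnot(inherits(maps, "map_set"))
  lv <- maps$levels
  k <- length(lv)
  tree <- maps$tree
  nn <- ape::Ntip(tree) + tree$Nnode
  freq <- matrix(0, nn, k, dimnames = list(NULL, lv))
  chg <- matrix(0, k, k, dimnames = list(lv, lv))
  for (m in maps$maps) {
    st <- mapped_node_states(m)
    freq[cbind(seq_len(nn), match(st, lv))] <- freq[cbind(seq_len(nn), match(st, lv))] + 1
    chg <- chg + count_changes(m, lv)
  }
  freq <- freq / length(maps$maps)
  chg <- chg / length(maps$maps)
  node_freq <- dplyr::bind_cols(
    tibble::tibble(node = seq_len(nn)),
    tibble::as_tibble(as.data.frame(freq)))
  idx <- which(row(chg) != col(chg), arr.ind = TRUE)
  mean_changes <- tibble::tibble(from = lv[idx[, 1]], to = lv[idx[, 2]],
                                 mean = chg[idx])
  structure(list(node_freq = node_freq, mean_changes = mean_changes,
                 n_maps = length(maps$maps)),
            class = "map_summary")
}

#' @export
print.map_summary <- function(x, ...) {
  cat(x$n_maps, "maps summarized; mean changes per type:\n")
  print(as.data.frame(x$mean_changes), row.names = FALSE)
  invisible(x)
}

count_changes <- function(map, lv) {
  k <- length(lv)
  chg <- matrix(0, k, k)
  for (m in map$maps) {
    if (length(m) < 2) next
    s <- match(names(m), lv)
    for (i in seq_len(length(s) - 1)) chg[s[i], s[i + 1]] <- chg[s[i], s[i + 1]] + 1
  }
  chg
}

#' Distribution of state changes across stochastic maps
#'
#' Counts changes of each (ordered) type per map and summarizes the sampled
#' distribution, including a 95% highest-posterior-density interval computed
#' as the shortest contiguous interval of the empirical distribution.
#'
#' @param maps A `map_set`.
#' @param hpd Coverage for the HPD interval (default 0.95).
#' @return An object of class `"change_density"`: tibble `summary` (from,
#'   to, mean, median, min, max, hpd_lower, hpd_upper) and matrix `draws`
#'   (maps x transition types).
#' @export
change_density <- function(maps, hpd = 0.95) {
  stopifnot(inherits(maps, "map_set"))
  lv <- maps$levels
  k <- length(lv)
  nm <- length(maps$maps)
  pairs <- which(row(diag(k)) != col(diag(k)), arr.ind = TRUE)
  draws <- matrix(0L, nm, nrow(pairs))
  colnames(draws) <- paste0(lv[pairs[, 1]], "->", lv[pairs[, 2]])
  for (s in seq_len(nm)) {
    chg <- count_changes(maps$maps[[s]], lv)
    draws[s, ] <- chg[pairs]
  }
  summ <- purrr::map_dfr(seq_len(ncol(draws)), function(j) {
    v <- draws[, j]
    h <- hpd_interval(v, hpd)
    tibble::tibble(from = lv[pairs[j, 1]], to = lv[pairs[j, 2]],
                   mean = mean(v), median = stats::median(v),
                   min = min(v), max = max(v),
                   hpd_lower = h[1], hpd_upper = h[2])
  })
  structure(list(summary = summ, draws = draws, coverage = hpd),
            class = "change_density")
}

## shortest contiguous interval covering >= `coverage` of the sample
hpd_interval <- function(v, coverage = 0.95) {
  s <- sort(v)
  n <- length(s)
  m <- ceiling(coverage * n)
  if (m >= n) return(c(s[1], s[n]))
  widths <- s[(m + 1):n] - s[1:(n - m)]
  i <- which.min(widths)
  c(s[i], s[i + m])
}

#' @export
print.change_density <- function(x, ...) {
  cat("Distribution of changes from stochastic mapping:\n")
  print(as.data.frame(x$summary), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Posterior density of a binary mapped character along every edge
#'
#' Each edge is discretized into `res` equal segments; the value at grid
#' point i (the tipward end of segment i, a fraction `i/res` along the
#' edge) is the fraction of maps in the *second* state at that point.
#'
#' @param maps A `map_set` over a binary character.
#' @param res Grid resolution per edge (default 100).
#' @return A tibble of class `"density_map"`: `edge`, `position` (fraction
#'   along edge), `prob` (posterior probability of the second state).
#' @export
density_map <- function(maps, res = 100) {
  stopifnot(inherits(maps, "map_set"))
  lv <- maps$levels
  if (length(lv) != 2) stop("density_map requires a binary mapped character")
  tree <- maps$tree
  nm <- length(maps$maps)
  out <- vector("list", nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    len <- tree$edge.length[e]
    pos <- seq_len(res) / res
    acc <- numeric(res)
    for (m in maps$maps) {
      seg <- m$maps[[e]]
      cut <- cumsum(seg)
      idx <- findInterval(pos * len, cut, left.open = TRUE) + 1
      idx[idx > length(seg)] <- length(seg)
      acc <- acc + (names(seg)[idx] == lv[2])
    }
    out[[e]] <- tibble::tibble(edge = e, position = pos, prob = acc / nm)
  }
  res_tbl <- dplyr::bind_rows(out)
  class(res_tbl) <- c("density_map", class(res_tbl))
  res_tbl
}

#' Lineages through time, split by mapped state
#'
#' For each map, counts the number of lineages in each state at every event
#' time (node heights and within-edge state changes); also returns the
#' pointwise mean across maps on the union time grid. At any time the state
#' counts sum to the total number of reconstructed lineages.
#'
#' @param maps A `map_set`.
#' @return A list of class `"ltt_by_state"`: `curves` (tibble: replicate,
#'   time, state, count) and `mean` (tibble: time, state, count).
#' @export
ltt_by_state <- function(maps) {
  stopifnot(inherits(maps, "map_set"))
  lv <- maps$levels
  tree <- maps$tree
  h <- node_heights(tree)
  H <- max(h)
  per_map <- vector("list", length(maps$maps))
  all_times <- sort(unique(c(0, h)))
  for (s in seq_along(maps$maps)) {
    m <- maps$maps[[s]]
    ## segment intervals in height coordinates
    st <- character(0); lo <- numeric(0); hi <- numeric(0)
    for (e in seq_len(nrow(tree$edge))) {
      base <- h[tree$edge[e, 1]]
      seg <- m$maps[[e]]
      ends <- base + cumsum(seg)
      starts <- c(base, head(ends, -1))
      st <- c(st, names(seg)); lo <- c(lo, starts); hi <- c(hi, ends)
    }
    times <- sort(unique(c(0, lo, hi)))
    times <- times[times < H]
    ## count segments covering each time (right-continuous: t in [lo, hi))
    cnt <- matrix(0L, length(times), length(lv))
    for (j in seq_along(lv)) {
      sel <- st == lv[j]
      if (!any(sel)) next
      cnt[, j] <- vapply(times, function(t) sum(lo[sel] <= t & hi[sel] > t), 0L)
    }
    ## at t = 0 count the root's two daughter edges
    per_map[[s]] <- tibble::tibble(
      replicate = s,
      time = rep(times, length(lv)),
      state = rep(lv, each = length(times)),
      count = as.integer(cnt))
    all_times <- sort(unique(c(all_times, times)))
  }
  curves <- dplyr::bind_rows(per_map)
  ## pointwise mean on the union grid (step functions, right-continuous)
  mean_tbl <- purrr::map_dfr(seq_along(maps$maps), function(s) {
    d <- per_map[[s]]
    purrr::map_dfr(lv, function(state) {
      dd <- d[d$state == state, ]
      idx <- findInterval(all_times, dd$time)
      idx[idx == 0] <- 1
      tibble::tibble(replicate = s, time = all_times, state = state,
                     count = dd$count[idx])
    })
  }) |>
    dplyr::group_by(.data$time, .data$state) |>
    dplyr::summarise(count = mean(.data$count), .groups = "drop")
  structure(list(curves = curves, mean = mean_tbl, levels = lv),
            class = "ltt_by_state")
}

#' @export
print.ltt_by_state <- function(x, ...) {
  cat("Lineages-through-time by state over", max(x$curves$replicate), "maps\n")
  invisible(x)
}

#' Plot mean lineages-through-time by state
#' @param object An `"ltt_by_state"` result.
#' @param ... Unused.
#' @export
autoplot.ltt_by_state <- function(object, ...) {
  ggplot2::ggplot(object$mean,
                  ggplot2::aes(x = .data$time, y = .data$count,
                               colour = .data$state)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time since root", y = "lineages") +
    ggplot2::theme_minimal()
}
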