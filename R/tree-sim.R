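#' Simulate a birth-death tree (Gillespie algorithm)
#'
#' Forward simulation with exponential waiting times starting from two crown
#' lineages. With `ntips` stopping, the simulation runs until the target
#' number of extant lineages is first reached, then the present is placed at
#' the end of one further waiting time (just before the next event would
#' occur), so the final inter-event interval is properly represented. Runs in
#' which the clade dies out before the stopping condition are re-simulated,
#' up to `max_tries` attempts.
#'
#' @param birth Speciation rate (> 0), per lineage per unit time.
#' @param death Extinction rate (>= 0).
#' @param ntips Stop when this many lineages are extant (mutually exclusive
#'   with `time`).
#' @param time Stop at this simulation time.
#' @param prune_extinct Drop lineages extinct before the present (returns the
#'   reconstructed tree). Default `TRUE`.
#' @param seed Optional integer seed for reproducibility.
#' @param max_tries Resimulation cap when conditioning on survival.
#' @return An ultrametric `phylo` (tips labelled `t1`, `t2`, ...).
#' @export
#' @examples
#' tr <- sim_bd_tree(birth = 1, ntips = 50, seed = 1)
#' ape::Ntip(tr)
sim_bd_tree <- function(birth, death = 0, ntips = NULL, time = NULL,
                        prune_extinct = TRUE, seed = NULL, max_tries = 1000) {
  if (birth <= 0) stop("birth rate must be > 0")
  if (death < 0) stop("death rate must be >= 0")
  if (is.null(ntips) == is.null(time))
    stop("give exactly one of `ntips` or `time`")
  if (!is.null(ntips) && ntips < 2) stop("ntips must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(max_tries)) {
    res <- sim_bd_once(birth, death, ntips, time)
    if (!is.null(res)) {
      tr <- build_phylo_from_events(res)
      if (prune_extinct && any(res$extinct)) {
        extinct_tips <- tr$tip.label[res$extinct[match(tr$tip.label, res$tip_name)]]
        if (ape::Ntip(tr) - length(extinct_tips) < 2) next
        tr <- ape::drop.tip(tr, extinct_tips)
      }
      return(tr)
    }
  }
  stop("all lineages went extinct in every attempt (", max_tries, " tries)")
}

## One forward pass. Returns NULL on extinction before the stop condition.
## Lineages are rows of a growing record: parent lineage, start time, end
## time, and fate (0 = extant at present, 1 = extinct, 2 = speciated).
sim_bd_once <- function(birth, death, ntips, time) {
  par <- c(0L, 0L); t0 <- c(0, 0); t1 <- c(NA_real_, NA_real_); fate <- c(NA_integer_, NA_integer_)
  active <- c(1L, 2L)
  t <- 0
  rate_tot <- function() length(active) * (birth + death)
  repeat {
    k <- length(active)
    if (k == 0L) return(NULL)
    if (!is.null(ntips) && k == ntips) {
      ## extend to just before the next event
      t <- t + rexp(1, rate_tot())
      break
    }
    w <- rexp(1, rate_tot())
    if (!is.null(time) && t + w >= time) { t <- time; break }
    t <- t + w
    i <- active[sample.int(k, 1)]
    if (runif(1) < birth / (birth + death)) {
      m <- length(par)
      par <- c(par, i, i); t0 <- c(t0, t, t); t1 <- c(t1, NA, NA)
      fate <- c(fate, NA_integer_, NA_integer_)
      t1[i] <- t; fate[i] <- 2L
      active <- c(active[active != i], m + 1L, m + 2L)
    } else {
      t1[i] <- t; fate[i] <- 1L
      active <- active[active != i]
    }
  }
  t1[active] <- t; fate[active] <- 0L
  tipflag <- fate != 2L
  list(par = par, t0 = t0, t1 = t1, fate = fate,
       tip = tipflag, extinct = fate[tipflag] == 1L,
       tip_name = paste0("t", seq_len(sum(tipflag))))
}

build_phylo_from_events <- function(res) {
  ntab <- length(res$par)
  is_tip <- res$tip
  n <- sum(is_tip)
  ## root is the crown node joining seed lineages 1 and 2 (parent record 0);
  ## a lineage that speciated contributes the internal node at its split
  nid <- integer(ntab)
  nid[is_tip] <- seq_len(n)
  nxt <- n + 2L
  kids <- split(seq_len(ntab), res$par)
  walk <- function(rec) {
    stack <- rec
    while (length(stack)) {
      r <- stack[1]; stack <- stack[-1]
      if (!is_tip[r]) {
        nid[r] <<- nxt; nxt <<- nxt + 1L
        stack <- c(kids[[as.character(r)]], stack)
      }
    }
  }
  root_id <- n + 1L
  for (seed_rec in c(1L, 2L)) if (!is_tip[seed_rec]) walk(seed_rec)
  ## edges: from parent's split node (or root for seeds) to this record's node
  pidx <- res$par
  pidx[pidx == 0L] <- NA_integer_
  ep <- nid[pidx]
  ep[is.na(ep)] <- root_id
  ec <- nid
  ## tips first in walk order is unnecessary; ape tolerates any consistent ids
  el <- res$t1 - res$t0
  tr <- structure(list(edge = cbind(ep, ec, deparse.level = 0),
                       edge.length = el,
                       tip.label = res$tip_name,
                       Nnode = n - 1L),
                  class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}
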