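#' Build the state space and design for the polymorphic trait evolution model
#'
#' Polymorphic conditions are subsets of the monomorphic levels, written
#' `"a+b"` (order-insensitive; canonicalized). Transitions gain or lose one
#' level at a time, so a change between monomorphic states a and b must pass
#' through the intermediate polymorphic condition a+b. The unordered space
#' contains every non-empty subset of the levels; the ordered space only
#' contiguous runs of the stated order (so e.g. the first and third of three
#' ordered levels cannot be co-expressed without the middle one).
#'
#' @param levels Monomorphic level labels.
#' @param ordered Logical; is the underlying character ordered?
#' @param order Explicit level order (required sensible input when
#'   `ordered = TRUE`; defaults to alphanumeric order with a warning).
#' @param model `"ER"` (one rate for all allowed moves), `"ARD"` (one rate
#'   per ordered move), or `"transient"` (one shared rate for every
#'   polymorphism-gaining move and another for every polymorphism-losing
#'   move).
#' @return A list of class `"poly_space"`: `levels`, `states` (full state
#'   list), `design` (an [build_design()]-style matrix over the full space),
#'   `ordered`, `model`.
#' @export
build_poly_space <- function(levels, ordered = FALSE, order = NULL,
                             model = c("ER", "ARD", "transient")) {
  model <- match.arg(model)
  if (ordered) {
    if (is.null(order)) {
      order <- sort(levels)
      warning("levels assumed ordered alphanumerically: ",
              paste(order, collapse = " < "))
    }
    if (!setequal(order, levels)) stop("`order` must cover all levels")
    levels <- order
  } else levels <- sort(levels)
  k <- length(levels)
  subsets <- list()
  if (ordered) {
    for (size in 1:k) for (start in 1:(k - size + 1))
      subsets[[length(subsets) + 1L]] <- levels[start:(start + size - 1)]
  } else {
    for (size in 1:k) {
      cmb <- utils::combn(k, size)
      for (j in seq_len(ncol(cmb)))
        subsets[[length(subsets) + 1L]] <- levels[cmb[, j]]
    }
    ## order by size then combination order (matches the conventional print)
    subsets <- subsets[order(lengths(subsets),
                             vapply(subsets, function(s) paste(match(s, levels), collapse = ","), ""))]
  }
  states <- vapply(subsets, paste, "", collapse = "+")
  ns <- length(states)
  D <- matrix(0L, ns, ns, dimnames = list(states, states))
  allowed <- function(a, b) {
    ## differ by exactly one level, one being a superset of the other
    la <- subsets[[a]]; lb <- subsets[[b]]
    (length(setdiff(la, lb)) + length(setdiff(lb, la)) == 1) &&
      (all(la %in% lb) || all(lb %in% la))
  }
  cls <- 0L
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    if (i == j || !allowed(i, j)) next
    D[i, j] <- switch(model,
      ER = 1L,
      ARD = { cls <- cls + 1L; cls },
      transient = if (length(subsets[[j]]) > length(subsets[[i]])) 1L else 2L)
  }
  structure(list(levels = levels, states = states,
                 design = structure(D, class = c("mk_design", "matrix")),
                 ordered = ordered, model = model),
            class = "poly_space")
}

#' @export
print.poly_space <- function(x, ...) {
  cat("Polymorphic state space (", if (x$ordered) "ordered" else "unordered",
      ", ", x$model, " model)\n", sep = "")
  cat("This is the design matrix of the model:\n")
  print(unclass(x$design))
  invisible(x)
}

## canonicalize "b+a" -> "a+b" against a poly space
canon_poly <- function(x, space) {
  vapply(as.character(x), function(v) {
    if (is.na(v)) return(NA_character_)
    parts <- strsplit(v, "+", fixed = TRUE)[[1]]
    idx <- match(parts, space$levels)
    if (anyNA(idx)) stop("unknown level in condition '", v, "'")
    paste(space$levels[sort(idx)], collapse = "+")
  }, "")
}

#' Fit the polymorphic trait evolution model
#'
#' Expands the state space with [build_poly_space()] and fits the extended
#' Mk model over it by maximum likelihood (see [fit_mk()]). Tip conditions
#' containing `"+"` are treated as observed polymorphic states.
#'
#' @inheritParams fit_mk
#' @inheritParams build_poly_space
#' @param nstarts Optimization restarts (default 10; these likelihood
#'   surfaces are multimodal).
#' @return An `mk_fit` with additional class `"polymk_fit"` and element
#'   `space`.
#' @export
fit_polymk <- function(tree, x, model = c("ER", "ARD", "transient"),
                       ordered = FALSE, order = NULL, prior = "equal",
                       nstarts = 10, seed = NULL) {
  model <- match.arg(model)
  if (is.null(names(x))) stop("trait vector must be named by tip label")
  obs <- as.character(x)
  mono <- sort(unique(unlist(strsplit(obs[!is.na(obs)], "+", fixed = TRUE))))
  space <- build_poly_space(mono, ordered = ordered, order = order, model = model)
  xc <- setNames(canon_poly(x, space), names(x))
  missing_states <- setdiff(unique(xc[!is.na(xc)]), space$states)
  if (length(missing_states))
    stop("observed condition(s) not in constructed space: ",
         paste(missing_states, collapse = ", "))
  fit <- fit_mk(tree, xc, design = space$design, prior = prior,
                nstarts = nstarts, seed = seed, levels = space$states)
  fit$space <- space
  class(fit) <- c("polymk_fit", class(fit))
  fit
}

#' Build the expanded state space for the hidden-rates model
#'
#' Each observed level gets `ncat` rate categories; hidden categories are
#' labelled with trailing stars (`O`, `O*`, `O**`, ...). In the full model,
#' observed-state transitions are allowed between equal categories and
#' category transitions between adjacent categories within a level. In the
#' umbral variant, observed-state change is only possible from (and to) the
#' first, labile category; the starred categories are inert.
#'
#' @param levels Observed level labels.
#' @param ncat Number of rate categories per level (scalar or per-level).
#' @param umbral Use the umbral (labile/inert) design.
#' @return A list of class `"hrm_space"`: `levels`, `ncat`, `states`,
#'   `level_of` (observed level of each expanded state), `design`.
#' @export
build_hrm_space <- function(levels, ncat = 2, umbral = FALSE) {
  k <- length(levels)
  ncat <- rep(as.integer(ncat), length.out = k)
  if (any(ncat < 1)) stop("ncat must be >= 1")
  states <- character(0); level_of <- character(0); cat_of <- integer(0)
  for (i in seq_len(k)) for (c in seq_len(ncat[i])) {
    states <- c(states, paste0(levels[i], strrep("*", c - 1)))
    level_of <- c(level_of, levels[i]); cat_of <- c(cat_of, c)
  }
  ns <- length(states)
  D <- matrix(0L, ns, ns, dimnames = list(states, states))
  cls <- 0L
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    if (i == j) next
    same_level <- level_of[i] == level_of[j]
    ok <- if (same_level) abs(cat_of[i] - cat_of[j]) == 1L
          else if (umbral) cat_of[i] == 1L && cat_of[j] == 1L
          else cat_of[i] == cat_of[j]
    if (ok) { cls <- cls + 1L; D[i, j] <- cls }
  }
  structure(list(levels = levels, ncat = ncat, states = states,
                 level_of = level_of, cat_of = cat_of,
                 design = structure(D, class = c("mk_design", "matrix")),
                 umbral = umbral),
            class = "hrm_space")
}

#' @export
print.hrm_space <- function(x, ...) {
  cat("Hidden-rates state space (", if (x$umbral) "umbral" else "full",
      "), ncat = [", paste(x$ncat, collapse = ", "), "]\n", sep = "")
  print(unclass(x$design))
  invisible(x)
}

#' Fit a hidden-rates model
#'
#' Observed tip states are spread over their hidden categories (partial
#' likelihood 1 on every category of the observed level) and the extended Mk
#' model is fitted over the expanded space.
#'
#' @inheritParams fit_mk
#' @inheritParams build_hrm_space
#' @param nstarts Optimization restarts (default 10).
#' @return An `mk_fit` with additional class `"hrm_fit"` and element `space`.
#' @export
fit_hrm <- function(tree, x, ncat = 2, umbral = FALSE, prior = "fitzjohn",
                    nstarts = 10, seed = NULL) {
  if (is.null(names(x))) stop("trait vector must be named by tip label")
  obs <- as.character(x)
  lv <- if (is.factor(x)) levels(x) else sort(unique(obs[!is.na(obs)]))
  space <- build_hrm_space(lv, ncat = ncat, umbral = umbral)
  ## expanded tip likelihood matrix
  xo <- setNames(obs, names(x))[tree$tip.label]
  tipL <- matrix(0, length(xo), length(space$states),
                 dimnames = list(tree$tip.label, space$states))
  for (i in seq_along(xo)) {
    if (is.na(xo[i])) { tipL[i, ] <- 1; next }
    if (!xo[i] %in% lv) stop("tip state '", xo[i], "' not among levels")
    tipL[i, space$level_of == xo[i]] <- 1
  }
  fit <- fit_mk(tree, tipL, design = space$design, prior = prior,
                nstarts = nstarts, seed = seed, levels = space$states)
  fit$space <- space
  class(fit) <- c("hrm_fit", class(fit))
  fit
}
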