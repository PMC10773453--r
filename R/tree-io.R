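#' Parse a phylogenetic tree from Newick or SIMMAP-extended Newick text
#'
#' Trees are returned in the standard `"phylo"` representation of the ape
#' package: tips numbered `1..n` in order of appearance, internal nodes
#' `n+1..2n-1` with the root at `n+1`. The SIMMAP dialect annotates each
#' branch with an ordered set of `{state,duration}` segments in place of a
#' plain branch length, e.g. `(A:{x,1},B:{x,0.4:y,0.6});`. Segments are
#' written (and stored) rootward-to-tipward, and their durations sum to the
#' branch length. SIMMAP input yields a mapped tree of class
#' `c("mapped_phylo", "phylo")` carrying a `maps` list: one named numeric
#' vector of segment durations (names are state labels) per edge, in the
#' row order of the tree's edge matrix.
#'
#' @param text A character string containing one tree.
#' @param format `"newick"` or `"simmap"`.
#' @return A `phylo` (Newick) or `mapped_phylo` (SIMMAP) object.
#' @export
#' @examples
#' tr <- parse_tree("(A:1,(B:0.5,C:0.5):0.5);")
#' mt <- parse_tree("(A:{x,1},B:{x,0.4:y,0.6});", format = "simmap")
#' mt$maps
parse_tree <- function(text, format = c("newick", "simmap")) {
  format <- match.arg(format)
  text <- trimws(text)
  if (format == "newick") {
    tr <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("tree parse error: ", conditionMessage(e)),
                   warning = function(w) stop("tree parse error: ", conditionMessage(w)))
    if (is.null(tr)) stop("tree parse error: not a valid newick string")
    if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
      stop("negative branch lengths are not allowed")
    return(tr)
  }
  parse_simmap_text(text)
}

## Recursive-descent parser for the SIMMAP dialect. Hand-written because the
## dialect is not a standard interchange format; plain Newick goes through ape.
parse_simmap_text <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  pos <- 1L
  npos <- length(chars)
  err <- function(msg) stop(sprintf("simmap parse error at character %d: %s", pos, msg))
  peek <- function() if (pos <= npos) chars[pos] else ""
  tip_labels <- character(0)
  ## children[[id]] holds child ids of internal clade id; edges filled later
  clades <- list()     # list of list(children=…, maps=…) for internals
  read_label <- function() {
    start <- pos
    if (peek() == "'") {
      pos <<- pos + 1L
      lab <- character(0)
      while (pos <= npos && chars[pos] != "'") { lab <- c(lab, chars[pos]); pos <<- pos + 1L }
      if (pos > npos) err("unterminated quoted label")
      pos <<- pos + 1L
      return(paste(lab, collapse = ""))
    }
    stopchars <- c(",", ")", "(", ":", ";", "{", "}")
    lab <- character(0)
    while (pos <= npos && !(chars[pos] %in% stopchars)) { lab <- c(lab, chars[pos]); pos <<- pos + 1L }
    paste(lab, collapse = "")
  }
  read_number <- function() {
    start <- pos
    ok <- c(as.character(0:9), ".", "-", "+", "e", "E")
    num <- character(0)
    while (pos <= npos && chars[pos] %in% ok) { num <- c(num, chars[pos]); pos <<- pos + 1L }
    if (!length(num)) err("expected a number")
    val <- suppressWarnings(as.numeric(paste(num, collapse = "")))
    if (is.na(val)) err("malformed number")
    val
  }
  read_map <- function() {
    ## "{state,len:state,len:...}" -- rootward first
    if (peek() != "{") err("expected '{'")
    pos <<- pos + 1L
    states <- character(0); durs <- numeric(0)
    repeat {
      st <- character(0)
      while (pos <= npos && !(chars[pos] %in% c(",", "}"))) { st <- c(st, chars[pos]); pos <<- pos + 1L }
      if (peek() != ",") err("expected ',' inside segment")
      pos <<- pos + 1L
      d <- read_number()
      if (d < 0) err("negative segment duration")
      states <- c(states, paste(st, collapse = ""))
      durs <- c(durs, d)
      if (peek() == ":") { pos <<- pos + 1L; next }
      if (peek() == "}") { pos <<- pos + 1L; break }
      err("expected ':' or '}' after segment")
    }
    setNames(durs, states)
  }
  ## returns list(node = list(tip=?, label=?, children=list), map = named vec or NULL)
  read_clade <- function() {
    node <- NULL
    if (peek() == "(") {
      pos <<- pos + 1L
      children <- list()
      repeat {
        children[[length(children) + 1L]] <- read_clade()
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        err("unmatched parenthesis: expected ',' or ')'")
      }
      lab <- read_label()
      node <- list(tip = FALSE, label = lab, children = children)
    } else {
      lab <- read_label()
      if (!nzchar(lab)) err("expected a tip label")
      node <- list(tip = TRUE, label = lab, children = NULL)
    }
    map <- NULL
    if (peek() == ":") {
      pos <<- pos + 1L
      if (peek() == "{") map <- read_map()
      else {
        len <- read_number()
        if (len < 0) err("negative branch length")
        map <- setNames(len, NA_character_)
      }
    }
    list(node = node, map = map)
  }
  root <- read_clade()
  if (peek() != ";") err("expected ';' at end of tree")
  ## flatten into phylo: tips in order of appearance, internals in preorder
  tips <- character(0)
  count_tips <- function(nd) {
    if (nd$tip) tips <<- c(tips, nd$label)
    else for (ch in nd$children) count_tips(ch$node)
  }
  count_tips(root$node)
  n <- length(tips)
  if (n < 2) stop("tree must have at least 2 tips")
  if (anyDuplicated(tips)) stop("duplicate tip labels")
  edge_p <- integer(0); edge_c <- integer(0); maps <- list(); elen <- numeric(0)
  next_internal <- n + 1L
  tip_i <- 0L
  assign_ids <- function(nd) {
    if (nd$tip) {
      tip_i <<- tip_i + 1L
      return(tip_i)
    }
    my_id <- next_internal
    next_internal <<- next_internal + 1L
    for (ch in nd$children) {
      cid <- assign_ids(ch$node)
      edge_p <<- c(edge_p, my_id); edge_c <<- c(edge_c, cid)
      mp <- ch$map
      if (is.null(mp)) stop("simmap parse error: every edge needs a segment map or length")
      maps[[length(maps) + 1L]] <<- mp
      elen <<- c(elen, sum(mp))
    }
    my_id
  }
  assign_ids(root$node)
  maps <- lapply(maps, canonicalize_map)
  tr <- structure(list(edge = cbind(edge_p, edge_c, deparse.level = 0),
                       edge.length = elen, tip.label = tips,
                       Nnode = as.integer(next_internal - 1L - n)),
                  class = "phylo")
  ## bring edges into ape's cladewise row order, permuting maps in step
  old_key <- paste(tr$edge[, 1], tr$edge[, 2])
  tr <- ape::reorder.phylo(tr, "cladewise")
  perm <- match(paste(tr$edge[, 1], tr$edge[, 2]), old_key)
  tr$maps <- maps[perm]
  class(tr) <- c("mapped_phylo", "phylo")
  validate_mapped(tr)
  tr
}

## merge consecutive same-state segments; drop zero-duration interior segments
canonicalize_map <- function(m) {
  if (length(m) > 1) {
    keep <- m > 0
    if (any(keep)) m <- m[keep] else m <- m[length(m)]
  }
  if (length(m) <= 1) return(m)
  st <- names(m); out_s <- st[1]; out_d <- unname(m[1])
  for (i in 2:length(m)) {
    if (st[i] == out_s[length(out_s)]) out_d[length(out_d)] <- out_d[length(out_d)] + m[i]
    else { out_s <- c(out_s, st[i]); out_d <- c(out_d, unname(m[i])) }
  }
  setNames(out_d, out_s)
}

validate_mapped <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$maps))
  if (length(tree$maps) != nrow(tree$edge))
    stop("maps must have one entry per edge")
  tot <- vapply(tree$maps, sum, 0)
  if (any(abs(tot - tree$edge.length) > 1e-8))
    stop("segment durations must sum to the edge length")
  invisible(tree)
}

#' Convert a tree plus per-edge segments into a mapped tree
#'
#' @param tree A `phylo`.
#' @param maps A list with one named numeric vector per edge row
#'   (names = states, values = durations, rootward to tipward).
#' @return A `mapped_phylo`.
#' @export
as_mapped_phylo <- function(tree, maps) {
  tree$maps <- lapply(maps, canonicalize_map)
  class(tree) <- unique(c("mapped_phylo", class(tree)))
  validate_mapped(tree)
  tree
}

#' State of each node implied by a mapped tree
#'
#' The state at a node is the tipward end of the segment map on its parent
#' edge (for the root, the rootward state of its child edges).
#'
#' @param tree A `mapped_phylo`.
#' @return Character vector indexed by node id (length `2n-1`).
#' @export
mapped_node_states <- function(tree) {
  validate_mapped(tree)
  nn <- ape::Ntip(tree) + tree$Nnode
  st <- character(nn)
  root <- ape::Ntip(tree) + 1L
  for (e in seq_len(nrow(tree$edge))) {
    m <- tree$maps[[e]]
    st[tree$edge[e, 2]] <- names(m)[length(m)]
    if (tree$edge[e, 1] == root) st[root] <- names(m)[1]
  }
  st
}

#' Serialize a tree to Newick or SIMMAP-extended Newick
#'
#' @param tree A `phylo` or `mapped_phylo`.
#' @param format `"newick"` or `"simmap"`; defaults to `"simmap"` when the
#'   tree carries segment maps.
#' @param digits Significant digits used for durations.
#' @return A single string ending in `";"`.
#' @export
write_tree <- function(tree, format = if (inherits(tree, "mapped_phylo")) "simmap" else "newick",
                       digits = 12) {
  format <- match.arg(format, c("newick", "simmap"))
  if (format == "newick") return(ape::write.tree(tree))
  if (is.null(tree$maps)) {
    ## a plain tree written as SIMMAP gets a single-state segment per edge
    tree$maps <- lapply(seq_len(nrow(tree$edge)), function(e)
      setNames(tree$edge.length[e], "0"))
  }
  validate_mapped(tree)
  n <- ape::Ntip(tree)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt <- function(x) format(x, digits = digits, scientific = FALSE, trim = TRUE)
  edge_txt <- function(e) {
    m <- tree$maps[[e]]
    seg <- paste(names(m), fmt(unname(m)), sep = ",", collapse = ":")
    paste0(clade_txt(tree$edge[e, 2]), ":{", seg, "}")
  }
  clade_txt <- function(v) {
    if (v <= n) return(tree$tip.label[v])
    kids <- children[[as.character(v)]]
    paste0("(", paste(vapply(kids, edge_txt, ""), collapse = ","), ")")
  }
  paste0(clade_txt(n + 1L), ";")
}

#' Height of every node above the root
#'
#' The root has height 0; a tip's height is the sum of branch lengths along
#' the root-to-tip path (the tree's time axis, typically Myr).
#'
#' @param tree A `phylo` with branch lengths.
#' @return Numeric vector indexed by node id (tips `1..n` first).
#' @export
node_heights <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  nn <- ape::Ntip(tree) + tree$Nnode
  h <- numeric(nn)
  ## parents precede children in a preorder (reverse postorder) sweep
  eo <- rev(ape::postorder(tree))
  for (e in eo) h[tree$edge[e, 2]] <- h[tree$edge[e, 1]] + tree$edge.length[e]
  h
}

#' Total tree height (maximum root-to-tip distance)
#' @param tree A `phylo`.
#' @return A number in branch-length units.
#' @export
tree_height <- function(tree) max(node_heights(tree))

#' Drop tips from a tree
#'
#' Removes the named tips, suppressing resulting unary nodes and merging
#' their branch lengths, so patristic distances among survivors are kept.
#'
#' @param tree A `phylo`.
#' @param drop Character vector of tip labels to remove.
#' @return The induced `phylo` on the remaining tips.
#' @export
drop_tips <- function(tree, drop) {
  if (!length(drop)) return(tree)
  unknown <- setdiff(drop, tree$tip.label)
  if (length(unknown)) stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  if (ape::Ntip(tree) - length(drop) < 2) stop("fewer than 2 tips would remain")
  ape::drop.tip(tree, drop)
}

## node ids (tips / internals) in the clade below `node`
clade_descendants <- function(tree, node) {
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    ch <- kids[[as.character(v)]]
    out <- c(out, ch)
    stack <- c(stack, ch[ch > ape::Ntip(tree)])
  }
  out
}
clade_tips <- function(tree, node)
  clade_descendants(tree, node)[clade_descendants(tree, node) <= ape::Ntip(tree)]
clade_nodes <- function(tree, node) {
  d <- clade_descendants(tree, node)
  c(node, d[d > ape::Ntip(tree)])
}

#' Phylogenetic variance-covariance matrix under Brownian motion
#'
#' Entry (i, j) is the height of the most recent common ancestor of tips i
#' and j (the shared root-to-MRCA path length); the diagonal holds tip
#' heights. This is the Brownian covariance kernel up to the rate sigma^2.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @return An n x n matrix with tip labels as dimnames.
#' @export
phylo_vcv <- function(tree) {
  n <- ape::Ntip(tree)
  h <- node_heights(tree)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  ## postorder accumulation of tip descendants; off-diagonals filled at the
  ## node where two tip sets first meet
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  po <- ape::postorder(tree)
  for (e in po) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    prev <- desc[[p]]
    if (!is.null(prev)) {
      C[prev, desc[[ch]]] <- h[p]
      C[desc[[ch]], prev] <- h[p]
    }
    desc[[p]] <- c(prev, desc[[ch]])
  }
  diag(C) <- h[seq_len(n)]
  C
}
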