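#' Generate a self-contained synthetic fixture (tree + traits + truth file)
#'
#' Simulates a birth-death tree, a discrete character (with its true
#' history), and a continuous Brownian trait, and writes them as plain-text
#' files: `tree.nwk` (Newick), `history.smap` (SIMMAP), `discrete.csv`,
#' `continuous.csv`, and `truth.json` recording every generating parameter.
#' Outputs are fully deterministic given `seed`.
#'
#' @param outdir Output directory (created if needed).
#' @param ntips Number of tips.
#' @param birth,death Tree simulation rates.
#' @param q Rate of the binary equal-rates discrete character.
#' @param sig2,a Brownian rate and root state of the continuous trait.
#' @param seed Integer seed (required: fixtures must be reproducible).
#' @return Invisibly, a list with the simulated objects (`tree`, `history`,
#'   `discrete`, `continuous`) and the file paths.
#' @export
make_fixture <- function(outdir, ntips = 50, birth = 1, death = 0,
                         q = 0.5, sig2 = 1, a = 0, seed) {
  if (missing(seed)) stop("a seed is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  tree <- sim_bd_tree(birth = birth, death = death, ntips = ntips)
  Q <- design_to_q(build_design(c("a", "b"), "ER"), q)
  disc <- sim_mk(tree, Q, history = TRUE)
  cont <- sim_bm(tree, sig2 = sig2, a = a)
  paths <- list(
    tree = file.path(outdir, "tree.nwk"),
    history = file.path(outdir, "history.smap"),
    discrete = file.path(outdir, "discrete.csv"),
    continuous = file.path(outdir, "continuous.csv"),
    truth = file.path(outdir, "truth.json"))
  writeLines(write_tree(tree, "newick"), paths$tree)
  writeLines(write_tree(disc$tree, "simmap"), paths$history)
  utils::write.csv(data.frame(tip = names(disc$states),
                              state = as.character(disc$states)),
                   paths$discrete, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(tip = names(cont), value = unname(cont)),
                   paths$continuous, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(ntips = ntips, birth = birth, death = death, q = q,
         sig2 = sig2, a = a, seed = seed),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(tree = tree, history = disc$tree, discrete = disc$states,
                 continuous = cont, paths = paths))
}

#' Read a tip trait table written by [make_fixture()]
#'
#' First column must be the tip label; the second the value.
#'
#' @param path CSV/TSV file path.
#' @param sep Field separator (`,` default).
#' @return A named vector.
#' @export
read_trait_csv <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  setNames(d[[2]], d[[1]])
}
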