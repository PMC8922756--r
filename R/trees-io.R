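## Newick I/O conventions: supports travel in internal-node labels; multi-
## tree files hold one newick per line. Thin wrappers over ape with the
## support-scale bookkeeping the collapsing step needs.

#' Read trees from a newick file
#'
#' @param path File with one newick string per line.
#' @param support_scale Scale of any internal-node support values:
#'   `"bootstrap"` (0-100) or `"probability"` (0-1).
#' @return A `multiPhylo`; each tree carries a `support_scale` attribute.
#' @export
read_trees <- function(path, support_scale = c("bootstrap", "probability")) {
  support_scale <- match.arg(support_scale)
  trees <- ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  for (i in seq_along(trees)) attr(trees[[i]], "support_scale") <- support_scale
  trees
}

#' Write trees to a newick file
#'
#' @param trees A `phylo` or `multiPhylo`.
#' @param path Output path; one newick per line, internal-node labels kept.
#' @return The path, invisibly.
#' @export
write_trees <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  ape::write.tree(trees, file = path)
  invisible(path)
}
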