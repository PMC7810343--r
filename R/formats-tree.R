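# NHX (New Hampshire eXtended) tree handling. NHX is Newick with structured
# "[&&NHX:...]" comment blocks on nodes; the comments are preserved as opaque
# strings and the Newick skeleton is parsed with ape.

#' Parse an NHX / Newick tree statement
#'
#' Strips `[...]` comment blocks (keeping them opaquely), parses the Newick
#' skeleton with \pkg{ape}, and summarises the topology. The root counts as an
#' internal node iff it has at least two children, which is how ape stores
#' rooted and unrooted trees.
#'
#' @param text A single Newick/NHX statement ending in `;` (string or lines).
#' @return A list of class `nhx_tree`: `phylo` (the ape tree), `n_tips`,
#'   `n_internal`, `tip_labels`, `has_branch_lengths`, and `nhx_comments`
#'   (character vector of the raw comment blocks, possibly empty).
#' @examples
#' parse_nhx("(A,B,(C,D));")$n_tips  # 4
#' @export
parse_nhx <- function(text) {
  txt <- paste(text, collapse = "")
  txt <- gsub("[[:space:]]", "", txt)
  if (!nzchar(txt) || !endsWith(txt, ";")) {
    stop_rfam("malformed_newick", "tree statement must end with ';'",
              position = nchar(txt))
  }
  comments <- regmatches(txt, gregexpr("\\[[^][]*\\]", txt))[[1L]]
  skeleton <- gsub("\\[[^][]*\\]", "", txt)
  if (grepl("^[^();,]+;$", skeleton)) {
    # lone labelled tip: no parenthesised node, so no internal node
    label <- sub(":.*", "", sub(";$", "", skeleton))
    return(structure(list(phylo = NULL, n_tips = 1L, n_internal = 0L,
                          tip_labels = label, has_branch_lengths = grepl(":", skeleton),
                          nhx_comments = comments),
                     class = "nhx_tree"))
  }
  phy <- tryCatch(
    ape::read.tree(text = skeleton),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || !inherits(phy, "phylo")) {
    stop_rfam("malformed_newick", "unparseable Newick statement", position = 1L)
  }
  structure(list(phylo = phy,
                 n_tips = length(phy$tip.label),
                 n_internal = phy$Nnode,
                 tip_labels = phy$tip.label,
                 has_branch_lengths = !is.null(phy$edge.length),
                 nhx_comments = comments),
            class = "nhx_tree")
}

#' @export
print.nhx_tree <- function(x, ...) {
  cat(sprintf("<nhx_tree> %d tips, %d internal nodes%s; %d NHX comment block(s)\n",
              x$n_tips, x$n_internal,
              if (x$has_branch_lengths) ", with branch lengths" else "",
              length(x$nhx_comments)))
  invisible(x)
}
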