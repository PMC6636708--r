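#' Dated phylogenetic trees
#'
#' A dated tree is an [ape::phylo] object whose branch lengths are in years
#' and whose tips are (nominally) extant at the present.  Time runs in years
#' before present (BP): the present is 0, the root age is positive, and ages
#' increase into the past.  The class `"dated_tree"` subclasses `"phylo"`, so
#' every ape function keeps working; it additionally carries a `root_age`
#' (the maximum root-to-tip path length, i.e. the crown age for an
#' ultrametric tree) and an optional `family` label.
#'
#' @param phy a `phylo` object with branch lengths in years.
#' @param family optional family name attached to the tree.
#' @return An object of class `c("dated_tree", "phylo")`.
#' @examples
#' phy <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' tr <- dated_tree(phy)
#' root_age(tr)  # 2
#' @export
dated_tree <- function(phy, family = NA_character_) {
  if (!inherits(phy, "phylo"))
    stop("`phy` must be a phylo object", call. = FALSE)
  validate_phylo_lengths(phy)
  if (ape::Ntip(phy) > 1L && has_singles(phy))
    stop("internal nodes must have >= 2 children (unresolved singleton node)",
         call. = FALSE)
  attr(phy, "root_age") <- max(node_depths(phy))
  attr(phy, "family") <- as.character(family)
  class(phy) <- unique(c("dated_tree", class(phy)))
  phy
}

#' @rdname dated_tree
#' @param tree a `dated_tree` (or plain `phylo`, for which the age is
#'   computed on the fly).
#' @export
root_age <- function(tree) {
  ra <- attr(tree, "root_age")
  if (is.null(ra)) ra <- max(node_depths(tree))
  ra
}

#' @rdname dated_tree
#' @export
family_name <- function(tree) {
  fam <- attr(tree, "family")
  if (is.null(fam)) NA_character_ else fam
}

# depth (years from the root) of every node; handles the 1-tip degenerate tree
node_depths <- function(phy) {
  if (ape::Ntip(phy) == 1L && is.null(phy$Nnode))
    return(c(phy$edge.length, 0))
  ape::node.depth.edgelength(phy)
}

has_singles <- function(phy) {
  tab <- tabulate(phy$edge[, 1L])
  any(tab == 1L)
}

validate_phylo_lengths <- function(phy) {
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  bad <- which(is.na(phy$edge.length))
  if (length(bad)) {
    node <- phy$edge[bad[1L], 2L]
    lab <- node_label(phy, node)
    stop(sprintf("missing branch length on the edge leading to node '%s'", lab),
         call. = FALSE)
  }
  neg <- which(phy$edge.length < 0)
  if (length(neg)) {
    node <- phy$edge[neg[1L], 2L]
    stop(sprintf("negative branch length (%g) on the edge leading to node '%s'",
                 phy$edge.length[neg[1L]], node_label(phy, node)),
         call. = FALSE)
  }
  invisible(TRUE)
}

node_label <- function(phy, node) {
  n <- ape::Ntip(phy)
  if (node <= n) phy$tip.label[node] else paste0("node_", node)
}

#' Read dated trees from Newick text
#'
#' Reads one or more trees in standard Newick (labels, colon-delimited branch
#' lengths in years, `;` terminator; `[...]` comments ignored).  Multi-tree
#' files hold one tree statement per line (or simply several `;`-terminated
#' statements).  Every non-root edge must carry a branch length; the root age
#' is computed as the maximum root-to-tip path length.
#'
#' @param source path to a Newick file, or a character string containing
#'   Newick text (anything with a `;` that is not an existing file path is
#'   treated as text).
#' @param family optional character vector of family labels recycled across
#'   the trees read.
#' @return A list of [dated_tree] objects, in input order.
#' @examples
#' read_newick("((A:1,B:1):1,C:2);")[[1]]
#' @export
read_newick <- function(source, family = NA_character_) {
  is_text <- length(source) == 1L && grepl(";", source) && !file.exists(source)
  txt <- if (is_text) source else {
    if (!file.exists(source))
      stop(sprintf("file not found: '%s'", source), call. = FALSE)
    paste(readLines(source, warn = FALSE), collapse = "\n")
  }
  txt <- strip_newick_comments(txt)
  check_parentheses(txt)
  pieces <- strsplit(txt, ";", fixed = TRUE)[[1L]]
  pieces <- pieces[nzchar(trimws(pieces))]
  if (!length(pieces))
    stop("no Newick tree statement found (missing ';'?)", call. = FALSE)
  family <- rep_len(family, length(pieces))
  out <- vector("list", length(pieces))
  for (i in seq_along(pieces)) {
    phy <- tryCatch(
      ape::read.tree(text = paste0(trimws(pieces[i]), ";")),
      error = function(e) stop(sprintf("tree %d: malformed Newick: %s",
                                       i, conditionMessage(e)), call. = FALSE))
    if (is.null(phy))
      stop(sprintf("tree %d: malformed Newick statement", i), call. = FALSE)
    out[[i]] <- dated_tree(phy, family = family[i])
  }
  out
}

# balanced-parenthesis pre-scan so malformed input fails with a character offset
check_parentheses <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("unbalanced ')' at character offset %d", i), call. = FALSE)
    }
  }
  if (depth > 0L)
    stop(sprintf("unclosed '(' (%d open at end of input, length %d)",
                 depth, length(chars)), call. = FALSE)
  invisible(TRUE)
}

strip_newick_comments <- function(txt) gsub("\\[[^]]*\\]", "", txt)

#' Write dated trees as Newick
#'
#' One tree statement per line; inverse of [read_newick()] on topology and
#' branch lengths (to within printed precision, >= 10 significant digits).
#'
#' @param trees a `dated_tree`/`phylo` or a list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  lines <- vapply(trees, function(tr) ape::write.tree(tr, digits = 12),
                  character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Node ages in years before present
#'
#' Ages are measured backwards from the present: `age(root) == root_age` and
#' `age(node) == root_age - (path length from the root)`.  Extant tips of an
#' ultrametric tree have age 0 (up to rounding in the source tree).
#'
#' @param tree a [dated_tree] or `phylo`.
#' @return Named numeric vector of length `Ntip + Nnode`; tips are named by
#'   their labels, internal nodes `node_<k>`.
#' @examples
#' node_ages(read_newick("((A:1,B:1):1,C:2);")[[1]])
#' @export
node_ages <- function(tree) {
  ra <- root_age(tree)
  depths <- node_depths(tree)
  ages <- ra - depths
  n <- ape::Ntip(tree)
  nn <- length(ages) - n
  names(ages) <- c(tree$tip.label,
                   if (nn > 0) paste0("node_", n + seq_len(nn)))
  ages
}

#' Drop non-extant tips
#'
#' Removes every tip whose age exceeds `tol * root_age` (relative tolerance;
#' published consensus trees are near- but rarely exactly ultrametric).
#' Unary nodes created by the pruning are collapsed with branch lengths
#' merged, and the root age is recomputed on the pruned tree.
#'
#' @param tree a [dated_tree] or `phylo`.
#' @param tol relative age tolerance below which a tip counts as extant.
#' @return A [dated_tree] containing only the extant tips.
#' @export
prune_to_extant <- function(tree, tol = 1e-6) {
  ra <- root_age(tree)
  n <- ape::Ntip(tree)
  ages <- node_ages(tree)[seq_len(n)]
  extant <- which(ages <= tol * ra)
  if (!length(extant))
    stop("no extant tips: every lineage in this tree is extinct", call. = FALSE)
  if (length(extant) == n) {
    return(dated_tree(strip_dated(tree), family = family_name(tree)))
  }
  if (length(extant) == 1L) {
    # keep.tip cannot return a 1-tip tree; build it from the surviving path
    lab <- tree$tip.label[extant]
    depth <- node_depths(tree)[extant]
    phy <- single_tip_tree(lab, depth)
    return(dated_tree(phy, family = family_name(tree)))
  }
  pruned <- ape::keep.tip(strip_dated(tree), extant)
  pruned$root.edge <- NULL
  dated_tree(pruned, family = family_name(tree))
}

strip_dated <- function(tree) {
  class(tree) <- "phylo"
  attr(tree, "root_age") <- NULL
  attr(tree, "family") <- NULL
  tree
}

single_tip_tree <- function(label, length) {
  phy <- list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = label,
              edge.length = length, Nnode = 1L)
  class(phy) <- "phylo"
  phy
}

#' @export
print.dated_tree <- function(x, ...) {
  fam <- family_name(x)
  cat(sprintf("Dated tree%s: %d extant-candidate tips, root age %.6g yr BP\n",
              if (is.na(fam)) "" else paste0(" [", fam, "]"),
              ape::Ntip(x), root_age(x)))
  invisible(x)
}
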