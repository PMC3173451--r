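#' @importFrom stats runif rexp rnorm setNames
#' @importFrom utils read.delim write.table head
NULL

# Leaf category vocabulary ---------------------------------------------------
#
# Every leaf of an analysis tree carries one category, kept in a character
# vector named by leaf label (never inside the tree object, so any ape
# operation leaves it valid):
#   "REFERENCE:<order>"  reference taxon of an alphaproteobacterial order
#   "MITOCHONDRIAL"      mitochondrially encoded protein
#   "ENVIRONMENTAL"      metagenome (GOS-like) sequence
#   "OUTGROUP"           outgroup taxon

#' Build a REFERENCE category tag for an order
#'
#' @param order order name, e.g. `"Rickettsiales"`
#' @return category string `"REFERENCE:<order>"`
#' @export
reference_category <- function(order) paste0("REFERENCE:", order)

#' Category kind (strips the order qualifier from REFERENCE tags)
#'
#' @param categories character vector of leaf categories
#' @return vector with values in REFERENCE, MITOCHONDRIAL, ENVIRONMENTAL,
#'   OUTGROUP
#' @export
category_kind <- function(categories) sub(":.*$", "", categories)

#' Order name of REFERENCE categories (NA for other kinds)
#' @param categories character vector of leaf categories
#' @export
category_order <- function(categories) {
  out <- ifelse(startsWith(categories, "REFERENCE:"),
                sub("^REFERENCE:", "", categories), NA_character_)
  names(out) <- names(categories)
  out
}

check_categories <- function(tree, categories) {
  missing <- setdiff(tree$tip.label, names(categories))
  if (length(missing) > 0L) {
    stop("leaves without a category: ", paste(head(missing, 5L), collapse = ", "))
  }
  kinds <- category_kind(categories[tree$tip.label])
  bad <- !kinds %in% c("REFERENCE", "MITOCHONDRIAL", "ENVIRONMENTAL", "OUTGROUP")
  if (any(bad)) {
    stop("invalid leaf categories: ",
         paste(unique(categories[tree$tip.label][bad]), collapse = ", "))
  }
  invisible(TRUE)
}

leaves_of_kind <- function(tree, categories, kind) {
  labs <- tree$tip.label
  labs[category_kind(categories[labs]) == kind]
}

# Newick I/O -----------------------------------------------------------------

newick_syntax_offset <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(i)
    }
  }
  if (depth != 0L || !any(chars == ";")) return(length(chars) + 1L)
  NULL
}

#' Parse a Newick tree
#'
#' Accepts a Newick string (or path to a file holding one tree). Branch
#' lengths are optional and default to 0; support values on internal nodes
#' are preserved as node labels.
#'
#' @param text Newick string, or path to a file containing one
#' @return a rooted or unrooted `phylo` tree
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- if (grepl("(", text, fixed = TRUE)) text else {
    paste(readLines(text, warn = FALSE), collapse = "")
  }
  off <- newick_syntax_offset(txt)
  if (!is.null(off)) {
    stop(sprintf("malformed Newick string at character offset %d", off))
  }
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("malformed Newick string at character offset 1")
  if (is.null(tr$edge.length)) {
    tr$edge.length <- numeric(nrow(tr$edge))
  } else {
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  tr
}

#' Write a tree (or return its Newick string)
#'
#' @param tree a `phylo`
#' @param file output path, or `NULL` to return the string
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = file)
  invisible(file)
}

#' Read a tree sample (one Newick tree per line)
#'
#' @param path file with one tree per line
#' @return list of `phylo` trees
#' @export
read_tree_sample <- function(path) {
  trees <- ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  unclass(trees)
}

#' Total branch length of a tree
#' @param tree a `phylo`
#' @export
total_branch_length <- function(tree) {
  if (is.null(tree$edge.length)) return(0)
  sum(tree$edge.length)
}

# Bipartition machinery ------------------------------------------------------

# tip labels below every node (index = ape node id)
clade_tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- tree$tip.label[i]
  po <- stats::reorder(tree, "postorder")$edge
  for (r in seq_len(nrow(po))) {
    sets[[po[r, 1L]]] <- c(sets[[po[r, 1L]]], sets[[po[r, 2L]]])
  }
  sets
}

# canonical key of the bipartition {side | rest}: the side holding the
# lexicographically smallest leaf, sorted, tab-joined
split_key <- function(side, all_labels) {
  ref <- sort(all_labels)[1L]
  s <- if (ref %in% side) side else setdiff(all_labels, side)
  paste(sort(s), collapse = "\t")
}

#' Non-trivial bipartitions of a tree
#'
#' Each internal branch induces one bipartition of the leaf set; trivial
#' bipartitions (single leaf versus the rest) are omitted. Keys are
#' canonical: the side holding the lexicographically smallest leaf, sorted
#' and tab-joined.
#'
#' @param tree a `phylo`
#' @return character vector of canonical split keys
#' @export
tree_splits <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  sets <- clade_tip_sets(tree)
  keys <- character(0)
  for (r in seq_len(nrow(tree$edge))) {
    side <- sets[[tree$edge[r, 2L]]]
    k <- length(side)
    if (k <= 1L || k >= n - 1L) next
    keys <- c(keys, split_key(side, labs))
  }
  unique(keys)
}

#' Test whether a leaf set is monophyletic
#'
#' On a rooted tree, true iff some clade's leaf set equals `leafset`; on an
#' unrooted tree, true iff the bipartition (`leafset` | rest) is present.
#'
#' @param tree a `phylo`
#' @param leafset non-empty subset of the tree's leaf labels
#' @export
is_monophyletic <- function(tree, leafset) {
  labs <- tree$tip.label
  leafset <- unique(leafset)
  if (length(leafset) == 0L) stop("leafset must be non-empty")
  unknown <- setdiff(leafset, labs)
  if (length(unknown) > 0L) {
    stop("unknown leaf labels: ", paste(head(unknown, 5L), collapse = ", "))
  }
  k <- length(leafset)
  n <- length(labs)
  if (k == n || k == 1L) return(TRUE)
  if (ape::is.rooted(tree)) {
    key <- paste(sort(leafset), collapse = "\t")
    sets <- clade_tip_sets(tree)
    for (node in seq_along(sets)) {
      if (length(sets[[node]]) == k &&
          paste(sort(sets[[node]]), collapse = "\t") == key) {
        return(TRUE)
      }
    }
    return(FALSE)
  }
  if (k == n - 1L) return(TRUE)
  split_key(leafset, labs) %in% tree_splits(tree)
}

#' Most recent common ancestor of a leaf set
#'
#' @param tree a rooted `phylo`
#' @param leafset leaf labels (a single label returns the tip itself)
#' @return ape node number
#' @export
mrca_node <- function(tree, leafset) {
  if (!ape::is.rooted(tree)) {
    stop("tree is unrooted; root it first (see root_with_outgroup)")
  }
  leafset <- unique(leafset)
  unknown <- setdiff(leafset, tree$tip.label)
  if (length(unknown) > 0L) {
    stop("unknown leaf labels: ", paste(head(unknown, 5L), collapse = ", "))
  }
  tips <- match(leafset, tree$tip.label)
  if (length(tips) == 1L) return(tips)
  ape::getMRCA(tree, tips)
}

#' Root a tree on the branch separating the outgroup from the ingroup
#'
#' The outgroup must form a bipartition of the unrooted tree. The separating
#' branch is bisected, so total branch length is conserved.
#'
#' @param tree a `phylo` (rooted input is unrooted first)
#' @param outgroup leaf labels of the outgroup
#' @return rooted `phylo`
#' @export
root_with_outgroup <- function(tree, outgroup) {
  og <- unique(outgroup)
  labs <- tree$tip.label
  unknown <- setdiff(og, labs)
  if (length(unknown) > 0L) {
    stop("unknown outgroup labels: ", paste(head(unknown, 5L), collapse = ", "))
  }
  if (length(og) >= length(labs)) stop("outgroup cannot contain all leaves")
  utree <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  ok <- length(og) == 1L || length(og) == length(labs) - 1L ||
    split_key(og, labs) %in% tree_splits(utree)
  if (!ok) {
    stop(sprintf("outgroup {%s} conflicts with the tree's splits: no branch separates it from the ingroup",
                 paste(sort(og), collapse = ",")))
  }
  r <- ape::root(utree, outgroup = og, resolve.root = TRUE)
  root <- setdiff(r$edge[, 1L], r$edge[, 2L])
  kids <- which(r$edge[, 1L] == root)
  if (length(kids) == 2L && !is.null(r$edge.length)) {
    tot <- sum(r$edge.length[kids])
    r$edge.length[kids] <- tot / 2
  }
  r
}
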