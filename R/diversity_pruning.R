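# Faith phylogenetic diversity and greedy maximum-PD taxon selection with
# must-keep constraints (the pruning step that reduces an environmental pool
# to a tractable, maximally diverse subset). Greedy selection on a tree
# attains the exact PD optimum when unconstrained (Steel/Pardi); must-keep
# seeding preserves optimality only for the unconstrained increments.

#' Configuration for diversity pruning
#'
#' @param k target subset size (default 150)
#' @param must_keep labels that must be in the selection (e.g. all reference
#'   taxa)
#' @param rooted use the rooted PD convention (include the path to the
#'   root); default is the unrooted spanning-subtree convention
#' @export
prune_config <- function(k = 150L, must_keep = character(), rooted = FALSE) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (k < length(must_keep)) stop("k smaller than the must-keep set")
  structure(list(k = k, must_keep = unique(must_keep), rooted = rooted),
            class = "prune_config")
}

tree_arrays <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  po <- stats::reorder(tree, "postorder")
  parent <- integer(nn)
  plen <- numeric(nn)
  parent[po$edge[, 2L]] <- po$edge[, 1L]
  elen <- po$edge.length
  if (is.null(elen)) elen <- numeric(nrow(po$edge))
  plen[po$edge[, 2L]] <- elen
  list(n = n, nn = nn, edge = po$edge, plen = plen, parent = parent,
       root = setdiff(po$edge[, 1L], po$edge[, 2L]))
}

#' Faith's phylogenetic diversity of a leaf subset
#'
#' Sum of branch lengths of the minimal subtree connecting the subset
#' (unrooted spanning-subtree convention; with `rooted = TRUE` the path to
#' the root is included).
#'
#' @param tree a `phylo`
#' @param subset leaf labels, at least 2
#' @param rooted include the root path (default FALSE)
#' @export
faith_pd <- function(tree, subset, rooted = FALSE) {
  subset <- unique(subset)
  unknown <- setdiff(subset, tree$tip.label)
  if (length(unknown) > 0L) {
    stop("unknown leaf labels: ", paste(head(unknown, 5L), collapse = ", "))
  }
  if (length(subset) < 2L) stop("PD needs a subset of at least 2 leaves")
  ta <- tree_arrays(tree)
  below <- numeric(ta$nn)
  below[match(subset, tree$tip.label)] <- 1
  for (r in seq_len(nrow(ta$edge))) {
    below[ta$edge[r, 1L]] <- below[ta$edge[r, 1L]] + below[ta$edge[r, 2L]]
  }
  bc <- below[ta$edge[, 2L]]
  include <- if (rooted) bc > 0 else bc > 0 & bc < length(subset)
  sum(ta$plen[ta$edge[, 2L]][include])
}

# distance from every node to the nearest node of a marked set, by one
# up-sweep (postorder) and one down-sweep (preorder)
dist_to_nodeset <- function(ta, marked) {
  d <- rep(Inf, ta$nn)
  d[marked] <- 0
  ed <- ta$edge
  for (r in seq_len(nrow(ed))) {
    p <- ed[r, 1L]; ch <- ed[r, 2L]
    v <- d[ch] + ta$plen[ch]
    if (v < d[p]) d[p] <- v
  }
  for (r in rev(seq_len(nrow(ed)))) {
    p <- ed[r, 1L]; ch <- ed[r, 2L]
    v <- d[p] + ta$plen[ch]
    if (v < d[ch]) d[ch] <- v
  }
  d
}

# nodes spanned by the selection: endpoints of edges with a strict subset of
# the selected tips below them; for a single selected tip, the tip itself
spanning_nodes <- function(ta, cnt, nsel, rooted = FALSE) {
  if (rooted) return(which(cnt > 0))
  ed <- ta$edge
  bc <- cnt[ed[, 2L]]
  on <- bc > 0 & bc < nsel
  if (!any(on)) which(cnt > 0)[1L] else unique(c(ed[on, 1L], ed[on, 2L]))
}

#' Greedy maximum-PD leaf selection
#'
#' Starts from the must-keep set if non-empty, otherwise from the two
#' leaves with maximal path length, and repeatedly adds the leaf with the
#' largest PD increment until `k` leaves are selected. Ties are broken by
#' lexicographically smallest label.
#'
#' @param tree a `phylo`
#' @param config a [prune_config()]
#' @return list(selection = ordered labels, pd = cumulative PD after each
#'   step)
#' @export
greedy_pd_select <- function(tree, config = prune_config()) {
  labs <- tree$tip.label
  n <- length(labs)
  if (config$k > n) stop("k exceeds the leaf count")
  unknown <- setdiff(config$must_keep, labs)
  if (length(unknown) > 0L) {
    stop("must-keep labels absent from the tree: ",
         paste(head(unknown, 5L), collapse = ", "))
  }
  ta <- tree_arrays(tree)
  cnt <- numeric(ta$nn)
  add_tip <- function(tip_idx) {
    node <- tip_idx
    while (node != 0L) {
      cnt[node] <<- cnt[node] + 1
      node <- ta$parent[node]
    }
  }
  selection <- character(0)
  if (length(config$must_keep) > 0L) {
    selection <- sort(config$must_keep)
    for (l in selection) add_tip(match(l, labs))
  } else {
    # double sweep: farthest tip from an arbitrary tip, then its farthest
    d0 <- dist_to_nodeset(ta, 1L)[seq_len(n)]
    u <- order(-d0, labs)[1L]
    du <- dist_to_nodeset(ta, u)[seq_len(n)]
    du[u] <- -Inf
    v <- order(-du, labs)[1L]
    first <- sort(labs[c(u, v)])
    selection <- first
    add_tip(match(first[1L], labs))
    add_tip(match(first[2L], labs))
  }
  pd <- if (length(selection) >= 2L) {
    faith_pd(tree, selection, rooted = config$rooted)
  } else 0
  pd_trace <- rep(pd, length(selection))
  in_sel <- labs %in% selection
  while (length(selection) < config$k) {
    marked <- spanning_nodes(ta, cnt, length(selection), config$rooted)
    d <- dist_to_nodeset(ta, marked)[seq_len(n)]
    d[in_sel] <- -Inf
    nxt <- order(-d, labs)[1L]
    pd <- pd + d[nxt]
    selection <- c(selection, labs[nxt])
    pd_trace <- c(pd_trace, pd)
    in_sel[nxt] <- TRUE
    add_tip(nxt)
  }
  list(selection = selection, pd = pd_trace)
}

#' Prune an ortholog dataset to a maximally diverse subset
#'
#' Restricts the dataset to the greedy maximum-PD selection on the guide
#' tree; the PD trajectory is recorded in the provenance log.
#'
#' @param dataset an [ortholog_dataset()]
#' @param tree guide tree whose leaves are exactly the dataset members
#' @param config a [prune_config()]
#' @return pruned [ortholog_dataset()]
#' @export
prune_dataset <- function(dataset, tree, config = prune_config()) {
  ids <- dataset$members$id
  if (!setequal(ids, tree$tip.label)) {
    stop("tree leaves and dataset members do not match")
  }
  sel <- greedy_pd_select(tree, config)
  keep <- dataset$members$id %in% sel$selection
  ortholog_dataset(
    marker = dataset$marker,
    members = dataset$members[keep, , drop = FALSE],
    alignment = if (!is.null(dataset$alignment)) {
      dataset$alignment[dataset$members$id[keep], , drop = FALSE]
    },
    provenance = c(dataset$provenance,
                   sprintf("pruned to k=%d by greedy max-PD (final PD %.6g; full-tree PD %.6g)",
                           config$k, sel$pd[length(sel$pd)],
                           total_branch_length(tree)))
  )
}
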