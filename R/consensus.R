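# Tree-sample utilities: split frequencies, majority-rule consensus and the
# max-diff convergence diagnostic for comparing two tree samples.

as_tree_list <- function(trees) {
  if (inherits(trees, "phylo")) return(list(trees))
  if (inherits(trees, "multiPhylo")) return(unclass(trees))
  if (!is.list(trees) || length(trees) == 0L) stop("empty tree sample")
  trees
}

check_same_leaves <- function(trees) {
  labs <- sort(trees[[1L]]$tip.label)
  for (t in trees) {
    if (!identical(sort(t$tip.label), labs)) {
      stop("trees have mismatched leaf sets")
    }
  }
  labs
}

#' Frequencies of non-trivial splits in a tree sample
#'
#' @param trees list of `phylo` trees over the same leaf set
#' @return named numeric vector: canonical split key -> frequency in (0, 1]
#' @export
split_frequencies <- function(trees) {
  trees <- as_tree_list(trees)
  check_same_leaves(trees)
  tab <- table(unlist(lapply(trees, tree_splits)))
  if (length(tab) == 0L) return(setNames(numeric(0), character(0)))
  setNames(as.numeric(tab) / length(trees), names(tab))
}

#' Majority-rule consensus of a tree sample
#'
#' After discarding the first `burnin_fraction` of the sample, the consensus
#' contains exactly the splits with frequency > 0.5; each retained internal
#' node is annotated (node label) with its split frequency.
#'
#' @param trees list of `phylo` trees over the same leaf set
#' @param burnin_fraction fraction of initial trees to discard, in [0, 1)
#' @return unrooted `phylo` with frequency node labels
#' @export
majority_rule_consensus <- function(trees, burnin_fraction = 0.25) {
  trees <- as_tree_list(trees)
  if (!is.numeric(burnin_fraction) || burnin_fraction < 0 || burnin_fraction >= 1) {
    stop("burnin_fraction must be in [0, 1)")
  }
  labs <- check_same_leaves(trees)
  drop <- floor(burnin_fraction * length(trees))
  kept <- trees[seq.int(drop + 1L, length(trees))]
  freq <- split_frequencies(kept)
  maj <- freq[freq > 0.5]
  ref <- labs[1L]
  # clade view: for each majority split, the side not holding the reference
  # leaf; splits with frequency > 0.5 are pairwise compatible, so these
  # clades form a laminar family and nest into a tree
  clades <- lapply(names(maj), function(k) {
    setdiff(labs, strsplit(k, "\t", fixed = TRUE)[[1L]])
  })
  ord <- order(lengths(clades))
  clades <- clades[ord]
  supports <- unname(maj)[ord]
  units <- lapply(labs, function(l) list(tips = l, nwk = l))
  for (i in seq_along(clades)) {
    cl <- clades[[i]]
    inside <- vapply(units, function(u) all(u$tips %in% cl), logical(1L))
    covered <- sort(unlist(lapply(units[inside], `[[`, "tips")))
    if (!identical(covered, sort(cl))) {
      stop("incompatible majority splits (should not happen)")
    }
    merged <- list(
      tips = covered,
      nwk = paste0("(", paste(vapply(units[inside], `[[`, "", "nwk"),
                              collapse = ","), ")",
                   format(supports[i], digits = 6))
    )
    units <- c(units[!inside], list(merged))
  }
  nwk <- paste0("(", paste(vapply(units, `[[`, "", "nwk"), collapse = ","), ");")
  cons <- ape::read.tree(text = nwk)
  ape::collapse.singles(cons)
}

#' Maximum split-frequency difference between two tree samples
#'
#' The bpcomp-style convergence diagnostic: the maximum over all observed
#' non-trivial splits of the absolute difference in frequency between the
#' two samples. The attribute `converged` records whether the value is at
#' most `threshold`.
#'
#' @param sample_a,sample_b lists of `phylo` trees over the same leaf set
#' @param threshold convergence cut-off (default 0.3)
#' @return numeric in [0, 1] with logical attribute `converged`
#' @export
split_maxdiff <- function(sample_a, sample_b, threshold = 0.3) {
  fa <- split_frequencies(sample_a)
  fb <- split_frequencies(sample_b)
  la <- sort(as_tree_list(sample_a)[[1L]]$tip.label)
  lb <- sort(as_tree_list(sample_b)[[1L]]$tip.label)
  if (!identical(la, lb)) stop("tree samples have mismatched leaf sets")
  keys <- union(names(fa), names(fb))
  if (length(keys) == 0L) {
    res <- 0
  } else {
    va <- fa[keys]; va[is.na(va)] <- 0
    vb <- fb[keys]; vb[is.na(vb)] <- 0
    res <- max(abs(va - vb))
  }
  attr(res, "converged") <- res <= threshold
  res
}
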