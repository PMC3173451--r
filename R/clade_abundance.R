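# Assignment of environmental leaves to reference clades, clade fraction
# and collapsed-clade summaries, and the rare-clade abundance arithmetic.

#' Configuration for overall-abundance estimation
#'
#' @param alpha_fraction_of_cells assumed fraction of all microbial cells
#'   that are alphaproteobacterial (default 0.325)
#' @export
abundance_config <- function(alpha_fraction_of_cells = 0.325) {
  stopifnot(alpha_fraction_of_cells >= 0, alpha_fraction_of_cells <= 1)
  structure(list(alpha_fraction_of_cells = alpha_fraction_of_cells),
            class = "abundance_config")
}

#' Tentatively assign environmental leaves to reference orders
#'
#' Each environmental leaf is assigned the order of the strict majority of
#' reference leaves in the smallest clade that contains the leaf and at
#' least one reference leaf; ties or mixed majorities give UNCLASSIFIED.
#'
#' @param tree rooted `phylo`
#' @param categories named leaf-category vector; reference leaves carry
#'   `"REFERENCE:<order>"`
#' @return data frame (id, order) with order `"UNCLASSIFIED"` where no
#'   strict majority exists
#' @export
assign_to_reference_clades <- function(tree, categories) {
  if (!ape::is.rooted(tree)) {
    stop("tree must be rooted (root with the outgroup first)")
  }
  check_categories(tree, categories)
  refs <- leaves_of_kind(tree, categories, "REFERENCE")
  if (length(refs) == 0L) stop("tree contains no reference leaves")
  env <- leaves_of_kind(tree, categories, "ENVIRONMENTAL")
  orders <- category_order(categories)
  sets <- clade_tip_sets(tree)
  ta <- tree_arrays(tree)
  assigned <- character(length(env))
  for (i in seq_along(env)) {
    node <- match(env[i], tree$tip.label)
    repeat {
      node <- ta$parent[node]
      refs_in <- intersect(sets[[node]], refs)
      if (length(refs_in) > 0L || node == ta$root) break
    }
    tab <- table(orders[refs_in])
    top <- which(tab == max(tab))
    assigned[i] <- if (length(top) == 1L && max(tab) > sum(tab) / 2) {
      names(tab)[top]
    } else {
      "UNCLASSIFIED"
    }
  }
  data.frame(id = env, order = assigned, stringsAsFactors = FALSE)
}

#' Clade fractions of assigned environmental sequences
#'
#' Percentage of assigned (non-UNCLASSIFIED) environmental leaves per
#' order; percentages sum to 100.
#'
#' @param assign data frame from [assign_to_reference_clades()]
#' @return named numeric vector of percentages, sorted decreasing
#' @export
clade_fractions <- function(assign) {
  a <- assign$order[assign$order != "UNCLASSIFIED"]
  if (length(a) == 0L) stop("no environmental sequences were assigned")
  sort(100 * table(a) / length(a), decreasing = TRUE) |>
    (\(x) setNames(as.numeric(x), names(x)))()
}

#' Collapsed-clade summary: total branch length and sequence count
#'
#' `l` is the sum of branch lengths within the clade below `node`
#' (excluding its stem); `n` is the number of environmental leaves in the
#' clade (all leaves when `categories` is NULL).
#'
#' @param tree a `phylo`
#' @param node ape node (or tip) number
#' @param categories optional named leaf-category vector
#' @return named numeric c(l, n)
#' @export
clade_summary <- function(tree, node, categories = NULL) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) {
    tips <- tree$tip.label[node]
    l <- 0
  } else {
    keep <- logical(n_tip + tree$Nnode)
    keep[node] <- TRUE
    ed <- stats::reorder(tree, "postorder")
    # preorder sweep: mark all descendants of `node`
    for (r in rev(seq_len(nrow(ed$edge)))) {
      if (keep[ed$edge[r, 1L]]) keep[ed$edge[r, 2L]] <- TRUE
    }
    # edges within the clade: child marked, excluding the stem above `node`
    inside <- keep[ed$edge[, 2L]] & ed$edge[, 2L] != node
    l <- sum(ed$edge.length[inside])
    tips <- tree$tip.label[which(keep[seq_len(n_tip)])]
  }
  n <- if (is.null(categories)) {
    length(tips)
  } else {
    sum(category_kind(categories[tips]) == "ENVIRONMENTAL")
  }
  c(l = l, n = n)
}

#' Fraction of sequences attributable to a rare clade
#'
#' @param n_clade sequences attributed to the clade
#' @param n_total total sequences in the dataset
#' @return percentage (full precision; round to one decimal for reporting)
#' @export
rare_clade_fraction <- function(n_clade, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_clade < 0 || n_clade > n_total) stop("n_clade must be in [0, n_total]")
  100 * n_clade / n_total
}

#' Overall cell abundance of a clade
#'
#' The clade's percentage among alphaproteobacterial sequences scaled by
#' the assumed alphaproteobacterial fraction of all cells. This is an
#' approximation: it treats sequence fractions as cell fractions.
#'
#' @param clade_pct clade percentage among alphaproteobacterial sequences
#' @param config an [abundance_config()]
#' @return percentage of all cells
#' @export
overall_abundance <- function(clade_pct, config = abundance_config()) {
  clade_pct * config$alpha_fraction_of_cells
}

#' Read a scaffold geography table
#'
#' Tab-separated with columns scaffold id, sample id, habitat type, sample
#' location and coordinates (header row required).
#'
#' @param path TSV file
#' @return data frame with normalised column names (scaffold_id, gos_id,
#'   habitat_type, sample_location, coordinates)
#' @export
read_scaffold_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 5L) stop("scaffold table needs 5 columns")
  names(df)[1:5] <- c("scaffold_id", "gos_id", "habitat_type",
                      "sample_location", "coordinates")
  df
}
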