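# The taxon jack-knife screen: repeated random subsamples of the
# environmental pool are combined with the fixed reference set, a tree is
# inferred per replicate, and environmental sequences placed inside the
# mitochondrial clade (or in its sister clade) are flagged.

#' Configuration for the jack-knife neighbour screen
#'
#' @param sample_size environmental sequences drawn per replicate, with
#'   replacement (default 100)
#' @param replicates number of replicates (default 100)
#' @param rng_seed optional seed set at the start of [run_screen()]
#' @param backend tree-inference backend, a function alignment -> `phylo`
#'   (default [nj_backend()] with composition-aware `"f81"` distances,
#'   which resolve the deep quartets around the mitochondrial clade more
#'   reliably than the Poisson correction)
#' @param neighbour_mode `"INSIDE_PLUS_SISTER"` (default) also flags
#'   environmental leaves in the sister clade of the mitochondrial MRCA;
#'   `"INSIDE_ONLY"` flags only leaves descending from it
#' @param min_flag_count a sequence enters the flagged set once it has been
#'   flagged in at least this many replicates (default 1)
#' @export
screen_config <- function(sample_size = 100L, replicates = 100L,
                          rng_seed = NULL, backend = NULL,
                          neighbour_mode = c("INSIDE_PLUS_SISTER", "INSIDE_ONLY"),
                          min_flag_count = 1L) {
  neighbour_mode <- match.arg(neighbour_mode)
  stopifnot(sample_size >= 1L, replicates >= 1L, min_flag_count >= 1L)
  if (is.null(backend)) backend <- nj_backend("f81")
  structure(list(sample_size = as.integer(sample_size),
                 replicates = as.integer(replicates),
                 rng_seed = rng_seed, backend = backend,
                 neighbour_mode = neighbour_mode,
                 min_flag_count = as.integer(min_flag_count)),
            class = "screen_config")
}

#' Draw one jack-knife sample (uniform, with replacement)
#'
#' @param pool id vector (non-empty)
#' @param m number of draws; may exceed the pool size
#' @return character vector of `m` ids (a multiset)
#' @export
jackknife_sample <- function(pool, m) {
  if (length(pool) == 0L) stop("cannot sample from an empty pool")
  sample(pool, m, replace = TRUE)
}

#' Probability that a pool member is never drawn across all replicates
#'
#' Closed form \eqn{(1 - 1/N)^{m r}} for `r` replicates of `m` uniform
#' draws with replacement from a pool of size `N`.
#'
#' @param N pool size (>= 1)
#' @param m draws per replicate
#' @param r number of replicates
#' @export
unsampled_fraction <- function(N, m, r) {
  if (N < 1) stop("pool size N must be at least 1")
  (1 - 1 / N)^(m * r)
}

#' Extract environmental sequences affiliated with the mitochondrial clade
#'
#' On a rooted tree, finds the MRCA of the mitochondrial leaves and returns
#' the environmental leaves descending from it; under
#' `"INSIDE_PLUS_SISTER"`, environmental leaves of its sister clade are
#' added (for a polytomous parent, the sister is the union of all
#' siblings). A sister clade whose reference leaves span more than one
#' order is the backbone of the phylogeny rather than a neighbour taxon
#' (this arises in replicates where the long outgroup branch pulls the
#' mitochondrial clade basal); such sisters contribute no flags.
#'
#' @param tree rooted `phylo`
#' @param categories named leaf-category vector
#' @param mode `"INSIDE_PLUS_SISTER"` or `"INSIDE_ONLY"`
#' @return sorted character vector of flagged environmental ids
#' @export
extract_mito_neighbours <- function(tree, categories,
                                    mode = c("INSIDE_PLUS_SISTER", "INSIDE_ONLY")) {
  mode <- match.arg(mode)
  if (!ape::is.rooted(tree)) {
    stop("tree must be rooted (root with the outgroup first)")
  }
  check_categories(tree, categories)
  mito <- leaves_of_kind(tree, categories, "MITOCHONDRIAL")
  if (length(mito) == 0L) stop("tree contains no mitochondrial leaf")
  env <- leaves_of_kind(tree, categories, "ENVIRONMENTAL")
  M <- mrca_node(tree, mito)
  sets <- clade_tip_sets(tree)
  flagged <- intersect(sets[[M]], env)
  if (mode == "INSIDE_PLUS_SISTER") {
    root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
    if (M != root) {
      parent <- tree$edge[tree$edge[, 2L] == M, 1L]
      sibs <- setdiff(tree$edge[tree$edge[, 1L] == parent, 2L], M)
      sister_tips <- unique(unlist(sets[sibs]))
      sister_orders <- unique(category_order(categories[
        intersect(sister_tips, leaves_of_kind(tree, categories, "REFERENCE"))]))
      if (length(sister_orders) <= 1L) {
        flagged <- union(flagged, intersect(sister_tips, env))
      }
    }
  }
  sort(flagged)
}

#' Run the jack-knife neighbour screen
#'
#' For each replicate, `sample_size` environmental sequences are drawn with
#' replacement, combined with the full reference set, a tree is inferred by
#' the backend, rooted with the outgroup, and mitochondrial-clade
#' neighbours are extracted. Replicates whose inference or rooting fails
#' are skipped and logged; more than 10% failures is an error.
#'
#' @param dataset environmental [ortholog_dataset()] (all members
#'   ENVIRONMENTAL, alignment required)
#' @param reference reference [ortholog_dataset()] including mitochondrial
#'   and outgroup members, aligned in the same coordinates
#' @param cfg a [screen_config()]
#' @return object of class `screen_result`: per-sequence counts (times
#'   sampled / times flagged), the flagged id set, and the un-sampled
#'   fraction estimate
#' @export
run_screen <- function(dataset, reference, cfg = screen_config()) {
  env_aln <- dataset$alignment
  ref_aln <- reference$alignment
  if (is.null(env_aln) || is.null(ref_aln)) stop("both datasets need alignments")
  if (ncol(env_aln) != ncol(ref_aln)) {
    stop("environmental and reference alignments have different widths")
  }
  categories <- c(dataset_categories(dataset), dataset_categories(reference))
  refs_kind <- category_kind(dataset_categories(reference))
  if (!any(refs_kind == "MITOCHONDRIAL")) {
    stop("reference dataset lacks mitochondrial members")
  }
  if (!any(refs_kind == "OUTGROUP")) {
    stop("reference dataset lacks outgroup members: tree cannot be rooted")
  }
  outgroup <- reference$members$id[refs_kind == "OUTGROUP"]
  pool <- dataset$members$id
  N <- length(pool)
  if (N == 0L) stop("empty environmental pool")
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  times_sampled <- setNames(integer(N), pool)
  times_flagged <- setNames(integer(N), pool)
  failures <- character(0)
  for (i in seq_len(cfg$replicates)) {
    samp <- jackknife_sample(pool, cfg$sample_size)
    ids <- sort(unique(samp))
    aln <- rbind(ref_aln, env_aln[ids, , drop = FALSE])
    res <- tryCatch({
      tr <- cfg$backend(aln)
      tr <- root_with_outgroup(tr, outgroup)
      extract_mito_neighbours(tr, categories, cfg$neighbour_mode)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", i, conditionMessage(res)))
      next
    }
    times_sampled[ids] <- times_sampled[ids] + 1L
    times_flagged[res] <- times_flagged[res] + 1L
  }
  if (length(failures) > 0.1 * cfg$replicates) {
    stop(sprintf("%d of %d screen replicates failed; first failure: %s",
                 length(failures), cfg$replicates, failures[1L]))
  }
  counts <- data.frame(id = pool, times_sampled = unname(times_sampled),
                       times_flagged = unname(times_flagged),
                       stringsAsFactors = FALSE)
  structure(list(
    counts = counts,
    flagged = sort(pool[times_flagged >= cfg$min_flag_count]),
    unsampled_fraction_estimate =
      unsampled_fraction(N, cfg$sample_size, cfg$replicates),
    failures = failures,
    config = cfg
  ), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %d sequences screened, %d flagged (un-sampled fraction %.3g, %d failed replicates)\n",
              nrow(x$counts), length(x$flagged),
              x$unsampled_fraction_estimate, length(x$failures)))
  invisible(x)
}

#' Concatenate flagged sequences by scaffold
#'
#' Keeps scaffolds that carry a flagged sequence and at least two genes
#' (the multi-gene scaffold filter), then concatenates the per-marker
#' aligned sequences in the fixed marker order of `alignments`; reference
#' taxa are concatenated in the same order. A scaffold with two genes from
#' the same marker is a paralogy flag and an error.
#'
#' @param flagged flagged environmental sequence ids
#' @param smap scaffold map data frame (scaffold_id, marker, seqid)
#' @param alignments named list of per-marker alignment matrices
#'   (environmental rows keyed by sequence id, reference rows by taxon)
#' @param reference_ids taxa to append using their rows of every marker
#'   alignment (gaps where absent)
#' @return list(alignment, partitions = data.frame(marker, start, end),
#'   scaffolds)
#' @export
scaffold_concat <- function(flagged, smap, alignments, reference_ids = character()) {
  stopifnot(all(c("scaffold_id", "marker", "seqid") %in% names(smap)))
  miss <- setdiff(flagged, smap$seqid)
  if (length(miss) > 0L) {
    stop("flagged ids absent from the scaffold map: ",
         paste(head(miss, 5L), collapse = ", "))
  }
  sc_flagged <- unique(smap$scaffold_id[smap$seqid %in% flagged])
  sub <- smap[smap$scaffold_id %in% sc_flagged, , drop = FALSE]
  if (anyDuplicated(sub[c("scaffold_id", "marker")])) {
    d <- sub[duplicated(sub[c("scaffold_id", "marker")]), ]
    stop(sprintf("scaffold %s carries marker %s twice (paralogy flag)",
                 d$scaffold_id[1L], d$marker[1L]))
  }
  genes_per <- table(sub$scaffold_id)
  keep <- sort(names(genes_per)[genes_per >= 2L])
  sub <- sub[sub$scaffold_id %in% keep, , drop = FALSE]
  markers_used <- intersect(names(alignments), unique(sub$marker))
  if (length(keep) == 0L || length(markers_used) == 0L) {
    return(list(alignment = matrix(character(0), 0L, 0L),
                partitions = data.frame(marker = character(0),
                                        start = integer(0), end = integer(0)),
                scaffolds = character(0)))
  }
  widths <- vapply(alignments[markers_used], ncol, integer(1L))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  rows <- c(keep, reference_ids)
  out <- matrix("-", length(rows), sum(widths), dimnames = list(rows, NULL))
  for (j in seq_along(markers_used)) {
    mk <- markers_used[j]
    cols <- starts[j]:ends[j]
    aln <- alignments[[mk]]
    g <- sub[sub$marker == mk, , drop = FALSE]
    for (r in seq_len(nrow(g))) {
      out[g$scaffold_id[r], cols] <- aln[g$seqid[r], ]
    }
    for (id in intersect(reference_ids, rownames(aln))) {
      out[id, cols] <- aln[id, ]
    }
  }
  list(alignment = out,
       partitions = data.frame(marker = markers_used, start = starts,
                               end = ends, stringsAsFactors = FALSE),
       scaffolds = keep)
}
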