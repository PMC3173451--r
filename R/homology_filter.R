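# Staged filtering of BLAST-style tabular hit files into curated ortholog
# datasets. All three thresholds are strict: E-value < evalue_max,
# HSP overlap (fraction of the query length) > seed_overlap_min for the
# initial retrieval, and > reciprocal_overlap_min for the reciprocal
# same-orthologous-group confirmation.

HIT_COLUMNS <- c("query", "subject", "pct_identity", "aln_len", "evalue",
                 "bitscore", "qcov_fraction", "subject_og", "subject_species")

#' Filter thresholds for the staged homology screen
#'
#' @param evalue_max hits qualify only with E-value strictly below this
#' @param seed_overlap_min minimum HSP overlap fraction (strict) for the
#'   initial seed/environmental retrieval
#' @param reciprocal_overlap_min minimum overlap fraction (strict) for the
#'   reciprocal confirmation search
#' @param dataset_min_count a marker dataset passes the size gate only with
#'   strictly more than this many retrieved sequences
#' @param best_hit_by `"bitscore"` (default) or `"evalue"`: ordering used to
#'   pick the best/top hit
#' @export
filter_config <- function(evalue_max = 1e-10, seed_overlap_min = 0.50,
                          reciprocal_overlap_min = 0.70,
                          dataset_min_count = 500L,
                          best_hit_by = c("bitscore", "evalue")) {
  best_hit_by <- match.arg(best_hit_by)
  stopifnot(evalue_max > 0,
            seed_overlap_min > 0, seed_overlap_min <= 1,
            reciprocal_overlap_min > 0, reciprocal_overlap_min <= 1,
            dataset_min_count > 0)
  structure(list(evalue_max = evalue_max,
                 seed_overlap_min = seed_overlap_min,
                 reciprocal_overlap_min = reciprocal_overlap_min,
                 dataset_min_count = as.integer(dataset_min_count),
                 best_hit_by = best_hit_by),
            class = "filter_config")
}

check_hit_table <- function(hits) {
  missing <- setdiff(HIT_COLUMNS, names(hits))
  if (length(missing) > 0L) {
    stop("hit table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (any(hits$evalue < 0)) stop("negative E-values in hit table")
  if (any(hits$qcov_fraction < 0 | hits$qcov_fraction > 1)) {
    stop("qcov_fraction outside [0, 1]")
  }
  invisible(TRUE)
}

#' Read / write a tab-separated hit table
#'
#' Columns: query, subject, pct_identity, aln_len, evalue, bitscore,
#' qcov_fraction, subject_og, subject_species (a documented superset of the
#' common 12-column tabular search format, with coverage as a fraction of
#' the query length).
#'
#' @param path TSV file
#' @export
read_hit_table <- function(path) {
  hits <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  check_hit_table(hits)
  hits
}

#' @rdname read_hit_table
#' @param hits hit table data frame
#' @export
write_hit_table <- function(hits, path) {
  check_hit_table(hits)
  utils::write.table(hits[HIT_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# deterministic ordering of hits: best first
order_hits <- function(hits, by = "bitscore") {
  if (by == "bitscore") {
    order(-hits$bitscore, hits$evalue, hits$subject)
  } else {
    order(hits$evalue, -hits$bitscore, hits$subject)
  }
}

passes <- function(hits, evalue_max, overlap_min) {
  hits$evalue < evalue_max & hits$qcov_fraction > overlap_min
}

#' Assign seed proteins to orthologous groups
#'
#' For each seed (query) protein, the orthologous group of its best hit
#' among hits with E-value < `evalue_max` and overlap > `seed_overlap_min`.
#' Seeds without a qualifying hit are reported with `og = NA` (unassigned).
#'
#' @param seed_hits hit table of seed proteins against the reference OG
#'   database
#' @param cfg a [filter_config()]
#' @return data frame (seed, og)
#' @export
assign_seed_orthologs <- function(seed_hits, cfg = filter_config()) {
  check_hit_table(seed_hits)
  qual <- seed_hits[passes(seed_hits, cfg$evalue_max, cfg$seed_overlap_min), ]
  seeds <- sort(unique(seed_hits$query))
  og <- rep(NA_character_, length(seeds))
  for (i in seq_along(seeds)) {
    h <- qual[qual$query == seeds[i], ]
    if (nrow(h) > 0L) og[i] <- h$subject_og[order_hits(h, cfg$best_hit_by)[1L]]
  }
  data.frame(seed = seeds, og = og, stringsAsFactors = FALSE)
}

#' Keep at most one member per species in an ortholog group
#'
#' Duplicate identical ids are collapsed first; among members of the same
#' species the one with the best bitscore against the seed is retained
#' (ties: lexicographically smallest id).
#'
#' @param members data frame with columns id, species, bitscore
#' @return subset of `members`
#' @export
dedup_per_species <- function(members) {
  stopifnot(all(c("id", "species", "bitscore") %in% names(members)))
  members <- members[!duplicated(members$id), , drop = FALSE]
  ord <- order(members$species, -members$bitscore, members$id)
  m <- members[ord, , drop = FALSE]
  m <- m[!duplicated(m$species), , drop = FALSE]
  m[order(m$id), , drop = FALSE]
}

#' Retrieve environmental candidate sequences for a marker
#'
#' Ids of environmental sequences (hit-table subjects; the seed protein is
#' the query) with at least one hit passing E-value < `evalue_max` and
#' overlap > `seed_overlap_min`.
#'
#' @param env_hits hit table: seed protein (query) vs environmental pool
#' @param cfg a [filter_config()]
#' @return sorted character vector of environmental ids
#' @export
retrieve_env_candidates <- function(env_hits, cfg = filter_config()) {
  check_hit_table(env_hits)
  sort(unique(env_hits$subject[passes(env_hits, cfg$evalue_max,
                                      cfg$seed_overlap_min)]))
}

#' Reciprocal same-group confirmation
#'
#' A candidate is retained only if its top hit back against the reference
#' database (among hits with E-value < `evalue_max` and overlap >
#' `reciprocal_overlap_min`) belongs to `expected_og`.
#'
#' @param candidate_hits hit table: candidates (query) vs reference OG
#'   database
#' @param expected_og orthologous-group id the top hit must belong to
#' @param cfg a [filter_config()]
#' @return sorted character vector of retained candidate ids
#' @export
reciprocal_og_filter <- function(candidate_hits, expected_og,
                                 cfg = filter_config()) {
  check_hit_table(candidate_hits)
  qual <- candidate_hits[passes(candidate_hits, cfg$evalue_max,
                                cfg$reciprocal_overlap_min), ]
  retained <- character(0)
  for (q in unique(qual$query)) {
    h <- qual[qual$query == q, ]
    top <- h[order_hits(h, cfg$best_hit_by)[1L], ]
    if (identical(top$subject_og, expected_og)) retained <- c(retained, q)
  }
  sort(retained)
}

#' Dataset-size gate
#'
#' TRUE only when strictly more than `dataset_min_count` sequences were
#' retrieved in the first search.
#'
#' @param candidate_count integer count of retrieved sequences
#' @param cfg a [filter_config()]
#' @export
dataset_gate <- function(candidate_count, cfg = filter_config()) {
  candidate_count > cfg$dataset_min_count
}

#' Mask gap-rich alignment columns
#'
#' A transparent stand-in for block-filtering programs: columns whose gap
#' fraction exceeds `max_gap_fraction` are removed, and the kept-column map
#' is reported so any external masker can be substituted.
#'
#' @param aln alignment matrix or named sequence strings
#' @param max_gap_fraction keep columns with gap fraction <= this (default 0.5)
#' @return list(alignment = masked matrix, kept = kept column indices)
#' @export
mask_columns <- function(aln, max_gap_fraction = 0.5) {
  m <- as_alignment_matrix(aln)
  gapfrac <- colMeans(matrix(m %in% GAP_CHARS, nrow(m), ncol(m)))
  kept <- which(gapfrac <= max_gap_fraction)
  if (length(kept) == 0L) stop("all alignment columns exceed the gap threshold")
  list(alignment = m[, kept, drop = FALSE], kept = kept)
}

# Curated per-marker sequence set --------------------------------------------

#' Construct an ortholog dataset
#'
#' One marker's curated sequence set: member ids with leaf categories, the
#' member sequences/alignment, and a provenance log recording which filter
#' admitted each member.
#'
#' @param marker marker name
#' @param members data frame (id, category)
#' @param alignment alignment matrix over the member ids (optional)
#' @param provenance character log lines
#' @export
ortholog_dataset <- function(marker, members, alignment = NULL,
                             provenance = character()) {
  stopifnot(all(c("id", "category") %in% names(members)))
  if (anyDuplicated(members$id)) stop("duplicate member ids")
  if (any(is.na(members$category) | members$category == "")) {
    stop("every member needs a category")
  }
  if (!is.null(alignment)) {
    alignment <- as_alignment_matrix(alignment)
    missing <- setdiff(members$id, rownames(alignment))
    if (length(missing) > 0L) {
      stop("members without sequences: ", paste(head(missing, 5L), collapse = ", "))
    }
    alignment <- alignment[members$id, , drop = FALSE]
  }
  structure(list(marker = marker, members = members, alignment = alignment,
                 provenance = provenance),
            class = "ortholog_dataset")
}

#' @export
print.ortholog_dataset <- function(x, ...) {
  cat(sprintf("<ortholog_dataset> marker %s: %d members (%s)\n", x$marker,
              nrow(x$members),
              paste(sprintf("%s=%d", names(table(category_kind(x$members$category))),
                            table(category_kind(x$members$category))),
                    collapse = ", ")))
  invisible(x)
}

#' Leaf categories of an ortholog dataset, named by member id
#' @param dataset an [ortholog_dataset()]
#' @export
dataset_categories <- function(dataset) {
  setNames(dataset$members$category, dataset$members$id)
}
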