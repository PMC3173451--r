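# Marker selection: phylogenetic coherence (dual monophyly of the
# mitochondrial sequences and of the alphaproteobacterial clade) and
# amino-acid composition-bias diagnostics.
#
# FYMINK/GARP convention: F, Y, M, I, N, K are encoded by AT-rich codon
# families and G, A, R, P by GC-rich ones, so their protein-level
# frequencies diagnose nucleotide compositional bias across lineages.

#' Amino acids diagnostic of AT-rich codon families
#' @export
AT_RESIDUES <- c("F", "Y", "M", "I", "N", "K")

#' Amino acids diagnostic of GC-rich codon families
#' @export
GC_RESIDUES <- c("G", "A", "R", "P")

#' AT- and GC-codon amino-acid frequencies of a protein sequence
#'
#' Gaps and ambiguity codes are excluded from the denominator.
#'
#' @param seq protein sequence (string or character vector of residues)
#' @param at_set,gc_set diagnostic residue sets (FYMINK / GARP by default)
#' @return named numeric c(f_AT, f_GC)
#' @export
at_gc_frequencies <- function(seq, at_set = AT_RESIDUES, gc_set = GC_RESIDUES) {
  r <- if (length(seq) == 1L) strsplit(toupper(seq), "", fixed = TRUE)[[1L]] else toupper(seq)
  aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  r <- r[r %in% aa20]
  if (length(r) == 0L) stop("empty effective sequence (no standard residues)")
  c(f_AT = mean(r %in% at_set), f_GC = mean(r %in% gc_set))
}

#' Per-taxon composition profile and lineage spread of a marker dataset
#'
#' Computes f_AT and f_GC for every taxon and the max-minus-min spread
#' across taxa; markers whose spread exceeds `threshold` ("a few percent")
#' are flagged as composition-biased.
#'
#' @param sequences alignment matrix, named sequence strings, or an
#'   [ortholog_dataset()]
#' @param threshold spread above which the marker is flagged (default 0.05)
#' @inheritParams at_gc_frequencies
#' @return list(profile = data.frame(taxon, f_AT, f_GC), spread_AT,
#'   spread_GC, flagged)
#' @export
composition_spread <- function(sequences, threshold = 0.05,
                               at_set = AT_RESIDUES, gc_set = GC_RESIDUES) {
  if (inherits(sequences, "ortholog_dataset")) sequences <- sequences$alignment
  if (is.matrix(sequences)) sequences <- alignment_strings(sequences)
  if (is.null(names(sequences))) stop("sequences must be named")
  if (length(sequences) < 2L) stop("composition spread needs at least 2 taxa")
  fr <- t(vapply(sequences, at_gc_frequencies, numeric(2L),
                 at_set = at_set, gc_set = gc_set))
  profile <- data.frame(taxon = names(sequences), f_AT = fr[, "f_AT"],
                        f_GC = fr[, "f_GC"], row.names = NULL,
                        stringsAsFactors = FALSE)
  spread_AT <- max(profile$f_AT) - min(profile$f_AT)
  spread_GC <- max(profile$f_GC) - min(profile$f_GC)
  list(profile = profile, spread_AT = spread_AT, spread_GC = spread_GC,
       flagged = spread_AT > threshold || spread_GC > threshold)
}

#' Phylogenetic-coherence test for a marker tree
#'
#' A marker passes when the mitochondrial sequences form a monophyletic
#' group and the alphaproteobacterial clade (reference + mitochondrial +
#' environmental leaves, i.e. everything but the outgroup) is monophyletic.
#' On unrooted trees monophyly is bipartition presence.
#'
#' @param tree a `phylo` over categorised leaves
#' @param categories named leaf-category vector (see [reference_category()])
#' @param marker_name optional marker name carried into the verdict
#' @return data frame (marker_name, mito_monophyletic, alpha_monophyletic,
#'   pass)
#' @export
coherence_test <- function(tree, categories, marker_name = NA_character_) {
  check_categories(tree, categories)
  mito <- leaves_of_kind(tree, categories, "MITOCHONDRIAL")
  refs <- leaves_of_kind(tree, categories, "REFERENCE")
  if (length(mito) < 1L) stop("coherence test needs at least 1 mitochondrial leaf")
  if (length(refs) < 2L) stop("coherence test needs at least 2 reference leaves")
  alpha <- setdiff(tree$tip.label, leaves_of_kind(tree, categories, "OUTGROUP"))
  data.frame(marker_name = marker_name,
             mito_monophyletic = is_monophyletic(tree, mito),
             alpha_monophyletic = is_monophyletic(tree, alpha),
             pass = is_monophyletic(tree, mito) && is_monophyletic(tree, alpha),
             stringsAsFactors = FALSE)
}

#' Select coherent markers
#'
#' Passing markers ordered by name, optionally truncated to a shortlist
#' for the computationally expensive downstream analyses.
#'
#' @param verdicts data frame of [coherence_test()] rows
#' @param shortlist_size maximum number of markers to keep (default all)
#' @return character vector of marker names
#' @export
select_markers <- function(verdicts, shortlist_size = Inf) {
  stopifnot(all(c("marker_name", "pass") %in% names(verdicts)))
  passing <- sort(verdicts$marker_name[verdicts$pass])
  head(passing, if (is.finite(shortlist_size)) shortlist_size else length(passing))
}
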