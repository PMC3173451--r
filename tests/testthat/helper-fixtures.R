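# Shared fixtures: random trees, additive distance matrices, and an
# independent (ape-based) bipartition oracle used to cross-check the
# package's own split machinery.

random_tree <- function(n, rooted = TRUE) {
  tr <- ape::rtree(n, rooted = rooted)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
  tr
}

# independent oracle: all bipartitions of a tree via ape::prop.part
oracle_splits <- function(tree) {
  labs <- tree$tip.label
  pp <- ape::prop.part(tree)
  keys <- vapply(pp, function(idx) {
    side <- labs[idx]
    ref <- sort(labs)[1L]
    s <- if (ref %in% side) side else setdiff(labs, side)
    paste(sort(s), collapse = "\t")
  }, character(1L))
  unique(keys)
}

oracle_is_mono_unrooted <- function(tree, leafset) {
  labs <- tree$tip.label
  k <- length(unique(leafset))
  if (k %in% c(1L, length(labs) - 1L, length(labs))) return(TRUE)
  ref <- sort(labs)[1L]
  s <- if (ref %in% leafset) leafset else setdiff(labs, leafset)
  key <- paste(sort(s), collapse = "\t")
  # drop the trivial whole-set partition reported by prop.part
  splits <- Filter(function(x) {
    length(strsplit(x, "\t", fixed = TRUE)[[1L]]) < length(labs)
  }, oracle_splits(tree))
  key %in% splits
}

# brute-force Faith PD: union of edges on all pairwise tip paths
oracle_faith_pd <- function(tree, subset) {
  idx <- match(subset, tree$tip.label)
  nodes_on_path <- function(a, b) {
    anc <- function(x) {
      out <- x
      repeat {
        up <- tree$edge[tree$edge[, 2L] == x, 1L]
        if (length(up) == 0L) break
        out <- c(out, up); x <- up
      }
      out
    }
    pa <- anc(a); pb <- anc(b)
    m <- intersect(pa, pb)[1L]
    c(pa[seq_len(which(pa == m) - 1L)], pb[seq_len(which(pb == m) - 1L)])
  }
  edges <- unique(unlist(lapply(utils::combn(idx, 2L, simplify = FALSE),
                                function(p) nodes_on_path(p[1L], p[2L]))))
  sum(tree$edge.length[match(edges, tree$edge[, 2L])])
}

# small labelled screen tree used across neighbour-extraction tests:
# outgroup, reference order, Rickettsiales, mitochondria, and env leaves
# planted inside the mitochondrial clade, in its sister clade, and far away
screen_fixture <- function() {
  nwk <- paste0("((OUT_1:0.1,OUT_2:0.1):0.5,((REF_S1:0.1,(REF_S2:0.1,",
                "ENV_far:0.1):0.05):0.3,((REF_R1:0.1,REF_R2:0.1):0.2,",
                "((MITO_1:0.1,(MITO_2:0.1,ENV_in:0.1):0.05):0.3,",
                "(ENV_sis1:0.1,ENV_sis2:0.1):0.2):0.1):0.1):0.2):0;")
  tree <- parse_newick(nwk)
  categories <- c(OUT_1 = "OUTGROUP", OUT_2 = "OUTGROUP",
                  REF_S1 = reference_category("SAR11"),
                  REF_S2 = reference_category("SAR11"),
                  REF_R1 = reference_category("Rickettsiales"),
                  REF_R2 = reference_category("Rickettsiales"),
                  MITO_1 = "MITOCHONDRIAL", MITO_2 = "MITOCHONDRIAL",
                  ENV_in = "ENVIRONMENTAL", ENV_sis1 = "ENVIRONMENTAL",
                  ENV_sis2 = "ENVIRONMENTAL", ENV_far = "ENVIRONMENTAL")
  list(tree = tree, categories = categories)
}

# minimal hit table row
hit_row <- function(query, subject, evalue, bitscore, qcov,
                    og = NA_character_, species = NA_character_) {
  data.frame(query = query, subject = subject, pct_identity = 70,
             aln_len = 300L, evalue = evalue, bitscore = bitscore,
             qcov_fraction = qcov, subject_og = og, subject_species = species,
             stringsAsFactors = FALSE)
}
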