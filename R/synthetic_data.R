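# Synthetic metagenome generator. Emulates the statistical structure the
# screen assumes: a reference phylogeny of alphaproteobacterial order
# clades with the mitochondrial clade sister to the Rickettsiales, a rare
# planted clade on the mitochondrial stem, an environmental pool dominated
# by a SAR11-like clade, lineage-specific AT-composition bias, scaffolds
# carrying 1-3 genes of one organism, and emulated BLAST-style hit tables
# with deliberate boundary records. Everything is labelled with truth.

default_aa_freqs <- function() {
  c(A = 0.078, R = 0.053, N = 0.043, D = 0.053, C = 0.019, Q = 0.039,
    E = 0.063, G = 0.072, H = 0.023, I = 0.053, L = 0.091, K = 0.059,
    M = 0.024, F = 0.039, P = 0.052, S = 0.068, T = 0.059, W = 0.014,
    Y = 0.032, V = 0.066)
}

#' Configuration of the synthetic metagenome generator
#'
#' Defaults emulate the study conditions the screen was designed for: 28
#' reference taxa in six order-like clades, 5 mitochondrial and 2 outgroup
#' taxa, an environmental pool of 1000 gene sequences dominated by the
#' SAR11-like clade (82.5%), and a rare planted clade (2% of the pool)
#' sister to the mitochondria, attached at the mitochondrial stem.
#'
#' @param rng_seed seed for the whole generation (full determinism)
#' @param order_sizes named integer vector: reference taxa per order
#' @param mito_count,outgroup_count mitochondrial / outgroup taxon counts
#' @param planted_clade_size founding lineages of the planted clade (0
#'   removes it)
#' @param planted_stem_length stem branch of the planted clade,
#'   substitutions/site
#' @param planted_attach `"mito_stem"` (planted sister to the mitochondria;
#'   default) or `"group_stem"` (sister to Rickettsiales+mitochondria)
#' @param env_pool_size environmental gene sequences drawn from
#'   `env_order_profile`
#' @param env_order_profile named proportions of the environmental pool per
#'   order (sums to at most 1)
#' @param planted_fraction additional planted-clade gene sequences, as a
#'   fraction of `env_pool_size`
#' @param seq_length alignment columns per marker
#' @param substitution_rate multiplier on branch lengths
#' @param bias_strength s in [0, 1]: stationary frequencies of AT-biased
#'   lineages are shifted by s toward the FYMINK set
#' @param biased_groups lineages receiving the AT shift
#' @param scaffold_gene_counts distribution of genes per scaffold over
#'   1, 2, 3
#' @param markers marker gene names
#' @param hit_noise list(evalue_jitter, overlap_jitter, decoy_rate)
#' @param within_branch_mean mean of the exponential branch lengths inside
#'   clades
#' @param backbone_edge_mean mean of the exponential part of backbone edges
#' @param backbone_edge_min floor added to every backbone edge (deep splits
#'   of the reference phylogeny are resolved in this system)
#' @param order_stem,mito_stem,outgroup_stem stem branch lengths of order
#'   clades, the mitochondrial clade and the outgroup
#' @param aa_freqs global stationary amino-acid frequencies (named, sums
#'   to 1)
#' @param at_set residues of the AT-rich codon families
#' @export
sim_config <- function(rng_seed = 1L,
                       order_sizes = c(SAR11 = 3L, Rickettsiales = 6L,
                                       Rhodobacterales = 6L,
                                       Rhodospirillales = 5L,
                                       Rhizobiales = 5L,
                                       Caulobacterales = 3L),
                       mito_count = 5L, outgroup_count = 2L,
                       planted_clade_size = 6L,
                       planted_stem_length = 0.3,
                       planted_attach = c("mito_stem", "group_stem"),
                       env_pool_size = 1000L,
                       env_order_profile = c(SAR11 = 0.825,
                                             Rhodobacterales = 0.093,
                                             Rhodospirillales = 0.074,
                                             Rhizobiales = 0.006,
                                             Rickettsiales = 0.002),
                       planted_fraction = 0.02,
                       seq_length = 500L, substitution_rate = 1,
                       bias_strength = 0.1,
                       biased_groups = c("SAR11", "Rickettsiales",
                                         "MITOCHONDRIAL", "PLANTED"),
                       scaffold_gene_counts = c("1" = 0.7, "2" = 0.25,
                                                "3" = 0.05),
                       markers = c("COX1", "COX2", "COB", "NAD7", "RPS2"),
                       hit_noise = list(evalue_jitter = 0,
                                        overlap_jitter = 0,
                                        decoy_rate = 0),
                       within_branch_mean = 0.05,
                       backbone_edge_mean = 0.07,
                       backbone_edge_min = 0.05,
                       order_stem = 0.25, mito_stem = 0.35,
                       outgroup_stem = 0.6,
                       aa_freqs = NULL,
                       at_set = AT_RESIDUES) {
  planted_attach <- match.arg(planted_attach)
  if (is.null(aa_freqs)) aa_freqs <- default_aa_freqs()
  aa_freqs <- aa_freqs / sum(aa_freqs)
  stopifnot(all(order_sizes >= 0), mito_count >= 1, outgroup_count >= 1,
            planted_clade_size >= 0, planted_stem_length >= 0,
            env_pool_size >= 0, planted_fraction >= 0,
            bias_strength >= 0, bias_strength <= 1,
            seq_length >= 1, substitution_rate >= 0,
            abs(sum(scaffold_gene_counts) - 1) < 1e-9)
  if (sum(env_order_profile) > 1 + 1e-9) {
    stop("env_order_profile proportions must sum to at most 1")
  }
  if (!all(names(env_order_profile) %in% names(order_sizes))) {
    stop("env_order_profile names must be orders in order_sizes")
  }
  structure(list(rng_seed = rng_seed, order_sizes = order_sizes,
                 mito_count = as.integer(mito_count),
                 outgroup_count = as.integer(outgroup_count),
                 planted_clade_size = as.integer(planted_clade_size),
                 planted_stem_length = planted_stem_length,
                 planted_attach = planted_attach,
                 env_pool_size = as.integer(env_pool_size),
                 env_order_profile = env_order_profile,
                 planted_fraction = planted_fraction,
                 seq_length = as.integer(seq_length),
                 substitution_rate = substitution_rate,
                 bias_strength = bias_strength,
                 biased_groups = biased_groups,
                 scaffold_gene_counts = scaffold_gene_counts,
                 markers = markers, hit_noise = hit_noise,
                 within_branch_mean = within_branch_mean,
                 backbone_edge_mean = backbone_edge_mean,
                 backbone_edge_min = backbone_edge_min,
                 order_stem = order_stem, mito_stem = mito_stem,
                 outgroup_stem = outgroup_stem,
                 aa_freqs = aa_freqs, at_set = at_set),
            class = "sim_config")
}

# draw environmental organisms until `n_target` gene sequences exist;
# each organism gets an order, 1-3 distinct markers, and one scaffold
draw_organisms <- function(cfg) {
  gdist <- cfg$scaffold_gene_counts
  draw_group <- function(n_target, orders, probs, prefix, min_orgs = 0L) {
    org <- character(0); ord <- character(0); mks <- list()
    total <- 0L; i <- 0L
    while (total < n_target || length(org) < min_orgs) {
      i <- i + 1L
      g <- as.integer(sample(names(gdist), 1L, prob = gdist))
      if (total >= n_target) g <- 1L  # padding organisms for min_orgs
      g <- max(1L, min(g, n_target - total, length(cfg$markers)))
      org <- c(org, sprintf("%s%04d", prefix, i))
      ord <- c(ord, if (length(orders) == 1L) orders else
        sample(orders, 1L, prob = probs))
      mks <- c(mks, list(sort(sample(cfg$markers, g))))
      total <- total + g
    }
    data.frame(id = org, order = ord,
               markers = vapply(mks, paste, "", collapse = ";"),
               n_genes = lengths(mks), stringsAsFactors = FALSE)
  }
  prof <- cfg$env_order_profile
  out <- draw_group(cfg$env_pool_size, names(prof), prof, "ORG")
  n_planted <- round(cfg$planted_fraction * cfg$env_pool_size)
  if (cfg$planted_clade_size > 0L && n_planted > 0L) {
    pl <- draw_group(n_planted, "PLANTED", 1, "PORG",
                     min_orgs = cfg$planted_clade_size)
    out <- rbind(out, pl)
  }
  out
}

# newick of a random subclade: random topology, exponential branch lengths
subclade_newick <- function(labels, mean_bl) {
  if (length(labels) == 0L) return(NULL)
  if (length(labels) == 1L) return(labels)
  tr <- ape::rtree(length(labels), br = function(k) rexp(k, 1 / mean_bl))
  tr$tip.label <- sample(labels)
  sub(";$", "", ape::write.tree(tr))
}

#' Simulate the labelled species tree
#'
#' Builds a rooted binary tree with one subtree per reference order (its
#' reference taxa mixed with the environmental organisms of that order),
#' the mitochondrial clade sister to the Rickettsiales, the planted clade
#' attached per `planted_attach`, and the outgroup at the root. Branch
#' lengths are exponential draws; clade stems are the configured constants.
#'
#' @param cfg a [sim_config()]
#' @param organisms optional organism table (drawn internally when NULL;
#'   note the caller is responsible for seeding the RNG)
#' @return list(tree, categories, organisms)
#' @export
simulate_species_tree <- function(cfg = sim_config(), organisms = NULL) {
  if (is.null(organisms)) organisms <- draw_organisms(cfg)
  e <- function() cfg$backbone_edge_min + rexp(1L, 1 / cfg$backbone_edge_mean)
  wb <- cfg$within_branch_mean
  stem <- function(nwk, len) sprintf("%s:%.8f", nwk, len)
  clade_of <- function(order) {
    refs <- if (cfg$order_sizes[[order]] > 0L) {
      sprintf("REF_%s_%02d", order, seq_len(cfg$order_sizes[[order]]))
    } else character(0)
    envs <- organisms$id[organisms$order == order]
    subclade_newick(c(refs, envs), wb)
  }
  orders <- names(cfg$order_sizes)
  has_tips <- vapply(orders, function(o) {
    cfg$order_sizes[[o]] > 0L || any(organisms$order == o)
  }, logical(1L))
  fl <- setdiff(orders[has_tips], "Rickettsiales")
  if (length(fl) == 0L) stop("no free-living order has any taxa")
  ladder <- stem(clade_of(fl[1L]), cfg$order_stem)
  for (o in fl[-1L]) {
    ladder <- sprintf("(%s,%s):%.8f", ladder, stem(clade_of(o), cfg$order_stem), e())
  }
  if (!("Rickettsiales" %in% orders[has_tips])) {
    stop("the Rickettsiales clade must have at least one taxon")
  }
  rick <- stem(clade_of("Rickettsiales"), cfg$order_stem)
  mito <- stem(subclade_newick(sprintf("MITO_%02d", seq_len(cfg$mito_count)), wb),
               cfg$mito_stem)
  planted_orgs <- organisms$id[organisms$order == "PLANTED"]
  if (length(planted_orgs) > 0L) {
    planted <- stem(subclade_newick(planted_orgs, wb), cfg$planted_stem_length)
    rick_group <- if (cfg$planted_attach == "mito_stem") {
      sprintf("(%s,(%s,%s):%.8f)", rick, mito, planted, e())
    } else {
      sprintf("((%s,%s):%.8f,%s)", rick, mito, e(), planted)
    }
  } else {
    rick_group <- sprintf("(%s,%s)", rick, mito)
  }
  outg <- stem(subclade_newick(sprintf("OUT_%02d", seq_len(cfg$outgroup_count)), wb),
               cfg$outgroup_stem)
  ingroup <- sprintf("(%s,%s:%.8f)", ladder, rick_group, e())
  nwk <- sprintf("(%s,%s:%.8f);", outg, ingroup, e())
  tree <- ape::read.tree(text = nwk)
  labs <- tree$tip.label
  categories <- setNames(rep("ENVIRONMENTAL", length(labs)), labs)
  for (o in orders) {
    categories[startsWith(labs, paste0("REF_", o, "_"))] <- reference_category(o)
  }
  categories[startsWith(labs, "MITO_")] <- "MITOCHONDRIAL"
  categories[startsWith(labs, "OUT_")] <- "OUTGROUP"
  list(tree = tree, categories = categories, organisms = organisms)
}

#' Evolve one marker alignment along a tree
#'
#' Per-site continuous-time substitution toward a global stationary
#' amino-acid frequency vector (an F81-style process calibrated so branch
#' lengths are expected substitutions/site); on branches whose whole
#' subtree consists of `biased_tips`, the target frequencies are shifted by
#' `bias_strength` toward the AT set. Alignments are gapless.
#'
#' @param tree a `phylo`
#' @param cfg a [sim_config()]
#' @param biased_tips tips of AT-biased lineages
#' @return gapless alignment matrix over the tree's tips
#' @export
evolve_alignment <- function(tree, cfg = sim_config(), biased_tips = character()) {
  L <- cfg$seq_length
  pi0 <- cfg$aa_freqs
  aa <- names(pi0)
  s <- cfg$bias_strength
  piA <- (1 - s) * pi0
  piA[cfg$at_set] <- piA[cfg$at_set] + s / length(cfg$at_set)
  beta <- 1 / (1 - sum(pi0^2))
  sets <- clade_tip_sets(tree)
  po <- stats::reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  seqs <- vector("list", n_tip + tree$Nnode)
  root <- setdiff(po$edge[, 1L], po$edge[, 2L])
  seqs[[root]] <- sample(aa, L, replace = TRUE, prob = pi0)
  elen <- po$edge.length
  if (is.null(elen)) elen <- numeric(nrow(po$edge))
  for (r in rev(seq_len(nrow(po$edge)))) {  # preorder
    p <- po$edge[r, 1L]; ch <- po$edge[r, 2L]
    t <- elen[r] * cfg$substitution_rate
    child <- seqs[[p]]
    hit <- runif(L) < 1 - exp(-beta * t)
    if (any(hit)) {
      pie <- if (length(biased_tips) > 0L && all(sets[[ch]] %in% biased_tips)) {
        piA
      } else {
        pi0
      }
      child[hit] <- sample(aa, sum(hit), replace = TRUE, prob = pie)
    }
    seqs[[ch]] <- child
  }
  out <- do.call(rbind, seqs[seq_len(n_tip)])
  rownames(out) <- tree$tip.label
  out
}

# tips of the lineages designated AT-biased
biased_tip_set <- function(st, cfg) {
  cats <- st$categories
  labs <- names(cats)
  tips <- character(0)
  for (g in cfg$biased_groups) {
    tips <- c(tips, switch(
      g,
      MITOCHONDRIAL = labs[cats == "MITOCHONDRIAL"],
      PLANTED = st$organisms$id[st$organisms$order == "PLANTED"],
      {
        c(labs[cats == reference_category(g)],
          st$organisms$id[st$organisms$order == g])
      }))
  }
  unique(tips)
}

#' Emit the environmental pool, scaffold map and truth labels
#'
#' One gene sequence per organism x carried marker, named
#' `GOS_<marker>_<organism>`; each organism's genes share one scaffold.
#'
#' @param cfg a [sim_config()]
#' @param st result of [simulate_species_tree()]
#' @param alignments named list of per-marker alignments over the tree tips
#' @return list(env_sequences (named strings), scaffold_map, truth)
#' @export
emit_metagenome <- function(cfg, st, alignments) {
  orgs <- st$organisms
  if (nrow(orgs) == 0L) {
    empty_truth <- data.frame(seqid = character(0), marker = character(0),
                              organism = character(0), order = character(0),
                              planted = logical(0), stringsAsFactors = FALSE)
    return(list(env_sequences = setNames(character(0), character(0)),
                scaffold_map = data.frame(scaffold_id = character(0),
                                          marker = character(0),
                                          seqid = character(0),
                                          stringsAsFactors = FALSE),
                truth = empty_truth))
  }
  rows <- do.call(rbind, lapply(seq_len(nrow(orgs)), function(i) {
    mks <- strsplit(orgs$markers[i], ";", fixed = TRUE)[[1L]]
    data.frame(organism = orgs$id[i], order = orgs$order[i], marker = mks,
               seqid = sprintf("GOS_%s_%s", mks, orgs$id[i]),
               scaffold_id = paste0("SCF_", orgs$id[i]),
               stringsAsFactors = FALSE)
  }))
  env <- setNames(vapply(seq_len(nrow(rows)), function(i) {
    paste(alignments[[rows$marker[i]]][rows$organism[i], ], collapse = "")
  }, character(1L)), rows$seqid)
  list(env_sequences = env,
       scaffold_map = rows[c("scaffold_id", "marker", "seqid")],
       truth = data.frame(seqid = rows$seqid, marker = rows$marker,
                          organism = rows$organism, order = rows$order,
                          planted = rows$order == "PLANTED",
                          stringsAsFactors = FALSE))
}

new_hit <- function(query, subject, evalue, bitscore, qcov, og = NA_character_,
                    species = NA_character_) {
  data.frame(query = query, subject = subject, pct_identity = 70,
             aln_len = 300L, evalue = evalue, bitscore = bitscore,
             qcov_fraction = qcov, subject_og = og, subject_species = species,
             stringsAsFactors = FALSE)
}

#' Emit emulated BLAST-style hit tables
#'
#' True orthologs receive strong hits to their own orthologous group;
#' decoy paralogs (at `hit_noise$decoy_rate`) receive cross-group top hits;
#' boundary records (E-value exactly 1e-10, overlap exactly 0.5 and 0.7)
#' are emitted deliberately so the strict thresholds are exercised.
#'
#' @param cfg a [sim_config()]
#' @param truth truth table from [emit_metagenome()]
#' @return list(seed_hits, env_hits (per marker), recip_hits (per marker),
#'   truth_ids, decoy_ids, boundary_ids)
#' @export
emit_hit_tables <- function(cfg, truth) {
  noise <- cfg$hit_noise
  jitter_e <- function(le, n) le + noise$evalue_jitter * rnorm(n)
  jitter_q <- function(q, n) pmin(1, pmax(0, q + noise$overlap_jitter * rnorm(n)))
  og <- function(m) paste0("OG_", m)
  seed_hits <- do.call(rbind, lapply(cfg$markers, function(m) {
    rbind(new_hit(paste0("SEED_", m), paste0(og(m), "_ref1"), 1e-80, 320, 0.92,
                  og(m), "refdb"),
          new_hit(paste0("SEED_", m), "OG_OTHER_ref1", 1e-20, 150, 0.80,
                  "OG_OTHER", "refdb"))
  }))
  env_hits <- list(); recip_hits <- list()
  truth_ids <- list(); decoy_ids <- list(); boundary_ids <- list()
  for (m in cfg$markers) {
    ids <- truth$seqid[truth$marker == m]
    n <- length(ids)
    n_dec <- round(noise$decoy_rate * n)
    dec <- if (n_dec > 0L) sprintf("GOS_%s_DECOY%03d", m, seq_len(n_dec)) else character(0)
    b_e <- sprintf("GOS_%s_BOUND_EVAL", m)
    b_c <- sprintf("GOS_%s_BOUND_COV", m)
    b_r <- sprintf("GOS_%s_BOUND_RECIP", m)
    eh <- rbind(
      if (n > 0L) new_hit(paste0("SEED_", m), ids,
              10^jitter_e(-(30 + 50 * runif(n)), n), round(150 + 200 * runif(n)),
              jitter_q(runif(n, 0.75, 0.95), n)),
      if (n_dec > 0L) new_hit(paste0("SEED_", m), dec,
                              10^jitter_e(-(20 + 20 * runif(n_dec)), n_dec),
                              round(120 + 100 * runif(n_dec)),
                              jitter_q(runif(n_dec, 0.6, 0.9), n_dec)),
      new_hit(paste0("SEED_", m), b_e, 1e-10, 180, 0.90),
      new_hit(paste0("SEED_", m), b_c, 1e-30, 180, 0.50)
    )
    rh <- rbind(
      if (n > 0L) new_hit(ids, paste0(og(m), "_ref1"),
              10^jitter_e(-(40 + 40 * runif(n)), n),
              round(220 + 80 * runif(n)), jitter_q(runif(n, 0.75, 0.95), n),
              og(m), "refdb"),
      if (n > 0L) new_hit(ids, "OG_OTHER_ref1", 1e-15, 110, 0.75, "OG_OTHER", "refdb"),
      if (n_dec > 0L) rbind(
        new_hit(dec, "OG_PARALOG_ref1", 1e-60, 300, 0.85, "OG_PARALOG", "refdb"),
        new_hit(dec, paste0(og(m), "_ref1"), 1e-20, 140, 0.80, og(m), "refdb")
      ),
      new_hit(b_r, paste0(og(m), "_ref1"), 1e-30, 200, 0.70, og(m), "refdb")
    )
    env_hits[[m]] <- eh
    recip_hits[[m]] <- rh
    truth_ids[[m]] <- sort(ids)
    decoy_ids[[m]] <- dec
    boundary_ids[[m]] <- c(b_e, b_c, b_r)
  }
  list(seed_hits = seed_hits, env_hits = env_hits, recip_hits = recip_hits,
       truth_ids = truth_ids, decoy_ids = decoy_ids,
       boundary_ids = boundary_ids)
}

#' Generate a complete labelled synthetic dataset
#'
#' Runs the whole generator under `cfg$rng_seed`: species tree, per-marker
#' alignments, environmental pool with scaffolds, and hit tables.
#' Byte-identical on re-run with the same configuration.
#'
#' @param cfg a [sim_config()]
#' @return object of class `simulated_dataset`
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  set.seed(cfg$rng_seed)
  st <- simulate_species_tree(cfg)
  biased <- biased_tip_set(st, cfg)
  alignments <- lapply(cfg$markers, function(m) {
    evolve_alignment(st$tree, cfg, biased)
  })
  names(alignments) <- cfg$markers
  meta <- emit_metagenome(cfg, st, alignments)
  hits <- emit_hit_tables(cfg, meta$truth)
  structure(list(config = cfg, tree = st$tree, categories = st$categories,
                 organisms = st$organisms, alignments = alignments,
                 env_sequences = meta$env_sequences,
                 scaffold_map = meta$scaffold_map, truth = meta$truth,
                 hits = hits),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset> seed %s: %d tree leaves, %d markers, %d environmental sequences (%d planted)\n",
              format(x$config$rng_seed), length(x$tree$tip.label),
              length(x$config$markers), nrow(x$truth), sum(x$truth$planted)))
  invisible(x)
}

#' Per-marker environmental and reference datasets of a simulation
#'
#' Packages one marker's environmental pool (rows renamed to GOS sequence
#' ids) and the reference set (reference + mitochondrial + outgroup taxa)
#' as [ortholog_dataset()]s ready for [run_screen()].
#'
#' @param sim a [simulate_dataset()] result
#' @param marker marker name
#' @param env_ids optional subset of environmental sequence ids
#' @return list(env, reference)
#' @export
marker_datasets <- function(sim, marker, env_ids = NULL) {
  stopifnot(marker %in% sim$config$markers)
  tr <- sim$truth[sim$truth$marker == marker, , drop = FALSE]
  if (!is.null(env_ids)) tr <- tr[tr$seqid %in% env_ids, , drop = FALSE]
  aln <- sim$alignments[[marker]]
  env_aln <- aln[tr$organism, , drop = FALSE]
  rownames(env_aln) <- tr$seqid
  env <- ortholog_dataset(
    marker = marker,
    members = data.frame(id = tr$seqid, category = "ENVIRONMENTAL",
                         stringsAsFactors = FALSE),
    alignment = env_aln
  )
  ref_ids <- names(sim$categories)[category_kind(sim$categories) != "ENVIRONMENTAL"]
  reference <- ortholog_dataset(
    marker = marker,
    members = data.frame(id = ref_ids,
                         category = unname(sim$categories[ref_ids]),
                         stringsAsFactors = FALSE),
    alignment = aln[ref_ids, , drop = FALSE]
  )
  list(env = env, reference = reference)
}
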