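test_that("generation is fully deterministic under the seed", {
  a <- simulate_dataset(sim_config(rng_seed = 9, env_pool_size = 60L))
  b <- simulate_dataset(sim_config(rng_seed = 9, env_pool_size = 60L))
  expect_identical(write_newick(a$tree), write_newick(b$tree))
  expect_identical(a$alignments, b$alignments)
  expect_identical(a$env_sequences, b$env_sequences)
  expect_identical(a$hits, b$hits)
  c <- simulate_dataset(sim_config(rng_seed = 10, env_pool_size = 60L))
  expect_false(identical(write_newick(a$tree), write_newick(c$tree)))
})

test_that("the species tree realises the designed clade structure", {
  cfg <- sim_config(rng_seed = 61, env_pool_size = 150L)
  set.seed(61)
  st <- simulate_species_tree(cfg)
  expect_true(ape::is.rooted(st$tree))
  expect_true(ape::is.binary(st$tree))
  for (o in names(cfg$order_sizes)) {
    tips <- c(names(st$categories)[st$categories == reference_category(o)],
              st$organisms$id[st$organisms$order == o])
    expect_true(is_monophyletic(st$tree, tips), info = o)
  }
  mito <- names(st$categories)[st$categories == "MITOCHONDRIAL"]
  planted <- st$organisms$id[st$organisms$order == "PLANTED"]
  expect_true(is_monophyletic(st$tree, mito))
  expect_true(is_monophyletic(st$tree, planted))
  # the Rickettsiales + mitochondria + planted group excludes all other orders
  rick <- c(names(st$categories)[st$categories == reference_category("Rickettsiales")],
            st$organisms$id[st$organisms$order == "Rickettsiales"])
  grp <- clade_tip_sets(st$tree)[[mrca_node(st$tree, c(mito, rick, planted))]]
  expect_setequal(grp, c(mito, rick, planted))
  # planted is sister to the mitochondrial clade under the default attachment
  mp <- clade_tip_sets(st$tree)[[mrca_node(st$tree, c(mito, planted))]]
  expect_setequal(mp, c(mito, planted))
})

test_that("planted_clade_size 0 removes the planted clade", {
  cfg <- sim_config(rng_seed = 62, env_pool_size = 50L,
                    planted_clade_size = 0L)
  sim <- simulate_dataset(cfg)
  expect_false(any(sim$organisms$order == "PLANTED"))
  expect_false(any(sim$truth$planted))
})

test_that("zero rate keeps sequences identical to the root", {
  cfg <- sim_config(rng_seed = 63, env_pool_size = 20L,
                    substitution_rate = 0)
  set.seed(63)
  st <- simulate_species_tree(cfg)
  aln <- evolve_alignment(st$tree, cfg)
  expect_equal(length(unique(apply(aln, 1, paste, collapse = ""))), 1L)
})

test_that("pairwise identity matches the substitution model's closed form", {
  # two leaves at distance d under the F81-style process: expected match
  # probability 1 - b(1 - exp(-d/b)) with b = 1 - sum(pi^2); cross-checked
  # against the transition matrix exponential
  cfg <- sim_config(rng_seed = 64, seq_length = 10000L)
  pi0 <- cfg$aa_freqs
  b <- 1 - sum(pi0^2)
  for (d in c(0.2, 0.8)) {
    tr <- parse_newick(sprintf("(X:%f,Y:%f);", d / 2, d / 2))
    set.seed(64)
    aln <- evolve_alignment(tr, cfg)
    p_obs <- mean(aln["X", ] != aln["Y", ])
    # matrix-exponential oracle for the F81 rate matrix
    beta <- 1 / b
    Q <- beta * (matrix(pi0, 20, 20, byrow = TRUE) - diag(20))
    P <- as.matrix(Matrix::expm(Q * d))
    p_theory <- 1 - sum(pi0 * diag(P))
    expect_equal(p_theory, b * (1 - exp(-beta * d)), tolerance = 1e-10)
    se <- sqrt(p_theory * (1 - p_theory) / cfg$seq_length)
    expect_lt(abs(p_obs - p_theory), 3 * se)
  }
})

test_that("environmental pool composition follows the order profile", {
  cfg <- sim_config(rng_seed = 65)
  sim <- simulate_dataset(cfg)
  non_planted <- sim$truth[!sim$truth$planted, ]
  expect_equal(nrow(non_planted), cfg$env_pool_size)
  for (o in names(cfg$env_order_profile)) {
    p <- cfg$env_order_profile[[o]]
    n <- sum(non_planted$order == o)
    sd3 <- 3 * sqrt(cfg$env_pool_size * p * (1 - p))
    # organisms carry 1-3 genes, so counts are clumped; allow the clump
    # factor on top of the multinomial band
    expect_lt(abs(n - cfg$env_pool_size * p), 2 * sd3 + 3)
  }
  # every sequence sits on exactly one scaffold
  expect_equal(sort(sim$scaffold_map$seqid), sort(sim$truth$seqid))
  expect_equal(anyDuplicated(sim$scaffold_map$seqid), 0L)
  # scaffolds carry 1-3 genes of distinct markers
  per <- table(sim$scaffold_map$scaffold_id)
  expect_true(all(per >= 1 & per <= 3))
  expect_equal(anyDuplicated(sim$scaffold_map[c("scaffold_id", "marker")]), 0L)
})

test_that("a degenerate order profile puts every sequence in that order", {
  cfg <- sim_config(rng_seed = 66, env_pool_size = 40L,
                    env_order_profile = c(SAR11 = 1),
                    planted_clade_size = 0L)
  sim <- simulate_dataset(cfg)
  expect_true(all(sim$truth$order == "SAR11"))
})

test_that("emitted hit tables drive the filters to exact truth recovery", {
  cfg <- sim_config(rng_seed = 67, env_pool_size = 150L,
                    hit_noise = list(evalue_jitter = 0, overlap_jitter = 0,
                                     decoy_rate = 0.1))
  sim <- simulate_dataset(cfg)
  fc <- filter_config()
  for (m in cfg$markers) {
    truth <- sim$hits$truth_ids[[m]]
    decoys <- sim$hits$decoy_ids[[m]]
    cand <- retrieve_env_candidates(sim$hits$env_hits[[m]], fc)
    expect_setequal(cand, c(truth, decoys))  # boundary records excluded
    kept <- reciprocal_og_filter(sim$hits$recip_hits[[m]], paste0("OG_", m), fc)
    expect_setequal(kept, truth)             # decoys rejected
    # boundary records present and rejected in every emission
    expect_true(all(sim$hits$boundary_ids[[m]] %in%
                      c(sim$hits$env_hits[[m]]$subject,
                        sim$hits$recip_hits[[m]]$query)))
    expect_false(any(sim$hits$boundary_ids[[m]] %in% c(cand, kept)))
  }
})

test_that("stationary composition is homogeneous when bias is off", {
  gaps <- sapply(c(71, 72, 73), function(seed) {
    cfg <- sim_config(rng_seed = seed, env_pool_size = 0L,
                      planted_clade_size = 0L, bias_strength = 0)
    set.seed(seed)
    st <- simulate_species_tree(cfg)
    aln <- evolve_alignment(st$tree, cfg, biased_tip_set(st, cfg))
    f <- vapply(rownames(aln), function(id) {
      at_gc_frequencies(paste(aln[id, ], collapse = ""))["f_AT"]
    }, numeric(1))
    biased <- rownames(aln) %in% biased_tip_set(st, cfg)
    mean(f[biased]) - mean(f[!biased])
  })
  # group means indistinguishable within 3 SE of the per-taxon spread
  expect_lt(abs(mean(gaps)), 3 * 0.02)
})
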