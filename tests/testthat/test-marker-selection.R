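test_that("AT/GC frequencies on the canonical extremes", {
  expect_equal(at_gc_frequencies("FYMINK"), c(f_AT = 1, f_GC = 0))
  expect_equal(at_gc_frequencies("GARP"), c(f_AT = 0, f_GC = 1))
  expect_equal(at_gc_frequencies("FGFG"), c(f_AT = 0.5, f_GC = 0.5))
  # gaps and ambiguity excluded from the denominator
  expect_equal(at_gc_frequencies("F-X?Y"), c(f_AT = 1, f_GC = 0))
  expect_error(at_gc_frequencies("--X"), "empty")
})

test_that("composition statistics are invariant under sequence shuffling", {
  set.seed(10)
  s <- paste(sample(c("F", "G", "L", "K", "P", "S"), 200, TRUE), collapse = "")
  shuffled <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(at_gc_frequencies(s), at_gc_frequencies(shuffled))
})

test_that("composition spread matches a brute-force pairwise scan", {
  expect_equal(composition_spread(c(x = "FYMINK", y = "GARP"))$spread_AT, 1)
  expect_equal(composition_spread(c(x = "LLLL", y = "LLLL"))$spread_AT, 0)
  set.seed(11)
  seqs <- setNames(replicate(10, paste(sample(c(AT_RESIDUES, GC_RESIDUES,
                                                "L", "S"), 80, TRUE),
                                       collapse = "")),
                   paste0("t", 1:10))
  cs <- composition_spread(seqs)
  f <- vapply(seqs, function(s) at_gc_frequencies(s)["f_AT"], numeric(1))
  brute <- max(vapply(seq_along(f), function(i) {
    max(abs(f[i] - f))
  }, numeric(1)))
  expect_equal(cs$spread_AT, brute)
})

test_that("coherence requires dual monophyly", {
  # coherent marker tree: intact mitochondrial clade inside the
  # alphaproteobacterial clade, outgroup outside
  good <- parse_newick(paste0("((OUT_1:1,OUT_2:1):1,((REF_S1:1,REF_S2:1):1,",
                              "((REF_R1:1,REF_R2:1):1,",
                              "(MITO_1:1,MITO_2:1):1):1):1):0;"))
  fx <- screen_fixture()
  v <- coherence_test(good, fx$categories[good$tip.label], "COX1")
  expect_true(v$mito_monophyletic)
  expect_true(v$alpha_monophyletic)
  expect_true(v$pass)
  # an environmental leaf nested inside the mitochondrial clade breaks
  # mitochondrial monophyly (the screen fixture plants one there)
  v_in <- coherence_test(fx$tree, fx$categories)
  expect_false(v_in$mito_monophyletic)
  # nest a mitochondrial leaf inside the SAR11 clade: mito monophyly breaks
  bad <- parse_newick(paste0("((OUT_1:1,OUT_2:1):1,((REF_S1:1,MITO_2:1):1,",
                             "((REF_R1:1,REF_R2:1):1,MITO_1:1):1):1):0;"))
  cats <- fx$categories[bad$tip.label]
  v2 <- coherence_test(bad, cats)
  expect_false(v2$mito_monophyletic)
  expect_false(v2$pass)
  # single mitochondrial leaf is trivially monophyletic
  single <- ape::drop.tip(bad, "MITO_2")
  v3 <- coherence_test(single, cats[single$tip.label])
  expect_true(v3$mito_monophyletic)
})

test_that("coherence agrees with the enumeration oracle on random trees", {
  set.seed(12)
  for (i in 1:40) {
    n_mito <- sample(2:4, 1)
    n_ref <- sample(3:6, 1)
    labs <- c(paste0("M", seq_len(n_mito)), paste0("R", seq_len(n_ref)),
              "O1", "O2")
    tr <- ape::rtree(length(labs), rooted = FALSE, tip.label = sample(labs))
    cats <- setNames(rep("OUTGROUP", length(labs)), labs)
    cats[startsWith(labs, "M")] <- "MITOCHONDRIAL"
    cats[startsWith(labs, "R")] <- reference_category("SAR11")
    v <- coherence_test(tr, cats)
    mito <- labs[startsWith(labs, "M")]
    alpha <- labs[!startsWith(labs, "O")]
    expect_equal(v$mito_monophyletic, oracle_is_mono_unrooted(tr, mito))
    expect_equal(v$alpha_monophyletic, oracle_is_mono_unrooted(tr, alpha))
  }
})

test_that("marker shortlisting is deterministic by name", {
  verdicts <- data.frame(
    marker_name = c("NAD7", "COX1", "RPS2", "COB", "ATP6"),
    pass = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(select_markers(verdicts), c("ATP6", "COB", "COX1", "NAD7"))
  expect_equal(select_markers(verdicts, 2), c("ATP6", "COB"))
  expect_equal(select_markers(verdicts, 10), c("ATP6", "COB", "COX1", "NAD7"))
  none <- verdicts; none$pass <- FALSE
  expect_length(select_markers(none), 0L)
})

test_that("simulated AT bias raises f_AT of biased lineages monotonically", {
  spreads <- sapply(c(0, 0.3, 0.6), function(s) {
    gaps <- sapply(c(31, 32, 33), function(seed) {
      cfg <- sim_config(rng_seed = seed, env_pool_size = 0L,
                        planted_clade_size = 0L, bias_strength = s,
                        seq_length = 400L)
      set.seed(seed)
      st <- simulate_species_tree(cfg)
      aln <- evolve_alignment(st$tree, cfg, biased_tip_set(st, cfg))
      f <- vapply(rownames(aln), function(id) {
        at_gc_frequencies(paste(aln[id, ], collapse = ""))["f_AT"]
      }, numeric(1))
      biased <- rownames(aln) %in% biased_tip_set(st, cfg)
      mean(f[biased]) - mean(f[!biased])
    })
    mean(gaps)
  })
  expect_lt(abs(spreads[1]), 0.03)       # no bias: groups indistinguishable
  expect_gt(spreads[2], spreads[1])
  expect_gt(spreads[3], spreads[2])
})
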