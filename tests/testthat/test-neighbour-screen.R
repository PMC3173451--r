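test_that("jack-knife sampling is reproducible and matches inclusion theory", {
  expect_error(jackknife_sample(character(0), 5), "empty")
  expect_identical(jackknife_sample("x", 1), "x")
  set.seed(31); a <- jackknife_sample(letters, 50)
  set.seed(31); b <- jackknife_sample(letters, 50)
  expect_identical(a, b)
  # inclusion frequency of one id over replicates matches 1-(1-1/N)^m
  set.seed(32)
  N <- 50; m <- 100; reps <- 4000
  pool <- paste0("s", 1:N)
  inc <- mean(vapply(1:reps, function(i) "s1" %in% jackknife_sample(pool, m),
                     logical(1)))
  p <- 1 - (1 - 1 / N)^m
  expect_lt(abs(inc - p), 3 * sqrt(p * (1 - p) / reps))
})

test_that("un-sampled fraction closed form and Monte Carlo agree", {
  expect_equal(unsampled_fraction(1, 1, 1), 0)
  expect_equal(unsampled_fraction(2, 1, 1), 0.5)
  expect_error(unsampled_fraction(0, 1, 1), "at least 1")
  set.seed(33)
  trials <- 1e5
  for (N in c(10, 100, 1000)) {
    for (m in c(10, 100)) {
      for (r in c(1, 10)) {
        p <- unsampled_fraction(N, m, r)
        # a fixed member's hit count across m*r uniform draws is
        # Binomial(m*r, 1/N); "never drawn" is a zero count
        mc <- mean(stats::rbinom(trials, m * r, 1 / N) == 0)
        se <- sqrt(max(p * (1 - p), 1 / trials) / trials)
        expect_lt(abs(mc - p), 3 * se + 1e-12)
      }
    }
  }
})

test_that("neighbour extraction separates inside, sister and far leaves", {
  fx <- screen_fixture()
  expect_setequal(extract_mito_neighbours(fx$tree, fx$categories,
                                          "INSIDE_PLUS_SISTER"),
                  c("ENV_in", "ENV_sis1", "ENV_sis2"))
  expect_identical(extract_mito_neighbours(fx$tree, fx$categories,
                                           "INSIDE_ONLY"), "ENV_in")
  expect_error(extract_mito_neighbours(ape::unroot(fx$tree), fx$categories),
               "rooted")
  no_mito <- ape::drop.tip(fx$tree, c("MITO_1", "MITO_2"))
  expect_error(extract_mito_neighbours(no_mito,
                                       fx$categories[no_mito$tip.label]),
               "mitochondrial")
})

test_that("polytomous parents flag the union of sibling clades", {
  tr <- parse_newick(paste0("((OUT_1:1):1,(MITO_1:1,(ENV_a:1):1,",
                            "(ENV_b:1,REF_R1:1):1):1):0;"))
  tr <- ape::collapse.singles(tr)
  cats <- c(OUT_1 = "OUTGROUP", MITO_1 = "MITOCHONDRIAL",
            ENV_a = "ENVIRONMENTAL", ENV_b = "ENVIRONMENTAL",
            REF_R1 = reference_category("Rickettsiales"))
  got <- extract_mito_neighbours(tr, cats, "INSIDE_PLUS_SISTER")
  expect_setequal(got, c("ENV_a", "ENV_b"))
})

test_that("a planted fixed-tree backend flags exactly its neighbour", {
  fx <- screen_fixture()
  env_ids <- c("ENV_in", "ENV_sis1", "ENV_sis2", "ENV_far")
  aln <- matrix("A", length(fx$tree$tip.label), 10,
                dimnames = list(fx$tree$tip.label, NULL))
  env <- ortholog_dataset("COX1",
                          data.frame(id = env_ids, category = "ENVIRONMENTAL"),
                          alignment = aln[env_ids, , drop = FALSE])
  ref_ids <- setdiff(fx$tree$tip.label, env_ids)
  ref <- ortholog_dataset("COX1",
                          data.frame(id = ref_ids,
                                     category = unname(fx$categories[ref_ids])),
                          alignment = aln[ref_ids, , drop = FALSE])
  fixed_backend <- function(aln) {
    ape::unroot(ape::keep.tip(fx$tree, rownames(aln)))
  }
  res <- run_screen(env, ref, screen_config(sample_size = 10, replicates = 1,
                                            rng_seed = 1,
                                            backend = fixed_backend))
  expect_true(all(res$flagged %in% c("ENV_in", "ENV_sis1", "ENV_sis2")))
  expect_true("ENV_in" %in% res$flagged ||
                res$counts$times_sampled[res$counts$id == "ENV_in"] == 0)
  # flag counts never exceed sampling counts
  expect_true(all(res$counts$times_flagged <= res$counts$times_sampled))
})

test_that("screen results are reproducible under a fixed seed", {
  sim <- simulate_dataset(sim_config(rng_seed = 5, env_pool_size = 120L))
  md <- marker_datasets(sim, "COX1")
  cfg <- screen_config(sample_size = 40, replicates = 5, rng_seed = 99)
  r1 <- run_screen(md$env, md$reference, cfg)
  r2 <- run_screen(md$env, md$reference, cfg)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$flagged, r2$flagged)
  expect_true(all(r1$counts$times_flagged <= r1$counts$times_sampled))
})

test_that("a pool without mitochondrial relatives flags nothing", {
  for (seed in c(41, 42, 43)) {
    sim <- simulate_dataset(sim_config(rng_seed = seed, env_pool_size = 150L,
                                       planted_clade_size = 0L))
    md <- marker_datasets(sim, "COX1")
    res <- run_screen(md$env, md$reference,
                      screen_config(sample_size = 50, replicates = 5,
                                    rng_seed = seed))
    # profile has ~0.2% Rickettsiales; anything flagged must be from there
    rick <- sim$truth$seqid[sim$truth$order == "Rickettsiales"]
    expect_true(all(res$flagged %in% rick))
  }
})

test_that("scaffold concatenation keeps multi-gene scaffolds and conserves residues", {
  smap <- data.frame(
    scaffold_id = c("S1", "S1", "S2", "S3", "S3", "S3"),
    marker = c("COX1", "COX2", "COX1", "COX1", "COX2", "COB"),
    seqid = c("g1", "g2", "g3", "g4", "g5", "g6"),
    stringsAsFactors = FALSE)
  mk_aln <- function(ids, width, letter) {
    matrix(letter, length(ids), width, dimnames = list(ids, NULL))
  }
  alns <- list(COX1 = mk_aln(c("g1", "g3", "g4", "REF1"), 4, "A"),
               COX2 = mk_aln(c("g2", "g5", "REF1"), 3, "C"),
               COB = mk_aln(c("g6", "REF1"), 2, "D"))
  out <- scaffold_concat(c("g1", "g3", "g4"), smap, alns, "REF1")
  # S2 has one gene: dropped; S1 two genes, S3 three genes: kept
  expect_setequal(out$scaffolds, c("S1", "S3"))
  expect_equal(ncol(out$alignment), 9)
  expect_equal(out$partitions$marker, c("COX1", "COX2", "COB"))
  expect_equal(out$partitions$start, c(1L, 5L, 8L))
  expect_equal(out$partitions$end, c(4L, 7L, 9L))
  expect_equal(paste(out$alignment["S1", ], collapse = ""), "AAAACCC--")
  expect_equal(paste(out$alignment["S3", ], collapse = ""), "AAAACCCDD")
  expect_equal(paste(out$alignment["REF1", ], collapse = ""), "AAAACCCDD")
  # flagged id missing from the map errors
  expect_error(scaffold_concat("zzz", smap, alns), "absent")
  # same marker twice on one scaffold is a paralogy flag
  bad <- rbind(smap, data.frame(scaffold_id = "S1", marker = "COX1",
                                seqid = "g9"))
  expect_error(scaffold_concat("g1", bad,
                               within(alns, COX1 <- rbind(COX1, g9 = rep("A", 4)))),
               "paralogy")
})
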