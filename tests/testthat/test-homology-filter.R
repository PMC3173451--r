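cfg <- filter_config()

test_that("all three thresholds are strict at their boundaries", {
  # E-value exactly 1e-10 and overlap exactly 0.5 both fail retrieval
  env <- rbind(hit_row("SEED", "e1", 1e-10, 200, 0.9),
               hit_row("SEED", "e2", 1e-30, 200, 0.5),
               hit_row("SEED", "e3", 1e-9, 200, 0.9),
               hit_row("SEED", "e4", 1e-20, 200, 0.51))
  expect_identical(retrieve_env_candidates(env, cfg), "e4")
  # reciprocal overlap exactly 0.7 fails
  rec <- hit_row("e4", "ref", 1e-30, 200, 0.70, og = "OG_A")
  expect_identical(reciprocal_og_filter(rec, "OG_A", cfg), character(0))
  rec2 <- hit_row("e4", "ref", 1e-30, 200, 0.71, og = "OG_A")
  expect_identical(reciprocal_og_filter(rec2, "OG_A", cfg), "e4")
})

test_that("seed ortholog assignment picks the best qualifying hit", {
  hits <- rbind(hit_row("s1", "a", 1e-9, 500, 0.9, og = "OG_X"),   # fails E
                hit_row("s1", "b", 1e-11, 180, 0.6, og = "OG_Y"),
                hit_row("s1", "c", 1e-11, 210, 0.6, og = "OG_Z"),
                hit_row("s2", "d", 1e-5, 100, 0.9, og = "OG_W"))
  out <- assign_seed_orthologs(hits, cfg)
  expect_equal(out$og[out$seed == "s1"], "OG_Z")  # bitscore 210 > 180
  expect_true(is.na(out$og[out$seed == "s2"]))    # unassigned, not an error
})

test_that("reciprocal filter rejects cross-group top hits", {
  rec <- rbind(hit_row("q1", "par", 1e-60, 300, 0.85, og = "OG_PAR"),
               hit_row("q1", "ok", 1e-20, 140, 0.80, og = "OG_A"),
               hit_row("q2", "ok", 1e-30, 260, 0.80, og = "OG_A"))
  expect_identical(reciprocal_og_filter(rec, "OG_A", cfg), "q2")
})

test_that("per-species dedup keeps the best-scoring member", {
  members <- data.frame(
    id = c("m1", "m2", "m3", "m3"),
    species = c("sp1", "sp1", "sp2", "sp2"),
    bitscore = c(150, 120, 90, 90), stringsAsFactors = FALSE)
  out <- dedup_per_species(members)
  expect_setequal(out$id, c("m1", "m3"))
  # all species distinct: identity
  distinct <- data.frame(id = c("a", "b"), species = c("x", "y"),
                         bitscore = c(1, 2), stringsAsFactors = FALSE)
  expect_equal(dedup_per_species(distinct), distinct)
})

test_that("dataset gate is strictly greater than 500", {
  expect_false(dataset_gate(500, cfg))
  expect_true(dataset_gate(501, cfg))
  expect_false(dataset_gate(0, cfg))
})

test_that("filters never invent members and are idempotent", {
  set.seed(88)
  env <- do.call(rbind, lapply(1:50, function(i) {
    hit_row("SEED", paste0("e", i), 10^-runif(1, 5, 40), 200, runif(1))
  }))
  cand <- retrieve_env_candidates(env, cfg)
  expect_true(all(cand %in% env$subject))
  env2 <- env[env$subject %in% cand, ]
  expect_identical(retrieve_env_candidates(env2, cfg), cand)
  rec <- do.call(rbind, lapply(cand, function(id) {
    hit_row(id, "ref", 10^-runif(1, 5, 40), 200, runif(1),
            og = sample(c("OG_A", "OG_B"), 1))
  }))
  kept <- reciprocal_og_filter(rec, "OG_A", cfg)
  expect_true(all(kept %in% cand))
  expect_identical(reciprocal_og_filter(rec[rec$query %in% kept, ], "OG_A", cfg),
                   kept)
})

test_that("column masking drops gap-rich columns and reports the map", {
  aln <- as_alignment_matrix(c(a = "AC-T", b = "AC-T", c = "A--T", d = "ACGT"))
  out <- mask_columns(aln, 0.5)
  expect_equal(out$kept, c(1L, 2L, 4L))   # col 3 has 3/4 gaps
  expect_equal(ncol(out$alignment), 3L)
  # one gap in 4 rows at threshold 0.5 is kept (fraction 0.25)
  out2 <- mask_columns(aln, 0.0)
  expect_equal(out2$kept, c(1L, 4L))      # only fully ungapped columns
  gapless <- as_alignment_matrix(c(a = "ACGT", b = "ACGT"))
  expect_equal(mask_columns(gapless, 0)$kept, 1:4)
  allgap <- as_alignment_matrix(c(a = "--", b = "--"))
  expect_error(mask_columns(allgap, 0.5), "gap threshold")
})

test_that("hit tables round-trip through TSV", {
  tmp <- tempfile(fileext = ".tsv")
  h <- rbind(hit_row("q", "s", 1e-12, 200, 0.8, "OG_A", "sp"),
             hit_row("q2", "s2", 1e-30, 100, 0.6, "OG_B", "sp2"))
  write_hit_table(h, tmp)
  back <- read_hit_table(tmp)
  expect_equal(back$evalue, h$evalue)
  expect_equal(back$subject_og, h$subject_og)
})
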