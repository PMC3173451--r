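# Stage orchestration: simulate -> filter -> select-markers -> prune ->
# screen -> abundance, each stage reading the previous stage's files from
# `out_dir` and writing seeded, provenance-stamped reports. The numbered
# drivers under analysis/ are thin wrappers over run_stage().

PIPELINE_STAGES <- c("simulate", "filter", "select-markers", "prune",
                     "screen", "abundance")

#' Configuration of the full pipeline
#'
#' @param sim a [sim_config()]
#' @param filter a [filter_config()]
#' @param prune a [prune_config()]
#' @param screen a [screen_config()]
#' @param abundance an [abundance_config()]
#' @param enforce_gate drop markers failing the dataset-size gate
#'   (default FALSE: at synthetic pool sizes the gate is reported, not
#'   enforced; the 500-sequence threshold assumes survey-scale pools of
#'   many hundreds per marker)
#' @export
pipeline_config <- function(sim = sim_config(), filter = filter_config(),
                            prune = prune_config(), screen = screen_config(),
                            abundance = abundance_config(),
                            enforce_gate = FALSE) {
  structure(list(sim = sim, filter = filter, prune = prune, screen = screen,
                 abundance = abundance, enforce_gate = enforce_gate),
            class = "pipeline_config")
}

config_checksum <- function(config) {
  txt <- paste(deparse(config[!vapply(config, is.function, logical(1L))]),
               collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)) %% .Machine$integer.max)
}

write_report <- function(df, path, seed, config) {
  con <- file(path, "w")
  writeLines(c(sprintf("# seed: %s", format(seed)),
               sprintf("# config: %s", config_checksum(unclass(config)))), con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  close(con)
  invisible(path)
}

read_report <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

require_input <- function(path) {
  if (!file.exists(path)) {
    stop(structure(class = c("ms_missing_input", "error", "condition"),
                   list(message = sprintf("missing input: %s", path),
                        call = NULL)))
  }
  path
}

#' Run one pipeline stage (or all of them)
#'
#' @param name one of simulate, filter, select-markers, prune, screen,
#'   abundance, or all
#' @param config a [pipeline_config()]
#' @param out_dir directory for all stage inputs/outputs
#' @param seed integer seed; recorded in every report header and used for
#'   every source of randomness (stage-specific offsets keep the stages
#'   independent, so `all` is exactly the composition of the stages)
#' @return invisibly, a named list of the files written
#' @export
run_stage <- function(name = c(PIPELINE_STAGES, "all"),
                      config = pipeline_config(), out_dir = "results/pipeline",
                      seed = 1L) {
  name <- match.arg(name)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (name == "all") {
    out <- lapply(PIPELINE_STAGES, run_stage, config = config,
                  out_dir = out_dir, seed = seed)
    return(invisible(setNames(do.call(c, out), NULL)))
  }
  switch(name,
         "simulate" = stage_simulate(config, out_dir, seed),
         "filter" = stage_filter(config, out_dir, seed),
         "select-markers" = stage_select_markers(config, out_dir, seed),
         "prune" = stage_prune(config, out_dir, seed),
         "screen" = stage_screen(config, out_dir, seed),
         "abundance" = stage_abundance(config, out_dir, seed))
}

pth <- function(out_dir, ...) file.path(out_dir, paste0(...))

stage_simulate <- function(config, out_dir, seed) {
  cfg <- config$sim
  cfg$rng_seed <- seed
  sim <- simulate_dataset(cfg)
  files <- character(0)
  write_newick(sim$tree, pth(out_dir, "true_tree.nwk"))
  write_report(data.frame(label = names(sim$categories),
                          category = unname(sim$categories)),
               pth(out_dir, "categories.tsv"), seed, cfg)
  write_report(sim$organisms, pth(out_dir, "organisms.tsv"), seed, cfg)
  write_report(sim$truth, pth(out_dir, "truth.tsv"), seed, cfg)
  write_report(sim$scaffold_map, pth(out_dir, "scaffold_map.tsv"), seed, cfg)
  write_fasta_aln(sim$env_sequences, pth(out_dir, "env_pool.fasta"))
  for (m in cfg$markers) {
    write_fasta_aln(sim$alignments[[m]], pth(out_dir, "aln_", m, ".fasta"))
    write_hit_table(sim$hits$env_hits[[m]], pth(out_dir, "hits_env_", m, ".tsv"))
    write_hit_table(sim$hits$recip_hits[[m]], pth(out_dir, "hits_recip_", m, ".tsv"))
  }
  write_hit_table(sim$hits$seed_hits, pth(out_dir, "hits_seed.tsv"))
  invisible(list.files(out_dir, full.names = TRUE))
}

stage_filter <- function(config, out_dir, seed) {
  fc <- config$filter
  seed_hits <- read_hit_table(require_input(pth(out_dir, "hits_seed.tsv")))
  assignments <- assign_seed_orthologs(seed_hits, fc)
  markers <- sub("^SEED_", "", assignments$seed)
  report <- list()
  for (i in seq_along(markers)) {
    m <- markers[i]
    env_hits <- read_hit_table(require_input(pth(out_dir, "hits_env_", m, ".tsv")))
    recip <- read_hit_table(require_input(pth(out_dir, "hits_recip_", m, ".tsv")))
    candidates <- retrieve_env_candidates(env_hits, fc)
    retained <- reciprocal_og_filter(recip, assignments$og[i], fc)
    retained <- intersect(retained, candidates)
    writeLines(retained, pth(out_dir, "retained_", m, ".txt"))
    report[[i]] <- data.frame(marker = m, og = assignments$og[i],
                              n_candidates = length(candidates),
                              n_retained = length(retained),
                              gate_pass = dataset_gate(length(candidates), fc),
                              stringsAsFactors = FALSE)
  }
  write_report(do.call(rbind, report), pth(out_dir, "filter_report.tsv"),
               seed, fc)
  invisible(pth(out_dir, "filter_report.tsv"))
}

load_marker_data <- function(config, out_dir, m) {
  aln <- read_fasta_aln(require_input(pth(out_dir, "aln_", m, ".fasta")))
  cats_df <- read_report(require_input(pth(out_dir, "categories.tsv")))
  categories <- setNames(cats_df$category, cats_df$label)
  truth <- read_report(require_input(pth(out_dir, "truth.tsv")))
  retained_file <- pth(out_dir, "retained_", m, ".txt")
  retained <- if (file.exists(retained_file)) readLines(retained_file) else NULL
  tr <- truth[truth$marker == m, , drop = FALSE]
  if (!is.null(retained)) tr <- tr[tr$seqid %in% retained, , drop = FALSE]
  env_aln <- aln[tr$organism, , drop = FALSE]
  rownames(env_aln) <- tr$seqid
  ref_ids <- names(categories)[category_kind(categories) != "ENVIRONMENTAL"]
  ref_ids <- intersect(rownames(aln), ref_ids)
  list(
    env = ortholog_dataset(m, data.frame(id = tr$seqid,
                                         category = "ENVIRONMENTAL",
                                         stringsAsFactors = FALSE),
                           alignment = env_aln),
    reference = ortholog_dataset(m, data.frame(id = ref_ids,
                                               category = unname(categories[ref_ids]),
                                               stringsAsFactors = FALSE),
                                 alignment = aln[ref_ids, , drop = FALSE]),
    categories = categories, truth = truth
  )
}

pipeline_markers <- function(config, out_dir) {
  rep_file <- require_input(pth(out_dir, "filter_report.tsv"))
  fr <- read_report(rep_file)
  if (config$enforce_gate) fr <- fr[fr$gate_pass, , drop = FALSE]
  fr$marker[fr$n_retained > 0L]
}

stage_select_markers <- function(config, out_dir, seed) {
  markers <- pipeline_markers(config, out_dir)
  rows <- list()
  for (m in markers) {
    d <- load_marker_data(config, out_dir, m)
    ref_aln <- d$reference$alignment
    tree <- neighbor_joining(pairwise_distance(ref_aln, "poisson"))
    v <- coherence_test(tree, d$categories, m)
    comp <- composition_spread(ref_aln)
    rows[[m]] <- cbind(v, spread_AT = comp$spread_AT,
                       spread_GC = comp$spread_GC,
                       composition_flagged = comp$flagged)
  }
  verdicts <- do.call(rbind, rows)
  write_report(verdicts, pth(out_dir, "marker_report.tsv"), seed, config$filter)
  writeLines(select_markers(verdicts), pth(out_dir, "selected_markers.txt"))
  invisible(pth(out_dir, "marker_report.tsv"))
}

selected_markers_file <- function(config, out_dir) {
  readLines(require_input(pth(out_dir, "selected_markers.txt")))
}

stage_prune <- function(config, out_dir, seed) {
  markers <- selected_markers_file(config, out_dir)
  rows <- list()
  for (m in markers) {
    d <- load_marker_data(config, out_dir, m)
    aln <- rbind(d$reference$alignment, d$env$alignment)
    tree <- neighbor_joining(pairwise_distance(aln, "poisson"))
    k <- min(config$prune$k, length(tree$tip.label))
    pc <- prune_config(k = k, must_keep = d$reference$members$id,
                       rooted = config$prune$rooted)
    sel <- greedy_pd_select(tree, pc)
    writeLines(sel$selection, pth(out_dir, "pruned_", m, ".txt"))
    rows[[m]] <- data.frame(marker = m, k = k,
                            pool = nrow(d$env$members),
                            pd = sel$pd[length(sel$pd)],
                            total_bl = total_branch_length(tree))
  }
  write_report(do.call(rbind, rows), pth(out_dir, "prune_report.tsv"),
               seed, config$prune)
  invisible(pth(out_dir, "prune_report.tsv"))
}

stage_screen <- function(config, out_dir, seed) {
  markers <- selected_markers_file(config, out_dir)
  flagged_all <- character(0)
  alignments <- list()
  ref_ids <- NULL
  rows <- list()
  for (i in seq_along(markers)) {
    m <- markers[i]
    d <- load_marker_data(config, out_dir, m)
    cfg <- config$screen
    cfg$rng_seed <- seed + 1000L * i
    res <- run_screen(d$env, d$reference, cfg)
    write_report(res$counts, pth(out_dir, "screen_", m, ".tsv"), seed, cfg)
    flagged_all <- c(flagged_all, res$flagged)
    aln <- rbind(d$env$alignment, d$reference$alignment)
    alignments[[m]] <- aln
    ref_ids <- d$reference$members$id
    rows[[m]] <- data.frame(marker = m, pool = nrow(res$counts),
                            flagged = length(res$flagged),
                            unsampled_fraction = res$unsampled_fraction_estimate,
                            failed_replicates = length(res$failures))
  }
  writeLines(sort(flagged_all), pth(out_dir, "flagged_ids.txt"))
  smap <- read_report(require_input(pth(out_dir, "scaffold_map.tsv")))
  cc <- scaffold_concat(flagged_all, smap, alignments, ref_ids)
  if (nrow(cc$alignment) > 0L) {
    write_fasta_aln(cc$alignment, pth(out_dir, "concat.fasta"))
    write_report(cc$partitions, pth(out_dir, "concat_partitions.tsv"),
                 seed, config$screen)
  }
  write_report(do.call(rbind, rows), pth(out_dir, "screen_report.tsv"),
               seed, config$screen)
  invisible(pth(out_dir, "screen_report.tsv"))
}

stage_abundance <- function(config, out_dir, seed) {
  markers <- selected_markers_file(config, out_dir)
  m <- if ("RPS2" %in% markers) "RPS2" else markers[1L]
  d <- load_marker_data(config, out_dir, m)
  aln <- rbind(d$reference$alignment, d$env$alignment)
  tree <- neighbor_joining(pairwise_distance(aln, "poisson"))
  outgroup <- d$reference$members$id[
    category_kind(d$reference$members$category) == "OUTGROUP"]
  tree <- root_with_outgroup(tree, outgroup)
  assign <- assign_to_reference_clades(tree, d$categories |>
    (\(x) c(x, setNames(rep("ENVIRONMENTAL", nrow(d$env$members)),
                        d$env$members$id)))())
  fr <- clade_fractions(assign)
  write_report(data.frame(id = assign$id, order = assign$order),
               pth(out_dir, "assignments_", m, ".tsv"), seed, config$abundance)
  # rare-clade arithmetic from the screen's flagged set on the first marker
  flagged <- readLines(require_input(pth(out_dir, "flagged_ids.txt")))
  m1 <- if ("COX1" %in% markers) "COX1" else markers[1L]
  pool1 <- read_report(require_input(pth(out_dir, "screen_", m1, ".tsv")))
  n_clade <- sum(flagged %in% pool1$id)
  pct <- rare_clade_fraction(n_clade, nrow(pool1))
  report <- data.frame(
    quantity = c(paste0("fraction_", names(fr)),
                 paste0("rare_clade_pct_", m1), "overall_abundance_pct"),
    value = c(unname(fr), pct, overall_abundance(pct, config$abundance)))
  write_report(report, pth(out_dir, "abundance_report.tsv"), seed,
               config$abundance)
  invisible(pth(out_dir, "abundance_report.tsv"))
}
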