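# Shared fixtures: tiny hand-built annotations and read tables, plus a
# cache so expensive seeded simulations are built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# four transcripts, three genes; gene gA has two isoforms
tiny_ann <- function(with_seq = FALSE) {
  tab <- data.table::data.table(
    transcript_id = c("tA.1", "tA.2", "tB.1", "tC.1"),
    gene_id = c("gA", "gA", "gB", "gC"),
    length = c(600L, 450L, 900L, 300L),
    cds_start = c(100L, 50L, 150L, 90L),
    cds_end = c(400L, 350L, 750L, 240L))
  seqs <- NULL
  if (with_seq) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(99)
    s <- vapply(tab$length, function(n)
      paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""),
      character(1L))
    seqs <- Biostrings::DNAStringSet(stats::setNames(s, tab$transcript_id))
  }
  annotation(tab, seqs)
}

# n single-isoform genes with identical geometry
ann_many <- function(n, n_codons = 100L, leader = 30L, utr3 = 70L) {
  len <- leader + 3L * n_codons + utr3
  annotation(data.table::data.table(
    transcript_id = sprintf("t%04d", seq_len(n)),
    gene_id = sprintf("g%04d", seq_len(n)),
    length = len, cds_start = leader, cds_end = leader + 3L * n_codons))
}

# raw alignment rows (the TSV dialect as an in-memory table)
raw_reads <- function(read_id, transcript_id, pos, length = 31L) {
  data.table::data.table(read_id = read_id, transcript_id = transcript_id,
                         pos = as.integer(pos), length = as.integer(length))
}

# processed-style read table (as after process_ribo_reads) built by hand
proc_reads <- function(transcript_id, a_site, gene_id = transcript_id,
                       weight = 1, length = 31L, region = "acorf",
                       n_genes = 1L, n_map = 1L) {
  n <- max(lengths(list(transcript_id, a_site)))
  data.table::data.table(
    read_id = sprintf("r%06d", seq_len(n)),
    transcript_id = transcript_id, gene_id = gene_id,
    pos = as.integer(a_site) - 17L, a_site = as.integer(a_site),
    length = as.integer(length), region = region,
    n_genes = as.integer(n_genes), n_map = as.integer(n_map),
    weight = weight)
}

# reads placed uniformly at random over given transcripts (processed-style)
uniform_reads <- function(ann, per_tx, read_len = 31L, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  tx <- ann$transcripts
  idx <- rep(seq_len(nrow(tx)), each = per_tx)
  pos <- floor(stats::runif(length(idx)) * (tx$length[idx] - read_len + 1L))
  data.table::data.table(
    read_id = sprintf("u%07d", seq_along(idx)),
    transcript_id = tx$transcript_id[idx],
    gene_id = tx$gene_id[idx],
    pos = as.integer(pos), a_site = as.integer(pos) + 17L,
    length = read_len, region = NA_character_,
    n_genes = 1L, n_map = 1L, weight = 1)
}

# seeded count-level simulation shared between DE tests and acceptance
de_sim_10k <- function() cached("de_sim_10k", {
  sc <- simulate_counts(n_genes = 10000L, replicates = 2L, frac_de = 0.05,
                        effect = 4, seed = 42L)
  lfc1 <- log_fold_changes(sc$counts_t[, 1], sc$counts_0[, 1])
  lfc2 <- log_fold_changes(sc$counts_t[, 2], sc$counts_0[, 2])
  z1 <- binned_z_scores(lfc1, pmin(sc$counts_t[, 1], sc$counts_0[, 1]))$z
  z2 <- binned_z_scores(lfc2, pmin(sc$counts_t[, 2], sc$counts_0[, 2]))$z
  sel <- select_threshold(z1, z2, target_fdr = 0.1)
  list(sc = sc, z1 = z1, z2 = z2, sel = sel)
})

# seeded queuing simulation shared between profile tests and acceptance
queue_sim <- function() cached("queue_sim", {
  cfg <- sim_config(n_genes = 500L, seed = 3L, libraries = "ribo",
                    time_points = 0L, replicates = 1L,
                    mean_reads_ribo = 120, term_stall = 20, queue_mean = 2,
                    frac_mrna_de = 0, frac_ribo_de = 0, frac_te_de = 0,
                    frac_uorf = 0, frac_readthrough = 0, frac_pause = 0)
  sim <- simulate_experiment(cfg)
  rd <- process_ribo_reads(sim$reads[[1L]], sim$annotation)
  list(sim = sim, reads = rd,
       metagene = metagene_profile(rd, sim$annotation, "stop"))
})

# seeded 31-nt periodicity simulation shared with acceptance
periodicity_sim <- function() cached("periodicity_sim", {
  cfg <- sim_config(n_genes = 100L, seed = 9L, libraries = "ribo",
                    time_points = 0L, replicates = 1L,
                    mean_reads_ribo = 600,
                    footprint_lengths = 29:35,
                    footprint_probs = c(0, 0, 1, 0, 0, 0, 0),
                    frac_multimap = 0, frac_isoform = 0,
                    frac_mrna_de = 0, frac_ribo_de = 0, frac_te_de = 0,
                    frac_uorf = 0, frac_readthrough = 0, frac_pause = 0)
  sim <- simulate_experiment(cfg)
  rd <- process_ribo_reads(sim$reads[[1L]], sim$annotation)
  list(sim = sim, reads = rd,
       screen = periodicity_screen(rd, sim$annotation))
})

# seeded uORF-induction simulation (deep coverage) shared with acceptance
uorf_sim <- function() cached("uorf_sim", {
  cfg <- sim_config(n_genes = 40L, seed = 11L, libraries = "ribo",
                    mean_reads_ribo = 3000, expr_sdlog = 0.5,
                    frac_uorf = 0.15, frac_mrna_de = 0, frac_ribo_de = 0,
                    frac_te_de = 0, frac_readthrough = 0, frac_pause = 0)
  sim <- simulate_experiment(cfg)
  ann <- sim$annotation
  smp <- sim$samples
  tps <- sort(unique(smp$time_min))
  recs <- lapply(sort(unique(smp$replicate)), function(rp) {
    by_time <- lapply(tps, function(tm) {
      sid <- smp[library_type == "ribo" & replicate == rp &
                   time_min == tm, sample_id]
      process_ribo_reads(sim$reads[[sid]], ann)
    })
    names(by_time) <- paste0("t", tps)
    center_shift_records(by_time, ann, time = paste0("t", max(tps)),
                         reference_time = paste0("t", min(tps)))
  })
  list(sim = sim, screen = center_shift_screen(recs, top_n = nrow(sim$truth)))
})

# seeded condition-specific pause simulation shared with acceptance
pause_sim <- function() cached("pause_sim", {
  cfg <- sim_config(n_genes = 30L, seed = 13L, libraries = "ribo",
                    time_points = c(0L, 60L), replicates = 2L,
                    mean_reads_ribo = 4000, expr_sdlog = 0.5,
                    frac_pause = 0.5, pause_strength = 50,
                    frac_mrna_de = 0, frac_ribo_de = 0, frac_te_de = 0,
                    frac_uorf = 0, frac_readthrough = 0)
  sim <- simulate_experiment(cfg)
  ann <- sim$annotation
  rd <- lapply(sim$samples$sample_id, function(sid)
    process_ribo_reads(sim$reads[[sid]], ann))
  names(rd) <- sim$samples$sample_id
  pair_r <- function(a, b)
    similarity_screen(rd[[a]], rd[[b]], ann)[excluded == FALSE, r]
  within <- c(pair_r("ribo_t000_r1", "ribo_t000_r2"),
              pair_r("ribo_t060_r1", "ribo_t060_r2"))
  cross <- c(pair_r("ribo_t000_r1", "ribo_t060_r1"),
             pair_r("ribo_t000_r2", "ribo_t060_r2"))
  list(sim = sim, reads = rd, within = within, cross = cross)
})
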