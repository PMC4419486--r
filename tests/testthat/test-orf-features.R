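test_that("center of density matches exhaustive prefix-sum enumeration", {
  brute <- function(counts) {
    n <- length(counts)
    for (c in seq_len(n)) {
      up <- if (c == 1L) 0 else sum(counts[1:(c - 1L)])
      if (up > sum(counts[c:n])) return(c)
    }
    n
  }
  set.seed(17)
  for (i in 1:1000) {
    counts <- rpois(sample(1:30, 1L), sample(c(0.5, 2, 10), 1L))
    if (!length(counts)) next
    expect_identical(center_of_density(counts), brute(counts))
  }
})

test_that("center of density worked examples enumerate correctly", {
  expect_equal(center_of_density(c(10, 0)), 2L)    # all reads first coordinate
  expect_equal(center_of_density(c(1, 100)), 2L)   # upstream never exceeds: last
  # downstream includes the coordinate itself: 6 upstream > 4 at-or-after
  expect_equal(center_of_density(rep(1, 10)), 7L)
  expect_error(center_of_density(numeric()), "empty")
})

test_that("compressed profiles keep exactly the commonly covered coordinates", {
  m <- rbind(t0 = c(1, 2, 0, 3, 1),
             t20 = c(2, 0, 1, 1, 1),
             t40 = c(1, 5, 2, 2, 0),
             t60 = c(3, 1, 1, 4, 2))
  cp <- compressed_profile(m)
  expect_equal(cp$coords, c(0L, 3L))   # columns 2, 3, 5 miss a time point
  expect_equal(unname(cp$counts[, 1]), c(1, 2, 1, 3))
  none <- compressed_profile(rbind(c(1, 0), c(0, 1)))
  expect_equal(length(none$coords), 0L)
  expect_equal(ncol(none$counts), 0L)
})

test_that("readthrough screen applies the strict >20 UTR3 read threshold", {
  ann <- tiny_ann(with_seq = TRUE)
  mk <- function(n_utr3) {
    list(s1 = data.table::rbindlist(list(
      proc_reads(rep("tB.1", 100L),
                 a_site = rep(200L + 3L * (0:24), 4L), gene_id = "gB",
                 region = "acorf"),
      proc_reads(rep("tB.1", n_utr3), a_site = rep(760L, n_utr3),
                 gene_id = "gB", region = "utr3"))))
  }
  expect_equal(nrow(screen_readthrough(mk(20L), ann)), 0L)
  out <- screen_readthrough(mk(21L), ann)
  expect_equal(unique(out$transcript_id), "tB.1")
  expect_equal(unique(out$utr3_reads), 21)
})

test_that("readthrough efficiency is the dORF/acORF density ratio", {
  # hand-built annotation whose sequence places one in-frame dORF stop
  leader <- strrep("A", 30)
  acorf <- paste0("ATG", strrep("GCT", 96), "TGA")  # 98 codons, 294 nt
  dorf <- paste0(strrep("GCT", 10), "TAA")
  utr3 <- paste0(dorf, strrep("A", 30))
  s <- paste0(leader, acorf, utr3)
  ann <- annotation(
    data.table::data.table(transcript_id = "t1", gene_id = "g1",
                           length = nchar(s), cds_start = 30L,
                           cds_end = 30L + 294L),
    Biostrings::DNAStringSet(c(t1 = s)))
  d <- downstream_orf(ann, "t1")
  expect_equal(d$start, 324L)
  expect_equal(d$end, 354L)      # 10 codons, stop excluded
  expect_true(d$has_stop)
  # acORF density 10/nt, dORF density 1/nt -> efficiency 0.1
  rd <- list(s1 = data.table::rbindlist(list(
    proc_reads(rep("t1", 2940L),
               a_site = rep(30L + (0:293), 10L), gene_id = "g1",
               region = "acorf"),
    proc_reads(rep("t1", 30L), a_site = rep(324L + (0:29), 1L),
               gene_id = "g1", region = "utr3"))))
  out <- screen_readthrough(rd, ann)
  expect_equal(out$efficiency, 0.1)
  expect_equal(out$stop_codon, "TGA")
  expect_equal(out$plus4_nt, "G")
})

test_that("transcripts without a downstream in-frame stop are flagged", {
  leader <- strrep("A", 30)
  acorf <- paste0("ATG", strrep("GCT", 96), "TGA")
  s <- paste0(leader, acorf, strrep("GC", 15))   # no in-frame stop in UTR3
  ann <- annotation(
    data.table::data.table(transcript_id = "t1", gene_id = "g1",
                           length = nchar(s), cds_start = 30L,
                           cds_end = 324L),
    Biostrings::DNAStringSet(c(t1 = s)))
  d <- downstream_orf(ann, "t1")
  expect_false(d$has_stop)
  expect_equal(d$end, nchar(s))
})

test_that("planted readthrough is recovered near its simulated fraction", {
  cfg <- sim_config(n_genes = 30L, seed = 5L, libraries = "ribo",
                    time_points = c(0L, 60L), replicates = 2L,
                    mean_reads_ribo = 2000, expr_sdlog = 0.5,
                    frac_readthrough = 0.2, frac_mrna_de = 0,
                    frac_ribo_de = 0, frac_te_de = 0, frac_uorf = 0,
                    frac_pause = 0)
  sim <- simulate_experiment(cfg)
  rd <- lapply(sim$reads, process_ribo_reads, ann = sim$annotation)
  out <- screen_readthrough(rd, sim$annotation)
  rt_genes <- sim$truth[class == "readthrough", gene_id]
  expect_true(all(unique(out$gene_id) %in% rt_genes))
  expect_gt(length(unique(out$gene_id)), 0L)
  eff <- out[, .(eff = mean(efficiency)), by = transcript_id]
  expect_equal(mean(eff$eff), 0.05, tolerance = 0.2)
  expect_true(all(unique(out$stop_codon) == "TGA"))
  expect_true(all(unique(out$plus4_nt) == "C"))
})

test_that("zero planted readthrough yields no candidates", {
  rd <- periodicity_sim()$reads    # no readthrough class in that config
  out <- screen_readthrough(list(s1 = rd), periodicity_sim()$sim$annotation)
  expect_equal(nrow(out), 0L)
})

test_that("leader effect compares fold-change distributions by rank sum", {
  set.seed(23)
  lfc <- rnorm(2200)
  grp <- rep(c(TRUE, FALSE), c(200, 2000))
  same <- leader_effect(lfc, sample(grp))
  expect_gt(same$p_value, 0.01)
  shifted <- lfc
  shifted[grp] <- shifted[grp] - 1     # planted repression of uORF genes
  eff <- leader_effect(shifted, grp)
  expect_lt(eff$p_value, 0.01)
  expect_equal(unname(eff$n), c(200L, 2000L))
  expect_error(leader_effect(lfc, rep(FALSE, 2200)), "at least 2")
})

test_that("center-shift records apply the strict >64 alignment filter", {
  ann <- ann_many(2L, n_codons = 100L)
  cs <- ann$transcripts$cds_start[1L]
  mk_time <- function(n1, n2, seed) {
    set.seed(seed)
    # ten fixed coordinates guarantee a non-empty compressed profile
    a1 <- cs + c(0:9, sample.int(280L, n1 - 10L, TRUE) + 9L)
    a2 <- cs + c(0:9, sample.int(280L, n2 - 10L, TRUE) + 9L)
    data.table::rbindlist(list(
      proc_reads(rep("t0001", n1), a_site = a1, gene_id = "g0001"),
      proc_reads(rep("t0002", n2), a_site = a2, gene_id = "g0002")))
  }
  by_time <- list(t0 = mk_time(16L, 17L, 1), t60 = mk_time(16L, 17L, 2),
                  t40 = mk_time(16L, 17L, 3), t20 = mk_time(16L, 17L, 4))
  rec <- center_shift_records(by_time, ann, time = "t60",
                              reference_time = "t0")
  expect_false("t0001" %in% rec$transcript_id)   # 64 alignments: excluded
  expect_true("t0002" %in% rec$transcript_id)    # 68: included
})

test_that("planted uORF induction ranks in the top candidates", {
  u <- uorf_sim()
  uorf_tx <- u$sim$truth[class == "uorf", transcript_id]
  top <- utils::head(u$screen$transcript_id, 2L * length(uorf_tx))
  expect_gte(mean(uorf_tx %in% top), 0.8)
  expect_lt(u$screen[transcript_id %in% uorf_tx, median(mean_shift)], 0)
})

test_that("unchanged profiles have zero center shift", {
  ann <- ann_many(1L, n_codons = 100L)
  cs <- ann$transcripts$cds_start[1L]
  set.seed(31)
  fixed <- proc_reads(rep("t0001", 80L),
                      a_site = cs + sample.int(290L, 80L, TRUE),
                      gene_id = "g0001")
  by_time <- list(t0 = fixed, t60 = data.table::copy(fixed))
  rec <- center_shift_records(by_time, ann, time = "t60",
                              reference_time = "t0")
  expect_equal(rec$shift, 0)
})

test_that("subcodon fractions classify 31-nt 5' ends over the first 50 codons", {
  ann <- ann_many(1L, n_codons = 100L)
  cs <- ann$transcripts$cds_start[1L]
  rd <- proc_reads(rep("t0001", 60L), a_site = 0L, gene_id = "g0001")
  rd[, pos := cs + 3L * (0:59)]        # all 5' ends on subcodon position 1
  s <- subcodon_distribution(rd, ann, "t0001")
  expect_equal(unname(s$fractions), c(1, 0, 0))
  expect_equal(sum(s$fractions), 1)
  expect_false(s$excluded)             # 50 distinct covered coordinates
  expect_equal(s$n_covered, 50L)       # positions 150..177 beyond codon 50 drop
})

test_that("the <50 covered coordinates exclusion is strict", {
  ann <- ann_many(1L, n_codons = 100L)
  cs <- ann$transcripts$cds_start[1L]
  mk <- function(k) {
    rd <- proc_reads(rep("t0001", k), a_site = 0L, gene_id = "g0001")
    rd[, pos := cs + seq_len(k) - 1L]
    rd
  }
  expect_true(subcodon_distribution(mk(49L), ann, "t0001")$excluded)
  expect_false(subcodon_distribution(mk(50L), ann, "t0001")$excluded)
})

test_that("simulated frame profile is recovered within binomial error", {
  p <- periodicity_sim()
  pooled <- p$screen$pooled
  expect_equal(sum(pooled), 1)
  expect_equal(unname(pooled["f3"]), 0.20, tolerance = 0.1)
  expect_equal(unname(pooled["f1"]), 0.60, tolerance = 0.05)
  # distortion flags stay off at the baseline profile
  rec <- p$screen$records[excluded == FALSE]
  expect_lt(mean(rec$distorted), 0.05)
})
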