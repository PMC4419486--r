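test_that("log fold changes follow the pseudocounted log2 ratio", {
  expect_equal(log_fold_changes(200, 100, 0), 1)
  expect_equal(log_fold_changes(150, 150, 1), 0)
  expect_equal(log_fold_changes(0, 0, 1), 0)
})

test_that("binned Z-scores standardize each expression bin", {
  set.seed(1)
  lfc <- rnorm(900)
  fl <- rlnorm(900)
  z <- binned_z_scores(lfc, fl, bin_size = 300L)
  expect_equal(sort(unique(z$bin)), 1:3)
  for (b in 1:3) {
    expect_equal(mean(z[bin == b, z]), 0, tolerance = 1e-12)
    expect_equal(sd(z[bin == b, z]), 1, tolerance = 1e-12)
  }
  # a gene at its bin mean scores 0; mean + 2 sd scores 2
  lfc2 <- c(1, 2, 3)        # mean 2, sd 1
  z2 <- binned_z_scores(c(lfc2, 4), c(1, 1, 1, 1), bin_size = 4L)
  expect_equal(z2$z[2], (2 - 2.5) / sd(c(1, 2, 3, 4)))
  simple <- binned_z_scores(c(0, 1, 2), rep(1, 3), bin_size = 3L)
  expect_equal(simple$z[2], 0)            # equals bin mean
  expect_equal(simple$z[3], 1)            # one sd above
})

test_that("a short trailing bin merges into the previous one", {
  z <- binned_z_scores(rnorm(250), runif(250), bin_size = 300L)
  expect_equal(unique(z$bin), 1L)          # 250 genes: one bin
  z2 <- binned_z_scores(rnorm(330), runif(330), bin_size = 300L,
                        min_last_bin = 50L)
  expect_equal(max(z2$bin), 1L)            # trailing 30 merged
  z3 <- binned_z_scores(rnorm(360), runif(360), bin_size = 300L,
                        min_last_bin = 50L)
  expect_equal(max(z3$bin), 2L)            # trailing 60 kept
  expect_error(binned_z_scores(1, 1), "fewer than 2")
})

test_that("discordant-sign FDR matches hand enumeration", {
  z1 <- c(3, -3, 3, 0.1)
  z2 <- c(3, -3, -3, 0.2)
  e <- estimate_fdr(z1, z2, 2.5)
  expect_equal(e$n_increased, 1L)
  expect_equal(e$n_decreased, 1L)
  expect_equal(e$fp, 1L)
  expect_equal(e$fdr, 0.5)
  # all concordant: zero FDR at any threshold
  expect_equal(estimate_fdr(c(3, -2), c(2.5, -3), 1)$fdr, 0)
  # threshold above every mean |Z|: nothing called, FDR defined 0
  expect_equal(estimate_fdr(z1, z2, 10)$fdr, 0)
})

test_that("DE counts are non-increasing in the threshold", {
  d <- de_sim_10k()
  curve <- d$sel$curve
  expect_true(all(diff(curve$n_increased) >= 0))  # curve ordered by falling T
  expect_true(all(diff(curve$n_decreased) >= 0))
  expect_true(all(diff(curve$fp) >= 0))
})

test_that("threshold selection returns the smallest qualifying plateau T", {
  z <- c(1, 2, 3)
  sel <- select_threshold(z, z, target_fdr = 0.1)
  expect_equal(sel$threshold, 1)          # FDR 0 everywhere: minimal grid T
  sel2 <- select_threshold(c(3, -3, 2), c(3, 3, -2), target_fdr = 1)
  expect_equal(sel2$threshold, min((abs(c(3, -3, 2)) + abs(c(3, 3, -2))) / 2))
})

test_that("selected threshold controls the discordant estimate near the target", {
  d <- de_sim_10k()
  expect_true(d$sel$attained)
  expect_lte(d$sel$fdr, 0.1)
  mz <- (d$z1 + d$z2) / 2
  called <- abs(mz) > d$sel$threshold
  realized <- sum(called & !d$sc$truth$de) / max(1L, sum(called))
  expect_lt(abs(realized - d$sel$fdr), 0.05)
})

test_that("null-only data yields agreeing, near-zero estimate and realized FDP", {
  scn <- simulate_counts(n_genes = 5000L, frac_de = 0, seed = 3L)
  l1 <- log_fold_changes(scn$counts_t[, 1], scn$counts_0[, 1])
  l2 <- log_fold_changes(scn$counts_t[, 2], scn$counts_0[, 2])
  z1 <- binned_z_scores(l1, pmin(scn$counts_t[, 1], scn$counts_0[, 1]))$z
  z2 <- binned_z_scores(l2, pmin(scn$counts_t[, 2], scn$counts_0[, 2]))$z
  sel <- suppressWarnings(select_threshold(z1, z2, 0.1))
  called <- abs((z1 + z2) / 2) > sel$threshold
  realized <- if (sum(called)) sum(called) / sum(called) else 0
  expect_lt(abs(sel$fdr - realized), 0.05)
  expect_lte(sum(called), 5000 * 0.002)   # essentially nothing called
})

test_that("planted 4-fold changes at adequate depth are recovered with high sensitivity", {
  d <- de_sim_10k()
  mz <- (d$z1 + d$z2) / 2
  called <- abs(mz) > d$sel$threshold
  floor4 <- pmin(d$sc$counts_t[, 1], d$sc$counts_0[, 1],
                 d$sc$counts_t[, 2], d$sc$counts_0[, 2])
  deep <- d$sc$truth$de & floor4 >= 64
  expect_gte(sum(called & deep) / sum(deep), 0.9)
})

# --- pause-peak robustness -------------------------------------------------

robust_fixture <- function() cached("robust_fixture", {
  n <- 60L
  ann <- ann_many(n, n_codons = 100L)
  cs <- ann$transcripts$cds_start[1L]
  set.seed(21)
  gene_reads <- function(gi, count, sample_id, codons = NULL) {
    if (count == 0L) return(NULL)
    cod <- if (is.null(codons)) sample.int(98L, count, TRUE) - 1L
           else rep_len(codons, count)
    proc_reads(sprintf("t%04d", gi), a_site = cs + 3L * cod + 1L,
               gene_id = sprintf("g%04d", gi))
  }
  build_sample <- function(sample_id, t60) {
    rows <- lapply(seq_len(n), function(gi) {
      cnt <- rnbinom(1L, size = 30, mu = 100)  # replicate noise per sample
      extra <- NULL
      if (t60 && gi == 1L)            # DE only through one pause codon
        extra <- gene_reads(gi, 300L, sample_id, codons = 50L)
      if (t60 && gi == 2L)            # uniform 4-fold elevation
        cnt <- 4L * cnt
      if (gi == 3L)                   # <3 covered codons
        return(data.table::rbindlist(list(
          gene_reads(gi, if (t60) 200L else 10L, sample_id,
                     codons = c(10L, 20L)))))
      data.table::rbindlist(c(list(gene_reads(gi, cnt, sample_id)),
                              if (!is.null(extra)) list(extra)))
    })
    dt <- data.table::rbindlist(rows)
    dt[, read_id := sprintf("%s_%07d", sample_id, seq_len(.N))]
    dt
  }
  reads <- list(r1_t0 = build_sample("r1_t0", FALSE),
                r2_t0 = build_sample("r2_t0", FALSE),
                r1_t60 = build_sample("r1_t60", TRUE),
                r2_t60 = build_sample("r2_t60", TRUE))
  meta <- data.table::data.table(
    sample_id = names(reads), replicate = c(1L, 2L, 1L, 2L),
    time_min = c(0L, 0L, 60L, 60L))
  counts <- data.table::rbindlist(lapply(names(reads), function(sid) {
    m <- meta[sample_id == sid]
    count_gene_regions(reads[[sid]], ann, "ribo", sid, m$replicate,
                       m$time_min)
  }))
  counts <- normalize_counts(counts)
  calls <- call_de(counts, "ribo", time = 60L, reference_time = 0L)
  flagged <- robust_de_filter(reads, counts[0L], ann, calls, meta)
  list(ann = ann, calls = calls, flagged = flagged)
})

test_that("DE driven by a single pause codon is flagged non-robust", {
  f <- robust_fixture()
  expect_equal(f$calls[gene_id == "g0001", label], "increased")
  expect_false(f$flagged[gene_id == "g0001", robust])
})

test_that("uniform fold elevation survives peak exclusion", {
  f <- robust_fixture()
  expect_equal(f$calls[gene_id == "g0002", label], "increased")
  expect_true(f$flagged[gene_id == "g0002", robust])
})

test_that("genes with fewer covered codons than peaks lose all signal", {
  f <- robust_fixture()
  expect_equal(f$calls[gene_id == "g0003", label], "increased")
  expect_false(f$flagged[gene_id == "g0003", robust])
})
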