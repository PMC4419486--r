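# Seeded synthetic ribo-seq/mRNA-seq generator with planted ground truth.
# Emulates a 2-replicate x 4-time-point stress time course: planted
# fold changes on ribo occupancy and TE, uORF induction in 5' leaders,
# termination queuing with a hard exclusion footprint, site-specific
# pauses, leaky stop codons, triplet-phased 5' ends and multimapping.

SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

#' Simulation configuration
#'
#' Defaults encode the emulated study design: two biological replicates
#' at 0/20/40/60 min of stress, ribo-seq footprints of 29--35 nt with
#' triplet-phased 5' ends (third-subcodon fraction 0.20), planted 4-fold
#' ribosome-occupancy and TE changes on small gene subsets, uORF
#' induction (leader x10, acORF x0.5 at 60 min), 5% leaky readthrough on
#' UGA-C stop contexts, strong single-codon pauses under stress, and
#' ribosome queuing at termination under control conditions that decays
#' with stress. Planted effects ramp linearly with time (full effect at
#' the last time point).
#'
#' @param n_genes Number of genes.
#' @param seed Seed controlling every random draw.
#' @param time_points Time points in minutes (first is the reference).
#' @param replicates Number of biological replicates.
#' @param libraries Library types to emit.
#' @param mean_reads_ribo,mean_reads_mrna Expected reads per gene at
#'   baseline (before expression weights and depth factors).
#' @param expr_sdlog Log-normal sd of per-gene expression weights.
#' @param nb_size Negative-binomial size (per-gene overdispersion of
#'   replicate counts).
#' @param depth_range Per-sample library depth factors are drawn
#'   uniformly from this range.
#' @param frac_mrna_de,mrna_de_fc Fraction/effect of genes whose mRNA
#'   (and, proportionally, ribo) level changes; TE stays flat.
#' @param frac_ribo_de,ribo_de_fc Fraction/effect of ribo-occupancy-only
#'   changes (half up, half down).
#' @param frac_te_de,te_de_fc Fraction/effect of TE changes (ribo moves,
#'   mRNA flat).
#' @param frac_uorf,uorf_leader_fc,uorf_acorf_fc uORF-induction genes:
#'   leader footprints multiplied by `uorf_leader_fc` and acORF reads by
#'   `uorf_acorf_fc` at the last time point.
#' @param frac_readthrough,readthrough_frac Readthrough genes (UGA stop,
#'   +4 C, in-frame downstream stop) and the fraction of ribosomes
#'   reading through.
#' @param frac_pause,pause_strength Pause genes: one codon's dwell time
#'   multiplied by `pause_strength` under stress (t > 0).
#' @param queue_mean Mean number of ribosomes queued behind termination
#'   at t = 0 (decays linearly to 0 at the last time point).
#' @param term_stall Stop-codon dwell multiplier at t = 0 (same decay).
#' @param queue_exclusion Hard exclusion distance between stacked
#'   footprint 5' ends (nt).
#' @param footprint_lengths,footprint_probs Footprint length
#'   distribution.
#' @param frame_profile Subcodon frame profile of footprint 5' ends
#'   (fractions at subcodon positions 1, 2, 3).
#' @param base_leader_frac Baseline leader footprint flux relative to the
#'   acORF.
#' @param frac_multimap Fraction of reads given 1--2 decoy gene-level
#'   mappings.
#' @param frac_isoform Fraction of genes with a second (5'-truncated)
#'   transcript isoform; reads in the shared region map to both.
#' @param leader_range,utr3_range,codon_range Length distributions
#'   (uniform integer ranges; codons include start and stop).
#' @param mrna_read_length mRNA-seq read length (nt).
#' @return A list of class `ribo_sim_config`.
#' @export
sim_config <- function(n_genes = 300L, seed = 1L,
                       time_points = c(0L, 20L, 40L, 60L),
                       replicates = 2L,
                       libraries = c("ribo", "mrna"),
                       mean_reads_ribo = 100, mean_reads_mrna = 100,
                       expr_sdlog = 1, nb_size = 20,
                       depth_range = c(0.7, 1.3),
                       frac_mrna_de = 0.05, mrna_de_fc = 4,
                       frac_ribo_de = 0.05, ribo_de_fc = 4,
                       frac_te_de = 0.05, te_de_fc = 4,
                       frac_uorf = 0.05, uorf_leader_fc = 10,
                       uorf_acorf_fc = 0.5,
                       frac_readthrough = 0.05, readthrough_frac = 0.05,
                       frac_pause = 0.05, pause_strength = 50,
                       queue_mean = 1, term_stall = 5,
                       queue_exclusion = 33L,
                       footprint_lengths = 29:35,
                       footprint_probs = c(0.05, 0.15, 0.40, 0.20, 0.10, 0.06, 0.04),
                       frame_profile = c(0.6, 0.2, 0.2),
                       base_leader_frac = 0.02,
                       frac_multimap = 0.05, frac_isoform = 0.05,
                       leader_range = c(60L, 240L),
                       utr3_range = c(60L, 240L),
                       codon_range = c(170L, 400L),
                       mrna_read_length = 50L) {
  cfg <- as.list(environment())
  fr <- c(frac_mrna_de, frac_ribo_de, frac_te_de, frac_uorf,
          frac_readthrough, frac_pause)
  if (any(fr < 0 | fr > 1) || sum(fr) > 1)
    stop("planted-class fractions must lie in [0,1] and sum to at most 1")
  stopifnot(length(footprint_probs) == length(footprint_lengths),
            abs(sum(frame_profile) - 1) < 1e-8,
            mean_reads_ribo > 0, mean_reads_mrna > 0)
  structure(cfg, class = "ribo_sim_config")
}

ramp <- function(t, time_points) {
  tmax <- max(time_points)
  if (tmax == 0) return(ifelse(t == 0, 0, 1))
  t / tmax
}

#' Simulate a transcriptome with planted features
#'
#' Generates transcripts (leader / acORF / 3' UTR), sequences and the
#' ground-truth skeleton. acORFs start with ATG and end in a stop codon;
#' readthrough genes get a UGA stop with a C at +4 and an in-frame
#' downstream stop; uORF genes carry an upstream ORF in the leader.
#' Fully deterministic given `(config, seed)`.
#'
#' @param config A `ribo_sim_config`.
#' @return List with `annotation` (a `ribo_annotation` with sequences)
#'   and `truth` (`data.table`).
#' @export
simulate_transcriptome <- function(config) {
  set.seed(config$seed)
  n <- config$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))
  cls <- rep("none", n)
  pool <- sample(n)
  take <- function(frac) {
    k <- round(frac * n)
    if (k == 0L) return(integer())
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  idx_mrna <- take(config$frac_mrna_de)
  idx_ribo <- take(config$frac_ribo_de)
  idx_te <- take(config$frac_te_de)
  idx_uorf <- take(config$frac_uorf)
  idx_rt <- take(config$frac_readthrough)
  idx_pause <- take(config$frac_pause)
  dir_of <- function(idx) ifelse(seq_along(idx) <= length(idx) / 2, 1, -1)
  cls[idx_mrna] <- paste0("mrna_de_", ifelse(dir_of(idx_mrna) > 0, "up", "down"))
  cls[idx_ribo] <- paste0("ribo_de_", ifelse(dir_of(idx_ribo) > 0, "up", "down"))
  cls[idx_te] <- paste0("te_de_", ifelse(dir_of(idx_te) > 0, "up", "down"))
  cls[idx_uorf] <- "uorf"
  cls[idx_rt] <- "readthrough"
  cls[idx_pause] <- "pause"

  leader_len <- sample(config$leader_range[1L]:config$leader_range[2L], n, TRUE)
  n_codons <- sample(config$codon_range[1L]:config$codon_range[2L], n, TRUE)
  utr3_len <- sample(config$utr3_range[1L]:config$utr3_range[2L], n, TRUE)
  leader_len[idx_uorf] <- pmax(leader_len[idx_uorf], 140L)

  uorf_start <- rep(NA_integer_, n)
  uorf_end <- rep(NA_integer_, n)
  pause_codon <- rep(NA_integer_, n)
  pause_codon[idx_pause] <- vapply(n_codons[idx_pause], function(nc)
    sample(20:(nc - 20L), 1L), integer(1L))
  rt_frac <- rep(0, n)
  rt_frac[idx_rt] <- config$readthrough_frac
  dorf_codons <- rep(NA_integer_, n)

  rand_nt <- function(k) paste(sample(c("A", "C", "G", "T"), k, TRUE),
                               collapse = "")
  seqs <- character(n)
  for (i in seq_len(n)) {
    leader <- rand_nt(leader_len[i])
    if (i %in% idx_uorf) {
      k <- sample(5:15, 1L)
      u_nt <- 3L * (k + 2L)
      us <- sample(20:(leader_len[i] - u_nt), 1L)
      uorf <- paste0("ATG", paste(sample(SENSE_CODONS, k, TRUE), collapse = ""),
                     "TAA")
      substr(leader, us + 1L, us + u_nt) <- uorf
      uorf_start[i] <- us
      uorf_end[i] <- us + u_nt
    }
    stop_codon <- if (i %in% idx_rt) "TGA" else sample(STOP_CODONS, 1L)
    acorf <- paste0("ATG",
                    paste(sample(SENSE_CODONS, n_codons[i] - 2L, TRUE),
                          collapse = ""),
                    stop_codon)
    utr3 <- rand_nt(utr3_len[i])
    if (i %in% idx_rt) {
      d_codons <- sample(10:min(30L, utr3_len[i] %/% 3L - 2L), 1L)
      dorf_codons[i] <- d_codons
      c_first <- sample(grep("^C", SENSE_CODONS, value = TRUE), 1L)
      dorf <- paste0(c_first,
                     paste(sample(SENSE_CODONS, d_codons - 1L, TRUE),
                           collapse = ""), "TAA")
      substr(utr3, 1L, nchar(dorf)) <- dorf
    }
    seqs[i] <- paste0(leader, acorf, utr3)
  }
  tx <- data.table::data.table(
    transcript_id = paste0(gene_id, ".t1"),
    gene_id = gene_id,
    length = leader_len + 3L * n_codons + utr3_len,
    cds_start = leader_len,
    cds_end = leader_len + 3L * n_codons)
  seq_list <- stats::setNames(seqs, tx$transcript_id)

  n_iso <- round(config$frac_isoform * n)
  iso_genes <- if (n_iso > 0) sort(sample(seq_len(n), n_iso)) else integer()
  iso_offset <- 30L
  if (length(iso_genes)) {
    iso <- tx[iso_genes]
    iso[, `:=`(transcript_id = paste0(gene_id, ".t2"),
               length = length - iso_offset,
               cds_start = cds_start - iso_offset,
               cds_end = cds_end - iso_offset)]
    seq_list <- c(seq_list, stats::setNames(
      substring(seqs[iso_genes], iso_offset + 1L), iso$transcript_id))
    tx <- data.table::rbindlist(list(tx, iso))
  }
  ann <- annotation(tx, seq = Biostrings::DNAStringSet(seq_list))

  tps <- setdiff(config$time_points, min(config$time_points))
  truth <- data.table::data.table(
    gene_id = gene_id, class = cls,
    transcript_id = paste0(gene_id, ".t1"),
    n_codons = n_codons,
    uorf_start = uorf_start, uorf_end = uorf_end,
    readthrough_frac = rt_frac,
    dorf_codons = dorf_codons,
    pause_codon = pause_codon,
    pause_strength = ifelse(is.na(pause_codon), NA_real_,
                            config$pause_strength))
  sgn <- function(cl, pref) ifelse(startsWith(cl, paste0(pref, "_up")), 1,
                            ifelse(startsWith(cl, paste0(pref, "_down")), -1, 0))
  for (t in tps) {
    rmp <- ramp(t, config$time_points)
    l_mrna <- sgn(cls, "mrna_de") * log2(config$mrna_de_fc) * rmp
    l_ribo <- l_mrna +
      sgn(cls, "ribo_de") * log2(config$ribo_de_fc) * rmp +
      sgn(cls, "te_de") * log2(config$te_de_fc) * rmp +
      ifelse(cls == "uorf", log2(config$uorf_acorf_fc) * rmp, 0)
    truth[[paste0("lfc_mrna_", t)]] <- l_mrna
    truth[[paste0("lfc_ribo_", t)]] <- l_ribo
    truth[[paste0("lfc_te_", t)]] <- l_ribo - l_mrna
  }
  list(annotation = ann, truth = truth)
}

#' Simulate sequencing libraries
#'
#' Draws per-gene negative-binomial read counts per sample and positions
#' ribo-seq footprints by a per-codon dwell model: baseline 1, planted
#' pauses multiply their codon's dwell under stress, a termination stall
#' inflates the stop codon's dwell and stacks queued footprints upstream
#' with a hard exclusion of `queue_exclusion` nt, readthrough genes
#' extend dwell into the downstream ORF at the planted readthrough
#' fraction, and uORF genes shift flux into the uORF interval while the
#' acORF is depleted. Footprint lengths and 5'-end subcodon frames follow
#' the configured distributions. mRNA-seq reads are uniform over the
#' transcript. A configured fraction of reads receives decoy multimapping
#' records; reads of isoform genes in the shared region map to both
#' isoforms (one gene-level location).
#'
#' @param transcriptome Output of [simulate_transcriptome()].
#' @param config The same `ribo_sim_config`.
#' @return A list of class `ribo_sim`: `annotation`, `truth`, `samples`
#'   (manifest `data.table`), `reads` (named list of raw alignment
#'   tables), `config`.
#' @export
simulate_libraries <- function(transcriptome, config) {
  set.seed(config$seed + 1L)
  ann <- transcriptome$annotation
  truth <- transcriptome$truth
  n <- nrow(truth)
  expr_w <- stats::rlnorm(n, meanlog = 0, sdlog = config$expr_sdlog)
  expr_w <- expr_w / mean(expr_w)
  samples <- data.table::CJ(library_type = config$libraries,
                            time_min = config$time_points,
                            replicate = seq_len(config$replicates),
                            sorted = FALSE)
  samples[, sample_id := sprintf("%s_t%03d_r%d", library_type, time_min,
                                 replicate)]
  samples[, depth_factor := stats::runif(.N, config$depth_range[1L],
                                         config$depth_range[2L])]
  tx <- ann$transcripts
  iso_map <- tx[endsWith(transcript_id, ".t2"),
                .(gene_id, iso_id = transcript_id, iso_len = length)]
  # plain-vector views of the primary transcripts, indexed like truth
  gm <- match(truth$transcript_id, tx$transcript_id)
  g_cds_start <- tx$cds_start[gm]
  g_len <- tx$length[gm]
  g_tx <- truth$transcript_id
  t0 <- min(config$time_points)
  reads <- vector("list", nrow(samples))
  names(reads) <- samples$sample_id
  for (si in seq_len(nrow(samples))) {
    smp <- samples[si]
    lfc_col <- paste0("lfc_", smp$library_type, "_", smp$time_min)
    lfc <- if (smp$time_min == t0) numeric(n) else truth[[lfc_col]]
    if (smp$library_type == "mrna") {
      mu <- config$mean_reads_mrna * expr_w * 2^lfc * smp$depth_factor
      nr <- stats::rnbinom(n, size = config$nb_size, mu = mu)
      rl <- pmin(config$mrna_read_length, g_len)
      gidx <- rep.int(seq_len(n), nr)
      pos <- floor(stats::runif(sum(nr)) * (g_len[gidx] - rl[gidx] + 1L))
      dt <- data.table::data.table(transcript_id = g_tx[gidx],
                                   pos = as.integer(pos),
                                   length = rl[gidx])
    } else {
      dt <- sim_ribo_sample(truth, expr_w, lfc, smp, config, t0,
                            g_cds_start, g_len, g_tx)
    }
    if (nrow(dt) == 0L) { reads[[si]] <- dt; next }
    dt[, read_id := sprintf("%s.%07d", smp$sample_id, seq_len(.N))]
    dt <- add_isoform_mappings(dt, tx, iso_map)
    dt <- add_decoy_mappings(dt, tx, config)
    data.table::setcolorder(dt, c("read_id", "transcript_id", "pos", "length"))
    reads[[si]] <- dt
  }
  structure(list(annotation = ann, truth = truth, samples = samples,
                 reads = reads, config = config),
            class = "ribo_sim")
}

# footprints for one ribo-seq sample, vectorized over genes
sim_ribo_sample <- function(truth, expr_w, lfc, smp, config, t0,
                            g_cds_start, g_len, g_tx) {
  n <- nrow(truth)
  rmp <- ramp(smp$time_min, config$time_points)
  stall <- 1 + (config$term_stall - 1) * (1 - rmp)
  qmean <- config$queue_mean * (1 - rmp)
  is_uorf <- truth$class == "uorf"
  leader_mult <- ifelse(is_uorf, 1 + (config$uorf_leader_fc - 1) * rmp, 1)
  mu_ac <- config$mean_reads_ribo * expr_w * 2^lfc * smp$depth_factor
  mu_ld <- config$mean_reads_ribo * expr_w * config$base_leader_frac *
    leader_mult * smp$depth_factor
  n_ac <- stats::rnbinom(n, size = config$nb_size, mu = mu_ac)
  n_ld <- stats::rnbinom(n, size = config$nb_size, mu = mu_ld)
  pause_on <- smp$time_min > t0
  # per-read gene indices and A-site codons for coding/dORF reads
  gidx <- rep.int(seq_len(n), n_ac)
  codon <- integer(length(gidx))
  at <- 0L
  for (gi in which(n_ac > 0L)) {
    nc <- truth$n_codons[gi]
    dwell <- rep.int(1, nc)
    if (pause_on && !is.na(truth$pause_codon[gi]))
      dwell[truth$pause_codon[gi] + 1L] <- truth$pause_strength[gi]
    dwell[nc] <- stall
    if (truth$readthrough_frac[gi] > 0 && !is.na(truth$dorf_codons[gi]))
      dwell <- c(dwell, rep.int(truth$readthrough_frac[gi],
                                truth$dorf_codons[gi]))
    codon[at + seq_len(n_ac[gi])] <-
      sample.int(length(dwell), n_ac[gi], TRUE, prob = dwell) - 1L
    at <- at + n_ac[gi]
  }
  nr <- length(gidx)
  k <- integer(nr)
  at_stop <- codon == truth$n_codons[gidx] - 1L
  if (qmean > 0 && any(at_stop))
    k[at_stop] <- stats::rgeom(sum(at_stop), prob = 1 / (1 + qmean))
  len <- sample(config$footprint_lengths, nr, TRUE,
                prob = config$footprint_probs)
  off <- a_site_offset(len)
  shift <- 3L * codon - off - config$queue_exclusion * k
  f <- sample(0:2, nr, TRUE, prob = config$frame_profile)
  jit <- ((f - shift %% 3L + 1L) %% 3L) - 1L
  p5 <- g_cds_start[gidx] + shift + jit
  ok <- p5 >= 0L & p5 + len <= g_len[gidx]
  coding <- data.table::data.table(transcript_id = g_tx[gidx[ok]],
                                   pos = p5[ok], length = len[ok])
  # leader footprints (uniform baseline; uORF-confined for uORF genes)
  lidx <- rep.int(seq_len(n), n_ld)
  nl <- length(lidx)
  if (nl) {
    llen <- sample(config$footprint_lengths, nl, TRUE,
                   prob = config$footprint_probs)
    loff <- a_site_offset(llen)
    lu <- is_uorf[lidx] & !is.na(truth$uorf_start[lidx])
    p5l <- integer(nl)
    if (any(lu)) {
      nuc <- (truth$uorf_end[lidx] - truth$uorf_start[lidx]) %/% 3L
      ucod <- floor(stats::runif(nl) * nuc)
      base <- truth$uorf_start[lidx] + 3L * ucod - loff
      fl <- sample(0:2, nl, TRUE, prob = config$frame_profile)
      jl <- ((fl - base %% 3L + 1L) %% 3L) - 1L
      p5l[lu] <- (base + jl)[lu]
    }
    hi <- g_cds_start[lidx] - 19L
    p5l[!lu] <- floor(stats::runif(sum(!lu)) * pmax(hi[!lu], 1L))
    okl <- p5l >= 0L & p5l + llen <= g_len[lidx] &
      p5l + loff < g_cds_start[lidx] & (lu | hi >= 1L)
    leader <- data.table::data.table(transcript_id = g_tx[lidx[okl]],
                                     pos = as.integer(p5l[okl]),
                                     length = llen[okl])
  } else leader <- NULL
  data.table::rbindlist(list(coding, leader), use.names = TRUE)
}

add_isoform_mappings <- function(dt, tx, iso_map) {
  if (nrow(iso_map) == 0L) return(dt)
  gid <- tx[data.table::J(dt$transcript_id), gene_id]
  m <- match(gid, iso_map$gene_id)
  sel <- which(!is.na(m) & dt$pos >= 30L & endsWith(dt$transcript_id, ".t1"))
  sel <- sel[dt$pos[sel] - 30L + dt$length[sel] <= iso_map$iso_len[m[sel]]]
  if (!length(sel)) return(dt)
  extra <- dt[sel]
  extra[, `:=`(transcript_id = iso_map$iso_id[m[sel]], pos = pos - 30L)]
  data.table::rbindlist(list(dt, extra), use.names = TRUE)
}

add_decoy_mappings <- function(dt, tx, config) {
  if (config$frac_multimap <= 0) return(dt)
  ids <- unique(dt$read_id)
  n_mm <- round(config$frac_multimap * length(ids))
  if (n_mm == 0L) return(dt)
  mm_ids <- sample(ids, n_mm)
  n_extra <- sample(1:2, n_mm, TRUE, prob = c(2, 1) / 3)
  first <- dt[match(mm_ids, read_id)]
  src <- first[rep.int(seq_len(n_mm), n_extra)]
  decoy_idx <- sample.int(nrow(tx), nrow(src), TRUE)
  # decoy hits land in the decoy's coding region, mimicking paralogous
  # CDS-to-CDS multimapping rather than uniform scatter
  extra <- data.table::data.table(
    read_id = src$read_id,
    transcript_id = tx$transcript_id[decoy_idx],
    dlen = tx$length[decoy_idx],
    lo = pmax(0L, tx$cds_start[decoy_idx] - 17L),
    hi = tx$cds_end[decoy_idx] - 21L,
    length = src$length,
    src_tx = src$transcript_id)
  extra <- extra[transcript_id != src_tx & dlen >= length & hi > lo]
  extra <- unique(extra, by = c("read_id", "transcript_id"))
  extra[, pos := lo + as.integer(floor(stats::runif(.N) * (hi - lo + 1L)))]
  extra[, pos := pmin(pos, dlen - length)]
  extra[, c("dlen", "src_tx", "lo", "hi") := NULL]
  data.table::rbindlist(list(dt, extra), use.names = TRUE)
}

#' Simulate a full experiment
#'
#' [simulate_transcriptome()] followed by [simulate_libraries()].
#'
#' @param config A `ribo_sim_config`.
#' @return A `ribo_sim` object.
#' @export
simulate_experiment <- function(config = sim_config()) {
  simulate_libraries(simulate_transcriptome(config), config)
}

#' @export
print.ribo_sim <- function(x, ...) {
  cat(sprintf("ribo_sim: %d genes, %d samples, %s reads\n",
              nrow(x$truth), nrow(x$samples),
              format(sum(vapply(x$reads, nrow, integer(1L))), big.mark = ",")))
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Emits the transcript FASTA, annotation TSV, truth TSV, sample
#' manifest, configuration YAML, and per-sample alignments as both the
#' TSV dialect and transcriptome-space SAM.
#'
#' @param sim A `ribo_sim`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_annotation(sim$annotation, file.path(dir, "annotation.tsv"),
                   file.path(dir, "transcripts.fa"))
  data.table::fwrite(sim$truth, file.path(dir, "truth.tsv"), sep = "\t")
  data.table::fwrite(sim$samples, file.path(dir, "manifest.tsv"), sep = "\t")
  cfg <- unclass(sim$config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  for (sid in names(sim$reads)) {
    write_alignments_tsv(sim$reads[[sid]], file.path(dir, paste0(sid, ".tsv")))
    write_sam(sim$reads[[sid]], sim$annotation,
              file.path(dir, paste0(sid, ".sam")))
  }
  invisible(dir)
}

#' Write alignments as transcriptome-space SAM
#'
#' Forward-strand, gap-free records; the first mapping of each read is
#' primary, further mappings carry the secondary flag.
#'
#' @param reads Raw alignment table.
#' @param ann A `ribo_annotation` (for `@SQ` lines and sequences).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(reads, ann, path) {
  tx <- ann$transcripts
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", tx$transcript_id, tx$length))
  dt <- data.table::copy(reads)
  dt[, flag := ifelse(seq_len(.N) == 1L, 0L, 256L), by = read_id]
  seqs <- if (!is.null(ann$seq)) {
    substring(as.character(ann$seq[dt$transcript_id]), dt$pos + 1L,
              dt$pos + dt$length)
  } else rep("*", nrow(dt))
  rec <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                 dt$read_id, dt$flag, dt$transcript_id, dt$pos + 1L,
                 dt$length, seqs)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Gene-level count simulation
#'
#' A light-weight generator of negative-binomial gene counts for two
#' conditions and `replicates` replicates, with a planted fraction of
#' genes changed by `effect`-fold (half up, half down). Used to exercise
#' the binned Z-score caller at scale without read-level simulation.
#'
#' @param n_genes Number of genes.
#' @param replicates Replicates per condition.
#' @param frac_de Fraction of genes with a planted change.
#' @param effect Fold change of planted genes.
#' @param mean_reads Median expected reads per gene (log-normal across
#'   genes, sdlog 1).
#' @param nb_size Negative-binomial size.
#' @param seed Seed.
#' @return List with `counts_t`, `counts_0` (gene x replicate matrices)
#'   and `truth` (`data.table`: `gene_id`, `de`, `direction`, `lfc`).
#' @export
simulate_counts <- function(n_genes = 10000L, replicates = 2L,
                            frac_de = 0.05, effect = 4, mean_reads = 100,
                            nb_size = 20, seed = 1L) {
  set.seed(seed)
  mu <- stats::rlnorm(n_genes, meanlog = log(mean_reads), sdlog = 1)
  n_de <- round(frac_de * n_genes)
  de_idx <- sample.int(n_genes, n_de)
  dir <- rep(0, n_genes)
  dir[de_idx] <- rep(c(1, -1), length.out = n_de)
  lfc <- dir * log2(effect)
  draw <- function(m) matrix(stats::rnbinom(n_genes * replicates,
                                            size = nb_size, mu = m),
                             nrow = n_genes)
  list(counts_0 = draw(mu), counts_t = draw(mu * 2^lfc),
       truth = data.table::data.table(gene_id = sprintf("g%05d", seq_len(n_genes)),
                                      de = dir != 0, direction = dir, lfc = lfc,
                                      mu_0 = mu, mu_t = mu * 2^lfc))
}
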