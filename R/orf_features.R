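# mRNA-specific screens: stop-codon readthrough, 5'-leader effect on
# acORF translation, center-of-density shift, triplet periodicity.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Locate the downstream ORF after the annotated stop
#'
#' The downstream ORF (dORF) runs from the end of the acORF to the next
#' in-frame stop codon in the 3' UTR (stop excluded). If no in-frame stop
#' occurs before the transcript end, the dORF ends at the transcript end
#' and is flagged.
#'
#' @param ann A `ribo_annotation` with sequences.
#' @param transcript_id Transcript id.
#' @return List with `start`, `end` (0-based, half-open), `has_stop`.
#' @export
downstream_orf <- function(ann, transcript_id) {
  r <- tx_row(ann, transcript_id)
  if (!r$has_cds) stop("transcript has no annotated CDS: ", transcript_id)
  s <- transcript_sequence(ann, transcript_id)
  p <- r$cds_end
  while (p + 3L <= r$length) {
    if (substr(s, p + 1L, p + 3L) %in% STOP_CODONS)
      return(list(start = r$cds_end, end = p, has_stop = TRUE))
    p <- p + 3L
  }
  list(start = r$cds_end, end = r$length, has_stop = FALSE)
}

#' Screen for leaky stop-codon readthrough
#'
#' Selects transcripts whose 3' UTR carries a weighted ribo-seq read
#' count strictly greater than `min_utr3_reads` (ambiguous alignments
#' included), locates the downstream ORF, and reports per-sample
#' readthrough efficiency = dORF density / acORF density (alignments per
#' nt of ORF), together with the stop-codon identity and the +4
#' nucleotide for the termination-context table.
#'
#' @param reads_by_sample Named list (sample_id -> processed ribo read
#'   table).
#' @param ann A `ribo_annotation` with sequences.
#' @param min_utr3_reads Strict threshold on pooled weighted 3' UTR reads.
#' @return `data.table` with one row per candidate transcript and sample:
#'   `transcript_id`, `gene_id`, `stop_codon`, `plus4_nt`, `utr3_reads`
#'   (pooled), `sample_id`, `acorf_density`, `dorf_density`, `efficiency`,
#'   `dorf_has_stop`.
#' @export
screen_readthrough <- function(reads_by_sample, ann, min_utr3_reads = 20) {
  pooled <- data.table::rbindlist(
    lapply(reads_by_sample, function(x)
      x[, .(transcript_id, a_site, weight, region)]))
  utr3 <- pooled[region == "utr3", .(utr3_reads = sum(weight)),
                 by = transcript_id]
  data.table::setkey(utr3, transcript_id)
  cand <- utr3[utr3_reads > min_utr3_reads, transcript_id]
  cand <- cand[ann$transcripts[data.table::J(cand), has_cds]]
  if (!length(cand)) return(empty_readthrough())
  rows <- lapply(cand, function(tid) {
    r <- tx_row(ann, tid)
    s <- transcript_sequence(ann, tid)
    d <- downstream_orf(ann, tid)
    acorf_len <- r$cds_end - r$cds_start
    dorf_len <- d$end - d$start
    stop_codon <- substr(s, r$cds_end - 2L, r$cds_end)
    plus4 <- if (r$cds_end < r$length)
      substr(s, r$cds_end + 1L, r$cds_end + 1L) else NA_character_
    per_sample <- data.table::rbindlist(lapply(names(reads_by_sample),
      function(sid) {
        sub <- reads_by_sample[[sid]][transcript_id == tid]
        ac <- sum(sub$weight[sub$a_site >= r$cds_start &
                               sub$a_site < r$cds_end]) / acorf_len
        dd <- if (dorf_len > 0)
          sum(sub$weight[sub$a_site >= d$start & sub$a_site < d$end]) / dorf_len
        else NA_real_
        data.table::data.table(sample_id = sid, acorf_density = ac,
                               dorf_density = dd,
                               efficiency = ifelse(ac > 0, dd / ac, NA_real_))
      }))
    per_sample[, `:=`(transcript_id = tid, gene_id = r$gene_id,
                      stop_codon = stop_codon, plus4_nt = plus4,
                      utr3_reads = utr3[data.table::J(tid), utr3_reads],
                      dorf_has_stop = d$has_stop)]
    per_sample
  })
  out <- data.table::rbindlist(rows)
  data.table::setcolorder(out, c("transcript_id", "gene_id", "stop_codon",
                                 "plus4_nt", "utr3_reads", "sample_id"))
  out[]
}

empty_readthrough <- function() {
  data.table::data.table(transcript_id = character(), gene_id = character(),
                         stop_codon = character(), plus4_nt = character(),
                         utr3_reads = numeric(), sample_id = character(),
                         acorf_density = numeric(), dorf_density = numeric(),
                         efficiency = numeric(), dorf_has_stop = logical())
}

#' Effect of 5'-leader translation on acORF fold changes
#'
#' Splits genes into leader-translated and others by `leader_translated`
#' and compares their acORF fold-change distributions with a two-sample
#' Wilcoxon rank-sum test, also returning the histograms (absolute and
#' relative frequency).
#'
#' @param log_fc Named per-gene log2 fold-change vector (acORF signal).
#' @param leader_translated Logical vector (same order) marking genes
#'   with translated 5' leaders.
#' @param breaks Histogram breaks passed to [graphics::hist()] logic
#'   (computed with [base::cut()]; default 20 equal-width bins).
#' @return List with `test` (the `htest`), `p_value`, `n` (group sizes)
#'   and `histogram` (`data.table`: `bin`, `group`, `count`, `freq`).
#' @export
leader_effect <- function(log_fc, leader_translated, breaks = 20L) {
  stopifnot(length(log_fc) == length(leader_translated))
  if (sum(leader_translated) < 2L || sum(!leader_translated) < 2L)
    stop("each group needs at least 2 genes")
  wt <- stats::wilcox.test(log_fc[leader_translated], log_fc[!leader_translated])
  cuts <- cut(log_fc, breaks = breaks, include.lowest = TRUE)
  h <- data.table::data.table(bin = cuts,
                              group = ifelse(leader_translated,
                                             "leader_translated", "other"))
  h <- h[, .(count = .N), by = .(bin, group)]
  h[, freq := count / sum(count), by = group]
  list(test = wt, p_value = wt$p.value,
       n = c(leader_translated = sum(leader_translated),
             other = sum(!leader_translated)),
       histogram = h[])
}

#' Compress time-course profiles to commonly covered coordinates
#'
#' Retains exactly the transcript coordinates that carry at least one
#' read in every time point, preserving order.
#'
#' @param profiles Numeric matrix, one row per time point, one column per
#'   transcript coordinate.
#' @return List with `coords` (0-based retained coordinates) and
#'   `counts` (matrix restricted to them; may have zero columns).
#' @export
compressed_profile <- function(profiles) {
  stopifnot(is.matrix(profiles))
  keep <- which(apply(profiles >= 1, 2, all))
  list(coords = keep - 1L,
       counts = profiles[, keep, drop = FALSE])
}

#' Center of ribosome density
#'
#' The center is the minimal compressed-profile index at which the
#' cumulative reads strictly upstream exceed the cumulative reads at or
#' downstream of it; if no index qualifies, the last index is returned.
#'
#' @param counts Non-empty numeric vector of compressed-profile counts
#'   for one time point.
#' @return 1-based index into the compressed profile.
#' @export
center_of_density <- function(counts) {
  n <- length(counts)
  if (n == 0L) stop("empty compressed profile")
  up <- c(0, cumsum(counts)[-n])
  down <- sum(counts) - up
  hit <- which(up > down)
  if (length(hit)) hit[1L] else n
}

#' Center-of-density shift records for one sample pair
#'
#' For each annotated coding transcript with strictly more than
#' `min_reads` ribo-seq alignments (summed over all time points), builds
#' nucleotide A-site profiles per time point, compresses them, and
#' records the normalized center shift between the reference and the
#' contrast time point: `(center_t - center_0) / n_covered`, where
#' `n_covered` is the number of compressed coordinates.
#'
#' @param reads_by_time Named list (time point -> processed ribo read
#'   table) for one replicate.
#' @param ann A `ribo_annotation`.
#' @param time,reference_time Names (in `reads_by_time`) of the
#'   contrasted time points.
#' @param min_reads Strict alignment-count threshold.
#' @return `data.table` with `transcript_id`, `total_reads`,
#'   `n_covered`, `center_ref`, `center_t`, `shift`.
#' @export
center_shift_records <- function(reads_by_time, ann, time,
                                 reference_time = names(reads_by_time)[1L],
                                 min_reads = 64) {
  txs <- ann$transcripts[has_cds == TRUE, transcript_id]
  totals <- data.table::rbindlist(lapply(reads_by_time, function(x)
    x[, .(transcript_id)]))[, .N, by = transcript_id]
  data.table::setkey(totals, transcript_id)
  txs <- intersect(txs, totals[N > min_reads, transcript_id])
  rows <- lapply(txs, function(tid) {
    mat <- do.call(rbind, lapply(reads_by_time, function(rd)
      as.numeric(build_profile(rd, ann, tid, "nucleotide", "a_site"))))
    rownames(mat) <- names(reads_by_time)
    cp <- compressed_profile(mat)
    if (ncol(cp$counts) == 0L) return(NULL)
    c0 <- center_of_density(cp$counts[reference_time, ])
    ct <- center_of_density(cp$counts[time, ])
    data.table::data.table(
      transcript_id = tid,
      total_reads = totals[data.table::J(tid), N],
      n_covered = ncol(cp$counts),
      center_ref = c0, center_t = ct,
      shift = (ct - c0) / ncol(cp$counts))
  })
  out <- data.table::rbindlist(Filter(Negate(is.null), rows))
  if (!nrow(out))
    out <- data.table::data.table(transcript_id = character(),
                                  total_reads = integer(), n_covered = integer(),
                                  center_ref = integer(), center_t = integer(),
                                  shift = numeric())
  out[]
}

#' Rank transcripts by 5'-ward center-of-density shift
#'
#' Averages normalized shifts across replicates and returns the `top_n`
#' transcripts with the greatest shift of density towards the 5' end
#' (most negative average shift first).
#'
#' @param records_by_replicate List of [center_shift_records()] tables,
#'   one per replicate.
#' @param top_n Number of candidates returned.
#' @return `data.table` with `transcript_id`, `mean_shift`, `rank`.
#' @export
center_shift_screen <- function(records_by_replicate, top_n = 200L) {
  all <- data.table::rbindlist(records_by_replicate)
  agg <- all[, .(mean_shift = mean(shift), n_replicates = .N),
             by = transcript_id]
  agg <- agg[order(mean_shift, transcript_id)]
  agg[, rank := seq_len(.N)]
  utils::head(agg, top_n)
}

#' Subcodon distribution of 31-nt footprints
#'
#' Classifies the 5' ends of unique 31-nt reads over the first
#' `first_n_codons` codons of the acORF by their subcodon position
#' (`(pos - cds_start) mod 3`). Transcripts covering fewer than
#' `min_covered` distinct coordinates are excluded; a third-subcodon
#' fraction above `distortion_threshold` flags triplet-periodicity
#' distortion (the typical baseline is ~20%).
#'
#' @param reads Processed ribo read table.
#' @param ann A `ribo_annotation`.
#' @param transcript_id Transcript id.
#' @param read_length Footprint length used (31 nt shows the strongest
#'   periodicity).
#' @param first_n_codons acORF codons considered.
#' @param min_covered Minimum distinct covered coordinates.
#' @param coordinate_unit Whether `min_covered` counts nucleotide
#'   positions (`"nt"`) or covered codons (`"codon"`).
#' @param distortion_threshold Third-subcodon fraction flagging
#'   distortion.
#' @return List with `transcript_id`, `n_reads`, `n_covered`, `fractions`
#'   (`f1`,`f2`,`f3`), `excluded`, `distorted`.
#' @export
subcodon_distribution <- function(reads, ann, transcript_id,
                                  read_length = 31L, first_n_codons = 50L,
                                  min_covered = 50L,
                                  coordinate_unit = c("nt", "codon"),
                                  distortion_threshold = 0.35) {
  coordinate_unit <- match.arg(coordinate_unit)
  r <- tx_row(ann, transcript_id)
  if (!r$has_cds) stop("transcript has no annotated CDS: ", transcript_id)
  sub <- reads[transcript_id == r$transcript_id & length == read_length &
                 n_genes == 1L & n_map == 1L]
  rel <- sub$pos - r$cds_start
  sub <- sub[rel >= 0L & rel < 3L * first_n_codons]
  rel <- sub$pos - r$cds_start
  n_cov <- if (coordinate_unit == "nt") length(unique(rel))
           else length(unique(rel %/% 3L))
  frames <- tabulate(rel %% 3L + 1L, nbins = 3L)
  fr <- if (nrow(sub)) frames / sum(frames) else rep(NA_real_, 3L)
  excl <- n_cov < min_covered
  list(transcript_id = transcript_id, n_reads = nrow(sub), n_covered = n_cov,
       fractions = stats::setNames(fr, c("f1", "f2", "f3")),
       excluded = excl,
       distorted = if (excl || anyNA(fr)) NA else fr[3L] > distortion_threshold)
}

#' Periodicity screen over all coding transcripts
#'
#' Applies [subcodon_distribution()] to every annotated coding
#' transcript and also reports the pooled subcodon fractions over the
#' non-excluded transcripts.
#'
#' @inheritParams subcodon_distribution
#' @return List with `records` (`data.table`) and `pooled` (`f1`,`f2`,`f3`).
#' @export
periodicity_screen <- function(reads, ann, read_length = 31L,
                               first_n_codons = 50L, min_covered = 50L,
                               coordinate_unit = c("nt", "codon"),
                               distortion_threshold = 0.35) {
  coordinate_unit <- match.arg(coordinate_unit)
  txs <- ann$transcripts[has_cds == TRUE, transcript_id]
  rows <- lapply(txs, function(tid) {
    s <- subcodon_distribution(reads, ann, tid, read_length, first_n_codons,
                               min_covered, coordinate_unit,
                               distortion_threshold)
    data.table::data.table(transcript_id = tid, n_reads = s$n_reads,
                           n_covered = s$n_covered, f1 = s$fractions[1L],
                           f2 = s$fractions[2L], f3 = s$fractions[3L],
                           excluded = s$excluded, distorted = s$distorted)
  })
  rec <- data.table::rbindlist(rows)
  kept <- rec[excluded == FALSE & n_reads > 0]
  pooled <- if (nrow(kept)) {
    tot <- kept[, .(f1 = sum(f1 * n_reads), f2 = sum(f2 * n_reads),
                    f3 = sum(f3 * n_reads))] / sum(kept$n_reads)
    unlist(tot)
  } else c(f1 = NA_real_, f2 = NA_real_, f3 = NA_real_)
  list(records = rec[], pooled = pooled)
}
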