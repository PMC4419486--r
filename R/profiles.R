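# Metagene profiles at initiation/termination (with queuing-peak
# detection) and pairwise profile similarity with depth matching.

#' Metagene profile at the start or stop codon
#'
#' Aggregates footprint 5'-end densities of qualifying transcripts around
#' a common anchor. A transcript qualifies when it is the longest variant
#' of its gene, carries at least `min_alignments` mapped alignments, is
#' longer than `min_length` nt and both its 5' leader and 3' UTR exceed
#' `min_flank` nt. Each transcript's window is normalized by its own
#' average density (window alignments per nt) before position-wise
#' averaging; the nucleotide-level average is also reported per codon
#' (sum of the 3 nt offsets of each codon). Offset 0 is the first
#' nucleotide of the start codon (`anchor = "start"`) or of the stop
#' codon (`anchor = "stop"`).
#'
#' @param reads Processed ribo read table (uses footprint 5' ends).
#' @param ann A `ribo_annotation`.
#' @param anchor `"start"` or `"stop"`.
#' @param upstream,downstream Window extent in nt (defaults: 45/150 for
#'   start, 150/45 for stop).
#' @param min_alignments,min_length,min_flank Transcript selection
#'   criteria (see above).
#' @param weighted Use multimapper weights.
#' @return A list of class `ribo_metagene`: `anchor`, `nt` (data.table
#'   `offset`, `density`, `n` transcripts contributing), `codon`
#'   (`codon_offset`, `density`), `n_transcripts`.
#' @export
metagene_profile <- function(reads, ann, anchor = c("start", "stop"),
                             upstream = NULL, downstream = NULL,
                             min_alignments = 100, min_length = 600,
                             min_flank = 45, weighted = TRUE) {
  anchor <- match.arg(anchor)
  if (is.null(upstream)) upstream <- if (anchor == "start") 45L else 150L
  if (is.null(downstream)) downstream <- if (anchor == "start") 150L else 45L
  tx <- ann$transcripts[has_cds == TRUE]
  tx <- tx[transcript_id %in% ann$genes$longest_transcript_id]
  tx <- tx[length > min_length & cds_start > min_flank &
             (length - cds_end) > min_flank]
  cnt <- reads[, .N, by = transcript_id]
  keep <- cnt[N >= min_alignments, transcript_id]
  tx <- tx[transcript_id %in% keep]
  if (nrow(tx) == 0L) stop("no transcript satisfies the metagene criteria")
  offsets <- seq.int(-upstream, downstream)
  win <- tx[, .(transcript_id,
                anchor_pos = if (anchor == "start") cds_start else cds_end - 3L,
                length)]
  win[, `:=`(win_lo = pmax(-upstream, -anchor_pos),
             win_hi = pmin(downstream, length - 1L - anchor_pos))]
  sub <- reads[transcript_id %in% win$transcript_id,
               .(transcript_id, pos,
                 w = if (weighted) weight else rep(1, .N))]
  sub <- merge(sub, win, by = "transcript_id")
  sub[, offset := pos - anchor_pos]
  sub <- sub[offset >= win_lo & offset <= win_hi]
  totals <- sub[, .(total = sum(w)), by = transcript_id]
  win <- merge(win, totals, by = "transcript_id", all.x = TRUE)
  win[is.na(total), total := 0]
  win[, avg := total / (win_hi - win_lo + 1L)]
  n_zero <- sum(win$avg == 0)
  if (n_zero) warning(n_zero, " transcript(s) with zero window density skipped")
  win <- win[avg > 0]
  n_used <- nrow(win)
  sub <- merge(sub, win[, .(transcript_id, avg)], by = "transcript_id")
  percell <- sub[, .(norm = sum(w) / avg[1L]), by = .(transcript_id, offset)]
  acc <- percell[, .(acc = sum(norm)), by = offset]
  # transcripts whose window covers each offset
  cover <- win[, .(n = sapply(offsets, function(o)
    sum(win_lo <= o & o <= win_hi)))]
  nt <- data.table::data.table(offset = offsets, n = cover$n)
  nt <- merge(nt, acc, by = "offset", all.x = TRUE)
  nt[is.na(acc), acc := 0]
  nt[, density := ifelse(n > 0, acc / n, NA_real_)]
  nt[, acc := NULL]
  data.table::setcolorder(nt, c("offset", "density", "n"))
  cod <- data.table::copy(nt)[!is.na(density)]
  cod[, codon_offset := floor(offset / 3)]
  codon <- cod[, .(density = sum(density)), by = codon_offset][order(codon_offset)]
  structure(list(anchor = anchor, nt = nt, codon = codon,
                 n_transcripts = n_used),
            class = "ribo_metagene")
}

#' @export
print.ribo_metagene <- function(x, ...) {
  cat(sprintf("ribo_metagene: anchor=%s, %d transcripts, offsets %d..%d nt\n",
              x$anchor, x$n_transcripts, min(x$nt$offset), max(x$nt$offset)))
  invisible(x)
}

#' Spacing of ribosome queuing peaks
#'
#' Detects the `n_peaks` highest local maxima (over a +/- 2 codon window,
#' strict) strictly upstream of the stop codon in a stop-anchored
#' metagene and returns the median spacing between consecutive peaks in
#' codons. Queued ribosomes stacked behind a slow termination event with
#' a ~33 nt exclusion footprint produce peaks 11 codons apart.
#'
#' @param metagene A stop-anchored `ribo_metagene`.
#' @param n_peaks Number of peaks to use.
#' @param window Half-width of the local-maximum window (codons).
#' @return Median spacing in codons; attribute `peaks` holds the codon
#'   offsets used.
#' @export
queue_peak_spacing <- function(metagene, n_peaks = 3L, window = 2L) {
  if (metagene$anchor != "stop") stop("need a stop-anchored metagene")
  cod <- metagene$codon[codon_offset < 0]
  d <- cod$density
  n <- length(d)
  if (n < n_peaks * 15L)
    stop("profile covers too few upstream codons for ", n_peaks, " peaks")
  is_max <- vapply(seq_len(n), function(i) {
    nb <- d[setdiff(max(1L, i - window):min(n, i + window), i)]
    length(nb) > 0 && all(d[i] > nb)
  }, logical(1L))
  if (sum(is_max) < n_peaks)
    stop("found ", sum(is_max), " local maxima; need ", n_peaks)
  cand <- cod[is_max][order(-density)][seq_len(n_peaks)]
  peaks <- sort(cand$codon_offset)
  out <- stats::median(diff(peaks))
  attr(out, "peaks") <- peaks
  out
}

#' Pearson similarity of two codon profiles
#'
#' Correlates codon-resolution acORF profiles from two samples; the
#' transcript is excluded when either sample's average acORF density is
#' at or below `min_density` footprints per nucleotide, or when either
#' vector has zero variance.
#'
#' @param profile_a,profile_b Codon-count vectors of equal length (one
#'   acORF; counts include the stop codon).
#' @param min_density Minimum mean footprints per nt (acORF nt length is
#'   `3 * length(profile)`).
#' @return List with `r` (`NA` when excluded), `excluded`, `reason`.
#' @export
profile_similarity <- function(profile_a, profile_b, min_density = 1) {
  stopifnot(length(profile_a) == length(profile_b))
  nt_len <- 3 * length(profile_a)
  if (sum(profile_a) / nt_len <= min_density ||
      sum(profile_b) / nt_len <= min_density)
    return(list(r = NA_real_, excluded = TRUE, reason = "low_density"))
  if (stats::sd(profile_a) == 0 || stats::sd(profile_b) == 0)
    return(list(r = NA_real_, excluded = TRUE, reason = "zero_variance"))
  list(r = stats::cor(profile_a, profile_b), excluded = FALSE, reason = NA_character_)
}

#' Transcript-wise profile similarity between two samples
#'
#' Builds unique-read codon profiles for the longest transcript of each
#' gene and applies [profile_similarity()].
#'
#' @param reads_a,reads_b Processed ribo read tables for the two samples.
#' @param ann A `ribo_annotation`.
#' @param min_density Density cutoff (footprints per nt).
#' @param label Comparison label stored in the result.
#' @return `data.table` with `transcript_id`, `comparison`, `r`,
#'   `excluded`, `reason`.
#' @export
similarity_screen <- function(reads_a, reads_b, ann, min_density = 1,
                              label = "pair") {
  txs <- ann$genes$longest_transcript_id
  txs <- txs[ann$transcripts[data.table::J(txs), has_cds]]
  rows <- lapply(txs, function(tid) {
    pa <- build_profile(reads_a, ann, tid, "codon", "a_site", unique_only = TRUE)
    pb <- build_profile(reads_b, ann, tid, "codon", "a_site", unique_only = TRUE)
    s <- profile_similarity(pa, pb, min_density)
    data.table::data.table(transcript_id = tid, comparison = label,
                           r = s$r, excluded = s$excluded, reason = s$reason)
  })
  data.table::rbindlist(rows)
}

#' Depth-matched profile similarity
#'
#' Repeatedly subsamples the deeper of two per-transcript read sets
#' without replacement down to the shallower set's size, correlates the
#' resulting codon profiles and reports the mean correlation.
#'
#' @param codons_a,codons_b Integer vectors of per-read acORF codon
#'   indices (0-based) for the two samples (unique reads).
#' @param n_codons Number of acORF codons.
#' @param repeats Number of subsampling repeats.
#' @param seed Seed for the subsampling generator (local RNG; the global
#'   RNG state is untouched).
#' @return List with `mean_r`, `r` (per repeat), `target_depth`.
#' @export
depth_matched_similarity <- function(codons_a, codons_b, n_codons,
                                     repeats = 10L, seed = 1L) {
  stopifnot(repeats >= 1L)
  na <- length(codons_a); nb <- length(codons_b)
  target <- min(na, nb)
  tab <- function(x) tabulate(x + 1L, nbins = n_codons)
  rs <- with_local_seed(seed, vapply(seq_len(repeats), function(i) {
    a <- if (na > target) sample(codons_a, target) else codons_a
    b <- if (nb > target) sample(codons_b, target) else codons_b
    stats::cor(tab(a), tab(b))
  }, numeric(1L)))
  list(mean_r = mean(rs), r = rs, target_depth = target)
}

# evaluate expr under a temporary, private RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write a metagene profile as TSV
#'
#' @param metagene A `ribo_metagene`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_metagene <- function(metagene, path) {
  out <- data.table::copy(metagene$nt)
  out[, anchor := metagene$anchor]
  data.table::fwrite(out[, .(anchor, offset, density, n)], path, sep = "\t")
  invisible(path)
}
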