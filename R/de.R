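# Binned local Z-score differential expression with empirical
# discordant-sign FDR, threshold selection and pause-peak robustness.

#' Per-gene log2 fold changes
#'
#' @param counts_t,counts_0 Numeric count vectors (same gene order).
#' @param pseudocount Added to both counts.
#' @return `log2((counts_t + pseudocount) / (counts_0 + pseudocount))`.
#' @export
log_fold_changes <- function(counts_t, counts_0, pseudocount = 1) {
  log2((counts_t + pseudocount) / (counts_0 + pseudocount))
}

#' Binned local Z-scores
#'
#' Genes are sorted by their expression floor (the minimal relevant count
#' across the compared samples) and grouped into consecutive bins of
#' `bin_size`; a trailing bin smaller than `min_last_bin` is merged into
#' the previous one. Within each bin, `Z = (log_fc - mean) / sd`.
#'
#' @param log_fc Per-gene log2 fold change.
#' @param expression_floor Per-gene minimal expression across the compared
#'   samples.
#' @param bin_size Genes per bin.
#' @param min_last_bin Minimum size of the last bin before merging.
#' @return `data.table` with `index` (input order), `bin`, `z`.
#' @export
binned_z_scores <- function(log_fc, expression_floor, bin_size = 300L,
                            min_last_bin = 50L) {
  n <- length(log_fc)
  stopifnot(length(expression_floor) == n)
  ord <- order(expression_floor, seq_len(n))
  bin_sorted <- (seq_len(n) - 1L) %/% bin_size + 1L
  n_bins <- max(bin_sorted)
  if (n_bins > 1L && sum(bin_sorted == n_bins) < min_last_bin)
    bin_sorted[bin_sorted == n_bins] <- n_bins - 1L
  bin <- integer(n)
  bin[ord] <- bin_sorted
  dt <- data.table::data.table(index = seq_len(n), bin = bin, lfc = log_fc)
  sizes <- dt[, .N, by = bin]
  if (any(sizes$N < 2L)) stop("bin with fewer than 2 genes")
  dt[, z := (lfc - mean(lfc)) / stats::sd(lfc), by = bin]
  dt[, .(index, bin, z)]
}

#' Empirical discordant-sign FDR at a threshold
#'
#' Genes are called increased when `(Z1+Z2)/2 > T` and decreased when
#' `(Z1+Z2)/2 < -T` (strict). The number of false positives is estimated
#' as the number of genes with `(|Z1|+|Z2|)/2 > T` whose replicate
#' Z-scores disagree in sign (`Z1*Z2 < 0`); the estimated FDR is FP
#' divided by the number of called genes (0 when nothing is called,
#' capped at 1).
#'
#' @param z1,z2 Replicate Z-score vectors.
#' @param threshold Threshold T.
#' @return List with `n_increased`, `n_decreased`, `fp`, `fdr`.
#' @export
estimate_fdr <- function(z1, z2, threshold) {
  mz <- (z1 + z2) / 2
  n_inc <- sum(mz > threshold)
  n_dec <- sum(mz < -threshold)
  fp <- sum((abs(z1) + abs(z2)) / 2 > threshold & z1 * z2 < 0)
  de <- n_inc + n_dec
  list(n_increased = n_inc, n_decreased = n_dec, fp = fp,
       fdr = if (de == 0L) 0 else min(1, fp / de))
}

#' FDR curve over observed thresholds
#'
#' @param z1,z2 Replicate Z-score vectors.
#' @param thresholds Optional threshold grid; defaults to the sorted
#'   unique observed values of `(|Z1|+|Z2|)/2`.
#' @return `data.table` with `threshold`, `n_increased`, `n_decreased`,
#'   `fp`, `fdr`, ordered by decreasing threshold.
#' @export
fdr_curve <- function(z1, z2, thresholds = NULL) {
  if (is.null(thresholds))
    thresholds <- sort(unique((abs(z1) + abs(z2)) / 2), decreasing = TRUE)
  rows <- lapply(thresholds, function(t) {
    e <- estimate_fdr(z1, z2, t)
    data.table::data.table(threshold = t, n_increased = e$n_increased,
                           n_decreased = e$n_decreased, fp = e$fp, fdr = e$fdr)
  })
  data.table::rbindlist(rows)
}

#' Select the DE threshold for a target FDR
#'
#' Scans the observed `(|Z1|+|Z2|)/2` values from the maximum downwards
#' and returns the smallest threshold whose estimated FDR is at or below
#' the target and that lies on the plateau reaching the maximum (the
#' estimate also satisfies the target at every larger scanned threshold).
#' If no threshold satisfies the target, the maximum observed threshold
#' is returned with a warning.
#'
#' @param z1,z2 Replicate Z-score vectors.
#' @param target_fdr Desired FDR in (0, 1].
#' @return List with `threshold`, `fdr` (estimate at the threshold),
#'   `attained` (logical) and `curve` (the [fdr_curve()]).
#' @export
select_threshold <- function(z1, z2, target_fdr = 0.1) {
  stopifnot(target_fdr > 0, target_fdr <= 1)
  curve <- fdr_curve(z1, z2)
  ok <- curve$fdr <= target_fdr
  if (!ok[1L]) {
    warning("no threshold attains the target FDR; returning the maximum")
    return(list(threshold = curve$threshold[1L], fdr = curve$fdr[1L],
                attained = FALSE, curve = curve))
  }
  run_end <- if (all(ok)) nrow(curve) else which(!ok)[1L] - 1L
  list(threshold = curve$threshold[run_end], fdr = curve$fdr[run_end],
       attained = TRUE, curve = curve)
}

#' Call differential expression for one signal and contrast
#'
#' Implements the full caller on a combined normalized count table:
#' per-replicate log2 fold changes of the chosen signal between
#' `time_min` and the reference time, binned local Z-scores (bins ranked
#' by the minimal relevant expression: ribo acORF counts for `"ribo"`,
#' mRNA totals for `"mrna"`, all four for `"te"`), threshold selection at
#' the target FDR, and classification by the replicate-mean Z.
#'
#' @param counts Normalized region count table holding both library types
#'   and all samples (columns as from [count_gene_regions()]).
#' @param signal `"ribo"`, `"mrna"` or `"te"`.
#' @param time Time point to contrast.
#' @param reference_time Baseline time point.
#' @param pseudocount Pseudocount for fold changes.
#' @param bin_size,min_last_bin Binning parameters (see
#'   [binned_z_scores()]).
#' @param target_fdr Target empirical FDR.
#' @return `data.table` of class `ribo_de` with per-gene `log2_fc_rep*`,
#'   `z1`, `z2`, `mean_z`, `bin`, `label` in
#'   `{"increased","decreased","unchanged"}`; attributes `threshold`,
#'   `fdr`, `attained`, `curve`, `signal`, `contrast`.
#' @export
call_de <- function(counts, signal = c("ribo", "mrna", "te"), time,
                    reference_time = 0, pseudocount = 1, bin_size = 300L,
                    min_last_bin = 50L, target_fdr = 0.1) {
  signal <- match.arg(signal)
  reps <- sort(unique(counts$replicate))
  if (length(reps) < 2L) stop("need at least 2 replicates")
  pick <- function(lib, tp, rep) {
    d <- counts[library_type == lib & time_min == tp & replicate == rep]
    data.table::setkey(d, gene_id)
    d
  }
  genes <- sort(unique(counts$gene_id))
  per_rep <- lapply(reps, function(rp) {
    rt <- pick("ribo", time, rp)[data.table::J(genes)]
    r0 <- pick("ribo", reference_time, rp)[data.table::J(genes)]
    mt <- pick("mrna", time, rp)[data.table::J(genes)]
    m0 <- pick("mrna", reference_time, rp)[data.table::J(genes)]
    if (signal == "ribo") {
      lfc <- log_fold_changes(rt$acorf, r0$acorf, pseudocount)
      floor_ <- pmin(rt$acorf, r0$acorf)
    } else if (signal == "mrna") {
      lfc <- log_fold_changes(mt$total, m0$total, pseudocount)
      floor_ <- pmin(mt$total, m0$total)
    } else {
      lfc <- log_fold_changes(rt$acorf, r0$acorf, pseudocount) -
        log_fold_changes(mt$total, m0$total, pseudocount)
      floor_ <- pmin(rt$acorf, r0$acorf, mt$total, m0$total)
    }
    z <- binned_z_scores(lfc, floor_, bin_size, min_last_bin)
    data.table::setkey(z, index)
    list(lfc = lfc, z = z$z, bin = z$bin)
  })
  z1 <- per_rep[[1L]]$z; z2 <- per_rep[[2L]]$z
  mean_z <- Reduce(`+`, lapply(per_rep, `[[`, "z")) / length(per_rep)
  sel <- select_threshold(z1, z2, target_fdr)
  label <- ifelse(mean_z > sel$threshold, "increased",
                  ifelse(mean_z < -sel$threshold, "decreased", "unchanged"))
  out <- data.table::data.table(
    gene_id = genes, signal = signal,
    contrast = paste0(time, "_vs_", reference_time),
    log2_fc_rep1 = per_rep[[1L]]$lfc, log2_fc_rep2 = per_rep[[2L]]$lfc,
    z1 = z1, z2 = z2, mean_z = mean_z, bin = per_rep[[1L]]$bin,
    label = label)
  data.table::setattr(out, "threshold", sel$threshold)
  data.table::setattr(out, "fdr", sel$fdr)
  data.table::setattr(out, "attained", sel$attained)
  data.table::setattr(out, "curve", sel$curve)
  data.table::setattr(out, "class", c("ribo_de", class(out)))
  out
}

#' Pause-peak robustness filter
#'
#' Tests whether each DE call survives removal of its strongest pause
#' sites: for every sample, the reads whose A-site falls on the 3
#' highest-density acORF codons of each transcript (ties broken 5'-most,
#' peaks found per sample) are removed, the counting, normalization and
#' the full DE procedure are re-run, and `robust` records whether the
#' gene is still called DE in the same direction.
#'
#' @param reads_by_sample Named list (sample_id -> processed ribo read
#'   table) for every ribo sample in `counts`.
#' @param mrna_counts Normalized mRNA count table (reused unchanged; pass
#'   the unnormalized one used originally for exactness — the function
#'   renormalizes ribo counts only).
#' @param ann A `ribo_annotation`.
#' @param calls A `ribo_de` result from [call_de()].
#' @param sample_meta `data.table` mapping `sample_id` to `replicate`,
#'   `time_min` for the ribo samples.
#' @param n_peaks Number of peak codons removed per transcript and sample.
#' @param ... Further arguments passed on to [call_de()].
#' @return `calls` with an added logical `robust` column.
#' @export
robust_de_filter <- function(reads_by_sample, mrna_counts, ann, calls,
                             sample_meta, n_peaks = 3L, ...) {
  stripped <- lapply(names(reads_by_sample), function(sid) {
    strip_peak_codons(reads_by_sample[[sid]], ann, n_peaks)
  })
  names(stripped) <- names(reads_by_sample)
  ribo2 <- data.table::rbindlist(lapply(names(stripped), function(sid) {
    m <- sample_meta[sample_id == sid]
    count_gene_regions(stripped[[sid]], ann, "ribo", sid,
                       m$replicate, m$time_min)
  }))
  ribo2 <- normalize_counts(ribo2)
  counts2 <- data.table::rbindlist(list(ribo2, mrna_counts), use.names = TRUE)
  tm <- as.integer(sub("_vs_.*$", "", calls$contrast[1L]))
  rf <- as.integer(sub("^.*_vs_", "", calls$contrast[1L]))
  calls2 <- call_de(counts2, signal = calls$signal[1L], time = tm,
                    reference_time = rf, ...)
  m <- merge(calls[, .(gene_id, label)],
             calls2[, .(gene_id, label2 = label)], by = "gene_id")
  m[, robust := label != "unchanged" & label == label2]
  out <- merge(calls, m[, .(gene_id, robust)], by = "gene_id", sort = FALSE)
  for (a in c("threshold", "fdr", "attained", "curve", "signal", "contrast"))
    data.table::setattr(out, a, attr(calls, a))
  data.table::setattr(out, "class", class(calls))
  out
}

# remove reads whose A-site codon is among the n highest-density acORF
# codons of its assigned transcript (computed per call, i.e. per sample)
strip_peak_codons <- function(reads, ann, n_peaks = 3L) {
  tx <- ann$transcripts
  dt <- data.table::copy(reads)
  dt[, cds_start := tx[data.table::J(dt$transcript_id), cds_start]]
  dt[, cds_end := tx[data.table::J(dt$transcript_id), cds_end]]
  dt[, codon := (a_site - cds_start) %/% 3L]
  dt[, in_acorf := !is.na(cds_start) & a_site >= cds_start & a_site < cds_end]
  dens <- dt[in_acorf == TRUE,
             .(w = sum(weight)), by = .(transcript_id, codon)]
  peaks <- dens[order(-w, codon), utils::head(.SD, n_peaks),
                by = transcript_id][, .(transcript_id, codon, peak = TRUE)]
  dt <- merge(dt, peaks, by = c("transcript_id", "codon"),
              all.x = TRUE, sort = FALSE)
  out <- dt[is.na(peak) | in_acorf == FALSE]
  out[, c("cds_start", "cds_end", "codon", "in_acorf", "peak") := NULL]
  out[]
}

#' Write DE results
#'
#' @param calls A `ribo_de` table.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_de <- function(calls, path) {
  data.table::fwrite(calls, path, sep = "\t")
  invisible(path)
}
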