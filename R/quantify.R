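# Weighted per-gene, per-region counting; scale-to-smallest-library
# normalization; translation-efficiency tables; per-transcript profiles.

#' Count weighted reads per gene and region
#'
#' Each retained ribo-seq read contributes its multimapper weight once per
#' gene to the region containing its A-site; mRNA-seq reads contribute to
#' `total` only. Genes lacking an annotated CDS accumulate ribo-seq reads
#' in `total` only. For CDS genes, `total = leader + acorf + utr3` holds
#' by construction for ribo libraries.
#'
#' @param reads Processed read table ([process_ribo_reads()] or
#'   [process_mrna_reads()]).
#' @param ann A `ribo_annotation`.
#' @param library_type `"ribo"` or `"mrna"`.
#' @param sample_id Sample label stored in the table.
#' @param replicate,time_min Optional sample metadata (stored as columns).
#' @return A `data.table` with one row per gene: `gene_id`, `sample_id`,
#'   `replicate`, `time_min`, `library_type`, `leader`, `acorf`, `utr3`,
#'   `total`. Genes absent from `reads` but present in the annotation get
#'   zero counts.
#' @export
count_gene_regions <- function(reads, ann, library_type = c("ribo", "mrna"),
                               sample_id = "sample", replicate = NA_integer_,
                               time_min = NA_integer_) {
  library_type <- match.arg(library_type)
  if (library_type == "ribo") {
    agg <- reads[, .(
      leader = sum(weight[region == "leader"]),
      acorf = sum(weight[region == "acorf"]),
      utr3 = sum(weight[region == "utr3"]),
      total = sum(weight)), by = gene_id]
  } else {
    agg <- reads[, .(leader = 0, acorf = 0, utr3 = 0,
                     total = sum(weight)), by = gene_id]
  }
  out <- merge(ann$genes[, .(gene_id)], agg, by = "gene_id", all.x = TRUE)
  for (cl in c("leader", "acorf", "utr3", "total"))
    data.table::set(out, which(is.na(out[[cl]])), cl, 0)
  out[, `:=`(sample_id = sample_id, replicate = replicate,
             time_min = time_min, library_type = library_type)]
  data.table::setcolorder(out, c("gene_id", "sample_id", "replicate",
                                 "time_min", "library_type"))
  out[]
}

#' Rescale libraries to the smallest one
#'
#' All samples of a library group (ribo-seq or mRNA-seq; both replicates
#' together) are put on the scale of the smallest library: counts in
#' sample *k* are multiplied by `min(x[i]) / x[k]`, where `x[k]` is the
#' sample's total counted reads. The smallest library is unchanged and
#' within-sample count ratios are preserved exactly.
#'
#' @param counts A region count table (rows from [count_gene_regions()],
#'   possibly several samples bound together). All rows are rescaled as
#'   one group; call separately per library type.
#' @return The rescaled table; attribute `rescaling_factors` is a named
#'   vector of the factors applied per sample.
#' @export
normalize_counts <- function(counts) {
  totals <- counts[, .(x = sum(total)), by = sample_id]
  if (any(totals$x == 0))
    stop("empty library: ", paste(totals$sample_id[totals$x == 0], collapse = ", "))
  totals[, factor := min(x) / x]
  fac <- stats::setNames(totals$factor, totals$sample_id)
  out <- data.table::copy(counts)
  f <- fac[out$sample_id]
  for (cl in c("leader", "acorf", "utr3", "total"))
    data.table::set(out, NULL, cl, out[[cl]] * f)
  data.table::setattr(out, "rescaling_factors", fac)
  out[]
}

#' Translation efficiency per gene and sample
#'
#' TE = (ribo acORF count + pseudocount) / (mRNA total count +
#' pseudocount), computed on normalized counts for samples matched by
#' replicate and time point.
#'
#' @param ribo,mrna Normalized region count tables for the two library
#'   types, with matching `replicate`/`time_min` metadata.
#' @param pseudocount Added to numerator and denominator.
#' @return `data.table` with `gene_id`, `replicate`, `time_min`, `ribo_acorf`,
#'   `mrna_total`, `te`.
#' @export
translation_efficiency <- function(ribo, mrna, pseudocount = 1) {
  m <- merge(ribo[, .(gene_id, replicate, time_min, ribo_acorf = acorf)],
             mrna[, .(gene_id, replicate, time_min, mrna_total = total)],
             by = c("gene_id", "replicate", "time_min"))
  m[, te := (ribo_acorf + pseudocount) / (mrna_total + pseudocount)]
  m[]
}

#' Footprint profile of one transcript
#'
#' Weighted counts along a transcript at nucleotide or codon resolution.
#' Codon resolution covers the acORF: the codon bin of an A-site at
#' position `p` is `floor((p - cds_start)/3)` (A-sites off-frame still
#' fall in that bin); positions outside the acORF are ignored. Nucleotide
#' resolution covers the whole transcript at the chosen anchor
#' (`a_site` or the footprint `five_prime` end). Anchor positions outside
#' the transcript are counted into an `overflow` attribute with a warning.
#'
#' @param reads Processed read table.
#' @param ann A `ribo_annotation`.
#' @param transcript_id Transcript to profile.
#' @param resolution `"nucleotide"` or `"codon"`.
#' @param anchor `"a_site"` or `"five_prime"`.
#' @param unique_only Use only unambiguously aligned reads (a single
#'   mapping overall).
#' @param weighted Multiply by multimapper weights (ignored when
#'   `unique_only`).
#' @return Numeric vector of length `transcript length` (nucleotide) or
#'   `acORF length / 3` (codon; includes the stop codon); attribute
#'   `overflow`.
#' @export
build_profile <- function(reads, ann, transcript_id,
                          resolution = c("nucleotide", "codon"),
                          anchor = c("a_site", "five_prime"),
                          unique_only = FALSE, weighted = TRUE) {
  resolution <- match.arg(resolution)
  anchor <- match.arg(anchor)
  r <- tx_row(ann, transcript_id)
  sub <- reads[transcript_id == r$transcript_id]
  if (unique_only) sub <- sub[n_genes == 1L & n_map == 1L]
  w <- if (weighted && !unique_only) sub$weight else rep(1, nrow(sub))
  p <- if (anchor == "a_site") sub$a_site else sub$pos
  overflow <- 0
  if (resolution == "nucleotide") {
    prof <- numeric(r$length)
    ok <- !is.na(p) & p >= 0L & p < r$length
    overflow <- sum(w[!ok])
    if (any(ok)) {
      tb <- tapply(w[ok], p[ok], sum)
      prof[as.integer(names(tb)) + 1L] <- tb
    }
  } else {
    if (!r$has_cds) stop("codon profile needs an annotated CDS: ", transcript_id)
    n_codon <- (r$cds_end - r$cds_start) %/% 3L
    prof <- numeric(n_codon)
    cod <- (p - r$cds_start) %/% 3L
    ok <- !is.na(cod) & cod >= 0L & cod < n_codon
    if (any(ok)) {
      tb <- tapply(w[ok], cod[ok], sum)
      prof[as.integer(names(tb)) + 1L] <- tb
    }
  }
  if (overflow > 0) warning(overflow, " read(s) outside transcript ",
                            transcript_id, " counted to overflow")
  attr(prof, "overflow") <- overflow
  prof
}

#' Write a region count table
#'
#' Long TSV serialization (gene, sample, region, count).
#'
#' @param counts Region count table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(counts, path) {
  long <- data.table::melt(counts,
    id.vars = c("gene_id", "sample_id", "replicate", "time_min", "library_type"),
    measure.vars = c("leader", "acorf", "utr3", "total"),
    variable.name = "region", value.name = "count")
  data.table::fwrite(long, path, sep = "\t")
  invisible(path)
}
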