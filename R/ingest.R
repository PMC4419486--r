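# Footprint ingest: FASTQ preprocessing, SAM/TSV alignment reading,
# A-site inference, within-transcript region priority, multimapper weighting.

REGION_PRIORITY <- c(acorf = 1L, leader = 2L, utr3 = 3L)

#' Preprocess raw reads
#'
#' Adapter trimming, spike-in and contaminant removal, and a minimum-length
#' filter, with full read accounting. Trimming removes the longest suffix of
#' each read that exactly matches a prefix of the adapter (minimum overlap
#' `min_overlap` nt, no mismatches). Reads exactly equal to the spike-in
#' oligo, or contained verbatim in any contaminant sequence (e.g. rRNA),
#' are removed after trimming.
#'
#' @param fastq Path to a FASTQ file.
#' @param adapter Adapter sequence (non-empty character scalar).
#' @param spike_in Optional spike-in oligo sequence; trimmed reads equal to
#'   it are removed.
#' @param contaminants Optional FASTA path of contaminant sequences.
#' @param min_length Minimum retained read length after trimming (nt).
#' @param min_overlap Minimum adapter overlap to trim (nt).
#' @param out Optional output FASTQ path for retained reads.
#' @return A list with `reads` (data.table: `read_id`, `seq`, `qual`),
#'   `stats` (named integer vector: `input`, `adapter_trimmed`,
#'   `spike_in_removed`, `contaminant_removed`, `length_filtered`,
#'   `retained`) and `out` (the path written, or `NULL`).
#' @export
preprocess_reads <- function(fastq, adapter, spike_in = NULL,
                             contaminants = NULL, min_length = 20L,
                             min_overlap = 5L, out = NULL) {
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  rec <- read_fastq(fastq)
  n <- nrow(rec)
  trim_k <- adapter_trim_lengths(rec$seq, adapter, min_overlap)
  keep_len <- nchar(rec$seq) - trim_k
  rec[, seq := substr(seq, 1L, keep_len)]
  rec[, qual := substr(qual, 1L, keep_len)]
  n_trimmed <- sum(trim_k > 0L)

  is_spike <- if (is.null(spike_in)) rep(FALSE, n) else rec$seq == spike_in
  is_contam <- rep(FALSE, n)
  if (!is.null(contaminants)) {
    cont <- Biostrings::readDNAStringSet(contaminants)
    for (cs in as.character(cont))
      is_contam <- is_contam | stringi::stri_detect_fixed(cs, rec$seq)
    is_contam <- is_contam & !is_spike
  }
  too_short <- nchar(rec$seq) < min_length & !is_spike & !is_contam
  keep <- !(is_spike | is_contam | too_short)
  stats <- c(input = n,
             adapter_trimmed = n_trimmed,
             spike_in_removed = sum(is_spike),
             contaminant_removed = sum(is_contam),
             length_filtered = sum(too_short),
             retained = sum(keep))
  kept <- rec[keep]
  if (!is.null(out)) write_fastq(kept, out)
  list(reads = kept, stats = stats, out = out)
}

# length of adapter prefix found as a suffix of each read (0 if none);
# longest match wins
adapter_trim_lengths <- function(seqs, adapter, min_overlap) {
  nc <- nchar(seqs)
  trim <- integer(length(seqs))
  for (k in seq(min(nchar(adapter), max(nc)), min_overlap)) {
    cand <- trim == 0L & nc >= k
    if (!any(cand)) next
    hit <- substr(seqs[cand], nc[cand] - k + 1L, nc[cand]) ==
      substr(adapter, 1L, k)
    trim[cand][hit] <- k
  }
  trim
}

read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: ", path, " has ", length(lines),
         " lines (not a multiple of 4)")
  n <- length(lines) %/% 4L
  id <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(id, "@") | !startsWith(plus, "+") |
                 nchar(seq) != nchar(qual))
  if (length(bad))
    stop("malformed FASTQ record at index ", bad[1L], " in ", path)
  data.table::data.table(read_id = sub("\\s.*$", "", substring(id, 2L)),
                         seq = seq, qual = qual)
}

write_fastq <- function(rec, path) {
  out <- character(4L * nrow(rec))
  out[seq(1L, by = 4L, length.out = nrow(rec))] <- paste0("@", rec$read_id)
  out[seq(2L, by = 4L, length.out = nrow(rec))] <- rec$seq
  out[seq(3L, by = 4L, length.out = nrow(rec))] <- "+"
  out[seq(4L, by = 4L, length.out = nrow(rec))] <- rec$qual
  writeLines(out, path)
  invisible(path)
}

#' Read transcriptome-space alignments
#'
#' Accepts either the package's 4-column TSV dialect
#' (`read_id`, `transcript_id`, `five_prime_pos`, `length`, 0-based) or a
#' transcriptome-space SAM file (converted and parsed via
#' \pkg{Rsamtools}). All candidate mappings of a read are grouped under a
#' shared `read_id`; the whole file is loaded, so row order is free.
#' Reverse-strand SAM records are dropped with a warning and counted in
#' the `dropped_reverse` attribute; only gap-free `<n>M` alignments are
#' accepted.
#'
#' @param path Alignment file (`.sam` or TSV).
#' @param ann A `ribo_annotation`; alignment references must exist in it.
#' @param format `"auto"` (by extension), `"tsv"` or `"sam"`.
#' @return A `data.table` with columns `read_id`, `transcript_id`,
#'   `pos` (0-based 5' end), `length`; attribute `dropped_reverse`.
#' @export
read_alignments <- function(path, ann, format = c("auto", "tsv", "sam")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "tsv"
  if (format == "tsv") {
    dt <- data.table::fread(path, header = FALSE, sep = "\t")
    data.table::setnames(dt, 1:4, c("read_id", "transcript_id", "pos", "length"))
    dt[, `:=`(read_id = as.character(read_id),
              transcript_id = as.character(transcript_id),
              pos = as.integer(pos), length = as.integer(length))]
    data.table::setattr(dt, "dropped_reverse", 0L)
  } else {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(bam), add = TRUE)
    p <- Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "cigar"))
    b <- Rsamtools::scanBam(bam, param = p)[[1L]]
    rev <- bitwAnd(b$flag, 16L) > 0L
    n_rev <- sum(rev)
    if (n_rev) warning(n_rev, " reverse-strand alignment(s) dropped")
    len <- suppressWarnings(as.integer(sub("^([0-9]+)M$", "\\1", b$cigar)))
    if (anyNA(len[!rev]))
      stop("only gap-free <n>M alignments are supported; offending CIGAR: ",
           b$cigar[!rev][which(is.na(len[!rev]))[1L]])
    dt <- data.table::data.table(
      read_id = as.character(b$qname)[!rev],
      transcript_id = as.character(b$rname)[!rev],
      pos = as.integer(b$pos)[!rev] - 1L,
      length = len[!rev])
    data.table::setattr(dt, "dropped_reverse", n_rev)
  }
  unknown <- setdiff(unique(dt$transcript_id), ann$transcripts$transcript_id)
  if (length(unknown))
    stop("alignment references unknown transcript(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  dt
}

#' Write alignments in the TSV dialect
#'
#' @param reads Alignment `data.table` (`read_id`, `transcript_id`, `pos`,
#'   `length`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_alignments_tsv <- function(reads, path) {
  data.table::fwrite(reads[, c("read_id", "transcript_id", "pos", "length")],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Infer ribosomal A-sites
#'
#' The A-site of a footprint is placed 17 nt downstream of its 5' end for
#' read lengths 29--33 and 18 nt downstream for lengths 34--35. Reads
#' shorter than 29 or longer than 35 nt are discarded, as are reads whose
#' inferred A-site falls beyond the transcript end; both discard classes
#' are counted in the returned attributes.
#'
#' @param reads Alignment `data.table`.
#' @param ann A `ribo_annotation`.
#' @return The table with an added `a_site` column, restricted to retained
#'   mappings; attributes `discarded_length` and `discarded_overflow`
#'   (counts of distinct reads fully lost to each filter).
#' @export
assign_a_site <- function(reads, ann) {
  dt <- data.table::copy(reads)
  offs <- a_site_offset(dt$length)
  keep_len <- !is.na(offs)
  n_len <- length(unique(dt$read_id[!keep_len]))
  dt <- dt[keep_len]
  dt[, a_site := pos + a_site_offset(length)]
  txlen <- ann$transcripts[data.table::J(dt$transcript_id), length]
  over <- dt$a_site >= txlen | dt$pos < 0L
  before <- unique(dt$read_id)
  dt <- dt[!over]
  n_over <- length(setdiff(before, unique(dt$read_id)))
  data.table::setattr(dt, "discarded_length", n_len)
  data.table::setattr(dt, "discarded_overflow", n_over)
  dt
}

#' A-site offset for footprint lengths
#'
#' @param length Integer vector of read lengths.
#' @return Integer offsets (17 for 29--33 nt, 18 for 34--35 nt, `NA`
#'   outside 29--35).
#' @export
a_site_offset <- function(length) {
  ifelse(length >= 29L & length <= 33L, 17L,
         ifelse(length >= 34L & length <= 35L, 18L, NA_integer_))
}

#' Resolve multiple mappings within one transcript
#'
#' When a read maps to several positions of the same transcript, the
#' mapping whose A-site falls in the highest-priority region is kept
#' (priority acORF > 5' leader > 3' UTR); ties within a region are broken
#' by the 5'-most position.
#'
#' @param reads Alignment table with `a_site` (see [assign_a_site()]).
#' @param ann A `ribo_annotation`.
#' @return One mapping per (read, transcript).
#' @export
resolve_within_transcript <- function(reads, ann) {
  dt <- add_region(reads, ann)
  dt[order(REGION_PRIORITY[region], pos),
     .SD[1L], by = .(read_id, transcript_id)]
}

add_region <- function(reads, ann, at = "a_site") {
  dt <- data.table::copy(reads)
  tx <- ann$transcripts[data.table::J(dt$transcript_id)]
  p <- dt[[at]]
  dt[, region := ifelse(!tx$has_cds, "none",
                   ifelse(p < tx$cds_start, "leader",
                     ifelse(p < tx$cds_end, "acorf", "utr3")))]
  dt
}

#' Weight multimapping reads at the gene level
#'
#' Mapping locations are counted per gene: a read hitting several
#' transcripts of one gene occupies a single location and keeps weight 1.
#' Reads at 2 or 3 gene-level locations get weights 1/2 and 1/3; reads at
#' more than 3 are discarded (counted in attribute `discarded_multimap`).
#' Within a gene the representative mapping is chosen by region priority,
#' then 5'-most position, then transcript id.
#'
#' @param reads Output of [resolve_within_transcript()] (ribo) or a
#'   deduplicated mRNA table carrying a `region` column.
#' @param ann A `ribo_annotation`.
#' @return One row per (read, gene) with `gene_id`, `n_genes`, `n_map`
#'   (raw mappings of the read) and `weight`.
#' @export
weight_multimappers <- function(reads, ann) {
  dt <- data.table::copy(reads)
  dt[, gene_id := ann$transcripts[data.table::J(dt$transcript_id), gene_id]]
  dt[, n_map := .N, by = read_id]
  dt <- dt[order(REGION_PRIORITY[region], pos, transcript_id),
           .SD[1L], by = .(read_id, gene_id)]
  dt[, n_genes := .N, by = read_id]
  n_disc <- length(unique(dt$read_id[dt$n_genes > 3L]))
  dt <- dt[n_genes <= 3L]
  dt[, weight := 1 / n_genes]
  data.table::setattr(dt, "discarded_multimap", n_disc)
  dt[]
}

#' Full ribo-seq read processing chain
#'
#' [assign_a_site()], [resolve_within_transcript()] and
#' [weight_multimappers()] in sequence, with accounting merged into a
#' `stats` attribute.
#'
#' @param reads Raw alignment table from [read_alignments()].
#' @param ann A `ribo_annotation`.
#' @return Processed read table (one row per read x gene) with columns
#'   `read_id`, `transcript_id`, `pos`, `length`, `a_site`, `region`,
#'   `gene_id`, `n_genes`, `n_map`, `weight`.
#' @export
process_ribo_reads <- function(reads, ann) {
  a <- assign_a_site(reads, ann)
  r <- resolve_within_transcript(a, ann)
  w <- weight_multimappers(r, ann)
  data.table::setattr(w, "stats", c(
    input = length(unique(reads$read_id)),
    discarded_length = attr(a, "discarded_length"),
    discarded_overflow = attr(a, "discarded_overflow"),
    discarded_multimap = attr(w, "discarded_multimap"),
    retained = length(unique(w$read_id))))
  w
}

#' mRNA-seq read processing
#'
#' mRNA reads carry no A-site; their position is the 5' end and they are
#' counted over the entire transcript. Reads shorter than `min_length` are
#' dropped; gene-level deduplication and 1/2, 1/3 multimapper weighting
#' apply as for ribo-seq.
#'
#' @param reads Raw alignment table.
#' @param ann A `ribo_annotation`.
#' @param min_length Minimum read length (nt).
#' @return Processed read table with `weight`; `region` is `"none"`.
#' @export
process_mrna_reads <- function(reads, ann, min_length = 20L) {
  dt <- reads[length >= min_length]
  dt <- data.table::copy(dt)
  dt[, region := "none"]
  dt[, gene_id := ann$transcripts[data.table::J(dt$transcript_id), gene_id]]
  dt[, n_map := .N, by = read_id]
  dt <- dt[order(pos, transcript_id), .SD[1L], by = .(read_id, gene_id)]
  dt[, n_genes := .N, by = read_id]
  n_disc <- length(unique(dt$read_id[dt$n_genes > 3L]))
  dt <- dt[n_genes <= 3L]
  dt[, weight := 1 / n_genes]
  dt[, a_site := NA_integer_]
  data.table::setattr(dt, "discarded_multimap", n_disc)
  dt[]
}
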