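# Transcriptome annotation: transcript-space models with the
# 5' leader / acORF / 3' UTR partition used by every downstream stage.

#' Load a transcriptome annotation
#'
#' Reads a tab-separated annotation table (and optionally the matching
#' transcript FASTA) describing transcripts in transcript-space coordinates.
#' Every coordinate in this package is 0-based and half-open; `cds_end` is
#' exclusive and includes the stop codon, so the annotated coding ORF (acORF)
#' spans `[cds_start, cds_end)` and its length is divisible by 3.
#'
#' The table has 5 or 6 tab-separated columns:
#' `transcript_id`, `gene_id`, `length`, `cds_start`, `cds_end`, and an
#' optional `name`. Lines starting with `#` are ignored. Transcripts without
#' an annotated CDS use `NA` for both CDS columns.
#'
#' @param table_path Path to the annotation TSV.
#' @param fasta_path Optional path to a FASTA file of transcript sequences.
#'   Sequences are only required by operations that read them (e.g. the
#'   readthrough screen); loading without them succeeds.
#' @return An object of class `ribo_annotation`: a list with
#'   `transcripts` (a `data.table` with one row per transcript),
#'   `genes` (per-gene table with the resolved longest transcript) and
#'   `seq` (a [Biostrings::DNAStringSet] or `NULL`).
#' @export
load_annotation <- function(table_path, fasta_path = NULL) {
  tab <- data.table::fread(table_path, header = FALSE, sep = "\t",
                           fill = TRUE, na.strings = c("NA", ""))
  if (ncol(tab) < 5L)
    stop("annotation table needs at least 5 tab-separated columns")
  data.table::setnames(tab, seq_len(ncol(tab)),
    c("transcript_id", "gene_id", "length", "cds_start", "cds_end",
      "name")[seq_len(ncol(tab))])
  tab <- tab[!startsWith(as.character(transcript_id), "#")]
  seqs <- NULL
  if (!is.null(fasta_path)) {
    seqs <- Biostrings::readDNAStringSet(fasta_path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
  }
  annotation(tab, seq = seqs)
}

#' Construct an annotation object from a table
#'
#' Programmatic constructor behind [load_annotation()]; validates all
#' transcript invariants and resolves the longest transcript per gene
#' (ties broken by lexicographically smallest transcript id).
#'
#' @param transcripts A data.frame/data.table with columns `transcript_id`,
#'   `gene_id`, `length`, `cds_start`, `cds_end` (and optional `name`).
#' @param seq Optional named [Biostrings::DNAStringSet] of transcript
#'   sequences.
#' @return A `ribo_annotation` object.
#' @export
annotation <- function(transcripts, seq = NULL) {
  tx <- data.table::as.data.table(transcripts)
  need <- c("transcript_id", "gene_id", "length", "cds_start", "cds_end")
  miss <- setdiff(need, names(tx))
  if (length(miss)) stop("missing annotation columns: ", paste(miss, collapse = ", "))
  tx[, `:=`(transcript_id = as.character(transcript_id),
            gene_id = as.character(gene_id),
            length = as.integer(length),
            cds_start = as.integer(cds_start),
            cds_end = as.integer(cds_end))]
  if (anyDuplicated(tx$transcript_id))
    stop("duplicated transcript_id in annotation")
  if (any(tx$length <= 0L)) stop("transcript length must be positive")
  tx[, has_cds := !is.na(cds_start) & !is.na(cds_end)]
  bad <- tx[has_cds & !(cds_start >= 0L & cds_start < cds_end & cds_end <= length)]
  if (nrow(bad))
    stop("invalid CDS coordinates for transcript(s): ",
         paste(bad$transcript_id, collapse = ", "))
  bad3 <- tx[has_cds & (cds_end - cds_start) %% 3L != 0L]
  if (nrow(bad3))
    stop("CDS not divisible by 3 for transcript(s): ",
         paste(bad3$transcript_id, collapse = ", "))
  if (!is.null(seq)) {
    missing_seq <- setdiff(tx$transcript_id, names(seq))
    if (length(missing_seq))
      stop("FASTA lacks sequence for: ", paste(missing_seq, collapse = ", "))
    wl <- Biostrings::width(seq[tx$transcript_id])
    if (any(wl != tx$length))
      stop("sequence length disagrees with annotation for: ",
           paste(tx$transcript_id[wl != tx$length], collapse = ", "))
  }
  data.table::setkey(tx, transcript_id)
  genes <- tx[order(-length, transcript_id),
              .(transcript_ids = list(sort(transcript_id)),
                longest_transcript_id = transcript_id[1L]),
              by = gene_id]
  data.table::setkey(genes, gene_id)
  structure(list(transcripts = tx, genes = genes, seq = seq),
            class = "ribo_annotation")
}

#' @export
print.ribo_annotation <- function(x, ...) {
  cat(sprintf("ribo_annotation: %d transcripts, %d genes, sequences: %s\n",
              nrow(x$transcripts), nrow(x$genes),
              if (is.null(x$seq)) "absent" else "present"))
  invisible(x)
}

tx_row <- function(ann, transcript_id) {
  .id <- as.character(transcript_id)[1L]
  r <- ann$transcripts[data.table::J(.id)]
  if (anyNA(r$length)) stop("unknown transcript: ", .id)
  r
}

#' Sequence of one transcript
#'
#' @param ann A `ribo_annotation`.
#' @param transcript_id Transcript identifier.
#' @return A character scalar.
#' @export
transcript_sequence <- function(ann, transcript_id) {
  if (is.null(ann$seq))
    stop("annotation was loaded without sequences; this operation needs them")
  as.character(ann$seq[[transcript_id]])
}

#' Region of transcript positions
#'
#' Maps transcript coordinates to the region partition
#' leader `[0, cds_start)`, acORF `[cds_start, cds_end)`,
#' utr3 `[cds_end, length)`.
#'
#' @param ann A `ribo_annotation`.
#' @param transcript_id A single transcript id.
#' @param pos Integer vector of 0-based transcript positions.
#' @return Character vector in `{"leader","acorf","utr3"}`.
#' @export
region_of <- function(ann, transcript_id, pos) {
  r <- tx_row(ann, transcript_id)
  if (any(pos < 0L | pos >= r$length))
    stop("position out of range for transcript ", transcript_id)
  if (!r$has_cds) stop("transcript ", transcript_id, " has no annotated CDS")
  ifelse(pos < r$cds_start, "leader",
         ifelse(pos < r$cds_end, "acorf", "utr3"))
}

#' Region lengths of a transcript
#'
#' @inheritParams region_of
#' @return Named integer vector `c(leader=, acorf=, utr3=)`.
#' @export
region_lengths <- function(ann, transcript_id) {
  r <- tx_row(ann, transcript_id)
  if (!r$has_cds) return(c(leader = 0L, acorf = 0L, utr3 = r$length))
  c(leader = r$cds_start,
    acorf = r$cds_end - r$cds_start,
    utr3 = r$length - r$cds_end)
}

#' Write an annotation table
#'
#' Inverse of the table half of [load_annotation()].
#'
#' @param ann A `ribo_annotation`.
#' @param table_path Output TSV path.
#' @param fasta_path Optional output FASTA path (requires sequences).
#' @return Invisibly, `table_path`.
#' @export
write_annotation <- function(ann, table_path, fasta_path = NULL) {
  cols <- intersect(c("transcript_id", "gene_id", "length",
                      "cds_start", "cds_end", "name"),
                    names(ann$transcripts))
  data.table::fwrite(ann$transcripts[, cols, with = FALSE], table_path,
                     sep = "\t", col.names = FALSE, na = "NA")
  if (!is.null(fasta_path)) {
    if (is.null(ann$seq)) stop("no sequences to write")
    Biostrings::writeXStringSet(ann$seq, fasta_path, width = 70L)
  }
  invisible(table_path)
}
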