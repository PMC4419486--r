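adapter <- "CTGTAGGCACCATCAATAGATCGGAAGAGCACACGTCTGAACTCCAGTCA"
spike <- "ATGTACACGGAGTCGACCCGCAACGCGA"

write_fastq_lines <- function(recs) {
  fq <- tempfile(fileext = ".fastq")
  writeLines(unlist(lapply(recs, function(s)
    c(paste0("@", s[1]), s[2], "+", strrep("I", nchar(s[2]))))), fq)
  fq
}

test_that("adapter suffixes are trimmed, spike-ins removed, stats account for all reads", {
  insert <- "AAACCCGGGTTTAAACCCGGGTTTAAACCC"
  fq <- write_fastq_lines(list(
    c("r1", paste0(insert, substr(adapter, 1, 10))),
    c("r2", spike),
    c("r3", insert),
    c("r4", "ACGTA")))
  p <- preprocess_reads(fq, adapter, spike)
  expect_equal(p$reads[read_id == "r1", seq], insert)
  expect_equal(p$reads[read_id == "r3", seq], insert)  # no adapter: unchanged
  expect_false("r2" %in% p$reads$read_id)
  s <- p$stats
  expect_equal(unname(s["spike_in_removed"]), 1L)
  expect_equal(unname(s["length_filtered"]), 1L)
  expect_equal(unname(s["retained"] + s["spike_in_removed"] +
                 s["contaminant_removed"] + s["length_filtered"]),
               unname(s["input"]))
})

test_that("adapter matches below the minimum overlap are left alone", {
  insert <- "AAACCCGGGTTTAAACCCGGGTTTAAACCC"
  fq <- write_fastq_lines(list(c("r1", paste0(insert, substr(adapter, 1, 4)))))
  p <- preprocess_reads(fq, adapter)
  expect_equal(p$reads$seq, paste0(insert, substr(adapter, 1, 4)))
})

test_that("contaminant substring matches are removed", {
  fq <- write_fastq_lines(list(c("r1", "AAACCCGGGTTTAAACCCGGGTTT"),
                               c("r2", "TTTTTTTTTTTTTTTTTTTTTTTT")))
  contam <- tempfile(fileext = ".fa")
  writeLines(c(">rRNA", paste0("GGGG", "AAACCCGGGTTTAAACCCGGGTTT", "GGGG")),
             contam)
  p <- preprocess_reads(fq, adapter, contaminants = contam)
  expect_equal(p$reads$read_id, "r2")
  expect_equal(unname(p$stats["contaminant_removed"]), 1L)
})

test_that("malformed FASTQ reports the record index", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "r2", "ACGT", "+", "IIII"), fq)
  expect_error(preprocess_reads(fq, adapter), "record at index 2")
  fq2 <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+"), fq2)
  expect_error(preprocess_reads(fq2, adapter), "multiple of 4")
})

test_that("A-site offsets follow the footprint-length rule", {
  ann <- tiny_ann()
  rd <- raw_reads(c("a", "b", "c", "d"), "tB.1",
                  pos = c(100L, 0L, 100L, 500L),
                  length = c(31L, 34L, 28L, 36L))
  out <- assign_a_site(rd, ann)
  expect_equal(out[read_id == "a", a_site], 117L)  # 17 nt downstream
  expect_equal(out[read_id == "b", a_site], 18L)   # 18 nt for 34-35
  expect_false(any(c("c", "d") %in% out$read_id))  # outside 29-35
  expect_equal(attr(out, "discarded_length"), 2L)
})

test_that("A-sites beyond the transcript end discard the mapping with a counter", {
  ann <- tiny_ann()
  rd <- raw_reads("a", "tC.1", pos = 290L, length = 31L)  # a_site 307 >= 300
  out <- assign_a_site(rd, ann)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "discarded_overflow"), 1L)
})

test_that("within-transcript multimappers resolve by region priority then 5'-most", {
  ann <- tiny_ann()  # tA.1: leader [0,100), acorf [100,400), utr3 [400,600)
  rd <- assign_a_site(raw_reads(
    c("r1", "r1", "r2", "r2", "r3", "r3"), "tA.1",
    pos = c(450L, 150L,  20L, 450L,  30L, 60L) - 17L), ann)
  res <- resolve_within_transcript(rd, ann)
  expect_equal(res[read_id == "r1", region], "acorf")   # acORF beats utr3
  expect_equal(res[read_id == "r2", region], "leader")  # leader beats utr3
  expect_equal(res[read_id == "r3", a_site], 30L)       # tie: 5'-most
})

test_that("multimapper weights are 1, 1/2, 1/3 at gene level and >3 discarded", {
  ann <- tiny_ann()
  base <- assign_a_site(raw_reads(
    c("m2", "m2", "iso", "iso"),
    c("tB.1", "tC.1", "tA.1", "tA.2"),
    pos = c(200L, 100L, 150L, 100L)), ann)
  w <- weight_multimappers(resolve_within_transcript(base, ann), ann)
  expect_equal(w[read_id == "m2", weight], c(0.5, 0.5))     # two genes
  expect_equal(w[read_id == "iso", weight], 1)              # one gene, 2 isoforms
  expect_equal(nrow(w[read_id == "iso"]), 1L)
  # a read hitting 4 gene-level locations is discarded
  ann4 <- ann_many(4L)
  r4 <- assign_a_site(raw_reads(rep("x", 4L), sprintf("t%04d", 1:4),
                                pos = rep(50L, 4L)), ann4)
  w4 <- weight_multimappers(resolve_within_transcript(r4, ann4), ann4)
  expect_equal(nrow(w4), 0L)
  expect_equal(attr(w4, "discarded_multimap"), 1L)
})

test_that("weighted totals never exceed read counts, equal iff unique", {
  sim <- periodicity_sim()$sim  # frac_multimap = 0
  rd0 <- process_ribo_reads(sim$reads[[1L]], sim$annotation)
  expect_equal(sum(rd0$weight), length(unique(rd0$read_id)))
  sim2 <- queue_sim()$sim  # default multimapper fraction
  rd1 <- process_ribo_reads(sim2$reads[[1L]], sim2$annotation)
  expect_lte(sum(rd1$weight), length(unique(rd1$read_id)))
  expect_lt(sum(rd1$weight), nrow(rd1))
})

test_that("alignments round-trip through the TSV dialect", {
  ann <- tiny_ann()
  rd <- raw_reads(c("r1", "r1", "r2"), c("tA.1", "tB.1", "tC.1"),
                  pos = c(100L, 200L, 50L), length = c(31L, 31L, 30L))
  path <- tempfile(fileext = ".tsv")
  write_alignments_tsv(rd, path)
  back <- read_alignments(path, ann, "tsv")
  expect_equal(as.data.frame(back), as.data.frame(rd), ignore_attr = TRUE)
})

test_that("SAM records group by read and reverse-strand records are dropped", {
  ann <- tiny_ann(with_seq = TRUE)
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", ann$transcripts$transcript_id,
            ann$transcripts$length),
    "r1\t0\ttA.1\t101\t255\t31M\t*\t0\t0\t*\t*",
    "r1\t256\ttB.1\t201\t255\t31M\t*\t0\t0\t*\t*",
    "r2\t16\ttC.1\t51\t255\t31M\t*\t0\t0\t*\t*"), sam)
  expect_warning(rd <- read_alignments(sam, ann, "sam"), "reverse-strand")
  expect_equal(attr(rd, "dropped_reverse"), 1L)
  expect_equal(nrow(rd[read_id == "r1"]), 2L)
  expect_equal(sort(rd[read_id == "r1", transcript_id]), c("tA.1", "tB.1"))
  expect_equal(rd[transcript_id == "tA.1", pos], 100L)  # 1-based SAM to 0-based
  expect_false("r2" %in% rd$read_id)
})

test_that("alignments to unknown references are rejected", {
  ann <- tiny_ann()
  path <- tempfile(fileext = ".tsv")
  write_alignments_tsv(raw_reads("r1", "ghost", 10L), path)
  expect_error(read_alignments(path, ann), "unknown transcript")
})

test_that("mRNA reads keep the 5' end, drop short reads, dedupe per gene", {
  ann <- tiny_ann()
  rd <- raw_reads(c("m1", "m1", "m2"), c("tA.1", "tA.2", "tB.1"),
                  pos = c(150L, 100L, 10L), length = c(50L, 50L, 15L))
  out <- process_mrna_reads(rd, ann)
  expect_equal(nrow(out), 1L)           # m2 under min length, m1 deduped
  expect_equal(out$weight, 1)
  expect_true(is.na(out$a_site))
})
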