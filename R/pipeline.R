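# End-to-end orchestration: configuration defaults mirroring the
# analysis parameters, and a driver wiring all stages together.

#' Pipeline parameter defaults
#'
#' Central record of every analysis parameter with its default:
#' `bin_size` 300 genes, `target_fdr` 0.10, A-site offsets 17 nt
#' (lengths 29--33) / 18 nt (34--35), `min_utr3_reads` 20 (strict),
#' `min_center_reads` 64 (strict), `periodicity_read_length` 31,
#' `first_n_codons` 50, metagene criteria (>= 100 alignments, length
#' > 600 nt, flanks > 45 nt), similarity density cutoff 1 footprint/nt,
#' `pseudocount` 1.
#'
#' @param ... Overrides of individual defaults.
#' @return Named list of parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    bin_size = 300L, min_last_bin = 50L, target_fdr = 0.10,
    pseudocount = 1,
    min_utr3_reads = 20, min_center_reads = 64,
    periodicity_read_length = 31L, first_n_codons = 50L,
    periodicity_min_covered = 50L, distortion_threshold = 0.35,
    leader_translated_min_reads = 10,
    metagene_min_alignments = 100, metagene_min_length = 600,
    metagene_min_flank = 45, metagene_downstream = 150L,
    similarity_min_density = 1, similarity_repeats = 10L,
    top_n_center_shift = 200L, seed = 1L)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  utils::modifyList(cfg, ov)
}

#' Run the full analysis pipeline on a simulated experiment
#'
#' Processes every sample's alignments (A-site assignment, region
#' priority, multimapper weighting), counts and normalizes per-gene
#' region tables, computes translation efficiency, calls differential
#' expression per signal for each time point against the reference,
#' builds start- and stop-anchored metagene profiles, and runs the
#' readthrough, leader-effect, center-of-density-shift and periodicity
#' screens. Deterministic given the configuration seed.
#'
#' @param sim A `ribo_sim` (or the result of [load_sim()]).
#' @param params A [pipeline_config()] list.
#' @param signals DE signals to call.
#' @param robust Also run the pause-peak robustness filter on the ribo
#'   DE calls (slower).
#' @return A list bundle with elements `processed` (reads per sample),
#'   `counts` (normalized combined table), `te`, `de` (list keyed
#'   `signal_time`), `metagene_start`, `metagene_stop`, `readthrough`,
#'   `leader_effect`, `center_shift`, `periodicity`, `accounting`.
#' @export
run_pipeline <- function(sim, params = pipeline_config(),
                         signals = c("ribo", "mrna", "te"),
                         robust = FALSE) {
  ann <- sim$annotation
  smp <- sim$samples
  processed <- list()
  accounting <- list()
  for (sid in smp$sample_id) {
    raw <- sim$reads[[sid]]
    lib <- smp[sample_id == sid, library_type]
    pr <- if (lib == "ribo") process_ribo_reads(raw, ann)
          else process_mrna_reads(raw, ann)
    processed[[sid]] <- pr
    st <- attr(pr, "stats")
    accounting[[sid]] <- if (is.null(st))
      c(input = length(unique(raw$read_id)),
        retained = length(unique(pr$read_id))) else st
    message(sprintf("[%s] %d reads in, %d retained", sid,
                    length(unique(raw$read_id)),
                    length(unique(pr$read_id))))
  }
  counts_raw <- data.table::rbindlist(lapply(smp$sample_id, function(sid) {
    m <- smp[sample_id == sid]
    count_gene_regions(processed[[sid]], ann, m$library_type, sid,
                       m$replicate, m$time_min)
  }))
  counts <- data.table::rbindlist(lapply(c("ribo", "mrna"), function(lib) {
    sub <- counts_raw[library_type == lib]
    if (nrow(sub) == 0L) return(sub)
    normalize_counts(sub)
  }))
  te <- if (all(c("ribo", "mrna") %in% smp$library_type))
    translation_efficiency(counts[library_type == "ribo"],
                           counts[library_type == "mrna"],
                           params$pseudocount) else NULL
  t0 <- min(smp$time_min)
  tps <- setdiff(sort(unique(smp$time_min)), t0)
  de <- list()
  have_both <- all(c("ribo", "mrna") %in% smp$library_type)
  for (sg in signals) {
    if (sg != "ribo" && !have_both) next
    if (sg == "ribo" && !"ribo" %in% smp$library_type) next
    for (tp in tps) {
      key <- paste0(sg, "_", tp)
      de[[key]] <- call_de(counts, signal = sg, time = tp,
                           reference_time = t0,
                           pseudocount = params$pseudocount,
                           bin_size = params$bin_size,
                           min_last_bin = params$min_last_bin,
                           target_fdr = params$target_fdr)
      message(sprintf("[de] %s: T=%.3f, est. FDR=%.3f, %d calls", key,
                      attr(de[[key]], "threshold"), attr(de[[key]], "fdr"),
                      sum(de[[key]]$label != "unchanged")))
    }
  }
  ribo_ids <- smp[library_type == "ribo", sample_id]
  ribo_reads <- processed[ribo_ids]
  pooled_ribo <- data.table::rbindlist(ribo_reads)
  mg_args <- list(ann = ann,
                  min_alignments = params$metagene_min_alignments,
                  min_length = params$metagene_min_length,
                  min_flank = params$metagene_min_flank)
  metagene_start <- try(do.call(metagene_profile,
    c(list(reads = pooled_ribo, anchor = "start",
           downstream = params$metagene_downstream), mg_args)), silent = TRUE)
  metagene_stop <- try(do.call(metagene_profile,
    c(list(reads = pooled_ribo, anchor = "stop",
           upstream = params$metagene_downstream), mg_args)), silent = TRUE)
  readthrough <- if (!is.null(ann$seq))
    screen_readthrough(ribo_reads, ann, params$min_utr3_reads) else NULL

  leader_eff <- NULL
  if ("ribo" %in% smp$library_type && length(tps)) {
    last <- max(tps)
    dk <- paste0("ribo_", last)
    if (!is.null(de[[dk]])) {
      leader_counts <- counts[library_type == "ribo",
                              .(leader = max(leader)), by = gene_id]
      data.table::setkey(leader_counts, gene_id)
      calls <- de[[dk]]
      lt <- leader_counts[data.table::J(calls$gene_id), leader] >=
        params$leader_translated_min_reads
      mean_lfc <- (calls$log2_fc_rep1 + calls$log2_fc_rep2) / 2
      leader_eff <- try(leader_effect(mean_lfc, lt), silent = TRUE)
    }
  }
  center_shift <- NULL
  if (length(tps)) {
    reps <- sort(unique(smp$replicate))
    rec <- lapply(reps, function(rp) {
      by_time <- lapply(sort(unique(smp$time_min)), function(tm) {
        sid <- smp[library_type == "ribo" & replicate == rp &
                     time_min == tm, sample_id]
        processed[[sid]]
      })
      names(by_time) <- paste0("t", sort(unique(smp$time_min)))
      center_shift_records(by_time, ann, time = paste0("t", max(tps)),
                           reference_time = paste0("t", t0),
                           min_reads = params$min_center_reads)
    })
    center_shift <- center_shift_screen(rec, params$top_n_center_shift)
  }
  periodicity <- periodicity_screen(pooled_ribo, ann,
                                    params$periodicity_read_length,
                                    params$first_n_codons,
                                    params$periodicity_min_covered,
                                    distortion_threshold = params$distortion_threshold)
  res <- list(processed = processed, counts = counts, te = te, de = de,
              metagene_start = metagene_start, metagene_stop = metagene_stop,
              readthrough = readthrough, leader_effect = leader_eff,
              center_shift = center_shift, periodicity = periodicity,
              accounting = accounting)
  if (robust && length(de)) {
    meta <- smp[library_type == "ribo",
                .(sample_id, replicate, time_min)]
    res$de_robust <- lapply(
      de[grep("^ribo_", names(de))], function(calls)
        robust_de_filter(ribo_reads, counts[library_type == "mrna"], ann,
                         calls, meta,
                         pseudocount = params$pseudocount,
                         bin_size = params$bin_size,
                         min_last_bin = params$min_last_bin,
                         target_fdr = params$target_fdr))
  }
  res
}

#' Load a simulated experiment written by [write_sim()]
#'
#' @param dir Directory produced by [write_sim()].
#' @param format Alignment format to read back.
#' @return A `ribo_sim`-shaped list usable with [run_pipeline()].
#' @export
load_sim <- function(dir, format = c("tsv", "sam")) {
  format <- match.arg(format)
  ann <- load_annotation(file.path(dir, "annotation.tsv"),
                         file.path(dir, "transcripts.fa"))
  truth <- data.table::fread(file.path(dir, "truth.tsv"))
  samples <- data.table::fread(file.path(dir, "manifest.tsv"))
  reads <- lapply(samples$sample_id, function(sid)
    read_alignments(file.path(dir, paste0(sid, ".", format)), ann, format))
  names(reads) <- samples$sample_id
  structure(list(annotation = ann, truth = truth, samples = samples,
                 reads = reads,
                 config = yaml::read_yaml(file.path(dir, "config.yaml"))),
            class = "ribo_sim")
}

#' Write the main pipeline tables to a directory
#'
#' @param res A [run_pipeline()] bundle.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_results <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(res$counts, file.path(dir, "counts.tsv"))
  for (k in names(res$de))
    write_de(res$de[[k]], file.path(dir, paste0("de_", k, ".tsv")))
  if (inherits(res$metagene_start, "ribo_metagene"))
    write_metagene(res$metagene_start, file.path(dir, "metagene_start.tsv"))
  if (inherits(res$metagene_stop, "ribo_metagene"))
    write_metagene(res$metagene_stop, file.path(dir, "metagene_stop.tsv"))
  if (!is.null(res$readthrough))
    data.table::fwrite(res$readthrough, file.path(dir, "readthrough.tsv"),
                       sep = "\t")
  if (!is.null(res$center_shift))
    data.table::fwrite(res$center_shift, file.path(dir, "center_shift.tsv"),
                       sep = "\t")
  data.table::fwrite(res$periodicity$records,
                     file.path(dir, "periodicity.tsv"), sep = "\t")
  invisible(dir)
}
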