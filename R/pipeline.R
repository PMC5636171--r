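#' Run the full retained-intron analysis pipeline
#'
#' Chains the package's stages end to end: simulate (or load) a
#' two-condition junction-count experiment, quantify Psi / delta-Psi /
#' Bayes factors with detection and significance filters, summarize the
#' direction of retention, annotate significant events for PTCs and NMD
#' susceptibility, score 3' splice-site strength and cis features, and (when
#' an event-type table is supplied) test per-category enrichment. All stage
#' outputs are written to `outdir` together with a machine-readable JSON
#' summary; the run is fully determined by the config seed.
#'
#' @param config A [sim_config()]. Its seed drives all randomness.
#' @param outdir Output directory (created if missing).
#' @param counts Optional replicate-level count table (data.frame or TSV
#'   path). When supplied, simulation of counts is skipped and
#'   sequence-feature stages run only if `sim` is also supplied.
#' @param sim Optional precomputed [generate_genome_annotation()] result.
#' @param event_type_table Optional data.frame (`category`, `n_detected`,
#'   `n_significant`) of the non-RI alternative-splicing categories; the RI
#'   row is replaced by this run's detected/significant counts and
#'   per-category enrichment is tested.
#' @param min_reads,grid_size,delta_psi_min,bf_min Quantification settings
#'   (defaults 20, 1001, 0.10, 20).
#' @param verbose Log stage progress to standard error.
#' @return Invisibly, the summary list (also written to
#'   `summary.json`).
#' @export
run_pipeline <- function(config = sim_config(), outdir = tempfile("ripsi_run_"),
                         counts = NULL, sim = NULL, event_type_table = NULL,
                         min_reads = 20L, grid_size = 1001L,
                         delta_psi_min = 0.10, bf_min = 20,
                         verbose = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = config$seed)

  # stage 1: inputs
  if (is.null(counts)) {
    if (is.null(sim)) {
      ri_log("simulate: generating genome, annotation and truth table",
             verbose = verbose)
      sim <- generate_genome_annotation(config)
    }
    counts <- simulate_counts(sim$truth, config)
    write_genome_fasta(sim$genome, file.path(outdir, "genome.fa"))
    write_models_gtf(sim$models, file.path(outdir, "annotation.gtf"))
    write_tsv_table(sim$truth, file.path(outdir, "truth.tsv"))
    ri_log("simulate: ", nrow(sim$truth), " events, ",
           sum(sim$truth$responsive), " responsive", verbose = verbose)
  } else if (is.character(counts)) {
    counts <- read_counts_tsv(counts)
  }
  write_tsv_table(counts, file.path(outdir, "counts.tsv"))
  write_config_yaml(config, file.path(outdir, "config.yaml"))

  # stage 2: quantification
  ri_log("quantify: ", length(unique(counts$event_id)), " events",
         verbose = verbose)
  results <- quantify_events(counts,
                             condition_a = config$condition_labels[1L],
                             condition_b = config$condition_labels[2L],
                             min_reads = min_reads, grid_size = grid_size,
                             delta_psi_min = delta_psi_min, bf_min = bf_min)
  write_tsv_table(results, file.path(outdir, "ri_results.tsv"))
  summary$n_events <- nrow(results)
  summary$n_detected <- sum(results$passes_detection)
  summary$n_significant <- sum(results$significant)
  ri_log("quantify: ", summary$n_detected, " detected, ",
         summary$n_significant, " significant", verbose = verbose)

  if (summary$n_significant > 0L) {
    dirf <- direction_fraction(results)
    summary$direction_fraction <- dirf$fraction
    summary$n_increased_retention <- dirf$n_positive
  }

  # stage 3: enrichment (optional input of the non-RI categories)
  if (!is.null(event_type_table)) {
    tab <- event_type_table[event_type_table$category != "RI", , drop = FALSE]
    tab <- rbind(tab, data.frame(category = "RI",
                                 n_detected = summary$n_detected,
                                 n_significant = summary$n_significant))
    enr <- event_type_enrichment(tab)
    write_tsv_table(enr, file.path(outdir, "event_type_enrichment.tsv"))
    summary$enrichment_p_adj <- stats::setNames(as.list(enr$p_adj), enr$category)
  }

  # stages 4-5 need sequences
  if (!is.null(sim)) {
    write_significant_bed(results, sim$events,
                          file.path(outdir, "significant_ri.bed"))
    ptc <- annotate_events_ptc(sim, results)
    write_tsv_table(ptc, file.path(outdir, "ptc_annotation.tsv"))
    summary$n_ptc <- sum(!is.na(ptc$stop_offset))
    summary$n_nmd_susceptible <- sum(ptc$nmd, na.rm = TRUE)
    ri_log("annotate-ptc: ", nrow(ptc), " significant events annotated",
           verbose = verbose)

    feats <- extract_event_features(sim)
    write_tsv_table(feats, file.path(outdir, "event_features.tsv"))
    cmp <- score_set_comparison(sim, results)
    if (!is.null(cmp)) {
      write_tsv_table(cmp$scores, file.path(outdir, "ss3_scores.tsv"))
      summary$score_comparison <- list(
        mean_significant = cmp$result$mean_a,
        mean_other = cmp$result$mean_b,
        difference = cmp$result$difference,
        test = cmp$result$test_name,
        p_value = cmp$result$p_value
      )
      ri_log("score-ss: ", cmp$result$test_name, " p = ",
             signif(cmp$result$p_value, 3), verbose = verbose)
    }
  } else {
    ri_log("sequence stages skipped: no genome/annotation available",
           verbose = verbose)
  }

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' PTC / NMD annotation of significant events of a simulated run
#'
#' Builds the intron-retained transcript for every significant event, scans
#' for the first in-frame stop, and applies the 50-nt NMD rule.
#'
#' @param sim A `ri_simulation`.
#' @param results Quantification table; only significant events are
#'   annotated (all events when `results` is NULL).
#' @return data.frame with one row per annotated event.
#' @export
annotate_events_ptc <- function(sim, results = NULL) {
  ids <- if (is.null(results)) names(sim$events)
         else results$event_id[isTRUE_vec(results$significant)]
  rows <- lapply(ids, function(ev_id) {
    ev <- sim$events[[ev_id]]
    model <- sim$models[[ev$transcript_id]]
    rt <- build_retained_transcript(model, ev, sim$genome)
    ann <- classify_nmd(scan_first_stop(rt), rt$junctions)
    data.frame(event_id = ev_id,
               stop_offset = ann$stop_offset,
               stop_codon = ann$stop_codon %||% NA_character_,
               in_intron = ann$located_in_intron,
               dist_last_junction = ann$distance_to_last_junction,
               nmd = ann$nmd_susceptible,
               aa_len = ann$truncated_aa_length,
               est_kda = ann$est_mass_kda,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(event_id = character(), stop_offset = integer(),
                      stop_codon = character(), in_intron = logical(),
                      dist_last_junction = integer(), nmd = logical(),
                      aa_len = integer(), est_kda = numeric())
  rownames(out) <- NULL
  out
}

#' Simple cis sequence features of every simulated event
#'
#' GC differential (intron vs downstream exon), nearest upstream AG
#' distance, and alternate-donor GTRAG positions in the event intron.
#'
#' @param sim A `ri_simulation`.
#' @return data.frame with one row per event.
#' @export
extract_event_features <- function(sim) {
  rows <- lapply(names(sim$events), function(ev_id) {
    ev <- sim$events[[ev_id]]
    chrom_seq <- genome_chrom(sim$genome, ev$chrom)
    orient <- function(iv) {
      s <- substr(chrom_seq, iv[1L] + 1L, iv[2L])
      if (ev$strand == "-") revcomp(s) else s
    }
    intron_seq <- orient(ev$intron)
    exon_seq <- orient(ev$exon_downstream)
    alt <- detect_alt_5ss(intron_seq)
    data.frame(event_id = ev_id,
               gc_diff = gc_differential(intron_seq, exon_seq),
               nearest_ag = nearest_upstream_ag(intron_seq),
               n_alt_5ss = length(alt),
               alt_5ss_positions = paste(alt, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# 3'SS strength comparison: significant (weakened) vs non-significant
# events, scored under a foreground model trained on non-significant
# (control) acceptor windows and a background model trained on decoys.
score_set_comparison <- function(sim, results) {
  sig_ids <- results$event_id[isTRUE_vec(results$significant)]
  other_ids <- setdiff(results$event_id, sig_ids)
  if (length(sig_ids) < 3L || length(other_ids) < 3L) return(NULL)
  windows <- vapply(sim$events, `[[`, "", "ss3_window")
  fg <- train_markov_3ss(unname(windows[other_ids]))
  bg <- train_markov_3ss(sim$ss3_background)
  scores <- score_3ss(windows[results$event_id], fg, bg)
  res <- compare_score_sets(unname(scores[sig_ids]), unname(scores[other_ids]))
  list(result = res,
       scores = data.frame(event_id = results$event_id,
                           score = unname(scores[results$event_id]),
                           significant = results$event_id %in% sig_ids,
                           stringsAsFactors = FALSE))
}
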