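# Synthetic two-condition retained-intron experiment: toy genome, gene
# models, truth table and replicated junction-count tables with planted
# retention effects, so every downstream stage can be verified in-process.

# base compositions used by the generator
COMP_BACKGROUND <- c(A = 0.27, C = 0.23, G = 0.23, T = 0.27)
COMP_PPT_STRONG <- c(A = 0.08, C = 0.36, G = 0.07, T = 0.49) # polypyrimidine tract

#' Configuration of the synthetic retained-intron experiment
#'
#' Defaults plant the study conditions the package is designed around: a
#' two-condition (normoxia vs hypoxia) design with 4 replicates per
#' condition, a designated EIF2B5-like gene whose retained intron gains
#' delta-Psi = 0.44 on a 0.10 baseline and whose 5' splice site spells an
#' in-frame stop codon, a 90% bias toward increased retention among
#' responsive introns, weakened 3' splice sites, and intron GC lowered by 6
#' percentage points relative to the downstream exon.
#'
#' @param n_genes Number of genes (one candidate RI event each).
#' @param exons_per_gene Exons per gene (>= 3, so every gene has >= 2
#'   introns).
#' @param exon_len_range,intron_len_range Length ranges in nt (introns must
#'   allow the 6-nt donor and 23-nt acceptor windows; minimum 40).
#' @param n_replicates_per_condition Replicates per condition (default 4).
#' @param fraction_responsive Fraction of events with a planted Psi change.
#' @param planted_delta_psi Delta-Psi of the designated event (default 0.44).
#' @param direction_bias Probability that a responsive event increases
#'   retention in condition B (default 0.90).
#' @param base_psi_range Range of baseline Psi values (condition A).
#' @param designated_base_psi Condition-A Psi of the designated event
#'   (default 0.10, a low normoxic baseline).
#' @param mean_depth Expected supporting reads per event and replicate.
#' @param nb_dispersion Negative-binomial dispersion k
#'   (variance `m + m^2/k`; default 10).
#' @param read_length,min_overhang Read geometry in nt (defaults 100 and 8).
#' @param weak_ss_mix Per-base probability of replacing the polypyrimidine
#'   tract base with a background base in responsive introns (default 0.5).
#' @param gc_shift Drop in GC fraction of responsive introns relative to the
#'   downstream exon (default 0.06).
#' @param condition_labels Length-2 character vector, reference first
#'   (default `c("normoxia", "hypoxia")`).
#' @param seed Integer seed; fully determines the generator's output.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 60L, exons_per_gene = 4L,
                       exon_len_range = c(90L, 210L),
                       intron_len_range = c(150L, 600L),
                       n_replicates_per_condition = 4L,
                       fraction_responsive = 0.3,
                       planted_delta_psi = 0.44,
                       direction_bias = 0.90,
                       base_psi_range = c(0.05, 0.50),
                       designated_base_psi = 0.10,
                       mean_depth = 500,
                       nb_dispersion = 10,
                       read_length = 100L,
                       min_overhang = 8L,
                       weak_ss_mix = 0.5,
                       gc_shift = 0.06,
                       condition_labels = c("normoxia", "hypoxia"),
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), exons_per_gene = as.integer(exons_per_gene),
              exon_len_range = as.integer(exon_len_range),
              intron_len_range = as.integer(intron_len_range),
              n_replicates_per_condition = as.integer(n_replicates_per_condition),
              fraction_responsive = fraction_responsive,
              planted_delta_psi = planted_delta_psi,
              direction_bias = direction_bias,
              base_psi_range = base_psi_range,
              designated_base_psi = designated_base_psi,
              mean_depth = mean_depth, nb_dispersion = nb_dispersion,
              read_length = as.integer(read_length),
              min_overhang = as.integer(min_overhang),
              weak_ss_mix = weak_ss_mix, gc_shift = gc_shift,
              condition_labels = condition_labels, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, why) if (!ok) stop("invalid '", field, "': ", why)
  chk(cfg$n_genes >= 1, "n_genes", "must be >= 1")
  chk(cfg$exons_per_gene >= 3, "exons_per_gene", "must be >= 3")
  chk(diff(cfg$exon_len_range) > 0 && cfg$exon_len_range[1] >= 30,
      "exon_len_range", "must be non-degenerate with minimum >= 30")
  chk(diff(cfg$intron_len_range) > 0 && cfg$intron_len_range[1] >= 40,
      "intron_len_range", "must be non-degenerate with minimum >= 40 (donor + acceptor windows)")
  chk(cfg$n_replicates_per_condition >= 1, "n_replicates_per_condition", "must be >= 1")
  chk(cfg$fraction_responsive >= 0 && cfg$fraction_responsive <= 1,
      "fraction_responsive", "must be in [0, 1]")
  chk(cfg$planted_delta_psi > 0 && cfg$planted_delta_psi < 1,
      "planted_delta_psi", "must be in (0, 1)")
  chk(cfg$direction_bias >= 0 && cfg$direction_bias <= 1,
      "direction_bias", "must be in [0, 1]")
  chk(cfg$base_psi_range[1] > 0 && cfg$base_psi_range[2] < 1 &&
        diff(cfg$base_psi_range) > 0,
      "base_psi_range", "must be a non-degenerate sub-interval of (0, 1)")
  chk(cfg$designated_base_psi > 0 &&
        cfg$designated_base_psi + cfg$planted_delta_psi < 1,
      "designated_base_psi", "0 < base and base + planted_delta_psi < 1 required")
  chk(cfg$mean_depth > 0, "mean_depth", "must be positive")
  chk(cfg$nb_dispersion > 0, "nb_dispersion", "must be positive")
  chk(cfg$read_length > 2 * cfg$min_overhang, "read_length",
      "must exceed 2 * min_overhang")
  chk(cfg$weak_ss_mix >= 0 && cfg$weak_ss_mix <= 1, "weak_ss_mix", "must be in [0, 1]")
  chk(abs(cfg$gc_shift) < 0.5, "gc_shift", "must have magnitude < 0.5")
  chk(length(cfg$condition_labels) == 2 &&
        !anyDuplicated(cfg$condition_labels), "condition_labels",
      "must be two distinct labels")
  invisible(cfg)
}

sample_comp <- function(n, comp) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = comp[DNA_BASES]), collapse = "")
}

comp_for_gc <- function(gc) {
  gc <- min(max(gc, 0.05), 0.95)
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

# acceptor window: 18 tract bases + AG (last 20 intronic nt)
sample_3ss_tail <- function(weak, weak_mix) {
  tract <- vapply(seq_len(18L), function(i) {
    comp <- if (weak && stats::runif(1) < weak_mix) COMP_BACKGROUND else COMP_PPT_STRONG
    sample(DNA_BASES, 1L, prob = comp[DNA_BASES])
  }, "")
  paste0(paste(tract, collapse = ""), "AG")
}

#' Generate a toy genome, annotation, and truth table
#'
#' Builds one gene per chromosome with canonical GT..AG introns on random
#' strands. One candidate retained-intron event is designated per gene. The
#' first gene is the designated EIF2B5-like gene: its event intron starts
#' with a GT(A/G)A donor so that retention spells an in-frame stop when the
#' upstream CDS phase is 2 (which the generator enforces), and its planted
#' Psi difference equals `planted_delta_psi`. Responsive introns receive
#' acceptor windows mixed toward background composition (`weak_ss_mix`) and
#' an intron body whose GC is lowered by `gc_shift` relative to the realized
#' GC of the downstream exon. Coding sequence is laid down as stop-free
#' sense codons so the designated PTC is the first in-frame stop.
#'
#' @param config A [sim_config()].
#' @return Object of class `ri_simulation`: list with `genome`
#'   (`Biostrings::DNAStringSet`), `models` (list of `transcript_model`),
#'   `events` (list of `intron_event`), `truth` (data.frame), `ss3_background`
#'   (decoy 23-mers for background model training), and `config`.
#' @export
generate_genome_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  n_resp <- round(config$fraction_responsive * n)
  sample_vec <- function(x, k) x[sample.int(length(x), k)]
  responsive_ids <- if (n_resp > 0)
    c(1L, sample_vec(setdiff(seq_len(n), 1L), max(n_resp - 1L, 0L)))
  else integer()
  # directions planted as an exact proportion of responsive events (which
  # events go up is random); the designated event always goes up
  up_ids <- integer()
  if (n_resp > 0) {
    n_up <- max(1L, round(config$direction_bias * n_resp))
    others <- setdiff(responsive_ids, 1L)
    up_ids <- c(1L, sample_vec(others, min(length(others), n_up - 1L)))
  }
  genome <- character(n)
  models <- vector("list", n)
  events <- vector("list", n)
  truth <- vector("list", n)
  senses <- sense_codons()
  senses_no_ta <- senses[substr(senses, 1L, 2L) != "TA"]

  for (g in seq_len(n)) {
    gene_id <- sprintf("gene%03d", g)
    tx_id <- paste0(gene_id, ".t1")
    chrom <- sprintf("chr%03d", g)
    designated <- g == 1L
    responsive <- g %in% responsive_ids
    strand <- if (designated) "+" else sample(c("+", "-"), 1L)

    n_ex <- config$exons_per_gene
    ex_len <- sample(seq(config$exon_len_range[1], config$exon_len_range[2]), n_ex,
                     replace = TRUE)
    in_len <- sample(seq(config$intron_len_range[1], config$intron_len_range[2]),
                     n_ex - 1L, replace = TRUE)
    k <- if (designated) max(2L, (n_ex - 1L) %/% 2L + 1L)
         else sample(seq_len(n_ex - 1L), 1L)

    # planted Psi values
    if (designated && responsive) {
      psi_a <- config$designated_base_psi
      psi_b <- psi_a + config$planted_delta_psi
      direction <- "up"
    } else if (responsive && !designated) {
      delta <- stats::runif(1, 0.15, 0.45)
      up <- g %in% up_ids
      if (up) {
        psi_a <- stats::runif(1, config$base_psi_range[1],
                              min(config$base_psi_range[2], 0.96 - delta))
        psi_b <- psi_a + delta
        direction <- "up"
      } else {
        psi_a <- stats::runif(1, max(config$base_psi_range[1], delta + 0.04), 0.96)
        psi_b <- psi_a - delta
        direction <- "down"
      }
    } else {
      psi_a <- psi_b <- stats::runif(1, config$base_psi_range[1],
                                     config$base_psi_range[2])
      direction <- "none"
    }

    # CDS layout: 5' UTR, sense-codon CDS across exons ending in TAA, 3' UTR
    cds_offset <- 30L
    utr3_len <- 30L
    if (designated) {
      # force upstream CDS phase 2 at the event intron start
      phase <- (sum(ex_len[seq_len(k)]) - cds_offset) %% 3L
      ex_len[k] <- ex_len[k] + (2L - phase) %% 3L
    }
    total_ex <- sum(ex_len)
    coding_len <- total_ex - cds_offset - utr3_len
    coding_len <- coding_len - (coding_len %% 3L)
    n_codons <- coding_len %/% 3L - 1L
    codons <- sample(senses, n_codons, replace = TRUE)
    if (designated) {
      # the codon split by the event intron must not start TA (which would
      # put the first stop just upstream of the intron as ..TA|G..)
      split_codon <- ((sum(ex_len[seq_len(k)]) - cds_offset) %/% 3L) + 1L
      if (split_codon <= n_codons && substr(codons[split_codon], 1L, 2L) == "TA")
        codons[split_codon] <- sample(senses_no_ta, 1L)
    }
    exonic <- paste0(sample_comp(cds_offset, COMP_BACKGROUND),
                     paste(codons, collapse = ""), "TAA",
                     sample_comp(total_ex - cds_offset - 3L * n_codons - 3L,
                                 COMP_BACKGROUND))
    exon_seqs <- character(n_ex)
    off <- 0L
    for (i in seq_len(n_ex)) {
      exon_seqs[i] <- substr(exonic, off + 1L, off + ex_len[i])
      off <- off + ex_len[i]
    }

    # intron sequences, transcribed orientation
    intron_seqs <- character(n_ex - 1L)
    for (i in seq_len(n_ex - 1L)) {
      is_event <- i == k
      donor <- if (designated && is_event) {
        paste0("GT", sample(c("A", "G"), 1L), "A",
               sample_comp(2L, COMP_BACKGROUND))
      } else {
        paste0("GT", sample_comp(4L, COMP_BACKGROUND))
      }
      acceptor <- sample_3ss_tail(weak = responsive && is_event,
                                  weak_mix = config$weak_ss_mix)
      body_gc <- if (responsive && is_event) {
        gc_fraction(exon_seqs[i + 1L]) - config$gc_shift
      } else if (is_event) {
        gc_fraction(exon_seqs[i + 1L])
      } else 0.45
      body <- sample_comp(in_len[i] - 26L, comp_for_gc(body_gc))
      intron_seqs[i] <- paste0(donor, body, acceptor)
    }

    # assemble the chromosome (transcribed orientation first)
    pieces <- character(2L * n_ex - 1L)
    pieces[seq(1L, 2L * n_ex - 1L, by = 2L)] <- exon_seqs
    pieces[seq(2L, 2L * n_ex - 2L, by = 2L)] <- intron_seqs
    body_tx <- paste(pieces, collapse = "")
    pad5 <- sample_comp(50L, COMP_BACKGROUND)
    pad3 <- sample_comp(50L, COMP_BACKGROUND)
    chrom_seq_tx <- paste0(pad5, body_tx, pad3)
    chrom_seq <- if (strand == "-") revcomp(chrom_seq_tx) else chrom_seq_tx
    genome[g] <- chrom_seq

    # genomic exon coordinates (0-based half-open)
    piece_len <- c(50L, rbind(ex_len, c(in_len, NA))[!is.na(rbind(ex_len, c(in_len, NA)))], 50L)
    starts_tx <- cumsum(c(0L, piece_len[-length(piece_len)]))
    total_len <- sum(piece_len)
    # transcript-orientation intervals of exons: pieces 2, 4, ... (after pad)
    ex_idx <- 1L + seq(1L, 2L * n_ex - 1L, by = 2L)
    ex_tx <- cbind(starts_tx[ex_idx], starts_tx[ex_idx] + ex_len)
    in_idx <- 1L + seq(2L, 2L * n_ex - 2L, by = 2L)
    in_tx <- cbind(starts_tx[in_idx], starts_tx[in_idx] + in_len)
    to_genomic <- function(iv) {
      if (strand == "+") iv else cbind(total_len - iv[, 2L], total_len - iv[, 1L])
    }
    ex_gen <- to_genomic(ex_tx)
    in_gen <- to_genomic(in_tx)
    ord <- order(ex_gen[, 1L])
    models[[g]] <- transcript_model(tx_id, gene_id, chrom, strand,
                                    ex_gen[ord, , drop = FALSE], cds_offset)

    # ex_gen / in_gen rows are indexed in transcribed order; each row is a
    # valid genomic interval on either strand
    event_id <- sprintf("%s.ri%d", gene_id, k)
    events[[g]] <- intron_event(
      event_id, gene_id, tx_id, chrom, strand,
      intron = in_gen[k, ],
      exon_upstream = ex_gen[k, ],
      exon_downstream = ex_gen[k + 1L, ],
      ss5_window = substr(intron_seqs[k], 1L, 6L),
      ss3_window = paste0(substr(intron_seqs[k], in_len[k] - 19L, in_len[k]),
                          substr(exon_seqs[k + 1L], 1L, 3L))
    )

    truth[[g]] <- data.frame(
      event_id = event_id, gene_id = gene_id, transcript_id = tx_id,
      chrom = chrom, strand = strand, intron_index = k,
      intron_length = in_len[k],
      psi_a = psi_a, psi_b = psi_b,
      responsive = responsive,
      direction = direction,
      ptc_planted = designated,
      weak_3ss = responsive,
      designated = designated,
      stringsAsFactors = FALSE
    )
  }

  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  ss3_background <- vapply(seq_len(250L),
                           function(i) sample_comp(23L, COMP_BACKGROUND), "")
  structure(list(
    genome = Biostrings::DNAStringSet(stats::setNames(genome, sprintf("chr%03d", seq_len(n)))),
    models = stats::setNames(models, vapply(models, `[[`, "", "transcript_id")),
    events = stats::setNames(events, vapply(events, `[[`, "", "event_id")),
    truth = truth,
    ss3_background = ss3_background,
    config = config
  ), class = "ri_simulation")
}

#' @export
print.ri_simulation <- function(x, ...) {
  cat(sprintf("ri_simulation: %d genes / events, %d responsive, seed %d\n",
              nrow(x$truth), sum(x$truth$responsive), x$config$seed))
  invisible(x)
}

#' Simulate replicate-level junction counts from a truth table
#'
#' For every event, condition and replicate, the total supporting reads `N`
#' are drawn from a negative binomial with mean `mean_depth` and dispersion
#' `nb_dispersion` (variance `m + m^2/k`); inclusion reads
#' `I ~ Binomial(N, w(psi_true))` with the same length-weighted mixture `w`
#' used in quantification; exclusion reads `E = N - I`. Inclusion reads are
#' split into 5' junction, intron body and 3' junction counts by a
#' multinomial proportional to the sub-region effective lengths.
#'
#' @param truth Truth table from [generate_genome_annotation()] (columns
#'   `event_id`, `intron_length`, `psi_a`, `psi_b` are used).
#' @param config The same [sim_config()] used for generation.
#' @return Count data.frame with columns `event_id`, `sample_id`,
#'   `condition`, `I_body`, `I_junc5`, `I_junc3`, `E`, `L_inc`, `L_exc`.
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  needed <- c("event_id", "intron_length", "psi_a", "psi_b")
  if (!all(needed %in% names(truth)))
    stop("truth table must contain columns: ", paste(needed, collapse = ", "))
  if (anyDuplicated(truth$event_id)) stop("duplicate event ids in truth table")
  set.seed(config$seed + 1L)
  reps <- config$n_replicates_per_condition
  lj <- config$read_length - 2L * config$min_overhang + 1L
  L_exc <- lj
  L_inc <- truth$intron_length + L_exc
  body_w <- pmax(L_inc - 2L * lj, 0L)

  grid <- expand.grid(rep = seq_len(reps), ci = 1:2,
                      ev = seq_len(nrow(truth)))
  psi <- ifelse(grid$ci == 1L, truth$psi_a[grid$ev], truth$psi_b[grid$ev])
  li <- L_inc[grid$ev]
  bw <- body_w[grid$ev]
  n <- nrow(grid)
  w <- psi_to_read_weight(psi, li, L_exc)
  N <- stats::rnbinom(n, size = config$nb_dispersion, mu = config$mean_depth)
  I <- stats::rbinom(n, N, w)
  # sequential multinomial split of I over (junc5, body, junc3) regions
  j5 <- stats::rbinom(n, I, lj / (2L * lj + bw))
  j3 <- stats::rbinom(n, I - j5, lj / (lj + bw))
  body <- I - j5 - j3
  cond <- config$condition_labels[grid$ci]
  data.frame(
    event_id = truth$event_id[grid$ev],
    sample_id = sprintf("%s_rep%d", cond, grid$rep),
    condition = cond,
    I_body = body, I_junc5 = j5, I_junc3 = j3,
    E = N - I,
    L_inc = li, L_exc = L_exc,
    stringsAsFactors = FALSE
  )
}
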