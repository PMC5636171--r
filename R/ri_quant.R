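#' Effective lengths for inclusion and exclusion isoforms
#'
#' Number of distinct read-start positions supporting the intron-retained
#' (inclusion) and spliced (exclusion) isoforms of a retained-intron event.
#' A read supports exclusion when it spans the exon-exon junction with at
#' least `min_overhang` nucleotides on each side; it supports inclusion when
#' it overlaps the intron by at least `min_overhang` nucleotides.
#'
#' @param intron_length Intron length in nucleotides (>= 1).
#' @param read_length Read length in nucleotides; must exceed
#'   `2 * min_overhang`.
#' @param min_overhang Minimum junction/intron overhang in nucleotides.
#' @return Named numeric vector with elements `L_inc` and `L_exc`, where
#'   `L_exc = read_length - 2*min_overhang + 1` and
#'   `L_inc = intron_length + L_exc`.
#' @examples
#' effective_lengths(100, 100, 8)  # L_inc = 185, L_exc = 85
#' @export
effective_lengths <- function(intron_length, read_length = 100L, min_overhang = 8L) {
  if (any(read_length <= 2 * min_overhang))
    stop("read_length must exceed 2 * min_overhang")
  if (any(intron_length < 1)) stop("intron_length must be >= 1")
  L_exc <- read_length - 2 * min_overhang + 1
  c(L_inc = intron_length + L_exc, L_exc = L_exc)
}

#' Pool replicate counts for one condition
#'
#' Sums junction and body counts component-wise across all replicates of the
#' given condition, per event, mirroring the merging of replicate alignment
#' files into a single file per treatment before quantification. Effective
#' lengths are annotation properties and must agree across replicates.
#'
#' @param counts Count table (data.frame) with columns `event_id`,
#'   `sample_id`, `condition`, `I_body`, `I_junc5`, `I_junc3`, `E`, `L_inc`,
#'   `L_exc`.
#' @param condition Condition label to pool.
#' @return A data.frame with one row per event: summed counts, unchanged
#'   effective lengths, `condition` set to the pooled label, and
#'   `n_replicates` recording how many samples were merged.
#' @export
pool_replicates <- function(counts, condition) {
  rows <- counts[counts$condition == condition, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no replicates found for condition '", condition, "'")
  split_rows <- split(rows, rows$event_id)
  pooled <- lapply(split_rows, function(d) {
    if (length(unique(d$L_inc)) != 1L || length(unique(d$L_exc)) != 1L)
      stop("inconsistent effective lengths across replicates of event '",
           d$event_id[1L], "'")
    data.frame(
      event_id = d$event_id[1L], condition = condition,
      I_body = sum(d$I_body), I_junc5 = sum(d$I_junc5), I_junc3 = sum(d$I_junc3),
      E = sum(d$E), L_inc = d$L_inc[1L], L_exc = d$L_exc[1L],
      n_replicates = nrow(d), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pooled)
  rownames(out) <- NULL
  out
}

# mixture weight: probability that a supporting read comes from the
# inclusion isoform when a fraction psi of transcripts retain the intron
psi_to_read_weight <- function(psi, L_inc, L_exc) {
  psi * L_inc / (psi * L_inc + (1 - psi) * L_exc)
}

#' Posterior over percent spliced in (Psi) for one pooled event
#'
#' Two-isoform binomial mixture with length weighting: given `I` inclusion
#' reads and `E` exclusion reads, `I ~ Binomial(I + E, w(psi))` with
#' `w(psi) = psi * L_inc / (psi * L_inc + (1 - psi) * L_exc)`. The posterior
#' under a uniform prior is evaluated on an equally spaced grid on \[0, 1\].
#' The length-corrected closed-form point estimate
#' `psi_hat = (I/L_inc) / (I/L_inc + E/L_exc)` is reported alongside.
#'
#' @param pooled One pooled event: a one-row data.frame or list with
#'   `I_body`, `I_junc5`, `I_junc3`, `E`, `L_inc`, `L_exc`.
#' @param grid_size Number of grid points (default 1001).
#' @return An object of class `psi_posterior`: list with `grid`, `mass`
#'   (normalized probabilities), `mean`, `map`, `ci95` (equal-tailed),
#'   `psi_hat`, and the inputs `I`, `E`, `L_inc`, `L_exc`.
#' @export
estimate_psi <- function(pooled, grid_size = 1001L) {
  I <- pooled$I_body + pooled$I_junc5 + pooled$I_junc3
  E <- pooled$E
  if (length(I) != 1L) stop("estimate_psi expects a single pooled event")
  if (I + E < 1) stop("undefined posterior: no supporting reads (I + E = 0)")
  L_inc <- pooled$L_inc
  L_exc <- pooled$L_exc
  grid <- seq(0, 1, length.out = grid_size)
  ll <- stats::dbinom(I, I + E, psi_to_read_weight(grid, L_inc, L_exc), log = TRUE)
  m <- max(ll[is.finite(ll)])
  lik <- exp(ll - m)
  lik[!is.finite(ll)] <- 0
  mass <- lik / sum(lik)
  cdf <- cumsum(mass)
  psi_hat <- if (I + E == 0) NA_real_ else (I / L_inc) / (I / L_inc + E / L_exc)
  structure(list(
    grid = grid, mass = mass,
    mean = sum(grid * mass),
    map = grid[which.max(mass)],
    ci95 = c(grid[which(cdf >= 0.025)[1L]], grid[which(cdf >= 0.975)[1L]]),
    psi_hat = psi_hat,
    log_lik = ll, I = I, E = E, L_inc = L_inc, L_exc = L_exc
  ), class = "psi_posterior")
}

#' @export
print.psi_posterior <- function(x, ...) {
  cat(sprintf("Psi posterior (grid %d): mean %.4f, MAP %.4f, 95%% CI [%.3f, %.3f], psi_hat %.4f\n",
              length(x$grid), x$mean, x$map, x$ci95[1L], x$ci95[2L], x$psi_hat))
  invisible(x)
}

#' Delta-Psi and Bayes factor between two conditions for one event
#'
#' Estimates per-condition Psi posteriors and compares the model in which
#' each condition has its own Psi (independent uniform priors) against the
#' model sharing a single Psi. The Bayes factor is the ratio of marginal
#' likelihoods `m1/m0` with `m1 = int L_A dpsi * int L_B dpsi` and
#' `m0 = int L_A(psi) L_B(psi) dpsi`, each integral by the trapezoid rule on
#' the grid. An event is `significant` when it passes detection and
#' `|delta_psi| > delta_psi_min` and `bayes_factor >= bf_min` (strict for
#' delta-Psi, inclusive for the Bayes factor).
#'
#' @param pooled_a,pooled_b Pooled counts for condition A (reference, e.g.
#'   normoxia) and condition B (e.g. hypoxia); see [estimate_psi()].
#' @param grid_size Grid points for posteriors and integrals.
#' @param passes_detection Detection-filter flag carried into the result
#'   (see [apply_detection_filter()]).
#' @param delta_psi_min,bf_min Significance thresholds (defaults 0.10
#'   and 20).
#' @return Object of class `delta_psi_result`: list with `delta_psi`
#'   (posterior mean B minus A), `bayes_factor`, `log10_bf`, per-condition
#'   posteriors, and flags `passes_detection`, `significant`.
#' @export
delta_psi_bayes_factor <- function(pooled_a, pooled_b, grid_size = 1001L,
                                   passes_detection = TRUE,
                                   delta_psi_min = 0.10, bf_min = 20) {
  post_a <- estimate_psi(pooled_a, grid_size)
  post_b <- estimate_psi(pooled_b, grid_size)
  h <- 1 / (grid_size - 1)
  log_m1 <- log_trapz(post_a$log_lik, h) + log_trapz(post_b$log_lik, h)
  log_m0 <- log_trapz(post_a$log_lik + post_b$log_lik, h)
  log_bf <- log_m1 - log_m0
  delta <- post_b$mean - post_a$mean
  bf <- exp(log_bf)
  structure(list(
    delta_psi = delta,
    bayes_factor = bf,
    log10_bf = log_bf / log(10),
    posterior_a = post_a, posterior_b = post_b,
    passes_detection = isTRUE(passes_detection),
    significant = isTRUE(passes_detection) && abs(delta) > delta_psi_min && bf >= bf_min
  ), class = "delta_psi_result")
}

#' Detection filter on pooled read support
#'
#' Retains an event only if its pooled supporting reads (inclusion plus
#' exclusion) reach `min_reads` in *both* conditions, the count filter used
#' at event identification.
#'
#' @param counts Replicate-level count table (see [pool_replicates()]).
#' @param min_reads Minimum pooled `I + E` per condition (default 20).
#' @param conditions Length-2 character vector of condition labels; defaults
#'   to the sorted unique labels present.
#' @return Character vector of retained event ids (subset of input events).
#' @export
apply_detection_filter <- function(counts, min_reads = 20L, conditions = NULL) {
  conditions <- conditions %||% sort(unique(counts$condition))
  if (length(conditions) != 2L)
    stop("expected exactly 2 conditions, got: ", paste(conditions, collapse = ", "))
  keep <- NULL
  for (cond in conditions) {
    pooled <- pool_replicates(counts, cond)
    tot <- pooled$I_body + pooled$I_junc5 + pooled$I_junc3 + pooled$E
    ok <- pooled$event_id[tot >= min_reads]
    keep <- if (is.null(keep)) ok else intersect(keep, ok)
  }
  sort(keep)
}

#' Quantify all retained-intron events in a two-condition count table
#'
#' Pools replicates per condition, applies the detection filter, and runs the
#' Psi posterior / delta-Psi / Bayes-factor machinery on every event.
#'
#' @param counts Replicate-level count table.
#' @param condition_a,condition_b Reference and stress condition labels
#'   (delta-Psi is B minus A). Default to the sorted unique labels.
#' @param min_reads,grid_size,delta_psi_min,bf_min See
#'   [apply_detection_filter()] and [delta_psi_bayes_factor()].
#' @return data.frame with one row per event: `event_id`, `psi_a`, `psi_b`
#'   (posterior means), `psi_hat_a`, `psi_hat_b`, `delta_psi`,
#'   `bayes_factor`, `log10_bf`, `passes_detection`, `significant`.
#' @export
quantify_events <- function(counts, condition_a = NULL, condition_b = NULL,
                            min_reads = 20L, grid_size = 1001L,
                            delta_psi_min = 0.10, bf_min = 20) {
  conds <- sort(unique(counts$condition))
  condition_a <- condition_a %||% conds[1L]
  condition_b <- condition_b %||% setdiff(conds, condition_a)[1L]
  pooled_a <- pool_replicates(counts, condition_a)
  pooled_b <- pool_replicates(counts, condition_b)
  detected <- apply_detection_filter(counts, min_reads,
                                     conditions = c(condition_a, condition_b))
  events <- sort(intersect(pooled_a$event_id, pooled_b$event_id))
  rows <- lapply(events, function(ev) {
    pa <- pooled_a[pooled_a$event_id == ev, ]
    pb <- pooled_b[pooled_b$event_id == ev, ]
    if (pa$I_body + pa$I_junc5 + pa$I_junc3 + pa$E < 1 ||
        pb$I_body + pb$I_junc5 + pb$I_junc3 + pb$E < 1) {
      return(data.frame(event_id = ev, psi_a = NA_real_, psi_b = NA_real_,
                        psi_hat_a = NA_real_, psi_hat_b = NA_real_,
                        delta_psi = NA_real_, bayes_factor = NA_real_,
                        log10_bf = NA_real_, passes_detection = FALSE,
                        significant = FALSE, stringsAsFactors = FALSE))
    }
    res <- delta_psi_bayes_factor(pa, pb, grid_size,
                                  passes_detection = ev %in% detected,
                                  delta_psi_min = delta_psi_min, bf_min = bf_min)
    data.frame(event_id = ev,
               psi_a = res$posterior_a$mean, psi_b = res$posterior_b$mean,
               psi_hat_a = res$posterior_a$psi_hat, psi_hat_b = res$posterior_b$psi_hat,
               delta_psi = res$delta_psi, bayes_factor = res$bayes_factor,
               log10_bf = res$log10_bf,
               passes_detection = res$passes_detection,
               significant = res$significant, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of significant events with increased retention
#'
#' Among events flagged significant, the fraction whose delta-Psi is
#' positive (more retention in condition B than condition A).
#'
#' @param results Result table from [quantify_events()].
#' @return List with `fraction`, `n_positive`, `n_significant`.
#' @export
direction_fraction <- function(results) {
  sig <- results[isTRUE_vec(results$significant), , drop = FALSE]
  if (nrow(sig) == 0L) stop("no significant events: direction fraction undefined")
  n_pos <- sum(sig$delta_psi > 0)
  list(fraction = n_pos / nrow(sig), n_positive = n_pos, n_significant = nrow(sig))
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Per-category enrichment of significant splicing events
#'
#' For each alternative-splicing category, compares the proportion of
#' significant events in that category against the pooled complement of all
#' other categories with a two-sample test for equality of proportions
#' (chi-square with Yates continuity correction), then adjusts across
#' categories by Benjamini-Hochberg.
#'
#' @param table data.frame with columns `category`, `n_detected`,
#'   `n_significant` (one row per category, e.g. A3SS, A5SS, AFE, ALE, MXE,
#'   RI, SE, TUTR).
#' @return data.frame with per-category proportions, chi-square statistic,
#'   raw `p_value` and BH-adjusted `p_adj`. Categories with zero detected
#'   events are skipped with a warning.
#' @export
event_type_enrichment <- function(table) {
  stopifnot(all(c("category", "n_detected", "n_significant") %in% names(table)))
  if (any(table$n_significant > table$n_detected))
    stop("n_significant exceeds n_detected in some category")
  zero <- table$n_detected == 0
  if (any(zero)) {
    warning("skipping categories with zero detected events: ",
            paste(table$category[zero], collapse = ", "))
    table <- table[!zero, , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(table)), function(i) {
    x1 <- table$n_significant[i]; n1 <- table$n_detected[i]
    x2 <- sum(table$n_significant[-i]); n2 <- sum(table$n_detected[-i])
    st <- prop_test_2sample(x1, n1, x2, n2, yates = TRUE)
    data.frame(category = table$category[i],
               prop_category = x1 / n1, prop_rest = x2 / n2,
               statistic = st$statistic, p_value = st$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_fdr(out$p_value)
  rownames(out) <- NULL
  out
}

#' Write significant retained introns as BED6
#'
#' @param results Result table from [quantify_events()].
#' @param events List of `intron_event` objects (coordinates of each event).
#' @param path Output BED file path.
#' @return Invisibly, the GRanges written. Score is `1000 * |delta_psi|`
#'   capped at 1000.
#' @export
write_significant_bed <- function(results, events, path) {
  sig <- results[isTRUE_vec(results$significant), , drop = FALSE]
  ev_by_id <- stats::setNames(events, vapply(events, `[[`, "", "event_id"))
  sel <- ev_by_id[sig$event_id]
  if (nrow(sig) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = vapply(sel, `[[`, "", "chrom"),
      ranges = IRanges::IRanges(
        start = vapply(sel, function(e) e$intron[1L], 0) + 1L,
        end = vapply(sel, function(e) e$intron[2L], 0)),
      strand = vapply(sel, `[[`, "", "strand"),
      name = sig$event_id,
      score = pmin(1000, round(1000 * abs(sig$delta_psi)))
    )
  }
  rtracklayer::export(gr, path, format = "bed")
  invisible(gr)
}
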