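#' Train a position-specific first-order Markov splice-site model
#'
#' Estimates an initial base distribution for the first window position and,
#' for every later position, a 4x4 conditional distribution
#' `P(x_i | x_{i-1})` from aligned windows of equal width. Counts are
#' smoothed with pseudocount `alpha` per cell, `(c + alpha) / (sum(c) + 4 alpha)`,
#' so all probabilities are strictly positive for `alpha > 0`. The default
#' window is the 23-mer 3' splice-site context: intron positions -20..-1
#' plus exon positions +1..+3.
#'
#' @param sequences Character vector of equal-length ACGT windows. Sequences
#'   with a deviant length or non-ACGT characters are rejected with a
#'   summary warning.
#' @param pseudocount Additive smoothing per count cell (default 0.5).
#' @param W Expected window width; defaults to the width of the first usable
#'   sequence.
#' @return Object of class `markov_3ss`: list with `W`, `initial`
#'   (length-4 probability vector), `trans` (list of 4x4 matrices, one per
#'   position 2..W, rows = preceding base, columns = current base),
#'   `pseudocount`, `n_train`.
#' @export
train_markov_3ss <- function(sequences, pseudocount = 0.5, W = NULL) {
  sequences <- toupper(sequences)
  W <- W %||% nchar(sequences[is_acgt(sequences)][1L])
  if (is.na(W) || length(W) == 0L) stop("no usable training sequence to set the window width")
  usable <- nchar(sequences) == W & is_acgt(sequences)
  if (any(!usable))
    warning(sum(!usable), " of ", length(sequences),
            " training sequences rejected (wrong length or non-ACGT)")
  sequences <- sequences[usable]
  if (length(sequences) == 0L) stop("no usable training sequences")
  mat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  tab <- function(x) {
    counts <- table(factor(x, levels = DNA_BASES))
    as.numeric(counts)
  }
  initial <- (tab(mat[, 1L]) + pseudocount) /
    (length(sequences) + 4 * pseudocount)
  names(initial) <- DNA_BASES
  trans <- vector("list", W)
  for (i in seq(2L, W)) {
    m <- matrix(pseudocount, 4L, 4L, dimnames = list(DNA_BASES, DNA_BASES))
    counts <- table(factor(mat[, i - 1L], levels = DNA_BASES),
                    factor(mat[, i], levels = DNA_BASES))
    m <- m + as.matrix(counts)
    trans[[i]] <- m / rowSums(m)
  }
  structure(list(W = W, initial = initial, trans = trans,
                 pseudocount = pseudocount, n_train = length(sequences)),
            class = "markov_3ss")
}

#' Log2 probability of windows under a Markov splice-site model
#'
#' Chain-rule product of the initial and per-position conditional
#' probabilities, in bits.
#'
#' @param model A `markov_3ss`.
#' @param sequences Character vector of ACGT windows of width `model$W`.
#' @return Numeric vector of log2 probabilities.
#' @export
markov_log2_prob <- function(model, sequences) {
  sequences <- toupper(sequences)
  if (any(nchar(sequences) != model$W)) stop("sequence width must equal model W")
  if (any(!is_acgt(sequences))) stop("sequences must be ACGT only")
  vapply(sequences, function(s) {
    b <- split_chars(s)
    lp <- log2(model$initial[[b[1L]]])
    for (i in seq(2L, model$W))
      lp <- lp + log2(model$trans[[i]][b[i - 1L], b[i]])
    lp
  }, 0, USE.NAMES = FALSE)
}

#' Splice-site strength score
#'
#' Log-odds of a window under a foreground (true splice site) model versus a
#' background (decoy) model, in bits:
#' `score = log2 P(seq | foreground) - log2 P(seq | background)`.
#'
#' @param sequences Character vector of ACGT windows.
#' @param foreground,background `markov_3ss` models of equal width.
#' @return Numeric vector of scores (bits), named by sequence when the input
#'   is named.
#' @export
score_3ss <- function(sequences, foreground, background) {
  if (foreground$W != background$W)
    stop("foreground and background models have different window widths")
  out <- markov_log2_prob(foreground, sequences) -
    markov_log2_prob(background, sequences)
  names(out) <- names(sequences)
  out
}

#' Sample windows from a Markov splice-site model
#'
#' @param model A `markov_3ss`.
#' @param n Number of windows to draw.
#' @return Character vector of `n` windows of width `model$W`.
#' @export
sample_markov_3ss <- function(model, n) {
  vapply(seq_len(n), function(i) {
    b <- character(model$W)
    b[1L] <- sample(DNA_BASES, 1L, prob = model$initial)
    for (j in seq(2L, model$W))
      b[j] <- sample(DNA_BASES, 1L, prob = model$trans[[j]][b[j - 1L], ])
    paste(b, collapse = "")
  }, "")
}

#' Compare two sets of splice-site strength scores
#'
#' Normality-gated two-group comparison (see [normality_gated_compare()])
#' of score sets, reporting group means and their difference.
#'
#' @param scores_a,scores_b Numeric score vectors (e.g. retained-intron 3'
#'   splice sites vs a control set).
#' @param alpha Normality-gate level.
#' @return `stat_result` with extra fields `mean_a`, `mean_b`,
#'   `difference` (A minus B).
#' @export
compare_score_sets <- function(scores_a, scores_b, alpha = 0.05) {
  res <- normality_gated_compare(list(A = scores_a, B = scores_b), alpha = alpha)
  res$mean_a <- mean(scores_a)
  res$mean_b <- mean(scores_b)
  res$difference <- res$mean_a - res$mean_b
  res
}

#' GC-content differential between an intron and its adjacent exon
#'
#' @param intron_seq,exon_seq Non-empty sequences; N bases are excluded from
#'   both numerator and denominator.
#' @return GC%(intron) minus GC%(exon), in percentage points.
#' @export
gc_differential <- function(intron_seq, exon_seq) {
  100 * (gc_fraction(intron_seq) - gc_fraction(exon_seq))
}

#' Distance from the 3' splice-site AG to the nearest upstream AG
#'
#' Scans the intron for AG dinucleotides upstream of the terminal 3' splice
#' site AG and returns the distance between their start positions. A short
#' distance is a feature of weak acceptor context.
#'
#' @param intron_seq Intron sequence, transcribed orientation, ending in AG
#'   (a warning is raised otherwise).
#' @param exclude_3ss_ag Exclude the terminal AG itself from the candidates
#'   (default TRUE).
#' @return Integer distance in nt, or `NA_integer_` when no other AG exists
#'   or the intron is shorter than 4 nt.
#' @export
nearest_upstream_ag <- function(intron_seq, exclude_3ss_ag = TRUE) {
  n <- nchar(intron_seq)
  if (n < 4L) return(NA_integer_)
  if (substr(intron_seq, n - 1L, n) != "AG")
    warning("intron does not end in AG")
  starts <- ag_positions(intron_seq)
  terminal <- n - 1L
  cand <- if (exclude_3ss_ag) setdiff(starts, terminal) else starts
  cand <- cand[cand < terminal]
  if (length(cand) == 0L) return(NA_integer_)
  as.integer(terminal - max(cand))
}

ag_positions <- function(seq) {
  b <- split_chars(seq)
  which(b[-length(b)] == "A" & b[-1L] == "G")
}

#' Scan a sequence for motif occurrences
#'
#' Motifs may be IUPAC degenerate strings (matched exactly over their
#' degeneracy) or position weight matrices (4-row numeric matrices with
#' rownames A, C, G, T; matches at or above `pwm_min_score`, interpreted on
#' the matrix's own score scale, e.g. log-odds). Matching uses
#' `Biostrings` fixed-pattern and PWM machinery.
#'
#' @param seq Subject sequence (ACGT).
#' @param motifs Named list (or character vector) of motifs.
#' @param pwm_min_score Minimum PWM score for a match (default 80% of the
#'   maximal score, `"80%"`; a numeric value is treated as an absolute
#'   threshold).
#' @return data.frame with columns `motif`, `n_matches`, and a list column
#'   `positions` of 1-based start positions. Malformed motifs are skipped
#'   with a warning.
#' @export
scan_motifs <- function(seq, motifs, pwm_min_score = "80%") {
  if (is.character(motifs)) motifs <- as.list(motifs)
  if (is.null(names(motifs)))
    names(motifs) <- vapply(seq_along(motifs), function(i) {
      if (is.character(motifs[[i]])) motifs[[i]] else paste0("pwm", i)
    }, "")
  subject <- Biostrings::DNAString(toupper(seq))
  rows <- lapply(names(motifs), function(nm) {
    m <- motifs[[nm]]
    hit_starts <- tryCatch({
      if (is.character(m)) {
        if (!grepl("^[ACGTRYSWKMBDHVN]+$", toupper(m)))
          stop("not an IUPAC motif")
        Biostrings::start(Biostrings::matchPattern(
          Biostrings::DNAString(toupper(m)), subject, fixed = FALSE))
      } else if (is.matrix(m) && nrow(m) == 4L) {
        rownames(m) <- rownames(m) %||% DNA_BASES
        Biostrings::start(Biostrings::matchPWM(m, subject,
                                               min.score = pwm_min_score))
      } else stop("motif must be an IUPAC string or a 4-row matrix")
    }, error = function(e) {
      warning("skipping malformed motif '", nm, "': ", conditionMessage(e))
      NULL
    })
    if (is.null(hit_starts)) return(NULL)
    data.frame(motif = nm, n_matches = length(hit_starts),
               positions = I(list(as.integer(hit_starts))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(motif = character(), n_matches = integer(),
                      positions = I(list()))
  rownames(out) <- NULL
  out
}

#' Candidate alternate 5' splice sites
#'
#' Positions of GTRAG (R = A or G) donor-consensus matches in a downstream
#' intron, 5' to 3'.
#'
#' @param seq Sequence to scan (transcribed orientation).
#' @return Integer vector of 1-based start positions (possibly empty).
#' @export
detect_alt_5ss <- function(seq) {
  hits <- scan_motifs(seq, c(alt_5ss = "GTRAG"))
  sort(hits$positions[[1L]])
}
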