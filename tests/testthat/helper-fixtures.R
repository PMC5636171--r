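# Shared fixtures built in code.

make_counts_row <- function(event_id = "ev1", sample_id = "s1",
                            condition = "normoxia", I_body = 10L,
                            I_junc5 = 5L, I_junc3 = 5L, E = 10L,
                            L_inc = 185, L_exc = 85) {
  data.frame(event_id = event_id, sample_id = sample_id, condition = condition,
             I_body = I_body, I_junc5 = I_junc5, I_junc3 = I_junc3, E = E,
             L_inc = L_inc, L_exc = L_exc, stringsAsFactors = FALSE)
}

pooled_event <- function(I = 50L, E = 50L, L_inc = 185, L_exc = 85) {
  list(I_body = I, I_junc5 = 0L, I_junc3 = 0L, E = E,
       L_inc = L_inc, L_exc = L_exc)
}

# independent fine-grid quadrature oracle for the Psi posterior mean and the
# Bayes factor (midpoint-free Riemann / trapezoid at G = 1e5); kept separate
# from the package implementation on purpose
oracle_psi_mean <- function(I, E, L_inc, L_exc, G = 1e5) {
  psi <- seq(0, 1, length.out = G)
  w <- psi * L_inc / (psi * L_inc + (1 - psi) * L_exc)
  ll <- dbinom(I, I + E, w, log = TRUE)
  lik <- exp(ll - max(ll[is.finite(ll)]))
  lik[!is.finite(ll)] <- 0
  sum(psi * lik) / sum(lik)
}

oracle_log_bf <- function(Ia, Ea, Ib, Eb, L_inc, L_exc, G = 1e5) {
  psi <- seq(0, 1, length.out = G)
  h <- 1 / (G - 1)
  w <- psi * L_inc / (psi * L_inc + (1 - psi) * L_exc)
  trapz_log <- function(ll) {
    m <- max(ll[is.finite(ll)])
    f <- exp(ll - m); f[!is.finite(ll)] <- 0
    m + log(h * (sum(f) - (f[1] + f[length(f)]) / 2))
  }
  lla <- dbinom(Ia, Ia + Ea, w, log = TRUE)
  llb <- dbinom(Ib, Ib + Eb, w, log = TRUE)
  trapz_log(lla) + trapz_log(llb) - trapz_log(lla + llb)
}

# tiny two-exon-plus-intron genome for ORF tests
toy_gene <- function(strand = "+") {
  # transcribed-orientation pieces
  exon1 <- "ATGGCCAAATTTGGGCCCAAA"            # 21 nt, starts ATG, stop-free
  intron <- "GTAAGTTTTTTTTTTTTTTTTTTTTTTCCCCCCCCCCCCCCCCCTTTTTTTTTTTTTTTTTTAG" # 65 nt
  exon2 <- "GCCGCTGCAGCTGCTGCAGCGGCTTAA"      # 27 nt, ends in stop
  exon3 <- "GCTGCAGCTGCAGCTGCAGCT"            # 21 nt
  intron2 <- "GTCTCTCTCTCTCTCTCTCTCTCTCTCTCTCTCTCTCTAG" # 40 nt
  tx <- paste0(exon1, intron, exon2, intron2, exon3)
  chrom_seq <- if (strand == "-") {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(tx)))
  } else tx
  lens <- c(nchar(exon1), nchar(intron), nchar(exon2), nchar(intron2), nchar(exon3))
  starts_tx <- cumsum(c(0, lens[-5]))
  iv_tx <- cbind(starts_tx, starts_tx + lens)
  total <- sum(lens)
  to_gen <- function(iv) if (strand == "+") iv else cbind(total - iv[, 2], total - iv[, 1])
  ex_gen <- to_gen(iv_tx[c(1, 3, 5), , drop = FALSE])
  in_gen <- to_gen(iv_tx[c(2, 4), , drop = FALSE])
  ord <- order(ex_gen[, 1])
  model <- transcript_model("t1", "g1", "chrT", strand, ex_gen[ord, ], cds_offset = 0L)
  # transcribed-order intron indexing: intron 1 between exon1 and exon2
  intron1_gen <- if (strand == "+") in_gen[1, ] else in_gen[1, ]
  event <- intron_event("g1.ri1", "g1", "t1", "chrT", strand,
                        intron = in_gen[1, ],
                        exon_upstream = to_gen(iv_tx[1, , drop = FALSE])[1, ],
                        exon_downstream = to_gen(iv_tx[3, , drop = FALSE])[1, ],
                        ss5_window = substr(intron, 1, 6),
                        ss3_window = paste0(substr(intron, nchar(intron) - 19,
                                                   nchar(intron)),
                                            substr(exon2, 1, 3)))
  list(genome = stats::setNames(c(chrom_seq), "chrT"), model = model,
       event = event, pieces = list(exon1 = exon1, intron = intron,
                                    exon2 = exon2, intron2 = intron2,
                                    exon3 = exon3))
}

random_acgt <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""), "")
}
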