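# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# 61 sense codons (standard table), used to build stop-free coding sequence
sense_codons <- function() {
  all3 <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1L, paste, collapse = "")
  setdiff(all3, STOP_CODONS)
}

#' @noRd
random_dna <- function(n, gc = 0.5) {
  stopifnot(gc >= 0, gc <= 1)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

split_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

gc_fraction <- function(x) {
  b <- split_chars(toupper(x))
  b <- b[b != "N"]
  if (length(b) == 0L) stop("sequence contains no non-N bases")
  mean(b %in% c("G", "C"))
}

is_acgt <- function(x) grepl("^[ACGT]+$", x)

# log of trapezoid-rule integral of exp(log_f) over a uniform grid with step h
log_trapz <- function(log_f, h) {
  finite <- is.finite(log_f)
  if (!any(finite)) return(-Inf)
  m <- max(log_f[finite])
  f <- exp(log_f - m)
  f[!finite] <- 0
  m + log(h * (sum(f) - (f[1L] + f[length(f)]) / 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ri_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message("[ripsi] ", ...)
}
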