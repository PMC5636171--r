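# Coordinates are 0-based half-open on the genome throughout this module;
# transcript offsets are 0-based. GTF I/O (io.R) converts to 1-based inclusive.

#' Construct a transcript model
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Integer matrix with two columns (`start`, `end`), 0-based
#'   half-open genomic intervals sorted by genomic start, non-overlapping.
#' @param cds_offset 0-based offset of the CDS start in transcript
#'   coordinates (transcribed orientation).
#' @return Object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds_offset = 0L) {
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L || any(exons[, 2L] <= exons[, 1L]))
    stop("exons must be non-empty intervals with end > start")
  if (is.unsorted(exons[, 1L], strictly = TRUE) && nrow(exons) > 1L)
    stop("exons must be sorted by genomic start")
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("exons overlap")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  tx_len <- sum(exons[, 2L] - exons[, 1L])
  if (cds_offset < 0L || tx_len < cds_offset + 3L)
    stop("CDS offset outside the transcript")
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons,
                 cds_offset = as.integer(cds_offset)),
            class = "transcript_model")
}

#' Construct a retained-intron event
#'
#' @param event_id,gene_id,transcript_id Identifiers.
#' @param chrom,strand Location.
#' @param intron Length-2 integer vector, 0-based half-open genomic interval
#'   of the intron (length >= 4).
#' @param exon_upstream,exon_downstream Flanking exon intervals (genomic,
#'   0-based half-open).
#' @param ss5_window First 6 intronic nt, transcribed orientation.
#' @param ss3_window Last 20 intronic nt plus first 3 exonic nt (23-mer),
#'   transcribed orientation.
#' @return Object of class `intron_event`.
#' @export
intron_event <- function(event_id, gene_id, transcript_id, chrom, strand,
                         intron, exon_upstream, exon_downstream,
                         ss5_window = NA_character_, ss3_window = NA_character_) {
  intron <- as.integer(intron)
  if (diff(intron) < 4L) stop("intron must be at least 4 nt")
  if (!is.na(ss5_window) && nchar(ss5_window) != 6L) stop("ss5_window must be 6 nt")
  if (!is.na(ss3_window) && nchar(ss3_window) != 23L) stop("ss3_window must be 23 nt")
  structure(list(event_id = event_id, gene_id = gene_id,
                 transcript_id = transcript_id, chrom = chrom, strand = strand,
                 intron = intron, exon_upstream = as.integer(exon_upstream),
                 exon_downstream = as.integer(exon_downstream),
                 ss5_window = ss5_window, ss3_window = ss3_window),
            class = "intron_event")
}

# transcript sequence of a model (spliced), transcribed orientation
spliced_sequence <- function(model, genome) {
  chrom_seq <- genome_chrom(genome, model$chrom)
  pieces <- apply(model$exons, 1L, function(iv) substr(chrom_seq, iv[1L] + 1L, iv[2L]))
  s <- paste(pieces, collapse = "")
  if (model$strand == "-") revcomp(s) else s
}

genome_chrom <- function(genome, chrom) {
  if (methods::is(genome, "DNAStringSet")) {
    if (!chrom %in% names(genome)) stop("chromosome '", chrom, "' not in genome")
    return(as.character(genome[[chrom]]))
  }
  if (!chrom %in% names(genome)) stop("chromosome '", chrom, "' not in genome")
  genome[[chrom]]
}

#' Build the intron-retained transcript
#'
#' Inserts the event's intron into the spliced transcript, reverse
#' complementing for minus-strand genes, and records the transcript-coordinate
#' positions of the *remaining* exon-exon junctions (the retained intron's
#' own former junction is absent). Junction positions are the number of
#' nucleotides 5' of the junction. By default only the retained intron's
#' junction is removed; downstream junctions remain unless `read_through`
#' names additional intron indices to retain conceptually (their junctions
#' are then dropped from the list as well).
#'
#' @param model A `transcript_model`.
#' @param event An `intron_event` whose intron lies between two consecutive
#'   exons of the model.
#' @param genome Named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences.
#' @param read_through Optional integer vector of further intron indices
#'   (1-based, transcribed order) whose junctions should also be removed.
#' @return Object of class `retained_transcript`: list with `seq`
#'   (transcribed orientation), `junctions` (0-based transcript positions),
#'   `cds_offset`, `intron_span` (0-based half-open transcript interval of
#'   the retained intron), and source ids.
#' @export
build_retained_transcript <- function(model, event, genome, read_through = integer()) {
  n_ex <- nrow(model$exons)
  # genomic index of the retained intron: gap between exon k and exon k+1
  gaps_start <- model$exons[-n_ex, 2L]
  gaps_end <- model$exons[-1L, 1L]
  k_genomic <- which(gaps_start == event$intron[1L] & gaps_end == event$intron[2L])
  if (length(k_genomic) != 1L)
    stop("event intron is not internal to transcript '", model$transcript_id, "'")
  chrom_seq <- genome_chrom(genome, model$chrom)
  exon_seqs <- apply(model$exons, 1L, function(iv) substr(chrom_seq, iv[1L] + 1L, iv[2L]))
  intron_seq <- substr(chrom_seq, event$intron[1L] + 1L, event$intron[2L])

  # assemble in genomic order with the intron inserted, then orient
  genomic_seq <- paste(c(exon_seqs[seq_len(k_genomic)], intron_seq,
                         exon_seqs[seq(k_genomic + 1L, n_ex)]), collapse = "")
  seq <- if (model$strand == "-") revcomp(genomic_seq) else genomic_seq

  intron_tx <- check_intron_boundaries(intron_seq, model$strand, event$event_id)

  # transcribed-order exon lengths and retained-intron index
  ex_len <- model$exons[, 2L] - model$exons[, 1L]
  if (model$strand == "-") {
    ex_len <- rev(ex_len)
    k_tx <- n_ex - k_genomic
  } else {
    k_tx <- k_genomic
  }
  intron_len <- diff(event$intron)
  # cumulative transcript position after exon i (with the intron inserted)
  pos <- cumsum(ex_len) + ifelse(seq_len(n_ex) > k_tx, intron_len, 0L)
  removed <- unique(c(k_tx, as.integer(read_through)))
  junctions <- pos[setdiff(seq_len(n_ex - 1L), removed)]
  intron_span <- c(sum(ex_len[seq_len(k_tx)]), sum(ex_len[seq_len(k_tx)]) + intron_len)

  structure(list(seq = seq, junctions = as.integer(junctions),
                 cds_offset = model$cds_offset,
                 intron_span = as.integer(intron_span),
                 intron_index = k_tx,
                 transcript_id = model$transcript_id,
                 event_id = event$event_id),
            class = "retained_transcript")
}

check_intron_boundaries <- function(intron_seq, strand, event_id) {
  tx <- if (strand == "-") revcomp(intron_seq) else intron_seq
  if (substr(tx, 1L, 2L) != "GT" || substr(tx, nchar(tx) - 1L, nchar(tx)) != "AG")
    warning("non-canonical intron boundaries (not GT..AG) for event '", event_id, "'")
  tx
}

#' First in-frame stop codon of an intron-retained transcript
#'
#' Scans codons from the CDS start and returns the first whose triplet is
#' TAA, TAG, or TGA, together with whether it falls inside the retained
#' intron and the length of the truncated protein it implies.
#'
#' @param rt A `retained_transcript`.
#' @return Object of class `ptc_annotation`: list with `stop_offset`
#'   (0-based transcript position of the stop codon, or `NA` when the ORF
#'   runs off the end), `stop_codon`, `located_in_intron`,
#'   `truncated_aa_length` (codons before the stop), `est_mass_kda`, and
#'   `open_ended` flag; NMD fields are filled by [classify_nmd()].
#' @export
scan_first_stop <- function(rt) {
  seq <- rt$seq
  start <- rt$cds_offset
  if (nchar(seq) < start + 3L) stop("sequence too short for the CDS offset")
  n_codons <- (nchar(seq) - start) %/% 3L
  for (i in seq_len(n_codons)) {
    off <- start + 3L * (i - 1L)
    codon <- substr(seq, off + 1L, off + 3L)
    if (codon %in% STOP_CODONS) {
      aa <- i - 1L
      return(structure(list(
        event_id = rt$event_id, stop_offset = off, stop_codon = codon,
        located_in_intron = off >= rt$intron_span[1L] && off + 3L <= rt$intron_span[2L],
        truncated_aa_length = aa, est_mass_kda = estimate_protein_mass(max(aa, 1L)),
        open_ended = FALSE, nmd_susceptible = NA,
        distance_to_last_junction = NA_integer_
      ), class = "ptc_annotation"))
    }
  }
  structure(list(event_id = rt$event_id, stop_offset = NA_integer_,
                 stop_codon = NA_character_, located_in_intron = NA,
                 truncated_aa_length = NA_integer_, est_mass_kda = NA_real_,
                 open_ended = TRUE, nmd_susceptible = FALSE,
                 distance_to_last_junction = NA_integer_),
            class = "ptc_annotation")
}

#' Classify NMD susceptibility by the 50-nt rule
#'
#' A stop codon is recognised as premature by nonsense-mediated decay
#' surveillance when it lies more than 50 nucleotides upstream of the final
#' exon-exon junction of the transcript. The distance is measured from the
#' 3' end of the stop codon to the last junction; `distance > 50` means
#' susceptible (strictly more than 50), a stop at or downstream of the last
#' junction is not, and a transcript with no remaining junctions is not.
#'
#' @param annotation A `ptc_annotation` from [scan_first_stop()].
#' @param junctions Integer vector of remaining exon-exon junction positions
#'   (0-based transcript coordinates).
#' @return The annotation with `nmd_susceptible` and
#'   `distance_to_last_junction` filled in.
#' @export
classify_nmd <- function(annotation, junctions) {
  if (isTRUE(annotation$open_ended) || is.na(annotation$stop_offset)) {
    annotation$nmd_susceptible <- FALSE
    return(annotation)
  }
  if (length(junctions) == 0L) {
    annotation$nmd_susceptible <- FALSE
    annotation$distance_to_last_junction <- NA_integer_
    return(annotation)
  }
  stop_end <- annotation$stop_offset + 3L
  dist <- max(junctions) - stop_end
  annotation$distance_to_last_junction <- as.integer(dist)
  annotation$nmd_susceptible <- dist > 50L
  annotation
}

#' Stop codon embedded in a 5' splice site
#'
#' The 5' splice-site consensus GURAGU can spell a stop codon: when the
#' upstream CDS phase is 2 a codon boundary falls immediately before window
#' position 2, and positions 2-4 read TAA or TGA in the retained transcript.
#'
#' @param ss5_window 6-nt intronic window (transcribed orientation,
#'   DNA alphabet).
#' @param upstream_cds_phase Number of coding nucleotides modulo 3 upstream
#'   of the intron (0, 1, or 2).
#' @return The stop codon (`"TAA"` or `"TGA"`) or `NA_character_`.
#' @export
detect_5ss_stop <- function(ss5_window, upstream_cds_phase) {
  if (nchar(ss5_window) != 6L) stop("ss5_window must be exactly 6 nt")
  if (!upstream_cds_phase %in% 0:2) stop("upstream_cds_phase must be 0, 1 or 2")
  if (substr(ss5_window, 1L, 2L) != "GT")
    warning("non-canonical 5' splice site (does not start GT)")
  triplet <- substr(ss5_window, 2L, 4L)
  if (upstream_cds_phase == 2L && triplet %in% c("TAA", "TGA")) triplet
  else NA_character_
}

#' Approximate protein mass from residue count
#'
#' Uses the standard mean residue mass of 110 Da.
#'
#' @param aa_length Number of residues (>= 1).
#' @return Mass in kDa, rounded to one decimal.
#' @export
estimate_protein_mass <- function(aa_length) {
  if (any(aa_length < 1)) stop("aa_length must be >= 1")
  round(aa_length * 0.110, 1L)
}

#' @export
print.ptc_annotation <- function(x, ...) {
  if (isTRUE(x$open_ended)) {
    cat("Open-ended ORF: no in-frame stop before the transcript end\n")
  } else {
    cat(sprintf("PTC %s at offset %d (%s), %d aa (~%.1f kDa), %s junction distance %s, NMD: %s\n",
                x$stop_codon, x$stop_offset,
                if (isTRUE(x$located_in_intron)) "in retained intron" else "outside intron",
                x$truncated_aa_length, x$est_mass_kda, "last",
                ifelse(is.na(x$distance_to_last_junction), "NA",
                       x$distance_to_last_junction),
                ifelse(is.na(x$nmd_susceptible), "unclassified",
                       x$nmd_susceptible)))
  }
  invisible(x)
}
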