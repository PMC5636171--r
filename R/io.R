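# File formats: FASTA via Biostrings, GTF/BED via rtracklayer, TSV via
# base utils. Internal coordinates are 0-based half-open; GTF is written and
# read as 1-based inclusive.

#' Write a genome to FASTA
#'
#' @param genome `Biostrings::DNAStringSet` (or named character vector).
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Read a genome FASTA
#'
#' Sequences are upper-cased on read.
#'
#' @param path FASTA file.
#' @return `Biostrings::DNAStringSet`.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  Biostrings::DNAStringSet(toupper(x))
}

#' Write transcript models to GTF
#'
#' Emits `transcript`, `exon` and `CDS`-start-bearing features with
#' `gene_id`/`transcript_id` attributes, converting internal 0-based
#' half-open coordinates to 1-based inclusive. The CDS offset is carried as
#' a `start_codon`-like 3-nt `CDS` feature at the CDS start so models
#' round-trip.
#'
#' @param models List of `transcript_model` objects.
#' @param path Output GTF path.
#' @export
write_models_gtf <- function(models, path) {
  feats <- lapply(models, function(m) {
    n_ex <- nrow(m$exons)
    tx_start <- min(m$exons[, 1L]) + 1L
    tx_end <- max(m$exons[, 2L])
    cds_gen <- transcript_to_genomic(m, m$cds_offset, 3L)
    data.frame(
      chrom = m$chrom,
      start = c(tx_start, m$exons[, 1L] + 1L, cds_gen[1L] + 1L),
      end = c(tx_end, m$exons[, 2L], cds_gen[2L]),
      strand = m$strand,
      type = c("transcript", rep("exon", n_ex), "CDS"),
      gene_id = m$gene_id, transcript_id = m$transcript_id,
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = df$strand, source = "ripsi",
                               type = df$type,
                               phase = ifelse(df$type == "CDS", 0L, NA_integer_),
                               gene_id = df$gene_id,
                               transcript_id = df$transcript_id)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

# genomic interval (0-based half-open) of `len` transcript nucleotides
# starting at transcript offset `off` (may span a junction; returns the
# covering genomic range of the first exon segment's start to keep the
# feature simple: here only used for the 3-nt CDS anchor, which the
# generator always places inside one exon)
transcript_to_genomic <- function(m, off, len) {
  ex <- m$exons
  ex_len <- ex[, 2L] - ex[, 1L]
  order_tx <- if (m$strand == "-") rev(seq_len(nrow(ex))) else seq_len(nrow(ex))
  remaining <- off
  for (i in order_tx) {
    if (remaining < ex_len[i]) {
      if (m$strand == "+") {
        s <- ex[i, 1L] + remaining
        return(c(s, min(s + len, ex[i, 2L])))
      } else {
        e <- ex[i, 2L] - remaining
        return(c(max(e - len, ex[i, 1L]), e))
      }
    }
    remaining <- remaining - ex_len[i]
  }
  stop("transcript offset beyond transcript end")
}

#' Read transcript models from GTF
#'
#' Parses `exon` features grouped by `transcript_id` (1-based inclusive,
#' converted to internal 0-based half-open) and recovers the CDS offset from
#' the 3-nt `CDS` anchor feature when present (0 otherwise).
#'
#' @param path GTF file.
#' @return Named list of `transcript_model` objects.
#' @export
read_models_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  cds <- gr[gr$type == "CDS"]
  out <- lapply(split(ex, ex$transcript_id), function(e) {
    exons <- cbind(GenomicRanges::start(e) - 1L, GenomicRanges::end(e))
    exons <- exons[order(exons[, 1L]), , drop = FALSE]
    strand <- as.character(GenomicRanges::strand(e))[1L]
    tx_id <- e$transcript_id[1L]
    cds_offset <- 0L
    this_cds <- cds[cds$transcript_id == tx_id]
    if (length(this_cds) > 0L) {
      cds_gen <- c(GenomicRanges::start(this_cds)[1L] - 1L,
                   GenomicRanges::end(this_cds)[1L])
      cds_offset <- genomic_to_transcript_offset(exons, strand, cds_gen)
    }
    transcript_model(tx_id, e$gene_id[1L],
                     as.character(GenomicRanges::seqnames(e))[1L],
                     strand, exons, cds_offset)
  })
  out[order(names(out))]
}

genomic_to_transcript_offset <- function(exons, strand, cds_gen) {
  ex_len <- exons[, 2L] - exons[, 1L]
  n <- nrow(exons)
  if (strand == "+") {
    off <- 0L
    for (i in seq_len(n)) {
      if (cds_gen[1L] >= exons[i, 1L] && cds_gen[1L] < exons[i, 2L])
        return(off + cds_gen[1L] - exons[i, 1L])
      off <- off + ex_len[i]
    }
  } else {
    off <- 0L
    for (i in rev(seq_len(n))) {
      if (cds_gen[2L] > exons[i, 1L] && cds_gen[2L] <= exons[i, 2L])
        return(off + exons[i, 2L] - cds_gen[2L])
      off <- off + ex_len[i]
    }
  }
  stop("CDS anchor outside exons")
}

#' Read or write a counts / truth / results TSV table
#'
#' Plain tab-separated tables with a header row.
#'
#' @param x data.frame to write.
#' @param path File path.
#' @return `read_tsv_table` returns a data.frame.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Read a counts TSV and validate its columns
#'
#' @param path TSV with columns `event_id`, `sample_id`, `condition`,
#'   `I_body`, `I_junc5`, `I_junc3`, `E`, `L_inc`, `L_exc`.
#' @return Validated data.frame.
#' @export
read_counts_tsv <- function(path) {
  counts <- read_tsv_table(path)
  needed <- c("event_id", "sample_id", "condition", "I_body", "I_junc5",
              "I_junc3", "E", "L_inc", "L_exc")
  missing <- setdiff(needed, names(counts))
  if (length(missing) > 0L)
    stop("counts file missing columns: ", paste(missing, collapse = ", "))
  num <- c("I_body", "I_junc5", "I_junc3", "E")
  for (col in num) {
    if (any(counts[[col]] < 0) || any(counts[[col]] != round(counts[[col]])))
      stop("column '", col, "' must contain non-negative integers")
  }
  if (any(counts$L_inc <= 0) || any(counts$L_exc <= 0))
    stop("effective lengths must be positive")
  counts
}

#' Write a sim_config echo as YAML
#'
#' @param config A `sim_config` (or plain named list).
#' @param path Output YAML path.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
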