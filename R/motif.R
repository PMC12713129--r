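#' Scan a promoter sequence for E-box motifs
#'
#' The canonical E-box CACGTG is its own reverse complement, so it is
#' scanned on the forward strand only and each site reported once with
#' strand `"+"`. With `include_noncanonical = TRUE` the degenerate class
#' CANNTG is scanned on both strands; a position matching from both
#' strands is collapsed to a single hit (forward strand wins). Hits use
#' 0-based half-open coordinates (BED convention), sorted by start;
#' overlapping hits are all reported. `N` in the sequence never matches.
#'
#' @param seq a single DNA string over ACGTN (case-insensitive).
#' @param include_noncanonical also report CANNTG sites.
#' @param seq_id identifier used in the output.
#' @return data.frame: `seq_id`, `start`, `end`, `strand`, `match`,
#'   `motif_class` (`"canonical"` or `"non-canonical"`).
#' @export
scan_ebox <- function(seq, include_noncanonical = FALSE,
                      seq_id = "seq") {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  if (grepl("[^ACGTN]", s))
    stop("invalid character in sequence (alphabet is ACGTN)",
         call. = FALSE)
  hits <- scan_pattern(s, "CACGTG", "canonical", "+")
  if (include_noncanonical) {
    fwd <- scan_pattern(s, "CA[ACGT][ACGT]TG", "non-canonical", "+")
    # reverse strand: a CANNTG on the minus strand reads CA..TG on the
    # reverse complement, i.e. CA[ACGT][ACGT]TG on revcomp(s)
    rc <- reverse_complement(s)
    rev <- scan_pattern(rc, "CA[ACGT][ACGT]TG", "non-canonical", "-")
    if (nrow(rev)) {
      n <- nchar(s)
      rev$start <- n - (rev$start + 6L)
      rev$end <- rev$start + 6L
    }
    nc <- rbind(fwd, rev)
    # canonical sites also match CANNTG; keep them only as canonical
    nc <- nc[!(nc$start %in% hits$start), , drop = FALSE]
    # same start from both strands: collapse, forward wins
    nc <- nc[order(nc$start, nc$strand), , drop = FALSE]
    nc <- nc[!duplicated(nc$start), , drop = FALSE]
    hits <- rbind(hits, nc)
  }
  if (nrow(hits)) {
    hits$seq_id <- seq_id
    hits <- hits[order(hits$start), c("seq_id", "start", "end", "strand",
                                      "match", "motif_class")]
  } else {
    hits <- data.frame(seq_id = character(), start = integer(),
                       end = integer(), strand = character(),
                       match = character(), motif_class = character())
  }
  rownames(hits) <- NULL
  hits
}

scan_pattern <- function(s, pattern, cls, strand) {
  # overlapping matches via lookahead-free stepping: gregexpr misses
  # overlaps, so scan from every offset
  n <- nchar(s)
  width <- 6L
  if (n < width)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), match = character(),
                      motif_class = character()))
  # vectorized window comparison keeps overlapping matches and stays
  # linear in sequence length
  subs <- substring(s, 1L:(n - width + 1L), width:n)
  ok <- if (grepl("[[]", pattern)) grepl(paste0("^", pattern, "$"), subs)
        else subs == pattern
  starts0 <- which(ok) - 1L
  if (!length(starts0))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), match = character(),
                      motif_class = character()))
  data.frame(start = starts0, end = starts0 + width,
             strand = strand,
             match = substring(s, starts0 + 1L, starts0 + width),
             motif_class = cls, stringsAsFactors = FALSE)
}

reverse_complement <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

#' Scan a FASTA file of promoters and write hits
#'
#' Runs [scan_ebox()] on every record and writes a BED6 file
#' (`chrom`, `start`, `end`, `name` = motif class, `score` = 0,
#' `strand`) plus a TSV with the matched text.
#'
#' @param fasta_path input FASTA.
#' @param bed_path,tsv_path output paths (`NULL` to skip either).
#' @param include_noncanonical see [scan_ebox()].
#' @return The combined hit data.frame, invisibly.
#' @export
scan_ebox_fasta <- function(fasta_path, bed_path = NULL, tsv_path = NULL,
                            include_noncanonical = FALSE) {
  seqs <- read_fasta(fasta_path)
  all <- do.call(rbind, lapply(names(seqs), function(id)
    scan_ebox(seqs[[id]], include_noncanonical, seq_id = id)))
  if (is.null(all))
    all <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      match = character(), motif_class = character())
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = all$seq_id, start = all$start,
                      end = all$end, name = all$motif_class, score = 0L,
                      strand = all$strand)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path)) write_results(all, tsv_path)
  invisible(all)
}
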