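## Nucleotide / protein sequence primitives.
##
## Sequences are plain character strings; sets of sequences are named
## character vectors (names = record ids).  Heavy string work is delegated
## to Biostrings where it matters; the coordinate bookkeeping is done here.

NT_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*")

#' Validate a nucleotide sequence
#'
#' Uppercases and checks that only A, C, G, T, N occur.
#'
#' @param x character scalar.
#' @return the validated, uppercased sequence.
#' @keywords internal
check_nt <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  bad <- gsub("[ACGTN]", "", x)
  if (nzchar(bad)) {
    stop("invalid nucleotide character(s): ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  }
  x
}

check_aa <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  bad <- setdiff(unique(strsplit(x, "")[[1]]), AA_ALPHABET)
  if (length(bad)) {
    stop("invalid amino-acid character(s): ", paste(bad, collapse = ", "))
  }
  x
}

#' Reverse complement of a DNA sequence
#'
#' @param seq character scalar over A/C/G/T/N (case-insensitive).
#' @return reverse-complemented sequence, uppercase.
#' @examples
#' reverse_complement("ATGC")   # "GCAT"
#' @export
reverse_complement <- function(seq) {
  seq <- check_nt(seq)
  if (!nzchar(seq)) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' The standard genetic code as a codon lookup table
#'
#' @return named character vector mapping each of the 64 codons to an
#'   amino-acid letter, with `*` for the three stop codons.
#' @export
standard_genetic_code <- function() {
  code <- Biostrings::GENETIC_CODE
  stopifnot(length(code) == 64L, sum(code == "*") == 3L)
  code
}

#' Translate one reading frame of a nucleotide sequence
#'
#' Frames follow the BLAST convention: `+1..+3` read the forward strand
#' starting at offsets 0..2; `-1..-3` read the reverse complement starting
#' at offsets 0..2.  Codons containing N translate to `X`; stop codons are
#' rendered `*`.
#'
#' @param seq nucleotide sequence (character scalar).
#' @param frame integer in `c(1, 2, 3, -1, -2, -3)`.
#' @param code codon table, default [standard_genetic_code()].
#' @return translated protein as a character scalar (possibly empty).
#' @export
translate_frame <- function(seq, frame, code = standard_genetic_code()) {
  stopifnot(abs(frame) %in% 1:3)
  seq <- check_nt(seq)
  s <- if (frame > 0) seq else reverse_complement(seq)
  off <- abs(frame) - 1L
  naa <- (nchar(s) - off) %/% 3L
  if (naa <= 0L) return("")
  starts <- off + 3L * seq_len(naa) - 2L
  codons <- substring(s, starts, starts + 2L)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"   # any codon containing N
  paste0(aa, collapse = "")
}

#' Translate all six reading frames
#'
#' @inheritParams translate_frame
#' @return named list of six proteins, names "+1".."-3".
#' @export
six_frame_translate <- function(seq, code = standard_genetic_code()) {
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  out <- lapply(frames, function(f) translate_frame(seq, f, code))
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out
}

#' Convert frame-local amino-acid coordinates to genomic nucleotides
#'
#' Maps a 1-based inclusive AA interval within the translation of a given
#' frame back to 1-based inclusive genomic nucleotide coordinates.  For
#' negative frames the pair is returned with `nt_start > nt_end`,
#' encoding the strand by coordinate order as in BLAST tabular output.
#'
#' @param frame frame id (`+1..+3`, `-1..-3`).
#' @param aa_start,aa_end 1-based AA positions within the frame translation.
#' @param contig_length length of the contig in nucleotides (required for
#'   negative frames).
#' @return integer vector `c(nt_start, nt_end)`.
#' @export
aa_to_genomic <- function(frame, aa_start, aa_end, contig_length) {
  stopifnot(abs(frame) %in% 1:3, aa_start >= 1L, aa_start <= aa_end)
  off <- abs(frame)
  max_aa <- (contig_length - (off - 1L)) %/% 3L
  if (aa_end > max_aa) {
    stop("AA interval [", aa_start, ",", aa_end,
         "] outside frame ", frame, " translation (", max_aa, " AA)")
  }
  p1 <- 3L * (aa_start - 1L) + off        # first nt, frame-local forward
  p2 <- 3L * aa_end + off - 1L            # last nt
  if (frame > 0) {
    c(p1, p2)
  } else {
    c(contig_length - p1 + 1L, contig_length - p2 + 1L)
  }
}

#' Read a FASTA file
#'
#' Accepts wrapped or single-line records and CRLF line endings.
#'
#' @param path file path.
#' @return named character vector of uppercased sequences; empty files give
#'   a zero-length vector.  Duplicate ids are an error.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(stats::setNames(character(0), character(0)))
  seqs <- toupper(as.character(set))
  ids <- names(set)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate FASTA ids: ", paste(dup, collapse = ", "))
  }
  stats::setNames(unname(seqs), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector (names = record ids).
#' @param path output path.
#' @param width line-wrap width; `Inf` writes single-line records.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)) || length(seqs) == 0L)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (is.finite(width) && nchar(s) > width) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    } else {
      writeLines(s, con)
    }
  }
  invisible(path)
}

#' Drop redundant peptide sequences
#'
#' Keeps one record per distinct amino-acid string (after uppercasing),
#' retaining the first-seen id.  I and L are kept distinct: the upstream
#' identification pipeline treats sequences verbatim.
#'
#' @param records named character vector of peptides.
#' @return deduplicated named character vector.
#' @export
dedupe_peptides <- function(records) {
  if (length(records) == 0L) return(records)
  up <- toupper(records)
  keep <- !duplicated(up)
  stats::setNames(unname(up[keep]), names(records)[keep])
}
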