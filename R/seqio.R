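#' Read a FASTA file into a named character vector
#'
#' Sequences are upper-cased on read. Record ids (the first whitespace-
#' delimited token of each header) must be unique.
#'
#' @param path Path to a FASTA file.
#' @param alphabet One of `"auto"`, `"dna"`, `"aa"`. With `"auto"` the
#'   alphabet is guessed from the residue composition; with an explicit
#'   alphabet the sequences are validated against it.
#' @return Named character vector of uppercase sequences, with an
#'   `"alphabet"` attribute.
#' @export
read_fasta <- function(path, alphabet = c("auto", "dna", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(seqs))) {
    dup <- names(seqs)[duplicated(names(seqs))][1L]
    stop("duplicate sequence id: ", dup)
  }
  if (any(!nzchar(seqs))) {
    stop("empty record: ", names(seqs)[!nzchar(seqs)][1L])
  }
  if (alphabet == "auto") alphabet <- guess_alphabet(seqs)
  validate_alphabet(seqs, alphabet)
  attr(seqs, "alphabet") <- alphabet
  seqs
}

#' Write sequences to FASTA (60-column wrap)
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named")
  }
  ss <- Biostrings::BStringSet(toupper(seqs))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

DNA_CHARS <- c("A", "C", "G", "T", "N",
               "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
AA_CHARS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*")

guess_alphabet <- function(seqs) {
  ch <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  ch <- setdiff(ch, "-")
  if (all(ch %in% c("A", "C", "G", "T", "N", "U"))) "dna" else "aa"
}

validate_alphabet <- function(seqs, alphabet) {
  valid <- if (alphabet == "dna") c(DNA_CHARS, "-") else c(AA_CHARS, "-")
  ch <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  bad <- setdiff(ch, valid)
  if (length(bad)) {
    stop("invalid ", alphabet, " symbol(s): ", paste(bad, collapse = ""))
  }
  invisible(TRUE)
}

#' Reverse complement of a DNA sequence
#' @param seq DNA string.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Translate a nucleotide sequence in a chosen frame
#'
#' Frames 1..3 read the forward strand with offsets 0..2; frames -1..-3 read
#' the reverse complement likewise. Trailing bases that do not complete a
#' codon are dropped; stop codons are rendered `*` (standard genetic code).
#'
#' @param seq DNA string.
#' @param frame Integer in `c(1:3, -1:-3)`.
#' @return Peptide string.
#' @export
translate_seq <- function(seq, frame = 1) {
  stopifnot(frame %in% c(1:3, -1:-3))
  s <- if (frame < 0) revcomp(seq) else seq
  off <- abs(frame) - 1L
  if (nchar(s) - off < 3L) stop("sequence too short to translate in frame ", frame)
  s <- substr(s, off + 1L, nchar(s))
  s <- substr(s, 1L, 3L * (nchar(s) %/% 3L))
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     if.fuzzy.codon = "X"))
}

#' Translate all six reading frames
#' @param seq DNA string.
#' @return Named character vector of 6 peptides (`F1 F2 F3 R1 R2 R3`).
#' @export
six_frame <- function(seq) {
  fr <- c(1, 2, 3, -1, -2, -3)
  out <- vapply(fr, function(f) translate_seq(seq, f), character(1))
  names(out) <- c("F1", "F2", "F3", "R1", "R2", "R3")
  out
}

# codon table snapshot (namespace lookups of GENETIC_CODE are costly in
# hot loops)
CODON_TABLE <- Biostrings::GENETIC_CODE

fast_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# codon-table translation identical to translate_seq, but cheap enough for
# shuffle-null hot loops (no XString construction); ambiguous codons -> X
fast_translate <- function(seq, frame = 1) {
  s <- if (frame < 0) fast_revcomp(seq) else seq
  off <- abs(frame) - 1L
  n <- nchar(s) - off
  if (n < 3L) return("")
  n3 <- 3L * (n %/% 3L)
  cods <- substring(s, off + seq(1L, n3, 3L), off + seq(3L, n3 + 2L, 3L))
  aa <- unname(CODON_TABLE[cods])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

fast_six_frame <- function(seq) {
  rc <- fast_revcomp(seq)
  c(F1 = fast_translate(seq, 1), F2 = fast_translate(seq, 2),
    F3 = fast_translate(seq, 3), R1 = fast_translate(rc, 1),
    R2 = fast_translate(rc, 2), R3 = fast_translate(rc, 3))
}
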