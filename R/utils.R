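# Shared low-level helpers: sequence utilities, Phred codecs, FASTA/FASTQ I/O.

#' Reverse-complement nucleotide strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements, same length as `x`.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# canonical form of a sequence: lexicographic min of itself and its reverse
# complement (strand-agnostic identity)
.canonical <- function(x) pmin(x, revcomp(x))

#' Decode Phred quality strings to integer scores
#'
#' @param quals character vector of quality strings (one per read).
#' @param offset ASCII offset, 33 for modern FASTQ, 64 for legacy.
#' @return list of integer vectors, one per read.
#' @export
phred_decode <- function(quals, offset = 33L) {
  lapply(quals, function(q) utf8ToInt(q) - as.integer(offset))
}

#' Encode integer Phred scores as a quality string
#'
#' @param scores integer vector (or list of integer vectors) of Phred scores.
#' @param offset ASCII offset (default 33).
#' @return character vector of quality strings.
#' @export
phred_encode <- function(scores, offset = 33L) {
  if (!is.list(scores)) scores <- list(scores)
  vapply(scores, function(s) intToUtf8(as.integer(s) + as.integer(offset)), "")
}

# decode uniform-length quality strings into an n x L integer matrix
.phred_matrix <- function(quals, offset = 33L) {
  L <- unique(nchar(quals))
  stopifnot(length(L) == 1L)
  m <- matrix(utf8ToInt(paste(quals, collapse = "")) - as.integer(offset),
              ncol = L, byrow = TRUE)
  m
}

# all w-mers of every sequence in v (positional, not unique); sequences of
# mixed length supported.  Two vectorization strategies: across sequences
# (many short reads) or across positions (few long sequences).
.kmers <- function(v, w) {
  if (length(v) == 0L) return(character(0))
  lens <- nchar(v)
  if (length(v) <= max(lens) - w + 1L) {
    out <- lapply(seq_along(v), function(i) {
      if (lens[i] < w) return(character(0))
      substring(v[i], 1L:(lens[i] - w + 1L), w:lens[i])
    })
    return(unlist(out, use.names = FALSE))
  }
  out <- lapply(sort(unique(lens)), function(l) {
    if (l < w) return(character(0))
    vv <- v[lens == l]
    unlist(lapply(seq_len(l - w + 1L), function(i) substr(vv, i, i + w - 1L)),
           use.names = FALSE)
  })
  unlist(out, use.names = FALSE)
}

# count mismatching characters between two equal-length strings
.str_mismatch <- function(a, b) sum(charToRaw(a) != charToRaw(b))

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file path.
#' @param offset Phred ASCII offset of the file (default 33).
#' @return data.frame with columns `read_id`, `bases`, `quals` (quality
#'   strings re-encoded at offset 33 internally).
#' @export
read_fastq <- function(path, offset = 33L) {
  # Biostrings warns about dropped metadata columns on plain FASTQ; noise
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  q <- as.character(Biostrings::quality(x))
  if (offset != 33L) {
    q <- vapply(q, function(s) intToUtf8(utf8ToInt(s) - offset + 33L), "",
                USE.NAMES = FALSE)
  }
  data.frame(read_id = names(x), bases = as.character(x), quals = q,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a read table to FASTQ
#'
#' @param reads data.frame with `read_id`, `bases`, `quals` (Phred+33).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads$bases)
  names(dna) <- reads$read_id
  qs <- Biostrings::QualityScaledDNAStringSet(
    dna, Biostrings::PhredQuality(reads$quals))
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector, or an `XStringSet`.
#' @param path output file path.
#' @param type "DNA" or "AA" when `seqs` is a character vector.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, type = c("DNA", "AA")) {
  if (is.character(seqs)) {
    type <- match.arg(type)
    seqs <- if (type == "DNA") Biostrings::DNAStringSet(seqs)
            else Biostrings::AAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file path.
#' @param type "DNA" or "AA".
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  x <- if (type == "DNA") Biostrings::readDNAStringSet(path)
       else Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

# write a two-column key/value TSV (used for reports)
.write_kv_tsv <- function(kv, path) {
  utils::write.table(
    data.frame(key = names(kv), value = unlist(kv, use.names = FALSE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
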