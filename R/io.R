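# File-format layer: FASTA/FASTQ reading and writing via Biostrings.
# The pipeline itself operates on in-memory tables; these functions are the
# boundary to the standard formats.

#' Read a FASTA file
#'
#' @param path FASTA file (optionally gzipped).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write sequences to FASTA
#'
#' @param x named character vector of sequences.
#' @param path output path (gzipped when it ends in `.gz`).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path,
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file (optionally gzipped).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  validate_fastq(path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = sub("\\s.*$", "", names(x)), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

# verify the 4-line record geometry before handing the file to the parser
# (which pads short quality lines instead of failing); errors name the
# first offending record
validate_fastq <- function(path) {
  con <- if (endsWith(path, ".gz")) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  done <- 0L
  repeat {
    lines <- readLines(con, n = 400000L, warn = FALSE)
    if (length(lines) == 0) break
    if (length(lines) %% 4 != 0)
      stop(sprintf("malformed FASTQ record %d in %s: truncated record",
                   done + length(lines) %/% 4L + 1L, path))
    i1 <- seq(1, length(lines), by = 4)
    ok <- startsWith(lines[i1], "@") & startsWith(lines[i1 + 2], "+") &
      nchar(lines[i1 + 1]) == nchar(lines[i1 + 3])
    if (!all(ok))
      stop(sprintf("malformed FASTQ record %d in %s",
                   done + which(!ok)[1], path))
    done <- done + length(i1)
  }
  invisible(path)
}

#' Write reads to FASTQ
#'
#' @param seqs,quals,ids character vectors of equal length.
#' @param path output path (gzipped when it ends in `.gz`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, quals, ids, path) {
  stopifnot(length(seqs) == length(quals), length(seqs) == length(ids))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(seqs, ids)),
    Biostrings::PhredQuality(quals))
  Biostrings::writeQualityScaledXStringSet(x, path,
                                           compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Read a paired FASTQ set into the pipeline's pair table
#'
#' Mate files must list the same fragments in the same order; read ids may
#' carry `/1`, `/2` suffixes which are stripped for pairing.
#'
#' @param r1,r2 paths to the two mate FASTQ files.
#' @param sample,experiment labels attached to every pair.
#' @return pair data.frame as produced by [simulate_paired_reads()]
#'   (without ground-truth columns).
#' @export
read_fastq_pair <- function(r1, r2, sample = "S", experiment = "e1") {
  a <- read_fastq(r1)
  b <- read_fastq(r2)
  ida <- sub("/[12]$", "", a$id)
  idb <- sub("/[12]$", "", b$id)
  if (nrow(a) != nrow(b) || any(ida != idb))
    stop("mate FASTQ files out of sync: read ids do not pair up")
  data.frame(pair_id = ida, sample = sample, experiment = experiment,
             seq1 = a$seq, qual1 = a$qual, seq2 = b$seq, qual2 = b$qual,
             stringsAsFactors = FALSE)
}
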