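# Small shared helpers: sequence arithmetic, coordinate conventions and the
# union-find used by read clustering. Coordinates are 1-based inclusive
# throughout the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of character sequences
#'
#' Thin vectorized wrapper around [Biostrings::reverseComplement()] for the
#' plain character vectors the pipeline carries internally.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequence with a given GC content
#'
#' @param n sequence length in bp.
#' @param gc_content target fraction of G+C bases.
#' @return a single character string of length `n`.
#' @export
random_dna <- function(n, gc_content = 0.5) {
  stopifnot(n >= 0, gc_content >= 0, gc_content <= 1)
  if (n == 0) return("")
  p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
         (1 - gc_content) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Length of a 1-based inclusive interval
#'
#' @param start,end interval bounds, 1-based inclusive, `end >= start`.
#' @return integer count of positions in the interval.
#' @examples
#' interval_length(484, 5940)  # 5457
#' @export
interval_length <- function(start, end) {
  stopifnot(all(end >= start))
  as.integer(end - start + 1)
}

#' Strict gap between two junction coordinates
#'
#' Number of reference bases strictly between the last base retained on the
#' 5' side of an insertion and the first base retained on its 3' side: the
#' size of the host deletion implied by a printed integration interval.
#'
#' @param five_prime_end last retained host base before the insert (1-based).
#' @param three_prime_start first retained host base after the insert.
#' @return integer number of deleted bases, `>= 0`.
#' @examples
#' junction_gap(25457909, 25457921)  # 11
#' @export
junction_gap <- function(five_prime_end, three_prime_start) {
  gap <- as.integer(three_prime_start - five_prime_end - 1)
  stopifnot(all(gap >= 0))
  gap
}

# substring replacement that tolerates vectors of positions in one string
replace_bases <- function(seq, pos, bases) {
  if (length(pos) == 0) return(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  s[pos] <- bases
  paste(s, collapse = "")
}

# paste that keeps zero-length inputs zero-length (paste0 would recycle
# them to "")
paste_ids <- function(x, suffix) {
  if (length(x) == 0) character(0) else paste0(x, suffix)
}

# union-find with path compression (C++ kernel); ids are 1..n; unions
# pairs (a[i], b[i]); returns component label per element, relabelled to
# consecutive integers in order of first appearance
uf_components <- function(n, a, b) {
  uf_components_cpp(as.integer(n), as.integer(a), as.integer(b))
}

# write a data.frame as TSV without quoting or row names
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
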