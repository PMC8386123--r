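# Characterization of the known-insertion contig: junction coordinates on
# the host, the implied host deletion, the integrated vector interval and
# printed-style identity statistics. All coordinates are 1-based
# inclusive; the deletion is counted strictly between the junctions, so
# an integration printed as spanning positions a-b implies a deletion of
# b - a - 1 bases.

#' Percent identity statistic at printed precision
#'
#' @param matches number of identical bases.
#' @param length alignment length (> 0).
#' @param decimals decimal places; rounding is half-away-from-zero, the
#'   convention of printed identity percentages.
#' @return a list of class `identity_stat`: `matches`, `alignment_length`,
#'   `percent`.
#' @examples
#' percent_identity(263, 270, 2)$percent  # 97.41
#' percent_identity(449, 487, 1)$percent  # 92.2
#' @export
percent_identity <- function(matches, length, decimals = 2) {
  if (length <= 0) stop("alignment length must be positive")
  stopifnot(matches >= 0, matches <= length)
  p <- 100 * matches / length
  scale <- 10^decimals
  percent <- floor(p * scale + 0.5 + 1e-9) / scale
  structure(list(matches = as.integer(matches),
                 alignment_length = as.integer(length),
                 percent = percent),
            class = "identity_stat")
}

#' @export
format.identity_stat <- function(x, ...) {
  sprintf("%s%% (%d/%d bp)",
          format(x$percent, trim = TRUE), x$matches, x$alignment_length)
}

#' @export
print.identity_stat <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Call the insertion represented by a contig
#'
#' Orients the contig to the vector forward strand, maps the host flanks
#' on either side of the principal vector-identity segment to the host
#' reference by local search, and derives the junction coordinates: the
#' right junction is the last host base present before the insert, the
#' left junction the first host base after it, and the deletion the
#' strict gap between them.
#'
#' @param contig a contig object with `segments`.
#' @param host_ref named character vector of host reference chromosomes.
#' @param vec the `vector_record` (unused for coordinates but retained
#'   for interface symmetry and validation).
#' @param flank_identity minimum percent identity of a flank hit.
#' @param min_flank minimum flank length in bp.
#' @param host_index optional prebuilt [build_search_index()] of
#'   `host_ref`.
#' @return a list of class `insertion_call`: `chrom`, `right_junction`,
#'   `left_junction`, `deleted_bp`, `integrated_interval`, `strand`,
#'   `flanks` (data.frame with per-flank coordinates and identity).
#' @export
call_insertion <- function(contig, host_ref, vec, flank_identity = 98,
                           min_flank = 20, host_index = NULL) {
  contig <- orient_to_principal(contig)
  seg <- principal_segment(contig)
  if (is.null(seg)) stop("contig has no vector-identity segment")
  clen <- contig$length
  left_len <- seg$contig_start - 1L
  right_len <- clen - seg$contig_end
  if (left_len < min_flank || right_len < min_flank)
    stop("contig flanks too short to map")
  left <- substring(contig$consensus, 1L, left_len)
  right <- substring(contig$consensus, seg$contig_end + 1L, clen)
  hits_for <- function(flank, junction_edge) {
    hits <- local_search(setNames(flank, "flank"), host_ref,
                         min_identity = flank_identity,
                         min_hit_len = min(min_flank, nchar(flank)),
                         subject_index = host_index)
    if (nrow(hits) == 0) stop("flank not found in host reference")
    # the hit must reach the junction-adjacent edge of the flank
    hits <- if (junction_edge == "end")
      hits[hits$query_end == nchar(flank), , drop = FALSE]
    else
      hits[hits$query_start == 1L, , drop = FALSE]
    if (nrow(hits) == 0) stop("flank alignment does not reach the junction")
    hits
  }
  lhits <- hits_for(left, "end")
  rhits <- hits_for(right, "start")
  # the flanks may hit several host loci (duplicated/collinear flanks);
  # pick the consistent pair with the smallest non-negative host gap
  best <- NULL
  for (i in seq_len(nrow(lhits))) {
    for (j in seq_len(nrow(rhits))) {
      if (lhits$subject[i] != rhits$subject[j] ||
          lhits$strand[i] != rhits$strand[j]) next
      if (lhits$strand[i] == "+") {
        rj <- lhits$subject_end[i]; lj <- rhits$subject_start[j]
      } else {
        rj <- rhits$subject_end[j]; lj <- lhits$subject_start[i]
      }
      gap <- lj - rj - 1L
      if (gap < 0) next
      if (is.null(best) || gap < best$gap)
        best <- list(i = i, j = j, gap = gap, rj = rj, lj = lj)
    }
  }
  if (is.null(best)) stop("flanks map to inconsistent host loci")
  h_left <- lhits[best$i, ]
  h_right <- rhits[best$j, ]
  strand <- h_left$strand
  right_junction <- best$rj
  left_junction <- best$lj
  deleted <- junction_gap(right_junction, left_junction)
  flanks <- data.frame(
    side = c("left", "right"),
    length = c(nchar(left), nchar(right)),
    host_start = c(h_left$subject_start, h_right$subject_start),
    host_end = c(h_left$subject_end, h_right$subject_end),
    matches = c(h_left$matches, h_right$matches),
    alignment_length = c(h_left$alignment_length,
                         h_right$alignment_length),
    identity = c(percent_identity(h_left$matches,
                                  h_left$alignment_length)$percent,
                 percent_identity(h_right$matches,
                                  h_right$alignment_length)$percent),
    stringsAsFactors = FALSE)
  structure(list(chrom = h_left$subject,
                 right_junction = as.integer(right_junction),
                 left_junction = as.integer(left_junction),
                 deleted_bp = deleted,
                 integrated_interval = c(seg$vector_start, seg$vector_end),
                 strand = strand,
                 flanks = flanks),
            class = "insertion_call")
}

#' @export
print.insertion_call <- function(x, ...) {
  cat(sprintf("Insertion call on %s (%s strand)\n", x$chrom, x$strand))
  cat(sprintf("  last host base before insert: %d\n", x$right_junction))
  cat(sprintf("  first host base after insert: %d\n", x$left_junction))
  cat(sprintf("  host deletion: %d bp\n", x$deleted_bp))
  cat(sprintf("  integrated vector interval: %d..%d (%d bp)\n",
              x$integrated_interval[1], x$integrated_interval[2],
              interval_length(x$integrated_interval[1],
                              x$integrated_interval[2])))
  for (i in seq_len(nrow(x$flanks)))
    cat(sprintf("  %s flank: %d bp, host %d..%d, identity %s%% (%d/%d bp)\n",
                x$flanks$side[i], x$flanks$length[i], x$flanks$host_start[i],
                x$flanks$host_end[i], format(x$flanks$identity[i]),
                x$flanks$matches[i], x$flanks$alignment_length[i]))
  invisible(x)
}
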