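# NUMT screening: consensus reads that sit closer (in edit distance) to a
# known nuclear mitochondrial segment than to the sample's own major mtDNA
# sequence are flagged and excluded from pileups.

#' Levenshtein edit distance
#'
#' Unit-cost edit distance between two sequences (wrapper over the C
#' implementation in [utils::adist()]).
#'
#' @param a,b Character strings.
#' @return Integer edit distance.
#' @export
edit_distance <- function(a, b) {
  as.integer(utils::adist(a, b)[1, 1])
}

#' Flag a consensus read as a potential NUMT
#'
#' A consensus read is flagged when its minimum edit distance to any NUMT
#' entry for its segment is strictly lower than its distance to the sample's
#' major sequence over the same span, or when its constituent reads were
#' already annotated as NUMT by the upstream aligner. Ties are not flagged.
#' Positions where the consensus base is `N` are excluded from all compared
#' strings.
#'
#' @param consensus_bases Consensus base string (may contain N).
#' @param numts_entries Character vector of NUMT sequences over the same
#'   span (may be empty: distance is then infinite and only
#'   `upstream_flag` applies).
#' @param major_bases Major-sequence string over the same span.
#' @param upstream_flag Aligner-level NUMT annotation of the family.
#' @return Logical.
#' @export
flag_numts <- function(consensus_bases, numts_entries, major_bases,
                       upstream_flag = FALSE) {
  if (isTRUE(upstream_flag)) return(TRUE)
  if (!length(numts_entries)) return(FALSE)
  keep <- which(encode_bases(consensus_bases) > 0L)
  cons <- substring_positions(consensus_bases, keep)
  majr <- substring_positions(major_bases, keep)
  nmts <- vapply(numts_entries, substring_positions, character(1), keep = keep)
  d_major <- edit_distance(cons, majr)
  d_numts <- min(vapply(nmts, function(s) edit_distance(cons, s), integer(1)))
  d_numts < d_major
}

substring_positions <- function(s, keep) {
  intToUtf8(utf8ToInt(s)[keep])
}

# Vectorised NUMT flagging for a consensus_set. Deduplicates identical
# consensus strings per segment so the quadratic edit distance runs once per
# distinct sequence.
flag_numts_set <- function(consensus, numts_db, major, panel, ref) {
  flags <- as.logical(consensus$numts_aligned)
  if (is.null(numts_db) || !nrow(numts_db)) return(flags)
  segs <- panel$segments
  for (k in seq_len(nrow(segs))) {
    idx <- which(consensus$segment_id == segs$segment_id[k])
    if (!length(idx)) next
    entries <- numts_db$bases[numts_db$segment_id == segs$segment_id[k]]
    if (!length(entries)) next
    canon <- unshift_position(segs$start[k]:segs$end[k], ref)
    major_seg <- paste(major[canon], collapse = "")
    strs <- consensus$bases[idx]
    uniq <- unique(strs)
    uflag <- vapply(uniq, function(s)
      flag_numts(s, entries, major_seg, upstream_flag = FALSE), logical(1))
    flags[idx] <- flags[idx] | uflag[match(strs, uniq)]
  }
  flags
}
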