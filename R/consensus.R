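# ---- encoding helpers -------------------------------------------------------

NT_CHARS <- c("A", "C", "G", "T")
.nt_code_lut <- local({
  lut <- integer(256)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  lut[utf8ToInt("a")] <- 1L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("g")] <- 3L; lut[utf8ToInt("t")] <- 4L
  lut
})

# nucleotide string -> integer codes (A1 C2 G3 T4, anything else incl. N -> 0)
encode_bases <- function(s) .nt_code_lut[utf8ToInt(s)]

decode_bases <- function(codes) {
  out <- rep("N", length(codes))
  ok <- codes >= 1L & codes <= 4L
  out[ok] <- NT_CHARS[codes[ok]]
  paste(out, collapse = "")
}

# phred+33 quality string <-> integer vector
decode_phred33 <- function(s) utf8ToInt(s) - 33L
encode_phred33 <- function(q) intToUtf8(pmin(pmax(as.integer(q), 0L), 93L) + 33L)

# ---- Eq.-level operations ---------------------------------------------------

#' Likelihood of an observed base call given a true nucleotide
#'
#' The per-read likelihood underlying the consensus merge: with base
#' alignment quality `baq`, the observed base equals the true nucleotide with
#' probability `1 - 10^(-baq/10)`, and is any particular one of the three
#' other nucleotides with probability `(1/3) * 10^(-baq/10)`.
#'
#' The raw formula is returned unmodified, so `baq = 0` gives a degenerate
#' match likelihood of exactly 0; the consensus routines floor BAQ at 2
#' before applying it (see [consensus_base()]).
#'
#' @param observed_base,hypothesis_nt Single nucleotides (A/C/G/T),
#'   vectorised.
#' @param baq Phred-scaled base alignment quality, `>= 0`.
#' @return Numeric likelihood(s).
#' @export
base_likelihood <- function(observed_base, baq, hypothesis_nt) {
  observed_base <- toupper(observed_base); hypothesis_nt <- toupper(hypothesis_nt)
  if (!all(observed_base %in% NT_CHARS) || !all(hypothesis_nt %in% NT_CHARS))
    stop("nucleotides must be A/C/G/T", call. = FALSE)
  if (any(baq < 0)) stop("baq must be >= 0", call. = FALSE)
  e <- 10^(-baq / 10)
  ifelse(observed_base == hypothesis_nt, 1 - e, e / 3)
}

# Vectorised log-space merge of base-call columns.
#
# code_mat: n_reads x L integer matrix (0 = not covered / N, 1..4 = A/C/G/T)
# baq_mat:  n_reads x L numeric matrix of BAQs
# group:    length-n_reads grouping vector (one output row per group)
# Returns list(base, qual, pmax, depth): G x L matrices, rows ordered by
# sort(unique(group)). base 0 encodes 'N' (posterior tie or no coverage).
merge_columns <- function(code_mat, baq_mat, group,
                          tie_tol = 1e-9, baq_floor = 2) {
  if (!is.matrix(code_mat)) code_mat <- matrix(code_mat, nrow = length(group))
  if (!is.matrix(baq_mat)) baq_mat <- matrix(baq_mat, nrow = length(group))
  covered <- code_mat > 0L
  intq <- is.integer(baq_mat) ||
    (max(baq_mat) <= 200 && all(baq_mat == as.integer(baq_mat)))
  if (intq) {
    # phred qualities are small integers: use lookup tables for the
    # likelihood terms instead of elementwise transcendentals
    qf <- pmin(pmax(as.integer(baq_mat), as.integer(baq_floor)), 200L) + 1L
    qq <- 0:200
    ee <- 10^(-pmax(qq, baq_floor) / 10)
    lmis <- matrix(log(ee / 3)[qf], nrow(code_mat), ncol(code_mat))
    delta <- matrix((log1p(-ee) - log(ee / 3))[qf],
                    nrow(code_mat), ncol(code_mat))
  } else {
    e <- 10^(-pmax(baq_mat, baq_floor) / 10)
    lmis <- log(e / 3)
    delta <- log1p(-e) - lmis
  }
  uncov <- which(!covered)
  if (length(uncov)) {             # zero out uncovered cells (N / no base)
    lmis[uncov] <- 0
    delta[uncov] <- 0
  }
  base_ll <- rowsum(lmis, group, reorder = TRUE)
  ll <- vector("list", 4L)
  for (nt in 1:4) {
    ll[[nt]] <- base_ll + rowsum(delta * (code_mat == nt), group,
                                 reorder = TRUE)
  }
  depth <- rowsum(covered + 0L, group, reorder = TRUE)
  G <- nrow(ll[[1]]); L <- ncol(ll[[1]])
  M <- cbind(as.vector(ll[[1]]), as.vector(ll[[2]]),
             as.vector(ll[[3]]), as.vector(ll[[4]]))
  i1 <- max.col(M, ties.method = "first")
  idx <- cbind(seq_len(nrow(M)), i1)
  s1 <- M[idx]
  tot <- s1 + log(rowSums(exp(M - s1)))
  p1 <- exp(s1 - tot)
  M[idx] <- -Inf
  s2 <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  p2 <- exp(s2 - tot)
  one_minus <- -expm1(s1 - tot)
  q <- suppressWarnings(round(-10 * log10(one_minus)))
  q[!is.finite(q)] <- 93L
  q <- pmin(pmax(q, 0L), 93L)
  base <- i1
  tie <- (p1 - p2) <= tie_tol
  base[tie] <- 0L
  q[tie] <- 0L
  nocov <- as.vector(depth) == 0L
  base[nocov] <- 0L; q[nocov] <- 0L; p1[nocov] <- NA_real_
  list(base = matrix(base, G, L), qual = matrix(as.integer(q), G, L),
       pmax = matrix(p1, G, L), depth = depth,
       groups = rownames(depth))
}

#' Bayesian consensus of one pileup column
#'
#' Merges base calls sharing a position (all reads of one barcode family)
#' into a consensus nucleotide: the posterior over the four nucleotides is
#' the product of per-read likelihoods (see [base_likelihood()]) under a
#' uniform prior, computed in log space; the consensus base is the posterior
#' mode and its quality `round(-10*log10(1 - pmax))`, clamped to phred
#' `[0, 93]`. BAQ values are floored at 2 so the match likelihood stays
#' positive; a posterior tie (within `1e-9`) yields base `"N"` with quality
#' 0.
#'
#' @param bases Character vector of observed bases (A/C/G/T).
#' @param baq Numeric vector of BAQs, same length.
#' @return List with `base` (character, possibly `"N"`), `qual` (integer
#'   phred), `pmax` (posterior of the mode).
#' @export
consensus_base <- function(bases, baq) {
  if (length(bases) == 0L) stop("empty column", call. = FALSE)
  if (length(baq) != length(bases))
    stop("bases and baq lengths differ", call. = FALSE)
  codes <- .nt_code_lut[utf8ToInt(paste(toupper(bases), collapse = ""))]
  if (any(codes == 0L)) stop("bases must be A/C/G/T", call. = FALSE)
  m <- merge_columns(matrix(codes, ncol = 1L), matrix(baq, ncol = 1L),
                     group = rep(1L, length(codes)))
  list(base = if (m$base[1] == 0L) "N" else NT_CHARS[m$base[1]],
       qual = m$qual[1], pmax = m$pmax[1])
}

# ---- family-level consensus -------------------------------------------------

#' Collapse barcode read families into consensus reads
#'
#' Takes a family table (one row per read; see [simulate_families()] for the
#' column dialect) and produces one consensus read per barcode family. By
#' default mate overlaps within a read pair are merged first and the merged
#' pair calls (base + phred quality) are then merged across pairs by the same
#' rule (`order = "overlap_first"`); `order = "joint"` merges every read of
#' the family in a single pass. Both orders agree at high BAQ.
#'
#' @param families Data frame with columns `barcode`, `segment_id`,
#'   `pair_index`, `mate`, `start_shifted`, `bases`, `baq` (phred+33 string),
#'   `mapq`, and optionally `numts_truth` / `numts_aligned`.
#' @param panel A `probe_panel` (see [make_panel()]) giving segment
#'   intervals in the shifted frame.
#' @param order Merge order for mate overlaps.
#' @return A data frame of class `consensus_set`, one row per family:
#'   `barcode`, `segment_id`, `start_shifted`, `bases`, `qual` (phred+33),
#'   `family_size` (number of pairs), `from_duplicates`, `mapq`,
#'   `numts_aligned` and (when present in the input) `numts_truth`.
#' @export
build_consensus_set <- function(families, panel,
                                order = c("overlap_first", "joint")) {
  order <- match.arg(order)
  stopifnot(is.data.frame(families))
  segs <- panel$segments
  out <- vector("list", nrow(segs))
  for (k in seq_len(nrow(segs))) {
    fk <- families[families$segment_id == segs$segment_id[k], , drop = FALSE]
    if (!nrow(fk)) next
    out[[k]] <- consensus_one_segment(fk, segs$start[k], segs$end[k], order)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(barcode = character(), segment_id = character(),
                      start_shifted = integer(), bases = character(),
                      qual = character(), family_size = integer(),
                      from_duplicates = logical(), mapq = integer(),
                      numts_aligned = logical(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("consensus_set", "data.frame")
  res
}

consensus_one_segment <- function(fk, seg_start, seg_end, order) {
  Lseg <- seg_end - seg_start + 1L
  n <- nrow(fk)
  # fast path: all reads span the whole segment
  if (all(fk$start_shifted == seg_start) && all(nchar(fk$bases) == Lseg)) {
    code <- matrix(.nt_code_lut[utf8ToInt(paste(fk$bases, collapse = ""))],
                   nrow = n, ncol = Lseg, byrow = TRUE)
    baq <- matrix(utf8ToInt(paste(fk$baq, collapse = "")) - 33L,
                  nrow = n, ncol = Lseg, byrow = TRUE)
  } else {
    code <- matrix(0L, n, Lseg)
    baq <- matrix(0, n, Lseg)
    for (i in seq_len(n)) {
      off <- fk$start_shifted[i] - seg_start
      len <- nchar(fk$bases[i])
      if (off < 0L || off + len > Lseg)
        stop("read outside its segment", call. = FALSE)
      code[i, (off + 1):(off + len)] <- encode_bases(fk$bases[i])
      baq[i, (off + 1):(off + len)] <- decode_phred33(fk$baq[i])
    }
  }
  ubc <- unique(fk$barcode)
  fid <- match(fk$barcode, ubc)                 # integer family id
  if (order == "overlap_first") {
    pkey <- fid * 16L + as.integer(fk$pair_index)  # pair_index <= 10
    upk <- sort(unique(pkey))
    st1 <- merge_columns(code, baq, match(pkey, upk))
    st2 <- merge_columns(st1$base, st1$qual, upk %/% 16L)
  } else {
    st2 <- merge_columns(code, baq, fid)
  }
  gid <- as.integer(st2$groups)                 # sorted unique family ids
  bcs <- ubc[gid]
  o <- match(bcs, fk$barcode)
  pairs <- tapply(fk$pair_index, fk$barcode,
                  function(p) length(unique(p)))[bcs]
  mapq <- tapply(fk$mapq, fk$barcode, max)[bcs]
  res <- data.frame(
    barcode = bcs,
    segment_id = fk$segment_id[o],
    start_shifted = seg_start,
    bases = vapply(seq_along(bcs), function(i) decode_bases(st2$base[i, ]),
                   character(1)),
    qual = vapply(seq_along(bcs), function(i) encode_phred33(st2$qual[i, ]),
                  character(1)),
    family_size = as.integer(pairs),
    from_duplicates = as.integer(pairs) >= 2L,
    mapq = as.integer(mapq),
    numts_aligned = if (!is.null(fk$numts_aligned))
      as.logical(tapply(fk$numts_aligned, fk$barcode, any)[bcs])
    else FALSE,
    stringsAsFactors = FALSE
  )
  if (!is.null(fk$numts_truth))
    res$numts_truth <- as.logical(tapply(fk$numts_truth, fk$barcode, any)[bcs])
  res
}

#' Consensus for a single read family
#'
#' Convenience wrapper around [build_consensus_set()] for one family.
#'
#' @param family Data frame of the family's reads (family-table columns).
#' @param panel A `probe_panel`.
#' @inheritParams build_consensus_set
#' @return One-row `consensus_set`.
#' @export
build_consensus <- function(family, panel, order = c("overlap_first", "joint")) {
  if (length(unique(family$barcode)) != 1L)
    stop("family must contain a single barcode", call. = FALSE)
  if (length(unique(family$segment_id)) != 1L)
    stop("reads in a family disagree on their segment", call. = FALSE)
  build_consensus_set(family, panel, order = match.arg(order))
}

#' Count mismatches of a consensus read against a major sequence
#'
#' Hamming count over non-N consensus bases, comparing the consensus read to
#' the sample's major mtDNA sequence over the read's canonical span.
#'
#' @param bases Consensus base string (may contain N).
#' @param canonical_pos Integer vector of canonical positions, one per base.
#' @param major Character vector of the major sequence over the whole genome.
#' @return Integer mismatch count.
#' @export
count_mismatches <- function(bases, canonical_pos, major) {
  codes <- encode_bases(bases)
  if (length(codes) != length(canonical_pos))
    stop("bases and canonical_pos lengths differ", call. = FALSE)
  keep <- codes > 0L
  sum(NT_CHARS[codes[keep]] != major[canonical_pos[keep]])
}
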