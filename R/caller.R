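# Pileup construction and six-filter low-frequency variant calling.

#' Sequencing error model for the exact Poisson filter
#'
#' @param rate Per-base consensus error rate (default 2e-4, i.e. 0.02%).
#' @param alpha Per-site significance threshold; default is a Bonferroni
#'   0.01 over the 16,569 sites of the full-length genome, kept as printed
#'   regardless of the genome actually analysed (configurable).
#' @return An object of class `error_model`.
#' @export
error_model <- function(rate = 2e-4, alpha = 0.01 / 16569) {
  if (rate <= 0 || rate >= 1) stop("rate must be in (0,1)", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  structure(list(rate = rate, alpha = alpha), class = "error_model")
}

#' Variant-calling thresholds
#'
#' Collects every numeric threshold of the QC scheme, with the standard
#' defaults: consensus reads need MAPQ >= 20 and pass the NUMT and
#' mismatch-excess screens (>5 mismatches in the coding region, >8 in the
#' D-loop); bases need quality >= 30; a called variant needs >= 100x depth
#' with >= 70% of bases at BAQ >= 30, a site outside low-complexity
#' intervals, >= 5 minor alleles, a log-likelihood quality score >= 5,
#' duplicate-stratum concordance (Fisher P >= 1e-4, fold-change <= 5,
#' duplicate-stratum VAF >= 0.2%), a significant exact Poisson error test,
#' and VAF >= 0.5%.
#'
#' @param mapq,baq Read- and base-level quality cut-offs.
#' @param mismatch_coding,mismatch_dloop Mismatch-excess limits (strict
#'   `>` exclusion).
#' @param min_depth,min_frac_baq30 Depth-composition filter.
#' @param min_minor Minimum minor-allele count.
#' @param min_loglik Minimum log-likelihood quality score.
#' @param min_fisher_p,max_fold_change,min_vaf_dup Duplicate-concordance
#'   filter.
#' @param min_vaf Minimum variant allele fraction of a call.
#' @param contamination_n Variant count at known polymorphic coding sites
#'   from which a sample is flagged as contaminated.
#' @return A list of class `caller_thresholds`.
#' @export
caller_thresholds <- function(mapq = 20, baq = 30,
                              mismatch_coding = 5, mismatch_dloop = 8,
                              min_depth = 100, min_frac_baq30 = 0.70,
                              min_minor = 5, min_loglik = 5,
                              min_fisher_p = 1e-4, max_fold_change = 5,
                              min_vaf_dup = 0.002, min_vaf = 0.005,
                              contamination_n = 11) {
  th <- as.list(environment())
  if (any(unlist(th) <= 0)) stop("thresholds must be positive", call. = FALSE)
  class(th) <- "caller_thresholds"
  th
}

# decode a consensus_set back into per-segment base/quality matrices
consensus_matrices <- function(consensus, panel) {
  segs <- panel$segments
  out <- list()
  for (k in seq_len(nrow(segs))) {
    idx <- which(consensus$segment_id == segs$segment_id[k])
    if (!length(idx)) next
    Lseg <- segs$end[k] - segs$start[k] + 1L
    base <- matrix(.nt_code_lut[utf8ToInt(paste(consensus$bases[idx],
                                                collapse = ""))],
                   nrow = length(idx), ncol = Lseg, byrow = TRUE)
    qual <- matrix(utf8ToInt(paste(consensus$qual[idx], collapse = "")) - 33L,
                   nrow = length(idx), ncol = Lseg, byrow = TRUE)
    out[[segs$segment_id[k]]] <- list(idx = idx, base = base, qual = qual,
                                      start = segs$start[k], end = segs$end[k])
  }
  out
}

# per-site allele counts over a subset of rows (codes with quality screen)
.accumulate_counts <- function(mats, ref, rows_keep, baq_min) {
  L <- ref$length
  counts <- matrix(0L, L, 4L, dimnames = list(NULL, NT_CHARS))
  cov_all <- integer(L); cov_q30 <- integer(L)
  for (m in mats) {
    keep <- rows_keep[m$idx]
    if (!any(keep)) next
    b <- m$base[keep, , drop = FALSE]
    q <- m$qual[keep, , drop = FALSE]
    canon <- unshift_position(m$start:m$end, ref)
    qual_ok <- q >= baq_min & b > 0L
    for (nt in 1:4) {
      cnt <- colSums(b == nt & qual_ok)
      counts[, nt] <- counts[, nt] + as.integer(rowsum_by_index(cnt, canon, L))
    }
    cov_all <- cov_all + as.integer(rowsum_by_index(colSums(b > 0L), canon, L))
    cov_q30 <- cov_q30 + as.integer(rowsum_by_index(colSums(qual_ok), canon, L))
  }
  list(counts = counts, cov_all = cov_all, cov_q30 = cov_q30)
}

# sum segment-column values into a genome-length vector by canonical index
rowsum_by_index <- function(x, index, L) {
  out <- numeric(L)
  agg <- rowsum(x, index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Derive the sample's major mtDNA sequence
#'
#' Per-site plurality allele over MAPQ/BAQ-qualifying consensus bases; sites
#' without coverage (and plurality ties) fall back to the reference allele.
#' The plurality is iterated once: a provisional major sequence drives the
#' mismatch-excess screen, and the final major sequence is recomputed from
#' the reads passing it.
#'
#' @param consensus A `consensus_set`.
#' @param ref An `mt_reference`.
#' @param panel A `probe_panel`.
#' @param thresholds A [caller_thresholds()] list.
#' @return Character vector of length `ref$length`.
#' @export
major_sequence <- function(consensus, ref, panel,
                           thresholds = caller_thresholds()) {
  mats <- consensus_matrices(consensus, panel)
  mapq_ok <- consensus$mapq >= thresholds$mapq
  major0 <- plurality_major(mats, ref, mapq_ok, thresholds$baq)
  mm <- mismatch_screen(consensus, mats, ref, major0, thresholds)
  plurality_major(mats, ref, mapq_ok & !mm$excess, thresholds$baq)
}

plurality_major <- function(mats, ref, rows_keep, baq_min) {
  acc <- .accumulate_counts(mats, ref, rows_keep, baq_min)
  top <- max.col(acc$counts, ties.method = "first")
  best <- acc$counts[cbind(seq_len(ref$length), top)]
  tied <- rowSums(acc$counts == best) > 1L
  major <- NT_CHARS[top]
  major[best == 0L | tied] <- ref$bases[best == 0L | tied]
  major
}

# mismatch counts vs a major sequence and the excess screen
mismatch_screen <- function(consensus, mats, ref, major, thresholds) {
  n <- nrow(consensus)
  count <- integer(n); dloop_mid <- logical(n)
  for (m in mats) {
    canon <- unshift_position(m$start:m$end, ref)
    major_codes <- match(major[canon], NT_CHARS)
    mmat <- matrix(rep(major_codes, each = nrow(m$base)), nrow = nrow(m$base))
    count[m$idx] <- as.integer(rowSums(m$base > 0L & m$base != mmat))
    mid <- canon[ceiling(ncol(m$base) / 2)]
    dloop_mid[m$idx] <- is_dloop(mid, ref)
  }
  excess <- ifelse(dloop_mid, count > thresholds$mismatch_dloop,
                   count > thresholds$mismatch_coding)
  list(count = count, dloop_mid = dloop_mid, excess = excess)
}

#' Build QC-filtered pileups from consensus reads
#'
#' Applies the read-level screens (MAPQ, NUMT flag, mismatch excess against
#' the iterated major sequence) and the base-level quality cut, then
#' accumulates per-site allele counts twice: over all qualifying consensus
#' reads and over the duplicate-built subset (families with >= 2 read
#' pairs). The BAQ>=30 base fraction per site is recorded before the
#' base-quality cut, over reads passing the read-level screens.
#'
#' @inheritParams major_sequence
#' @param numts_db Optional `numts_db` for edit-distance NUMT flagging.
#' @return Object of class `mt_pileup`: list with `sites` (data frame
#'   `pos`, allele counts `A`/`C`/`G`/`T`, duplicate-stratum counts
#'   `*_dup`, `depth`, `depth_dup`, `frac_baq30`), `major`, and the
#'   annotated `consensus` table (`mismatch_count`, `numts_flag`,
#'   `excluded`).
#' @export
build_pileup <- function(consensus, ref, panel, numts_db = NULL,
                         thresholds = caller_thresholds()) {
  mats <- consensus_matrices(consensus, panel)
  mapq_ok <- consensus$mapq >= thresholds$mapq
  major0 <- plurality_major(mats, ref, mapq_ok, thresholds$baq)
  mm0 <- mismatch_screen(consensus, mats, ref, major0, thresholds)
  major <- plurality_major(mats, ref, mapq_ok & !mm0$excess, thresholds$baq)
  mm <- mismatch_screen(consensus, mats, ref, major, thresholds)
  numts_flag <- flag_numts_set(consensus, numts_db, major, panel, ref)
  keep <- mapq_ok & !mm$excess & !numts_flag

  acc_all <- .accumulate_counts(mats, ref, keep, thresholds$baq)
  acc_dup <- .accumulate_counts(mats, ref, keep & consensus$from_duplicates,
                                thresholds$baq)
  sites <- data.frame(pos = seq_len(ref$length))
  for (nt in NT_CHARS) sites[[nt]] <- acc_all$counts[, nt]
  for (nt in NT_CHARS) sites[[paste0(nt, "_dup")]] <- acc_dup$counts[, nt]
  sites$depth <- as.integer(rowSums(acc_all$counts))
  sites$depth_dup <- as.integer(rowSums(acc_dup$counts))
  sites$cov_prefilter <- acc_all$cov_all
  sites$frac_baq30 <- ifelse(acc_all$cov_all > 0,
                             acc_all$cov_q30 / acc_all$cov_all, 0)
  cons <- consensus
  cons$mismatch_count <- mm$count
  cons$numts_flag <- numts_flag
  cons$excluded <- !keep
  structure(list(sites = sites, major = major, consensus = cons,
                 thresholds = thresholds),
            class = "mt_pileup")
}

#' @export
print.mt_pileup <- function(x, ...) {
  cat(sprintf("mt_pileup: %d sites, median depth %d; %d/%d consensus reads excluded\n",
              nrow(x$sites), as.integer(stats::median(x$sites$depth)),
              sum(x$consensus$excluded), nrow(x$consensus)))
  invisible(x)
}

#' Log-likelihood quality score of a candidate variant
#'
#' Phred-scaled binomial log10 likelihood ratio of the observed minor-allele
#' count under the variant hypothesis (allele fraction
#' `max(vaf, error rate)`) versus the error-only hypothesis (allele
#' fraction = error rate). Zero when the observed fraction does not exceed
#' the error rate; increases with the minor count at fixed depth.
#'
#' @param minor_count,depth Observed minor-allele count and site depth.
#' @param vaf Variant allele fraction (defaults to `minor_count/depth`).
#' @param model An [error_model()].
#' @return Numeric score, `>= 0`.
#' @export
loglik_score <- function(minor_count, depth, vaf = minor_count / depth,
                         model = error_model()) {
  if (any(depth <= 0)) stop("depth must be positive", call. = FALSE)
  p1 <- pmax(vaf, model$rate)
  10 * (stats::dbinom(minor_count, depth, p1, log = TRUE) -
          stats::dbinom(minor_count, depth, model$rate, log = TRUE)) / log(10)
}

#' Duplicate-stratum concordance of a candidate variant
#'
#' Compares the minor-allele fraction between consensus reads built with
#' duplicates (families with >= 2 pairs) and without (singleton families):
#' a two-sided Fisher's exact test on the 2x2 minor/other x
#' duplicate/singleton table, the VAF fold-change between strata (a zero
#' VAF in either covered stratum counts as infinite), and the
#' duplicate-stratum VAF itself.
#'
#' @param minor_count,depth Minor count and depth over all qualifying reads.
#' @param minor_dup,depth_dup Same restricted to duplicate-built reads.
#' @param thresholds A [caller_thresholds()] list.
#' @return List `fisher_p`, `fold_change`, `vaf_dup`, `vaf_sing`, `pass`.
#' @export
dup_concordance <- function(minor_count, depth, minor_dup, depth_dup,
                            thresholds = caller_thresholds()) {
  minor_sing <- minor_count - minor_dup
  depth_sing <- depth - depth_dup
  if (minor_dup > depth_dup || minor_sing < 0 || depth_sing < 0)
    stop("inconsistent duplicate-stratum counts", call. = FALSE)
  vaf_dup <- if (depth_dup > 0) minor_dup / depth_dup else 0
  vaf_sing <- if (depth_sing > 0) minor_sing / depth_sing else 0
  tab <- matrix(c(minor_dup, depth_dup - minor_dup,
                  minor_sing, depth_sing - minor_sing), 2L)
  fisher_p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1
  else stats::fisher.test(tab, alternative = "two.sided")$p.value
  fold_change <- if (vaf_dup > 0 && vaf_sing > 0)
    max(vaf_dup, vaf_sing) / min(vaf_dup, vaf_sing) else Inf
  if (vaf_dup == vaf_sing && vaf_dup > 0) fold_change <- 1
  pass <- fisher_p >= thresholds$min_fisher_p &&
    fold_change <= thresholds$max_fold_change &&
    vaf_dup >= thresholds$min_vaf_dup
  list(fisher_p = fisher_p, fold_change = fold_change,
       vaf_dup = vaf_dup, vaf_sing = vaf_sing, pass = pass)
}

#' Exact Poisson error-rate test
#'
#' Upper-tail exact Poisson p-value for the observed minor-allele count
#' against the expected error count `rate * depth`:
#' `P(X >= minor_count)`, `X ~ Poisson(rate * depth)`. The associated filter
#' passes when `p < alpha` (strict).
#'
#' @inheritParams loglik_score
#' @return Numeric p-value in (0, 1].
#' @export
poisson_error_test <- function(minor_count, depth, model = error_model()) {
  if (any(depth <= 0)) stop("depth must be positive", call. = FALSE)
  stats::ppois(minor_count - 1, lambda = model$rate * depth,
               lower.tail = FALSE)
}

#' Call heteroplasmic variants from a pileup
#'
#' For every site with a non-zero minor allele (the most frequent allele
#' other than the sample's major allele), evaluates the six quality filters
#' and records each verdict; a variant is `called` when all six pass and
#' its VAF (over all qualifying reads) is at least `min_vaf`.
#'
#' @param pileup An `mt_pileup`.
#' @param model An [error_model()].
#' @param ref An `mt_reference`.
#' @param all_sites Return every covered site (audit mode) instead of only
#'   sites with a minor allele observed.
#' @return Data frame of class `variant_calls`; one row per evaluated site
#'   with alleles, counts, VAFs for both strata, the filter statistics and
#'   pass/fail verdicts `f_depth`, `f_lowcomp`, `f_minminor`, `f_loglik`,
#'   `f_dup`, `f_poisson`, and `called`.
#' @export
call_variants <- function(pileup, model = error_model(), ref,
                          all_sites = FALSE) {
  th <- pileup$thresholds
  s <- pileup$sites
  counts <- as.matrix(s[, NT_CHARS])
  counts_dup <- as.matrix(s[, paste0(NT_CHARS, "_dup")])
  major_code <- match(pileup$major, NT_CHARS)
  idx <- cbind(seq_len(nrow(s)), major_code)
  minor_mat <- counts
  minor_mat[idx] <- -1L
  minor_code <- max.col(minor_mat, ties.method = "first")
  minor_count <- minor_mat[cbind(seq_len(nrow(s)), minor_code)]
  minor_count[minor_count < 0L] <- 0L
  rows <- if (all_sites) which(s$depth > 0) else which(minor_count > 0)
  if (!length(rows)) return(empty_calls())
  lc <- classify_region(s$pos[rows], ref)$low_complexity
  out <- data.frame(
    pos = s$pos[rows],
    ref_allele = ref$bases[s$pos[rows]],
    major_allele = pileup$major[rows],
    minor_allele = NT_CHARS[minor_code[rows]],
    depth = s$depth[rows],
    minor_count = minor_count[rows],
    depth_dup = s$depth_dup[rows],
    minor_dup = counts_dup[cbind(rows, minor_code[rows])],
    frac_baq30 = s$frac_baq30[rows],
    stringsAsFactors = FALSE
  )
  out$vaf <- ifelse(out$depth > 0, out$minor_count / out$depth, 0)
  out$vaf_dup <- ifelse(out$depth_dup > 0, out$minor_dup / out$depth_dup, 0)
  out$loglik <- ifelse(out$depth > 0,
                       loglik_score(out$minor_count, out$depth,
                                    out$vaf, model), 0)
  out$poisson_p <- ifelse(out$depth > 0,
                          poisson_error_test(out$minor_count, out$depth,
                                             model), 1)
  dup <- lapply(seq_len(nrow(out)), function(i)
    dup_concordance(out$minor_count[i], out$depth[i],
                    out$minor_dup[i], out$depth_dup[i], th))
  out$fisher_p <- vapply(dup, `[[`, numeric(1), "fisher_p")
  out$fold_change <- vapply(dup, `[[`, numeric(1), "fold_change")
  out$f_depth <- out$depth >= th$min_depth & out$frac_baq30 >= th$min_frac_baq30
  out$f_lowcomp <- !lc
  out$f_minminor <- out$minor_count >= th$min_minor
  out$f_loglik <- out$loglik >= th$min_loglik
  out$f_dup <- vapply(dup, `[[`, logical(1), "pass")
  out$f_poisson <- out$poisson_p < model$alpha
  out$called <- out$f_depth & out$f_lowcomp & out$f_minminor & out$f_loglik &
    out$f_dup & out$f_poisson & out$vaf >= th$min_vaf
  rownames(out) <- NULL
  class(out) <- c("variant_calls", "data.frame")
  out
}

empty_calls <- function() {
  out <- data.frame(pos = integer(), ref_allele = character(),
                    major_allele = character(), minor_allele = character(),
                    depth = integer(), minor_count = integer(),
                    depth_dup = integer(), minor_dup = integer(),
                    frac_baq30 = numeric(), vaf = numeric(),
                    vaf_dup = numeric(), loglik = numeric(),
                    poisson_p = numeric(), fisher_p = numeric(),
                    fold_change = numeric(), f_depth = logical(),
                    f_lowcomp = logical(), f_minminor = logical(),
                    f_loglik = logical(), f_dup = logical(),
                    f_poisson = logical(), called = logical(),
                    stringsAsFactors = FALSE)
  class(out) <- c("variant_calls", "data.frame")
  out
}

#' @export
print.variant_calls <- function(x, ...) {
  cat(sprintf("variant_calls: %d sites evaluated, %d called\n",
              nrow(x), sum(x$called)))
  if (sum(x$called))
    print.data.frame(x[x$called, c("pos", "major_allele", "minor_allele",
                                   "depth", "minor_count", "vaf", "vaf_dup")],
                     row.names = FALSE, digits = 4)
  invisible(x)
}

#' Screen a sample for cross-sample contamination
#'
#' Counts called variants falling on known polymorphic alleles in the
#' coding (non-D-loop) region; an excess (default >= 11) indicates
#' low-level contamination with a different mtDNA haplotype.
#'
#' @param calls A `variant_calls` data frame (called rows are counted).
#' @param polymorphisms Data frame (`pos`, `alt`) of known polymorphisms.
#' @param ref An `mt_reference`.
#' @param threshold Flagging threshold (count `>=` threshold flags).
#' @return List `count`, `flagged`.
#' @export
contamination_check <- function(calls, polymorphisms, ref, threshold = 11L) {
  called <- calls[calls$called, , drop = FALSE]
  if (!nrow(called)) return(list(count = 0L, flagged = FALSE))
  coding <- classify_region(called$pos, ref)$region != "dloop"
  key <- paste(called$pos, called$minor_allele)
  poly_key <- paste(polymorphisms$pos, polymorphisms$alt)
  n <- sum(coding & key %in% poly_key)
  list(count = n, flagged = n >= threshold)
}
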