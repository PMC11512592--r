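# Hand-built consensus/pileup constructors shared by the caller and
# acceptance tests.

toy_ref40 <- function() {
  memo("toy_ref40", {
    set.seed(1)
    seqc <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    regions <- data.frame(
      name = c("DLOOP", "PG"), kind = c("dloop", "protein"),
      start = c(1L, 101L), end = c(100L, 280L),
      strand = c(".", "heavy"), frame_start = c(NA, 101L))
    ref <- mt_reference(seqc, regions, shift_bp = 0L)
    list(ref = ref, panel = make_panel(ref, 1L))
  })
}

cons_row <- function(bases, qual = 40L, barcode = "b1", family_size = 2L,
                     mapq = 60L, numts_aligned = FALSE) {
  data.frame(barcode = barcode, segment_id = "seg001", start_shifted = 1L,
             bases = bases,
             qual = mtstamp:::encode_phred33(rep(qual, nchar(bases))),
             family_size = family_size,
             from_duplicates = family_size >= 2L,
             mapq = mapq, numts_aligned = numts_aligned,
             stringsAsFactors = FALSE)
}

mutate_at <- function(s, pos, ref) {
  v <- strsplit(s, "")[[1]]
  v[pos] <- vapply(v[pos], function(b) setdiff(c("A","C","G","T"), b)[1], "")
  paste(v, collapse = "")
}

# single-site pileup with prescribed counts for boundary checks
site_pileup <- function(ref, pos, depth, minor, depth_dup, minor_dup,
                        frac_baq30 = 1, thresholds = caller_thresholds()) {
  sites <- data.frame(pos = seq_len(ref$length))
  for (nt in c("A", "C", "G", "T")) sites[[nt]] <- 0L
  for (nt in c("A", "C", "G", "T")) sites[[paste0(nt, "_dup")]] <- 0L
  major <- ref$bases
  minor_nt <- setdiff(c("A", "C", "G", "T"), major[pos])[1]
  sites[pos, major[pos]] <- depth - minor
  sites[pos, minor_nt] <- minor
  sites[pos, paste0(major[pos], "_dup")] <- depth_dup - minor_dup
  sites[pos, paste0(minor_nt, "_dup")] <- minor_dup
  sites$depth <- rowSums(sites[, c("A", "C", "G", "T")])
  sites$depth_dup <- rowSums(sites[, paste0(c("A", "C", "G", "T"), "_dup")])
  sites$cov_prefilter <- sites$depth
  sites$frac_baq30 <- frac_baq30
  structure(list(sites = sites, major = major,
                 consensus = NULL, thresholds = thresholds),
            class = "mt_pileup")
}
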