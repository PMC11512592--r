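test_that("per-read likelihood follows the phred error model exactly", {
  expect_equal(base_likelihood("A", 30, "A"), 0.999, tolerance = 1e-12)
  expect_equal(base_likelihood("A", 30, "C"), 1 / 3000, tolerance = 1e-12)
  expect_identical(base_likelihood("A", 0, "A"), 0)    # degenerate raw formula
  expect_equal(base_likelihood("A", 0, "C"), 1 / 3)
  expect_error(base_likelihood("A", 30, "X"), "A/C/G/T")
  expect_error(base_likelihood("A", -1, "A"), ">= 0")
})

test_that("single-column consensus matches the probability-space oracle", {
  # singleton family returns its own base and BAQ
  r <- consensus_base("A", 30)
  expect_identical(r$base, "A")
  expect_identical(r$qual, 30L)
  expect_equal(r$pmax, 0.999, tolerance = 1e-9)

  # discordant pair resolved towards the higher-quality call
  r <- consensus_base(c("A", "C"), c(30, 20))
  o <- consensus_oracle(c("A", "C"), c(30, 20))
  expect_identical(r$base, "A")
  expect_identical(r$qual, o$qual)   # ~10
  expect_equal(r$pmax, o$pmax, tolerance = 1e-12)
  expect_equal(r$qual, 10L)

  # symmetric conflict is a tie: N with quality 0, pmax ~0.5
  r <- consensus_base(c("A", "C"), c(30, 30))
  expect_identical(r$base, "N")
  expect_identical(r$qual, 0L)
  expect_equal(r$pmax, 0.5, tolerance = 1e-3)

  expect_error(consensus_base(character(0), numeric(0)), "empty")
})

test_that("consensus is permutation-invariant and agrees with the oracle on random columns", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(1:6, 1)
    bases <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    baq <- sample(c(2, 10, 20, 30, 40, 63), n, replace = TRUE)
    r <- consensus_base(bases, baq)
    o <- consensus_oracle(bases, baq)
    expect_identical(r$base, o$base)
    expect_identical(r$qual, o$qual)
    expect_equal(r$pmax, o$pmax, tolerance = 1e-10)
    perm <- sample(n)
    r2 <- consensus_base(bases[perm], baq[perm])
    expect_identical(r2[c("base", "qual")], r[c("base", "qual")])
    expect_equal(r2$pmax, r$pmax, tolerance = 1e-12)
  }
})

test_that("concordant evidence never lowers a posterior; discordant never raises it", {
  # posterior of a fixed nucleotide, assembled from the package likelihood
  posterior_of <- function(bases, baq, nt) {
    lik <- vapply(c("A", "C", "G", "T"), function(h)
      prod(base_likelihood(bases, pmax(baq, 2), h)), numeric(1))
    unname(lik[nt] / sum(lik))
  }
  set.seed(77)
  for (i in 1:100) {
    n <- sample(1:5, 1)
    bases <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    baq <- sample(c(10, 20, 30, 40), n, replace = TRUE)
    r <- consensus_base(bases, baq)
    if (r$base == "N") next
    extra_q <- sample(c(10, 20, 30, 40), 1)
    p0 <- posterior_of(bases, baq, r$base)
    expect_equal(p0, r$pmax, tolerance = 1e-9)
    p_conc <- posterior_of(c(bases, r$base), c(baq, extra_q), r$base)
    expect_gte(p_conc + 1e-12, p0)
    other <- setdiff(c("A", "C", "G", "T"), r$base)[1]
    p_disc <- posterior_of(c(bases, other), c(baq, extra_q), r$base)
    expect_lte(p_disc, p0 + 1e-12)
  }
})

make_family <- function(base_strings, baq_ints, pair_index = NULL,
                        segment_id = "seg001", start = 1L,
                        barcode = "fam1", mapq = 60L) {
  n <- length(base_strings)
  if (is.null(pair_index)) pair_index <- rep(seq_len(ceiling(n / 2)),
                                             each = 2)[seq_len(n)]
  data.frame(barcode = barcode, segment_id = segment_id,
             pair_index = pair_index,
             mate = ave(pair_index, pair_index, FUN = seq_along),
             start_shifted = start,
             bases = base_strings,
             baq = vapply(baq_ints, function(q)
               mtstamp:::encode_phred33(rep(q, nchar(base_strings[1]))),
               character(1)),
             mapq = mapq, stringsAsFactors = FALSE)
}

toy_panel_ref <- function(L = 12L) {
  seqc <- paste(rep(c("A", "C", "G", "T"), length.out = L), collapse = "")
  regions <- data.frame(name = "RR", kind = "rRNA", start = 1L, end = L,
                        strand = "heavy", frame_start = NA)
  ref <- mt_reference(seqc, regions, shift_bp = 0L)
  list(ref = ref, panel = make_panel(ref, 1L))
}

test_that("family consensus recovers the molecule and annotates structure", {
  tp <- toy_panel_ref()
  mol <- tp$ref$sequence

  # three identical error-free pairs reproduce the molecule
  fam <- make_family(rep(mol, 6), rep(40, 6))
  cs <- build_consensus(fam, tp$panel)
  expect_identical(cs$bases, mol)
  expect_identical(cs$family_size, 3L)
  expect_true(cs$from_duplicates)

  # one BAQ-30 miscall among 4 pairs is outvoted
  bad <- mol
  substr(bad, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                               substr(mol, 5, 5))[1]
  fam <- make_family(c(rep(mol, 7), bad), rep(30, 8))
  cs <- build_consensus(fam, tp$panel)
  expect_identical(cs$bases, mol)

  # a singleton (one unpaired read) keeps its own bases and BAQs
  fam1 <- make_family(mol, 27, pair_index = 1L)
  cs1 <- build_consensus(fam1, tp$panel)
  expect_identical(cs1$bases, mol)
  expect_identical(mtstamp:::decode_phred33(cs1$qual),
                   rep(27L, nchar(mol)))
  expect_identical(cs1$family_size, 1L)
  expect_false(cs1$from_duplicates)

  # families must agree on their segment
  fam_bad <- make_family(rep(mol, 2), rep(30, 2))
  fam_bad$segment_id <- c("seg001", "seg002")
  expect_error(build_consensus(fam_bad, tp$panel), "disagree")
})

test_that("mate-overlap-first and joint merge orders agree at high BAQ", {
  ref <- mini_ref(); panel <- mini_panel()
  truth <- truth_set(depth = 40, seed = 9, baq_levels = 40, baq_probs = 1,
                     depth_jitter_sdlog = 0)
  fam <- simulate_families(truth, panel, ref)
  c1 <- build_consensus_set(fam, panel, order = "overlap_first")
  c2 <- build_consensus_set(fam, panel, order = "joint")
  expect_identical(c1$bases, c2$bases)
})

test_that("consensus qualities stay in the ASCII-encodable phred range", {
  s <- std_sample()
  q <- unlist(lapply(s$consensus$qual, mtstamp:::decode_phred33))
  expect_true(all(q >= 0L & q <= 93L))
})

test_that("mismatch counting is a Hamming count over non-N bases", {
  major <- strsplit("ACGTACGTACGT", "")[[1]]
  expect_identical(count_mismatches("ACGTACGTACGT", 1:12, major), 0L)
  expect_identical(count_mismatches("TTTTTTGTACGT", 1:12, major), 5L)
  # N positions are invisible
  expect_identical(count_mismatches("NNGTACGTACGT", 1:12, major), 0L)
  expect_identical(count_mismatches("NTGTACGTACGT", 1:12, major), 1L)
})

test_that("consensus error rate at family_size >= 3 and BAQ 30 is below 1e-5", {
  s <- std_sample()
  ref <- mini_ref(); panel <- mini_panel()
  segs <- panel$segments
  cons <- s$consensus[s$consensus$family_size >= 3, ]
  het_pos <- s$het$pos
  n_bases <- 0L; n_err <- 0L
  for (k in seq_len(nrow(segs))) {
    rows <- cons[cons$segment_id == segs$segment_id[k], ]
    if (!nrow(rows)) next
    canon <- unshift_position(segs$start[k]:segs$end[k], ref)
    truth_codes <- match(ref$bases[canon], c("A", "C", "G", "T"))
    keep_cols <- !(canon %in% het_pos)   # spiked sites are not errors
    for (i in seq_len(nrow(rows))) {
      codes <- mtstamp:::encode_bases(rows$bases[i])
      called <- codes > 0L & keep_cols
      n_bases <- n_bases + sum(called)
      n_err <- n_err + sum(codes[called] != truth_codes[called])
    }
  }
  expect_gt(n_bases, 5e5)
  # observed errors must not significantly exceed 1e-5 per base
  p_excess <- stats::pbinom(n_err - 1, n_bases, 1e-5, lower.tail = FALSE)
  expect_gt(p_excess, 0.01)
  expect_lt(n_err / n_bases, 1e-5)
})
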