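test_that("major sequence is the iterated plurality with reference fallback", {
  tp <- toy_ref40(); ref <- tp$ref; mol <- ref$sequence
  # all reads identical: that sequence
  cs <- do.call(rbind, lapply(1:5, function(i)
    cons_row(mol, barcode = paste0("b", i))))
  expect_identical(paste(major_sequence(cs, ref, tp$panel), collapse = ""),
                   mol)
  # 60/40 plurality at one site
  alt_seq <- mutate_at(mol, 150, ref)
  cs <- rbind(do.call(rbind, lapply(1:3, function(i)
    cons_row(alt_seq, barcode = paste0("a", i)))),
    do.call(rbind, lapply(1:2, function(i)
      cons_row(mol, barcode = paste0("b", i)))))
  mj <- major_sequence(cs, ref, tp$panel)
  expect_identical(mj[150], substr(alt_seq, 150, 150))
  # exact 50/50 tie retains the reference allele
  cs <- rbind(cons_row(alt_seq, barcode = "a1"), cons_row(mol, barcode = "b1"))
  mj <- major_sequence(cs, ref, tp$panel)
  expect_identical(mj[150], ref$bases[150])
})

test_that("pileups enforce read- and base-level screens", {
  tp <- toy_ref40(); ref <- tp$ref; mol <- ref$sequence
  base <- do.call(rbind, lapply(1:10, function(i)
    cons_row(mol, barcode = paste0("ok", i))))

  # MAPQ 19 contributes nowhere
  cs <- rbind(base, cons_row(mol, barcode = "low", mapq = 19L))
  pu <- build_pileup(cs, ref, tp$panel)
  expect_true(all(pu$sites$depth == 10L))
  expect_true(pu$consensus$excluded[pu$consensus$barcode == "low"])

  # 6 mismatches in a coding-region read are an excess (> 5); 5 are not
  cs <- rbind(base,
              cons_row(mutate_at(mol, 201:206, ref), barcode = "mm6"),
              cons_row(mutate_at(mol, 211:215, ref), barcode = "mm5"))
  pu <- build_pileup(cs, ref, tp$panel)
  expect_true(pu$consensus$excluded[pu$consensus$barcode == "mm6"])
  expect_false(pu$consensus$excluded[pu$consensus$barcode == "mm5"])
  expect_identical(pu$consensus$mismatch_count[pu$consensus$barcode == "mm6"],
                   6L)

  # D-loop-midpoint reads tolerate up to 8 mismatches (toy ref: the read
  # midpoint is coding, so craft a D-loop-only segment via the mini ref)
  ref2 <- mini_ref(); panel2 <- mini_panel()
  truth <- truth_set(depth = 30, seed = 4, baq_levels = 60, baq_probs = 1,
                     depth_jitter_sdlog = 0)
  fam <- simulate_families(truth, panel2, ref2)
  cs2 <- build_consensus_set(fam, panel2)
  segs <- panel2$segments
  mids <- vapply(seq_len(nrow(segs)), function(k)
    unshift_position(segs$start[k] +
                       (segs$end[k] - segs$start[k]) %/% 2L, ref2),
    integer(1))
  dseg <- segs$segment_id[which(mtstamp:::is_dloop(mids, ref2))[1]]
  i <- which(cs2$segment_id == dseg)[1]
  v <- cs2[i, ]
  v$barcode <- "dl8"; v$bases <- mutate_at(v$bases, 10:17, ref2)  # 8 changes
  w <- cs2[i, ]
  w$barcode <- "dl9"; w$bases <- mutate_at(w$bases, 30:38, ref2)  # 9 changes
  pu2 <- build_pileup(rbind(cs2, v, w), ref2, panel2)
  expect_false(pu2$consensus$excluded[pu2$consensus$barcode == "dl8"])
  expect_true(pu2$consensus$excluded[pu2$consensus$barcode == "dl9"])

  # base quality 29 is dropped from counts but kept in the BAQ30 fraction
  cs <- rbind(base, cons_row(mol, qual = 29L, barcode = "q29"))
  pu <- build_pileup(cs, ref, tp$panel)
  expect_true(all(pu$sites$depth == 10L))
  expect_true(all(pu$sites$cov_prefilter == 11L))
  expect_equal(pu$sites$frac_baq30, rep(10 / 11, 300))

  # N bases are invisible
  cs <- rbind(base, cons_row(paste0("NN", substr(mol, 3, 300)),
                             barcode = "nn"))
  pu <- build_pileup(cs, ref, tp$panel)
  expect_identical(pu$sites$depth[1:2], c(10L, 10L))
  expect_identical(pu$sites$depth[3], 11L)
})

test_that("log-likelihood quality score matches its closed form", {
  em <- error_model()
  expect_identical(loglik_score(0, 4000, model = em), 0)
  s <- loglik_score(20, 4000, model = em)
  expect_equal(s, loglik_oracle(20, 4000, em$rate), tolerance = 1e-9)
  expect_gt(s, 5)
  expect_lt(loglik_score(1, 4000, model = em), 5)
  # increases with the minor count at fixed depth
  sc <- loglik_score(1:50, 4000, vaf = (1:50) / 4000, model = em)
  expect_true(all(diff(sc) > -1e-12))
  set.seed(3)
  for (i in 1:50) {
    n <- sample(500:5000, 1); k <- sample(0:40, 1)
    expect_equal(loglik_score(k, n, model = em),
                 loglik_oracle(k, n, em$rate), tolerance = 1e-9)
  }
})

test_that("duplicate-stratum concordance follows the Fisher/fold-change/floor rule", {
  th <- caller_thresholds()
  # identical VAF in both strata passes when the duplicate VAF clears 0.2%
  r <- dup_concordance(30, 6000, 15, 3000, th)
  expect_equal(r$fisher_p, 1, tolerance = 1e-9)
  expect_equal(r$fold_change, 1)
  expect_true(r$pass)
  # duplicate-stratum VAF below 0.2% fails regardless of p
  r <- dup_concordance(7, 6000, 3, 3000, th)
  expect_false(r$pass)
  expect_lt(r$vaf_dup, 0.002)
  # one empty stratum is an infinite fold change: fail
  r <- dup_concordance(30, 4000, 30, 3000, th)
  expect_identical(r$fold_change, Inf)
  expect_false(r$pass)
  # no duplicate reads at all: vaf_dup 0, fail
  r <- dup_concordance(30, 4000, 0, 0, th)
  expect_false(r$pass)
  # exact hypergeometric oracle across random tables
  set.seed(14)
  for (i in 1:200) {
    depth_dup <- sample(50:2000, 1)
    depth_sing <- sample(50:2000, 1)
    minor_dup <- rbinom(1, depth_dup, 0.01)
    minor_sing <- rbinom(1, depth_sing, runif(1, 0.001, 0.05))
    r <- dup_concordance(minor_dup + minor_sing, depth_dup + depth_sing,
                         minor_dup, depth_dup, th)
    tab <- matrix(c(minor_dup, depth_dup - minor_dup,
                    minor_sing, depth_sing - minor_sing), 2)
    expect_equal(r$fisher_p, fisher_oracle(t(tab)), tolerance = 1e-7)
  }
})

test_that("exact Poisson error test matches a partial-sum oracle", {
  em <- error_model()
  expect_identical(poisson_error_test(0, 4000, em), 1)
  expect_equal(poisson_error_test(5, 4000, em),
               poisson_tail_oracle(5, 0.8), tolerance = 1e-12)
  set.seed(6)
  for (i in 1:100) {
    d <- sample(100:8000, 1); k <- sample(0:30, 1)
    expect_equal(poisson_error_test(k, d, em),
                 poisson_tail_oracle(k, em$rate * d), tolerance = 1e-10)
  }
  # printed Bonferroni default
  expect_equal(em$alpha, 0.01 / 16569)
})

test_that("calling requires every filter and the VAF floor", {
  ref <- mini_ref()
  em <- error_model()
  # clean site: depth 2000, minor 12 (VAF 0.6%), balanced duplicates
  pu <- site_pileup(ref, 700L, 2000L, 12L, 1000L, 6L)
  v <- call_variants(pu, em, ref)
  expect_identical(nrow(v), 1L)
  expect_true(v$called)
  expect_true(all(unlist(v[, c("f_depth", "f_lowcomp", "f_minminor",
                               "f_loglik", "f_dup", "f_poisson")])))
  expect_equal(v$vaf, 0.006)

  # minor 4 fails the minimum minor-allele count
  v <- call_variants(site_pileup(ref, 700L, 2000L, 4L, 1000L, 2L), em, ref)
  expect_false(v$called); expect_false(v$f_minminor)
  # depth 99 fails the depth-composition filter
  v <- call_variants(site_pileup(ref, 700L, 99L, 10L, 50L, 5L), em, ref)
  expect_false(v$called); expect_false(v$f_depth)
  expect_true(v$f_minminor)
  # depth 100 passes it
  v <- call_variants(site_pileup(ref, 700L, 100L, 10L, 50L, 5L), em, ref)
  expect_true(v$f_depth)
  # BAQ30 fraction below 70% fails
  v <- call_variants(site_pileup(ref, 700L, 2000L, 12L, 1000L, 6L,
                                 frac_baq30 = 0.69), em, ref)
  expect_false(v$f_depth)
  # low-complexity site fails filter (ii) only
  v <- call_variants(site_pileup(ref, 70L, 2000L, 12L, 1000L, 6L), em, ref)
  expect_false(v$called); expect_false(v$f_lowcomp)
  expect_true(v$f_minminor && v$f_poisson)
  # VAF below 0.5% blocks the call even with all filters green
  v <- call_variants(site_pileup(ref, 700L, 4000L, 18L, 2000L, 9L), em, ref)
  expect_true(all(unlist(v[, c("f_depth", "f_lowcomp", "f_minminor",
                               "f_loglik", "f_dup", "f_poisson")])))
  expect_false(v$called)
  expect_lt(v$vaf, 0.005)
  # a p-value exactly at alpha fails the strict Poisson cut
  pu <- site_pileup(ref, 700L, 2000L, 12L, 1000L, 6L)
  p_at <- poisson_error_test(12L, 2000L, em)
  em_eq <- error_model(rate = em$rate, alpha = p_at)
  v <- call_variants(pu, em_eq, ref)
  expect_false(v$f_poisson)
})

test_that("a call is exactly the conjunction of its six verdicts on random sites", {
  ref <- mini_ref()
  em <- error_model()
  th <- caller_thresholds()
  set.seed(99)
  n <- 10000
  depth <- sample(50:5000, n, TRUE)
  minor <- pmin(rbinom(n, depth, runif(n, 0, 0.02)), depth)
  depth_dup <- vapply(depth, function(d) sample(0:d, 1), integer(1))
  minor_dup <- mapply(function(m, dd, d)
    if (m == 0) 0L else rbinom(1, m, dd / d), minor, depth_dup, depth)
  pos <- sample(ref$length, n, TRUE)
  frac <- sample(c(1, 0.9, 0.6), n, TRUE, prob = c(0.8, 0.1, 0.1))
  verdicts <- vapply(seq_len(n), function(i) {
    if (minor[i] == 0) return(rep(NA, 7))
    pu <- NULL
    d <- depth[i]; m <- minor[i]; dd <- depth_dup[i]; md <- min(minor_dup[i],
                                                                dd)
    f1 <- d >= th$min_depth && frac[i] >= th$min_frac_baq30
    f2 <- !classify_region(pos[i], ref)$low_complexity
    f3 <- m >= th$min_minor
    f4 <- loglik_score(m, d, model = em) >= th$min_loglik
    f5 <- dup_concordance(m, d, md, dd, th)$pass
    f6 <- poisson_error_test(m, d, em) < em$alpha
    c(f1, f2, f3, f4, f5, f6, f1 && f2 && f3 && f4 && f5 && f6 &&
        m / d >= th$min_vaf)
  }, logical(7))
  keep <- which(minor > 0)
  # recompute through call_variants one site at a time on a subset
  idx <- sample(keep, 300)
  for (i in idx) {
    md <- min(minor_dup[i], depth_dup[i])
    pu <- site_pileup(ref, pos[i], depth[i], minor[i], depth_dup[i], md,
                      frac_baq30 = frac[i])
    v <- call_variants(pu, em, ref)
    row <- v[v$pos == pos[i], ]
    expect_identical(unname(unlist(row[, c("f_depth", "f_lowcomp",
                                           "f_minminor", "f_loglik",
                                           "f_dup", "f_poisson")])),
                     verdicts[1:6, i])
    expect_identical(row$called, verdicts[7, i])
    expect_identical(row$called, all(verdicts[1:6, i]) &&
                       minor[i] / depth[i] >= th$min_vaf)
  }
})

test_that("contamination screen counts coding variants at known polymorphic sites", {
  ref <- mini_ref()
  poly <- data.frame(pos = c(400:420, 1000:1010), alt = "A")
  poly$alt <- ifelse(ref$bases[poly$pos] == "A", "C", "A")
  mkcalls <- function(pos, alt) {
    if (!length(pos))
      return(data.frame(pos = integer(), ref_allele = character(),
                        major_allele = character(),
                        minor_allele = character(), called = logical(),
                        stringsAsFactors = FALSE))
    data.frame(pos = pos, ref_allele = ref$bases[pos],
               major_allele = ref$bases[pos], minor_allele = alt,
               called = TRUE, stringsAsFactors = FALSE)
  }
  v11 <- mkcalls(poly$pos[1:11], poly$alt[1:11])
  r <- contamination_check(v11, poly, ref)
  expect_identical(r$count, 11L)
  expect_true(r$flagged)
  v3 <- mkcalls(poly$pos[1:3], poly$alt[1:3])
  r <- contamination_check(v3, poly, ref)
  expect_identical(r$count, 3L)
  expect_false(r$flagged)
  r <- contamination_check(mkcalls(integer(0), character(0)), poly, ref)
  expect_identical(r$count, 0L)
  expect_false(r$flagged)
  # D-loop positions and non-polymorphic alleles do not count
  vd <- mkcalls(c(1900L, 1901L), c("A", "A"))
  vd$minor_allele <- ifelse(ref$bases[vd$pos] == "A", "C", "A")
  r <- contamination_check(vd, poly, ref)
  expect_identical(r$count, 0L)
})
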