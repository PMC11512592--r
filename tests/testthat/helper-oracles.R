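# Shared fixtures (memoized: built once per test run) and independent
# oracles. Oracles are deliberately written with different algorithms than
# the package code paths they check.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

mini_ref <- function() memo("mini_ref", load_mini_reference())
mini_panel <- function() memo("mini_panel", make_panel(mini_ref(), 8))

# heteroplasmy sites: spread out, outside low-complexity intervals,
# ref base replaced by a fixed different alt
pick_het_sites <- function(ref, n, vaf, seed = 404L) {
  set.seed(seed)
  lc <- classify_region(seq_len(ref$length), ref)$low_complexity
  pos <- sort(sample(which(!lc), n))
  alt <- vapply(pos, function(p) setdiff(c("A", "C", "G", "T"),
                                         ref$bases[p])[1], character(1))
  data.frame(pos = pos, alt = alt, vaf = vaf)
}

# one standard ultra-deep sample shared by several property tests
std_sample <- function() memo("std_sample", {
  ref <- mini_ref(); panel <- mini_panel()
  het <- pick_het_sites(ref, 20, vaf = 0.01)
  truth <- truth_set(sample_id = "std", heteroplasmies = het, depth = 4000,
                     duplicate_rate = 0.5, baq_levels = 30, baq_probs = 1,
                     depth_jitter_sdlog = 0, seed = 11L)
  fam <- simulate_families(truth, panel, ref)
  cons <- build_consensus_set(fam, panel)
  pu <- build_pileup(cons, ref, panel)
  calls <- call_variants(pu, error_model(), ref)
  list(truth = truth, het = het, families = fam, consensus = cons,
       pileup = pu, calls = calls)
})

# ---- independent oracles ----------------------------------------------------

# vertebrate mitochondrial genetic code, written out by hand
MITO_CODE_ORACLE <- c(
  TTT="F",TTC="F",TTA="L",TTG="L", CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="M",ATG="M", GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S", CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T", GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*", CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K", GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="W",TGG="W", CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="*",AGG="*", GGT="G",GGC="G",GGA="G",GGG="G")

COMP_ORACLE <- c(A = "T", C = "G", G = "C", T = "A")

# brute-force coding effect: rebuild the coding sequence of the gene,
# substitute, translate both, compare full protein strings
coding_effect_oracle <- function(pos, alt, gene, ref) {
  gpos <- gene$start:gene$end
  if (gene$strand == "light") gpos <- rev(gpos)
  mrna <- ref$bases[gpos]
  if (gene$strand == "light") mrna <- unname(COMP_ORACLE[mrna])
  mrna2 <- mrna
  i <- match(pos, gpos)
  mrna2[i] <- if (gene$strand == "light") unname(COMP_ORACLE[alt]) else alt
  # start offset relative to the annotated frame
  fs_i <- match(gene$frame_start, gpos)
  mrna <- mrna[fs_i:length(mrna)]; mrna2 <- mrna2[fs_i:length(mrna2)]
  pad <- (3 - length(mrna) %% 3) %% 3
  mrna <- c(mrna, rep("A", pad)); mrna2 <- c(mrna2, rep("A", pad))
  tr <- function(v) paste(MITO_CODE_ORACLE[
    vapply(seq(1, length(v), 3), function(j)
      paste(v[j:(j + 2)], collapse = ""), character(1))], collapse = "")
  if (tr(mrna) == tr(mrna2)) "synonymous" else "non_synonymous"
}

# probability-space consensus oracle (no logs, direct products)
consensus_oracle <- function(bases, baq, baq_floor = 2, tie_tol = 1e-9) {
  e <- 10^(-pmax(baq, baq_floor) / 10)
  lik <- vapply(c("A", "C", "G", "T"), function(nt)
    prod(ifelse(bases == nt, 1 - e, e / 3)), numeric(1))
  post <- unname(lik / sum(lik))
  o <- order(post, decreasing = TRUE)
  pmax_ <- post[o[1]]
  if (pmax_ - post[o[2]] <= tie_tol)
    return(list(base = "N", qual = 0L, pmax = pmax_))
  q <- round(-10 * log10(1 - pmax_))
  if (!is.finite(q)) q <- 93
  list(base = c("A", "C", "G", "T")[o[1]], qual = as.integer(min(max(q, 0), 93)),
       pmax = pmax_)
}

# quadratic dynamic-programming Levenshtein oracle
edit_distance_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m))
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                           d[i, j] + (x[i] != y[j]))
  d[n + 1, m + 1]
}

# exact Poisson upper tail by direct partial series sum (upper terms until
# they become negligible; avoids 1-minus cancellation)
poisson_tail_oracle <- function(k, lambda) {
  if (k <= 0) return(1)
  i <- k:(k + 2000L)
  sum(exp(-lambda + i * log(lambda) - lgamma(i + 1)))
}

# two-sided Fisher exact p by hypergeometric enumeration with lchoose
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + c_; n <- b + d; k <- a + b
  lo <- max(0L, k - n); hi <- min(k, m)
  logp <- function(x) lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  probs <- exp(vapply(lo:hi, logp, numeric(1)))
  pobs <- exp(logp(a))
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# closed-form binomial log-likelihood-ratio score
loglik_oracle <- function(k, n, rate) {
  p1 <- max(k / n, rate)
  lb <- function(p) lchoose(n, k) + k * log(p) + (n - k) * log(1 - p)
  l0 <- if (k == 0) lb(rate) else lb(rate)
  10 * (lb(p1) - l0) / log(10)
}
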