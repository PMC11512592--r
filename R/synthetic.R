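# Synthetic read-family and cohort generator. Emulates the probe-capture
# design the caller assumes: the shifted genome is tiled by probe segments,
# every captured molecule carries a unique barcode, reads are 2 x full
# segment span, about half of the families carry PCR duplicates, and
# per-base miscalls follow the phred error model of their BAQ.

#' Tile the shifted genome with probe segments
#'
#' Builds a contiguous, non-overlapping panel of capture segments covering
#' every position of the shifted genome (canonical length plus the copied
#' origin-spanning prefix) exactly once.
#'
#' @param ref An `mt_reference`.
#' @param n_segments Number of segments (default 46, the standard panel
#'   size for the full-length genome).
#' @param arm_length Nominal probe arm length stored with the panel
#'   (annotation only).
#' @return An object of class `probe_panel` with a `segments` data frame
#'   (`segment_id`, `start`, `end`, `arm_length`; shifted-frame
#'   coordinates).
#' @export
make_panel <- function(ref, n_segments = 46L, arm_length = 20L) {
  n_segments <- as.integer(n_segments)
  Ls <- ref$length + ref$shift_bp
  if (is.na(n_segments) || n_segments < 1L)
    stop("n_segments must be >= 1", call. = FALSE)
  if (n_segments > Ls)
    stop("more segments than shifted genome positions", call. = FALSE)
  bounds <- floor(seq(0L, Ls, length.out = n_segments + 1L))
  segments <- data.frame(
    segment_id = sprintf("seg%03d", seq_len(n_segments)),
    start = as.integer(bounds[-length(bounds)] + 1L),
    end = as.integer(bounds[-1]),
    arm_length = as.integer(arm_length),
    stringsAsFactors = FALSE
  )
  structure(list(segments = segments, shifted_length = Ls,
                 ref_length = ref$length, shift_bp = ref$shift_bp),
            class = "probe_panel")
}

#' @export
print.probe_panel <- function(x, ...) {
  cat(sprintf("probe_panel: %d segments tiling %d shifted bp (genome %d + shift %d)\n",
              nrow(x$segments), x$shifted_length, x$ref_length, x$shift_bp))
  invisible(x)
}

#' Ground-truth description of one simulated sample
#'
#' Defaults reflect the capture design the caller targets: unique-read depth
#' around 4000x per segment, roughly half of the families with PCR
#' duplicates, BAQ mostly 30 with a 10% mass at 20, and a lognormal
#' (+/- 20%) per-segment depth jitter.
#'
#' @param sample_id Sample label.
#' @param haplotype_variants Data frame (`pos`, `alt`) of homoplasmic
#'   differences from the reference.
#' @param heteroplasmies Data frame (`pos`, `alt`, `vaf`) with VAFs in
#'   (0, 0.5]; molecules (families) carry the mutant allele with
#'   probability `vaf`.
#' @param numts_fraction Fraction of families drawn from NUMT sequences
#'   (in `[0, 0.5)`).
#' @param depth Target unique-read (family) depth per segment.
#' @param duplicate_rate Probability a family has >= 2 read pairs; the pair
#'   count is `min(1 + Geometric, 10)` tuned so `P(>=2)` equals this rate.
#' @param baq_levels,baq_probs Per-base BAQ distribution.
#' @param mapq Mapping quality assigned to simulated reads.
#' @param depth_jitter_sdlog Lognormal sdlog of per-segment depth jitter
#'   (0 disables).
#' @param numts_upstream_rate Fraction of true-NUMT families that also carry
#'   the aligner-level NUMT annotation.
#' @param seed Integer seed making the sample reproducible.
#' @return An object of class `truth_set`.
#' @export
truth_set <- function(sample_id = "S1",
                      haplotype_variants = NULL,
                      heteroplasmies = NULL,
                      numts_fraction = 0,
                      depth = 4000,
                      duplicate_rate = 0.5,
                      baq_levels = c(30, 20),
                      baq_probs = c(0.9, 0.1),
                      mapq = 60L,
                      depth_jitter_sdlog = 0.2,
                      numts_upstream_rate = 0.5,
                      seed = 1L) {
  empty <- function(...) {
    d <- data.frame(...)
    d[0, , drop = FALSE]
  }
  if (is.null(haplotype_variants))
    haplotype_variants <- empty(pos = 0L, alt = "A")
  if (is.null(heteroplasmies))
    heteroplasmies <- empty(pos = 0L, alt = "A", vaf = 0)
  if (nrow(heteroplasmies) &&
      (any(heteroplasmies$vaf <= 0) || any(heteroplasmies$vaf > 0.5)))
    stop("heteroplasmy VAFs must lie in (0, 0.5]", call. = FALSE)
  if (numts_fraction < 0 || numts_fraction >= 0.5)
    stop("numts_fraction must lie in [0, 0.5)", call. = FALSE)
  if (depth < 0) stop("depth must be >= 0", call. = FALSE)
  if (duplicate_rate < 0 || duplicate_rate >= 1)
    stop("duplicate_rate must lie in [0, 1)", call. = FALSE)
  structure(list(sample_id = sample_id,
                 haplotype_variants = haplotype_variants,
                 heteroplasmies = heteroplasmies,
                 numts_fraction = numts_fraction,
                 depth = depth,
                 duplicate_rate = duplicate_rate,
                 baq_levels = baq_levels, baq_probs = baq_probs,
                 mapq = as.integer(mapq),
                 depth_jitter_sdlog = depth_jitter_sdlog,
                 numts_upstream_rate = numts_upstream_rate,
                 seed = as.integer(seed)),
            class = "truth_set")
}

#' Synthetic NUMT sequence collection
#'
#' For each capture segment, generates NUMT-like variant sequences: the
#' reference segment with a fixed number of substitutions (default 2-10),
#' mimicking nuclear mitochondrial segments and their common-polymorphism
#' variants.
#'
#' @param ref An `mt_reference`.
#' @param panel A `probe_panel`.
#' @param n_per_segment Entries per segment.
#' @param n_diffs_range Range of substitution counts per entry.
#' @param seed Integer seed.
#' @return Data frame (`segment_id`, `name`, `bases`) of class `numts_db`.
#' @export
make_numts_db <- function(ref, panel, n_per_segment = 2L,
                          n_diffs_range = c(2L, 10L), seed = 99L) {
  set.seed(seed)
  segs <- panel$segments
  shifted <- shifted_sequence(ref)
  out <- list()
  for (k in seq_len(nrow(segs))) {
    seg_seq <- shifted[segs$start[k]:segs$end[k]]
    for (j in seq_len(n_per_segment)) {
      nd <- sample(n_diffs_range[1]:n_diffs_range[2], 1L)
      nd <- min(nd, length(seg_seq))
      at <- sample(length(seg_seq), nd)
      s <- seg_seq
      s[at] <- vapply(s[at], function(b) sample(setdiff(NT_CHARS, b), 1L),
                      character(1))
      out[[length(out) + 1L]] <- data.frame(
        segment_id = segs$segment_id[k],
        name = sprintf("%s_numt%d", segs$segment_id[k], j),
        bases = paste(s, collapse = ""), stringsAsFactors = FALSE)
    }
  }
  db <- do.call(rbind, out)
  class(db) <- c("numts_db", "data.frame")
  db
}

# character vector of the shifted genome (prefix = final shift_bp bases)
shifted_sequence <- function(ref) {
  if (ref$shift_bp == 0L) return(ref$bases)
  c(ref$bases[(ref$length - ref$shift_bp + 1L):ref$length], ref$bases)
}

# haplotype of a sample: reference with homoplasmic variants applied
haplotype_bases <- function(truth, ref) {
  h <- ref$bases
  hv <- truth$haplotype_variants
  if (nrow(hv)) {
    if (any(hv$pos < 1L | hv$pos > ref$length))
      stop("haplotype variant position outside genome", call. = FALSE)
    h[hv$pos] <- toupper(hv$alt)
  }
  h
}

#' Simulate barcode-grouped read families for one sample
#'
#' Draws families per probe segment (unique barcodes, truncated-geometric
#' duplicate pair counts), assigns each family's molecule from the sample
#' haplotype with heteroplasmies applied per molecule, replaces a
#' `numts_fraction` of molecules with NUMT sequences, and emits 2 reads per
#' pair spanning the segment with per-base BAQ-governed miscalls (uniform
#' over the three other bases). Deterministic under the truth set's seed.
#'
#' @param truth A `truth_set`.
#' @param panel A `probe_panel`.
#' @param ref An `mt_reference`.
#' @param numts_db Optional `numts_db`; required when
#'   `truth$numts_fraction > 0`.
#' @return Family table: one row per read with columns `barcode`,
#'   `segment_id`, `pair_index`, `mate`, `start_shifted`, `bases`, `baq`
#'   (phred+33), `mapq`, `numts_truth`, `numts_aligned`.
#' @export
simulate_families <- function(truth, panel, ref, numts_db = NULL) {
  stopifnot(inherits(truth, "truth_set"), inherits(panel, "probe_panel"))
  het <- truth$heteroplasmies
  if (nrow(het) && (any(het$pos < 1L) || any(het$pos > ref$length)))
    stop("heteroplasmy position outside genome", call. = FALSE)
  if (truth$numts_fraction > 0 && is.null(numts_db))
    stop("numts_fraction > 0 requires a numts_db", call. = FALSE)
  set.seed(truth$seed)
  hap <- haplotype_bases(truth, ref)
  hap_shift <- if (ref$shift_bp == 0L) hap else
    c(hap[(ref$length - ref$shift_bp + 1L):ref$length], hap)
  segs <- panel$segments
  out <- vector("list", nrow(segs))
  for (k in seq_len(nrow(segs))) {
    out[[k]] <- simulate_segment_families(truth, ref, numts_db,
                                          segs[k, ], hap_shift)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

simulate_segment_families <- function(truth, ref, numts_db, seg, hap_shift) {
  Lseg <- seg$end - seg$start + 1L
  nf <- truth$depth
  if (truth$depth_jitter_sdlog > 0)
    nf <- nf * stats::rlnorm(1, meanlog = -truth$depth_jitter_sdlog^2 / 2,
                             sdlog = truth$depth_jitter_sdlog)
  nf <- max(0L, as.integer(round(nf)))
  if (nf == 0L) return(NULL)

  seg_pos_shifted <- seg$start:seg$end
  seg_pos_canon <- unshift_position(seg_pos_shifted, ref)
  mol_base <- encode_bases(paste(hap_shift[seg_pos_shifted], collapse = ""))

  # molecule matrix: one row per family
  mol <- matrix(rep(mol_base, each = nf), nrow = nf)
  het <- truth$heteroplasmies
  if (nrow(het)) {
    for (i in seq_len(nrow(het))) {
      cols <- which(seg_pos_canon == het$pos[i])
      if (!length(cols)) next
      mut <- stats::runif(nf) < het$vaf[i]
      alt_code <- encode_bases(toupper(het$alt[i]))
      for (cc in cols) mol[mut, cc] <- alt_code
    }
  }
  numts_truth <- rep(FALSE, nf)
  numts_aligned <- rep(FALSE, nf)
  if (truth$numts_fraction > 0) {
    entries <- numts_db[numts_db$segment_id == seg$segment_id, , drop = FALSE]
    if (nrow(entries)) {
      is_numt <- stats::runif(nf) < truth$numts_fraction
      idx <- which(is_numt)
      if (length(idx)) {
        pick <- sample(nrow(entries), length(idx), replace = TRUE)
        for (j in seq_along(idx))
          mol[idx[j], ] <- encode_bases(entries$bases[pick[j]])
        numts_truth[idx] <- TRUE
        numts_aligned[idx] <- stats::runif(length(idx)) < truth$numts_upstream_rate
      }
    }
  }

  # duplicate structure: pairs per family = min(1 + Geom, 10), P(>=2) = rate
  pairs <- pmin(1L + stats::rgeom(nf, prob = 1 - truth$duplicate_rate), 10L)
  fam_of_pair <- rep(seq_len(nf), pairs)
  pair_index <- sequence(pairs)
  n_reads <- 2L * length(fam_of_pair)
  fam_of_read <- rep(fam_of_pair, each = 2L)
  pair_of_read <- rep(pair_index, each = 2L)
  mate <- rep(1:2, length(fam_of_pair))

  reads <- mol[fam_of_read, , drop = FALSE]
  baq <- matrix(truth$baq_levels[sample.int(length(truth$baq_levels),
                                            n_reads * Lseg, replace = TRUE,
                                            prob = truth$baq_probs)],
                n_reads, Lseg)
  # place miscalls sparsely: per BAQ level, a binomial error count over its
  # cells plus a uniform subset equals iid per-cell Bernoulli(10^(-BAQ/10))
  err_idx <- integer(0)
  for (lvl in unique(as.vector(truth$baq_levels))) {
    cells <- which(baq == lvl)
    if (!length(cells)) next
    k <- stats::rbinom(1L, length(cells), 10^(-lvl / 10))
    if (k > 0L) err_idx <- c(err_idx, sample(cells, k))
  }
  if (length(err_idx)) {
    d <- sample(1:3, length(err_idx), replace = TRUE)
    reads[err_idx] <- (reads[err_idx] - 1L + d) %% 4L + 1L
  }

  barcodes <- sprintf("%s_bc%06d", seg$segment_id, seq_len(nf))
  data.frame(
    barcode = barcodes[fam_of_read],
    segment_id = seg$segment_id,
    pair_index = pair_of_read,
    mate = mate,
    start_shifted = seg$start,
    bases = read_rows_to_strings(reads),
    baq = baq_rows_to_strings(baq),
    mapq = truth$mapq,
    numts_truth = numts_truth[fam_of_read],
    numts_aligned = numts_aligned[fam_of_read],
    stringsAsFactors = FALSE
  )
}

read_rows_to_strings <- function(code_mat) {
  ints <- utf8ToInt("ACGT")[t(code_mat)]
  n <- nrow(code_mat); L <- ncol(code_mat)
  vapply(seq_len(n), function(i) intToUtf8(ints[((i - 1L) * L + 1L):(i * L)]),
         character(1))
}

baq_rows_to_strings <- function(baq_mat) {
  ints <- t(baq_mat) + 33L
  n <- nrow(baq_mat); L <- ncol(baq_mat)
  vapply(seq_len(n), function(i) intToUtf8(ints[((i - 1L) * L + 1L):(i * L)]),
         character(1))
}

# ---- cohort-level simulation ------------------------------------------------

#' Cohort design for incidence simulations
#'
#' Defaults emulate a three-group skeletal-muscle study: 23 controls, 22
#' premanifest and 21 early-stage carriers, ages in the low 30s to late 50s,
#' and per-category Poisson mutation incidence calibrated to reported group
#' means (D-loop around 3 per sample, coding around 1-1.7, with the
#' pathogenic fraction of non-synonymous mutations rising from 0.2 in
#' controls to 1 in early-stage disease).
#'
#' @param groups Named integer vector of group sizes.
#' @param age_range Named list of (min, max) ages per group.
#' @param means Matrix of Poisson means, rows = groups, columns =
#'   categories `dloop`, `synonymous`, `nonsynonymous`, `rna`.
#' @param age_slope Named numeric log-linear age slope per category
#'   (per year, applied around `age_ref`).
#' @param age_ref Reference age at which `means` apply.
#' @param pathogenic_fraction Named per-group probability that a
#'   non-synonymous mutation is pathogenic.
#' @param seed Integer seed.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(groups = c(control = 23L, premanifest = 22L,
                                     early_stage = 21L),
                          age_range = list(control = c(31, 55),
                                           premanifest = c(31, 56),
                                           early_stage = c(35, 58)),
                          means = NULL,
                          age_slope = c(dloop = 0, synonymous = 0,
                                        nonsynonymous = 0, rna = 0),
                          age_ref = 45,
                          pathogenic_fraction = c(control = 0.2,
                                                  premanifest = 0.5,
                                                  early_stage = 1.0),
                          seed = 1L) {
  cats <- c("dloop", "synonymous", "nonsynonymous", "rna")
  if (is.null(means)) {
    means <- rbind(control = c(3.04, 0.41, 0.22, 0.41),
                   premanifest = c(2.91, 0.30, 0.55, 0.30),
                   early_stage = c(3.29, 0.64, 0.38, 0.64))
    colnames(means) <- cats
    means <- means[names(groups)[names(groups) %in% rownames(means)], ,
                   drop = FALSE]
    extra <- setdiff(names(groups), rownames(means))
    for (g in extra) {
      means <- rbind(means, control = means["control", ])
      rownames(means)[nrow(means)] <- g
    }
    means <- means[names(groups), , drop = FALSE]
  }
  if (any(groups < 1L)) stop("group sizes must be positive", call. = FALSE)
  if (any(means < 0)) stop("Poisson means must be >= 0", call. = FALSE)
  slope <- stats::setNames(rep(0, length(cats)), cats)
  slope[names(age_slope)] <- age_slope
  structure(list(groups = groups, age_range = age_range, means = means,
                 age_slope = slope, age_ref = age_ref,
                 pathogenic_fraction = pathogenic_fraction,
                 categories = cats, seed = as.integer(seed)),
            class = "cohort_design")
}

#' Catalogue of all single-nucleotide substitutions and their classes
#'
#' Enumerates the 3L possible substitutions of the genome, with region and
#' coding-effect classes. Used to place simulated mutations in
#' category-compatible sites and as the exhaustive oracle for annotation
#' round-trips.
#'
#' @param ref An `mt_reference`.
#' @return Data frame (`pos`, `ref`, `alt`, `region`, `low_complexity`,
#'   `effect`).
#' @export
substitution_catalogue <- function(ref) {
  pos <- rep(seq_len(ref$length), each = 3L)
  refb <- ref$bases[pos]
  alt <- unlist(lapply(ref$bases, function(b) setdiff(NT_CHARS, b)),
                use.names = FALSE)
  cls <- classify_region(pos, ref)
  eff <- coding_effect(pos, refb, alt, ref)
  data.frame(pos = pos, ref = refb, alt = alt, region = cls$region,
             low_complexity = cls$low_complexity, effect = eff,
             stringsAsFactors = FALSE)
}

#' Simulate a cohort of samples with known mutation incidence
#'
#' Per-sample category counts are drawn from the design's Poisson model
#' (log-linear in age around the reference age); mutation positions and
#' alleles are placed uniformly among category-compatible substitutions
#' outside low-complexity intervals, with VAFs uniform on (0.01, 0.10).
#'
#' @param design A `cohort_design`.
#' @param ref An `mt_reference`.
#' @param catalogue Optional precomputed [substitution_catalogue()].
#' @return List with `mutations` (per-sample truth mutation table),
#'   `counts` (cohort table of true per-category counts, see
#'   [tabulate_sample()] for columns) and `samples` (sample metadata).
#' @export
simulate_cohort <- function(design, ref, catalogue = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  if (is.null(catalogue)) catalogue <- substitution_catalogue(ref)
  cat_pool <- list(
    dloop = catalogue[catalogue$region == "dloop" & !catalogue$low_complexity, ],
    synonymous = catalogue[catalogue$effect == "synonymous" &
                             !catalogue$low_complexity, ],
    nonsynonymous = catalogue[catalogue$effect == "non_synonymous" &
                                !catalogue$low_complexity, ],
    rna = catalogue[catalogue$effect == "rna" & !catalogue$low_complexity, ]
  )
  samples <- list(); muts <- list()
  sid <- 0L
  for (g in names(design$groups)) {
    for (i in seq_len(design$groups[[g]])) {
      sid <- sid + 1L
      id <- sprintf("%s_%02d", g, i)
      rng <- design$age_range[[g]]
      age <- round(stats::runif(1, rng[1], rng[2]), 1)
      row <- data.frame(sample_id = id, group = g, age = age,
                        stringsAsFactors = FALSE)
      for (cat in design$categories) {
        lam <- design$means[g, cat] *
          exp(design$age_slope[[cat]] * (age - design$age_ref))
        n <- stats::rpois(1, lam)
        row[[cat]] <- n
        if (n > 0L && nrow(cat_pool[[cat]])) {
          pick <- cat_pool[[cat]][sample(nrow(cat_pool[[cat]]), n,
                                         replace = FALSE), ]
          pick$sample_id <- id; pick$group <- g; pick$age <- age
          pick$category <- cat
          pick$pathogenic <- if (cat == "nonsynonymous")
            stats::runif(n) < design$pathogenic_fraction[[g]] else FALSE
          pick$vaf <- stats::runif(n, 0.01, 0.10)
          muts[[length(muts) + 1L]] <- pick
        }
      }
      samples[[sid]] <- row
    }
  }
  counts <- do.call(rbind, samples)
  counts$coding <- counts$synonymous + counts$nonsynonymous + counts$rna
  counts$all <- counts$dloop + counts$coding
  mutations <- if (length(muts)) do.call(rbind, muts) else
    data.frame(pos = integer(), ref = character(), alt = character(),
               region = character(), low_complexity = logical(),
               effect = character(), sample_id = character(),
               group = character(), age = numeric(), category = character(),
               pathogenic = logical(), vaf = numeric())
  mutations$pathogenic_truth <- mutations$pathogenic
  counts$pathogenic_nonsyn <- vapply(counts$sample_id, function(s)
    sum(mutations$pathogenic[mutations$sample_id == s]), numeric(1))
  rownames(counts) <- rownames(mutations) <- NULL
  list(mutations = mutations, counts = counts,
       samples = counts[, c("sample_id", "group", "age")])
}

#' Build annotation lookup tables consistent with a simulated truth
#'
#' Produces CADD-phred-like, disease-association and known-polymorphism
#' tables (keyed by `pos`, `alt`) such that annotating the simulated
#' mutations under the pathogenicity rule reproduces the designed
#' pathogenic flags: pathogenic non-synonymous truth mutations get a CADD
#' phred > 20 and no polymorphism entry; non-pathogenic ones get a low
#' score (or a polymorphism entry when `polymorphic_fraction` applies).
#'
#' @param mutations Truth mutation table from [simulate_cohort()].
#' @param seed Integer seed.
#' @param polymorphic_fraction Fraction of non-pathogenic non-synonymous
#'   mutations masked via the known-polymorphism list despite a high score.
#' @return List of data frames `cadd`, `disease`, `polymorphisms`.
#' @export
make_annotation_tables <- function(mutations, seed = 7L,
                                   polymorphic_fraction = 0.25) {
  set.seed(seed)
  ns <- unique(mutations[mutations$effect == "non_synonymous",
                         c("pos", "ref", "alt", "pathogenic_truth")])
  if (!nrow(ns))
    return(list(
      cadd = data.frame(pos = integer(), ref = character(),
                        alt = character(), phred = numeric()),
      disease = data.frame(pos = integer(), alt = character(),
                           source = character()),
      polymorphisms = data.frame(pos = integer(), alt = character(),
                                 frequency = numeric())))
  # a (pos, alt) may be drawn as pathogenic in one sample and not another;
  # resolve at the allele level (pathogenic wins) to keep tables consistent
  key <- paste(ns$pos, ns$alt)
  patho <- tapply(ns$pathogenic_truth, key, any)
  ns <- ns[!duplicated(key), ]
  ns$pathogenic_truth <- as.logical(patho[paste(ns$pos, ns$alt)])
  n <- nrow(ns)
  phred <- ifelse(ns$pathogenic_truth, stats::runif(n, 21, 40),
                  stats::runif(n, 0.1, 15))
  masked <- !ns$pathogenic_truth & stats::runif(n) < polymorphic_fraction
  phred[masked] <- stats::runif(sum(masked), 21, 40)
  cadd <- data.frame(pos = ns$pos, ref = ns$ref, alt = ns$alt,
                     phred = round(phred, 2))
  dz <- ns$pathogenic_truth & phred <= 21
  disease <- data.frame(pos = ns$pos[dz], alt = ns$alt[dz],
                        source = rep("simulated", sum(dz)))
  poly <- data.frame(pos = ns$pos[masked], alt = ns$alt[masked],
                     frequency = round(stats::runif(sum(masked), 0.01, 0.5), 3))
  list(cadd = cadd, disease = disease, polymorphisms = poly)
}
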