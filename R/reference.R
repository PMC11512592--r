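#' Circular mtDNA reference with region map
#'
#' Builds the central reference object used throughout the pipeline: the
#' circular genome sequence, the D-loop (control region) interval, a set of
#' low-complexity intervals that are masked during variant calling, the gene
#' table (protein / tRNA / rRNA features with strand and reading frame), and
#' the shift convention used at alignment time (the final `shift_bp` bases of
#' the circle are copied to the front of the "shifted" frame so that reads
#' spanning the origin align contiguously).
#'
#' Coordinates are 1-based inclusive throughout ("m." notation). Intervals
#' with `start > end` wrap around the origin; wrapping is supported for the
#' D-loop and for region classification, but protein-coding features must not
#' wrap.
#'
#' @param sequence Single nucleotide string (A/C/G/T), the circular genome in
#'   canonical orientation.
#' @param regions Data frame with columns `name`, `kind` (one of `protein`,
#'   `tRNA`, `rRNA`, `dloop`, `low_complexity`), `start`, `end`, `strand`
#'   (`heavy`/`light`, `.` for non-genes) and `frame_start` (1-based position
#'   of codon 1; `NA` for non-protein rows).
#' @param shift_bp Number of terminal bases copied to the start of the
#'   shifted frame (default 120).
#' @return An object of class `mt_reference`.
#' @seealso [load_reference()], [classify_region()], [coding_effect()]
#' @export
mt_reference <- function(sequence, regions, shift_bp = 120L) {
  sequence <- toupper(as.character(sequence)[1])
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(bases)
  if (L < 1L) stop("reference sequence is empty", call. = FALSE)
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("reference sequence must contain only A/C/G/T", call. = FALSE)
  shift_bp <- as.integer(shift_bp)
  if (shift_bp < 0L || shift_bp >= L)
    stop("shift_bp must be in [0, length)", call. = FALSE)

  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  req <- c("name", "kind", "start", "end")
  if (!all(req %in% names(regions)))
    stop("region config needs columns name, kind, start, end", call. = FALSE)
  if (is.null(regions$strand)) regions$strand <- "."
  if (is.null(regions$frame_start)) regions$frame_start <- NA_integer_
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  regions$frame_start <- as.integer(regions$frame_start)

  bad <- regions$start < 1L | regions$start > L | regions$end < 1L | regions$end > L
  if (any(bad))
    stop(sprintf("region interval out of bounds [1, %d]: %s",
                 L, paste(regions$name[bad], collapse = ", ")), call. = FALSE)

  kinds <- c("protein", "tRNA", "rRNA", "dloop", "low_complexity")
  if (!all(regions$kind %in% kinds))
    stop("unknown region kind: ",
         paste(setdiff(regions$kind, kinds), collapse = ", "), call. = FALSE)

  dl <- regions[regions$kind == "dloop", , drop = FALSE]
  if (nrow(dl) > 1L) stop("more than one dloop interval configured", call. = FALSE)
  dloop <- if (nrow(dl) == 1L) c(dl$start, dl$end) else NULL

  lc <- regions[regions$kind == "low_complexity", , drop = FALSE]
  if (nrow(lc) > 1L) {
    pos_lc <- unlist(lapply(seq_len(nrow(lc)), function(i)
      interval_positions(lc$start[i], lc$end[i], L)))
    if (anyDuplicated(pos_lc))
      stop("low-complexity intervals overlap", call. = FALSE)
  }

  genes <- regions[regions$kind %in% c("protein", "tRNA", "rRNA"), , drop = FALSE]
  if (nrow(genes)) {
    pr <- genes$kind == "protein"
    if (any(pr & genes$start > genes$end))
      stop("protein features must not wrap the origin", call. = FALSE)
    if (any(pr & is.na(genes$frame_start)))
      stop("protein features need frame_start", call. = FALSE)
    if (any(pr & !(genes$strand %in% c("heavy", "light"))))
      stop("protein features need strand heavy/light", call. = FALSE)
  }

  structure(list(
    sequence = sequence,
    bases = bases,
    length = L,
    shift_bp = shift_bp,
    dloop = dloop,
    low_complexity = lc[, c("name", "start", "end"), drop = FALSE],
    gene_table = genes[, c("name", "kind", "start", "end", "strand", "frame_start"),
                       drop = FALSE],
    regions = regions
  ), class = "mt_reference")
}

#' @export
print.mt_reference <- function(x, ...) {
  cat(sprintf("mt_reference: circular genome of %d bp (shift %d bp)\n",
              x$length, x$shift_bp))
  if (!is.null(x$dloop))
    cat(sprintf("  D-loop: m.%d-m.%d%s\n", x$dloop[1], x$dloop[2],
                if (x$dloop[1] > x$dloop[2]) " (wraps origin)" else ""))
  cat(sprintf("  genes: %d protein, %d tRNA, %d rRNA; %d low-complexity intervals\n",
              sum(x$gene_table$kind == "protein"),
              sum(x$gene_table$kind == "tRNA"),
              sum(x$gene_table$kind == "rRNA"),
              nrow(x$low_complexity)))
  invisible(x)
}

# positions of a 1-based inclusive interval, wrap-aware
interval_positions <- function(start, end, L) {
  if (start <= end) start:end else c(start:L, 1:end)
}

in_interval <- function(pos, start, end) {
  if (start <= end) pos >= start & pos <= end else pos >= start | pos <= end
}

#' Load a circular mtDNA reference from FASTA plus a region config
#'
#' @param fasta_path Path to a single-record FASTA file.
#' @param region_config Path to a TSV with columns `name`, `kind`, `start`,
#'   `end`, `strand`, `frame_start`, or a data frame with those columns.
#' @param shift_bp See [mt_reference()].
#' @return An `mt_reference` object.
#' @export
load_reference <- function(fasta_path, region_config, shift_bp = 120L) {
  dna <- Biostrings::readDNAStringSet(fasta_path)
  if (length(dna) != 1L)
    stop(sprintf("FASTA '%s' must contain exactly one sequence (found %d)",
                 fasta_path, length(dna)), call. = FALSE)
  regions <- if (is.character(region_config)) {
    read_region_config(region_config)
  } else {
    region_config
  }
  mt_reference(as.character(dna[[1]]), regions, shift_bp = shift_bp)
}

#' Read a region/gene configuration TSV
#'
#' @param path TSV with header `name kind start end strand frame_start`.
#' @return Data frame suitable for [mt_reference()].
#' @export
read_region_config <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(name = "character", kind = "character",
                                   strand = "character"),
                    na.strings = c("NA", "."))
}

#' Map positions between the shifted and the canonical frame
#'
#' Alignment uses a "shifted" genome in which the final `shift_bp` bases are
#' copied to the front, so a position in the shifted frame can denote either
#' the copied prefix (mapping to the end of the circle) or the body (mapping
#' one-to-one after subtracting the shift). `unshift_position()` normalises a
#' shifted coordinate to the canonical circle; `shift_position()` gives the
#' body coordinate of a canonical position in the shifted frame.
#'
#' @param pos Integer vector of 1-based positions.
#' @param ref An `mt_reference`.
#' @return Integer vector of mapped 1-based positions.
#' @export
unshift_position <- function(pos, ref) {
  pos <- as.integer(pos)
  L <- ref$length; s <- ref$shift_bp
  if (any(is.na(pos)) || any(pos < 1L) || any(pos > L + s))
    stop(sprintf("shifted position out of range [1, %d]", L + s), call. = FALSE)
  ifelse(pos <= s, L - s + pos, pos - s)
}

#' @rdname unshift_position
#' @export
shift_position <- function(pos, ref) {
  pos <- as.integer(pos)
  L <- ref$length; s <- ref$shift_bp
  if (any(is.na(pos)) || any(pos < 1L) || any(pos > L))
    stop(sprintf("canonical position out of range [1, %d]", L), call. = FALSE)
  pos + s
}

#' Classify genome positions by region
#'
#' Assigns each position its primary region class -- `dloop` when inside the
#' (possibly origin-wrapping) control region, otherwise `protein_coding` or
#' `rna_coding` when covered by a gene feature, otherwise `other_coding` --
#' plus an independent low-complexity overlay flag.
#'
#' @param pos Integer vector of canonical 1-based positions.
#' @param ref An `mt_reference`.
#' @return Data frame with columns `pos`, `region` and `low_complexity`.
#' @export
classify_region <- function(pos, ref) {
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L) || any(pos > ref$length))
    stop(sprintf("position out of range [1, %d]", ref$length), call. = FALSE)
  region <- region_class_vector(ref)[pos]
  lc <- logical(length(pos))
  if (nrow(ref$low_complexity)) {
    for (i in seq_len(nrow(ref$low_complexity)))
      lc <- lc | in_interval(pos, ref$low_complexity$start[i],
                             ref$low_complexity$end[i])
  }
  data.frame(pos = pos, region = region, low_complexity = lc,
             stringsAsFactors = FALSE)
}

# full-genome vector of primary region classes (cached per call site)
region_class_vector <- function(ref) {
  cls <- rep("other_coding", ref$length)
  gt <- ref$gene_table
  if (nrow(gt)) {
    for (i in seq_len(nrow(gt))) {
      p <- interval_positions(gt$start[i], gt$end[i], ref$length)
      val <- if (gt$kind[i] == "protein") "protein_coding" else "rna_coding"
      cls[p][cls[p] == "other_coding"] <- val
    }
  }
  if (!is.null(ref$dloop))
    cls[interval_positions(ref$dloop[1], ref$dloop[2], ref$length)] <- "dloop"
  cls
}

# D-loop vs coding distinction used by the read-level mismatch screen
is_dloop <- function(pos, ref) {
  if (is.null(ref$dloop)) return(rep(FALSE, length(pos)))
  in_interval(pos, ref$dloop[1], ref$dloop[2])
}

MT_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Coding effect of a single-nucleotide substitution
#'
#' Classifies substitutions as `synonymous`/`non_synonymous` inside protein
#' features (translating with the vertebrate mitochondrial genetic code,
#' reverse-complementing light-strand genes, and completing incomplete
#' terminal codons with A per the polyadenylation convention), `rna` inside
#' tRNA/rRNA features, and `non_coding` elsewhere. Vectorised over `pos`,
#' `ref_allele`, `alt_allele`.
#'
#' @param pos Canonical 1-based positions.
#' @param ref_allele,alt_allele Single-nucleotide alleles; `ref_allele` must
#'   match the reference sequence.
#' @param ref An `mt_reference`.
#' @return Character vector of effect classes.
#' @export
coding_effect <- function(pos, ref_allele, alt_allele, ref) {
  pos <- as.integer(pos)
  n <- length(pos)
  ref_allele <- toupper(rep_len(ref_allele, n))
  alt_allele <- toupper(rep_len(alt_allele, n))
  if (any(pos < 1L) || any(pos > ref$length))
    stop("position out of range", call. = FALSE)
  mism <- ref$bases[pos] != ref_allele
  if (any(mism))
    stop(sprintf("ref allele mismatch at m.%s (reference has %s)",
                 paste(pos[mism], collapse = ","),
                 paste(ref$bases[pos[mism]], collapse = ",")), call. = FALSE)
  if (!all(alt_allele %in% c("A", "C", "G", "T")))
    stop("alt alleles must be single nucleotides A/C/G/T", call. = FALSE)

  code <- mito_genetic_code()
  gt <- ref$gene_table
  out <- rep("non_coding", n)
  for (j in seq_len(n)) {
    p <- pos[j]
    hit <- NULL
    if (nrow(gt)) {
      inside <- vapply(seq_len(nrow(gt)), function(i)
        in_interval(p, gt$start[i], gt$end[i]), logical(1))
      prot <- which(inside & gt$kind == "protein")
      rna <- which(inside & gt$kind != "protein")
      if (length(prot)) hit <- gt[prot[1], ] else if (length(rna)) {
        out[j] <- "rna"; next
      }
    }
    if (is.null(hit)) next
    out[j] <- protein_effect(p, alt_allele[j], hit, ref, code)
  }
  out
}

mito_genetic_code <- function() {
  Biostrings::getGeneticCode("2")
}

# effect of one substitution inside one protein feature
protein_effect <- function(p, alt, gene, ref, code) {
  heavy <- gene$strand == "heavy"
  fs <- gene$frame_start
  offset <- if (heavy) p - fs else fs - p
  if (offset < 0L) return("non_coding")   # upstream of the annotated frame
  ci <- offset %/% 3L
  cpos <- if (heavy) fs + 3L * ci + 0:2 else fs - 3L * ci - 0:2
  mrna_base <- function(q, subst_pos = NA, subst = NA) {
    vapply(q, function(g) {
      if (g < 1L || g > ref$length ||
          (heavy && g > gene$end) || (!heavy && g < gene$start))
        return("A")  # incomplete stop codon completed by polyadenylation
      b <- if (!is.na(subst_pos) && g == subst_pos) subst else ref$bases[g]
      if (heavy) b else unname(MT_COMPLEMENT[b])
    }, character(1))
  }
  cod_ref <- paste(mrna_base(cpos), collapse = "")
  cod_alt <- paste(mrna_base(cpos, subst_pos = p, subst = alt), collapse = "")
  if (unname(code[cod_ref]) == unname(code[cod_alt])) "synonymous" else "non_synonymous"
}

#' Paths to the bundled miniature reference fixtures
#'
#' A 2,000-bp synthetic circular mini-genome with two protein genes (one per
#' strand), one tRNA, one rRNA, a 300-bp origin-wrapping "D-loop" and two
#' low-complexity intervals, plus a full-length (16,569-bp coordinate frame)
#' region config with the standard human mtDNA gene annotation.
#'
#' @return Named list of file paths (`mini_fasta`, `mini_regions`,
#'   `rcrs_regions`).
#' @export
reference_fixtures <- function() {
  list(
    mini_fasta = system.file("extdata", "mini_genome.fa", package = "mtstamp",
                             mustWork = TRUE),
    mini_regions = system.file("extdata", "mini_genome_regions.tsv",
                               package = "mtstamp", mustWork = TRUE),
    rcrs_regions = system.file("extdata", "rcrs_like_regions.tsv",
                               package = "mtstamp", mustWork = TRUE)
  )
}

#' Load the bundled 2,000-bp mini reference
#'
#' @param shift_bp Shift convention to use (default 120, as for the
#'   full-length genome).
#' @return An `mt_reference`.
#' @export
load_mini_reference <- function(shift_bp = 120L) {
  fx <- reference_fixtures()
  load_reference(fx$mini_fasta, fx$mini_regions, shift_bp = shift_bp)
}

#' Synthetic full-length mtDNA-like genome
#'
#' Generates a random 16,569-bp sequence compatible with the bundled
#' full-length region config. The sequence is synthetic (the true rCRS
#' sequence is not bundled); it supports coordinate-frame and pipeline demos
#' at the canonical genome size.
#'
#' @param seed Integer seed.
#' @return An `mt_reference` of length 16,569.
#' @export
synthetic_full_length_reference <- function(seed = 1L) {
  withr_seed <- .Random.seed_exists()
  old <- if (withr_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (withr_seed) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  seqc <- paste(sample(c("A", "C", "G", "T"), 16569L, replace = TRUE),
                collapse = "")
  mt_reference(seqc, read_region_config(reference_fixtures()$rcrs_regions),
               shift_bp = 120L)
}

.Random.seed_exists <- function() exists(".Random.seed", envir = globalenv())
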