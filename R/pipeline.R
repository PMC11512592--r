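# Pipeline orchestration and file IO: configuration, per-sample stage
# execution (families -> consensus -> pileup -> calls -> annotation),
# cohort reports, TSV/VCF writers and a provenance block.

#' Pipeline configuration
#'
#' Bundles the reference, panel geometry, error model and filter thresholds
#' with their standard defaults.
#'
#' @param ref An `mt_reference`.
#' @param n_segments Probe panel size (46 for the full-length genome; use
#'   fewer for miniature genomes).
#' @param model An [error_model()].
#' @param thresholds A [caller_thresholds()] list.
#' @param consensus_order Mate-overlap merge order, see
#'   [build_consensus_set()].
#' @param seed Integer base seed for simulation-driven runs.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(ref, n_segments = 46L,
                            model = error_model(),
                            thresholds = caller_thresholds(),
                            consensus_order = "overlap_first",
                            seed = 1L) {
  stopifnot(inherits(ref, "mt_reference"), inherits(model, "error_model"),
            inherits(thresholds, "caller_thresholds"))
  structure(list(ref = ref, panel = make_panel(ref, n_segments),
                 model = model, thresholds = thresholds,
                 consensus_order = consensus_order,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the calling pipeline for one sample
#'
#' families -> consensus reads -> NUMT/mismatch-screened pileup -> variant
#' calls -> contamination screen.
#'
#' @param families Family table (see [simulate_families()]).
#' @param config A `pipeline_config`.
#' @param numts_db Optional `numts_db`.
#' @param polymorphisms Optional known-polymorphism table for the
#'   contamination screen.
#' @return List `consensus`, `pileup`, `calls`, `contamination`.
#' @export
call_sample <- function(families, config, numts_db = NULL,
                        polymorphisms = NULL) {
  consensus <- build_consensus_set(families, config$panel,
                                   order = config$consensus_order)
  pileup <- build_pileup(consensus, config$ref, config$panel,
                         numts_db = numts_db,
                         thresholds = config$thresholds)
  calls <- call_variants(pileup, config$model, config$ref)
  contamination <- if (!is.null(polymorphisms))
    contamination_check(calls, polymorphisms, config$ref,
                        threshold = config$thresholds$contamination_n)
  else NULL
  list(consensus = consensus, pileup = pileup, calls = calls,
       contamination = contamination)
}

#' Run the full pipeline over a simulated or supplied cohort
#'
#' For each sample, executes the per-sample calling stages, annotates the
#' calls and tabulates incidence; then produces the cohort-level reports.
#' All artifacts are written under `out_dir` as plain-text TSV/VCF/JSON,
#' with per-stage record counts logged via `message()`.
#'
#' @param config A `pipeline_config`.
#' @param truths List of `truth_set` objects (one per sample) to simulate
#'   from, or `NULL` when `family_tables` supplies pre-made read families.
#' @param family_tables Optional named list of family tables keyed by
#'   sample id.
#' @param metadata Data frame (`sample_id`, `group`, `age`).
#' @param tables Annotation tables, see [annotate_calls()].
#' @param numts_db Optional `numts_db`.
#' @param out_dir Output directory (created if missing); `NULL` disables
#'   writing.
#' @return List `per_sample` (per-sample stage results), `mutations`
#'   (annotated mutation table), `cohort` (cohort count table), `report`
#'   ([cohort_report()] output), `provenance`.
#' @export
run_pipeline <- function(config, truths = NULL, family_tables = NULL,
                         metadata, tables, numts_db = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(truths) && is.null(family_tables))
    stop("supply either truths or family_tables", call. = FALSE)
  ids <- metadata$sample_id
  per_sample <- list(); mutlist <- list()
  counts_log <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    fam <- if (!is.null(family_tables)) {
      if (is.null(family_tables[[id]]))
        stop(sprintf("missing family table for sample '%s' (stage: input)",
                     id), call. = FALSE)
      family_tables[[id]]
    } else {
      simulate_families(truths[[i]], config$panel, config$ref, numts_db)
    }
    res <- call_sample(fam, config, numts_db = numts_db,
                       polymorphisms = tables$polymorphisms)
    ann <- annotate_calls(res$calls, config$ref, tables)
    if (nrow(ann)) ann$sample_id <- id
    res$annotated <- ann
    per_sample[[id]] <- res
    mutlist[[id]] <- ann
    counts_log[[id]] <- c(reads = nrow(fam), consensus = nrow(res$consensus),
                          called = sum(res$calls$called))
    message(sprintf("[%s] reads=%d consensus=%d evaluated=%d called=%d",
                    id, nrow(fam), nrow(res$consensus), nrow(res$calls),
                    sum(res$calls$called)))
  }
  mutations <- do.call(rbind, mutlist[vapply(mutlist, nrow, 1L) > 0])
  if (is.null(mutations))
    mutations <- cbind(empty_calls()[0, ],
                       data.frame(alt = character(), region = character(),
                                  low_complexity = logical(),
                                  effect = character(),
                                  cadd_phred = numeric(),
                                  disease_associated = logical(),
                                  known_polymorphism = logical(),
                                  pathogenic = logical(),
                                  sample_id = character()))
  cohort <- tabulate_cohort(mutations, metadata)
  groups <- unique(metadata$group)
  ctrl <- intersect("control", groups)
  cases <- setdiff(groups, c("control", "external_control"))
  report <- if (length(ctrl) && length(cases))
    cohort_report(cohort, control_groups = ctrl, case_groups = cases,
                  trend_groups = list(controls = ctrl, cases = cases))
  else NULL
  provenance <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    n_samples = length(ids),
    genome_length = config$ref$length,
    n_segments = nrow(config$panel$segments),
    thresholds = unclass(config$thresholds),
    error_model = unclass(config$model),
    stage_counts = counts_log
  )
  out <- list(per_sample = per_sample, mutations = mutations,
              cohort = cohort, report = report, provenance = provenance)
  if (!is.null(out_dir)) write_pipeline_artifacts(out, config, out_dir)
  invisible(out)
}

write_pipeline_artifacts <- function(result, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(result$per_sample)) {
    calls <- result$per_sample[[id]]$calls
    write_calls_vcf(calls, config$ref,
                    file.path(out_dir, paste0(id, ".calls.vcf")),
                    sample_id = id)
  }
  write_tsv(result$mutations, file.path(out_dir, "mutations.tsv"))
  write_tsv(result$cohort, file.path(out_dir, "cohort_counts.tsv"))
  if (!is.null(result$report)) {
    write_tsv(result$report$means, file.path(out_dir, "report_means.tsv"))
    write_tsv(result$report$age_trends,
              file.path(out_dir, "report_age_trends.tsv"))
  }
  jsonlite::write_json(result$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}

# ---- tabular IO -------------------------------------------------------------

#' Read and write the family-table and generic TSV dialects
#'
#' `write_family_table()`/`read_family_table()` round-trip the read-family
#' dialect losslessly; malformed rows raise a line-numbered error.
#'
#' @param families Family table data frame.
#' @param path File path.
#' @return `read_family_table()` returns the family table.
#' @export
write_family_table <- function(families, path) {
  write_tsv(families, path)
}

#' @rdname write_family_table
#' @export
read_family_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         quote = "", comment.char = "")
  need <- c("barcode", "segment_id", "pair_index", "mate", "start_shifted",
            "bases", "baq", "mapq")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(sprintf("family table '%s' lacks columns: %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  bad <- which(nchar(x$bases) != nchar(x$baq))
  if (length(bad))
    stop(sprintf("family table '%s': base/BAQ length mismatch at line %d",
                 path, bad[1] + 1L), call. = FALSE)
  x
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write variant calls as a VCF-dialect file
#'
#' One record per *called* variant with INFO fields `VAF`, `VAFDUP`,
#' `MINOR`, `DEPTH` and the six filter verdicts; an empty call set yields a
#' valid header-only file.
#'
#' @param calls A `variant_calls` data frame.
#' @param ref An `mt_reference`.
#' @param path Output path.
#' @param sample_id Sample label recorded in the header.
#' @param contig Contig name for the CHROM column.
#' @return The path, invisibly.
#' @export
write_calls_vcf <- function(calls, ref, path, sample_id = "sample",
                            contig = "chrM") {
  called <- calls[calls$called, , drop = FALSE]
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contig, ref$length),
    sprintf("##sample=<ID=%s>", sample_id),
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Minor allele fraction over all qualifying consensus reads\">",
    "##INFO=<ID=VAFDUP,Number=1,Type=Float,Description=\"Minor allele fraction over duplicate-built consensus reads\">",
    "##INFO=<ID=MINOR,Number=1,Type=Integer,Description=\"Minor allele count\">",
    "##INFO=<ID=DEPTH,Number=1,Type=Integer,Description=\"Qualifying consensus read depth\">",
    "##INFO=<ID=MAJOR,Number=1,Type=String,Description=\"Sample major allele\">",
    "##INFO=<ID=FILTERS,Number=6,Type=String,Description=\"Verdicts depth,lowcomp,minminor,loglik,dup,poisson\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  recs <- character(0)
  if (nrow(called)) {
    verdict <- function(v) ifelse(v, "PASS", "FAIL")
    info <- sprintf(
      "VAF=%.6g;VAFDUP=%.6g;MINOR=%d;DEPTH=%d;MAJOR=%s;FILTERS=%s,%s,%s,%s,%s,%s",
      called$vaf, called$vaf_dup, called$minor_count, called$depth,
      called$major_allele,
      verdict(called$f_depth), verdict(called$f_lowcomp),
      verdict(called$f_minminor), verdict(called$f_loglik),
      verdict(called$f_dup), verdict(called$f_poisson))
    recs <- sprintf("%s\t%d\t.\t%s\t%s\t%.0f\tPASS\t%s",
                    contig, called$pos, called$ref_allele,
                    called$minor_allele,
                    pmin(called$loglik, 9999), info)
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}
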