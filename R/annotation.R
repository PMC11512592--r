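# Functional annotation of called mutations: region class, coding effect
# under the vertebrate mitochondrial code, and the pathogenicity rule
# (non-synonymous, CADD phred > 20 or disease-associated, and not a known
# polymorphism).

#' Annotate called variants
#'
#' Adds genomic region, coding effect and pathogenicity to variant calls.
#' The substitution annotated is reference -> minor allele; when the minor
#' allele equals the reference base (a heteroplasmy restoring the reference
#' on a divergent haplotype), the major allele is annotated instead so the
#' two alleles actually segregating are compared. Lookup tables are keyed by
#' `(pos, alt)`; a missing CADD entry is treated as "not > 20".
#'
#' Pathogenicity is restricted to protein-altering changes:
#' `non_synonymous` effect AND (CADD phred > 20 OR disease association) AND
#' not a known polymorphism.
#'
#' @param calls A `variant_calls` data frame.
#' @param ref An `mt_reference`.
#' @param tables List with data frames `cadd` (`pos`, `alt`, `phred`),
#'   `disease` (`pos`, `alt`) and `polymorphisms` (`pos`, `alt`).
#' @param called_only Annotate only rows with `called = TRUE` (default).
#' @return Data frame of class `annotated_mutations`: the call columns plus
#'   `alt` (annotated allele), `region`, `low_complexity`, `effect`,
#'   `cadd_phred`, `disease_associated`, `known_polymorphism`,
#'   `pathogenic`.
#' @export
annotate_calls <- function(calls, ref, tables, called_only = TRUE) {
  x <- if (called_only) calls[calls$called, , drop = FALSE] else calls
  if (!nrow(x)) {
    out <- cbind(x, data.frame(alt = character(), region = character(),
                               low_complexity = logical(),
                               effect = character(), cadd_phred = numeric(),
                               disease_associated = logical(),
                               known_polymorphism = logical(),
                               pathogenic = logical()))
    class(out) <- c("annotated_mutations", "data.frame")
    return(out)
  }
  alt <- ifelse(x$minor_allele == x$ref_allele, x$major_allele,
                x$minor_allele)
  cls <- classify_region(x$pos, ref)
  eff <- coding_effect(x$pos, x$ref_allele, alt, ref)
  key <- paste(x$pos, alt)
  cadd <- tables$cadd
  cadd_phred <- cadd$phred[match(key, paste(cadd$pos, cadd$alt))]
  disease <- key %in% paste(tables$disease$pos, tables$disease$alt)
  poly <- key %in% paste(tables$polymorphisms$pos, tables$polymorphisms$alt)
  out <- x
  out$alt <- alt
  out$region <- cls$region
  out$low_complexity <- cls$low_complexity
  out$effect <- eff
  out$cadd_phred <- cadd_phred
  out$disease_associated <- disease
  out$known_polymorphism <- poly
  out$pathogenic <- eff == "non_synonymous" &
    ((!is.na(cadd_phred) & cadd_phred > 20) | disease) & !poly
  rownames(out) <- NULL
  class(out) <- c("annotated_mutations", "data.frame")
  out
}

#' Per-sample mutation category counts
#'
#' Tabulates annotated mutations of one sample into the standard incidence
#' categories: `all`, `dloop`, `coding` (everything outside the D-loop,
#' including RNA genes and other non-D-loop sites), `synonymous`,
#' `nonsynonymous`, `rna` and `pathogenic_nonsyn`.
#'
#' @param mutations An `annotated_mutations` data frame for one sample.
#' @return One-row data frame of counts.
#' @export
tabulate_sample <- function(mutations) {
  dl <- mutations$region == "dloop"
  data.frame(
    all = nrow(mutations),
    dloop = sum(dl),
    coding = sum(!dl),
    synonymous = sum(mutations$effect == "synonymous"),
    nonsynonymous = sum(mutations$effect == "non_synonymous"),
    rna = sum(mutations$effect == "rna"),
    pathogenic_nonsyn = sum(mutations$pathogenic)
  )
}

#' Tabulate a cohort of annotated samples
#'
#' @param mutations An `annotated_mutations` data frame with a `sample_id`
#'   column.
#' @param metadata Data frame (`sample_id`, `group`, `age`); samples
#'   without mutations get zero counts.
#' @return Cohort table: metadata columns plus the [tabulate_sample()]
#'   categories.
#' @export
tabulate_cohort <- function(mutations, metadata) {
  rows <- lapply(seq_len(nrow(metadata)), function(i) {
    m <- mutations[mutations$sample_id == metadata$sample_id[i], ,
                   drop = FALSE]
    cbind(metadata[i, c("sample_id", "group", "age"), drop = FALSE],
          tabulate_sample(m))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read the annotation lookup tables from TSV files
#'
#' @param cadd,disease,polymorphisms File paths; columns as documented in
#'   [annotate_calls()].
#' @return List of data frames.
#' @export
read_annotation_tables <- function(cadd, disease, polymorphisms) {
  list(cadd = utils::read.delim(cadd, stringsAsFactors = FALSE),
       disease = utils::read.delim(disease, stringsAsFactors = FALSE),
       polymorphisms = utils::read.delim(polymorphisms,
                                         stringsAsFactors = FALSE))
}
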