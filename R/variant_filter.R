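# Technical- and frequency-based pre-filters applied before any
# information-theory analysis.

#' Filter configuration
#'
#' @param min_qual minimum variant QUAL kept (inclusive).
#' @param min_base_phred upstream caller's base-quality setting; recorded for
#'   the report only, not applied here.
#' @param max_population_af population allele frequency at or above which a
#'   variant is considered common.
#' @param max_cohort_carriers cohort carrier count above which (strictly) a
#'   variant is considered common.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_qual = 50, min_base_phred = 30,
                          max_population_af = 0.01, max_cohort_carriers = 5L) {
  stopifnot(min_qual >= 0, max_population_af >= 0, max_cohort_carriers >= 0)
  structure(list(min_qual = min_qual, min_base_phred = min_base_phred,
                 max_population_af = max_population_af,
                 max_cohort_carriers = as.integer(max_cohort_carriers)),
            class = "filter_config")
}

#' Remove low-quality variant calls
#'
#' Variants with `QUAL < min_qual` (or missing QUAL) are removed; the
#' boundary value itself is kept.
#'
#' @param variants data.frame with at least a `qual` column.
#' @param config a [filter_config()].
#' @return list with `kept` and `removed` data.frames; `removed` gains a
#'   `reason` column.
#' @export
technical_filter <- function(variants, config = filter_config()) {
  qual <- variants$qual
  fail_missing <- is.na(qual)
  fail_low <- !fail_missing & qual < config$min_qual
  removed <- variants[fail_missing | fail_low, , drop = FALSE]
  if (nrow(removed)) {
    removed$reason <- ifelse(is.na(removed$qual), "missing QUAL",
                             sprintf("QUAL %.6g < %.6g", removed$qual,
                                     config$min_qual))
  } else {
    removed$reason <- character(0)
  }
  list(kept = variants[!(fail_missing | fail_low), , drop = FALSE],
       removed = removed)
}

#' Partition variants into rare and common
#'
#' A variant is common iff its population allele frequency is at or above
#' `max_population_af` (default 1 %) OR it is carried by strictly more than
#' `max_cohort_carriers` (default 5) cohort members.  Missing allele
#' frequency is treated as rare (novel variants are the analysis focus).
#'
#' @param variants data.frame with `carrier_count` and optionally
#'   `population_af` columns.
#' @param config a [filter_config()].
#' @return list with `rare` and `common` data.frames; `common` gains a
#'   `reason` column.
#' @export
frequency_filter <- function(variants, config = filter_config()) {
  af <- variants$population_af
  if (is.null(af)) af <- rep(NA_real_, nrow(variants))
  carriers <- variants$carrier_count
  if (is.null(carriers)) carriers <- rep(0L, nrow(variants))
  af_common <- !is.na(af) & af >= config$max_population_af
  carrier_common <- carriers > config$max_cohort_carriers
  common <- variants[af_common | carrier_common, , drop = FALSE]
  if (nrow(common)) {
    common$reason <- ifelse(af_common[af_common | carrier_common],
                            sprintf("AF >= %.4g", config$max_population_af),
                            sprintf("> %d cohort carriers",
                                    config$max_cohort_carriers))
  } else {
    common$reason <- character(0)
  }
  list(rare = variants[!(af_common | carrier_common), , drop = FALSE],
       common = common)
}

#' Annotate population allele frequencies from a lookup table
#'
#' @param variants variant data.frame (`chrom`, 0-based `pos`, `ref`, `alt`).
#' @param af_table data.frame from [read_allele_freqs()].
#' @return `variants` with a `population_af` column (NA when absent from the
#'   table).
#' @export
annotate_allele_freqs <- function(variants, af_table) {
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  idx <- match(key(variants), key(af_table))
  variants$population_af <- af_table$af[idx]
  variants
}

#' Flag indel calls in homopolymer runs for manual review
#'
#' Indels adjacent to (or inside) a single-base run of `min_run` or more
#' identical bases are error-prone in short-read data; no computable rescue
#' rule exists, so such calls are only flagged `manual_review`.
#'
#' @param variants variant data.frame.
#' @param ref a `ref_store` from [read_reference()].
#' @param min_run run length triggering the flag.
#' @return `variants` with logical `manual_review` column.
#' @export
flag_homopolymer_indels <- function(variants, ref, min_run = 6L) {
  n <- nrow(variants)
  flag <- logical(n)
  for (i in seq_len(n)) {
    if (nchar(variants$ref[i]) == nchar(variants$alt[i])) next
    chrom <- variants$chrom[i]
    contig_len <- nchar(ref[[chrom]])
    lo <- max(0L, variants$pos[i] - min_run)
    hi <- min(contig_len, variants$pos[i] + nchar(variants$ref[i]) + min_run)
    ctx <- fetch_seq(ref, chrom, lo, hi)
    flag[i] <- grepl(sprintf("A{%d}|C{%d}|G{%d}|T{%d}",
                             min_run, min_run, min_run, min_run), ctx)
  }
  variants$manual_review <- flag
  variants
}
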