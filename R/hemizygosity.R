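# Candidate hemizygous (deleted) interval detection from cohort genotypes.
#
# A sample's long genotype-silent stretches are compared with the rest of
# the cohort: a true deletion removes heterozygosity in the carrier while
# the other samples stay polymorphic over the same, marker-rich interval.

#' Find non-polymorphic stretches in one sample
#'
#' Maximal intervals with zero heterozygous calls in the sample, at least
#' `min_length` nt long, and with repetitive-element content below
#' `max_repeat_frac`.
#'
#' @param het_pos 0-based positions where the sample is heterozygous.
#' @param region c(start, end), 0-based half-open captured region.
#' @param min_length minimum stretch length (nt).
#' @param repeat_mask optional data.frame (`start`, `end`) of repetitive
#'   intervals.
#' @param max_repeat_frac maximum tolerated repeat fraction (strict `<`).
#' @return data.frame with `start`, `end`, `length`, `repeat_frac`.
#' @export
find_nonpolymorphic_stretches <- function(het_pos, region,
                                          min_length = 1000L,
                                          repeat_mask = NULL,
                                          max_repeat_frac = 0.10) {
  het_pos <- sort(unique(het_pos[het_pos >= region[[1L]] &
                                   het_pos < region[[2L]]]))
  bounds <- c(region[[1L]] - 1L, het_pos, region[[2L]])
  starts <- utils::head(bounds, -1L) + 1L
  ends <- utils::tail(bounds, -1L)
  keep <- (ends - starts) >= min_length
  out <- data.frame(start = starts[keep], end = ends[keep])
  out$length <- out$end - out$start
  out$repeat_frac <- vapply(seq_len(nrow(out)), function(i) {
    if (is.null(repeat_mask) || !nrow(repeat_mask)) return(0)
    ov <- pmin(out$end[i], repeat_mask$end) - pmax(out$start[i], repeat_mask$start)
    sum(pmax(0L, ov)) / out$length[i]
  }, numeric(1L))
  out[out$repeat_frac < max_repeat_frac, , drop = FALSE]
}

#' Assess one non-polymorphic interval for hemizygosity
#'
#' The interval is a deletion candidate iff strictly more than
#' `min_support` of the control samples are heterozygous at two or more
#' well-distributed loci inside it (pairwise separation of at least
#' `length / spread_divisor`), and the interval is not fully contained in a
#' supplied LD haploblock.  Informative markers at which the case is
#' non-polymorphic are aggregated into an expected-heterozygosity weight
#' (`sum of 2 AF (1 - AF)`).
#'
#' @param interval c(start, end), 0-based half-open.
#' @param case sample name of the putative carrier.
#' @param het matrix of logicals, samples x markers (`TRUE` =
#'   heterozygous), with rownames = sample names.
#' @param marker_pos 0-based marker positions (columns of `het`).
#' @param marker_af population allele frequencies of the markers.
#' @param ld_blocks optional data.frame (`start`, `end`) of haploblocks in
#'   strong LD.
#' @param min_support control-support fraction threshold (strict `>`).
#' @param min_loci minimum well-distributed het loci per supporting control.
#' @param spread_divisor well-distributed means separation >=
#'   `length / spread_divisor`.
#' @param min_controls controls required for a verdict.
#' @return object of class `hemizygosity_call` with `verdict` in
#'   `{candidate, rejected, insufficient-controls}` plus the evidence
#'   fields.
#' @export
assess_hemizygosity <- function(interval, case, het, marker_pos, marker_af,
                                ld_blocks = NULL, min_support = 0.8,
                                min_loci = 2L, spread_divisor = 10,
                                min_controls = 10L) {
  len <- interval[[2L]] - interval[[1L]]
  in_iv <- marker_pos >= interval[[1L]] & marker_pos < interval[[2L]]
  controls <- setdiff(rownames(het), case)

  if (length(controls) < min_controls) {
    return(structure(list(sample = case, interval = interval, length = len,
                          verdict = "insufficient-controls",
                          control_support_fraction = NA_real_,
                          het_loci_in_controls = NULL,
                          informativeness_weight = NA_real_,
                          excluded_by_ld = NA),
                     class = "hemizygosity_call"))
  }
  min_sep <- len / spread_divisor
  ctrl_het <- het[controls, in_iv, drop = FALSE]
  pos_iv <- marker_pos[in_iv]
  n_het <- rowSums(ctrl_het)
  spread_ok <- apply(ctrl_het, 1L, function(h) {
    p <- pos_iv[h]
    length(p) >= min_loci && (max(p) - min(p)) >= min_sep
  })
  support <- mean(spread_ok)

  excluded <- FALSE
  if (!is.null(ld_blocks) && nrow(ld_blocks)) {
    excluded <- any(ld_blocks$start <= interval[[1L]] &
                      interval[[2L]] <= ld_blocks$end)
  }
  case_hom <- !het[case, in_iv]
  info_w <- sum(2 * marker_af[in_iv][case_hom] * (1 - marker_af[in_iv][case_hom]))

  verdict <- if (support > min_support && !excluded) "candidate" else "rejected"
  structure(list(sample = case, interval = interval, length = len,
                 verdict = verdict,
                 control_support_fraction = support,
                 het_loci_in_controls = stats::setNames(n_het, controls),
                 informativeness_weight = info_w,
                 excluded_by_ld = excluded),
            class = "hemizygosity_call")
}

#' Screen a whole cohort for candidate hemizygous intervals
#'
#' Runs [find_nonpolymorphic_stretches()] and [assess_hemizygosity()] for
#' every sample.
#'
#' @param het samples x markers logical matrix (rownames = samples).
#' @param marker_pos,marker_af marker positions and allele frequencies.
#' @param region captured region c(start, end).
#' @param ... passed to the two stage functions (`min_length`,
#'   `repeat_mask`, `max_repeat_frac` to the finder; the rest to the
#'   assessor).
#' @param min_length minimum stretch length (nt).
#' @param repeat_mask,max_repeat_frac see [find_nonpolymorphic_stretches()].
#' @return data.frame of calls: `sample`, `start`, `end`, `length`,
#'   `control_support_fraction`, `informativeness_weight`, `verdict`.
#' @export
screen_hemizygosity <- function(het, marker_pos, marker_af, region,
                                min_length = 1000L, repeat_mask = NULL,
                                max_repeat_frac = 0.10, ...) {
  rows <- list()
  for (s in rownames(het)) {
    iv <- find_nonpolymorphic_stretches(marker_pos[het[s, ]], region,
                                        min_length = min_length,
                                        repeat_mask = repeat_mask,
                                        max_repeat_frac = max_repeat_frac)
    for (i in seq_len(nrow(iv))) {
      call <- assess_hemizygosity(c(iv$start[i], iv$end[i]), s, het,
                                  marker_pos, marker_af, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, start = iv$start[i], end = iv$end[i],
        length = iv$length[i],
        control_support_fraction = call$control_support_fraction,
        informativeness_weight = call$informativeness_weight,
        verdict = call$verdict, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample = character(0), start = integer(0), end = integer(0),
               length = integer(0), control_support_fraction = numeric(0),
               informativeness_weight = numeric(0), verdict = character(0))
  rownames(out) <- NULL
  out
}

#' @export
print.hemizygosity_call <- function(x, ...) {
  cat(sprintf("<hemizygosity %s> %s [%d,%d) %d nt, support %.2f%s\n",
              x$verdict, x$sample, x$interval[[1L]], x$interval[[2L]],
              x$length,
              if (is.na(x$control_support_fraction)) NA_real_ else
                x$control_support_fraction,
              if (isTRUE(x$excluded_by_ld)) " [LD-excluded]" else ""))
  invisible(x)
}
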