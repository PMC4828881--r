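# RNA-binding-protein binding-site (RBBS) analysis for UTR variants.

#' Flag a UTR variant altering an RNA-binding-protein site
#'
#' A change is flagged when (a) `|delta Ri| >= 4.0` bits at a position that
#' is a site on at least one allele (`max(Ri,initial, Ri,final) >= 0` bits;
#' without this guard every deep-negative fluctuation of a non-site would
#' qualify), OR (b) the site is created/strengthened across the model mean
#' (`Ri,final >= Rsequence` and `Ri,initial < Rsequence`); either way the
#' flag is suppressed when the site overlaps, or sits within
#' `suppress_dist` nt (footprint edge to footprint edge) of, a stronger
#' pre-existing site of a different RBP on the variant sequence.
#'
#' @param change a `site_change` under the RBP's model.
#' @param rbp_model the RBP's `iwm`.
#' @param neighborhood_sites data.frame of pre-existing sites of *other*
#'   RBPs on the variant sequence: columns `factor`, `position` (anchor),
#'   `ri`, `width`, `offset`.
#' @param in_utr is the variant inside an annotated UTR? (error if not)
#' @param min_change magnitude threshold (bits).
#' @param suppress_dist suppression distance (nt).
#' @return list with `flagged`, `clause` (`"a"`, `"b"` or `NA`),
#'   `suppressed_by` (factor name or `NA`), `reason`, `ri_initial`,
#'   `ri_final`, `delta_ri`.
#' @export
flag_rbbs_variant <- function(change, rbp_model, neighborhood_sites = NULL,
                              in_utr = TRUE, min_change = 4.0,
                              suppress_dist = 10L) {
  if (!isTRUE(in_utr)) stop("RBBS analysis applies only to UTR variants")
  d <- change$delta_ri
  ri_i <- change$ref_score$ri
  ri_f <- change$alt_score$ri
  rs <- rbp_model$r_sequence

  clause <- if (abs(d) >= min_change && max(ri_i, ri_f) >= 0) "a"
            else if (ri_f >= rs && ri_i < rs) "b"
            else NA_character_
  if (is.na(clause)) {
    return(list(flagged = FALSE, clause = NA_character_,
                suppressed_by = NA_character_,
                reason = "below RBBS thresholds",
                ri_initial = ri_i, ri_final = ri_f, delta_ri = d))
  }

  # clause (c): proximity suppression by a stronger site of another RBP
  if (!is.null(neighborhood_sites) && nrow(neighborhood_sites)) {
    cand_start <- change$alt_score$position - (rbp_model$offset - 1L)
    cand_end <- cand_start + iwm_width(rbp_model) - 1L
    o <- neighborhood_sites
    o_start <- o$position - (o$offset - 1L)
    o_end <- o_start + o$width - 1L
    gap <- pmax(0L, pmax(o_start - cand_end, cand_start - o_end))
    hit <- gap <= suppress_dist & o$ri > ri_f & o$factor != rbp_model$id
    if (any(hit)) {
      k <- which(hit)[[which.max(o$ri[hit])]]
      return(list(flagged = FALSE, clause = clause,
                  suppressed_by = o$factor[[k]],
                  reason = sprintf("stronger pre-existing %s site within %d nt",
                                   o$factor[[k]], suppress_dist),
                  ri_initial = ri_i, ri_final = ri_f, delta_ri = d))
    }
  }
  list(flagged = TRUE, clause = clause, suppressed_by = NA_character_,
       reason = if (clause == "a") "|delta Ri| >= 4 bits"
                else "site created/strengthened across Rsequence",
       ri_initial = ri_i, ri_final = ri_f, delta_ri = d)
}

#' Scan a sequence with a set of RBP models
#'
#' Convenience wrapper producing the `neighborhood_sites` table used by
#' [flag_rbbs_variant()]: every anchor position of every model, with the
#' model's footprint geometry attached.
#'
#' @param seq sequence to scan (the variant sequence for clause (c)).
#' @param models named list of RBP `iwm`s.
#' @param min_ri keep only sites with `ri >= min_ri`.
#' @return data.frame with `factor`, `position`, `ri`, `width`, `offset`.
#' @export
scan_rbp_sites <- function(seq, models, min_ri = 0) {
  rows <- lapply(models, function(m) {
    sc <- scan_iwm(seq, m)
    sc <- sc[sc$ri >= min_ri, , drop = FALSE]
    if (!nrow(sc)) return(NULL)
    data.frame(factor = m$id, position = sc$position, ri = sc$ri,
               width = iwm_width(m), offset = m$offset,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(factor = character(0), position = integer(0),
                      ri = numeric(0), width = integer(0), offset = integer(0))
  }
  rownames(out) <- NULL
  out
}
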