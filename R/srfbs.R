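# Splicing-regulatory-factor binding-site (SRFBS) analysis: flagging large
# information changes and interpreting them in the factor's documented
# splicing context (SRSF1/2/5/6, hnRNPH, hnRNPA1, ELAVL1, TIA1, PTB).

#' Context rule for one splicing regulatory factor
#'
#' @param factor factor name.
#' @param allowed_region `"exonic"`, `"intronic"` or `"either"` — where
#'   changes to this factor's sites are considered.
#' @param role `"enhancer"`, `"repressor"`, `"acceptor-proofreader"` (hnRNPA1)
#'   or `"blocker"` (PTB).
#' @return list of class `srf_rule`.
#' @export
srf_rule <- function(factor, allowed_region = c("either", "exonic", "intronic"),
                     role = c("enhancer", "repressor", "acceptor-proofreader",
                              "blocker")) {
  structure(list(factor = factor, allowed_region = match.arg(allowed_region),
                 role = match.arg(role)),
            class = "srf_rule")
}

#' Default context rules for the modeled splicing regulatory factors
#'
#' TIA1 acts as an intronic enhancer of exon definition, hnRNPA1 proofreads
#' the 3' splice site and represses exon recognition elsewhere, PTB blocks
#' factors with overlapping sites without enhancing or repressing itself,
#' and the SR proteins are exonic enhancers.
#'
#' @return named list of [srf_rule()]s.
#' @export
default_srf_rules <- function() {
  rules <- list(
    srf_rule("SRSF1", "exonic", "enhancer"),
    srf_rule("SRSF2", "exonic", "enhancer"),
    srf_rule("SRSF5", "exonic", "enhancer"),
    srf_rule("SRSF6", "exonic", "enhancer"),
    srf_rule("hnRNPH", "either", "repressor"),
    srf_rule("hnRNPA1", "either", "acceptor-proofreader"),
    srf_rule("ELAVL1", "either", "repressor"),
    srf_rule("TIA1", "intronic", "enhancer"),
    srf_rule("PTB", "either", "blocker"))
  stats::setNames(rules, vapply(rules, `[[`, "", "factor"))
}

#' Flag a variant altering a splicing-regulatory-factor site
#'
#' Flags variants with (a) a decrease of >= 4.0 bits at a site whose initial
#' strength was at least the model's `Rsequence`, or (b) an increase of
#' >= 4.0 bits reaching a final strength of >= 0 bits.  Applies only to
#' exonic variants or those within `max_exon_dist` nt of an exon (caller
#' supplies the distance).
#'
#' @param change a `site_change` under the factor's model.
#' @param factor_model the factor's `iwm`.
#' @param exon_distance distance (nt) from the variant to the nearest exon;
#'   0 for exonic variants.
#' @param min_change magnitude threshold (bits).
#' @param max_exon_dist region-of-interest width (nt).
#' @return list with `flagged`, `clause` (`"a"`, `"b"` or `NA`), `reason`,
#'   `ri_initial`, `ri_final`, `delta_ri`.
#' @export
flag_srf_variant <- function(change, factor_model, exon_distance = 0L,
                             min_change = 4.0, max_exon_dist = 500L) {
  d <- change$delta_ri
  ri_i <- change$ref_score$ri
  ri_f <- change$alt_score$ri
  if (exon_distance > max_exon_dist) {
    return(list(flagged = FALSE, clause = NA_character_,
                reason = "beyond exon-proximity window",
                ri_initial = ri_i, ri_final = ri_f, delta_ri = d))
  }
  if (d <= -min_change && ri_i >= factor_model$r_sequence) {
    return(list(flagged = TRUE, clause = "a",
                reason = "strong site weakened >= 4 bits",
                ri_initial = ri_i, ri_final = ri_f, delta_ri = d))
  }
  if (d >= min_change && ri_f >= 0) {
    return(list(flagged = TRUE, clause = "b",
                reason = "site strengthened >= 4 bits to Ri >= 0",
                ri_initial = ri_i, ri_final = ri_f, delta_ri = d))
  }
  list(flagged = FALSE, clause = NA_character_,
       reason = "information change below thresholds",
       ri_initial = ri_i, ri_final = ri_f, delta_ri = d)
}

#' Factor-aware change in exon-definition strength
#'
#' Folds an SRF's site change into the affected exon's `Ri,total`: enhancer
#' contributions add to exon strength, repressor contributions subtract, so
#' `delta Ri,total = delta exon + role_sign * delta factor`.
#'
#' @param exon_ref,exon_alt `exon_definition`s on the reference and variant
#'   sequences (pass the same object twice when splice sites are untouched).
#' @param change the factor's `site_change`.
#' @param rule the factor's [srf_rule()].
#' @return bits (change in factor-aware exon strength, alt - ref).
#' @export
srf_exon_delta <- function(exon_ref, exon_alt, change, rule) {
  sign <- switch(rule$role,
                 enhancer = 1,
                 repressor = -1,
                 `acceptor-proofreader` = -1,  # repressive away from acceptor
                 blocker = 0)
  (exon_alt$ri_total - exon_ref$ri_total) + sign * change$delta_ri
}

#' Contextual interpretation of a flagged SRFBS variant
#'
#' Converts a flagged site change into exactly one of
#' `prioritized` / `deprioritized` / `neutral`, with a machine-readable
#' reason:
#' * decreases of factor-aware exon strength smaller than `benign_drop`
#'   (default 3.0 bits, i.e. 8-fold) are deprioritized as potentially benign;
#' * a site abolished while an equivalent-strength site (|Ri difference| <=
#'   `equiv_bits`) exists within `redundant_dist` nt is neutral (redundancy);
#' * TIA1 changes are considered only for intronic variants;
#' * hnRNPA1 gains within `proofread_dist` nt of the 3' splice site are
#'   proofreading (deprioritized); hnRNPA1 changes elsewhere act as
#'   repression;
#' * PTB changes carry no direct effect: the overlapped factors' sites must
#'   be re-scanned (`action = "rescan-overlapped"`).
#'
#' @param flag result of [flag_srf_variant()] (must be flagged).
#' @param rule the factor's [srf_rule()].
#' @param delta_ri_total factor-aware exon-strength change
#'   ([srf_exon_delta()]), bits.
#' @param region `"exonic"` or `"intronic"` location of the variant.
#' @param acceptor_distance distance (nt) from the site footprint to the
#'   nearest 3' splice site.
#' @param redundant_site optional list(`ri`, `distance`) describing the
#'   nearest equivalent site of the same factor on the variant sequence.
#' @param benign_drop,equiv_bits,redundant_dist,proofread_dist thresholds.
#' @return list with `decision` (`"prioritized"`, `"deprioritized"`,
#'   `"neutral"`), `reason`, and optional `action`.
#' @export
contextual_interpretation <- function(flag, rule, delta_ri_total,
                                      region = c("exonic", "intronic"),
                                      acceptor_distance = Inf,
                                      redundant_site = NULL,
                                      benign_drop = 3.0, equiv_bits = 0.5,
                                      redundant_dist = 2L,
                                      proofread_dist = 10L) {
  region <- match.arg(region)
  if (!isTRUE(flag$flagged)) {
    return(list(decision = "deprioritized", reason = "not flagged"))
  }
  if (rule$role == "blocker") {
    return(list(decision = "neutral", reason = "PTB blocks overlapping factors; no direct effect",
                action = "rescan-overlapped"))
  }
  if (rule$allowed_region == "intronic" && region != "intronic") {
    return(list(decision = "deprioritized",
                reason = sprintf("%s considered only intronic", rule$factor)))
  }
  if (rule$allowed_region == "exonic" && region != "exonic") {
    return(list(decision = "deprioritized",
                reason = sprintf("%s considered only exonic", rule$factor)))
  }
  if (!is.null(redundant_site) &&
      redundant_site$distance <= redundant_dist &&
      abs(redundant_site$ri - flag$ri_initial) <= equiv_bits &&
      flag$delta_ri < 0) {
    return(list(decision = "neutral",
                reason = sprintf("equivalent site within %d nt (redundant)",
                                 redundant_dist)))
  }
  if (rule$role == "acceptor-proofreader" &&
      acceptor_distance <= proofread_dist && flag$delta_ri > 0) {
    return(list(decision = "deprioritized",
                reason = "hnRNPA1 gain adjacent to acceptor supports proofreading"))
  }
  if (delta_ri_total > -benign_drop) {
    return(list(decision = "deprioritized",
                reason = sprintf("exon-strength decrease < %.1f bits (potentially benign)",
                                 benign_drop)))
  }
  list(decision = "prioritized",
       reason = sprintf("factor-aware exon strength drops %.1f bits",
                        -delta_ri_total))
}
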