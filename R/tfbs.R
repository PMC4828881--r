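# Transcription-factor binding-site analysis inside gene promoter regions.

#' Promoter region of a gene
#'
#' The interval from `upstream` nt (default 10 kb) upstream of the
#' transcription start site through the end of the first intron, clipped to
#' the contig.
#'
#' @param gene a `gene_model`.
#' @param contig_length length of the contig the gene lives on.
#' @param upstream nt upstream of the TSS.
#' @return list of class `promoter_region` with `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`.
#' @export
promoter_region <- function(gene, contig_length, upstream = 10000L) {
  if (nrow(gene$exons) < 2L) stop("promoter region requires at least 2 exons (intron 1)")
  if (gene$strand == "+") {
    start <- max(0L, gene$tss - upstream)
    end <- gene$exons[2L, "start"]            # end of intron 1
  } else {
    start <- gene$exons[nrow(gene$exons) - 1L, "end"]
    end <- min(contig_length, gene$tss + 1L + upstream)
  }
  structure(list(gene_id = gene$gene_id, chrom = gene$chrom,
                 start = as.integer(start), end = as.integer(end),
                 strand = gene$strand),
            class = "promoter_region")
}

#' Membership test for promoter regions
#' @param pos 0-based position(s).
#' @param region a `promoter_region`.
#' @return logical.
#' @export
in_promoter <- function(pos, region) {
  pos >= region$start & pos < region$end
}

#' Flag a variant altering a transcription-factor binding site
#'
#' Weakened: the site was strong (`Ri,initial >= Rsequence`) and loses
#' >= 4.0 bits.  Created/strengthened: the site reaches
#' `Ri,final >= Rsequence` and is the strongest site of that factor in the
#' surrounding genomic interval (it must exceed every site unaltered by the
#' variant within `window` nt).
#'
#' @param change a `site_change` under the factor's model.
#' @param tf_model the factor's `iwm`.
#' @param local_sites data.frame (`position`, `ri`) of the factor's sites in
#'   the surrounding interval on the variant sequence, excluding sites whose
#'   footprint overlaps the variant (i.e. the unaltered sites).
#' @param window interval half-width (nt) around the variant.
#' @param min_change magnitude threshold (bits).
#' @return list with `flagged`, `kind` (`"weakened"`, `"created"` or `NA`),
#'   `reason`, `ri_initial`, `ri_final`, `delta_ri`.
#' @export
flag_tfbs_variant <- function(change, tf_model, local_sites = NULL,
                              window = 50L, min_change = 4.0) {
  d <- change$delta_ri
  ri_i <- change$ref_score$ri
  ri_f <- change$alt_score$ri
  rs <- tf_model$r_sequence
  if (ri_i >= rs && d <= -min_change) {
    return(list(flagged = TRUE, kind = "weakened",
                reason = "strong TFBS weakened >= 4 bits",
                ri_initial = ri_i, ri_final = ri_f, delta_ri = d))
  }
  if (ri_f >= rs) {
    pos <- change$alt_score$position
    strongest <- TRUE
    if (!is.null(local_sites) && nrow(local_sites)) {
      near <- local_sites[abs(local_sites$position - pos) <= window &
                            local_sites$position != pos, , drop = FALSE]
      strongest <- !nrow(near) || ri_f > max(near$ri)
    }
    if (strongest) {
      return(list(flagged = TRUE, kind = "created",
                  reason = "novel/strengthened TFBS, strongest in interval",
                  ri_initial = ri_i, ri_final = ri_f, delta_ri = d))
    }
    return(list(flagged = FALSE, kind = NA_character_,
                reason = "stronger pre-existing site in interval",
                ri_initial = ri_i, ri_final = ri_f, delta_ri = d))
  }
  list(flagged = FALSE, kind = NA_character_,
       reason = "below TFBS thresholds",
       ri_initial = ri_i, ri_final = ri_f, delta_ri = d)
}

#' Function-aware filtering of flagged TFBS variants
#'
#' Drops combinations whose predicted direction cannot dysregulate the
#' target: a transcriptional activator whose binding is strengthened, or a
#' repressor whose binding is weakened.  Unknown roles are kept with a
#' warning.
#'
#' @param flag result of [flag_tfbs_variant()] (must be flagged).
#' @param tf_role `"activator"`, `"repressor"` or `NA`.
#' @return list with `prioritize` (logical) and `reason`.
#' @export
tf_function_filter <- function(flag, tf_role) {
  if (!isTRUE(flag$flagged)) {
    return(list(prioritize = FALSE, reason = "not flagged"))
  }
  strengthened <- identical(flag$kind, "created") || flag$delta_ri > 0
  if (is.na(tf_role) || !tf_role %in% c("activator", "repressor")) {
    warning("unknown TF role; keeping variant")
    return(list(prioritize = TRUE, reason = "unknown TF role (kept)"))
  }
  if (tf_role == "activator" && strengthened) {
    return(list(prioritize = FALSE,
                reason = "activator with strengthened binding"))
  }
  if (tf_role == "repressor" && !strengthened) {
    return(list(prioritize = FALSE,
                reason = "repressor with weakened binding"))
  }
  list(prioritize = TRUE,
       reason = sprintf("%s with %s binding", tf_role,
                        if (strengthened) "strengthened" else "weakened"))
}
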