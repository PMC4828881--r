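# Coding-consequence annotation and truncation-based prioritization.

# CDS segments (genomic, transcription-oriented) and the spliced CDS string
.cds_segments <- function(gene) {
  ex <- gene$exons
  keep <- ex[, "end"] > gene$cds_start & ex[, "start"] < gene$cds_end
  seg <- ex[keep, , drop = FALSE]
  seg[, "start"] <- pmax(seg[, "start"], gene$cds_start)
  seg[, "end"] <- pmin(seg[, "end"], gene$cds_end)
  seg
}

.spliced <- function(seq, segments) {
  paste(vapply(seq_len(nrow(segments)), function(i) {
    substr(seq, segments[i, "start"] + 1L, segments[i, "end"])
  }, ""), collapse = "")
}

.translate <- function(dna) {
  dna <- substr(dna, 1L, 3L * (nchar(dna) %/% 3L))
  if (!nchar(dna)) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                     if.fuzzy.codon = "X"))
}

#' Annotate the coding consequence of an exonic variant
#'
#' Splices the CDS (transcription orientation), applies the variant,
#' translates, and classifies the consequence.  Frameshifts are read
#' through the downstream exonic sequence (3' UTR included) until the first
#' stop in the new frame.  Variants spanning an intron/exon boundary get no
#' coding call (consequence `"defer-splicing"`): they belong to the
#' splicing module.
#'
#' @param variant list(`pos` 0-based genomic, `ref`, `alt`).
#' @param gene transcription-oriented `gene_model` (see [orient_gene()]).
#' @param seq transcription-oriented contig sequence.
#' @return object of class `coding_consequence`: `consequence` in
#'   `{nonsense, frameshift_indel, inframe_indel, missense, synonymous,
#'   defer-splicing}`, `stop_codon_position` (1-based residue or `NA`),
#'   `residues_lost`, `distance_from_cterm`, `protein_change`.
#' @export
annotate_coding <- function(variant, gene, seq) {
  pos <- variant$pos
  ref_len <- nchar(variant$ref)
  segs <- .cds_segments(gene)
  in_seg <- which(segs[, "start"] <= pos & pos + ref_len <= segs[, "end"])
  overlaps <- any(segs[, "start"] < pos + ref_len & pos < segs[, "end"])
  if (!length(in_seg)) {
    if (overlaps) {
      return(structure(list(consequence = "defer-splicing",
                            stop_codon_position = NA_integer_,
                            residues_lost = NA_integer_,
                            distance_from_cterm = NA_integer_,
                            protein_change = NA_character_),
                       class = "coding_consequence"))
    }
    stop("variant does not overlap the CDS")
  }
  obs <- substr(seq, pos + 1L, pos + ref_len)
  if (toupper(obs) != toupper(variant$ref)) {
    stop(sprintf("reference mismatch at position %d", pos))
  }

  # CDS coordinate of the variant start
  seg_i <- in_seg[[1L]]
  before <- if (seg_i > 1L) sum(segs[seq_len(seg_i - 1L), "end"] -
                                segs[seq_len(seg_i - 1L), "start"]) else 0L
  cds_pos <- before + (pos - segs[seg_i, "start"])   # 0-based in CDS

  cds_ref <- .spliced(seq, segs)
  # downstream exonic sequence past the CDS for frameshift readthrough
  tail3 <- if (nrow(gene$utr3)) .spliced(seq, gene$utr3) else ""
  cds_alt <- paste0(substr(cds_ref, 1L, cds_pos), variant$alt,
                    substr(cds_ref, cds_pos + ref_len + 1L, nchar(cds_ref)))

  prot_ref <- .translate(cds_ref)
  prot_alt <- .translate(paste0(cds_alt, tail3))

  indel <- nchar(variant$alt) != ref_len
  frameshift <- indel && ((nchar(variant$alt) - ref_len) %% 3L != 0L)

  stop_alt <- regexpr("*", prot_alt, fixed = TRUE)
  stop_ref <- regexpr("*", prot_ref, fixed = TRUE)
  stop_alt <- if (stop_alt > 0L) as.integer(stop_alt) else NA_integer_
  stop_ref <- if (stop_ref > 0L) as.integer(stop_ref) else NA_integer_

  premature <- !is.na(stop_alt) && (is.na(stop_ref) || stop_alt < stop_ref)
  consequence <- if (frameshift) "frameshift_indel"
    else if (indel) "inframe_indel"
    else if (premature) "nonsense"
    else if (substr(prot_alt, cds_pos %/% 3L + 1L, cds_pos %/% 3L + 1L) !=
             substr(prot_ref, cds_pos %/% 3L + 1L, cds_pos %/% 3L + 1L)) "missense"
    else "synonymous"

  L <- gene$protein_length
  stop_pos <- if (premature || (frameshift && !is.na(stop_alt))) stop_alt
              else NA_integer_
  residues_lost <- if (!is.na(stop_pos)) L - stop_pos + 1L else NA_integer_
  dist_cterm <- if (!is.na(stop_pos)) L - stop_pos else NA_integer_

  aa_pos <- cds_pos %/% 3L + 1L
  change <- if (consequence %in% c("missense", "nonsense", "synonymous")) {
    sprintf("p.%s%d%s", substr(prot_ref, aa_pos, aa_pos), aa_pos,
            if (consequence == "nonsense") "Ter"
            else substr(prot_alt, aa_pos, aa_pos))
  } else if (!is.na(stop_pos)) {
    sprintf("p.%sfs (STOP at p.%d)", aa_pos, stop_pos)
  } else {
    NA_character_
  }

  structure(list(consequence = consequence,
                 stop_codon_position = stop_pos,
                 residues_lost = residues_lost,
                 distance_from_cterm = dist_cterm,
                 protein_change = change),
            class = "coding_consequence")
}

#' Residues lost to a premature stop codon
#'
#' `residues_lost = protein_length - stop_position + 1`: the count includes
#' the residue replaced by the stop itself.
#'
#' @param protein_length full protein length (residues).
#' @param stop_position 1-based residue index of the premature stop.
#' @return integer residues lost.
#' @export
residues_lost <- function(protein_length, stop_position) {
  stopifnot(stop_position >= 1, stop_position <= protein_length)
  as.integer(protein_length - stop_position + 1L)
}

#' Prioritize a coding consequence by predicted truncation
#'
#' Frameshift indels are always prioritized; nonsense variants only when
#' the premature stop lies more than `min_cterm_distance` residues from the
#' C-terminus; missense variants are routed to external-evidence annotation
#' and never auto-prioritized.
#'
#' @param consequence a `coding_consequence`.
#' @param min_cterm_distance residues (strict `>`).
#' @return list with `prioritize` (logical) and `reason`.
#' @export
prioritize_truncation <- function(consequence, min_cterm_distance = 50L) {
  cq <- consequence$consequence
  if (cq == "frameshift_indel") {
    return(list(prioritize = TRUE, reason = "frameshift indel"))
  }
  if (cq == "nonsense") {
    if (!is.na(consequence$distance_from_cterm) &&
        consequence$distance_from_cterm > min_cterm_distance) {
      return(list(prioritize = TRUE,
                  reason = sprintf("premature stop %d residues from C-terminus",
                                   consequence$distance_from_cterm)))
    }
    return(list(prioritize = FALSE,
                reason = sprintf("stop within %d residues of C-terminus",
                                 min_cterm_distance)))
  }
  if (cq == "missense") {
    return(list(prioritize = FALSE,
                reason = "missense routed to external predictors"))
  }
  list(prioritize = FALSE, reason = cq)
}

#' @export
print.coding_consequence <- function(x, ...) {
  cat(sprintf("<coding consequence> %s %s", x$consequence,
              if (is.na(x$protein_change)) "" else x$protein_change))
  if (!is.na(x$residues_lost)) cat(sprintf(" (%d AA short)", x$residues_lost))
  cat("\n")
  invisible(x)
}
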