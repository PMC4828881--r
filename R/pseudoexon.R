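# Detection of intronic variants predicted to activate pseudoexons.
#
# A call requires, jointly:
#   (1) the variant strengthens an intronic cryptic splice site by
#       > 1.0 bits (strict), and
#   (2) the strengthened site reaches Ri,final >= Rsequence - 1 s.d. of its
#       model, and
#   (3) a pre-existing site of opposite polarity with Ri > Rsequence - 1 s.d.
#       (strict) lies in the correct orientation to define an exon of
#       10-250 nt, and
#   (4) both flanking intron remnants are >= 100 nt, and
#   (5) an hnRNPA1 proofreading site with Ri >= its Rsequence sits within
#       `hnrnp_dist` nt of the pseudoexon acceptor boundary.

# anchors whose matrix footprint covers any reference base of the variant
.anchors_covering <- function(iwm, var_pos, var_ref_len, lo, hi) {
  L <- iwm_width(iwm)
  off <- iwm$offset
  # window start w covers [w, w+L-1]; anchor = w + off - 1
  w_lo <- var_pos - L + 1L
  w_hi <- var_pos + var_ref_len - 1L
  anchors <- (w_lo:w_hi) + off - 1L
  anchors[anchors >= lo & anchors <= hi]
}

.model_floor <- function(iwm, warn_missing_sd = TRUE) {
  sd <- iwm$r_sequence_sd
  if (!isTRUE(iwm$sd_defined)) {
    if (warn_missing_sd) warning(sprintf(
      "model '%s' has no training-site s.d. (PWM-derived); using 0", iwm$id))
    sd <- 0
  }
  iwm$r_sequence - sd
}

#' Detect pseudoexon activation by an intronic variant
#'
#' Applies the five-part rule described above and, when several partner
#' sites qualify, reports the strongest exon definition (by `Ri,total`) with
#' the rest as alternates.
#'
#' @param seq transcription-oriented contig sequence (reference).
#' @param variant list(`pos` 0-based, `ref`, `alt`); must lie inside
#'   `intron`.
#' @param intron c(start, end), 0-based half-open, transcription order.
#' @param acceptor_iwm,donor_iwm,hnrnpa1_iwm models; hnRNPA1 provides the
#'   acceptor-proofreading check.
#' @param delta_min activation threshold (bits, strict `>`).
#' @param min_len,max_len pseudoexon length bounds (nt, inclusive).
#' @param min_remnant minimum intron remnant on each side (nt).
#' @param hnrnp_dist maximum distance (nt) from the pseudoexon acceptor
#'   boundary to the nearest edge of a qualifying hnRNPA1 footprint.
#' @param length_dist an [exon_length_dist()] for ranking partner choices.
#' @return object of class `pseudoexon_call`, or `NULL` when any condition
#'   fails.
#' @export
detect_pseudoexon <- function(seq, variant, intron, acceptor_iwm, donor_iwm,
                              hnrnpa1_iwm, delta_min = 1.0, min_len = 10L,
                              max_len = 250L, min_remnant = 100L,
                              hnrnp_dist = 10L,
                              length_dist = exon_length_dist()) {
  pos <- variant$pos
  ref_len <- nchar(variant$ref)
  if (pos < intron[[1L]] || pos + ref_len > intron[[2L]]) {
    stop(sprintf("variant at %d is not inside the intron [%d,%d)", pos,
                 intron[[1L]], intron[[2L]]))
  }
  shift <- nchar(variant$alt) - ref_len
  alt_seq <- paste0(substr(seq, 1L, pos), variant$alt,
                    substr(seq, pos + ref_len + 1L, nchar(seq)))
  adj <- function(p) ifelse(p >= pos + ref_len, p + shift, p)

  activated <- list()
  for (polarity in c("acceptor", "donor")) {
    iwm <- if (polarity == "acceptor") acceptor_iwm else donor_iwm
    floor_i <- .model_floor(iwm)
    anchors <- .anchors_covering(iwm, pos, ref_len, intron[[1L]],
                                 intron[[2L]] - 1L)
    for (a in anchors) {
      ch <- tryCatch(delta_ri(seq, variant, iwm, a), error = function(e) NULL)
      if (is.null(ch)) next
      if (ch$delta_ri > delta_min && ch$alt_score$ri >= floor_i) {
        activated[[length(activated) + 1L]] <-
          list(polarity = polarity, anchor = a, change = ch)
      }
    }
  }
  if (!length(activated)) return(NULL)

  candidates <- list()
  for (act in activated) {
    partner_iwm <- if (act$polarity == "acceptor") donor_iwm else acceptor_iwm
    floor_p <- .model_floor(partner_iwm)
    partners <- scan_iwm(seq, partner_iwm)
    partners <- partners[partners$ri > floor_p, , drop = FALSE]
    partners <- partners[partners$position >= intron[[1L]] &
                           partners$position < intron[[2L]], , drop = FALSE]
    for (j in seq_len(nrow(partners))) {
      p <- partners[j, ]
      if (act$polarity == "donor") {
        acc_pos <- p$position; acc_ri <- p$ri
        don_pos <- act$anchor; don_ri <- act$change$alt_score$ri
      } else {
        acc_pos <- act$anchor; acc_ri <- act$change$alt_score$ri
        don_pos <- p$position; don_ri <- p$ri
      }
      len <- don_pos - acc_pos
      if (len < min_len || len > max_len) next
      remnant_a <- acc_pos - intron[[1L]]
      remnant_b <- intron[[2L]] - don_pos
      if (remnant_a < min_remnant || remnant_b < min_remnant) next

      # proofreading: strong hnRNPA1 site near the pseudoexon acceptor,
      # evaluated on the variant sequence
      hn <- scan_iwm(alt_seq, hnrnpa1_iwm)
      hn <- hn[hn$ri >= hnrnpa1_iwm$r_sequence, , drop = FALSE]
      acc_alt <- adj(acc_pos)
      ok_hn <- FALSE
      hn_site <- NULL
      if (nrow(hn)) {
        L <- iwm_width(hnrnpa1_iwm)
        off <- hnrnpa1_iwm$offset
        fp_start <- hn$position - (off - 1L)
        fp_end <- fp_start + L - 1L
        d <- pmax(0L, pmax(fp_start - acc_alt, acc_alt - fp_end))
        k <- which.min(d)
        if (d[[k]] <= hnrnp_dist) {
          ok_hn <- TRUE
          hn_site <- list(position = hn$position[[k]], ri = hn$ri[[k]],
                          distance = d[[k]])
        }
      }
      if (!ok_hn) next

      gs <- gap_surprisal(len, length_dist)
      candidates[[length(candidates) + 1L]] <- list(
        activated = act, partner = list(position = p$position, ri = p$ri),
        acceptor = list(position = acc_pos, ri = acc_ri),
        donor = list(position = don_pos, ri = don_ri),
        lengths = c(new_intron_a = remnant_a, pseudoexon = len,
                    new_exon_b = remnant_b),
        ri_total = acc_ri + don_ri - gs,
        hnrnpa1_site = hn_site,
        frameshift = (len %% 3L) != 0L)
    }
  }
  if (!length(candidates)) return(NULL)
  ord <- order(-vapply(candidates, `[[`, 0, "ri_total"))
  best <- candidates[[ord[[1L]]]]
  best$alternates <- candidates[ord[-1L]]
  best$variant <- variant
  best$intron <- intron
  best$lengths_str <- paste(best$lengths, collapse = "/")
  class(best) <- "pseudoexon_call"
  best
}

#' @export
print.pseudoexon_call <- function(x, ...) {
  cat(sprintf(
    "<pseudoexon call> activated %s at %d (%.1f -> %.1f bits), partner Ri %.1f\n",
    x$activated$polarity, x$activated$anchor,
    x$activated$change$ref_score$ri, x$activated$change$alt_score$ri,
    x$partner$ri))
  cat(sprintf("  intron division %s%s; hnRNPA1 %.1f bits at %d nt\n",
              x$lengths_str,
              if (x$frameshift) " (frameshift)" else " (in frame)",
              x$hnrnpa1_site$ri, x$hnrnpa1_site$distance))
  invisible(x)
}
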