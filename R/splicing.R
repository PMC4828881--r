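# Natural and cryptic splice-site analysis with exon-definition (Ri,total)
# isoform ranking.
#
# All functions operate in transcription orientation; use orient_gene() to
# mirror a minus-strand gene onto the plus strand first.

#' Mirror a gene model and its sequence into transcription orientation
#'
#' Plus-strand genes pass through unchanged.  For minus-strand genes the
#' contig is reverse-complemented and all coordinates mirrored
#' (`p' = n - 1 - p` for anchors, half-open intervals swap ends), so every
#' downstream computation can assume transcription runs left to right.
#'
#' @param gene a `gene_model`.
#' @param seq the contig sequence the model lives on.
#' @return list with `seq`, `gene` (now `"+"`), and `map_back(p)` converting
#'   oriented anchor coordinates back to the original contig.
#' @export
orient_gene <- function(gene, seq) {
  if (gene$strand == "+") {
    return(list(seq = seq, gene = gene, map_back = identity))
  }
  n <- nchar(seq)
  mirror_iv <- function(m) {
    out <- cbind(start = n - m[, "end"], end = n - m[, "start"])
    out[order(out[, "start"]), , drop = FALSE]
  }
  g <- gene
  g$strand <- "+"
  g$tss <- n - 1L - gene$tss
  g$exons <- mirror_iv(gene$exons)
  cds <- c(n - gene$cds_end, n - gene$cds_start)
  g$cds_start <- cds[[1L]]
  g$cds_end <- cds[[2L]]
  g$utr5 <- mirror_iv(gene$utr5)
  g$utr3 <- mirror_iv(gene$utr3)
  list(seq = revcomp(seq), gene = g, map_back = function(p) n - 1L - p)
}

#' Exon-length distribution for gap-surprisal penalties
#'
#' Either a log-normal density over exon lengths (default roughly matching
#' the human internal-exon length spectrum, mode ~120 nt) or an empirical
#' table of lengths and probabilities.
#'
#' @param type `"lognormal"` or `"empirical"`.
#' @param meanlog,sdlog log-normal parameters.
#' @param lengths,probs empirical support and probabilities.
#' @param support integer range outside which the tail value is used (with a
#'   warning).
#' @return object of class `length_dist`.
#' @export
exon_length_dist <- function(type = c("lognormal", "empirical"),
                             meanlog = log(120) + 0.45^2, sdlog = 0.45,
                             lengths = NULL, probs = NULL,
                             support = c(10L, 10000L)) {
  type <- match.arg(type)
  if (type == "empirical") {
    stopifnot(length(lengths) == length(probs), all(probs >= 0))
    probs <- probs / sum(probs)
    support <- range(lengths)
    modal <- lengths[[which.max(probs)]]
  } else {
    modal <- round(exp(meanlog - sdlog^2))
  }
  structure(list(type = type, meanlog = meanlog, sdlog = sdlog,
                 lengths = lengths, probs = probs, support = support,
                 modal = modal),
            class = "length_dist")
}

.length_prob <- function(len, dist) {
  if (dist$type == "lognormal") {
    stats::dlnorm(len, dist$meanlog, dist$sdlog)
  } else {
    i <- match(len, dist$lengths)
    ifelse(is.na(i), min(dist$probs[dist$probs > 0]), dist$probs[i])
  }
}

#' Gap surprisal of an exon length
#'
#' `-log2 P(length) / P(modal length)`: the information penalty for defining
#' an exon of unusual length; 0 at the modal length.
#'
#' @param length exon length (nt).
#' @param dist an [exon_length_dist()].
#' @return bits (non-negative for unimodal distributions).
#' @export
gap_surprisal <- function(length, dist = exon_length_dist()) {
  if (length < dist$support[[1L]] || length > dist$support[[2L]]) {
    warning(sprintf("exon length %d outside distribution support [%d,%d]; using tail value",
                    length, dist$support[[1L]], dist$support[[2L]]))
    length <- max(dist$support[[1L]], min(length, dist$support[[2L]]))
  }
  -log2(.length_prob(length, dist) / .length_prob(dist$modal, dist))
}

#' Exon definition: joint strength of an acceptor/donor pair
#'
#' `Ri,total = acceptor Ri + donor Ri - gap surprisal(exon length)`, the
#' exon-recognition strength used to rank isoforms.
#'
#' @param acceptor,donor `site_score`s; the acceptor anchor is the first
#'   exonic base and the donor anchor the first intronic base, so the exon
#'   length is `donor$position - acceptor$position`.
#' @param length_dist an [exon_length_dist()].
#' @return object of class `exon_definition` with `acceptor`, `donor`,
#'   `exon_length`, `gap_surprisal`, `ri_total`.
#' @export
exon_definition <- function(acceptor, donor, length_dist = exon_length_dist()) {
  len <- donor$position - acceptor$position
  if (len <= 0) stop("acceptor must lie upstream of donor in transcription order")
  gs <- gap_surprisal(len, length_dist)
  structure(list(acceptor = acceptor, donor = donor, exon_length = len,
                 gap_surprisal = gs,
                 ri_total = acceptor$ri + donor$ri - gs),
            class = "exon_definition")
}

#' @export
print.exon_definition <- function(x, ...) {
  cat(sprintf("<exon %d-%d (%d nt)> acc %.1f + don %.1f - gap %.1f = Ri,total %.1f bits\n",
              x$acceptor$position, x$donor$position, x$exon_length,
              x$acceptor$ri, x$donor$ri, x$gap_surprisal, x$ri_total))
  invisible(x)
}

#' Natural and cryptic splice sites of a gene
#'
#' Scores the acceptor model at every internal exon start and the donor
#' model at every exon end (anchored at the intron/exon boundaries), and
#' scans for cryptic sites (Ri > 0) within `window` nt of any exon.
#'
#' @param seq transcription-oriented contig sequence.
#' @param gene transcription-oriented `gene_model` (see [orient_gene()]).
#' @param acceptor_iwm,donor_iwm splice-site models.
#' @param window cryptic-site search distance from the nearest exon (nt).
#' @return list of class `splice_inventory` with data.frames `natural`
#'   (`kind`, `exon`, `position`, `ri`) and `cryptic` (`kind`, `position`,
#'   `ri`, `dist_to_exon`).
#' @export
splice_inventory <- function(seq, gene, acceptor_iwm, donor_iwm,
                             window = 300L) {
  ex <- gene$exons
  n_ex <- nrow(ex)
  nat <- list()
  for (i in seq_len(n_ex)) {
    if (i > 1L) {
      s <- score_site(seq, acceptor_iwm, ex[i, "start"])
      nat[[length(nat) + 1L]] <- data.frame(kind = "acceptor", exon = i,
                                            position = s$position, ri = s$ri)
    }
    if (i < n_ex) {
      s <- score_site(seq, donor_iwm, ex[i, "end"])
      nat[[length(nat) + 1L]] <- data.frame(kind = "donor", exon = i,
                                            position = s$position, ri = s$ri)
    }
  }
  natural <- do.call(rbind, nat)

  dist_to_exon <- function(p) {
    inside <- any(ex[, "start"] <= p & p < ex[, "end"])
    if (inside) return(0L)
    min(abs(c(p - ex[, "end"] + 1L, ex[, "start"] - p)))
  }
  cryptic <- list()
  for (kind in c("acceptor", "donor")) {
    iwm <- if (kind == "acceptor") acceptor_iwm else donor_iwm
    sc <- scan_iwm(seq, iwm)
    sc <- sc[sc$ri > 0, , drop = FALSE]
    if (!nrow(sc)) next
    sc$dist_to_exon <- vapply(sc$position, dist_to_exon, 0L)
    sc <- sc[sc$dist_to_exon <= window, , drop = FALSE]
    is_nat <- sc$position %in% natural$position[natural$kind == kind]
    sc <- sc[!is_nat, , drop = FALSE]
    if (nrow(sc)) {
      sc$kind <- kind
      cryptic[[kind]] <- sc[, c("kind", "position", "ri", "dist_to_exon")]
    }
  }
  cryptic <- if (length(cryptic)) do.call(rbind, cryptic) else
    data.frame(kind = character(0), position = integer(0), ri = numeric(0),
               dist_to_exon = integer(0))
  rownames(cryptic) <- NULL
  structure(list(natural = natural, cryptic = cryptic, window = window),
            class = "splice_inventory")
}

#' Flag a variant altering a natural splice site
#'
#' Flags a weakening of >= 1.0 bits at a natural site; classifies the site
#' as `abolished` when the final strength falls below `ri_minimum` (default
#' 1.6 bits) and `leaky` otherwise.
#'
#' @param change a `site_change` computed against a natural-site model.
#' @param ri_minimum minimum functional site strength (bits).
#' @param min_drop weakening threshold (bits, positive).
#' @return list with `flagged`, `category` (`"abolished"`, `"leaky"` or
#'   `"none"`), `ri_initial`, `ri_final`, `delta_ri`.
#' @export
flag_natural_site_variant <- function(change, ri_minimum = 1.6,
                                      min_drop = 1.0) {
  d <- change$delta_ri
  flagged <- d <= -min_drop
  category <- if (!flagged) "none"
              else if (change$alt_score$ri < ri_minimum) "abolished"
              else "leaky"
  list(flagged = flagged, category = category,
       ri_initial = change$ref_score$ri, ri_final = change$alt_score$ri,
       delta_ri = d)
}

#' Flag a variant strengthening a cryptic splice site
#'
#' Flags a strengthened cryptic site within `max_distance` nt of the nearest
#' exon whose final strength is at least that of the nearest natural site of
#' the same polarity.
#'
#' @param change a `site_change` at a non-natural position.
#' @param natural_same_polarity `site_score` of the nearest natural site of
#'   the same polarity.
#' @param distance_nt distance from the cryptic site to the nearest exon.
#' @param max_distance search radius (nt).
#' @return list with `flagged`, `reason`, `ri_final`, `delta_ri`.
#' @export
flag_cryptic_site_variant <- function(change, natural_same_polarity,
                                      distance_nt, max_distance = 300L) {
  d <- change$delta_ri
  ri_final <- change$alt_score$ri
  flagged <- d > 0 && distance_nt <= max_distance &&
    ri_final >= natural_same_polarity$ri
  reason <- if (d <= 0) "not strengthened"
            else if (distance_nt > max_distance) "beyond distance window"
            else if (ri_final < natural_same_polarity$ri) "weaker than natural site"
            else "strengthened to >= natural site strength"
  list(flagged = flagged, reason = reason, ri_final = ri_final, delta_ri = d)
}

#' Rank candidate splice isoforms of one exon by exon-definition strength
#'
#' Enumerates candidate exons for the affected exon from the natural site
#' pair and cryptic sites (Ri > 0) within `window` nt, on the
#' variant-applied sequence; ranks them by `Ri,total` and converts strengths
#' into relative abundances (`2^ri_total`, normalized).  When the natural
#' pair falls below `ri_minimum` at either site an exon-skipping isoform is
#' reported carrying the weakened pair's residual `ri_total`.  Ties in
#' `ri_total` are broken shorter-exon-first, then 5'-most.
#'
#' @param seq transcription-oriented contig sequence (reference).
#' @param gene transcription-oriented `gene_model`.
#' @param exon_index index (transcription order) of the exon analyzed; must
#'   be internal (have both an acceptor and a donor).
#' @param acceptor_iwm,donor_iwm splice-site models.
#' @param variant optional list(`pos`, `ref`, `alt`) applied before scoring.
#' @param ri_minimum minimum functional site strength (bits).
#' @param window cryptic-site search distance (nt).
#' @param length_dist an [exon_length_dist()].
#' @return object of class `isoform_prediction`: data.frame `isoforms`
#'   (ranked) plus `flags` list (`exon_skipping`, `cryptic_use`, `leaky`).
#' @export
rank_isoforms <- function(seq, gene, exon_index, acceptor_iwm, donor_iwm,
                          variant = NULL, ri_minimum = 1.6, window = 300L,
                          length_dist = exon_length_dist()) {
  ex <- gene$exons
  if (exon_index <= 1L || exon_index >= nrow(ex)) {
    stop("isoform ranking requires an internal exon (acceptor and donor)")
  }
  acc_nat <- ex[exon_index, "start"]
  don_nat <- ex[exon_index, "end"]

  work_seq <- seq
  shift <- 0L
  if (!is.null(variant)) {
    obs <- substr(seq, variant$pos + 1L, variant$pos + nchar(variant$ref))
    if (toupper(obs) != toupper(variant$ref)) {
      stop(sprintf("reference mismatch at position %d", variant$pos))
    }
    work_seq <- paste0(substr(seq, 1L, variant$pos), variant$alt,
                       substr(seq, variant$pos + nchar(variant$ref) + 1L,
                              nchar(seq)))
    shift <- nchar(variant$alt) - nchar(variant$ref)
  }
  adj <- function(p) if (!is.null(variant) && p >= variant$pos + nchar(variant$ref))
    p + shift else p
  acc_nat_w <- adj(acc_nat)
  don_nat_w <- adj(don_nat)

  lo <- max(iwm_width(acceptor_iwm), acc_nat_w - window)
  hi <- min(nchar(work_seq) - iwm_width(donor_iwm), don_nat_w + window)

  cand_sites <- function(iwm, natural_pos) {
    sc <- scan_iwm(work_seq, iwm)
    sc <- sc[sc$position >= lo & sc$position <= hi, , drop = FALSE]
    keep <- sc$ri >= ri_minimum | sc$position == natural_pos
    sc <- sc[keep & sc$ri > 0 | sc$position == natural_pos, , drop = FALSE]
    sc$natural <- sc$position == natural_pos
    if (!natural_pos %in% sc$position) {
      nat <- score_site(work_seq, iwm, natural_pos)
      sc <- rbind(sc, data.frame(position = natural_pos, ri = nat$ri,
                                 natural = TRUE))
    }
    sc
  }
  accs <- cand_sites(acceptor_iwm, acc_nat_w)
  dons <- cand_sites(donor_iwm, don_nat_w)

  rows <- list()
  for (i in seq_len(nrow(accs))) {
    for (j in seq_len(nrow(dons))) {
      a <- accs[i, ]
      d <- dons[j, ]
      len <- d$position - a$position
      if (len < 2L) next
      wt <- a$natural && d$natural
      # non-natural pairs need both sites functional and a plausible length
      if (!wt && (a$ri < ri_minimum || d$ri < ri_minimum)) next
      if (!wt && (len < length_dist$support[[1L]] ||
                  len > length_dist$support[[2L]])) next
      ed <- suppressWarnings(
        exon_definition(list(position = a$position, ri = a$ri),
                        list(position = d$position, ri = d$ri),
                        length_dist))
      rows[[length(rows) + 1L]] <- data.frame(
        acceptor_pos = a$position, acceptor_ri = a$ri,
        donor_pos = d$position, donor_ri = d$ri,
        exon_length = ed$exon_length, gap_surprisal = ed$gap_surprisal,
        ri_total = ed$ri_total, is_wildtype = wt, kind = "exon")
    }
  }
  iso <- if (length(rows)) do.call(rbind, rows) else
    data.frame(acceptor_pos = integer(0), acceptor_ri = numeric(0),
               donor_pos = integer(0), donor_ri = numeric(0),
               exon_length = integer(0), gap_surprisal = numeric(0),
               ri_total = numeric(0), is_wildtype = logical(0),
               kind = character(0))

  wt_row <- iso[iso$is_wildtype, , drop = FALSE]
  wt_acc_ri <- if (nrow(wt_row)) wt_row$acceptor_ri[[1L]] else -Inf
  wt_don_ri <- if (nrow(wt_row)) wt_row$donor_ri[[1L]] else -Inf
  skipping <- wt_acc_ri < ri_minimum || wt_don_ri < ri_minimum

  if (skipping) {
    resid <- if (nrow(wt_row)) wt_row$ri_total[[1L]] else -Inf
    iso <- iso[!iso$is_wildtype, , drop = FALSE]
    iso <- rbind(iso, data.frame(acceptor_pos = NA_integer_,
                                 acceptor_ri = NA_real_,
                                 donor_pos = NA_integer_,
                                 donor_ri = NA_real_,
                                 exon_length = 0L, gap_surprisal = NA_real_,
                                 ri_total = resid, is_wildtype = FALSE,
                                 kind = "skip"))
  }
  if (!nrow(iso)) {
    iso <- data.frame(acceptor_pos = NA_integer_, acceptor_ri = NA_real_,
                      donor_pos = NA_integer_, donor_ri = NA_real_,
                      exon_length = 0L, gap_surprisal = NA_real_,
                      ri_total = -Inf, is_wildtype = FALSE, kind = "skip")
  }

  ord <- order(-iso$ri_total, iso$exon_length,
               ifelse(is.na(iso$acceptor_pos), .Machine$integer.max,
                      iso$acceptor_pos))
  iso <- iso[ord, , drop = FALSE]
  iso$rank <- seq_len(nrow(iso))
  w <- 2^iso$ri_total
  iso$rel_abundance <- if (all(w == 0)) rep(1 / nrow(iso), nrow(iso)) else
    w / sum(w)
  iso$isoform_id <- paste0("iso", iso$rank)
  rownames(iso) <- NULL

  leaky <- FALSE
  if (!is.null(variant) && nrow(wt_row)) {
    ref_acc <- score_site(seq, acceptor_iwm, acc_nat)
    ref_don <- score_site(seq, donor_iwm, don_nat)
    dropped <- (ref_acc$ri - wt_acc_ri) >= 1.0 || (ref_don$ri - wt_don_ri) >= 1.0
    leaky <- dropped && !skipping
  }
  flags <- list(exon_skipping = skipping,
                cryptic_use = !isTRUE(iso$is_wildtype[[1L]]) &&
                  iso$kind[[1L]] == "exon",
                leaky = leaky)
  structure(list(isoforms = iso, flags = flags, exon_index = exon_index),
            class = "isoform_prediction")
}

#' @export
print.isoform_prediction <- function(x, ...) {
  cat(sprintf("<isoform prediction, exon %d> flags: %s\n", x$exon_index,
              paste(names(Filter(isTRUE, x$flags)), collapse = ", ")))
  print(x$isoforms[, c("isoform_id", "kind", "exon_length", "ri_total",
                       "rel_abundance", "is_wildtype")])
  invisible(x)
}
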