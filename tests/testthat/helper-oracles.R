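# Independent brute-force oracles shared by module and acceptance tests.
# These recompute results with naive nested loops and direct rule
# transcription, never through the package's scanning/detection paths.

# pseudoexon fixture: scrubbed intron background with planted partner
# acceptor, hnRNPA1 proofreading site, and a core-broken donor repaired by
# the variant
pe_fixture <- function(acc_at = 500L, don_at = 711L, hn_at = 502L,
                       plant_hn = TRUE, break_rows = 5L, seed = 55) {
  dm <- the_models()
  acc <- dm$models$acceptor
  don <- dm$models$donor
  hn <- dm$models$hnRNPA1
  set.seed(seed)
  seq <- scrub_dinucs(rand_dna(2400))
  seq <- plant_at(seq, acc_at - (acc$offset - 1L), consensus_seq(acc))
  if (plant_hn) seq <- plant_at(seq, hn_at, consensus_seq(hn))
  dsite <- consensus_seq(don)
  for (r in break_rows) substr(dsite, r, r) <- "C"
  seq <- plant_at(seq, don_at - (don$offset - 1L), dsite)
  v <- list(pos = don_at + 1L, ref = "C", alt = "T")
  list(seq = seq, v = v, intron = c(200L, 2200L), acc = acc, don = don,
       hn = hn, acc_at = acc_at, don_at = don_at)
}

# exhaustive (site, partner) pairs satisfying the five pseudoexon rules
oracle_pseudoexon_pairs <- function(fx) {
  alt_seq <- apply_variant(fx$seq, fx$v)
  out <- list()
  for (polarity in c("acceptor", "donor")) {
    m <- if (polarity == "acceptor") fx$acc else fx$don
    pm <- if (polarity == "acceptor") fx$don else fx$acc
    floor_m <- m$r_sequence - m$r_sequence_sd
    floor_p <- pm$r_sequence - pm$r_sequence_sd
    L <- nrow(m$riw)
    for (anchor in fx$intron[[1]]:(fx$intron[[2]] - 1L)) {
      w0 <- anchor - (m$offset - 1L)
      if (w0 < 0 || w0 + L > nchar(fx$seq)) next
      if (fx$v$pos < w0 || fx$v$pos >= w0 + L) next
      ri_ref <- naive_ri(substr(fx$seq, w0 + 1, w0 + L), m)
      ri_alt <- naive_ri(substr(alt_seq, w0 + 1, w0 + L), m)
      if (!(ri_alt - ri_ref > 1.0 && ri_alt >= floor_m)) next
      pL <- nrow(pm$riw)
      for (pa in fx$intron[[1]]:(fx$intron[[2]] - 1L)) {
        pw0 <- pa - (pm$offset - 1L)
        if (pw0 < 0 || pw0 + pL > nchar(fx$seq)) next
        if (!(naive_ri(substr(fx$seq, pw0 + 1, pw0 + pL), pm) > floor_p)) next
        acc_pos <- if (polarity == "donor") pa else anchor
        don_pos <- if (polarity == "donor") anchor else pa
        len <- don_pos - acc_pos
        if (len < 10 || len > 250) next
        if (acc_pos - fx$intron[[1]] < 100 ||
            fx$intron[[2]] - don_pos < 100) next
        hL <- nrow(fx$hn$riw)
        ok <- FALSE
        for (ha in 0:(nchar(alt_seq) - hL)) {
          if (naive_ri(substr(alt_seq, ha + 1, ha + hL), fx$hn) <
              fx$hn$r_sequence) next
          gap <- max(0L, max(ha - acc_pos, acc_pos - (ha + hL - 1L)))
          if (gap <= 10L) {
            ok <- TRUE
            break
          }
        }
        if (ok) out[[length(out) + 1L]] <- c(acc_pos, don_pos)
      }
    }
  }
  out
}

# detect_pseudoexon call rendered as the same pair set
pkg_pseudoexon_pairs <- function(fx) {
  call <- detect_pseudoexon(fx$seq, fx$v, fx$intron, fx$acc, fx$don, fx$hn)
  if (is.null(call)) return(list())
  c(list(c(call$acceptor$position, call$donor$position)),
    lapply(call$alternates,
           function(a) c(a$acceptor$position, a$donor$position)))
}

# naive RBBS flag for one variant x model: best |delta| anchor by direct
# summation, rule clauses transcribed, clause (c) by exhaustive rescan
oracle_rbbs_flag <- function(utr, alt_utr, v, m, models) {
  L <- nrow(m$riw)
  best <- NULL
  for (a in (v$pos - L + 1L):v$pos) {
    if (a < 0 || a + L > nchar(utr)) next
    ri_ref <- naive_ri(substr(utr, a + 1, a + L), m)
    ri_alt <- naive_ri(substr(alt_utr, a + 1, a + L), m)
    d <- ri_alt - ri_ref
    beats <- !is.null(best) &&
      (abs(d) > abs(best$d) + 1e-9 ||
         (abs(d) > abs(best$d) - 1e-9 &&
            max(ri_ref, ri_alt) > max(best$ri_ref, best$ri_alt) + 1e-9))
    if (is.null(best) || beats) {
      best <- list(a = a, d = d, ri_ref = ri_ref, ri_alt = ri_alt)
    }
  }
  if (is.null(best)) return(NA)
  hit <- (abs(best$d) >= 4.0 && max(best$ri_ref, best$ri_alt) >= 0) ||
    (best$ri_alt >= m$r_sequence && best$ri_ref < m$r_sequence)
  if (hit) {
    cs <- best$a
    ce <- best$a + L - 1L
    for (oid in setdiff(names(models), m$id)) {
      om <- models[[oid]]
      oL <- nrow(om$riw)
      for (oa in 0:(nchar(alt_utr) - oL)) {
        ori <- naive_ri(substr(alt_utr, oa + 1, oa + oL), om)
        if (ori <= best$ri_alt || ori < 0) next
        gap <- max(0L, max(oa - ce, cs - (oa + oL - 1L)))
        if (gap <= 10L) hit <- FALSE
      }
    }
  }
  hit
}
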