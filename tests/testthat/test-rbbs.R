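# RNA-binding-protein binding-site rules for UTR variants.

stub_rbp <- function(r_sequence = 7.0, id = "RBPstub", width = 6L) {
  structure(list(riw = matrix(0, width, 4), r_sequence = r_sequence,
                 r_sequence_sd = 1, sampling_correction = 0,
                 polarity = "motif", offset = 1L, id = id, n_sites = 100L,
                 freq = NULL, sd_defined = TRUE), class = "iwm")
}

test_that("RBBS flagging uses the magnitude OR creation clause", {
  m <- stub_rbp(7.0)
  a <- flag_rbbs_variant(make_change(9.8, -19.9), m)
  expect_true(a$flagged)
  expect_equal(a$clause, "a")
  b <- flag_rbbs_variant(make_change(3.3, 6.9), m, min_change = 4.0)
  expect_false(b$flagged)                       # +3.6, final < Rsequence
  b2 <- flag_rbbs_variant(make_change(3.3, 7.1), m)
  expect_true(b2$flagged)                       # crosses Rsequence
  expect_equal(b2$clause, "b")
  expect_error(flag_rbbs_variant(make_change(1, 9), m, in_utr = FALSE),
               "UTR")
})

test_that("each RBBS clause is individually necessary", {
  m <- stub_rbp(7.0)
  # (a) boundary: |delta| = 4.0 flags, 3.99 does not (when (b) also fails)
  expect_true(flag_rbbs_variant(make_change(10.0, 6.0), m)$flagged)
  expect_false(flag_rbbs_variant(make_change(10.0, 6.01), m)$flagged)
  # (a) site-existence guard: a big swing between two non-sites never flags
  expect_false(flag_rbbs_variant(make_change(-12.0, -16.0), m)$flagged)
  expect_true(flag_rbbs_variant(make_change(0.0, -4.0), m)$flagged)
  # (b) needs both sides of Rsequence: init below, final at/above
  expect_true(flag_rbbs_variant(make_change(6.99, 7.0), m)$flagged)
  expect_false(flag_rbbs_variant(make_change(7.0, 7.5), m)$flagged)
  expect_false(flag_rbbs_variant(make_change(5.0, 6.99), m)$flagged)
  # (c) suppression distance boundary: 10 nt suppresses, 11 does not
  hood <- function(pos) data.frame(factor = "OTHER", position = pos,
                                   ri = 12.0, width = 6L, offset = 1L)
  # candidate footprint is [100, 105]; edge-to-edge gap of 10 suppresses
  ch <- make_change(9.8, -19.9, pos = 100L)
  near <- flag_rbbs_variant(ch, m, hood(100L + 5L + 10L))
  expect_false(near$flagged)
  expect_equal(near$suppressed_by, "OTHER")
  far <- flag_rbbs_variant(ch, m, hood(100L + 5L + 11L))
  expect_true(far$flagged)
  # a weaker neighboring site never suppresses
  weak <- data.frame(factor = "OTHER", position = 104L, ri = -25.0,
                     width = 6L, offset = 1L)
  expect_true(flag_rbbs_variant(ch, m, weak)$flagged)
  # same-factor sites never suppress
  self <- data.frame(factor = "RBPstub", position = 104L, ri = 12.0,
                     width = 6L, offset = 1L)
  expect_true(flag_rbbs_variant(ch, m, self)$flagged)
})

test_that("exhaustive scanning of a synthetic UTR matches a naive oracle", {
  dm <- the_models()
  rbp_ids <- dm$meta$factor[dm$meta$class == "RBP"]
  models <- dm$models[rbp_ids]
  set.seed(31)
  utr <- rand_dna(300)
  # two adjacent strong sites exercise clause (c) suppressions; an isolated
  # third site exercises unsuppressed flags
  utr <- plant_at(utr, 100, consensus_seq(models$RBFOX))
  utr <- plant_at(utr, 109, consensus_seq(models$SF3B4))
  utr <- plant_at(utr, 250, consensus_seq(models$CELF4))

  variants <- lapply(c(seq(5, 290, by = 17), 100:114, 250:255),
                     function(p) {
    ref <- substr(utr, p + 1, p + 1)
    alt <- if (ref == "T") "A" else setdiff(c("A", "C", "G", "T"), ref)[[1]]
    list(pos = p, ref = ref, alt = alt)
  })

  flags_pkg <- flags_naive <- list()
  for (v in variants) {
    alt_utr <- apply_variant(utr, v)
    hood <- scan_rbp_sites(alt_utr, models, min_ri = 0)
    for (id in names(models)) {
      m <- models[[id]]
      ch <- itvus:::.best_change(utr, v, m)
      if (is.null(ch)) next
      fl <- flag_rbbs_variant(ch, m, hood[hood$factor != id, , drop = FALSE])
      flags_pkg[[paste(v$pos, id)]] <- fl$flagged
      flags_naive[[paste(v$pos, id)]] <- oracle_rbbs_flag(utr, alt_utr, v, m,
                                                          models)
    }
  }
  expect_equal(flags_pkg, flags_naive)
  expect_gt(sum(unlist(flags_pkg)), 0)   # the scan exercised real flags
})

test_that("suppression verdicts are symmetric under strand flip of the fixture", {
  dm <- the_models()
  rbp_ids <- dm$meta$factor[dm$meta$class == "RBP"]
  models <- dm$models[rbp_ids]
  set.seed(41)
  utr <- rand_dna(200)
  utr <- plant_at(utr, 60, consensus_seq(models$CELF4))
  p <- 70L
  v <- list(pos = p, ref = substr(utr, p + 1, p + 1), alt = "G")
  if (v$ref == "G") v$alt <- "A"
  verdict <- function(seq, v) {
    alt <- apply_variant(seq, v)
    hood <- scan_rbp_sites(alt, models, min_ri = 0)
    vapply(names(models), function(id) {
      ch <- itvus:::.best_change(seq, v, models[[id]])
      if (is.null(ch)) return(NA)
      flag_rbbs_variant(ch, models[[id]],
                        hood[hood$factor != id, , drop = FALSE])$flagged
    }, logical(1))
  }
  fwd <- verdict(utr, v)
  # mirrored fixture: reverse complement sequence and variant
  utr_rc <- revcomp(utr)
  v_rc <- list(pos = nchar(utr) - 1L - p, ref = revcomp(v$ref),
               alt = revcomp(v$alt))
  # models scan the given strand, so score the mirrored fixture against the
  # reverse-complemented models to ask the identical biological question
  models_rc <- lapply(models, function(m) {
    m$riw <- m$riw[rev(seq_len(nrow(m$riw))), c("T", "G", "C", "A")]
    colnames(m$riw) <- c("A", "C", "G", "T")
    m$offset <- nrow(m$riw) - m$offset + 1L
    m
  })
  rev_verdict <- vapply(names(models), function(id) {
    alt_rc <- apply_variant(utr_rc, v_rc)
    hood <- scan_rbp_sites(alt_rc, models_rc, min_ri = 0)
    ch <- itvus:::.best_change(utr_rc, v_rc, models_rc[[id]])
    if (is.null(ch)) return(NA)
    flag_rbbs_variant(ch, models_rc[[id]],
                      hood[hood$factor != id, , drop = FALSE])$flagged
  }, logical(1))
  expect_equal(fwd, rev_verdict)
})
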