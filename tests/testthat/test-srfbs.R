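# Splicing-regulatory-factor site rules and contextual interpretation.

stub_model <- function(r_sequence = 5.0, id = "stub") {
  structure(list(riw = matrix(0, 6, 4), r_sequence = r_sequence,
                 r_sequence_sd = 1, sampling_correction = 0,
                 polarity = "motif", offset = 1L, id = id, n_sites = 100L,
                 freq = NULL, sd_defined = TRUE), class = "iwm")
}

test_that("SRF flagging requires 4 bits with the matching strength clause", {
  m <- stub_model(r_sequence = 5.0)
  # clause b: strengthened site reaching Ri >= 0
  b <- flag_srf_variant(make_change(0.7, 5.3), m)
  expect_true(b$flagged)
  expect_equal(b$clause, "b")
  # clause a: needs a strong initial site
  a <- flag_srf_variant(make_change(6.0, 1.5), m)
  expect_true(a$flagged)
  expect_equal(a$clause, "a")
  expect_false(flag_srf_variant(make_change(4.0, -0.5), m)$flagged)  # init < Rseq
  expect_false(flag_srf_variant(make_change(8.0, 4.1), m)$flagged)   # -3.9 bits
  expect_false(flag_srf_variant(make_change(-10, -5.5), m)$flagged)  # final < 0
  # outside the 500-nt region of interest nothing is flagged
  expect_false(flag_srf_variant(make_change(6.0, 1.5), m,
                                exon_distance = 501L)$flagged)
})

test_that("each clause of the SRF rule is individually necessary at the boundary", {
  m <- stub_model(r_sequence = 5.0)
  # (a) magnitude boundary: -4.0 flags, -3.99 does not (init strong in both)
  expect_true(flag_srf_variant(make_change(6.0, 2.0), m)$flagged)
  expect_false(flag_srf_variant(make_change(6.0, 2.01), m)$flagged)
  # (a) strength clause: same -4.0 drop, weak initial site does not flag
  expect_false(flag_srf_variant(make_change(4.99, 0.99), m)$flagged)
  # (b) magnitude boundary: +4.0 flags, +3.99 does not (final >= 0 in both)
  expect_true(flag_srf_variant(make_change(0.0, 4.0), m)$flagged)
  expect_false(flag_srf_variant(make_change(0.0, 3.99), m)$flagged)
  # (b) final-strength clause: same +4.0 gain, negative final does not flag
  expect_false(flag_srf_variant(make_change(-6.0, -2.0), m)$flagged)
})

test_that("contextual interpretation is total and applies the documented roles", {
  rules <- default_srf_rules()
  m <- stub_model(5.0)
  fl <- flag_srf_variant(make_change(9.0, 1.0), m)   # strong loss

  # small exon-strength decrease is potentially benign
  d <- contextual_interpretation(fl, rules$SRSF1, -2.9, "exonic")
  expect_equal(d$decision, "deprioritized")
  # boundary: a full 3.0-bit decrease is kept
  expect_equal(contextual_interpretation(fl, rules$SRSF1, -3.0,
                                         "exonic")$decision, "prioritized")
  # redundant equivalent site within 2 nt neutralizes
  n <- contextual_interpretation(fl, rules$SRSF1, -8.0, "exonic",
                                 redundant_site = list(ri = 9.2, distance = 2L))
  expect_equal(n$decision, "neutral")
  # equivalent site too far away does not neutralize
  expect_equal(contextual_interpretation(fl, rules$SRSF1, -8.0, "exonic",
                                         redundant_site = list(ri = 9.2, distance = 3L))$decision,
               "prioritized")
  # TIA1 only acts intronic
  expect_equal(contextual_interpretation(fl, rules$TIA1, -8.0,
                                         "exonic")$decision, "deprioritized")
  expect_equal(contextual_interpretation(fl, rules$TIA1, -8.0,
                                         "intronic")$decision, "prioritized")
  # hnRNPA1 gain next to the acceptor is proofreading
  gain <- flag_srf_variant(make_change(0.7, 5.3), m)
  expect_equal(contextual_interpretation(gain, rules$hnRNPA1, -8.0, "exonic",
                                         acceptor_distance = 5)$decision,
               "deprioritized")
  expect_equal(contextual_interpretation(gain, rules$hnRNPA1, -8.0, "exonic",
                                         acceptor_distance = 50)$decision,
               "prioritized")
  # PTB triggers re-evaluation of overlapped factors instead of a direct call
  p <- contextual_interpretation(fl, rules$PTB, -8.0, "exonic")
  expect_equal(p$decision, "neutral")
  expect_equal(p$action, "rescan-overlapped")

  # totality: every combination yields exactly one decision with a reason
  grid <- expand.grid(rule = names(rules), drt = c(-8, -1),
                      region = c("exonic", "intronic"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    out <- contextual_interpretation(fl, rules[[grid$rule[i]]], grid$drt[i],
                                     grid$region[i])
    expect_true(out$decision %in% c("prioritized", "deprioritized", "neutral"))
    expect_true(nzchar(out$reason))
  }
})

test_that("factor-aware exon strength adds enhancers and subtracts repressors", {
  rules <- default_srf_rules()
  ed <- structure(list(ri_total = 12), class = "exon_definition")
  loss <- make_change(8, 2)   # -6 bits at the factor site
  expect_equal(srf_exon_delta(ed, ed, loss, rules$TIA1), -6)      # enhancer
  expect_equal(srf_exon_delta(ed, ed, loss, rules$ELAVL1), 6)     # repressor
  expect_equal(srf_exon_delta(ed, ed, loss, rules$PTB), 0)        # blocker
  ed2 <- structure(list(ri_total = 9), class = "exon_definition")
  expect_equal(srf_exon_delta(ed, ed2, loss, rules$SRSF1), -9)
})
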