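# Natural/cryptic splice-site rules and exon-definition isoform ranking.

test_that("natural-site flagging applies the 1-bit rule with abolished/leaky classes", {
  # abolished: strength collapses below the functional minimum
  ab <- flag_natural_site_variant(make_change(11.0, 0.1))
  expect_true(ab$flagged)
  expect_equal(ab$category, "abolished")
  # leaky: weakened >= 1 bit but still functional
  lk <- flag_natural_site_variant(make_change(6.8, 4.1))
  expect_true(lk$flagged)
  expect_equal(lk$category, "leaky")
  # below the rule
  expect_false(flag_natural_site_variant(make_change(8.0, 7.5))$flagged)
  # boundary: exactly -1.0 bits is flagged
  expect_true(flag_natural_site_variant(make_change(8.0, 7.0))$flagged)
  # strengthened sites are never flagged
  expect_false(flag_natural_site_variant(make_change(5.0, 9.0))$flagged)
  # configurable minimum
  expect_equal(flag_natural_site_variant(make_change(6.8, 4.1),
                                         ri_minimum = 5)$category, "abolished")
})

test_that("cryptic-site flagging needs strengthening, proximity, and parity with the natural site", {
  nat <- list(ri = 6.9)
  ok <- flag_cryptic_site_variant(make_change(3.9, 9.4), nat, 245)
  expect_true(ok$flagged)
  expect_false(flag_cryptic_site_variant(make_change(3.9, 9.4), nat, 400)$flagged)
  expect_false(flag_cryptic_site_variant(make_change(3.9, 6.0), nat, 245)$flagged)
  expect_false(flag_cryptic_site_variant(make_change(9.4, 3.9), nat, 245)$flagged)
  # boundary: equal strength qualifies ("equivalent or greater")
  expect_true(flag_cryptic_site_variant(make_change(3.0, 6.9), nat, 300)$flagged)
})

test_that("gap surprisal is zero at the mode and matches a brute-force ratio", {
  dist <- exon_length_dist()
  expect_equal(gap_surprisal(dist$modal, dist), 0)
  # empirical distribution oracle
  emp <- exon_length_dist(type = "empirical",
                          lengths = c(50, 100, 150, 200),
                          probs = c(0.1, 0.5, 0.3, 0.1))
  for (len in c(50, 150, 200)) {
    probs <- c(0.1, 0.5, 0.3, 0.1) / sum(c(0.1, 0.5, 0.3, 0.1))
    oracle <- -log2(probs[[match(len, c(50, 100, 150, 200))]] / probs[[2]])
    expect_equal(gap_surprisal(len, emp), oracle)
  }
  expect_warning(gap_surprisal(5, dist), "outside distribution support")
})

test_that("exon definition recombines site strengths minus gap surprisal", {
  dist <- exon_length_dist()
  acc <- list(position = 100L, ri = 9.2)
  don <- list(position = 100L + dist$modal, ri = 7.4)
  ed <- exon_definition(acc, don, dist)
  expect_equal(ed$ri_total, acc$ri + don$ri - ed$gap_surprisal, tolerance = 1e-9)
  expect_equal(ed$exon_length, dist$modal)
  expect_equal(ed$gap_surprisal, 0)
  expect_error(exon_definition(don, acc, dist), "upstream")
})

test_that("splice inventory places natural sites on exon boundaries", {
  dm <- the_models()
  sim <- simulate_gene(2, dm)
  inv <- splice_inventory(sim$seq, sim$gene, dm$models$acceptor,
                          dm$models$donor)
  ex <- sim$gene$exons
  nat_acc <- inv$natural[inv$natural$kind == "acceptor", ]
  nat_don <- inv$natural[inv$natural$kind == "donor", ]
  expect_equal(sort(nat_acc$position), sort(ex[-1, "start"]))
  expect_equal(sort(nat_don$position), sort(ex[-nrow(ex), "end"]))
  expect_true(all(inv$natural$ri > 8))   # planted sites are strong
  for (kind in c("acceptor", "donor")) {
    expect_false(any(inv$cryptic$position[inv$cryptic$kind == kind] %in%
                       inv$natural$position[inv$natural$kind == kind]))
  }
  expect_true(all(inv$cryptic$dist_to_exon <= 300))
})

test_that("isoform ranking keeps the wild type on top without a variant", {
  dm <- the_models()
  sim <- simulate_gene(1, dm)
  ip <- rank_isoforms(sim$seq, sim$gene, 2, dm$models$acceptor,
                      dm$models$donor)
  expect_true(ip$isoforms$is_wildtype[[1]])
  expect_equal(ip$isoforms$rank[[1]], 1L)
  expect_equal(sum(ip$isoforms$rel_abundance), 1, tolerance = 1e-6)
  expect_false(ip$flags$exon_skipping)
  expect_false(ip$flags$cryptic_use)
  # rank order strictly follows ri_total
  expect_true(all(diff(ip$isoforms$ri_total) <= 1e-9))
})

test_that("abolishing a natural acceptor promotes cryptic use and reports skipping", {
  dm <- the_models()
  sim <- simulate_gene(1, dm)
  anchor <- sim$gene$exons[2, "start"]
  # mutate the near-invariant G of the acceptor AG core (matrix row 10)
  core_pos <- anchor - 1L
  v <- list(pos = core_pos, ref = substr(sim$seq, core_pos + 1, core_pos + 1),
            alt = "T")
  stopifnot(v$ref == "G")
  ch <- delta_ri(sim$seq, v, dm$models$acceptor, anchor)
  expect_lt(ch$alt_score$ri, 1.6)
  ip <- rank_isoforms(sim$seq, sim$gene, 2, dm$models$acceptor,
                      dm$models$donor, variant = v)
  expect_false(isTRUE(ip$isoforms$is_wildtype[[1]]))
  expect_true(ip$flags$exon_skipping)
  expect_true("skip" %in% ip$isoforms$kind)
  expect_equal(sum(ip$isoforms$rel_abundance), 1, tolerance = 1e-6)

  # antisymmetry: reverting the variant restores the wild-type top isoform
  alt_seq <- apply_variant(sim$seq, v)
  back <- rank_isoforms(alt_seq, sim$gene, 2, dm$models$acceptor,
                        dm$models$donor,
                        variant = list(pos = v$pos, ref = v$alt, alt = v$ref))
  expect_true(back$isoforms$is_wildtype[[1]])
})

test_that("equal-strength isoforms share abundance and shorter exons rank first", {
  dm <- the_models()
  acc_m <- dm$models$acceptor
  don_m <- dm$models$donor
  set.seed(12)
  bg <- scrub_dinucs(rand_dna(1200))
  site_a <- consensus_seq(acc_m)
  site_d <- consensus_seq(don_m)
  seq <- bg
  seq <- plant_at(seq, 500 - (acc_m$offset - 1L), site_a)  # natural acceptor
  seq <- plant_at(seq, 550 - (acc_m$offset - 1L), site_a)  # identical cryptic
  seq <- plant_at(seq, 650 - (don_m$offset - 1L), site_d)  # shared donor
  gene <- gene_model("TIE", "chrT", "+", tss = 100,
                     exon_starts = c(100, 500, 900),
                     exon_ends = c(160, 650, 1000),
                     cds_start = 120, cds_end = 950, protein_length = 10)
  dist <- exon_length_dist(type = "empirical", lengths = c(100, 150),
                           probs = c(0.5, 0.5))
  ip <- rank_isoforms(seq, gene, 2, acc_m, don_m, length_dist = dist)
  iso <- ip$isoforms
  expect_equal(nrow(iso), 2)
  expect_equal(iso$ri_total[[1]], iso$ri_total[[2]], tolerance = 1e-9)
  expect_equal(iso$rel_abundance, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(iso$exon_length, c(100L, 150L))  # shorter first on ties
})

test_that("planted natural-site abolitions are always recovered; sub-bit changes never flagged", {
  dm <- the_models()
  for (seed in 1:4) {
    sim <- simulate_gene(seed, dm)
    anchor <- sim$gene$exons[2, "start"]
    core <- anchor - 1L   # invariant G of the AG core
    v <- list(pos = core, ref = substr(sim$seq, core + 1, core + 1), alt = "C")
    expect_equal(v$ref, "G")
    ch <- delta_ri(sim$seq, v, dm$models$acceptor, anchor)
    fl <- flag_natural_site_variant(ch)
    expect_true(fl$flagged)
    expect_equal(fl$category, "abolished")
  }
  # perturbations under 1 bit at the same site are never flagged
  sim <- simulate_gene(1, dm)
  anchor <- sim$gene$exons[2, "start"]
  hits <- 0L
  for (off in -(1:10)) {
    pos <- anchor + off - (dm$models$acceptor$offset - 1L) + 10L
    ref <- substr(sim$seq, pos + 1, pos + 1)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      ch <- delta_ri(sim$seq, list(pos = pos, ref = ref, alt = alt),
                     dm$models$acceptor, anchor)
      if (abs(ch$delta_ri) < 1.0) {
        hits <- hits + 1L
        expect_false(flag_natural_site_variant(ch)$flagged)
      }
    }
  }
  expect_gt(hits, 0L)
})
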