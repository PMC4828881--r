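# Individual-information weight matrices and Ri scoring.

test_that("perfectly conserved and uninformative site sets behave analytically", {
  m <- build_iwm_from_sites(rep("ACGT", 10), apply_correction = FALSE)
  expect_equal(m$r_sequence, 8)                    # 2 bits x 4 positions
  expect_equal(m$r_sequence_sd, 0)
  # observed base: 2 bits less the Laplace pseudocount penalty
  expect_equal(unname(m$riw[1, "A"]), 2 + log2(10 / 13))
  expect_equal(unname(m$riw[2, "C"]), 2 + log2(10 / 13))

  u <- build_iwm_from_sites(c("A", "C", "G", "T"), apply_correction = FALSE)
  expect_equal(unname(u$riw[1, ]), rep(0, 4))
  expect_equal(u$r_sequence, 0)
})

test_that("r_sequence matches an independent column-entropy oracle", {
  sites <- c("ACGTAC", "ACGTTC", "AGGTAC", "ACGAAC",
             "TCGTAC", "ACCTAC", "ACGTAG", "CCGTAC")
  m <- build_iwm_from_sites(sites, apply_correction = FALSE)
  # oracle: sum over columns of 2 - H(l), entropy from raw counts
  chars <- do.call(rbind, strsplit(sites, ""))
  oracle <- 0
  for (l in seq_len(ncol(chars))) {
    p <- table(factor(chars[, l], levels = c("A", "C", "G", "T"))) / nrow(chars)
    p <- p[p > 0]
    oracle <- oracle + 2 - sum(-p * log2(p))
  }
  expect_equal(m$r_sequence, unname(oracle), tolerance = 1e-12)
})

test_that("the small-sample correction shifts weights and content by e(n)", {
  sites <- c("ACGTAC", "ACGTTC", "AGGTAC", "ACGAAC")
  m0 <- build_iwm_from_sites(sites, apply_correction = FALSE)
  m1 <- build_iwm_from_sites(sites, apply_correction = TRUE)
  e <- 3 / (2 * log(2) * 4)
  expect_equal(m1$sampling_correction, e)
  expect_equal(m1$riw, m0$riw - e)
  expect_equal(m1$r_sequence, m0$r_sequence - 6 * e)
  expect_true(all(m1$riw <= 2 - e + 1e-12))
})

test_that("invalid site sets are rejected", {
  expect_error(build_iwm_from_sites(character(0)), "at least one")
  expect_error(build_iwm_from_sites(c("ACGT", "ACG")), "ragged")
  expect_error(build_iwm_from_sites(c("ACGT", "ACXT")), "outside")
})

test_that("training-site mean Ri equals r_sequence when all bases are observed", {
  # every base observed in every column -> no pseudocount perturbation and
  # the identity E[Ri] = Rsequence is exact
  set.seed(7)
  sites <- replicate(40, paste(sample(c("A", "C", "G", "T"), 5,
                                      replace = TRUE,
                                      prob = c(0.4, 0.3, 0.2, 0.1)),
                               collapse = ""))
  chars <- do.call(rbind, strsplit(sites, ""))
  stopifnot(all(apply(chars, 2, function(x) length(unique(x))) == 4))
  m <- build_iwm_from_sites(sites, apply_correction = FALSE)
  ri <- vapply(sites, function(s) score_site(s, m, 0)$ri, numeric(1))
  expect_equal(mean(ri), m$r_sequence, tolerance = 1e-6)
  expect_equal(stats::sd(ri), m$r_sequence_sd, tolerance = 1e-9)
})

test_that("PWM conversion evaluates log2 frequencies directly", {
  p1 <- build_iwm_from_pwm(frequency_matrix(matrix(c(1, 0, 0, 0), 1)))
  expect_equal(unname(p1$riw[1, "A"]), 2, tolerance = 1e-3)
  expect_equal(unname(p1$riw[1, c("C", "G", "T")]), rep(-17.93, 3),
               tolerance = 0.01)
  expect_equal(p1$r_sequence_sd, 0)
  expect_false(p1$sd_defined)

  u <- build_iwm_from_pwm(matrix(0.25, nrow = 3, ncol = 4))
  expect_equal(unname(u$riw), matrix(0, 3, 4), tolerance = 1e-12)
  expect_equal(u$r_sequence, 0)

  half <- build_iwm_from_pwm(matrix(rep(c(0.5, 0.5, 0, 0), each = 4), 4))
  expect_equal(half$r_sequence, 4, tolerance = 1e-3)

  expect_error(frequency_matrix(matrix(c(0, 0, 0, 0), 1)), "summing to 0")
})

test_that("site scoring equals naive summation on every window and respects strand", {
  m <- the_models()$models$donor
  seq <- rand_dna(200, seed = 11)
  sc <- scan_iwm(seq, m)
  for (i in seq_len(nrow(sc))) {
    expect_equal(sc$ri[[i]], naive_ri_at(seq, m, sc$position[[i]]),
                 tolerance = 1e-9)
  }
  # matrix bound: no window exceeds the sum of per-column maxima
  expect_true(all(sc$ri <= consensus_ri(m) + 1e-9))
  # consensus scores the maximum
  expect_equal(score_site(consensus_seq(m), m, m$offset - 1L)$ri,
               consensus_ri(m))
  # strand symmetry: mirrored anchor on the reverse complement
  pos <- 77L
  plus <- score_site(seq, m, pos, "+")
  minus <- score_site(revcomp(seq), m, nchar(seq) - 1L - pos, "-")
  expect_equal(minus$ri, plus$ri)

  expect_error(score_site(seq, m, 1L), "bounds")
  expect_warning(score_site("ACGNACGTACGT", the_models()$models$hnRNPA1, 0L),
                 "non-ACGT")
})

test_that("delta_ri localizes variant effects and is antisymmetric", {
  m <- the_models()$models$hnRNPA1
  seq <- rand_dna(80, seed = 3)
  anchor <- 40L
  # variant outside the footprint changes nothing
  v_far <- list(pos = 10L, ref = substr(seq, 11, 11), alt = "A")
  if (v_far$ref == "A") v_far$alt <- "C"
  expect_equal(delta_ri(seq, v_far, m, anchor)$delta_ri, 0)

  # consensus -> worst base equals the column difference
  cseq <- plant_at(seq, anchor, consensus_seq(m))
  worst_col <- 3L
  worst_base <- c("A", "C", "G", "T")[[which.min(m$riw[worst_col, ])]]
  v <- list(pos = anchor + worst_col - 1L,
            ref = substr(cseq, anchor + worst_col, anchor + worst_col),
            alt = worst_base)
  ch <- delta_ri(cseq, v, m, anchor)
  expect_equal(ch$delta_ri,
               min(m$riw[worst_col, ]) - max(m$riw[worst_col, ]),
               tolerance = 1e-9)
  expect_equal(ch$delta_ri, ch$alt_score$ri - ch$ref_score$ri)

  # antisymmetry: reverting sums to zero
  alt_seq <- apply_variant(cseq, v)
  back <- delta_ri(alt_seq, list(pos = v$pos, ref = v$alt, alt = v$ref),
                   m, anchor)
  expect_equal(ch$delta_ri + back$delta_ri, 0, tolerance = 1e-12)

  expect_error(delta_ri(cseq, list(pos = 5L, ref = "N", alt = "A"), m, anchor),
               "mismatch")
})

test_that("indels re-anchor at the boundary and report the best local anchor", {
  m <- the_models()$models$hnRNPA1
  seq <- rand_dna(120, seed = 9)
  anchor <- 60L
  seq <- plant_at(seq, anchor, consensus_seq(m))
  # 2-nt deletion upstream of the site shifts the anchor; the site itself
  # is untouched, so the best local anchor restores the full score
  v <- list(pos = 20L, ref = substr(seq, 21, 23), alt = substr(seq, 21, 21))
  ch <- delta_ri(seq, v, m, anchor)
  expect_false(is.null(ch$best_alt_anchor))
  expect_equal(ch$best_alt_anchor$ri, score_site(seq, m, anchor)$ri,
               tolerance = 1e-9)
  expect_equal(ch$best_alt_anchor$position, anchor - 2L)
})

test_that("fold change is 2^|delta| with direction, strictly monotone", {
  expect_equal(fold_change(-4)$fold, 16)
  expect_equal(fold_change(-4)$direction, "decrease")
  expect_equal(fold_change(0)$fold, 1)
  expect_equal(fold_change(0)$direction, "none")
  expect_equal(fold_change(2.5)$fold, 2^2.5)
  d <- seq(0, 12, by = 0.25)
  f <- vapply(d, function(x) fold_change(x)$fold, numeric(1))
  expect_true(all(diff(f) > 0))
  f2 <- vapply(-d, function(x) fold_change(x)$fold, numeric(1))
  expect_equal(f2, f)
  expect_error(fold_change(Inf), "finite")
})

test_that("matrices rebuilt from sampled sites recover the generator", {
  # all-positive columns (no pseudocount asymmetry); n large enough that
  # every cell's log-frequency error is well inside 0.15 bits
  profile <- matrix(c(0.50, 0.30, 0.25, 0.40,
                      0.20, 0.30, 0.25, 0.25,
                      0.20, 0.20, 0.25, 0.20,
                      0.10, 0.20, 0.25, 0.15), nrow = 4)
  gen <- build_iwm_from_pwm(frequency_matrix(profile), id = "gen")
  set.seed(101)
  sites <- sample_sites(gen, 5000, method = "multinomial")
  fit <- build_iwm_from_sites(sites, apply_correction = FALSE)
  expect_lt(max(abs(fit$riw - gen$riw)), 0.15)
  expect_lt(abs(fit$r_sequence - gen$r_sequence), 0.1)
})

test_that("matrix files round-trip and PWM files convert on read", {
  m <- the_models()$models$RBFOX
  path <- withr::local_tempfile(fileext = ".iwm")
  write_iwm(m, path)
  m2 <- read_iwm(path)
  expect_equal(unname(m2$riw), unname(m$riw), tolerance = 1e-6)
  expect_equal(m2$r_sequence, m$r_sequence, tolerance = 1e-6)
  expect_equal(m2$offset, m$offset)
  expect_equal(m2$polarity, m$polarity)

  pwm_path <- withr::local_tempfile(fileext = ".pwm")
  writeLines(c("#PWM toy polarity=motif offset=1",
               "0.7\t0.1\t0.1\t0.1",
               "0.25\t0.25\t0.25\t0.25"), pwm_path)
  p <- read_iwm(pwm_path)
  expect_equal(unname(p$riw[1, "A"]), 2 + log2(0.7), tolerance = 1e-9)
  expect_equal(unname(p$riw[2, ]), rep(0, 4), tolerance = 1e-9)
})
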