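# Coding-consequence annotation and truncation prioritization.

test_that("residues-lost arithmetic counts the stop position itself", {
  expect_equal(residues_lost(1186, 414), 773L)
  expect_equal(residues_lost(1186, 348), 839L)
  expect_equal(residues_lost(3418, 2520), 899L)
  expect_equal(residues_lost(3418, 3098), 321L)
  expect_equal(residues_lost(1186, 561), 626L)
  expect_error(residues_lost(100, 101))
})

# one shared fixture gene for consequence tests
fix <- local({
  dm <- the_models()
  simulate_gene(6, dm)
})

cds_base <- function(sim, cds_offset) {
  segs <- itvus:::.cds_segments(sim$gene)
  rem <- cds_offset
  for (i in seq_len(nrow(segs))) {
    w <- segs[i, "end"] - segs[i, "start"]
    if (rem < w) return(segs[i, "start"] + rem)
    rem <- rem - w
  }
  stop("offset beyond CDS")
}

test_that("the reference CDS translates to the annotated protein without stops", {
  segs <- itvus:::.cds_segments(fix$gene)
  cds <- itvus:::.spliced(fix$seq, segs)
  prot <- itvus:::.translate(cds)
  expect_equal(substr(prot, 1, 1), "M")
  expect_equal(nchar(prot), fix$gene$protein_length + 1L)  # incl. stop
  expect_equal(regexpr("*", prot, fixed = TRUE)[[1]],
               fix$gene$protein_length + 1L)
})

test_that("nonsense substitutions report stop position and residues lost", {
  segs <- itvus:::.cds_segments(fix$gene)
  cds <- itvus:::.spliced(fix$seq, segs)
  L <- fix$gene$protein_length
  # find a codon whose first base can become T to give a TAA/TAG/TGA stop
  target <- NA
  for (k in 2:(L - 60)) {
    codon <- substr(cds, 3 * k - 2, 3 * k)
    if (substr(codon, 2, 3) %in% c("AA", "AG", "GA") &&
        substr(codon, 1, 1) != "T") {
      target <- k
      break
    }
  }
  stopifnot(!is.na(target))
  gpos <- cds_base(fix, 3L * (target - 1L))
  v <- list(pos = gpos, ref = substr(fix$seq, gpos + 1, gpos + 1), alt = "T")
  cc <- annotate_coding(v, fix$gene, fix$seq)
  expect_equal(cc$consequence, "nonsense")
  expect_equal(cc$stop_codon_position, target)
  expect_equal(cc$residues_lost, L - target + 1L)
  expect_equal(cc$distance_from_cterm, L - target)
  expect_true(prioritize_truncation(cc)$prioritize)
})

test_that("frameshift indels are prioritized; in-frame indels and synonymous are not", {
  gpos <- cds_base(fix, 60L)
  ref1 <- substr(fix$seq, gpos + 1, gpos + 1)
  fsv <- list(pos = gpos, ref = ref1, alt = paste0(ref1, "A"))
  fs <- annotate_coding(fsv, fix$gene, fix$seq)
  expect_equal(fs$consequence, "frameshift_indel")
  expect_true(prioritize_truncation(fs)$prioritize)
  # the new frame's stop is found by read-through
  expect_false(is.na(fs$stop_codon_position))

  inf <- list(pos = gpos, ref = substr(fix$seq, gpos + 1, gpos + 4),
              alt = ref1)
  cc_in <- annotate_coding(inf, fix$gene, fix$seq)
  expect_equal(cc_in$consequence, "inframe_indel")
  expect_false(prioritize_truncation(cc_in)$prioritize)

  # wobble-position change that keeps the residue: search one
  segs <- itvus:::.cds_segments(fix$gene)
  cds <- itvus:::.spliced(fix$seq, segs)
  syn <- NA
  for (k in 5:40) {
    codon <- substr(cds, 3 * k - 2, 3 * k)
    for (alt in setdiff(c("A", "C", "G", "T"), substr(codon, 3, 3))) {
      mut <- paste0(substr(codon, 1, 2), alt)
      aa0 <- itvus:::.translate(codon)
      aa1 <- itvus:::.translate(mut)
      if (aa0 == aa1 && aa1 != "*") {
        syn <- list(k = k, alt = alt)
        break
      }
    }
    if (!anyNA(syn)) break
  }
  gpos3 <- cds_base(fix, 3L * (syn$k - 1L) + 2L)
  sv <- list(pos = gpos3, ref = substr(fix$seq, gpos3 + 1, gpos3 + 1),
             alt = syn$alt)
  cc_syn <- annotate_coding(sv, fix$gene, fix$seq)
  expect_equal(cc_syn$consequence, "synonymous")
  expect_false(prioritize_truncation(cc_syn)$prioritize)
})

test_that("the C-terminal 50-residue rule gates nonsense prioritization", {
  mk <- function(dist) {
    structure(list(consequence = "nonsense",
                   stop_codon_position = 1000L - dist,
                   residues_lost = dist + 1L,
                   distance_from_cterm = dist,
                   protein_change = "p.X"), class = "coding_consequence")
  }
  expect_false(prioritize_truncation(mk(40L))$prioritize)
  expect_false(prioritize_truncation(mk(50L))$prioritize)  # strict >
  expect_true(prioritize_truncation(mk(51L))$prioritize)
  miss <- structure(list(consequence = "missense", stop_codon_position = NA,
                         residues_lost = NA, distance_from_cterm = NA,
                         protein_change = "p.A1V"),
                    class = "coding_consequence")
  expect_false(prioritize_truncation(miss)$prioritize)
})

test_that("boundary-spanning variants defer to the splicing module", {
  b <- fix$gene$exons[2, "start"]   # first base of an internal CDS exon
  v <- list(pos = b - 2L, ref = substr(fix$seq, b - 1L, b + 2L), alt = "A")
  cc <- annotate_coding(v, fix$gene, fix$seq)
  expect_equal(cc$consequence, "defer-splicing")
  v_out <- list(pos = 10L, ref = substr(fix$seq, 11, 11), alt = "T")
  expect_error(annotate_coding(v_out, fix$gene, fix$seq), "overlap")
})
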