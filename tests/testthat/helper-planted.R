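# End-to-end planted-truth fixture: one variant per prioritization category
# planted into a synthetic gene + cohort VCF, with file-based inputs as the
# pipeline consumes them.  Candidate positions for the searched variants are
# required to be "clean": they must not co-flag another category's rule, so
# each planted variant tests exactly its own analysis path.

build_planted_fixture <- function(seed = 3, n_samples = 12L,
                                  dir = tempfile("planted")) {
  if (!dir.exists(dir)) dir.create(dir)
  dm <- the_models()
  sim <- simulate_gene(seed, dm)
  g <- sim$gene
  seq <- sim$seq
  acc <- dm$models$acceptor
  don <- dm$models$donor
  planted <- list()
  occupied <- list()
  reserve <- function(lo, hi) occupied[[length(occupied) + 1L]] <<- c(lo, hi)
  clash <- function(p) any(vapply(occupied, function(iv) {
    p >= iv[[1]] && p <= iv[[2]]
  }, TRUE))
  note <- function(category, pos, ref, alt) {
    planted[[length(planted) + 1L]] <<- data.frame(
      category = category, pos = pos, ref = ref, alt = alt,
      stringsAsFactors = FALSE)
  }

  ## tf: consensus GATA3 in the promoter; the variant breaks its T core
  seq <- plant_at(seq, 1500L, consensus_seq(dm$models$GATA3))
  reserve(1500L, 1507L)
  note("tf", 1503L, "T", "G")

  ## natural_splicing: abolish the exon-2 donor core G
  dpos <- g$exons[2, "end"]
  note("natural_splicing", dpos, "G", "C")
  reserve(dpos - 3L, dpos + 5L)

  ## cryptic_splicing: weaken the natural exon-2 acceptor (reference edit),
  ## plant a core-broken cryptic acceptor 40 nt upstream; the variant
  ## repairs its core A so the cryptic exon outcompetes the natural one
  a2 <- g$exons[2, "start"]
  stopifnot(substr(seq, a2 - 2L, a2 - 2L) == "C")
  seq <- plant_at(seq, a2 - 3L, "A")
  cs <- consensus_seq(acc)
  substr(cs, 9, 9) <- "C"
  cr_anchor <- a2 - 40L
  seq <- plant_at(seq, cr_anchor - 10L, cs)
  reserve(cr_anchor - 10L, cr_anchor + 1L)
  note("cryptic_splicing", cr_anchor - 2L, "C", "A")

  ## pseudoexon in intron 1: partner acceptor + hnRNPA1, core-broken donor
  i1 <- c(g$exons[1, "end"], g$exons[2, "start"])
  pe_acc <- i1[[1]] + 400L
  seq <- plant_at(seq, pe_acc - 10L, consensus_seq(acc))
  seq <- plant_at(seq, pe_acc + 2L, consensus_seq(dm$models$hnRNPA1))
  ds <- consensus_seq(don)
  substr(ds, 5, 5) <- "C"
  pe_don <- pe_acc + 211L
  seq <- plant_at(seq, pe_don - 3L, ds)
  reserve(pe_acc - 10L, pe_don + 5L)
  note("pseudoexon", pe_don + 1L, "C", "T")

  ## srf: broken hnRNPA1 in exon 2, frame-safe, away from the acceptor
  cds_off_of <- function(p) {
    segs <- itvus:::.cds_segments(g)
    off <- 0L
    for (i in seq_len(nrow(segs))) {
      if (p >= segs[i, "start"] && p < segs[i, "end"]) {
        return(off + p - segs[i, "start"])
      }
      off <- off + segs[i, "end"] - segs[i, "start"]
    }
    NA_integer_
  }
  hn_at <- a2 + 60L
  while ((cds_off_of(hn_at) %% 3L) != 1L) hn_at <- hn_at + 1L
  hs <- consensus_seq(dm$models$hnRNPA1)
  substr(hs, 3, 3) <- "C"
  seq <- plant_at(seq, hn_at, hs)
  reserve(hn_at, hn_at + 5L)
  note("srf", hn_at + 2L, "C", "G")

  srf_ids <- dm$meta$factor[dm$meta$class == "SRF"]
  srf_clean <- function(pos, ref, alt) {
    v <- list(pos = pos, ref = ref, alt = alt)
    for (id in srf_ids) {
      m <- dm$models[[id]]
      for (ch in itvus:::.all_changes(seq, v, m)) {
        if (flag_srf_variant(ch, m)$flagged) return(FALSE)
      }
    }
    TRUE
  }

  ## indel: frameshift insertion in exon-3 CDS, SRF-clean
  ins_at <- NULL
  for (off in seq(30L, 90L, by = 2L)) {
    p <- g$exons[3, "start"] + off
    rb1 <- substr(seq, p + 1L, p + 1L)
    if (!clash(p) && srf_clean(p, rb1, paste0(rb1, "A"))) {
      ins_at <- p
      break
    }
  }
  stopifnot(!is.null(ins_at))
  note("indel", ins_at, substr(seq, ins_at + 1L, ins_at + 1L),
       paste0(substr(seq, ins_at + 1L, ins_at + 1L), "A"))
  reserve(ins_at, ins_at)

  ## nonsense and missense, searched in the CDS away from plants
  segs <- itvus:::.cds_segments(g)
  cds <- itvus:::.spliced(seq, segs)
  gpos_of <- function(off) {
    for (i in seq_len(nrow(segs))) {
      w <- segs[i, "end"] - segs[i, "start"]
      if (off < w) return(segs[i, "start"] + off)
      off <- off - w
    }
  }
  L <- g$protein_length
  non <- NULL
  for (k in 5:(L - 55)) {
    codon <- substr(cds, 3 * k - 2, 3 * k)
    if (substr(codon, 2, 3) %in% c("AA", "AG", "GA") &&
        substr(codon, 1, 1) != "T") {
      p <- gpos_of(3L * (k - 1L))
      if (!clash(p) && srf_clean(p, substr(codon, 1, 1), "T")) {
        non <- list(pos = p, ref = substr(codon, 1, 1))
        break
      }
    }
  }
  stopifnot(!is.null(non))
  note("nonsense", non$pos, non$ref, "T")
  reserve(non$pos, non$pos)

  mis <- NULL
  for (k in 5:(L - 5)) {
    codon <- substr(cds, 3 * k - 2, 3 * k)
    for (alt in setdiff(c("A", "C", "G", "T"), substr(codon, 1, 1))) {
      mut <- paste0(alt, substr(codon, 2, 3))
      aa0 <- itvus:::.translate(codon)
      aa1 <- itvus:::.translate(mut)
      if (aa0 != aa1 && aa1 != "*") {
        p <- gpos_of(3L * (k - 1L))
        if (!clash(p) && srf_clean(p, substr(codon, 1, 1), alt)) {
          mis <- list(pos = p, ref = substr(codon, 1, 1), alt = alt)
          break
        }
      }
    }
    if (!is.null(mis)) break
  }
  stopifnot(!is.null(mis))
  note("missense", mis$pos, mis$ref, mis$alt)
  reserve(mis$pos, mis$pos)

  rbp_ids <- dm$meta$factor[dm$meta$class == "RBP"]
  rbp_clean <- function(pos, ref, alt) {
    v <- list(pos = pos, ref = ref, alt = alt)
    for (id in rbp_ids) {
      m <- dm$models[[id]]
      for (ch in itvus:::.all_changes(seq, v, m)) {
        if (flag_rbbs_variant(ch, m)$flagged) return(FALSE)
      }
    }
    TRUE
  }

  ## utr_binding: broken RBFOX in the 3' UTR whose repair neither ranks in
  ## the top structure decile nor flags an SRF site
  eng <- fold_engine_hairpin()
  rs <- consensus_seq(dm$models$RBFOX)
  substr(rs, 6, 6) <- "C"
  ub_at <- NULL
  for (off in seq(30L, 110L, by = 8L)) {
    p <- g$utr3[1, "start"] + off
    cand_seq <- plant_at(seq, p, rs)
    utr3 <- substr(cand_seq, g$utr3[1, "start"] + 1L, g$utr3[1, "end"])
    sr <- structure_disruption_rank(
      utr3, list(pos = p + 5L - g$utr3[1, "start"], ref = "C", alt = "G"),
      engine = eng)
    if (sr$p_value < 0.1) next
    seq_keep <- seq
    seq <- cand_seq
    if (srf_clean(p + 5L, "C", "G")) {
      ub_at <- p
      break
    }
    seq <- seq_keep
  }
  stopifnot(!is.null(ub_at))
  reserve(ub_at, ub_at + 5L)
  note("utr_binding", ub_at + 5L, "C", "G")

  ## utr_structure: the most structure-disruptive clean 5' UTR substitution
  utr5 <- substr(seq, g$utr5[1, "start"] + 1L, g$utr5[1, "end"])
  base_rank <- structure_disruption_rank(
    utr5, list(pos = 0L, ref = substr(utr5, 1, 1), alt = substr(utr5, 1, 1)),
    engine = eng)
  cand <- base_rank$all_distances
  us <- NULL
  for (i in seq_len(36)) {
    gp <- g$utr5[1, "start"] + cand$pos[[i]]
    if (!clash(gp) && rbp_clean(gp, cand$ref[[i]], cand$alt[[i]]) &&
        srf_clean(gp, cand$ref[[i]], cand$alt[[i]])) {
      us <- list(pos = gp, ref = cand$ref[[i]], alt = cand$alt[[i]])
      break
    }
  }
  stopifnot(!is.null(us))
  note("utr_structure", us$pos, us$ref, us$alt)

  planted <- do.call(rbind, planted)
  rownames(planted) <- NULL
  planted$sample <- seq_len(nrow(planted))
  sim$seq <- seq

  cohort <- simulate_cohort(seed + 1000L, sim, n_samples = n_samples,
                            planted = planted,
                            vcf_path = file.path(dir, "cohort.vcf"))
  write_fasta(seq, g$chrom, file.path(dir, "ref.fa"))
  write_gene_models(list(sim$gene), file.path(dir, "genes.tsv"))
  # allele-frequency table for the background markers, from the VCF records
  vl <- cohort$vcf_lines
  vl <- vl[!startsWith(vl, "#")]
  fields <- do.call(rbind, strsplit(vl, "\t"))
  af <- data.frame(chrom = fields[, 1], pos = as.integer(fields[, 2]),
                   ref = fields[, 4], alt = fields[, 5],
                   af = suppressWarnings(as.numeric(sub("AF=", "",
                                                        fields[, 8]))),
                   stringsAsFactors = FALSE)
  af <- af[!is.na(af$af), ]
  utils::write.table(af, file.path(dir, "af.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(paste(g$chrom, 0L, nchar(seq), "capture", sep = "\t"),
             file.path(dir, "regions.bed"))
  list(dir = dir, planted = planted, sim = sim, dm = dm, cohort = cohort)
}

run_planted_pipeline <- function(fx, out_dir = NULL, overrides = NULL) {
  run_pipeline(reference = file.path(fx$dir, "ref.fa"),
               genes = file.path(fx$dir, "genes.tsv"),
               vcf_path = file.path(fx$dir, "cohort.vcf"),
               models = fx$dm,
               regions = file.path(fx$dir, "regions.bed"),
               af_table = file.path(fx$dir, "af.tsv"),
               overrides = overrides,
               out_dir = out_dir)
}

# memoized fixture+result shared between pipeline and acceptance tests
the_planted_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- build_planted_fixture()
      cache <<- list(fx = fx, res = run_planted_pipeline(fx))
    }
    cache
  }
})
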