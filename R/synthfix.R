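# Synthetic genomes, gene models, binding-site models and cohort VCFs with
# planted ground truth, so every analysis module is testable without
# external data.  All randomness flows through a single seed per generator
# call; model construction itself is fully deterministic.

# Deterministic aligned sites realizing a frequency profile: per column,
# counts are the largest-remainder rounding of n * p, and letters are dealt
# in a column-offset rotation so joint composition varies across sites.
.sites_from_profile <- function(profile, n) {
  L <- nrow(profile)
  cols <- matrix("", nrow = n, ncol = L)
  for (l in seq_len(L)) {
    p <- profile[l, ] / sum(profile[l, ])
    raw <- n * p
    cnt <- floor(raw)
    rem <- n - sum(cnt)
    if (rem > 0) {
      extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1L
    }
    letters4 <- rep(.BASES, times = cnt)
    rot <- ((seq_len(n) - 1L + (l - 1L) * 7L) %% n) + 1L
    cols[, l] <- letters4[rot]
  }
  apply(cols, 1L, paste, collapse = "")
}

.profile <- function(...) {
  m <- do.call(rbind, list(...))
  colnames(m) <- .BASES
  m
}

# row helper: consensus base with probability p, rest split evenly
.col <- function(base, p = 0.85) {
  v <- rep((1 - p) / 3, 4L)
  v[match(base, .BASES)] <- p
  v
}
.colmix <- function(bases, probs) {
  v <- rep(0.0, 4L)
  v[match(bases, .BASES)] <- probs
  v / sum(v)
}

#' Default binding-site model set
#'
#' Builds the information weight matrices used by the synthetic fixtures
#' and the default pipeline: splice acceptor/donor models, splicing
#' regulatory factors (SRSF1, TIA1, PTB, ELAVL1, hnRNPH, hnRNPA1),
#' promoter transcription factors (GATA3, E2F4, SP1, RUNX3, GABPA) and UTR
#' RNA-binding proteins (RBFOX, SF3B4, CELF4, NCL, KHDRBS1).  Training
#' sites are realized deterministically from fixed frequency profiles
#' (n = `n_train` sites per model), so `Rsequence` and its s.d. are defined
#' for every model.  The splice-site models carry near-invariant AG/GT core
#' dinucleotides, so a single core substitution can abolish a site.
#'
#' @param n_train training sites per model.
#' @return list with `models` (named list of `iwm`s) and `meta`
#'   (data.frame: `factor`, `class`, `role`).
#' @export
default_models <- function(n_train = 2000L) {
  specs <- list(
    acceptor = list(profile = .profile(
      .colmix(c("C", "T", "A", "G"), c(0.40, 0.40, 0.10, 0.10)),
      .colmix(c("C", "T", "A", "G"), c(0.40, 0.40, 0.10, 0.10)),
      .colmix(c("C", "T", "A", "G"), c(0.40, 0.40, 0.10, 0.10)),
      .colmix(c("C", "T", "A", "G"), c(0.40, 0.40, 0.10, 0.10)),
      .colmix(c("C", "T", "A", "G"), c(0.42, 0.42, 0.08, 0.08)),
      .colmix(c("C", "T", "A", "G"), c(0.42, 0.42, 0.08, 0.08)),
      .colmix(c("C", "T", "A", "G"), c(0.45, 0.45, 0.05, 0.05)),
      .col("C", 0.70), .col("A", 0.998), .col("G", 0.998),
      .col("G", 0.50), .colmix(c("A", "G", "C", "T"), c(0.35, 0.25, 0.2, 0.2))),
      polarity = "acceptor", offset = 11L, class = "SS", role = "acceptor"),
    donor = list(profile = .profile(
      .colmix(c("C", "A", "G", "T"), c(0.40, 0.30, 0.20, 0.10)),
      .col("A", 0.60), .col("G", 0.78),
      .col("G", 0.998), .col("T", 0.998), .col("A", 0.62), .col("A", 0.70),
      .col("G", 0.78), .colmix(c("T", "C", "G", "A"), c(0.45, 0.2, 0.2, 0.15))),
      polarity = "donor", offset = 4L, class = "SS", role = "donor"),
    hnRNPA1 = list(profile = .profile(
      .col("T", 0.82), .col("A", 0.82), .col("G", 0.86), .col("G", 0.86),
      .col("G", 0.82), .col("A", 0.78)),
      polarity = "motif", offset = 1L, class = "SRF",
      role = "acceptor-proofreader"),
    SRSF1 = list(profile = .profile(
      .col("C", 0.75), .col("G", 0.75), .col("A", 0.8), .col("A", 0.8),
      .col("G", 0.8), .col("A", 0.75), .col("A", 0.7)),
      polarity = "motif", offset = 1L, class = "SRF", role = "enhancer"),
    TIA1 = list(profile = .profile(
      .col("T", 0.85), .col("T", 0.85), .col("T", 0.85), .col("T", 0.8),
      .col("T", 0.8), .col("C", 0.7)),
      polarity = "motif", offset = 1L, class = "SRF", role = "enhancer"),
    PTB = list(profile = .profile(
      .col("T", 0.8), .col("C", 0.8), .col("T", 0.82), .col("T", 0.82),
      .col("C", 0.8), .col("T", 0.75)),
      polarity = "motif", offset = 1L, class = "SRF", role = "blocker"),
    ELAVL1 = list(profile = .profile(
      .col("T", 0.8), .col("T", 0.8), .col("T", 0.75), .col("A", 0.75),
      .col("T", 0.8), .col("T", 0.75)),
      polarity = "motif", offset = 1L, class = "SRF", role = "repressor"),
    hnRNPH = list(profile = .profile(
      .col("G", 0.85), .col("G", 0.85), .col("G", 0.85), .col("A", 0.75),
      .col("G", 0.8), .col("G", 0.8)),
      polarity = "motif", offset = 1L, class = "SRF", role = "repressor"),
    GATA3 = list(profile = .profile(
      .col("A", 0.8), .col("G", 0.9), .col("A", 0.92), .col("T", 0.92),
      .col("A", 0.9), .col("A", 0.75), .col("G", 0.7), .col("A", 0.6)),
      polarity = "motif", offset = 1L, class = "TF", role = "activator"),
    E2F4 = list(profile = .profile(
      .col("T", 0.8), .col("T", 0.85), .col("T", 0.85), .col("G", 0.85),
      .col("G", 0.9), .col("C", 0.9), .col("G", 0.9), .col("C", 0.85)),
      polarity = "motif", offset = 1L, class = "TF", role = "activator"),
    SP1 = list(profile = .profile(
      .col("G", 0.85), .col("G", 0.9), .col("G", 0.9), .col("G", 0.8),
      .col("C", 0.8), .col("G", 0.9), .col("G", 0.9), .col("G", 0.8)),
      polarity = "motif", offset = 1L, class = "TF", role = "activator"),
    RUNX3 = list(profile = .profile(
      .col("T", 0.8), .col("G", 0.9), .col("T", 0.85), .col("G", 0.9),
      .col("G", 0.9), .col("T", 0.8)),
      polarity = "motif", offset = 1L, class = "TF", role = "repressor"),
    GABPA = list(profile = .profile(
      .col("C", 0.7), .col("C", 0.75), .col("G", 0.9), .col("G", 0.92),
      .col("A", 0.92), .col("A", 0.9), .col("G", 0.75), .col("T", 0.7)),
      polarity = "motif", offset = 1L, class = "TF", role = "activator"),
    RBFOX = list(profile = .profile(
      .col("T", 0.88), .col("G", 0.92), .col("C", 0.92), .col("A", 0.92),
      .col("T", 0.9), .col("G", 0.88)),
      polarity = "motif", offset = 1L, class = "RBP", role = "splicing"),
    SF3B4 = list(profile = .profile(
      .col("A", 0.8), .col("T", 0.82), .col("C", 0.82), .col("A", 0.85),
      .col("A", 0.85), .col("C", 0.78)),
      polarity = "motif", offset = 1L, class = "RBP", role = "splicing"),
    CELF4 = list(profile = .profile(
      .col("T", 0.85), .col("G", 0.85), .col("T", 0.85), .col("G", 0.85),
      .col("T", 0.82), .col("G", 0.82)),
      polarity = "motif", offset = 1L, class = "RBP", role = "stability"),
    NCL = list(profile = .profile(
      .col("T", 0.8), .col("C", 0.85), .col("C", 0.88), .col("C", 0.88),
      .col("G", 0.85), .col("A", 0.8)),
      polarity = "motif", offset = 1L, class = "RBP", role = "translation"),
    KHDRBS1 = list(profile = .profile(
      .col("A", 0.8), .col("T", 0.85), .col("A", 0.85), .col("A", 0.85),
      .col("A", 0.8), .col("T", 0.75)),
      polarity = "motif", offset = 1L, class = "RBP", role = "stability"))

  models <- lapply(names(specs), function(nm) {
    sp <- specs[[nm]]
    build_iwm_from_sites(.sites_from_profile(sp$profile, n_train),
                         apply_correction = FALSE, polarity = sp$polarity,
                         offset = sp$offset, id = nm)
  })
  names(models) <- names(specs)
  meta <- data.frame(factor = names(specs),
                     class = vapply(specs, `[[`, "", "class"),
                     role = vapply(specs, `[[`, "", "role"),
                     stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  list(models = models, meta = meta)
}

#' Sample training-site sequences from a matrix's implied distribution
#'
#' @param iwm an `iwm` carrying its frequency matrix.
#' @param n sites to draw.
#' @param method `"multinomial"` draws each column independently;
#'   `"stratified"` deals the expected counts deterministically
#'   (largest-remainder rounding).
#' @return character vector of site sequences.
#' @export
sample_sites <- function(iwm, n, method = c("multinomial", "stratified")) {
  method <- match.arg(method)
  if (is.null(iwm$freq)) stop("matrix does not carry base frequencies")
  f <- iwm$freq$freq
  if (method == "stratified") return(.sites_from_profile(f, n))
  L <- nrow(f)
  cols <- vapply(seq_len(L), function(l) {
    sample(.BASES, n, replace = TRUE, prob = f[l, ])
  }, character(n))
  if (n == 1L) cols <- matrix(cols, nrow = 1L)
  apply(cols, 1L, paste, collapse = "")
}

# place a string into a sequence at 0-based position
.plant <- function(seq, at, what) {
  stopifnot(at >= 0L, at + nchar(what) <= nchar(seq))
  paste0(substr(seq, 1L, at), what, substr(seq, at + nchar(what) + 1L, nchar(seq)))
}

#' Simulate a gene with planted splice sites and motifs
#'
#' Generates a plus-strand gene: 5' flank, a first exon opening with a
#' 5' UTR and the CDS start, internal exons, a final exon carrying the stop
#' codon and 3' UTR, and a 3' flank.  Natural splice sites are planted at
#' every intron boundary by sampling a strong site from the model's implied
#' distribution (resampling until it scores within 2 bits of the consensus);
#' the CDS is stop-free except for its terminal codon.  Additional motif
#' sites can be planted at caller-chosen anchors.
#'
#' @param seed RNG seed for this genome.
#' @param models model set from [default_models()].
#' @param exon_lengths,intron_lengths exon/intron lengths (nt), 5' to 3';
#'   `length(intron_lengths) == length(exon_lengths) - 1`.
#' @param utr5_len,utr3_len UTR lengths inside the first/last exon.
#' @param flank5,flank3 flanking sequence (nt); the promoter lives in
#'   `flank5`.
#' @param plant optional data.frame (`model`, `pos` 0-based anchor) of extra
#'   sites to plant (consensus sequence of the model).
#' @param gene_id,chrom identifiers.
#' @return list with `seq`, `gene` (a `gene_model`), `manifest` (data.frame
#'   of planted elements: `element`, `model`, `position`, `ri`).
#' @export
simulate_gene <- function(seed, models, exon_lengths = c(220L, 160L, 260L),
                          intron_lengths = c(1400L, 1600L),
                          utr5_len = 120L, utr3_len = 150L,
                          flank5 = 2000L, flank3 = 800L,
                          plant = NULL, gene_id = "GENE1", chrom = "chrS") {
  set.seed(seed)
  n_ex <- length(exon_lengths)
  stopifnot(n_ex >= 2L, length(intron_lengths) == n_ex - 1L)
  total <- flank5 + sum(exon_lengths) + sum(intron_lengths) + flank3
  seq <- paste(sample(.BASES, total, replace = TRUE), collapse = "")

  # exon coordinates
  starts <- integer(n_ex)
  ends <- integer(n_ex)
  at <- flank5
  for (i in seq_len(n_ex)) {
    starts[[i]] <- at
    ends[[i]] <- at + exon_lengths[[i]]
    at <- ends[[i]] + if (i < n_ex) intron_lengths[[i]] else 0L
  }

  # CDS geometry: starts after the 5' UTR, ends before the 3' UTR; trim the
  # start so the CDS length is a whole number of codons
  cds_start <- starts[[1L]] + utr5_len
  cds_end <- ends[[n_ex]] - utr3_len
  cds_len <- sum(pmin(ends, cds_end) - pmax(starts, cds_start))
  cds_start <- cds_start + (cds_len %% 3L)

  gene <- gene_model(gene_id, chrom, "+", tss = starts[[1L]],
                     exon_starts = starts, exon_ends = ends,
                     cds_start = cds_start, cds_end = cds_end,
                     protein_length = 0L)
  segs <- .cds_segments(gene)
  cds_len <- sum(segs[, "end"] - segs[, "start"])
  protein_length <- cds_len %/% 3L - 1L  # terminal codon is the stop

  # stop-free CDS: ATG + random sense codons + TAA
  codons <- apply(expand.grid(.BASES, .BASES, .BASES), 1L, paste, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA", "ATG"))
  body <- paste(sample(sense, cds_len %/% 3L - 2L, replace = TRUE),
                collapse = "")
  cds_seq <- paste0("ATG", body, "TAA")
  at <- 0L
  for (i in seq_len(nrow(segs))) {
    w <- segs[i, "end"] - segs[i, "start"]
    seq <- .plant(seq, segs[i, "start"], substr(cds_seq, at + 1L, at + w))
    at <- at + w
  }

  strong_site <- function(iwm) {
    best <- consensus_ri(iwm)
    for (k in seq_len(200L)) {
      s <- sample_sites(iwm, 1L)
      if (.ri_string(s, iwm) >= best - 2) return(s)
    }
    consensus_seq(iwm)
  }
  manifest <- list()
  note <- function(element, model, position, s) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      element = element, model = model, position = position,
      ri = .ri_string(s, models$models[[model]]), stringsAsFactors = FALSE)
  }
  acc <- models$models$acceptor
  don <- models$models$donor
  for (i in seq_len(n_ex)) {
    if (i > 1L) {  # acceptor anchored at first exon base
      s <- strong_site(acc)
      seq <- .plant(seq, starts[[i]] - (acc$offset - 1L), s)
      note("natural_acceptor", "acceptor", starts[[i]], s)
    }
    if (i < n_ex) {  # donor anchored at first intron base
      s <- strong_site(don)
      seq <- .plant(seq, ends[[i]] - (don$offset - 1L), s)
      note("natural_donor", "donor", ends[[i]], s)
    }
  }
  if (!is.null(plant)) {
    for (i in seq_len(nrow(plant))) {
      m <- models$models[[plant$model[[i]]]]
      s <- consensus_seq(m)
      a0 <- plant$pos[[i]] - (m$offset - 1L)
      seq <- .plant(seq, a0, s)
      note("planted_site", plant$model[[i]], plant$pos[[i]], s)
    }
  }

  # repair any premature stop introduced by site planting inside the CDS
  fix_rounds <- 0L
  repeat {
    cds_now <- .spliced(seq, segs)
    prot <- .translate(cds_now)
    hit <- regexpr("*", substr(prot, 1L, protein_length), fixed = TRUE)
    if (hit < 0L) break
    fix_rounds <- fix_rounds + 1L
    if (fix_rounds > 50L) stop("unable to build a stop-free CDS with the requested plants")
    cpos <- (as.integer(hit) - 1L) * 3L  # 0-based CDS offset of stop codon
    rem <- cpos
    for (i in seq_len(nrow(segs))) {
      w <- segs[i, "end"] - segs[i, "start"]
      if (rem < w) { gpos <- segs[i, "start"] + rem; break }
      rem <- rem - w
    }
    seq <- .plant(seq, gpos, "C")
  }

  gene$protein_length <- as.integer(protein_length)
  list(seq = seq, gene = gene, manifest = do.call(rbind, manifest))
}

#' Simulate a cohort VCF over a synthetic gene
#'
#' Background SNVs are placed on a regular grid with allele frequencies
#' drawn from `af_range` and Hardy-Weinberg genotypes per sample; planted
#' variants are heterozygous in their designated carrier(s) only; a planted
#' hemizygous deletion silences heterozygosity in its carrier across the
#' interval.  Records are written as VCF v4.1 text.
#'
#' @param seed RNG seed.
#' @param sim gene simulation from [simulate_gene()].
#' @param n_samples cohort size.
#' @param planted data.frame (`sample` index, `pos` 0-based, `ref`, `alt`)
#'   of variants to plant (heterozygous, QUAL high).
#' @param deletion optional list(`sample`, `start`, `end`) hemizygous
#'   interval.
#' @param marker_spacing background marker grid spacing (nt).
#' @param af_range background allele-frequency range.
#' @param qual_range QUAL range for background records.
#' @param vcf_path output path; when `NULL` the lines are returned unwritten.
#' @return list with `vcf_lines`, `path`, `markers` (data.frame `pos`, `af`),
#'   `het` (samples x markers logical matrix), `samples`.
#' @export
simulate_cohort <- function(seed, sim, n_samples = 20L, planted = NULL,
                            deletion = NULL, marker_spacing = 250L,
                            af_range = c(0.2, 0.5), qual_range = c(60, 900),
                            vcf_path = NULL) {
  set.seed(seed)
  seq <- sim$seq
  n <- nchar(seq)
  samples <- sprintf("S%02d", seq_len(n_samples))

  pos <- seq(from = marker_spacing %/% 2L, to = n - 1L, by = marker_spacing)
  if (!is.null(planted)) pos <- setdiff(pos, planted$pos)
  af <- stats::runif(length(pos), af_range[[1L]], af_range[[2L]])
  # HWE genotypes: 0/1/2 alt copies
  gt <- vapply(af, function(p) {
    sample(0:2, n_samples, replace = TRUE,
           prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
  }, integer(n_samples))
  if (n_samples == 1L) gt <- matrix(gt, nrow = 1L)
  rownames(gt) <- samples
  if (!is.null(deletion)) {
    in_del <- pos >= deletion$start & pos < deletion$end
    gt[deletion$sample, in_del] <- 0L  # loss of heterozygosity in carrier
  }

  ref_at <- function(p) substr(seq, p + 1L, p + 1L)
  other <- function(b) sample(setdiff(.BASES, b), 1L)
  recs <- character(0)
  gt_str <- c("0/0", "0/1", "1/1")
  for (j in seq_along(pos)) {
    rb <- ref_at(pos[[j]])
    recs <- c(recs, paste(c(sim$gene$chrom, pos[[j]] + 1L, ".", rb, other(rb),
                            sprintf("%.0f", stats::runif(1, qual_range[[1L]],
                                                         qual_range[[2L]])),
                            "PASS", sprintf("AF=%.4f", af[[j]]), "GT",
                            gt_str[gt[, j] + 1L]), collapse = "\t"))
  }
  if (!is.null(planted)) {
    for (i in seq_len(nrow(planted))) {
      g <- rep("0/0", n_samples)
      g[[planted$sample[[i]]]] <- "0/1"
      recs <- c(recs, paste(c(sim$gene$chrom, planted$pos[[i]] + 1L, ".",
                              planted$ref[[i]], planted$alt[[i]], "500",
                              "PASS", ".", "GT", g), collapse = "\t"))
    }
  }
  ord <- order(as.integer(vapply(strsplit(recs, "\t"), `[[`, "", 2L)))
  header <- c("##fileformat=VCFv4.1",
              sprintf("##contig=<ID=%s,length=%d>", sim$gene$chrom, n),
              "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  lines <- c(header, recs[ord])
  if (!is.null(vcf_path)) writeLines(lines, vcf_path)
  het <- gt == 1L
  colnames(het) <- as.character(pos)
  list(vcf_lines = lines, path = vcf_path,
       markers = data.frame(pos = pos, af = af), het = het, samples = samples)
}

#' Simulate genotype heterozygosity for hemizygosity power studies
#'
#' A lightweight cohort: informative markers on a regular grid with allele
#' frequencies drawn from `af_range`, per-sample heterozygosity under
#' Hardy-Weinberg, and optionally one planted hemizygous deletion silencing
#' heterozygosity in its carrier.
#'
#' @param seed RNG seed.
#' @param n_samples cohort size.
#' @param region_length captured region length (nt).
#' @param marker_spacing marker grid spacing (nt).
#' @param af_range marker allele-frequency range.
#' @param deletion optional c(start, end) planted hemizygous interval.
#' @param carrier sample index carrying the deletion.
#' @return list with `het` (samples x markers), `marker_pos`, `marker_af`,
#'   `region`, `carrier`.
#' @export
simulate_hemizygosity_cohort <- function(seed, n_samples = 20L,
                                         region_length = 40000L,
                                         marker_spacing = 250L,
                                         af_range = c(0.2, 0.5),
                                         deletion = NULL, carrier = 1L) {
  set.seed(seed)
  pos <- seq(from = marker_spacing %/% 2L, to = region_length - 1L,
             by = marker_spacing)
  af <- stats::runif(length(pos), af_range[[1L]], af_range[[2L]])
  het <- vapply(af, function(p) {
    stats::runif(n_samples) < 2 * p * (1 - p)
  }, logical(n_samples))
  if (n_samples == 1L) het <- matrix(het, nrow = 1L)
  rownames(het) <- sprintf("S%02d", seq_len(n_samples))
  if (!is.null(deletion)) {
    het[carrier, pos >= deletion[[1L]] & pos < deletion[[2L]]] <- FALSE
  }
  list(het = het, marker_pos = pos, marker_af = af,
       region = c(0L, region_length), carrier = carrier)
}

#' Write the factor metadata table for a model set
#' @param models model set from [default_models()].
#' @param path output file.
#' @export
write_factor_meta <- function(models, path) {
  utils::write.table(models$meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
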