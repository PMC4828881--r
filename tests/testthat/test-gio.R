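# FASTA/VCF/BED/table I/O and coordinate conventions.

test_that("reference round-trips through FASTA and honors strand/bounds", {
  seq <- rand_dna(300, seed = 5)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seq, "chrT", fa)
  ref <- read_reference(fa)
  expect_equal(fetch_seq(ref, "chrT", 0, 300), seq)
  expect_equal(fetch_seq(ref, "chrT", 17, 17), "")
  expect_equal(fetch_seq(ref, "chrT", 10, 40, "-"),
               revcomp(substr(seq, 11, 40)))
  expect_error(fetch_seq(ref, "chrZ", 0, 5), "not found")
  expect_error(fetch_seq(ref, "chrT", 0, 400), "out of bounds")
})

test_that("VCF and internal coordinates are inverse bijections", {
  pos <- c(1L, 17L, 100000L)
  expect_equal(internal_to_vcf(vcf_to_internal(pos)), pos)
  expect_equal(vcf_to_internal(internal_to_vcf(pos - 1L)), pos - 1L)
})

test_that("cohort VCF reading splits alleles, filters regions, and conserves counts", {
  set.seed(21)
  header <- c("##fileformat=VCFv4.1",
              "##contig=<ID=chrT,length=10000>",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", "SA", "SB"), collapse = "\t"))
  mk <- function(pos, ref, alt, qual = "99", gts = c("0/1", "0/0")) {
    paste(c("chrT", pos, ".", ref, alt, qual, "PASS", ".", "GT", gts),
          collapse = "\t")
  }
  pos_in <- sample(1000:1999, 40)
  pos_out <- sample(5000:5999, 58)
  recs <- c(vapply(pos_in, function(p) mk(p, "A", "G"), ""),
            vapply(pos_out, function(p) mk(p, "C", "T"), ""),
            mk(1500, "A", "G,T", gts = c("1/2", "0/1")),  # in-region, 2 ALTs
            paste(c("chrT", "abc", ".", "A", "G", "50", "PASS", ".", "GT",
                    "0/0", "0/0"), collapse = "\t"))      # malformed POS
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(header, recs), vcf)

  bed <- data.frame(chrom = "chrT", start = 999L, end = 2000L, name = "cap")
  res <- read_cohort_vcf(vcf, bed)
  expect_equal(unname(res$counts[["total"]]), 100)
  expect_equal(unname(res$counts[["malformed"]]), 1)
  expect_equal(unname(res$counts[["excluded_region"]]), 58)
  # conservation: kept records + excluded + malformed = total
  expect_equal(res$counts[["records_kept"]] + res$counts[["excluded_region"]] +
                 res$counts[["malformed"]], res$counts[["total"]])
  # multi-allelic split: 41 kept records -> 42 allele rows
  expect_equal(nrow(res$variants), 42)
  multi <- res$variants[res$variants$pos == 1499, ]
  expect_equal(sort(multi$alt), c("G", "T"))
  expect_equal(multi$carrier_count, c(2L, 1L))
  # 1-based POS became 0-based internally
  expect_true(all(res$variants$pos >= 999 & res$variants$pos < 2000))
  expect_equal(res$samples, c("SA", "SB"))
})

test_that("gene models round-trip through the annotation table with derived UTRs", {
  g <- gene_model("G1", "chrT", "+", tss = 100,
                  exon_starts = c(100, 400, 800),
                  exon_ends = c(200, 500, 950),
                  cds_start = 150, cds_end = 900, protein_length = 99)
  expect_equal(unname(g$utr5), matrix(c(100, 150), 1))
  expect_equal(unname(g$utr3), matrix(c(900, 950), 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_models(list(G1 = g), path)
  g2 <- read_gene_models(path)$G1
  expect_equal(g2$exons, g$exons)
  expect_equal(g2$cds_start, g$cds_start)
  expect_equal(g2$protein_length, g$protein_length)
  expect_equal(g2$utr3, g$utr3)

  expect_error(gene_model("bad", "chrT", "+", 0, c(0, 50), c(60, 100),
                          10, 90, 10), "overlap")
})

test_that("minus-strand genes orient onto the transcribed strand reversibly", {
  seq <- rand_dna(1000, seed = 33)
  g <- gene_model("G2", "chrT", "-", tss = 899,
                  exon_starts = c(100, 400, 800),
                  exon_ends = c(200, 500, 900),
                  cds_start = 150, cds_end = 850, protein_length = 10)
  o <- orient_gene(g, seq)
  expect_equal(o$gene$strand, "+")
  expect_equal(o$seq, revcomp(seq))
  # first oriented exon is the mirrored last genomic exon
  expect_equal(unname(o$gene$exons[1, ]), c(1000 - 900, 1000 - 800))
  # anchor mapping is an involution
  p <- 123L
  expect_equal(o$map_back(o$map_back(p)), p)
  # oriented exonic sequence equals the reverse complement of genomic exons
  ex1 <- substr(o$seq, o$gene$exons[1, "start"] + 1, o$gene$exons[1, "end"])
  expect_equal(ex1, revcomp(substr(seq, 801, 900)))
})

test_that("allele-frequency and factor tables read with conversions applied", {
  af <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\taf",
               "chrT\t101\tA\tG\t0.25",
               "chrT\t202\tC\tT\t0.001"), af)
  tab <- read_allele_freqs(af)
  expect_equal(tab$pos, c(100L, 201L))

  fm <- withr::local_tempfile(fileext = ".tsv")
  write_factor_meta(the_models(), fm)
  meta <- read_factor_meta(fm)
  expect_true(all(c("factor", "class", "role") %in% names(meta)))
  expect_true("PTB" %in% meta$factor)
})
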