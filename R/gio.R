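# Readers/writers for the formats the pipeline consumes, and the coordinate
# conventions shared by all modules.  Internal coordinates are 0-based
# half-open; VCF-style 1-based coordinates exist only at the I/O boundary.

#' Convert between VCF (1-based) and internal (0-based) coordinates
#' @param pos integer vector.
#' @return integer vector.
#' @export
vcf_to_internal <- function(pos) as.integer(pos) - 1L

#' @rdname vcf_to_internal
#' @export
internal_to_vcf <- function(pos) as.integer(pos) + 1L

#' Load a reference FASTA into a sequence store
#'
#' @param fasta path to a FASTA file.
#' @return object of class `ref_store` (named uppercase character vector of
#'   contig sequences) supporting [fetch_seq()].
#' @export
read_reference <- function(fasta) {
  ss <- Biostrings::readDNAStringSet(fasta)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  structure(as.list(seqs), class = "ref_store")
}

#' Fetch a sub-sequence from a reference store
#'
#' @param ref a `ref_store` from [read_reference()].
#' @param chrom contig name.
#' @param start,end 0-based half-open interval; `start == end` yields `""`.
#' @param strand `"+"` (reference strand) or `"-"` (reverse complement).
#' @return character scalar.
#' @export
fetch_seq <- function(ref, chrom, start, end, strand = "+") {
  if (is.null(ref[[chrom]])) stop("contig not found in reference: ", chrom)
  s <- ref[[chrom]]
  n <- nchar(s)
  if (start < 0L || end > n || start > end) {
    stop(sprintf("interval [%d,%d) out of bounds for contig %s (length %d)",
                 start, end, chrom, n))
  }
  if (start == end) return("")
  out <- substr(s, start + 1L, end)
  if (strand == "-") out <- revcomp(out)
  out
}

#' Read capture-region / LD-block intervals from BED
#'
#' @param path BED file (chrom, start, end, optional name); BED is already
#'   0-based half-open so coordinates pass through unchanged.
#' @return data.frame with `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name")[
                             seq_len(max(3L, ncol(utils::read.table(path, sep = "\t",
                                                                    header = FALSE,
                                                                    nrows = 1L))))])
  if (is.null(bed$name)) bed$name <- ""
  bed[, c("chrom", "start", "end", "name")]
}

#' Read gene models from a tab-delimited annotation table
#'
#' One row per gene with columns: `gene_id`, `chrom`, `strand`, `tss`
#' (0-based), `exon_starts`/`exon_ends` (comma-separated, 0-based half-open,
#' in transcription order), `cds_start`, `cds_end`, `protein_length`.
#' UTR intervals are derived from the exon/CDS geometry.
#'
#' @param path file path.
#' @return named list of `gene_model` objects; each has `gene_id`, `chrom`,
#'   `strand`, `tss`, `exons` (matrix with `start`,`end`), `cds_start`,
#'   `cds_end`, `utr5`, `utr3` (interval matrices), `protein_length`.
#' @export
read_gene_models <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  models <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    gene_model(
      gene_id = row$gene_id, chrom = row$chrom, strand = row$strand,
      tss = row$tss,
      exon_starts = as.integer(strsplit(row$exon_starts, ",")[[1L]]),
      exon_ends = as.integer(strsplit(row$exon_ends, ",")[[1L]]),
      cds_start = row$cds_start, cds_end = row$cds_end,
      protein_length = row$protein_length)
  })
  stats::setNames(models, vapply(models, `[[`, "", "gene_id"))
}

#' Construct a gene model
#'
#' @param gene_id,chrom,strand identifiers; strand `"+"` or `"-"`.
#' @param tss 0-based transcription start.
#' @param exon_starts,exon_ends 0-based half-open exon intervals in
#'   transcription order (genomic order for `"+"` genes).
#' @param cds_start,cds_end 0-based half-open CDS span on the genome.
#' @param protein_length residues.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, tss, exon_starts, exon_ends,
                       cds_start, cds_end, protein_length) {
  stopifnot(length(exon_starts) == length(exon_ends),
            all(exon_ends > exon_starts))
  ord <- order(exon_starts)
  exons <- cbind(start = exon_starts[ord], end = exon_ends[ord])
  if (nrow(exons) > 1L &&
      any(exons[-1L, "start"] < exons[-nrow(exons), "end"])) {
    stop("exons overlap")
  }
  # UTR pieces: exonic sequence outside [cds_start, cds_end)
  clip <- function(lo, hi) {
    keep <- exons[, "end"] > lo & exons[, "start"] < hi
    if (!any(keep)) return(matrix(numeric(0), 0L, 2L,
                                  dimnames = list(NULL, c("start", "end"))))
    m <- exons[keep, , drop = FALSE]
    m[, "start"] <- pmax(m[, "start"], lo)
    m[, "end"] <- pmin(m[, "end"], hi)
    m
  }
  left <- clip(-Inf, cds_start)
  right <- clip(cds_end, Inf)
  utr5 <- if (strand == "+") left else right
  utr3 <- if (strand == "+") right else left
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 tss = as.integer(tss), exons = exons,
                 cds_start = as.integer(cds_start),
                 cds_end = as.integer(cds_end),
                 utr5 = utr5, utr3 = utr3,
                 protein_length = as.integer(protein_length)),
            class = "gene_model")
}

#' Write gene models to the tab-delimited annotation table format
#' @param models list of `gene_model`s.
#' @param path output file.
#' @export
write_gene_models <- function(models, path) {
  rows <- lapply(models, function(g) {
    data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
               tss = g$tss,
               exon_starts = paste(g$exons[, "start"], collapse = ","),
               exon_ends = paste(g$exons[, "end"], collapse = ","),
               cds_start = g$cds_start, cds_end = g$cds_end,
               protein_length = g$protein_length,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an allele-frequency table
#'
#' Tab-delimited with header `chrom pos ref alt af` (`pos` 1-based, as in
#' VCF), emulating a dbSNP frequency lookup.
#'
#' @param path file path.
#' @return data.frame with internal 0-based `pos`.
#' @export
read_allele_freqs <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  tab$pos <- vcf_to_internal(tab$pos)
  tab
}

#' Read the factor metadata table
#'
#' Tab-delimited with header `factor class role`: `class` in
#' `{SS, SRF, TF, RBP}`, `role` e.g. `activator`, `repressor`, `enhancer`,
#' `enhancer-intronic`, `acceptor-proofreader`, `blocker`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_factor_meta <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Read a cohort VCF into a per-allele variant table
#'
#' Parses with `vcfR`, splits multi-allelic records into one row per ALT
#' allele, converts positions to internal 0-based coordinates, and (when
#' `region_bed` is given) drops variants outside the capture regions,
#' keeping count.  Malformed records (unparseable POS/REF/ALT) are skipped
#' and counted.
#'
#' @param vcf_path VCF v4.x file.
#' @param region_bed optional data.frame from [read_bed()].
#' @return list with `variants` (data.frame: `chrom`, `pos` 0-based, `ref`,
#'   `alt`, `qual`, `gt` genotype matrix columns collapsed to a
#'   sample-named character matrix attribute, `carrier_count`,
#'   `hom_alt_count`), `samples`, and `counts`
#'   (`total`, `emitted`, `excluded_region`, `malformed`).
#' @export
read_cohort_vcf <- function(vcf_path, region_bed = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  gt_raw <- if ("gt" %in% slotNames(v) && ncol(v@gt) > 1L) {
    vcfR::extract.gt(v, element = "GT")
  } else {
    NULL
  }
  samples <- if (is.null(gt_raw)) character(0) else colnames(gt_raw)

  rows <- list()
  malformed <- 0L
  excluded <- 0L
  for (i in seq_len(n_rec)) {
    pos1 <- suppressWarnings(as.integer(fix[i, "POS"]))
    ref <- fix[i, "REF"]
    alt_field <- fix[i, "ALT"]
    if (is.na(pos1) || is.na(ref) || is.na(alt_field) || !nzchar(ref) ||
        !grepl("^[ACGTNacgtn,]+$", alt_field)) {
      malformed <- malformed + 1L
      next
    }
    chrom <- fix[i, "CHROM"]
    pos0 <- pos1 - 1L
    if (!is.null(region_bed)) {
      inside <- any(region_bed$chrom == chrom &
                    region_bed$start <= pos0 & pos0 < region_bed$end)
      if (!inside) {
        excluded <- excluded + 1L
        next
      }
    }
    qual <- suppressWarnings(as.numeric(fix[i, "QUAL"]))
    alts <- strsplit(alt_field, ",", fixed = TRUE)[[1L]]
    gts <- if (is.null(gt_raw)) NULL else gt_raw[i, , drop = TRUE]
    for (k in seq_along(alts)) {
      if (toupper(alts[[k]]) == toupper(ref)) next
      carriers <- 0L
      hom <- 0L
      gt_alle <- character(0)
      if (!is.null(gts)) {
        alleles <- lapply(strsplit(gts, "[/|]"), function(a) suppressWarnings(as.integer(a)))
        has <- vapply(alleles, function(a) any(a == k, na.rm = TRUE), logical(1L))
        hom_s <- vapply(alleles, function(a) length(a) > 0L &&
                          all(!is.na(a)) && all(a == k), logical(1L))
        carriers <- sum(has)
        hom <- sum(hom_s)
        gt_alle <- gts
      }
      rows[[length(rows) + 1L]] <- list(chrom = chrom, pos = pos0,
                                        ref = toupper(ref),
                                        alt = toupper(alts[[k]]),
                                        qual = qual,
                                        carrier_count = carriers,
                                        hom_alt_count = hom,
                                        gt = list(gt_alle))
    }
  }
  variants <- if (length(rows)) {
    data.frame(
      chrom = vapply(rows, `[[`, "", "chrom"),
      pos = vapply(rows, `[[`, 0L, "pos"),
      ref = vapply(rows, `[[`, "", "ref"),
      alt = vapply(rows, `[[`, "", "alt"),
      qual = vapply(rows, `[[`, 0, "qual"),
      carrier_count = vapply(rows, `[[`, 0L, "carrier_count"),
      hom_alt_count = vapply(rows, `[[`, 0L, "hom_alt_count"),
      stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), qual = numeric(0),
               carrier_count = integer(0), hom_alt_count = integer(0))
  }
  if (length(rows)) {
    gtm <- do.call(rbind, lapply(rows, function(r) r$gt[[1L]]))
    if (!is.null(gtm) && ncol(gtm) == length(samples)) colnames(gtm) <- samples
    attr(variants, "gt") <- gtm
  }
  list(variants = variants, samples = samples,
       counts = c(total = n_rec,
                  emitted = nrow(variants),
                  records_kept = n_rec - malformed - excluded,
                  excluded_region = excluded,
                  malformed = malformed))
}

#' Write a single-contig FASTA file
#' @param seq sequence string.
#' @param name contig name.
#' @param path output file.
#' @export
write_fasta <- function(seq, name, path) {
  ss <- Biostrings::DNAStringSet(seq)
  names(ss) <- name
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
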