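# End-to-end orchestration: filtering funnel, per-category information
# analyses, aggregation into flagged/prioritized sets, and report emission.

.CATEGORIES <- c("indel", "nonsense", "missense", "natural_splicing",
                 "cryptic_splicing", "pseudoexon", "srf", "tf",
                 "utr_structure", "utr_binding")

#' Locate a variant relative to a gene model
#'
#' @param pos 0-based variant start.
#' @param ref_len reference allele length.
#' @param gene transcription-oriented `gene_model`.
#' @param contig_len contig length.
#' @param promoter_upstream promoter extent upstream of the TSS (nt).
#' @return list: `region` (`cds`, `utr5`, `utr3`, `exonic`, `intronic`,
#'   `flank`), `exon_distance`, `in_promoter`, `intron` (c(start,end) or
#'   NULL), `spans_boundary`.
#' @keywords internal
.locate_variant <- function(pos, ref_len, gene, contig_len,
                            promoter_upstream = 10000L) {
  ex <- gene$exons
  lo <- pos
  hi <- pos + max(1L, ref_len)
  in_iv <- function(m) any(m[, "start"] < hi & lo < m[, "end"])
  fully_in <- function(m) any(m[, "start"] <= lo & hi <= m[, "end"])
  segs <- .cds_segments(gene)
  exonic <- in_iv(ex)
  spans <- exonic && !fully_in(ex)
  region <- if (fully_in(segs)) "cds"
    else if (nrow(gene$utr5) && fully_in(gene$utr5)) "utr5"
    else if (nrow(gene$utr3) && fully_in(gene$utr3)) "utr3"
    else if (exonic) "exonic"
    else if (lo >= ex[1L, "start"] && hi <= ex[nrow(ex), "end"]) "intronic"
    else "flank"
  dist <- if (exonic) 0L else
    min(abs(c(lo - ex[, "end"] + 1L, ex[, "start"] - lo)))
  intron <- NULL
  if (region == "intronic") {
    for (i in seq_len(nrow(ex) - 1L)) {
      if (lo >= ex[i, "end"] && hi <= ex[i + 1L, "start"]) {
        intron <- c(ex[i, "end"], ex[i + 1L, "start"])
        break
      }
    }
  }
  prom <- promoter_region(gene, contig_len, promoter_upstream)
  list(region = region, exon_distance = as.integer(dist),
       in_promoter = in_promoter(pos, prom), intron = intron,
       spans_boundary = spans)
}

# all scoreable changes of a model across anchors covering the variant
.all_changes <- function(seq, variant, iwm, lo = 0L, hi = nchar(seq) - 1L) {
  anchors <- .anchors_covering(iwm, variant$pos, nchar(variant$ref), lo, hi)
  out <- list()
  for (a in anchors) {
    ch <- tryCatch(suppressWarnings(delta_ri(seq, variant, iwm, a)),
                   error = function(e) NULL)
    if (!is.null(ch)) out[[length(out) + 1L]] <- ch
  }
  out
}

# TRUE when change a beats change b: larger |delta Ri|, with near-ties
# (within 1e-9 bits, as arise between overlapping anchors of a repetitive
# motif) broken toward the anchor holding the stronger site
.beats <- function(a, b) {
  da <- abs(a$delta_ri)
  db <- abs(b$delta_ri)
  if (da > db + 1e-9) return(TRUE)
  if (da < db - 1e-9) return(FALSE)
  max(a$ref_score$ri, a$alt_score$ri) >
    max(b$ref_score$ri, b$alt_score$ri) + 1e-9
}

# strongest (by |delta Ri|) change of a model across anchors covering the
# variant, restricted to [lo, hi] anchors when given
.best_change <- function(seq, variant, iwm, lo = 0L,
                         hi = nchar(seq) - 1L) {
  best <- NULL
  for (ch in .all_changes(seq, variant, iwm, lo, hi)) {
    if (is.null(best) || .beats(ch, best)) best <- ch
  }
  best
}

# the flagged change with the largest |delta Ri| under a rule function
# returning list(flagged = ...); NULL when no anchor's change flags
.best_flagged <- function(changes, flag_fun) {
  best <- NULL
  for (ch in changes) {
    fl <- flag_fun(ch)
    if (!isTRUE(fl$flagged)) next
    if (is.null(best) || .beats(ch, best$ch)) {
      best <- list(ch = ch, flag = fl)
    }
  }
  best
}

#' Pipeline configuration
#'
#' @param filter a [filter_config()].
#' @param ri_minimum minimum functional splice-site strength (bits).
#' @param cryptic_window cryptic-site distance from the nearest exon (nt).
#' @param srf_window SRFBS region of interest around exons (nt).
#' @param promoter_upstream promoter extent (nt).
#' @param tf_interval TFBS strongest-in-interval half-width (nt).
#' @param structure_p UTR-structure prioritization cutoff.
#' @param fold_engine folding engine for UTR structure analysis.
#' @param length_dist exon-length distribution for gap surprisal.
#' @param hemi_min_length minimum non-polymorphic stretch screened (nt).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(filter = filter_config(), ri_minimum = 1.6,
                            cryptic_window = 300L, srf_window = 500L,
                            promoter_upstream = 10000L, tf_interval = 50L,
                            structure_p = 0.1,
                            fold_engine = fold_engine_hairpin(),
                            length_dist = exon_length_dist(),
                            hemi_min_length = 1000L) {
  structure(list(filter = filter, ri_minimum = ri_minimum,
                 cryptic_window = cryptic_window, srf_window = srf_window,
                 promoter_upstream = promoter_upstream,
                 tf_interval = tf_interval, structure_p = structure_p,
                 fold_engine = fold_engine, length_dist = length_dist,
                 hemi_min_length = hemi_min_length),
            class = "pipeline_config")
}

# analyze one rare variant against one gene; returns rows of evidence
.analyze_variant <- function(v, gene, seq, models, meta, config) {
  loc <- .locate_variant(v$pos, nchar(v$ref), gene, nchar(seq),
                         config$promoter_upstream)
  acc <- models$acceptor
  don <- models$donor
  out <- list()
  add <- function(category, flagged, prioritized, evidence) {
    out[[length(out) + 1L]] <<- data.frame(
      category = category, flagged = flagged, prioritized = prioritized,
      evidence = evidence, stringsAsFactors = FALSE)
  }
  variant <- list(pos = v$pos, ref = v$ref, alt = v$alt)
  is_indel <- nchar(v$ref) != nchar(v$alt)

  ## coding consequences
  if (loc$region == "cds" || (loc$spans_boundary &&
                              v$pos + nchar(v$ref) > gene$cds_start &&
                              v$pos < gene$cds_end)) {
    cc <- tryCatch(annotate_coding(variant, gene, seq),
                   error = function(e) NULL)
    if (!is.null(cc) && cc$consequence != "defer-splicing") {
      pri <- prioritize_truncation(cc)
      cat_name <- switch(cc$consequence,
                         frameshift_indel = "indel", inframe_indel = "indel",
                         nonsense = "nonsense", missense = "missense",
                         NA_character_)
      if (!is.na(cat_name)) {
        add(cat_name, TRUE, pri$prioritize,
            sprintf("%s %s; %s", cc$consequence,
                    ifelse(is.na(cc$protein_change), "", cc$protein_change),
                    pri$reason))
      }
    }
  }

  ## natural splice sites: variant inside a natural-site footprint
  nat_positions <- list()
  ex <- gene$exons
  for (i in seq_len(nrow(ex))) {
    if (i > 1L) nat_positions[[length(nat_positions) + 1L]] <-
      list(kind = "acceptor", iwm = acc, anchor = ex[i, "start"], exon = i)
    if (i < nrow(ex)) nat_positions[[length(nat_positions) + 1L]] <-
      list(kind = "donor", iwm = don, anchor = ex[i, "end"], exon = i)
  }
  hit_natural <- FALSE
  for (np in nat_positions) {
    L <- iwm_width(np$iwm)
    w0 <- np$anchor - (np$iwm$offset - 1L)
    if (v$pos + nchar(v$ref) <= w0 || v$pos >= w0 + L) next
    hit_natural <- TRUE
    ch <- tryCatch(suppressWarnings(delta_ri(seq, variant, np$iwm, np$anchor)),
                   error = function(e) NULL)
    if (is.null(ch)) next
    fl <- flag_natural_site_variant(ch, config$ri_minimum)
    if (fl$flagged) {
      ev <- sprintf("natural %s exon %d: %s -> %s bits (%s)", np$kind,
                    np$exon, format_bits(fl$ri_initial),
                    format_bits(fl$ri_final), fl$category)
      exi <- if (np$kind == "acceptor") np$exon else np$exon
      pri <- fl$category %in% c("abolished", "leaky")
      if (exi > 1L && exi < nrow(ex)) {
        iso <- tryCatch(rank_isoforms(seq, gene, exi, acc, don,
                                      variant = variant,
                                      ri_minimum = config$ri_minimum,
                                      window = config$cryptic_window,
                                      length_dist = config$length_dist),
                        error = function(e) NULL)
        if (!is.null(iso)) {
          ev <- sprintf("%s; top isoform %s", ev, iso$isoforms$kind[[1L]])
        }
      }
      add("natural_splicing", TRUE, pri, ev)
    }
  }

  ## cryptic splice sites (not at a natural site, near an exon)
  if (!hit_natural && loc$exon_distance <= config$cryptic_window &&
      loc$region != "flank") {
    for (kind in c("acceptor", "donor")) {
      iwm <- if (kind == "acceptor") acc else don
      same_kind <- Filter(function(np) np$kind == kind, nat_positions)
      if (!length(same_kind)) next
      d_nat <- vapply(same_kind, function(np) abs(np$anchor - v$pos), 0)
      np_near <- same_kind[[which.min(d_nat)]]
      nearest <- list(ri = score_site(seq, np_near$iwm, np_near$anchor)$ri)
      hit <- .best_flagged(.all_changes(seq, variant, iwm), function(ch) {
        flag_cryptic_site_variant(ch, nearest, loc$exon_distance,
                                  config$cryptic_window)
      })
      if (!is.null(hit)) {
        ch <- hit$ch
        fl <- hit$flag
        # prioritized only when the cryptic exon displaces the natural one
        exi <- 2L  # internal exon nearest the variant
        d_ex <- vapply(2:(max(2L, nrow(ex) - 1L)), function(i) {
          min(abs(v$pos - ex[i, "start"]), abs(v$pos - ex[i, "end"]))
        }, numeric(1L))
        exi <- (2:(max(2L, nrow(ex) - 1L)))[which.min(d_ex)]
        pri <- FALSE
        iso <- tryCatch(rank_isoforms(seq, gene, exi, acc, don,
                                      variant = variant,
                                      ri_minimum = config$ri_minimum,
                                      window = config$cryptic_window,
                                      length_dist = config$length_dist),
                        error = function(e) NULL)
        if (!is.null(iso)) pri <- !isTRUE(iso$isoforms$is_wildtype[[1L]])
        add("cryptic_splicing", TRUE, pri,
            sprintf("cryptic %s %s -> %s bits at %d nt from exon%s", kind,
                    format_bits(ch$ref_score$ri),
                    format_bits(fl$ri_final), loc$exon_distance,
                    if (pri) "; predicted to outcompete natural exon" else
                      "; natural exon remains stronger"))
      }
    }
  }

  ## pseudoexon activation
  if (loc$region == "intronic" && !is.null(loc$intron)) {
    pe <- tryCatch(
      detect_pseudoexon(seq, variant, loc$intron, acc, don,
                        models$hnRNPA1, length_dist = config$length_dist),
      error = function(e) NULL)
    if (!is.null(pe)) {
      add("pseudoexon", TRUE, TRUE,
          sprintf("pseudoexon %s%s; hnRNPA1 %s bits at %d nt",
                  pe$lengths_str,
                  if (pe$frameshift) " (frameshift)" else "",
                  format_bits(pe$hnrnpa1_site$ri), pe$hnrnpa1_site$distance))
    }
  }

  ## splicing regulatory factors
  if (loc$exon_distance <= config$srf_window && loc$region != "flank") {
    srf_rules <- default_srf_rules()
    srf_ids <- meta$factor[meta$class == "SRF"]
    region2 <- if (loc$region %in% c("cds", "utr5", "utr3", "exonic"))
      "exonic" else "intronic"
    for (id in srf_ids) {
      m <- models[[id]]
      if (is.null(m)) next
      hit <- .best_flagged(.all_changes(seq, variant, m), function(ch) {
        flag_srf_variant(ch, m, loc$exon_distance,
                         max_exon_dist = config$srf_window)
      })
      if (is.null(hit)) next
      ch <- hit$ch
      fl <- hit$flag
      rule <- srf_rules[[id]]
      if (is.null(rule)) rule <- srf_rule(id, "either", "repressor")
      # factor-aware exon-definition change over the nearest internal exon
      drt <- -Inf
      exi <- NA_integer_
      if (nrow(ex) >= 3L) {
        d_ex <- vapply(2:(nrow(ex) - 1L), function(i) {
          min(abs(v$pos - ex[i, "start"]), abs(v$pos - ex[i, "end"]))
        }, numeric(1L))
        exi <- (2:(nrow(ex) - 1L))[which.min(d_ex)]
        ed <- exon_definition(score_site(seq, acc, ex[exi, "start"]),
                              score_site(seq, don, ex[exi, "end"]),
                              config$length_dist)
        drt <- srf_exon_delta(ed, ed, ch, rule)
      }
      acc_dist <- if (!is.na(exi))
        abs(ch$alt_score$position - ex[exi, "start"]) else Inf
      ci <- contextual_interpretation(fl, rule, drt, region2,
                                      acceptor_distance = acc_dist)
      add("srf", TRUE, ci$decision == "prioritized",
          sprintf("%s %s -> %s bits (clause %s); %s", id,
                  format_bits(fl$ri_initial), format_bits(fl$ri_final),
                  fl$clause, ci$reason))
    }
  }

  ## transcription factors (promoter)
  if (loc$in_promoter) {
    tf_ids <- meta$factor[meta$class == "TF"]
    for (id in tf_ids) {
      m <- models[[id]]
      if (is.null(m)) next
      alt_seq <- paste0(substr(seq, 1L, v$pos), v$alt,
                        substr(seq, v$pos + nchar(v$ref) + 1L, nchar(seq)))
      local <- scan_iwm(alt_seq, m)
      local <- local[abs(local$position - v$pos) <= config$tf_interval +
                       iwm_width(m), , drop = FALSE]
      # exclude sites whose footprint overlaps the variant (they are altered)
      fp0 <- local$position - (m$offset - 1L)
      altered <- fp0 <= v$pos & v$pos < fp0 + iwm_width(m)
      unaltered <- local[!altered, , drop = FALSE]
      hit <- .best_flagged(.all_changes(seq, variant, m), function(ch) {
        flag_tfbs_variant(ch, m, unaltered, window = config$tf_interval)
      })
      if (is.null(hit)) next
      ch <- hit$ch
      fl <- hit$flag
      role <- meta$role[meta$factor == id][1L]
      ff <- suppressWarnings(tf_function_filter(fl, role))
      add("tf", TRUE, ff$prioritize,
          sprintf("%s %s -> %s bits (%s); %s", id, format_bits(fl$ri_initial),
                  format_bits(fl$ri_final), fl$kind, ff$reason))
    }
  }

  ## UTR analyses
  if (loc$region %in% c("utr5", "utr3")) {
    utr_iv <- if (loc$region == "utr5") gene$utr5 else gene$utr3
    k <- which(utr_iv[, "start"] <= v$pos & v$pos < utr_iv[, "end"])[1L]
    utr_seq <- substr(seq, utr_iv[k, "start"] + 1L, utr_iv[k, "end"])
    upos <- v$pos - utr_iv[k, "start"]

    # structure disruption (substitutions only)
    if (!is_indel && nchar(utr_seq) >= 20L) {
      sr <- tryCatch(
        structure_disruption_rank(utr_seq,
                                  list(pos = upos, ref = v$ref, alt = v$alt),
                                  engine = config$fold_engine,
                                  p_cutoff = config$structure_p),
        error = function(e) NULL)
      if (!is.null(sr)) {
        add("utr_structure", sr$prioritized, sr$prioritized,
            sprintf("structure rank %d/%d, p = %.3f", sr$rank, sr$total,
                    sr$p_value))
      }
    }

    # RNA-binding proteins
    rbp_ids <- meta$factor[meta$class == "RBP"]
    alt_seq <- paste0(substr(seq, 1L, v$pos), v$alt,
                      substr(seq, v$pos + nchar(v$ref) + 1L, nchar(seq)))
    rbp_models <- models[intersect(rbp_ids, names(models))]
    hood <- scan_rbp_sites(alt_seq, rbp_models, min_ri = 0)
    for (id in names(rbp_models)) {
      m <- rbp_models[[id]]
      others <- hood[hood$factor != id, , drop = FALSE]
      changes <- .all_changes(seq, variant, m)
      hit <- .best_flagged(changes, function(ch) {
        flag_rbbs_variant(ch, m, others, in_utr = TRUE)
      })
      if (!is.null(hit)) {
        fl <- hit$flag
        add("utr_binding", TRUE, TRUE,
            sprintf("%s %s -> %s bits (clause %s, %s-fold)", id,
                    format_bits(fl$ri_initial), format_bits(fl$ri_final),
                    fl$clause, format_fold(fold_change(fl$delta_ri)$fold)))
      } else {
        for (ch in changes) {
          fl <- flag_rbbs_variant(ch, m, others, in_utr = TRUE)
          if (!is.na(fl$suppressed_by)) {
            add("utr_binding", FALSE, FALSE,
                sprintf("%s change suppressed by %s", id, fl$suppressed_by))
            break
          }
        }
      }
    }
  }

  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Run the full prioritization pipeline
#'
#' Applies the filtering funnel (region, quality, frequency), routes every
#' rare variant through the per-category analyses, aggregates flags into
#' prioritization records, and assembles the reports: a variant-level
#' table, a gene x category count matrix of prioritized variants, a
#' per-sample funnel summary, and annotated VCF lines with `ITV_*` INFO
#' tags.
#'
#' @param reference `ref_store` (or FASTA path).
#' @param genes named list of `gene_model`s (or annotation table path).
#' @param vcf_path cohort VCF path.
#' @param models model set from [default_models()] (or a directory of
#'   matrix files plus a metadata table).
#' @param regions optional capture-region BED data.frame (or path).
#' @param af_table optional allele-frequency table (or path).
#' @param ld_blocks optional LD haploblock data.frame (or path).
#' @param overrides optional data.frame (`chrom`, `pos` 1-based, `ref`,
#'   `alt`, `status` in `{pathogenic, benign}`) superseding computed status.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for TSV/VCF report files.
#' @return list of class `pipeline_result`: `records`, `count_matrix`,
#'   `sample_summary`, `funnel`, `hemizygosity`, `vcf_lines`.
#' @export
run_pipeline <- function(reference, genes, vcf_path, models,
                         regions = NULL, af_table = NULL, ld_blocks = NULL,
                         overrides = NULL, config = pipeline_config(),
                         out_dir = NULL) {
  if (is.character(reference)) reference <- read_reference(reference)
  if (is.character(genes)) genes <- read_gene_models(genes)
  if (is.character(regions)) regions <- read_bed(regions)
  if (is.character(af_table)) af_table <- read_allele_freqs(af_table)
  if (is.character(ld_blocks)) ld_blocks <- read_bed(ld_blocks)

  cohort <- read_cohort_vcf(vcf_path, regions)
  variants <- cohort$variants
  n_samples <- length(cohort$samples)
  gt <- attr(variants, "gt")

  tf_res <- technical_filter(variants, config$filter)
  if (!is.null(af_table)) {
    tf_res$kept <- annotate_allele_freqs(tf_res$kept, af_table)
  }
  ff <- frequency_filter(tf_res$kept, config$filter)
  rare <- ff$rare

  funnel <- c(total = unname(cohort$counts[["total"]]),
              in_region = unname(cohort$counts[["emitted"]]),
              qual_pass = nrow(tf_res$kept),
              rare = nrow(rare), flagged = 0L, prioritized = 0L)

  records <- list()
  for (i in seq_len(nrow(rare))) {
    v <- rare[i, ]
    for (g in genes) {
      if (g$chrom != v$chrom) next
      seq <- reference[[g$chrom]]
      o <- orient_gene(g, seq)
      v_o <- v
      if (g$strand == "-") {
        # mirror the variant onto the oriented strand
        v_o$pos <- nchar(seq) - (v$pos + nchar(v$ref))
        v_o$ref <- revcomp(v$ref)
        v_o$alt <- revcomp(v$alt)
      }
      ev <- .analyze_variant(v_o, o$gene, o$seq, models$models, models$meta,
                             config)
      if (is.null(ev)) next
      key <- sprintf("%s:%d:%s>%s", v$chrom, v$pos + 1L, v$ref, v$alt)
      records[[length(records) + 1L]] <- cbind(
        data.frame(variant = key, gene = g$gene_id, chrom = v$chrom,
                   pos = v$pos, ref = v$ref, alt = v$alt,
                   carrier_count = v$carrier_count,
                   row_id = as.integer(rownames(rare)[[i]]),
                   stringsAsFactors = FALSE),
        ev)
    }
  }
  evidence <- if (length(records)) do.call(rbind, records) else
    data.frame(variant = character(0), gene = character(0),
               chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), carrier_count = integer(0),
               row_id = integer(0), category = character(0),
               flagged = logical(0), prioritized = logical(0),
               evidence = character(0))

  ## collapse evidence into one record per variant
  recs <- list()
  for (key in unique(evidence$variant)) {
    e <- evidence[evidence$variant == key, , drop = FALSE]
    flagged_cats <- unique(e$category[e$flagged])
    pri_cats <- unique(e$category[e$prioritized])
    status <- if (length(pri_cats)) "prioritized"
              else if (length(flagged_cats)) "flagged" else "dropped"
    reason <- paste(e$evidence, collapse = " | ")
    if (!is.null(overrides) && nrow(overrides)) {
      ov <- overrides[overrides$chrom == e$chrom[[1L]] &
                        overrides$pos == e$pos[[1L]] + 1L &
                        overrides$ref == e$ref[[1L]] &
                        overrides$alt == e$alt[[1L]], , drop = FALSE]
      if (nrow(ov)) {
        status <- if (ov$status[[1L]] == "pathogenic") "prioritized" else "dropped"
        reason <- paste("override:", ov$status[[1L]], "|", reason)
      }
    }
    recs[[length(recs) + 1L]] <- data.frame(
      variant = key, gene = e$gene[[1L]], chrom = e$chrom[[1L]],
      pos = e$pos[[1L]], ref = e$ref[[1L]], alt = e$alt[[1L]],
      carrier_count = e$carrier_count[[1L]],
      categories = paste(sort(unique(e$category)), collapse = ","),
      flagged_categories = paste(sort(flagged_cats), collapse = ","),
      prioritized_categories = paste(sort(pri_cats), collapse = ","),
      status = status, evidence = reason, row_id = e$row_id[[1L]],
      stringsAsFactors = FALSE)
  }
  records_df <- if (length(recs)) do.call(rbind, recs) else
    data.frame(variant = character(0), gene = character(0),
               chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), carrier_count = integer(0),
               categories = character(0), flagged_categories = character(0),
               prioritized_categories = character(0), status = character(0),
               evidence = character(0), row_id = integer(0))
  funnel[["flagged"]] <- sum(records_df$status %in% c("flagged", "prioritized"))
  funnel[["prioritized"]] <- sum(records_df$status == "prioritized")

  ## gene x category count matrix of prioritized variants (unique variants)
  cm <- matrix(0L, nrow = length(genes), ncol = length(.CATEGORIES),
               dimnames = list(vapply(genes, `[[`, "", "gene_id"),
                               .CATEGORIES))
  pri <- records_df[records_df$status == "prioritized", , drop = FALSE]
  for (i in seq_len(nrow(pri))) {
    for (cat_name in strsplit(pri$prioritized_categories[[i]], ",")[[1L]]) {
      if (cat_name %in% .CATEGORIES) {
        cm[pri$gene[[i]], cat_name] <- cm[pri$gene[[i]], cat_name] + 1L
      }
    }
  }

  ## per-sample funnel
  sample_summary <- NULL
  if (!is.null(gt) && n_samples > 0L) {
    per_sample <- function(rows_gt) {
      colSums(matrix(grepl("1", rows_gt, fixed = TRUE),
                     nrow = nrow(rows_gt)))
    }
    total_s <- per_sample(gt)
    rare_gt <- gt[as.integer(rownames(rare)), , drop = FALSE]
    rare_s <- per_sample(rare_gt)
    pri_s <- if (nrow(pri)) per_sample(gt[pri$row_id, , drop = FALSE]) else
      stats::setNames(rep(0L, n_samples), cohort$samples)
    sample_summary <- data.frame(sample = cohort$samples,
                                 total = as.integer(total_s),
                                 post_filter = as.integer(rare_s),
                                 prioritized = as.integer(pri_s))
  }

  ## hemizygosity screen (from VCF genotypes, cohort markers)
  hemi <- NULL
  if (!is.null(gt) && n_samples >= 11L) {
    het <- t(apply(gt, 2L, function(col) {
      vapply(strsplit(col, "[/|]"), function(a) {
        a <- suppressWarnings(as.integer(a))
        length(unique(a[!is.na(a)])) > 1L
      }, logical(1L))
    }))
    if (ncol(gt) == 1L) het <- matrix(het, ncol = 1L)
    rownames(het) <- cohort$samples
    af <- variants$population_af
    af_known <- if (!is.null(af)) !is.na(af) else rep(FALSE, nrow(variants))
    est_af <- variants$carrier_count / (2 * n_samples)
    marker_af <- ifelse(af_known, af, est_af)
    chrom0 <- genes[[1L]]$chrom
    on_chrom <- variants$chrom == chrom0
    region <- c(0L, nchar(reference[[chrom0]]))
    hemi <- screen_hemizygosity(het[, on_chrom, drop = FALSE],
                                variants$pos[on_chrom],
                                marker_af[on_chrom], region,
                                min_length = config$hemi_min_length,
                                ld_blocks = ld_blocks)
  }

  ## annotated VCF lines
  vcf_lines <- c("##fileformat=VCFv4.1",
                 "##INFO=<ID=ITV_CAT,Number=.,Type=String,Description=\"Flagged categories\">",
                 "##INFO=<ID=ITV_STATUS,Number=1,Type=String,Description=\"Prioritization status\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO"), collapse = "\t"))
  if (nrow(records_df)) {
    ord <- order(records_df$chrom, records_df$pos)
    rr <- records_df[ord, , drop = FALSE]
    vcf_lines <- c(vcf_lines, vapply(seq_len(nrow(rr)), function(i) {
      paste(c(rr$chrom[[i]], rr$pos[[i]] + 1L, ".", rr$ref[[i]],
              rr$alt[[i]], ".", "PASS",
              sprintf("ITV_CAT=%s;ITV_STATUS=%s",
                      gsub(",", "|", rr$flagged_categories[[i]]),
                      rr$status[[i]])), collapse = "\t")
    }, ""))
  }

  res <- structure(list(records = records_df, count_matrix = cm,
                        sample_summary = sample_summary, funnel = funnel,
                        hemizygosity = hemi, vcf_lines = vcf_lines,
                        removed = list(technical = tf_res$removed,
                                       common = ff$common)),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_reports(res, out_dir)
  res
}

#' Classify one prioritization record
#'
#' Recomputes the status from the per-category decisions, honoring an
#' optional override table (variant -> pathogenic/benign) that supersedes
#' the computed status.
#'
#' @param record one row of a `pipeline_result$records` data.frame.
#' @param overrides optional override table (see [run_pipeline()]).
#' @return character status: `"prioritized"`, `"flagged"` or `"dropped"`.
#' @export
classify <- function(record, overrides = NULL) {
  status <- if (nzchar(record$prioritized_categories)) "prioritized"
            else if (nzchar(record$flagged_categories)) "flagged"
            else "dropped"
  if (!is.null(overrides) && nrow(overrides)) {
    ov <- overrides[overrides$chrom == record$chrom &
                      overrides$pos == record$pos + 1L &
                      overrides$ref == record$ref &
                      overrides$alt == record$alt, , drop = FALSE]
    if (nrow(ov)) {
      status <- if (ov$status[[1L]] == "pathogenic") "prioritized" else "dropped"
    }
  }
  status
}

#' Write pipeline reports to a directory
#'
#' @param res a `pipeline_result`.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_reports <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(variants = file.path(out_dir, "variants.tsv"),
             counts = file.path(out_dir, "gene_category_counts.tsv"),
             samples = file.path(out_dir, "sample_summary.tsv"),
             funnel = file.path(out_dir, "funnel.tsv"),
             hemi = file.path(out_dir, "hemizygosity.tsv"),
             vcf = file.path(out_dir, "annotated.vcf"))
  utils::write.table(res$records[setdiff(names(res$records), "row_id")],
                     paths[["variants"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(gene = rownames(res$count_matrix),
                                res$count_matrix, check.names = FALSE),
                     paths[["counts"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(res$sample_summary)) {
    utils::write.table(res$sample_summary, paths[["samples"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.table(data.frame(stage = names(res$funnel),
                                count = as.integer(res$funnel)),
                     paths[["funnel"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(res$hemizygosity)) {
    utils::write.table(res$hemizygosity, paths[["hemi"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  writeLines(res$vcf_lines, paths[["vcf"]])
  invisible(paths)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline result>\n  funnel: ",
      paste(sprintf("%s=%d", names(x$funnel), x$funnel), collapse = " -> "),
      "\n", sep = "")
  if (nrow(x$records)) {
    cat(sprintf("  %d variants with evidence (%d prioritized)\n",
                nrow(x$records), sum(x$records$status == "prioritized")))
  }
  invisible(x)
}
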