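# Individual-information weight matrices and Ri / delta-Ri scoring.
#
# Conventions used throughout the package:
#   * alphabet A,C,G,T (columns of all matrices, in that order);
#   * sequence coordinates are 0-based internally;
#   * a matrix "anchors" at a biological coordinate: row `offset` of the
#     matrix aligns with the anchored base (e.g. the first exonic base for
#     acceptor models, the first intronic base for donor models).

.BASES <- c("A", "C", "G", "T")

#' Convert a nucleotide string to integer codes
#'
#' @param seq character scalar; case-insensitive.
#' @return integer vector, A=1, C=2, G=3, T=4, NA for any other letter.
#' @keywords internal
seq_to_idx <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], .BASES)
}

#' Reverse complement of a nucleotide string
#'
#' Thin wrapper over [Biostrings::reverseComplement()] so all modules share
#' one strand convention.
#'
#' @param seq character scalar (A/C/G/T/N).
#' @return character scalar.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Small-sample information correction e(n)
#'
#' Approximate expected overestimate of information content when column
#' frequencies are estimated from `n` aligned sites, for a 4-letter
#' alphabet: e(n) = 3 / (2 ln2 n) bits per position.
#'
#' @param n number of training sites.
#' @return bits per position (0 when `n` is 0 or missing).
#' @export
sampling_correction <- function(n) {
  if (is.null(n) || length(n) == 0L || is.na(n) || n <= 0) return(0)
  3 / (2 * log(2) * n)
}

#' Construct a base-frequency matrix
#'
#' @param freq numeric matrix, positions x 4 (columns A,C,G,T); rows must sum
#'   to 1 (before or after pseudocount renormalization).
#' @param n_sites number of training sites behind the frequencies (0 =
#'   unknown, e.g. a published PWM).
#' @param pseudocount probability mass added to zero cells, after which each
#'   row is renormalized. Keeps downstream log-scores finite.
#' @return object of class `freq_matrix` with elements `freq`, `n_sites`,
#'   `pseudocount`.
#' @export
frequency_matrix <- function(freq, n_sites = 0L, pseudocount = 1e-6) {
  freq <- as.matrix(freq)
  if (ncol(freq) != 4L) stop("frequency matrix must have 4 columns (A,C,G,T)")
  if (nrow(freq) < 1L) stop("frequency matrix must have at least one position")
  if (any(freq < 0) || any(is.na(freq))) stop("frequencies must be non-negative")
  rs <- rowSums(freq)
  if (any(rs <= 0)) stop("frequency matrix has a column of the site summing to 0")
  freq <- freq / rs
  zero <- freq == 0
  if (any(zero)) {
    freq[zero] <- pseudocount
    freq <- freq / rowSums(freq)
  }
  colnames(freq) <- .BASES
  structure(list(freq = freq, n_sites = as.integer(n_sites),
                 pseudocount = pseudocount),
            class = "freq_matrix")
}

.new_iwm <- function(riw, r_sequence, r_sequence_sd, correction, polarity,
                     offset, id, n_sites, freq = NULL, sd_defined = TRUE) {
  colnames(riw) <- .BASES
  structure(list(
    riw = riw,
    r_sequence = r_sequence,
    r_sequence_sd = r_sequence_sd,
    sampling_correction = correction,
    polarity = polarity,
    offset = as.integer(offset),
    id = id,
    n_sites = as.integer(n_sites),
    freq = freq,
    sd_defined = sd_defined
  ), class = "iwm")
}

#' Build an information weight matrix from aligned binding-site sequences
#'
#' Each cell of the weight matrix is `riw(b,l) = 2 + log2 f(b,l) - e(n)`,
#' where `f` are the observed base frequencies (zero cells receive a Laplace
#' pseudocount of one count) and `e(n)` the small-sample correction.  The
#' mean information content `r_sequence` is `sum_l (2 - H(l) - e(n))` with
#' `H(l)` the Shannon entropy of the raw column frequencies, and
#' `r_sequence_sd` is the standard deviation of the training-site Ri values.
#'
#' `N` bases contribute nothing to the column they fall in.
#'
#' @param sites character vector of equal-length site sequences (A/C/G/T/N).
#' @param apply_correction apply `e(n)`? Default `TRUE`.
#' @param polarity site class tag: `"acceptor"`, `"donor"` or `"motif"`.
#' @param offset 1-based row index of the position aligned to the biological
#'   anchor (e.g. the intron/exon boundary).
#' @param id model identifier.
#' @param pseudocount count added to zero cells (Laplace, default 1).
#' @return object of class `iwm`.
#' @export
build_iwm_from_sites <- function(sites, apply_correction = TRUE,
                                 polarity = "motif", offset = 1L,
                                 id = "iwm", pseudocount = 1) {
  if (length(sites) < 1L) stop("at least one site sequence is required")
  lens <- nchar(sites)
  if (length(unique(lens)) != 1L) stop("site sequences have ragged lengths")
  L <- lens[[1L]]
  chars <- toupper(do.call(rbind, strsplit(sites, "", fixed = TRUE)))
  bad <- !(chars %in% c(.BASES, "N"))
  if (any(bad)) stop("sites contain letters outside {A,C,G,T,N}")

  counts <- vapply(seq_len(L), function(l) {
    tabulate(match(chars[, l], .BASES), nbins = 4L)
  }, numeric(4L))
  counts <- t(counts)                       # L x 4
  n_eff <- rowSums(counts)                  # per-column non-N count
  if (any(n_eff == 0)) stop("a column contains only N bases")
  n <- length(sites)

  f_raw <- counts / n_eff
  # entropy of the raw (unsmoothed) column distribution; 0 log 0 = 0
  H <- apply(f_raw, 1L, function(p) { p <- p[p > 0]; -sum(p * log2(p)) })

  # pseudocount on zero cells only, then renormalize
  cs <- counts
  zero <- cs == 0
  cs[zero] <- pseudocount
  f_sm <- cs / rowSums(cs)

  e_n <- if (apply_correction) sampling_correction(n) else 0
  riw <- 2 + log2(f_sm) - e_n
  r_sequence <- sum(2 - H - e_n)

  m <- .new_iwm(riw, r_sequence, 0, e_n, polarity, offset, id, n,
                freq = frequency_matrix(f_sm, n_sites = n,
                                        pseudocount = pseudocount))
  ri_train <- vapply(sites, function(s) .ri_string(s, m), numeric(1L))
  m$r_sequence_sd <- if (n > 1L) stats::sd(ri_train) else 0
  m
}

#' Build an information weight matrix from a base-frequency PWM
#'
#' `riw(b,l) = 2 + log2 f(b,l)`; no sampling correction is applied because
#' the number of sites behind a published PWM is unknown, and
#' `r_sequence_sd` is set to 0 and marked undefined.
#'
#' @param pwm a [frequency_matrix()] or a plain positions x 4 matrix.
#' @inheritParams build_iwm_from_sites
#' @return object of class `iwm`.
#' @export
build_iwm_from_pwm <- function(pwm, polarity = "motif", offset = 1L,
                               id = "pwm") {
  if (!inherits(pwm, "freq_matrix")) pwm <- frequency_matrix(pwm)
  f <- pwm$freq
  H <- apply(f, 1L, function(p) -sum(p * log2(p)))
  riw <- 2 + log2(f)
  .new_iwm(riw, sum(2 - H), 0, 0, polarity, offset, id, pwm$n_sites,
           freq = pwm, sd_defined = FALSE)
}

#' @export
print.iwm <- function(x, ...) {
  cat(sprintf("<iwm '%s'> %d positions, polarity=%s, offset=%d\n",
              x$id, nrow(x$riw), x$polarity, x$offset))
  cat(sprintf("  Rsequence = %.2f bits (s.d. %.2f%s), e(n) = %.4f, n = %d\n",
              x$r_sequence, x$r_sequence_sd,
              if (isTRUE(x$sd_defined)) "" else ", undefined-from-PWM",
              x$sampling_correction, x$n_sites))
  invisible(x)
}

#' Footprint width of a matrix
#' @param iwm an `iwm`.
#' @return integer number of positions.
#' @export
iwm_width <- function(iwm) nrow(iwm$riw)

#' Maximum achievable Ri of a matrix (sum of per-position maxima)
#' @param iwm an `iwm`.
#' @return bits.
#' @export
consensus_ri <- function(iwm) sum(apply(iwm$riw, 1L, max))

#' Consensus sequence of a matrix
#' @param iwm an `iwm`.
#' @return character scalar.
#' @export
consensus_seq <- function(iwm) {
  paste(.BASES[apply(iwm$riw, 1L, which.max)], collapse = "")
}

# Ri of a bare string exactly as long as the matrix footprint.
.ri_string <- function(s, iwm, warn = TRUE) {
  idx <- seq_to_idx(s)
  L <- nrow(iwm$riw)
  if (length(idx) != L) stop("window length does not match matrix footprint")
  if (anyNA(idx)) {
    if (warn) warning("non-ACGT base in scoring window; using minimum cell value")
    mins <- apply(iwm$riw, 1L, min)
    rows <- seq_len(L)
    ok <- !is.na(idx)
    sum(iwm$riw[cbind(rows[ok], idx[ok])]) + sum(mins[!ok])
  } else {
    sum(iwm$riw[cbind(seq_len(L), idx)])
  }
}

#' Score one binding site
#'
#' Computes the individual information Ri (bits) of the matrix anchored at
#' `position`: row `offset` of the matrix aligns with the base at `position`.
#' On the minus strand the reverse complement is scored 5'->3', with the
#' anchor mirrored onto the same genomic base.
#'
#' @param seq reference sequence (character scalar).
#' @param iwm an `iwm`.
#' @param position 0-based anchor coordinate on `seq`.
#' @param strand `"+"` or `"-"`.
#' @return object of class `site_score`: list with `position`, `strand`,
#'   `ri` (bits), `model_id`.
#' @export
score_site <- function(seq, iwm, position, strand = "+") {
  n <- nchar(seq)
  if (strand == "-") {
    out <- score_site(revcomp(seq), iwm, n - 1L - position, "+")
    out$position <- position
    out$strand <- "-"
    return(out)
  }
  L <- nrow(iwm$riw)
  start <- position - (iwm$offset - 1L)      # 0-based window start
  if (start < 0L || start + L > n) stop("scoring window out of sequence bounds")
  win <- substr(seq, start + 1L, start + L)
  structure(list(position = position, strand = strand,
                 ri = .ri_string(win, iwm), model_id = iwm$id),
            class = "site_score")
}

#' @export
print.site_score <- function(x, ...) {
  cat(sprintf("<site %s@%d(%s)> Ri = %.1f bits\n",
              x$model_id, x$position, x$strand, x$ri))
  invisible(x)
}

#' Score a matrix at every possible anchor of a sequence
#'
#' @inheritParams score_site
#' @return data.frame with columns `position` (0-based anchor) and `ri`.
#' @export
scan_iwm <- function(seq, iwm, strand = "+") {
  n <- nchar(seq)
  L <- nrow(iwm$riw)
  if (strand == "-") {
    sc <- scan_iwm(revcomp(seq), iwm, "+")
    sc$position <- n - 1L - sc$position
    return(sc[order(sc$position), , drop = FALSE])
  }
  idx <- seq_to_idx(seq)
  mins <- apply(iwm$riw, 1L, min)
  starts <- seq_len(n - L + 1L)              # 1-based window starts
  ri <- numeric(length(starts))
  for (l in seq_len(L)) {
    b <- idx[starts + l - 1L]
    v <- iwm$riw[l, ][b]
    v[is.na(b)] <- mins[l]
    ri <- ri + v
  }
  data.frame(position = starts - 1L + (iwm$offset - 1L), ri = ri)
}

#' Change in individual information caused by a variant
#'
#' Scores the site anchored at `site_anchor` on the reference and on the
#' variant-edited sequence and reports the difference (alt - ref, bits).
#' Indels re-score the edited sequence at the same boundary coordinate
#' (shifted by the length difference when the edit lies 5' of the anchor);
#' the best-scoring anchor within +/- the indel length is reported as a
#' secondary result in the `best_alt_anchor` element.
#'
#' @param seq reference sequence.
#' @param variant list or one-row data.frame with `pos` (0-based), `ref`,
#'   `alt` allele strings.
#' @param iwm an `iwm`.
#' @param site_anchor 0-based anchor coordinate of the site under test.
#' @param strand `"+"` or `"-"`.
#' @return object of class `site_change`: `ref_score`, `alt_score`,
#'   `delta_ri`, and `best_alt_anchor` (NULL for substitutions).
#' @export
delta_ri <- function(seq, variant, iwm, site_anchor, strand = "+") {
  pos <- variant$pos
  ref <- toupper(variant$ref)
  alt <- toupper(variant$alt)
  obs <- substr(seq, pos + 1L, pos + nchar(ref))
  if (toupper(obs) != ref) {
    stop(sprintf("reference mismatch at position %d: expected '%s', found '%s'",
                 pos, ref, obs))
  }
  alt_seq <- paste0(substr(seq, 1L, pos), alt,
                    substr(seq, pos + nchar(ref) + 1L, nchar(seq)))
  shift <- nchar(alt) - nchar(ref)
  alt_anchor <- if (shift != 0L && site_anchor >= pos + nchar(ref)) {
    site_anchor + shift
  } else {
    site_anchor
  }
  ref_score <- score_site(seq, iwm, site_anchor, strand)
  alt_score <- score_site(alt_seq, iwm, alt_anchor, strand)

  best <- NULL
  if (shift != 0L) {
    span <- abs(shift)
    cand <- (alt_anchor - span):(alt_anchor + span)
    ris <- vapply(cand, function(p) {
      tryCatch(score_site(alt_seq, iwm, p, strand)$ri, error = function(e) -Inf)
    }, numeric(1L))
    k <- which.max(ris)
    best <- list(position = cand[[k]], ri = ris[[k]])
  }
  structure(list(ref_score = ref_score, alt_score = alt_score,
                 delta_ri = alt_score$ri - ref_score$ri,
                 best_alt_anchor = best),
            class = "site_change")
}

#' @export
print.site_change <- function(x, ...) {
  cat(sprintf("<site change %s> %.1f -> %.1f bits (delta %.1f)\n",
              x$ref_score$model_id, x$ref_score$ri, x$alt_score$ri, x$delta_ri))
  invisible(x)
}

#' Minimum fold change in binding affinity implied by a delta-Ri
#'
#' A change of `d` bits bounds the change in binding affinity by `2^|d|`-fold;
#' the direction (reduction for negative `d`) is reported separately.
#'
#' @param delta_ri bits (finite).
#' @return list with `fold` (`2^|delta_ri|`) and `direction` (`"increase"`,
#'   `"decrease"` or `"none"`).
#' @export
fold_change <- function(delta_ri) {
  if (!is.finite(delta_ri)) stop("delta_ri must be finite")
  list(fold = 2^abs(delta_ri),
       direction = if (delta_ri > 0) "increase"
                   else if (delta_ri < 0) "decrease" else "none")
}

#' Format bits and fold changes for reports
#'
#' Bits are shown to 1 decimal; folds to 2 significant figures at >= 10 and
#' 1 decimal below 10.
#'
#' @param x numeric.
#' @return character.
#' @export
format_bits <- function(x) sprintf("%.1f", x)

#' @rdname format_bits
#' @export
format_fold <- function(x) {
  ifelse(x >= 10, formatC(signif(x, 2), format = "fg", big.mark = ""),
         sprintf("%.1f", x))
}

# --- matrix file I/O (tab-delimited, '#IWM'/'#PWM' header) -------------------

#' Write an information weight matrix to a tab-delimited file
#'
#' Format: header line
#' `#IWM <id> polarity=<p> offset=<int> rsequence=<float> sd=<float>`
#' followed by one row per position with four bit values (A,C,G,T).
#'
#' @param iwm an `iwm`.
#' @param path output file.
#' @export
write_iwm <- function(iwm, path) {
  hdr <- sprintf("#IWM %s polarity=%s offset=%d rsequence=%.6f sd=%.6f nsites=%d",
                 iwm$id, iwm$polarity, iwm$offset, iwm$r_sequence,
                 iwm$r_sequence_sd, iwm$n_sites)
  body <- apply(iwm$riw, 1L, function(r) paste(sprintf("%.6f", r), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an information weight matrix (or frequency PWM) file
#'
#' Accepts the `#IWM` format written by [write_iwm()] and the equivalent
#' `#PWM` format whose rows hold base probabilities; PWM input is converted
#' via [build_iwm_from_pwm()].
#'
#' @param path file path.
#' @return object of class `iwm`.
#' @export
read_iwm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- lines[[1L]]
  if (!grepl("^#(IWM|PWM)\\b", hdr)) stop("missing #IWM/#PWM header: ", path)
  toks <- strsplit(trimws(sub("^#", "", hdr)), "[ \t]+")[[1L]]
  kind <- toks[[1L]]
  id <- toks[[2L]]
  kv <- strsplit(grep("=", toks[-(1:2)], value = TRUE, fixed = TRUE), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  get <- function(k, d) if (k %in% names(meta)) meta[[k]] else d
  vals <- do.call(rbind, lapply(lines[-1L], function(l) {
    as.numeric(strsplit(trimws(l), "[ \t]+")[[1L]])
  }))
  if (ncol(vals) != 4L) stop("matrix rows must have 4 values (A,C,G,T)")
  polarity <- get("polarity", "motif")
  offset <- as.integer(get("offset", "1"))
  if (kind == "PWM") {
    return(build_iwm_from_pwm(frequency_matrix(vals,
                                               n_sites = as.integer(get("nsites", "0"))),
                              polarity = polarity, offset = offset, id = id))
  }
  .new_iwm(vals,
           r_sequence = as.numeric(get("rsequence", NA)),
           r_sequence_sd = as.numeric(get("sd", "0")),
           correction = 0, polarity = polarity, offset = offset, id = id,
           n_sites = as.integer(get("nsites", "0")))
}
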