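# SNPfold-style ranking of a UTR variant's disruption of mRNA base-pairing
# structure.  The folding engine is pluggable: the ranking statistic only
# needs a per-position pairing-probability profile.

#' Built-in partition-function folding engine
#'
#' Returns an engine function mapping a sequence to its per-position
#' base-pairing probability profile, computed by a thermodynamic-weighted
#' Nussinov-style partition function (pair weights GC/AU/GU, no stacking or
#' loop terms) with inside-outside pair probabilities.  Suitable for
#' sequences up to a few hundred nt.
#'
#' @param min_loop minimum hairpin loop length (nt).
#' @param wgc,wau,wgu relative Boltzmann weights per pair type.
#' @return function(seq) -> numeric profile in `[0, 1]`.
#' @export
fold_engine_bpp <- function(min_loop = 3L, wgc = 3, wau = 2, wgu = 1) {
  function(seq) fold_bpp_cpp(seq, min_loop, wgc, wau, wgu)
}

#' Deterministic hairpin-count toy folding engine
#'
#' A fast stand-in profile for exercising the ranking machinery on long
#' UTRs: each position's "pairing propensity" is the weighted fraction of
#' complementary bases within a local window (GC=3, AU=2, GU=1), which
#' reacts to substitutions the way a pairing profile does while costing
#' O(window) per position.
#'
#' @param window local window half-width (nt).
#' @param min_loop minimum separation (nt).
#' @return function(seq) -> numeric profile.
#' @export
fold_engine_hairpin <- function(window = 25L, min_loop = 3L) {
  w_of <- function(a, b) {
    gc <- (a == 3L & b == 2L) | (a == 2L & b == 3L)
    au <- (a == 1L & b == 4L) | (a == 4L & b == 1L)
    gu <- (a == 3L & b == 4L) | (a == 4L & b == 3L)
    3 * gc + 2 * au + 1 * gu
  }
  function(seq) {
    idx <- seq_to_idx(seq)
    n <- length(idx)
    acc <- numeric(n)
    for (d in (min_loop + 1L):window) {
      if (d >= n) break
      i <- seq_len(n - d)
      w <- w_of(idx[i], idx[i + d])
      w[is.na(w)] <- 0
      acc[i] <- acc[i] + w
      acc[i + d] <- acc[i + d] + w
    }
    acc / (3 * 2 * window)   # scale into [0, ~1]
  }
}

#' Minimum-free-energy style structure as a dot-bracket string
#'
#' Maximum-weight Nussinov structure under the same pair weights as
#' [fold_engine_bpp()].
#'
#' @param seq sequence.
#' @inheritParams fold_engine_bpp
#' @return dot-bracket character scalar.
#' @export
mfe_dotbracket <- function(seq, min_loop = 3L, wgc = 3, wau = 2, wgu = 1) {
  fold_mfe_dotbracket_cpp(seq, min_loop, wgc, wau, wgu)
}

.profile_distance <- function(a, b) {
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) {
    return(if (max(abs(a - b)) < 1e-12) 0 else 1)
  }
  1 - stats::cor(a, b)
}

#' Rank a UTR substitution by predicted structure disruption
#'
#' Computes the structure-change score (1 - Pearson correlation between the
#' wild-type and mutant pairing-probability profiles) for the query variant
#' and for every possible single-nucleotide substitution of the UTR
#' (`3 x length` of them), ranks the query most-disruptive-first (ties
#' broken by position, then alt allele), and converts the rank into
#' `p = rank / total`.  Variants with `p < 0.1` are prioritized.
#'
#' @param utr_seq UTR sequence (>= 20 nt).
#' @param variant list(`pos` 0-based within the UTR, `ref`, `alt`); single
#'   substitutions only.
#' @param engine folding engine function (see [fold_engine_bpp()],
#'   [fold_engine_hairpin()]).
#' @param p_cutoff prioritization threshold on the rank p-value.
#' @return object of class `structure_rank`: list with `distance`, `rank`,
#'   `total`, `p_value`, `prioritized`, and `all_distances` (data.frame over
#'   the full substitution space).
#' @export
structure_disruption_rank <- function(utr_seq, variant,
                                      engine = fold_engine_bpp(),
                                      p_cutoff = 0.1) {
  L <- nchar(utr_seq)
  if (L < 20L) stop("UTR must be at least 20 nt")
  if (nchar(variant$ref) != 1L || nchar(variant$alt) != 1L) {
    stop("only single-nucleotide substitutions are supported")
  }
  pos <- variant$pos
  ref_base <- toupper(substr(utr_seq, pos + 1L, pos + 1L))
  if (ref_base != toupper(variant$ref)) {
    stop(sprintf("reference mismatch at UTR position %d: expected '%s', found '%s'",
                 pos, variant$ref, ref_base))
  }
  wt <- engine(utr_seq)
  bases <- c("A", "C", "G", "T")
  total <- 3L * L

  positions <- rep(seq_len(L) - 1L, each = 3L)
  refs <- strsplit(toupper(utr_seq), "", fixed = TRUE)[[1L]][positions + 1L]
  alts <- unlist(lapply(refs[seq(1L, length(positions), by = 3L)],
                        function(b) setdiff(bases, b)), use.names = FALSE)
  dist <- numeric(total)
  for (i in seq_len(total)) {
    s <- utr_seq
    substr(s, positions[[i]] + 1L, positions[[i]] + 1L) <- alts[[i]]
    dist[[i]] <- .profile_distance(wt, engine(s))
  }
  all_d <- data.frame(pos = positions, ref = refs, alt = alts,
                      distance = dist, stringsAsFactors = FALSE)
  ord <- order(-all_d$distance, all_d$pos, all_d$alt)
  all_d <- all_d[ord, , drop = FALSE]
  all_d$rank <- seq_len(total)
  rownames(all_d) <- NULL

  if (toupper(variant$alt) == ref_base) {
    qdist <- 0
    qrank <- total
  } else {
    hit <- which(all_d$pos == pos & all_d$alt == toupper(variant$alt))
    qdist <- all_d$distance[[hit]]
    qrank <- all_d$rank[[hit]]
  }
  p <- qrank / total
  structure(list(variant = variant, distance = qdist, rank = qrank,
                 total = total, p_value = p,
                 prioritized = p < p_cutoff, all_distances = all_d),
            class = "structure_rank")
}

#' Rank p-value from a printed rank/total pair
#'
#' The rank statistic's arithmetic in isolation: `p = rank / total`, where
#' `total = 3 x UTR length` counts every possible substitution.
#'
#' @param rank 1-based most-disruptive-first rank.
#' @param total number of possible substitutions.
#' @return p-value in (0, 1].
#' @export
snpfold_p_value <- function(rank, total) {
  stopifnot(rank >= 1, rank <= total)
  rank / total
}

#' @export
print.structure_rank <- function(x, ...) {
  cat(sprintf("<structure rank> %d/%d, p = %.3f%s (distance %.4g)\n",
              x$rank, x$total, x$p_value,
              if (x$prioritized) " [prioritized]" else "", x$distance))
  invisible(x)
}
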