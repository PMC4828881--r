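# Shared fixtures and independent oracle helpers.  Oracles deliberately use
# naive loop-based code paths, separate from the package implementation.

# memoized default model set (deterministic, but not free to rebuild)
the_models <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- default_models()
    cache
  }
})

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# naive per-position Ri of a window, by character lookup in a loop
naive_ri <- function(window, iwm) {
  chars <- strsplit(toupper(window), "")[[1]]
  total <- 0
  for (l in seq_along(chars)) {
    b <- which(c("A", "C", "G", "T") == chars[[l]])
    total <- total + if (length(b)) iwm$riw[l, b] else min(iwm$riw[l, ])
  }
  unname(total)
}

# naive Ri at an anchor of a full sequence
naive_ri_at <- function(seq, iwm, anchor) {
  start <- anchor - (iwm$offset - 1L)
  naive_ri(substr(seq, start + 1L, start + nrow(iwm$riw)), iwm)
}

# stub site_change for rule-level tests
make_change <- function(ri_initial, ri_final, pos = 100L, model_id = "stub") {
  structure(list(
    ref_score = structure(list(position = pos, strand = "+",
                               ri = ri_initial, model_id = model_id),
                          class = "site_score"),
    alt_score = structure(list(position = pos, strand = "+",
                               ri = ri_final, model_id = model_id),
                          class = "site_score"),
    delta_ri = ri_final - ri_initial,
    best_alt_anchor = NULL), class = "site_change")
}

# apply a substitution/indel to a sequence string
apply_variant <- function(seq, v) {
  paste0(substr(seq, 1L, v$pos), v$alt,
         substr(seq, v$pos + nchar(v$ref) + 1L, nchar(seq)))
}

# remove every occurrence of the given dinucleotides from a sequence
# (used to build intron backgrounds free of chance splice-site cores)
scrub_dinucs <- function(seq, dinucs = c("AG", "GT"), sub = "CC") {
  repeat {
    hit <- FALSE
    for (d in dinucs) {
      if (grepl(d, seq, fixed = TRUE)) {
        seq <- gsub(d, sub, seq, fixed = TRUE)
        hit <- TRUE
      }
    }
    if (!hit) return(seq)
  }
}

# plant a string into a sequence at a 0-based offset
plant_at <- function(seq, at, what) {
  paste0(substr(seq, 1L, at), what,
         substr(seq, at + nchar(what) + 1L, nchar(seq)))
}
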