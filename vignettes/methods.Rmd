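---
title: "Information-theory variant prioritization: models, rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-theory variant prioritization: models, rules, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itvus)
```

## The scoring model

Every analysis in `itvus` rests on individual information. A binding-site
model is a weight matrix whose cell for base $b$ at position $l$ is

$$R_{iw}(b,l) = 2 + \log_2 f(b,l) - e(n),$$

with $f$ the base frequencies of the aligned training sites and
$e(n) = 3/(2\ln 2\, n)$ bits per position the small-sample correction for
a four-letter alphabet (the correction is switchable; published frequency
PWMs, whose $n$ is unknown, get $e = 0$). A candidate site's strength
$R_i$ is the sum of its per-position weights, in bits; it estimates the
binding free energy contribution of that specific sequence. The model
mean $R_\mathrm{sequence} = \sum_l (2 - H(l) - e(n))$ is the average
$R_i$ over the training sites, and its standard deviation over those
sites is kept alongside, because several decision rules are phrased as
"within one s.d. of the mean".

A variant's effect on a site is $\Delta R_i = R_{i,\mathrm{final}} -
R_{i,\mathrm{initial}}$, and $2^{\Delta R_i}$ bounds the fold change in
binding affinity: the common currency that lets splice sites,
splicing-regulatory-factor sites, transcription-factor sites and
RNA-binding-protein sites be compared on one scale.

### Numerical conventions

* **Pseudocounts.** When building from aligned sites, zero-count cells
  receive one count (Laplace) and the column is renormalized; observed
  cells keep their raw frequencies up to that renormalization. When
  converting a frequency PWM, zero cells receive $10^{-6}$ probability
  mass. Both conventions exist only to keep scores finite: a zero cell
  has no defensible finite information, and the chosen mass barely
  perturbs informative columns.
* **Entropy estimator.** $H(l)$ is computed from the raw column
  frequencies ($0\log 0 = 0$). With this choice the identity
  $\mathbb{E}[R_i] = R_\mathrm{sequence}$ over the training sites is
  exact whenever every base is observed at every position; pseudocount
  smoothing of unobserved cells introduces a small bias otherwise, which
  the test suite quantifies on a zero-cell-free fixture.
* **Coordinates.** Internally 0-based and half-open everywhere; 1-based
  coordinates exist only at the VCF/table boundary. A matrix anchors at a
  biological coordinate: its `offset` row aligns with, e.g., the first
  exonic base (acceptors) or the first intronic base (donors). Minus
  strands are handled by scoring the reverse complement with the anchor
  mirrored onto the same genomic base, and whole minus-strand genes are
  mirrored into transcription orientation (`orient_gene()`) before
  analysis.
* **Non-ACGT bases** contribute the minimum cell of their column and
  raise a warning — never silently.
* **Indels** are scored by editing the sequence and re-anchoring at the
  same boundary coordinate (shifted by the length difference when the
  edit lies 5' of the anchor); the best-scoring anchor within ± the indel
  length is reported as a secondary result, since a deletion can slide a
  site rather than destroy it.
* **Overlapping anchors.** When one variant touches several anchors of a
  repetitive motif, the reported change is the one with the largest
  $|\Delta R_i|$; near-ties (within $10^{-9}$ bits, which arise exactly
  for periodic motifs) break toward the anchor holding the stronger
  site, so verdicts do not depend on floating-point summation order.

## Decision rules and their parameters

All thresholds are arguments with the defaults below.

| Rule | Default | Meaning |
|---|---|---|
| natural splice site | ΔRi ≤ −1.0 bits | flag a weakened natural site |
| `ri_minimum` | 1.6 bits | below this a splice site is non-functional ("abolished"; weakened but above is "leaky") |
| cryptic site | ≤ 300 nt of an exon, final ≥ nearest natural site of the same polarity | flag activated cryptic sites |
| SRFBS | \|ΔRi\| ≥ 4.0 bits with strength clauses | clause (a) loss at a strong site (initial ≥ R_sequence); clause (b) gain reaching ≥ 0 bits |
| SRF context | exon-strength drop ≥ 3.0 bits (8-fold) | smaller factor-aware drops are potentially benign |
| redundancy | ≤ 2 nt, \|Ri difference\| ≤ 0.5 bits | an equivalent site next door neutralizes a loss |
| TFBS | promoter = 10 kb upstream of TSS through intron 1; ΔRi ≤ −4.0 at strong sites, or created site ≥ R_sequence and strongest within ± 50 nt | function-aware drop of (activator, strengthened) and (repressor, weakened) |
| RBBS | \|ΔRi\| ≥ 4.0 (with a site on at least one allele) or creation across R_sequence; suppressed within 10 nt of a stronger site of another RBP | UTR variants only |
| pseudoexon | ΔRi > 1.0 (strict), final ≥ R_sequence − 1 s.d., partner > R_sequence − 1 s.d. (strict), exon 10–250 nt, remnants ≥ 100 nt, hnRNPA1 ≥ its R_sequence within 10 nt of the acceptor | all five jointly |
| truncation | stop > 50 residues from the C-terminus, or any frameshift indel | prioritized coding consequences |
| UTR structure | p = rank/3L < 0.1 | most-disruptive-first rank over all substitutions |
| filters | QUAL ≥ 50; common if AF ≥ 1 % or > 5 cohort carriers | applied before any scoring |

Interpretation choices where the rules as stated leave room:

* "Same phase" for the cryptic-site comparison is read as same
  *polarity* (acceptor vs donor); reading-frame phase is carried as
  metadata instead.
* The hnRNPA1 proofreading distance defaults to 10 nt, with the stricter
  5 nt variant available by argument (`hnrnp_dist`), since both values
  appear in the literature describing the screen.
* "Equivalent strength" for the 2-nt redundancy rule is quantified as
  |Ri difference| ≤ 0.5 bits.
* The factor-aware exon strength folds an SRF's site into
  $R_{i,total}$ additively: enhancers add their $\Delta R_i$,
  repressors (and hnRNPA1 away from the acceptor) subtract it, and PTB
  contributes nothing directly — a PTB change instead triggers
  re-evaluation of factors with overlapping sites. The additive
  convention is an explicit modeling assumption; numeric exon-strength
  values under it are therefore comparative, not literal reproductions
  of any external tool.
* The RBBS magnitude clause carries a site-existence guard
  ($\max(R_{i,\mathrm{initial}}, R_{i,\mathrm{final}}) \ge 0$): without
  it, any ≥ 4-bit fluctuation between two deeply negative non-sites
  would flag, flooding reports with positions no RBP ever bound.
* `residues_lost` counts the stop-gained position itself
  ($L - \mathrm{stop} + 1$). Published truncation tables mix this
  convention with $L - \mathrm{stop}$ between genes; the inclusive
  convention matches the majority of internally consistent rows and is
  applied uniformly.
* Missense variants are annotated and forwarded but never
  auto-prioritized: their assessment belongs to external conservation
  and structure predictors, for which the reports keep hook columns.

## Exon definition and isoform ranking

An exon's recognition strength is $R_{i,total} = R_i(\mathrm{acceptor}) +
R_i(\mathrm{donor}) - \mathrm{gap\ surprisal}(L)$, where the gap
surprisal $-\log_2 P(L)/P(L_\mathrm{modal})$ penalizes unusual exon
lengths. The default length distribution is log-normal with a mode of
~120 nt and $\sigma_{\log} = 0.45$, matching the human internal-exon
length spectrum's shape; an empirical table can be supplied instead, and
lengths outside the distribution's support use the tail value with a
warning. Candidate isoforms for an affected exon enumerate the natural
pair and all cryptic sites above `ri_minimum` within 300 nt; relative
abundances are $2^{R_{i,total}}$ normalized over the reported isoforms,
ties break shorter-exon-first then 5'-most, and exon skipping is reported
when either natural site falls below `ri_minimum`, carrying the weakened
pair's residual strength. This single-exon treatment deliberately avoids
multi-exon combinatorics: each variant is interpreted against its local
exon, which is how per-exon reports are framed.

## UTR structure ranking

The structure statistic needs only a per-position pairing-probability
profile, so the folding engine is pluggable. The built-in engine is a
thermodynamic-weighted Nussinov-style partition function (pair weights
GC = 3, AU = 2, GU = 1, minimum loop 3 nt, no stacking or loop entropies)
with inside–outside pair probabilities, written in C++; it is intended
for UTRs up to a few hundred nt, beyond which the double-precision
partition function can overflow. A deterministic hairpin-count engine
(`fold_engine_hairpin()`) scales to multi-kilobase UTRs and is used where
only the ranking machinery is under study; the per-position unpaired/
paired vector (not the full pair matrix) is the correlated quantity. The
variant's score is $1 -$ Pearson correlation between wild-type and
mutant profiles, ranked most-disruptive-first against all $3L$
substitutions with ties broken by position then alternate allele;
$p = \mathrm{rank}/3L$, prioritizing $p < 0.1$. Only this ranking
arithmetic — not any particular thermodynamic parameter set — is the
quantity the framework depends on. Minimum-free-energy structures are
rendered as dot-bracket strings only.

## Hemizygosity detection

A candidate hemizygous interval in one sample is a maximal stretch with
zero heterozygous calls, at least `min_length` long (default 1000 nt)
and with < 10 % repetitive content, such that strictly more than 80 % of
the control samples are heterozygous at ≥ 2 *well-distributed* loci
inside it, and the interval is not fully contained in a supplied LD
haploblock. "Well-distributed" is operationalized as a pairwise
separation of at least length/10 — the rule needs loci that bracket a
real deletion rather than a single clustered haplotype. Informative
markers at which the case is non-polymorphic are aggregated by expected
heterozygosity $\sum 2\,\mathrm{AF}(1-\mathrm{AF})$, reported as an
informativeness weight.

The power study simulates 20-sample cohorts over a 40-kb region with
informative markers every 250 nt (AF uniform on 0.2–0.5) and screens at
`min_length = 5000`. The screening length is a study choice, not the
function default: at realistic marker densities a 1-kb window contains
only ~4 informative loci, too few for the > 80 %/≥ 2-loci control rule to
separate chance homozygosity from deletion — the separation comes
entirely from marker count, and ≥ 5 kb windows (~20 markers) put chance
all-homozygous runs below $10^{-4}$ per window while controls support
real deletions essentially always. Under these conditions the screen
recovers planted ≥ 5-kb deletions in ≥ 95 % of 200 simulated cohorts with
≤ 5 % of deletion-free cohorts producing any candidate; both numbers are
recomputed by the test suite and the acceptance script. Junctional-read
detection of breakpoints is upstream of this package: tools that infer
rearrangements from read pairs conventionally require several supporting
reads (e.g. ≥ 4) spanning > 700 nt, and their output can be supplied as
intervals if available.

## The synthetic study and what it shows

`simulate_gene()` builds a three-exon plus-strand gene (~6.4 kb: 2 kb
promoter flank, 220/160/260-nt exons, 1.4/1.6-kb introns, 120/150-nt
UTRs) with natural splice sites sampled near each model's consensus and a
stop-free CDS; `simulate_cohort()` adds Hardy–Weinberg background markers
and planted variants as VCF. The binding-site models themselves are
deterministic: training sites realized from fixed frequency profiles
(n = 2000 per model) with near-invariant AG/GT splice-site cores, so a
single core substitution abolishes a site, as with empirically trained
splice models. The end-to-end test plants one variant per prioritization
category — each chosen so it does not co-trigger another category's rule
— and requires the pipeline to flag all ten (recall 1.0), with exactly
one prioritized entry per auto-prioritizable category in the gene ×
category count matrix.

The weight-matrix recovery check rebuilds a matrix from 500 sites
sampled from a known model and requires every cell within 0.15 bits.
That tolerance dictates the generator matrix: at $n = 500$ the sampling
error of $\log_2 \hat f$ is ~0.065 bits s.d. at $f = 0.5$ but exceeds
0.15 bits for rare bases ($f \lesssim 0.1$), so the recovery fixture uses
conserved and balanced two-base columns — the regime in which a per-cell
0.15-bit claim is statistically meaningful at that depth.

What passing does **not** show about real data: the generator's uniform
background has none of the compositional structure (CpG depletion, Alu
repeats, polypyrimidine-rich introns) that makes real scans noisier; its
models are cleaner than ChIP-seq- or SELEX-derived ones; cohort LD is
absent except where explicitly supplied; and planted effects are large
by construction. The suite validates the machinery — scoring identities
against brute-force oracles, rule boundaries, funnel bookkeeping,
determinism — not clinical sensitivity.

## Problem sizes and runtime

Tests run exhaustive oracles on 200–300-nt sequences and 2-kb introns,
partition-function folding on ≤ 60-nt UTRs with the toy engine covering
200–1500 nt, one ~6.4-kb pipeline fixture with a 12-sample cohort, and
400 simulated 20-sample hemizygosity cohorts; the full suite and the
acceptance script each complete in about a minute on one CPU. These
sizes were chosen as the smallest at which every rule, oracle and
statistic is exercised non-trivially.

## Known limitations

* Single-exon isoform enumeration; no branch-point or multi-exon models.
* The built-in folding engine is deliberately simple; plug in a
  partition-function folder's profile for thermodynamic realism.
* SRF exon-strength algebra is additive by assumption (above).
* Hemizygosity verdicts prioritize individuals for follow-up; they are
  not deletion calls with breakpoints.
* Classification stops at flagged/prioritized; clinical
  classification requires functional and segregation evidence outside
  any sequence-only framework.
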