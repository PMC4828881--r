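# itvus — information-theory prioritization of variants of uncertain significance

Gene-panel sequencing of hereditary breast/ovarian cancer patients yields
thousands of rare variants per cohort, most of them non-coding and of
uncertain significance. `itvus` implements a unified information-theory
framework for triaging them: every class of protein-binding element —
splice donors and acceptors, splicing regulatory factors (SRSF1, hnRNPA1,
TIA1, PTB, ...), promoter transcription factors, and UTR RNA-binding
proteins — is scored on the same bit scale, so one pair of numbers
(*R*<sub>i</sub> before and after the variant) describes any
variant–element interaction. Around that engine the package provides
splice-isoform and pseudoexon prediction, UTR secondary-structure
disruption ranking, protein-truncation triage, cohort-level hemizygous
deletion detection, a filtering/prioritization pipeline, and a synthetic
data generator so the whole stack is testable without patient data.

## The model

For a binding-site model built from *n* aligned sites with base
frequencies *f*(*b*, *l*), the individual-information weight of base *b*
at position *l* is

    Riw(b, l) = 2 + log2 f(b, l) − e(n)      [bits]

where *e*(*n*) = 3/(2 ln2 · n) is the small-sample correction. A
sequence's score *R*<sub>i</sub> is the sum of its per-position weights;
the model's mean information content is *R*<sub>sequence</sub> =
Σ<sub>l</sub> (2 − *H*(*l*) − *e*(*n*)). A variant changes a site by
ΔR<sub>i</sub> = R<sub>i,final</sub> − R<sub>i,initial</sub>, which bounds
the change in binding affinity by 2^ΔRi — a 4-bit loss is at least a
16-fold drop in affinity. Exon recognition strength is
*R*<sub>i,total</sub> = acceptor R<sub>i</sub> + donor R<sub>i</sub> −
gap surprisal(exon length), and candidate isoforms are ranked by it.
UTR variants are additionally ranked by how much they perturb the mRNA
base-pairing probability profile: the variant's structure-change score is
ranked against all 3L possible substitutions of the UTR and reported as
*p* = rank / 3L.

## Worked example

```r
library(itvus)
models <- default_models()
sim <- simulate_gene(1, models)
acc <- models$models$acceptor

# the natural acceptor of exon 2 sits at the exon boundary
anchor <- sim$gene$exons[2, "start"]
score_site(sim$seq, acc, anchor)
#> <site acceptor@3620(+)> Ri = 12.0 bits

# a G>T substitution in the invariant AG core of that acceptor
v <- list(pos = anchor - 1L, ref = "G", alt = "T")
change <- delta_ri(sim$seq, v, acc, anchor)
change
#> <site change acceptor> 12.0 -> 1.1 bits (delta -11.0)
fold_change(change$delta_ri)$fold
#> [1] 1996
flag_natural_site_variant(change)$category
#> [1] "abolished"
```

The site falls from 12.0 to 1.1 bits — below the 1.6-bit functional
minimum, so the acceptor is called abolished, with an at least ~2000-fold
loss of binding affinity. Exon-definition analysis then predicts what the
spliceosome does instead:

```r
iso <- rank_isoforms(sim$seq, sim$gene, exon_index = 2,
                     models$models$acceptor, models$models$donor,
                     variant = v)
head(iso$isoforms[, c("kind", "exon_length", "ri_total", "rel_abundance")], 3)
#>   kind exon_length ri_total rel_abundance
#> 1 exon         241 18.53769    0.51158419
#> 2 exon         135 17.85633    0.31901178
#> 3 exon          47 15.06956    0.04622817
```

The wild-type exon disappears from the ranking; cryptic acceptors take
over (a 241-nt and a 135-nt exon carry ~83 % of the predicted splice
forms) and exon skipping is reported as a flag. The same scoring engine
drives the SRF/TF/RBP rules, the pseudoexon detector, and the pipeline
(`run_pipeline()`, or the `inst/cli/itvus` command line), which emits a
variant-level report, a gene × category count matrix, per-sample funnel
summaries, and an annotated VCF.

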