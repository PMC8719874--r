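---
title: "Trio-exome burden analysis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio-exome burden analysis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioburden)
```

# The problem

A "genetic autopsy" of a sudden-unexplained-death cohort asks whether the
decedents carry more damaging coding variation than chance allows. With
trio data (decedent child plus both living parents), three variant classes
are informative: de novo mutations (DNMs, present heterozygously in the
child and absent from both parental germlines), transmitted parental-mosaic
variants (postzygotic in a parent, constitutional in the child), and
inherited deleterious heterozygous variants whose transmission rate can be
tested against the Mendelian null of one half. `trioburden` implements the
full analysis chain — trio calling with hard quality control, a
trinucleotide-context expected-mutation model, exact burden and carrier
tests, overtransmission tests, and interaction-network enrichment — plus a
synthetic trio-cohort generator so that every stage can be validated
without access to protected human data.

# Trio calling

A site is called de novo when the child is genotyped heterozygous with an
alternate allele fraction of at least `min_child_alt_allele_fraction`
(default 0.30) and depth at least 10; both parents are genotyped
homozygous-reference at depth at least 10, with alternate-read evidence
within a tolerance; and the variant is absent from a reference control
cohort. Trios accumulating 6 or more DNM calls are excluded outright: an
excess of Mendelian-violation calls marks a sample-quality problem, not
biology.

**Parental hom-ref tolerance.** We allow a hom-ref parent up to
`max(2 reads, 2% of depth)` alternate reads. The floor matters: with a
0.5% per-read error rate and ~90x depth, a parent shows 2 or more alternate
error reads at about 7% of sites, so a 1-read floor would veto roughly one
in seven true DNMs through either parent while a 2-read floor rejects well
under 2% — the difference between a caller that can and cannot reach 95%
sensitivity under realistic noise.

**Mosaic band.** A transmitted parental-mosaic call requires a passing
heterozygous child, exactly one parent genotyped hom-ref whose alternate
fraction lies in 0.03–0.20 (below the 0.30 heterozygous detection band),
and a clean other parent. Two refinements keep the call sets disjoint and
precise: mosaic-band evidence must exceed the hom-ref tolerance (weaker
evidence is indistinguishable from sequencing error, and such sites remain
de novo candidates — the de novo interpretation takes precedence), and at
least `min_mosaic_alt_reads = 4` alternate reads are required, since 2–3
error reads at typical depths land in the band far too easily. Sites where
both parents show band-level evidence are skipped with a logged reason.

Genotype quality is not modelled; allele depths and total depth are the
only read-level evidence, which is sufficient for the generator's evidence
model and keeps the thresholds fully declared and configurable.

# The expected-mutation null

For each gene the per-chromosome, per-generation probability of a de novo
SNV of a given effect class is the sum, over all coding positions and
alternate bases, of the trimer-context substitution rate times an indicator
that the substitution yields that class under the standard genetic code
(frame taken from the CDS start). Cohort expectations scale linearly:
`probability x 2 chromosomes x n_trios`. Stop-gains count as LoF;
stop-losses count as nonsynonymous but not LoF, matching the convention
that LoF means stop-gain, frameshift or essential-splice damage. At CDS
edges the missing flanking base is imputed as the mean rate over the four
compatible trimers — a deterministic rule, and `expected_count()` accepts
explicit flanks so chunked computation is exactly additive.

The bundled rate table is synthetic but realistically shaped (transitions
over transversions near 2:1, CpG transitions boosted ~8x, log-normal
context noise) and then calibrated once: rates are rescaled so that the
toy exome's nonsynonymous expectation at a 124-trio reference cohort is
85.5, the scale of a real trio-exome study. Absolute expectations are
therefore calibrated, not derived from trio data; relative per-gene,
per-class structure comes from the sequence context and the genetic code.
Coding indels sit outside the trimer framework and are modelled as a
single genome-wide rate (default 0.1 per trio) apportioned across genes by
coding length.

# Burden and carrier statistics

Observed-versus-expected burden uses the exact one-sided Poisson tail
`P(X >= observed)`; the companion effect estimate is observed minus
expected with a lower bound from the exact (Garwood) Poisson confidence
limit for the observed count, shifted by the expectation. Case/control
carrier comparisons condition on the 2x2 margins: the p-value uses the
minimum-likelihood two-sided rule, the odds ratio is the conditional
maximum-likelihood estimate under the noncentral hypergeometric model, and
the interval inverts the exact test — the conventions of
`stats::fisher.test`, which reproduce the odds ratios conventionally
reported alongside Fisher exact tests (the sample cross-product would
differ in the second decimal). Mosaic-origin calls enter carrier tables
only when the control cohort was called with the same trio-based pipeline
(`include_mosaics = TRUE`); against externally called controls they are
excluded, since external pipelines cannot see transmitted mosaicism.

No multiple-testing adjustment is applied; reports carry nominal p-values
together with the number of tests performed, matching the screening
character of the analysis.

Overtransmission is an exact one-sided binomial test at null 0.5 over
qualifying variants — LoF in a gene with LOEUF < 0.35, or missense with a
ClinVar pathogenic/likely-pathogenic label — enumerated per (variant,
carrier parent), so a variant carried by both parents contributes two
Bernoulli trials. Within-family dependence is ignored, a deliberate
simplification consistent with counting each qualifying variant once.
Entries with a missing child genotype are flagged indeterminate and
removed from the denominator rather than imputed. X-chromosome sites are
excluded (the 0.5 null assumes autosomal biparental inheritance).
Recessive-genotype formation uses the analogous exact tail at 0.25 per
opportunity.

# Network enrichment

Mutated genes are partitioned at a scaled-deleteriousness threshold
(default 15; scores scale as `-10 log10(rank fraction)`, so 20 means top
1%). Each gene appears once as a node with the maximum score among its
mutations and a multiplicity annotation. Edge enrichment counts edges with
both endpoints in the hit set and compares against resampled node sets of
equal size. Two nulls are exposed: uniform sampling, and the default
degree-matched sampling within degree-quintile bins, which approximates a
background that accounts for the proclivity of well-connected proteins to
interact. The permutation p-value `(1 + #{null >= obs}) / (B + 1)` is
never zero and has resolution `1/(B + 1)`; the default 9,999 permutations
resolves p-values of a few percent. Clusters are connected components of
the induced subgraph with at least three members, ordered by size with
lexicographic tie-breaks, and the coding-length check (mean member length
in kb) guards against clusters driven purely by large, mutation-prone
genes. Evidence-channel labels on edges are carried as metadata and
optional filters, never re-scored; the graph itself is always a
user-supplied input (a bundled preferential-attachment toy graph exists
only to exercise the machinery).

# The synthetic cohort generator

The generator's defaults encode the study conditions the package targets:
124 case and 573 control trios; coding de novo SNVs and indels Poisson
with means 1.0 and 0.1 per trio; 3.8% of de novo-appearing events mosaic
in origin with parental blood allele fraction Uniform(0.03, 0.20); site
depths negative-binomial with mean 89x (dispersion 8); binomial
allele fractions (p = 0.5) at heterozygous sites; 0.5% per-read error at
hom-ref sites; qualifying deleterious parental heterozygotes at 14/124
per trio transmitted with probability `transmission_bias` (null 0.5); and
recessive opportunities at 2/124 per trio. De novo events are placed
across genes proportionally to their trimer-model probabilities, so
observed/expected comparisons against `geneset_expected()` are internally
consistent; a configurable nonsynonymous enrichment factor multiplies
in-set case rates only. Noise-only and allele-balance-artifact sites
(child genotyped het at 10–28% fraction) exercise the caller's rejection
paths.

The toy genome is ~200 genes with log-uniform coding lengths 0.3–15 kb,
ATG-initiated sense codons and a terminal stop, plus per-gene LOEUF-like
constraint values — enough sequence realism for the trimer model to act on
true context. What the generator does *not* emulate: alignment artifacts,
mapping bias, batch effects, population structure, relatedness errors,
genotype-quality miscalibration, multi-nucleotide events, or realistic
gene-family structure. Passing tests therefore validate the statistical
machinery and calling logic under the declared evidence model, not
robustness to real-world sequencing pathology.

One residual scale note: the per-trio SNV mean (1.0) and the calibrated
exome-wide nonsynonymous expectation (85.5/124 = 0.69 per trio, i.e. about
0.98 per trio over all classes) differ by ~2%. The simulator honours the
configured per-trio mean exactly, so absolute observed/expected
comparisons on simulated data carry that ~2% inflation; enrichment-factor
recovery uses the in-set/out-of-set double ratio, from which the scale
cancels.

# Numerical and testing choices

Problem sizes in the test-suite were chosen to bound Monte-Carlo error,
not to chase significance: mean-convergence checks use 2,000 trios with
3-standard-error tolerances; enrichment-factor recovery uses four
independent 1,000-trio cohorts against analytic Poisson means; type-I
calibration uses 10,000 null replicates of the exact tests (both are
conservative, so rejection rates sit below the nominal 5%); caller
validation uses the full default cohort at a fixed seed; network-null
calibration compares against the closed form `C(k,2) x density` on an
Erdős–Rényi graph at 3 Monte-Carlo standard errors. Exhaustive oracles
back the exact tests: Fisher p-values are checked against full
margin-conditioned enumeration for every 2x2 table with total at most 40,
and per-gene expectations against brute-force enumeration of all `9L`
substitutions on short genes.

Degenerate inputs are handled explicitly: empty call sets propagate as
empty results; a zero observed count gives p = 1; degenerate 2x2 margins
return a flagged undefined odds ratio; missing genotypes are skipped with
logged reasons, never raised as errors; gene symbols absent from a
catalogue warn and are excluded rather than silently dropped.

# Known limitations

Effect classes are consumed from annotation tables, never computed from
transcripts — the package contains no annotation engine. The mosaic caller
trades sensitivity at the low end of the band (true mosaics below ~4
supporting reads are indistinguishable from error and surface as de novo
calls). The trimer rate table being calibrated rather than empirical means
absolute expectations on real data require substituting a published rate
table via `read_rate_table()`. Formal transmission-disequilibrium testing
across extended pedigrees, ancestry inference, and relatedness QC are out
of scope.
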