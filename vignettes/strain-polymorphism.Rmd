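---
title: "Detecting substrain polymorphism with a binomial error model"
author: "strainpulse authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting substrain polymorphism with a binomial error model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainpulse)
```

## The problem

A small symbiont genome — for example the chloroplast of an alga living
inside a freshwater sponge — is sequenced not as a clone but as a
population: the reads of one metagenomic or metatranscriptomic sample mix
several closely related substrain genotypes at unknown abundances. At any
reference position, the pileup of read bases then contains a mixture signal
(true allelic variation between substrains) on top of sequencing noise.
strainpulse separates the two with a per-site binomial error model, and
layers on top of it the quantities one wants for interpreting a
dysbiosis-like shift of the symbiont population: per-gene polymorphism
statistics across samples, majority-consensus sequences, and an estimate of
how strongly the apparent mutation rate is accelerated relative to the
lineage's background molecular clock.

## The site test

Let $N_s$ be the number of filtered reads covering site $s$ and $T_s$ the
number of reads supporting the most abundant (dominant) allele there. Under
the non-polymorphic null hypothesis every non-dominant base is a sequencing
error occurring independently at rate $E$, so $T_s \sim
\mathrm{Binomial}(N_s, 1 - E)$. The null is rejected when the probability of
seeing at least $N_s - T_s$ error reads,

$$p_s = P\{\mathrm{Binomial}(N_s, 1 - E) \le T_s\},$$

falls below $\alpha$. A rejected site is **polymorphic**; a rejected site
where the alternative alleles jointly outnumber the dominant one
($T_s < N_s - T_s$) is additionally classed a **mutation** site — the
signature of a locally displaced dominant lineage rather than a minor
admixture. Failing to reject means either no alternative allele exists or
the coverage cannot distinguish low-frequency alleles from noise.

Two readings of the rejection rule are possible: the tail event above, or
the point mass $P\{\mathrm{Binomial}(N_s, 1-E) = T_s\}$. The package
defaults to the tail (`mode = "tail"`): a pure point mass is not a coherent
rejection rule for large $N_s$, where every outcome has a small probability.
The point-mass variant is retained (`mode = "pmf"`) for sensitivity
analysis, not as a recommended test.

Alternative alleles are pooled: the statistic uses only $N_s - T_s$, with no
per-allele test, no genotype likelihoods and no strand-bias model. The test
is applied per site at level $\alpha$ with no multiplicity correction, which
is the convention this analysis style uses; an optional Bonferroni flag
exists but is off by default. A consequence worth keeping in mind is that
across tens of kilobases a small percentage of tested sites will be false
positives by construction; the discreteness of the binomial makes the
realized rate conservative (below $\alpha$), which the test suite and the
acceptance script verify by null simulation.

## Filters and their defaults

| Parameter | Default | Units | Role |
|---|---|---|---|
| `error_rate` (E) | 0.01 | probability/base | Illumina-scale global error rate; quality strings do **not** modulate it |
| `alpha` | 0.05 | — | per-site significance level |
| `min_base_quality` | 30 | Phred | bases below are removed before counting |
| `min_read_identity` | 0.99 | fraction | reads with lower identity to the reference are ignored entirely |
| `min_coverage` | 5 | reads | sites with $N_s$ below are *untested*, not non-polymorphic |
| `mode` | "tail" | — | rejection rule, see above |

Read identity is computed as matches over aligned columns (CIGAR M/=/X
only), on the raw aligned bases *before* quality masking; soft-clipped and
inserted bases are excluded from the denominator, and reads flagged
duplicate, secondary or supplementary are skipped, mirroring a conventional
samtools-style pileup. Indels are ignored outright — no indel alleles, and
deletion gaps contribute no count — because the site statistic is defined
only over substitution alleles. The coverage gate exists because shallow
sites cannot reject the null for any allele configuration; calling them
"non-polymorphic" would conflate absence of evidence with evidence of
absence, so they are reported as `untested` and excluded from fraction
denominators everywhere.

## Coordinates and determinism

All coordinates are 1-based inclusive, the R and Bioconductor convention
(SAM, VCF and GRanges are all 1-based), used consistently in memory, in
count tables and in VCF output. Ties for the dominant allele are broken
alphabetically (A < C < G < T) and counted in a log message; this keeps
every output deterministic. Given fixed inputs and configuration, count
tables, call tables, VCF and consensus FASTA are bit-identical across runs.

## Per-gene summaries and the cross-sample union

For comparing samples, the union of positions called polymorphic (or
mutation) in *any* sample is formed first. Within each gene, that union is
decomposed into three exclusive categories for each sample: sites
polymorphic only elsewhere, sites polymorphic here (but majority-dominant),
and mutation-class sites here; the three fractions partition the gene's
union. The summed filtered depth over the gene (`total_reads`) is carried
along and drawn as circle area in `plot_gene_summaries()` (radius a monotone
transform of depth, square root by default, configurable).

Overlapping genes each count every site they contain, while genome-wide
totals are computed over positions, never by summing gene rows — the two
views stay consistent and nothing is double-counted. With disjoint genes,
genic plus intergenic totals are exactly additive, which is tested.

## Consensus sequences

`build_consensus()` takes the dominant allele at every covered position and
the reference base where coverage is zero, yielding a full-length sequence
fit for downstream comparative analysis. The alternative of substituting
only at sites that rejected the null is available via
`polymorphic_only = TRUE`; it is not the default because a consensus
restricted to rejected sites silently keeps reference bases at genuinely
divergent but shallow positions, and a full-length majority sequence is the
less surprising object.

## The acceleration estimate

With $f_{poly}$ the genome-wide fraction of tested sites called polymorphic
and $f_{mut|poly}$ the fraction of those in the mutation class, the
genome-wide mutation-class fraction is $f_{mut} = f_{poly} \cdot
f_{mut|poly}$. If that fraction accrued over a disease episode of duration
$t_{dis}$, while the lineage's background divergence is $d$ substitutions
per site over a separation time $t_{div}$, the acceleration factor is

$$A = \frac{f_{mut} / t_{dis}}{d / t_{div}}.$$

Two open choices are resolved as follows. "One season" of disease is taken
as $t_{dis} = 1$ year by default — the only value consistent with the
headline arithmetic ($0.016 \times 0.125 = 0.002$ of the genome in one year
against $0.2$ per $10^6$ years gives $A = 10^4$) — and is configurable. The
background distance is used raw, as an uncorrected distance-over-time rate;
whether it originates as a substitution distance or as one minus percent
identity changes nothing in the arithmetic. A Jukes–Cantor multiple-hit
correction ($-\tfrac34\log(1 - \tfrac43 d)$) is available and off by
default; at $d = 0.2$ it raises the background rate by about 17% and lowers
$A$ accordingly. No confidence interval is attached: the inputs are
scenario assumptions, not estimates with sampling error, and the ratio is
meant as an order-of-magnitude statement.

## What the simulator generates — and what it does not

`simulate_strains()` embodies the dominant-plus-minor substrain picture:
strain 1 *is* the reference lineage, strains $2..K$ substitute each site
independently with probability `divergence` to a uniformly chosen different
base. `simulate_sample()` then draws per-site Poisson coverage, assigns each
read to a strain by the abundance vector, and miscalls each base with
probability `error_rate` to a uniform different base — exactly the caller's
null (single strain) and alternative (mixture) generative structure, which
is what makes the size and power checks meaningful. Multi-sample scenarios
reuse one truth table with different abundance vectors (e.g. a skewed
0.95/0.05 healthy sample against a flattened 0.6/0.4 diseased one).

Per-site (pileup-level) simulation is the primary mode because the caller
consumes site counts; read mode emits fixed-length (default 150 bp) reads
with uniform start positions and can write SAM, and its tally replays the
same base-quality and identity filters the loader applies, so SAM emission
and ingestion agree exactly. Note that with divergent strains and realistic
error rates the 99% identity filter really bites at read level — a 150 bp
read needs only two mismatches to fall below it — which is faithful to how
the filter behaves on real data.

Deliberately **not** modelled: linkage between sites (the analysis is
site-wise), realistic read-length and quality profiles (all simulated bases
carry one Phred value, default 40), PCR duplicates, mapping ambiguity and
paired-end structure, and any RNA expression-level structure (RNA samples
are simulated as DNA-like with their own coverage means). Passing tests on
these simulations therefore validate the statistical machinery under its
own assumptions; they do not certify behaviour under alignment artefacts or
expression heterogeneity in real libraries.

## Numerical choices and problem sizes

P-values are computed with `pbinom`, stable far beyond $N = 10^6$; the test
suite checks it against an independent log-space brute-force summation of
the error PMF for every $(N \le 500, T \le N)$ at $10^{-12}$ relative
error over the normalized double range (below about $10^{-308}$ both routes
underflow and only "negligible" can be asserted). Abundance vectors must
sum to 1 within $10^{-9}$. Degenerate inputs fail loudly: zero-depth sites
cannot be tested, $T > N$ is an error, missing quality strings name the
offending read, and a reference-id mismatch between alignments and FASTA is
a hard error rather than a silent empty result.

The validation suite uses desk-scale problem sizes chosen to make the
statistical assertions sharp without waste: the null size check pools ten
replicates of a 10 kb single-strain genome at mean coverage 100; the power
and consensus-recovery check uses a 100 kb two-strain genome at 1%
divergence (about a thousand ground-truth sites) with a 30% minor strain at
coverage 100, where the per-site detection probability is essentially one.

## Known limitations

The global error rate is a single constant; quality strings gate bases but
do not enter the likelihood, so base-specific error structure (e.g.
end-of-read degradation, context effects) can inflate the realized false
positive rate on real data relative to the simulated bound. The mutation
class is a per-site majority statement and does not phase alleles into
haplotypes, so it cannot distinguish one displaced substrain from several
partial ones. The acceleration ratio inherits every scenario assumption
(divergence time, distance, season length) linearly; it should be read as
an order of magnitude, never as a measurement with error bars.
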