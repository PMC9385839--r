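---
title: "Models and methods behind holosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind holosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(holosim)
```

holosim asks a focused question: when a single RNA sample contains an
animal host and its bacterial symbionts, how much of each partner's
transcriptome survives each of the two standard ways of removing ribosomal
RNA — oligo(dT) poly(A) capture versus subtractive rRNA depletion? The
package answers it with a generative simulator whose biases are the
*documented biology* of the two RNA classes, followed by the same
evaluation chain one would run on real sequencing data. This vignette is
the package's own account of those models: what is assumed, what each
parameter means, and where the genuinely open design choices were made.

## 1. The transcript-pool model

A holobiont is a set of species specifications (`species_spec()`). For
species $s$ with $n_s$ genes:

* **Expression.** Exactly $\mathrm{round}(f_s n_s)$ genes are expressed
  ($f_s$ = `expressed_fraction`); the rest are silent with abundance zero.
  Expressed genes receive molar abundances
  $a_g \sim \mathrm{LogNormal}(0, \sigma_s^2)$, with $\sigma_s$ =
  `expression_dispersion` on the natural-log scale (1.5 for the host, 1.2
  for symbionts by default). The log-normal gives the heavy-tailed,
  several-orders-of-magnitude spread typical of bulk expression; it is a
  modelling convenience, not an estimate for any particular organism.
* **rRNA dominance.** Abundances are scaled so that mRNA totals
  $w_s(1-\rho_s)$ and the species' rRNA loci share $w_s\rho_s$ equally,
  where $\rho_s$ = `rrna_transcript_fraction` (default 0.85 for the host,
  0.95 for bacteria — total RNA is overwhelmingly ribosomal in both
  kingdoms) and $w_s$ = `pool_weight`, the species' relative RNA mass in
  the combined pool. `pool_weight` is the one knob the holobiont-level
  composition hangs on: the defaults (host 1; symbionts 0.02, 0.006,
  0.004) describe a host-dominated community with three symbionts of
  decreasing abundance, and were chosen once as a realistic shape for an
  animal–bacterial holobiont rather than fitted to any dataset.
* **Poly(A) capture probability.** Stable eukaryotic mRNA carries long
  poly(A) tails, so its per-gene capture probability under oligo(dT) is
  `polya_mean_capture` with no gene dependence (default 1, configurable
  for sensitivity analyses). Bacterial mRNA is transiently polyadenylated
  on its way to degradation, and the set of tagged transcripts at any
  instant is gene-dependent (turnover rates differ between genes), so each
  bacterial gene draws
  $c_g \sim \mathrm{Beta}(mc, (1-m)c)$ with mean $m$ =
  `polya_mean_capture` (default 0.2) and concentration $c$ =
  `polya_capture_concentration` (default 2). The Beta is the minimal
  bounded-support two-parameter family for a probability; nothing deeper
  is claimed for it, and both parameters are configuration, not
  hard-coded. No default should be read as an estimate of any real
  symbiont's biology — the real quantities are unknown. rRNA is never
  polyadenylated: its capture probability is 0.

Library preparation (`apply_protocol()`) is then a deterministic thinning:
poly(A) capture multiplies every entry by $c_g$; rRNA depletion multiplies
rRNA by $1-e$ with $e$ = `rrna_depletion_efficiency` (default 0.95 — a
high-efficiency commercial kit, the true value of which is not published);
`none` is the identity. Because every factor is in $[0,1]$, protocols can
only remove material, an invariant the tests assert. Physical bacterial
cell enrichment before extraction is modelled as a multiplier on symbiont
pool weights (`enrich_bacteria()`, 50× in the enriched arms, 1× in the
unenriched arm); the enrichment achieved by real
centrifugation/filtration protocols is only qualitatively known, so the
factor is declared illustrative.

## 2. The read model

`generate_reads()` draws `n_pairs` source transcripts multinomially by
post-protocol abundance, a fragment length
$\mathrm{round}(N(\texttt{insert\_mean}=250, \texttt{insert\_sd}=40))$
clamped to $[\texttt{read\_length}, \text{transcript length}]$, and a
uniform fragment start. Mates are 75 bp ends of the fragment in FR
orientation. Strandedness follows dUTP chemistry: **mate 1 is antisense**
to the transcript and mate 2 sense, which is exactly what
`strandedness = "reverse"` counting expects; `"stranded_forward"` swaps
the mates for other chemistries. Substitution errors are uniform per base
(`error_rate`, default 0.002); Phred qualities are truncated-normal per
base (mean 35, sd 5, clamped to [2, 40]). Indels, PCR duplicates,
hexamer-priming positional bias and realistic rRNA sequence conservation
are deliberately out of scope — none of them interacts with the metrics
under study, and the last one is worth restating: because genomes are
random DNA, simulated rRNA is species-unique, whereas real bacterial rRNA
is conserved enough to cross-map between symbionts. Cross-genome
ambiguity is therefore *rarer* in simulation than in reality, and the
ambiguous-discard machinery is exercised by planted-duplication tests
rather than by the default pool.

Transcripts shorter than one read length cannot be sampled; a pool with no
sampleable transcript is an explicit error.

## 3. The evaluation chain

**Trimming** (`trim_pairs()`) reproduces the common recipe for 75 bp
reads: crop the first 10 bp, scan 5'→3' with a 4 bp window and truncate at
the start of the first window whose mean Phred quality is below 20, then
drop any pair whose mate ends below 60 bp. Pairs are kept intact or
dropped entirely — orphan mates are never propagated. A mate shorter than
the window fails outright. The quality steps are idempotent; the 5' crop,
by construction, is not, which is why the idempotence test excludes it.

**Assignment** (`build_index()`, `assign_pairs()`) replaces spliced
alignment with k-mer seed chaining: synthetic genes are intron-free, and
genome-level attribution (not base-level alignment) is all the downstream
metrics consume. Both strands of every scaffold are indexed (k = 21,
2-bit-packed into doubles, so k ≤ 26); each mate contributes seeds at a
fixed stride (7 bp), and seed hits sharing scaffold, strand and alignment
diagonal are chained. A species supports a pair when both mates have at
least `min_seed_hits` (2) chained hits, on opposite strands, within
`insert_bound` (1000 bp). Exactly one supporting species ⇒ `assigned`;
two or more ⇒ `ambiguous_genome` — ties are *never* resolved by score,
because competitive mapping discards anything compatible with more than
one partner genome; zero ⇒ `unaligned`. With 7 seeds per 65 bp mate and 2
required hits, up to roughly three substitution errors per mate are
tolerated. How a spliced aligner flags "aligned to more than one genome"
is tool-specific; the seed-support definition used here is a declared
stand-in with the same discard semantics.

**Counting** (`count_genes()`) applies union-overlap semantics per
assigned pair on its best locus: overlapping CDS are collected under the
strand rule (reverse: gene strand opposite mate 1's aligned strand), then
one gene ⇒ count +1, several ⇒ `ambiguous_feature_pairs`, none ⇒
`no_feature_pairs` (which is where residual rRNA reads land, since rRNA
loci are not CDS). This is a semantic, not bit-level, emulation of
CIGAR-aware union counting. Two exact integer identities hold for every
sample and are asserted as acceptance properties:
`pairs = assigned + unaligned + ambiguous_genome` and
`assigned = counted + ambiguous_feature + no_feature`.

**Metrics.** Gene coverage is expressed genes over *all* annotated genes,
at thresholds 1 (detection) and 5 (the usual pre-filter before
differential expression); it is non-increasing in the threshold. Depth
summaries are over expressed genes only (zeros excluded), matching how
mapped-gene depth boxplots are drawn; a zero-inclusive variant is a flag.
The median uses the midpoint rule, quartiles are type-7. Spearman
correlation is computed over the full gene vector including zeros with
average ranks for ties; a constant vector makes rank correlation
undefined, so such samples are flagged with a warning and `NA` rather
than a silent `NaN`. Between-method tests default to Welch's unequal
variance t-test (the variance assumption is genuinely open; pooled
variance is a flag), one-tailed where the scientific question is
directional (symbiont coverage gains), two-tailed for host parity.
Replicate spreads are reported as mean ± sd — with n = 3 the convention
is ambiguous between sd and sem, so both are computed and sd is the
default display. If both groups are exactly constant, the documented rule
is p = 1 for equal means and p = 0 otherwise, instead of an exception.

**GO statistics.** GO terms are flat labels — terms are tallied exactly as
annotated, with no ontology-graph ancestor propagation, matching direct
annotation-export tallies. A term is expressed when any member gene has at
least one read pair. Per-GO expressed-gene counts and proportions are
computed per replicate and averaged arithmetically (counts and proportions
independently, since both are reported). The top-N differential table
ranks terms by absolute difference in mean expressed-gene number; ties are
broken lexicographically by GO id — the tie rule is invented but
deterministic. Namespaces are pooled in the ranking; a per-namespace
variant would be a straightforward filter on the GO map.

## 4. Numerical and structural choices

* **Coordinates are 1-based, closed intervals** throughout — the native
  convention of the R/Bioconductor interval stack — so GFF3 emission needs
  no conversion and `IRanges` operations need no shims.
* **Reproducibility.** Every stochastic stage draws from a substream seed
  derived by hashing `(seed, stage label, species / arm / replicate)`
  (`substream_seed()`). Consequences, both tested: identical configs and
  seeds give byte-identical output TSVs, and adding a species or a
  replicate leaves every other stream untouched. Output files carry a
  content hash of the configuration; re-running into a directory stamped
  with a different hash is refused unless forced.
* **Gene layout.** Genes and rRNA loci are placed sequentially with
  100–300 bp spacers on a single scaffold per species, so features never
  overlap and feature-level ambiguity in the default pool is essentially
  zero; the ambiguous-feature path is exercised with hand-built overlapping
  annotations.
* **Interfaces.** Everything tabular is a tibble; fitted comparisons have
  `tidy()`/`glance()` methods; result types have `plot_*()`/`autoplot()`
  views; the orchestration layer is plain functions
  (`run_experiment()`, `import_counts()`, `read_experiment_config()`)
  with a thin Rscript wrapper in `inst/scripts/` for shell use.

## 5. What the simulator does and does not establish

The default experiment — four species (host plus three symbionts of
decreasing abundance), three rRNA-depleted and three poly(A) replicates at
50× bacterial enrichment plus one unenriched poly(A) library, $10^5$
pairs per sample — reproduces the qualitative pattern expected from the
biology: host coverage within a few percentage points between the
enriched arms, symbiont coverage strictly higher under rRNA depletion in
every replicate, the unenriched library worst for bacteria, and the same
direction in expressed-GO percentages. The test suite asserts exactly
these directional statements, plus oracle equivalence of every core
operation on hundreds of randomized instances, exact read conservation,
and a closed-form check: with Poisson read allocation over $10^4$ genes,
empirical coverage at thresholds 1 and 5 must sit within 3σ of
$\frac{100}{n}\sum_i P(X \ge t \mid \lambda_i)$ under the thinned rates
of each protocol.

Problem sizes in the tests are chosen for statistical resolution at
interactive speed: 600 host / 3 × 300 symbiont genes and $10^5$ pairs per
sample for the full experiment, $10^4$ genes for law-of-large-numbers and
Poisson checks, and hundreds of tiny randomized instances for the
oracles.

What passing these tests does *not* show: that any particular real
holobiont has capture mean 0.2, enrichment 50×, or depletion efficiency
0.95 — those are illustrative; that rRNA cross-mapping between related
symbionts is negligible (it is not, in real data — see §2); or anything
about splice-aware alignment, normalisation, or differential-expression
testing, which are all out of scope. The package's claim is narrower and
checkable: *given* the documented stability/polyadenylation biology, the
standard evaluation chain, re-implemented faithfully, yields the reported
protocol biases — and every step of that chain agrees with independent
brute-force oracles.
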