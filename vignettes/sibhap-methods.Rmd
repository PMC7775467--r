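---
title: "Methods: haplotype fine-mapping and functional follow-up for discordant sibling pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype fine-mapping and functional follow-up for discordant sibling pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sibhap)
```

## The study design sibhap models

Extreme-phenotype sibling-pair designs classify affected sib pairs by two
clinical parameters: a patient is *severely* affected when both parameters
fall strictly below the 25th population centile, *mildly* affected when both
lie strictly above the 75th, and unclassified otherwise. Pairs are then
*concordant mild*, *concordant severe*, or *discordant* (one mild, one
severe sib). The design's power comes from a paradox: a *cis*-regulatory
variant associated with the *discordance of a pair* is necessarily shared by
both sibs of the pair, so the phenotypic difference within the pair must be
driven by something else — a *trans*-acting factor, such as a nucleic-acid
binding protein, whose genotype differs between the sibs. sibhap implements
the complete analysis chain around this idea: pair classification,
EM-based haplotype association with pair-preserving permutation, divergent
site calling on resequenced haplotypes, allele-specific binding-site
prediction, a contaminant filter for gel-shift protein mass spectrometry
(EMSA-PSeq), read-through transcript modelling, and nested ΔΔCt
quantification of knockdown qPCR — plus a synthetic-data generator that
embodies the cis×trans model, so every stage can be exercised and calibrated
without patient data.

## Haplotype frequencies and explanation lists

Unphased multilocus genotypes are phase-ambiguous. For a marker subset,
`em_haplotype_frequencies()` maximizes the multinomial likelihood
$\ell(f) = \sum_g n_g \log \sum_{(h_1,h_2) \sim g} f_{h_1} f_{h_2}
(2 - \delta_{h_1 h_2})$, where the inner sum runs over the unordered
haplotype pairs compatible with genotype class $g$. Individuals with missing
calls contribute through all compatible completions rather than being
dropped — the same weighting that later drives the association statistic.
Implementation choices:

* individuals are collapsed into distinct genotype classes, so EM cost does
  not grow with cohort size (this is what makes 100,000+ EM fits feasible in
  the permutation suites);
* initialization is the deterministic product of single-marker allele
  frequencies; a seed matters only if random restarts are requested
  (default none);
* haplotypes are coded in mixed radix over the panel, giving a deterministic
  lexicographic order for output and tie-breaking;
* convergence: `tol = 1e-8` on both frequency change and log-likelihood
  increase, `max_iter = 1000`; the log-likelihood is asserted non-decreasing
  at every step;
* *training-set mode*: when a prior frequency table is supplied, frequencies
  are fixed and only the per-individual weighted explanation lists are
  computed. This mirrors the use of a larger training cohort to stabilize
  rare-haplotype assignment in small case/reference subsamples.
* estimation pools all individuals by default (case + reference pooled
  estimation); founder-only estimation is available by passing founder ids.

`explanation_lists()` reports each individual's compatible unordered pairs
$(h_1, h_2)$ weighted by $f_{h_1} f_{h_2} (2 - \delta_{h_1 h_2})$,
normalized to 1. An individual incompatible with every positive-frequency
haplotype falls back to uniform weights over its compatible pairs, with a
warning — a visible signal of a genotyping error or an inadequate prior.

Marker informativeness uses MAF $= 1 -$ (largest allele frequency), which
extends to microsatellites without special-casing, and the strict threshold
MAF $> 0.4$. Linkage disequilibrium is summarized by $D' = |D|/D_{max}$ from
EM-estimated two-marker frequencies (multiallelic markers reduced to major
vs other); adjacent informative markers with $D' > 0.8$ chain into blocks.

## Association testing

The group contrast statistic is a likelihood ratio on EM frequencies,
$\Lambda = 2(\hat\ell_1 + \hat\ell_2 - \hat\ell_{pooled})$. Its null
distribution is never assumed chi-square; significance always comes from
permutation, which keeps the statistic honest under phase ambiguity,
missing data and small samples. Two pair-preserving relabelling schemes are
provided:

* **interpair** (`group_flip`): each pair's group label flips with
  probability 1/2, both siblings always moving together — pairs, not
  individuals, are the exchangeable sampling unit;
* **intrapair** (`within_pair_swap`): within each discordant pair the
  mild/severe labels swap independently with probability 1/2; genotypes and
  pair membership are untouched.

P-values use the add-one estimator $(1 + \#\{\Lambda^{(b)} \ge
\Lambda\})/(1 + B)$. Multiple testing across marker combinations is
corrected by the min-p (Westfall–Young) scheme: one sequence of relabellings
is shared by all combinations, each permutation's minimum per-combination
p-value is recorded, and $p_{corr}(c)$ is the add-one fraction of
permutations whose min-p is at most $p_{raw}(c)$. This preserves the
correlation structure of overlapping combinations — a duplicated combination
costs nothing, and for independent combinations the correction approaches
the Šidák form $1 - (1 - p)^k$ (both properties are tested). Pooled
frequencies are computed once per combination (pooled data is
label-invariant); the two group EMs are re-run for every relabelling,
starting from the pooled estimate.

The transmission disequilibrium test counts transmissions/non-transmissions
of allele 1 from heterozygous parents to affected offspring,
$\chi^2 = (b - c)^2/(b + c)$ on 1 df. Signal localization merges maximal
runs of consecutive significant adjacent-marker segments into candidate
fragments spanning their outermost markers.

## Divergent sites, probes and binding-site comparison

On resequenced haplotypes tagged by their phenotype association, a position
is *divergent* when every discordance-tagged haplotype differs there from
every concordance-tagged haplotype — the set-disjointness rule that, applied
to the published 18-position matrix bundled as `resequencing_matrix()`,
returns exactly six SNPs. Probe construction slices an odd-length window
centred on the variant (35-mers for gel-shift baits, ±20 bp windows for
binding-site prediction) and substitutes the requested allele at the centre.

The PWM scanner is deliberately generic: a matrix of per-position,
per-base weights and a threshold are inputs; the score is the plain additive
sum and both strands are scanned. No pseudocount or information-content
logic is built in, because matrix libraries differ and belong upstream. For
each SNP a (factor, offset, strand) site is *allele-unique* when predicted
on one allele's window and absent from the other's; counts pool over SNPs
and are compared with a two-sided exact binomial test against an equal
split. A chi-square variant sits behind a flag for sensitivity analysis,
since exact-binomial and large-sample answers diverge noticeably at the
counts this assay produces (e.g. a 6 vs 21 split).

## The EMSA-PSeq contaminant filter

Protein mass spectrometry of a gel-shift band identifies hundreds of
proteins, most of them comigration artefacts, sticky DNA binders or handling
contaminants. The filter turns per-sample identifications into a presence
matrix over a structured sample sheet (SNP probes with two alleles, a
consensus-probe positive control, empty negative controls, denaturing-gel
lanes) and passes a protein for a target SNP only if it is

1. absent from every empty negative control,
2. absent from every native-gel sample of other SNPs' probes,
3. below 200 ppm reference abundance (strictly; unknown abundance fails —
   the conservative reading), and
4. annotated as nucleic-acid binding.

Denaturing-gel lanes lack the native multiprotein complexes and are excluded
from criteria 1–2 by default (flag-controlled). Per-criterion flags are
always reported, the filter is monotone in control presence, and spliceosome
components are flagged as excluded from prioritization but never deleted —
they are plausible binders that are uninformative as *trans* candidates.
Identification scores convert to match probabilities as
$P = 10^{-score/10}$.

## Read-through transcripts and truncated ORFs

A gene model (1-based inclusive exon intervals, transcript-coordinate CDS
start) splices against a genomic sequence; `readthrough_transcript()`
continues past a chosen exon's donor site into the intron, whose retained
length is a parameter — deliberately so, because the 3′ end of such
transcripts is usually not determined by the assays that detect them.
Translation runs the standard genetic code to the first in-frame stop and
reports residues encoded at/after a marked exon/intron junction, so a
read-through with an in-frame junction and a planted intronic stop yields a
truncation length known by construction. The bundled
`make_minigene(preset = "scnn1b_analog")` is a *synthetic* gene of the
published dimensions — 13 exons, a 640-residue spliced protein, an in-frame
junction after 195 codons at the end of exon 3, a stop 26 codons into
intron 3, hence a 221-residue read-through product — used because no genomic
sequence is bundled with the package; building the real gene model from a
reference annotation is a documented download recipe, not data.

## Nested ΔΔCt with the unrelated-value rule

Technical duplicates are averaged; $\Delta Ct = Ct_{target} -
Ct_{housekeeping}$ per plate. For a treatment vs the transfection control,
all nine case×reference combinations of the triplicate plates are formed and
each is centred by the experiment's mean transfection-agent effect
($\Delta Ct_{growth} - \Delta Ct_{transfection}$, itself a nine-combination
mean). Because the nine values share plates, only an *unrelated* subset — a
perfect matching using each case and reference plate once — enters the rank
test; the deterministic index-matched diagonal is used (a seeded random
matching is available to show the conclusion is matching-invariant), giving
three values per biological experiment, pooled across experiments into a
two-sided Wilcoxon signed-rank test against zero (exact for n ≤ 25).
The whole construction is invariant to adding a constant to one amplicon's
Ct values, and experiments with fewer than two valid replicates in any
required condition are excluded, not imputed. Densitometric gel-shift
signals are normalized within experiment by the paired isotype-control lane
(ratio; zero controls exclude the experiment) and compared across probe
alleles by an exact Mann–Whitney U test.

## The synthetic cohort generator

`simulate_cohort()` draws founder cis haplotypes from a preset pool whose
frequencies follow the published concordant-pair distribution
(0.599/0.185/0.129 + rare remainder), a biallelic trans locus, and transmits
both to sibs Mendelianly. Phenotypes follow

$$y_{ip} = \mu - \beta_{cis} X_{cis}
           - \beta_{int}\, R\, (X_{trans} - 2 f_{trans})
           + c_{fam} + u_i + \varepsilon_{ip},$$

lower = worse. Three design choices matter and were made deliberately:

* **Per-chromosome (additive) receptive coding.** A cis-regulatory element
  acts on its own chromosome's gene copy, so $R = X_{cis}/2$ by default.
  With the preset pool the receptive haplotype is common (0.599), and a
  carrier-dominant coding saturates — some 84% of individuals are carriers
  and no group can be enriched much beyond baseline; the strong
  chromosome-frequency enrichment seen among discordant pairs (≈ 0.84 vs
  ≈ 0.60) requires homozygote weighting. Dominant coding remains available
  behind the flag.
* **Centred, functionally divergent trans alleles.** The trans dosage is
  centred at its population mean: among receptive carriers one allele is
  protective, the other deleterious. An uncentred burden coding would give
  carriers a nonzero mean shift — an effective cis main effect that drives
  concordant-severe enrichment instead of discordance.
* **Structured noise.** $c_{fam}$ (SD 1.2) is shared by a family,
  $u_i$ (SD 0.4) by both clinical parameters of one patient,
  $\varepsilon_{ip}$ (SD 0.6) is per parameter. Sibling designs have exactly
  this covariance anatomy; structurally, concordance can arise from the
  family-shared channel (so concordant pairs carry cis haplotypes near their
  population frequency) while discordance cannot, making discordant pairs
  the mechanism-enriched class. With all shared components at zero the
  pair-classification rate reduces to the product of independent tail
  probabilities, which is tested.

Defaults — 318 families (the scale of the emulated study), $\beta_{int} = 3$,
$f_{trans} = 0.5$ — were fixed when the mechanism was designed and are not
tuned per analysis. The generator emulates founder haplotype structure,
Mendelian transmission, centile-based selection and the cis×trans phenotype
model; it does **not** emulate recombination within the panel, genotyping
error, ascertainment by clinic, survivor effects, or realistic genome-wide
LD (filler markers use a first-order copying process with a target adjacent
D′ only). Passing tests therefore demonstrate the *machinery* is correct and
calibrated under the stated model, not that any particular real cohort
satisfies that model.

`simulate_emsapseq()` emits the 25-sample layout (3 SNPs × 2 alleles × 3
native replicates, one consensus probe, three empty negatives, three
denaturing lanes) with background contaminants appearing across samples
under a dropout rate and planted binders confined to their probe's samples;
background proteins occupy the complementary filter strata (abundant, or
rare-but-not-nucleic-acid-binding), so planted-truth recovery is exact by
design and the filter's sensitivity/false-positive test is sharp.
`simulate_ct()` plants condition effects on target amplicons
(default −1.2-cycle knockdown, +0.3-cycle transfection-agent effect) over
3 experiments × 3 plates × technical duplicates with 0.15-cycle plate noise.
All generators are seed-deterministic and emit manifests with parameter and
content hashes.

## Numerical and testing choices

* Coordinates are 1-based inclusive throughout; the read-through junction is
  the transcript coordinate of the last exonic base.
* Boundary conventions are strict everywhere they matter: centile cuts
  (25/75 exclusive), MAF (> 0.4), abundance (< 200 ppm), block D′ (> 0.8).
* Exact small-sample tests (binomial, Wilcoxon, Mann–Whitney) are delegated
  to R's stats implementations and cross-checked against brute-force
  enumeration of the full permutation distribution for n ≤ 8 in the test
  suite, keeping implementation and oracle separate.
* Genotype-class completions are capped at 65,536 per class; beyond that the
  marker subset or missingness must be reduced rather than silently
  truncated.
* Problem sizes in the test suite were chosen to make Monte-Carlo error
  small relative to each tolerance: EM recovery averages 5 cohorts of
  n = 200 against a 0.01-grid likelihood oracle; type-I calibration uses
  500 null cohorts of 40 pairs × 200 permutations (binomial 95% bounds at
  α = 0.05); the min-p/Šidák comparison uses 400 permutations × 4 replicate
  cohorts; filter recovery uses 100 planted datasets; the directional
  enrichment check uses 100 generator runs.

## Known limitations

* The family-likelihood weighting of pedigree-aware haplotype software is
  richer than the multinomial EM used here; sibs are treated as individuals
  in the likelihood and as pairs only in the permutation unit. This is the
  documented interpretation, controlled by the permutation scheme.
* The equal-distribution count test is an exact binomial; published
  count-based procedures differ in detail and can give visibly different
  p-values at small counts, which is why the chi-square variant exists as a
  sensitivity check rather than a replacement.
* The PWM scanner is a generic additive scorer; it does not reproduce any
  proprietary matrix library's core/matrix-similarity scoring.
* Real genotype data may violate the generator's assumptions (no
  within-panel recombination, clean Mendelian transmission, Gaussian noise);
  the acceptance of the machinery on synthetic data does not certify those
  assumptions.
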