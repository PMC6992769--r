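---
title: "Methods: SNP landscape, annotation and diversity analysis in gbsland"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP landscape, annotation and diversity analysis in gbsland}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbsland)
```

`gbsland` implements the analysis stages that follow variant calling in a
genotyping-by-sequencing (GBS) study of a diploid germplasm panel: quality
filtering of the SNP matrix, landscape summaries (substitution spectrum,
heterozygosity, coverage, density), genomic-context and variant-effect
annotation against gene models, and genetic-diversity analysis (distances,
UPGMA, PCA, admixture with Evanno ΔK model selection). This vignette is the
package's own account of the methods, their assumptions, and the design
choices that were genuinely open.

## Data model

Diploid biallelic genotypes are stored as alt-allele dosage: 0 (hom-ref),
1 (het), 2 (hom-alt), `NA` (missing). Phase is discarded at import —
every statistic computed downstream (minor allele frequency,
heterozygosity, identity-by-state, the admixture likelihood) is a function
of dosage alone, so retaining phase would add cost without information.
Read depth, when present in `FORMAT/DP`, is kept alongside in a matrix of
the same shape. Coordinates are 1-based closed everywhere internally and
in VCF/GFF3; only bedGraph output converts to 0-based half-open.

Multi-allelic records and indels are excluded at import (and counted):
the methods implemented here are defined for biallelic SNPs only.
Genotypes other than `0/0`, `0/1`, `1/0`, `1/1` — half-calls, higher ALT
indexes — map to missing rather than erroring, since GBS callers emit
them routinely.

## Quality filtering

The cascade mirrors a standard GBS pipeline and is applied in a fixed,
accountable order:

1. **Depth mask** — every call with `DP < min_depth` (default 6) becomes
   missing. The boundary is inclusive: depth exactly 6 survives. Masking
   is per-genotype, because a depth threshold on a VCF most plausibly
   refers to genotype DP; a site-mean mode is available behind
   `site_mean_depth` for pipelines that filtered that way. Calls with
   *unknown* depth fail the filter by default (conservative); set
   `unknown_depth_passes = TRUE` to accept them.
2. **Presence** — site kept if called in at least `min_presence_fraction`
   (default 80%) of accessions.
3. **Missingness** — site kept if its missing fraction is strictly below
   `max_missing_fraction` (default 5%).
4. **MAF** — site kept if minor allele frequency is strictly above
   `min_maf` (default 0.05). MAF is computed from called genotypes only.

Presence and missingness look redundant but are distinct thresholds
applied at different stages of real pipelines (initial calling vs final
selection); both are kept, individually configurable. Whether presence
precedes MAF is not observable from a final call set; presence-first is
the documented default. The `FilterReport` accounts for every removal:
input = output + Σ removals holds by construction and is asserted.

## Landscape statistics

*Substitution spectrum.* Each SNP belongs to exactly one of six unordered
classes; A/G and C/T are transitions, the rest transversions. The Ts/Tv
ratio is reported exactly (no rounding); with zero transversions it is
undefined (`NA`), not an error.

*Heterozygosity* is 100 × het calls / called genotypes per accession.

*Coverage.* Per chromosome: first/last SNP, covered span (last − first),
span as a fraction of chromosome length, bp per SNP, and the maximum gap
between consecutive SNPs with its flanking positions. **bp per SNP uses
the covered span, not the chromosome size** — this is the convention that
reproduces published per-pseudomolecule tables of this kind.

*Density.* Windows are non-overlapping 1 Mb tiles by default; a
"sliding" caption with step = width reduces to tiling, and true sliding
windows are available via `sliding = TRUE`. For per-group tracks a site
counts toward a group only when it is polymorphic (MAF > 0) within that
group's accessions — a site fixed within a group carries no information
for it. This rule is an assumption of ours and is configurable by simply
passing no groups.

*Array cross-referencing* is an exact (chromosome, position)
intersection; a manifest declaring a different assembly is refused rather
than silently matched.

*Group comparison.* The chi-square on the groups × region-category count
table is Pearson's test of homogeneity (`stats::chisq.test`, no
continuity correction), df = (r−1)(c−1).

## Genomic context and variant effects

Context classification assigns each SNP one of `cds`, `utr5`, `utr3`,
`intron`, `intergenic`. Within a transcript the label follows from the
exon/CDS intervals; **across transcripts the severity precedence
cds > utr5 > utr3 > intron** selects the reported context. The
alternative — a designated primary transcript — is not reconstructible
from a final call set, so the SnpEff-style "most severe" collapse is the
declared choice. "Exonic" in summary tables means CDS; UTRs are tallied
separately. Intergenic SNPs within 1,000 bp upstream of a transcription
start site (strand-aware: lower coordinates on `+`, higher on `-`) are
flagged as promoter SNPs; promoter is a subset of intergenic, never of
genic.

Effect prediction is per SNP × transcript:

* splice donor/acceptor: the canonical 2 bp at each intron end in
  transcript orientation (the broader 3–8 bp splice region is out of
  scope);
* coding positions: the codon is located in the transcript frame,
  reverse-complemented on the minus strand; same amino acid →
  `synonymous_variant`, different → `missense_variant`, alternate codon a
  stop → `stop_gained`, reference codon a stop → `stop_lost`, initiator
  ATG destroyed → `start_lost`;
* outside all transcripts: one `upstream_gene_variant` /
  `downstream_gene_variant` record if within 5,000 bp of the nearest gene
  (strand-aware; 5 kb matches the common annotator default), else
  `intergenic_variant`.

The impact map is fixed: stop/start/splice → high, missense → moderate,
synonymous → low, everything non-coding → modifier. Per-SNP summaries
take the highest-impact effect across transcripts, ties broken by a fixed
effect order.

Degenerate inputs: a SNP whose REF disagrees with the genome sequence is
recorded in a `ref_mismatch` table and skipped from effect calls (it
stays in context statistics). A transcript whose CDS length is not
divisible by three is flagged `incomplete` and excluded from codon-level
calls; a SNP covered only by incomplete transcripts falls back to a
positional record.

Missense changes are further classified by amino-acid property:
nonpolar {G,A,V,L,I,P,F,M,W}, polar {S,T,C,Y,N,Q}, acidic {D,E}, basic
{K,R,H}. Histidine-as-basic and glycine-as-nonpolar is the most common
convention; the partition is an argument (`classes`) for users who follow
another. The partition covering all 20 residues exactly once is asserted.

## Genetic diversity

*Distance.* `d(i,j) = 1 − IBS`: one minus the mean shared-allele
fraction over jointly non-missing sites (dosage pairs differing by
0/1/2 share 2/1/0 alleles). The upstream tool chain this emulates does
not document its tree distance; 1−IBS is the conventional genotype
distance and the choice is isolated behind the distance interface.

*UPGMA* is average-linkage clustering (`stats::hclust`) with merge
heights halved into an ultrametric tree, so cophenetic distances
reproduce ultrametric inputs exactly. Ties are made reproducible by
ordering accessions lexicographically before clustering.

*PCA* operates on the accessions × sites dosage matrix, missing entries
imputed with the per-site mean, sites centered but not scaled (the
genotype-PCA default of the emulated tool chain); unit-variance scaling
is behind a flag. Variance-explained fractions come from the
eigenvalues.

*Admixture.* Population structure is estimated with a maximum-likelihood
admixture model: memberships Q (n × K rows on the simplex) and
population allele frequencies F (K × L) maximize

$$\ell(Q,F)=\sum_{i,l}\Big[g_{il}\log\textstyle\sum_k q_{ik}f_{kl}
+(2-g_{il})\log\sum_k q_{ik}(1-f_{kl})\Big]$$

over non-missing entries, by EM updates with simplex/box constraints.
This is the standard frequentist counterpart of the Bayesian MCMC tool
used in such studies: the same decision problem (memberships + K), fully
deterministic given a seed. Frequencies are clamped to
[10⁻⁶, 1−10⁻⁶] to keep the likelihood finite; the log-likelihood is
non-decreasing at every iteration (asserted in tests). K = 1 has the
closed form f = mean dosage / 2.

Convergence deserves a note: the likelihood plateaus well before the
membership estimates stop moving, so the stopping rule (relative ℓ
change below `tol`) defaults to a deliberately tight 10⁻⁸ with
`max_iter = 2000`. The replicate fits used for model selection run at
lighter settings (300 iterations, 10⁻⁵) because only the likelihood
value is needed there and replicate scatter is exactly what the Evanno
denominator measures; the final Q at the selected K should come from a
fresh tight fit, which is what `run_pipeline()` does.

*Model selection.* For each K in a range (default 1–6 at desk scale, 10
replicate seeds per K), the Evanno statistic
ΔK = \|mean ℓ(K+1) − 2 mean ℓ(K) + mean ℓ(K−1)\| / sd(ℓ(K)) is computed
over replicate log-likelihoods, and the interior K maximizing ΔK is
selected. ΔK is undefined at the range ends and wherever the replicate
sd is zero; those K are excluded (with a warning if nothing remains).
Because the EM is deterministic per seed, replicate scatter reflects
local optima rather than MCMC noise; on weakly structured panels this
can make ΔK erratic, a known limitation of transplanting ΔK to a
likelihood setting.

*Assignment.* An accession joins its maximum-membership population when
that membership is ≥ 0.80 (boundary inclusive), otherwise it is labeled
admixed — so an F1 hybrid with memberships (0.5, 0.5) is admixed.

## The synthetic-data generator

The generator emulates, at toy scale, the structure of a stone-fruit
rootstock germplasm panel genotyped by GBS against an eight-pseudomolecule
reference:

* **Genome**: a few short chromosomes carrying non-overlapping genes on
  both strands; each transcript has a 5′UTR, a CDS that starts ATG, ends
  at a stop and contains no internal stop (sense codons are drawn
  directly), canonical GT..AG introns, and a 3′UTR. Genes are separated
  by at least twice the promoter window so planted promoter/intergenic
  labels are unambiguous.
* **Planted variants** carry provable truth labels: a stop-gain's
  alternate codon is verified to be a stop in transcript frame, a splice
  donor lies in the first two intron bases, a promoter variant within
  1,000 bp upstream of the TSS, strand-aware. Coding plants are placed in
  single-transcript genes so the cross-transcript collapse cannot blur
  the truth.
* **Genotypes**: K ancestral populations under the Balding–Nichols
  F-model (population frequency ~ Beta around a Uniform(0.1, 0.9)
  ancestral frequency, divergence parameter Fst), pure members one-hot,
  F1 hybrids exactly (0.5, 0.5) — mirroring inter-subgeneric hybrids
  with ~50/50 membership and ~40% heterozygosity — Dirichlet-admixed
  accessions, duplicated accessions as exact copies with independent
  missingness, missing-completely-at-random calls, and negative-binomial
  read depths independent of genotype.

What it deliberately does **not** model: linkage disequilibrium (loci are
independent), restriction-site fragment sampling, depth–genotype
coupling, allele-frequency correlation between populations, or
sequencing error. Passing tests on this generator therefore demonstrate
correctness of the bookkeeping and estimators under the stated model,
not robustness to the full messiness of real GBS data.

Default problem sizes are chosen as the smallest at which each behaviour
is comfortably observable: a 3 × 60 kb genome with 18 genes for
annotation (including an exhaustive per-base oracle comparison), and
500-locus, ~30-accession panels at Fst 0.15 for diversity — the scale at
which the admixture EM, ΔK selection and UPGMA clade recovery are
exercised end to end in seconds.

## Known limitations

* ΔK inherits its usual blind spots (undefined at K = 1, unstable when
  one population is barely sampled) plus the local-optima caveat above.
* The effect predictor handles SNPs only — indels and multi-nucleotide
  variants are out of scope, as is KOG/orthology functional annotation.
* Promoter annotation is a fixed upstream window; no TSS evidence beyond
  the gene model is used.
* The VCF reader trusts `GT`/`DP` and ignores genotype likelihoods.
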