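---
title: "Regionally adjusted screens for lineage-accelerated evolution"
author: "accelscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regionally adjusted screens for lineage-accelerated evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelscreen)
```

## The scientific question

Genes involved in human parturition are expected to have evolved unusually
fast on the lineage leading to humans: the combination of a large neonatal
head and a narrow, bipedal pelvis plausibly selected for a relatively
shorter gestation. `accelscreen` implements the computational machinery for
testing this idea: screens that ask, gene by gene (and conserved noncoding
element by element), whether the rate of evolution on the human lineage --
or on the human plus human--chimpanzee-ancestor lineages combined --
significantly exceeds what the locus's own genomic neighborhood predicts,
followed by gene-wise aggregation, FDR control, a life-history/allometry
analysis, and a candidate-gene case-control association stage.

## The acceleration model

### Coding sequences

Codon evolution follows the MG94xHKY85 model: codons differing at more
than one nucleotide never interchange directly; a single-nucleotide change
has rate proportional to the target nucleotide's position-specific (F3x4)
frequency, multiplied by $\kappa$ for transitions and by a nonsynonymous
factor for amino-acid-changing substitutions.  We normalize the generator
so that branch lengths read in *expected synonymous substitutions per
codon site*, which makes the following decomposition natural: on branch
$i$ the synonymous length is the regional rate $dSr_i$, and the
nonsynonymous length is

$$ n_i = a_i \cdot \omega \cdot dSr_i, $$

where $a_i$ is a per-branch *constraint scaling* estimated from the
locus's neighborhood and $\omega$ is the gene-wise rate multiplier.
Because $a_i$ and a regional omega multiply the same product, they are not
separately identifiable; we absorb the regional omega into $a_i$, so
$a_i$ reads directly as the regional dN/dS scale on branch $i$ and
$\omega$ as the gene's rate *relative to its regional expectation* (the
"dN/dS-adj" reading).  A gene evolving exactly as its neighborhood
predicts has $\omega = 1$.

The regional parameters ($dSr_i$, $a_i$, and a shared $\kappa$) are
estimated by maximizing the concatenated likelihood of the flanking genes
-- by default the 10 upstream and 10 downstream loci -- on the fixed
seven-taxon topology
(((Human,Chimpanzee),Macaque),((Mouse,Rat),(Dog,Cow))).  Only branch
lengths are ever estimated, never the topology, and fitting uses the
unrooted tree: for reversible models the likelihood is invariant to root
placement (pulley principle), so a degree-2 root is collapsed.

The acceleration test is then a likelihood-ratio test with one degree of
freedom.  Null: a single free $\omega$ scales the nonsynonymous
expectation of *every* branch.  Alternative: the focal lineage's
multiplier is freed to a separate parameter $R$, shared across the human
terminal branch and the human--chimpanzee ancestor branch in the combined
configuration, so both configurations add exactly one parameter.  The
statistic $2(\ln L_1 - \ln L_0)$ (clamped at zero) is referred to
$\chi^2_1$.

### Noncoding elements

Conserved noncoding elements (retained when their conservation score is at
least 400) are tested the same way under an HKY85 nucleotide model: the
per-branch expected lengths $dNC_i$ come from the nearest flanking
conserved sequence accumulated to a 25 kb span (walking outward by
proximity), the null frees one element-wide rate multiplier $r$, and the
alternative frees the focal lineage's multiplier.  Element base
frequencies are estimated empirically per element; element p-values are
aggregated per gene by assigning each element to its nearest gene
(boundary-to-boundary distance, containment wins, ties to the
lower-coordinate gene, strand ignored) and Fisher-combining
($-2\sum\ln p_i$ vs $\chi^2_{2k}$).

### Multiple testing

Screen-wide significance uses Storey q-values: $\hat\pi_0$ is the
tail-count estimator smoothed over the grid $\lambda = 0, 0.05, \dots,
0.90$ with a df-3 smoothing spline evaluated at the largest $\lambda$ and
capped to $(0, 1]$; $q_i = \min_{p_j \ge p_i} \hat\pi_0\, m\, p_j /
\mathrm{rank}(p_j)$.  The association stage corrects for the effective
number of independent SNP tests via simpleM (smallest $k$ whose top-$k$
correlation-matrix eigenvalues explain 99.5% of the variance, in blocks of
at most 200 SNPs) and a Bonferroni threshold $\alpha/M_\mathrm{eff}$.

## Numerical choices

* Likelihoods are computed by Felsenstein pruning over collapsed site
  patterns, in compiled code; transition matrices come from the
  eigendecomposition of the $\pi$-symmetrized generator with
  scaling-and-squaring as a fallback, and rows are clamped/renormalized
  against round-off so they are stochastic to $10^{-12}$.
* Gap and ambiguity characters are missing data and are marginalized --
  never a fifth state; a codon containing any ambiguous base is masked
  whole, as are (with a warning) stop codons.
* Rates are optimized on the log scale.  One-dimensional subproblems use
  Brent's method over the full bound interval ($\omega, R \in [10^{-6},
  100]$, $\kappa \in [0.1, 20]$) with a log-scale tolerance of $2 \times
  10^{-3}$, which bounds the induced log-likelihood error well below the
  resolution of the LRT; multi-parameter fits (regional contexts, the
  stand-alone two-ratio test) use L-BFGS-B.  The alternative model is
  maximized by coordinate descent from the null solution; because each
  sweep is a global Brent search, additional perturbed starts are engaged
  only when a descent terminates on a parameter bound, which is where
  multimodality can actually bite.  Boundary solutions and
  non-convergence are flagged on the result object rather than silently
  accepted.
* Branch lengths are floored at $10^{-6}$ substitutions/site to keep the
  optimization away from $\log 0$; estimates at the floor are flagged
  (`rate_floor`).
* A p-value of exactly 0 entering Fisher combination is clamped to
  1e-300 with a warning.
* Squared-change parsimony solves the stationarity linear system exactly;
  branch lengths are ignored by default (cost is the plain sum of squared
  parent--child differences), with an optional weighted variant (squared
  change divided by branch length, equivalent to the Brownian-motion ML
  reconstruction).  A degree-2 root is collapsed first, which is what
  makes the textbook four-tip example (tips 1, 3, 5, 7 giving internal
  values 3 and 5 at cost 12) come out as stated.

## What the synthetic data emulate

The generator produces every input the pipeline consumes, with the
planted truth recorded alongside: codon and nucleotide alignments evolved
forward along the seven-taxon tree (root state from the stationary
distribution, per-branch transition matrices), locus neighborhoods in
which the neighbors share the regional $(dSr_i, a_i)$ while the focal
gene carries its own $\omega$ and optionally an accelerated $R$,
conserved elements with scores straddling the 400 threshold, Brownian
trait values on a primate tree, and LD-structured case-control genotypes
(latent Gaussian AR($\rho$) haplotype blocks at Hardy--Weinberg
equilibrium, cases and controls rejection-sampled against the logistic
penetrance implied by a planted per-allele odds ratio at a designated
causal SNP).  A single master seed deterministically derives every
component seed, so identical configurations reproduce identical outputs
byte for byte.

Default generator values are chosen to look like the real study system:
per-branch synonymous lengths mirror mammalian divergence (short ape
branches near 0.01, rodent branches near 0.1), constraint scalings spread
around a typical mammalian dN/dS of 0.2, $\kappa = 2$, gene lengths of
300 codons, 500 bp elements, a 165/163 case-control design with a planted
odds ratio of 1.8 at minor allele frequency 0.3 (matching the cohort the
association stage models), missingness 2%, and baseline prevalence 5%.

What the generator does *not* emulate: indels and alignment error,
site-to-site rate variation, selection on synonymous sites, recombination
and demographic structure in the genotypes, and ascertainment of the SNP
panel.  Passing tests therefore validate the estimators and their
operating characteristics under the stated models, not robustness to
those real-data complications.

## Calibration experiments and their regime

The null calibration of both LRTs (2,000 simulated null loci each; 300
codons or 500 bp on the seven-taxon tree) and the parameter-recovery
studies (regional rates from 20 neighbors x 300 codons; focal $R$ over
200 replicates; odds-ratio recovery over 500 replicates at 165/163) use a
flat regional parameter set -- $dSr_i = 0.15$, $a_i = 0.8$, $\omega =
0.3$, i.e. roughly 11 expected focal nonsynonymous events per gene --
rather than the mammal-realistic defaults.  The reason is statistical,
not cosmetic: the $\chi^2_1$ reference distribution is an asymptotic
approximation, and on a branch as short as the real human terminal branch
(~0.2 expected nonsynonymous events per 300-codon gene) the focal-lineage
LRT is strongly *conservative* -- the information about $R$ is a handful
of discrete events, so rejections at nominal 5% occur at roughly 2%.
This is a known limitation of branch tests on very short branches and
applies equally to the real screen: under-rejection, not inflation, so
the screen's FDR control is not jeopardized, but power on the terminal
human branch is materially lower than the asymptotic analysis suggests.
The combined human + ancestor configuration, and the element test (whose
information is all substitutions, not just nonsynonymous ones), sit much
closer to the asymptotic regime.

Regional-recovery accuracy is summarized as the *mean* absolute relative
error across the 22 per-branch parameters: at 20 neighbors x 300 codons
the per-branch sampling standard error is about 4%, so the maximum over
22 estimates exceeds 10% routinely by pure noise while the mean sits near
5%.

## Design choices made where the design was open

* **Rooted vs unrooted fitting**: unrooted, since reversibility makes the
  root unidentifiable; the simulator may still use a rooted tree.
* **Codon frequencies**: F3x4 estimated empirically from the focal gene
  plus its neighbors (pseudo-count of 0.5 per cell so no frequency is
  exactly zero).
* **$\kappa$ sharing**: one $\kappa$ per regional context, shared by the
  focal gene's test; per-gene $\kappa$ would add a nuisance dimension
  with negligible effect on the rate contrast.
* **Boundary LRTs**: plain 1-df $\chi^2$ p-values throughout; no
  boundary mixture halving.  Boundary solutions are flagged instead.
* **Nearest gene**: gene-body (boundary-to-boundary) distance rather than
  TSS distance, the common BED convention; switchable by supplying TSS
  intervals as the gene loci.
* **Fisher combination** treats element p-values as independent;
  elements near one gene share regional context, so combined p-values
  should be read as a ranking device rather than exact tail
  probabilities.
* **HWE filter**: 1-df chi-squared (not the exact test), controls only.
* **Allelic test**: no continuity correction by default (`correct =
  TRUE` available).
* **Duplicate probes**: collapsed on identical chromosome + position,
  keeping the copy with the highest call rate.
* **Ancestry**: the CEU-cluster covariate is accepted as an input column
  and used in the adjusted logistic model; ancestry inference itself is
  out of scope.
* **Allometric groups**: regression helpers fit any supplied grouping, so
  the all-mammal line can be fitted with or without primates.

## Problem sizes used by the shipped experiments

The packaged tests run the complete screen logic end to end at desk
scale: pipeline smoke runs use 2 loci x 4 neighbors (60-codon neighbors,
90-codon genes, 3 elements each, 2 kb flanks, 10 SNPs); the calibration
suite uses the full 2,000-replicate null screens and the recovery sizes
listed above; the regional-recovery experiment uses a full window of 20
neighbors of 300 codons.  These sizes keep the whole suite within a
practical runtime on one core while leaving each experiment's Monte-Carlo
error well inside its acceptance band.

## Known limitations

* No site-class (M-series) models and no synonymous-rate variation across
  sites; the screen detects lineage-wise acceleration, not site-specific
  positive selection, and the criterion is acceleration relative to the
  regional expectation, not dN/dS > 1.
* Neighboring genes that are themselves accelerated inflate the regional
  expectation and can mask a focal signal (gene families cluster).
* The conservativeness of the focal-branch LRT on very short branches,
  discussed above.
* Fisher combination ignores dependence among a gene's elements.
* The PLINK reader covers the text ped/map dialect only, and the
  association stage has no imputation, kinship, or haplotype phasing.
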