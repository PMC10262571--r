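---
title: "Simulating genomic mating schemes in a closed nucleus"
author: "gmatesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating genomic mating schemes in a closed nucleus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmatesim)
```

## The question the package addresses

After genomic selection has picked the parents of the next generation, the
breeder still has to decide *who mates whom*. Truncation selection plus
assortative pairing maximizes short-term response but concentrates the
pedigree and accelerates inbreeding; random pairing wastes some response.
Genomic mating treats mate allocation as an optimization problem over the
mating incidence matrix $P$ ($N_c$ matings $\times$ $N$ parents, each row
carrying $\tfrac12$ on its sire and dam columns), trading

$$\mathrm{Gain}(P) = \mathbf{1}' P\, G\, M a
\qquad\text{against}\qquad
\mathrm{Inbreeding}(P) = \mathbf{1}' (P G P' + D)\, \mathbf{1},$$

where $G$ is a genomic relationship matrix over the selected parents, $Ma$
their marker-predicted merit, and $D$ a per-mating Mendelian-sampling
dispersion. The package simulates a closed pig-like nucleus forward in time
and compares three traditional schemes (random, positive assortative,
negative assortative pairing of the selected 30 sires and 900 dams) with
genomic-mating schemes that read either the maximum-gain or the
minimum-inbreeding endpoint off the nondominated frontier of this
two-objective problem, with $G$ built either from SNP dosages (VanRaden) or
from shared haplotype segments (ROH).

## Simulation model

**Genome and founders.** The default genome is 18 chromosomes of 100 cM,
each carrying 1,700 biallelic markers and 17 biallelic QTL at uniform random
positions. Founder haplotypes are produced by explicit forward simulation:
every locus starts at allele frequency 0.5, then two phases of random
mating with a 1:1 sex ratio (2,000 individuals for 1,000 generations, a
bottleneck to 400 for another 1,000) with symmetric allele-flip mutation at
$2.5\times10^{-5}$ per locus per gamete let drift and mutation reach a
quasi-equilibrium that carries realistic linkage disequilibrium. Because
the equilibrium erases the starting state, initializing at frequency 0.5 is
innocuous. Thirty males and 900 females sampled from the last historical
generation become the pedigree founders ($F_{PED}=0$). Loci that are fixed
in that sample stay in the map but are excluded from allele-frequency sums
in the GRM and BayesB, which keeps matrix shapes stable across generations.

**Meiosis.** Gametes follow the stepwise rule: the first locus of each
chromosome copies a uniformly chosen parental strand; each subsequent locus
switches strand with probability
$r = \tfrac12\,(1 - e^{-2c})$ (Haldane, no interference), $c$ the
adjacent-locus distance in Morgan. A uniform draw exactly at the switch
threshold (a measure-zero event) counts as "no switch". The first haplotype
of every offspring is always the sire's gamete, the second the dam's.

**Traits.** QTL effects are drawn as $|a_j| \sim \Gamma(0.4, 1)$ with
random sign, then rescaled by a single scalar so the founder cohort's QTL
dosage variance equals $h^2 \sigma_p^2$ exactly ($\sigma_p^2 = 1000$;
$h^2 \in \{0.1, 0.3, 0.5\}$) — the QTL carry all of the genetic variance.
Random signs are needed because a one-sided gamma draw would make gains
trivially directional. Two true-breeding-value modes are provided and
config-switchable because they are *not* identical: `genomic` sums QTL
dosages, while the default `recursive` mode uses
$g_i = \tfrac12 g_s + \tfrac12 g_d + w_i$ with
$w_i \sim N\!\big(0, \tfrac14 (1-f_s)\sigma_a^2 + \tfrac14
(1-f_d)\sigma_a^2\big)$, $\sigma_a^2$ frozen at the base-generation genetic
variance and $f_s, f_d$ the parents' pedigree inbreeding. One fresh
$w_i$ is drawn per offspring; the alternative reading that sums separate
sire and dam deviations would correlate full sibs' deviations and is not
implemented. Phenotypes are $y = \mu + g + e$, $e \sim N(0, \sigma_e^2)$,
drawn fresh every generation. The two TBV modes agree in expectation
(tested), so the discrepancy between marker inheritance and pedigree
recursion is visible rather than hidden.

**Genomic prediction.** Marker effects are re-estimated each generation by
BayesB on the rolling two-generation reference (the candidate cohort and
its parents' cohort), with a 20,000/1,000/20 chain at full scale. The
sampler is the classical mixture model — an effect is exactly zero with
prior probability $\pi$ and otherwise carries its own scaled-inverse-
$\chi^2(\nu, S^2)$ variance — implemented as an indicator/per-marker-
variance Gibbs sampler: marker variances remain part of the chain state
(sampled from the prior while a marker is excluded) so the inclusion
indicator has a proper full conditional. This samples the same posterior as
the original Metropolis-Hastings-on-blocks formulation without proposal
tuning. $\pi$ defaults to 0.95, matching the simulated architecture
(roughly 1% of loci are QTL); $\nu = 4.2$, and $S^2$ solves the expected
genetic variance under the prior with an a-priori marker $R^2$ of one half.
Candidates are ranked by $\mathrm{GEBV} = \hat\mu + \sum_j \hat a_j x_{ij}$
and the top 30 males / 900 females are selected, ties broken by id.

**Relationship matrices and inbreeding.** The SNP GRM is VanRaden method 1,
$G = ZZ' / (2\sum_j p_j(1-p_j))$ with $Z$ centered by $2p_j$; allele
frequencies are recomputed in the cohort being analyzed each generation
(a config flag can freeze them instead; the choice is invisible for the
within-cohort comparisons reported here). The ROH matrix is twice the
shared-segment kinship of phased haplotypes: for each pair, the genetic
length in maximal identical stretches of at least 1 cM and 20 markers
(both configurable), averaged over the four strand combinations and
divided by the assayable map length; an individual's own two strands give
the diagonal, so full autozygosity yields 2. True simulated phase is used
directly — no statistical phasing. Pedigree inbreeding uses the tabular
method, which is provably equal to Wright's path counting (and is tested
against a path-enumeration oracle on small pedigrees). The marker-based
inbreeding estimator is reported in two flavours: the per-marker-normalized
form $\frac1m \sum_j (x_j - 2p_j)^2 / (2 p_j (1-p_j)) - 1$ and the
pooled-denominator form that equals the VanRaden diagonal minus one
exactly.

## The mate-allocation optimizer

Plans are encoded as a dam-to-sire assignment vector: every dam appears in
exactly one mating, and sire usage is bounded by a capacity. The search is
a hybrid genetic algorithm with simulated-annealing acceptance: each
population member carries its own scalarization weight $\lambda$ spread
over $[0,1]$ (so the population sweeps the frontier), tournament selection
of size 2, uniform crossover followed by capacity repair, per-dam
reassignment mutation at rate $1/n_{dams}$, and acceptance of non-improving
mutants with geometric temperature decay ($T_0 = 1$, ratio 0.995). An
elitist archive retains every nondominated $(\mathrm{Gain},
\mathrm{Inbreeding})$ plan; the `GM gain` and `GM inb` schemes are its two
endpoints. On instances small enough to enumerate, the endpoints match
exhaustive search (tested over seeded random instances).

A structural property of these objectives is worth knowing: with dam
uniqueness and $\tfrac12$-entries, both objectives depend on the plan only
through per-sire usage counts (the gain is linear and the group coancestry
quadratic in the usage vector, and the dispersion term separates by
parent). Two consequences follow. First, when the capacity equals
$n_{dams}/n_{sires}$ exactly — the balanced barn constraint of the
traditional schemes — every feasible plan ties on both objectives and the
frontier collapses to a point. The genomic schemes therefore run with a
capacity slack factor (`gmCapacityFactor`, default 2) that lets
contributions differ between sires; this is the package's resolution of an
open modelling question, and it is configurable back to 1. Second, given
the optimal usage counts the specific sire-dam pairing is objective-
neutral, so reported plans are one representative of an equivalence class.

## The experiment driver

`runExperiment()` reproduces the five-generation loop: founders mate
randomly (balanced blocks), a second random-mating generation creates the
two-cohort reference, BayesB is fitted, the generation-0 cohort is scored
and its parents selected — all *before* scheme divergence, so every scheme
in a replicate shares founders, burn-in, the first fit, and generation-0
metrics. Each scheme then advances generations of: plan construction,
litters of 10 (5 males / 5 females; odd litters alternate), trait
assignment, BayesB refit, scoring, selection. Reported statistics follow
the evaluation definitions: $\Delta G$ is the mean generation-to-generation
change in cohort-average GEBV (telescoping to $(\bar a_5 - \bar a_0)/5$),
and $\Delta F = 1 - e^{\beta}$ with $\beta$ the OLS slope of
$\ln(1 - F_u)$ on generation number, computed from mean pedigree
inbreeding (marker-based inbreeding is tracked alongside). Replicate
$r$ uses seed $\texttt{baseSeed} + r$.

## Problem sizes: desk and full-scale presets

`fullScalePreset()` mirrors the full study (30,600 markers, 9,000 offspring per
generation, 20,000-iteration chains, a 200 x 800 genetic algorithm, five
generations, five replicates) and is meant for cluster runs.
`deskPreset()` is the package's reduced configuration for interactive work
and the test suite: 2 chromosomes x 50 cM with 200 markers + 10 QTL each,
a 200 to 120 historical population run 200 + 200 generations (sizes chosen
so the founder draw of 5 males / 50 females fits a 1:1 sex ratio and a few
hundred generations of drift produce desk-scale LD), 5 sires / 50 dams,
litter 4, three scheme generations, a 4,000/500/10 chain and a 50 x 200
genetic algorithm. The second foundation generation's parents are chosen
at random because no GEBVs exist before the first fit.

```{r, eval = FALSE}
res <- runExperiment(deskPreset(), h2Values = 0.5, replicates = 5)
formatSummary(res$summary)
```

## What the synthetic data can and cannot show

The generator emulates drift-mutation equilibrium haplotypes, linked
biallelic loci, a sparse additive architecture, truncation selection and
closed-nucleus mating — enough to test every algorithmic component against
oracles and to reproduce directional contrasts (positive assortative
mating accrues inbreeding faster than random mating; selection response is
positive at every heritability). It does not reproduce the full-scale
quantitative results at desk scale: with 5 sires and 50 dams the
between-replicate spread of $\Delta G$ and mean $F_{PED}$ exceeds the few-
percent differences that separate genomic from assortative schemes at full
scale, so paired desk-scale comparisons of those two families are noise-
dominated, and the capacity slack that makes the genomic frontier
non-degenerate lets the max-gain endpoint concentrate matings — which
raises its offspring inbreeding relative to a balanced barn. Real-data
features outside the model: dominance/epistasis, maternal and
genotype-by-environment effects, multi-trait correlations, variable litter
size, overlapping generations, crossover interference, sex chromosomes,
and statistical phasing error (real-data users must supply phased input).

## Numerical choices and degenerate inputs

Locus positions are rounded to $10^{-6}$ cM with ties re-drawn; maps
denser than $10^4$ loci per cM are rejected. Monomorphic markers are
excluded from frequency sums and pinned to zero effect; a reference window
with zero phenotypic variance returns zero effects with a warning rather
than failing the run. $h^2 = 0$ rescales all QTL effects to zero.
Selection and the assortative orderings break GEBV ties by ascending id,
so runs are exactly reproducible. Relationship matrices are symmetrized to
machine precision; frontier nondomination uses a $10^{-12}$ tolerance.
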