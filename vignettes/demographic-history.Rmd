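---
title: "Detecting bottlenecks and dating effective-population-size change from microsatellites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting bottlenecks and dating effective-population-size change from microsatellites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msatdemog)
```

# Scope and data model

`msatdemog` analyses diploid microsatellite genotypes from one or more
populations to ask two questions that arise constantly in conservation
genetics: *has this population recently lost effective size?* and *when did
its major decline happen?* The motivating study design is a pair of
long-isolated carnivore populations (a northwestern and a southern Sierra
Nevada fisher population) with small historical museum samples and larger
contemporary samples, but nothing in the package is specific to that system.

All genotypes live in a `GenotypeDataset`: integer allele sizes in repeat
units per individual and locus, with population, optional deme and optional
sample-year metadata. Working in repeat units (rather than Genepop codes or
fragment lengths) matters because both the stepwise-mutation likelihood and
the M-ratio are defined on the repeat-unit lattice; the per-locus affine map
`size = (code - offset) / motif_length` is applied once at import and
inverted at export. Genepop files cannot carry deme or age metadata, so those
travel in a plain TSV sidecar. A half-missing diploid call is demoted to
fully missing: keeping a lone allele would bias allele counts toward
whichever allele amplifies more reliably.

# Summary statistics

The diversity and differentiation layer is conventional: Nei's unbiased
expected heterozygosity, rarefied allelic richness (default rarefaction size
8 gene copies, i.e. the 4 fully typed individuals a small museum sample may
offer), Weir-Cockerham variance-component estimators for both F~IS~ and
F~ST~ (one coherent framework, combined across alleles and loci as a ratio
of sums, which is stable when rare alleles appear), and an allele-size
analogue R~ST~ built from the same weighted one-way ANOVA so that pairwise
F~ST~ and R~ST~ are directly comparable. Slightly negative estimates are
reported as computed; clamping is left to display code, because tests on
simulated panmixia need to see the undistorted estimator.

Exact tests (Hardy-Weinberg proportions, gametic disequilibrium, genic
differentiation) condition on the observed margins. Where the table space is
small the package enumerates it completely; otherwise it samples the null
directly - random re-pairing of gene copies for the Hardy-Weinberg test,
Patefield sampling (`r2dtable`) for contingency tables. Direct sampling was
chosen over the traditional Markov-chain walk because it is unbiased without
burn-in and its Monte Carlo error is plain binomial; the default is 10^4
tables. Multi-locus p-values combine by Fisher's method, and family-wise
corrections use Rice's sequential Bonferroni (Holm step-down, strict
inequality).

# The coalescent simulator

The synthetic-data engine is a backward-in-time coalescent with mutation,
written in C++:

* **Demography.** `DemographicTrajectory` encodes a single size change:
  N(t) = N0 at sampling, N1 beyond the change time T, with exponential,
  linear, constant or abrupt ("step") interpolation. Waiting times are drawn
  by exact inversion of the closed-form cumulative intensity
  $\Lambda(t)=\int_0^t du/N(u)$, so no time discretization is involved.
* **Mutation.** The two-phase model: with probability `pSingle` a mutation
  moves one repeat unit, otherwise `multistepMin + Geom(q)` units, either
  sign. Two community conventions coexist and both are supported: the
  heterozygosity-excess convention fixes the *variance* of the multistep law
  (variance 12, minimum step 1), while the M-ratio convention fixes its
  *mean* (3.5) with multistep meaning *strictly more than one unit*
  (minimum 2, hence q = 0.4). The minimum-2 reading reproduces published
  M-ratio critical values across sample sizes and theta values to within
  about 0.03, which the minimum-1 reading does not; the choice is exposed as
  `multistepMin` rather than hidden.
* **Structure and serial sampling.** A finite island model (per-deme sizes,
  symmetric migration, optional merge times) is simulated by thinning with
  exact segment-wise rate bounds (N(t) is monotone between boundaries), and
  any gene copy may be sampled at an arbitrary age, which yields temporal
  (historical/contemporary) sample pairs from a single lineage.
* **Forward mode.** For bottleneck power experiments where "breeding
  individuals" semantics matter, a small Wright-Fisher routine evolves a
  gene pool forward through a collapse.

Root allele state is 0 and sizes are offsets; every statistic in the package
is translation invariant, and datasets shift sizes by +100 units only so
they can round-trip through Genepop coding. Under a constant size and strict
stepwise mutation the simulator reproduces the Ohta-Kimura closed form
He = 1 - 1/sqrt(1 + 2 theta) and the pairwise identity
E[(x_i - x_j)^2] = theta, which the test suite checks at Monte Carlo
precision - these two identities pin down both the time scale and the
mutation scale of the engine.

`fisherScenario()` packages the motivating study design as one reproducible
synthetic bundle: two populations isolated for ~1300 generations, each
declining exponentially from N1 = 1800 to N0 = 150 at T = 300 generations;
the contemporary southern population subdivided into three demes (sizes 50,
migration 0.03, separated 150 generations ago - calibrated once so realized
deme-pair F~ST~ sits in the moderate 0.05-0.13 band); historical samples 19
generations (95 years at 5 years/generation) older than contemporary ones;
sample sizes 5/148/16/127 at 10 loci. Two caveats documented here
deliberately: with N0 = 150 the 19-generation temporal F~ST~ is ~0.03
(the serial-coalescent expectation gap/(gap + 4Ne)), far below the ~0.2 the
motivating data show - those values are only compatible with much smaller
recent sizes or sampling noise at n = 5; and the between-population F~ST~ of
the synthetic bundle (~0.35-0.5) sits at or above the top of the observed
0.10-0.37 range, because 300 generations at the declined sizes generate that
much drift on their own. The generator therefore emulates the *design*
(sampling structure, diversity levels, decline geometry), not every printed
statistic simultaneously - they are not mutually consistent under a single
size-change model.

# The three bottleneck detectors

**Heterozygosity excess.** After a bottleneck, rare alleles disappear faster
than gene diversity, so observed He exceeds the equilibrium expectation
*conditional on the observed allele count k*. The conditional null is
simulated: a single multi-locus theta is matched by bisection so that the
summed expected allele count equals the summed observed count, and
coalescent replicates at that theta are kept only when they carry exactly k
alleles. Matching theta per locus to that locus's own k - a tempting
shortcut - inflates the test's size badly (empirically ~0.15 at nominal
0.05), because the k distribution is right-skewed: most loci sit below their
expectation and receive a too-small theta, hence a too-low equilibrium He.
The across-locus statistic is the one-tailed Wilcoxon signed rank on
(observed - expected He). Its classical symmetric-null p-value is itself
anticonservative here (~0.10 empirically) because the conditional He
distribution is left-skewed, so the reference distribution of the Wilcoxon
statistic is instead taken from the same simulations (one simulated He per
locus per pseudo-dataset). The calibrated test holds its nominal 5% size
within binomial error in the acceptance suite; the classical p-value is
still reported as `p.classical` for comparison with older software. Loci
with a single allele carry no information and are dropped with a message.

**Mode shift.** Allele proportions pooled across loci are binned into ten
frequency classes of width 0.1; at equilibrium the rarest class is modal
(L-shape), and a verdict of "shifted" requires the rare-class count to be
*strictly* smaller than some higher class (ties count as not shifted - the
conservative reading). The test refuses groups of fewer than 30 individuals,
where its type-I error is known to be poor; that is why historical museum
samples typically get no mode-shift verdict. The package's power experiment
(`modeShiftPower`) holds a Wright-Fisher population of 20 breeders for a
chosen number of generations after an equilibrium start. Power is strongly
time-dependent: a collapse held only ~5 generations is flagged in well under
half of replicates, and the commonly cited >= 0.8 detectability of a
20-breeder bottleneck is reached only a few dozen generations after
collapse (and earlier for smaller bottlenecks). The power experiment
defaults to the severe early condition rather than the favourable one.

**M-ratio.** M = k/s per locus, with s = (size range in repeat units) + 1,
the number of occupiable states - this bounds M in (0, 1], which a bare
range denominator would not. The multi-locus value is the unweighted mean
over polymorphic loci. Because a bottleneck erases alleles but barely
shrinks the range, M falls after a decline and recovers only over hundreds
of generations. Significance comes from `mCritical`: the 5% quantile of the
multi-locus mean M over equilibrium replicate datasets at a given theta =
4 Ne mu (default 10,000 replicates; fewer than 1,000 triggers a stability
warning), with mu entering only through theta (the conventional
mu = 5e-4 is kept in the defaults for documentation parity). Since the
pre-decline Ne is unknown, the battery evaluates a theta grid (1, 2, 5, 10,
i.e. pre-decline Ne of 500-5000 at mu = 5e-4).

`bottleneckBattery` runs all three detectors for a group, and - because
pooling differentiated demes distorts them (a Wahlund deficit of
heterozygotes masquerades as missing heterozygosity excess and vice versa) -
repeats them per deme when deme labels exist.

# The size-change model and its sampler

The Bayesian stage models one change of effective size: coalescent
genealogies per locus under N(t) (exponential or linear interpolation),
strict stepwise mutation along branches, and theta = 2 N0 mu, so the
per-locus mutation rate is mu_l = theta_l / (2 N0). The branch transition
probability of a net displacement d over a branch with expected mutation
count m is the Skellam form e^{-m} I_{|d|}(m), evaluated in the log domain
with a series fallback where the scaled Bessel function underflows. Priors
are hierarchical log-normals on log10(N0), log10(N1), log10(T in
generations) and log10(theta): each has a normal prior whose mean and SD are
themselves drawn from hyperpriors, the SD truncated at zero; per-locus
thetas share one prior mean and SD. Defaults are wide (means 10^3 for sizes
and time, 10^-0.5 for theta, a decade of spread) and fully overridable; a
non-hierarchical mode fixes the prior at its hyperprior means. T is
parameterized in generations throughout; conversion to years (and the
addition of a historical sample's age) is purely presentational and happens
in `calibrateTime`/`summarizePosterior`.

The Metropolis-Hastings move set, per sweep:

* node-time slides (uniform between the bracketing nodes) and a
  multiplicative root-gap move, scaled in number with tree size - large
  genealogies barely mix otherwise;
* "wide exchange" subtree swaps (symmetric, validity-checked both ways), to
  move through topology space;
* integer random walks on internal allele states;
* log10-scale random walks on N0, N1, T and each theta_l;
* a *joint scale shift*: adding one log10 delta to N0, N1, T and all node
  times leaves the likelihood exactly invariant (the coalescent density
  change cancels the time Jacobian, and mu rescales against branch
  lengths), so the move is accepted on the prior ratio alone and carries the
  chain along the scale ridge that dominates this model's autocorrelation;
* an N0/N1 exchange, which lets the chain cross between decline-like and
  expansion-like modes;
* Gibbs updates for the hierarchical prior means and random-walk updates for
  the truncated prior SDs.

Step sizes adapt toward ~30% acceptance during the first 20% of the run
only and are frozen afterwards, so the recorded portion is a fixed-kernel
chain. Genealogies initialize from a coalescent draw under the starting
trajectory with internal states copied from a random child (valid support
for any mu > 0); demographic parameters start at moment anchors (per-locus
theta from the heterozygosity inverse of the stepwise equilibrium, the
N1/N0 ratio from the ratio of size-variance to heterozygosity scale) -
initialization affects burn-in length, not the stationary law. With zero
polymorphic loci the chain samples its prior, and the test suite checks
exactly that (Kolmogorov-Smirnov distance to iid hierarchical prior draws),
the standard end-to-end correctness check for an MCMC implementation.

Desk-scale defaults (2 x 10^4 sweeps thinned to 2 x 10^3 records, 3-5
replicate chains) are sized for synthetic datasets of tens of individuals
and ten loci, where the acceptance suite demonstrates: prior recovery, and
on simulated 150-vs-2000 declines 300 generations old (40 individuals, 10
loci) a posterior mass on r = N0/N1 < 1 above 0.9 with at least substantial
Bayes-factor support in >= 80% of replicates. Real datasets should scale
the run lengths up (the settings are arguments, not constants) and always
use replicate chains gated by the multivariate potential scale reduction
factor.

# Post-processing

`trimAndPool` drops the first 10% of each chain for diagnostics and pools
the final 50% across chains for summaries (five 20,000-record chains pool
to 50,000 records). `mpsrf` implements the Brooks-Gelman multivariate
potential scale reduction factor, (n-1)/n + ((m+1)/m) lambda_1 with
lambda_1 the top eigenvalue of W^{-1}B/n; the default gate is 1.1 and
exceeding it warns rather than fails, since a slightly rough chain still
carries information. Summaries are the mode (Gaussian-kernel density,
reference-rule bandwidth) and shortest 90% interval (sorted-window scan),
both computed on the log10 scale the chains are stored on and
back-transformed - the posteriors are near log-normal, and an HPD computed
on the natural scale would be dominated by the heavy right tail. The Bayes
factor for decline is posterior odds over prior odds of the *event*
r < 1 - invariant to reparameterization - with prior odds taken from direct
sampling of the hierarchical prior (no closed form exists), add-one
continuity and an explicit bound flag when a cell is empty, and the
conventional support categories (0.33/3/10). The fraction of the pooled
time posterior older than a reference age (e.g. a settlement horizon) is
reported when asked.

# Numerical and degenerate-input policy

* Monomorphic loci: He = 0 and A = 1 in diversity tables; excluded from the
  M-ratio mean and the excess test; Hardy-Weinberg p = 1 flagged
  untestable.
* Exact-test ties: tables are compared on log-probabilities with a 1e-9
  absolute tolerance so ties count as "at least as extreme".
* Monte Carlo p-values use add-one continuity, so they are never exactly 0.
* The intensity inversion uses log1p/expm1 forms and degenerates cleanly
  (exponential with N1 = N0 is constant; T = 0 means the ancestral size
  everywhere).
* -Inf log-likelihoods (negative branch, impossible displacement at mu = 0)
  are propagated, never NaN.
* All stochastic stages take explicit seeds; dataset simulators derive
  per-locus sub-seed streams from one master seed so any locus can be
  regenerated in isolation.

# Known limitations

* The simulator has no recombination, selection or allele-size bounds; no
  size caps means simulated ranges can exceed what fragment-length assays
  would resolve.
* The inference model fits one size change per population and no migration;
  structured populations must be handled by sampling design (analyzing
  demes separately or sampling evenly across them), as the battery does.
* The heterozygosity-excess calibration conditions on a single shared theta
  across loci; panels with order-of-magnitude mutation-rate heterogeneity
  across loci would stress that approximation.
* Passing the synthetic-data checks shows the machinery is correct under
  the model; real microsatellite data add genotyping error, null alleles
  and deviations from the two-phase model that no synthetic test covers.
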