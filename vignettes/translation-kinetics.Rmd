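---
title: "Deriving translation kinetics from ribosome profiling with riboTASEP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving translation kinetics from ribosome profiling with riboTASEP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboTASEP)
```

## The problem

Ribosome profiling (ribo-seq) counts sequencing reads from ribosome-protected
mRNA fragments; together with matched RNA-seq it measures, in arbitrary
units, how densely ribosomes populate each transcript and where along the
coding sequence they dwell. riboTASEP turns such codon-resolution count data
into quantitative translation kinetics: per-codon elongation rates shared
across the transcriptome and per-gene initiation rates, inferred by fitting a
stochastic model of translation to the measured densities.

The package assumes counts that are already assigned to codons (footprints by
their A-site, mRNA fragments by their centre). Read trimming, alignment and
A-site offset calibration are upstream contracts, not part of this package.

## Segment trees: multi-scale density measurements

Counting reads per codon is too noisy for quantitative work; counting them
per CDS hides all positional signal. The compromise implemented in
`buildSegmentTree()` is a recursive binary partition of each CDS. For a
segment $[l, r]$ the per-replicate densities are

$$d^{ribo}_{[l,r]} = \frac{R_{[l,r]}}{L_{[l,r]} N_R}, \qquad
  d^{mRNA}_{[l,r]} = \frac{M_{[l,r]}}{L_{[l,r]} N_M},$$

with $R, M$ the segment read counts, $L_{[l,r]} = r - l + 1$ the length and
$N_R, N_M$ the library sizes. Their ratio $\omega = d^{ribo}/d^{mRNA}$
estimates the per-transcript ribosome density; computing the mRNA density per
segment (rather than per gene) cancels local sequencing bias shared between
the two assays. Cut points divide the combined (ribo + RNA, all replicates)
reads as equally as possible between the two children, ties going to the
smaller cut position; segments with no reads at all split at the midpoint.

Recursion continues only while reliability holds: a node is split only if
**both** prospective children have at least `min_reads` (default 128) summed
reads in each assay separately and at least `min_segment_codons` (default 20)
codons. The thresholds could equally be read as applying to the segment
itself before splitting; we require them of the children so that every stored
node is reliable — nothing below the floor is ever retained. Half-splits
(keeping only one passing child) are never created. Genes flagged as dubious
or mitochondrial are excluded upstream via an exclusion list; the builder is
annotation-agnostic.

A density-dependent bias can affect ratio measurements; `correctDensityBias()`
exposes a pluggable hook for removing it. The default is the identity. The
shipped reference method isotonically detrends each replicate's deviation
from the across-replicate mean log-ratio against log density. Only the
*differential* (between-replicate) component of such a bias is identifiable
from replicates alone; a bias component common to all replicates is
indistinguishable from signal, which is a structural limit of any
replicate-based correction, and the main reason the hook is pluggable.

## The log-normal error model

Inter-replicate errors of sequencing-derived densities are well described as
log-normal. Each segment's ratio is modelled as
$\ln\mathcal{N}(\mu_j, \sigma_j)$: `segmentMu()` estimates $\mu_j$ as the log
of the geometric mean of the replicate ratios. Per-segment $\sigma_j$ cannot
be estimated from two replicates, so segments from all genes are pooled into
`n_length_groups` (default 10) equal-content length groups
(`makeLengthGroups()`; edges at quantiles of the length distribution, snapped
between distinct lengths so assignment is unique). Per group,
`estimateSigma()` collects inter-replicate errors
$e = \ln(\omega^{(1)}/\omega^{(2)})$ over all unordered replicate pairs and
fits a centred normal, $\hat\sigma_{ire} = \sqrt{\overline{e^2}}$ (a robust
$1.4826 \cdot \mathrm{MAD}$ variant is available). Because the log-ratio of
two iid log-normal measurements has twice the log-variance of a single one,
the stored group shape is $\sigma^{group} = \hat\sigma_{ire}/\sqrt{2}$.
Groups with fewer than 10 segments borrow the nearest filled group's value.
$\sigma$ is floored (default $10^{-3}$) because the objective weights
segments by $1/\sigma^2$.

With duplicate measurements, pooling all replicate pairs versus using one
fixed ordered pair coincide up to sign, so the pooled definition is used
throughout.

## The ℓ-TASEP model and its simulation

Translation is modelled as a totally asymmetric simple exclusion process
with extended particles: gene $g$ is a lattice of $S^g$ codons; ribosomes
cover $L$ codons (default 10, matching the footprint size), initiate at rate
$k_0^g$ when codons $1..L$ are free, hop $i \to i+1$ at codon-specific rate
$k_i$ when codon $i+L$ is free, and detach from the last codon at the stop
codon's rate. Elongation rates are codon-specific and shared across genes;
termination rates default to 1. Conventions fixed here (the physics does not
depend on where the A-site sits within the footprint, but an implementation
must choose): the A-site is the 5'-most covered codon; footprints may
overhang the 3' end so termination is always reachable; occupancy time is
credited to the A-site codon only, matching how reads are assigned; the free
ribosome pool is not modelled ($o_0 \equiv 1$).

`simulateGene()` samples the process in continuous time with an
Erlang-accelerated scheme. With total attempt rate
$k = k_0 + \sum_i o_i k_i$ and enabled (state-changing) rate $k_+$, the
number of attempts until the next state change is geometric with success
probability $p_+ = k_+/k$ (support $1, 2, \dots$ — the state-changing
attempt itself counts), the elapsed time is Erlang with that shape and rate
$k$, and the executed event is drawn from the enabled events with
probability proportional to its rate — the conditional law of the naive
categorical draw given that a state change occurred, so the scheme is
distributionally identical to the naive rejection algorithm while doing work
only for state changes. When nothing is ever blocked, $p_+ = 1$ and the
scheme degenerates to the standard Gillespie algorithm. The naive rejection
scheme is also shipped (`method = "rejection"`) and serves as an independent
oracle in the tests, alongside `exactOccupancy()`, which solves the
stationary master equation by state enumeration for small lattices.

Each run discards a burn-in until 1000 termination events (with a defensive
event cap, default $10^8$, for near-zero-flux genes), then executes up to
$10^7$ state changes, checking segment-mean occupancies first after
$5 \times 10^5$ steps and every $10^6$ thereafter, stopping early when the
maximum absolute change between consecutive checks drops below
$\epsilon = 10^{-3}$. Convergence is monitored on the gene's own tree
segments when supplied, else on CDS deciles. Occupancy is
$n_i = T_i/T$ and the protein production rate $J = F/T$.

Per-gene RNG streams are derived from (master seed, gene id), so
`batchSimulate()` results are independent of gene order and of how a batch
is partitioned across workers.

## Scoring models against measurements

For segment $j$ with prediction $N_j$ (the arithmetic mean of $n_i$ over the
segment) the objective sums

$$\psi = \sum_{g}\sum_{j \in J^g}
  \Big[-\frac{(\ln N_j - \mu_j + \ln C)^2}{2\sigma_j^2} - \ln N_j\Big],$$

the segment-wise log-normal log-likelihood with constants dropped. $C$ is
the unknown scale between model occupancy units and measurement units; the
maximizing value has the closed form

$$\ln C = \frac{\sum_j \sigma_j^{-2} (\mu_j - \ln N_j)}
               {\sum_j \sigma_j^{-2}},$$

implemented in `optimalLnC()` and verified in the tests against an
independent numeric maximization. Two numerical choices are worth noting:
segment means of exactly zero (possible at finite sampling) are floored at
$10^{-8}$ before taking logs, and the $-\ln N$ Jacobian term is kept exactly
as it appears in the density, which makes $\psi$ values comparable only
within a fixed tree and error model. `evaluateModel()` accepts occupancy
profiles from any source, so external models can be scored on the same
footing.

## Initiation-rate approximation

Fitting thousands of per-gene initiation rates inside the optimizer is
infeasible; instead they are *approximated* from the data for any candidate
set of elongation rates. A proposed scaling factor $\tilde C$ (the same
object as $C$, but supplied up front, e.g. from ribosomes and mRNA molecules
per cell — see `proposedLnC()`) converts each gene's root-segment ratio into
a dimensionless occupancy target $\exp(\mu_{root} - \ln\tilde C)$.
`approxK0()` then finds the $k_0$ whose simulated mean density matches the
target. The inversion starts from the no-interference closed form
($n_i = k_0/k_i$, so $k_0 = \mathrm{target}/\overline{1/k_i}$; exact in the
initiation-limited regime this data occupies) and, when refinement
simulations are enabled, bisects on $\log k_0$ against simulated density —
valid because simulated density is nondecreasing in $k_0$, and stable
because all verification runs of a gene share one seed. Unreachable targets
saturate at the bracket top (default $100 \times \min_i k_i$) and are
flagged rather than erroring. The number of refinement simulations is
configurable: the fitting inner loop uses 0 (pure closed form), final
evaluations use 12. The cheap estimator is deliberately simple and
documented as such; it preserves the density-matching contract at low cost,
which is what the surrounding machinery needs.

## Fitting

`fitRates()` maximizes $\psi$ over log elongation rates with CMA-ES
(implemented in `cmaES()` with the standard rank-1 + rank-$\mu$ updates and
cumulative step-size adaptation; no CMA-ES implementation existed in the
package's dependency environment, and the algorithm is standard). TASEP
output is invariant to a common rescaling of all rates together with $k_0$,
so one codon's rate (default GAA, chosen for its ubiquity) is fixed at its
starting value to pin the scale. In `mode = "elong"` all other codons
present in the data are searched (codons absent from the training genes are
unidentifiable and keep their starting rates — on the full 61-sense-codon
yeast-scale problem this is the standard 63-parameter search including stop
codons); `mode = "init_only"` keeps the starting elongation rates and only
re-approximates initiation rates. Candidates within a generation share a
simulation seed (common random numbers reduce the noise seen by the ranking
step) and seeds are fresh across generations so the search cannot overfit
one noise realization; the final incumbent is re-evaluated at the full
simulation budget.

Cross-validation (`crossval()`) uses greedily balanced folds — genes sorted
by segment count, each joining the fold with the smallest segment total,
then gene count, ties shuffled deterministically — and by default trains on
one fold while testing on the rest (the inverted split keeps fitting cheap
on large data; `invert = TRUE` gives the conventional split). Test-time
initiation rates are re-approximated from the test genes' own trees.
`geomMeanRates()` combines fold fits into a consensus rate set for
subsequent initiation-only fitting on all data.

## Synthetic data: what it emulates and what it does not

`generateSynthData()` is the package's test harness: it draws codon
sequences and initiation rates, computes true occupancies with the
simulator at full budget, and samples counts. Footprint counts at codon $i$
are Poisson with mean
$\mathrm{ribo\_depth} \cdot m_g \cdot n_i \cdot e^{\varepsilon}$, RNA counts
Poisson with mean
$\mathrm{rna\_depth} \cdot m_g \cdot e^{\varepsilon'} \cdot \mathrm{pos}_i$,
where $m_g$ is a log-normal per-gene mRNA abundance,
$\varepsilon, \varepsilon'$ are gene-level, per-replicate, per-assay normal
draws of sd `replicate_noise_sigma` (default 0.3 — this produces the
log-normal inter-replicate errors the error model assumes, with single-
measurement ratio shape $\sqrt{2} \times 0.3$), and $\mathrm{pos}_i$ are
unit-mean gamma factors (RNA coverage uniform in expectation; a shared-bias
knob exists to check that the ratio cancels biases common to both assays).
Footprint means scale with $m_g$, so the density ratio estimates
per-transcript occupancy up to one dataset-wide scale, whose true value is
reported as `lnC_true`. Poisson (rather than multinomial) sampling per
position keeps the contract simple; realized totals become the library
sizes. Default depths (500/20 per codon per unit abundance) put typical
genes comfortably above the 128-read threshold, and default initiation
rates (log-uniform 0.005–0.1 against unit elongation rates) keep genes in
the initiation-limited regime that real yeast data occupies.

Codon usage is homogeneous by default; `usage_block_codons` switches on
regional usage (each block of that many codons draws its own usage from a
Dirichlet centred on the global frequencies), mimicking the regional
codon-usage structure of real transcripts such as 5' ramps.

What the generator does *not* emulate: sequence-specific ligation and PCR
biases, ribosome drop-off and pausing, 5'UTR scanning, finite ribosome or
tRNA pools, or codon-context effects on elongation. Passing tests therefore
demonstrate correctness of the inference machinery under the model's own
assumptions, not robustness to every artefact of real ribosome profiling
libraries.

## Validation scales

The test suite validates the simulator against exact stationary solutions
of enumerated master equations (lattices up to $S = 8$, $L \le 3$), against
the two-state closed form for a single site, and against the naive
rejection scheme on 100-codon genes; the closed-form $\ln C$ against
numeric maximization; threshold and cut-point behaviour against exhaustive
search; error-model recovery at 3000+ segments per group; initiation-rate
inversion on 30 forward-simulated genes; and end-to-end rate recovery on a
deliberately scaled-down study — 20 genes of 300 codons over an 8-codon
alphabet with true rates spanning 4-fold, CMA-ES with population 12 and a
few dozen generations at reduced inner simulation budgets. These problem
sizes are the package's own choice of desk-scale validation: large enough
to exercise every code path and to make parameter recovery measurable,
small enough to run routinely. Inferences on transcriptome-scale data use
the same code paths with the default full budgets.

The recovery study's design deserves a note on identifiability. Because
initiation rates are re-approximated per gene for every candidate rate set,
gene-level average density carries no information about elongation rates;
only *within-gene* variation in codon composition between segments does.
At transcriptome scale (tens of thousands of segments) the composition
variation of homogeneous random sequences suffices, but at 20 genes it is
far too weak for the measurement noise it competes with. The recovery
experiment therefore generates sequences with regional codon usage
(`usage_block_codons = 25`, `usage_alpha = 4`) and uses a replicate noise
of 0.1 — data whose positional structure and noise are scaled in proportion
to the data volume. Both knobs are properties of the validation study, not
of the generator's defaults.

## Known limitations

- The density-dependent bias correction can only remove between-replicate
  differential bias; the original procedure this hook stands in for is not
  part of the package.
- The cheap density estimator inside `approxK0()` is a no-interference
  approximation; in strongly elongation-limited regimes the bisection falls
  back on simulation entirely, at higher cost.
- $\psi$ values are only comparable for a fixed segment tree and error
  model; no absolute goodness-of-fit scale is implied.
- The error model assumes segment-level log-normal noise; count-level
  (Poisson) noise at the reliability floor adds a small upward bias to
  $\hat\sigma$ for the shortest groups.
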