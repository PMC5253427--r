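---
title: "Models and methods behind landgenr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind landgenr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landgenr)
```

This vignette explains the statistical machinery the package implements,
the conventions and numerical choices it commits to, what the synthetic
generator does and does not emulate, and the design decisions that were
genuinely open. It states no empirical number that the test suite or
`scripts/acceptance.R` does not itself compute.

# The scientific problem

Individually georeferenced animals from a handful of local populations are
genotyped at codominant microsatellite loci. The questions are (i) how much
recent directional gene flow connects the local populations, and (ii) which
landscape hypothesis — no spatial structure, isolation by geographic
distance (IBD), isolation by landscape resistance (habitat suitability or
predation risk, consumed as cost rasters), or isolation by anthropogenic
barriers (roads, cutblocks, other linear features) — best explains genetic
distance and relatedness among individuals, overall and within
behaviour-defined subgroups (seasonally migratory vs. sedentary animals,
with unclassified animals only in the "all" group).

All coordinates are planar metres in one shared projection; the package
does no geodesy. Rasters follow the ESRI ASCII grid registration: row 1 is
the top row, cell (r, c) centred at
`(x0 + (c − 0.5)·h, y0 + (nrow − r + 0.5)·h)`.

# Genetic distances

**Rousset's a_r between individuals.** For locus $l$, $Q_{w,l}$ is the
probability that the two gene copies *within* an individual are identical
in state, averaged over **all** individuals scored at that locus (the
sample-wide reference, matching the cited software's default; a
focal-pair-only reference is undefined whenever both members are
heterozygous), and $Q_{ij,l}$ is the mean identity over the four
between-individual gene pairs. Then

$$a_r(i,j) \;=\; \frac{\sum_l \big(Q_{w,l} - Q_{ij,l}\big)}
                     {\sum_l \big(1 - Q_{w,l}\big)},$$

with both sums restricted to loci where *both* individuals are scored, so
the estimator stays a ratio over a common locus set (missing data are
dropped pairwise). Negative values are reported as computed — truncation
would bias the downstream correlation analyses. The degenerate case where
every usable locus has $Q_{w,l}=1$ (everybody homozygous for one shared
allele) is an error, not a zero.

**Weir–Cockerham θ between populations.** For each population pair the
standard variance components $a$ (among populations), $b$ (among
individuals within populations) and $c$ (within individuals) are summed
over alleles and loci and combined as $\hat\theta = \sum a / \sum(a+b+c)$.
Monomorphic loci contribute nothing; negative estimates are retained. The
test suite checks this implementation against an independently coded
gene-level ANOVA mean-squares formulation — two algebraically different
routes to the same estimator.

**ML relatedness.** For each pair the likelihood of the IBD coefficients
$(k_0,k_1,k_2)$ (probability of sharing 0/1/2 genes identical by descent at
a locus) uses the standard unordered genotype-pair probabilities given
pooled allele frequencies; $\hat r = k_1/2 + k_2$. The optimiser is a
coarse simplex grid (step 0.05) followed by deterministic pattern-search
refinement; grid ties break toward larger $k_0$ (the less-related
explanation). The genealogical constraint $k_1^2 \ge 4k_0k_2$ is *not*
imposed, matching the cited software's default. With
`null_alleles = TRUE`, a per-locus null allele is appended with frequency
from the Brookfield heterozygote-deficit estimator
$\max\{0, (H_e-H_o)/(1+H_e)\}$ before likelihoods are evaluated; the toggle
isolates the assumption, default off. Significance re-draws both
individuals' alleles from the pooled frequencies (locus structure and
missingness preserved), $p = (1 + \#\{r^\ast \ge r_{obs}\})/(B+1)$ at
$B = 5000$ by default. Because $\hat r$ is a boundary MLE with an atom at
exactly 0 under the unrelated null, this p-value is valid but
conservative at the atom; the test suite therefore checks validity of the
reported p and distributional uniformity of its random-tie-broken version.

The reporting categories follow the published translation exactly: 0
unrelated, (0, 0.25] weak, (0.25, 0.5] moderate, (0.5, 1) high, 1 full.

# Landscape distances

*Euclidean / IBD:* straight-line distances, natural log for the IBD model;
a coincident pair under the log transform is an error naming the pair. The
log matrix's diagonal is set to 0 by convention and never enters any
vectorized statistic. Only the Euclidean matrix is log-transformed by
default; any cost matrix can be log-transformed explicitly by the caller
(used in the model-selection validation below).

*Least-cost paths:* individuals snap to their raster cell centre; the
raster becomes an 8-connected lattice with edge weight
`mean(cost_a, cost_b) · cellsize` (× √2 diagonally), and pairwise cost is
the Dijkstra shortest-path total (delegated to igraph; the test oracle is
an independent hand-coded Dijkstra over an explicit edge list). No-data
cells leave the graph; a disconnected pair is `NA` and propagates by
pairwise deletion, with a flagged count.

*Barrier crossings:* the number of **distinct features** whose geometry
intersects the open segment between two individuals — a winding road
crossed twice counts once, because the hypothesis concerns how many
barriers separate the pair, not the crossing count. Tangent contacts and
endpoints exactly on a feature count; for polygons, boundary contact or an
endpoint inside counts. These tie-breaks are declared so tests are
deterministic.

# Mantel machinery and reciprocal causal modelling

All matrix statistics vectorize the strict lower triangle, excluding the
diagonal. The simple Mantel statistic is the Pearson correlation of the two
vectors; the null jointly permutes row/column labels of the predictor
matrix; `p = (1 + #{r* ≥ r_obs})/(B+1)` (mirrored/two-sided per tail), so
the smallest attainable p is `1/(B+1)`. For n ≤ 9 with enough requested
permutations the full n! enumeration is used and p becomes an exact count
including the identity. Missing entries are deleted pairwise inside every
permutation.

The partial Mantel test residualizes both `vec(G)` and `vec(A)` on
`vec(C)` by simple linear regression and correlates the residuals. The
permutation scheme permutes the labels of the *residualized predictor
matrix* (residual-matrix permutation, Legendre's "method 3") — it
preserves the control structure and is standard in the causal-modelling
literature; an identical or perfectly collinear control is an error.

Reciprocal causal modelling runs both partial tests for every ordered model
pair: `entry[i, j] = r(G, M_j | M_i)` with principal models in columns and
alternatives in rows. A model is **fully supported** iff its column is all
positive (it survives every alternative) *and* its row is all non-positive
(no alternative survives it); column-only gives **partially supported**.
The verdict uses the sign of r only — the published decision rule speaks of
positive and negative values, not significance — while per-cell permutation
p-values are reported alongside for inspection.

# Distance-based linear models

The response matrix is Gower-centred: $A = -D^2/2$,
$G = (I - \tfrac{1}{n}11')A(I - \tfrac{1}{n}11')$. For a hat matrix $H$ of
intercept + predictor columns ($q$ added columns),

$$F = \frac{\mathrm{tr}(HGH)/q}{\mathrm{tr}((I-H)G(I-H))/(n-q-1)},
\qquad \%\mathrm{var} = 100\,\frac{\mathrm{tr}(HGH)}{\mathrm{tr}(G)}.$$

This reduces *exactly* to the classical regression/ANOVA F for a
univariate Euclidean response — the module's primary oracle, asserted to
1e-9 — and is cross-checked against vegan's `adonis2`. Categorical
predictors are dummy-coded against a first-level reference; declared groups
(coordinates, vegetation PCs) enter as one block with $q$ = block size, so
a group is one table row with one F. Non-Euclidean genetic distance
matrices can carry negative eigenvalues; the trace arithmetic is used
as-is, which is why conditional %var can legitimately be negative and is
not floored.

Permutation schemes: marginal tests permute the units of $G$; conditional
and sequential tests permute the units of the reduced-model residual matrix
$R = (I-H_{cov})G(I-H_{cov})$ and recompute the added-F on the permuted
$R$ (residual permutation under the reduced model). Forward selection
greedily adds the predictor maximising added $\mathrm{tr}(HGH)$, reporting
added F, added %var and a conditional p per step; by default all
predictors are entered (the shape of the published sequential tables), and
a predictor collinear with what is already entered contributes 0 with a
flagged row. Population-level analyses treat the two directions of the
migration matrix as separate responses, converted to dissimilarities as
`1 − m` (declared; the source analysis says only that they were response
matrices), with mean inter-centroid distance as covariate.

# The recent-migration sampler

The model is the Wilson–Rannala recent-migration model: each sampled
individual in population $i$ has latent ancestry — non-migrant, first-
($P = m_{ij}$) or second-generation migrant from $j$
($P = 2 m_{ij} m_{ii}$) — and its genotype likelihood per locus is
Hardy–Weinberg-with-inbreeding in the source frequencies for gen-0/1
(homozygote $p_a^2(1-F)+p_aF$, heterozygote $2p_ap_b(1-F)$), or a one-gene-
from-each-pool product for gen-2 (no inbreeding term). The total
immigration constraint $\sum_{j\ne i} m_{ij} \le 1/3$ guarantees the
ancestry prior is a proper distribution (since
$\sum_j m_{ij}(1+2m_{ii}) \le 1$); the prior on each row of $m$ is uniform
over that constrained simplex, $F_i$ uniform on [0,1], allele frequencies
Dirichlet(1).

One iteration = one Gibbs re-assignment of a random individual's ancestry
(over the $1 + 2(K-1)$ states) plus one random-walk proposal from one of
three families: an $m$ entry (reflected in its feasible interval), an $F$
(reflected in [0,1]), or a frequency move shifting mass between two alleles
at one locus. With no usable loci the sampler demonstrably reproduces the
prior (off-diagonal mean 1/9 at K = 3, checked against direct Monte-Carlo
draws from the constrained simplex) — a whole-sampler correctness
guardrail, since the exact proposal mechanics of the original program are
not described in the source material.

The documented default plan is the full published protocol (3 chains of
3·10⁶ iterations, 10⁶ burn-in, thinning 2000, deltas tuned by pilot
bisection into the 40–60% acceptance window); the package's own tests use
shorter explicit plans (300k iterations) at which parameter recovery of a
planted rate is verified. Summaries pool thinned post-burn-in samples
across chains: means, equal-tailed 95% credible intervals, gene-flow
classes (m < 0.030 low, 0.030–0.100 moderate — both printed boundaries
assigned to the moderate class by declared convention, since the source
prints open inequalities on both sides — and > 0.100 high), net emigration
(outgoing minus incoming, summing to zero over populations), and a split
R-hat per entry with a warning above 1.2. All randomness, in R and in the
compiled samplers, flows from R's RNG, so `set.seed()` gives bit-identical
runs.

# The synthetic-data generator

`simulate_genotypes()` is a forward-time allele-frequency simulator: initial
frequencies per locus from a symmetric Dirichlet (independently per
population by default, or one shared ancestral pool with
`shared_initial_freqs = TRUE`); each generation, migration mixes
frequencies ($p_i' = \sum_j m_{ij} p_j$, with $m$ explicit, island, or
$\propto e^{-(d/\lambda)}$ in Euclidean or least-cost distance,
row-normalised to a total immigration ≤ 1/3 so synthetic truth stays
inside the estimator's prior support) and drift resamples $2N$ gene copies
multinomially. The final generation is sampled into diploid individuals
(Hardy–Weinberg within population), scattered around their centroid,
labelled migratory/sedentary/unclassified i.i.d. with the study's observed
proportions (126:21:60) as defaults.

Two optional modes serve specific validations. `migrant_sampling = TRUE`
runs the generations as pure drift and applies the migration matrix as
individual-level migrant ancestry at the sampling step — the
recent-migration estimator's own data model, which is the correct
data-generating process for testing *that* estimator (its estimand is the
fraction of sampled individuals with recent migrant ancestry, not a
per-gene-copy mixing rate). `sedentary_structured = TRUE` maintains a
parallel frequency track with migration scaled down for sedentary
individuals, reproducing the qualitative migratory/sedentary contrast in
spatial structure.

What the generator does **not** emulate: mutation (no mutation model;
acceptable at the simulated timescales), overlapping generations,
selection, telemetry-based behaviour classification (labels are i.i.d.
draws), genotyping error and allele dropout (only missingness via
`missing_rate`), and realistic cartography (landscapes are Gaussian cost
bumps plus an optional wall with one gap and straight-line barrier
features). Passing tests therefore validate the estimators under their own
assumptions; they do not certify behaviour under mutation-drift
equilibrium, scoring artefacts or real movement ecology.

Default study shape: 8 local populations on a ring, 207 individuals, 14
loci with 5–15 alleles, N = 100, 100 generations, distance-decay migration
— the sampling design of the motivating study, at desk scale.

# Validation experiments and their problem sizes

The acceptance suite (and `scripts/acceptance.R`) runs five experiment
families; sizes were chosen to make each check sharp at desk scale and are
stated here as the package's own design:

* **Exact oracles** — full 5! Mantel enumeration; hand-coded Dijkstra on
  rasters up to 20×20; classical-F reduction at n = 30; a hand-counted
  4-individual/2-locus a_r fixture.
* **Calibration** — 200 replicates at n = 20 with 999 permutations for
  Mantel, partial Mantel and DISTLM (plain KS uniformity), and the
  validity + tie-randomized-uniformity pair for the relatedness
  randomization described above.
* **Closed forms** — 16-deme island model at N = 100, m = 0.01 for 120
  generations, 30 sampled per deme, 20 replicates: mean pairwise θ is
  compared with the infinite-island expectation 1/(1+4Nm) = 0.20 within
  ±0.05, a band set from theory because a finite K-deme system has
  expectation 1/(1+4Nm(K/(K−1))²) ≈ 0.18 at K = 16; and heterozygosity
  decay (1 − 1/(2N))^t in a closed N = 50 population over 30 generations.
* **Migration recovery** — 3 populations × 50 individuals, 14 loci,
  independent Dirichlet ancestry (strong divergence), migrant-ancestry
  sampling with a planted m₁₂ = 0.20 (and 0.05 elsewhere, keeping every
  row inside the 1/3 constraint); 20 fits at 300k iterations check 95%-CI
  coverage of the planted rate, and a zero-migration fit must collapse to
  the boundary (all off-diagonals < 0.03).
* **Model-selection recovery** — 16 populations hugging both sides of a
  high-cost wall whose single gap sits at the top edge, so cost distance
  and straight-line distance decouple for most cross-wall pairs; recent
  divergence (120 generations, N = 60) from one shared ancestral pool;
  gene flow $\propto e^{-LCP/4000\,m}$. Candidate models are the true
  surface's log cost distance, log Euclidean distance and a decoy surface
  of random cost bumps. Two analytical facts shaped this design: if
  genetic distance were exactly linear in the true cost distance, the
  partialled alternative's expected correlation is exactly zero and the
  sign-based verdict would be a coin flip — the experiment therefore uses
  the transient, non-equilibrium regime in which divergence is convex in
  cost distance, which an equilibrium (saturating, concave) regime would
  destroy; and seed-to-seed noise is dominated by drift realization, which
  shrinks with panel size, so the validation panel uses 40 loci (the
  study-emulating default stays at 14). Log cost distances are used for
  all candidate models symmetrically, matching the log transform of the
  IBD null.

# Known limitations

* The relatedness optimiser returns boundary estimates (exactly 0 or 1)
  with positive probability; interval estimates are out of scope.
* Least-cost distances inherit the 8-connected lattice metric's ≤ 8.24%
  overestimate of straight-line cost on uniform surfaces.
* The partial-Mantel permutation null is approximate (as all standard
  schemes are); its calibration is verified empirically under the tested
  nulls, not proved.
* The migration sampler limits migrant ancestry to two generations, as the
  underlying model does; deeper ancestry is absorbed into non-migrants.
* `distlm` forms n×n hat and Gower matrices; comfortable into the low
  thousands of individuals, not designed beyond that.
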