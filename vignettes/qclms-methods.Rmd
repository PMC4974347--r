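---
title: "Quantitative cross-linking comparison and cross-link-driven integrative modeling"
author: "qclms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative cross-linking comparison and cross-link-driven integrative modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qclms)
```

# The scientific problem

Chemical cross-linking with an amine-reactive reagent such as BS3 covalently
tethers residue pairs whose C&alpha; atoms are within a bounded distance in
solution. Identified cross-links are therefore distance restraints, and
*quantitative* cross-linking/mass spectrometry (QCLMS) goes one step
further: by cross-linking two conformational states of the same protein with
light (BS3) and heavy (BS3-d4) isotopologues, mixing them, and comparing MS1
peak areas, it measures which residue-residue proximities are preserved,
gained, lost, or changed in yield between conformers. The motivating system
is complement component C3 and its two activated derivatives C3b
(proteolytic) and C3(H2O) (spontaneously hydrolysed), a ~1641-residue,
two-chain, thirteen-domain protein whose TED domain migrates along the
length of the molecule upon activation.

`qclms` implements the complete downstream analysis twice over:

1. **Quantitation comparison** — from peptide-level light/heavy peak areas
   to per-residue-pair fold changes, replica validation, outlier
   classification into five categories, and the three-way merge of two
   pairwise comparisons.
2. **Integrative modeling** — from a cross-link set plus known domain
   structures to a Bayesian, coarse-grained ensemble model of the domain
   architecture, with clustering, precision/accuracy metrics, localization
   densities and restraint-satisfaction maps.

A fully seeded synthetic-data module generates ground-truthed inputs for
every stage, so the whole pipeline is testable end to end without any
external data.

# Part 1: the quantitation comparison

## From peak areas to fold changes

Each quantified cross-linked peptide pair contributes, per sample, a light
and a heavy elution peak area. The **label orientation** of the sample (which
condition carried the heavy linker) converts these into a condition-oriented
ratio, so a peptide's signal fold change is always
$\log_2(\text{condition}_1/\text{condition}_2)$ regardless of labeling.
Within each sample all peptide ratios are **normalized to their median**,
which cancels the systematic bias introduced by imperfect 1:1 mixing of the
two digests; the planted-bias simulation in `simulate_quant()` demonstrates
exact removal. A residue pair's fold change is the **median of its
supporting peptides** (midpoint convention for even counts), reducing
sensitivity to a single aberrant peptide measurement.

## The label-swap replica rule

Every experiment consists of two samples with exchanged labels. A link is
accepted only when both samples agree: both quantify it as a doublet (the
two values are averaged), or both see a singlet *for the same condition*
(the link becomes a unique-link candidate). Anything else — a link seen in
only one replica, or a doublet in one and a singlet in the other — is
rejected with a reason code. Across experiments, doublet values are
averaged when a link is quantified in both; the case "doublet in one
experiment, singlet in the other" has no canonical resolution, so the
package resolves it to the quantified (doublet) call and flags the link
(`mixed_detection`) rather than deciding silently.

## Significance A and the five categories

Enrichment is decided by the robust percentile outlier test on the
comparison's fold-change distribution: with $m$ the median,
$\sigma_R = P_{84.13} - m$ and $\sigma_L = m - P_{15.87}$ estimate the
one-sided spreads (each equals one SD for a Gaussian), the query's robust
$z$ is computed on its own side, and
$p = \tfrac12\,\mathrm{erfc}(z/\sqrt2)$. Percentiles use R's default
(type 7) interpolation; interpolation conventions differ between tools but
the difference is far below the decision threshold for realistic sample
sizes. The test is applied per comparison on the final per-link
fold changes, raw $p < 0.05$, no multiple-testing correction — the
standard usage of this test in proteomics workflows. With fewer than 8 quantified values
or zero spread the test is undefined; `classify_crosslinks()` then reports
all quantified links as mutual with `p = NA` (a degenerate comparison
cannot support enrichment claims).

The five categories are: unique to condition 1 or 2 (consistent singlets),
enriched in 1 or 2 ($p < \alpha$ with the matching sign), and mutual.
Exchanging the conditions negates every fold change and mirrors every
category — a property the test suite checks wholesale.

## The three-way merge

Two pairwise comparisons that share their reference condition combine into
a three-set Venn view: each link's category encodes presence/absence in the
two conditions it was measured between, and the union is partitioned into
six populated categories plus the theoretically possible seventh (present
in both non-reference conditions, absent in the reference). Conflicting
presence calls for the shared reference are flagged per link, never
dropped. `modeling_restraint_set()` extracts the links present in a chosen
condition and assigns each the `consistent` uncertainty class when it was
observed in both comparisons and `single` otherwise — the input to Part 2.

# Part 2: cross-link-driven integrative modeling

## Representation

Domains with known structure are rigid bodies of one bead per residue at
the C&alpha; positions (radius 2.4 A); linkers and unstructured segments
are flexible strings of one 3.0 A bead per residue. One body — for C3 the
MG1-6/&alpha;'NT "key-ring" core — is the **core**: it is held fixed during
sampling (removing global drift) and is the superposition target of every
ensemble analysis.

## The Bayesian score

The posterior $p(M\mid D, I) \propto p(D \mid M, I)\,p(M, I)$ is sampled as
a score (negative log posterior). The likelihood of observing cross-link
$k$ with bead-bead distance $d_k$ is

$$\psi_{c(k)} + (1 - 2\psi_{c(k)})\, f(d_k), \qquad
  f(d) = \frac{1}{1 + e^{(d - d_0)/\lambda}},$$

where $\psi_c \in (0, 0.5)$ is the sampled uncertainty of the link's class
($\psi_C$ for links identified consistently across experiments, $\psi_I$
for links identified once; one value per class). At $d = d_0$ every link
contributes $\log\tfrac12$ independent of $\psi$; spurious links can be
"explained away" at cost $\log\psi$. The $\psi$ prior is uniform on
$[0.01, 0.49]$, proposals are Gaussian ($\sigma = 0.01$) with reflection at
the bounds.

The prior comprises soft-sphere excluded volume between beads of different
bodies/strings (quadratic in the overlap, $k = 1\,\mathrm{A}^{-2}$, with the
usual 1-2/1-3 bonded exemption), an upper-bounded harmonic connectivity
restraint between sequence-consecutive beads (rest length 4 A per residue
of separation), and a two-sided harmonic on each disulfide (rest 6 A,
$k = 10\,\mathrm{A}^{-2}$) — for C3, the 851-1491 interchain bond.

**Forward-model calibration.** $d_0$ and $\lambda$ are deliberately
config-exposed. The default $d_0 = 35$ A, $\lambda = 2$ A matches the
satisfaction criterion used for real BS3 data, where linker reach,
side-chain flexibility and coordinate error all contribute slack. For
synthetic data the right calibration is different: when detections are
generated by a hard distance cutoff, the statistically matched forward
model is a near-step function just beyond that cutoff — a wide, shallow
logistic would actively pull true links inward of their planted distances
and bias every domain toward the core. The two-state toy preset therefore
models its 13 A detections with $d_0 = 13.5$ A, $\lambda = 0.3$ A. This
calibration was fixed from the generator's definition (cutoff + sharpness),
not fitted to any result.

## Sampling

Replica-exchange Metropolis Monte Carlo: a geometric temperature ladder
(dimensionless $T$, dividing the score in the acceptance rule), one move
per replica per sweep chosen uniformly among rigid-body translation
(&le; 4 A), rigid-body rotation (&le; 0.03 rad about the body centroid),
flexible-bead translation (&le; 5 A), and a $\psi$ perturbation. Neighbor
swaps with acceptance $\min\{1, \exp[(1/T_i - 1/T_j)(S_i - S_j)]\}$ are
attempted every 10 sweeps on alternating parities. The coldest replica's
configuration is recorded once per sweep. Initialization places each
movable body at a random orientation and position in a bounding sphere
around the fixed core. The published protocol used 32 replicas at
$T \in [1, 2.5]$ and 200,000 models over two independent runs; the
package's **desk profile** (the `sampler_config()` default) is 8 replicas,
20,000 models, one run — chosen so a complete benchmark run takes minutes
on one CPU. All sampling is exactly reproducible from the seed.

## Ensemble analysis

The $n$ best-scoring models (ties broken by model index) are superposed on
the core and clustered by k-means on the flattened coordinates (Euclidean
distance in that feature space is proportional to all-bead RMSD); $k$ is a
user choice: for complement, the native-like and activated-like systems
form one cluster each and the hydrolysed form two.
Each cluster's center is its medoid (member minimizing mean RMSD to
co-members). **Precision** is the mean member-to-center RMSD after core
superposition; **accuracy** is the mean member-to-reference RMSD when a
reference structure exists, with per-domain breakdowns of both. A
cross-link is **satisfied** when its bead distance is below 35 A in at
least one cluster member (the ensemble read as alternative conformations);
a per-center-model call is also reported, along with a bead-bead contact
frequency map. **Localization densities** convert a cluster into per-domain
voxel occupancy probabilities (fraction of members in which any bead
sphere of the domain intersects the voxel), written as CCP4/MRC volumes by
a minimal writer included here because no installed R package emits that
format.

# The synthetic-data module

`make_toy_protein()` builds compact multi-domain proteins: each domain is a
3.8 A-spaced bead cluster on a balanced grid, domains are placed in contact
(center spacing 12.5 A for 12-residue domains, i.e. surfaces at excluded-
volume contact, as real domains pack), and linkers are laid along outward-
bulging arcs at ~3.8 A spacing and then relaxed by a deterministic
steric-descent pass — so every planted state is a physically relaxed
configuration of the modeling prior (prior score ~0 instead of hundreds
for naive straight-line linkers; without this the score optimum is
systematically displaced from the planted truth and no recovery criterion
is meaningful). States are rigid rearrangements of the same domains.

`simulate_crosslinks()` draws links among reactive-residue pairs (K/S/T/Y)
with a hard detection cutoff; each emitted link is spurious with
probability `noise_rate`, drawn from beyond-cutoff pairs. The two-state
variant draws link identities once and derives per-state presence from the
geometry, so planted two-state categories are exact.
`simulate_quant()` emits the full label-swap design (2 experiments x 2
swapped samples): doublets with planted effect + peptide noise + per-sample
mixing bias, singlets with the correct orientation, and 1-3 supporting
peptide pairs per link.

**Preset conditions.** The two-state preset uses 3 domains x 12 residues,
6-residue linkers, a 13 A detection reach (appropriate to a molecule only
~38 A long — the 27.4 A BS3 reach would make nearly every pair linkable),
40 links at 5% noise for the quantitation exercise and 60 links for the
modeling-recovery exercise, planted null effects evenly spaced in
[-0.8, 0.8] log2 units (a realistic null spread that is free of accidental
outliers by construction) and enrichment effects of +/-3. The complement-
like benchmark (`synthetic_benchmark_protein()`) has 7 domains in three
states emulating the hallmark TED migration and shoulder rearrangements,
with the published link-set sizes (82/75/85) at 5% noise.

**What the synthetic data do not emulate:** peptide misassignment within
windows of the true site, retention-time effects, correlated noise between
label channels, intensity-dependent variance, and within-domain
flexibility. Passing tests therefore validate the *computational* pipeline
— the bookkeeping, statistics, sampling and metrics — not robustness to
every failure mode of real MS data.

# Numerical and design choices

- Median convention: midpoint of the central pair for even counts,
  everywhere.
- `max_link_distance()` sums sorted side-chain lengths so the limit is
  bit-identical under argument swap.
- Unresolved residues in crystal structures are substituted by the nearest
  resolved residue in sequence, ties toward the lower number; alternate
  locations resolve to the highest occupancy (first on ties); insertion-
  code residues are excluded from the mature-numbering mapping. Mature
  numbering maps to author numbering by a per-chain offset, default 0.
- The seventh Venn category (present in both non-reference conditions,
  absent in the reference) is reported and flagged, never silently merged.
- Cluster tie-breaks: `select_best()` orders by score then model index;
  k-means uses a fixed seed and 10 restarts.
- Every stochastic operation takes an explicit seed and restores the
  caller's RNG state.

# Known limitations

- The sampler is plain R; the desk profile samples ~10^5 score evaluations
  per minute on ~100-bead systems. Atom-level systems are out of scope.
- Upper-bound-type restraints leave a feasible region whose diameter —
  not the sampler — limits recovery precision; for the toy preset this is
  a few Angstrom, for the complement-like benchmark of order 10 A, in line
  with the precision reported for the real system (~15 A).
- One $\psi$ per class is sampled (not per link), reading the class
  uncertainty as an average over its links.
- k-means on coordinates assumes clusters of comparable spread; for
  strongly uneven ensembles a medoid-based partitioner would be a drop-in
  replacement.
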