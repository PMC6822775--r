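---
title: "Phyletic couplings from presence/absence profiles: model, inference and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phyletic couplings from presence/absence profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phydca)
```

## The model

The data object is a binary phylogenetic profile matrix (PPM): `M` genomes
by `N` domain families, entry 1 when a domain occurs in a genome at least
once (paralog counts are deliberately discarded — presence is what
covaries informatively across species). `phydca` models a genome's profile
$(n_1,\dots,n_N) \in \{0,1\}^N$ with the pairwise maximum-entropy
(lattice-gas) distribution

$$P(n_1,\dots,n_N) = \frac{1}{Z}\exp\Big\{\sum_{i<j} J_{ij} n_i n_j
  + \sum_i h_i n_i\Big\},$$

the unique maximum-entropy model reproducing the empirical single and pair
presence frequencies $f_i$ and $f_{ij}$. The couplings $J_{ij}$ are the
quantity of interest: they are *direct* interaction parameters, whereas the
correlations in the data mix direct effects, chains of couplings, and
shared phylogeny. A domain pair can be strongly correlated through an
intermediate partner while its direct coupling is essentially zero — the
key failure mode of classical phylogenetic profiling that the global model
repairs.

The $\{0,1\}$ (lattice-gas) encoding is used throughout, not $\pm 1$
(Ising) spins; couplings from the two conventions differ by linear
transformations and must not be compared entry-wise.

## Profile construction

`build_ppm()` collapses long-format `(genome, domain, copies)` records into
the binary matrix, idempotently (duplicate or multi-copy records are
presence). Rows and columns are sorted in C-locale lexicographic order so
downstream rankings and serializations are deterministic. Duplicate
near-identical species are retained as given: phylogenetic redundancy is a
property of genome databases, not an artifact to silently undo.

`filter_by_frequency()` removes domains occurring in fewer than a fraction
`f_min` or more than `f_max` of genomes. Near-omnipresent domains (e.g.
core replication/translation machinery) carry no covariation signal;
near-absent ones provide too few observations. Fractions are converted to
integer presence-count bounds as $[\lceil f_{\min} M\rceil, \lfloor f_{\max}
M\rfloor]$ — at $M = 1041$ genomes the 5%/95% defaults give counts 53 to
988. The ceil/floor convention is chosen precisely because it reproduces
these canonical integer bounds. `restrict_to_reference()` optionally keeps
only domains found in a reference genome's repertoire, the usual way to
focus the analysis on an organism of interest.

## Inference

Exact maximum-likelihood fitting requires the partition function $Z$,
i.e. a sum over $2^N$ states — hopeless beyond toy sizes, so $Z$ is never
computed. Two standard approximations are implemented.

**Mean field** (`mf_couplings()`): couplings are the negated off-diagonal
of the inverse connected-correlation matrix, $J = -C^{-1}$ with
$C_{ij} = f'_{ij} - f'_i f'_j$. Frequencies are first shrunk towards the
uniform independent model by a pseudocount $\lambda$:
$f' = (1-\lambda) f + \lambda/2$, $f'_{ij} = (1-\lambda) f_{ij} +
\lambda/4$ ($i \ne j$), which regularizes $C$ against rank deficiency when
$M < N(N-1)/2$. Default $\lambda = 0.01$: large enough to stabilize the
inversion on realistic matrices, small enough not to visibly bias couplings
on the synthetic benchmarks below. Biases follow from mean-field
consistency, $h_i = \mathrm{logit}(f'_i) - \sum_j J_{ij} f'_j$.

**Pseudo-likelihood maximization** (`plm_couplings()`): for each domain
$i$, the conditional model $P(n_i = 1 \mid n_{\setminus i}) =
\mathrm{logistic}(h_i + \sum_j J_{ij} n_j)$ is an L2-penalized logistic
regression of column $i$ on all other columns, maximized by damped Newton
iterations until the gradient norm falls below $10^{-6}$ (cap 500
iterations, error on non-convergence naming the offending domain). The two
asymmetric estimates of each coupling are averaged. Defaults
$\ell_2(J) = \ell_2(h) = 0.01$, the customary order of magnitude in
PLM-based coupling inference; the ridge also guards against quasi-separated
columns. Pseudo-likelihood is consistent: fitted on the exact model
distribution (all $2^N$ states weighted by their Boltzmann probabilities,
via the `weights` argument), it recovers planted parameters to numerical
precision — the test suite asserts this at $N = 4$, and it is the package's
sharpest correctness oracle for the optimizer.

Both routes are deterministic given the input; there is no randomness in
inference.

**APC** (`apc_correct()`): the average product correction
$S_{ij} = J_{ij} - \bar J_{i\cdot}\bar J_{j\cdot}/\bar J$ (means over
off-diagonal entries) removes the uniform component a heterogeneously
conserved domain contributes to all its couplings. It is applied to the
signed couplings. Default ranking (`rank_pairs()`) uses *uncorrected*
couplings with APC opt-in: on phyletic couplings the correction is known to
have only a limited effect, and raw $J$ values are the interpretable
quantity (they are what significance thresholds are stated in). Note one
non-obvious property, asserted in the tests: APC is *not* a small
perturbation of an isolated strong coupling — a lone nonzero pair in an
otherwise empty matrix loses about half its value, since row means and the
grand mean shrink at the same rate as $N$ grows.

## Correlation baselines

`hamming_scores()`, `pearson_scores()` and `fisher_scores()` implement the
classical local measures: normalized Hamming distance (mismatch fraction),
signed Pearson correlation of the binary columns, and the two-sided
Fisher's exact p-value of the pair's 2×2 contingency table. The two-sided
rule sums hypergeometric tables whose probability does not exceed the
observed one (relative tolerance $1+10^{-7}$, matching standard
implementations), clamped at 1. Rankings are by relatedness in the positive
direction: Pearson ranks by *signed* r descending, so anti-correlated pairs
are ranked last rather than folded into "related" — the comparison of
interest is against positive relations. All $N(N-1)/2$ pairs are scored
densely.

## Positive relation sets

`relations` functions assemble ground-truth positives from five evidence
classes: domain pairs co-occurring in one protein
(`intra_protein_pairs()`), pairs across proteins of one operon
(`operon_pairs()` — any two distinct domains in the operon), full bipartite
domain expansion of interacting protein pairs (`ppi_pairs()` — a
deliberately permissive rule that dilutes precision but loses no true
pair), pre-computed structural contact lists (`structure_pairs()`), and
metabolically related enzymes (`metabolic_pairs()`). The metabolic rule
first discards *currency metabolites* — those participating in more than 50
reactions (water, ATP, …), strictly greater-than on substrate-or-product
participation — then relates reaction pairs sharing a substrate, sharing a
product, or chaining (product of one is substrate of the other, tested in
both directions, which also covers reversible reactions without modelling
reversibility). Domain pairs are emitted across reaction pairs only, not
within one reaction's enzyme set — a conservative reading; within-reaction
multi-enzyme pairs would anyway largely be covered by the operon and
intra-protein classes. `merge_relations()` forms the deduplicated union,
keeping per-pair source labels, so one pair supported by several classes
counts once.

## Evaluation

`ppv_curve()` gives the fraction of known positives among the top $k$
ranked pairs. `enrichment_bins()` counts, per bin of 100 ranked pairs,
membership in each (possibly overlapping) evidence class.
`compare_prediction_sets()` cross-tabulates two or three top-$k$ lists by
membership pattern (`YES`/`NO`/`-` with `-` aggregating), reporting
elements, true positives and PPV per pattern; patterns with no `YES` are
omitted because the complement of all sets is unbounded.

`significance_threshold()` operationalizes the visual histogram-overlay
reading of a significance cutoff: pairs ranked by descending coupling, the
local PPV at rank $k$ is the positive fraction in a 100-pair window
*centered* on $k$, and the threshold is the coupling at the deepest rank
down to which local PPV stays ≥ 0.5. The centered window was a deliberate
choice over a trailing one: with positives occupying exactly the top $R$
ranks, a centered window pinpoints the transition at rank $R$, while a
trailing window overshoots by half a window. Window size and PPV level are
exposed.

`build_signed_network()` thresholds $|J|$ into a signed graph;
`triangle_census()` enumerates triangles by their sign multiset. Here
"frustrated" follows the coupling-network usage — a `++-` triangle, one
avoidance link between two co-occurrence links — not the statistical-physics
parity convention. Biologically, an absence of `++-` triangles alongside
`+--` ones indicates that *whole processes* are swapped between alternative
solutions rather than single domains being exchanged inside an otherwise
positively coupled module. `correlation_vs_distance()` profiles mean $|r|$
against unweighted shortest-path distance on the coupling network
(disconnected pairs form the baseline class), showing direct pairs as most
correlated with decay along coupling chains towards a residual background —
the fingerprint of indirect correlation.

## Synthetic generator and what it does (not) show

`make_planted_model()` draws a sparse ground-truth coupling network —
edges uniform among pairs, weights $\pm J$ (optionally jittered), biases
uniform in $[-1, 0]$ so marginal frequencies fall in the informative
mid-range that survives frequency filtering. `gibbs_sample()` samples
genomes from the Boltzmann distribution by single-site Gibbs updates in
fixed sweep order (reproducibility at fixed seed), with local fields
maintained incrementally. Defaults: 1,000 burn-in sweeps, thinning 10 —
validated against exhaustive $2^N$ enumeration (`lattice_gas_exact()`) in
the test suite, where sampled pair frequencies sit within three Monte-Carlo
standard errors of the exact marginals. `tree_gibbs_sample()` optionally
evolves profiles along a random binary genealogy (lineage duplication with
per-branch conditional resampling of a domain fraction), a minimal
emulation of the phylogenetic confound in which shared ancestry amplifies
single events; it is off by default and makes no claim to realistic
gain/loss dynamics.

The generator draws i.i.d. genomes from the very model family the
estimators assume. Passing tests therefore demonstrate *inference
correctness* — the optimizers solve the problem they are posed, the sampler
samples the right distribution, couplings beat correlations at edge
detection under known ground truth. They do **not** demonstrate robustness
to the features of real genome data the generator omits: phylogenetic
non-independence of species (except via the optional tree mode),
domain-gain/loss rate heterogeneity, annotation noise, and model
misspecification (higher-order interactions). Conclusions about real PPMs
rest on the model's track record, not on these tests.

## Benchmark problem sizes and numerical choices

The validation harness runs at sizes chosen to make each property sharply
testable at interactive runtimes: exhaustive-enumeration oracles at
$N \le 4$ (16 states), sampler calibration at $N = 4$ with 4,000 genomes,
sparse-model recovery at $N = 30$, 8 edges, $|J| = 1$, $M = 5{,}000$
(edge-detection AUC ≥ 0.95 for both MF and PLM), and MF–PLM concordance at
$N = 50$, $M = 2{,}000$, where the two inference routes agree with Pearson
correlation well above 0.9 — the synthetic counterpart of the high MF/PLM
concordance seen on real profile matrices. Chain benchmarks for the
couplings-versus-correlations comparison use *mixed* strong/weak chains
(couplings 2, 2, 0.6 repeating): on a homogeneous chain every direct
correlation exceeds every indirect one and Pearson trivially ties the
couplings at AUC 1; heterogeneity creates the regime the claim is about,
where correlation routed through two strong links overtakes a weak direct
link and only the global model ranks the true edge higher.

Other numerical details: frequency statistics are exact rational counts
over $M$; the MF route errors (rather than pseudo-inverting) on a singular
correlation matrix, with the advice to raise the pseudocount; logistic
probabilities are clamped at $10^{-12}$ inside the PLM objective;
tie-breaks in all rankings are lexicographic on the pair identifiers;
`rank_pairs()` assigns exactly-zero couplings to neither tail; and
degenerate filter/restriction results (zero domains left) return valid
empty matrices with a warning rather than erroring, so pipelines can detect
and report the condition.

## Limitations

Pure-R inference is comfortable to a few hundred domains and $10^4$
genomes; genome-scale matrices ($N \gtrsim 2{,}000$) make PLM the dominant
cost and would benefit from compiled per-node solvers. Phylogenetic bias is
only emulated, not corrected — couplings on strongly structured species
samples inherit whatever bias survives the global model's disentangling.
Negative couplings are only observable between domains that can both occur
in the profile universe; restricting domains to one reference genome
systematically understates mutual exclusion, and analyses of avoidance
should use the widest domain set available.
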