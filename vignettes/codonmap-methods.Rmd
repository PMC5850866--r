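---
title: "Estimating dN and dS under nonstationary base composition with codonmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating dN and dS under nonstationary base composition with codonmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The ratio of nonsynonymous to synonymous substitution rates, dN/dS, is the
workhorse statistic for measuring selection on protein-coding genes: it
approximates ω, the ratio of fixation probabilities of nonsynonymous versus
neutral mutations. Standard estimators assume the sequence composition is at
the equilibrium of the substitution process ("stationarity"). In many real
clades this is false — GC content drifts over time in mammals, endosymbiotic
bacteria, cyanobacteria and elsewhere — and fitting a stationary model to
compositionally drifting sequences biases ω, dN and dS systematically: when
GC decreases along the tree, ω is overestimated; when it increases, ω is
underestimated; dN and dS themselves tend to be underestimated whenever the
equilibrium composition is extreme and the composition is moving.

`codonmap` addresses this in two steps, deliberately kept separate:

1. **Maximum-likelihood fitting** of a codon model that does *not* assume
   stationarity: the root is given its own composition, distinct from the
   model equilibrium, and different branches may carry different models.
2. **Stochastic mapping** under the fitted model: on each branch, the
   posterior expectation of the number of synonymous and nonsynonymous
   events, integrated over *all* substitution scenarios compatible with the
   data (not just the most parsimonious or most likely one), normalized by
   the expected opportunity for such events under the neutral version of
   the same model.

## The model

The substitution model is the Yang–Nielsen (1998) codon model, YN98, on the
61 sense codons of the standard nuclear code. Between codons differing at
exactly one position the instantaneous rate is

    q(x -> y)  ∝  π_y · κ^[transition] · ω^[nonsynonymous],

and multiple-hit changes have rate zero. Parameters, with defaults used as
optimizer starting values:

| parameter | meaning | domain | start |
|-----------|---------|--------|-------|
| κ | transition/transversion rate ratio | (0, ∞), bounded [1e-3, 100] in fitting | 2 |
| ω | nonsynonymous/synonymous ratio | [0, ∞), bounded [1e-4, 100] | 0.3 |
| equilibrium composition | F1X4 (3 free) or F3X4 (9 free) nucleotide frequencies | simplex | empirical composition of the alignment |
| root composition | same parameterization, free in nonstationary templates | simplex | empirical composition |
| branch lengths | expected substitutions per codon | bounded [1e-6, 20] | input tree, else 0.1 |

Codon frequencies are products of position-wise nucleotide frequencies with
stop codons zeroed and the remainder renormalized. Every generator is
normalized so that a sequence at equilibrium accumulates one substitution
per codon per unit time; branch lengths therefore have those units. The
generator is time-reversible, so its spectral decomposition is computed via
the symmetrization `diag(√π) Q diag(1/√π)`, which guarantees a real
spectrum and stable eigenvectors; the decomposition is cached and reused by
every matrix exponential and mapping integral.

Three fitting templates are available: `stationary` (root = equilibrium),
`nonstationary` (free root composition), and `nonhomogeneous`
(nonstationary plus one model per branch group). Degrees of freedom for
likelihood-ratio tests between templates are always derived from the
templates' own parameter counts, never hard-coded, because the count
depends on the frequency scheme and the partition in use.

## Stochastic mapping and the dN/dS estimator

For a branch b with endpoints conditioned on the data D and model M, the
package computes, in closed form from the spectral decomposition:

- `E(N_L | b, D, M)` — expected number of events in label set L
  (synonymous or nonsynonymous) via the integral
  `∫₀ᵗ exp(Qs) (Q ∘ 1_L) exp(Q(t−s)) ds`;
- `E(A⁰_L | b, D, M)` — expected mean, along the branch, of the
  instantaneous ability of the *neutral* model M0 (the same model with
  ω = 1) to perform L-events; the same integral with the label-rate matrix
  replaced by the diagonal reward `a_L^{M0}(s) = Σ_{y: (s→y)∈L} Q⁰_{sy}`,
  divided by the branch length.

When two eigenvalues coincide within 1e-9 the integrand kernel
`(e^{λᵢt} − e^{λⱼt})/(λᵢ − λⱼ)` switches to its confluent limit `t·e^{λᵢt}`.
Endpoint conditioning uses the joint posterior of the branch's top and
bottom states, obtained from an inside (pruning) and outside pass; both
passes rescale per site, and the per-branch normalizer cancels the scales
exactly, so no global bookkeeping is needed.

The branch estimates are

    dN = E(N_nonsyn) / (3 · E(A⁰_nonsyn)),
    dS = E(N_syn)   / (3 · E(A⁰_syn)),

where the denominator counts "(non)synonymous site equivalents": because
the neutral model is normalized to one substitution per codon per unit
time, its total ability is 1 per codon, and the conventional
per-nucleotide accounting makes it 3 per nucleotide — the factor 3 is
applied exactly once, here. At neutrality (ω = 1, stationary composition)
counts and abilities coincide in expectation and dN ≈ dS ≈ t/3, which the
test suite verifies.

One modeling point deserves emphasis: the ability expectation that enters
dN/dS is the branch *mean* of the instantaneous ability (the time integral
divided by t). The low-level `conditional_expected_ability()` returns the
raw time integral; `branch_dnds()` performs the division. With the mean
convention the neutral closed form above holds; with the raw integral it
would not.

By default M0 is re-normalized to unit equilibrium rate on its own
equilibrium. The alternative — reusing the parent model's scale — is
available (`renormalize_m0 = FALSE`), since either convention is
defensible; re-normalization is the default because the "ability equals 1
per codon per unit time" property is stated for the model used in the
normalization, and only the re-normalized M0 has it. The ability model is
also fully pluggable (`ability_model =`), as the mapping machinery does
not care whether the reward model equals the path model.

Clade-level rates are sums of branch rates, and the clade ratio is the
ratio of the sums (ΣdN/ΣdS); the mean of per-branch ratios is available
behind `method = "mean_ratio"` but is not the default, because summing is
the natural aggregation of counts and site-equivalents.

## The simulator

`simulate_alignment()` draws a root sequence from the scene's root
distribution and evolves each codon site independently along the tree by
exact Gillespie simulation, classifying and counting every realized jump.
The recorded per-branch ground truth (event counts and realized
time-integrated abilities) is what makes the mapping estimators testable:
the suite checks that posterior expected counts are unbiased for the true
counts across replicates.

The simulation grid mirrors the conditions of the bias study: a six-taxon
mammalian topology (((human, chimp), macaque), (mouse, rat), dog) with a
homogeneous YN98+F1X4 model, root G+C θ_root and equilibrium G+C θ_eq each
ranging over 0.1–0.9 in steps of 0.1, and ω ∈ {0.1, 0.9, 1, 1.1}. The
single-θ composition uses the symmetric split A = T = (1−θ)/2,
G = C = θ/2, making θ the lone compositional degree of freedom. The
reference study does not publish branch lengths for this tree; the fixture
defaults to 0.1 substitutions per codon on every branch (0.05 on the short
human–chimp stem) and is configurable. All quantitative expectations tied
to this tree are therefore reproduced in direction and approximate
magnitude, not to the digit.

Desk-scale defaults are 10 replicates of 1000 codons per grid cell
(the full-scale study used 100 × 3000); the acceptance analyses and the
test suite use these sizes, chosen so a complete simulate–fit–map cell
runs in minutes while Monte-Carlo standard errors remain small enough to
resolve the biases of interest. The neutral self-consistency analysis uses
20 replicates, because the per-replicate aggregated dN/dS is the noisiest
of the reported quantities (sd ≈ 0.14 at 1000 codons). What the simulator does *not* emulate:
indels and alignment error, selection heterogeneity across sites, CpG
context effects, and within-gene compositional gradients. Passing tests on
simulated data therefore validate the estimator's internal consistency
and its behavior under compositional nonstationarity — not robustness to
real-data artifacts.

## Numerical choices

- **Optimization**: L-BFGS-B on transformed parameters (log for branch
  lengths, κ, ω; additive log-ratio for compositions), convergence at
  roughly 1e-6 absolute on the log-likelihood, 3 starts by default (data-
  informed, neutral, jittered). Fits in the test suite use a single
  data-informed start, which the recovery experiments show is sufficient
  at these problem sizes.
- **Zero-frequency states** are floored at 1e-12 and renormalized so the
  chain remains irreducible on all 61 codons and indexing stays uniform
  across branch models.
- **Transition matrices** clip roundoff negatives to zero and renormalize
  rows; `t = 0` returns the exact identity so that unreachable endpoints
  are detected crisply.
- **Missing data** (gaps, ambiguity codes) are marginalized as all-ones
  partial likelihoods; in-frame stop codons are a hard intake error.
- **Per-site rescaling** in both pruning passes prevents underflow on
  deep trees; mapped quantities are normalized per branch so the scale
  factors cancel algebraically.
- **Ties in the spectrum** (gap < 1e-9) use the confluent kernel.

## Known limitations

- Variances and higher moments of the mapped counts are not computed;
  only expectations are.
- The mapping estimates correspond to a single E-step; no EM iteration
  for branch-specific ω is performed.
- Site-heterogeneous selection models (site classes, mixtures) are out of
  scope; the mapping machinery would apply per mixture component, but no
  such models are provided.
- Tree topology is always user-supplied; there is no topology search, and
  the root placement is taken as given (nonstationary likelihoods depend
  on it, so automatic re-rooting would be wrong).
- A reducible composition (frequencies exactly zero) is handled by
  flooring rather than by excluding states; extremely skewed compositions
  near the floor may slow the optimizer.
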