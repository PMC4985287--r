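---
title: "Methods: quantitative analysis of combinatorial fitness landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative analysis of combinatorial fitness landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitscape)
```

# Scope

`fitscape` analyses combinatorially complete protein fitness landscapes of
the kind produced by deep mutational scanning of a small set of interacting
sites — the motivating system is a four-site landscape (GB1 sites 39, 40,
41, 54; wild type VDGV) spanning all 20^4 = 160,000 amino-acid
combinations, assayed by an in vitro binding selection and sequenced before
and after selection. The package covers the full quantitative chain:
fitness from counts, pairwise epistasis, direct-path accessibility,
Fourier decomposition into epistatic orders, extra-dimensional bypass
detection, sparse-model imputation of missing variants, and adaptive-walk
simulation. Everything runs equally on measured tables and on the built-in
synthetic generator, which carries known ground truth.

# Fitness from sequencing counts

Fitness of variant $i$ is the wild-type-normalized enrichment ratio

$$w_i = \frac{c_{i,\mathrm{sel}} / c_{i,\mathrm{in}}}
             {c_{\mathrm{WT},\mathrm{sel}} / c_{\mathrm{WT},\mathrm{in}}},$$

unitless with $w_\mathrm{WT} \equiv 1$. Variants with fewer than
`min_input = 10` input reads are moved to the missing set rather than
given a noisy ratio; the threshold is configurable. The wild-type fitness
is pinned to exactly 1 (it is 1 by construction; floating-point division
is not allowed to perturb the anchor). $w = 0$ (no selected reads) is
treated as lethal in the assay sense; only an exact zero counts as lethal
in summaries, because the assay's detection limit (~0.01) makes small
positive values indistinguishable in reliability from one another but
still distinct from a hard zero.

# Pairwise epistasis

For substitutions $a$, $b$ on background $BG$:

$$\varepsilon_{ab,BG} = \ln\frac{w_{ab}}{w_{BG}}
 - \ln\frac{w_a}{w_{BG}} - \ln\frac{w_b}{w_{BG}}.$$

Because fitness below the detection limit (~0.01) is unreliable, three
adjustment rules temper $\varepsilon$: a quad entirely at the floor
yields 0; a floored single mutant permits only $\max(0, \varepsilon)$; a
floored double mutant permits only $\min(0, \varepsilon)$; when the last
two apply together the value is 0. The rules only ever shrink
$|\varepsilon|$ — a property the test suite asserts. Note that
$\varepsilon$ is symmetric in $a$ and $b$ and also invariant under viewing
the same face from the double-mutant corner (the four log terms are
unchanged); the implementation and tests use that equality.

Type classification ranks the four fitness values: each mutation's effect
sign is compared across the partner's two backgrounds; no flip is
magnitude, one flip sign, two flips reciprocal sign epistasis. Exact ties
count as "no flip": a zero effect does not witness a sign change.
Ruggedness of a complete $2^d$ subgraph is $f_\mathrm{sign} +
2 f_\mathrm{reciprocal}$ over its $\binom{d}{2} 2^{d-2}$ quads
(24 at $d=4$), weighting classes by how strongly they block direct paths.

# Direct paths through diallelic subgraphs

A diallelic subgraph between two genotypes differing at $d$ sites contains
the $2^d$ allele combinations; a direct path is one of the $d!$ orderings
of the substitutions, accessible when fitness increases strictly at every
step (neutral steps block: no fixation model assigns a neutral mutation a
positive fixation probability). Accessible orderings are counted by
dynamic programming over the subset lattice and cross-checked in the tests
by exhaustive enumeration. Path realization probabilities multiply
per-step fixation probabilities (below), with denominators over all
fitter neighbors *within* the subgraph, then renormalize over the $d!$
direct paths; the skew of the resulting distribution is summarized by a
Gini index computed from sorted cumulative probabilities, normalized so a
uniform distribution scores 0 and a single-path distribution scores 1.

Single-peak subgraph enumeration keeps complete subgraphs whose designated
endpoint is the unique local maximum among the $2^d$ members (the source
itself is a candidate peak, so a source that is locally maximal disquali-
fies a from-source subgraph). Default destination windows: fitness > 1
(beneficial) away from the source; fitness in (0.01, 1) toward it. Whether
the endpoint is also *reachable* (at least one accessible ordering) is
reported as a separate column rather than folded into the filter, since
the two criteria answer different questions.

# Fourier decomposition

On a subgraph, fitness is expanded over site subsets $k$ as
$f(z) = \sum_k \hat f_k (-1)^{z \cdot k}$ with
$\hat f_k = 2^{-d} \sum_z f(z) (-1)^{z \cdot k}$ — the Walsh basis, whose
order-1 terms are main effects, order-2 pairwise epistasis, and orders
$\ge 3$ higher-order epistasis. The transform is its own scaled inverse
and satisfies Parseval's identity; both are asserted to 1e-10 relative in
the tests. "Variance explained" by a truncation is reported two ways:
squared Pearson correlation between reconstruction and input, and the
Parseval share of non-constant power. The two agree at the endpoints but
differ in between; both are emitted because the correlation version
matches how reconstruction quality is usually plotted, while the Parseval
share is the exact variance decomposition. The screen for higher-order
epistasis ranks complete subgraphs by order-2 variance explained
(ascending) and flags the bottom quantile (default 0.1%); ranking ties
break by destination lexicographic order so the screen is deterministic
without a seed. The destinations' position frequency matrix summarizes
which amino-acid combinations concentrate the higher-order signal.
Setting higher-order coefficients to zero and reconstructing
(`remove_higher_order()`) feeds the ruggedness and path analyses to ask
what pairwise epistasis alone would allow.

# Extra-dimensional bypass

A reciprocal-sign quad with a fitter double mutant traps direct
adaptation. Two escape mechanisms are tested exhaustively per quad:

* **conversion** — substitute one interacting site with a third amino acid
  ($00 \to c0 \to c1 \to 11$); at most $19 \times 2 - 2 = 36$ candidates;
* **detour** — gain and later lose a mutation at a third site
  ($000 \to 100 \to \{110, 101\} \to 111 \to 011$); at most
  $19 (L - 2)$ candidates (38 at $L = 4$).

A candidate succeeds only if its route increases fitness strictly at every
step; lethal or missing intermediates fail the candidate (a missing one is
additionally counted so both success denominators can be reported). On the
3-site cube the Taylor coefficients $\alpha$ are solved from the eight
corner values; the cube's digit convention puts the detour site on the
left digit and the focal pair on the right two. Successful detours are
classified by the lifted face: magnitude epistasis (scenario B), or sign
epistasis split by whether the $001 \to 101$ edge opens (C) or not (D).
For B and C the edge inequalities force $\alpha_{123} < 0$ — higher-order
epistasis is necessary — while D admits $\alpha_{123} = 0$. The tests
verify this by rejection-sampling tens of thousands of random cubes and by
an explicit D witness constructed with $\alpha_{123} = 0$.

# Imputation model

Missing variants are imputed from a sparse log-linear model of fitness:

$$\log f = \alpha_0 + \sum_i \beta_i M_i + \sum_j \gamma_j P_j
          + \sum_k \delta_k T_k,$$

with binary indicators for every single mutation
($N_M = 19 \times 4 = 76$ in the full four-site space), every pairwise
combination ($N_P = 19^2 \binom{4}{2} = 2166$), and every three-way
combination at the 39/41/54 triple ($N_T = 19^3 = 6859$) — 9102
coefficients with the intercept. Restricting three-way terms to one triple
is predictor selection by structural knowledge: those three side chains
pack against each other in the protein core, and the higher-order screen
concentrates there. The fit is L1-penalized least squares (glmnet
coordinate descent) on the natural-log fitness of non-lethal measured
variants only; lethal variants are excluded (log 0) and never overwritten
by imputation, and imputed values are strictly positive. Indicators are
left unstandardized (they share a common binary scale) and the intercept
is unpenalized. K-fold cross-validation MSE is computed on the log scale —
the fit's own response — and reported per $\lambda$. The default
$\lambda = 10^{-4}$ is the conventional choice for imputation in this
landscape; `lambda_choice = "cv"` instead takes the CV minimum, which is
what the parameter-recovery checks use, since coefficient recovery
benefits from the weaker penalty the CV curve selects.

# Adaptive walks

The fitness graph joins Hamming-distance-1 genotypes with a directed edge
toward strictly higher fitness; peaks are nodes with out-degree 0. Three
fixation models give per-step probabilities over the $M$ fitter
neighbors: greedy (all mass on the largest fitness; represents pervasive
clonal interference), correlated ($P_{i\to k} = (w_k - w_i)/\sum_n
(w_n - w_i)$; the strong-selection weak-mutation regime), and equal
($1/M$). Greedy ties break by lexicographic genotype order so basins of
attraction are a true partition; the choice is arbitrary but must be
deterministic. Walk steps are classified post hoc against the walk's own
realized endpoint by the change in Hamming distance: towards (−1),
conversion (0), detour (+1); bookkeeping identities (#towards − #detour =
starting distance; class counts sum to length) are asserted per walk in
the tests. Accessibility classes come from layered breadth-first search on
the directed graph: unreachable, reachable at the distance lower bound
(direct), or only beyond it (indirect required). Under genetic-code
constraints the adjacency is restricted to amino-acid pairs with sense
codons one nucleotide apart (stop codons never serve as intermediates),
and the distance lower bound becomes the per-site code-graph shortest
path summed over sites. Outcome entropy is the Shannon entropy (natural
log, $0 \ln 0 \equiv 0$) of empirical endpoint frequencies over $n = 1000$
walks.

# Synthetic generator

`synthetic_spec()` defaults encode the study conditions the analyses
assume: $L = 4$, 20 letters, 6.6% missing, 19.7% lethal, Gaussian
log-fitness noise with SD 0.05, and three-way interactions confined to
the 39/41/54 triple. Sparsity and spread of the interaction terms
(pairwise density 0.05, SD 0.3; three-way density 0.02, SD 0.4; additive
SD 0.5) are the package's own choices of a realistically sparse epistatic
structure: most site pairs interact weakly or not at all, a minority
strongly. Lethality is imposed after the log-linear draw by overwriting
random non-wild-type genotypes with 0, mirroring the fact that the
imputation model is fit on non-lethal variants only; missingness then
removes a random fraction. All randomness flows through one seed per
call. Count simulation inverts the enrichment definition: input counts
are multinomial with Dirichlet-perturbed frequencies (libraries are never
perfectly uniform), selected counts multinomial with probability
proportional to input frequency times fitness.

What the generator does *not* emulate: nucleotide-level sequencing error,
codon-level library bias, selection-round stochasticity beyond
multinomial sampling, and any correlation between lethality and sequence
composition. Tests passing on synthetic data therefore validate the
algorithms and their contracts, not the biological accuracy of any
particular measured landscape.

# Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline at reduced
alphabets chosen so the complete analysis stays comfortably interactive:
graph and subgraph analyses on 4–6 letters at $L = 3$–4 (up to 1296
genotypes), oracle comparisons on ≤ 4096-node instances, and parameter
recovery on an 11-letter, four-site space (14,641 genotypes — the same
order as the motivating 160,000-variant landscape's non-missing portion
divided across folds). The pipeline scales to the full 20-letter space;
only wall-clock time changes.

Other numerical choices: comparisons that gate path accessibility are
strict (`>`); "lethal" means exactly 0; the detection limit enters only
through the epsilon adjustment rules and the deleterious fitness window
(0.01, 1) of to-source subgraph enumeration; Fourier and Taylor systems
are solved exactly (Walsh matrix multiplication, triangular solve), so
round trips are tested at 1e-10–1e-12 tolerances; fitness files are
written in full double precision.

# Known limitations

* Analyses assume the monotone-walk regime: no valley crossing, drift,
  tunneling, or recombination.
* The unique-peak subgraph filter and the bypass survey treat missing
  variants conservatively (skip and count); with heavily incomplete
  landscapes, impute first.
* Imputed landscapes inherit the model's smoothness; peak and basin
  statistics on a completed landscape depend on the imputation model, and
  alternative fits can shift them.
* Protein fitness here is assay fitness (binding-coupled enrichment); no
  claim is made about organismal fitness.
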