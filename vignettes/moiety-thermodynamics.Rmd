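---
title: "Moiety-based thermodynamics: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moiety-based thermodynamics: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The standard transformed Gibbs energy change of a biochemical reaction,
$\Delta_r G'^\circ$, determines its feasible direction and, together with
metabolite concentrations, the driving force available to it. Direct
measurements (apparent equilibrium constants $K'$) exist for only a few
hundred enzymatic reactions, so genome-scale and *de novo* pathway work
depends on group-contribution estimation: write the reaction energy as a sum
of fitted contributions of molecular substructures. Classical group
contribution uses a hand-curated substructure list, which leaves some
metabolites undecomposable and, because the curated groups ignore
stereochemistry, assigns exactly zero to many isomerase and transferase
reactions whose measured energies are not zero.

`moietherm` implements the automated alternative: every non-hydrogen atom of
a metabolite is described by its *bonding environment* — the induced
subgraph on all atoms within one or two bonds — encoded as a canonical
(optionally isomeric) SMILES fragment. These atom-environment *moieties*
are generated mechanically from the structure, so every parseable metabolite
is decomposable, and keeping the stereo annotations lets mirror-image
environments carry different contributions.

## Fragmentation model

For a molecule with heavy atoms $a = 1 \dots H$, the radius-$r$ environment
of $a$ is the induced subgraph on all atoms within $r$ bonds of $a$,
including every bond among those atoms (ring closures between peripheral
atoms are kept). The environment is written as a canonical SMILES fragment;
with stereochemistry disabled all chirality annotations are stripped first.
Each heavy atom contributes exactly one environment, so for every molecule
and radius the moiety counts sum to the heavy-atom count — the conservation
invariant asserted throughout the test suite. Radius 0 is excluded (a bare
atom carries no bonding information) and radii above 2 are rejected: the
moiety alphabet grows combinatorially with radius and overfits the amount of
experimental data available for training.

Per-compound counts are collected into the incidence matrix $G_{i,g}$
(compounds $\times$ moieties). With both radii requested, $G$ is the
horizontal concatenation of the radius-1 and radius-2 matrices; columns are
namespaced by radius (`r1:`/`r2:` prefixes) and ordered lexicographically so
the matrix is reproducible run to run. For a reaction with stoichiometric
column $S_{\cdot j}$ (reactants negative), the feature vector is the net
moiety change $x_j = S_{\cdot j}^T G$, which is antisymmetric under reaction
reversal and sums to the signed heavy-atom change at each radius.

Three properties of fragment keys are worth knowing:

* Keys are *unrooted* canonical fragment SMILES. The two heavy atoms of
  hydroxylamine both see the whole two-atom fragment, so NH$_2$OH yields a
  single key `NO` with count 2. This matches the toolkit convention the
  stereochemistry worked example validates.
* A stereo tag on a fragment centre encodes parent context: re-canonicalizing
  `C[C@@H](C)O` *as a standalone molecule* drops the tag because the two
  methyl neighbours are locally indistinguishable. Keys are therefore
  canonical with respect to the fragment extractor; idempotence under
  re-canonicalization holds for stereo-free keys.
* Moiety keys are canonicalization-dependent, so every incidence matrix and
  fitted model records the toolkit name and version (RDKit, driven through a
  bundled Python worker), and models refuse to be meaningful across
  canonicalization dialects.

The stereochemistry worked example — a C15 tricyclic sesquiterpene on the
zizaane skeleton whose structure was reconstructed to match its published
decomposition behaviour (the structure figure itself is not machine-readable)
— splits into 7 radius-1 moieties with stereochemistry and 5 without; the
pair `C[C@@H](C)C` / `CC(C)C` is the canonical illustration of what stereo
stripping merges.

## Regression model

Observed reaction energies (standardized to reference protonation states,
below) are modelled as
$$y_j = x_j \cdot \Delta_g G^\circ + \varepsilon_j, \qquad
  \varepsilon_j \sim N(0, \beta^{-1}),$$
with an isotropic zero-mean Gaussian prior
$\Delta_g G^\circ \sim N(0, \alpha^{-1} I)$. The posterior mode equals the
ridge estimate with penalty $\lambda = \alpha/\beta$; there is deliberately
no intercept, so a reaction with zero net moiety change predicts exactly
zero. The posterior covariance is
$S_N = (\alpha I + \beta X^T X)^{-1}$ and the predictive distribution for a
change vector $x$ is Gaussian with mean $x \cdot \Delta_g G^\circ$ and
variance $1/\beta + x^T S_N x$.

Unless both precisions are supplied, they are estimated by MacKay-style
evidence maximization: iterate
$\gamma = \sum_i \beta\lambda_i/(\alpha + \beta\lambda_i)$
(the effective number of well-determined parameters, with $\lambda_i$ the
eigenvalues of $X^TX$), $\alpha \leftarrow \gamma / \lVert m \rVert^2$,
$\beta \leftarrow (n - \gamma)/\mathrm{RSS}$, to a relative tolerance of
$10^{-6}$ with at most 300 iterations from $\alpha = \beta = 1$. The
optimum is insensitive to the initialization (asserted over 50 random
starts), which is why a fixed default initialization is safe. Numerically,
eigenvalues below $10^{-12}$ of the largest are treated as an exact null
space: their projections of $X^T y$ are zeroed rather than amplified, which
keeps noiseless (and rank-deficient) problems stable; on such problems
$\beta$ saturates at a cap of $10^{12}$, i.e. an effectively noise-free
likelihood.

Moieties absent from the training columns contribute zero to the predictive
mean and their full prior variance $x_g^2/\alpha$ to the predictive
variance. Coverage is therefore never lost: unseen chemistry widens the
interval instead of aborting the prediction, and the variance floor
$\beta^{-1/2}$ holds always.

A nonlinear alternative — a single-hidden-layer perceptron with 100
rectified-linear units trained by L-BFGS on the mean squared error — is
provided for comparison. It is implemented directly (forward pass, analytic
gradients, `stats::optim`) because no installed R package offers this exact
architecture with L-BFGS training; the seed argument is mandatory since the
fit is otherwise not reproducible. On the reference experimental corpus the
linear combined-radius model is the better-calibrated choice
(cross-validation error of the nonlinear variants is worse despite lower
training error), so the linear model is the default everywhere.

Overfitting is measured by leave-one-out cross-validation at the reaction
level: each held-out reaction is predicted by a model refitted (including
hyperparameters) without it, and the median absolute error is reported. A
subsampled mode (every $k$-th reaction) exists for desk-scale runs and is
flagged in its output.

## Protonation states and conditions

A compound in solution is a Boltzmann mixture of protonation states
(pseudoisomers). Training observations arrive as $K'$ or
$\Delta_r G'^\circ$ at some pH, ionic strength $I$ and temperature $T$; the
regression operates on energies of single reference pseudoisomers. The
per-compound offset between the two frames is
$$\Delta\Delta G = RT\ln 10\, m\, \mathrm{pH}
  - RT \ln \sum_{n=0}^{N_H} \exp\Big[\ln 10 \sum_{i=m+1}^{n}
  (\mathrm{p}K_a(i) - \mathrm{pH}) +
  \frac{A\,(z_n^2 - n)\sqrt{I}}{RT\,(1 + 1.6\sqrt{I})}\Big],$$
where $m$ and $z_{\mathrm{ref}}$ describe the reference state (most abundant
at pH 7, $I = 0.25$ M), $z_n = z_{\mathrm{ref}} + (n - m)$, and
$A = 2.91482$ kJ mol$^{-1}$ M$^{-1/2}$ is the extended Debye–Hückel
prefactor in the Alberty convention (the inner sum runs downward with
negated sign for $n < m$). The Boltzmann sum is evaluated with log-sum-exp
so extreme $\mathrm{p}K_a$ values cannot overflow. The implementation is
checked against an independent oracle that enumerates the pseudoisomer
formation energies explicitly and Boltzmann-averages them, plus two closed
forms: $\Delta\Delta G = 0$ for a compound with no dissociable protons, and
$\Delta\Delta G = RT\ln 10\, m\,\mathrm{pH}$ when all deprotonated states
are suppressed. $\Delta\Delta G$ is nondecreasing in pH (its slope is
$RT\ln 10$ times the mean bound-proton count).

Training observations are standardized at reaction level,
$\Delta_r G^\circ = \Delta_r G'^\circ_{\mathrm{obs}} - \sum_i S_{ij}
\Delta\Delta G_i$, and predictions are transformed back with the exact
inverse — the round trip is machine-precision exact by construction, and the
predictive standard deviation passes through unchanged because the transform
is deterministic given the specs. Solving for per-compound formation
energies is deliberately avoided: the regression consumes reaction energies
directly, so the reaction-level transform is sufficient and better
conditioned. $\mathrm{p}K_a$ values are user-supplied (TSV); compounds
without a specification contribute a zero offset with a warning, which is
also the default treatment of novel metabolites. Actual (non-standard)
driving forces add $RT \sum_i S_{ij}\ln c_i$; the gas constant factor is
included on dimensional grounds. The proton itself is never a compound —
its bookkeeping lives entirely inside the transform — and water is an
ordinary compound.

## Reaction rules and directionality

Reactions performing the same substrate-to-product transformation share a
net moiety-change vector; deduplicating by that vector yields reaction
rules usable by retrosynthetic pathway search. A rule and its exact
negation are unified by orienting the vector so its first nonzero entry (in
the lexicographic moiety order) is positive, recording each member's
original direction. A rule is labelled irreversible only when *both* its
$\pm k\sigma$ credible interval excludes zero ($k = 3$ by default, ~99.7%)
*and* $|\Delta_r G'^\circ|$ exceeds a conservative cutoff (20 kJ/mol by
default) — concentrations are rarely known at design time and can tilt
smaller driving forces. Labels are antisymmetric in the mean, and inflating
the uncertainty can only move rules toward `reversible`.

## Synthetic corpus: what it emulates and what it does not

The generator builds a library from a fixed template grammar — carbon
chains of length 2–8 decorated with up to two substituents from {OH, NH2,
SH, CH3, Cl}, optionally at stereocentres — which guarantees chemically
valid molecules without random graph generation. True moiety contributions
are drawn from $N(0, 30^2)$ kJ/mol, matching the scale of contributions
fitted on experimental corpora; observations are exactly additive in
radius-1 moieties plus $N(0, \sigma^2)$ noise with $\sigma = 1$ kJ/mol by
default; the default problem size is 40 molecules and 1,000 sparse
reactions. The library always contains the 2-butanol enantiomer pair and
the reaction interconverting them, whose change vector is zero without
stereochemistry and nonzero with it — the epimerase scenario.

One structural fact shapes the recovery tests: incidence matrices carry
exact counting identities (a hydroxyl oxygen's environment count equals the
summed counts of the carbon environments it decorates), so $X = S^T G$ can
never have full column rank. The generator therefore requires the reaction
set to preserve the library's information content
($\mathrm{rank}(S^TG) = \mathrm{rank}(G)$, redrawing otherwise), and
`identifiable_moieties()` reports which contribution axes lie in the row
space. Noiseless corpora are recovered to numerical precision on
identifiable axes; on all axes the $\pm 3$ posterior-sd intervals cover the
generating values (the truth is drawn from the prior, so Bayesian coverage
holds without identifiability).

What passing these tests shows — and does not show — about real data: the
generator realizes the statistical structure of the estimation problem
(sparse integer designs, shared moieties, additive energetics, Gaussian
noise) but not real thermochemistry: its "energies" are synthetic, its
molecules are small acyclic templates, its reactions are not element
balanced, and measurement error in real equilibrium data is neither
Gaussian nor homoscedastic. Accuracy numbers on real corpora must come from
the experimental training data (the public TECRDB-derived corpus can be
pointed to with `load_thermo_corpus()`, never downloaded automatically).

## Numerical and interface choices

* Problem sizes in the routine test/verification runs are desk-scale by
  design: 200 template molecules for the conservation sweep, 50 random
  instances for the closed-form ridge comparison, corpora of 1,000
  reactions across 5 seeds for recovery, and 20-fold-subsampled LOOCV.
* Element balance of a reaction (hydrogens excluded, since protonation is
  the transform's business) is checked and *flagged*, not enforced:
  rule-like transformations often track cofactors externally.
* Any compound ID absent from the compound table must come with a structure
  (InChI or SMILES); the `N#####` naming of novel metabolites is a
  convention, not enforced semantics.
* Temperature defaults to 298.15 K, pH 7, $I$ = 0.25 M; each training row
  carries its own conditions. All energies are kJ/mol.
* Model bundles are JSON at full precision and embed the moiety index, both
  precisions, the posterior covariance, the decomposition mode and the
  toolkit version. The CLI prints 2 decimals; JSON output is full
  precision.
* Structures containing metal atoms or repeat-unit wildcards are rejected
  with a dedicated error class: no training information exists for them.

## Known limitations

* Stereocentres whose neighbourhoods only differ beyond the chosen radius
  cannot be resolved (implicit-hydrogen fragment SMILES carry no tag when
  the in-radius neighbours are locally equivalent), so some isomerase
  reactions still register a zero change vector even at combined radii.
* Contributions of moieties tied together by counting identities are only
  determined up to the identity; predictions are unaffected, but
  per-moiety interpretation should consult `identifiable_moieties()`.
* The pseudoisomer model covers protonation only — no magnesium binding and
  no temperature dependence of the dissociation constants.
* Moiety keys do not transfer across canonicalization toolkits or versions;
  retrain (or at least re-derive the incidence matrix) when the toolkit
  changes.
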