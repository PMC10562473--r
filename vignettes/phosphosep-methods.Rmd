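---
title: "Models and methods behind phosphosep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phosphosep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(phosphosep)
```

`phosphosep` studies one question from several directions: how does
CDK-driven multisite phosphorylation change the tendency of an
intrinsically disordered protein (IDP) to undergo liquid--liquid phase
separation? Each phosphate adds two negative charges at a serine or
threonine, so multisite phosphorylation rewrites both the net charge and
the charge patterning of a disordered chain. The package provides the
sequence models, the polymer-physics calculations, the single-chain
simulator, the FRAP kinetics fit, and the phosphoproteome statistics needed
to analyse that mechanism end-to-end, plus seeded generators so everything
runs offline on synthetic inputs.

## Charge sequences

Residue charges are table lookups: Asp/Glu $-1e$, Arg/Lys $+1e$, all
others neutral. Two named schemes differ only in histidine — neutral in
the `scdm` scheme used for analytical calculations, $+0.5e$ in the `cg`
scheme used by the bead simulator — because the two conventions serve
different downstream models and should never be mixed silently.
Phosphorylated S/T carries $-2e$; a phosphomimetic substitution (S/T to
D/E) only $-1e$, which is exactly why mimics often fail to reproduce
phosphorylation effects: at eleven sites the difference is $-22e$ versus
$-11e$. Terminal charges and pH dependence are ignored; the underlying
coarse-grained models are fixed-charge models, and adding titration would
suggest a precision the theory does not have.

Phosphosite combinations are enumerated as bitmask subsets (site $i$ maps
to bit $i$), which makes scans deterministic, order-independent, and easy
to key. Enumeration refuses more than 20 sites by default ($2^n$ memory).

## Selecting the analysis IDR

Disorder is read either from AlphaFold per-residue confidence (pLDDT,
disordered below 50) or an IUPred-style score (disordered above 0.5).
For pLDDT tracks the analysis region is the longest contiguous window in
which more than 60% of residues are disordered, found by exact search over
all windows (ties resolved to the smallest start). Inside that window the
longest ordered run (LOR) is located; if it exceeds 15% of the window the
window is truncated to end just before the run, and the rule is re-applied
to the remainder. When the longest ordered run sits at the very start of
the window there is no prefix to keep, so the run itself is trimmed and
the search continues on the disordered remainder — without this edge rule
a qualifying window with an ordered flank would vanish entirely. The 15%
threshold is a convention, exposed as a parameter. IUPred tracks use the
simpler rule: the longest run of consecutive disordered residues.

## SCDM maps

The sequence charge decoration matrix assigns each residue pair $(i, j)$ a
measure of how the charge pattern of the intervening segment promotes
(negative) or opposes (positive) contact between them. The default kernel
is the windowed charge-decoration sum

$$\mathrm{SCDM}(i,j) \;=\; \frac{1}{j-i} \sum_{i \le n < m \le j}
q_m q_n \sqrt{m-n},$$

computed with an $O(N^2)$ recurrence and verified in the tests against an
independent brute-force double sum. The kernel sits behind a named-kernel
interface (any function `(q, i, j)` can be swapped in) because variants of
this family differ in distance exponent and normalisation between
publications; the interface is the containment boundary for that choice.
One caution discovered while testing: the *mean* over all matrix entries
is not a blockiness metric — windows interior to a charge block are
purely repulsive, so a diblock has a higher matrix mean than an
alternating sequence even though it is far more attractive overall. The
scalar chain SCD (`sequence_scd()`), equivalently the $(1, N)$ entry, is
the monotone statistic and is what the synthetic polyampholyte family is
scored with.

## Phase diagrams

The free energy per lattice site (in $kT$, lengths in bond units) of a
solution of chains with charge sequence $\{q_i\}$ is

$$f(\phi) = \frac{\phi}{N}\ln\phi + \phi_c \ln \phi_c
          + \phi_s\ln\phi_s - \chi\phi^2 + f_{el}(\phi),$$

with solvent $\phi_s = 1 - (1 + r)\phi$ and, when the chain carries net
charge $Q$, neutralising counterions at $\phi_c = r\phi$, $r = |Q|/N$.
The Flory--Huggins term couples as $\chi = \varepsilon/T^*$ and collects
hydrophobic, cation-$\pi$ and other non-electrostatic attractions;
$\varepsilon = 2\,kT$ is the generic default, with $2.5\,kT$ used for the
consensus-repeat runs, where phase separation in vitro required crowding.
The electrostatic correlation term is the one-loop (RPA) integral built
from the Gaussian-chain sequence charge structure factor

$$S(k) = \frac{1}{N}\sum_{m,n} q_m q_n e^{-k^2|m-n|/6},$$

$$f_{el} = \frac{1}{4\pi^2}\int_0^\infty k^2
\left[\ln(1 + x(k)) - x(k)\right] dk, \qquad
x(k) = \frac{4\pi \ell_B}{k^2}\bigl(\phi\,(r + S(k)) + 2\rho_{salt}\bigr),$$

with $\ell_B = 1/T^*$; subtracting the linear term removes the
self-energy and regularises the ultraviolet end. Counterions matter:
without their translational entropy (an effective $r/\phi$ term in the
curvature) the model has no penalty for net charge, and the suppression
of phase separation by charge overshoot — the heart of the
phosphorylation switch — disappears. Added salt is exposed as a
dimensionless density, default zero.

The reduced temperature $T^*$ is the ratio of bond length to Bjerrum
length, so electrostatics strengthen as $T^*$ falls; together with
$\chi = \varepsilon/T^*$ this means only orderings and ratios of $T^*$
are meaningful, never absolute temperatures.

Numerics: all four $\phi$-derivatives of $f$ are analytic, including the
correlation integral (the integrand's derivatives are closed-form), so no
finite differences appear anywhere. The $k$-integral uses Gauss--Legendre
quadrature on a log grid (192 nodes from $10^{-9}$ to 60) plus an
analytic $1/k$ tail. The critical point is the highest $T^*$ at which
$\min_\phi \partial^2 f/\partial\phi^2 = 0$, found by bisection (the
minimiser is then the critical density, where the third derivative
vanishes by construction); with electrostatics off this reproduces the
Flory--Huggins closed form $\phi_c = 1/(1+\sqrt N)$,
$\chi_c = (1+1/\sqrt N)^2/2$ to $10^{-6}$, the package's standing oracle.
Coexistence at each temperature is solved by monotone bisection on the
chemical potential between the spinodal bounds (equal grand potential in
both phases), which closes chemical-potential and pressure gaps to
machine precision; dilute branches are bracketed down to $\phi = 10^{-14}$
in log space because charged dilute arms are extremely small.

Two electrostatics modes are exposed. `rpa` — the reference
implementation used everywhere by default — takes Gaussian chain
statistics as given. `rg_rpa` renormalises them with a Flory-type
single-chain variational factor $x$ (elastic cost $\tfrac32(x - \ln x)$
balanced against the unscreened intrachain charge energy, which scales as
$x^{-1/2}$), then uses $e^{-k^2 x|m-n|/6}$ in $S(k)$. The full
renormalised theory in the literature couples $x$ to density and
screening self-consistently; the variational single-chain condition here
is the package's own simplification, kept behind the mode switch so a
verbatim implementation can replace it without touching callers. All
package-level claims are checked in `rpa` mode and are mode-agnostic
properties (orderings, closed-form limits, thermodynamic consistency).

## The combinatorial phosphosite scan

`phospho_scan()` computes critical points for every phosphorylation
pattern of a candidate-site list ($2^{11} = 2048$ for the consensus
repeat). The quadrature kernel and the structure-factor machinery are
cached across patterns; caching is an optimisation contract only —
results are identical with or without it, and a test permutes the
candidate order to prove it. Per-stoichiometry extremes (highest and
lowest $T_c^*$) are flagged so full phase diagrams need only be drawn for
them and the unmodified sequence.

The bundled `ki67_consensus_repeat()` is a synthetic 122-residue
stand-in, not a natural sequence: a basic disordered repeat with eleven
proline-directed S/T sites and net charge $+7e$. The net charge was
chosen once, from the mechanism the scan probes: each phosphosite adds
$-2e$, so charge neutrality falls mid-scan ($k \approx 3.5$) and full
phosphorylation overshoots to $-15e$, farther from neutral than the
unmodified chain. Under the free energy above this produces the
characteristic buffered switch: a handful of phosphosites *raise* the
critical temperature (the chain approaches neutrality and polyampholyte
attraction grows), while eight or more *lower* it below the unmodified
value (net-charge penalty dominates). The acceptance suite asserts the
full pattern on all 2048 combinations.

## The coarse-grained simulator

One bead per residue; harmonic bonds (1000 kJ/mol/nm$^2$, 0.38 nm);
screened Coulomb with a 1 nm Debye length on the `cg` charge scheme;
short-range interactions $4\lambda_{ij}\epsilon[(\sigma_{ij}/r)^{12} -
(\sigma_{ij}/r)^6]$ with per-residue $\lambda, \sigma$ combined by
arithmetic means from an editable parameter table
(`inst/extdata/cg_params.tsv`, standard hydrophobicity-scale values;
the phospho-S/T rows are provisional), $\lambda$ for Arg--Arg overridden
to 0.01 after combination so excluded volume survives, and an
Ashbaugh--Hatch split available behind a switch. Pair potentials are cut
at $3\sigma_{ij}$ (Coulomb at 3.5 nm) and shifted to zero. Dynamics are
BAOAB Langevin at 10 fs and 25 ps$^{-1}$ — stable for the stiff bonds at
this time step — with bitwise-reproducible seeded noise.

Desk-scale sampling choices, stated as such: replica exchange is replaced
by independent seeded runs on a temperature ladder; multi-chain slab
simulation is out of scope (density profiles come from files or the
synthetic generator); production runs in the tests are $10^5$–$10^6$
steps. Two sampling facts shaped the test design. First, the thermal
mean of a harmonic bond *includes the radial Jacobian*:
$\langle r\rangle = r_0 + 2kT/(\kappa r_0) + O(kT^2)$, about $+3.4\%$ at
300 K — so the simulator is checked against the exact one-dimensional
quadrature of that average, not against the bare $r_0$. Second, the
global size of a 122-mer relaxes on the Rouse time
($\sim 10^7$ steps here), so single runs are bias-dominated; the
ideal-chain check instead averages an ensemble of short runs whose
random-walk initial conformations are themselves equilibrium draws.
Interacting chains start from an extended conformation, or from a random
walk with a force-capped push-off (`cap_steps`) to relax overlaps.

Estimators: mass-uniform radius of gyration with the standard
10-block SEM; intramolecular distances $R(|i-j|)$ fitted by
$R = 0.55\,|i-j|^\nu$ with the prefactor fixed and separations below 5
excluded (log-space linear solve); the theta temperature is the linear
interpolation of $\nu(T) = 0.5$, taking the lowest-temperature crossing
with a warning if there are several. Coexistence densities come from the
standard slab windows (dilute 0–60 and 140–200 nm, dense 90–110 nm on a
200 nm axis, with proportional rescaling and a warning on other axis
lengths), and the critical temperature from
$\rho_H - \rho_L = A\,(T_c - T)^{0.325}$ with the 3D Ising exponent
fixed, solved by Levenberg--Marquardt from a linearised start.

## FRAP kinetics

Traces are corrected for acquisition photobleaching by dividing each
region by the whole-nucleus mean at the same time point (exact for
multiplicative drift), then scaled so the pre-bleach level is 1. Recovery
is fitted with the single-exponential model $y = c - a e^{-k t}$ via a
self-starting asymptotic regression polished by Levenberg--Marquardt;
non-recovering traces are returned flagged rather than as errors. Two
half-time conventions are exposed and every value is tagged: the source
model's printed form $1/(k \ln 2)$ and the conventional $\ln 2 / k$; they
differ by exactly $(\ln 2)^2$, and which one a published number uses
cannot always be determined, so neither is silently assumed. Total
recovery is $(y_{max} - y_{min})/(1 - y_{min})$. A note on precision:
for the canonical test design (2% noise, 100 one-second samples,
$k = 0.1$) the Cramér--Rao bound already puts the best achievable
relative error on $k$ at 3.3%, so the tests assert efficiency against
that bound rather than an unattainable hit rate.

## Phosphoproteome statistics

The pipeline mirrors standard phosphoproteomics practice: log2
intensities, per-sample median normalisation, left-censored imputation
(normal draws downshifted 1.8 dataset-sd with 0.3 sd width), one-way
ANOVA across timepoints with Benjamini--Hochberg control at 5% to call
dynamic sites. The compositional-bias correction asks, per protein, how
many phosphorylated S/T would fall in disordered regions if
phosphorylation were indifferent to disorder — expected
$= n_{phospho} \times (\text{S/T in IDR})/(\text{S/T total})$ — and
tests the observed count with a one-sided binomial (the null family is
not named in the source material; binomial matches the expected-count
construction and is documented as the choice). Tyrosines are excluded
throughout, matching the S/T framing of the counts. The pooled odds
ratio uses the 2x2 table of phosphorylatable residues
(phosphorylated or not, disordered or not) with Fisher exact inference
and the conditional-MLE interval; a protein-stratified Mantel--Haenszel
estimator is available because "common odds ratio" can be read either
way. Zero cells get the Haldane--Anscombe correction, flagged. Kinase
motif classification implements the printed consensus rules as offset
tables (the asterisk in rule strings marks the phosphosite, not a regex
quantifier; "hydrophobic" is fixed as A,V,I,L,M,F,W,Y); a regex oracle
built independently from the same rule strings checks every label on
random sequences. Group comparisons of disorder fractions use
Wilcoxon--Mann--Whitney for two groups and Kruskal--Wallis with Dunn's
two-sided post hoc z-tests (implemented from the standard mean-rank
formula with ties correction, as no installed package provides it) and
BH adjustment across pairs — always across the full family of one call,
never across silently merged families.

## Synthetic data

The generators define the study conditions rather than adapting to them.
`synth_proteome()` plants: one disordered block per protein (pLDDT
$\sim N(35, 8)$ inside, $N(85, 6)$ outside, clamped); S/T/P- and
charge-enriched composition inside blocks; phosphorylation assigned so
the disordered-vs-structured odds ratio equals a planted value (default
4.6); a configurable fraction of dynamic sites with a 4-sd peak in one
timepoint; and intensity-dependent logistic missingness, because the
downshifted imputation being tested presumes left censoring. Ground
truth always rides along. `synth_polyampholyte()` builds E/K families of
fixed composition and varying block size; `synth_frap()` and
`synth_physics_curves()` generate model-exact (optionally noisy) traces,
distance curves, coexistence gaps and slab profiles, including off-centre
slabs to exercise re-centring.

What passing tests on these generators shows — and does not. Parameter
recovery on planted structure demonstrates the estimators are correct and
calibrated *under the generating model*: real phosphoproteomes have
correlated sites, protein-level random effects, and missingness
mechanisms beyond a logistic in intensity; real IDPs have secondary
structure propensities and non-electrostatic specificity the charge
models ignore. The physics claims are likewise reduced-unit orderings,
not absolute predictions: the theory cannot place transition
temperatures in Kelvin, and the simulator's desk-scale runs cannot
reproduce cluster-scale absolute chain dimensions.

## Problem sizes used by the test suite

Chosen once, as the package's own desk-scale conditions: the full 2048
pattern scan at $N = 122$; coexistence solved on 6–12 temperature
diagrams; bonded-chain checks at $10^6$ steps and 36 seeded short runs;
the phosphorylation-direction run at $2 \times 6 \times 10^5$ steps with
paired seeds; odds-ratio recovery on 100 proteomes of roughly 2000 sites
per planted value; null FDR on 50 proteomes.

## Known limitations

* The `rg_rpa` renormalisation is a single-chain variational
  simplification, not the full density-coupled theory; `rpa` is the
  reference mode.
* Counterion treatment is mean-field (no condensation); added salt is a
  single screening density.
* The phospho-S/T $\lambda/\sigma$ rows in the parameter table are
  provisional values, editable in place.
* One interval per protein is returned by IDR selection (an option lists
  all qualifying windows); multi-IDR proteins are not split.
* The simulator is single-chain only; slab profiles must come from
  outside or from the generator.
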