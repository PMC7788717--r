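---
title: "A condition-specific biomass objective for lipid accumulation in oleaginous yeast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A condition-specific biomass objective for lipid accumulation in oleaginous yeast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oleagem)
```

## The modeling problem

Oleaginous yeasts such as *Cutaneotrichosporon oleaginosus* accumulate
storage lipid — up to more than half of their dry weight — when carbon is
plentiful and nitrogen is not. Flux balance analysis (FBA) predicts
phenotypes by maximizing a biomass objective under steady-state mass balance
(`S v = 0`) and flux bounds, but a *fixed* biomass composition cannot
represent a cell whose composition itself is the phenotype of interest. The
package therefore makes the biomass objective a function of the
carbon-to-nitrogen (C/N) ratio of the uptake rates and propagates that
dependence through growth simulations, lipid-production protocols, gene
knockouts and flux sampling.

## The biomass model

Under nitrogen starvation the macromolecular weight fractions of dry cell
weight (DCW) are partitioned as

$$w_C + w_P + w_{TL} = 0.95,$$

with carbohydrate pinned at $w_C = 0.11$ (nitrogen depletion drives cells to
a maximal structural/storage carbohydrate content, estimated conservatively
from low-C/N chemostat data) and the residual 5% assigned to nucleic acids,
cofactors and minerals, treated as constant. Total lipid follows a quadratic
function of the C/N mass ratio $x$ (g C / g N), fitted to chemostat
measurements:

$$w_{TL}(x) = \frac{-0.002\,x^2 + 0.59\,x + 1.9}{100},$$

and protein absorbs the remainder. The quadratic peaks at $x = 147.5$
(45.4% lipid) and is evaluated on the g/g scale; molar ratios are converted
by $x_{g/g} = x_{mol/mol} \cdot 12.011 / 14.007$, which maps the critical
molar ratio 12.83 to 11 g/g.

```{r}
lipid_weight_percent(c(0, 50, 100, 147.5, 240))
compose_biomass(100, mode = "starvation")
```

Numerical conventions worth stating:

* The polynomial is clamped to $[0, 79]$% so that $w_P \ge 0$ for every
  C/N; beyond the vertex it *decreases* as the fit dictates — no plateau is
  imposed, because the analyses apply the fit up to C/N = 240 without one.
* "Replete" (nitrogen-abundant) mode uses a static composition
  (40/45/10/5% by default). These numbers are configuration, not fitted
  values; they stand in for the measured nitrogen-abundant composition.
* Assembled reactions use coefficients $w_i / MW_i$ (g/mmol), so the
  coefficient-times-MW sum — the molecular weight of the biomass
  pseudo-metabolite — is exactly 1 g/mmol and the biomass flux is the
  specific growth rate in 1/h. Component molecular weights: carbohydrate
  162.14 g/mol (anhydroglucose residue), protein 110 g/mol (average amino
  acid residue), lipid 1000 g/mol (standardized pool), "other" 300 g/mol.
  The identity is verified to $10^{-6}$ for every composition.

The lipid fraction keeps a fixed internal profile: 90% triacylglycerol, 10%
phospholipids split equally among PS, PE and PC. Fatty acids enter through
an artificial acyl-CoA pool whose coefficients are the fatty-acid weight
percentages of total lipid (25/10/57/7% for C16:0/C18:0/C18:1/C18:2)
divided by the molecular weights of the CoA thioesters — i.e. mmol of
acyl-CoA per gram of pool. Multiplying each coefficient by its thioester
molecular weight therefore recovers the weight percentages:

```{r}
acyl_pool_fractions()
```

The printed percentages sum to 99, not 100; the package reports the mass
shares exactly as implied by the printed coefficients rather than
renormalizing by the coefficient *sum*, because molar renormalization would
distort the C16:0 share (25% becomes 25.8%, which rounds to 26).

## The simulation protocols

**Minimal medium.** CO2, water, protons, O2, iron(II), phosphate,
potassium, sodium, sulphate and ammonium have unconstrained uptake
(exchange lower bounds −1000); everything else starts closed. Exchange
reactions are written so that positive flux is secretion.

**C/N conditions.** The carbon exchange is fixed on both bounds (the C/N
ratio is defined between *realized* uptake rates, so carbon must be
consumed exactly); nitrogen is offered as a capacity (lower bound only).
Forcing nitrogen consumption would make every nitrogen-replete cell
infeasible — growth cannot absorb arbitrary excess nitrogen and the network
has no overflow route — and in the nitrogen-limited regime that matters for
lipid accumulation the offered nitrogen is fully consumed anyway, so the
realized C/N equals the nominal one exactly where the distinction counts.

**Lipid production.** Growth is maximized first; if $\mu^* > 0.2$ 1/h the
biomass flux is constrained to $[0.9 \cdot 0.2, 0.2]$ (the growth plateau
observed past the critical C/N), otherwise to $[0.9\mu^*, \mu^*]$ — a
window rather than a point constraint, for solver robustness and symmetry
with the high-growth rule. The lipid-body exchange is then maximized. Two
quantities are reported: the export flux, and the biomass-embedded lipid
production (biomass flux × lipid weight fraction). The sum of the two is
the flux through the lipid pool. The *mode contrast* (condition-specific vs
static biomass) lives in the embedded component: under a fixed biomass
window the maximal export is set by the carbon surplus and is nearly
insensitive to composition, while the embedded lipid production rises with
C/N exactly when the composition does.

**Knockouts.** Reactions whose gene rule evaluates to FALSE under a
deletion are closed; growth and the lipid protocol are re-run. A growth
threshold of $10^{-6}$ 1/h separates "no growth" from numerical noise.

## The synthetic model

`build_toy_gem()` constructs a ~125-reaction, four-compartment (cytosol,
mitochondrion, extracellular, lipid particle) model with a manifest of
ground-truth properties used by the tests (intended category counts,
intentionally lumped reactions, essential genes, carbon-source atom counts,
pathway map). Design choices that shape its phenotypes:

* **ATP-citrate lyase (ACL) is the sole route to cytosolic acetyl-CoA.**
  There is no acetyl-CoA synthetase bypass (the phosphoketolase route ends
  in acetate, which can only be secreted), so deleting the dedicated ACL
  gene abolishes fatty-acid synthesis and — because every biomass
  composition contains lipid — growth.
* **No ethanol assimilation by default.** The ethanol exchange and
  transporter exist, but without alcohol/aldehyde dehydrogenase and
  acetyl-CoA synthetase ethanol is a dead end, reproducing the predicted
  absence of growth on ethanol. `include_ethanol_assimilation = TRUE`
  restores the pathway together with the glyoxylate shunt and PEP
  carboxykinase a C2 substrate requires.
* **Glycerol grows slower than glucose at equal C-mol.** Glycerol import is
  lumped with its proton-symport cost (one ATP per glycerol via the plasma
  membrane ATPase) and the FAD-linked glycerol-3-phosphate shuttle is
  lumped with a zero phosphorylation yield, so glycerol's catabolism is
  energetically inferior per C-mol despite its higher degree of reduction.
* **Malic enzyme is mitochondrial and NAD-dependent**, as annotated for
  this organism; cytosolic NADPH therefore comes from the oxidative pentose
  phosphate pathway, which is what makes PPP fluxes rise with lipid demand.
* **Lumped pseudo-species** (averaged lipids, carbohydrate, protein,
  "other") carry annotated molecular weights derived chain-wise so every
  lipid reaction conserves mass exactly; reactions involving them are
  excluded from elemental balancing, and the one formula-bearing lump (the
  pyrimidine synthesis shortcut) is declared in the manifest.
* **No proton uniport into the cytosol.** Protons leave through the pumped
  route only; a free inward path would register as a spurious
  proton-dissipation cycle in the energy audit.
* Construction is deterministic; the optional `bound_jitter` (with `seed`)
  perturbs only the default metabolic flux caps, for robustness tests.

The generator emulates the topology and the qualitative physiology of the
organism's central and lipid metabolism, not its scale: the real
reconstruction has ~1550 reactions, 11 compartments, branched amino-acid
and nucleotide metabolism and many isoenzymes. Tests passing on the toy
model certify the *machinery* (biomass construction, protocols, audit,
sampling, I/O) and the encoded causal structure; they do not validate
numerical predictions for the real organism.

## Energy audit

Following the standard dissipation-reaction method, one irreversible
dissipation reaction per carrier (ATP, CTP, GTP, UTP, NADH, NADPH, FADH2,
proton export) is added; all other fluxes are clamped to $[-1,1]$ /
$[0,1]$ (forced maintenance lower bounds are relaxed to the clamp floor;
knocked-out reactions stay off), all exchange uptakes are closed, and each
dissipation flux is maximized. Any maximum above $10^{-6}$ certifies an
energy-generating cycle, reported with its flux-carrying support. The
audit is anti-monotone in network size (removing reactions can never create
a cycle), which the tests exercise.

## Flux sampling and Z-scores

The sampler is artificial-centering hit-and-run over
$\{v: Sv = 0,\ lb \le v \le ub\}$: warmup points are flux-variability
optima (polytope extreme points), directions run from random warmup points
through the running center (so they stay inside the feasible affine
subspace, including along fixed coordinates), and numerical drift is
removed by orthogonal projection onto the null space at every recorded
point; each point is verified against $|Sv|_\infty \le 10^{-6}$ and the
bounds. The chain records every 8th step. A wall-clock budget is
deliberately *not* used — a step-count budget keeps results reproducible
across hardware for a fixed seed.

Condition comparison uses
$Z = (\bar v_{cond} - \bar v_{ref}) / \sqrt{s_{cond}^2 + s_{ref}^2}$
per reaction, with C/N = 6 g/g as the reference; positive Z means the flux
increased under nitrogen limitation. The source method does not print its
exact formula; this independent-combination form matches the sign
semantics of the original figures and is declared here. Both sd and se are
reported, since the original error bars' normalization is ambiguous.

Carbon levels stated in grams are mapped to chemostat uptake rates as
$25 \cdot c_g / 12.011$ mmol C gDCW$^{-1}$ h$^{-1}$ (then divided by the
carbon atoms of the source), which places the 16–32 g series inside the
validated uptake decade; the factor is configuration, not physiology. The
acetyl-CoA series fixes urea at an offered 25 mmol/gDCW/h and raises
carbon to realize each C/N, which bounds that sweep to C/N ≲ 17 g/g within
the ±1000 flux caps.

## Problem sizes

The default analysis and test settings are desk-scale by choice: the
synthetic model has ~125 reactions; sampling uses 300–500 points with full
flux-variability warmup (the headline analyses used 5000 points, which the
`n` argument restores); grids are coarsened to a handful of uptakes per
axis. The statistical tolerances in the tests (3 standard errors on box
means, majority shares for Z-score signs) are set for these sizes.

## Known limitations

* The LP core is a dense bounded-variable simplex: right for models up to a
  few thousand variables, not for multi-compartment pan-genome models.
* FBA degeneracy means individual optimal flux vectors are not unique; only
  objective values and protocol outputs are contractual. Sampling, not
  FBA, is the tool for flux distributions.
* The quadratic lipid fit is consumed as given; refitting it (and the
  replete-mode composition) requires the original chemostat data.
* Z-scores compare sampled distributions, not biological replicates; they
  quantify constraint-geometry shifts, not measurement uncertainty.
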