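# oleagem

Constraint-based analysis of lipid accumulation in the oleaginous yeast
*Cutaneotrichosporon oleaginosus*, for systems-biology researchers studying
microbial lipid production under nitrogen limitation.

Oleaginous yeasts re-route excess carbon into storage lipids when nitrogen
runs short; the carbon-to-nitrogen (C/N) ratio of the medium is the main
control variable. A genome-scale metabolic model can only predict this if its
biomass objective reflects the condition: `oleagem` implements a
**condition-specific biomass objective function** in which the macromolecular
composition of biomass is a function of C/N, and couples it to a flux balance
analysis (FBA) engine, simulation protocols for lipid production and gene
knockouts, an energy-cycle audit, and hit-and-run sampling of the flux
polytope with Z-score comparison between conditions.

The core model, in the field's usual notation:

- Weight fractions of dry cell weight (DCW) under nitrogen starvation
  satisfy `w_C + w_P + w_TL = 0.95`, with carbohydrate pinned at
  `w_C = 0.11` and 5% assigned to nucleic acids, cofactors and minerals.
- Total lipid follows the quadratic fit
  `w_TL(x) = (-0.002 x² + 0.59 x + 1.9) / 100` with `x` the C/N ratio in
  g/g, clamped to `[0, 79]`% (maximum 45.4% at the vertex `x = 147.5`);
  protein takes the remainder.
- The lipid fraction is 90% triacylglycerol and 10% phospholipids
  (PS/PE/PC in equal thirds); fatty acids enter through an acyl-CoA pool
  reaction `0.24952 C16:0-CoA + 0.096712 C18:0-CoA + 0.55233 C18:1-CoA +
  0.067963 C18:2-CoA -> pool`, whose coefficients are weight percentages
  divided by the thioester molecular weights.
- The assembled biomass reaction is standardized to a molecular weight of
  1 g/mmol, so its flux is the specific growth rate µ (1/h).
- Lipid production protocol: maximize biomass; if `µ* > 0.2` 1/h constrain
  the biomass flux to `[0.9·0.2, 0.2]`, otherwise to `[0.9 µ*, µ*]`; then
  maximize the lipid-body exchange.

Everything runs against a bundled ~125-reaction synthetic genome-scale model
of the organism's central carbon and lipid metabolism (glycolysis, pentose
phosphate pathway, phosphoketolase route, TCA cycle with citrate export,
ATP-citrate lyase, acetyl-CoA carboxylase, a lumped fatty acid synthase,
desaturation, TAG/phospholipid synthesis and a lipid-body exchange), so no
download is needed. SBML Level 3 + FBC and a native JSON dialect are
supported for external models. The LP core is a bounded-variable simplex
included in the package.

## Worked example

```r
library(oleagem)

tg <- build_toy_gem()          # synthetic model + ground-truth manifest
fba(tg$model)$objective        # growth on glucose minimal medium
#> [1] 0.8915314

# C/N ratio of the high-lipid experimental medium (16 g/l glycerol, 1 g/l NH4Cl)
cn_ratio_from_medium(medium_spec(
  data.frame(id = c("glycerol", "nh4cl"), conc_g_l = c(16, 1))))
#> C/N = 27.88 mol/mol = 23.91 g/g

# condition-specific biomass at C/N = 100 g/g
compose_biomass(100, mode = "starvation")
#> biomass composition (starvation, C/N = 100 g/g):
#>   carbohydrate 11.0%  protein 43.1%  total lipid 40.9%  other 5.0%

# ATP-citrate lyase knockout: growth and lipid production collapse
ko <- knockout_growth(tg$model, tg$manifest$acl_gene)
c(mu = ko$mu, lipid = ko$lipid_flux)
#>           mu        lipid
#> 1.142403e-12 0.000000e+00
```

The growth rate of 0.89 1/h is the glucose validation condition (uptake
10 mmol/gDCW/h, replete biomass). The composition at C/N = 100 shows the
starvation partition: carbohydrate fixed at 11%, lipid at 40.9% from the
quadratic, protein absorbing the rest. The knockout result reflects the
network structure: citrate export plus ATP-citrate lyase is the only route
to cytosolic acetyl-CoA, so deleting the ACL gene abolishes fatty-acid
synthesis and, because biomass always contains lipid, growth.

## Analysis workflow

The numbered scripts under `analysis/` run the package's computational
experiments at desk scale and write tables under `results/`:

| script | what it does |
|---|---|
| `01_build_model.R` | build, structurally check and export the synthetic model |
| `02_validate_model.R` | energy-cycle audit, carbon-source growth screen, ACL knockout |
| `03_cn_lipid_grid.R` | lipid production across C/N, dynamic vs static biomass |
| `04_acetylcoa_series.R` | sampled fluxes of citrate transport/ACL/acyl pool/lipid export vs C/N |
| `05_zscore_series.R` | per-reaction Z-scores of flux shifts against the C/N = 6 g/g reference |

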