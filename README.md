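# trophoweb

Tools for assembling, comparing and energetically annotating **binary
(presence/absence) trophic networks**, built around the kind of question a
severe ecosystem disturbance raises: how did the food web of a coastal
lagoon change between the period before a eutrophication event and the
period after it? The motivating system is the Comacchio Lagoon (northern
Adriatic), where the 1980s eutrophication replaced seagrass meadows with a
cyanobacteria-dominated regime; the package ships the published summary
tables of that contrast and everything needed to rerun the same analysis on
any pair of webs — or on synthetic ones.

The intended users are ecologists comparing food webs across time, sites or
disturbance regimes from literature-compiled interaction data, where only
binary diet information (plus, sometimes, biomasses) is available.

## What it computes

A web is a directed graph with edges oriented **prey → predator** (energy
flow) and node attributes: category (producer, cyanobacteria, detritus,
animal), functional group, total biomass *B* (g) and mean body mass *M* (g).

**Topology** (on the symmetrized web, where *i*–*j* are linked iff
*x*<sub>ij</sub> + *x*<sub>ji</sub> ≥ 1):

- density *D* = 2*L* / *N*(*N* − 1);
- degree-weighted overall clustering *CL* = Σ *k*<sub>i</sub>*c*<sub>i</sub> / Σ *k*<sub>i</sub>,
  with *c*<sub>i</sub> the local clustering coefficient;
- average geodesic distance *d* over unordered pairs;
- small-world ratio *SW* = *CL*/*d*;
- normalized degree centrality nDC<sub>i</sub> = *k*<sub>i</sub>/(*N* − 1) and
  normalized betweenness nBC<sub>i</sub> = 100 · *B*<sub>i</sub> / [(*N* − 1)(*N* − 2)/2],
  with exact shortest-path counts (Brandes accumulation).

**Trophic levels** (on the directed web): basal nodes (producers,
cyanobacteria, detritus, and anything with no prey) are fixed at TL = 1;
every consumer satisfies TL<sub>i</sub> = 1 + Σ<sub>j</sub> *q*<sub>ij</sub> TL<sub>j</sub>
with equal diet shares *q* over its prey (binary webs). The system is solved
exactly as a dense linear solve.

**Energy fluxes**: steady-state fluxes *F*[i,j] = *W*[i,j] *G*<sub>j</sub>
with biomass-scaled preferences *W* and total consumption *G* satisfying the
per-prey-efficiency balance

&nbsp;&nbsp;Σ<sub>i</sub> *e*<sub>i</sub> *F*[i,j] = *X*<sub>j</sub> + Σ<sub>k</sub> *F*[j,k]

for every consumer *j*, where *e*<sub>i</sub> is the assimilation efficiency
of prey *i*'s category (defaults: animal 0.906, producer/cyanobacteria
0.545, detritus 0.158) and *X*<sub>j</sub> = *a* *M*<sub>j</sub><sup>*b*</sup> *B*<sub>j</sub>
the metabolic loss (defaults *a* = 0.71, *b* = −0.25; basal losses are 0 and
basal biomass is the placeholder 1, the top-down convention).

A seeded **niche-interval generator** (`generate_niche_web()`) produces
connected, acyclic binary webs with calibrated undirected density, plus
lognormal biomass/body-mass attributes and baseline/perturbed web pairs
emulating a disturbance (`generate_disturbance_pair()`).

## Worked example

```r
library(trophoweb)

web <- food_web(
  edges = data.frame(
    prey     = c("Ruppia", "Ruppia", "Detritus", "Detritus", "Grazers", "Copepoda", "Grazers"),
    predator = c("Grazers", "Mugil",  "Copepoda", "Grazers",  "Mugil",   "Atherina", "Atherina")),
  nodes = data.frame(
    name      = c("Ruppia",   "Detritus", "Grazers", "Copepoda", "Mugil", "Atherina"),
    category  = c("producer", "detritus", "animal",  "animal",   "animal", "animal"),
    biomass   = c(NA,         NA,         120,        35,         60,      25),
    body_mass = c(NA,         NA,         0.4,        0.001,      350,     4)),
  label = "demo")

global_metrics(symmetrize(web))
#>                                          metric abbreviation     value
#> 1                               Number of nodes            N 6.0000000
#> 2                               Number of links            L 7.0000000
#> 3                               Network density            D 0.4666667
#> 4 Weighted overall graph clustering coefficient           CL 0.3333333
#> 5                              Average distance            d 1.6666667
#> 6                             Small world index           SW 0.2000000

trophic_levels(web)
#> Trophic levels (equal diet shares; 2 basal nodes at TL = 1)
#> Atherina    Mugil Copepoda  Grazers Detritus   Ruppia
#>      3.0      2.5      2.0      2.0      1.0      1.0

energy_fluxes(web)
#> <flux_model 'demo'> 6 nodes (2 basal), 7 positive fluxes
#>   total flux 1295, Shannon flow diversity H = 0.8988
#>   max |balance residual| = 1.07e-14
```

The global table says the demo web is dense (*D* = 0.47: almost half of all
possible feeding relationships are realized), moderately clustered, and
two steps across on average. The trophic levels read off the energy
pathways: grazers and copepods feed one level above the plant/detritus
base, the mullet's mixed diet puts it at 2.5, and the fish-eating *Atherina*
tops the web at 3.0. The flux model distributes each consumer's energetic
demand over its prey in proportion to prey biomass; the balance residual
(~1e-14) confirms that assimilated inflow exactly meets metabolic loss plus
predation outflow at every consumer.

For a full two-web comparison use `compare_webs()` or
`run_full_analysis(pre, post, out_dir = "...")`, which writes the global
and node metric tables, trophic levels, flux matrices (raw and log10) and a
comparison report. The published Comacchio summary tables are available via
`comacchio_environment()`, `comacchio_global_metrics()`,
`comacchio_functional_groups()` and `comacchio_scheme()`.

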