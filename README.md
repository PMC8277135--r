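# seabedrisk

Causal, probabilistic environmental risk assessment for seabed mineral
extraction.

Seabed mining — for example removing ferromanganese (FeMn) concretions from
the Baltic seabed by suction hopper dredging — is a prospective activity with
essentially no observational impact data. `seabedrisk` implements the
workflow such assessments use when expert knowledge is the only evidence
available:

1. **Risk identification.** Individual expert causal maps (directed graphs of
   cause–effect beliefs, with optional 1–3 link strengths) are harmonized
   against a synonym table and merged into one combined causal network that
   keeps per-expert provenance on every connection.
2. **Quantification.** A subnetwork is promoted to a discrete Bayesian
   network: random variables carry conditional probability tables (CPTs),
   while *decision* variables (mining intensity, depth of extracted
   sediment, processing return technique) are controlled by the operator and
   carry no prior. CPTs can be initialized from ranked parent influences
   (direction and magnitude per parent, populated by a scoring algorithm)
   and adjusted row-by-row in a second expert session.
3. **Scenario analysis.** Exact posterior distributions (variable
   elimination) of benthic-fauna mortality are queried under alternative
   mining scenarios, and stressors are ranked by their effect on expected
   mortality.

The model at the core is the mortality combination for a benthic functional
group within a discrete mining block. Relative mortality is discretized into
five ordered classes (0–10 / 11–30 / 31–60 / 61–80 / 81–100 %). Direct
mortality D (proportionate to the mined fraction of the block) and indirect
mortality I (of the fauna remaining after extraction, exposed to suspended
sediment, sediment deposition, and contaminant release) combine as

    T = D + I · (1 − D)

computed by numerical approximation at 1 % accuracy: class distributions are
expanded uniformly onto the integer-percent grid 0…100, combined pairwise
with half-up rounding, and re-binned into the five classes. The resulting
25-row CPT makes total mortality a deterministic function of its two
parents.

A synthetic-data module generates everything the pipeline consumes — 11
expert maps of 8–24 variables drawn from a hidden 53-variable / 96-connection
consensus graph, an 18-node Bayesian network with monotone
pressure→mortality CPTs, and a full factorial scenario suite — so every
stage is testable offline. The packaged fixtures under `inst/extdata/` are
synthetic stand-ins built to that elicited scale (filenames carry
`_synthetic`); the original fitted CPTs can be loaded through
`read_cpt_table()` / `read_model_file()` when available.

## Worked example

```r
library(seabedrisk)

# 1. combined causal network from the packaged expert maps
maps <- read_concept_maps(system.file("extdata", "expert_maps_synthetic.csv",
                                      package = "seabedrisk"))
syn  <- read_synonym_table(system.file("extdata", "synonyms_synthetic.csv",
                                       package = "seabedrisk"))
net  <- merge_concept_maps(lapply(maps, harmonize, synonyms = syn))
summarize_network(net)[c("n_nodes", "n_edges")]
#> $n_nodes
#> [1] 53
#> $n_edges
#> [1] 96

# 2. an 18-node Bayesian network with synthetic monotone CPTs
bn <- generate_network(synthetic_config(seed = 1))
bn
#> <bn_network> 18 variables (3 decision, 15 random), 28 edges

# 3. scenario A: mining 75% of a discrete block, 11-30 cm sediment extracted
run_scenario(bn, scenario_A())
#> <scenario_result> A (depth_of_extracted_sediment=11-30 cm;mining_intensity=75% removed)
#>   sessile_epifauna.total       most probable 81-100% (p=0.609)
#>   sessile_epifauna.indirect    most probable 81-100% (p=0.216)
#>   mobile_epifauna.total        most probable 81-100% (p=0.511)
#>   mobile_epifauna.indirect     most probable 0-10% (p=0.281)
#>   infauna.total                most probable 81-100% (p=0.591)
#>   infauna.indirect             most probable 11-30% (p=0.261)
```

The 53/96 counts are the scale of the combined causal map; the scenario
posteriors show, per functional group, the probability of each mortality
class — here (with synthetic CPTs) mining 75 % of the block makes 81–100 %
total mortality the most probable outcome for every group, driven mostly by
the proportional direct mortality, while indirect mortality stays widely
distributed.

The exact mortality arithmetic is deterministic:

```r
g <- function(x) { p <- numeric(101); p[x + 1] <- 1; p }
which(combine_mortality(g(75), g(20)) == 1) - 1   # 75 + 20 * 0.25
#> [1] 80
```

## Command line

```sh
Rscript -e 'seabedrisk::seabedrisk_cli()' make-fixtures --out ws --seed 1
Rscript -e 'seabedrisk::seabedrisk_cli()' pipeline \
  --maps ws/expert_maps_synthetic.csv --synonyms ws/synonyms_synthetic.csv \
  --model ws/model_synthetic.txt --scenarios ws/scenarios_synthetic.txt \
  --out ws/out
```

`pipeline` writes the combined-network exports (GraphML, DOT, adjacency
matrix), scenario posterior tables, and a `manifest.json` with input/output
checksums and every defaulted decision (e.g. the uniform policy applied to
unset decision variables).

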