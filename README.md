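# ExhibitSpace

Space-use, territoriality and exhibit-preference analysis for groups of
animals living in bounded enclosures, from scan-sampled location data.

Territoriality in enclosure-housed groups is hard to observe directly,
especially in cryptic species such as crocodilians. ExhibitSpace infers it
from spatial overlap: each individual's utilization distribution (UD) is
estimated by fixed-kernel density estimation with the enclosure boundary
as a barrier, the 95% isopleth defines the home range (HR) and the 50%
isopleth the core area (CA), and dyadic overlap is quantified with the
utilization distribution overlap index

UDOI = A_ij · ∫∫ UD_i(x,y) · UD_j(x,y) dx dy

at the three space-use levels HR-HR, HR-CA and CA-CA. A strict decrease of
mean overlap across those levels is the signature of a territorial group.
The kernel bandwidth is the optimal bandwidth h = (2/(3n))^(1/4)·σ, with σ
the standard distance of the locations. Exhibit preference uses the
Vanderploeg–Scavia electivity index E* = (W − 1/n)/(W + 1/n) with
W_i = (r_i/p_i)/Σ(r_j/p_j), comparing each feature's observed use r_i to
its availability p_i. Rank-based group tests (Mann-Whitney, Wilcoxon
signed-rank, Friedman, Bonferroni-adjusted) compare use against
expectation, across seasons and across times of day. A synthetic
scan-data generator with territorial and non-territorial scenarios
validates the whole pipeline by parameter recovery.

Intended users: researchers and animal-care scientists analysing
scan-sampled positional data in zoos, aquaria, farms or any enclosure
with a known map.

## Worked example

```r
library(ExhibitSpace)

map <- table1Exhibit()              # packaged 12-feature exhibit, 620.65 m^2
featureTable(map)[2, ]
#>   code    name area_m2 percent_exhibit
#> 2   B2 Beach 2    45.6        7.347136

coh <- simulateCohort(simulationConfig("territorial", seed = 1), map)
nrow(coh)                           # 19314 records, ~1.8 scans/day, 2 years
fit <- estimateRanges(coh, map)     # 72 UDs: 18 individuals x 4 periods
ov  <- udoiTable(fit)
prof <- territorialityProfile(ov, degreeTable(ov))
prof$summary[c("season", "level", "mean_udoi", "mean_degree")]
#>   season level    mean_udoi mean_degree
#> 1   cold HR-HR 0.1549651368  17.0000000
#> 2   cold HR-CA 0.0093209667   4.5555556
#> 3   cold CA-CA 0.0009759961   0.2222222
#> 4   warm HR-HR 0.1758577750  17.0000000
#> 5   warm HR-CA 0.0129357141   4.9722222
#> 6   warm CA-CA 0.0016457178   0.7222222
prof$territorial
#> cold warm
#> TRUE TRUE
```

Mean UDOI falls by two orders of magnitude from HR-HR to CA-CA in both
seasons — the generator's separated activity centres are recovered as
territoriality. `runPipeline(pipelineConfig(...))` runs the same analysis
from a locations CSV and optional GeoJSON exhibit map and writes every
table (range areas, dyadic UDOI, degree, seasonal edge lists, electivity
per stratum, group tests) as CSV with a JSON run manifest;
`inst/scripts/pipeline.R` wraps `simulate` and `run` for shell use.

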