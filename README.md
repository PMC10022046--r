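# sihnet — intermunicipal patient-journey networks

Most municipalities cannot provide every health service, so public health
systems regionalize care: patients travel from their municipality of
residence to a reference municipality that offers the procedure. `sihnet`
turns hospitalization records — in the schema of Brazil's SIH/SUS reduced
(RD) files, which carry the municipality of residence and the municipality
of occurrence of each admission — into yearly **origin–destination
networks**, and computes the journey indices a municipal health manager
needs to see whether their municipality is becoming a provider hub or is
still exporting patients, and over what distances.

For a focal municipality and each year, the package reports six indices
over the directed weighted graph G = (V, A) of intermunicipal journeys
(arcs weighted by journey counts, self-journeys excluded):

| index | meaning |
|---|---|
| k_I (in-degree) | number of distinct municipalities sending patients in |
| k_O (out-degree) | number of distinct municipalities residents travel to |
| F_I (incoming flow) | total journeys arriving for the procedure |
| F_O (outgoing flow) | total journeys by residents leaving for it |
| D̄ (mean arc length, per direction) | flow-weighted mean straight-line distance, D̄ = Σₐ Dₐ·Fₐ / Σₐ Fₐ (km); `NA` when the corresponding degree is 0 |

Distances are straight lines between municipality city points: planar
Euclidean on UTM coordinates (the default; both endpoints are projected
into one zone) or great-circle. A seeded gravity-model generator
(Poisson journey counts with expected flow `theta · pop_O · cap_D ·
exp(−d/decay_km)`) produces realistic synthetic record sets so the entire
pipeline is testable without any data download. Networks export to GEXF
(with `lat`/`lon`/`macroregion` node attributes, so Gephi can draw the
network on the territory) and GraphML.

## Worked example

```r
library(sihnet)

s   <- synthetic_scenario(seed = 42)     # 50 municipalities, 5 providers, 2008-2020
reg <- generate_registry(s)
rec <- generate_records(s, reg)          # 9829 records
nets <- records_to_networks(rec, reg, years = s$years)
nets[["2014"]]
#> <flow_network> year 2014: 47 vertices, 138 arcs, total flow 732 (intermunicipal only)

hub <- s$provider_codes[1]               # "290045", the largest provider
head(time_series(nets, hub), 4)
#>   year in_degree out_degree incoming_flow outgoing_flow mean_in_length_km mean_out_length_km
#> 1 2008        44          4           358            48           330.445            466.748
#> 2 2009        40          4           324            70           329.517            478.034
#> 3 2010        46          4           377            66           321.375            480.699
#> 4 2011        41          4           355            60           324.389            476.471

macroregion_breakdown(nets[["2014"]], hub, "incoming")
#> <macroregion_breakdown> year 2014, incoming (39 counterpart municipalities)
#>   Southeast        16 (41.0%)
#>   Southwest         9 (23.1%)
#>   Northeast         7 (17.9%)
#>   Northwest         7 (17.9%)
```

Reading: in 2008 patients reached the hub from 44 distinct municipalities
(358 journeys, travelling on average 330.4 km), while its own residents
left for 4 other municipalities (48 journeys). A degree of 0 in a
direction makes that direction's mean length `NA` — no journeys, no
distance.

On real coordinates (city points of 8 Bahia municipalities shipped under
`inst/extdata/`):

```r
reg <- read_registry(system.file("extdata", "bahia_municipalities.csv", package = "sihnet"))
distance_km("293330", "292740", reg)                           # Vitória da Conquista -> Salvador
#> 328.28   (km, UTM planar)
distance_km("293330", "292740", reg, method = "great_circle")
#> 328.79
```

## Command line

```sh
Rscript -e 'sihnet::sihnet_cli()' synth   --out data --seed 1
Rscript -e 'sihnet::sihnet_cli()' build   --records data/records.csv --registry data/registry.csv \
    --years 2008-2020 --out nets
Rscript -e 'sihnet::sihnet_cli()' indices --records data/records.csv --registry data/registry.csv \
    --focal 290045 --years 2008-2020 --out report
```

`build` writes one OD-matrix CSV, one edge-list CSV and one GEXF file per
year plus a JSON run manifest; `indices` writes the yearly index table
(`NA` cells as the literal string `NA`, distances rounded to 2 decimals).
A `--config file` with flat `key: value` lines may replace the flags;
flags win over the file. An optional procedure-code list
(`--procedures codes.txt`, one code per line) restricts the records to one
procedure group before anything is counted — networks of different
procedure groups should not be mixed.

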