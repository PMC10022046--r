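Package: sihnet
Title: Intermunicipal Patient-Journey Networks from Hospital Admission Records
Version: 0.1.0
Authors@R: person("sihnet", "maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds yearly origin-destination networks of intermunicipal patient
    journeys from hospitalization records in the SIH/SUS reduced-file (RD) schema,
    filtered to a procedure group, and computes per-municipality journey indices:
    in- and out-degree, incoming and outgoing flow, and flow-weighted mean arc
    lengths over straight-line (UTM planar or great-circle) distances. Includes a
    seeded gravity-model record generator for end-to-end testing, GEXF/GraphML
    exporters for network visualization, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
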