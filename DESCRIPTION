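Package: herbnet
Title: Network-Pharmacology Funnel Analysis with Synthetic Ground Truth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of the compound-to-pathway
    network-pharmacology funnel used to study multi-compound herbal
    medicines: ADME screening of candidate compounds by oral bioavailability
    and drug-likeness, merging of per-compound target predictions and
    intersection with a disease gene set, construction and export of
    compound-target and compound-target-pathway networks, two-round
    median-threshold hub screening of a protein-protein interaction network
    by degree, betweenness and closeness, hypergeometric overrepresentation
    analysis with Benjamini-Hochberg false-discovery-rate control, and the
    validation-side arithmetic (2^-ddCt relative expression, binding-affinity
    classification). A synthetic-data module generates every pipeline input
    with known planted structure (passing compounds, overlap sets, hub nodes,
    enriched terms, fold changes) so the whole funnel can be run and verified
    at desk scale without querying external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    xml2,
    yaml
Config/testthat/edition: 3
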