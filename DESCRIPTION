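Package: cpatopo
Title: Evolution-Guided Topology Annotation for CPA/AT-Like Membrane Transporters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating the membrane topology of secondary-transporter
    families of the CPA/AT type: a topology-label algebra covering canonical,
    broken and reentrant helices; projection of per-sequence topology
    predictions onto a seed alignment with tree-guided reordering, consensus
    ("initial") topologies and subfamily splitting; template-guided inference
    of missing broken/reentrant helices and transfer of repeat/subdomain
    annotations; positive-inside (KR-bias) topology-model selection; core-helix
    sequence motifs and insertion free-energy scoring; E-value-weighted
    family/repeat homology networks; alignment dotplots and CA distance maps;
    and a seeded generator of tree-structured synthetic transporter families
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    igraph,
    stats,
    utils
Suggests:
    bio3d,
    ggplot2,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
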