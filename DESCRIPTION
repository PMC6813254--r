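Package: inoviscope
Title: Detection and Classification of Inovirus Prophages in Microbial Genomes
Version: 0.1.0
Authors@R:
    person("Inoviscope", "Developers", email = "inoviscope@example.org",
           role = c("aut", "cre"))
Description: Detects inovirus (filamentous phage) proviruses and contigs in
    annotated bacterial and archaeal genomes or metagenome assemblies by
    combining a morphogenesis-ATPase (pI-like) marker-gene search with a
    random-forest classifier over genome-context features, delineates provirus
    boundaries through direct-repeat attachment (att) sites, dereplicates
    detections into species by average nucleotide identity with tiered seed
    priority, builds protein clusters and profile-merged protein families,
    derives a gene-content taxonomy from a bipartite genome-gene-family
    network, and screens hosts for CRISPR spacer targeting, Caudovirales
    co-infection and toxin-antitoxin systems. A synthetic-data module
    generates annotated genomes with planted proviruses, confounder elements
    and full ground truth so that every stage can be exercised and benchmarked
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    methods,
    randomForest,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
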