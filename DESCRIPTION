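Package: synmir
Title: Synergistic miRNA Pair Discovery from Matched Tumor/Normal Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Identifies synergistically acting miRNA pairs from matched
    tumor/normal miRNA and mRNA expression profiles. The pipeline performs
    paired differential-expression testing with empirical-Bayes moderated
    t-statistics and Benjamini-Hochberg FDR control, builds a bipartite
    miRNA-target network from expression anti-correlation combined with
    sequence-based target predictions (context+ score and probability of
    conserved targeting), scores every miRNA pair by the similarity of
    their target-weight vectors (Fisher z-transformed Pearson correlation),
    assesses significance by exact or Monte Carlo randomization tests, and
    quantifies functional synergy as the number of Gene Ontology terms
    significantly enriched in both miRNAs' target sets. A synthetic-data
    generator with planted differential expression, repressive
    miRNA-target links and planted synergistic pairs makes every stage
    testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
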