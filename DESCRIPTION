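Package: vlmcsig
Title: Alignment-Free Sample Comparison Using Variable-Length Markov
    Chain Sequence Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Alignment-free comparison of transcriptomic and
    metatranscriptomic sequencing samples from their k-tuple (k-mer)
    frequency signatures.  Background nucleotide composition is modelled
    either by a fixed-order Markov chain or by a variable-length Markov
    chain (VLMC) context tree estimated from the reads themselves: a full
    prefix tree of contexts is pruned by a count-weighted Kullback-Leibler
    statistic whose threshold is selected by minimising a read-based
    Akaike information criterion.  Centered k-tuple counts under the
    fitted background model feed the normalised dissimilarities d2S and
    d2*, alongside d2 and Lp-norm measures; pairwise dissimilarity
    matrices are clustered with UPGMA and compared to reference trees by
    the rooted-triples distance and the clade symmetric difference.  A
    seeded synthetic-community read simulator (mock gene catalogs,
    fold-change designs, lognormal expression noise, negative-binomial
    depths) makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
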