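Package: pprlink
Title: Privacy-Preserving Record Linkage with Hashed Tokens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for privacy-preserving record linkage (PPRL) across
    distributed health data networks. Generates de-identified patient
    tokens as keyed salted hashes of normalized identifier combinations
    (including phonetic soundex encoding of names), manages a layered
    site/transit/coordinating-center encryption lifecycle for those
    tokens, links records across sites by a majority-vote rule over
    available token slots with union-find clustering into a master
    Match Index, computes multi-site patient overlap statistics, and
    consolidates demographic characteristics tables with discordance
    adjudication. Includes a synthetic multi-site population generator
    with known ground-truth linkage for end-to-end evaluation, and a
    command-line pipeline that enforces the token/analysis privacy
    boundary.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    openssl,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
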