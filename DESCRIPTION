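Package: wobblescan
Title: Plant miRNA Target Scanning with G:U Wobble Scoring and
    Elicitation Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts plant miRNA targets by exhaustive ungapped scanning of
    transcript collections under a four-rule complementarity filter (weighted
    mismatch score with G:U wobble pairs scored 0.5, limits on contiguous
    mismatches, on 5' seed-region mismatches, and a strict no-mismatch
    constraint at the cleavage-spanning central positions), and implements the
    companion expression conventions of a two-condition elicitation
    transcriptome study: per-million relative abundance, fold changes with an
    explicit not-determined state for genes silent in the control, inclusive
    twofold differential-expression calling, fourfold pathway direction
    summaries, and integration of target predictions with miRNA and target
    expression directions into complementary/concordant pattern tables. A
    synthetic-data module generates transcriptomes with planted target sites,
    single-rule decoys, and negative-binomial two-condition count tables with
    planted fold tiers, so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
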