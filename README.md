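# wobblescan

Plant miRNAs silence their targets through near-perfect, antiparallel base
pairing, so candidate targets can be predicted by scanning a transcript
collection for windows that pair almost completely with a miRNA. `wobblescan`
implements such a scanner for elicitation transcriptome studies (the
motivating system is methyl-jasmonate-elicited *Taxus* cell cultures, where
miRNA-mediated regulation of paclitaxel biosynthesis genes is of interest),
together with the expression conventions those studies use and a synthetic
data generator that makes the whole pipeline testable without any external
data.

## The rules and statistics at the core

**Four-rule duplex filter.** A miRNA of length *L* (positions 1..*L* from its
5′ end) is aligned, ungapped and antiparallel, against every length-*L*
window of a transcript: miRNA position *i* pairs with window position
*L* − *i* + 1. Each position is a Watson–Crick **match**, a **G:U wobble**
(scored 0.5), or a **mismatch** (scored 1). A window is a predicted target
site iff

1. weighted total score ≤ 4 (so 3 mismatches + 2 G:U = 4.0 passes and
   4 mismatches + 1 G:U = 4.5 fails),
2. no run of more than 2 contiguous mismatches,
3. at most 1 mismatch in the 5′ seed region (positions 1–9),
4. no mismatch at the central, cleavage-spanning positions 10–11.

By default a G:U wobble is penalized in the score but is not a "mismatch" for
rules 2–4; `rule_config(gu_counts_in_positional_rules = TRUE)` selects the
stricter reading.

**Expression conventions.** Libraries are scaled to transcripts per million
(`relative_abundance`); fold change is elicited/nonelicited with an explicit
*n.d.* state when the nonelicited abundance is zero (and an undefined 0/0
state excluded from calling); a gene is differentially expressed when its
fold change is ≥ 2 (or ≤ 1/2; *n.d.* counts as up) and its p-value ≤ 0.05,
both inclusive (`classify_de`). Pathways are labelled increased / decreased /
mixed / none from their ≥ 4-fold members (`summarize_pathways`), and target
predictions are combined with miRNA and target directions into
complementary / concordant / indeterminate pairs
(`build_integration_table`), complementary pairs being the signature expected
under miRNA-mediated repression.

**Synthetic data.** `make_transcriptome` plants target sites with controlled
mismatch/wobble configurations (and decoys violating exactly one rule) in a
random transcriptome; `simulate_counts` draws two-condition
negative-binomial count tables with planted fold tiers {1, 2, 4, n.d.};
`simulate_study` couples both into an end-to-end fixture with known
complementary/concordant pair counts.

## Worked example

```r
library(wobblescan)

mir <- mirna("tcm-miR171", "UGAUUGAGCCGUGCCAAUAUC", direction = "down")
site <- build_site(mir$sequence, mismatch_positions = 13, gu_positions = 2)
dup <- score_duplex(mir, site)
print(dup)
#> GAUAUUGGAACGGCUCAAUUA
#> |||||||| ||||||||||o|
#> CUAUAACCGUGCCGAGUUAGU
#> score 1.50 (1 mismatch, 1 G:U, 19 match); max run 1; seed 0; central 0
evaluate_rules(dup)
#> passed: TRUE (total TRUE, contiguous TRUE, seed TRUE, central TRUE)
```

The display shows the target site 5′→3′ on top and the miRNA 3′→5′ below;
`|` is a match, `o` a G:U wobble, a blank a mismatch. The planted mismatch at
miRNA position 13 and wobble at position 2 give score 1 × 1.0 + 1 × 0.5 =
1.5, within all four rules.

```r
set.seed(1)
backbone <- paste(sample(c("A","C","G","U"), 300, TRUE), collapse = "")
substr(backbone, 121, 141) <- site
hits <- scan_pair(mir, list(id = "Contig0042", sequence = backbone))
hits[, c("mirna_id","transcript_id","start","end","score")]
#>     mirna_id transcript_id start end score
#> 1 tcm-miR171    Contig0042   120 141   1.5
```

The scanner reports the planted window (0-based, half-open coordinates) and
nothing else. Joining hits with expression directions:

```r
expr <- expression_table(data.frame(
  id = c("Contig0042", "Contig0007", "Contig099"),
  count_nonelicited = c(40, 0, 120),
  count_elicited = c(160, 25, 115),
  adjusted_p = c(0.003, 0.001, 0.8)))
expr[, c("id", "fold", "nd", "direction")]
#>           id      fold    nd direction
#> 1 Contig0042 2.1333333 FALSE        up
#> 2 Contig0007       Inf  TRUE        up
#> 3  Contig099 0.5111111 FALSE unchanged

dirs <- data.frame(mirna_id = "tcm-miR171", direction = "down")
build_integration_table(hits, dirs, expr)[, c("mirna_id", "transcript_id",
                                              "n_sites", "pattern")]
#>     mirna_id transcript_id n_sites       pattern
#> 1 tcm-miR171    Contig0042       1 complementary
```

`Contig0042` is up-regulated (fold 2.13, p = 0.003) while its predicted
regulator is down-regulated: a complementary pair. `Contig0007` illustrates
the *n.d.* convention — silent in the nonelicited culture, so its fold is not
determined but it is counted as up-regulated and flagged.

## Command line

A thin wrapper at `inst/scripts/wobblescan` exposes the stages as
subcommands:

```sh
wobblescan simulate  --seed 7 --out fixtures/
wobblescan scan      --mirnas fixtures/mirnas.fasta \
                     --transcripts fixtures/transcripts.fasta --out hits.tsv
wobblescan de        --expression fixtures/counts.tsv --out de.tsv
wobblescan pathways  --expression de.tsv --pathways fixtures/pathways.tsv --out pw.tsv
wobblescan integrate --hits hits.tsv --mirna-directions fixtures/mirna_directions.tsv \
                     --expression de.tsv --out integration.tsv
wobblescan report    --dir fixtures/
```

All table output is TSV (header row, `.` for missing, `nd` for
not-determined folds) and files are written atomically.

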