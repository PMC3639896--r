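# Duplex core: pairing alphabet, G:U-weighted mismatch score, four-rule verdicts.

.BASES <- c("A", "C", "G", "U", "N")

# 5x5 pair-state table indexed by (miRNA base, target base); 0 = Watson-Crick
# match, 1 = G:U wobble, 2 = mismatch. N never pairs.
.PAIR_LUT <- local({
  lut <- matrix(2L, 5, 5, dimnames = list(.BASES, .BASES))
  lut["A", "U"] <- 0L
  lut["U", "A"] <- 0L
  lut["G", "C"] <- 0L
  lut["C", "G"] <- 0L
  lut["G", "U"] <- 1L
  lut["U", "G"] <- 1L
  lut
})

.STATE_LABELS <- c("match", "gu", "mismatch")

.encode <- function(seq) {
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1L]], .BASES)
  if (anyNA(codes)) {
    stop("sequence contains characters outside {A,C,G,U,N}; normalize first",
         call. = FALSE)
  }
  codes
}

#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' Uppercases, replaces thymine with uracil (miRNA inputs are RNA while
#' transcript FASTA is usually DNA), and rejects any character outside
#' `{A,C,G,U,N}`.
#'
#' @param raw A single non-empty nucleotide string.
#' @return The normalized sequence (character scalar, RNA alphabet).
#' @examples
#' normalize_sequence("acgt")  # "ACGU"
#' @export
normalize_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw)) {
    stop("'raw' must be a single non-empty nucleotide string", call. = FALSE)
  }
  up <- chartr("T", "U", toupper(raw))
  chars <- strsplit(up, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% .BASES))
  if (length(bad)) {
    stop(sprintf("illegal character '%s' at position %d (allowed: A,C,G,U,N after T->U)",
                 chars[bad[1L]], bad[1L]), call. = FALSE)
  }
  up
}

#' Pairing state of one miRNA base against one target base
#'
#' Antiparallel base pairing states: Watson-Crick pairs (`A:U`, `U:A`, `G:C`,
#' `C:G`) are `"match"`, the wobble pairs `G:U` and `U:G` are `"gu"`, and
#' everything else (including any pair involving `N`) is `"mismatch"`.
#' Vectorized over both arguments.
#'
#' @param mirna_base,target_base Normalized single bases (recycled).
#' @return Character vector in `c("match", "gu", "mismatch")`.
#' @examples
#' pair_state("A", "U")  # match
#' pair_state("G", "U")  # gu (wobble, scored 0.5)
#' @export
pair_state <- function(mirna_base, target_base) {
  mi <- match(mirna_base, .BASES)
  ti <- match(target_base, .BASES)
  if (anyNA(mi) || anyNA(ti)) {
    stop("bases must be normalized single characters in {A,C,G,U,N}",
         call. = FALSE)
  }
  .STATE_LABELS[.PAIR_LUT[cbind(mi, ti)] + 1L]
}

#' Rule configuration for the four-rule target filter
#'
#' Thresholds for the complementarity filter: a candidate site is accepted when
#' (i) the G:U-weighted total mismatch score is at most `max_total_score`
#' (mismatch = 1, G:U wobble = `gu_score`), (ii) no run of contiguous
#' mismatches exceeds `max_contiguous_mismatch`, (iii) mismatches in the 5'
#' seed region (`seed_region`, miRNA positions counted from the 5' end) do not
#' exceed `max_seed_mismatch`, and (iv) no mismatch falls in the central,
#' cleavage-spanning region (`central_region`).
#'
#' By default G:U wobbles contribute to the score but are not counted as
#' mismatches by the positional rules (run/seed/central); set
#' `gu_counts_in_positional_rules = TRUE` for the stricter reading.
#'
#' @param max_total_score Maximum weighted score (default 4).
#' @param max_contiguous_mismatch Longest tolerated mismatch run (default 2).
#' @param seed_region Inclusive 1-based miRNA position range, default `c(1, 9)`.
#' @param max_seed_mismatch Maximum mismatches in the seed region (default 1).
#' @param central_region Inclusive 1-based range with zero tolerated
#'   mismatches, default `c(10, 11)`.
#' @param gu_score Score contribution of a G:U wobble (default 0.5).
#' @param gu_counts_in_positional_rules Logical; treat wobbles as mismatches in
#'   the run/seed/central rules (default `FALSE`).
#' @return An object of class `"rule_config"`.
#' @export
rule_config <- function(max_total_score = 4,
                        max_contiguous_mismatch = 2L,
                        seed_region = c(1L, 9L),
                        max_seed_mismatch = 1L,
                        central_region = c(10L, 11L),
                        gu_score = 0.5,
                        gu_counts_in_positional_rules = FALSE) {
  stopifnot(
    is.numeric(max_total_score), length(max_total_score) == 1L, max_total_score >= 0,
    is.numeric(max_contiguous_mismatch), length(max_contiguous_mismatch) == 1L,
    max_contiguous_mismatch >= 0,
    is.numeric(seed_region), length(seed_region) == 2L,
    seed_region[1L] >= 1L, seed_region[2L] >= seed_region[1L],
    is.numeric(max_seed_mismatch), length(max_seed_mismatch) == 1L, max_seed_mismatch >= 0,
    is.numeric(central_region), length(central_region) == 2L,
    central_region[1L] >= 1L, central_region[2L] >= central_region[1L],
    is.numeric(gu_score), length(gu_score) == 1L, gu_score >= 0,
    is.logical(gu_counts_in_positional_rules), length(gu_counts_in_positional_rules) == 1L
  )
  structure(list(
    max_total_score = as.numeric(max_total_score),
    max_contiguous_mismatch = as.integer(max_contiguous_mismatch),
    seed_region = as.integer(seed_region),
    max_seed_mismatch = as.integer(max_seed_mismatch),
    central_region = as.integer(central_region),
    gu_score = as.numeric(gu_score),
    gu_counts_in_positional_rules = gu_counts_in_positional_rules
  ), class = "rule_config")
}

#' @export
print.rule_config <- function(x, ...) {
  cat("Four-rule target filter configuration\n")
  cat(sprintf("  max total score (mismatch 1, G:U %.2f): %.2f\n",
              x$gu_score, x$max_total_score))
  cat(sprintf("  max contiguous mismatches: %d\n", x$max_contiguous_mismatch))
  cat(sprintf("  seed region %d-%d: <= %d mismatch(es)\n",
              x$seed_region[1L], x$seed_region[2L], x$max_seed_mismatch))
  cat(sprintf("  central region %d-%d: no mismatch\n",
              x$central_region[1L], x$central_region[2L]))
  cat(sprintf("  G:U counts in positional rules: %s\n",
              x$gu_counts_in_positional_rules))
  invisible(x)
}

#' Construct a miRNA record
#'
#' @param id Identifier.
#' @param sequence Nucleotide sequence, 5' to 3'; normalized on construction.
#' @param family Optional family label.
#' @param direction Optional expression direction in
#'   `c("up", "down", "unchanged")`.
#' @param min_length Minimum accepted length (default 12).
#' @return An object of class `"mirna"`.
#' @export
mirna <- function(id, sequence, family = NA_character_,
                  direction = NA_character_, min_length = 12L) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- normalize_sequence(sequence)
  if (nchar(sequence) < min_length) {
    stop(sprintf("miRNA '%s' is shorter than %d nt", id, min_length),
         call. = FALSE)
  }
  if (!is.na(direction) && !direction %in% c("up", "down", "unchanged")) {
    stop("direction must be one of up/down/unchanged", call. = FALSE)
  }
  structure(list(id = id, sequence = sequence, family = family,
                 direction = direction), class = "mirna")
}

# Longest run of TRUE in a logical vector.
.max_run <- function(flag) {
  if (!any(flag)) return(0L)
  r <- rle(flag)
  max(r$lengths[r$values])
}

# Positional mismatch indicator under a config (optionally counting wobbles).
.positional_mismatch <- function(codes, config) {
  if (config$gu_counts_in_positional_rules) codes >= 1L else codes == 2L
}

.check_regions <- function(config, L) {
  if (config$central_region[2L] > L || config$seed_region[2L] > L) {
    stop(sprintf(
      "seed/central region extends beyond the miRNA length (%d nt)", L),
      call. = FALSE)
  }
}

#' Score a miRNA:site duplex
#'
#' Aligns a miRNA against a candidate target site of the same length in the
#' antiparallel orientation: miRNA position `i` (1-based from the miRNA 5' end)
#' pairs with site position `L - i + 1` (site given 5' to 3'). The duplex score
#' is `n_mismatch * 1 + n_gu * gu_score`.
#'
#' @param mirna A [mirna()] object or a plain nucleotide string (5' to 3').
#' @param site Candidate site on the target, 5' to 3', same length as the
#'   miRNA; both sequences must be normalized (see [normalize_sequence()]).
#' @param config A [rule_config()]; supplies `gu_score`.
#' @return An object of class `"duplex_alignment"`: a list with the per-position
#'   `states` (indexed by miRNA position), `score`, `n_match`, `n_gu`,
#'   `n_mismatch`, `max_run_mismatch`, `seed_mismatches`, `central_mismatches`,
#'   plus the sequences. Positional counts are reported under the configured
#'   wobble convention.
#' @examples
#' d <- score_duplex("UGACAGAAGAGAGUGAGCACA", "UGUGCUCACUCUCUUCUGUCA")
#' d$score  # 0: perfect complement
#' @export
score_duplex <- function(mirna, site, config = rule_config()) {
  if (inherits(mirna, "mirna")) {
    mirna_id <- mirna$id
    mseq <- mirna$sequence
  } else {
    mirna_id <- NA_character_
    mseq <- mirna
  }
  stopifnot(is.character(mseq), length(mseq) == 1L,
            is.character(site), length(site) == 1L,
            inherits(config, "rule_config"))
  L <- nchar(mseq)
  if (nchar(site) != L) {
    stop(sprintf("site length (%d) must equal miRNA length (%d)",
                 nchar(site), L), call. = FALSE)
  }
  m <- .encode(mseq)
  s <- .encode(site)
  # miRNA position i pairs with site position L - i + 1
  codes <- .PAIR_LUT[cbind(m, rev(s))]
  .check_regions(config, L)
  .duplex_from_codes(codes, mirna_id, mseq, site, config)
}

.duplex_from_codes <- function(codes, mirna_id, mseq, site, config) {
  pos_mm <- .positional_mismatch(codes, config)
  seed <- config$seed_region[1L]:config$seed_region[2L]
  central <- config$central_region[1L]:config$central_region[2L]
  n_gu <- sum(codes == 1L)
  n_mismatch <- sum(codes == 2L)
  structure(list(
    mirna_id = mirna_id,
    mirna_seq = mseq,
    site_sequence = site,
    states = .STATE_LABELS[codes + 1L],
    n_match = sum(codes == 0L),
    n_gu = n_gu,
    n_mismatch = n_mismatch,
    score = n_mismatch + config$gu_score * n_gu,
    max_run_mismatch = .max_run(pos_mm),
    seed_mismatches = sum(pos_mm[seed]),
    central_mismatches = sum(pos_mm[central])
  ), class = "duplex_alignment")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat(render_duplex(x), sep = "\n")
  cat(sprintf("score %.2f (%d mismatch, %d G:U, %d match); max run %d; seed %d; central %d\n",
              x$score, x$n_mismatch, x$n_gu, x$n_match,
              x$max_run_mismatch, x$seed_mismatches, x$central_mismatches))
  invisible(x)
}

#' Apply the four-rule target filter to a duplex
#'
#' Rule verdicts for a scored duplex: total weighted score, contiguous
#' mismatch run, seed-region mismatch count, and the no-mismatch central
#' region. A site passes only when all four rules pass.
#'
#' Positional counts (run/seed/central) are recomputed from the stored states
#' under `config`, so a duplex scored under one wobble convention can be judged
#' under another.
#'
#' @param duplex A `"duplex_alignment"` from [score_duplex()].
#' @param config A [rule_config()].
#' @return An object of class `"rule_verdict"`: logicals `pass_total`,
#'   `pass_contiguous`, `pass_seed`, `pass_central`, and their conjunction
#'   `passed`.
#' @export
evaluate_rules <- function(duplex, config = rule_config()) {
  stopifnot(inherits(duplex, "duplex_alignment"), inherits(config, "rule_config"))
  codes <- match(duplex$states, .STATE_LABELS) - 1L
  L <- length(codes)
  .check_regions(config, L)
  pos_mm <- .positional_mismatch(codes, config)
  seed <- config$seed_region[1L]:config$seed_region[2L]
  central <- config$central_region[1L]:config$central_region[2L]
  score <- sum(codes == 2L) + config$gu_score * sum(codes == 1L)
  v <- list(
    pass_total = score <= config$max_total_score,
    pass_contiguous = .max_run(pos_mm) <= config$max_contiguous_mismatch,
    pass_seed = sum(pos_mm[seed]) <= config$max_seed_mismatch,
    pass_central = sum(pos_mm[central]) == 0L
  )
  v$passed <- v$pass_total && v$pass_contiguous && v$pass_seed && v$pass_central
  structure(v, class = "rule_verdict")
}

#' @export
print.rule_verdict <- function(x, ...) {
  cat(sprintf("passed: %s (total %s, contiguous %s, seed %s, central %s)\n",
              x$passed, x$pass_total, x$pass_contiguous, x$pass_seed,
              x$pass_central))
  invisible(x)
}

#' Reverse complement in the RNA alphabet
#'
#' @param seq Normalized RNA sequence.
#' @return The reverse complement (A<->U, G<->C; N stays N), 5' to 3'.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  comp <- chartr("ACGUN", "UGCAN", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}
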