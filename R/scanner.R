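# Transcriptome-wide target-site scanner plus a deliberately naive oracle.

.HIT_COLUMNS <- c("mirna_id", "transcript_id", "start", "end", "score",
                  "n_match", "n_gu", "n_mismatch", "max_run_mismatch",
                  "seed_mismatches", "central_mismatches", "site_seq")

.empty_hits <- function() {
  data.frame(
    mirna_id = character(), transcript_id = character(),
    start = integer(), end = integer(), score = numeric(),
    n_match = integer(), n_gu = integer(), n_mismatch = integer(),
    max_run_mismatch = integer(), seed_mismatches = integer(),
    central_mismatches = integer(), site_seq = character(),
    stringsAsFactors = FALSE
  )
}

#' Candidate site windows along a transcript
#'
#' All ungapped full-length windows a miRNA can be aligned against: 0-based,
#' half-open `(i, i + L)` for `i = 0 .. transcript_length - L`.
#'
#' @param transcript_length,mirna_length Non-negative integers.
#' @return A data frame with columns `start`, `end`; zero rows when the
#'   transcript is shorter than the miRNA.
#' @examples
#' nrow(candidate_windows(100, 21))  # 80
#' @export
candidate_windows <- function(transcript_length, mirna_length) {
  stopifnot(is.numeric(transcript_length), length(transcript_length) == 1L,
            is.numeric(mirna_length), length(mirna_length) == 1L)
  if (transcript_length < 0 || mirna_length < 0) {
    stop("lengths must be non-negative", call. = FALSE)
  }
  n <- transcript_length - mirna_length + 1L
  if (n <= 0L) return(data.frame(start = integer(), end = integer()))
  start <- 0:(n - 1L)
  data.frame(start = as.integer(start),
             end = as.integer(start + mirna_length))
}

.as_mirna_fields <- function(mirna) {
  if (inherits(mirna, "mirna")) {
    list(id = mirna$id, sequence = mirna$sequence)
  } else if (is.character(mirna) && length(mirna) == 1L) {
    list(id = NA_character_, sequence = mirna)
  } else {
    stop("'mirna' must be a mirna() object or a single sequence string",
         call. = FALSE)
  }
}

.as_transcript_fields <- function(transcript) {
  if (is.data.frame(transcript)) {
    stopifnot(nrow(transcript) == 1L, all(c("id", "sequence") %in% names(transcript)))
    list(id = transcript$id, sequence = transcript$sequence)
  } else if (is.list(transcript) && all(c("id", "sequence") %in% names(transcript))) {
    list(id = transcript$id, sequence = transcript$sequence)
  } else {
    stop("'transcript' must be a list or one-row data frame with id and sequence",
         call. = FALSE)
  }
}

# Vectorized window scoring over one (miRNA, transcript) pair. Returns the
# per-window statistic table; when keep_all = FALSE only passing windows.
.window_table <- function(mirna_id, mseq, transcript_id, tseq, config,
                          keep_all = FALSE) {
  L <- nchar(mseq)
  .check_regions(config, L)
  m <- .encode(mseq)
  s <- .encode(tseq)
  nW <- length(s) - L + 1L
  if (nW <= 0L) return(.empty_hits())
  # miRNA position i pairs with site offset L - i within the window
  idx <- outer(seq_len(nW) - 1L, L:1, `+`)
  codes <- matrix(.PAIR_LUT[cbind(rep(m, each = nW), s[idx])], nW, L)
  is_mm <- codes == 2L
  n_mismatch <- as.integer(rowSums(is_mm))
  n_gu <- as.integer(rowSums(codes == 1L))
  score <- n_mismatch + config$gu_score * n_gu
  pos_mm <- if (config$gu_counts_in_positional_rules) codes >= 1L else is_mm
  run <- integer(nW)
  max_run <- integer(nW)
  for (i in seq_len(L)) {
    run <- (run + 1L) * as.integer(pos_mm[, i])
    max_run <- pmax(max_run, run)
  }
  seed <- config$seed_region[1L]:config$seed_region[2L]
  central <- config$central_region[1L]:config$central_region[2L]
  seed_mm <- as.integer(rowSums(pos_mm[, seed, drop = FALSE]))
  central_mm <- as.integer(rowSums(pos_mm[, central, drop = FALSE]))
  keep <- if (keep_all) rep(TRUE, nW) else {
    score <= config$max_total_score &
      max_run <= config$max_contiguous_mismatch &
      seed_mm <= config$max_seed_mismatch &
      central_mm == 0L
  }
  if (!any(keep)) return(.empty_hits())
  w <- which(keep)
  start <- w - 1L
  data.frame(
    mirna_id = mirna_id, transcript_id = transcript_id,
    start = start, end = start + L,
    score = score[w],
    n_match = as.integer(L - n_mismatch[w] - n_gu[w]),
    n_gu = n_gu[w], n_mismatch = n_mismatch[w],
    max_run_mismatch = as.integer(max_run[w]),
    seed_mismatches = seed_mm[w], central_mismatches = central_mm[w],
    site_seq = substring(tseq, start + 1L, start + L),
    stringsAsFactors = FALSE
  )
}

#' Scan one transcript for target sites of one miRNA
#'
#' Evaluates every full-length ungapped window of the transcript against the
#' miRNA (antiparallel pairing) and reports the windows passing the four-rule
#' filter, ordered by start. Overlapping sites are all reported. Coordinates
#' are 0-based, half-open, on the transcript's forward (sense) strand.
#'
#' @param mirna A [mirna()] object or sequence string (5' to 3', normalized).
#' @param transcript A list or one-row data frame with `id` and `sequence`
#'   (normalized RNA alphabet, 5' to 3').
#' @param config A [rule_config()].
#' @return A hit data frame with columns `mirna_id`, `transcript_id`, `start`,
#'   `end`, `score`, `n_match`, `n_gu`, `n_mismatch`, `max_run_mismatch`,
#'   `seed_mismatches`, `central_mismatches`, `site_seq`.
#' @export
scan_pair <- function(mirna, transcript, config = rule_config()) {
  m <- .as_mirna_fields(mirna)
  tr <- .as_transcript_fields(transcript)
  stopifnot(inherits(config, "rule_config"))
  .window_table(m$id, m$sequence, tr$id, tr$sequence, config)
}

#' Scan all miRNAs against all transcripts
#'
#' Concatenates [scan_pair()] over the Cartesian product of the two
#' collections, sorted by `(mirna_id, transcript_id, start)`. Per-miRNA
#' summary counts (number of sites and number of distinct target transcripts)
#' are attached as the `"summary"` attribute; see [hit_summary()].
#'
#' @param mirnas A list of [mirna()] objects, or a data frame with columns
#'   `id` and `sequence` (normalized).
#' @param transcripts A data frame with columns `id` and `sequence`
#'   (normalized), e.g. from [read_fasta()] or [make_transcriptome()].
#' @param config A [rule_config()].
#' @param best_per_pair Keep only the best hit per (miRNA, transcript) pair:
#'   lowest score, ties broken by smallest start (default `FALSE`: report all
#'   sites).
#' @return The combined hit data frame (see [scan_pair()]).
#' @export
scan_all <- function(mirnas, transcripts, config = rule_config(),
                     best_per_pair = FALSE) {
  if (is.data.frame(mirnas)) {
    stopifnot(all(c("id", "sequence") %in% names(mirnas)))
    mir_ids <- mirnas$id
    mir_seqs <- mirnas$sequence
  } else {
    mir_ids <- vapply(mirnas, function(m) .as_mirna_fields(m)$id, character(1))
    mir_seqs <- vapply(mirnas, function(m) .as_mirna_fields(m)$sequence, character(1))
  }
  stopifnot(is.data.frame(transcripts),
            all(c("id", "sequence") %in% names(transcripts)))
  if (anyDuplicated(mir_ids)) {
    stop("duplicate miRNA ids: ",
         paste(unique(mir_ids[duplicated(mir_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(transcripts$id)) {
    stop("duplicate transcript ids: ",
         paste(unique(transcripts$id[duplicated(transcripts$id)]), collapse = ", "),
         call. = FALSE)
  }
  out <- vector("list", length(mir_ids) * nrow(transcripts))
  k <- 0L
  for (mi in seq_along(mir_ids)) {
    for (ti in seq_len(nrow(transcripts))) {
      k <- k + 1L
      out[[k]] <- .window_table(mir_ids[mi], mir_seqs[mi],
                                transcripts$id[ti], transcripts$sequence[ti],
                                config)
    }
  }
  hits <- if (k == 0L) .empty_hits() else {
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  }
  if (is.null(hits) || nrow(hits) == 0L) hits <- .empty_hits()
  hits <- hits[order(hits$mirna_id, hits$transcript_id, hits$start), ,
               drop = FALSE]
  rownames(hits) <- NULL
  if (best_per_pair && nrow(hits) > 0L) {
    key <- paste(hits$mirna_id, hits$transcript_id, sep = "\r")
    ord <- order(key, hits$score, hits$start)
    hits <- hits[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
    hits <- hits[order(hits$mirna_id, hits$transcript_id, hits$start), ,
                 drop = FALSE]
    rownames(hits) <- NULL
  }
  attr(hits, "summary") <- hit_summary(hits)
  hits
}

#' Summarize a hit table
#'
#' Reports sites and distinct target transcripts per miRNA, and the two
#' transcriptome-wide totals (total sites and total distinct target
#' transcripts) — both are reported because a "potential target" count can be
#' read either per-site or per-transcript.
#'
#' @param hits A hit data frame from [scan_all()] or [scan_pair()].
#' @return A list with `per_mirna` (data frame: `mirna_id`, `n_sites`,
#'   `n_transcripts`), `total_sites`, and `total_target_transcripts`.
#' @export
hit_summary <- function(hits) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0L) {
    return(list(per_mirna = data.frame(mirna_id = character(),
                                       n_sites = integer(),
                                       n_transcripts = integer()),
                total_sites = 0L, total_target_transcripts = 0L))
  }
  sites <- table(hits$mirna_id)
  trans <- tapply(hits$transcript_id, hits$mirna_id,
                  function(x) length(unique(x)))
  per <- data.frame(mirna_id = names(sites),
                    n_sites = as.integer(sites),
                    n_transcripts = as.integer(trans[names(sites)]),
                    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  list(per_mirna = per,
       total_sites = nrow(hits),
       total_target_transcripts = length(unique(hits$transcript_id)))
}

#' Naive reference scanner (testing oracle)
#'
#' Same contract as [scan_pair()], implemented as a straight-line per-window,
#' per-position loop that shares no code with the production scanner beyond
#' [pair_state()]. Exists so the fast scanner can be checked for exact
#' equivalence; it is deliberately slow and simple.
#'
#' @inheritParams scan_pair
#' @return A hit data frame identical in shape to [scan_pair()]'s.
#' @export
oracle_scan <- function(mirna, transcript, config = rule_config()) {
  m <- .as_mirna_fields(mirna)
  tr <- .as_transcript_fields(transcript)
  stopifnot(inherits(config, "rule_config"))
  mchars <- strsplit(m$sequence, "", fixed = TRUE)[[1L]]
  tchars <- strsplit(tr$sequence, "", fixed = TRUE)[[1L]]
  L <- length(mchars)
  if (config$seed_region[2L] > L || config$central_region[2L] > L) {
    stop("seed/central region extends beyond the miRNA length", call. = FALSE)
  }
  n_windows <- length(tchars) - L + 1L
  rows <- list()
  if (n_windows >= 1L) {
    for (start0 in 0:(n_windows - 1L)) {
      site <- tchars[(start0 + 1L):(start0 + L)]
      # miRNA position i pairs the site read 3' to 5'
      states <- pair_state(mchars, rev(site))
      n_gu <- 0L; n_mm <- 0L; run <- 0L; max_run <- 0L
      seed_mm <- 0L; central_mm <- 0L
      for (i in seq_len(L)) {
        st <- states[i]
        if (st == "gu") n_gu <- n_gu + 1L
        if (st == "mismatch") n_mm <- n_mm + 1L
        counts_positionally <- st == "mismatch" ||
          (st == "gu" && config$gu_counts_in_positional_rules)
        if (counts_positionally) {
          run <- run + 1L
          if (run > max_run) max_run <- run
          if (i >= config$seed_region[1L] && i <= config$seed_region[2L]) {
            seed_mm <- seed_mm + 1L
          }
          if (i >= config$central_region[1L] && i <= config$central_region[2L]) {
            central_mm <- central_mm + 1L
          }
        } else {
          run <- 0L
        }
      }
      score <- n_mm + config$gu_score * n_gu
      ok <- score <= config$max_total_score &&
        max_run <= config$max_contiguous_mismatch &&
        seed_mm <= config$max_seed_mismatch &&
        central_mm == 0L
      if (ok) {
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = m$id, transcript_id = tr$id,
          start = start0, end = start0 + L, score = score,
          n_match = L - n_mm - n_gu, n_gu = n_gu, n_mismatch = n_mm,
          max_run_mismatch = max_run, seed_mismatches = seed_mm,
          central_mismatches = central_mm,
          site_seq = paste(site, collapse = ""),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) return(.empty_hits())
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  out$n_match <- as.integer(out$n_match)
  out$n_gu <- as.integer(out$n_gu)
  out$n_mismatch <- as.integer(out$n_mismatch)
  out$max_run_mismatch <- as.integer(out$max_run_mismatch)
  out$seed_mismatches <- as.integer(out$seed_mismatches)
  out$central_mismatches <- as.integer(out$central_mismatches)
  out
}
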