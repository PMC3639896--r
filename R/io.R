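# Readers/writers for FASTA and TSV tables, duplex rendering, and the flat
# key:value run configuration. All file outputs are written atomically
# (temp file + rename) so failed runs leave no partial artifacts.

.write_atomic <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(pattern = ".tmp_", tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop("could not move temporary file onto ", path, call. = FALSE)
  }
  invisible(path)
}

#' Read a FASTA file of nucleotide sequences
#'
#' Sequence ids are the first whitespace-delimited token of each header.
#' Sequences are normalized to the RNA alphabet on read (uppercased, T
#' replaced by U; see [normalize_sequence()]); the original alphabet is
#' recorded.
#'
#' @param path FASTA file path.
#' @return Data frame with columns `id`, `sequence` (normalized RNA),
#'   `alphabet` (`"DNA"` if the record contained T/t, else `"RNA"`), and
#'   `desc` (remainder of the header, `NA` if none).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    stop("malformed FASTA '", path, "': ", conditionMessage(e),
                         call. = FALSE)
                  })
  if (length(set) == 0L) {
    stop("malformed FASTA '", path, "': no records", call. = FALSE)
  }
  headers <- names(set)
  raw <- as.character(set)
  empty <- !nzchar(raw)
  if (any(empty)) {
    stop(sprintf("malformed FASTA '%s': record %d ('%s') has no sequence",
                 path, which(empty)[1L], headers[which(empty)[1L]]),
         call. = FALSE)
  }
  ids <- vapply(strsplit(headers, "[ \t]+"), `[`, character(1), 1L)
  desc <- sub("^[^ \t]+[ \t]*", "", headers)
  desc[!nzchar(desc)] <- NA_character_
  alphabet <- ifelse(grepl("[Tt]", raw), "DNA", "RNA")
  sequence <- vapply(seq_along(raw), function(i) {
    tryCatch(normalize_sequence(raw[i]), error = function(e) {
      stop(sprintf("malformed FASTA '%s': record %d ('%s'): %s",
                   path, i, ids[i], conditionMessage(e)), call. = FALSE)
    })
  }, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  data.frame(id = ids, sequence = sequence, alphabet = alphabet, desc = desc,
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param records Data frame with columns `id` and `sequence`.
#' @param path Output path (written atomically).
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  .write_atomic(path, function(tmp) Biostrings::writeXStringSet(set, tmp))
}

#' Write a table as TSV
#'
#' Tab-separated, header row, `"."` for missing values; written atomically.
#' Re-running a stage on identical inputs is byte-identical.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tsv <- function(x, path) {
  stopifnot(is.data.frame(x))
  .write_atomic(path, function(tmp) {
    utils::write.table(x, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = ".", fileEncoding = "UTF-8")
  })
}

#' Read a TSV table written by [write_tsv()]
#'
#' @param path Input path.
#' @return Data frame (`"."` read as `NA`).
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# fold column text convention: "nd" for not-determined (Inf), "." for 0/0
.fold_to_text <- function(fold) {
  out <- formatC(fold, format = "g", digits = 6)
  out[is_nd(fold)] <- "nd"
  out[is.nan(fold) | is.na(fold)] <- "."
  out
}

.text_to_fold <- function(txt) {
  out <- suppressWarnings(as.numeric(txt))
  out[txt %in% "nd"] <- Inf
  out[is.na(txt) | txt %in% "."] <- NaN
  out
}

#' Render a duplex as a three-line text block
#'
#' Conventional duplex display: target site 5' to 3' on top, a pairing line
#' (`"|"` match, `"o"` G:U wobble, `" "` mismatch), and the miRNA written 3'
#' to 5' underneath so paired bases align vertically.
#'
#' @param duplex A `"duplex_alignment"` from [score_duplex()].
#' @return Character vector of three equal-length lines.
#' @export
render_duplex <- function(duplex) {
  stopifnot(inherits(duplex, "duplex_alignment"))
  symbols <- c(match = "|", gu = "o", mismatch = " ")
  # site position j pairs miRNA position L - j + 1
  pairing <- paste(symbols[rev(duplex$states)], collapse = "")
  mirna_rev <- paste(rev(strsplit(duplex$mirna_seq, "", fixed = TRUE)[[1L]]),
                     collapse = "")
  c(duplex$site_sequence, pairing, mirna_rev)
}

#' Run configuration
#'
#' Bundles the four-rule filter thresholds with the expression-analysis
#' thresholds and the simulation seed; round-trips losslessly through the flat
#' `key: value` config file format (see [write_run_config()]).
#'
#' @param rules A [rule_config()].
#' @param fold_threshold,p_threshold DE thresholds (see [classify_de()]).
#' @param pathway_fold_threshold Pathway threshold (see
#'   [summarize_pathways()]).
#' @param seed Integer seed for the synthetic-data generators.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(rules = rule_config(), fold_threshold = 2,
                       p_threshold = 0.05, pathway_fold_threshold = 4,
                       seed = 1L) {
  stopifnot(inherits(rules, "rule_config"),
            fold_threshold > 0, p_threshold >= 0, p_threshold <= 1,
            pathway_fold_threshold > 0)
  structure(list(rules = rules,
                 fold_threshold = as.numeric(fold_threshold),
                 p_threshold = as.numeric(p_threshold),
                 pathway_fold_threshold = as.numeric(pathway_fold_threshold),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write a run configuration as a flat key: value file
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  r <- config$rules
  lines <- c(
    sprintf("max_total_score: %.17g", r$max_total_score),
    sprintf("max_contiguous_mismatch: %d", r$max_contiguous_mismatch),
    sprintf("seed_region: %d,%d", r$seed_region[1L], r$seed_region[2L]),
    sprintf("max_seed_mismatch: %d", r$max_seed_mismatch),
    sprintf("central_region: %d,%d", r$central_region[1L], r$central_region[2L]),
    sprintf("gu_score: %.17g", r$gu_score),
    sprintf("gu_counts_in_positional_rules: %s",
            tolower(r$gu_counts_in_positional_rules)),
    sprintf("fold_threshold: %.17g", config$fold_threshold),
    sprintf("p_threshold: %.17g", config$p_threshold),
    sprintf("pathway_fold_threshold: %.17g", config$pathway_fold_threshold),
    sprintf("seed: %d", config$seed)
  )
  .write_atomic(path, function(tmp) writeLines(lines, tmp))
}

#' Read a run configuration written by [write_run_config()]
#'
#' @param path Input path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  m <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*:\\s*(.*?)\\s*$", lines))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("malformed config line: ", lines[which(bad)[1L]], call. = FALSE)
  }
  kv <- stats::setNames(vapply(m, `[`, character(1), 3L),
                        vapply(m, `[`, character(1), 2L))
  pair <- function(key) as.integer(strsplit(kv[[key]], ",")[[1L]])
  run_config(
    rules = rule_config(
      max_total_score = as.numeric(kv[["max_total_score"]]),
      max_contiguous_mismatch = as.integer(kv[["max_contiguous_mismatch"]]),
      seed_region = pair("seed_region"),
      max_seed_mismatch = as.integer(kv[["max_seed_mismatch"]]),
      central_region = pair("central_region"),
      gu_score = as.numeric(kv[["gu_score"]]),
      gu_counts_in_positional_rules = kv[["gu_counts_in_positional_rules"]] == "true"
    ),
    fold_threshold = as.numeric(kv[["fold_threshold"]]),
    p_threshold = as.numeric(kv[["p_threshold"]]),
    pathway_fold_threshold = as.numeric(kv[["pathway_fold_threshold"]]),
    seed = as.integer(kv[["seed"]])
  )
}
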