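# Pairing of target-scan hits with miRNA and target expression directions.

.DIRECTIONS <- c("up", "down", "unchanged")

#' Expression-pattern class of a miRNA/target pair
#'
#' A pair is `"complementary"` when the miRNA and its predicted target moved
#' in opposite directions after elicitation (the pattern expected under
#' miRNA-mediated repression), `"concordant"` when both moved the same way,
#' and `"indeterminate"` when either is unchanged. Vectorized.
#'
#' @param mirna_direction,target_direction Labels in
#'   `c("up", "down", "unchanged")` (recycled).
#' @return Character vector in
#'   `c("complementary", "concordant", "indeterminate")`.
#' @examples
#' classify_pair("down", "up")  # complementary
#' @export
classify_pair <- function(mirna_direction, target_direction) {
  if (!all(mirna_direction %in% .DIRECTIONS) ||
      !all(target_direction %in% .DIRECTIONS)) {
    stop("directions must be in {up, down, unchanged}", call. = FALSE)
  }
  n <- max(length(mirna_direction), length(target_direction))
  m <- rep_len(mirna_direction, n)
  t <- rep_len(target_direction, n)
  out <- rep("indeterminate", n)
  changed <- m != "unchanged" & t != "unchanged"
  out[changed & m == t] <- "concordant"
  out[changed & m != t] <- "complementary"
  out
}

#' Integrate target hits with expression directions
#'
#' Aggregates a hit table to the (miRNA, transcript) level (expression
#' direction is a transcript property, so pattern claims are made per pair,
#' not per site), joins miRNA and target directions, and classifies each
#' pair's expression pattern.
#'
#' @param hits Hit data frame from [scan_all()].
#' @param mirna_directions Data frame with columns `mirna_id`, `direction`
#'   (labels in `up/down/unchanged`); every miRNA in `hits` must be present.
#' @param expression Expression table from [expression_table()] (columns `id`,
#'   `direction`); transcripts missing from it are given
#'   `missing_expression = TRUE` and the direction in `default_direction`.
#' @param default_direction Direction assumed for transcripts without
#'   expression data (default `"unchanged"`).
#' @return Data frame with one row per (miRNA, transcript) pair: `mirna_id`,
#'   `mirna_direction`, `transcript_id`, `target_direction`, `n_sites`,
#'   `best_score` (minimum duplex score across sites), `missing_expression`,
#'   `pattern`; sorted by (mirna_id, transcript_id). Pattern counts are
#'   attached as the `"pattern_counts"` attribute.
#' @export
build_integration_table <- function(hits, mirna_directions, expression,
                                    default_direction = "unchanged") {
  stopifnot(is.data.frame(hits),
            all(c("mirna_id", "transcript_id", "score") %in% names(hits)),
            is.data.frame(mirna_directions),
            all(c("mirna_id", "direction") %in% names(mirna_directions)),
            is.data.frame(expression),
            all(c("id", "direction") %in% names(expression)),
            default_direction %in% .DIRECTIONS)
  unknown <- setdiff(unique(hits$mirna_id), mirna_directions$mirna_id)
  if (length(unknown)) {
    stop("miRNA id(s) missing from the direction table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (nrow(hits) == 0L) {
    out <- data.frame(mirna_id = character(), mirna_direction = character(),
                      transcript_id = character(), target_direction = character(),
                      n_sites = integer(), best_score = numeric(),
                      missing_expression = logical(), pattern = character(),
                      stringsAsFactors = FALSE)
    attr(out, "pattern_counts") <- c(complementary = 0L, concordant = 0L,
                                     indeterminate = 0L)
    return(out)
  }
  key <- paste(hits$mirna_id, hits$transcript_id, sep = "\r")
  first <- !duplicated(key)
  pairs <- data.frame(mirna_id = hits$mirna_id[first],
                      transcript_id = hits$transcript_id[first],
                      stringsAsFactors = FALSE)
  pairs$n_sites <- as.integer(table(key)[key[first]])
  pairs$best_score <- as.numeric(tapply(hits$score, key, min)[key[first]])
  pairs$mirna_direction <-
    mirna_directions$direction[match(pairs$mirna_id, mirna_directions$mirna_id)]
  expr_idx <- match(pairs$transcript_id, expression$id)
  pairs$missing_expression <- is.na(expr_idx)
  pairs$target_direction <- ifelse(pairs$missing_expression,
                                   default_direction,
                                   expression$direction[expr_idx])
  pairs$pattern <- classify_pair(pairs$mirna_direction, pairs$target_direction)
  out <- pairs[order(pairs$mirna_id, pairs$transcript_id),
               c("mirna_id", "mirna_direction", "transcript_id",
                 "target_direction", "n_sites", "best_score",
                 "missing_expression", "pattern")]
  rownames(out) <- NULL
  attr(out, "pattern_counts") <- pattern_counts(out)
  out
}

#' Pattern counts of an integration table
#'
#' @param integration Data frame from [build_integration_table()].
#' @return Named integer vector with counts of `complementary`, `concordant`
#'   and `indeterminate` pairs.
#' @export
pattern_counts <- function(integration) {
  stopifnot(is.data.frame(integration), "pattern" %in% names(integration))
  counts <- table(factor(integration$pattern,
                         levels = c("complementary", "concordant",
                                    "indeterminate")))
  stats::setNames(as.integer(counts), names(counts))
}
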