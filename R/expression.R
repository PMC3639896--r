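# Abundance, fold-change, DE-flagging and pathway-direction conventions.

#' Per-million relative abundance
#'
#' Scales one library's transcript counts to relative abundances summing to
#' 10^6 (transcripts per million).
#'
#' @param counts Non-negative numeric vector with at least one positive entry.
#' @return Numeric vector `counts / sum(counts) * 1e6`.
#' @examples
#' relative_abundance(c(5, 5))  # 500000 500000
#' @export
relative_abundance <- function(counts) {
  if (!is.numeric(counts) || length(counts) == 0L) {
    stop("'counts' must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative and non-missing", call. = FALSE)
  }
  total <- sum(counts)
  if (total <= 0) {
    stop("all-zero library: relative abundance undefined", call. = FALSE)
  }
  counts / total * 1e6
}

#' Fold change with the zero-denominator convention
#'
#' `elicited / nonelicited`, with two sentinel states: when the nonelicited
#' (control) abundance is zero and the elicited abundance is positive the fold
#' change is *not determined* (n.d.), represented as `Inf`; when both are zero
#' it is undefined, represented as `NaN`, and such records are excluded from
#' differential-expression calling. Vectorized.
#'
#' @param elicited,nonelicited Non-negative abundances (recycled).
#' @return Numeric vector; `Inf` marks n.d., `NaN` marks 0/0.
#' @seealso [is_nd()]
#' @examples
#' fold_change(10, 0)  # Inf (n.d.)
#' fold_change(4, 2)   # 2
#' @export
fold_change <- function(elicited, nonelicited) {
  if (!is.numeric(elicited) || !is.numeric(nonelicited)) {
    stop("abundances must be numeric", call. = FALSE)
  }
  if (any(elicited < 0, na.rm = TRUE) || any(nonelicited < 0, na.rm = TRUE)) {
    stop("abundances must be non-negative", call. = FALSE)
  }
  elicited / nonelicited
}

#' Is a fold change "not determined"?
#'
#' @param fold Numeric fold changes from [fold_change()].
#' @return Logical; `TRUE` where the control abundance was zero while the
#'   elicited abundance was positive.
#' @export
is_nd <- function(fold) {
  is.infinite(fold) & fold > 0
}

#' Differential-expression direction call
#'
#' Implements the inclusive twofold rule: a record is `"up"` when its fold
#' change is at least `fold_threshold` (n.d. records count as up) and its
#' p-value is at most `p_threshold`; `"down"` when the fold change is at most
#' `1 / fold_threshold` under the same p criterion; otherwise `"unchanged"`.
#' Undefined folds (0/0, `NaN`) are never called. When `p` is `NULL` or
#' missing for a record, the p criterion is skipped for that record.
#'
#' @param fold Numeric fold changes (see [fold_change()]).
#' @param p Optional p-values in `[0, 1]` (adjusted or raw, whichever the
#'   study supplies), recycled against `fold`.
#' @param fold_threshold Fold cutoff, default 2 (inclusive; down cutoff is its
#'   reciprocal).
#' @param p_threshold Significance cutoff, default 0.05 (inclusive).
#' @return Character vector in `c("up", "down", "unchanged")`.
#' @examples
#' classify_de(c(2, 1.9, 0.4), c(0.04, 0.001, 0.01))  # up unchanged down
#' @export
classify_de <- function(fold, p = NULL, fold_threshold = 2,
                        p_threshold = 0.05) {
  stopifnot(is.numeric(fold), is.numeric(fold_threshold),
            length(fold_threshold) == 1L, fold_threshold > 0,
            is.numeric(p_threshold), length(p_threshold) == 1L)
  if (is.null(p)) p <- rep(NA_real_, length(fold))
  if (length(p) == 1L) p <- rep(p, length(fold))
  stopifnot(length(p) == length(fold))
  bad_p <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad_p)) {
    stop("p-values outside [0, 1] at: ",
         paste(which(bad_p), collapse = ", "), call. = FALSE)
  }
  significant <- is.na(p) | p <= p_threshold
  direction <- rep("unchanged", length(fold))
  defined <- !is.na(fold) & !is.nan(fold)
  direction[defined & significant & fold >= fold_threshold] <- "up"
  direction[defined & significant & fold <= 1 / fold_threshold] <- "down"
  direction
}

#' Build an annotated expression table
#'
#' Takes a two-condition table (counts or precomputed per-million abundances),
#' computes per-million abundances where needed, fold changes with the n.d.
#' convention, and DE direction calls.
#'
#' @param x Data frame with columns `id`, `count_nonelicited`,
#'   `count_elicited` (or `abundance_*` when `input = "tpm"`), and optionally
#'   `adjusted_p`.
#' @param input `"counts"` (converted via [relative_abundance()] per library)
#'   or `"tpm"` (values used as given).
#' @param fold_threshold,p_threshold Passed to [classify_de()].
#' @return Data frame with columns `id`, `abundance_nonelicited`,
#'   `abundance_elicited`, `adjusted_p`, `fold`, `nd`, `direction`. The
#'   attribute `"p_criterion_used"` records whether a p column was supplied.
#' @export
expression_table <- function(x, input = c("counts", "tpm"),
                             fold_threshold = 2, p_threshold = 0.05) {
  input <- match.arg(input)
  stopifnot(is.data.frame(x), "id" %in% names(x))
  cols <- if (input == "counts") {
    c("count_nonelicited", "count_elicited")
  } else {
    c("abundance_nonelicited", "abundance_elicited")
  }
  if (!all(cols %in% names(x))) {
    stop("expected columns: ", paste(cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(x$id)) stop("duplicate ids in expression table", call. = FALSE)
  ab_n <- as.numeric(x[[cols[1L]]])
  ab_e <- as.numeric(x[[cols[2L]]])
  if (input == "counts") {
    ab_n <- relative_abundance(ab_n)
    ab_e <- relative_abundance(ab_e)
  }
  has_p <- "adjusted_p" %in% names(x)
  p <- if (has_p) as.numeric(x$adjusted_p) else rep(NA_real_, nrow(x))
  fold <- fold_change(ab_e, ab_n)
  out <- data.frame(
    id = as.character(x$id),
    abundance_nonelicited = ab_n,
    abundance_elicited = ab_e,
    adjusted_p = p,
    fold = fold,
    nd = is_nd(fold),
    direction = classify_de(fold, p, fold_threshold, p_threshold),
    stringsAsFactors = FALSE
  )
  attr(out, "p_criterion_used") <- has_p
  out
}

#' Pathway-level direction summary
#'
#' Classifies each pathway by the strong (default fourfold) changes among its
#' members: a member counts as up when its DE direction is `"up"` and its fold
#' change is at least `pathway_fold_threshold` (n.d. counts), and as down when
#' its direction is `"down"` and its fold change is at most the reciprocal
#' threshold. A pathway is `"increased"` when it has up members and no down
#' members, `"decreased"` for the reverse, `"mixed"` when it has both, and
#' `"none"` when it has neither. Members may belong to several pathways.
#'
#' @param records An expression table from [expression_table()] (columns `id`,
#'   `fold`, `direction`).
#' @param pathway_map Long-format data frame with columns `pathway_id`,
#'   `member_id`.
#' @param pathway_fold_threshold Fold cutoff for counting a member, default 4.
#' @return Data frame with columns `pathway_id`, `n_members`, `n_up`,
#'   `n_down`, `n_missing`, `classification`. Members absent from `records`
#'   are counted in `n_missing` (with a warning) and never toward a direction.
#' @export
summarize_pathways <- function(records, pathway_map, pathway_fold_threshold = 4) {
  stopifnot(is.data.frame(records),
            all(c("id", "fold", "direction") %in% names(records)),
            is.data.frame(pathway_map),
            all(c("pathway_id", "member_id") %in% names(pathway_map)),
            is.numeric(pathway_fold_threshold), pathway_fold_threshold > 0)
  idx <- match(pathway_map$member_id, records$id)
  missing <- is.na(idx)
  if (any(missing)) {
    warning(sprintf("%d pathway member(s) missing from the expression table",
                    sum(missing)), call. = FALSE)
  }
  fold <- records$fold[idx]
  direction <- records$direction[idx]
  member_up <- !missing & direction == "up" & fold >= pathway_fold_threshold
  member_down <- !missing & direction == "down" &
    fold <= 1 / pathway_fold_threshold
  ids <- unique(pathway_map$pathway_id)
  n_up <- as.integer(tapply(member_up, pathway_map$pathway_id, sum)[ids])
  n_down <- as.integer(tapply(member_down, pathway_map$pathway_id, sum)[ids])
  n_missing <- as.integer(tapply(missing, pathway_map$pathway_id, sum)[ids])
  n_members <- as.integer(table(pathway_map$pathway_id)[ids])
  classification <- rep("none", length(ids))
  classification[n_up > 0L & n_down == 0L] <- "increased"
  classification[n_down > 0L & n_up == 0L] <- "decreased"
  classification[n_up > 0L & n_down > 0L] <- "mixed"
  empty <- n_members == n_missing
  if (any(empty)) {
    warning("pathway(s) with no resolvable members: ",
            paste(ids[empty], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(pathway_id = ids, n_members = n_members, n_up = n_up,
                    n_down = n_down, n_missing = n_missing,
                    classification = classification, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
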