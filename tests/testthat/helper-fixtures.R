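# Shared test fixtures: random sequence generators and an independent
# brute-force re-implementation of the four-rule filter, coded straight from
# the rule definitions with no shared logic with the package internals.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

rand_mirna_seq <- function(L = 21L) {
  repeat {
    s <- rand_seq(L)
    if (grepl("[GU]", s)) return(s)
  }
}

# pairing states computed by hand from the two character vectors
brute_states <- function(mirna_seq, site_seq) {
  m <- strsplit(mirna_seq, "", fixed = TRUE)[[1L]]
  s <- rev(strsplit(site_seq, "", fixed = TRUE)[[1L]])
  wc <- c(A = "U", U = "A", G = "C", C = "G", N = "?")
  out <- character(length(m))
  for (i in seq_along(m)) {
    out[i] <- if (wc[[m[i]]] == s[i]) {
      "match"
    } else if ((m[i] == "G" && s[i] == "U") || (m[i] == "U" && s[i] == "G")) {
      "gu"
    } else {
      "mismatch"
    }
  }
  out
}

# independent verdict: naive position loop over the states
brute_verdict <- function(states, config = rule_config()) {
  score <- 0
  run <- 0L
  max_run <- 0L
  seed_mm <- 0L
  central_mm <- 0L
  for (i in seq_along(states)) {
    st <- states[i]
    if (st == "mismatch") score <- score + 1
    if (st == "gu") score <- score + config$gu_score
    positional <- st == "mismatch" ||
      (st == "gu" && config$gu_counts_in_positional_rules)
    if (positional) {
      run <- run + 1L
      max_run <- max(max_run, run)
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
  list(
    pass_total = score <= config$max_total_score,
    pass_contiguous = max_run <= config$max_contiguous_mismatch,
    pass_seed = seed_mm <= config$max_seed_mismatch,
    pass_central = central_mm == 0L,
    passed = score <= config$max_total_score &&
      max_run <= config$max_contiguous_mismatch &&
      seed_mm <= config$max_seed_mismatch &&
      central_mm == 0L
  )
}

# embed a site into a transcript at a 0-based start
plant_site <- function(transcript_seq, site_seq, start0) {
  stopifnot(start0 + nchar(site_seq) <= nchar(transcript_seq))
  substr(transcript_seq, start0 + 1L, start0 + nchar(site_seq)) <- site_seq
  transcript_seq
}

# toy expression records for pathway tests
expr_records <- function(ids, folds, directions) {
  data.frame(id = ids, fold = folds, direction = directions,
             stringsAsFactors = FALSE)
}
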