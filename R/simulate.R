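# Synthetic-data generators: transcriptomes with planted target sites and
# single-rule decoys, and two-condition negative-binomial count tables with
# planted fold tiers. Everything is deterministic given the config seed.

.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.subseed <- function(seed, offset) {
  (as.integer(seed) %% 2000000000L) + offset
}

#' Simulation configuration
#'
#' Ground-truth description of the synthetic study: a small set of random
#' miRNAs, a random transcriptome carrying planted target sites and
#' single-rule decoys, and a two-condition count table with planted fold
#' tiers under negative-binomial noise.
#'
#' Defaults emulate the structure of a two-library elicitation experiment:
#' transcript lengths centred on ~680 nt, one library per condition at a depth
#' of 10^5 counts over 200 genes, negative-binomial dispersion 0.1 (biological
#' CV ~32%), and fold tiers \{1, 2, 4, n.d.\} with the 2x and 4x tiers split
#' evenly between up- and down-regulation so the two libraries stay mass-
#' balanced under per-million normalization.
#'
#' @param seed Integer seed; every generator output is a deterministic
#'   function of it.
#' @param n_mirnas,mirna_length Number and length of random miRNAs.
#' @param n_transcripts Number of transcripts.
#' @param length_meanlog,length_sdlog,min_length Log-normal transcript length
#'   distribution (median `exp(length_meanlog)` nt) and lower clip.
#' @param base_probs Background base composition over A, C, G, U.
#' @param n_planted_sites Number of rule-passing planted sites.
#' @param n_decoys Number of decoy sites, cycled over the four rules.
#' @param max_planted_mismatches,max_planted_gu Per-site caps for random
#'   planted (passing) sites.
#' @param n_genes Genes in the count table.
#' @param depth Expected library depth (counts per condition).
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param mean_range Log-uniform range for baseline expression means
#'   (arbitrary units; rescaled to `depth`).
#' @param fold_tiers Data frame with columns `tier` (labels among
#'   `"1"`, `"2"`, `"0.5"`, `"4"`, `"0.25"`, `"nd"`, `"off"`) and `n` (gene
#'   counts, summing to `n_genes`). `"nd"` plants a gene silent in the
#'   nonelicited library; `"off"` one silenced by elicitation.
#' @param rules A [rule_config()] used to verify planted sites and decoys.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1L,
                              n_mirnas = 8L,
                              mirna_length = 21L,
                              n_transcripts = 100L,
                              length_meanlog = log(684),
                              length_sdlog = 0.35,
                              min_length = 150L,
                              base_probs = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                              n_planted_sites = 60L,
                              n_decoys = 12L,
                              max_planted_mismatches = 3L,
                              max_planted_gu = 2L,
                              n_genes = 200L,
                              depth = 1e5,
                              dispersion = 0.1,
                              mean_range = c(50, 5000),
                              fold_tiers = data.frame(
                                tier = c("1", "2", "0.5", "4", "0.25", "nd"),
                                n = c(140L, 15L, 15L, 10L, 10L, 10L)
                              ),
                              rules = rule_config()) {
  stopifnot(
    is.numeric(seed), length(seed) == 1L,
    n_mirnas >= 1L, mirna_length >= 12L, n_transcripts >= 1L,
    min_length >= mirna_length,
    length(base_probs) == 4L, all(base_probs >= 0), sum(base_probs) > 0,
    n_planted_sites >= 0L, n_decoys >= 0L,
    n_genes >= 1L, depth > 0, dispersion >= 0,
    length(mean_range) == 2L, mean_range[1L] > 0, mean_range[2L] >= mean_range[1L],
    is.data.frame(fold_tiers), all(c("tier", "n") %in% names(fold_tiers)),
    all(fold_tiers$n >= 0L), sum(fold_tiers$n) == n_genes,
    all(fold_tiers$tier %in% c("1", "2", "0.5", "4", "0.25", "nd", "off")),
    inherits(rules, "rule_config")
  )
  structure(list(
    seed = as.integer(seed), n_mirnas = as.integer(n_mirnas),
    mirna_length = as.integer(mirna_length),
    n_transcripts = as.integer(n_transcripts),
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    min_length = as.integer(min_length),
    base_probs = base_probs / sum(base_probs),
    n_planted_sites = as.integer(n_planted_sites),
    n_decoys = as.integer(n_decoys),
    max_planted_mismatches = as.integer(max_planted_mismatches),
    max_planted_gu = as.integer(max_planted_gu),
    n_genes = as.integer(n_genes), depth = depth, dispersion = dispersion,
    mean_range = mean_range, fold_tiers = fold_tiers, rules = rules
  ), class = "simulation_config")
}

.random_seq <- function(n, base_probs) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE, prob = base_probs),
        collapse = "")
}

# Tier label -> fold multiplier applied to the nonelicited mean.
.tier_fold <- function(tier) {
  switch(tier,
         "1" = 1, "2" = 2, "0.5" = 0.5, "4" = 4, "0.25" = 0.25,
         "nd" = Inf, "off" = 0,
         stop("unknown tier: ", tier, call. = FALSE))
}

#' Build a target site from a planted-site spec
#'
#' Starts from the miRNA's exact reverse complement, then forces mismatches
#' (the lexicographically first non-pairing, non-wobble base, for determinism)
#' and G:U wobbles (the target base is substituted so the pair becomes G:U) at
#' the stated miRNA positions. Positions are 1-based from the miRNA 5' end;
#' miRNA position `i` maps to site position `L - i + 1`.
#'
#' @param mirna_seq Normalized miRNA sequence.
#' @param mismatch_positions,gu_positions Disjoint integer sets of 1-based
#'   miRNA positions; G:U positions must carry a G or U miRNA base.
#' @return The site sequence (5' to 3'), ready to embed in a transcript.
#' @export
build_site <- function(mirna_seq, mismatch_positions, gu_positions) {
  L <- nchar(mirna_seq)
  mm <- as.integer(mismatch_positions)
  gu <- as.integer(gu_positions)
  if (length(intersect(mm, gu))) {
    stop("mismatch and G:U position sets must be disjoint", call. = FALSE)
  }
  if (any(c(mm, gu) < 1L) || any(c(mm, gu) > L)) {
    stop("planted positions outside [1, miRNA length]", call. = FALSE)
  }
  mchars <- strsplit(mirna_seq, "", fixed = TRUE)[[1L]]
  schars <- strsplit(reverse_complement(mirna_seq), "", fixed = TRUE)[[1L]]
  for (i in mm) {
    cand <- c("A", "C", "G", "U")
    first_mm <- cand[which(pair_state(rep(mchars[i], 4L), cand) == "mismatch")[1L]]
    schars[L - i + 1L] <- first_mm
  }
  for (i in gu) {
    schars[L - i + 1L] <- switch(mchars[i],
      G = "U", U = "G",
      stop(sprintf("G:U planting requires a G or U miRNA base at position %d", i),
           call. = FALSE))
  }
  paste(schars, collapse = "")
}

.format_positions <- function(pos) {
  if (!length(pos)) "" else paste(sort(as.integer(pos)), collapse = ",")
}

.parse_positions <- function(txt) {
  if (is.na(txt) || !nzchar(txt)) integer(0) else
    as.integer(strsplit(txt, ",", fixed = TRUE)[[1L]])
}

# Random rule-passing planted-site spec (mismatches outside seed/central).
.sample_passing_spec <- function(mirna_seq, config) {
  L <- nchar(mirna_seq)
  rules <- config$rules
  seed_pos <- rules$seed_region[1L]:rules$seed_region[2L]
  central_pos <- rules$central_region[1L]:rules$central_region[2L]
  free <- setdiff(seq_len(L), c(seed_pos, central_pos))
  mchars <- strsplit(mirna_seq, "", fixed = TRUE)[[1L]]
  wobble_ok <- which(mchars %in% c("G", "U"))
  for (try in 1:200) {
    n_mm <- sample(0:config$max_planted_mismatches, 1L)
    mm <- sort(free[sample.int(length(free), min(n_mm, length(free)))])
    gu_cand <- setdiff(wobble_ok, mm)
    n_gu <- sample(0:config$max_planted_gu, 1L)
    gu <- sort(gu_cand[sample.int(length(gu_cand), min(n_gu, length(gu_cand)))])
    site <- build_site(mirna_seq, mm, gu)
    if (evaluate_rules(score_duplex(mirna_seq, site, rules), rules)$passed) {
      return(list(mismatch_positions = mm, gu_positions = gu))
    }
  }
  stop("failed to sample a passing planted-site spec", call. = FALSE)
}

#' Decoy planted-site spec violating exactly one rule
#'
#' Constructs mismatch/wobble position sets whose planted site fails exactly
#' the named rule and passes the other three (verified through
#' [evaluate_rules()] before returning).
#'
#' @param rule_to_violate One of `"total"`, `"contiguous"`, `"seed"`,
#'   `"central"`.
#' @param mirna_seq Normalized miRNA sequence (needed because a G:U wobble can
#'   only be planted opposite a G or U miRNA base).
#' @param config A [rule_config()].
#' @return A list with `mismatch_positions` and `gu_positions` (1-based miRNA
#'   positions).
#' @export
make_decoy <- function(rule_to_violate = c("total", "contiguous", "seed", "central"),
                       mirna_seq, config = rule_config()) {
  rule_to_violate <- match.arg(rule_to_violate)
  stopifnot(is.character(mirna_seq), length(mirna_seq) == 1L,
            inherits(config, "rule_config"))
  L <- nchar(mirna_seq)
  if (L < 12L) stop("miRNA too short for decoy construction", call. = FALSE)
  seed_pos <- config$seed_region[1L]:config$seed_region[2L]
  central_pos <- config$central_region[1L]:config$central_region[2L]
  free <- setdiff(seq_len(L), c(seed_pos, central_pos))
  free_after <- free[free > max(central_pos)]
  mchars <- strsplit(mirna_seq, "", fixed = TRUE)[[1L]]
  spec <- switch(rule_to_violate,
    central = list(mismatch_positions = max(central_pos), gu_positions = integer(0)),
    seed = {
      if (length(seed_pos) < 3L) stop("seed region too short for a seed decoy",
                                      call. = FALSE)
      list(mismatch_positions = c(seed_pos[2L], seed_pos[2L] + 3L),
           gu_positions = integer(0))
    },
    contiguous = {
      k <- config$max_contiguous_mismatch + 1L
      runs <- free_after[seq_len(k)]
      if (length(free_after) < k || any(diff(runs) != 1L)) {
        stop("miRNA too short for a contiguous-run decoy", call. = FALSE)
      }
      list(mismatch_positions = runs, gu_positions = integer(0))
    },
    total = {
      if (length(free_after) < 5L) {
        stop("miRNA too short for a total-score decoy", call. = FALSE)
      }
      mm <- free_after[c(1L, 2L, 4L, 5L)]
      gu_cand <- setdiff(which(mchars %in% c("G", "U")), mm)
      if (length(gu_cand)) {
        list(mismatch_positions = mm, gu_positions = gu_cand[1L])
      } else {
        list(mismatch_positions = c(mm, seed_pos[3L]), gu_positions = integer(0))
      }
    }
  )
  site <- build_site(mirna_seq, spec$mismatch_positions, spec$gu_positions)
  v <- evaluate_rules(score_duplex(mirna_seq, site, config), config)
  flags <- c(total = v$pass_total, contiguous = v$pass_contiguous,
             seed = v$pass_seed, central = v$pass_central)
  if (v$passed || any(!flags[names(flags) != rule_to_violate]) ||
      flags[[rule_to_violate]]) {
    stop(sprintf("could not construct a decoy violating exactly the '%s' rule",
                 rule_to_violate), call. = FALSE)
  }
  spec
}

#' Generate a transcriptome with planted target sites and decoys
#'
#' Draws random miRNAs and random i.i.d.-background transcripts, then plants
#' `n_planted_sites` rule-passing target sites (random mismatch/wobble
#' configurations outside the seed and central regions) and `n_decoys` decoy
#' sites, each violating exactly one rule (cycled over the four rules). Sites
#' are built from the miRNA's reverse complement (see [make_decoy()] for the
#' substitution conventions) and written into non-overlapping transcript
#' windows. Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param mirnas Optional data frame with columns `id`, `sequence` to use
#'   instead of random miRNAs.
#' @param site_specs Optional data frame predetermining the planted sites:
#'   columns `mirna_id`, `transcript_idx` (1-based), `mismatch_positions`,
#'   `gu_positions` (comma-separated strings), `kind` (`"planted"`). When
#'   given, replaces the random planted sites (decoys are still added).
#' @return A list with `mirnas` (data frame `id`, `sequence`), `transcripts`
#'   (data frame `id`, `sequence`), and `sites` — the ground-truth ledger with
#'   one row per planted site: `mirna_id`, `transcript_id`, `position`
#'   (0-based start), `mismatch_positions`, `gu_positions` (comma-separated,
#'   1-based miRNA positions), `kind` (`"planted"`/`"decoy"`), `decoy_rule`,
#'   `site_seq`, and `expected_pass` as evaluated by [score_duplex()] +
#'   [evaluate_rules()] on the planted window.
#' @export
make_transcriptome <- function(config = simulation_config(), mirnas = NULL,
                               site_specs = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(.subseed(config$seed, 0L), {
    L <- config$mirna_length
    if (is.null(mirnas)) {
      mirnas <- data.frame(
        id = sprintf("mir%02d", seq_len(config$n_mirnas)),
        sequence = vapply(seq_len(config$n_mirnas), function(i) {
          repeat {
            s <- .random_seq(L, config$base_probs)
            # need at least one wobble-capable base for G:U planting
            if (grepl("[GU]", s)) return(s)
          }
        }, character(1)),
        stringsAsFactors = FALSE
      )
    } else {
      stopifnot(is.data.frame(mirnas), all(c("id", "sequence") %in% names(mirnas)))
      L <- unique(nchar(mirnas$sequence))
      if (length(L) != 1L) stop("miRNAs must share one length", call. = FALSE)
    }
    lens <- pmax(config$min_length,
                 round(stats::rlnorm(config$n_transcripts,
                                     config$length_meanlog,
                                     config$length_sdlog)))
    transcripts <- data.frame(
      id = sprintf("t%04d", seq_len(config$n_transcripts)),
      sequence = vapply(lens, .random_seq, character(1),
                        base_probs = config$base_probs),
      stringsAsFactors = FALSE
    )

    # assemble the planted-site specs (random passing sites unless given)
    specs <- list()
    if (is.null(site_specs)) {
      for (k in seq_len(config$n_planted_sites)) {
        mi <- ((k - 1L) %% nrow(mirnas)) + 1L
        sp <- .sample_passing_spec(mirnas$sequence[mi], config)
        specs[[length(specs) + 1L]] <- list(
          mirna_id = mirnas$id[mi], transcript_idx = NA_integer_,
          mismatch_positions = sp$mismatch_positions,
          gu_positions = sp$gu_positions,
          kind = "planted", decoy_rule = NA_character_)
      }
    } else {
      for (k in seq_len(nrow(site_specs))) {
        specs[[length(specs) + 1L]] <- list(
          mirna_id = site_specs$mirna_id[k],
          transcript_idx = as.integer(site_specs$transcript_idx[k]),
          mismatch_positions = .parse_positions(site_specs$mismatch_positions[k]),
          gu_positions = .parse_positions(site_specs$gu_positions[k]),
          kind = "planted", decoy_rule = NA_character_)
      }
    }
    rules4 <- c("total", "contiguous", "seed", "central")
    for (k in seq_len(config$n_decoys)) {
      mi <- ((k - 1L) %% nrow(mirnas)) + 1L
      rule <- rules4[((k - 1L) %% 4L) + 1L]
      sp <- make_decoy(rule, mirnas$sequence[mi], config$rules)
      specs[[length(specs) + 1L]] <- list(
        mirna_id = mirnas$id[mi], transcript_idx = NA_integer_,
        mismatch_positions = sp$mismatch_positions,
        gu_positions = sp$gu_positions,
        kind = "decoy", decoy_rule = rule)
    }

    # place each site into a non-overlapping window of a transcript
    occupied <- vector("list", nrow(transcripts))
    ledger <- vector("list", length(specs))
    for (k in seq_along(specs)) {
      sp <- specs[[k]]
      site <- build_site(mirnas$sequence[match(sp$mirna_id, mirnas$id)],
                          sp$mismatch_positions, sp$gu_positions)
      placed <- FALSE
      for (try in 1:500) {
        ti <- if (!is.na(sp$transcript_idx)) sp$transcript_idx
              else sample.int(nrow(transcripts), 1L)
        tlen <- nchar(transcripts$sequence[ti])
        if (tlen < L) {
          if (!is.na(sp$transcript_idx)) break else next
        }
        start0 <- sample.int(tlen - L + 1L, 1L) - 1L
        window <- c(start0, start0 + L)  # 0-based half-open
        clash <- any(vapply(occupied[[ti]], function(iv) {
          window[1L] < iv[2L] && iv[1L] < window[2L]
        }, logical(1)))
        if (clash) next
        seq <- transcripts$sequence[ti]
        substr(seq, start0 + 1L, start0 + L) <- site
        transcripts$sequence[ti] <- seq
        occupied[[ti]] <- c(occupied[[ti]], list(window))
        mseq <- mirnas$sequence[match(sp$mirna_id, mirnas$id)]
        verdict <- evaluate_rules(score_duplex(mseq, site, config$rules),
                                  config$rules)
        ledger[[k]] <- data.frame(
          mirna_id = sp$mirna_id, transcript_id = transcripts$id[ti],
          position = start0,
          mismatch_positions = .format_positions(sp$mismatch_positions),
          gu_positions = .format_positions(sp$gu_positions),
          kind = sp$kind, decoy_rule = sp$decoy_rule,
          site_seq = site, expected_pass = verdict$passed,
          stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place a planted site without overlap; ",
             "reduce n_planted_sites or lengthen transcripts", call. = FALSE)
      }
    }
    sites <- do.call(rbind, c(ledger, list(make.row.names = FALSE)))
    list(mirnas = mirnas, transcripts = transcripts, sites = sites)
  })
}

# Tier assignment -> count table; p-values are the ground-truth significance
# of the planted mean shift (conditional exact binomial test on the expected
# counts), not a test on the noisy observed counts.
.simulate_counts_from_tiers <- function(tiers, config, gene_ids) {
  n <- length(tiers)
  folds <- vapply(tiers, .tier_fold, numeric(1))
  base <- exp(stats::runif(n, log(config$mean_range[1L]),
                           log(config$mean_range[2L])))
  mu_n <- ifelse(is.infinite(folds), 0, base)
  mu_e <- ifelse(is.infinite(folds), base, base * folds)
  # Balance the expected library masses so planted folds are realized in
  # relative-abundance (per-million) space: rescale the baseline means of the
  # down-regulated genes so the up- and down-regulated mass cancels (total
  # mRNA mass conservation, the standard normalization assumption). Without
  # this, planted per-million folds would compress by sum(mu_n)/sum(mu_e).
  down <- is.finite(folds) & folds < 1
  c_up <- sum(mu_e[!down] - mu_n[!down])
  c_down <- sum(mu_n[down] - mu_e[down])
  if (c_down > 0) {
    alpha <- c_up / c_down
    mu_n[down] <- mu_n[down] * alpha
    mu_e[down] <- mu_e[down] * alpha
  }
  scale <- config$depth / sum(mu_n)
  mu_n <- mu_n * scale
  mu_e <- mu_e * scale
  draw <- function(mu) {
    if (config$dispersion == 0) stats::rpois(n, mu)
    else stats::rnbinom(n, mu = mu, size = 1 / config$dispersion)
  }
  count_n <- draw(mu_n)
  count_e <- draw(mu_e)
  p_true <- vapply(seq_len(n), function(i) {
    xn <- round(mu_n[i]); xe <- round(mu_e[i])
    if (xn + xe == 0) return(NA_real_)
    stats::binom.test(xe, xn + xe, p = 0.5)$p.value
  }, numeric(1))
  direction_true <- rep("unchanged", n)
  direction_true[folds >= 2 | is.infinite(folds)] <- "up"
  direction_true[folds <= 0.5] <- "down"
  list(
    table = data.frame(id = gene_ids,
                       count_nonelicited = as.numeric(count_n),
                       count_elicited = as.numeric(count_e),
                       adjusted_p = p_true, stringsAsFactors = FALSE),
    truth = data.frame(id = gene_ids, tier = tiers, true_fold = folds,
                       true_direction = direction_true,
                       mu_nonelicited = mu_n, mu_elicited = mu_e,
                       stringsAsFactors = FALSE)
  )
}

#' Simulate a two-condition count table with planted fold tiers
#'
#' Per gene, a baseline mean is drawn log-uniformly from `mean_range` and
#' rescaled so the nonelicited library sums to `depth`; the elicited mean is
#' the baseline times the planted tier fold (`"nd"` genes are silent in the
#' nonelicited library, `"off"` genes in the elicited one). Counts are drawn
#' from a negative binomial with the configured dispersion. The emitted
#' `adjusted_p` column holds the ground-truth p-value of the planted mean
#' shift: a conditional exact binomial test ([stats::binom.test()]) on the
#' expected (true-mean) counts, so unplanted genes carry p = 1 and planted
#' shifts carry their true significance independent of the sampling noise.
#'
#' @param config A [simulation_config()].
#' @param gene_ids Optional gene identifiers (length `n_genes`).
#' @param tiers Optional per-gene tier labels overriding
#'   `config$fold_tiers` (length `n_genes`).
#' @return A list with `table` (data frame `id`, `count_nonelicited`,
#'   `count_elicited`, `adjusted_p`) and `truth` (per-gene tier, true fold —
#'   `Inf` for n.d. —, true direction, and the true means).
#' @export
simulate_counts <- function(config = simulation_config(), gene_ids = NULL,
                            tiers = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(.subseed(config$seed, 1L), {
    if (is.null(tiers)) {
      tiers <- sample(rep(config$fold_tiers$tier, config$fold_tiers$n))
    }
    stopifnot(length(tiers) == config$n_genes)
    if (is.null(gene_ids)) gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
    stopifnot(length(gene_ids) == config$n_genes)
    .simulate_counts_from_tiers(tiers, config, gene_ids)
  })
}

#' Simulate a complete elicitation study
#'
#' Couples the transcriptome and count generators into one end-to-end fixture:
#' miRNAs with expression directions, transcripts carrying planted sites for
#' designed (miRNA, target) pairs, a count table over the same transcript ids,
#' and a pathway map. The designed pairs use on/off (n.d.-style) target
#' expression so their realized directions are unambiguous under count noise,
#' giving exact ground-truth complementary/concordant pattern counts:
#' `n_complementary` pairs where miRNA and target moved oppositely and
#' `n_concordant` pairs where they moved together. Decoy sites are planted as
#' in [make_transcriptome()]; remaining transcripts receive a background tier
#' mix (~70% unchanged, symmetric 2x and 4x tiers, a few n.d. genes).
#'
#' @param config A [simulation_config()]; `n_mirnas` must be at least
#'   `n_complementary + n_concordant` and `n_transcripts` large enough to host
#'   one target transcript per pair.
#' @param n_complementary,n_concordant Number of designed pairs of each
#'   pattern (defaults 5 and 3).
#' @param sites_per_pair Planted sites per designed pair (default 2; tests
#'   site aggregation).
#' @return A list: `mirnas` (data frame `id`, `sequence`, `direction`),
#'   `transcripts`, `sites` ledger, `counts` (list `table`/`truth`, gene ids =
#'   transcript ids), `pathway_map` (columns `pathway_id`, `member_id`),
#'   `planted_patterns` (named counts), and the `config`.
#' @export
simulate_study <- function(config = simulation_config(),
                           n_complementary = 5L, n_concordant = 3L,
                           sites_per_pair = 2L) {
  stopifnot(inherits(config, "simulation_config"),
            n_complementary >= 0L, n_concordant >= 0L, sites_per_pair >= 1L)
  n_pairs <- n_complementary + n_concordant
  if (config$n_mirnas < n_pairs) {
    stop("need at least n_complementary + n_concordant miRNAs", call. = FALSE)
  }
  if (config$n_transcripts < n_pairs) {
    stop("need at least one transcript per designed pair", call. = FALSE)
  }
  # designed directions: alternate the orientation within each pattern class
  mirna_dir <- character(n_pairs)
  target_tier <- character(n_pairs)
  for (k in seq_len(n_pairs)) {
    comp <- k <= n_complementary
    mirna_up <- k %% 2L == 0L
    mirna_dir[k] <- if (mirna_up) "up" else "down"
    target_up <- if (comp) !mirna_up else mirna_up
    target_tier[k] <- if (target_up) "nd" else "off"
  }
  # designed pairs: miRNA k targets transcript k, with perfect-complement sites
  pair_specs <- do.call(rbind, lapply(seq_len(n_pairs), function(k) {
    data.frame(mirna_id = sprintf("mir%02d", k),
               transcript_idx = k,
               mismatch_positions = rep("", sites_per_pair),
               gu_positions = "",
               stringsAsFactors = FALSE)
  }))
  trome <- make_transcriptome(config, site_specs = pair_specs)
  dirs <- rep("unchanged", config$n_mirnas)
  dirs[seq_len(n_pairs)] <- mirna_dir
  trome$mirnas$direction <- dirs

  # tier assignment over transcripts-as-genes
  .with_seed(.subseed(config$seed, 2L), {
    n <- config$n_transcripts
    tiers <- rep("1", n)
    free <- setdiff(seq_len(n), seq_len(n_pairs))
    n_free <- length(free)
    pool <- c(rep("2", ceiling(0.07 * n_free)), rep("0.5", ceiling(0.07 * n_free)),
              rep("4", ceiling(0.05 * n_free)), rep("0.25", ceiling(0.05 * n_free)),
              rep("nd", ceiling(0.03 * n_free)))
    pool <- c(pool, rep("1", max(0L, n_free - length(pool))))[seq_len(n_free)]
    tiers[free] <- sample(pool)
    tiers[seq_len(n_pairs)] <- target_tier
    cfg_counts <- config
    cfg_counts$n_genes <- n
    counts <- .simulate_counts_from_tiers(tiers, cfg_counts, trome$transcripts$id)

    # pathway map: consecutive blocks of ~10 genes, plus overlap members
    block <- 10L
    pw <- data.frame(
      pathway_id = sprintf("pw%02d", ((seq_len(n) - 1L) %/% block) + 1L),
      member_id = trome$transcripts$id,
      stringsAsFactors = FALSE
    )
    extra_n <- max(1L, n %/% 20L)
    extra <- data.frame(
      pathway_id = sample(unique(pw$pathway_id), extra_n, replace = TRUE),
      member_id = sample(trome$transcripts$id, extra_n),
      stringsAsFactors = FALSE
    )
    pathway_map <- unique(rbind(pw, extra))
    rownames(pathway_map) <- NULL

    list(mirnas = trome$mirnas, transcripts = trome$transcripts,
         sites = trome$sites, counts = counts, pathway_map = pathway_map,
         planted_patterns = c(complementary = as.integer(n_complementary),
                              concordant = as.integer(n_concordant),
                              indeterminate = 0L),
         config = config)
  })
}
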