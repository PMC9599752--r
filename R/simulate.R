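#' Configuration of the synthetic 4C experiment
#'
#' Describes a single-chromosome toy experiment with the statistical
#' structure the analysis assumes: restriction sites at roughly geometric
#' spacings (4-cutter sites in real genomes are approximately exponentially
#' spaced, expected ~256 bp), contact counts falling off as a power law of
#' distance from the bait, negative-binomial overdispersion, a contact peak
#' planted in the first (whisker-pad-like) condition and absent in the
#' second (kidney-like), and deliberately inflated scores inside the
#' viewpoint exclusion window so tests can verify that exclusion works.
#'
#' @param seed Integer master seed; every random draw flows from it through
#'   a per-condition/per-replicate counter scheme, so any single replicate
#'   is reproducible in isolation.
#' @param contig_name,contig_length Toy contig; default 2 Mb `chrS`
#'   (`S` for synthetic).
#' @param mean_primary_spacing,mean_secondary_spacing Mean distance (bases)
#'   between planted NlaIII / DpnII sites; defaults 300 / 280.
#' @param bait_center Bait coordinate; default mid-contig (1 Mb).
#' @param excluded_region Viewpoint exclusion window; default bait +/- 3 kb,
#'   comparable in width to real 4C viewpoint exclusions.
#' @param total_reads Expected total fragment score per replicate outside
#'   the exclusion window; default 100,000.
#' @param decay_exponent Power-law exponent of the expected decay;
#'   default -1, matching the fixed slope of the profile-correction model.
#' @param peak_region Planted contact peak; the default 9 kb window 85 kb
#'   from the bait covers about 30 fragments at the default spacing.
#' @param peak_fold Fold enrichment of the peak in the first condition;
#'   `peak_fold = 1` encodes the null (kidney-like everywhere).
#' @param dispersion Negative-binomial overdispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts. Default 0.1, typical
#'   of 4C fragment counts.
#' @param n_replicates_per_condition Replicates per condition; default 2.
#' @param conditions Names of the two conditions; the peak is planted in
#'   the first.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              contig_name = "chrS",
                              contig_length = 2e6,
                              mean_primary_spacing = 300,
                              mean_secondary_spacing = 280,
                              bait_center = 1e6,
                              excluded_region = NULL,
                              total_reads = 1e5,
                              decay_exponent = -1,
                              peak_region = NULL,
                              peak_fold = 3,
                              dispersion = 0.1,
                              n_replicates_per_condition = 2,
                              conditions = c("whisker_pad", "kidney")) {
  stopifnot(contig_length > 1e4, mean_primary_spacing > 4,
            mean_secondary_spacing > 4,
            bait_center > 0, bait_center < contig_length,
            total_reads > 0, peak_fold >= 1, dispersion >= 0,
            n_replicates_per_condition >= 1, length(conditions) == 2L)
  if (is.null(excluded_region)) {
    excluded_region <- region(contig_name, bait_center - 3000,
                              bait_center + 3000, "viewpoint_exclusion")
  }
  if (is.null(peak_region)) {
    peak_region <- region(contig_name, bait_center + 85000,
                          bait_center + 94000, "planted_peak")
  }
  stopifnot(peak_region$start >= 0, peak_region$end <= contig_length,
            excluded_region$start >= 0,
            excluded_region$end <= contig_length,
            excluded_region$start < bait_center,
            excluded_region$end > bait_center)
  structure(list(seed = as.integer(seed), contig_name = contig_name,
                 contig_length = contig_length,
                 mean_primary_spacing = mean_primary_spacing,
                 mean_secondary_spacing = mean_secondary_spacing,
                 bait_center = bait_center,
                 excluded_region = excluded_region,
                 total_reads = total_reads,
                 decay_exponent = decay_exponent,
                 peak_region = peak_region, peak_fold = peak_fold,
                 dispersion = dispersion,
                 n_replicates_per_condition =
                   as.integer(n_replicates_per_condition),
                 conditions = conditions),
            class = c("simulation_config", "list"))
}

replicate_seed <- function(config, condition_idx, replicate_idx) {
  (config$seed * 1000L + condition_idx * 100L + replicate_idx) %%
    .Machine$integer.max
}

#' Generate a toy genome with planted restriction sites
#'
#' Random ACGT background with `CATG` planted at geometric spacings (mean
#' `mean_primary_spacing`) and `GATC` at `mean_secondary_spacing`. The
#' background is cleaned so that no accidental `CATG`/`GATC` occurs outside
#' the planted sites; in-silico digestion of the result therefore recovers
#' exactly the planted sites. Deterministic given the seed.
#'
#' @param config A [simulation_config()].
#' @return A named character vector of length 1 (the contig sequence).
#' @export
make_toy_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, {
    len <- config$contig_length
    plant <- function(mean_spacing, avoid = numeric(0)) {
      n_est <- ceiling(len / (mean_spacing - 4) * 1.5) + 10
      gaps <- 4 + stats::rgeom(n_est, prob = 1 / (mean_spacing - 4))
      pos <- cumsum(gaps)
      pos <- pos[pos <= len - 4]
      if (length(avoid)) {
        near <- vapply(pos, function(p) {
          any(abs(avoid - p) < 4)
        }, logical(1))
        pos <- pos[!near]
      }
      pos
    }
    p1 <- plant(config$mean_primary_spacing)
    p2 <- plant(config$mean_secondary_spacing, avoid = p1)
    if (length(p1) < 3L || length(p2) < 3L) {
      stop("infeasible spacing: too few planted sites on a ", len,
           " bp contig")
    }

    chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    protected <- rep(FALSE, len)
    for (p in p1) {
      chars[(p + 1):(p + 4)] <- c("C", "A", "T", "G")
      protected[(p + 1):(p + 4)] <- TRUE
    }
    for (p in p2) {
      chars[(p + 1):(p + 4)] <- c("G", "A", "T", "C")
      protected[(p + 1):(p + 4)] <- TRUE
    }

    # scrub accidental motif occurrences outside the planted sites
    for (iter in seq_len(50)) {
      seq <- paste(chars, collapse = "")
      found1 <- find_motif_sites(seq, enzyme_nlaiii()) - 4  # motif starts
      found2 <- find_motif_sites(seq, enzyme_dpnii())
      acc <- c(setdiff(found1, p1), setdiff(found2, p2))
      if (length(acc) == 0L) break
      for (q in acc) {
        span <- (q + 1):(q + 4)
        free <- span[!protected[span]]
        if (length(free) == 0L) next  # overlaps planted motifs only
        i <- free[1]
        chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
      }
      if (iter == 50L) stop("failed to scrub accidental motifs")
    }
    stats::setNames(paste(chars, collapse = ""), config$contig_name)
  })
}

#' Simulate two-condition replicate 4C fragment scores
#'
#' The expected score of a fragment at distance `d` from the bait center is
#' `lambda(d) = A * d^decay_exponent`, multiplied by `peak_fold` when the
#' fragment midpoint falls in the peak region and the condition is the
#' enriched one. `A` is set per condition so the expected scores outside
#' the exclusion window sum to `total_reads`. Realized scores are
#' negative-binomial (Poisson when `dispersion = 0`). Fragments inside the
#' exclusion window get a deliberately huge deterministic score -- real
#' viewpoint-proximal signal is dominated by self-ligation -- so any leak
#' past [exclude_viewpoint()] is loud.
#'
#' @param map A `fragment_map` of the toy genome.
#' @param config A [simulation_config()].
#' @return A named list (one element per condition) of lists of raw
#'   `score_track`s, one per replicate, each carrying the bait region as
#'   metadata; the config is attached as an attribute.
#' @export
simulate_scores <- function(map, config) {
  stopifnot(inherits(map, "fragment_map"),
            inherits(config, "simulation_config"))
  frag <- tibble::as_tibble(map)
  frag <- frag[frag$chrom == config$contig_name, , drop = FALSE]
  if (nrow(frag) == 0L) stop("fragment map has no fragments on contig ",
                             config$contig_name)
  mid <- (frag$start + frag$end) / 2
  d <- abs(mid - config$bait_center)
  in_excl <- frag$start < config$excluded_region$end &
    frag$end > config$excluded_region$start
  if (any(!in_excl & d < 1)) {
    stop("fragment at the bait center is outside the exclusion window; ",
         "widen excluded_region")
  }
  in_peak <- mid >= config$peak_region$start & mid < config$peak_region$end
  base <- ifelse(in_excl, 0, d^config$decay_exponent)
  bait <- region(config$contig_name, config$bait_center - 50,
                 config$bait_center + 50, "bait")

  out <- purrr::imap(
    stats::setNames(seq_along(config$conditions), config$conditions),
    function(ci, cname) {
      enriched <- ci == 1L
      fold <- ifelse(in_peak & enriched, config$peak_fold, 1)
      lambda <- base * fold
      lambda <- lambda * config$total_reads / sum(lambda)
      planted_big <- round(50 * max(lambda))
      purrr::map(seq_len(config$n_replicates_per_condition), function(ri) {
        withr::with_seed(replicate_seed(config, ci, ri), {
          score <- if (config$dispersion > 0) {
            stats::rnbinom(length(lambda), mu = lambda,
                           size = 1 / config$dispersion)
          } else {
            stats::rpois(length(lambda), lambda)
          }
          score[in_excl] <- planted_big
          fr <- frag
          fr$score <- as.numeric(score)
          new_score_track(fr, stage = "raw", bait = bait)
        })
      })
    })
  attr(out, "config") <- config
  out
}

#' Population decay intercept under the simulation law
#'
#' The fixed-slope intercept estimator averages
#' `log10(score) + log10(d)` over fragments with positive score inside the
#' fit range, so its population value under the simulation law is the
#' `P(score > 0)`-weighted mean of `E[log10(score) | score > 0] + log10(d)`
#' (computed by exact pmf summation per fragment). The value is on the raw
#' count scale; subtract `log10` of a track's realized normalization mean
#' (its `norm_mean` attribute) to get the expected intercept of a fit on
#' that normalized track. Because counts are discrete, this population
#' value sits slightly below `log10(A)`; the gap shrinks as counts grow.
#'
#' @param map A `fragment_map` of the toy genome.
#' @param config A [simulation_config()]; the null (second) condition's
#'   expected scores are used.
#' @param params A [signal_params()] list supplying the fit range.
#' @return A list: `intercept_raw` (population estimand, raw scale),
#'   `log10_A` (the decay amplitude itself), `n_fragments`.
#' @export
decay_truth <- function(map, config, params = signal_params()) {
  stopifnot(inherits(map, "fragment_map"),
            inherits(config, "simulation_config"))
  frag <- tibble::as_tibble(map)
  frag <- frag[frag$chrom == config$contig_name, , drop = FALSE]
  mid <- (frag$start + frag$end) / 2
  d <- abs(mid - config$bait_center)
  in_excl <- frag$start < config$excluded_region$end &
    frag$end > config$excluded_region$start
  base <- ifelse(in_excl, 0, d^config$decay_exponent)
  a_const <- config$total_reads / sum(base)
  lambda <- base * a_const

  sel <- !in_excl & d >= params$fit_min_distance &
    d <= params$fit_max_distance
  mu <- lambda[sel]
  dd <- d[sel]
  size <- if (config$dispersion > 0) 1 / config$dispersion else Inf
  stats_one <- function(m) {
    kmax <- if (is.finite(size)) {
      stats::qnbinom(1 - 1e-12, mu = m, size = size)
    } else {
      stats::qpois(1 - 1e-12, m)
    }
    k <- seq_len(max(kmax, 1))
    pk <- if (is.finite(size)) {
      stats::dnbinom(k, mu = m, size = size)
    } else {
      stats::dpois(k, m)
    }
    c(p_pos = sum(pk), e_log = sum(pk * log10(k)))
  }
  st <- vapply(mu, stats_one, c(p_pos = 0, e_log = 0))
  w <- st["p_pos", ]
  # E[log10 s | s>0] + log10 d, weighted by the eligibility probability
  intercept_raw <- sum(w * (st["e_log", ] / w + log10(dd))) / sum(w)
  list(intercept_raw = intercept_raw, log10_A = log10(a_const),
       n_fragments = length(mu))
}

#' Write a ready-to-run synthetic fixture bundle
#'
#' Writes the toy genome FASTA, the fragment BED, one score TSV per
#' condition and replicate, and a pipeline YAML config wired to those
#' files. Regenerating with the same seed gives byte-identical files.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths (with `config_path`
#'   pointing at the YAML).
#' @export
write_fixture_bundle <- function(config, dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genome <- make_toy_genome(config)
  map <- digest_genome(genome)
  sims <- simulate_scores(map, config)

  fasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), fasta)
  bed <- file.path(dir, "fragments.bed")
  write_fragment_map(map, bed)

  score_paths <- purrr::imap(sims, function(reps, cname) {
    purrr::imap_chr(reps, function(tr, ri) {
      p <- file.path(dir, sprintf("%s_rep%d.tsv", cname, ri))
      write_score_table(tr, p)
      p
    })
  })

  cfg <- list(
    genome = "genome.fa",
    enzymes = list(primary = "NlaIII:CATG:4", secondary = "DpnII:GATC:0"),
    conditions = purrr::map(score_paths, basename),
    viewpoint = list(
      name = "synthetic_bait",
      excluded = format_region(config$excluded_region),
      bait = format_region(region(config$contig_name,
                                  config$bait_center - 50,
                                  config$bait_center + 50))),
    target_regions = list(planted_peak = format_region(config$peak_region)),
    signal = unclass(signal_params()),
    stats = unclass(stats_params()),
    seed = config$seed,
    output_dir = "pipeline_out")
  config_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, config_path)
  invisible(list(genome = fasta, fragment_map = bed,
                 score_tables = score_paths, config_path = config_path))
}
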