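#' Validate and resolve a pipeline configuration
#'
#' Reads a YAML configuration (or an equivalent named list), fills in every
#' default, parses region strings (UCSC-style separators accepted), and
#' aggregates all validation problems into a single error message.
#'
#' A minimal config needs only `genome` and two `conditions` entries; the
#' viewpoint exclusion windows and target regions of the Lef1/Leaf study
#' (see [study_regions()]) are preloaded as defaults when the viewpoint
#' `name` is `"lef1_promoter"` or `"leaf"`.
#'
#' @param x Path to a YAML file, or a named list with the same structure.
#' @param base_dir Directory against which relative file paths are
#'   resolved; defaults to the config file's directory.
#' @return A resolved configuration of class `fourc_config`.
#' @export
validate_config <- function(x, base_dir = NULL) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("config file not found: ", x)
    base_dir <- base_dir %||% dirname(x)
    x <- yaml::read_yaml(x)
  }
  base_dir <- base_dir %||% "."
  stopifnot(is.list(x))
  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)
  resolve <- function(p) {
    ifelse(file.exists(p), p, file.path(base_dir, p))
  }

  genome <- x$genome
  if (is.null(genome)) {
    note("missing key 'genome' (FASTA path)")
  } else {
    genome <- resolve(genome)
    if (!file.exists(genome)) note(paste0("genome file not found: ", genome))
  }

  enzymes <- tryCatch({
    list(primary = parse_enzyme(x$enzymes$primary %||% "NlaIII:CATG:4"),
         secondary = parse_enzyme(x$enzymes$secondary %||% "DpnII:GATC:0"))
  }, error = function(e) {
    note(paste0("key 'enzymes': ", conditionMessage(e)))
    NULL
  })

  conditions <- x$conditions
  if (is.null(conditions) || length(conditions) != 2L ||
      is.null(names(conditions)) || any(!nzchar(names(conditions)))) {
    note("key 'conditions' must name exactly two conditions, each a list of replicate input files")
    conditions <- NULL
  } else {
    conditions <- purrr::map(conditions, function(files) {
      files <- resolve(unlist(files))
      missing <- files[!file.exists(files)]
      if (length(missing)) {
        note(paste0("replicate input file(s) not found: ",
                    paste(missing, collapse = ", ")))
      }
      files
    })
  }

  vp <- x$viewpoint %||% list()
  vp_name <- vp$name %||% "viewpoint"
  defaults <- list(lef1_promoter = "lef1_promoter_exclusion",
                   leaf = "leaf_exclusion")
  excluded <- tryCatch({
    if (!is.null(vp$excluded)) {
      parse_region(vp$excluded, name = paste0(vp_name, "_exclusion"))
    } else if (vp_name %in% names(defaults)) {
      study_region(defaults[[vp_name]])
    } else {
      note("key 'viewpoint.excluded' is required for viewpoints without preloaded defaults")
      NULL
    }
  }, error = function(e) {
    note(paste0("key 'viewpoint.excluded': ", conditionMessage(e)))
    NULL
  })
  bait <- tryCatch({
    if (!is.null(vp$bait)) parse_region(vp$bait, name = vp_name) else excluded
  }, error = function(e) {
    note(paste0("key 'viewpoint.bait': ", conditionMessage(e)))
    NULL
  })
  if (!is.null(bait) && !is.null(excluded) &&
      (bait$chrom != excluded$chrom || bait$start >= excluded$end ||
       bait$end <= excluded$start)) {
    note("viewpoint.excluded must overlap viewpoint.bait")
  }

  targets <- x$target_regions
  target_regions <- tryCatch({
    if (is.null(targets)) {
      tr <- study_regions()
      tr <- tr[tr$role == "analysis_region", , drop = FALSE]
      stats::setNames(purrr::map(seq_len(nrow(tr)), function(i) {
        region(tr$chrom[i], tr$start[i], tr$end[i], name = tr$name[i])
      }), tr$name)
    } else {
      stats::setNames(purrr::imap(targets, function(s, nm) {
        parse_region(s, name = nm)
      }), names(targets))
    }
  }, error = function(e) {
    note(paste0("key 'target_regions': ", conditionMessage(e)))
    NULL
  })

  signal <- tryCatch({
    do.call(signal_params, x$signal %||% list())
  }, error = function(e) {
    note(paste0("key 'signal': ", conditionMessage(e)))
    NULL
  })
  stats_p <- tryCatch({
    sp <- x$stats %||% list()
    if (!is.null(sp$star_thresholds)) {
      sp$star_thresholds <- as.numeric(unlist(sp$star_thresholds))
    }
    do.call(stats_params, sp)
  }, error = function(e) {
    note(paste0("key 'stats': ", conditionMessage(e)))
    NULL
  })

  if (length(errors)) {
    stop("invalid pipeline config:\n  - ",
         paste(errors, collapse = "\n  - "))
  }
  structure(list(genome = genome, enzymes = enzymes,
                 conditions = conditions,
                 viewpoint = list(name = vp_name, bait = bait,
                                  excluded = excluded),
                 target_regions = target_regions,
                 signal = signal, stats = stats_p,
                 end_tolerance = x$end_tolerance %||% 5,
                 keep_blind = isTRUE(x$keep_blind),
                 output_dir = file.path(base_dir,
                                        x$output_dir %||% "fourc_out"),
                 seed = as.integer(x$seed %||% 1L)),
            class = c("fourc_config", "list"))
}

load_replicate_track <- function(path, map, config) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "txt")) {
    read_score_table(path, map, keep_blind = config$keep_blind)
  } else {
    reads <- read_aligned_reads(path)
    assign_reads(reads, map, end_tolerance = config$end_tolerance,
                 keep_blind = config$keep_blind)
  }
}

#' Run the full contact-quantification pipeline
#'
#' Digest -> score -> exclude viewpoint -> normalize -> smooth (browser
#' tracks) and profile-correct (testing tracks) -> differential contact test
#' per target region. Writes, under the configured output directory,
#' bedGraphs and score TSVs for every stage and replicate, the test results
#' as TSV and JSON, a long-format table of region fragment scores ready for
#' boxplotting, and a run log echoing every parameter. Identical inputs
#' produce byte-identical outputs.
#'
#' @param config A `fourc_config` from [validate_config()].
#' @return Invisibly, a list of class `fourc_run`: the fragment map, the
#'   per-condition track lists (all stages per replicate), the `tests`
#'   tibble, the long `region_scores` table, and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "fourc_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  say("fourcquant %s | seed=%d | viewpoint=%s",
      as.character(utils::packageVersion("fourcquant")), config$seed,
      config$viewpoint$name)
  say("signal: norm_halfwidth=%g smooth_window=%d fit_range=[%g,%g]",
      config$signal$norm_halfwidth, config$signal$smooth_window,
      config$signal$fit_min_distance, config$signal$fit_max_distance)
  say("stats: alpha=%g stars=%s exact_max_n=%d | end_tolerance=%g keep_blind=%s",
      config$stats$alpha,
      paste(config$stats$star_thresholds, collapse = "/"),
      config$stats$exact_max_n, config$end_tolerance, config$keep_blind)
  say("excluded=%s bait=%s", format_region(config$viewpoint$excluded),
      format_region(config$viewpoint$bait))

  map <- digest_genome(config$genome, config$enzymes$primary,
                       config$enzymes$secondary)
  say("fragment map: %d fragments on %d contig(s)", nrow(map),
      length(unique(map$chrom)))
  write_fragment_map(map, file.path(out_dir, "fragments.bed"))

  tracks <- purrr::imap(config$conditions, function(files, cname) {
    purrr::imap(files, function(path, ri) {
      run_stage <- function(stage, expr) {
        tryCatch(expr, error = function(e) {
          stop("stage ", stage, " failed for condition ", cname,
               " replicate ", ri, ": ", conditionMessage(e), call. = FALSE)
        })
      }
      raw <- run_stage("scoring", {
        tr <- load_replicate_track(path, map, config)
        exclude_viewpoint(tr, config$viewpoint$excluded,
                          bait = config$viewpoint$bait)
      })
      norm <- run_stage("normalization",
                        normalize_local_mean(raw, config$signal))
      smooth <- run_stage("smoothing", running_mean(norm, config$signal))
      fit <- run_stage("decay_fit", fit_decay(norm, config$signal))
      corrected <- run_stage("profile_correction",
                             profile_correct(norm, fit))
      say("%s rep%d: %d retained fragments, %d excluded, decay intercept %.4f (n=%d)",
          cname, ri, nrow(raw), attr(raw, "n_removed"), fit$intercept,
          fit$n_points)
      stages <- list(raw = raw, normalized = norm, smoothed = smooth,
                     profile_corrected = corrected)
      for (st in names(stages)) {
        base <- sprintf("%s_rep%d_%s", cname, ri, st)
        write_bedgraph(stages[[st]], file.path(out_dir,
                                               paste0(base, ".bedgraph")),
                       name = base)
        write_score_table(stages[[st]], file.path(out_dir,
                                                  paste0(base, ".tsv")))
      }
      c(stages, list(decay_fit = fit))
    })
  })

  cond_names <- names(config$conditions)
  tests <- purrr::map(config$target_regions, function(reg) {
    compare_conditions(tracks[[1]], tracks[[2]], reg,
                       params = config$stats,
                       condition_names = cond_names)
  })
  tests <- dplyr::bind_rows(tests)
  class(tests) <- unique(c("contact_test", class(tests)))
  for (i in seq_len(nrow(tests))) {
    say("test %s [%s]: U=%g p=%.4g %s", tests$region_name[i],
        tests$stage[i], tests$U[i], tests$p_two_tailed[i], tests$stars[i])
  }
  readr::write_tsv(tibble::as_tibble(tests),
                   file.path(out_dir, "contact_tests.tsv"))
  jsonlite::write_json(as.data.frame(tests),
                       file.path(out_dir, "contact_tests.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  region_scores <- purrr::map(config$target_regions, function(reg) {
    purrr::imap(tracks, function(reps, cname) {
      purrr::imap(reps, function(stages, ri) {
        purrr::map(c("normalized", "profile_corrected"), function(st) {
          v <- suppressWarnings(extract_region_scores(stages[[st]], reg))
          if (length(v) == 0L) return(NULL)
          tibble::tibble(region = reg$name, condition = cname,
                         replicate = ri, stage = st, score = v)
        }) |> dplyr::bind_rows()
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  readr::write_tsv(region_scores, file.path(out_dir, "region_scores.tsv"))

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(structure(list(map = map, tracks = tracks, tests = tests,
                           region_scores = region_scores,
                           output_dir = out_dir, config = config),
                      class = "fourc_run"))
}
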