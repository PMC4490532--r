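# End-to-end pipeline driver: one configuration in, one artifact
# directory out (tags, profiles, alignments, calls, precursor tables,
# census), with a manifest and run log.

#' Default pipeline configuration
#'
#' @param ... Overrides for any configuration entry.
#' @return Configuration list: `simulate` (logical), `sim` (arguments for
#'   [sim_config()]), input paths (`reads`, `transcripts`, `mirnas`,
#'   `hairpins`, `ncrna`; used when `simulate` is FALSE), stage parameters
#'   (`adapter`, `min_overlap`, `min_len`, `max_len`, `max_score`,
#'   `window`), and `seed`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    simulate = TRUE,
    sim = list(),
    reads = NULL, transcripts = NULL, mirnas = NULL,
    hairpins = NULL, ncrna = NULL,
    adapter = "TGGAATTCTCGGGTGCCAAGG",
    min_overlap = 5L, min_len = 18L, max_len = 24L,
    max_score = 4.5, window = 1L,
    seed = 1L
  )
  utils::modifyList(cfg, list(...))
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file path.
#' @return Configuration list (defaults filled in, see
#'   [pipeline_config()]).
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @noRd
run_stage <- function(name, log_con, expr) {
  msg <- sprintf("[%s] stage: %s", format(Sys.time(), "%H:%M:%S"), name)
  if (!is.null(log_con)) writeLines(msg, log_con)
  tryCatch(expr, error = function(e) {
    stop("pipeline aborted in stage '", name, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the degradome pipeline end to end
#'
#' Executes simulate (optional), preprocess, map/profile, target scan,
#' cleavage calling, precursor analysis and census, writing every table to
#' `out_dir` along with `manifest.json` (package version, configuration
#' hash, seed) and `run.log`. Under a fixed seed two runs produce
#' byte-identical outputs.
#'
#' @param config Configuration list from [pipeline_config()] /
#'   [read_pipeline_config()], or a YAML path.
#' @param out_dir Output directory.
#' @return Invisibly, a list with every intermediate object (`sim`, `tags`,
#'   `stats`, `hits`, `profiles`, `alignments`, `calls`,
#'   `precursor_products`, `precursor_calls`, `feedback_loops`,
#'   `star_pairs`, `census`, `tallies`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)

  sim <- NULL
  catalog <- NULL
  if (isTRUE(config$simulate)) {
    sim <- run_stage("simulate", log_con, {
      sc <- do.call(sim_config, c(list(seed = config$seed), config$sim))
      simulate_degradome(sc, file.path(out_dir, "sim"))
    })
    reads <- sim$reads
    transcripts <- sim$transcripts
    catalog <- sim$mature
    hairpins <- sim$hairpins
    ncrna <- sim$ncrna
    adapter <- sim$config$adapter
  } else {
    run_stage("load inputs", log_con, {
      if (is.null(config$reads)) stop("no reads file configured")
      if (is.null(config$transcripts)) stop("no transcript file configured")
      if (is.null(config$mirnas)) stop("no miRNA catalog configured")
      for (f in c(config$reads, config$transcripts, config$mirnas,
                  config$hairpins, config$ncrna)) {
        if (!is.null(f) && !file.exists(f)) stop("missing input file: ", f)
      }
    })
    reads <- run_stage("load reads", log_con, read_reads(config$reads))
    transcripts <- run_stage("mapping inputs", log_con,
                             read_fasta(config$transcripts))
    catalog <- run_stage("mapping inputs", log_con,
                         read_mirna_catalog(config$mirnas))
    hairpins <- if (!is.null(config$hairpins)) read_fasta(config$hairpins)
    ncrna <- if (!is.null(config$ncrna)) read_fasta(config$ncrna)
    adapter <- config$adapter
  }

  pre <- run_stage("preprocess", log_con, {
    preprocess_reads(reads, adapter, ncrna_set = ncrna,
                     min_overlap = config$min_overlap,
                     min_len = config$min_len, max_len = config$max_len)
  })
  mapped <- run_stage("mapping", log_con, map_tags(pre$tags, transcripts))
  profiles <- run_stage("profiles", log_con, build_profiles(mapped$hits))
  alignments <- run_stage("target scan", log_con, {
    mirnas <- stats::setNames(catalog$sequence, catalog$id)
    scan_catalog(mirnas, transcripts, max_score = config$max_score)
  })
  calls <- run_stage("cleavage calls", log_con,
                     call_cleavages(alignments, profiles,
                                    window = config$window))

  precursor_products <- precursor_calls <- feedback_loops <- star_pairs <- NULL
  if (!is.null(hairpins) && length(hairpins)) {
    precursor_products <- run_stage("precursor products", log_con, {
      queries <- rbind(pre$tags,
                       data.frame(sequence = normalize_seq(catalog$sequence),
                                  count = 0, stringsAsFactors = FALSE))
      locate_products(queries, hairpins)
    })
    precursor_calls <- run_stage("precursor calls", log_con, {
      precursor_self_targets(catalog, hairpins, pre$tags,
                             max_score = config$max_score,
                             window = config$window)
    })
    feedback_loops <- run_stage("feedback loops", log_con, {
      if ("precursor_id" %in% names(catalog)) {
        detect_feedback_loops(precursor_calls, catalog)
      } else {
        # derive precursor families from hairpin identifiers by stripping a
        # conventional precursor prefix (pre-/Precur-/precursor-)
        fam <- sub("^(pre|precur|precursor)[-_]", "", names(hairpins),
                   ignore.case = TRUE)
        detect_feedback_loops(precursor_calls, catalog,
                              precursor_families = stats::setNames(
                                fam, names(hairpins)))
      }
    })
    star_pairs <- run_stage("star pairs", log_con, {
      all_calls <- rbind(calls, precursor_calls)
      functional_star_pairs(all_calls, catalog)
    })
  }

  census <- run_stage("census", log_con, category_census(calls))
  tallies <- run_stage("census", log_con, targets_per_mirna(calls))

  run_stage("write outputs", log_con, {
    write_tsv_stable(pre$tags, file.path(out_dir, "tags.tsv"))
    stats_out <- pre$stats
    stats_out$unannotated_tags <- mapped$unannotated_tags
    stats_out$unannotated_reads <- mapped$unannotated_reads
    jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_tsv_stable(mapped$hits, file.path(out_dir, "hits.tsv"))
    write_tsv_stable(as.data.frame(profiles),
                     file.path(out_dir, "profiles.tsv"))
    write_tsv_stable(alignments, file.path(out_dir, "alignments.tsv"))
    write_tsv_stable(calls, file.path(out_dir, "calls.tsv"))
    if (!is.null(precursor_products)) {
      write_tsv_stable(precursor_products,
                       file.path(out_dir, "precursor_products.tsv"))
      write_tsv_stable(precursor_calls,
                       file.path(out_dir, "precursor_calls.tsv"))
      write_tsv_stable(feedback_loops,
                       file.path(out_dir, "feedback_loops.tsv"))
      write_tsv_stable(star_pairs, file.path(out_dir, "star_pairs.tsv"))
    }
    write_tsv_stable(census, file.path(out_dir, "census.tsv"))
    write_tsv_stable(tallies$tally, file.path(out_dir, "tallies.tsv"))
    # t-plot tables, one per called transcript
    tplot_dir <- file.path(out_dir, "tplots")
    dir.create(tplot_dir, showWarnings = FALSE)
    for (tx in unique(calls$transcript_id)) {
      tab <- tplot(profile_for(profiles, tx), calls, transcript_id = tx)
      write_tsv_stable(tab, file.path(tplot_dir, paste0(tx, ".tsv")))
    }
    cfg_file <- tempfile()
    yaml::write_yaml(config[order(names(config))], cfg_file)
    manifest <- list(
      package = "degracall",
      version = as.character(utils::packageVersion("degracall")),
      seed = config$seed,
      config_md5 = unname(tools::md5sum(cfg_file)),
      n_calls = nrow(calls),
      n_transcripts_called = length(unique(calls$transcript_id))
    )
    unlink(cfg_file)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  invisible(list(sim = sim, tags = pre$tags, stats = pre$stats,
                 hits = mapped$hits, profiles = profiles,
                 alignments = alignments, calls = calls,
                 precursor_products = precursor_products,
                 precursor_calls = precursor_calls,
                 feedback_loops = feedback_loops, star_pairs = star_pairs,
                 census = census, tallies = tallies))
}
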