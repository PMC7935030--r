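#' Pipeline configuration
#'
#' Assembles the declarative configuration driving [run_pipeline()]:
#' synthetic cohort settings (or an input manifest for existing recordings),
#' filtering, segmentation, PTE, surrogate-pruning, NBS and metrics
#' parameters, plus a master seed from which every stage derives its own.
#'
#' @param out_dir output directory for stage artifacts.
#' @param synth list: `n_subjects`, `n_nodes`, `fs`, `band`, `couplings`,
#'   `planted`, `delta`, `noise_sd`, `jitter_sd`, `duration_s`. Set to
#'   `NULL` and supply `manifest` to ingest existing recordings.
#' @param manifest path to a cohort manifest CSV (used when `synth` is
#'   `NULL`).
#' @param filters list overriding [filter_spec()] defaults.
#' @param segment list: `length_s`, `count`.
#' @param pte list overriding [pte_params()] defaults.
#' @param surrogate list: `n_surrogates`, `alpha`, `tolerance`.
#' @param nbs list: `t_threshold`, `n_permutations`, `tail`.
#' @param metrics list: `include_sigma`, `n_random`, `swaps_per_edge`,
#'   `communities` (logical), `n_iterations`.
#' @param seed master seed.
#' @param stages character vector of stages to run, in order.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            synth = list(),
                            manifest = NULL,
                            filters = list(),
                            segment = list(),
                            pte = list(),
                            surrogate = list(),
                            nbs = list(),
                            metrics = list(),
                            seed = 1L,
                            stages = c("synth", "preprocess", "connect",
                                       "prune", "nbs", "metrics", "stats")) {
  check_scalar(seed, "seed", integerish = TRUE)
  defaults <- list(
    synth = list(n_subjects = 8, n_nodes = 32, fs = 256,
                 band = c(0.53, 35), couplings = NULL, planted = NULL,
                 delta = 0.4, noise_sd = 0.5, jitter_sd = 0.05,
                 duration_s = 300),
    filters = list(highpass_hz = 0.53, notch_band_hz = c(48, 52),
                   lowpass_hz = 97, analysis_band_hz = c(0.53, 35)),
    segment = list(length_s = 4, count = 15),
    pte = list(delay = NULL, n_bins = "scott", delay_mode = "band"),
    surrogate = list(n_surrogates = 100, alpha = 0.05, tolerance = 1e-3),
    nbs = list(t_threshold = 3, n_permutations = 500, tail = "positive"),
    metrics = list(include_sigma = FALSE, n_random = 100,
                   swaps_per_edge = 100, communities = FALSE,
                   n_iterations = 100))
  cfg <- list(
    out_dir = out_dir,
    manifest = manifest,
    synth = if (is.null(synth)) NULL else
      modifyList(defaults$synth, synth, keep.null = TRUE),
    filters = modifyList(defaults$filters, filters, keep.null = TRUE),
    segment = modifyList(defaults$segment, segment),
    pte = modifyList(defaults$pte, pte, keep.null = TRUE),
    surrogate = modifyList(defaults$surrogate, surrogate),
    nbs = modifyList(defaults$nbs, nbs),
    metrics = modifyList(defaults$metrics, metrics),
    seed = as.integer(seed),
    stages = stages)
  if (is.null(cfg$synth) && is.null(cfg$manifest))
    stop_param("either `synth` settings or a `manifest` must be given")
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

stage_done <- function(out, stage, hash) {
  f <- file.path(out, stage, ".done")
  file.exists(f) && identical(readLines(f, n = 1), hash)
}

mark_done <- function(out, stage, hash) {
  writeLines(hash, file.path(out, stage, ".done"))
}

stage_dir <- function(out, stage) {
  d <- file.path(out, stage)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

log_stage <- function(verbose, stage, msg, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(msg, ...)))
}

#' Run the full connectivity pipeline
#'
#' Executes the configured stages in order — synthesize (or ingest),
#' filter, estimate per-segment PTE networks and average them, prune against
#' surrogate ensembles, run the paired NBS comparison, compute graph
#' metrics, and run the density-adjusted group statistics — writing each
#' stage's artifacts under `out_dir` and skipping stages whose outputs
#' already exist for an identical configuration (hash check).
#'
#' @param config a [pipeline_config()].
#' @param verbose emit per-stage progress messages.
#' @return (invisibly) list with the stage artifact paths and the loaded
#'   headline results (`nbs`, `metrics`, `stats`), plus `skipped`, the
#'   stages skipped by the hash check.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  jsonlite::write_json(unclass(config), file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  skipped <- character()
  fspec <- do.call(filter_spec, config$filters)
  pparams <- pte_params(delay = config$pte$delay,
                        n_bins = config$pte$n_bins,
                        analysis_band = config$filters$analysis_band_hz,
                        delay_mode = config$pte$delay_mode)
  sessions <- c("pre", "post")

  # --- synth ---------------------------------------------------------------
  if ("synth" %in% config$stages && !is.null(config$synth)) {
    d <- stage_dir(out, "synth")
    if (stage_done(out, "synth", hash)) {
      skipped <- c(skipped, "synth")
    } else {
      sy <- config$synth
      model <- source_model(sy$n_nodes, sy$fs, sy$band,
                            couplings = sy$couplings,
                            noise_sd = sy$noise_sd,
                            seed = derive_seed(config$seed, 1L))
      spec <- cohort_spec(sy$n_subjects, model, planted = sy$planted,
                          delta = sy$delta, jitter_sd = sy$jitter_sd)
      cohort <- generate_cohort(spec, duration_s = sy$duration_s)
      rows <- list()
      for (s in seq_along(cohort$subjects)) for (ses in sessions) {
        p <- file.path(d, sprintf("sub%02d_%s.rds", s, ses))
        write_recording(cohort$subjects[[s]][[ses]], p, format = "binary")
        rows[[length(rows) + 1]] <- data.frame(subject = s, session = ses,
                                               path = p)
      }
      write_manifest(do.call(rbind, rows), file.path(d, "manifest.csv"))
      mark_done(out, "synth", hash)
      log_stage(verbose, "synth", "%d subjects x 2 sessions written",
                length(cohort$subjects))
    }
    manifest_path <- file.path(d, "manifest.csv")
  } else {
    manifest_path <- config$manifest
    if (is.null(manifest_path) || !file.exists(manifest_path))
      stop_param("no input: stage 'synth' disabled and manifest missing")
  }
  manifest <- read_manifest(manifest_path)

  read_rec <- function(path) {
    fmt <- if (grepl("\\.rds$", path)) "binary" else "text"
    tryCatch(read_recording(path, fmt), error = function(e)
      stop_param("failed reading recording '%s': %s", path,
                 conditionMessage(e)))
  }

  # --- preprocess: denoise + analysis band ---------------------------------
  if ("preprocess" %in% config$stages) {
    d <- stage_dir(out, "preprocess")
    if (stage_done(out, "preprocess", hash)) {
      skipped <- c(skipped, "preprocess")
    } else {
      for (r in seq_len(nrow(manifest))) {
        rec <- read_rec(manifest$path[r])
        rec <- apply_filters(rec, fspec)
        rec <- apply_analysis_band(rec, fspec$analysis_band_hz)
        write_recording(rec, file.path(d, sprintf("sub%02d_%s.rds",
                                                  manifest$subject[r],
                                                  manifest$session[r])),
                        format = "binary")
      }
      mark_done(out, "preprocess", hash)
      log_stage(verbose, "preprocess", "%d recordings filtered",
                nrow(manifest))
    }
  }

  filt_path <- function(s, ses)
    file.path(out, "preprocess", sprintf("sub%02d_%s.rds", s, ses))
  seg_seed <- function(s, ses)
    derive_seed(config$seed, 2L, s, match(ses, sessions))

  # --- connect: segment PTE networks, averaged -----------------------------
  if ("connect" %in% config$stages) {
    d <- stage_dir(out, "connect")
    if (stage_done(out, "connect", hash)) {
      skipped <- c(skipped, "connect")
    } else {
      for (r in seq_len(nrow(manifest))) {
        s <- manifest$subject[r]; ses <- manifest$session[r]
        rec <- read_rec(filt_path(s, ses))
        avg <- subject_network(rec, pparams,
                               segment_length_s = config$segment$length_s,
                               n_segments = config$segment$count,
                               seed = seg_seed(s, ses))
        write_network(avg, file.path(d, sprintf("sub%02d_%s.tsv", s, ses)))
      }
      mark_done(out, "connect", hash)
      log_stage(verbose, "connect", "%d averaged networks written",
                nrow(manifest))
    }
  }

  avg_path <- function(s, ses)
    file.path(out, "connect", sprintf("sub%02d_%s.tsv", s, ses))

  # --- prune: surrogate ensembles ------------------------------------------
  if ("prune" %in% config$stages) {
    d <- stage_dir(out, "prune")
    if (stage_done(out, "prune", hash)) {
      skipped <- c(skipped, "prune")
    } else {
      for (r in seq_len(nrow(manifest))) {
        s <- manifest$subject[r]; ses <- manifest$session[r]
        rec <- read_rec(filt_path(s, ses))
        real <- read_network(avg_path(s, ses))
        ens <- build_surrogate_ensemble(
          rec, config$surrogate$n_surrogates, pparams,
          segment_length_s = config$segment$length_s,
          n_segments = config$segment$count,
          segment_seed = seg_seed(s, ses),
          seed = derive_seed(config$seed, 3L, s, match(ses, sessions)))
        pr <- prune_network(real, ens, alpha = config$surrogate$alpha,
                            tolerance = config$surrogate$tolerance)
        saveRDS(ens, file.path(d, sprintf("ensemble_sub%02d_%s.rds", s,
                                          ses)))
        write_network(pr$network,
                      file.path(d, sprintf("sub%02d_%s.tsv", s, ses)))
        jsonlite::write_json(
          list(n_retained = pr$n_retained,
               critical_count = pr$critical_count,
               alpha = pr$alpha, tolerance = pr$tolerance,
               n_surrogates = pr$n_surrogates),
          file.path(d, sprintf("sub%02d_%s.json", s, ses)),
          auto_unbox = TRUE)
        log_stage(verbose, "prune", "sub%02d %s: %d edges retained",
                  s, ses, pr$n_retained)
      }
      mark_done(out, "prune", hash)
    }
  }

  pruned_path <- function(s, ses)
    file.path(out, "prune", sprintf("sub%02d_%s.tsv", s, ses))
  subjects <- sort(unique(manifest$subject))
  load_session <- function(ses)
    lapply(subjects, function(s) read_network(pruned_path(s, ses)))

  results <- list(skipped = NULL)

  # --- nbs -------------------------------------------------------------------
  if ("nbs" %in% config$stages) {
    d <- stage_dir(out, "nbs")
    if (stage_done(out, "nbs", hash) &&
        file.exists(file.path(d, "result.rds"))) {
      skipped <- c(skipped, "nbs")
    } else {
      res <- nbs_permutation_test(load_session("pre"), load_session("post"),
                                  t_threshold = config$nbs$t_threshold,
                                  n_permutations = config$nbs$n_permutations,
                                  seed = derive_seed(config$seed, 4L),
                                  tail = config$nbs$tail)
      write.table(summary(res), file.path(d, "components.csv"),
                  row.names = FALSE, sep = ",")
      labels <- rownames(res$t) %||% as.character(seq_len(nrow(res$t)))
      edges <- do.call(rbind, lapply(seq_along(res$components),
                                     function(k) {
        e <- res$components[[k]]$edges
        data.frame(component = k, source = labels[e[, 1]],
                   target = labels[e[, 2]],
                   t = res$t[e])
      }))
      if (is.null(edges))
        edges <- data.frame(component = integer(), source = character(),
                            target = character(), t = numeric())
      write.table(edges, file.path(d, "edges.csv"), row.names = FALSE,
                  sep = ",")
      jsonlite::write_json(res$params, file.path(d, "params.json"),
                           auto_unbox = TRUE)
      saveRDS(res, file.path(d, "result.rds"))
      mark_done(out, "nbs", hash)
      log_stage(verbose, "nbs", "%d suprathreshold components",
                length(res$components))
    }
    results$nbs <- readRDS(file.path(d, "result.rds"))
  }

  # --- metrics ---------------------------------------------------------------
  if ("metrics" %in% config$stages) {
    d <- stage_dir(out, "metrics")
    if (stage_done(out, "metrics", hash) &&
        file.exists(file.path(d, "global.csv"))) {
      skipped <- c(skipped, "metrics")
    } else {
      mc <- config$metrics
      glob <- list(); loc <- list()
      for (s in subjects) for (ses in sessions) {
        net <- read_network(pruned_path(s, ses))
        gm <- graph_metrics(net, include_sigma = mc$include_sigma,
                            n_random = mc$n_random,
                            swaps_per_edge = mc$swaps_per_edge,
                            seed = derive_seed(config$seed, 5L, s,
                                               match(ses, sessions)))
        glob[[length(glob) + 1]] <- data.frame(
          subject = s, session = ses, density = gm$density,
          connection_density = gm$connection_density,
          global_efficiency = gm$global_efficiency,
          transitivity = gm$transitivity,
          characteristic_path_length = gm$characteristic_path_length,
          sigma = if (mc$include_sigma) as.numeric(gm$sigma) else NA_real_)
        loc[[length(loc) + 1]] <- data.frame(
          subject = s, session = ses, node = gm$degree$node,
          clustering = unname(gm$clustering),
          betweenness = unname(as.numeric(gm$betweenness)),
          in_degree = gm$degree$in_degree,
          out_degree = gm$degree$out_degree)
        if (isTRUE(mc$communities)) {
          hp <- multiscale_communities(net, mc$n_iterations,
                                       seed = derive_seed(config$seed, 6L,
                                                          s,
                                                          match(ses,
                                                                sessions)))
          write.table(data.frame(node = gm$degree$node,
                                 community = hp$paths),
                      file.path(d, sprintf("communities_sub%02d_%s.tsv",
                                           s, ses)),
                      row.names = FALSE, sep = "\t", quote = FALSE)
        }
      }
      write.table(do.call(rbind, glob), file.path(d, "global.csv"),
                  row.names = FALSE, sep = ",")
      write.table(do.call(rbind, loc), file.path(d, "local.csv"),
                  row.names = FALSE, sep = ",")
      mark_done(out, "metrics", hash)
      log_stage(verbose, "metrics", "metrics for %d networks",
                2 * length(subjects))
    }
    results$metrics <- read.table(file.path(d, "global.csv"), header = TRUE,
                                  sep = ",")
  }

  # --- stats -----------------------------------------------------------------
  if ("stats" %in% config$stages) {
    d <- stage_dir(out, "stats")
    if (stage_done(out, "stats", hash) &&
        file.exists(file.path(d, "global.csv"))) {
      skipped <- c(skipped, "stats")
    } else {
      gm <- read.table(file.path(out, "metrics", "global.csv"),
                       header = TRUE, sep = ",")
      pre <- gm[gm$session == "pre", ][order(gm$subject[gm$session == "pre"]), ]
      post <- gm[gm$session == "post", ][order(gm$subject[gm$session == "post"]), ]
      measures <- c("global_efficiency", "transitivity",
                    "characteristic_path_length")
      rows <- lapply(measures, function(m) {
        a <- ancova_group_density(pre[[m]], post[[m]], pre$density,
                                  post$density)
        data.frame(measure = m, estimate = a$estimate, F = a$F, p = a$p,
                   density_coef = a$density_coef, df = a$df)
      })
      write.table(do.call(rbind, rows), file.path(d, "global.csv"),
                  row.names = FALSE, sep = ",")
      mark_done(out, "stats", hash)
      log_stage(verbose, "stats", "group statistics written")
    }
    results$stats <- read.table(file.path(d, "global.csv"), header = TRUE,
                                sep = ",")
  }

  results$skipped <- skipped
  results$out_dir <- out
  invisible(results)
}
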