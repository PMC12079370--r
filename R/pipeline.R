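## Orchestration: configuration, full-run pipeline and provenance.

#' Read a pipeline configuration
#'
#' Loads a YAML run configuration and fills defaults. The configuration has
#' three blocks: `simulate` (any [synth_config()] field), `preprocess` (any
#' [preprocess()] parameter), `analysis` (`channels`, `n_perm`, `method`,
#' `q`, `window_s`, `hrf_shift_s`, `lags_s`, `sync_t_channels`,
#' `sync_s_channels`, `stages`), plus top-level `seed` and `out_dir`.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return a validated config list of class `run_config`.
#' @export
pipeline_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$simulate <- cfg$simulate %||% list()
  cfg$preprocess <- cfg$preprocess %||% list()
  a <- cfg$analysis %||% list()
  a$n_perm <- a$n_perm %||% 200
  a$method <- a$method %||% "phase_randomize"
  a$q <- a$q %||% 0.05
  a$window_s <- a$window_s %||% 15
  a$hrf_shift_s <- a$hrf_shift_s %||% 6
  a$lags_s <- a$lags_s %||% c(-seq(14, 6, by = -2), seq(6, 14, by = 2))
  a$stages <- a$stages %||% c("rsa", "boundary", "decode", "sync")
  cfg$analysis <- a
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, preprocesses it, and runs the configured
#' analysis stages: RSA with permutation inference, boundary contrast on
#' the strongest RSA channel, leave-one-dyad-out decoding plus pISC, and
#' the teacher-student synchronization scan. Results are written as TSV and
#' JSON under `out_dir` (when set), together with a provenance record of
#' versions, seed and parameters. Any stage failure halts the run with a
#' stage-tagged error.
#'
#' @param config a [pipeline_config()] (or YAML path / bare list).
#' @return a result bundle (list) with the cohort, fitted objects and the
#'   provenance record.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else
    pipeline_config(config)
  a <- cfg$analysis
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  bundle <- list(config = cfg)
  cohort <- stage("simulate", {
    sim_args <- cfg$simulate
    recall_probs <- sim_args$recall_probs
    recall_distortion <- sim_args$recall_distortion %||% 0
    sim_args$recall_probs <- NULL
    sim_args$recall_distortion <- NULL
    sc <- do.call(synth_config, c(sim_args,
                                  list(seed = child_seed(cfg$seed, 1))))
    simulate_cohort(sc, recall_probs = recall_probs,
                    recall_distortion = recall_distortion)
  })
  cohort <- stage("preprocess", {
    do.call(preprocess_cohort, c(list(cohort), cfg$preprocess))
  })
  bundle$cohort <- cohort
  if ("rsa" %in% a$stages) {
    bundle$rsa <- stage("rsa", {
      isrsa(cohort, channels = a$channels, n_perm = a$n_perm,
            method = a$method, q = a$q, seed = child_seed(cfg$seed, 2))
    })
  }
  if ("boundary" %in% a$stages) {
    bundle$boundary <- stage("boundary", {
      ch <- if (!is.null(bundle$rsa)) {
        bundle$rsa$table$channel[which.max(bundle$rsa$table$r)]
      } else {
        a$channels[1] %||% 1
      }
      boundary_test(cohort, channel = ch, window_s = a$window_s,
                    hrf_shift_s = a$hrf_shift_s)
    })
  }
  if ("decode" %in% a$stages) {
    bundle$decode <- stage("decode", {
      ch <- if (!is.null(bundle$rsa)) {
        bundle$rsa$table$channel[which.max(bundle$rsa$table$r)]
      } else {
        a$channels[1] %||% 1
      }
      dec <- decode_knowledge(cohort, channel = ch)
      pisc <- neural_pisc(Filter(Negate(is.null),
                                 dec$decoding$per_student))
      list(decoding = dec, neural_pisc = pisc,
           behavioral_pisc = if (!is.null(cohort$recall)) {
             behavioral_pisc(cohort$recall)
           })
    })
  }
  if ("sync" %in% a$stages) {
    bundle$sync <- stage("sync", {
      sync_scan(cohort$teacher, cohort,
                t_channels = a$sync_t_channels %||% a$channels,
                s_channels = a$sync_s_channels %||% a$channels,
                lags_s = a$lags_s, n_perm = a$sync_n_perm %||% 0,
                method = a$method, q = a$q,
                seed = child_seed(cfg$seed, 3))
    })
  }
  bundle$provenance <- list(
    package = "classrsa",
    package_version = as.character(utils::packageVersion("classrsa")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    analysis = a[setdiff(names(a), "stages")],
    stages = a$stages)
  if (!is.null(cfg$out_dir)) {
    write_bundle(bundle, cfg$out_dir)
  }
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- bundle$cohort
  write_events(cohort$event_set, file.path(out_dir, "events.tsv"))
  write_sim_matrix(cohort$knowledge, file.path(out_dir, "knowledge.tsv"))
  qc <- lapply(cohort$qc, function(q) {
    list(artifact_frac = q$artifact_frac, bad = q$bad,
         excluded = q$excluded)
  })
  jsonlite::write_json(qc, file.path(out_dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$rsa)) {
    write_rsa_table(bundle$rsa, file.path(out_dir, "rsa.tsv"))
  }
  if (!is.null(bundle$boundary)) {
    write_boundary_table(bundle$boundary, file.path(out_dir, "boundary.tsv"))
    jsonlite::write_json(bundle$boundary$group,
                         file.path(out_dir, "boundary_group.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(bundle$decode)) {
    tab <- bundle$decode$decoding$table
    tab$pisc_neural <- bundle$decode$neural_pisc
    if (!is.null(bundle$decode$behavioral_pisc)) {
      tab$pisc_behavioral <- as.numeric(bundle$decode$behavioral_pisc)
    }
    write.table(tab, file.path(out_dir, "decode.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(bundle$decode$decoding$group,
                         file.path(out_dir, "decode_group.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(bundle$sync)) {
    write_sync_table(bundle$sync, file.path(out_dir, "sync.tsv"))
  }
  jsonlite::write_json(bundle$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
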