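#' Default pipeline run configuration
#'
#' One nested list drives [run_pipeline()]: the output directory, the
#' master seed (deterministically propagated to every stage), the stages to
#' execute, and per-stage settings. Any stage left out of `stages` must
#' find its input artifact already on disk in `out_dir`.
#'
#' @param out_dir run directory (created if needed).
#' @param seed master seed.
#' @param stages character subset of
#'   `c("simulate", "preprocess", "select", "train", "evaluate", "compare")`.
#' @param synthetic arguments for [synthetic_config()] (stage `simulate`).
#' @param selection arguments for [monte_carlo_rfecv()] (stage `select`);
#'   set `selection = NULL` to train on all 136 coordinates.
#' @param drn arguments overriding [drn_config()] defaults (stage `train`).
#' @param comparison arguments for [run_comparison()] (stage `compare`).
#' @return a list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("mfd_run_"), seed = 1L,
                       stages = c("simulate", "preprocess", "select",
                                  "train", "evaluate"),
                       synthetic = list(), selection = list(n_reps = 5),
                       drn = list(), comparison = list(n_trials = 2)) {
  structure(list(out_dir = out_dir, seed = seed, stages = stages,
                 synthetic = synthetic, selection = selection,
                 drn = drn, comparison = comparison),
            class = "run_config")
}

pipeline_stop <- function(stage, e) {
  abort_mfd(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            "mfd_stage_error")
}

#' Run the detection pipeline end to end
#'
#' Executes the enabled stages in order — simulate, preprocess, select,
#' train, evaluate, compare — writing every artifact (dataset CSVs, the
#' split, the normalisation state, the selection result, the fitted model,
#' JSON reports) plus an exact config snapshot into the run directory, so
#' a run can be replayed from its snapshot alone. A stage that is toggled
#' off reads its input artifact from the run directory. Stage failures
#' halt with a stage-named error; artifacts written so far are retained.
#'
#' @param config a [run_config()].
#' @return the run directory path, invisibly.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(name) file.path(config$out_dir, name)
  snapshot <- unclass(config)
  yaml::write_yaml(snapshot, art("config.yaml"))
  stage_on <- function(s) s %in% config$stages

  if (stage_on("simulate")) {
    tryCatch({
      sc <- do.call(synthetic_config,
                    utils::modifyList(list(seed = derive_seed(config$seed, 1)),
                                      config$synthetic))
      sim <- generate_dataset(sc)
      write_mfd_csv(sim$dataset, art("dataset.csv"))
      jsonlite::write_json(
        list(informative = sim$truth$informative,
             secondary = sim$truth$secondary,
             majority_rate = sim$truth$majority_rate,
             base_per_level = sim$truth$base_per_level),
        art("truth.json"), digits = NA, auto_unbox = TRUE)
    }, error = function(e) pipeline_stop("simulate", e))
  }

  if (stage_on("preprocess")) {
    tryCatch({
      ds <- read_mfd_csv(art("dataset.csv"))
      sp <- split_mfd(ds, seed = derive_seed(config$seed, 2))
      pre <- preprocess_mfd(ds, fit_index = sp$train)
      write_mfd_csv(pre$dataset, art("clean.csv"))
      write_minmax_json(pre$state, art("norm.json"))
      jsonlite::write_json(sp, art("split.json"), digits = NA)
    }, error = function(e) pipeline_stop("preprocess", e))
  }

  if (stage_on("select")) {
    tryCatch({
      if (is.null(config$selection)) {
        jsonlite::write_json(
          list(retained = feature_names_all(), threshold = 0,
               frequency = NULL),
          art("selection.json"), digits = NA, auto_unbox = TRUE)
      } else {
        ds <- read_mfd_csv(art("clean.csv"))
        sp <- jsonlite::read_json(art("split.json"), simplifyVector = TRUE)
        sel <- do.call(monte_carlo_rfecv, c(
          list(x = landmark_matrix(ds)[sp$train, , drop = FALSE],
               y = ds$kss[sp$train],
               seed = derive_seed(config$seed, 3)),
          config$selection))
        jsonlite::write_json(
          list(retained = sel$retained, threshold = sel$threshold,
               n_reps = sel$n_reps, frequency = as.list(sel$frequency)),
          art("selection.json"), digits = NA, auto_unbox = TRUE)
      }
    }, error = function(e) pipeline_stop("select", e))
  }

  if (stage_on("train")) {
    tryCatch({
      ds <- read_mfd_csv(art("clean.csv"))
      sp <- jsonlite::read_json(art("split.json"), simplifyVector = TRUE)
      sel <- jsonlite::read_json(art("selection.json"), simplifyVector = TRUE)
      x <- landmark_matrix(ds)[, sel$retained, drop = FALSE]
      dcfg <- do.call(drn_config, utils::modifyList(
        list(input_dim = ncol(x), classes = sort(unique(ds$kss))),
        config$drn))
      fit <- drnrf(x[sp$train, , drop = FALSE], ds$kss[sp$train],
                   drn = dcfg,
                   norm_state = read_minmax_json(art("norm.json")),
                   seed = derive_seed(config$seed, 4))
      saveRDS(fit, art("model.rds"))
    }, error = function(e) pipeline_stop("train", e))
  }

  if (stage_on("evaluate")) {
    tryCatch({
      ds <- read_mfd_csv(art("clean.csv"))
      sp <- jsonlite::read_json(art("split.json"), simplifyVector = TRUE)
      sel <- jsonlite::read_json(art("selection.json"), simplifyVector = TRUE)
      fit <- readRDS(art("model.rds"))
      x <- landmark_matrix(ds)[, sel$retained, drop = FALSE]
      pred <- predict(fit, x[sp$test, , drop = FALSE])
      rep <- evaluate_predictions(ds$kss[sp$test], pred)
      jsonlite::write_json(
        list(accuracy = rep$accuracy, deviation = rep$deviation,
             n = rep$n, confusion = unclass(rep$confusion),
             per_class = rep$per_class, flagged = rep$flagged),
        art("report.json"), digits = NA, auto_unbox = TRUE,
        dataframe = "columns")
      utils::write.csv(rep$confusion, art("confusion.csv"))
    }, error = function(e) pipeline_stop("evaluate", e))
  }

  if (stage_on("compare")) {
    tryCatch({
      ds <- read_mfd_csv(art("dataset.csv"))
      sel <- if (file.exists(art("selection.json"))) {
        jsonlite::read_json(art("selection.json"), simplifyVector = TRUE)
      } else NULL
      cmp <- do.call(run_comparison, c(
        list(ds = ds, features = sel$retained,
             seed = derive_seed(config$seed, 5)),
        config$comparison))
      write_comparison_json(cmp, art("comparison.json"))
    }, error = function(e) pipeline_stop("compare", e))
  }

  invisible(config$out_dir)
}

parse_cli_args <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      abort_mfd(sprintf("unexpected argument '%s'", a), "mfd_cli_error")
    }
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      out[[key]] <- TRUE
      i <- i + 1
    } else {
      out[[key]] <- args[i + 1]
      i <- i + 2
    }
  }
  out
}

num_or <- function(v, default) if (is.null(v)) default else as.numeric(v)

#' Command-line entry point
#'
#' Dispatcher behind the `mfd` command script (`inst/cli/mfd.R`).
#' Subcommands: `simulate`, `extract`, `preprocess`, `select`, `train`,
#' `evaluate`, `compare`, `run`; each takes `--key value` options and maps
#' onto the exported function of the same purpose. Returns an exit code (0
#' on success) rather than calling [quit()] so it can be tested in-process.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return integer exit code: 0 success, 1 usage error, 2 stage failure.
#' @export
mfd_main <- function(args) {
  usage <- function() {
    cat("usage: mfd <simulate|extract|preprocess|select|train|evaluate|compare|run> [--key value ...]\n")
    1L
  }
  if (!length(args)) return(usage())
  cmd <- args[1]
  opt <- tryCatch(parse_cli_args(args[-1]), error = function(e) e)
  if (inherits(opt, "error")) {
    message(conditionMessage(opt))
    return(usage())
  }
  code <- tryCatch({
    switch(cmd,
      simulate = {
        sc <- synthetic_config(
          n_participants = num_or(opt$participants, 10),
          frames_per_participant = num_or(opt$frames, 200),
          effect_scale = num_or(opt[["effect-scale"]], 1),
          seed = num_or(opt$seed, 1))
        sim <- generate_dataset(sc)
        write_mfd_csv(sim$dataset, opt$out %||% "synthetic.csv")
        if (!is.null(opt$truth)) {
          jsonlite::write_json(sim$truth[c("informative", "secondary",
                                           "majority_rate")],
                               opt$truth, digits = NA, auto_unbox = TRUE)
        }
        0L
      },
      extract = {
        # image -> landmark extraction requires a detector plugged in by
        # the caller; none ships with the core package
        detector <- getOption("drnrf.detector", NULL)
        if (is.null(detector)) {
          message("no landmark detector is installed; ",
                  "set options(drnrf.detector = ...) to plug one in")
          3L
        } else {
          files <- list.files(opt$images, pattern = "\\.png$",
                              full.names = TRUE)
          frames <- list()
          for (i in seq_along(files)) {
            res <- extract_landmarks(read_face_image(files[i]), detector,
                                     participant_id = opt$participant %||% "p1",
                                     frame_index = i - 1L)
            if (res$status == "ok") frames[[length(frames) + 1]] <- res$frame
          }
          coords <- do.call(rbind, lapply(frames, function(f) f$coords))
          ds <- mfd_data(coords, rep(as.integer(num_or(opt$kss, 3)),
                                     length(frames)),
                         participant_id = opt$participant %||% "p1")
          write_mfd_csv(ds, opt$out %||% "extracted.csv")
          0L
        }
      },
      preprocess = {
        ds <- read_mfd_csv(opt[["in"]])
        pre <- preprocess_mfd(ds)
        write_mfd_csv(pre$dataset, opt$out %||% "clean.csv")
        if (!is.null(opt$state)) write_minmax_json(pre$state, opt$state)
        0L
      },
      select = {
        ds <- read_mfd_csv(opt[["in"]])
        sel <- monte_carlo_rfecv(landmark_matrix(ds), ds$kss,
                                 n_reps = num_or(opt$reps, 20),
                                 threshold = num_or(opt$threshold, 0.1),
                                 seed = num_or(opt$seed, 1))
        jsonlite::write_json(list(retained = sel$retained,
                                  threshold = sel$threshold,
                                  frequency = as.list(sel$frequency)),
                             opt$out %||% "selection.json",
                             digits = NA, auto_unbox = TRUE)
        0L
      },
      train = {
        ds <- read_mfd_csv(opt[["in"]])
        keep <- if (!is.null(opt$selection)) {
          jsonlite::read_json(opt$selection, simplifyVector = TRUE)$retained
        } else feature_names_all()
        x <- landmark_matrix(ds)[, keep, drop = FALSE]
        fit <- drnrf(x, ds$kss,
                     drn = drn_config(ncol(x), classes = sort(unique(ds$kss)),
                                      epochs = num_or(opt$epochs, 100)),
                     seed = num_or(opt$seed, 1))
        saveRDS(fit, opt$model %||% "model.rds")
        0L
      },
      evaluate = {
        fit <- readRDS(opt$model)
        ds <- read_mfd_csv(opt$test)
        x <- landmark_matrix(ds)[, fit$feature_names, drop = FALSE]
        rep <- evaluate_predictions(ds$kss, predict(fit, x))
        jsonlite::write_json(list(accuracy = rep$accuracy,
                                  deviation = rep$deviation, n = rep$n,
                                  confusion = unclass(rep$confusion)),
                             opt$report %||% "report.json",
                             digits = NA, auto_unbox = TRUE)
        0L
      },
      compare = {
        ds <- read_mfd_csv(opt[["in"]])
        cmp <- run_comparison(ds, n_trials = num_or(opt$trials, 10),
                              seed = num_or(opt$seed, 1))
        write_comparison_json(cmp, opt$out %||% "comparison.json")
        0L
      },
      run = {
        cfg <- if (!is.null(opt$config)) {
          raw <- yaml::read_yaml(opt$config)
          do.call(run_config, raw)
        } else {
          run_config(out_dir = opt$out %||% "mfd_run",
                     seed = num_or(opt$seed, 1))
        }
        if (!is.null(opt$out)) cfg$out_dir <- opt$out
        if (!is.null(opt$seed)) cfg$seed <- as.integer(num_or(opt$seed, 1))
        run_pipeline(cfg)
        0L
      },
      usage())
  }, error = function(e) {
    message(conditionMessage(e))
    2L
  })
  code
}
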