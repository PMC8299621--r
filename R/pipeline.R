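# Pipeline orchestration: simulate|score -> featurize -> prune -> fit ->
# evaluate -> report, with a JSON run manifest per output directory.

default_pipeline_config <- function() {
  list(
    seed = 1,
    simulate = NULL,   # sim_config overrides, or NULL when inputs given
    inputs = NULL,     # list(fasta, regions, degradome, cap, rpf, exclusion)
    score = list(min_cap_reads = 50, min_cleaved_frac = 0.2,
                 percentile_band = c(5, 95), test_fraction = 0.1),
    features = list(),   # feature_config overrides
    prune = list(target_r = 0.1, pair_r = 0.6),
    fit = list(penalty = "l1", lambda = "auto", folds = 10,
               tolerance = 0.05, transform = "log10", features = "all")
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]])) {
      merge_config(base[[k]], override[[k]])
    } else override[[k]]
  }
  base
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  merge_config(default_pipeline_config(), config)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

# Recursively reduce a config to JSON-serializable primitives.
strip_for_json <- function(x) {
  if (is.function(x)) return(NULL)
  if (is.list(x)) {
    x <- lapply(x, strip_for_json)
    x <- x[!vapply(x, is.null, TRUE)]
    return(unclass(x))
  }
  if (is.data.frame(x)) return(as.list(unclass(x)))
  x
}

write_manifest <- function(dir, cfg, stages_run) {
  inputs <- unlist(cfg$inputs)
  hashes <- if (length(inputs)) {
    h <- tools::md5sum(inputs[file.exists(inputs)])
    as.list(h)
  } else NULL
  manifest <- list(
    package = "cleavefeat",
    version = as.character(utils::packageVersion("cleavefeat")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = cfg$seed,
    stages = stages_run,
    input_hashes = hashes,
    config = strip_for_json(cfg))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load inputs) -> score -> featurize -> prune ->
#' fit -> evaluate -> report, writing each stage's artifacts plus a run
#' manifest to `out_dir`. A stage failure halts the run with the failing
#' stage named; artifacts of completed stages are retained. With
#' `resume = TRUE`, stages whose outputs already exist are skipped, so a
#' run is resumable from prior outputs. Given the same config and seed,
#' all reports (everything except the time-stamped manifest) are
#' byte-identical across runs.
#'
#' @param config Pipeline configuration: a nested list or a path to a JSON
#'   file with entries `seed`, `simulate` (sim_config overrides) or
#'   `inputs` (paths fasta/regions/degradome/cap/rpf/exclusion), `score`,
#'   `features`, `prune` and `fit`.
#' @param out_dir Output directory.
#' @param resume Skip stages whose outputs exist (default FALSE).
#' @return Invisibly, a list with the in-memory artifacts (`cs`, `matrix`,
#'   `pruned`, `model`, `eval`, `report`, and `truth` for simulated runs).
#' @export
run_pipeline <- function(config = list(), out_dir, resume = FALSE) {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages_run <- character()
  mark <- function(s) stages_run <<- c(stages_run, s)

  # ---- simulate or load inputs
  truth <- NULL
  if (!is.null(cfg$simulate) || is.null(cfg$inputs)) {
    sim_over <- cfg$simulate %||% list()
    sim_over$seed <- sim_over$seed %||% cfg$seed
    sc <- do.call(sim_config, sim_over)
    sim_dir <- file.path(out_dir, "sim")
    stage("simulate", {
      if (!(resume && file.exists(file.path(sim_dir, "transcripts.fa")))) {
        tx <- simulate_transcripts(sc)
        deg <- simulate_degradome(tx, sc)
        rib <- simulate_ribosome(tx, sc, deg$truth)
        write_simulation(tx, deg, rib, sim_dir)
        truth <- deg$truth
        mark("simulate")
      }
    })
    cfg$inputs <- list(fasta = file.path(sim_dir, "transcripts.fa"),
                       regions = file.path(sim_dir, "regions.tsv"),
                       degradome = file.path(sim_dir, "degradome.tsv"),
                       cap = file.path(sim_dir, "cap.tsv"),
                       rpf = file.path(sim_dir, "rpf.tsv"))
    feats <- cfg$features
    if (!length(feats)) {
      cfg$features <- sc$feature_config
    }
  }

  # ---- score
  transcripts <- stage("score", {
    for (f in c("fasta", "regions", "degradome", "cap")) {
      if (is.null(cfg$inputs[[f]]) || !file.exists(cfg$inputs[[f]])) {
        stop("missing input: ", f)
      }
    }
    read_transcripts(cfg$inputs$fasta, cfg$inputs$regions)
  })
  artifacts <- list(truth = truth)
  sites_path <- file.path(out_dir, "sites.tsv")
  cs <- stage("score", {
    cap <- read_count_track(cfg$inputs$cap, "cap", transcripts)
    degr <- read_count_track(cfg$inputs$degradome, "degradome",
                             transcripts)
    ab <- compute_abundance(cap, cfg$score$min_cap_reads)
    cs <- compute_cs_table(degr, ab)
    excl <- if (!is.null(cfg$inputs$exclusion)) {
      read.delim(cfg$inputs$exclusion, stringsAsFactors = FALSE)
    }
    cs <- filter_reliable_sites(cs, transcripts, excl,
                                cfg$score$min_cleaved_frac,
                                unlist(cfg$score$percentile_band))
    cs <- split_sites(cs, cfg$score$test_fraction, cfg$seed)
    write.table(cs$sites, sites_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    mark("score")
    cs
  })
  artifacts$cs <- cs

  occupancy <- stage("score", {
    if (!is.null(cfg$inputs$rpf) && file.exists(cfg$inputs$rpf)) {
      cap <- read_count_track(cfg$inputs$cap, "cap", transcripts)
      rpf <- read_count_track(cfg$inputs$rpf, "rpf", transcripts)
      compute_ro_table(rpf, compute_abundance(cap,
                                              cfg$score$min_cap_reads),
                       transcripts)
    }
  })

  # ---- featurize
  fmat_path <- file.path(out_dir, "features.tsv")
  fm <- stage("featurize", {
    fc <- if (inherits(cfg$features, "cf_feature_config")) cfg$features
      else do.call(feature_config, cfg$features)
    fm <- build_feature_matrix(cs, transcripts, occupancy, fc)
    write_feature_matrix(fm, fmat_path)
    mark("featurize")
    fm
  })
  artifacts$matrix <- fm

  # ---- prune
  pruned <- stage("prune", {
    pr <- prune_features(fm, cfg$prune$target_r, cfg$prune$pair_r)
    write_feature_matrix(pr$matrix, file.path(out_dir, "pruned.tsv"))
    write_prune_report(pr$report, file.path(out_dir, "prune_report.tsv"))
    mark("prune")
    pr
  })
  artifacts$pruned <- pruned

  # ---- fit + evaluate + report
  model <- stage("fit", {
    mc <- model_config(penalty = cfg$fit$penalty,
                       cv_folds = cfg$fit$folds, seed = cfg$seed,
                       features = cfg$fit$features,
                       transform = cfg$fit$transform)
    lam <- cfg$fit$lambda
    if (identical(lam, "auto")) {
      cv <- cv_lambda(pruned$matrix, mc)
      write.table(cv, file.path(out_dir, "cv_table.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      lam <- select_lambda(cv, cfg$fit$tolerance)
    }
    m <- fit_penalized(pruned$matrix, mc, lam)
    mark("fit")
    m
  })
  artifacts$model <- model

  ev <- stage("evaluate", {
    rows <- if (any(pruned$matrix$sites$split == "test")) "test" else "all"
    e <- predict_and_evaluate(model, pruned$matrix, rows)
    write_model_report(model, unclass(e),
                       file.path(out_dir, "model.json"))
    mark("evaluate")
    e
  })
  artifacts$eval <- ev

  artifacts$report <- stage("report", {
    rep <- coefficient_report(model, pruned$matrix$specs)
    write_coefficient_report(rep, file.path(out_dir, "coefficients.tsv"))
    mark("report")
    rep
  })

  write_manifest(out_dir, cfg, stages_run)
  invisible(artifacts)
}

#' Apply a saved model to new transcripts (exogenous-gene prediction)
#'
#' Rebuilds the model's features for sites on new transcripts (e.g. a
#' transgene) and predicts their cleavage efficiency — the workflow used
#' to validate a sequence-only model on an exogenous gene.
#'
#' @param model_path Path to a JSON model report.
#' @param transcripts Named list of `cf_transcript`.
#' @param sites data.frame with columns gene, position (optional y for
#'   evaluation).
#' @param config The `cf_feature_config` the model was trained with.
#' @param occupancy Optional `cf_ro_table`.
#' @return data.frame of gene, position, predicted value (transform
#'   scale), plus an `eval` attribute when `y` was supplied.
#' @export
predict_new_sites <- function(model_path, transcripts, sites,
                              config = feature_config(),
                              occupancy = NULL) {
  loaded <- read_model_report(model_path)
  model <- loaded$model
  fm <- build_feature_matrix(sites, transcripts, occupancy, config)
  keep <- match(names(model$beta), fm$specs$name)
  if (anyNA(keep)) {
    stop("predict_new_sites: feature space does not cover the model")
  }
  fm2 <- subset_features(fm, keep)
  yhat <- predict(model, fm2, rows = "all")
  out <- data.frame(gene = fm2$sites$gene, position = fm2$sites$position,
                    predicted = yhat, stringsAsFactors = FALSE)
  if (!all(is.na(fm2$sites$y))) {
    y <- transform_y(fm2$sites$y, model$transform)
    r <- if (sd(yhat) == 0 || sd(y) == 0) 0 else cor(yhat, y)
    attr(out, "eval") <- list(mse = mean((yhat - y)^2), r = r,
                              n = length(y))
  }
  out
}
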