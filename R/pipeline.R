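#' Pipeline configuration
#'
#' One configuration object for the whole simulate -> preprocess -> bands ->
#' reduce -> train -> evaluate run. May be built in code or read from a YAML
#' file with the same block structure (`simulate:`, `preprocess:`, `bands:`,
#' `reduce:`, `model:`); the global seed propagates to any stage lacking its
#' own.
#'
#' @param simulate list of [synthetic_config()] arguments (or `NULL` to skip
#'   simulation and read `input`/`metadata` files instead).
#' @param input,metadata paths to a wide spectra CSV and metadata CSV, used
#'   when `simulate` is `NULL`.
#' @param preprocess list of [preprocess_config()] arguments.
#' @param bands `NULL` for [default_bands()] or a path to a CSV of
#'   `name, lo, hi, assignment`.
#' @param reduce list: `method` ("lda"), `pca_variance_target`,
#'   `loading_fraction`.
#' @param model list: `train_fraction`, `stratified`, `folds`, `repeats`,
#'   `reduced_grids`, `meta_mode`.
#' @param seed global integer seed.
#' @param out_dir run directory to create.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = list(), input = NULL, metadata = NULL,
                            preprocess = list(), bands = NULL,
                            reduce = list(), model = list(),
                            seed = 1L, out_dir = "ramanstage_run") {
  structure(list(simulate = simulate, input = input, metadata = metadata,
                 preprocess = preprocess, bands = bands, reduce = reduce,
                 model = model, seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with blocks `simulate`, `preprocess`, `bands`,
#'   `reduce`, `model` and top-level `seed` / `out_dir`.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y[intersect(names(y),
    names(formals(pipeline_config)))])
}

log_line <- function(con, stage, ...) {
  rec <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
           list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
}

#' Run the full staged pipeline
#'
#' Executes simulate (or read) -> preprocess -> bands -> reduce -> train ->
#' evaluate, writing every intermediate artifact into the run directory:
#' `spectra.csv`, `meta.csv`, `clean.csv`, `qc.csv`, `bands.csv`,
#' `stats.csv`, `scores.csv`, `loadings.csv`, `model/` (serialized bundle +
#' manifest) and `report.json`, plus a structured JSON-lines log and a run
#' manifest. Rerunning with the same configuration reproduces every
#' artifact; `report.json` is byte-identical across runs.
#'
#' @param config a [pipeline_config()].
#' @return the run directory path, invisibly; artifacts as side effects.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$simulate) && (is.null(config$input) || !file.exists(config$input)))
    stop("no simulate block and no readable input file; nothing to run")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(config$out_dir, "log.jsonl"), open = "wt")
  on.exit(close(logf))

  # -- simulate / read ------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    scfg <- do.call(synthetic_config, sim_args)
    gen <- generate_dataset(scfg)
    set <- gen$spectra
    write_spectra_wide(set, file.path(config$out_dir, "spectra.csv"),
                       file.path(config$out_dir, "meta.csv"))
    log_line(logf, "simulate", seed = scfg$seed, n = n_spectra(set))
  } else {
    set <- read_spectra_wide(config$input, config$metadata)
    log_line(logf, "read", n = n_spectra(set))
  }

  # -- preprocess -----------------------------------------------------------
  pcfg <- do.call(preprocess_config, config$preprocess)
  clean <- preprocess(set, pcfg)
  write_spectra_wide(clean, file.path(config$out_dir, "clean.csv"))
  qc <- data.frame(spectrum_id = clean$meta$spectrum_id,
                   n_spikes = clean$meta$n_spikes,
                   integral_pre = apply(set$intensity, 1L, function(y)
                     pracma::trapz(set$wavenumber, y)),
                   integral_post = apply(clean$intensity, 1L, function(y)
                     pracma::trapz(clean$wavenumber, y)))
  utils::write.csv(qc[order(qc$spectrum_id), ], file.path(config$out_dir, "qc.csv"),
                   row.names = FALSE)
  log_line(logf, "preprocess", spikes_removed = sum(clean$meta$n_spikes))

  # -- bands ----------------------------------------------------------------
  bands <- if (is.null(config$bands)) default_bands() else {
    b <- utils::read.csv(config$bands, stringsAsFactors = FALSE)
    stopifnot(all(c("name", "lo", "hi") %in% names(b)))
    b
  }
  bt <- band_table(clean, bands)
  utils::write.csv(bt$areas, file.path(config$out_dir, "bands.csv"), row.names = FALSE)
  utils::write.csv(compare_all_groups(bt), file.path(config$out_dir, "stats.csv"),
                   row.names = FALSE)
  log_line(logf, "bands", n_bands = nrow(bands))

  # -- reduce ---------------------------------------------------------------
  rc <- config$reduce
  vt <- if (is.null(rc$pca_variance_target)) 0.99 else rc$pca_variance_target
  lfrac <- if (is.null(rc$loading_fraction)) 0.10 else rc$loading_fraction
  ldam <- fit_lda(clean, pca_variance_target = vt)
  sc <- project(ldam, clean)
  scores <- data.frame(spectrum_id = rep(clean$meta$spectrum_id, ncol(sc)),
                       axis = rep(colnames(sc), each = nrow(sc)),
                       score = as.vector(sc))
  utils::write.csv(scores, file.path(config$out_dir, "scores.csv"), row.names = FALSE)
  loads <- do.call(rbind, lapply(seq_len(nrow(ldam$directions)), function(a)
    data.frame(axis = paste0("LD", a), wavenumber = clean$wavenumber,
               loading = ldam$directions[a, ],
               top_fraction = clean$wavenumber %in%
                 top_loading_wavenumbers(ldam, clean$wavenumber, a, lfrac))))
  utils::write.csv(loads, file.path(config$out_dir, "loadings.csv"), row.names = FALSE)
  log_line(logf, "reduce", axes = nrow(ldam$directions), pca_k = ldam$pca$k)

  # -- train / evaluate -----------------------------------------------------
  mc <- config$model
  split <- split_train_test(clean,
    train_fraction = if (is.null(mc$train_fraction)) 0.75 else mc$train_fraction,
    stratified = if (is.null(mc$stratified)) TRUE else mc$stratified,
    seed = if (is.null(mc$seed)) config$seed else mc$seed)
  cv <- cv_spec(folds = if (is.null(mc$folds)) 10L else mc$folds,
                repeats = if (is.null(mc$repeats)) 5L else mc$repeats,
                seed = if (is.null(mc$seed)) config$seed else mc$seed)
  specs <- base_learner_specs(reduced = isTRUE(mc$reduced_grids))
  bundle <- fit_stacked(split$train, cv = cv, specs = specs,
                        meta_mode = if (is.null(mc$meta_mode)) "prob" else mc$meta_mode)
  mdir <- file.path(config$out_dir, "model")
  dir.create(mdir, showWarnings = FALSE)
  saveRDS(bundle, file.path(mdir, "bundle.rds"))
  jsonlite::write_json(list(class_order = bundle$class_order,
                            cv = unclass(cv), seed = config$seed,
                            meta_mode = bundle$meta_mode,
                            tuned = lapply(bundle$learners, function(l) as.list(l$best)),
                            gbm = as.list(bundle$meta$best),
                            meta_layout = bundle$meta_layout),
                       file.path(mdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report <- evaluate(bundle, split$test)
  write_report(report, file.path(config$out_dir, "report.json"), "json")
  log_line(logf, "evaluate", n_test = report$n_test,
           overall_accuracy = report$overall_accuracy)

  # -- manifest -------------------------------------------------------------
  cfg_plain <- unclass(config)
  jsonlite::write_json(list(
    config = cfg_plain,
    config_hash = digest_config(cfg_plain),
    version = as.character(utils::packageVersion("ramanstage")),
    seed = config$seed),
    file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, force = TRUE)
  invisible(config$out_dir)
}

# small stable hash of the configuration (polynomial rolling hash of its
# serialized form; an identifier, not a cryptographic digest)
digest_config <- function(x) {
  s <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in s) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
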