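#' Default pipeline configuration
#'
#' Collects every tunable of the simulate -> (preprocess) -> dfnc ->
#' decompose -> entropy -> stats chain with the reference defaults:
#' 40-TR rectangle tapered by a Gaussian of sd 3 TRs, window step 1,
#' model order 8 with 150 consolidated ICA runs, k = 3 entropy neighbor,
#' 10000 permutations. The synthetic stage defaults are the package's
#' reference study conditions (see [simulate_cohort()]).
#'
#' @param output_dir Run directory for stage outputs and the manifest.
#' @param master_seed Master seed; stage seeds derive from it by fixed
#'   offsets (simulate +0, ICA runs +1000+i, entropy jitter +2000,
#'   permutations +3000).
#' @param ... Overrides for any default, as `name = value`; nested lists
#'   (`window`, `decomposition`, `entropy`, `stats`, `simulate`,
#'   `preprocess`) are replaced per-field.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir = tempfile("dfnc_run_"),
                            master_seed = 1L, ...) {
  cfg <- list(
    output_dir = output_dir,
    master_seed = as.integer(master_seed),
    simulate = list(n_subjects = 60, n_networks = 20, m = 4,
                    scan_len = 160, n_sites = 7, scale_ratio = 0.5,
                    control_scale = 0.2, level = "bold"),
    preprocess = list(enabled = FALSE, max_order = 3, z_thresh = 3.5,
                      low_hz = 0.01, high_hz = 0.15, order = 5),
    window = list(rect_len = 40, gauss_sd = 3, step = 1,
                  fisher_z = FALSE),
    decomposition = list(m = 4, R = 150, max_iter = 512, tol = 1e-6,
                         batch_size = 256),
    entropy = list(k = 3, jitter_sd = NULL),
    stats = list(B = 10000, alpha = 0.05, jb_alpha = 0.05)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  stopifnot(cfg$window$rect_len >= 2, cfg$window$gauss_sd >= 0,
            cfg$window$step >= 1, cfg$decomposition$m >= 2,
            cfg$decomposition$R >= 2, cfg$entropy$k >= 1,
            cfg$stats$B >= 100)
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg[setdiff(names(cfg), "output_dir")]), f)
  unname(tools::md5sum(f))
}

#' Analyze a cohort in memory
#'
#' The full analysis chain on an in-memory cohort: (optional)
#' preprocessing, tapered sliding-window FNC per subject (skipped for
#' dFNC-level cohorts, whose subjects already are trajectory records),
#' subject concatenation, PCA + repeated InfoMax ICA with ICASSO
#' consolidation, per-subject source isolation, Kozachenko-Leonenko
#' entropy, and the group-comparison report.
#'
#' @param cohort A [simulate_cohort()] result, or a list with `subjects`
#'   (list of [subject_timecourses()] or `dfnc_series`) and `covariates`.
#' @param config A [pipeline_config()].
#' @return List with `series`, `concat`, `decomposition`,
#'   `subject_sources`, `entropy` (the entropy table), `report`, and
#'   `config`.
#' @export
analyze_cohort <- function(cohort, config = pipeline_config()) {
  seed <- config$master_seed
  subjects <- cohort$subjects
  if (inherits(subjects[[1]], "subject_timecourses")) {
    if (isTRUE(config$preprocess$enabled)) {
      pp <- config$preprocess
      subjects <- lapply(subjects, preprocess_timecourses,
                         max_order = pp$max_order, z_thresh = pp$z_thresh,
                         low_hz = pp$low_hz, high_hz = pp$high_hz,
                         order = pp$order)
    }
    taper <- build_taper(config$window$rect_len, config$window$gauss_sd)
    series <- lapply(subjects, sliding_fnc, taper = taper,
                     step = config$window$step,
                     fisher_z = config$window$fisher_z)
  } else {
    series <- subjects
  }
  concat <- concatenate_subjects(series)
  dec <- ica_decompose(concat$X, m = config$decomposition$m,
                       R = config$decomposition$R, seed = seed + 1000L,
                       max_iter = config$decomposition$max_iter,
                       tol = config$decomposition$tol,
                       batch_size = config$decomposition$batch_size)
  subs <- split_subject_sources(dec$sources, concat$index_map)
  tab <- entropy_table(subs, cohort$covariates, k = config$entropy$k,
                       jitter_sd = config$entropy$jitter_sd,
                       seed = seed + 2000L)
  rep_ <- build_report(tab, cohort$covariates, B = config$stats$B,
                       alpha = config$stats$alpha,
                       jb_alpha = config$stats$jb_alpha,
                       seed = seed + 3000L)
  list(series = series, concat = concat, decomposition = dec,
       subject_sources = subs, entropy = tab, report = rep_,
       config = config)
}

stage_order <- c("simulate", "preprocess", "dfnc", "decompose",
                 "entropy", "stats")

stage_dir <- function(cfg, name) file.path(cfg$output_dir, name)

manifest_path <- function(cfg) file.path(cfg$output_dir, "manifest.json")

read_manifest <- function(cfg) {
  p <- manifest_path(cfg)
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE)
  else list(config_hash = config_hash(cfg), stages = list())
}

record_stage <- function(cfg, name, files, elapsed) {
  man <- read_manifest(cfg)
  man$config_hash <- config_hash(cfg)
  man$master_seed <- cfg$master_seed
  man$stages[[name]] <- list(
    files = as.list(tools::md5sum(files)),
    elapsed_s = round(elapsed, 3),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(man, manifest_path(cfg), auto_unbox = TRUE,
                       digits = NA)
  man$stages[[name]]
}

require_stage <- function(cfg, name) {
  d <- stage_dir(cfg, name)
  if (!dir.exists(d) || length(list.files(d)) == 0)
    stop("missing upstream outputs: run stage '", name, "' first")
  man <- read_manifest(cfg)
  recorded <- man$stages[[name]]$files
  if (!is.null(recorded)) {
    cur <- tools::md5sum(names(recorded))
    bad <- names(recorded)[is.na(cur) | cur != unlist(recorded)]
    if (length(bad))
      stop("checksum mismatch for upstream file(s): ",
           paste(basename(bad), collapse = ", "))
  }
  d
}

#' Run one pipeline stage against the run directory
#'
#' Each stage reads the previous stage's on-disk outputs and writes its
#' own under `<output_dir>/<stage>/`, appending a manifest entry with
#' file checksums, wall time and the configuration hash. Re-running a
#' stage with identical config and inputs reproduces identical outputs.
#'
#' @param name One of `"simulate"`, `"preprocess"`, `"dfnc"`,
#'   `"decompose"`, `"entropy"`, `"stats"`.
#' @param cfg A [pipeline_config()].
#' @return The manifest entry for the stage, invisibly.
#' @export
run_stage <- function(name, cfg) {
  name <- match.arg(name, stage_order)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  out <- stage_dir(cfg, name)
  dir.create(out, showWarnings = FALSE)
  seed <- cfg$master_seed

  if (name == "simulate") {
    sim <- cfg$simulate
    cohort <- simulate_cohort(
      n_subjects = sim$n_subjects, n_networks = sim$n_networks,
      m = sim$m, scan_len = sim$scan_len, level = "bold",
      n_sites = sim$n_sites, scale_ratio = sim$scale_ratio,
      control_scale = sim$control_scale, rect_len = cfg$window$rect_len,
      gauss_sd = cfg$window$gauss_sd, seed = seed)
    write_cohort(cohort, out)
  } else if (name == "preprocess") {
    src <- require_stage(cfg, "simulate")
    pp <- cfg$preprocess
    for (f in list.files(src, pattern = "\\.tsv$", full.names = TRUE)) {
      tc <- read_timecourses(f)
      if (isTRUE(pp$enabled))
        tc <- preprocess_timecourses(tc, max_order = pp$max_order,
                                     z_thresh = pp$z_thresh,
                                     low_hz = pp$low_hz,
                                     high_hz = pp$high_hz,
                                     order = pp$order)
      utils::write.table(tc$data, file.path(out, basename(f)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  } else if (name == "dfnc") {
    src <- if (dir.exists(stage_dir(cfg, "preprocess")) &&
               length(list.files(stage_dir(cfg, "preprocess"))))
      stage_dir(cfg, "preprocess") else require_stage(cfg, "simulate")
    taper <- build_taper(cfg$window$rect_len, cfg$window$gauss_sd)
    meta <- NULL
    for (f in list.files(src, pattern = "\\.tsv$", full.names = TRUE)) {
      s <- sliding_fnc(read_timecourses(f), taper,
                       step = cfg$window$step,
                       fisher_z = cfg$window$fisher_z)
      utils::write.table(s$data, file.path(out, basename(f)), sep = "\t",
                         row.names = FALSE, col.names = FALSE,
                         quote = FALSE)
      meta <- list(window_centers = s$window_centers,
                   n_networks = s$n_networks,
                   rect_len = cfg$window$rect_len,
                   gauss_sd = cfg$window$gauss_sd,
                   step = cfg$window$step,
                   ordering = "row-major upper triangle")
    }
    jsonlite::write_json(meta, file.path(out, "window.json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (name == "decompose") {
    src <- require_stage(cfg, "dfnc")
    meta <- jsonlite::read_json(file.path(src, "window.json"),
                                simplifyVector = TRUE)
    files <- list.files(src, pattern = "\\.tsv$", full.names = TRUE)
    series <- lapply(files, function(f) {
      structure(list(subject_id = sub("\\.tsv$", "", basename(f)),
                     data = as.matrix(utils::read.delim(f, header = FALSE)),
                     window_centers = meta$window_centers,
                     n_networks = meta$n_networks),
                class = "dfnc_series")
    })
    concat <- concatenate_subjects(series)
    dec <- ica_decompose(concat$X, m = cfg$decomposition$m,
                         R = cfg$decomposition$R, seed = seed + 1000L,
                         max_iter = cfg$decomposition$max_iter,
                         tol = cfg$decomposition$tol,
                         batch_size = cfg$decomposition$batch_size)
    utils::write.table(dec$patterns, file.path(out, "patterns.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    subs <- split_subject_sources(dec$sources, concat$index_map)
    for (id in names(subs))
      utils::write.table(subs[[id]], file.path(out, paste0(id, "_sources.tsv")),
                         sep = "\t", row.names = FALSE, col.names = FALSE,
                         quote = FALSE)
    jsonlite::write_json(
      list(stability = dec$stability, m = dec$m, R = dec$R,
           seed = dec$seed, source_order = dec$source_order,
           n_networks = meta$n_networks),
      file.path(out, "decomposition.json"), auto_unbox = TRUE, digits = NA)
  } else if (name == "entropy") {
    src <- require_stage(cfg, "decompose")
    files <- list.files(src, pattern = "_sources\\.tsv$", full.names = TRUE)
    subs <- lapply(files, function(f)
      as.matrix(utils::read.delim(f, header = FALSE)))
    names(subs) <- sub("_sources\\.tsv$", "", basename(files))
    cov <- read_covariates(file.path(require_stage(cfg, "simulate"),
                                     "covariates.csv"))
    tab <- entropy_table(subs, cov, k = cfg$entropy$k,
                         jitter_sd = cfg$entropy$jitter_sd,
                         seed = seed + 2000L)
    utils::write.csv(tab, file.path(out, "entropy.csv"), row.names = FALSE)
  } else if (name == "stats") {
    src <- require_stage(cfg, "entropy")
    tab <- utils::read.csv(file.path(src, "entropy.csv"),
                           stringsAsFactors = FALSE)
    cov <- read_covariates(file.path(require_stage(cfg, "simulate"),
                                     "covariates.csv"))
    rep_ <- build_report(tab, cov, B = cfg$stats$B,
                         alpha = cfg$stats$alpha,
                         jb_alpha = cfg$stats$jb_alpha,
                         seed = seed + 3000L)
    utils::write.csv(rep_, file.path(out, "report.csv"), row.names = FALSE)
  }

  files <- list.files(out, full.names = TRUE, recursive = TRUE)
  entry <- record_stage(cfg, name, files,
                        proc.time()[["elapsed"]] - t0)
  invisible(entry)
}

#' Run the full pipeline
#'
#' Executes simulate, (preprocess when enabled), dfnc, decompose, entropy
#' and stats in order against the run directory and returns the manifest.
#'
#' @param cfg A [pipeline_config()].
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stages <- stage_order
  if (!isTRUE(cfg$preprocess$enabled))
    stages <- setdiff(stages, "preprocess")
  for (s in stages) run_stage(s, cfg)
  invisible(read_manifest(cfg))
}

#' Validate an input directory
#'
#' Checks the TSV time-course files (rectangular, numeric, no missing
#' values) and the covariate table (schema, subject coverage, duplicate
#' ids) and returns a machine-readable issue list; it reports rather than
#' throws.
#'
#' @param dir Directory holding `*.tsv` time courses and
#'   `covariates.csv`.
#' @return Data frame with columns `file`, `issue`; zero rows when the
#'   directory is well-formed.
#' @export
validate_inputs <- function(dir) {
  issues <- list()
  add <- function(file, issue)
    issues[[length(issues) + 1]] <<- data.frame(
      file = file, issue = issue, stringsAsFactors = FALSE)
  tsvs <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  if (!length(tsvs)) add(dir, "no time-course TSV files found")
  ids <- character()
  for (f in tsvs) {
    lines <- readLines(f, warn = FALSE)
    nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
    if (length(unique(nfield)) > 1) {
      add(basename(f), sprintf("ragged rows (first at row %d)",
                               which(nfield != nfield[1])[1]))
      next
    }
    dat <- utils::read.delim(f)
    if (anyNA(dat)) add(basename(f), "missing values")
    if (!all(vapply(dat, is.numeric, TRUE)))
      add(basename(f), "non-numeric columns")
    ids <- c(ids, sub("\\.tsv$", "", basename(f)))
  }
  covf <- file.path(dir, "covariates.csv")
  if (!file.exists(covf)) {
    add("covariates.csv", "file missing")
  } else {
    cov <- utils::read.csv(covf, stringsAsFactors = FALSE)
    need <- c("subject_id", "diagnosis", "site", "age", "gender")
    miss <- setdiff(need, names(cov))
    if (length(miss))
      add("covariates.csv", paste("missing columns:",
                                  paste(miss, collapse = ", ")))
    if ("subject_id" %in% names(cov)) {
      dup <- cov$subject_id[duplicated(cov$subject_id)]
      if (length(dup))
        add("covariates.csv", paste("duplicated subject ids:",
                                    paste(unique(dup), collapse = ", ")))
      orphans <- setdiff(ids, cov$subject_id)
      for (o in orphans)
        add("covariates.csv", paste("subject missing from covariates:", o))
    }
    if ("diagnosis" %in% names(cov) && !all(cov$diagnosis %in% 0:1))
      add("covariates.csv", "diagnosis values outside {0, 1}")
  }
  if (!length(issues))
    return(data.frame(file = character(), issue = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, issues)
}
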