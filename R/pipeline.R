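#' Pipeline configuration
#'
#' Bundles every setting of the full analysis: input paths (or in-memory
#' objects), the protein exclusions, reporter thresholds, reporter
#' weighting, the models to fit, the `Q` scan range, restarts and seed.
#'
#' @param data A `y2h_data` object, or `NULL` if `y2h_path` is given.
#' @param y2h_path Path to a Y2H record table (see [parse_y2h_table()]).
#' @param covariate_paths Named character vector of PHYLIP square
#'   distance-matrix paths (e.g. `c("DIII/IV" = ..., DIII = ..., DIV = ...)`),
#'   or `NULL`.
#' @param covariates A ready `covariate_set` (alternative to paths).
#' @param exclusions Protein ids dropped before modelling.
#' @param xgal_threshold,his3_threshold Reporter thresholds for the binary
#'   network.
#' @param weights Reporter weighting for the valued network (preset name
#'   or length-2 vector).
#' @param models Named list of model specs, each
#'   `list(family = , covariates = <names or NULL>)`.  `NULL` selects a
#'   default set: a Bernoulli model on the binary network, a Gaussian
#'   model on the valued network, and one regression model per covariate
#'   grouping supplied.
#' @param Q_range Cluster counts to scan.
#' @param n_restarts EM restarts per fit.
#' @param seed Integer seed.
#' @param out_dir Output directory for the report bundle.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(data = NULL, y2h_path = NULL,
                            covariate_paths = NULL, covariates = NULL,
                            exclusions = c("ARF3", "ARF17", "ARF11"),
                            xgal_threshold = "+", his3_threshold = 0.45,
                            weights = "A", models = NULL, Q_range = 1:7,
                            n_restarts = 5, seed = 1, out_dir = ".") {
  if (is.null(data) && is.null(y2h_path)) {
    abort("either data or y2h_path is required")
  }
  if (!is.null(y2h_path) && !file.exists(y2h_path)) {
    abort(paste0("y2h_path does not exist: ", y2h_path))
  }
  for (p in covariate_paths) {
    if (!file.exists(p)) abort(paste0("covariate path does not exist: ", p))
  }
  if (!length(Q_range)) abort("Q_range must be non-empty")
  structure(list(data = data, y2h_path = y2h_path,
                 covariate_paths = covariate_paths, covariates = covariates,
                 exclusions = exclusions, xgal_threshold = xgal_threshold,
                 his3_threshold = his3_threshold, weights = weights,
                 models = models, Q_range = Q_range,
                 n_restarts = n_restarts, seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

default_models <- function(cov_names) {
  models <- list(BM = list(family = "bernoulli", covariates = NULL),
                 GM = list(family = "gaussian", covariates = NULL))
  if (length(cov_names) >= 1) {
    models[["LRM-1"]] <- list(family = "gaussian_regression",
                              covariates = cov_names[1])
  }
  if (length(cov_names) >= 2) {
    models[["LRM-2"]] <- list(family = "gaussian_regression",
                              covariates = cov_names[2:min(3, length(cov_names))])
  }
  models
}

#' Run the full analysis pipeline
#'
#' parse -> filter -> binarize -> standardize -> model scans -> cluster
#' diagnostics -> reports.  Writes, under `config$out_dir`:
#' `binary_network.tsv` and `binary_edges.tsv`, `valued_network.tsv` with
#' `valued_weights.json`, one `scan-<model>.tsv` per model, a
#' `best_fits.json` with the selected parameters and cluster-distance
#' matrices, one `clusters-<model>.tsv` membership table (sorted by
#' D(i,q), most central first), `partition_match.tsv`, and
#' `manifest.json` echoing the resolved configuration and seed.
#' Re-running with the same config and seed reproduces all outputs
#' bit-identically.  Any stage failure aborts with the stage name and
#' removes the partial outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the networks, scans, best fits,
#'   diagnostics and the written file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  emit <- function(path) { written <<- c(written, path); path }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  log_line <- function(...) message("[auxnet] ", sprintf(...))

  dat <- stage("parse", {
    d <- if (!is.null(config$data)) config$data else
      parse_y2h_table(config$y2h_path)
    log_line("parse: %d proteins, %d records", nrow(d$roster),
             nrow(d$records))
    d
  })
  dat <- stage("filter", {
    d <- filter_regulators(dat, config$exclusions)
    log_line("filter: %d proteins retained", nrow(d$roster))
    d
  })
  binary <- stage("binarize", {
    b <- build_binary_network(dat, config$xgal_threshold,
                              config$his3_threshold)
    write_binary_network(b, emit(file.path(out_dir, "binary_network.tsv")),
                         emit(file.path(out_dir, "binary_edges.tsv")))
    log_line("binarize: %d edges", sum(b$Z[upper.tri(b$Z)]))
    b
  })
  valued <- stage("standardize", {
    v <- standardized_distance_matrix(dat, config$weights)
    write_valued_network(v, emit(file.path(out_dir, "valued_network.tsv")),
                         emit(file.path(out_dir, "valued_weights.json")))
    log_line("standardize: mean x = %.6f", mean(v$X, na.rm = TRUE))
    v
  })
  covariates <- stage("covariates", {
    cs <- config$covariates
    if (is.null(cs) && length(config$covariate_paths)) {
      mats <- lapply(config$covariate_paths, read_phylip_square)
      cs <- align_covariates(mats, dat$roster$protein)
    }
    if (!is.null(cs)) {
      cs <- align_covariates(cs$matrices, dat$roster$protein)
      log_line("covariates: %s", paste(cs$names, collapse = ", "))
    }
    cs
  })
  models <- config$models
  if (is.null(models)) {
    models <- default_models(if (is.null(covariates)) character(0)
                             else covariates$names)
  }
  results <- stage("fit", {
    purrr::imap(models, function(spec, nm) {
      net <- if (spec$family == "bernoulli") binary else valued
      covs <- if (is.null(spec$covariates)) NULL else
        align_covariates(covariates$matrices[spec$covariates],
                         dat$roster$protein)
      scan <- model_scan(net, covs, spec$family, config$Q_range,
                         config$n_restarts, config$seed)
      write_scan_table(scan, emit(file.path(out_dir,
                                            paste0("scan-", nm, ".tsv"))))
      best <- scan$fit[[which.max(scan$icl)]]
      readr::write_tsv(cluster_table(best, net),
                       emit(file.path(out_dir,
                                      paste0("clusters-", nm, ".tsv"))),
                       progress = FALSE)
      log_line("fit %s (%s): best Q = %d, ICL = %.3f", nm, spec$family,
               best$Q, best$icl)
      list(name = nm, spec = spec, net = net, scan = scan, best = best)
    })
  })
  diagnostics <- stage("diagnose", {
    purrr::map(results, function(r) {
      D <- profile_distance_matrix(r$net)
      cluster_distance_matrix(D, r$best$tau)
    })
  })
  stage("report", {
    best_fits <- purrr::imap(results, function(r, nm) {
      f <- r$best
      list(family = f$family, Q = f$Q, d = f$d, alpha = f$alpha,
           pi = f$pi, mu = f$mu,
           beta = if (is.null(f$beta)) NULL else
             purrr::map(seq_len(f$d), ~f$beta[.x, , ]),
           sigma2 = f$sigma2, J = f$J, icl = f$icl,
           cluster_distances = diagnostics[[nm]]$cluster_cluster,
           n_q = diagnostics[[nm]]$n_q)
    })
    jsonlite::write_json(best_fits, emit(file.path(out_dir, "best_fits.json")),
                         auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
    readr::write_tsv(partition_match_matrix(purrr::map(results, "best")),
                     emit(file.path(out_dir, "partition_match.tsv")),
                     progress = FALSE)
    manifest <- list(
      package = "auxnet",
      version = as.character(utils::packageVersion("auxnet")),
      seed = config$seed,
      exclusions = config$exclusions,
      thresholds = list(xgal = config$xgal_threshold,
                        his3 = config$his3_threshold),
      weights = as.list(resolve_weights(config$weights)),
      Q_range = config$Q_range,
      n_restarts = config$n_restarts,
      models = purrr::map(models, function(m)
        list(family = m$family,
             covariates = if (is.null(m$covariates)) list() else
               as.list(m$covariates))),
      n_proteins = nrow(dat$roster))
    jsonlite::write_json(manifest, emit(file.path(out_dir, "manifest.json")),
                         auto_unbox = TRUE, digits = NA)
  })
  invisible(list(data = dat, binary = binary, valued = valued,
                 covariates = covariates, results = results,
                 diagnostics = diagnostics, files = written))
}
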