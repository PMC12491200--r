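#' Run the full analysis pipeline
#'
#' Chains every stage on one configuration: replicate descriptive
#' statistics, one-sample limit tests, deterministic and Monte Carlo risk
#' tables, optional LOD screening of the measurements, and optional GC-MS
#' class summaries. All outputs are plain CSV plus a JSON run manifest
#' recording input digests, configuration, seed and package version.
#' Re-running with identical inputs and seed reproduces every CSV
#' byte-for-byte (the manifest differs only in its timestamp).
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list. Recognised keys: `concentrations`, `toxicity`, `exposure`
#'   (file paths; the first two required), optional `calibration` and
#'   `compounds` paths, optional `nd_token` (default `"ND"`), optional
#'   `risk_elements` (elements to carry into the risk chain; defaults to
#'   the elements of the toxicity table), and a `monte_carlo` block with
#'   `iterations`, `seed`, `percentiles`.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a named list of the paths written.
#' @export
run_full_analysis <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      rlang::abort(paste0("config file not found: ", config),
                   class = "herbrisk_io_error")
    }
    config <- yaml::read_yaml(config)
  }
  for (key in c("concentrations", "toxicity")) {
    if (is.null(config[[key]])) {
      rlang::abort(paste0("[config] missing required key: ", key),
                   class = "herbrisk_config_error")
    }
    if (!file.exists(config[[key]])) {
      rlang::abort(paste0("[config] ", key, " file not found: ",
                          config[[key]]),
                   class = "herbrisk_io_error")
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  log_stage <- function(stage, msg) message(sprintf("[%s] %s", stage, msg))

  nd_token <- config$nd_token %||% "ND"
  ms <- read_concentration_table(config$concentrations, nd_token = nd_token)
  log_stage("io", sprintf("read %d measurement records", nrow(ms)))
  tox <- read_toxicity_reference(config$toxicity)
  params <- if (!is.null(config$exposure)) {
    read_exposure_config(config$exposure)
  } else {
    exposure_parameters()
  }

  if (!is.null(config$calibration)) {
    calib <- read_calibration(config$calibration)
    lods <- stats::setNames(calib$lod, calib$element)
    ms <- flag_nondetects(ms, lods)
    paths$lod <- file.path(out_dir, "lod.csv")
    write_table(calib, paths$lod, "generic")
  }

  summ <- concentration_summary(ms)
  log_stage("qc_stats", sprintf("summarised %d cells", nrow(summ)))
  paths$summary <- file.path(out_dir, "summary.csv")
  write_table(summ, paths$summary, "summary")

  lt <- limit_tests(ms, tox)
  paths$limit_tests <- file.path(out_dir, "limit_tests.csv")
  write_table(lt, paths$limit_tests, "limit_tests")

  risk_elements <- config$risk_elements %||% tox$element
  ms_risk <- ms[ms$element %in% risk_elements, , drop = FALSE]
  det <- deterministic_risk_table(ms_risk, tox, params)
  log_stage("risk_deterministic",
            sprintf("%d risk records, %d hazard indices",
                    nrow(det$risk), nrow(det$hazard_index)))
  paths$risk <- file.path(out_dir, "risk.csv")
  write_table(det, paths$risk, "risk")
  paths$hazard_index <- file.path(out_dir, "hazard_index.csv")
  write_table(det$hazard_index, paths$hazard_index, "hazard_index")

  mc_block <- config$monte_carlo %||% list()
  cfg <- mc_config(
    n_iterations = mc_block$iterations %||% 10000L,
    seed = mc_block$seed %||% 1L,
    percentiles = unlist(mc_block$percentiles %||% c(0.5, 0.95))
  )
  log_stage("risk_montecarlo",
            sprintf("%d iterations, seed %d", cfg$n_iterations, cfg$seed))
  prob <- monte_carlo_risk(ms_risk, tox, params, cfg)
  paths$prob_risk <- file.path(out_dir, "prob_risk.csv")
  write_table(prob, paths$prob_risk, "prob_risk")

  if (!is.null(config$compounds)) {
    comp <- read_compound_table(config$compounds)
    paths$class_summary <- file.path(out_dir, "class_summary.csv")
    write_table(class_summary(comp), paths$class_summary, "class_summary")
  }

  manifest <- list(
    tool = "herbrisk",
    version = as.character(utils::packageVersion("herbrisk")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    n_iterations = cfg$n_iterations,
    config = config[vapply(config, function(x)
      is.atomic(x) || is.list(x), logical(1))],
    input_md5 = as.list(tools::md5sum(unlist(
      config[intersect(c("concentrations", "toxicity", "exposure",
                         "calibration", "compounds"), names(config))]
    )))
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}

#' Path to a bundled example data file
#'
#' The package ships a small reference dataset: triplicate elemental
#' concentrations of three street-vendor herbal concoctions (samples A, B
#' and C) with the matching toxicity reference, exposure configuration,
#' a synthetic calibration-blank table and GC-MS identified-compound
#' tables for the hexane and ethyl acetate extracts.
#'
#' @param file File name, e.g. `"concentrations.csv"`; `NULL` lists the
#'   available files.
#' @return The full path, or the vector of available file names.
#' @export
#' @examples
#' herbrisk_example()
herbrisk_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "herbrisk"))
  } else {
    path <- system.file("extdata", file, package = "herbrisk")
    if (!nzchar(path)) {
      rlang::abort(paste0("no bundled file named '", file, "'"),
                   class = "herbrisk_io_error")
    }
    path
  }
}
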