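#' Read a long-format replicate concentration table
#'
#' Expects a CSV with columns `sample_id`, `element`, `replicate` and
#' `concentration` (mg/kg). Cells equal to `nd_token` mark non-detects;
#' they are retained as records but carry no numeric value.
#'
#' @param path Path to the CSV file.
#' @param nd_token Token marking non-detectable concentrations. Default
#'   `"ND"`, the convention used on instrument report sheets.
#'
#' @return A [as_measurement_set()] tibble.
#' @export
read_concentration_table <- function(path, nd_token = "ND") {
  raw <- read_csv_strict(path)
  required <- c("sample_id", "element", "replicate", "concentration")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("concentration table '", path, "' is missing column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "herbrisk_schema_error"
    )
  }
  conc_chr <- trimws(as.character(raw$concentration))
  nd <- !is.na(conc_chr) & conc_chr == nd_token
  conc <- suppressWarnings(as.double(conc_chr))
  conc[nd] <- NA_real_
  unparsed <- which(!nd & is.na(conc) & !is.na(conc_chr) & conc_chr != "")
  if (length(unparsed) > 0) {
    rlang::abort(
      paste0("non-numeric concentration (and not '", nd_token,
             "') in row(s): ", paste(unparsed, collapse = ", ")),
      class = "herbrisk_validation_error"
    )
  }
  neg <- which(!nd & !is.na(conc) & conc < 0)
  if (length(neg) > 0) {
    rlang::abort(
      paste0("negative concentration in row(s): ",
             paste(neg, collapse = ", ")),
      class = "herbrisk_validation_error"
    )
  }
  as_measurement_set(tibble::tibble(
    sample_id = as.character(raw$sample_id),
    element = as.character(raw$element),
    replicate = as.integer(raw$replicate),
    concentration = conc,
    nondetect = nd
  ))
}

#' Read a per-element toxicity reference table
#'
#' Expects a CSV with columns `element`, `rfd` (oral reference dose,
#' mg/kg/day), `csf` (cancer slope factor, (mg/kg/day)^-1; blank when the
#' element has no published slope factor) and `who_limit` (WHO/FAO
#' permissible concentration, mg/kg; blank when none applies).
#'
#' @param path Path to the CSV file.
#' @return A tibble with one row per element; blank `csf`/`who_limit`
#'   become `NA`.
#' @export
read_toxicity_reference <- function(path) {
  raw <- read_csv_strict(path)
  required <- c("element", "rfd", "csf", "who_limit")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("toxicity table '", path, "' is missing column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "herbrisk_schema_error"
    )
  }
  tox <- tibble::tibble(
    element = as.character(raw$element),
    rfd = blank_to_na(raw$rfd),
    csf = blank_to_na(raw$csf),
    who_limit = blank_to_na(raw$who_limit)
  )
  dup <- unique(tox$element[duplicated(tox$element)])
  if (length(dup) > 0) {
    rlang::abort(
      paste0("duplicate element(s) in toxicity table: ",
             paste(dup, collapse = ", ")),
      class = "herbrisk_validation_error"
    )
  }
  bad_rfd <- which(is.na(tox$rfd) | tox$rfd <= 0)
  if (length(bad_rfd) > 0) {
    rlang::abort(
      paste0("rfd must be > 0; offending element(s): ",
             paste(tox$element[bad_rfd], collapse = ", ")),
      class = "herbrisk_validation_error"
    )
  }
  if (any(!is.na(tox$csf) & tox$csf < 0)) {
    rlang::abort("csf must be >= 0 when present",
                 class = "herbrisk_validation_error")
  }
  if (any(!is.na(tox$who_limit) & tox$who_limit <= 0)) {
    rlang::abort("who_limit must be > 0 when present",
                 class = "herbrisk_validation_error")
  }
  tox
}

#' Read a flat key-value exposure configuration
#'
#' Accepts lines of the form `key = value` or `key: value` with keys
#' `ir`, `ef`, `ed`, `bw` and optionally `at` (defaults to `365 * ed`).
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path Path to the configuration file.
#' @return An [exposure_parameters()] object.
#' @export
read_exposure_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("exposure config not found: ", path),
                 class = "herbrisk_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "[:=]", fixed = FALSE)
  bad <- lengths(kv) != 2
  if (any(bad)) {
    rlang::abort(
      paste0("malformed line(s) in exposure config: ",
             paste(lines[bad], collapse = "; ")),
      class = "herbrisk_schema_error"
    )
  }
  keys <- tolower(trimws(vapply(kv, `[`, "", 1)))
  vals <- suppressWarnings(as.double(trimws(vapply(kv, `[`, "", 2))))
  names(vals) <- keys
  unknown <- setdiff(keys, c("ir", "ef", "ed", "bw", "at"))
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown exposure key(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "herbrisk_schema_error")
  }
  need <- setdiff(c("ir", "ef", "ed", "bw"), keys)
  if (length(need) > 0) {
    rlang::abort(paste0("exposure config is missing key(s): ",
                        paste(need, collapse = ", ")),
                 class = "herbrisk_schema_error")
  }
  if ("at" %in% keys) {
    exposure_parameters(ir = vals[["ir"]], ef = vals[["ef"]],
                        ed = vals[["ed"]], bw = vals[["bw"]],
                        at = vals[["at"]])
  } else {
    exposure_parameters(ir = vals[["ir"]], ef = vals[["ef"]],
                        ed = vals[["ed"]], bw = vals[["bw"]])
  }
}

#' Write an analysis table as CSV with a fixed schema
#'
#' Column order is deterministic per schema. Risk quantities (`edi`, `thq`,
#' `cr`, `hi`, `value`) are written in scientific notation with 3
#' significant figures, the display convention of regulatory risk tables;
#' all other numeric columns keep full (15 significant digit) precision.
#' For `schema = "risk"`, `x` may be the list returned by
#' [deterministic_risk_table()], in which case each sample's per-element
#' rows are followed by its hazard-index row (`element = "HI"`, the index
#' in the `thq` column), mirroring the usual report layout.
#'
#' @param x A data frame, or for `schema = "risk"` optionally a list with
#'   elements `risk` and `hazard_index`.
#' @param path Output file path.
#' @param schema One of `"risk"`, `"hazard_index"`, `"summary"`,
#'   `"limit_tests"`, `"prob_risk"`, `"class_summary"`, `"generic"`.
#' @return Invisibly, the path written.
#' @export
write_table <- function(x, path,
                        schema = c("generic", "risk", "hazard_index",
                                   "summary", "limit_tests", "prob_risk",
                                   "class_summary")) {
  schema <- match.arg(schema)
  risk_cols <- c("edi", "thq", "cr", "hi", "value")
  if (schema == "risk" && is.list(x) && !is.data.frame(x) &&
      all(c("risk", "hazard_index") %in% names(x))) {
    x <- interleave_hi_rows(x$risk, x$hazard_index)
  }
  x <- tibble::as_tibble(x)
  order_map <- list(
    risk = c("sample_id", "element", "concentration", "edi", "thq", "cr",
             "cr_band", "estimator"),
    hazard_index = c("sample_id", "hi", "n_elements", "elements"),
    summary = c("sample_id", "element", "n", "mean", "sd", "cv_percent",
                "ci_low", "ci_high"),
    limit_tests = c("sample_id", "element", "mean", "sd", "limit",
                    "t_statistic", "p_value", "significant"),
    prob_risk = c("sample_id", "element", "metric", "percentile", "value"),
    class_summary = c("sample_id", "compound_class", "percent")
  )
  if (!is.null(order_map[[schema]])) {
    cols <- intersect(order_map[[schema]], names(x))
    x <- x[, c(cols, setdiff(names(x), cols)), drop = FALSE]
  }
  for (nm in names(x)) {
    if (is.numeric(x[[nm]])) {
      digits <- if (nm %in% risk_cols && schema != "generic") 2L else 14L
      out <- formatC(x[[nm]], format = "e", digits = digits)
      out[is.na(x[[nm]])] <- NA_character_
      x[[nm]] <- out
    }
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tryCatch(
    readr::write_csv(x, path, na = ""),
    error = function(e) {
      rlang::abort(paste0("cannot write table to '", path, "': ",
                          conditionMessage(e)),
                   class = "herbrisk_io_error")
    }
  )
  invisible(path)
}

interleave_hi_rows <- function(risk, hi) {
  blocks <- lapply(unique(risk$sample_id), function(s) {
    block <- risk[risk$sample_id == s, , drop = FALSE]
    h <- hi[hi$sample_id == s, , drop = FALSE]
    if (nrow(h) == 1) {
      hi_row <- block[0, , drop = FALSE]
      hi_row[1, "sample_id"] <- s
      hi_row[1, "element"] <- "HI"
      hi_row[1, "thq"] <- h$hi
      if ("estimator" %in% names(block)) {
        hi_row[1, "estimator"] <- block$estimator[1]
      }
      block <- dplyr::bind_rows(block, hi_row)
    }
    block
  })
  dplyr::bind_rows(blocks)
}

# -- internal helpers --------------------------------------------------------

read_csv_strict <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("input file not found: ", path),
                 class = "herbrisk_io_error")
  }
  raw <- tryCatch(
    suppressWarnings(readr::read_csv(path, col_types = readr::cols(
      .default = readr::col_character()
    ), progress = FALSE)),
    error = function(e) {
      rlang::abort(paste0("cannot parse '", path, "': ",
                          conditionMessage(e)),
                   class = "herbrisk_schema_error")
    }
  )
  if (nrow(raw) == 0 && ncol(raw) == 0) {
    rlang::abort(paste0("file '", path, "' is empty"),
                 class = "herbrisk_schema_error")
  }
  raw
}

blank_to_na <- function(x) {
  x <- trimws(as.character(x))
  x[!nzchar(x) | is.na(x)] <- NA_character_
  suppressWarnings(as.double(x))
}
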