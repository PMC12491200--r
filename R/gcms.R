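#' Relative percentage abundance from integrated peak areas
#'
#' Each compound's share of the total integrated peak area, in percent.
#' Percentages sum to exactly 100 before any rounding.
#'
#' @param areas Numeric vector of peak areas, all > 0.
#' @return Numeric vector of percentages, same length and names as `areas`.
#' @export
#' @examples
#' relative_abundance(c(1, 1, 2)) # 25, 25, 50
relative_abundance <- function(areas) {
  if (length(areas) == 0) {
    rlang::abort("need at least one peak",
                 class = "herbrisk_insufficient_data_error")
  }
  if (any(!is.finite(areas) | areas <= 0)) {
    rlang::abort("all peak areas must be finite and > 0",
                 class = "herbrisk_validation_error")
  }
  100 * areas / sum(areas)
}

#' Read a GC-MS identified-compound table
#'
#' Expects CSV columns `name`, `formula`, `class`, `retention_time`
#' followed by one relative-abundance column per sample (optionally
#' prefixed `abundance_`). Cells holding `-` or blank mean the compound was
#' not observed in that sample. The same compound name may legitimately
#' recur at different retention times; each (name, retention time) row is
#' a distinct record.
#'
#' @param path Path to the CSV file.
#' @param absent_token Cell token for "not observed". Default `"-"`.
#' @return A long tibble with columns `record_id`, `name`, `formula`,
#'   `compound_class`, `retention_time`, `sample_id`, `abundance`
#'   (`NA` = absent). Rows absent in every sample are kept (with all-`NA`
#'   abundance) and trigger a warning.
#' @export
read_compound_table <- function(path, absent_token = "-") {
  raw <- read_csv_strict(path)
  required <- c("name", "formula", "class", "retention_time")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("compound table '", path, "' is missing column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "herbrisk_schema_error"
    )
  }
  sample_cols <- setdiff(names(raw), required)
  if (length(sample_cols) == 0) {
    rlang::abort("compound table has no per-sample abundance columns",
                 class = "herbrisk_schema_error")
  }
  bad_class <- which(is.na(raw$class) | !nzchar(trimws(raw$class)))
  if (length(bad_class) > 0) {
    rlang::abort(
      paste0("missing/blank compound class in row(s): ",
             paste(bad_class, collapse = ", ")),
      class = "herbrisk_validation_error"
    )
  }
  rt <- suppressWarnings(as.double(raw$retention_time))
  bad_rt <- which(is.na(rt) | rt < 0)
  if (length(bad_rt) > 0) {
    rlang::abort(
      paste0("retention_time must be numeric >= 0; row(s): ",
             paste(bad_rt, collapse = ", ")),
      class = "herbrisk_validation_error"
    )
  }
  parse_ab <- function(x, col) {
    x <- trimws(as.character(x))
    absent <- is.na(x) | !nzchar(x) | x == absent_token
    val <- suppressWarnings(as.double(x))
    val[absent] <- NA_real_
    bad <- which(!absent & (is.na(val) | val < 0 | val > 100))
    if (length(bad) > 0) {
      rlang::abort(
        paste0("abundance in column '", col,
               "' outside [0, 100] or non-numeric; row(s): ",
               paste(bad, collapse = ", ")),
        class = "herbrisk_validation_error"
      )
    }
    val
  }
  ab <- lapply(sample_cols, function(cn) parse_ab(raw[[cn]], cn))
  names(ab) <- sub("^abundance_", "", sample_cols)
  all_absent <- Reduce(`&`, lapply(ab, is.na))
  if (any(all_absent)) {
    warning(sprintf("%d compound row(s) have no abundance in any sample",
                    sum(all_absent)), call. = FALSE)
  }
  wide <- tibble::tibble(
    record_id = seq_len(nrow(raw)),
    name = as.character(raw$name),
    formula = as.character(raw$formula),
    compound_class = trimws(as.character(raw$class)),
    retention_time = rt
  )
  for (s in names(ab)) wide[[s]] <- ab[[s]]
  tidyr::pivot_longer(wide, cols = dplyr::all_of(names(ab)),
                      names_to = "sample_id", values_to = "abundance")
}

#' Aggregate compound abundances by chemical class
#'
#' Sums the relative abundances of one sample's identified compounds
#' within each class, plus the total identified percentage (the sum over
#' all compounds). Compounds absent in the sample contribute nothing.
#'
#' @param records Long compound tibble from [read_compound_table()] or
#'   [generate_compound_table()].
#' @param sample_id Sample to aggregate.
#' @return A list with `sample_id`, `per_class` (tibble `compound_class`,
#'   `percent`, descending) and `total_identified`.
#' @export
aggregate_by_class <- function(records, sample_id) {
  if (!sample_id %in% records$sample_id) {
    rlang::abort(paste0("unknown sample_id: ", sample_id),
                 class = "herbrisk_lookup_error")
  }
  present <- records[records$sample_id == sample_id &
                       !is.na(records$abundance), , drop = FALSE]
  per_class <- present |>
    dplyr::group_by(.data$compound_class) |>
    dplyr::summarise(percent = sum(.data$abundance), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$percent))
  list(sample_id = sample_id, per_class = per_class,
       total_identified = sum(present$abundance))
}

#' Class summary across all samples
#'
#' Long-format class totals for every sample, with a `Total identified`
#' row per sample.
#'
#' @param records Long compound tibble.
#' @return A tibble with columns `sample_id`, `compound_class`, `percent`.
#' @export
class_summary <- function(records) {
  dplyr::bind_rows(lapply(unique(records$sample_id), function(s) {
    agg <- aggregate_by_class(records, s)
    dplyr::bind_rows(
      tibble::tibble(sample_id = s,
                     compound_class = agg$per_class$compound_class,
                     percent = agg$per_class$percent),
      tibble::tibble(sample_id = s,
                     compound_class = "Total identified",
                     percent = agg$total_identified)
    )
  }))
}
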