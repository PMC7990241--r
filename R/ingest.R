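#' Parse a CSV or XLSX feature table into a raw text grid
#'
#' Reads a sample-by-metabolite spreadsheet without any numeric coercion: every
#' cell is kept as text so that role assignment and validation can inspect the
#' original values. The first row is treated as the header. Ragged CSV rows are
#' padded with empty cells and reported in the `problems` attribute.
#'
#' @param path Path to a `.csv` or `.xlsx` file.
#' @param format `"auto"` (by extension), `"csv"` or `"xlsx"`. XLSX reads the
#'   first sheet only.
#' @return A `metabo_raw` object: a list with `header` (character), `cells`
#'   (character matrix of data rows), `n_rows`, `n_cols` and a `problems`
#'   tibble describing padded ragged rows.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,g,m1", "A,ctl,1.0", "B,trt,2.0"), f)
#' raw <- parse_table(f)
#' raw$n_rows
parse_table <- function(path, format = c("auto", "csv", "xlsx")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort_mp(paste0("file not found: ", path), "metabopipe_parse_error")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      csv = "csv",
      xlsx = "xlsx",
      abort_mp(paste0("unsupported format: .", ext), "metabopipe_parse_error")
    )
  }
  if (format == "csv") {
    df <- tryCatch(
      suppressWarnings(readr::read_csv(
        path,
        col_types = readr::cols(.default = readr::col_character()),
        na = character(),
        name_repair = "minimal",
        progress = FALSE,
        show_col_types = FALSE
      )),
      error = function(e) abort_mp(paste0("malformed CSV: ", conditionMessage(e)),
                                   "metabopipe_parse_error")
    )
    probs <- readr::problems(df)
    probs <- tibble::as_tibble(probs)
  } else {
    df <- tryCatch(
      readxl::read_excel(path, sheet = 1, col_types = "text",
                         .name_repair = "minimal"),
      error = function(e) abort_mp(paste0("malformed XLSX: ", conditionMessage(e)),
                                   "metabopipe_parse_error")
    )
    probs <- tibble::tibble()
  }
  if (nrow(df) == 0L || ncol(df) == 0L) {
    abort_mp("no data rows found", "metabopipe_parse_error")
  }
  cells <- as.matrix(as.data.frame(lapply(df, as.character),
                                   stringsAsFactors = FALSE, check.names = FALSE))
  cells[is.na(cells)] <- ""
  dimnames(cells) <- NULL
  structure(
    list(
      header = names(df),
      cells = cells,
      n_rows = nrow(cells),
      n_cols = ncol(cells),
      problems = probs
    ),
    class = "metabo_raw"
  )
}

#' @export
print.metabo_raw <- function(x, ...) {
  cat("<metabo_raw> ", x$n_rows, " data rows x ", x$n_cols, " columns\n", sep = "")
  cat("header:", paste(utils::head(x$header, 8), collapse = ", "),
      if (x$n_cols > 8) "..." else "", "\n")
  invisible(x)
}

COLUMN_ROLES <- c("primary_id", "group", "factor", "masked", "measurement",
                  "sample_mass")

#' Assign a role to every column of a raw table
#'
#' Each column of the grid gets one role: `primary_id` (the sample identifier),
#' `group` (the comparison group label), `factor` (other sample metadata),
#' `masked` (ignored in analysis), `measurement` (a metabolite column) or
#' `sample_mass` (sample weight/volume for normalization). With auto-detection
#' the first column becomes the primary ID, the second the group, and remaining
#' columns become measurements when all their cells parse as numbers (missing
#' tokens allowed) and factors otherwise. Explicit `role_map` entries override
#' auto-detection. Roles are accepted as given here; consistency (exactly one
#' primary ID, at least one measurement, ...) is checked later by
#' [validate_table()].
#'
#' @param raw A `metabo_raw` from [parse_table()].
#' @param role_map Optional named list/vector mapping column index (1-based) to
#'   a role, e.g. `list("3" = "masked")`.
#' @param auto_detect Apply the default heuristic to columns absent from
#'   `role_map` (default `TRUE`). When `FALSE`, `role_map` must cover all
#'   columns.
#' @param masked_rows Integer indices of data rows excluded from the
#'   measurement block (kept in the raw grid).
#' @return A `metabo_table` holding the text grid, the per-column roles and the
#'   masked-row set. Use [measurements()], [sample_meta()] and
#'   [metabolite_names()] to access the parsed pieces.
#' @export
assign_roles <- function(raw, role_map = NULL, auto_detect = TRUE,
                         masked_rows = integer()) {
  stopifnot(inherits(raw, "metabo_raw"))
  n <- raw$n_cols
  roles <- rep(NA_character_, n)
  if (!is.null(role_map)) {
    idx <- as.integer(names(role_map))
    if (anyNA(idx) || any(idx < 1L | idx > n)) {
      abort_mp("role_map index out of range")
    }
    vals <- unlist(role_map, use.names = FALSE)
    bad <- setdiff(vals, COLUMN_ROLES)
    if (length(bad)) abort_mp(paste0("unknown role: ", bad[1]))
    roles[idx] <- vals
  }
  if (auto_detect) {
    for (j in which(is.na(roles))) {
      if (j == 1L) {
        roles[j] <- "primary_id"
      } else if (j == 2L) {
        roles[j] <- "group"
      } else {
        parsed <- parse_measurement_text(raw$cells[, j])
        roles[j] <- if (any(parsed$bad)) "factor" else "measurement"
      }
    }
  }
  if (anyNA(roles)) {
    abort_mp("role_map does not cover all columns and auto_detect is disabled")
  }
  masked_rows <- sort(unique(as.integer(masked_rows)))
  if (length(masked_rows) && any(masked_rows < 1L | masked_rows > raw$n_rows)) {
    abort_mp("masked_rows index out of range")
  }
  structure(
    list(
      header = raw$header,
      cells = raw$cells,
      roles = roles,
      masked_rows = masked_rows,
      n_rows = raw$n_rows,
      n_cols = raw$n_cols
    ),
    class = "metabo_table"
  )
}

#' @export
print.metabo_table <- function(x, ...) {
  kept <- length(active_rows(x))
  cat("<metabo_table> ", kept, " samples x ",
      sum(x$roles == "measurement"), " metabolites\n", sep = "")
  cat("roles:", paste(sprintf("%s=%s", utils::head(x$header, 6),
                              utils::head(x$roles, 6)), collapse = ", "),
      if (x$n_cols > 6) "..." else "", "\n")
  if (length(x$masked_rows)) cat("masked rows:", length(x$masked_rows), "\n")
  invisible(x)
}

#' @noRd
active_rows <- function(table) {
  setdiff(seq_len(table$n_rows), table$masked_rows)
}

#' Extract the numeric measurement block of a table
#'
#' @param table A `metabo_table`.
#' @return A tibble (unmasked samples x metabolites) of parsed numeric values;
#'   missing tokens (`""`, `"NA"`, `"NaN"`, case-insensitive) become `NA`.
#'   Non-numeric text also becomes `NA` here; [validate_table()] flags it.
#' @export
measurements <- function(table) {
  stopifnot(inherits(table, "metabo_table"))
  rows <- active_rows(table)
  cols <- which(table$roles == "measurement")
  out <- lapply(cols, function(j) {
    parse_measurement_text(table$cells[rows, j])$values
  })
  names(out) <- table$header[cols]
  tibble::as_tibble(out, .name_repair = "minimal")
}

#' Sample metadata of a table
#'
#' @param table A `metabo_table`.
#' @return A tibble with `sample_id`, `group`, any factor columns and any
#'   sample-mass column, one row per unmasked sample.
#' @export
sample_meta <- function(table) {
  stopifnot(inherits(table, "metabo_table"))
  rows <- active_rows(table)
  out <- list()
  id_col <- which(table$roles == "primary_id")[1]
  grp_col <- which(table$roles == "group")[1]
  out$sample_id <- if (!is.na(id_col)) table$cells[rows, id_col] else
    as.character(rows)
  out$group <- if (!is.na(grp_col)) table$cells[rows, grp_col] else
    NA_character_
  for (j in which(table$roles == "factor")) {
    out[[table$header[j]]] <- table$cells[rows, j]
  }
  for (j in which(table$roles == "sample_mass")) {
    out[[table$header[j]]] <- parse_measurement_text(table$cells[rows, j])$values
  }
  tibble::as_tibble(out, .name_repair = "minimal")
}

#' Metabolite names (measurement column headers)
#' @param table A `metabo_table`.
#' @return Character vector of measurement column names.
#' @export
metabolite_names <- function(table) {
  stopifnot(inherits(table, "metabo_table"))
  table$header[table$roles == "measurement"]
}

#' Validation thresholds
#'
#' @param max_missing_fraction_per_group Maximum tolerated fraction of missing
#'   cells for a metabolite within any single group (default 0.25).
#' @param max_missing_fraction_overall Same bound across all samples (default
#'   0.25).
#' @param low_variance_threshold Variance floor below which a measurement
#'   column is flagged as (near-)constant (default 1e-8).
#' @return A list of class `metabo_validation_config`.
#' @export
validation_config <- function(max_missing_fraction_per_group = 0.25,
                              max_missing_fraction_overall = 0.25,
                              low_variance_threshold = 1e-8) {
  stopifnot(
    max_missing_fraction_per_group >= 0, max_missing_fraction_per_group <= 1,
    max_missing_fraction_overall >= 0, max_missing_fraction_overall <= 1,
    low_variance_threshold >= 0
  )
  structure(
    list(
      max_missing_fraction_per_group = max_missing_fraction_per_group,
      max_missing_fraction_overall = max_missing_fraction_overall,
      low_variance_threshold = low_variance_threshold
    ),
    class = "metabo_validation_config"
  )
}

#' Validate a role-assigned table for analysis readiness
#'
#' Emits machine-readable error and warning items rather than raising; a table
#' is analysis-ready iff the report has no `error` item. Errors: no / multiple
#' primary-ID or group columns, duplicate sample IDs, non-numeric text in a
#' measurement cell (distinct from the recognised missing tokens), duplicate
#' metabolite names, no measurement column, and missing-data fraction above the
#' configured threshold per group or overall. Warnings: measurement columns
#' with variance below the floor and groups with fewer than 3 samples.
#'
#' @param table A `metabo_table`.
#' @param config A [validation_config()].
#' @return A tibble of class `metabo_report` with columns `code`, `severity`,
#'   `context`, `row`, `column` (1-based locators into the input grid, `NA`
#'   when not applicable).
#' @export
validate_table <- function(table, config = validation_config()) {
  stopifnot(inherits(table, "metabo_table"))
  items <- list()
  add <- function(code, severity, context, row = NA_integer_,
                  column = NA_integer_) {
    items[[length(items) + 1L]] <<- tibble::tibble(
      code = code, severity = severity, context = context,
      row = as.integer(row), column = as.integer(column)
    )
  }
  rows <- active_rows(table)
  id_cols <- which(table$roles == "primary_id")
  grp_cols <- which(table$roles == "group")
  meas_cols <- which(table$roles == "measurement")

  if (length(id_cols) == 0L) {
    add("missing_primary_id", "error", "no column has the primary_id role")
  } else if (length(id_cols) > 1L) {
    for (j in id_cols[-1]) {
      add("multiple_primary_id", "error",
          "more than one column has the primary_id role", column = j)
    }
  }
  if (length(grp_cols) == 0L) {
    add("missing_group", "error", "no column has the group role")
  } else if (length(grp_cols) > 1L) {
    for (j in grp_cols[-1]) {
      add("multiple_group", "error",
          "more than one column has the group role", column = j)
    }
  }
  if (length(meas_cols) == 0L) {
    add("no_measurements", "error", "no column has the measurement role")
  }

  if (length(id_cols) >= 1L) {
    ids <- table$cells[rows, id_cols[1]]
    dup <- ids[duplicated(ids)]
    for (d in unique(dup)) {
      for (r in rows[ids == d][-1]) {
        add("duplicate_primary_id", "error",
            paste0("sample ID '", d, "' occurs more than once"),
            row = r, column = id_cols[1])
      }
    }
  }

  mn <- table$header[meas_cols]
  for (nm in unique(mn[duplicated(mn)])) {
    for (j in meas_cols[mn == nm][-1]) {
      add("duplicate_metabolite_name", "error",
          paste0("metabolite name '", nm, "' occurs more than once"),
          column = j)
    }
  }

  groups <- if (length(grp_cols) >= 1L) table$cells[rows, grp_cols[1]] else NULL

  for (j in meas_cols) {
    txt <- table$cells[rows, j]
    parsed <- parse_measurement_text(txt)
    for (k in which(parsed$bad)) {
      add("non_numeric_measurement", "error",
          paste0("cell '", txt[k], "' in metabolite '", table$header[j],
                 "' is not numeric"),
          row = rows[k], column = j)
    }
    frac_all <- mean(is.na(parsed$values))
    if (frac_all > config$max_missing_fraction_overall) {
      add("excess_missing_overall", "error",
          sprintf("metabolite '%s' is %.0f%% missing overall",
                  table$header[j], 100 * frac_all),
          column = j)
    }
    if (!is.null(groups)) {
      for (g in unique(groups)) {
        frac_g <- mean(is.na(parsed$values[groups == g]))
        if (frac_g > config$max_missing_fraction_per_group) {
          add("excess_missing_group", "error",
              sprintf("metabolite '%s' is %.0f%% missing in group '%s'",
                      table$header[j], 100 * frac_g, g),
              column = j)
        }
      }
    }
    obs <- parsed$values[!is.na(parsed$values)]
    if (length(obs) >= 2L && !any(parsed$bad) &&
        stats::var(obs) < config$low_variance_threshold) {
      add("low_variance", "warning",
          paste0("metabolite '", table$header[j],
                 "' has excessively low variance"),
          column = j)
    }
  }

  if (!is.null(groups)) {
    tab <- table(groups)
    for (g in names(tab)[tab < 3L]) {
      add("small_group", "warning",
          paste0("group '", g, "' has fewer than 3 samples"))
    }
  }

  out <- if (length(items)) dplyr::bind_rows(items) else
    tibble::tibble(code = character(), severity = character(),
                   context = character(), row = integer(), column = integer())
  class(out) <- c("metabo_report", class(out))
  out
}

#' Is a validation report free of errors?
#' @param report A `metabo_report` from [validate_table()].
#' @return `TRUE` iff no item has severity `"error"`.
#' @export
is_valid <- function(report) {
  stopifnot(inherits(report, "metabo_report"))
  !any(report$severity == "error")
}

#' Decompose a validated table into its three analysis tables
#'
#' Splits a clean table into the numeric measurement block, the per-sample
#' metadata and the per-metabolite metadata — the canonical three-table form
#' the downstream modules consume.
#'
#' @param table A `metabo_table` that validates with no errors.
#' @param config Validation thresholds used for the readiness check.
#' @return A list with `measurements` (tibble, samples x metabolites),
#'   `sample_meta` (tibble: `sample_id`, `group`, factors, sample mass) and
#'   `metabolite_meta` (tibble: `metabolite`, original `column` index).
#' @export
decompose <- function(table, config = validation_config()) {
  report <- validate_table(table, config)
  if (!is_valid(report)) {
    abort_mp(paste0("table has ", sum(report$severity == "error"),
                    " outstanding validation error(s); fix before decompose"),
             "metabopipe_contract_error")
  }
  list(
    measurements = measurements(table),
    sample_meta = sample_meta(table),
    metabolite_meta = tibble::tibble(
      metabolite = metabolite_names(table),
      column = which(table$roles == "measurement")
    )
  )
}

#' Write a table to CSV / a report or network to JSON
#'
#' Plain deterministic writers: identical input yields byte-identical output.
#'
#' @param x A data frame (written as CSV), a `metabo_report` or
#'   `metabo_network` (written as JSON).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_output <- function(x, path) {
  if (inherits(x, "metabo_network")) {
    jsonlite::write_json(network_node_link(x), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  } else if (inherits(x, "metabo_report")) {
    items <- lapply(seq_len(nrow(x)), function(i) as.list(x[i, ]))
    jsonlite::write_json(items, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else if (is.data.frame(x)) {
    readr::write_csv(x, path, progress = FALSE)
  } else {
    abort_mp("unsupported object for write_output")
  }
  invisible(path)
}
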