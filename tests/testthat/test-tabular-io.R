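test_that("CSV parsing preserves cell text verbatim with a header row", {
  f <- write_csv_lines(c("id,g,m1", "A,ctl,1.0", "B,trt,2.0"))
  raw <- parse_table(f)
  expect_s3_class(raw, "metabo_raw")
  expect_equal(raw$header, c("id", "g", "m1"))
  expect_equal(raw$n_rows, 2L)
  expect_equal(raw$n_cols, 3L)
  expect_equal(raw$cells[1, ], c("A", "ctl", "1.0"))  # no numeric coercion
})

test_that("degenerate files raise parse errors", {
  empty <- write_csv_lines(character())
  expect_error(parse_table(empty), class = "metabopipe_parse_error")
  expect_error(parse_table(tempfile(fileext = ".csv")),
               class = "metabopipe_parse_error")
  bad_ext <- tempfile(fileext = ".txt")
  writeLines("a,b", bad_ext)
  expect_error(parse_table(bad_ext), class = "metabopipe_parse_error")
  header_only <- write_csv_lines("id,g,m1")
  expect_error(parse_table(header_only), class = "metabopipe_parse_error")
})

test_that("ragged CSV rows are padded with empty cells", {
  f <- write_csv_lines(c("id,g,m1", "A,ctl,1.0", "B,trt"))
  raw <- suppressWarnings(parse_table(f))
  expect_equal(raw$n_cols, 3L)
  expect_equal(raw$cells[2, 3], "")
})

test_that("XLSX yields the same grid as the equivalent CSV", {
  rows <- list(list("id", "g", "m1"), list("A", "ctl", "1.0"),
               list("B", "trt", "2.0"))
  xf <- tempfile(fileext = ".xlsx")
  write_xlsx_via_python(rows, xf)
  expect_true(file.exists(xf))
  raw_x <- parse_table(xf)
  raw_c <- parse_table(write_csv_lines(c("id,g,m1", "A,ctl,1.0", "B,trt,2.0")))
  expect_equal(raw_x$header, raw_c$header)
  expect_equal(raw_x$cells, raw_c$cells)
})

test_that("auto-detect assigns id/group/measurement/factor roles", {
  f <- write_csv_lines(c("id,g,m1,site", "A,ctl,1.0,x", "B,trt,2.0,y"))
  tbl <- assign_roles(parse_table(f))
  expect_equal(tbl$roles, c("primary_id", "group", "measurement", "factor"))
  expect_equal(metabolite_names(tbl), "m1")
})

test_that("explicit role overrides win and masked columns drop from measurements", {
  f <- write_csv_lines(c("id,g,m1", "A,ctl,1.0", "B,trt,2.0"))
  tbl <- assign_roles(parse_table(f), role_map = list("3" = "masked"))
  expect_equal(ncol(measurements(tbl)), 0L)
  expect_error(assign_roles(parse_table(f), role_map = list("9" = "masked")),
               "out of range")
})

test_that("conflicting role maps are accepted at assignment, flagged by validate", {
  f <- write_csv_lines(c("id,g,m1", "A,ctl,1.0", "B,trt,2.0"))
  tbl <- assign_roles(parse_table(f),
                      role_map = list("1" = "primary_id", "2" = "primary_id"))
  report <- validate_table(tbl)
  expect_true("multiple_primary_id" %in% report$code)
  expect_true("missing_group" %in% report$code)
  expect_false(is_valid(report))
})

test_that("validate flags duplicate IDs, non-numeric cells and low variance", {
  f <- write_csv_lines(c(
    "id,grp,m1,m2",
    "A,ctl,1.0,5",
    "A,ctl,n/a?,5",
    "B,trt,3.0,5",
    "C,trt,4.0,5"
  ))
  # m1 must be declared a measurement: auto-detect would demote it to factor
  report <- validate_table(assign_roles(parse_table(f),
                                        role_map = list("3" = "measurement")))
  expect_true("duplicate_primary_id" %in% report$code)
  expect_true("non_numeric_measurement" %in% report$code)
  lv <- report[report$code == "low_variance", ]
  expect_equal(lv$severity, "warning")
  expect_equal(lv$column, 4L)   # locator points at the constant column
  nn <- report[report$code == "non_numeric_measurement", ]
  expect_equal(nn$row, 2L)
  expect_equal(nn$column, 3L)
})

test_that("missing tokens are missing, not non-numeric, and thresholds apply", {
  f <- write_csv_lines(c(
    "id,grp,m1",
    "A,ctl,NA",
    "B,ctl,2.0",
    "C,ctl,3.0",
    "D,trt,nan",
    "E,trt,",
    "F,trt,6.0"
  ))
  report <- validate_table(assign_roles(parse_table(f)))
  expect_false("non_numeric_measurement" %in% report$code)
  # 3/6 missing overall > 0.25, and 2/3 missing in trt > 0.25
  expect_true("excess_missing_overall" %in% report$code)
  expect_true("excess_missing_group" %in% report$code)
  # configurable thresholds silence both
  lax <- validation_config(max_missing_fraction_per_group = 1,
                           max_missing_fraction_overall = 1)
  expect_true(is_valid(validate_table(assign_roles(parse_table(f)), lax)))
})

test_that("a clean table validates with an empty report, deterministically", {
  tbl <- toy_table()
  report <- validate_table(tbl)
  expect_equal(nrow(report), 0L)
  expect_identical(report, validate_table(tbl))  # purity
})

test_that("small groups draw a warning, not an error", {
  f <- write_csv_lines(c("id,grp,m1", "A,ctl,1.0", "B,trt,2.0", "C,trt,3.0"))
  report <- validate_table(assign_roles(parse_table(f)))
  expect_true(all(report$code %in% "small_group"))
  expect_true(is_valid(report))
})

test_that("decompose partitions a valid table into three tables", {
  parts <- decompose(toy_table())
  expect_equal(dim(parts$measurements), c(6L, 3L))
  expect_equal(names(parts$sample_meta), c("sample_id", "group"))
  expect_equal(nrow(parts$metabolite_meta), 3L)
  expect_equal(parts$metabolite_meta$metabolite, c("ala", "gly", "val"))
  expect_equal(parts$measurements$ala, 1:6 * 1.0)
})

test_that("masked rows are excluded from measurements and sample_meta", {
  tbl <- assign_roles(parse_table(toy_csv()), masked_rows = 2L)
  parts <- decompose(tbl)
  expect_equal(nrow(parts$measurements), 5L)
  expect_false("B" %in% parts$sample_meta$sample_id)
})

test_that("decompose refuses tables with outstanding validation errors", {
  f <- write_csv_lines(c("id,grp,m1", "A,ctl,1.0", "A,ctl,2.0", "B,trt,3.0"))
  tbl <- assign_roles(parse_table(f))
  expect_error(decompose(tbl), class = "metabopipe_contract_error")
})

test_that("write -> parse round trip is the identity on measurements", {
  parts <- decompose(toy_table())
  f <- tempfile(fileext = ".csv")
  write_output(parts$measurements, f)
  again <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(as.data.frame(again), as.data.frame(parts$measurements))
  # byte-stable
  f2 <- tempfile(fileext = ".csv")
  write_output(parts$measurements, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("validation reports serialize to JSON with one object per item", {
  f <- write_csv_lines(c("id,grp,m1", "A,ctl,1.0", "A,ctl,x", "B,trt,3.0"))
  report <- validate_table(assign_roles(parse_table(f)))
  jf <- tempfile(fileext = ".json")
  write_output(report, jf)
  items <- jsonlite::read_json(jf)
  expect_equal(length(items), nrow(report))
  expect_equal(items[[1]]$code, report$code[1])
})
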