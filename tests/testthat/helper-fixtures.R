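# Shared fixtures and independent oracles. Everything is generated in code;
# no stored data files.

write_csv_lines <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# clean 6-sample, 3-metabolite table (two groups of 3: no warnings expected)
toy_csv <- function() {
  write_csv_lines(c(
    "id,grp,ala,gly,val",
    "A,ctl,1.0,10,100",
    "B,ctl,2.0,20,110",
    "C,ctl,3.0,30,120",
    "D,trt,4.0,40,130",
    "E,trt,5.0,50,140",
    "F,trt,6.0,60,150"
  ))
}

toy_table <- function() {
  assign_roles(parse_table(toy_csv()))
}

random_positive_matrix <- function(n, p, seed) {
  withr::with_seed(seed, {
    m <- matrix(exp(rnorm(n * p, 2, 0.8)), n, p)
    colnames(m) <- paste0("m", seq_len(p))
    tibble::as_tibble(as.data.frame(m))
  })
}

# correlated complete matrix for imputation benchmarking: latent-factor blocks
correlated_matrix <- function(n = 20, p = 12, rho = 0.7, seed = 1) {
  cfg <- simulation_config(
    n_samples_per_group = n / 2, n_metabolites = p, n_differential = 0,
    n_correlated_blocks = 2, block_size = p / 2,
    within_block_correlation = rho, seed = seed
  )
  sim <- simulate_dataset(cfg)
  list(data = sim$truth$clean, groups = sim$table$group)
}

# Exhaustive two-sided rank-sum p-value: enumerate every assignment of the
# pooled values to the first group and count statistics at least as extreme.
# Independent of wilcox.test (direct enumeration of the null distribution).
rank_sum_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  nx <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  subsets <- utils::combn(n, nx)
  w_all <- apply(subsets, 2, function(idx) {
    sum(r[idx]) - nx * (nx + 1) / 2
  })
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  min(p, 1)
}

# Pooled-variance two-sample t-test p (closed form; oracle for k = 2 Tukey)
pooled_t_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  t_stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * stats::pt(abs(t_stat), df = nx + ny - 2, lower.tail = FALSE)
}

rmse <- function(a, b) sqrt(mean((as.matrix(a) - as.matrix(b))^2))

# write a small xlsx at test time with the pre-installed Python openpyxl
write_xlsx_via_python <- function(rows, path) {
  py <- jsonlite::toJSON(rows, auto_unbox = TRUE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "from openpyxl import Workbook",
    sprintf("rows = json.loads(r'''%s''')", py),
    "wb = Workbook()",
    "ws = wb.active",
    "for r in rows:",
    "    ws.append(r)",
    sprintf("wb.save(r'%s')", path)
  ), script)
  status <- system2("python", script, stdout = TRUE, stderr = TRUE)
  invisible(status)
}
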