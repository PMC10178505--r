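# Run-table I/O and the bundled garlic-leaf extraction study fixtures.
#
# The central container is the *run table*: one row per experimental run
# with run_id, space_type, one column per factor (actual units), the
# measured responses, and optionally per-method predicted columns named
# <response>_rsm / <response>_ann.

fixture_md5 <- c(
  design_levels      = "04815d73c8301dedbf1bd1180872f8c1",
  runs               = "67b742691e1931c3fd278868b783029c",
  rsm_coefficients   = "b4d4ab5abdf9445c23c15154c6a42ea0",
  comparison_metrics = "caac5e1e782fe2dbedd62d035cee648a"
)

#' Bundled reference tables of the garlic-leaf extraction study
#'
#' Machine-readable copies of the published tables of a 20-run
#' ultrasound-assisted extraction experiment on garlic (*Allium sativum*)
#' leaf powder: the design levels, the full run table with measured and
#' model-predicted responses, the reported second-order model coefficients,
#' and the reported model-comparison statistics. Fixture files are frozen;
#' their checksums are verified on every load.
#'
#' @param name One of `"design_levels"`, `"runs"`, `"rsm_coefficients"`,
#'   `"comparison_metrics"`.
#' @return A tibble with the table's printed values.
#' @examples
#' uae_fixture("runs")
#' uae_fixture("rsm_coefficients")
#' @export
uae_fixture <- function(name = c("design_levels", "runs", "rsm_coefficients",
                                 "comparison_metrics")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("garlic_", name, ".csv"),
                      package = "uaeopt", mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(fixture_md5[name]))) {
    stop("Fixture '", name, "' failed its integrity checksum.", call. = FALSE)
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' The 20-run garlic-leaf extraction run table
#'
#' Convenience accessor for `uae_fixture("runs")`: the rotatable central
#' composite design (8 factorial, 6 axial, 6 center runs) over ultrasound
#' amplitude, treatment time and ethanol concentration, with measured
#' extraction yield (%), total phenol content (mg GAE/g), total flavonoid
#' content (mg QE/g) and DPPH antioxidant activity (%), plus the published
#' response-surface and neural-network predicted columns and per-run
#' energy metadata.
#'
#' @return A 20-row tibble.
#' @examples
#' garlic_runs()
#' @export
garlic_runs <- function() {
  uae_fixture("runs")
}

#' Names of the measured responses in the garlic study
#' @return Character vector `c("yield", "tpc", "tfc", "antioxidant")`.
#' @export
garlic_responses <- function() {
  c("yield", "tpc", "tfc", "antioxidant")
}

#' Read a run table from CSV
#'
#' Reads a run-table CSV (RFC-4180, "." decimal separator), checks it
#' against a factor table, labels each run's design region and snaps the
#' coded coordinates to nominal design levels. Rows whose coded coordinates
#' are all zero are labeled `center`, rows with exactly one coordinate at
#' `-+alpha` are `axial`, rows with all coordinates at `-+1` are
#' `factorial`, anything else `offdesign`. Missing response values are
#' rejected, not imputed: the downstream analysis assumes a complete design.
#'
#' @param path CSV file path (or literal data / connection as accepted by
#'   [readr::read_csv()]).
#' @param factors Factor table (see [factor_spec()]).
#' @param responses Response column names to require; default: every
#'   numeric column that is neither a factor, an id, nor a `_rsm`/`_ann`
#'   prediction column.
#' @param snap_tol Snap tolerance passed to [code_values()].
#' @return A run-table tibble with `run_id`, `space_type`, factor and
#'   response columns; factor table attached as attribute `"factors"`.
#' @examples
#' path <- system.file("extdata", "garlic_runs.csv", package = "uaeopt")
#' rt <- read_run_table(path, garlic_factors())
#' @export
read_run_table <- function(path, factors, responses = NULL, snap_tol = 0.1) {
  check_factors(factors)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(factors$name, names(raw))
  if (length(miss)) {
    stop("Run table is missing factor column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.null(responses)) {
    skip <- c("run_id", "space_type", factors$name)
    responses <- setdiff(names(raw)[vapply(raw, is.numeric, logical(1))], skip)
    responses <- responses[!grepl("_(rsm|ann)$", responses)]
    responses <- setdiff(responses, c("applied_energy", "calorimetric_energy"))
  }
  miss <- setdiff(responses, names(raw))
  if (length(miss)) {
    stop("Run table is missing response column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in c(factors$name, responses)) {
    if (!is.numeric(raw[[col]])) {
      stop("Column '", col, "' is not numeric; check the CSV for stray text.",
           call. = FALSE)
    }
    bad <- which(!is.finite(raw[[col]]))
    if (length(bad)) {
      stop("Missing or non-finite value in column '", col, "', row ",
           bad[1], ".", call. = FALSE)
    }
  }
  n_distinct_pts <- nrow(unique(raw[factors$name]))
  if (n_distinct_pts < nrow(factors) + 1) {
    stop("Run table needs at least k + 1 distinct design points.",
         call. = FALSE)
  }

  coded <- code_values(raw, factors, snap = TRUE, tol = snap_tol)
  alpha <- ccd_alpha(nrow(factors))
  space_type <- apply(as.matrix(coded), 1, function(x) {
    if (all(x == 0)) "center"
    else if (sum(abs(x) == alpha) == 1 && sum(x != 0) == 1) "axial"
    else if (all(abs(x) == 1)) "factorial"
    else "offdesign"
  })

  out <- raw
  out$space_type <- space_type
  if (!"run_id" %in% names(out)) out$run_id <- seq_len(nrow(out))
  front <- c("run_id", "space_type", factors$name)
  out <- dplyr::relocate(out, dplyr::all_of(front))
  structure(out, factors = factors, class = class(out))
}

#' Write a run table (or any design/report tibble) to CSV
#'
#' @param data Tibble to write.
#' @param path Output file path.
#' @return `data`, invisibly.
#' @export
write_run_table <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}

#' Read/write a factor configuration as a flat key-value file
#'
#' One line per key, `factor.property = value`, e.g.
#' `amplitude.center = 45`. Properties `center` and `step` are required per
#' factor; `units` is optional.
#'
#' @param path File path.
#' @return For `read_factor_config()`, a factor table; for
#'   `write_factor_config()`, the factor table invisibly.
#' @examples
#' tmp <- tempfile(fileext = ".cfg")
#' write_factor_config(garlic_factors(), tmp)
#' read_factor_config(tmp)
#' @export
read_factor_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop("Malformed config line: '", lines[which(bad)[1]], "'", call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  parts <- strsplit(keys, ".", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("Config keys must look like '<factor>.<property>'.", call. = FALSE)
  }
  fac <- vapply(parts, `[`, "", 1L)
  prop <- vapply(parts, `[`, "", 2L)
  out <- lapply(unique(fac), function(f) {
    get <- function(p, required = TRUE) {
      i <- which(fac == f & prop == p)
      if (!length(i)) {
        if (required) stop("Factor '", f, "' is missing '", p, "'.",
                           call. = FALSE)
        return(NA_character_)
      }
      vals[i[1]]
    }
    units <- get("units", required = FALSE)
    factor_spec(f,
                center = as.numeric(get("center")),
                step = as.numeric(get("step")),
                units = if (is.na(units)) "" else units)
  })
  dplyr::bind_rows(out)
}

#' @rdname read_factor_config
#' @param factors Factor table to write.
#' @export
write_factor_config <- function(factors, path) {
  check_factors(factors)
  lines <- unlist(lapply(seq_len(nrow(factors)), function(i) {
    f <- factors[i, ]
    c(sprintf("%s.units = %s", f$name, f$units),
      sprintf("%s.center = %.15g", f$name, f$center),
      sprintf("%s.step = %.15g", f$name, f$step))
  }))
  writeLines(lines, path)
  invisible(factors)
}
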