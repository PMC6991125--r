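count_table_columns <- c("host", "inoculum", "vitamin", "replicate",
                         "time_h", "count_per_uL")

validate_count_table <- function(table) {
  missing_cols <- setdiff(count_table_columns, names(table))
  if (length(missing_cols)) {
    stop_churchill("schema", "count table is missing column(s): %s",
                   paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(table$time_h)) || any(table$time_h < 0)) {
    bad <- which(!is.finite(table$time_h) | table$time_h < 0)[1]
    stop_churchill("schema", "time_h must be finite and >= 0 (row %d)", bad)
  }
  bad <- which(!is.finite(table$count_per_uL) | table$count_per_uL <= 0)
  if (length(bad)) {
    stop_churchill("invalid_count",
                   "count_per_uL must be > 0 (first offending row: %d)", bad[1])
  }
  key <- paste(table$host, table$inoculum, table$vitamin, table$replicate,
               table$time_h, sep = "\r")
  if (anyDuplicated(key)) {
    stop_churchill("duplicate_key",
                   "duplicate (host, inoculum, vitamin, replicate, time_h) at row %d",
                   anyDuplicated(key))
  }
  invisible(table)
}

#' Read a tidy count table
#'
#' Reads a CSV with columns `host`, `inoculum`, `vitamin`, `replicate`,
#' `time_h`, `count_per_uL`, validates the schema (positive counts,
#' non-negative times, no duplicated timepoints within a replicate) and
#' splits it into per-replicate series.
#'
#' @param path CSV file path.
#' @return A list of [count_series()], timepoints sorted ascending.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) {
    stop_churchill("io", "file not found: %s", path)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$replicate <- as.character(tab$replicate)
  count_table_series(tab)
}

#' Write a tidy count table
#'
#' @param table a count-table data frame (e.g. [simulate_experiment()]
#'   output).
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  validate_count_table(table)
  write_csv12(table, path)
}

# 12-significant-digit CSV, so write/read round-trips are lossless at the
# documented precision
write_csv12 <- function(d, path) {
  num <- vapply(d, is.numeric, TRUE)
  d[num] <- lapply(d[num], function(x) format(x, digits = 12, trim = TRUE,
                                              scientific = FALSE))
  ok <- tryCatch({
    utils::write.csv(d, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_churchill("io", "cannot write %s: %s",
                                  path, conditionMessage(ok))
  invisible(path)
}

#' Write / read the per-replicate parameter table
#'
#' Serialises the per-replicate responses (growth exponent, maximum
#' abundance, decline exponent, convergence flag) as CSV; numeric values
#' round-trip to 12 significant digits.
#'
#' @param records a per-replicate parameter data frame
#'   ([fit_replicates()] output).
#' @param path CSV path.
#' @return `path` invisibly (write); the data frame (read).
#' @export
write_parameter_table <- function(records, path) {
  if (!NROW(records)) {
    stop_churchill("empty_input", "no replicate records to write")
  }
  write_csv12(records, path)
}

#' @rdname write_parameter_table
#' @export
read_parameter_table <- function(path) {
  if (!file.exists(path)) stop_churchill("io", "file not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("host", "inoculum", "vitamin", "replicate", "growth",
            "max_abundance", "decline")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop_churchill("schema", "parameter table is missing column(s): %s",
                   paste(missing_cols, collapse = ", "))
  }
  d$replicate <- as.character(d$replicate)
  d
}

#' Write the three impact report tables
#'
#' Writes `inoculation_vs_control.csv`, `inoculation_pairs.csv` and
#' `vitamin_effects.csv` (rows at adjusted p below alpha) plus `_all`
#' variants with every comparison, into `dir`.
#'
#' @param tables an `"impact_tables"` object from [build_impact_tables()].
#' @param dir output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_report_tables <- function(tables, dir) {
  if (!inherits(tables, "impact_tables")) {
    stop_churchill("specification", "tables must come from build_impact_tables()")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- c(inoculation = "inoculation_vs_control",
            pairwise = "inoculation_pairs",
            vitamin = "vitamin_effects")
  files <- character(0)
  for (nm in names(stem)) {
    f1 <- file.path(dir, paste0(stem[[nm]], ".csv"))
    f2 <- file.path(dir, paste0(stem[[nm]], "_all.csv"))
    write_csv12(tables$significant[[nm]], f1)
    write_csv12(tables$full[[nm]], f2)
    files <- c(files, f1, f2)
  }
  invisible(files)
}

#' Convert a mass concentration to picomolar
#'
#' Utility for expressing medium vitamin doses in molar units:
#' micrograms per litre divided by the molar mass, in picomolar.  At the
#' f/2 doses this gives approximately 2.96e5 pM for thiamine·HCl
#' (100 ug/L, 337.27 g/mol) and 2.05e3 pM for biotin (0.5 ug/L,
#' 244.31 g/mol).
#'
#' @param mass_ug_per_L mass concentration in micrograms per litre (>= 0).
#' @param molar_mass_g_per_mol molar mass in grams per mole (> 0).
#' @return Concentration in pM.
#' @examples
#' mass_to_molar(100, 337.27)  # ~2.96e5 pM
#' @export
mass_to_molar <- function(mass_ug_per_L, molar_mass_g_per_mol) {
  if (any(!is.finite(molar_mass_g_per_mol)) || any(molar_mass_g_per_mol <= 0)) {
    stop_churchill("domain", "molar mass must be > 0")
  }
  if (any(!is.finite(mass_ug_per_L)) || any(mass_ug_per_L < 0)) {
    stop_churchill("domain", "mass concentration must be >= 0")
  }
  (mass_ug_per_L * 1e-6 / molar_mass_g_per_mol) * 1e12
}
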