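#' Read concentration-time data from a long-format CSV
#'
#' Expects one row per observation. Default columns: `subject_id`, `group`,
#' `matrix`, `time` (hours), `concentration` (ng/mL plasma, ng/g tissue),
#' and optionally `dose_amount` (mg/kg) and `route`. A `schema` map renames
#' non-standard headers. Rows are grouped into one [pk_profile] per
#' (subject, matrix) and sorted by time.
#'
#' @param path Path to the CSV file.
#' @param schema Named character vector mapping standard names to the file's
#'   column names, e.g. `c(time = "t_hr")`.
#' @return A list of [pk_profile] objects.
#' @export
read_pk_csv <- function(path, schema = NULL) {
  df <- read_checked_csv(path,
                         required = c("subject_id", "group", "matrix",
                                      "time", "concentration"),
                         numeric_cols = c("time", "concentration"),
                         schema = schema)
  key <- interaction(df$subject_id, df$matrix, df$time, drop = TRUE)
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1]
    stop(sprintf("duplicate (subject, matrix, time) at row %d of %s",
                 bad, path), call. = FALSE)
  }
  neg <- which(df$concentration < 0)
  if (length(neg)) {
    stop(sprintf("negative concentration at row %d of %s", neg[1], path),
         call. = FALSE)
  }
  split_df <- split(df, interaction(df$subject_id, df$matrix, drop = TRUE))
  profiles <- lapply(split_df, function(d) {
    d <- d[order(d$time), , drop = FALSE]
    pk_profile(subject_id = d$subject_id[1], group = d$group[1],
               matrix = d$matrix[1], times = d$time,
               concentrations = d$concentration,
               dose_amount = if ("dose_amount" %in% names(d))
                 as.numeric(d$dose_amount[1]) else NA_real_,
               route = if ("route" %in% names(d)) d$route[1] else "iv")
  })
  unname(profiles)
}

#' Read equilibrium-dialysis measurements from CSV
#'
#' Columns: `matrix`, `donor_conc`, `receiver_conc`, `dilution_factor`.
#'
#' @inheritParams read_pk_csv
#' @return A list of [dialysis_measurement] objects.
#' @export
read_dialysis_csv <- function(path, schema = NULL) {
  df <- read_checked_csv(path,
                         required = c("matrix", "donor_conc",
                                      "receiver_conc", "dilution_factor"),
                         numeric_cols = c("donor_conc", "receiver_conc",
                                          "dilution_factor"),
                         schema = schema)
  lapply(seq_len(nrow(df)), function(i) {
    dialysis_measurement(matrix = df$matrix[i], donor_conc = df$donor_conc[i],
                         receiver_conc = df$receiver_conc[i],
                         dilution_factor = df$dilution_factor[i])
  })
}

#' Read a replicate-resolved viability table from CSV
#'
#' Columns: `cell_line`, `concentration` (nM), `viability` (percent of
#' control), optional `replicate` and `co_treatment`. One
#' [viability_table] is returned per (cell_line, co_treatment).
#'
#' @inheritParams read_pk_csv
#' @return A list of [viability_table] objects.
#' @export
read_viability_csv <- function(path, schema = NULL) {
  df <- read_checked_csv(path,
                         required = c("cell_line", "concentration",
                                      "viability"),
                         numeric_cols = c("concentration", "viability"),
                         schema = schema)
  if (!"co_treatment" %in% names(df)) df$co_treatment <- NA_character_
  key <- paste(df$cell_line,
               ifelse(is.na(df$co_treatment), "", df$co_treatment),
               sep = "|")
  lapply(split(df, key), function(d) {
    viability_table(cell_line = d$cell_line[1],
                    concentrations = d$concentration,
                    viability = d$viability,
                    replicate = if ("replicate" %in% names(d)) d$replicate,
                    co_treatment = d$co_treatment[1])
  })
}

#' Read bioluminescence series from CSV
#'
#' Columns: `animal_id`, `group`, `time` (days), `flux` (photons/s).
#'
#' @inheritParams read_pk_csv
#' @return A list of [bli_series] objects.
#' @export
read_bli_csv <- function(path, schema = NULL) {
  df <- read_checked_csv(path,
                         required = c("animal_id", "group", "time", "flux"),
                         numeric_cols = c("time", "flux"), schema = schema)
  lapply(split(df, df$animal_id), function(d) {
    d <- d[order(d$time), , drop = FALSE]
    bli_series(animal_id = d$animal_id[1], group = d$group[1],
               times = d$time, flux = d$flux)
  })
}

#' Read survival records from CSV
#'
#' Columns: `animal_id`, `group`, `time` (days), `event` (1 death,
#' 0 censored).
#'
#' @inheritParams read_pk_csv
#' @return A [survival_records] data.frame.
#' @export
read_survival_csv <- function(path, schema = NULL) {
  df <- read_checked_csv(path,
                         required = c("animal_id", "group", "time", "event"),
                         numeric_cols = c("time", "event"), schema = schema)
  survival_records(df$animal_id, df$group, df$time, df$event)
}

read_checked_csv <- function(path, required, numeric_cols, schema = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (std in names(schema)) {
      if (schema[[std]] %in% names(df)) {
        names(df)[names(df) == schema[[std]]] <- std
      }
    }
  }
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop(sprintf("non-numeric value in column '%s' at row %d of %s",
                   col, bad[1], path), call. = FALSE)
    }
    df[[col]] <- v
  }
  df
}

#' Write a stage result as CSV plus a human-readable summary
#'
#' Writes the tabular form of `results` to `path` and a short text summary
#' alongside it (same name, `.txt` extension). Re-reading the CSV reproduces
#' the values as formatted. An empty result writes a header-only CSV with a
#' warning.
#'
#' @param results A data.frame (or object coercible via `as.data.frame`),
#'   e.g. an NCA, binding, partition, dose-response or efficacy summary.
#' @param path Output CSV path.
#' @param digits Significant digits retained in the CSV (default 6).
#' @return Invisibly, the path written.
#' @export
write_report <- function(results, path, digits = 6) {
  df <- as.data.frame(results)
  if (nrow(df) == 0) warning("writing empty result set: header-only CSV")
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  utils::write.csv(df, path, row.names = FALSE)
  txt <- sub("\\.csv$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  lines <- c(sprintf("neuropk report: %d record(s), %d field(s)",
                     nrow(df), ncol(df)),
             sprintf("written: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
             "", utils::capture.output(print(df)))
  writeLines(lines, txt)
  invisible(path)
}
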