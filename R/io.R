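#' Read a wide fold-change table with a sample sheet
#'
#' Reads per-protein fold-changes across the temperature gradient from a
#' wide TSV/CSV (one row per protein) together with a sample sheet that
#' declares, for each sample, its condition, replicate and the ten
#' temperature columns with their temperatures. The sample sheet is either
#' a YAML file or an already-parsed list with elements
#' `protein_id_column` and `samples` (each sample: `sample_id`,
#' `condition`, `replicate`, `columns` = list of `column`/`temperature`
#' pairs).
#'
#' Values are assumed to be fold-changes already referenced to the lowest
#' temperature; with `re_reference = TRUE` each series is divided by its
#' own lowest-temperature value instead. Empty cells and `NA` are read as
#' missing.
#'
#' @param path path to the wide data table (TSV by default; `sep` as in
#'   [utils::read.delim()]).
#' @param sample_sheet path to a YAML sample sheet, or an equivalent list.
#' @param sep field separator of the data table.
#' @param re_reference divide each series by its lowest-temperature value.
#' @return a [melt_dataset()].
#' @export
read_fold_change_table <- function(path, sample_sheet, sep = "\t",
                                   re_reference = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("data file not found: %s", path), call. = FALSE)
  }
  sheet <- if (is.character(sample_sheet)) {
    if (!file.exists(sample_sheet)) {
      stop(sprintf("sample sheet not found: %s", sample_sheet),
           call. = FALSE)
    }
    yaml::read_yaml(sample_sheet)
  } else {
    sample_sheet
  }
  id_col <- sheet$protein_id_column
  if (is.null(id_col)) {
    stop("sample sheet must name `protein_id_column`", call. = FALSE)
  }
  if (is.null(sheet$samples) || !length(sheet$samples)) {
    stop("sample sheet declares no samples", call. = FALSE)
  }

  raw <- utils::read.delim(path, sep = sep, check.names = FALSE,
                           na.strings = c("NA", ""),
                           stringsAsFactors = FALSE)
  if (!id_col %in% names(raw)) {
    stop(sprintf("missing column in data table: %s", id_col),
         call. = FALSE)
  }
  ids <- as.character(raw[[id_col]])
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate protein ID: %s",
                 ids[duplicated(ids)][1]), call. = FALSE)
  }

  samples <- data.frame(
    sample_id = vapply(sheet$samples, `[[`, "", "sample_id"),
    condition = vapply(sheet$samples, `[[`, "", "condition"),
    replicate = vapply(sheet$samples, function(s) {
      as.integer(s$replicate)
    }, 1L),
    stringsAsFactors = FALSE
  )

  # every sample must declare the same temperature grid
  temp_list <- lapply(sheet$samples, function(s) {
    vapply(s$columns, function(cc) as.numeric(cc$temperature), 1)
  })
  temperatures <- temp_list[[1]]
  for (tl in temp_list) {
    if (length(tl) != length(temperatures) ||
        any(tl != temperatures)) {
      stop("all samples must share one temperature grid", call. = FALSE)
    }
  }
  if (is.unsorted(temperatures, strictly = TRUE)) {
    stop("temperatures must be strictly ascending", call. = FALSE)
  }

  values <- array(NA_real_,
                  dim = c(length(ids), nrow(samples), length(temperatures)))
  for (s in seq_along(sheet$samples)) {
    cols <- vapply(sheet$samples[[s]]$columns, `[[`, "", "column")
    missing_cols <- setdiff(cols, names(raw))
    if (length(missing_cols)) {
      stop(sprintf("missing column in data table: %s", missing_cols[1]),
           call. = FALSE)
    }
    for (j in seq_along(cols)) {
      col <- raw[[cols[j]]]
      if (is.character(col)) {
        bad <- which(!is.na(col) & is.na(suppressWarnings(as.numeric(col))))
        if (length(bad)) {
          stop(sprintf("non-numeric value at row %d, column %s",
                       bad[1], cols[j]), call. = FALSE)
        }
        col <- as.numeric(col)
      }
      values[, s, j] <- col
    }
  }

  if (re_reference) {
    base <- values[, , 1, drop = FALSE]
    values <- values / as.vector(base)
  }

  melt_dataset(values, temperatures, samples, ids,
               provenance = list(source = path,
                                 sep = sep,
                                 re_reference = re_reference))
}

# floats are serialized at 6 significant digits so that re-runs are
# byte-identical and round-trips are exact at that documented precision
fmt_num <- function(x) {
  out <- formatC(x, digits = 6, format = "g")
  out[is.na(x)] <- ""
  out
}

#' Write a dataset as a wide TSV plus YAML sample sheet
#'
#' Inverse of [read_fold_change_table()]: columns are named
#' `<sample_id>_T<temperature>`, floats carry 6 significant digits,
#' missing values are empty cells.
#'
#' @param dataset a [melt_dataset()].
#' @param path output TSV path.
#' @param sample_sheet_path output YAML sample-sheet path (optional).
#' @return invisibly, the paths written.
#' @export
write_melt_dataset <- function(dataset, path, sample_sheet_path = NULL) {
  stopifnot(inherits(dataset, "melt_dataset"))
  tt <- dataset$temperatures
  df <- data.frame(protein_id = dataset$protein_ids,
                   stringsAsFactors = FALSE)
  sheet_samples <- list()
  for (s in seq_len(nrow(dataset$samples))) {
    sid <- dataset$samples$sample_id[s]
    cols <- sprintf("%s_T%g", sid, tt)
    for (j in seq_along(tt)) {
      df[[cols[j]]] <- fmt_num(dataset$values[, s, j])
    }
    sheet_samples[[s]] <- list(
      sample_id = sid,
      condition = dataset$samples$condition[s],
      replicate = dataset$samples$replicate[s],
      columns = lapply(seq_along(tt), function(j) {
        list(column = cols[j], temperature = tt[j])
      })
    )
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(sample_sheet_path)) {
    yaml::write_yaml(list(protein_id_column = "protein_id",
                          samples = sheet_samples),
                     sample_sheet_path)
  }
  invisible(c(path, sample_sheet_path))
}

#' Write the ground-truth manifest of a synthetic dataset
#'
#' @param truth truth data frame from [generate_dataset()].
#' @param path output TSV path.
#' @export
write_truth_manifest <- function(truth, path) {
  out <- truth
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- fmt_num(out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Validate completeness and baseline of a dataset
#'
#' Counts proteins complete in every sample and flags series whose
#' lowest-temperature fold-change deviates from the reference value 1.0 by
#' more than `baseline_tol` (such series were probably not referenced to
#' the lowest temperature, or carry a strong baseline distortion).
#'
#' @param dataset a [melt_dataset()].
#' @param baseline_tol allowed absolute deviation of the lowest-temperature
#'   value from 1.0 before a warning is recorded.
#' @return an object of class `validation_report`: totals, per-sample
#'   missingness counts and warning strings.
#' @export
validate_dataset <- function(dataset, baseline_tol = 0.1) {
  stopifnot(inherits(dataset, "melt_dataset"))
  cm <- complete_matrix(dataset)
  per_sample_missing <- colSums(!cm)
  warnings <- character(0)
  base <- dataset$values[, , 1, drop = TRUE]
  if (is.null(dim(base))) base <- matrix(base, ncol = nrow(dataset$samples))
  off <- which(abs(base - 1) > baseline_tol, arr.ind = TRUE)
  if (nrow(off)) {
    for (k in seq_len(min(nrow(off), 50))) {
      warnings <- c(warnings, sprintf(
        "series %s / %s: lowest-temperature value %.3g differs from 1.0",
        dataset$protein_ids[off[k, 1]],
        dataset$samples$sample_id[off[k, 2]],
        base[off[k, 1], off[k, 2]]))
    }
    if (nrow(off) > 50) {
      warnings <- c(warnings,
                    sprintf("... and %d more baseline deviations",
                            nrow(off) - 50))
    }
  }
  structure(
    list(n_proteins_total = length(dataset$protein_ids),
         n_complete_all_samples = sum(rowSums(cm) == ncol(cm)),
         per_sample_missing = per_sample_missing,
         warnings = warnings),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation: %d/%d proteins complete in all samples\n",
              x$n_complete_all_samples, x$n_proteins_total))
  if (length(x$warnings)) {
    cat(sprintf("  %d warnings (first: %s)\n", length(x$warnings),
                x$warnings[1]))
  }
  invisible(x)
}

#' Write the per-protein score table
#'
#' One row per protein with plateau statistics, ED components, ED score,
#' delta Tm and exclusion reason, as produced by [score_dataset()].
#'
#' @param scores score table data frame.
#' @param path output CSV path.
#' @export
write_score_table <- function(scores, path) {
  out <- scores
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- fmt_num(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a hit table to CSV
#'
#' Rows are ordered hits first (by rank, i.e. descending ED score), then
#' non-hits by descending ED score, so the ranked hit list reads from the
#' top of the file.
#'
#' @param hit_table a `hit_table` from [select_hits()].
#' @param path output CSV path.
#' @export
write_hit_table <- function(hit_table, path) {
  stopifnot(inherits(hit_table, "hit_table"))
  tab <- hit_table$table
  ord <- order(!tab$is_hit, ifelse(is.na(tab$rank), Inf, tab$rank),
               -tab$ed_score, tab$protein_id)
  out <- tab[ord, ]
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- fmt_num(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a JSON run report
#'
#' @param report named list (config echo, thresholds, stage counts,
#'   normalization factors, seed).
#' @param path output JSON path.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
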