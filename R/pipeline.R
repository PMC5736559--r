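#' Run the full thermal-shift analysis pipeline
#'
#' Orchestrates one end-to-end run: read (or simulate) the fold-change
#' dataset, validate it, normalize each run against its fitted proteome
#' melting trend, apply the plateau filters, fit per-protein melting
#' curves, compute ED scores and delta Tm, select and rank hits with the
#' median + k * MAD cutoffs, flag flat-curve hits, and write the score
#' table, hit table and a JSON run report into `out_dir`.
#'
#' Exactly one input source must be given: either `input` +
#' `sample_sheet` (paths) or `dataset` (an in-memory [melt_dataset()]) or
#' `generator` (a [generator_config()]; the synthetic dataset and its
#' truth manifest are then also written to `out_dir`).
#'
#' @param input path to a wide fold-change table (with `sample_sheet`).
#' @param sample_sheet path to the YAML sample sheet describing `input`.
#' @param dataset an in-memory [melt_dataset()].
#' @param generator a [generator_config()] to simulate from.
#' @param config an [analysis_config()].
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output and returns results in memory only.
#' @param skip_normalization analyze the input as-is (for pre-normalized
#'   tables).
#' @param fallback_identity passed to [normalize_dataset()].
#' @param re_reference passed to [read_fold_change_table()].
#' @return invisibly, a list with `dataset` (normalized), `factors`,
#'   `scores`, `fits`, `hit_table`, `truth` (generator input only) and
#'   `report` (the stage-count/threshold summary written as JSON).
#' @export
run_pipeline <- function(input = NULL, sample_sheet = NULL,
                         dataset = NULL, generator = NULL,
                         config = analysis_config(),
                         out_dir = NULL,
                         skip_normalization = FALSE,
                         fallback_identity = FALSE,
                         re_reference = FALSE) {
  n_sources <- (!is.null(input)) + (!is.null(dataset)) +
    (!is.null(generator))
  if (n_sources != 1) {
    stop("give exactly one input source: `input`, `dataset` or `generator`",
         call. = FALSE)
  }

  truth <- NULL
  seed <- NULL
  if (!is.null(generator)) {
    sim <- generate_dataset(generator)
    dataset <- sim$dataset
    truth <- sim$truth
    seed <- generator$seed
  } else if (!is.null(input)) {
    if (is.null(sample_sheet)) {
      stop("`sample_sheet` is required with `input`", call. = FALSE)
    }
    dataset <- read_fold_change_table(input, sample_sheet,
                                      re_reference = re_reference)
  }

  validation <- validate_dataset(dataset)

  if (skip_normalization) {
    factors <- NULL
    normalized <- dataset
  } else {
    norm <- normalize_dataset(dataset, fallback_identity = fallback_identity)
    normalized <- norm$dataset
    factors <- norm$factors
  }

  scored <- score_dataset(normalized, config)
  hit_table <- select_hits(scored$scores, config)
  hit_table <- flag_flat_curves(hit_table, scored$fits)

  tab <- hit_table$table
  report <- list(
    package_version = as.character(utils::packageVersion("meltshift")),
    seed = seed,
    config = unclass(config),
    generator = if (!is.null(generator)) unclass(generator),
    stage_counts = list(
      parsed = validation$n_proteins_total,
      complete_all_samples = validation$n_complete_all_samples,
      retained_after_filters = sum(tab$retained & tab$complete),
      scored = sum(!is.na(tab$ed_score)),
      with_defined_delta_tm = sum(!is.na(tab$delta_tm)),
      hits = sum(tab$is_hit),
      flat_flagged_hits = sum(tab$is_hit & tab$flat_flag)
    ),
    thresholds = hit_table$thresholds,
    normalization = if (!is.null(factors)) {
      lapply(factors, function(f) {
        list(scaling_factor = f$scaling_factor,
             normalization_factor = f$normalization_factor)
      })
    },
    validation_warnings = length(validation$warnings)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(generator)) {
      write_melt_dataset(dataset, file.path(out_dir, "dataset.tsv"),
                         file.path(out_dir, "samples.yaml"))
      write_truth_manifest(truth, file.path(out_dir, "truth.tsv"))
    }
    write_score_table(scored$scores,
                      file.path(out_dir, "score_table.csv"))
    write_hit_table(hit_table, file.path(out_dir, "hit_table.csv"))
    write_run_report(report, file.path(out_dir, "run_report.json"))
  }

  invisible(list(dataset = normalized, factors = factors,
                 scores = scored$scores, fits = scored$fits,
                 hit_table = hit_table, truth = truth, report = report))
}

#' Compare two completed runs
#'
#' Intersects the hit lists of two pipeline runs (the "commonly targeted"
#' proteins) and optionally writes the combined list as CSV. Runs over
#' different temperature grids are intersected by protein ID with a
#' warning.
#'
#' @param run_a,run_b results of [run_pipeline()] (lists carrying a
#'   `hit_table` and `dataset`).
#' @param path optional output CSV path.
#' @return the common-hit data frame from [intersect_hit_lists()].
#' @export
compare_runs <- function(run_a, run_b, path = NULL) {
  ta <- run_a$dataset$temperatures
  tb <- run_b$dataset$temperatures
  if (length(ta) != length(tb) || any(ta != tb)) {
    warning("runs use different temperature grids; intersecting by protein ID",
            call. = FALSE)
  }
  common <- intersect_hit_lists(run_a$hit_table, run_b$hit_table)
  if (!is.null(path)) {
    out <- common
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  common
}
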