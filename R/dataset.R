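#' Melting-curve dataset container
#'
#' Holds fold-change melting data for a CETSA-style experiment: a
#' proteins x samples x temperatures array of fold-changes (referenced to
#' the lowest temperature), the temperature grid, and a sample sheet
#' mapping each sample to its condition (`vehicle` or `compound`) and
#' replicate index. Missing values (`NA`) are allowed; a protein is
#' "complete" for a sample when all temperature channels are present.
#'
#' @param values numeric 3D array `[protein, sample, temperature]`.
#'   Dimnames for proteins and samples are taken from `protein_ids` and
#'   `samples$sample_id` if absent.
#' @param temperatures strictly ascending numeric vector of temperatures
#'   (degrees C), one per third array dimension.
#' @param samples data frame with columns `sample_id`, `condition`
#'   (`"vehicle"` or `"compound"`) and `replicate` (integer).
#' @param protein_ids character vector of unique protein identifiers, one
#'   per first array dimension.
#' @param provenance free-form list recording source files, parse options
#'   and transformations applied.
#' @return an object of class `melt_dataset`.
#' @export
melt_dataset <- function(values, temperatures, samples, protein_ids,
                         provenance = list()) {
  if (length(dim(values)) != 3) {
    stop("`values` must be a 3D array [protein, sample, temperature]",
         call. = FALSE)
  }
  if (anyDuplicated(protein_ids)) {
    stop("duplicate protein IDs", call. = FALSE)
  }
  if (dim(values)[1] != length(protein_ids) ||
      dim(values)[2] != nrow(samples) ||
      dim(values)[3] != length(temperatures)) {
    stop("`values` dimensions must match protein_ids, samples, temperatures",
         call. = FALSE)
  }
  if (is.unsorted(temperatures, strictly = TRUE)) {
    stop("`temperatures` must be strictly ascending", call. = FALSE)
  }
  req <- c("sample_id", "condition", "replicate")
  if (!all(req %in% names(samples))) {
    stop("`samples` must have columns sample_id, condition, replicate",
         call. = FALSE)
  }
  if (!all(samples$condition %in% c("vehicle", "compound"))) {
    stop("sample conditions must be 'vehicle' or 'compound'", call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample IDs", call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("fold-changes must be >= 0 where present", call. = FALSE)
  }
  dimnames(values) <- list(protein_ids, samples$sample_id, NULL)
  structure(
    list(values = values, temperatures = temperatures,
         samples = samples, protein_ids = protein_ids,
         provenance = provenance),
    class = "melt_dataset"
  )
}

#' @export
print.melt_dataset <- function(x, ...) {
  cat(sprintf(
    "melt_dataset: %d proteins x %d samples x %d temperatures (%.0f-%.0f C)\n",
    length(x$protein_ids), nrow(x$samples), length(x$temperatures),
    min(x$temperatures), max(x$temperatures)))
  tab <- table(x$samples$condition)
  cat("  samples:",
      paste(sprintf("%s x%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  n_missing <- sum(is.na(x$values))
  if (n_missing > 0) cat(sprintf("  %d missing values\n", n_missing))
  invisible(x)
}

#' Per-sample completeness of each protein
#'
#' @param dataset a [melt_dataset()].
#' @return logical matrix proteins x samples; `TRUE` when all temperature
#'   channels are present.
#' @export
complete_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "melt_dataset"))
  apply(!is.na(dataset$values), c(1, 2), all)
}

#' Sample IDs of one condition, ordered by replicate
#' @noRd
samples_of <- function(dataset, condition) {
  s <- dataset$samples[dataset$samples$condition == condition, ]
  s$sample_id[order(s$replicate)]
}
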