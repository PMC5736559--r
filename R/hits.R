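#' Robust median + k * MAD cutoff
#'
#' The MAD here is the raw median absolute deviation,
#' `median(|x - median(x)|)`, with no normal-consistency constant
#' (1.4826), matching the published cutoff definition; set
#' `scaled = TRUE` to use the scaled MAD for sensitivity analysis.
#'
#' @param values numeric vector; non-finite entries are dropped.
#' @param k multiplier (default 2.75).
#' @param scaled apply the 1.4826 normal-consistency constant.
#' @return list with `median`, `mad`, `cutoff = median + k * mad`, `n`.
#' @examples
#' mad_cutoff(c(1, 2, 3, 4, 100))  # median 3, mad 1, cutoff 5.75
#' @export
mad_cutoff <- function(values, k = 2.75, scaled = FALSE) {
  x <- values[is.finite(values)]
  if (!length(x)) {
    stop("need at least one finite value", call. = FALSE)
  }
  if (k <= 0) stop("`k` must be > 0", call. = FALSE)
  med <- stats::median(x)
  mad <- stats::median(abs(x - med))
  if (scaled) mad <- mad * 1.4826
  list(median = med, mad = mad, cutoff = med + k * mad, n = length(x))
}

#' Select and rank hits by ED score and delta Tm
#'
#' Computes the two robust cutoffs — median + k * MAD over the ED scores
#' of all retained, scored proteins, and the same over all defined delta
#' Tm values — and flags as hits the proteins strictly exceeding both
#' (a positive thermal shift that is both large and reproducible). Hits
#' are ranked by descending ED score; ties are broken by descending delta
#' Tm, then by protein ID, so the ranking is deterministic.
#'
#' @param scores score table from [score_dataset()] (its `scores`
#'   element).
#' @param config an [analysis_config()].
#' @return an object of class `hit_table`: list with `table` (the score
#'   table plus `passes_ed`, `passes_dtm`, `is_hit`, `rank`, `flat_flag`
#'   columns), `thresholds` (both cutoffs and their components) and
#'   `config`. Proteins that were never scored carry `NA` flags.
#' @export
select_hits <- function(scores, config = analysis_config()) {
  scored <- !is.na(scores$ed_score)
  n_scored <- sum(scored)
  if (n_scored == 0) stop("no scored proteins", call. = FALSE)
  if (n_scored < config$min_scored) {
    warning(sprintf(
      "only %d scored proteins; median + k*MAD cutoffs may be unstable",
      n_scored), call. = FALSE)
  }
  ed_cut <- mad_cutoff(scores$ed_score[scored], k = config$mad_multiplier,
                       scaled = config$scaled_mad)
  has_dtm <- scored & !is.na(scores$delta_tm)
  if (!any(has_dtm)) {
    stop("no proteins with defined delta Tm", call. = FALSE)
  }
  dtm_cut <- mad_cutoff(scores$delta_tm[has_dtm],
                        k = config$mad_multiplier,
                        scaled = config$scaled_mad)

  tab <- scores
  tab$passes_ed <- ifelse(scored, scores$ed_score > ed_cut$cutoff, NA)
  tab$passes_dtm <- ifelse(has_dtm, scores$delta_tm > dtm_cut$cutoff, NA)
  tab$is_hit <- !is.na(tab$passes_ed) & !is.na(tab$passes_dtm) &
    tab$passes_ed & tab$passes_dtm
  tab$rank <- NA_integer_
  hits <- which(tab$is_hit)
  if (length(hits)) {
    ord <- hits[order(-tab$ed_score[hits], -tab$delta_tm[hits],
                      tab$protein_id[hits])]
    tab$rank[ord] <- seq_along(ord)
  }
  tab$flat_flag <- FALSE

  structure(
    list(table = tab,
         thresholds = list(
           ed_median = ed_cut$median, ed_mad = ed_cut$mad,
           ed_cutoff = ed_cut$cutoff,
           dtm_median = dtm_cut$median, dtm_mad = dtm_cut$mad,
           dtm_cutoff = dtm_cut$cutoff,
           k = config$mad_multiplier,
           n_scored_ed = ed_cut$n, n_scored_dtm = dtm_cut$n),
         config = config),
    class = "hit_table"
  )
}

#' @export
print.hit_table <- function(x, ...) {
  th <- x$thresholds
  cat(sprintf(
    "hit_table: %d hits / %d scored (ED cutoff %.4g, dTm cutoff %.4g)\n",
    sum(x$table$is_hit), th$n_scored_ed, th$ed_cutoff, th$dtm_cutoff))
  hits <- x$table[x$table$is_hit, ]
  if (nrow(hits)) {
    hits <- hits[order(hits$rank), ]
    n_show <- min(nrow(hits), 10)
    for (i in seq_len(n_show)) {
      cat(sprintf("  %2d. %s  ED %.4g  dTm %+.2f C%s\n", hits$rank[i],
                  hits$protein_id[i], hits$ed_score[i], hits$delta_tm[i],
                  if (hits$flat_flag[i]) "  [inspect: flat]" else ""))
    }
    if (nrow(hits) > n_show) cat(sprintf("  ... %d more\n",
                                         nrow(hits) - n_show))
  }
  invisible(x)
}

#' Flag hits with flat or high-plateau control curves
#'
#' Melting curves that are flat, or that keep a high plateau at the hot
#' end of the gradient, are less likely to reflect direct binding. Hits
#' whose mean control fitted amplitude (`upper - lower`) falls below
#' `amplitude_threshold`, or whose mean control bottom plateau exceeds
#' `bottom_threshold`, receive a non-fatal "inspect manually" flag. The
#' flag never changes hit status or rank — curation is left to the
#' analyst, not automated.
#'
#' @param hit_table a [select_hits()] result.
#' @param fits per-(protein, sample) fit table from [fit_melt_curves()].
#' @param amplitude_threshold minimum control curve amplitude.
#' @param bottom_threshold maximum control bottom plateau.
#' @return the hit table with `flat_flag` updated.
#' @export
flag_flat_curves <- function(hit_table, fits, amplitude_threshold = 0.5,
                             bottom_threshold = 0.25) {
  stopifnot(inherits(hit_table, "hit_table"))
  tab <- hit_table$table
  for (i in which(tab$is_hit)) {
    f <- fits[fits$protein_id == tab$protein_id[i] &
                grepl("^vehicle", fits$sample_id) & fits$converged, ]
    if (!nrow(f)) next
    amplitude <- mean(f$upper - f$lower)
    bottom <- mean(f$lower)
    tab$flat_flag[i] <- amplitude < amplitude_threshold ||
      bottom > bottom_threshold
  }
  hit_table$table <- tab
  hit_table
}

#' Intersect two hit lists
#'
#' Proteins hit in both analyses (e.g. two compounds), each carrying its
#' rank in either list, ordered by the sum of ranks (ascending), ties by
#' protein ID — the "commonly targeted" list.
#'
#' @param a,b `hit_table` objects over comparable protein ID spaces.
#' @return data frame with `protein_id`, `rank_a`, `rank_b`, `rank_sum`.
#' @export
intersect_hit_lists <- function(a, b) {
  stopifnot(inherits(a, "hit_table"), inherits(b, "hit_table"))
  ha <- a$table[a$table$is_hit, c("protein_id", "rank")]
  hb <- b$table[b$table$is_hit, c("protein_id", "rank")]
  common <- merge(ha, hb, by = "protein_id",
                  suffixes = c("_a", "_b"))
  names(common) <- c("protein_id", "rank_a", "rank_b")
  common$rank_sum <- common$rank_a + common$rank_b
  common <- common[order(common$rank_sum, common$protein_id), ]
  rownames(common) <- NULL
  common
}
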