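#' Analysis configuration
#'
#' Houses the tunable constants of the hit-selection procedure. Defaults
#' are the published values: proteins are removed when the average control
#' fold-change over the 3 highest temperatures is not below 0.3 (no bottom
#' plateau) or the average over the 3 lowest temperatures is not above
#' 0.85 (already melting at the start of the gradient); melting points are
#' read at the 0.5 fold-change level; hit cutoffs are median + 2.75 * MAD.
#'
#' @param bottom_plateau_cutoff control average over the last 3
#'   temperatures must be strictly below this (default 0.3).
#' @param top_plateau_cutoff control average over the first 3 temperatures
#'   must be strictly above this (default 0.85).
#' @param tm_level fold-change level defining Tm (default 0.5).
#' @param mad_multiplier `k` in the median + k * MAD cutoff
#'   (default 2.75).
#' @param ed_pairing `"all_pairs"` (every treated x control replicate
#'   pair; 4 terms for 2 + 2 replicates) or `"matched_pairs"` (replicate
#'   k vs replicate k only).
#' @param curve_basis `"normalized_values"` (ED on the normalized
#'   fold-change vectors) or `"fitted_curves"` (ED on fitted LL4 curves
#'   evaluated on the grid).
#' @param scaled_mad use the 1.4826 normal-consistency constant in the MAD
#'   (default `FALSE`: raw MAD, for sensitivity analysis only).
#' @param min_scored minimum number of scored proteins below which the MAD
#'   cutoffs are flagged as unstable (warning, not error).
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(bottom_plateau_cutoff = 0.3,
                            top_plateau_cutoff = 0.85,
                            tm_level = 0.5,
                            mad_multiplier = 2.75,
                            ed_pairing = c("all_pairs", "matched_pairs"),
                            curve_basis = c("normalized_values",
                                            "fitted_curves"),
                            scaled_mad = FALSE,
                            min_scored = 50) {
  ed_pairing <- match.arg(ed_pairing)
  curve_basis <- match.arg(curve_basis)
  for (f in c("bottom_plateau_cutoff", "top_plateau_cutoff", "tm_level")) {
    v <- get(f)
    if (v <= 0 || v >= 1) {
      stop(sprintf("`%s` must be in (0, 1)", f), call. = FALSE)
    }
  }
  if (mad_multiplier <= 0) {
    stop("`mad_multiplier` must be > 0", call. = FALSE)
  }
  structure(
    list(bottom_plateau_cutoff = bottom_plateau_cutoff,
         top_plateau_cutoff = top_plateau_cutoff,
         tm_level = tm_level,
         mad_multiplier = mad_multiplier,
         ed_pairing = ed_pairing,
         curve_basis = curve_basis,
         scaled_mad = scaled_mad,
         min_scored = min_scored),
    class = "analysis_config"
  )
}

#' Euclidean distance between two melting curves
#'
#' @param u,v numeric vectors of equal length (finite).
#' @return `sqrt(sum((u - v)^2))`.
#' @examples
#' euclidean_distance(rep(0.1, 10), rep(0, 10))  # sqrt(0.1) = 0.3162...
#' @export
euclidean_distance <- function(u, v) {
  if (length(u) != length(v)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  if (any(!is.finite(u)) || any(!is.finite(v))) {
    stop("vectors must be finite", call. = FALSE)
  }
  sqrt(sum((u - v)^2))
}

#' Plateau filtering on control melting behavior
#'
#' Computes, per protein, the control (vehicle) fold-change averaged over
#' replicates at the 3 lowest and 3 highest temperatures, and flags
#' whether the protein shows a proper top plateau (average over the first
#' 3 temperatures above the cutoff; proteins already melting at the start
#' of the gradient are false-positive prone) and a proper bottom plateau
#' (average over the last 3 temperatures below the cutoff; a high bottom
#' plateau means the protein never really melted). Only proteins passing
#' both filters are retained for shift scoring.
#'
#' @param dataset a normalized [melt_dataset()].
#' @param config an [analysis_config()].
#' @return data frame, one row per protein: `protein_id`,
#'   `complete_control` (complete in every vehicle replicate),
#'   `avg_first3`, `avg_last3`, `pass_bottom`, `pass_top`, `retained`.
#' @export
plateau_filter <- function(dataset, config = analysis_config()) {
  stopifnot(inherits(dataset, "melt_dataset"))
  ctrl <- samples_of(dataset, "vehicle")
  if (!length(ctrl)) stop("dataset has no vehicle samples", call. = FALSE)
  m <- length(dataset$temperatures)
  first3 <- seq_len(3)
  last3 <- seq(m - 2, m)
  v <- dataset$values[, ctrl, , drop = FALSE]
  cm <- apply(!is.na(v), 1, all)
  # mean over control replicates then over the 3 channels
  avg_first3 <- apply(v[, , first3, drop = FALSE], 1, mean)
  avg_last3 <- apply(v[, , last3, drop = FALSE], 1, mean)
  pass_bottom <- !is.na(avg_last3) &
    avg_last3 < config$bottom_plateau_cutoff
  pass_top <- !is.na(avg_first3) &
    avg_first3 > config$top_plateau_cutoff
  data.frame(
    protein_id = dataset$protein_ids,
    complete_control = cm,
    avg_first3 = avg_first3,
    avg_last3 = avg_last3,
    pass_bottom = pass_bottom,
    pass_top = pass_top,
    retained = cm & pass_bottom & pass_top,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Thermal-shift scores for one protein
#'
#' Computes the published shift statistics from the four melting curves of
#' one protein (2 conditions x replicates):
#' * `sum_ed_inter_treatment`: sum of Euclidean distances between treated
#'   and control curves (all treated x control pairs by default) — the
#'   apparent shift signal;
#' * `sum_ed_inter_replicate`: sum of within-condition replicate distances
#'   — the noise;
#' * `ed_score = sum_ed_inter_treatment / 10^(sum_ed_inter_replicate)`,
#'   so replicate disagreement penalizes the shift signal exponentially;
#' * `delta_tm`: mean over matched replicate indices of
#'   `Tm(compound, k) - Tm(vehicle, k)` at the configured fold-change
#'   level; defined only when all four melting points are defined.
#'
#' @param vehicle_curves,compound_curves numeric matrices, one row per
#'   replicate, one column per temperature.
#' @param vehicle_tm,compound_tm numeric vectors of melting points per
#'   replicate (`NA` where undefined).
#' @param config an [analysis_config()].
#' @return list with `sum_ed_inter_treatment`, `sum_ed_inter_replicate`,
#'   `ed_score`, `delta_tm` (`NA` if any Tm undefined), `complete`.
#' @export
shift_scores <- function(vehicle_curves, compound_curves,
                         vehicle_tm, compound_tm,
                         config = analysis_config()) {
  vehicle_curves <- rbind(vehicle_curves)
  compound_curves <- rbind(compound_curves)
  if (ncol(vehicle_curves) != ncol(compound_curves)) {
    stop("curves must share one temperature grid", call. = FALSE)
  }
  complete <- !anyNA(vehicle_curves) && !anyNA(compound_curves)
  if (!complete) {
    return(list(sum_ed_inter_treatment = NA_real_,
                sum_ed_inter_replicate = NA_real_,
                ed_score = NA_real_, delta_tm = NA_real_,
                complete = FALSE))
  }
  nv <- nrow(vehicle_curves)
  nc <- nrow(compound_curves)

  sum_ed_t <- 0
  if (config$ed_pairing == "all_pairs") {
    for (i in seq_len(nc)) {
      for (j in seq_len(nv)) {
        sum_ed_t <- sum_ed_t +
          euclidean_distance(compound_curves[i, ], vehicle_curves[j, ])
      }
    }
  } else {
    for (k in seq_len(min(nc, nv))) {
      sum_ed_t <- sum_ed_t +
        euclidean_distance(compound_curves[k, ], vehicle_curves[k, ])
    }
  }

  sum_ed_r <- 0
  for (mat in list(vehicle_curves, compound_curves)) {
    nr <- nrow(mat)
    if (nr >= 2) {
      for (i in seq_len(nr - 1)) {
        for (j in seq(i + 1, nr)) {
          sum_ed_r <- sum_ed_r + euclidean_distance(mat[i, ], mat[j, ])
        }
      }
    }
  }

  ed_score <- sum_ed_t / 10^sum_ed_r

  k <- min(length(vehicle_tm), length(compound_tm))
  diffs <- compound_tm[seq_len(k)] - vehicle_tm[seq_len(k)]
  delta_tm <- if (anyNA(diffs)) NA_real_ else mean(diffs)

  list(sum_ed_inter_treatment = sum_ed_t,
       sum_ed_inter_replicate = sum_ed_r,
       ed_score = ed_score,
       delta_tm = delta_tm,
       complete = TRUE)
}

#' Score every protein of a normalized dataset
#'
#' Runs the plateau filters, fits melting curves for the retained proteins
#' (all four samples), and computes [shift_scores()] per protein. Proteins
#' failing a filter keep their plateau statistics but are not fitted or
#' scored; the `exclusion_reason` column records why a protein carries no
#' scores.
#'
#' @param dataset a normalized [melt_dataset()].
#' @param config an [analysis_config()].
#' @param fits optional precomputed [fit_melt_curves()] table covering the
#'   retained proteins (must use the same `tm_level`).
#' @return list with `scores` (data frame, one row per protein) and `fits`
#'   (the per-(protein, sample) fit table for retained proteins).
#' @export
score_dataset <- function(dataset, config = analysis_config(),
                          fits = NULL) {
  stopifnot(inherits(dataset, "melt_dataset"))
  plateau <- plateau_filter(dataset, config)
  cm <- complete_matrix(dataset)
  complete_all <- rowSums(cm) == ncol(cm)

  veh <- samples_of(dataset, "vehicle")
  cmp <- samples_of(dataset, "compound")
  if (!length(cmp)) stop("dataset has no compound samples", call. = FALSE)

  to_fit <- plateau$protein_id[plateau$retained & complete_all]
  if (is.null(fits)) {
    fits <- fit_melt_curves(dataset, proteins = to_fit,
                            tm_level = config$tm_level)
  }

  n <- length(dataset$protein_ids)
  scores <- cbind(plateau, data.frame(
    complete = complete_all,
    sum_ed_inter_treatment = NA_real_,
    sum_ed_inter_replicate = NA_real_,
    ed_score = NA_real_,
    delta_tm = NA_real_,
    tm_vehicle = NA_real_,
    tm_compound = NA_real_,
    exclusion_reason = "",
    stringsAsFactors = FALSE
  ))

  tm_of <- function(pid, sid) {
    row <- fits$protein_id == pid & fits$sample_id == sid
    if (!any(row) || !fits$tm_defined[which(row)[1]]) return(NA_real_)
    fits$tm[which(row)[1]]
  }

  curve_of <- function(pid, sid) {
    if (config$curve_basis == "normalized_values") {
      return(dataset$values[pid, sid, ])
    }
    row <- which(fits$protein_id == pid & fits$sample_id == sid)
    if (!length(row) || !fits$converged[row[1]]) {
      return(rep(NA_real_, length(dataset$temperatures)))
    }
    p <- ll4_params(fits$slope[row[1]], fits$lower[row[1]],
                    fits$upper[row[1]], fits$inflection[row[1]])
    ll4_response(p, dataset$temperatures)
  }

  for (i in seq_len(n)) {
    pid <- dataset$protein_ids[i]
    if (!scores$complete[i]) {
      scores$exclusion_reason[i] <- "incomplete replicates"
      next
    }
    if (!scores$retained[i]) {
      scores$exclusion_reason[i] <- if (!scores$pass_bottom[i]) {
        "high bottom plateau"
      } else {
        "no top plateau (melting at start)"
      }
      next
    }
    vc <- do.call(rbind, lapply(veh, function(s) curve_of(pid, s)))
    cc <- do.call(rbind, lapply(cmp, function(s) curve_of(pid, s)))
    vtm <- vapply(veh, function(s) tm_of(pid, s), 1)
    ctm <- vapply(cmp, function(s) tm_of(pid, s), 1)
    ss <- shift_scores(vc, cc, vtm, ctm, config)
    scores$sum_ed_inter_treatment[i] <- ss$sum_ed_inter_treatment
    scores$sum_ed_inter_replicate[i] <- ss$sum_ed_inter_replicate
    scores$ed_score[i] <- ss$ed_score
    scores$delta_tm[i] <- ss$delta_tm
    scores$tm_vehicle[i] <- mean(vtm)
    scores$tm_compound[i] <- mean(ctm)
    if (is.na(ss$delta_tm)) {
      scores$exclusion_reason[i] <- "undefined Tm (excluded from dTm cutoff)"
    }
  }
  list(scores = scores, fits = fits)
}
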