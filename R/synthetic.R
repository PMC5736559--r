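#' Configuration for the synthetic CETSA dataset generator
#'
#' Defines the study conditions the generator emulates: a proteome of
#' `n_proteins` melting over a 10-point temperature gradient, measured in
#' `n_replicates` fully independent replicates per condition (vehicle and
#' compound), with a minority of `n_targets` proteins thermally stabilized
#' by the compound, plus non-melters (high bottom plateau), early melters
#' (already denaturing at the lowest temperatures), run-level baseline
#' distortions and additive measurement noise.
#'
#' Class membership (melter / non-melter / early-melter) is assigned
#' deterministically by quota: `floor(frac * n_proteins)` proteins per
#' class, placed by a seeded shuffle, so that filter-count expectations are
#' exact rather than binomial. Targets are drawn from the melter class.
#'
#' @param n_proteins number of proteins.
#' @param n_targets number of true targets (thermally shifted under
#'   compound); must not exceed the melter-class quota.
#' @param temperatures strictly ascending 10-point temperature grid
#'   (degrees C). Default 37-64 C in 3 C steps.
#' @param n_replicates replicates per condition (default 2).
#' @param tm_distribution `c(mean, sd)` in degrees C for baseline
#'   inflection temperatures.
#' @param slope_distribution `c(mean, sd)` for LL4 slopes (positive =
#'   decreasing curve).
#' @param target_delta_tm `c(mean, sd)` in degrees C for compound-induced
#'   inflection shifts of targets; draws are rejected until positive
#'   (positive = stabilization).
#' @param frac_non_melters fraction of proteins with bottom plateau >= 0.35
#'   (these fail the bottom-plateau filter).
#' @param frac_early_melters fraction of proteins already melting at the
#'   lowest temperatures (top-plateau average <= 0.82; these fail the
#'   top-plateau filter).
#' @param noise_sd additive Gaussian noise sd on the fold-change scale;
#'   values are clipped at 0 after noise.
#' @param run_baseline_distortion amplitude of the per-run multiplicative
#'   bias profile (baseline offset plus linear-in-temperature-index tilt);
#'   0 disables distortion exactly.
#' @param seed integer RNG seed; the same seed and config give a
#'   byte-identical dataset.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_proteins = 1000,
                             n_targets = 20,
                             temperatures = seq(37, 64, by = 3),
                             n_replicates = 2,
                             tm_distribution = c(mean = 50, sd = 5),
                             slope_distribution = c(mean = 10, sd = 2),
                             target_delta_tm = c(mean = 4, sd = 1),
                             frac_non_melters = 0.1,
                             frac_early_melters = 0.05,
                             noise_sd = 0.02,
                             run_baseline_distortion = 0.05,
                             seed = 1L) {
  bad <- function(field, why) {
    stop(sprintf("invalid generator config: `%s` %s", field, why),
         call. = FALSE)
  }
  if (n_proteins < 1) bad("n_proteins", "must be >= 1")
  if (n_targets < 0) bad("n_targets", "must be >= 0")
  if (n_targets > n_proteins) bad("n_targets", "must be <= n_proteins")
  if (length(temperatures) != 10) bad("temperatures", "must have 10 entries")
  if (is.unsorted(temperatures, strictly = TRUE)) {
    bad("temperatures", "must be strictly ascending")
  }
  if (any(temperatures <= 0)) bad("temperatures", "must be positive")
  if (n_replicates < 1) bad("n_replicates", "must be >= 1")
  for (f in c("frac_non_melters", "frac_early_melters")) {
    v <- get(f)
    if (v < 0 || v > 1) bad(f, "must be in [0, 1]")
  }
  if (frac_non_melters + frac_early_melters > 1) {
    bad("frac_non_melters", "+ frac_early_melters must be <= 1")
  }
  n_nm <- floor(frac_non_melters * n_proteins)
  n_em <- floor(frac_early_melters * n_proteins)
  if (n_targets > n_proteins - n_nm - n_em) {
    bad("n_targets", "exceeds the melter-class quota")
  }
  if (noise_sd < 0) bad("noise_sd", "must be >= 0")
  if (run_baseline_distortion < 0) {
    bad("run_baseline_distortion", "must be >= 0")
  }
  if (tm_distribution[[2]] < 0) bad("tm_distribution", "sd must be >= 0")
  if (slope_distribution[[1]] <= 0) {
    bad("slope_distribution", "mean must be > 0 (decreasing curves)")
  }
  if (target_delta_tm[[2]] < 0) bad("target_delta_tm", "sd must be >= 0")
  structure(
    list(n_proteins = as.integer(n_proteins),
         n_targets = as.integer(n_targets),
         temperatures = as.numeric(temperatures),
         n_replicates = as.integer(n_replicates),
         tm_distribution = as.numeric(tm_distribution),
         slope_distribution = as.numeric(slope_distribution),
         target_delta_tm = as.numeric(target_delta_tm),
         frac_non_melters = frac_non_melters,
         frac_early_melters = frac_early_melters,
         noise_sd = noise_sd,
         run_baseline_distortion = run_baseline_distortion,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Upper plateau d such that the LL4 curve equals exactly 1.0 at the lowest
# temperature: with A = 1/(1 + exp(b (ln T0 - ln e))), solving
# c + (d - c) A = 1 gives d = c + (1 - c)/A. Keeps the series equal to its
# generating curve while anchoring the fold-change reference at 1.
upper_for_unit_baseline <- function(slope, lower, inflection, t0) {
  a <- 1 / (1 + exp(slope * (log(t0) - log(inflection))))
  lower + (1 - lower) / a
}

# Draw one protein's control-curve parameters by rejection sampling so the
# class contract holds exactly on zero-noise data: melters pass both
# plateau filters with margin, non-melters fail only the bottom filter,
# early melters fail only the top filter. Margins (0.88 / 0.27 / 0.82)
# leave headroom around the 0.85 / 0.3 cutoffs so normalization wobble
# cannot flip a class across a filter.
draw_class_params <- function(class, config) {
  tt <- config$temperatures
  t0 <- tt[1]
  first3 <- seq_len(3)
  last3 <- seq(length(tt) - 2, length(tt))
  tm_mean <- config$tm_distribution[1]
  tm_sd <- config$tm_distribution[2]
  sl_mean <- config$slope_distribution[1]
  sl_sd <- config$slope_distribution[2]
  for (i in seq_len(10000)) {
    if (class == "early_melter") {
      slope <- stats::runif(1, 8, 15)
      inflection <- stats::runif(1, t0 + 0.5, t0 + 4)
      lower <- stats::runif(1, 0, 0.15)
    } else {
      slope <- stats::rnorm(1, sl_mean, sl_sd)
      inflection <- stats::rnorm(1, tm_mean, tm_sd)
      lower <- if (class == "non_melter") {
        stats::runif(1, 0.35, 0.6)
      } else {
        stats::runif(1, 0, 0.15)
      }
      if (slope < 4 || inflection <= t0) next
    }
    upper <- upper_for_unit_baseline(slope, lower, inflection, t0)
    p <- ll4_params(slope, lower, upper, inflection)
    y <- ll4_response(p, tt)
    avg_first3 <- mean(y[first3])
    avg_last3 <- mean(y[last3])
    ok <- switch(class,
      melter = avg_first3 >= 0.88 && avg_last3 <= 0.27,
      non_melter = avg_first3 >= 0.88 && avg_last3 >= 0.35,
      early_melter = avg_first3 <= 0.82 && avg_last3 <= 0.27)
    if (ok) return(p)
  }
  stop(sprintf("could not draw %s-class parameters under this config",
               class), call. = FALSE)
}

#' Generate a synthetic CETSA dataset with known ground truth
#'
#' Builds one fold-change series per (protein, condition, replicate) on the
#' configured temperature grid. Each series is its protein's generating LL4
#' curve evaluated on the grid (exactly 1.0 at the lowest temperature by
#' construction), then multiplied by a per-run smooth distortion profile
#' and perturbed by additive Gaussian noise clipped at 0. Target proteins'
#' compound-condition curves use `inflection + true_delta_tm` with the
#' upper plateau re-anchored to 1.0 at the lowest temperature.
#'
#' @param config a [generator_config()].
#' @return list with elements `dataset` (a [melt_dataset()]) and `truth`
#'   (data frame, one row per protein: `protein_id`, `is_target`, `class`,
#'   `true_slope`, `true_lower`, `true_tm_vehicle` (vehicle inflection, C),
#'   `true_delta_tm` (inflection shift, 0 for non-targets),
#'   `true_upper_vehicle`, `true_upper_compound`, and the exact
#'   0.5-fold-change crossings `true_tm05_vehicle` / `true_tm05_compound`
#'   of the generating curves, `NA` where the curve never crosses 0.5).
#' @examples
#' sim <- generate_dataset(generator_config(n_proteins = 50, n_targets = 3,
#'                                          seed = 1))
#' sim$dataset
#' table(sim$truth$class)
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "generator_config")) {
    stop("`config` must be a generator_config", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(config$seed)

  n <- config$n_proteins
  tt <- config$temperatures
  m <- length(tt)
  ids <- sprintf("P%05d", seq_len(n))

  # deterministic class quotas via a seeded shuffle
  n_nm <- floor(config$frac_non_melters * n)
  n_em <- floor(config$frac_early_melters * n)
  perm <- sample.int(n)
  class <- rep("melter", n)
  class[perm[seq_len(n_nm)]] <- "non_melter"
  if (n_em > 0) class[perm[n_nm + seq_len(n_em)]] <- "early_melter"
  melters <- which(class == "melter")
  targets <- sort(melters[sample.int(length(melters), config$n_targets)])
  is_target <- seq_len(n) %in% targets

  samples <- data.frame(
    sample_id = c(sprintf("vehicle_r%d", seq_len(config$n_replicates)),
                  sprintf("compound_r%d", seq_len(config$n_replicates))),
    condition = rep(c("vehicle", "compound"), each = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), times = 2),
    stringsAsFactors = FALSE
  )
  ns <- nrow(samples)

  # per-run multiplicative bias: a constant baseline offset of up to the
  # full amplitude (the removable run-level signal the scaling factor
  # corrects) times a smooth linear-in-temperature-index drift at a fifth
  # of the amplitude (kept small because a strong tilt is not removable
  # by per-run fit-and-anchor normalization); exactly 1 when amplitude 0
  a <- config$run_baseline_distortion
  distortion <- matrix(1, nrow = ns, ncol = m)
  if (a > 0) {
    for (s in seq_len(ns)) {
      v <- stats::runif(1, -1, 1)
      u <- stats::runif(1, -1, 1)
      distortion[s, ] <- (1 + a * v) *
        (1 + (a / 5) * u * (seq_len(m) - 1) / (m - 1))
    }
  }

  truth <- data.frame(
    protein_id = ids, is_target = is_target, class = class,
    true_slope = NA_real_, true_lower = NA_real_,
    true_tm_vehicle = NA_real_, true_delta_tm = 0,
    true_upper_vehicle = NA_real_, true_upper_compound = NA_real_,
    true_tm05_vehicle = NA_real_, true_tm05_compound = NA_real_,
    stringsAsFactors = FALSE
  )

  values <- array(NA_real_, dim = c(n, ns, m),
                  dimnames = list(ids, samples$sample_id, NULL))
  d_mean <- config$target_delta_tm[1]
  d_sd <- config$target_delta_tm[2]

  for (i in seq_len(n)) {
    pv <- draw_class_params(class[i], config)
    delta <- 0
    pc <- pv
    if (is_target[i]) {
      repeat {
        delta <- stats::rnorm(1, d_mean, d_sd)
        if (delta > 0) break
      }
      e_c <- pv$inflection + delta
      pc <- ll4_params(pv$slope, pv$lower,
                       upper_for_unit_baseline(pv$slope, pv$lower, e_c,
                                               tt[1]),
                       e_c)
    }
    truth$true_slope[i] <- pv$slope
    truth$true_lower[i] <- pv$lower
    truth$true_tm_vehicle[i] <- pv$inflection
    truth$true_delta_tm[i] <- delta
    truth$true_upper_vehicle[i] <- pv$upper
    truth$true_upper_compound[i] <- pc$upper
    truth$true_tm05_vehicle[i] <- melting_point(pv)$tm
    truth$true_tm05_compound[i] <- melting_point(pc)$tm
    yv <- ll4_response(pv, tt)
    yc <- ll4_response(pc, tt)
    for (s in seq_len(ns)) {
      base <- if (samples$condition[s] == "vehicle") yv else yc
      values[i, s, ] <- base * distortion[s, ]
    }
  }

  if (config$noise_sd > 0) {
    values <- values + stats::rnorm(length(values), 0, config$noise_sd)
    values <- pmax(values, 0)
  }

  dataset <- melt_dataset(values, tt, samples, ids,
                          provenance = list(generator = unclass(config)))
  list(dataset = dataset, truth = truth)
}
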