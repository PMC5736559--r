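# Independent oracles and small fixtures shared across tests.

# naive per-coordinate loop, independent of euclidean_distance()
naive_euclidean <- function(u, v) {
  s <- 0
  for (i in seq_along(u)) s <- s + (u[i] - v[i])^2
  sqrt(s)
}

# numeric root of ll4_response(T) = level, independent of the closed form
bisect_tm <- function(params, level = 0.5) {
  f <- function(tt) ll4_response(params, tt) - level
  stats::uniroot(f, interval = c(params$inflection * 1e-3,
                                 params$inflection * 1e3),
                 tol = 1e-12, maxiter = 2000)$root
}

# sort-based median, independent of stats::median
sort_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

default_grid <- seq(37, 64, by = 3)

# tiny hand-built dataset: `curves` is a list of per-sample value matrices
# (proteins x temperatures) or a function(condition, replicate) -> matrix
make_dataset <- function(curves, ids, temperatures = default_grid,
                         n_replicates = 2) {
  samples <- data.frame(
    sample_id = c(sprintf("vehicle_r%d", seq_len(n_replicates)),
                  sprintf("compound_r%d", seq_len(n_replicates))),
    condition = rep(c("vehicle", "compound"), each = n_replicates),
    replicate = rep(seq_len(n_replicates), 2),
    stringsAsFactors = FALSE)
  values <- array(NA_real_, dim = c(length(ids), nrow(samples),
                                    length(temperatures)))
  for (s in seq_len(nrow(samples))) {
    values[, s, ] <- curves(samples$condition[s], samples$replicate[s])
  }
  melt_dataset(values, temperatures, samples, ids)
}

# melter-like LL4 curve anchored at 1.0 at the lowest temperature
unit_curve <- function(slope, lower, inflection,
                       temperatures = default_grid) {
  a <- 1 / (1 + exp(slope * (log(temperatures[1]) - log(inflection))))
  upper <- lower + (1 - lower) / a
  ll4_response(ll4_params(slope, lower, upper, inflection), temperatures)
}
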