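test_that("MAD cutoff matches hand computations", {
  hc <- mad_cutoff(c(1, 2, 3, 4, 100), k = 2.75)
  expect_equal(hc$median, 3)
  expect_equal(hc$mad, 1)
  expect_equal(hc$cutoff, 5.75)

  expect_equal(mad_cutoff(c(-1, 0, 1), k = 2.75)$cutoff, 2.75)

  # constant vector: MAD 0, cutoff equals the constant
  cc <- mad_cutoff(rep(7, 20))
  expect_equal(cc$mad, 0)
  expect_equal(cc$cutoff, 7)

  expect_equal(mad_cutoff(c(1, 2, 3), k = 2, scaled = TRUE)$cutoff,
               2 + 2 * 1.4826)
  expect_error(mad_cutoff(numeric(0)), "at least one")
  expect_error(mad_cutoff(c(NA, NaN)), "at least one")
})

test_that("a null dataset yields exactly zero hits", {
  sim <- generate_dataset(generator_config(n_proteins = 100, n_targets = 0,
                                           noise_sd = 0,
                                           run_baseline_distortion = 0,
                                           seed = 37))
  out <- score_dataset(sim$dataset)
  ht <- select_hits(out$scores)
  expect_equal(sum(ht$table$is_hit), 0)
  expect_equal(ht$thresholds$ed_cutoff, 0)
  expect_equal(ht$thresholds$dtm_cutoff, 0)
})

test_that("hits strictly exceed both cutoffs and are ranked by ED score", {
  sim <- generate_dataset(generator_config(n_proteins = 300, n_targets = 12,
                                           seed = 39))
  out <- score_dataset(normalize_dataset(sim$dataset)$dataset)
  ht <- select_hits(out$scores)
  tab <- ht$table
  th <- ht$thresholds
  hits <- tab[tab$is_hit, ]
  expect_gt(nrow(hits), 0)
  expect_true(all(hits$ed_score > th$ed_cutoff))
  expect_true(all(hits$delta_tm > th$dtm_cutoff))
  ranked <- hits[order(hits$rank), ]
  expect_equal(ranked$rank, seq_len(nrow(ranked)))
  expect_true(all(diff(ranked$ed_score) <= 0))
  # cutoffs never fall below the medians (k > 0, MAD >= 0)
  expect_gte(th$ed_cutoff, th$ed_median)
  expect_gte(th$dtm_cutoff, th$dtm_median)
})

test_that("equal ED scores break ties by delta Tm then protein ID", {
  scores <- data.frame(
    protein_id = c("P3", "P1", "P2", sprintf("N%02d", 1:60)),
    retained = TRUE, complete = TRUE,
    ed_score = c(5, 5, 5, rep(0.01, 60)),
    delta_tm = c(2, 3, 3, rep(0.001, 60)),
    stringsAsFactors = FALSE)
  ht <- select_hits(scores)
  hits <- ht$table[ht$table$is_hit, ]
  expect_equal(hits$protein_id[order(hits$rank)], c("P1", "P2", "P3"))
})

test_that("raising k never increases the number of hits", {
  sim <- generate_dataset(generator_config(n_proteins = 300, n_targets = 12,
                                           seed = 53))
  out <- score_dataset(normalize_dataset(sim$dataset)$dataset)
  counts <- vapply(c(1, 2, 2.75, 4, 6), function(k) {
    sum(select_hits(out$scores,
                    analysis_config(mad_multiplier = k))$table$is_hit)
  }, 1)
  expect_true(all(diff(counts) <= 0))
})

test_that("median and MAD resist 10% contamination", {
  set.seed(59)
  null_scores <- rnorm(200, 0.2, 0.02)
  clean <- mad_cutoff(null_scores)
  contaminated <- c(null_scores[1:180], rep(1e6, 20))
  dirty <- mad_cutoff(contaminated)
  expect_lt(abs(dirty$median - clean$median), 0.01)
  expect_lt(abs(dirty$mad - clean$mad), 0.01)
})

test_that("few scored proteins triggers an instability warning", {
  scores <- data.frame(protein_id = sprintf("P%d", 1:10),
                       retained = TRUE, complete = TRUE,
                       ed_score = runif(10), delta_tm = rnorm(10))
  expect_warning(select_hits(scores), "unstable")
})

test_that("flat-curve flags annotate hits without changing ranks", {
  sim <- generate_dataset(generator_config(n_proteins = 200, n_targets = 10,
                                           seed = 61))
  out <- score_dataset(normalize_dataset(sim$dataset)$dataset)
  ht <- select_hits(out$scores)
  flagged <- flag_flat_curves(ht, out$fits)
  expect_identical(flagged$table$is_hit, ht$table$is_hit)
  expect_identical(flagged$table$rank, ht$table$rank)
  # healthy melters (amplitude ~1, bottom < 0.15) are unflagged
  expect_false(any(flagged$table$flat_flag))

  # force a shallow control fit for the top hit: flag raised
  top <- flagged$table$protein_id[which(flagged$table$rank == 1)]
  fits2 <- out$fits
  rows <- fits2$protein_id == top & grepl("^vehicle", fits2$sample_id)
  fits2$upper[rows] <- fits2$lower[rows] + 0.3
  reflagged <- flag_flat_curves(ht, fits2)
  expect_true(reflagged$table$flat_flag[reflagged$table$protein_id == top])
  expect_identical(reflagged$table$rank, ht$table$rank)
})

test_that("hit-list intersection carries both ranks, ordered by rank sum", {
  mk <- function(ids, ranks, all_ids) {
    tab <- data.frame(protein_id = all_ids,
                      ed_score = 0, delta_tm = 0,
                      is_hit = all_ids %in% ids,
                      rank = NA_integer_, flat_flag = FALSE,
                      stringsAsFactors = FALSE)
    tab$rank[match(ids, tab$protein_id)] <- ranks
    structure(list(table = tab, thresholds = list(),
                   config = analysis_config()), class = "hit_table")
  }
  all_ids <- sprintf("P%d", 1:6)
  a <- mk(c("P1", "P2", "P3"), 1:3, all_ids)
  b <- mk(c("P2", "P3", "P4"), c(2, 1, 3), all_ids)
  common <- intersect_hit_lists(a, b)
  # rank sums tie at 4 (2+2 and 3+1); tie broken by protein ID
  expect_equal(common$protein_id, c("P2", "P3"))
  expect_equal(common$rank_sum, c(4, 4))
  expect_equal(intersect_hit_lists(a, a)$protein_id, c("P1", "P2", "P3"))
  expect_equal(nrow(intersect_hit_lists(a, mk("P6", 1, all_ids))), 0)
})
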