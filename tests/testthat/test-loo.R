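# a hand-built 4-record library: query q plus refs at controlled distances
loo_fixture <- function() {
  w <- 100
  base <- strrep("A", w)
  mutate_at <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    ch[seq_len(k)] <- "G"
    paste(ch, collapse = "")
  }
  make_library(
    ids  = c("q", "same_bin", "near", "far"),
    seqs = c(base, mutate_at(base, 1), mutate_at(base, 5), mutate_at(base, 20)),
    bins = c("B1", "B1", "B2", "B3"),
    orders = c("O1", "O1", "O1", "O2"),
    families = c("F1", "F1", "F1", "F2"))
}

test_that("top hit respects the exclusion divergence and similarity ranking", {
  lib <- loo_fixture()
  D <- distance_matrix(lib)
  # exclusion 2%: the 1% same-BIN neighbour is skipped, the 5% ref wins
  hit <- top_hit("q", lib, D, loo_config(exclusion_div = 0.02))
  expect_equal(hit$hit_id, "near")
  expect_equal(hit$similarity, 95)
  # exclusion 0 + only self excluded: global nearest neighbour
  hit0 <- top_hit("q", lib, D, loo_config(exclusion_div = 0))
  expect_equal(hit0$hit_id, "same_bin")
  # no eligible candidate -> NULL
  expect_null(top_hit("q", lib, D, loo_config(exclusion_div = 0.5)))
  expect_error(top_hit("nope", lib, D), "unknown")
})

test_that("hits with insufficient overlap are ineligible", {
  w <- 100
  lib <- make_library(
    ids = c("q", "short"),
    seqs = c(strrep("A", w), paste0(strrep("G", 30), strrep("-", w - 30))),
    bins = c("B1", "B2"), families = c("F1", "F2"))
  D <- distance_matrix(lib)
  expect_null(top_hit("q", lib, D, loo_config(exclusion_div = 0)))   # 30% overlap < 50%
  hit <- top_hit("q", lib, D, loo_config(exclusion_div = 0, min_overlap_frac = 0.3))
  expect_equal(hit$hit_id, "short")
})

test_that("equal-similarity ties resolve to the smallest id", {
  w <- 50
  mut <- function(k) paste0(strrep("G", k), strrep("A", w - k))
  lib <- make_library(c("q", "zz", "aa"), c(strrep("A", w), mut(5), mut(5)),
                      bins = c("B1", "B2", "B3"))
  D <- distance_matrix(lib)
  expect_equal(top_hit("q", lib, D, loo_config(0))$hit_id, "aa")
})

test_that("top_hit with exclusion 0 equals a brute-force nearest-neighbour scan", {
  withr::local_seed(31)
  lib <- random_library(20, width = 60, gap_rate = 0, ambig_rate = 0)
  D <- distance_matrix(lib)
  cfg <- loo_config(exclusion_div = 0, min_overlap_frac = 0.01)
  for (i in seq_len(nrow(lib))) {
    d <- D$d[i, ]; d[i] <- NA
    # oracle: smallest distance, ties by C-locale id order
    ord <- order(d, rank(lib$id))
    want <- lib$id[ord[1]]
    got <- top_hit(lib$id[i], lib, D, cfg)
    # queries identical to another sequence have d = 0 which is not > 0;
    # the oracle skips those the same way
    eligible <- which(!is.na(d) & d > 0)
    if (length(eligible) > 0) {
      want <- lib$id[eligible[order(d[eligible], rank(lib$id[eligible]))[1]]]
      expect_equal(got$hit_id, want)
    }
  }
})

test_that("raising the exclusion divergence never increases top-hit similarity", {
  withr::local_seed(32)
  lib <- generate_library(synthetic_config(n_orders = 2, families_per_order = 3,
                                           bins_per_family = 3, seqs_per_bin = 2,
                                           seed = 5))$library
  D <- distance_matrix(lib)
  sims <- sapply(c(0, 0.02, 0.05, 0.10), function(e) {
    r <- loo_identify(lib, loo_config(e), D = D)
    r$similarity
  })
  for (k in 2:ncol(sims)) {
    comparable <- !is.na(sims[, k]) & !is.na(sims[, k - 1])
    expect_true(all(sims[comparable, k] <= sims[comparable, k - 1]))
  }
})

test_that("loo_identify scores correctness at both ranks", {
  lib <- loo_fixture()
  res <- loo_identify(lib, loo_config(0.02))
  expect_s3_class(res, "identification_results")
  expect_equal(nrow(res), 4L)
  q <- res[res$query_id == "q", ]
  expect_true(q$correct_order && q$correct_family)
  # 'far' (sole member of F2/O2) must hit an F1 record: wrong at both ranks
  far <- res[res$query_id == "far", ]
  expect_false(far$correct_family)
  expect_false(far$correct_order)
  expect_error(loo_identify(lib[1, ]), "at least 2")
})

test_that("two records in different orders misidentify each other", {
  lib <- make_library(c("a", "b"), c(strrep("A", 50), strrep("G", 50)),
                      bins = c("B1", "B2"), orders = c("O1", "O2"),
                      families = c("F1", "F2"))
  res <- loo_identify(lib, loo_config(0))
  expect_equal(res$predicted_order, c("O2", "O1"))
  expect_false(any(res$correct_order))
})

test_that("success summaries conserve counts between global and grouped forms", {
  withr::local_seed(33)
  lib <- generate_library(synthetic_config(n_orders = 3, families_per_order = 2,
                                           bins_per_family = 3, seqs_per_bin = 1,
                                           seed = 6))$library
  res <- loo_identify(lib, loo_config(0.02))
  all_tab <- summarize_success(res, by = "all")
  ord_tab <- summarize_success(res, by = "order")
  expect_equal(sum(ord_tab$n_queries), all_tab$n_queries)
  expect_equal(sum(ord_tab$n_assigned), all_tab$n_assigned)
  expect_equal(sum(ord_tab$n_unassignable), all_tab$n_unassignable)
  # perfect fixture: every family has >= 3 BINs within reach
  expect_equal(all_tab$family_success_pct, 100)
})

test_that("unassignable queries are counted separately, not as failures", {
  w <- 60
  lib <- make_library(c("a", "b", "c"), rep(strrep("A", w), 3),
                      bins = c("B1", "B2", "B3"),
                      families = c("F1", "F1", "F2"))
  # all records are identical: no candidate strictly exceeds any exclusion
  res <- loo_identify(lib, loo_config(0))
  expect_true(all(is.na(res$hit_id)))
  tab <- summarize_success(res)
  expect_equal(tab$n_unassignable, 3L)
  expect_equal(tab$n_assigned, 0L)
})
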