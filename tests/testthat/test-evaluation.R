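test_that("roc_auc_and_recall handles perfect, random and degenerate calls", {
  calls <- data.frame(
    mutation_id = sprintf("m%02d", 1:10),
    score = c(6:10, 1:5),
    category = c(rep("driver", 5), rep("passenger", 5)),
    confidence = 0.1, stringsAsFactors = FALSE
  )
  truth <- setNames(c(rep("driver", 5), rep("passenger", 5)),
                    calls$mutation_id)
  ev <- roc_auc_and_recall(calls, truth)
  expect_equal(ev$auc, 1.0)
  expect_equal(ev$recall, 1.0)

  none <- calls; none$category <- "no-call"
  expect_equal(roc_auc_and_recall(none, truth)$recall, 0)

  withr::with_seed(4, {
    n <- 2000
    rnd <- data.frame(mutation_id = sprintf("r%04d", 1:n),
                      score = rnorm(n), category = "no-call",
                      confidence = NA_real_, stringsAsFactors = FALSE)
    rtruth <- setNames(sample(c("driver", "passenger"), n, replace = TRUE),
                       rnd$mutation_id)
    expect_lt(abs(roc_auc_and_recall(rnd, rtruth)$auc - 0.5), 0.05)
  })

  onec <- setNames(rep("driver", 10), calls$mutation_id)
  expect_warning(ev1 <- roc_auc_and_recall(calls, onec), "single class")
  expect_true(is.na(ev1$auc))
  expect_equal(ev1$recall, 0.5)
})

test_that("prevalence correlation matches the textbook formula", {
  expect_equal(prevalence_correlation(1:5, 2 * (1:5) + 3), 1.0)
  expect_equal(prevalence_correlation(1:5, -(1:5)), -1.0)
  x <- c(1, 2, 3, 4); y <- c(1, 2, 2, 5)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(prevalence_correlation(x, y), r_oracle)
  expect_error(prevalence_correlation(c(2, 2, 2), 1:3), "constant")
  expect_error(prevalence_correlation(1:2, 1:2), "3 points")
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  expect_equal(enrichment_pvalue(10, 5, 5, 0), 1.0)
  expect_equal(enrichment_pvalue(10, 5, 5, 5), 1 / 252)
  withr::with_seed(6, {
    for (i in 1:40) {
      N <- sample(5:25, 1); K <- sample.int(N, 1); n <- sample.int(N, 1)
      k <- sample(max(0, K + n - N):min(K, n), 1)
      expect_equal(enrichment_pvalue(N, K, n, k), oracle_hyper(N, K, n, k),
                   tolerance = 1e-12)
    }
  })
  expect_error(enrichment_pvalue(10, 11, 5, 2), "invalid")
  expect_error(enrichment_pvalue(10, 5, 5, 6), "invalid")
})

test_that("score-group comparison behaves at the extremes", {
  expect_gt(compare_score_groups(1:20, 1:20), 0.9)
  expect_lt(compare_score_groups(101:120, 1:20), 1e-6)
  expect_equal(compare_score_groups(1, 2), 1.0)
  expect_error(compare_score_groups(numeric(), 1:3), "non-empty")
})

test_that("rare mutations are isolated singletons outside the training sets", {
  cat_ <- bind_catalog(
    cat_row("r1", "GA", 100, "S1"),                 # rare
    cat_row("r2", "GB", 5000, "S2"),                # rare but excluded below
    cat_row("n1", "GC", 9000, "S3"),                # neighbour 2 bp away
    cat_row("n2", "GC", 9002, "S4"),
    cat_row("d1", "GD", 20000, "S5"),               # recurrent variant
    cat_row("d2", "GD", 20000, "S6")
  )
  expect_setequal(find_rare_mutations(cat_), c("r1", "r2"))
  expect_equal(find_rare_mutations(cat_, exclude = "r2"), "r1")
  # a narrower vicinity frees the 2 bp-apart neighbours
  expect_setequal(find_rare_mutations(cat_, window_bp = 1),
                  c("r1", "r2", "n1", "n2"))
})

test_that("panel enrichment assembles hypergeometric counts from calls", {
  calls <- data.frame(
    mutation_id = sprintf("m%02d", 1:10),
    score = 1:10,
    category = c(rep("driver", 4), rep("no-call", 6)),
    confidence = NA_real_, stringsAsFactors = FALSE
  )
  genes <- setNames(c(rep("EGFR", 3), rep("XG", 7)), calls$mutation_id)
  en <- panel_enrichment(calls, genes, gene_list("EGFR"))
  expect_equal(en[c("N", "K", "n", "k")], list(N = 10, K = 4, n = 3, k = 3))
  expect_equal(en$p_value, oracle_hyper(10, 4, 3, 3))
  expect_equal(en$panel_fraction, 1.0)
})
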