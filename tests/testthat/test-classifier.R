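toy_model <- function(seed = 1, n = 60, effect = 3) {
  st <- make_study(fixture_spec(n_drivers = n, n_passengers = 2 * n,
                                n_features = 3, n_informative = 2,
                                effect_size = effect, seed = seed))
  list(st = st,
       model = train_model(st$table, st$labels, c("inf01", "inf02")))
}

test_that("class weights are inverse frequency normalised to mean one", {
  expect_equal(unname(class_weights(c(rep("driver", 10),
                                      rep("passenger", 10)))), c(1, 1))
  w <- class_weights(c(driver = 1768, passenger = 8075))
  expect_equal(unname(w["driver"] / w["passenger"]), 8075 / 1768)
  expect_equal(mean(w * c(1768, 8075) / sum(c(1768, 8075)) * 2), 1)
})

test_that("a separable toy problem trains to AUC 1 with driver-high scores", {
  withr::with_seed(12, {
    n <- 60
    m <- cbind(a = c(runif(n, 3, 4), runif(2 * n, 0, 1)),
               b = c(runif(n, 3, 4), runif(2 * n, 0, 1)))
    rownames(m) <- sprintf("m%03d", seq_len(3 * n))
  })
  labels <- setNames(c(rep("driver", 60), rep("passenger", 120)),
                     rownames(m))
  model <- train_model(feature_table(m), labels, c("a", "b"))
  s <- score_mutations(model, feature_table(m))
  expect_equal(feature_auc(s[labels == "driver"], s[labels == "passenger"]),
               1.0)
  expect_gt(mean(s[labels == "driver"]), mean(s[labels == "passenger"]))
})

test_that("scoring is deterministic, row-order invariant, and projective", {
  tm <- toy_model(seed = 3, effect = 1.5)
  s1 <- score_mutations(tm$model, tm$st$table)
  expect_identical(s1, score_mutations(tm$model, tm$st$table))

  perm <- sample(nrow(tm$st$table$values))
  shuffled <- feature_table(tm$st$table$values[perm, , drop = FALSE],
                            tm$st$table$kinds)
  expect_equal(score_mutations(tm$model, shuffled)[names(s1)], s1)

  # a column not among the selected features does not affect scores
  extra <- cbind(tm$st$table$values, bonus = seq_len(nrow(tm$st$table$values)))
  expect_equal(score_mutations(tm$model, feature_table(extra)), s1)

  dropped <- feature_table(tm$st$table$values[, "inf01", drop = FALSE])
  expect_error(score_mutations(tm$model, dropped), "inf02")

  # duplicated rows receive identical scores
  dup <- tm$st$table$values[c(1, 1), , drop = FALSE]
  rownames(dup) <- c("u1", "u2")
  sd2 <- score_mutations(tm$model, feature_table(dup))
  expect_equal(unname(sd2[1]), unname(sd2[2]))
})

test_that("categorize applies the percentile rules with strict inequalities", {
  model <- structure(list(q90_passenger = 1, q10_driver = -1,
                          train_scores = list(driver = 1:10 / 10,
                                              passenger = -(1:10) / 10)),
                     class = "driver_model")
  expect_equal(unname(categorize(model, c(1.5, 1, 0, -1, -1.5))),
               c("driver", "no-call", "no-call", "no-call", "passenger"))
  # crossed thresholds: driver rule takes precedence, with a warning
  crossed <- model; crossed$q90_passenger <- -1; crossed$q10_driver <- 1
  expect_warning(got <- categorize(crossed, 0), "precedence")
  expect_equal(unname(got), "driver")
})

test_that("confidence is the strict same-class tail fraction", {
  model <- structure(list(train_scores = list(driver = as.numeric(1:100),
                                              passenger = as.numeric(-(1:9)))),
                     class = "driver_model")
  # driver score above 95 of 100 training drivers -> 0.05
  expect_equal(unname(confidence_score(model, 95.5, "driver")), 0.05)
  # above the maximum training driver -> 0
  expect_equal(unname(confidence_score(model, 101, "driver")), 0)
  # passenger at the median of 9 distinct scores -> 4/9 = (n-1)/(2n)
  expect_equal(unname(confidence_score(model, -5, "passenger")), 4 / 9)
  expect_true(is.na(confidence_score(model, 0, "no-call")))
  # ties are not "more extreme"
  expect_equal(unname(confidence_score(model, 100, "driver")), 0)
})

test_that("training-set calls respect the 10% percentile bound", {
  tm <- toy_model(seed = 11, n = 80, effect = 1)
  s <- score_mutations(tm$model, tm$st$table)
  y <- tm$st$labels
  pas <- s[y == "passenger"]; drv <- s[y == "driver"]
  tie_pas <- mean(pas == tm$model$q90_passenger)
  expect_lte(mean(categorize(tm$model, pas) == "driver"), 0.10 + tie_pas)
  tie_drv <- mean(drv == tm$model$q10_driver)
  expect_lte(mean(categorize(tm$model, drv) == "passenger"), 0.10 + tie_drv)
})

test_that("confidence of training members is near-uniform on ranks", {
  tm <- toy_model(seed = 7, n = 100, effect = 1)
  drv <- tm$model$train_scores$driver
  conf <- empirical_confidence(drv, drv, "upper")
  n <- length(drv)
  ks <- max(abs(sort(conf) - (seq_len(n) - 1) / n))
  expect_lt(ks, 2 / n)
})

test_that("models survive serialisation with identical predictions", {
  tm <- toy_model(seed = 5, effect = 1.5)
  path <- withr::local_tempfile(fileext = ".rds")
  write_model(tm$model, path)
  back <- read_model(path)
  expect_identical(predict_calls(back, tm$st$table),
                   predict_calls(tm$model, tm$st$table))
})
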