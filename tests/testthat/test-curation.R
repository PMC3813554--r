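cfg <- curation_config()

test_that("stringent drivers require recurrence and no same-gene confounder", {
  base <- bind_catalog(
    cat_row("m1", "TP53", 100, "A"),
    cat_row("m2", "TP53", 100, "B")
  )
  expect_setequal(stringent_drivers(base, config = cfg), c("m1", "m2"))

  confounded <- bind_catalog(base, cat_row("m3", "TP53", 900, "A",
                                           class = "nonsense"))
  expect_equal(stringent_drivers(confounded, config = cfg), character())

  # a confounder in a different gene does not disqualify
  other_gene <- bind_catalog(base, cat_row("m3", "EGFR", 900, "A",
                                           class = "nonsense"))
  expect_setequal(stringent_drivers(other_gene, config = cfg), c("m1", "m2"))

  singleton <- bind_catalog(cat_row("m1", "TP53", 100, "A"))
  expect_equal(stringent_drivers(singleton, config = cfg), character())

  bl <- site_blacklist(c("chr1:100"))
  expect_equal(stringent_drivers(base, bl, cfg), character())
})

test_that("stringent passengers come from hypermutated samples only", {
  hyper <- do.call(bind_catalog, lapply(1:56, function(i)
    cat_row(sprintf("h%02d", i), sprintf("G%02d", i), i * 1000, "HYP")))
  quiet <- do.call(bind_catalog, lapply(1:10, function(i)
    cat_row(sprintf("q%02d", i), "GQ", 500000 + i * 1000, "QUIET")))
  cat56 <- bind_catalog(hyper, quiet)

  got <- stringent_passengers(cat56, config = cfg)   # threshold 55, strict >
  expect_setequal(got, sprintf("h%02d", 1:56))

  census <- gene_list(c("G01", "G02"))
  got2 <- stringent_passengers(cat56, cancer_genes = census, config = cfg)
  expect_setequal(got2, sprintf("h%02d", 3:56))

  # at exactly the threshold (not over), the sample contributes nothing
  at55 <- do.call(bind_catalog, lapply(1:55, function(i)
    cat_row(sprintf("h%02d", i), sprintf("G%02d", i), i * 1000, "HYP")))
  expect_equal(stringent_passengers(at55, config = cfg), character())
})

test_that("expanded drivers fire on each of the three rules", {
  # rule 1: 3 primary samples of another cancer type; gene mutated in target
  r1 <- bind_catalog(
    cat_row("t1", "BRAF", 100, "S0", ctype = "GBM"),
    cat_row("o1", "BRAF", 5000, "S1", ctype = "OVC"),
    cat_row("o2", "BRAF", 5000, "S2", ctype = "OVC"),
    cat_row("o3", "BRAF", 5000, "S3", ctype = "OVC")
  )
  expect_true(all(c("o1", "o2", "o3") %in% expanded_drivers(r1, "GBM", cfg)))

  # rule 2: site shared by 1 missense + 3 indels
  r2 <- bind_catalog(
    cat_row("m1", "KRAS", 200, "S1", ctype = "GBM"),
    cat_row("i1", "KRAS", 200, "S2", class = "indel", alt = "-", ctype = "OVC"),
    cat_row("i2", "KRAS", 200, "S3", class = "indel", alt = "-", ctype = "OVC"),
    cat_row("i3", "KRAS", 200, "S4", class = "indel", alt = "-", ctype = "OVC")
  )
  expect_equal(expanded_drivers(r2, "GBM", cfg), "m1")

  # rule 3: 5 records inside the centred 25 bp window
  r3 <- bind_catalog(
    cat_row("c0", "PIK3CA", 1000, "S1", ctype = "GBM"),
    cat_row("c1", "PIK3CA", 988, "S2", ctype = "OVC"),
    cat_row("c2", "PIK3CA", 994, "S3", ctype = "OVC"),
    cat_row("c3", "PIK3CA", 1006, "S4", ctype = "OVC"),
    cat_row("c4", "PIK3CA", 1012, "S5", ctype = "OVC")
  )
  expect_true("c0" %in% expanded_drivers(r3, "GBM", cfg))
  # 13 bp away is outside pos +/- 12: dropping one inside record breaks it
  r3b <- r3; r3b$pos[5] <- 1013L
  expect_false("c0" %in% expanded_drivers(r3b, "GBM", cfg))

  # isolated singleton fails all three rules
  iso <- bind_catalog(cat_row("s1", "NF1", 100, "S1", ctype = "GBM"))
  expect_equal(expanded_drivers(iso, "GBM", cfg), character())

  # stringent subtraction removes the variant
  expect_false("m1" %in% expanded_drivers(r2, "GBM", cfg, exclude = "m1"))
})

test_that("expanded passengers are isolated in-type primary singletons", {
  base <- bind_catalog(
    cat_row("p1", "GENEA", 100, "S1", ctype = "GBM"),
    cat_row("x1", "GENEB", 120, "S2", ctype = "GBM")     # 20 bp away
  )
  expect_setequal(expanded_passengers(base, "GBM", config = cfg),
                  c("p1", "x1"))

  near <- base; near$pos[2] <- 110L                       # 10 bp away
  expect_equal(expanded_passengers(near, "GBM", config = cfg), character())

  twice <- bind_catalog(
    cat_row("p1", "GENEA", 100, "S1", ctype = "GBM"),
    cat_row("p2", "GENEA", 100, "S2", ctype = "GBM")
  )
  expect_equal(expanded_passengers(twice, "GBM", config = cfg), character())

  census <- gene_list("GENEA")
  expect_equal(expanded_passengers(base, "GBM", census, cfg), "x1")
})

test_that("expanded window rules match the brute-force pairwise oracle", {
  for (seed in 1:25) {
    cat_ <- random_catalog(n = sample(50:220, 1), seed = seed)
    expect_setequal(expanded_drivers(cat_, "GBM", cfg),
                    oracle_expanded_drivers(cat_, "GBM", cfg))
    expect_setequal(expanded_passengers(cat_, "GBM", config = cfg),
                    oracle_expanded_passengers(cat_, "GBM", config = cfg))
  }
})

test_that("curated sets are mutually disjoint and rules are monotone", {
  for (seed in 1:8) {
    cat_ <- random_catalog(n = 150, seed = 100 + seed)
    sets <- curate_training_sets(cat_, "GBM",
                                 cancer_genes = gene_list("G01"),
                                 config = cfg)
    all_ids <- c(sets$stringent$drivers, sets$stringent$passengers,
                 sets$expanded$drivers, sets$expanded$passengers)
    expect_equal(anyDuplicated(all_ids), 0)

    # adding records never removes an expanded driver, and can only shrink
    # the expanded passengers
    extra <- random_catalog(n = 50, seed = 900 + seed)
    extra$mutation_id <- paste0("x", extra$mutation_id)
    grown <- bind_catalog(cat_, extra)
    expect_true(all(expanded_drivers(cat_, "GBM", cfg) %in%
                      expanded_drivers(grown, "GBM", cfg)))
    expect_true(all(expanded_passengers(grown, "GBM", config = cfg)[
      !grepl("^x", expanded_passengers(grown, "GBM", config = cfg))] %in%
        expanded_passengers(cat_, "GBM", config = cfg)))
  }
})

test_that("curation config validates windows and thresholds", {
  expect_error(curation_config(hotspot_window_bp = 24), "odd")
  expect_error(curation_config(stringent_min_samples = 0), "positive")
})
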