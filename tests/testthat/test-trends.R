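make_records <- function(lengths, ids = sprintf("c%03d", seq_along(lengths))) {
  data.frame(cas_id = ids, fluorinated_chain_length = lengths,
             stringsAsFactors = FALSE)
}

test_that("noiseless linear data recover the exact slope with R^2 = 1", {
  rec <- make_records(rep(1:10, each = 3))
  s <- -6.0 - 0.2 * rec$fluorinated_chain_length
  tab <- score_table(matrix(s, ncol = 1, dimnames = list(rec$cas_id, "PXR")))
  cv <- chain_length_affinity_curve(rec, tab, "PXR")
  expect_equal(cv$slope, -0.2, tolerance = 1e-12)
  expect_equal(cv$intercept, -6.0, tolerance = 1e-12)
  expect_equal(cv$r_squared, 1.0, tolerance = 1e-12)
  expect_equal(cv$points$n, rep(3L, 10))
})

test_that("a single chain length is insufficient for a trend", {
  rec <- make_records(rep(4L, 5))
  tab <- score_table(matrix(-7, 5, 1, dimnames = list(rec$cas_id, "PXR")))
  expect_error(chain_length_affinity_curve(rec, tab, "PXR"),
               class = "edcscreen_insufficient_data_error")
  expect_error(chain_length_affinity_curve(rec, tab, "XXX"),
               class = "edcscreen_key_error")
})

test_that("the fitted R^2 equals the squared Pearson correlation of the means", {
  withr::local_seed(31)
  rec <- make_records(rep(1:12, each = 5))
  s <- -5 - 0.25 * rec$fluorinated_chain_length + rnorm(nrow(rec), 0, 0.4)
  tab <- score_table(matrix(s, ncol = 1, dimnames = list(rec$cas_id, "CAR")))
  cv <- chain_length_affinity_curve(rec, tab, "CAR")
  expect_equal(cv$r_squared,
               cor(cv$points$length, cv$points$mean_score)^2,
               tolerance = 1e-9)
})

test_that("planted slopes are recovered within 3 standard errors, tightening as noise shrinks", {
  for (sigma in c(0.3, 0.1, 0.01)) {
    rec <- generate_fluorinated_smiles(50 * 10, lengths = 1:10, seed = 101)
    st <- generate_score_table(rec, receptors = "PXR", beta0 = -6, beta1 = -0.2,
                               sigma = sigma, seed = 202)
    recs <- transform(rec, fluorinated_chain_length = true_chain_length)
    cv <- chain_length_affinity_curve(recs, st$table, "PXR", over = "raw")
    expect_lt(abs(cv$slope - (-0.2)) / cv$slope_se, 3,
              label = paste("z at sigma", sigma))
  }
  # noiseless generation recovers the generator exactly
  rec <- generate_fluorinated_smiles(60, lengths = 1:6, group_probs = c(none = 1),
                                     seed = 5)
  st0 <- generate_score_table(rec, receptors = "PXR", beta0 = -6, beta1 = -0.2,
                              sigma = 0, seed = 6)
  cv0 <- chain_length_affinity_curve(
    transform(rec, fluorinated_chain_length = true_chain_length), st0$table, "PXR")
  expect_equal(cv0$slope, -0.2, tolerance = 1e-10)
  expect_equal(cv0$r_squared, 1.0, tolerance = 1e-10)
})

test_that("chain-length categories split at six/seven carbons", {
  rec <- make_records(c(0L, 1L, 6L, 7L, 26L))
  cat <- categorize_chain_lengths(rec)
  expect_equal(as.character(cat),
               c("uncategorized", "short", "short", "long", "long"))
})

test_that("group affinity means pool multi-group compounds into every group row", {
  rec <- data.frame(cas_id = c("a", "b", "c"),
                    functional_groups = c("alcohol", "alcohol", "urea;halide"),
                    stringsAsFactors = FALSE)
  tab <- score_table(matrix(c(-8.0, -8.4, -9.0), ncol = 1,
                            dimnames = list(c("a", "b", "c"), "CAR")))
  ga <- functional_group_affinity_table(rec, tab)
  expect_equal(ga$mean_score[ga$group == "alcohol"], -8.2)
  expect_equal(ga$n[ga$group == "alcohol"], 2L)
  # compound c contributes to both urea and halide rows
  expect_setequal(ga$group[ga$n == 1], c("urea", "halide"))
  # zero-member groups are absent
  expect_false("ester" %in% ga$group)
  # grand count conservation and order invariance
  expect_equal(sum(ga$n), 4L)
  ga2 <- functional_group_affinity_table(rec[c(3, 1, 2), ], tab)
  expect_equal(ga[order(ga$group), ], ga2[order(ga2$group), ],
               ignore_attr = TRUE)
})

test_that("hydrophobicity summaries flag bioaccumulative top binders", {
  withr::local_seed(55)
  n <- 30
  rec <- data.frame(cas_id = sprintf("c%02d", 1:n),
                    logp = c(runif(15, 6, 9), runif(15, 1, 4)),
                    stringsAsFactors = FALSE)
  # strongest 15 scores belong to the high-logP half
  s <- c(runif(15, -12, -10), runif(15, -8, -5))
  tab <- score_table(matrix(s, ncol = 1, dimnames = list(rec$cas_id, "CAR")))
  hs <- hydrophobicity_summary(rec, tab, "CAR", n_top = 15)
  expect_equal(hs$n_bioaccumulative, 15L)
  expect_gte(hs$logp_min, 6)
  expect_lte(hs$logp_max, 9)

  low <- transform(rec, logp = logp - 10)
  expect_equal(hydrophobicity_summary(low, tab, "CAR")$n_bioaccumulative, 0L)
  expect_error(hydrophobicity_summary(rec[1:5, ], tab, "CAR", n_top = 15),
               class = "edcscreen_insufficient_data_error")
})
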