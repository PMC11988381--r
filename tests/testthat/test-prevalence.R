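test_that("ranking sorts ascending, skips missing cells, breaks ties by compound id", {
  m <- matrix(c(-9.7, -8.4, NA, -6.6,
                -8.0, -8.0, -7.0, NA), 4, 2,
              dimnames = list(c("b", "a", "d", "c"), c("PXR", "CAR")))
  tab <- score_table(m)
  top2 <- rank_binders(tab, "PXR", 2)
  expect_equal(top2$cas_id, c("b", "a"))
  expect_equal(top2$score, c(-9.7, -8.4))
  # tie at -8.0 resolved lexicographically
  car <- rank_binders(tab, "CAR", 3)
  expect_equal(car$cas_id, c("a", "b", "d"))
  expect_error(rank_binders(tab, "nope"), class = "edcscreen_key_error")
})

test_that("column extremes agree with rank 1 and swap under negation", {
  withr::local_seed(77)
  m <- matrix(-runif(40, 4, 12), 20, 2,
              dimnames = list(sprintf("c%02d", 1:20), c("PXR", "CAR")))
  tab <- score_table(m)
  for (rc in colnames(m)) {
    expect_equal(column_extreme(tab, rc, "strongest")$cas_id,
                 rank_binders(tab, rc, nrow(m))$cas_id[1])
  }
  neg <- score_table(-m)
  expect_equal(column_extreme(tab, "PXR", "strongest")$cas_id,
               column_extreme(neg, "PXR", "weakest")$cas_id)
  single <- score_table(matrix(-5, dimnames = list("only", "AR")))
  expect_equal(column_extreme(single, "AR", "strongest")$cas_id, "only")
  expect_equal(column_extreme(single, "AR", "weakest")$cas_id, "only")
  allna <- score_table(matrix(NA_real_, dimnames = list("x", "AR")))
  expect_error(column_extreme(allna, "AR"), class = "edcscreen_empty_column_error")
})

test_that("printed per-class tables reproduce their published extremes", {
  t9 <- table9()
  car <- column_extreme(t9, "CAR", "strongest")
  expect_equal(car$cas_id, "84-61-7")  # dicyclohexyl phthalate
  expect_equal(car$score, -9.7)
  expect_equal(rank_binders(t9, "CAR", 1)$cas_id, "84-61-7")
  ror <- column_extreme(t9, "RORgt", "weakest")
  expect_equal(ror$score, -5.4)

  t7 <- table7()
  expect_equal(column_extreme(t7, "PPARd", "strongest")$score, -12.3)  # Hydramethylnon
  expect_equal(column_extreme(t7, "PPARd", "strongest")$cas_id, "118401")
  expect_equal(column_extreme(t7, "PXR", "strongest")$score, -10.8)   # Noviflumuron

  t8 <- table8()
  car8 <- column_extreme(t8, "CAR", "strongest")
  expect_equal(car8$cas_id, "24038-68-4")
  expect_equal(car8$score, -11.5)
})

test_that("cross-receptor prevalence counts list membership set-wise", {
  t4 <- read_top_binder_table(extdata("table4_pfas_top25.csv"))
  pv <- cross_receptor_prevalence(t4)
  expect_equal(pv$counts$count[pv$counts$cas_id == "662-28-2"], 3L)
  memb <- pv$membership[pv$membership$cas_id == "662-28-2", ]
  expect_setequal(memb$receptor, c("CAR", "PXR", "AR"))
  expect_equal(memb$rank[memb$receptor == "PXR"], 18L)
  expect_equal(memb$rank[memb$receptor == "AR"], 16L)

  t5 <- read_top_binder_table(extdata("table5_pbde_top25.csv"))
  pv5 <- cross_receptor_prevalence(t5)
  expect_equal(pv5$counts$count[pv5$counts$cas_id == "366791-32-4"], 5L)
  m5 <- pv5$membership[pv5$membership$cas_id == "366791-32-4", ]
  expect_setequal(m5$receptor, c("PPARd", "PXR", "PPARa", "PPARg", "RORgt"))

  # disjoint lists count every compound once; totals conserve
  dis <- cross_receptor_prevalence(list(A = c("x", "y"), B = c("z")))
  expect_true(all(dis$counts$count == 1L))
  expect_equal(sum(pv$counts$count), nrow(pv$membership))
  # invariance under list order
  pv_r <- cross_receptor_prevalence(rev(t4))
  expect_equal(pv$counts, pv_r$counts)
})

test_that("heat matrices keep the numbers and map strongest to the red end", {
  m <- matrix(c(-12.3, -7, -8, -6), 2, 2,
              dimnames = list(c("a", "b"), c("PXR", "CAR")))
  hm <- heatmap_matrix(score_table(m))
  expect_equal(hm$matrix, m)
  ramp <- grDevices::colorRampPalette(c("green", "yellow", "red"))(100)
  expect_equal(hm$colors["a", "PXR"], ramp[100])  # strongest -> red extreme
  expect_equal(hm$colors["b", "CAR"], ramp[1])    # weakest -> green extreme
  # all-equal scores render uniformly
  u <- heatmap_matrix(score_table(matrix(-7, 2, 2,
        dimnames = list(c("a", "b"), c("PXR", "CAR")))))
  expect_equal(length(unique(as.vector(u$colors))), 1L)
  # csv side-channel matches the cells
  f <- tempfile(fileext = ".csv")
  heatmap_matrix(score_table(m), csv = f)
  back <- read_score_table(f)
  expect_equal(unclass(back), m)

  t7 <- table7()
  hm7 <- heatmap_matrix(t7)
  strongest <- which(hm7$matrix == -12.3, arr.ind = TRUE)
  expect_equal(hm7$colors[strongest], ramp[100])
})
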