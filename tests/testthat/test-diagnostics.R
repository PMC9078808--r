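test_that("predicted positive rate divides detected by gold cases", {
  expect_equal(positive_rate(19, 17), 89.47)
  expect_equal(positive_rate(5, 0), 0)
  expect_equal(positive_rate(7, 7), 100)
  expect_equal(positive_rate(c(19, 45), c(17, 41)), c(89.47, 91.11))
  expect_error(positive_rate(0, 0), "at least 1")
  expect_error(positive_rate(5, 6), "exceeds")
  expect_error(positive_rate(5, -1), "negative")
})

test_that("binary performance reproduces the cohort's printed percentages", {
  # CEUS resectability 2x2
  expect_equal(unname(binary_performance(87, 4, 9, 2)), c(95.60, 81.82, 94.12))
  # CT (specificity from the counts: 7/11 = 63.64)
  expect_equal(unname(binary_performance(81, 10, 7, 4)), c(89.01, 63.64, 86.27))
  # degenerate classifier that never calls positive
  expect_equal(unname(binary_performance(0, 5, 8, 0)),
               c(0, 100, round(100 * 8 / 13, 2)))
  expect_error(binary_performance(3, -1, 2, 0), "nonnegative")
  expect_error(binary_performance(0, 0, 3, 1), "nonempty")
})

test_that("accuracy equals the independent recount identity", {
  set.seed(16)
  for (i in 1:25) {
    v <- sample(0:40, 4, replace = TRUE)
    if (v[1] + v[2] == 0 || v[3] + v[4] == 0) next
    perf <- binary_performance(v[1], v[2], v[3], v[4])
    expect_equal(perf[["accuracy"]], round(100 * (v[1] + v[3]) / sum(v), 2))
  }
})

test_that("contingency fixtures validate their counts", {
  tab <- generate_contingency_fixture(list(T1 = c(19, 17), "T2-T3" = c(45, 41)))
  expect_s3_class(tab, "contingency_table")
  expect_equal(tab$gold_n, c(19L, 45L))
  expect_equal(tab$detected_n[tab$stage == "T1"], 17L)
  zero <- generate_contingency_fixture(list(X = c(5, 0)))
  expect_equal(positive_rate(zero$gold_n, zero$detected_n), 0)
  expect_error(generate_contingency_fixture(list(T1 = c(-1, 0))), "negative")
  expect_error(generate_contingency_fixture(list(T1 = c(3, 4))), "exceed")
  r <- resectability_table(87, 4, 9, 2)
  expect_s3_class(r, "resectability_table")
  expect_error(resectability_table(1, 2, -3, 4), "nonnegative")
})

test_that("modality comparison uses chi-squared with exact-test fallback", {
  a <- generate_contingency_fixture(list(S = c(100, 90)), "A")
  b <- generate_contingency_fixture(list(S = c(100, 90)), "B")
  same <- compare_modalities(a, b)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  # hand-computed 2x2 with continuity correction: 90/100 vs 10/100
  b2 <- generate_contingency_fixture(list(S = c(100, 10)), "B")
  out <- compare_modalities(a, b2)
  m <- matrix(c(90, 10, 10, 90), 2, 2, byrow = TRUE)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  chi2_hand <- sum((abs(m - expected) - 0.5)^2 / expected)
  expect_equal(out$chi2, chi2_hand)
  expect_equal(out$method, "chisq_cc")

  # tiny counts trigger the exact fallback with a valid p
  t1 <- generate_contingency_fixture(list(S = c(4, 1)), "A")
  t2 <- generate_contingency_fixture(list(S = c(4, 3)), "B")
  small <- compare_modalities(t1, t2)
  expect_equal(small$method, "fisher_exact")
  expect_true(small$p >= 0 && small$p <= 1)
  expect_true(is.na(small$chi2))

  expect_error(compare_modalities(a, generate_contingency_fixture(list(Z = c(100, 2)))),
               "stage labels")
})

test_that("the shipped clinical tables load and summarize end to end", {
  staging <- ceus_staging_counts()
  resect <- ceus_resectability_counts()
  expect_equal(nrow(staging), 18L)
  expect_equal(sort(unique(staging$modality)), c("CEUS", "CT"))
  # T staging covers the full 102-patient cohort
  expect_equal(sum(staging$gold_n[staging$modality == "CEUS" &
                                    staging$stage %in% c("T1", "T2-T3", "T4")]), 102L)
  summ <- diagnostic_summary(staging, resect)
  expect_s3_class(summ, "diagnostic_summary")
  expect_equal(summ$ppr$ppr[summ$ppr$stage == "T1" & summ$ppr$modality == "CEUS"],
               89.47)
  expect_equal(summ$performance$sensitivity, c(95.60, 89.01))
  expect_true(all(summ$ppr$ppr >= 0 & summ$ppr$ppr <= 100))
  expect_equal(nrow(summ$comparison), 9L)
})

test_that("count CSVs round-trip through the reader", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("modality,tp,fn,tn,fp", "CEUS,87,4,9,2"), path)
  tab <- read_counts_csv(path)
  expect_s3_class(tab, "resectability_table")
  expect_equal(tab$tp, 87L)
  writeLines(c("a,b", "1,2"), path)
  expect_error(read_counts_csv(path), "unrecognized")
  unlink(path)
})
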