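test_that("rib_count_table tallies sides and shares", {
  patients <- data.frame(patient_id = "p1")
  co <- validate_cohort(patients,
                        data.frame(patient_id = "p1", rib = 1,
                                   side = "left", percent = 50))
  tab <- rib_count_table(co)
  expect_equal(tab$left[1], 1)
  expect_equal(tab$right[1], 0)
  expect_equal(tab$total[1], 1)
  expect_equal(tab$percent[1], 100)
  expect_equal(attr(tab, "grand_total"), 1)
  expect_equal(attr(tab, "left_share"), 100)
})

test_that("rib_count_table percents sum to 100 and resist reordering", {
  for (seed in 1:5) {
    sim <- generate_cohort(sim_params(n_patients = 50, seed = seed))
    tab <- rib_count_table(sim$cohort)
    expect_equal(tab$total, tab$left + tab$right)
    expect_equal(sum(tab$percent), 100, tolerance = 0.05)

    shuffled <- sim$cohort
    set.seed(seed + 100)
    shuffled$fractures <- shuffled$fractures[sample(nrow(
      shuffled$fractures)), ]
    shuffled$patients <- shuffled$patients[sample(nrow(
      shuffled$patients)), ]
    tab2 <- rib_count_table(shuffled)
    expect_equal(tab2$total, tab$total)
    expect_equal(attr(tab2, "grand_total"), attr(tab, "grand_total"))
  }
})

test_that("mann_whitney reproduces hand-enumerated small cases", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(unname(mw$statistic), 0)
  expect_equal(mw$p.value, 2 / 6)

  mw_same <- mann_whitney(1:5, 1:5)
  expect_equal(unname(mw_same$statistic), 12.5)   # n^2 / 2 under midranks
  expect_equal(mw_same$p.value, 1)

  expect_error(mann_whitney(numeric(), 1:3), "non-empty")
})

test_that("mann_whitney U is complementary and matches wilcox.test", {
  set.seed(41)
  for (i in 1:10) {
    x <- rnorm(sample(5:40, 1))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    ux <- unname(mann_whitney(x, y)$statistic)
    uy <- unname(mann_whitney(y, x)$statistic)
    expect_equal(ux + uy, length(x) * length(y))
    expect_equal(ux, unname(wilcox.test(x, y)$statistic))
  }
  # large-sample p agrees with wilcox.test's uncorrected normal approx
  x <- rnorm(80)
  y <- rnorm(90, 0.3)
  expect_equal(mann_whitney(x, y)$p.value,
               wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-12)
})

test_that("exact enumeration agrees with the independent oracle, with ties", {
  set.seed(42)
  cases <- list(
    list(x = c(1, 2), y = c(3, 4)),
    list(x = c(1, 1, 2), y = c(1, 3)),
    list(x = sample(1:4, 4, TRUE), y = sample(1:4, 4, TRUE)),
    list(x = rnorm(3), y = rnorm(5)),
    list(x = c(5, 5, 5), y = c(5, 5))
  )
  for (cs in cases) {
    mw <- mann_whitney(cs$x, cs$y)
    orc <- oracle_mann_whitney(cs$x, cs$y)
    expect_equal(unname(mw$statistic), orc$U)
    expect_equal(mw$p.value, orc$p)
  }
})

test_that("mann_whitney holds its nominal type-I error", {
  set.seed(43)
  n_rep <- 1000
  rejections <- 0
  for (i in seq_len(n_rep)) {
    x <- rnorm(100)
    y <- rnorm(100)
    if (mann_whitney(x, y)$p.value < 0.05) rejections <- rejections + 1
  }
  expect_gte(rejections / n_rep, 0.03)
  expect_lte(rejections / n_rep, 0.07)
})

test_that("contingency_2x2 matches closed-form chi-square and Fisher", {
  m <- matrix(c(24, 2, 53, 23), 2, byrow = TRUE)
  res <- contingency_2x2(m, method = "chi_square")
  expect_equal(res$statistic, oracle_chisq_2x2(m), tolerance = 1e-9)
  expect_equal(res$statistic, 5.334, tolerance = 1e-3)

  even <- matrix(10, 2, 2)
  res_even <- contingency_2x2(even, method = "chi_square")
  expect_equal(res_even$statistic, 0)
  expect_equal(res_even$p.value, 1)

  diag1 <- matrix(c(1, 0, 0, 1), 2)
  res_f <- contingency_2x2(diag1)   # auto: expected cells < 5
  expect_equal(res_f$method, "fisher")
  expect_equal(res_f$p.value, 1)
  expect_equal(res_f$p.value, oracle_fisher_2x2(diag1))
})

test_that("auto method selection follows the expected-count rule", {
  big <- matrix(c(30, 20, 25, 25), 2)
  expect_equal(contingency_2x2(big)$method, "chi_square")
  small <- matrix(c(8, 1, 2, 9), 2)
  expect_equal(contingency_2x2(small)$method, "fisher")
  yates <- contingency_2x2(big, method = "chi_square_yates")
  expect_equal(yates$method, "chi_square_yates")
  expect_lt(yates$statistic, contingency_2x2(big, "chi_square")$statistic)
  expect_error(contingency_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margins")
})

test_that("fisher p matches hypergeometric enumeration on random tables", {
  set.seed(44)
  for (i in 1:20) {
    m <- matrix(rpois(4, 4) + c(1, 0, 0, 1), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    res <- contingency_2x2(m, method = "fisher")
    expect_equal(res$p.value, oracle_fisher_2x2(m), tolerance = 1e-9)
  }
})

test_that("position_comparison splits records by patient flag", {
  patients <- data.frame(patient_id = c("f1", "f2", "n1", "n2"),
                         sternum = c(1, 1, 0, 0))
  fractures <- data.frame(
    patient_id = c("f1", "f1", "f2", "n1", "n2", "n2"),
    rib = 5, side = "left",
    percent = c(90, 90, 90, 10, 10, 10))
  co <- validate_cohort(patients, fractures)
  cmp <- position_comparison(co, "sternum")
  expect_equal(cmp$mean_yes, 90)
  expect_equal(cmp$mean_no, 10)
  expect_equal(cmp$shift_estimate, 80)
  expect_equal(cmp$n_yes, 3)
  expect_true(cmp$U <= cmp$n_yes * cmp$n_no && cmp$U >= 0)

  expect_error(position_comparison(co, "clavicle"), "no fracture records")

  cmp_pat <- position_comparison(co, "sternum", unit = "patient")
  expect_equal(cmp_pat$n_yes, 2)
  expect_equal(cmp_pat$mean_yes, 90)
})

test_that("upper_rib_association builds the patient-level 2x2 table", {
  patients <- data.frame(patient_id = c("f1", "f2", "n1", "n2"),
                         clavicle = c(1, 1, 0, 0))
  fractures <- data.frame(patient_id = c("f1", "f2", "n1", "n2"),
                          rib = c(2, 2, 8, 9), side = "left", percent = 50)
  co <- validate_cohort(patients, fractures)
  res <- upper_rib_association(co, "clavicle")
  expect_equal(res$rate_yes, 1)
  expect_equal(res$rate_no, 0)
  expect_equal(unname(res$counts[1, ]), c(2, 0))

  # with the full rib range, everyone with >= 1 fracture is involved
  res_all <- upper_rib_association(co, "clavicle", ribs = 1:12)
  expect_equal(res_all$rate_yes, 1)
  expect_equal(res_all$rate_no, 1)
})

test_that("cohort_summary reports descriptives on the toy cohort", {
  co <- toy_cohort()
  s <- cohort_summary(co)
  expect_equal(s$n_patients, 3)
  expect_equal(s$n_fracture_lines, 5)
  expect_equal(unname(s$lines_per_patient["mean"]), 5 / 3)
  expect_equal(unname(s$flag_prevalence["n", "clavicle"]), 1)
  expect_equal(unname(s$position["mean"]), mean(c(15, 25, 25, 65, 90)))
})
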