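toy_cohort <- function() {
  as_cohort(data.frame(
    patient_id = sprintf("P%d", 1:6),
    age = c(60, 65, 70, 62, 58, 75),
    sex = rep(c("male", "female"), 3),
    diagnosis = c("LUAD", "LUAD", "LUAD", "other", "other", "LUAD"),
    los = c(10, 12, 9, 7, 8, 14),
    used_herb = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
    admission_symptoms = I(list(c("cough", "asthma"), "cough", "cough",
                                character(0), "cough", "asthma")),
    relieved_symptoms = I(list("cough", character(0), "cough",
                               character(0), character(0), "asthma")),
    stringsAsFactors = FALSE))
}

test_that("usage table counts the four diagnosis-by-usage cells", {
  tab <- build_usage_table(toy_cohort(), "LUAD")
  expect_equal(unclass(tab), matrix(c(2L, 2L, 1L, 1L), 2, byrow = TRUE,
               dimnames = list(c("LUAD", "other"), c("yes", "no"))))
  expect_equal(sum(tab), 6)
  expect_error(build_usage_table(toy_cohort()[0, ], "LUAD"), "empty")
})

test_that("chi-square matches the 2x2 closed form and handles degeneracy", {
  # closed-form oracle: n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))
  closed_form <- function(a, b, c, d) {
    n <- a + b + c + d
    n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  }
  set.seed(11)
  for (i in 1:25) {
    cells <- rpois(4, 30) + 1
    res <- chi_square_test(contingency_2x2(cells[1], cells[2],
                                           cells[3], cells[4]))
    expect_equal(res$statistic,
                 closed_form(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
    # invariance under row swap and column swap
    swapped <- chi_square_test(contingency_2x2(cells[3], cells[4],
                                               cells[1], cells[2]))
    expect_equal(res$statistic, swapped$statistic, tolerance = 1e-12)
    cols <- chi_square_test(contingency_2x2(cells[2], cells[1],
                                            cells[4], cells[3]))
    expect_equal(res$p, cols$p, tolerance = 1e-12)
  }

  perfect <- chi_square_test(contingency_2x2(10, 10, 10, 10))
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$p, 1)

  expect_error(chi_square_test(contingency_2x2(0, 0, 5, 5)), "degenerate")
  expect_error(chi_square_test(contingency_2x2(5, 0, 5, 0)), "degenerate")
  # Yates correction shrinks the statistic
  expect_lt(chi_square_test(contingency_2x2(12, 5, 6, 14), TRUE)$statistic,
            chi_square_test(contingency_2x2(12, 5, 6, 14), FALSE)$statistic)
})

test_that("Welch t-test handles identical, separated and degenerate groups", {
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  far <- welch_t_test(c(0, 0, 0, 0), c(10, 10, 10, 10.0001))
  expect_lt(far$p, 0.001)

  # frozen closed-form Welch check: t = (m1-m2)/sqrt(s1^2/n1 + s2^2/n2)
  a <- c(1, 2, 3, 4, 5)
  b <- c(2, 4, 6, 8, 10, 12)
  res <- welch_t_test(a, b)
  se <- sqrt(var(a) / 5 + var(b) / 6)
  expect_equal(res$t, (mean(a) - mean(b)) / se, tolerance = 1e-12)

  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
  expect_equal(welch_t_test(c(2, 2), c(2, 2))$p, 1)
})

test_that("improvement ratios are exact half-up percentages", {
  expect_equal(improvement_ratio(25, 76), 32.89)
  expect_equal(improvement_ratio(19, 32), 59.38)  # 59.375 rounds up
  expect_equal(improvement_ratio(3, 4), 75.00)
  expect_equal(improvement_ratio(0, 5), 0.00)
  expect_equal(improvement_ratio(18, 52), 34.62)
  expect_true(is.na(improvement_ratio(0, 0)))
  expect_error(improvement_ratio(6, 5), "exceeds")
  expect_error(improvement_ratio(-1, 5), "non-negative")

  # bounded and monotone in relieved at fixed present
  for (present in c(3, 7, 31)) {
    ratios <- improvement_ratio(0:present, rep(present, present + 1))
    expect_true(all(ratios >= 0 & ratios <= 100))
    expect_true(all(diff(ratios) >= 0))
  }
})

test_that("improvement table stratifies by usage and sorts by relief", {
  tab <- build_improvement_table(toy_cohort(), c("cough", "asthma"))
  expect_equal(tab$symptom, c("cough", "asthma"))
  expect_equal(tab$used_present, c(2L, 1L))
  expect_equal(tab$used_relieved, c(1L, 0L))
  expect_equal(tab$unused_present, c(2L, 1L))
  expect_equal(tab$unused_relieved, c(1L, 1L))
  expect_equal(tab$used_ratio, c(50, 0))

  # presence totals add across arms to whole-cohort prevalence
  all_adm <- unlist(toy_cohort()$admission_symptoms)
  expect_equal(tab$used_present + tab$unused_present,
               as.integer(table(all_adm)[tab$symptom]),
               ignore_attr = TRUE)

  # unseen symptom: present 0, undefined ratio
  none <- build_improvement_table(toy_cohort(), "headache")
  expect_equal(none$used_present, 0L)
  expect_true(is.na(none$used_ratio))

  # single used patient with one relieved symptom
  one <- toy_cohort()[1, ]
  tab1 <- build_improvement_table(one, "cough")
  expect_equal(unlist(tab1[, 2:5]), c(1L, 1L, 0L, 0L), ignore_attr = TRUE)
  expect_equal(tab1$used_ratio, 100)
})

test_that("symptom ranking orders by count with alphabetical ties", {
  ranked <- rank_admission_symptoms(toy_cohort(), "used", k = 5)
  expect_equal(ranked$symptom, c("cough", "asthma"))  # k > distinct -> all
  expect_equal(ranked$count, c(2L, 1L))

  # tie broken alphabetically
  tie <- as_cohort(data.frame(
    patient_id = "P1", age = 60, sex = "male", diagnosis = "X", los = 1,
    used_herb = TRUE,
    admission_symptoms = I(list(c("zeta", "alpha"))),
    relieved_symptoms = I(list(character(0)))))
  expect_equal(rank_admission_symptoms(tie, "used", 2)$symptom,
               c("alpha", "zeta"))

  expect_error(rank_admission_symptoms(toy_cohort()[1:2, ], "unused", 1),
               "empty")
  expect_error(rank_admission_symptoms(toy_cohort(), "used", 0), ">= 1")
})
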