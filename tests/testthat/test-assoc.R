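example_table <- function() {
  tab <- rbind(presence = c(20L, 30L, 50L), absence = c(80L, 70L, 50L))
  colnames(tab) <- c("healthy", "adenoma", "carcinoma")
  tab
}

test_that("contingency tables tally presence by state with full denominators", {
  pres <- cbind(g = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  rownames(pres) <- paste0("p", 1:6)
  pr <- profiles_from_presence(pres, rep(c("healthy", "adenoma", "carcinoma"), 2))
  tab <- build_contingency(pr, "g")
  expect_equal(unname(tab["presence", ]), c(1L, 1L, 1L))
  expect_equal(unname(colSums(tab)), c(2L, 2L, 2L))

  pres[] <- FALSE
  pr <- profiles_from_presence(pres, rep(c("healthy", "adenoma", "carcinoma"), 2))
  expect_equal(unname(build_contingency(pr, "g")["presence", ]), c(0L, 0L, 0L))

  # brute-force tally on a synthetic cohort
  pr <- cohort_profiles(generate_cohort(small_null_config(n = 15, seed = 8)))
  tab <- build_contingency(pr, "g2")
  for (s in colnames(tab)) {
    sel <- pr$info$disease_state == s
    expect_equal(unname(tab["presence", s]), sum(pr$presence[sel, "g2"]))
  }
})

test_that("Pearson chi-squared matches closed-form arithmetic and base R", {
  res <- chi_squared_test(example_table())
  expect_equal(res$statistic, 21.0, tolerance = 1e-12)
  expect_equal(res$df, 2L)
  expect_equal(res$p_raw, exp(-10.5), tolerance = 1e-12)
  expect_equal(res$expected_min, 100 * 100 / 300)
  expect_false(res$degenerate)

  # exact independence
  tab <- rbind(presence = c(10, 10, 10), absence = c(20, 20, 20))
  res <- chi_squared_test(tab)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_raw, 1)

  # zero row margin: degenerate, not NaN
  tab <- rbind(presence = c(0, 0, 0), absence = c(5, 6, 7))
  res <- chi_squared_test(tab)
  expect_true(res$degenerate)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_raw, 1)

  expect_error(chi_squared_test(rbind(c(1, 0), c(2, 0))), "zero column")

  # column permutation invariance + agreement with chisq.test
  set.seed(13)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 20) + 1, nrow = 2)
    res <- chi_squared_test(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p_raw, ref$p.value, tolerance = 1e-10)
    perm <- tab[, sample(3)]
    expect_equal(chi_squared_test(perm)$statistic, res$statistic,
                 tolerance = 1e-12)
  }
})

test_that("chi-squared p agrees with a fixed-margin permutation null", {
  set.seed(17)
  chi_stat <- function(tab) {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  for (i in 1:3) {
    p <- runif(3, 0.3, 0.7)
    pres <- rbinom(3, 100, p)
    tab <- rbind(pres, 100 - pres)
    res <- chi_squared_test(tab)
    null_tabs <- r2dtable(20000, rowSums(tab), colSums(tab))
    p_perm <- mean(vapply(null_tabs, chi_stat, numeric(1)) >=
                     res$statistic - 1e-9)
    expect_lt(abs(p_perm - res$p_raw), 0.015)
  }
})

test_that("Benjamini-Hochberg reproduces the step-up adjustment", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.04, 0.05)),
               c(0.04, 0.04, 0.05, 0.05))
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(benjamini_hochberg(numeric(0)), numeric(0))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(19)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    q <- benjamini_hochberg(p)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in sorted order
    sh <- sample(length(p))
    expect_equal(benjamini_hochberg(p[sh]), q[sh])  # order invariance
  }
})

test_that("the stage score test matches its closed form and the glm oracle", {
  presence <- rep(rep(c(TRUE, FALSE), 4), c(2, 8, 4, 6, 6, 4, 8, 2))
  stage <- rep(c("I", "II", "III", "IV"), each = 10)
  res <- stage_score_test(presence, stage)
  expect_equal(res$statistic, 8.0, tolerance = 1e-12)
  expect_equal(res$df, 1L)
  expect_equal(res$p_raw, pchisq(8, 1, lower.tail = FALSE), tolerance = 1e-12)

  # equal carriage across stages: statistic 0, p 1
  res0 <- stage_score_test(rep(c(TRUE, FALSE), 20),
                           rep(c("I", "II", "III", "IV"), each = 10))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_raw, 1)

  # all presence identical: degenerate
  resd <- stage_score_test(rep(TRUE, 20), rep(c("I", "II"), each = 10))
  expect_true(resd$degenerate)

  expect_error(stage_score_test(c(TRUE, FALSE), c("I", "I")), "distinct stages")
  expect_error(stage_score_test(c(TRUE, FALSE), c("I", "V")), "V")

  # oracle: Rao score test from a full glm fit
  set.seed(23)
  for (i in 1:25) {
    n <- 60
    x <- sample(1:4, n, replace = TRUE)
    y <- rbinom(n, 1, plogis(-0.5 + 0.3 * x))
    if (length(unique(y)) < 2) next
    mine <- stage_score_test(y, x)
    ref <- anova(glm(y ~ x, family = binomial,
                     control = glm.control(epsilon = 1e-12)), test = "Rao")
    expect_equal(mine$statistic, ref$Rao[2], tolerance = 1e-6)
    expect_equal(mine$p_raw, ref$`Pr(>Chi)`[2], tolerance = 1e-6)
  }
})

test_that("stage profiles normalize per stage and omit empty stages", {
  pres <- cbind(g = rep(c(TRUE, FALSE), c(3, 3)))
  rownames(pres) <- paste0("p", 1:6)
  pr <- profiles_from_presence(pres, rep("carcinoma", 6),
                               stage = rep("II", 6))
  sp <- stage_profile(pr, "g")
  expect_equal(sp$stage, "II")  # only stage II is reported
  expect_equal(sp$prop_carriers, 0.5)
  expect_equal(sp$n_stage, 6)

  # unstaged participants are excluded from denominators
  pr <- profiles_from_presence(pres, rep("carcinoma", 6),
                               stage = c("II", "II", NA, NA, "II", "II"))
  sp <- stage_profile(pr, "g")
  expect_equal(sp$n_stage, 4)
  expect_equal(sp$prop_carriers, 0.5)
})

test_that("associate_all tests every gene with one BH family and a direction", {
  expect_equal(nrow(associate_all(
    cohort_profiles(generate_cohort(small_null_config(n = 5, seed = 2))),
    genes = character(0))), 0)

  # planted carcinoma enrichment is flagged with the right direction
  set.seed(29)
  n <- 40
  states <- rep(c("healthy", "adenoma", "carcinoma"), each = n)
  pres <- cbind(hot = c(rbinom(2 * n, 1, 0.2), rbinom(n, 1, 0.8)) == 1,
                cold = rbinom(3 * n, 1, 0.5) == 1)
  rownames(pres) <- paste0("p", seq_len(3 * n))
  res <- associate_all(profiles_from_presence(pres, states))
  expect_equal(res$p_adj, benjamini_hochberg(res$p_raw))
  hot <- res[res$feature == "hot", ]
  expect_equal(hot$direction, "carcinoma")
  expect_lt(hot$p_adj, 0.01)
  expect_equal(hot$signif %in% c("**", "***"), TRUE)

  # ties in direction break toward the more advanced state
  pres_tie <- cbind(g = rep(c(TRUE, FALSE), 3))
  rownames(pres_tie) <- paste0("p", 1:6)
  res_tie <- associate_all(profiles_from_presence(
    pres_tie, rep(c("healthy", "adenoma", "carcinoma"), each = 2)))
  expect_equal(res_tie$direction, "carcinoma")
})

test_that("associate_stage applies the score test over staged carcinoma participants", {
  set.seed(37)
  n <- 120
  stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE)
  x <- c(I = 1, II = 2, III = 3, IV = 4)[stage]
  pres <- cbind(trend = rbinom(n, 1, plogis(-2 + 0.8 * x)) == 1,
                flat = rbinom(n, 1, 0.5) == 1)
  rownames(pres) <- paste0("p", 1:n)
  pr <- profiles_from_presence(pres, rep("carcinoma", n), stage = stage)
  res <- associate_stage(pr)
  expect_lt(res$p_adj[res$feature == "trend"],
            res$p_adj[res$feature == "flat"])
  expect_error(associate_stage(pr, states = "healthy"), "no staged")
})
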