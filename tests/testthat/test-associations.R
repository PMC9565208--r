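test_that("binary-predictor RRRs equal closed-form odds ratios", {
  set.seed(31)
  for (rep in 1:25) {
    n1 <- sample(20:150, 1); n2 <- sample(20:150, 1)
    a <- sample(2:(n1 - 2), 1); b <- sample(2:(n2 - 2), 1)
    est <- rrr_from_counts(c(`1` = a, `2` = b), c(`1` = n1, `2` = n2))
    or <- (b / (n2 - b)) / (a / (n1 - a))
    expect_equal(est$rrr, or, tolerance = 1e-6)
    expect_true(est$ci_low < est$rrr & est$rrr < est$ci_high)
  }
})

test_that("multinomial fits cross-check against an independent optimizer", {
  skip_if_not_installed("nnet")
  set.seed(8)
  y <- sample(1:3, 400, replace = TRUE)
  x <- rnorm(400) + 0.4 * (y == 3)
  ours <- multinomial_rrr(y, x, reference = 1)
  ref <- nnet::multinom(factor(y) ~ x, trace = FALSE, maxit = 500,
                        reltol = 1e-14)
  expect_equal(ours$rrr, unname(exp(coef(ref)[, "x"])), tolerance = 1e-3)
})

test_that("slopes are invariant to constant shifts of the predictor", {
  set.seed(12)
  y <- sample(1:4, 500, replace = TRUE)
  educ <- rnorm(500, 12, 4) + 0.3 * y
  a <- multinomial_rrr(y, educ, reference = 1)
  b <- multinomial_rrr(y, educ + 100, reference = 1)
  expect_equal(a$rrr, b$rrr, tolerance = 1e-8)
})

test_that("re-referencing is consistent and reciprocal", {
  set.seed(13)
  y <- rep(1:3, c(80, 100, 120))
  x <- rbinom(300, 1, c(0.2, 0.4, 0.6)[y])
  base <- multinomial_rrr(y, x, reference = 1)
  ab <- rrr_pair(base, 3, 2)
  expect_equal(ab$rrr,
               base$rrr[base$cluster == "3"] / base$rrr[base$cluster == "2"],
               tolerance = 1e-6)
  # direct refit with the other reference agrees
  direct <- multinomial_rrr(y, x, reference = 2)
  expect_equal(ab$rrr, direct$rrr[direct$cluster == "3"], tolerance = 1e-6)
  ba <- rrr_pair(base, 2, 3)
  expect_equal(ab$rrr * ba$rrr, 1, tolerance = 1e-6)
})

test_that("separation from zero cells is flagged, not dropped", {
  est <- rrr_from_counts(c(`1` = 0, `2` = 10), c(`1` = 30, `2` = 40))
  expect_false(est$finite[est$cluster == "2"])
  expect_equal(nrow(est), 1)
})

test_that("Poisson rate ratios reduce to ratios of sample means", {
  # identical counts in every cluster: all ratios exactly 1
  y <- rep(1:3, each = 30)
  cnt <- rep(rep(0:4, each = 6), 3)
  rr <- poisson_rate_ratio(y, cnt, reference = 1)
  expect_equal(rr$rrr, c(1, 1), tolerance = 1e-12)

  set.seed(20)
  for (rep in 1:20) {
    g <- rep(1:4, times = sample(15:60, 4))
    cnt <- rpois(length(g), c(0.8, 1.5, 2.5, 3.2)[g])
    if (mean(cnt[g == 1]) == 0) next
    rr <- poisson_rate_ratio(g, cnt, reference = 1)
    means <- tapply(cnt, g, mean)
    expect_equal(rr$rrr, as.numeric(means[2:4] / means[1]), tolerance = 1e-9)
  }

  # doubling one cluster's counts doubles its rate ratio
  g <- rep(1:3, each = 40)
  set.seed(21)
  cnt <- rpois(120, 2) + 1
  r1 <- poisson_rate_ratio(g, cnt, reference = 1)
  cnt2 <- ifelse(g == 3, cnt * 2, cnt)
  r2 <- poisson_rate_ratio(g, cnt2, reference = 1)
  expect_equal(r2$rrr[r2$cluster == "3"], 2 * r1$rrr[r1$cluster == "3"],
               tolerance = 1e-9)
})

test_that("estimated RRRs converge to the generator's prevalence odds ratios", {
  # two balanced clusters so each odds is estimated from ~10000 records:
  # the Wald SE of the log odds ratio is then ~0.03, well inside 10%
  prev <- c(0.30, 0.60)
  vars <- analysis_variables()
  clusters <- lapply(1:2, function(i)
    cluster_spec(i, 1000,
                 mean = as.list(setNames(c(70, 0.65, 0.6, 20, 22, 40), vars)),
                 sd = as.list(setNames(c(5, 0.1, 0.1, 5, 1, 3), vars)),
                 prevalence = list(HTN = prev[i]), comorbid_rate = 2))
  spec <- synthetic_spec("woman", clusters, n = 20000, seed = 77)
  gen <- generate_cohort(spec)
  est <- multinomial_rrr(gen$truth, gen$cohort$HTN, reference = 1)
  odds <- prev / (1 - prev)
  expect_equal(est$rrr[est$cluster == "2"], odds[2] / odds[1],
               tolerance = 0.1)
})

test_that("association tables assemble and format pairwise results", {
  gen <- generate_cohort(study_spec("woman", seed = 15, n = 800))
  assoc <- association_table(gen$truth, gen$cohort)
  expect_true(all(assoc$p >= 0 & assoc$p <= 1, na.rm = TRUE))
  expect_true(all(c("multinomial", "poisson") %in% assoc$model))
  # every ordered pair appears for HTN
  htn <- assoc[assoc$condition == "HTN", ]
  expect_equal(nrow(htn), choose(7, 2))
  txt <- format_association_table(assoc)
  expect_true(any(grepl("HTN", txt)))
})
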