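test_that("the normality/variance gates route to the right branch", {
  # heavy-tailed clusters: Shapiro-Wilk should catch exponential data
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    x <- rexp(150); g <- rep(1:3, each = 50)
    hits <- hits + (select_cluster_test(x, g)$test == "kw_dunn")
  }
  expect_gte(hits, 95)

  # normal clusters with equal variances: classical ANOVA branch
  hits <- 0
  for (s in 1:100) {
    set.seed(1000 + s)
    x <- rnorm(150, mean = rep(c(0, 1, 2), each = 50))
    hits <- hits + (select_cluster_test(x, rep(1:3, each = 50))$test ==
                      "anova_tukey")
  }
  expect_gte(hits, 80)

  # 10x variance ratio: whenever the data pass the normality gate (the
  # Shapiro step falsely rejects ~14% of truly normal triples at 0.05),
  # Brown-Forsythe must route to Welch/Games-Howell essentially always
  welch <- 0; past_gate <- 0
  for (s in 1:100) {
    set.seed(2000 + s)
    x <- c(rnorm(50, 0, 1), rnorm(50, 0, 1), rnorm(50, 0, sqrt(10)))
    sel <- select_cluster_test(x, rep(1:3, each = 50))
    if (sel$test != "kw_dunn") {
      past_gate <- past_gate + 1
      welch <- welch + (sel$test == "welch_gameshowell")
    }
  }
  expect_gte(past_gate, 70)
  expect_gte(welch / past_gate, 0.95)

  # clusters too small for Shapiro-Wilk are flagged and sent to ranks
  set.seed(1)
  expect_warning(sel <- select_cluster_test(rnorm(23),
                                            rep(c(1, 2, 3), c(10, 11, 2))),
                 "< 3 observations")
  expect_equal(sel$test, "kw_dunn")
  expect_equal(sel$flagged, "3")
})

test_that("Tukey and Games-Howell agree when their assumptions coincide", {
  # identical residual patterns: sample variances exactly equal across
  # clusters, so the studentized-range statistics are identical and the
  # p-values differ only through the df at O(1/df)
  set.seed(42)
  base <- rnorm(2000)
  x <- c(base, base + 0.11, base + 0.16)
  g <- rep(1:3, each = 2000)
  tk <- posthoc_tukey(x, g)
  gh <- posthoc_games_howell(x, g)
  # same unordered pairs, opposite orientation conventions
  expect_equal(paste(gh$g1, gh$g2), paste(tk$g2, tk$g1))
  expect_equal(gh$estimate, -tk$estimate, tolerance = 1e-12)
  expect_equal(gh$p, tk$p, tolerance = 2e-4)
})

test_that("Dunn z statistics match a direct computation on a small fixture", {
  x <- c(3.1, 4.2, 5.3, 1.0, 2.2, 6.4, 7.5, 8.1, 2.9)
  g <- rep(c("a", "b", "c"), each = 3)
  got <- posthoc_dunn(x, g, adjust = "none")
  # independent large-sample z: rank means over N(N+1)/12 spread (no ties)
  r <- rank(x); N <- length(x)
  rb <- tapply(r, g, mean)
  se <- sqrt(N * (N + 1) / 12 * (1 / 3 + 1 / 3))
  z_ab <- (rb[["a"]] - rb[["b"]]) / se
  z_ac <- (rb[["a"]] - rb[["c"]]) / se
  expect_equal(got$statistic[got$g1 == "a" & got$g2 == "b"], z_ab,
               tolerance = 1e-12)
  expect_equal(got$statistic[got$g1 == "a" & got$g2 == "c"], z_ac,
               tolerance = 1e-12)
  expect_equal(got$p, 2 * pnorm(-abs(got$statistic)), tolerance = 1e-12)
  # Holm adjustment never decreases a p-value
  holm <- posthoc_dunn(x, g, adjust = "holm")
  expect_true(all(holm$p >= got$p - 1e-15))
})

test_that("pairwise matrices detect forced separation with direction", {
  set.seed(7)
  raw <- data.frame(age = c(rnorm(100, 0, 1), rnorm(100, 5, 1)))
  cells <- pairwise_matrix(raw, rep(1:2, each = 100), variables = "age")
  expect_equal(nrow(cells), 1)
  expect_true(cells$significant)
  expect_equal(cells$direction, "greater")    # cluster 2 mean is larger
  expect_equal(cells$i, "2")

  # flipping the group labels mirrors the direction
  cells2 <- pairwise_matrix(raw, rep(2:1, each = 100), variables = "age")
  expect_equal(cells2$direction, "less")

  # constant variable: every cell 'none' with a warning
  rawc <- data.frame(age = rep(1, 60))
  expect_warning(cc <- pairwise_matrix(rawc, rep(1:3, each = 20),
                                       variables = "age"), "constant")
  expect_true(all(cc$direction == "none"))
  expect_false(any(cc$significant))
})

test_that("comparison matrices cover all pairs and format like the tables", {
  gen <- generate_cohort(study_spec("woman", seed = 21, n = 400))
  raw <- derive_ratios(gen$cohort)
  cells <- pairwise_matrix(raw, gen$truth)
  expect_equal(nrow(cells), 6 * choose(7, 2))
  expect_true(all(cells$p >= 0 & cells$p <= 1, na.rm = TRUE))
  expect_true(all(cells$direction[!cells$significant] == "none"))
  expect_true(all(cells$direction[cells$significant] %in% c("greater", "less")))
  txt <- format_comparison_matrix(cells)
  expect_true(any(grepl("^7 vs 1: ", txt)))
  expect_true(any(grepl("Grip/BMI|Gait/Height|LAM%", txt)))
})

test_that("sex comparisons route and summarize like the cohort table", {
  db <- apply_eligibility(simulate_study_database(seed = 2))
  sc <- sex_comparison(db)
  expect_true(all(sc$p >= 0 & sc$p <= 1))
  expect_true(all(sc$test %in% c("t_equal", "t_unequal", "mann_whitney",
                                 "chi2")))
  expect_true(all(c("age", "grip_bmi", "HTN") %in% sc$variable))
  expect_match(sc$women[sc$variable == "HTN"], "^\\d+ \\(")

  # identical groups presented as the two sexes: zero mean difference
  df <- make_cohort_df(40, sex = "woman", seed = 3)
  df2 <- df; df2$sex <- "man"; df2$id <- paste0("M", df2$id)
  same <- as_cohort(rbind(df, df2))
  sc2 <- sex_comparison(same, continuous = "lam_pct", categorical = character(0))
  expect_equal(sc2$p, 1, tolerance = 1e-12)

  expect_error(sex_comparison(as_cohort(df)), "both sexes")
})

test_that("Mann-Whitney agrees with the exact rank-permutation oracle", {
  set.seed(5)
  w <- round(runif(6), 3); m <- round(runif(5) + 0.3, 3)
  p_wilcox <- wilcox.test(w, m, exact = TRUE)$p.value
  # exhaustive permutation distribution of the rank-sum statistic
  pooled <- c(w, m); n1 <- length(w)
  combs <- combn(length(pooled), n1)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  stats <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- n1 * (length(pooled) + 1) / 2
  p_perm <- mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
  expect_equal(p_wilcox, p_perm, tolerance = 1e-12)
})
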