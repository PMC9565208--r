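#' Choose the omnibus/post hoc branch for one variable across clusters
#'
#' Shapiro-Wilk within each cluster gates normality: any rejection routes
#' the variable to Kruskal-Wallis with Dunn post hocs. Otherwise
#' Brown-Forsythe (median-centered Levene) gates variance homogeneity:
#' equal variances give ANOVA with Tukey, unequal give Welch ANOVA with
#' Games-Howell. Clusters with fewer than 3 observations (Shapiro-Wilk
#' undefined) are flagged and the variable routed to the rank branch with a
#' warning.
#'
#' @param values Numeric vector.
#' @param groups Cluster labels (coercible to factor).
#' @param alpha_norm,alpha_var Gate significance levels.
#' @return List: `test` (one of `"anova_tukey"`, `"welch_gameshowell"`,
#'   `"kw_dunn"`), `shapiro_p` per cluster, `levene_p`, `flagged`.
#' @export
select_cluster_test <- function(values, groups, alpha_norm = 0.05,
                                alpha_var = 0.05) {
  groups <- factor(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  if (nlevels(groups) < 2) stop("need at least 2 clusters")
  ns <- table(groups)
  small <- names(ns)[ns < 3]
  if (length(small)) {
    warning("cluster(s) with < 3 observations (", paste(small, collapse = ", "),
            "); Shapiro-Wilk undefined, routing to kw_dunn")
    return(list(test = "kw_dunn", shapiro_p = NULL, levene_p = NA_real_,
                flagged = small))
  }
  shapiro_p <- vapply(levels(groups), function(g) {
    x <- values[groups == g]
    if (stats::sd(x) == 0) return(0)     # degenerate: treat as non-normal
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  if (any(shapiro_p < alpha_norm))
    return(list(test = "kw_dunn", shapiro_p = shapiro_p, levene_p = NA_real_,
                flagged = character(0)))
  lev <- car::leveneTest(values ~ groups, center = stats::median)
  levene_p <- lev[["Pr(>F)"]][1]
  test <- if (levene_p < alpha_var) "welch_gameshowell" else "anova_tukey"
  list(test = test, shapiro_p = shapiro_p, levene_p = levene_p,
       flagged = character(0))
}

pair_grid <- function(lv) {
  cmb <- utils::combn(seq_along(lv), 2)
  data.frame(g1 = lv[cmb[1, ]], g2 = lv[cmb[2, ]], stringsAsFactors = FALSE)
}

#' Post hoc pairwise tests
#'
#' `posthoc_tukey()`: Tukey HSD adjusted p-values from [stats::TukeyHSD()].
#' `posthoc_games_howell()`: Welch-type pairwise t statistics referred to
#' the studentized range with Welch-Satterthwaite degrees of freedom.
#' `posthoc_dunn()`: rank-based z statistics with the tie-corrected pooled
#' variance, two-sided p-values, Holm-adjusted by default.
#'
#' @param values Numeric vector.
#' @param groups Cluster labels.
#' @param adjust P-value adjustment for Dunn (any [stats::p.adjust()]
#'   method; `"none"` for unadjusted).
#' @return Data frame (g1, g2, estimate = mean/rank-mean difference g1-g2,
#'   statistic, p).
#' @export
posthoc_tukey <- function(values, groups) {
  groups <- factor(groups)
  tk <- stats::TukeyHSD(stats::aov(values ~ groups))$groups
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(g1 = vapply(nm, `[`, "", 1), g2 = vapply(nm, `[`, "", 2),
             estimate = tk[, "diff"], statistic = NA_real_,
             p = tk[, "p adj"], row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname posthoc_tukey
#' @export
posthoc_games_howell <- function(values, groups) {
  groups <- factor(groups)
  lv <- levels(groups)
  k <- length(lv)
  m <- tapply(values, groups, mean)
  v <- tapply(values, groups, stats::var)
  n <- tapply(values, groups, length)
  pr <- pair_grid(lv)
  est <- stat <- p <- numeric(nrow(pr))
  for (i in seq_len(nrow(pr))) {
    a <- pr$g1[i]; b <- pr$g2[i]
    se2 <- v[[a]] / n[[a]] + v[[b]] / n[[b]]
    t <- (m[[a]] - m[[b]]) / sqrt(se2)
    df <- se2^2 / ((v[[a]] / n[[a]])^2 / (n[[a]] - 1) +
                   (v[[b]] / n[[b]])^2 / (n[[b]] - 1))
    est[i] <- m[[a]] - m[[b]]
    stat[i] <- t
    p[i] <- stats::ptukey(abs(t) * sqrt(2), nmeans = k, df = df,
                          lower.tail = FALSE)
  }
  data.frame(g1 = pr$g1, g2 = pr$g2, estimate = est, statistic = stat, p = p,
             stringsAsFactors = FALSE)
}

#' @rdname posthoc_tukey
#' @export
posthoc_dunn <- function(values, groups, adjust = "holm") {
  groups <- factor(groups)
  lv <- levels(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  pr <- pair_grid(lv)
  z <- (unlist(rbar[pr$g1]) - unlist(rbar[pr$g2])) /
    sqrt(s2 * (1 / unlist(n[pr$g1]) + 1 / unlist(n[pr$g2])))
  p <- stats::p.adjust(2 * stats::pnorm(-abs(z)), method = adjust)
  data.frame(g1 = pr$g1, g2 = pr$g2,
             estimate = as.numeric(unlist(rbar[pr$g1]) - unlist(rbar[pr$g2])),
             statistic = as.numeric(z), p = as.numeric(p),
             stringsAsFactors = FALSE)
}

#' Pairwise comparison matrix across clusters
#'
#' For each analysis variable: route via [select_cluster_test()], evaluate
#' all k(k-1)/2 post hoc pairs, and mark significant cells with the
#' direction of the cluster-mean difference (`greater`/`less`, read as "the
#' mean in cluster i is greater/less than in cluster j", i > j). The
#' omnibus p-value is reported for transparency; by default post hocs are
#' not gated on it (the published pairwise tables are read directly), set
#' `gate_omnibus = TRUE` for strict gating.
#'
#' @param raw Data frame with the analysis variables (see [derive_ratios()]).
#' @param member_labels Cluster label per row of `raw`.
#' @param variables Variables to compare (default all six).
#' @param alpha Significance level for cells.
#' @param gate_omnibus If `TRUE`, cells are significant only when the
#'   omnibus test is also significant at `alpha`.
#' @param dunn_adjust Dunn p-value adjustment.
#' @param alpha_norm,alpha_var Gate levels for the routing tests.
#' @return Data frame of cells: variable, i, j (i > j), test, omnibus_p, p,
#'   direction (`greater`/`less`/`none`), significant.
#' @export
pairwise_matrix <- function(raw, member_labels, variables = analysis_variables(),
                            alpha = 0.05, gate_omnibus = FALSE,
                            dunn_adjust = "holm",
                            alpha_norm = 0.05, alpha_var = 0.05) {
  groups <- factor(member_labels)
  if (nlevels(droplevels(groups)) < 2) stop("need >= 2 non-empty clusters")
  cells <- list()
  for (v in variables) {
    values <- raw[[v]]
    ok <- !is.na(values)
    x <- values[ok]; g <- droplevels(groups[ok])
    if (stats::sd(x) == 0) {
      warning("variable ", v, " constant everywhere; all cells 'none'")
      pr <- pair_grid(levels(g))
      cells[[v]] <- data.frame(variable = v, i = pr$g2, j = pr$g1,
                               test = NA_character_, omnibus_p = NA_real_,
                               p = NA_real_, direction = "none",
                               significant = FALSE, stringsAsFactors = FALSE)
      next
    }
    sel <- select_cluster_test(x, g, alpha_norm, alpha_var)
    omnibus_p <- switch(sel$test,
      anova_tukey = summary(stats::aov(x ~ g))[[1]][["Pr(>F)"]][1],
      welch_gameshowell = stats::oneway.test(x ~ g, var.equal = FALSE)$p.value,
      kw_dunn = stats::kruskal.test(x, g)$p.value)
    ph <- switch(sel$test,
      anova_tukey = posthoc_tukey(x, g),
      welch_gameshowell = posthoc_games_howell(x, g),
      kw_dunn = posthoc_dunn(x, g, adjust = dunn_adjust))
    means <- tapply(x, g, mean)
    sig <- ph$p < alpha & (!gate_omnibus | omnibus_p < alpha)
    # orient cells as (i, j) with i the later factor level (higher cluster)
    swap <- match(ph$g1, levels(g)) > match(ph$g2, levels(g))
    i <- ifelse(swap, ph$g1, ph$g2); j <- ifelse(swap, ph$g2, ph$g1)
    di <- means[i] - means[j]
    cells[[v]] <- data.frame(
      variable = v, i = i, j = j, test = sel$test, omnibus_p = omnibus_p,
      p = ph$p,
      direction = ifelse(!sig, "none", ifelse(di > 0, "greater", "less")),
      significant = sig, row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  out
}

#' Render comparison cells as a compact text table
#'
#' One line per significant cell in the published style, e.g.
#' `7 vs 1: >Age`, meaning the variable mean in cluster 7 is greater than
#' in cluster 1.
#'
#' @param cells Result of [pairwise_matrix()].
#' @return Character vector (one formatted row per cluster pair).
#' @export
format_comparison_matrix <- function(cells) {
  disp <- stats::setNames(analysis_variables(display = TRUE),
                          analysis_variables())
  sig <- cells[cells$significant, , drop = FALSE]
  if (!nrow(sig)) return(character(0))
  key <- paste(sig$i, "vs", sig$j)
  vapply(split(sig, key)[unique(key)], function(d)
    paste0(d$i[1], " vs ", d$j[1], ": ",
           paste0(ifelse(d$direction == "greater", ">", "<"),
                  ifelse(d$variable %in% names(disp), disp[d$variable],
                         d$variable),
                  collapse = " ")),
    character(1), USE.NAMES = FALSE)
}

#' Descriptive comparison of women and men
#'
#' Continuous variables: Kolmogorov-Smirnov normality per sex (against a
#' normal with the sample moments); if both sexes look normal, a
#' Brown-Forsythe gate selects the equal- or unequal-variance t-test,
#' otherwise a Mann-Whitney test. Categorical variables: Pearson chi-square
#' (no continuity correction) on the contingency table. Summaries are
#' mean +/- sd or n (%).
#'
#' @param cohort A `cohort_table` containing both sexes.
#' @param continuous Continuous variable names (columns of the cohort or of
#'   [derive_ratios()]).
#' @param categorical Categorical (0/1 condition) column names.
#' @param alpha Gate level for normality/variance routing.
#' @return Data frame: variable, women, men, test, p.
#' @export
sex_comparison <- function(cohort,
                           continuous = c("age", "gait_height", "grip_bmi",
                                          "balance", "lam_pct", "fat_pct",
                                          "height", "bmi", "gait_speed",
                                          "grip_strength", "educ_years"),
                           categorical = condition_codes(),
                           alpha = 0.05) {
  df <- as.data.frame(cohort)
  if (!all(c("woman", "man") %in% df$sex)) stop("both sexes must be present")
  ratios <- tryCatch(derive_ratios(cohort), error = function(e) NULL)
  if (!is.null(ratios))
    for (v in setdiff(names(ratios), c("id", names(df)))) df[[v]] <- ratios[[v]]
  rows <- list()
  for (v in intersect(continuous, names(df))) {
    w <- df[[v]][df$sex == "woman"]; m <- df[[v]][df$sex == "man"]
    w <- w[!is.na(w)]; m <- m[!is.na(m)]
    if (!length(w) || !length(m)) next
    ksp <- vapply(list(w, m), function(x)
      suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value),
      numeric(1))
    if (all(ksp >= alpha)) {
      g <- factor(rep(c("w", "m"), c(length(w), length(m))))
      levp <- car::leveneTest(c(w, m) ~ g, center = stats::median)[["Pr(>F)"]][1]
      equal <- levp >= alpha
      test <- if (equal) "t_equal" else "t_unequal"
      p <- stats::t.test(w, m, var.equal = equal)$p.value
    } else {
      test <- "mann_whitney"
      p <- suppressWarnings(stats::wilcox.test(w, m)$p.value)
    }
    fmt <- function(x) sprintf("%.1f ± %.1f", mean(x), stats::sd(x))
    rows[[v]] <- data.frame(variable = v, women = fmt(w), men = fmt(m),
                            test = test, p = p, stringsAsFactors = FALSE)
  }
  for (v in intersect(categorical, names(df))) {
    x <- df[[v]]
    ok <- !is.na(x) & !is.na(df$sex)
    tab <- table(df$sex[ok], factor(x[ok], levels = c(0, 1)))
    if (any(rowSums(tab) == 0) || length(unique(x[ok])) < 2) next
    p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    fmt <- function(s) sprintf("%d (%.1f)", tab[s, "1"],
                               100 * tab[s, "1"] / sum(tab[s, ]))
    rows[[v]] <- data.frame(variable = v, women = fmt("woman"),
                            men = fmt("man"), test = "chi2", p = p,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
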