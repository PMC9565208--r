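# Newton-Raphson maximum-likelihood fit of a univariate multinomial logit:
# P(y = g | x) proportional to exp(b0_g + b1_g x), reference category fixed
# at 0. Quadratic convergence gives machine-precision agreement with the
# closed-form per-category odds ratios for a binary predictor, which Wald
# inference then uses via the observed information.
fit_multinomial <- function(y, x, ref, maxit = 200, tol = 1e-12) {
  y <- factor(y)
  lv <- levels(y)
  if (!as.character(ref) %in% lv) stop("reference level not present")
  lv <- c(as.character(ref), setdiff(lv, as.character(ref)))
  y <- factor(y, levels = lv)
  keep <- !is.na(y) & !is.na(x)
  y <- y[keep]; x <- x[keep]
  if (length(unique(x)) < 2) stop("predictor does not vary")
  J <- length(lv)
  # aggregate: unique covariate values with per-category counts
  ux <- sort(unique(x))
  Xd <- cbind(1, ux)
  Cnt <- t(vapply(ux, function(u) as.numeric(table(y[x == u])), numeric(J)))
  Ni <- rowSums(Cnt)
  p <- 2L                                # intercept + slope
  B <- matrix(0, J - 1, p)
  npar <- (J - 1) * p
  for (it in seq_len(maxit)) {
    Eta <- Xd %*% t(B)                   # n_u x (J-1)
    Eta <- cbind(0, Eta)
    Eta <- Eta - apply(Eta, 1, max)
    P <- exp(Eta) / rowSums(exp(Eta))    # n_u x J
    Pn <- P[, -1, drop = FALSE]
    grad <- numeric(npar)
    Hess <- matrix(0, npar, npar)
    for (g in seq_len(J - 1)) {
      rg <- (g - 1) * p + 1:2
      grad[rg] <- colSums((Cnt[, g + 1] - Ni * Pn[, g]) * Xd)
      for (h in seq_len(J - 1)) {
        rh <- (h - 1) * p + 1:2
        wgh <- Ni * Pn[, g] * ((g == h) - Pn[, h])
        Hess[rg, rh] <- t(Xd) %*% (wgh * Xd)
      }
    }
    step <- tryCatch(solve(Hess, grad), error = function(e) NULL)
    if (is.null(step)) break
    B <- B + matrix(step, J - 1, p, byrow = TRUE)
    if (max(abs(step)) < tol) break
  }
  separated <- any(abs(B) > 30)
  vcov <- tryCatch(solve(Hess), error = function(e)
    matrix(NA_real_, npar, npar))
  list(levels = lv, coef = B, vcov = vcov, separated = separated,
       iterations = it)
}

#' Relative risk ratios from a univariate multinomial logistic model
#'
#' Fits cluster membership against a single predictor (binary condition
#' flag or continuous covariate) by maximum likelihood and reports, per
#' non-reference cluster, the exponentiated predictor coefficient (the
#' relative risk ratio), its Wald 95% confidence interval and p-value. For
#' a binary predictor the RRR equals the closed-form odds ratio of the
#' per-cluster 2x2 table against the reference. Zero cells (separation)
#' are flagged `finite = FALSE` and reported with one-sided intervals
#' rather than dropped.
#'
#' @param member_labels Cluster label per participant.
#' @param predictor Numeric (0/1 for conditions) per participant.
#' @param reference Reference cluster label.
#' @param condition Optional condition code carried into the output.
#' @param conf Confidence level.
#' @return Data frame: condition, cluster, reference, rrr, ci_low, ci_high,
#'   p, finite, model.
#' @export
multinomial_rrr <- function(member_labels, predictor, reference = 1,
                            condition = NA_character_, conf = 0.95) {
  fit <- fit_multinomial(member_labels, predictor, reference)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  out <- lapply(seq_along(fit$levels)[-1], function(gi) {
    g <- gi - 1
    b <- fit$coef[g, 2]
    se <- sqrt(fit$vcov[(g - 1) * 2 + 2, (g - 1) * 2 + 2])
    finite <- !fit$separated || abs(b) <= 30
    data.frame(condition = condition, cluster = fit$levels[gi],
               reference = fit$levels[1],
               rrr = exp(b),
               ci_low = if (finite) exp(b - z * se) else
                 if (b > 0) exp(b - z * se) else 0,
               ci_high = if (finite) exp(b + z * se) else
                 if (b > 0) Inf else exp(b + z * se),
               p = 2 * stats::pnorm(-abs(b / se)),
               finite = finite, model = "multinomial",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  attr(out, "fit") <- fit
  out
}

#' RRR between any two clusters
#'
#' Re-references a fitted univariate multinomial model: the coefficient
#' contrast `b_a - b_b` gives RRR(a vs b), with the Wald variance from the
#' joint covariance, so `rrr_pair(f, a, b) == RRR(a vs ref)/RRR(b vs ref)`.
#'
#' @param rrr Result of [multinomial_rrr()].
#' @param a,b Cluster labels to compare (either may be the reference).
#' @param conf Confidence level.
#' @return One-row data frame in the same layout as [multinomial_rrr()].
#' @export
rrr_pair <- function(rrr, a, b, conf = 0.95) {
  fit <- attr(rrr, "fit")
  if (is.null(fit)) stop("rrr must carry its fit (from multinomial_rrr)")
  lv <- fit$levels
  pos <- function(g) match(as.character(g), lv) - 1   # 0 = reference
  ia <- pos(a); ib <- pos(b)
  if (is.na(ia) || is.na(ib)) stop("unknown cluster label")
  cf <- function(i) if (i == 0) 0 else fit$coef[i, 2]
  vv <- function(i) if (i == 0) 0 else fit$vcov[(i - 1) * 2 + 2, (i - 1) * 2 + 2]
  cv <- if (ia > 0 && ib > 0) fit$vcov[(ia - 1) * 2 + 2, (ib - 1) * 2 + 2] else 0
  b_ <- cf(ia) - cf(ib)
  se <- sqrt(vv(ia) + vv(ib) - 2 * cv)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  data.frame(condition = rrr$condition[1], cluster = as.character(a),
             reference = as.character(b),
             rrr = exp(b_), ci_low = exp(b_ - z * se),
             ci_high = exp(b_ + z * se),
             p = 2 * stats::pnorm(-abs(b_ / se)),
             finite = is.finite(b_) && abs(b_) <= 60, model = "multinomial",
             stringsAsFactors = FALSE)
}

#' RRRs directly from per-cluster event counts
#'
#' Convenience wrapper reconstructing the participant-level data from
#' per-cluster condition counts and sizes, then fitting the univariate
#' multinomial model of [multinomial_rrr()].
#'
#' @param events Named (by cluster label) event counts.
#' @param totals Cluster sizes, same names.
#' @param reference Reference cluster label.
#' @param condition Condition code for the output.
#' @return As [multinomial_rrr()].
#' @export
rrr_from_counts <- function(events, totals, reference = names(totals)[1],
                            condition = NA_character_) {
  stopifnot(length(events) == length(totals), all(events <= totals))
  labs <- names(totals) %||% seq_along(totals)
  y <- rep(labs, times = totals)
  x <- unlist(lapply(seq_along(totals), function(i)
    rep(c(1, 0), c(events[i], totals[i] - events[i]))))
  multinomial_rrr(y, x, reference = reference, condition = condition)
}

#' Poisson rate ratios for comorbidity counts
#'
#' Log-linear Poisson model of the count on cluster indicators; for this
#' single-factor model the fitted rate ratio per cluster equals the ratio
#' of that cluster's mean count to the reference mean. Wald 95% intervals
#' and p-values are reported. Missing counts are dropped pairwise; a
#' reference cluster with mean 0 yields non-finite ratios, flagged.
#'
#' @param member_labels Cluster label per participant.
#' @param counts Non-negative integer counts.
#' @param reference Reference cluster label.
#' @param conf Confidence level.
#' @return Data frame: condition, cluster, reference, rrr (rate ratio),
#'   ci_low, ci_high, p, finite, model.
#' @export
poisson_rate_ratio <- function(member_labels, counts, reference = 1,
                               conf = 0.95) {
  keep <- !is.na(counts) & !is.na(member_labels)
  counts <- counts[keep]; member_labels <- member_labels[keep]
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  y <- stats::relevel(factor(member_labels), ref = as.character(reference))
  fit <- stats::glm(counts ~ y, family = stats::poisson(),
                    control = stats::glm.control(epsilon = 1e-14, maxit = 100))
  cf <- summary(fit)$coefficients
  idx <- grep("^y", rownames(cf))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ref_mean <- mean(counts[y == levels(y)[1]])
  out <- data.frame(condition = "NUMCOM",
                    cluster = sub("^y", "", rownames(cf)[idx]),
                    reference = levels(y)[1],
                    rrr = exp(cf[idx, "Estimate"]),
                    ci_low = exp(cf[idx, "Estimate"] - z * cf[idx, "Std. Error"]),
                    ci_high = exp(cf[idx, "Estimate"] + z * cf[idx, "Std. Error"]),
                    p = cf[idx, "Pr(>|z|)"],
                    finite = ref_mean > 0 & is.finite(cf[idx, "Estimate"]),
                    model = "poisson", stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' All-pairs association table for a set of conditions
#'
#' Runs the univariate multinomial model per condition (and the Poisson
#' model for the comorbidity count) and reports every ordered cluster pair
#' (a > b), in the layout of the published pairwise association tables.
#'
#' @param member_labels Cluster label per participant.
#' @param cohort `cohort_table` aligned with `member_labels`.
#' @param conditions Condition columns to test (binary or continuous, e.g.
#'   `educ_years`).
#' @param counts_var Column holding the comorbidity count (`NULL` to skip).
#' @param alpha Significance filter used by [format_association_table()].
#' @return Data frame of pairwise estimates with p-values.
#' @export
association_table <- function(member_labels, cohort,
                              conditions = c("CI", "ADLD", "FF", "educ_years",
                                             "PVD", "HTN"),
                              counts_var = "num_comorbid", alpha = 0.05) {
  df <- as.data.frame(cohort)
  labs <- sort(unique(member_labels))
  rows <- list()
  for (cond in conditions) {
    x <- df[[cond]]
    if (is.null(x) || length(unique(x[!is.na(x)])) < 2) next
    base <- multinomial_rrr(member_labels, x, reference = labs[1],
                            condition = cond)
    for (a in labs) for (b in labs) {
      if (match(a, labs) <= match(b, labs)) next
      rows[[paste(cond, a, b)]] <- rrr_pair(base, a, b)
    }
  }
  if (!is.null(counts_var) && counts_var %in% names(df)) {
    for (b in labs) {
      pr <- poisson_rate_ratio(member_labels, df[[counts_var]], reference = b)
      pr <- pr[match(pr$cluster, as.character(labs)) > match(b, labs), ,
               drop = FALSE]
      if (nrow(pr)) rows[[paste("NUMCOM", b)]] <- pr
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}

#' @rdname association_table
#' @param assoc Result of [association_table()].
#' @export
format_association_table <- function(assoc, alpha = attr(assoc, "alpha") %||% 0.05) {
  sig <- assoc[!is.na(assoc$p) & assoc$p < alpha & assoc$finite, , drop = FALSE]
  if (!nrow(sig)) return(character(0))
  key <- paste(sig$cluster, "vs", sig$reference)
  vapply(split(sig, key)[unique(key)], function(d)
    paste0(d$cluster[1], " vs ", d$reference[1], ": ",
           paste(sprintf("%.1f %s", d$rrr,
                         ifelse(d$condition == "educ_years", "EDUC",
                                d$condition)), collapse = " ")),
    character(1), USE.NAMES = FALSE)
}
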