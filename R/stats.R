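#' Shapiro-Wilk normality check
#'
#' @param x Numeric series, n >= 3 (Shapiro-Wilk requires 3-5000 values;
#'   longer series are subsampled to the first 5000).
#' @param alpha Decision threshold.
#' @return A list with `W`, `p`, `decision` ("normal" / "non-normal" /
#'   "degenerate") and `degenerate` flag (constant input).
#' @export
normality_check <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3) stop("normality check needs at least 3 values")
  if (stats::sd(x) == 0)
    return(list(W = NA_real_, p = NA_real_, decision = "degenerate",
                degenerate = TRUE))
  if (length(x) > 5000) x <- x[1:5000]
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value,
       decision = if (sw$p.value < alpha) "non-normal" else "normal",
       degenerate = FALSE)
}

#' Correlation with automatic method selection
#'
#' Policy `"auto"` follows the study convention: Pearson when both series
#' pass normality, otherwise Spearman rank-order correlation (used for all
#' tract-level call-count analyses). Policy `"log_pearson"` applies a
#' `log(x + 1)` transform to the first series (counts admit zeros) before
#' Pearson.
#'
#' @param x,y Numeric series of equal length >= 4. For `log_pearson`, `x`
#'   is the count variable.
#' @param policy One of `"auto"`, `"pearson"`, `"spearman"`,
#'   `"log_pearson"`.
#' @return A list with `estimate`, `p`, `method`, `n` and a
#'   `zero_variance` flag (estimate `NA` when flagged).
#' @export
correlate <- function(x, y, policy = c("auto", "pearson", "spearman",
                                       "log_pearson")) {
  policy <- match.arg(policy)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("correlation needs at least 4 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(estimate = NA_real_, p = NA_real_, method = policy,
                n = length(x), zero_variance = TRUE))

  method <- switch(policy,
    pearson = "pearson",
    spearman = "spearman",
    log_pearson = "pearson",
    auto = {
      nx <- normality_check(x); ny <- normality_check(y)
      if (identical(nx$decision, "normal") && identical(ny$decision, "normal"))
        "pearson" else "spearman"
    })
  if (policy == "log_pearson") x <- log1p(x)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = FALSE,
                    alternative = "two.sided"))
  list(estimate = unname(ct$estimate), p = ct$p.value,
       method = if (policy == "log_pearson") "log_pearson" else method,
       n = length(x), zero_variance = FALSE)
}

# Compact letter display from a symmetric significance matrix: groups are
# sorted by decreasing mean; every maximal set of mutually non-different
# groups gets one letter.
letters_from_sig <- function(sig, means) {
  k <- length(means)
  ord <- order(-means)
  if (k > 16) stop("letter display supports up to 16 groups")
  subsets <- list()
  for (code in seq_len(2^k - 1)) {
    members <- which(bitwAnd(code, 2^(seq_len(k) - 1)) > 0)
    if (all(!sig[members, members])) subsets[[length(subsets) + 1]] <- members
  }
  keep <- vapply(subsets, function(s) {
    !any(vapply(subsets, function(t)
      length(t) > length(s) && all(s %in% t), logical(1)))
  }, logical(1))
  cliques <- subsets[keep]
  best <- vapply(cliques, function(s) max(means[s]), numeric(1))
  cliques <- cliques[order(-best)]
  lab <- rep("", k)
  for (i in seq_along(cliques))
    for (g in cliques[[i]]) lab[g] <- paste0(lab[g], letters[i])
  lab
}

#' Between-period comparison with significance letters
#'
#' One-way ANOVA across the Pre / EHE / Post day groups followed by Tukey
#' HSD pairwise comparisons at `alpha`; groups sharing no letter differ
#' significantly. A period is flagged `distinct` when it shares no letter
#' with any other period (e.g. an extreme-heat period whose mean differs
#' from both flanking periods).
#'
#' @param value Numeric daily values.
#' @param period Grouping factor/character (>= 2 groups of >= 2 values).
#' @param alpha Significance level.
#' @return A list with a `summary` data.frame (`period`, `n`, `mean`, `sd`,
#'   `letters`, `distinct`), the overall `anova_p`, and the `tukey` table.
#' @export
period_compare <- function(value, period, alpha = 0.05) {
  period <- factor(period)
  if (nlevels(period) < 2) stop("need at least 2 groups")
  if (any(table(period) < 2)) stop("every group needs at least 2 values")
  lev <- levels(period)
  k <- length(lev)
  means <- tapply(value, period, mean)
  resid_sd <- stats::sd(value - means[period])
  sig <- matrix(FALSE, k, k, dimnames = list(lev, lev))
  if (is.na(resid_sd) || resid_sd < 1e-10 * max(1, abs(mean(value)))) {
    # degenerate within-group variance: groups differ iff their means do
    an_p <- NA_real_
    tk <- NULL
    for (i in seq_len(k)) for (j in seq_len(k))
      sig[i, j] <- abs(means[i] - means[j]) >
        1e-10 * max(1, abs(mean(value)))
  } else {
    fit <- stats::aov(value ~ period)
    an_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$period
    for (cmp in rownames(tk)) {
      pr <- strsplit(cmp, "-", fixed = TRUE)[[1]]
      s <- tk[cmp, "p adj"] < alpha
      sig[pr[1], pr[2]] <- sig[pr[2], pr[1]] <- s
    }
  }
  lab <- letters_from_sig(sig, as.numeric(means))
  shared <- vapply(seq_len(k), function(i) {
    any(vapply(setdiff(seq_len(k), i), function(j) {
      length(intersect(strsplit(lab[i], "")[[1]],
                       strsplit(lab[j], "")[[1]])) > 0
    }, logical(1)))
  }, logical(1))
  list(summary = data.frame(period = lev,
                            n = as.integer(table(period)),
                            mean = as.numeric(means),
                            sd = as.numeric(tapply(value, period, stats::sd)),
                            letters = lab,
                            distinct = !shared,
                            stringsAsFactors = FALSE),
       anova_p = an_p, tukey = tk)
}
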