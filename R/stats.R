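#' Jarque-Bera normality test
#'
#' JB = n/6 (S^2 + (K - 3)^2 / 4) with sample skewness S = m3 / m2^(3/2)
#' and kurtosis K = m4 / m2^2 (central moments with 1/n weights); the
#' p-value is from the chi-square distribution with 2 degrees of freedom
#' (asymptotic null).
#'
#' @param values numeric vector, n >= 4.
#' @return list: `statistic`, `p_value`, `skewness`, `kurtosis`, `n`.
#' @export
jarque_bera <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 4) stop("Jarque-Bera needs at least 4 values")
  m <- mean(values)
  xc <- values - m
  m2 <- mean(xc^2)
  if (m2 <= 0) stop("degenerate sample: zero variance")
  S <- mean(xc^3) / m2^1.5
  K <- mean(xc^4) / m2^2
  jb <- n / 6 * (S^2 + (K - 3)^2 / 4)
  list(statistic = jb, p_value = pchisq(jb, df = 2, lower.tail = FALSE),
       skewness = S, kurtosis = K, n = n)
}

#' One-way ANOVA with Bonferroni post hoc comparisons
#'
#' Fixed-effects one-way ANOVA across groups, followed by all pairwise
#' two-sided t tests with Bonferroni adjustment over the number of pairs.
#' Pairwise tests use the classical pooled-variance convention by default
#' (`pool_sd = TRUE`, pooling across all groups); a Welch variant is
#' available. Groups with fewer than two values are excluded with a
#' warning. Per-group Jarque-Bera normality screens are attached when every
#' group has at least four values.
#'
#' @param values numeric vector of observations.
#' @param groups factor/character of the same length.
#' @param alpha significance level (default 0.05).
#' @param pool_sd pooled-variance pairwise tests (default `TRUE`).
#' @return a `comparison_result`: list with `f_stat`, `p_value`, `df`,
#'   `pairwise` (data.frame: group1, group2, p_adj, significant),
#'   `normality` (data.frame or NULL), `alpha`, `groups_used`.
#' @export
anova_bonferroni <- function(values, groups, alpha = 0.05,
                             pool_sd = TRUE) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning("excluding groups with < 2 values: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) stop("need at least 2 groups with >= 2 values")
  if (all(tapply(values, groups, var) == 0))
    stop("degenerate input: zero within-group variance in every group")

  dat <- data.frame(y = values, g = groups)
  fit <- aov(y ~ g, data = dat)
  at <- anova(fit)
  f_stat <- at[["F value"]][1]
  p_value <- at[["Pr(>F)"]][1]

  pw <- pairwise.t.test(values, groups, p.adjust.method = "bonferroni",
                        pool.sd = pool_sd)
  pm <- pw$p.value
  pairs <- which(!is.na(pm), arr.ind = TRUE)
  pairwise <- data.frame(
    group1 = rownames(pm)[pairs[, 1]],
    group2 = colnames(pm)[pairs[, 2]],
    p_adj = pm[pairs],
    stringsAsFactors = FALSE)
  pairwise$significant <- pairwise$p_adj < alpha

  normality <- NULL
  if (all(sizes[sizes >= 2] >= 4)) {
    normality <- do.call(rbind, lapply(levels(groups), function(g) {
      jb <- tryCatch(jarque_bera(values[groups == g]),
                     error = function(e) list(statistic = NA_real_,
                                              p_value = NA_real_))
      data.frame(group = g, jb_statistic = jb$statistic,
                 jb_p = jb$p_value)
    }))
  }

  structure(list(f_stat = f_stat, p_value = p_value,
                 df = at$Df, pairwise = pairwise, normality = normality,
                 alpha = alpha, groups_used = levels(groups)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.3g (df %d, %d), p = %.4g\n",
              x$f_stat, x$df[1], x$df[2], x$p_value))
  sig <- x$pairwise[x$pairwise$significant, , drop = FALSE]
  if (nrow(sig) > 0) {
    cat(sprintf("Significant pairs (Bonferroni, alpha = %.3g):\n", x$alpha))
    for (i in seq_len(nrow(sig)))
      cat(sprintf("  %s vs %s: p_adj = %.4g\n", sig$group1[i],
                  sig$group2[i], sig$p_adj[i]))
  } else {
    cat("No pair significant after Bonferroni adjustment.\n")
  }
  invisible(x)
}

#' Signed percent difference against a reference
#'
#' `100 * (other - reference) / reference`, rounded to one decimal (the
#' reporting precision of group contrasts).
#'
#' @param reference_mean reference group mean (non-zero).
#' @param other_mean other group mean.
#' @param digits decimals to round to (default 1).
#' @return signed percent difference.
#' @export
percent_contrast <- function(reference_mean, other_mean, digits = 1) {
  if (reference_mean == 0) stop("reference mean must be non-zero")
  round(100 * (other_mean - reference_mean) / reference_mean, digits)
}

#' Group comparison over a metric table
#'
#' Runs [anova_bonferroni()] for each metric column of a per-VOI result
#' table, treating per-VOI values as independent observations.
#'
#' @param results data.frame with a `group` column and metric columns.
#' @param metrics character vector of metric column names; default all
#'   numeric columns except `voi`.
#' @param alpha significance level.
#' @return named list of `comparison_result` objects (metrics with any
#'   non-finite or degenerate data are skipped with a message).
#' @export
compare_groups <- function(results, metrics = NULL, alpha = 0.05) {
  stopifnot("group" %in% names(results))
  if (is.null(metrics)) {
    num <- vapply(results, is.numeric, logical(1))
    metrics <- setdiff(names(results)[num], c("voi", "sample"))
  }
  out <- list()
  for (m in metrics) {
    v <- results[[m]]
    ok <- is.finite(v)
    res <- tryCatch(
      anova_bonferroni(v[ok], results$group[ok], alpha = alpha),
      error = function(e) {
        message("skipping ", m, ": ", conditionMessage(e))
        NULL
      })
    if (!is.null(res)) out[[m]] <- res
  }
  out
}
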