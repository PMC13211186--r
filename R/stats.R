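# Dish-level statistical pipeline: Shapiro-Wilk and Levene assumption
# checks, paired/unpaired Student t tests, one-way ANOVA and Fisher's least
# significant difference (LSD) post hoc, applied to dish means (the dish is
# the experimental unit). Significance threshold alpha = 0.05 throughout.
# Standard tests are delegated to the stats package; LSD (no base
# equivalent) uses the pooled ANOVA error with no multiplicity adjustment
# and is gated on ANOVA significance.

stat_result <- function(test, statistic, df, p_value, alpha = 0.05, ...) {
  structure(list(test = test, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p_value), alpha = alpha,
                 significant = is.finite(p_value) && p_value < alpha, ...),
            class = "ivm_stat")
}

#' @export
print.ivm_stat <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g%s\n", x$test,
              x$statistic, paste(signif(x$df, 6), collapse = ", "),
              x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' W statistic and p-value via the Royston approximation (as implemented in
#' `stats::shapiro.test`). Requires 3 <= n <= 5000 and non-zero variance; W
#' is invariant under affine transforms of the input.
#'
#' @param values Numeric vector.
#' @param alpha Significance level.
#' @return An `ivm_stat` with the W statistic (`df` is the sample size).
#' @export
shapiro_wilk <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  abort_if(n < 3 || n > 5000, "Shapiro-Wilk requires 3 <= n <= 5000")
  abort_if(stats::var(values) == 0, "all values identical (zero variance)")
  r <- stats::shapiro.test(values)
  stat_result("shapiro_wilk", r$statistic, n, r$p.value, alpha)
}

#' Levene's test for homogeneity of variance
#'
#' One-way ANOVA on absolute deviations from the group center (mean by
#' default; median gives the Brown-Forsythe variant).
#'
#' @param groups List of numeric vectors, each of length >= 2.
#' @param center `"mean"` or `"median"`.
#' @param alpha Significance level.
#' @return An `ivm_stat` with the F statistic and `(df1, df2)`.
#' @export
levene <- function(groups, center = c("mean", "median"), alpha = 0.05) {
  center <- match.arg(center)
  abort_if(!is.list(groups) || length(groups) < 2, "need >= 2 groups")
  abort_if(any(vapply(groups, length, integer(1)) < 2),
           "each group needs n >= 2")
  cfun <- if (center == "mean") mean else stats::median
  devs <- lapply(groups, function(g) abs(g - cfun(g)))
  if (stats::var(unlist(devs)) == 0) {
    # degenerate: all absolute deviations equal -> no variance heterogeneity
    k <- length(groups); n <- length(unlist(devs))
    return(stat_result("levene", 0, c(k - 1, n - k), 1, alpha,
                       center = center))
  }
  a <- one_way_anova(devs)
  stat_result("levene", a$F, c(a$df_between, a$df_within), a$p_value, alpha,
              center = center)
}

#' Paired two-tailed Student's t test
#'
#' t on the within-pair differences `post - pre`, df = n - 1; used for
#' pre- versus post-incubation diameters measured on the same oocytes.
#'
#' @param pre,post Paired numeric vectors of equal length (n >= 2).
#' @param alpha Significance level.
#' @return An `ivm_stat`.
#' @export
paired_t <- function(pre, post, alpha = 0.05) {
  abort_if(length(pre) != length(post), "pre/post length mismatch")
  abort_if(length(pre) < 2, "need n >= 2 pairs")
  d <- post - pre
  if (stats::var(d) == 0 && all(d == 0)) {
    return(stat_result("paired_t", 0, length(d) - 1, 1, alpha,
                       mean_difference = 0))
  }
  abort_if(stats::var(d) == 0, "zero difference variance with nonzero shift")
  r <- stats::t.test(d)
  stat_result("paired_t", r$statistic, r$parameter, r$p.value, alpha,
              mean_difference = mean(d))
}

#' Unpaired two-tailed Student's t test
#'
#' Pooled-variance two-sample t, df = `n_a + n_b - 2`.
#'
#' @param a,b Numeric vectors, each n >= 2.
#' @param alpha Significance level.
#' @return An `ivm_stat`.
#' @export
unpaired_t <- function(a, b, alpha = 0.05) {
  abort_if(length(a) < 2 || length(b) < 2, "each group needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    abort_if(mean(a) != mean(b),
             "zero pooled variance with unequal means (infinite t)")
    return(stat_result("unpaired_t", 0, length(a) + length(b) - 2, 1, alpha,
                       mean_difference = 0))
  }
  r <- stats::t.test(a, b, var.equal = TRUE)
  stat_result("unpaired_t", r$statistic, r$parameter, r$p.value, alpha,
              mean_difference = mean(a) - mean(b))
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition; F = MSB/MSW with p from the F
#' distribution. Group means, sizes and the pooled mean squared error are
#' retained for the LSD post hoc test.
#'
#' @param groups Named or unnamed list of numeric vectors (>= 2 groups, each
#'   n >= 2).
#' @param alpha Significance level.
#' @return An object of class `ivm_anova` with fields `ss_between`,
#'   `ss_within`, `df_between`, `df_within`, `ms_between`, `ms_within`
#'   (pooled MSE), `F`, `p_value`, `group_means`, `group_sizes`.
#' @export
one_way_anova <- function(groups, alpha = 0.05) {
  abort_if(!is.list(groups) || length(groups) < 2, "need >= 2 groups")
  abort_if(any(vapply(groups, length, integer(1)) < 2),
           "each group needs n >= 2")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  y <- unlist(groups, use.names = FALSE)
  abort_if(stats::var(y) == 0, "all observations identical (zero MSW)")
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  tab <- stats::anova(stats::lm(y ~ g))
  structure(list(ss_between = tab$`Sum Sq`[1], ss_within = tab$`Sum Sq`[2],
                 df_between = tab$Df[1], df_within = tab$Df[2],
                 ms_between = tab$`Mean Sq`[1], ms_within = tab$`Mean Sq`[2],
                 F = tab$`F value`[1], p_value = tab$`Pr(>F)`[1],
                 group_means = vapply(groups, mean, numeric(1)),
                 group_sizes = vapply(groups, length, integer(1)),
                 alpha = alpha),
            class = "ivm_anova")
}

#' @export
print.ivm_anova <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g%s\n",
              x$df_between, x$df_within, x$F, x$p_value,
              if (x$p_value < x$alpha) " *" else ""))
  invisible(x)
}

#' Fisher's LSD post hoc test
#'
#' For each group pair,
#' `t = (mean_i - mean_j) / sqrt(MSE * (1/n_i + 1/n_j))` with the
#' within-group df and a two-tailed p, with no multiplicity adjustment.
#' Pairwise results are computed unconditionally but flagged `gated = TRUE`
#' (not interpretable) unless the omnibus ANOVA is significant at `alpha`.
#'
#' @param anova An `ivm_anova`.
#' @param alpha Significance level for the gate and the pairwise decisions.
#' @return A data frame with one row per pair: `group_i`, `group_j`,
#'   `mean_diff`, `t`, `df`, `p_value`, `significant`, `gated`.
#' @export
lsd_posthoc <- function(anova, alpha = 0.05) {
  abort_if(!inherits(anova, "ivm_anova"), "'anova' must be an ivm_anova")
  gn <- names(anova$group_means)
  gated <- anova$p_value >= alpha
  pairs <- utils::combn(seq_along(gn), 2)
  out <- data.frame(group_i = gn[pairs[1, ]], group_j = gn[pairs[2, ]],
                    stringsAsFactors = FALSE)
  out$mean_diff <- anova$group_means[pairs[1, ]] -
    anova$group_means[pairs[2, ]]
  se <- sqrt(anova$ms_within * (1 / anova$group_sizes[pairs[1, ]] +
                                  1 / anova$group_sizes[pairs[2, ]]))
  out$t <- unname(out$mean_diff / se)
  out$mean_diff <- unname(out$mean_diff)
  out$df <- anova$df_within
  out$p_value <- 2 * stats::pt(-abs(out$t), out$df)
  out$significant <- !gated & out$p_value < alpha
  out$gated <- gated
  out
}

#' Run the full dish-level analysis
#'
#' For each endpoint (GVBD rate and mean diameter change), checks normality
#' per group (Shapiro-Wilk, where group size permits) and variance
#' homogeneity (Levene), then compares groups with an unpaired t test (two
#' groups) or one-way ANOVA followed by the gated LSD post hoc (more than
#' two groups). Assumption-check failures raise warnings; no nonparametric
#' fallback is applied.
#'
#' @param dishes Dish-summary data frame from [summarize_dishes()], with
#'   `group`, `gvbd_rate_percent`, `mean_delta_um`.
#' @param alpha Significance level (default 0.05).
#' @param endpoints Endpoint columns to analyse.
#' @return A list of class `ivm_report`, one element per endpoint, each with
#'   `assumptions` (list of `ivm_stat`), `omnibus` (`ivm_stat` or
#'   `ivm_anova`) and `posthoc` (LSD table or `NULL`).
#' @export
run_analysis <- function(dishes, alpha = 0.05,
                         endpoints = c("gvbd_rate_percent",
                                       "mean_delta_um")) {
  dishes <- as.data.frame(dishes)
  abort_if(!"group" %in% names(dishes), "dishes need a 'group' column")
  report <- list()
  for (ep in endpoints) {
    abort_if(!ep %in% names(dishes), "missing endpoint column: ", ep)
    groups <- split(dishes[[ep]], dishes$group)
    small <- names(groups)[vapply(groups, length, integer(1)) < 2]
    abort_if(length(small) > 0,
             "group(s) with < 2 dishes: ", paste(small, collapse = ", "))
    abort_if(length(groups) < 2, "need >= 2 groups")
    assum <- list()
    for (gname in names(groups)) {
      g <- groups[[gname]]
      if (length(g) >= 3 && stats::var(g) > 0) {
        sw <- shapiro_wilk(g, alpha)
        if (sw$significant) {
          warning(sprintf("endpoint %s, group %s: normality check fails (p = %.3g)",
                          ep, gname, sw$p_value), call. = FALSE)
        }
        assum[[paste0("shapiro_", gname)]] <- sw
      }
    }
    if (all(vapply(groups, stats::var, numeric(1)) >= 0)) {
      lv <- levene(groups, alpha = alpha)
      if (lv$significant) {
        warning(sprintf("endpoint %s: variance homogeneity check fails (p = %.3g)",
                        ep, lv$p_value), call. = FALSE)
      }
      assum$levene <- lv
    }
    if (length(groups) == 2) {
      omnibus <- unpaired_t(groups[[1]], groups[[2]], alpha)
      posthoc <- NULL
    } else {
      omnibus <- one_way_anova(groups, alpha)
      posthoc <- lsd_posthoc(omnibus, alpha)
    }
    report[[ep]] <- list(endpoint = ep, assumptions = assum,
                         omnibus = omnibus, posthoc = posthoc)
  }
  structure(report, class = "ivm_report")
}

#' @export
print.ivm_report <- function(x, ...) {
  for (ep in x) {
    cat("== endpoint:", ep$endpoint, "==\n")
    if (inherits(ep$omnibus, "ivm_anova")) print(ep$omnibus)
    else print(ep$omnibus)
    if (!is.null(ep$posthoc)) {
      if (ep$posthoc$gated[1]) {
        cat("LSD pairs computed but gated (ANOVA not significant)\n")
      } else {
        sig <- ep$posthoc[ep$posthoc$significant, , drop = FALSE]
        cat(sprintf("LSD: %d/%d pairs significant at alpha %.2g\n",
                    nrow(sig), nrow(ep$posthoc), ep$omnibus$alpha))
      }
    }
  }
  invisible(x)
}

# Serialize a report to plain lists for JSON output.
report_to_list <- function(report) {
  lapply(report, function(ep) {
    list(endpoint = ep$endpoint,
         assumptions = lapply(ep$assumptions, unclass),
         omnibus = unclass(ep$omnibus),
         posthoc = ep$posthoc)
  })
}
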