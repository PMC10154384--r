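#' Normality and variance gating for group comparisons
#'
#' Reproduces the test-selection scheme conventional in cell-mechanics
#' studies: Shapiro-Wilk per group at `alpha` (all pass -> parametric branch;
#' any fail -> nonparametric branch), with Levene's test for variance
#' homogeneity selecting the Welch / Brown-Forsythe correction on the
#' parametric branch. A constant-valued group cannot be normality-tested and
#' routes to the nonparametric branch with a warning.
#'
#' @param groups named list of numeric vectors (each n >= 3).
#' @param alpha gate level (default 0.05).
#' @return list with `branch` (`"parametric"` or `"nonparametric"`),
#'   `equal_variance` flag, and the per-group `shapiro_p` and `levene_p`.
#' @export
normality_gate <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, integer(1)) >= 3))
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  const <- vapply(groups, function(x) var(x) == 0, logical(1))
  if (any(const)) {
    warning("constant-valued group(s): ",
            paste(names(groups)[const], collapse = ", "),
            "; routing to the nonparametric branch")
    return(list(branch = "nonparametric", equal_variance = NA,
                shapiro_p = rep(NA_real_, length(groups)),
                levene_p = NA_real_))
  }
  sp <- vapply(groups, function(x) shapiro.test(x)$p.value, numeric(1))
  df <- data.frame(value = unlist(groups),
                   group = factor(rep(names(groups),
                                      vapply(groups, length, integer(1)))))
  lev <- car::leveneTest(value ~ group, data = df)
  lev_p <- lev[["Pr(>F)"]][1]
  if (all(sp > alpha)) {
    list(branch = "parametric", equal_variance = lev_p > alpha,
         shapiro_p = sp, levene_p = lev_p)
  } else {
    list(branch = "nonparametric", equal_variance = lev_p > alpha,
         shapiro_p = sp, levene_p = lev_p)
  }
}

#' Dunn's nonparametric pairwise post-hoc test
#'
#' Rank-sum z statistics with tie correction after a Kruskal-Wallis omnibus;
#' two-sided p-values adjusted with Holm's method by default.
#'
#' @param groups named list of numeric vectors.
#' @param p_adjust adjustment method (see [stats::p.adjust()]).
#' @return data.frame: comparison, z, p, adjusted p, method.
#' @export
dunn_test <- function(groups, p_adjust = "holm") {
  stopifnot(length(groups) >= 2)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups)
  g <- rep(names(groups), vapply(groups, length, integer(1)))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  cmb <- utils::combn(names(groups), 2, simplify = FALSE)
  out <- do.call(rbind, lapply(cmb, function(pr) {
    z <- (rbar[[pr[1]]] - rbar[[pr[2]]]) /
      sqrt(s2 * (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
    data.frame(comparison = paste(pr[1], "-", pr[2]), z = z,
               p = 2 * pnorm(-abs(z)))
  }))
  out$p_adj <- pmin(1, pmax(out$p, p.adjust(out$p, method = p_adjust)))
  out$method <- "dunn"
  rownames(out) <- NULL
  out
}

stat_result <- function(family, statistic, p, posthoc = NULL, gate = NULL,
                        degenerate = FALSE) {
  structure(list(family = family, statistic = unname(statistic),
                 p = unname(p), posthoc = posthoc, gate = gate,
                 degenerate = degenerate),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic = %.4g, p = %.4g%s\n",
              x$family, x$statistic, x$p,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  if (!is.null(x$posthoc)) {
    cat("post-hoc:\n"); print(x$posthoc)
  }
  invisible(x)
}

#' Gated group comparison with matching post-hoc procedure
#'
#' Applies [normality_gate()] and runs the selected family: t-test (Welch if
#' variances differ) or Mann-Whitney for two groups; ANOVA (with
#' Welch / Brown-Forsythe correction if variances differ) or Kruskal-Wallis
#' for more. Post-hoc: Tukey (all pairs) or Dunnett (versus
#' `reference_group`) on the parametric branch, Dunn (Holm-adjusted) on the
#' nonparametric branch. The post-hoc procedure can be forced with `posthoc`
#' since figure legends sometimes prescribe it explicitly.
#'
#' @param groups named list of numeric vectors (each n >= 3).
#' @param reference_group optional reference level for Dunnett-style
#'   comparisons.
#' @param alpha gate level.
#' @param posthoc `NULL` (choose by gate and reference), or one of
#'   `"tukey"`, `"dunnett"`, `"dunn"`, `"none"`.
#' @param branch `"auto"` (gate decides) or an explicit `"parametric"` /
#'   `"nonparametric"` override, for when the analysis plan prescribes the
#'   family regardless of the gate.
#' @return a `stat_result` with `family`, `statistic`, `p`, a `posthoc`
#'   data.frame (comparison, p_adj, method) and the `gate` decision.
#' @export
compare_groups <- function(groups, reference_group = NULL, alpha = 0.05,
                           posthoc = NULL,
                           branch = c("auto", "parametric", "nonparametric")) {
  stopifnot(is.list(groups), length(groups) >= 2)
  branch <- match.arg(branch)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  if (!is.null(reference_group) && !reference_group %in% names(groups))
    stop("reference_group '", reference_group, "' not among the groups")
  gate <- normality_gate(groups, alpha)
  if (branch != "auto") gate$branch <- branch
  k <- length(groups)
  df <- data.frame(value = unlist(groups),
                   group = factor(rep(names(groups),
                                      vapply(groups, length, integer(1))),
                                  levels = names(groups)))
  if (!is.null(reference_group))
    df$group <- stats::relevel(df$group, ref = reference_group)

  if (gate$branch == "parametric" && k == 2) {
    tt <- t.test(groups[[1]], groups[[2]],
                 var.equal = isTRUE(gate$equal_variance))
    res <- stat_result("t", tt$statistic, tt$p.value, gate = gate)
  } else if (gate$branch == "parametric") {
    if (isTRUE(gate$equal_variance)) {
      fit <- aov(value ~ group, data = df)
      sm <- summary(fit)[[1]]
      res <- stat_result("anova", sm[["F value"]][1], sm[["Pr(>F)"]][1],
                         gate = gate)
    } else {
      wt <- oneway.test(value ~ group, data = df, var.equal = FALSE)
      res <- stat_result("welch_bf_anova", wt$statistic, wt$p.value,
                         gate = gate)
    }
  } else if (k == 2) {
    identical2 <- identical(sort(groups[[1]]), sort(groups[[2]]))
    wt <- suppressWarnings(wilcox.test(groups[[1]], groups[[2]]))
    res <- stat_result("mann_whitney", wt$statistic,
                       if (identical2) 1 else wt$p.value, gate = gate,
                       degenerate = identical2)
  } else {
    kw <- kruskal.test(df$value, df$group)
    res <- stat_result("kruskal_wallis", kw$statistic, kw$p.value,
                       gate = gate)
  }

  method <- posthoc %||% {
    if (k == 2) "none"
    else if (gate$branch == "nonparametric") "dunn"
    else if (is.null(reference_group)) "tukey" else "dunnett"
  }
  res$posthoc <- switch(
    method,
    none = NULL,
    tukey = {
      fit <- aov(value ~ group, data = df)
      tk <- TukeyHSD(fit)$group
      data.frame(comparison = rownames(tk), p_adj = tk[, "p adj"],
                 method = "tukey", row.names = NULL)
    },
    dunnett = {
      fit <- aov(value ~ group, data = df)
      gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
      sm <- summary(gl)
      data.frame(comparison = names(sm$test$coefficients),
                 p_adj = as.numeric(sm$test$pvalues),
                 method = "dunnett", row.names = NULL)
    },
    dunn = {
      dn <- dunn_test(groups)
      data.frame(comparison = dn$comparison, p_adj = dn$p_adj,
                 method = "dunn", row.names = NULL)
    },
    stop("unknown post-hoc method '", method, "'")
  )
  res
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Zero differences are dropped (Wilcoxon's convention); if every difference
#' is zero the result is the degenerate p = 1.
#'
#' @param before,after paired numeric vectors of equal length (n >= 6).
#' @return a `stat_result` with family `"wilcoxon_signed_rank"`.
#' @export
paired_test <- function(before, after) {
  stopifnot(length(before) == length(after), length(before) >= 6)
  d <- after - before
  d <- d[d != 0]
  if (length(d) == 0)
    return(stat_result("wilcoxon_signed_rank", NA_real_, 1,
                       degenerate = TRUE))
  wt <- suppressWarnings(wilcox.test(d, mu = 0, alternative = "two.sided"))
  stat_result("wilcoxon_signed_rank", wt$statistic, wt$p.value)
}
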