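#' Significance label from a p-value
#'
#' Star convention: `***` p < 0.001, `**` 0.001 < p < 0.01, `*`
#' 0.01 < p < 0.05, otherwise empty. Boundary values (exactly 0.001,
#' 0.01, 0.05) get the less significant label.
#'
#' @param p p-value(s) in [0, 1].
#' @return Character vector of labels.
#' @export
significance_label <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  out <- rep("", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out
}

.check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need >= 2 groups")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("each group needs >= 2 values")
  }
  groups
}

.group_frame <- function(groups) {
  data.frame(value = unlist(groups, use.names = FALSE),
             group = factor(rep(names(groups),
                                vapply(groups, length, integer(1)))))
}

#' One-way ANOVA with Tukey's range test
#'
#' Omnibus F-test over the groups (one value per independent run)
#' followed by Tukey HSD pairwise comparisons. Degenerate input (zero
#' variance everywhere with equal means) yields omnibus p = 1.
#'
#' @param groups Named list of numeric vectors.
#' @return Object of class `group_comparison`: `omnibus_p`, `omnibus_stat`
#'   (F), `pairwise` (data.frame pair, p, label), `method`,
#'   `group_means`.
#' @export
anova_tukey <- function(groups) {
  groups <- .check_groups(groups)
  df <- .group_frame(groups)
  if (all(unlist(lapply(groups, function(g) diff(range(g)) == 0))) &&
      length(unique(vapply(groups, mean, numeric(1)))) == 1L) {
    pw <- t(combn(names(groups), 2))
    pairwise <- data.frame(pair = paste(pw[, 1], pw[, 2], sep = "-"),
                           p = 1, label = "")
    return(structure(list(omnibus_p = 1, omnibus_stat = 0,
                          pairwise = pairwise, method = "anova_tukey",
                          group_means = vapply(groups, mean, numeric(1))),
                     class = "group_comparison"))
  }
  fit <- aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  omnibus_p <- an[["Pr(>F)"]][1]
  tk <- TukeyHSD(fit)$group
  pairwise <- data.frame(pair = rownames(tk), p = tk[, "p adj"],
                         label = significance_label(tk[, "p adj"]))
  rownames(pairwise) <- NULL
  structure(list(omnibus_p = omnibus_p, omnibus_stat = an[["F value"]][1],
                 pairwise = pairwise, method = "anova_tukey",
                 group_means = vapply(groups, mean, numeric(1))),
            class = "group_comparison")
}

#' Kruskal-Wallis with pairwise Wilcoxon tests
#'
#' Omnibus Kruskal-Wallis test followed by pairwise Wilcoxon tests;
#' `paired = TRUE` (signed-rank, pairing on run index) requires equal
#' group sizes. Pairwise p-values are adjusted for multiple testing
#' (Holm by default).
#'
#' @param groups Named list of numeric vectors.
#' @param paired Use the signed-rank test on run-index pairs.
#' @param correction Method for [stats::p.adjust()].
#' @return A `group_comparison` (with `group_medians`).
#' @export
kruskal_wilcoxon <- function(groups, paired = TRUE, correction = "holm") {
  groups <- .check_groups(groups)
  if (paired && length(unique(vapply(groups, length, integer(1)))) != 1L) {
    stop("paired mode requires equal group sizes")
  }
  df <- .group_frame(groups)
  kw <- suppressWarnings(kruskal.test(value ~ group, data = df))
  pw <- t(combn(names(groups), 2))
  praw <- apply(pw, 1, function(pr) {
    x <- groups[[pr[1]]]
    y <- groups[[pr[2]]]
    if (paired && all(x == y)) return(1)        # no nonzero differences
    suppressWarnings(wilcox.test(x, y, paired = paired))$p.value
  })
  padj <- p.adjust(praw, method = correction)
  pairwise <- data.frame(pair = paste(pw[, 1], pw[, 2], sep = "-"),
                         p = padj, p_raw = praw,
                         label = significance_label(padj))
  structure(list(omnibus_p = kw$p.value, omnibus_stat = unname(kw$statistic),
                 pairwise = pairwise,
                 method = if (paired) "kruskal_wilcoxon_paired"
                          else "kruskal_mannwhitney",
                 correction = correction,
                 group_medians = vapply(groups, median, numeric(1))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: omnibus p = %.4g %s\n", x$method,
              x$omnibus_p, significance_label(min(x$omnibus_p, 1))))
  print(x$pairwise, row.names = FALSE)
  if (x$omnibus_p >= 0.05) {
    cat("note: pairwise tests reported although omnibus p >= 0.05\n")
  }
  invisible(x)
}

#' Bootstrap standard error of a statistic
#'
#' Standard deviation of the statistic over `n_boot` resamples with
#' replacement; deterministic given (`values`, `seed`, `n_boot`).
#'
#' @param values Numeric vector (>= 2 values).
#' @param statistic `"median"`, `"mean"`, or a function.
#' @param n_boot Number of bootstrap repeats.
#' @param seed RNG seed.
#' @return Standard error (numeric scalar).
#' @export
bootstrap_se <- function(values, statistic = c("median", "mean"),
                         n_boot = 10000, seed = 1L) {
  stopifnot(length(values) >= 2)
  f <- if (is.function(statistic)) statistic else
    switch(match.arg(statistic), median = median, mean = mean)
  if (diff(range(values)) == 0) return(0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(values)
  reps <- vapply(seq_len(n_boot), function(b) {
    f(values[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  sd(reps)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Pre-checks gating ANOVA versus Kruskal-Wallis
#'
#' Shapiro-Wilk normality per group and a Levene (Brown-Forsythe,
#' median-centred) homogeneity test across groups at `alpha`; if either
#' assumption fails, the nonparametric branch is recommended.
#'
#' @param groups Named list of numeric vectors.
#' @param alpha Gate level.
#' @return List: `recommended` ("anova" or "kruskal"), `shapiro_p`
#'   (per group), `levene_p`.
#' @export
select_test <- function(groups, alpha = 0.05) {
  groups <- .check_groups(groups)
  shapiro_p <- vapply(groups, function(g) {
    if (diff(range(g)) == 0) return(0)  # degenerate: not normal
    shapiro.test(g)$p.value
  }, numeric(1))
  dev <- lapply(groups, function(g) abs(g - median(g)))
  lev_df <- .group_frame(dev)
  levene_p <- if (all(unlist(dev) == 0)) 1 else
    summary(aov(value ~ group, data = lev_df))[[1]][["Pr(>F)"]][1]
  ok <- all(shapiro_p > alpha) && levene_p > alpha
  list(recommended = if (ok) "anova" else "kruskal",
       shapiro_p = shapiro_p, levene_p = levene_p)
}

#' Compare metric groups the way the study protocol does
#'
#' Runs the assumption pre-checks and dispatches to [anova_tukey()] or
#' [kruskal_wilcoxon()]; either branch can be forced.
#'
#' @param groups Named list of per-run metric values.
#' @param test `"auto"`, `"anova"` or `"kruskal"`.
#' @param ... Passed to [kruskal_wilcoxon()].
#' @return A `group_comparison` with the pre-check results attached.
#' @export
compare_groups <- function(groups, test = c("auto", "anova", "kruskal"),
                           ...) {
  test <- match.arg(test)
  checks <- select_test(groups)
  branch <- if (test == "auto") checks$recommended else test
  out <- if (branch == "anova") anova_tukey(groups)
         else kruskal_wilcoxon(groups, ...)
  out$checks <- checks
  out
}
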