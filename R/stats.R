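#' Shapiro-Wilk normality p-value
#'
#' Thin wrapper over the standard Shapiro-Wilk test used by the dispatch in
#' [compare_groups()]. A constant vector (zero variance) has no defined W
#' statistic and is reported as non-normal (p = 0) with a warning.
#'
#' @param values numeric vector, n >= 3.
#' @return p-value in \[0, 1\].
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L) {
    stop("shapiro_wilk() needs at least 3 values", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    warning("constant vector: Shapiro-Wilk undefined, reported non-normal",
            call. = FALSE)
    return(0)
  }
  stats::shapiro.test(values)$p.value
}

#' Normality-dispatched group comparison
#'
#' Reproduces the statistics convention of the source workflow: every group
#' is first checked with Shapiro-Wilk at `alpha`. When all groups pass,
#' parametric tests are used — a two-tailed unpaired Student t-test for two
#' groups, or one-way ANOVA with Tukey HSD pairwise comparisons for more.
#' When any group fails, nonparametric analogues are used — Mann-Whitney for
#' two groups, or Kruskal-Wallis with Dunn pairwise comparisons
#' (Bonferroni-adjusted) for more. Pairwise significance codes follow the
#' star convention (*, P < 0.05; **, P < 0.01; ***, P < 0.001).
#'
#' @param samples named list of numeric vectors, one per group; at least two
#'   groups, each of size >= 3.
#' @param alpha significance level for the normality dispatch and the codes
#'   (default 0.05).
#' @return Object of class `group_comparison`: `groups` (named sizes),
#'   `test_used` (one of `"t_test"`, `"mann_whitney"`, `"anova_tukey"`,
#'   `"kruskal_wallis_dunn"`), `normality_p`, `omnibus_p`, `pairwise_p`,
#'   `significance` (codes per pair).
#' @export
compare_groups <- function(samples, alpha = 0.05) {
  if (!is.list(samples) || length(samples) < 2L) {
    stop("compare_groups() needs a list of >= 2 groups", call. = FALSE)
  }
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    names(samples) <- paste0("group", seq_along(samples))
  }
  ns <- vapply(samples, length, integer(1))
  if (any(ns < 3L)) {
    stop("every group needs n >= 3 (got: ",
         paste(ns, collapse = ", "), ")", call. = FALSE)
  }
  norm_p <- vapply(samples, function(x) {
    suppressWarnings(shapiro_wilk(x))
  }, numeric(1))
  parametric <- all(norm_p > alpha)
  k <- length(samples)
  pair_names <- function(nms) {
    cmb <- utils::combn(nms, 2L)
    paste(cmb[1, ], cmb[2, ], sep = " vs ")
  }
  if (k == 2L) {
    if (parametric) {
      test_used <- "t_test"
      p <- stats::t.test(samples[[1]], samples[[2]], var.equal = TRUE)$p.value
    } else {
      test_used <- "mann_whitney"
      p <- suppressWarnings(
        stats::wilcox.test(samples[[1]], samples[[2]])$p.value)
    }
    omnibus_p <- p
    pairwise <- stats::setNames(p, pair_names(names(samples)))
  } else {
    values <- unlist(samples, use.names = FALSE)
    grp <- factor(rep(names(samples), ns), levels = names(samples))
    if (parametric) {
      test_used <- "anova_tukey"
      fit <- stats::aov(values ~ grp)
      omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
      tk <- stats::TukeyHSD(fit)$grp
      # TukeyHSD names pairs "b-a"; normalize to "a vs b" in combn order
      cmb <- utils::combn(names(samples), 2L)
      pairwise <- stats::setNames(numeric(ncol(cmb)), pair_names(names(samples)))
      for (j in seq_len(ncol(cmb))) {
        key1 <- paste0(cmb[2, j], "-", cmb[1, j])
        key2 <- paste0(cmb[1, j], "-", cmb[2, j])
        row <- if (key1 %in% rownames(tk)) key1 else key2
        pairwise[j] <- tk[row, "p adj"]
      }
    } else {
      test_used <- "kruskal_wallis_dunn"
      omnibus_p <- stats::kruskal.test(values, grp)$p.value
      pairwise <- dunn_pairwise(values, grp)
    }
  }
  structure(list(
    groups = stats::setNames(ns, names(samples)),
    test_used = test_used,
    normality_p = norm_p,
    omnibus_p = omnibus_p,
    pairwise_p = pairwise,
    significance = vapply(pairwise, sig_code, character(1)),
    alpha = alpha
  ), class = "group_comparison")
}

# Dunn's pairwise z-tests on pooled ranks with tie correction,
# Bonferroni-adjusted.
dunn_pairwise <- function(values, grp) {
  rk <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(rk, grp, mean)
  n <- tapply(rk, grp, length)
  nms <- levels(grp)
  cmb <- utils::combn(nms, 2L)
  m <- ncol(cmb)
  p <- numeric(m)
  for (j in seq_len(m)) {
    a <- cmb[1, j]; b <- cmb[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[a]] + 1 / n[[b]]))
    z <- (mean_rank[[a]] - mean_rank[[b]]) / se
    p[j] <- min(1, 2 * stats::pnorm(-abs(z)) * m)
  }
  stats::setNames(p, paste(cmb[1, ], cmb[2, ], sep = " vs "))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (", x$test_used, ")\n", sep = "")
  cat("  groups:",
      paste(sprintf("%s (n=%d)", names(x$groups), x$groups), collapse = ", "),
      "\n")
  cat("  normality p:",
      paste(signif(x$normality_p, 3), collapse = ", "), "\n")
  cat("  omnibus p:", signif(x$omnibus_p, 4), "\n")
  for (nm in names(x$pairwise_p)) {
    cat(sprintf("  %-30s p = %-10.4g %s\n", nm, x$pairwise_p[[nm]],
                x$significance[[nm]]))
  }
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties), with the
#' p-value from the standard large-sample t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return Object of class `correlation_result`: `rho`, `p_value`, `n`.
#'   When either variable has zero variance after ranking, `rho` is `NA`
#'   and the result is flagged (`degenerate = TRUE`).
#' @export
#' @examples
#' spearman(1:5, c(2, 1, 4, 3, 5)) # rho = 0.7
spearman <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y lengths differ", call. = FALSE)
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("spearman() needs n >= 3", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("zero variance after ranking: rho undefined", call. = FALSE)
    return(structure(list(rho = NA_real_, p_value = NA_real_, n = n,
                          degenerate = TRUE),
                     class = "correlation_result"))
  }
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(rho = rho, p_value = p, n = n, degenerate = FALSE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f, p = %.4g, n = %d %s\n",
              x$rho, x$p_value, x$n, sig_code(x$p_value)))
  invisible(x)
}

#' Empirical ROC curve and AUC
#'
#' Evaluates a continuous readout as a classifier for `positive_class`
#' under the convention "higher value, more likely positive". The curve is
#' swept over all observed thresholds (predict positive when value >=
#' threshold) and the AUC is the Mann-Whitney probability
#' `P(value_pos > value_neg) + 0.5 P(tie)`, which equals the trapezoidal
#' area under the empirical curve. Orientation is never flipped: a marker
#' lower in the positive class yields an AUC below 0.5, reported as-is.
#'
#' @param values numeric marker values.
#' @param labels class labels, same length.
#' @param positive_class the label treated as positive; both classes must be
#'   present.
#' @return Object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `positive_class`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(values, labels, positive_class) {
  if (length(values) != length(labels)) {
    stop("values and labels lengths differ", call. = FALSE)
  }
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  pos <- labels == positive_class
  if (!any(pos) || all(pos)) {
    stop("both classes must be present", call. = FALSE)
  }
  vp <- values[pos]; vn <- values[!pos]
  n1 <- length(vp); n0 <- length(vn)
  # Mann-Whitney via ranks: U = R1 - n1(n1+1)/2, ties counted 1/2
  rk <- rank(c(vp, vn))
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)
  thr <- c(Inf, sort(unique(values), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(vp >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(vn < t), numeric(1))
  structure(list(
    thresholds = thr, sensitivity = sens, specificity = spec,
    auc = auc, positive_class = as.character(positive_class),
    n_pos = n1, n_neg = n0
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("Empirical ROC: positive = %s (n=%d vs n=%d), AUC = %.4f\n",
              x$positive_class, x$n_pos, x$n_neg, x$auc))
  invisible(x)
}
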