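new_stat_result <- function(statistic, df, p, method, estimate = NULL) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p = unname(p), estimate = estimate, method = method),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  dfs <- paste(format(x$df, digits = 4), collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n",
              x$method, x$statistic, dfs, x$p))
  invisible(x)
}

#' Two-sided paired t-test
#'
#' @param a,b paired numeric vectors of equal length (n >= 2).
#' @return A `stat_result` with `statistic` (t), `df`, `p`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stopf("paired vectors must have equal length")
  if (length(a) < 2) stopf("need n >= 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0) stopf("zero difference variance")
  tt <- stats::t.test(a, b, paired = TRUE)
  new_stat_result(tt$statistic, tt$parameter, tt$p.value, "paired t")
}

#' Within-subject (repeated-measures) ANOVA
#'
#' One- or two-way ANOVA with subject as the blocking factor, fitted by
#' standard within-subject sums-of-squares partitioning
#' (`aov` with `Error(subject/...)` strata). The table must be complete
#' and balanced: every subject measured in every cell.
#'
#' @param values numeric outcome, or a subjects x conditions matrix for
#'   the one-way case.
#' @param subject,f1,f2 factors (vectors parallel to `values`); `f2`
#'   `NULL` for one-way.
#' @param effect which effect to report: `"f1"`, `"f2"`, or
#'   `"interaction"` (default: `"f1"` for one-way, `"interaction"` for
#'   two-way).
#' @return A `stat_result` with `statistic` (F), `df`
#'   (effect, error), `p`, plus the full `table` attribute.
#' @export
rm_anova <- function(values, subject = NULL, f1 = NULL, f2 = NULL,
                     effect = NULL) {
  if (is.matrix(values)) {
    n <- nrow(values)
    k <- ncol(values)
    subject <- factor(rep(seq_len(n), k))
    f1 <- factor(rep(seq_len(k), each = n))
    values <- as.numeric(values)
  }
  subject <- factor(subject)
  f1 <- factor(f1)
  two_way <- !is.null(f2)
  if (two_way) f2 <- factor(f2)
  if (nlevels(f1) < 2) stopf("need >= 2 levels per factor")
  cells <- if (two_way) table(subject, f1, f2) else table(subject, f1)
  if (any(cells == 0)) stopf("missing cells: design must be complete (no imputation)")
  if (length(unique(as.vector(cells))) != 1) {
    stopf("unbalanced design: equal cell counts required")
  }
  dat <- data.frame(y = values, subject = subject, f1 = f1)
  if (two_way) {
    dat$f2 <- f2
    fit <- stats::aov(y ~ f1 * f2 + Error(subject / (f1 * f2)), data = dat)
    if (is.null(effect)) effect <- "interaction"
    term <- switch(effect, f1 = "f1", f2 = "f2", interaction = "f1:f2",
                   stopf("unknown effect '%s'", effect))
  } else {
    fit <- stats::aov(y ~ f1 + Error(subject / f1), data = dat)
    if (is.null(effect)) effect <- "f1"
    term <- "f1"
  }
  sm <- summary(fit)
  for (stratum in sm) {
    tab <- stratum[[1]]
    hit <- trimws(rownames(tab)) == term
    if (any(hit)) {
      i <- which(hit)
      err <- trimws(rownames(tab)) == "Residuals"
      res <- new_stat_result(tab[i, "F value"],
                             c(tab[i, "Df"], tab[err, "Df"]),
                             tab[i, "Pr(>F)"],
                             sprintf("repeated-measures ANOVA (%s)", term))
      attr(res, "table") <- sm
      return(res)
    }
  }
  stopf("effect '%s' not found in the ANOVA table", term)
}

#' Pearson correlation with two-sided p
#'
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` df.
#'
#' @param x,y numeric vectors (n >= 4, both nonconstant).
#' @return A `stat_result` with `estimate` (r), `statistic` (t),
#'   `df`, `p`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stopf("input lengths differ")
  if (length(x) < 4) stopf("need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  new_stat_result(ct$statistic, ct$parameter, ct$p.value, "Pearson",
                  estimate = unname(ct$estimate))
}

#' Compare two dependent, non-overlapping correlations (Dunn-Clark z)
#'
#' Tests `r12 = r34` where both correlations are measured on the same
#' `n` subjects and share no variable (e.g. trajectory-length/accuracy
#' correlations from two sessions). Fisher-transforms both correlations;
#' `z = (z1 - z2) sqrt((n - 3) / (2 - 2 c))` where `c` is the
#' correlation between the transformed estimates computed from the four
#' cross-correlations of the involved variables (Dunn & Clark 1969):
#' `c = psi / ((1 - r12^2)(1 - r34^2))` with
#' `psi = 1/2 r12 r34 (r13^2 + r14^2 + r23^2 + r24^2) + r13 r24 +
#' r14 r23 - r12 (r13 r14 + r23 r24) - r34 (r13 r23 + r14 r24)`.
#'
#' @param r12,r34 the two correlations to compare (`|r| < 1`).
#' @param cross named vector/list with elements `r13`, `r14`, `r23`,
#'   `r24`: correlations crossing the two variable pairs.
#' @param n number of subjects (>= 10).
#' @return A `stat_result` with `statistic` (z), `p`; `df` is `Inf`.
#' @export
compare_dependent_correlations <- function(r12, r34, cross, n) {
  need <- c("r13", "r14", "r23", "r24")
  cross <- unlist(cross)
  if (!all(need %in% names(cross))) {
    stopf("cross must supply %s", paste(need, collapse = ", "))
  }
  if (n < 10) stopf("need n >= 10")
  rs <- c(r12 = r12, r34 = r34, cross[need])
  if (any(!is.finite(rs)) || any(abs(rs) > 1)) stopf("correlations must lie in [-1, 1]")
  if (abs(r12) == 1 || abs(r34) == 1) stopf("|r| = 1: Fisher transform undefined")
  r13 <- cross[["r13"]]; r14 <- cross[["r14"]]
  r23 <- cross[["r23"]]; r24 <- cross[["r24"]]
  psi <- 0.5 * r12 * r34 * (r13^2 + r14^2 + r23^2 + r24^2) +
    r13 * r24 + r14 * r23 -
    r12 * (r13 * r14 + r23 * r24) -
    r34 * (r13 * r23 + r14 * r24)
  cc <- psi / ((1 - r12^2) * (1 - r34^2))
  cc <- max(min(cc, 0.999999), -0.999999)
  z <- (atanh(r12) - atanh(r34)) * sqrt((n - 3) / (2 - 2 * cc))
  new_stat_result(z, Inf, 2 * stats::pnorm(-abs(z)), "Dunn-Clark z")
}

#' Dunn-Clark comparison from raw data columns
#'
#' Convenience wrapper: computes `cor(x1, y1)`, `cor(x2, y2)` and the
#' four cross-correlations from subject-level data, then calls
#' [compare_dependent_correlations()].
#'
#' @param x1,y1 first variable pair; `x2,y2` second pair (all length n).
#' @return A `stat_result`; the two correlations are attached as
#'   attribute `"correlations"`.
#' @export
compare_dependent_correlations_data <- function(x1, y1, x2, y2) {
  n <- length(x1)
  stopifnot(length(y1) == n, length(x2) == n, length(y2) == n)
  r12 <- stats::cor(x1, y1)
  r34 <- stats::cor(x2, y2)
  cross <- c(r13 = stats::cor(x1, x2), r14 = stats::cor(x1, y2),
             r23 = stats::cor(y1, x2), r24 = stats::cor(y1, y2))
  res <- compare_dependent_correlations(r12, r34, cross, n)
  attr(res, "correlations") <- c(r12 = r12, r34 = r34)
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: `p_fdr(i) = min_{j >= i} (m / rank_j) p(j)`
#' capped at 1, monotone nondecreasing in raw-p order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
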