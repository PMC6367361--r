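# Normality-gated statistical testing, correlation dispatch and the
# comparative-Ct relative-expression computation.

#' Normality-gated group comparison
#'
#' Reproduces the decision rule common in cell-biomechanics studies: each
#' group is checked for normality with the Shapiro-Wilk test; if every
#' group passes (p > `alpha`), an ANOVA is applied - repeated-measures
#' (`value ~ group + Error(pair)`) when a pairing key is supplied, one-way
#' otherwise. If any group fails, the nonparametric Kruskal-Wallis test is
#' used instead. A constant-valued group forces the nonparametric branch
#' with a warning (its normality is undefined). The chosen branch and the
#' per-group normality p-values are returned for audit, so the decision is
#' a pure, reproducible function of the data. Significance convention:
#' p < 0.05. No multiple-testing correction is applied by default; set
#' `p_adjust = "holm"` when testing families of hypotheses.
#'
#' @param values Numeric response vector.
#' @param group Factor (>= 2 levels, each with n >= 3).
#' @param pair Optional pairing key (factor) for repeated measures.
#' @param alpha Normality-gate level (default 0.05).
#' @param p_adjust Either `"none"` (default) or a method for
#'   [stats::p.adjust()] applied by the caller across a family; stored for
#'   audit only.
#' @return List of class `dispatch_test`: `test` (name), `branch`
#'   (`"anova"`, `"paired_anova"` or `"kruskal"`), `statistic`, `p.value`,
#'   `normality_p` (per group), `significant` (p < 0.05).
#' @export
normality_gated_test <- function(values, group, pair = NULL, alpha = 0.05,
                                 p_adjust = "none") {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  ns <- tapply(values, group, length)
  if (any(ns < 3L)) stop("each group needs n >= 3")
  norm_p <- vapply(levels(group), function(g) {
    v <- values[group == g]
    if (stats::sd(v) == 0) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  forced <- any(is.na(norm_p))
  if (forced)
    warning("constant-valued group: nonparametric branch forced")
  all_normal <- !forced && all(norm_p > alpha)
  if (all_normal) {
    if (!is.null(pair)) {
      pair <- as.factor(pair)
      dat <- data.frame(values = values, group = group, pair = pair)
      fit <- stats::aov(values ~ group + Error(pair), data = dat)
      tab <- summary(fit)[["Error: Within"]][[1L]]
      i <- grep("^group", trimws(rownames(tab)))
      stat <- tab[i, "F value"]
      p <- tab[i, "Pr(>F)"]
      branch <- "paired_anova"; test <- "repeated-measures ANOVA"
    } else {
      fit <- stats::aov(values ~ group)
      tab <- summary(fit)[[1L]]
      i <- grep("^group", trimws(rownames(tab)))
      stat <- tab[i, "F value"]
      p <- tab[i, "Pr(>F)"]
      branch <- "anova"; test <- "one-way ANOVA"
    }
  } else {
    kt <- stats::kruskal.test(values, group)
    stat <- unname(kt$statistic); p <- kt$p.value
    branch <- "kruskal"; test <- "Kruskal-Wallis"
  }
  structure(list(test = test, branch = branch, statistic = unname(stat),
                 p.value = p, normality_p = norm_p, alpha = alpha,
                 significant = p < 0.05, p_adjust = p_adjust),
            class = "dispatch_test")
}

#' @export
print.dispatch_test <- function(x, ...) {
  cat(sprintf("%s (branch: %s)\n  statistic = %.4g, p = %.4g%s\n",
              x$test, x$branch, x$statistic, x$p.value,
              if (x$significant) " *" else ""))
  cat("  normality p per group:",
      paste(sprintf("%.3g", x$normality_p), collapse = ", "), "\n")
  invisible(x)
}

#' Normality-gated correlation
#'
#' Pearson correlation when both variables pass the Shapiro-Wilk normality
#' check at `alpha`, Spearman rank correlation otherwise.
#'
#' @param x,y Equal-length numeric vectors, length >= 4, nonzero variance.
#' @param alpha Normality-gate level (default 0.05).
#' @return List with `method` (`"pearson"` or `"spearman"`), `coefficient`,
#'   `p.value`.
#' @export
auto_correlation <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y), length(x) >= 4L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  normal <- stats::shapiro.test(x)$p.value > alpha &&
            stats::shapiro.test(y)$p.value > alpha
  method <- if (normal) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  list(method = method, coefficient = unname(ct$estimate),
       p.value = ct$p.value)
}

#' Relative expression by the comparative Ct method
#'
#' Per sample, `dCt = Ct_target - Ct_ref` (the reference gene, e.g.
#' beta-actin, absorbs loading differences); `ddCt = dCt - dCt_calibrator`;
#' relative expression `= 2^(-ddCt)`. The calibrator sample has expression
#' exactly 1, and a 1-cycle increase of the target Ct halves expression.
#'
#' @param ct_target,ct_ref Positive Ct values per sample, equal length.
#' @param calibrator Index or name (if `samples` given) of the calibrator.
#' @param samples Optional sample names.
#' @return Data frame with `sample`, `dct`, `ddct`, `rel_expression`.
#' @examples
#' comparative_ct(c(25, 24), c(19, 18), calibrator = 1)
#' @export
comparative_ct <- function(ct_target, ct_ref, calibrator = 1,
                           samples = NULL) {
  stopifnot(length(ct_target) == length(ct_ref))
  if (any(!is.finite(ct_ref))) stop("missing reference Ct")
  if (any(ct_target <= 0) || any(ct_ref <= 0))
    stop("Ct values must be positive")
  if (is.null(samples)) samples <- as.character(seq_along(ct_target))
  cal <- if (is.character(calibrator)) match(calibrator, samples)
         else as.integer(calibrator)
  if (is.na(cal) || cal < 1L || cal > length(samples))
    stop("calibrator sample not found")
  dct <- ct_target - ct_ref
  ddct <- dct - dct[cal]
  data.frame(sample = samples, dct = dct, ddct = ddct,
             rel_expression = 2^(-ddct))
}
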