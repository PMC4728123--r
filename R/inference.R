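#' Group summary: mean with SD or SEM
#'
#' The reporting convention used throughout: mean and standard deviation
#' for small numbers of independent measurements (colocalization slopes,
#' enrichment ratios), mean and standard error of the mean for very large
#' track-level samples.
#'
#' @param values numeric vector, non-empty.
#' @param error_mode `"sd"` or `"sem"` -- which error the printed summary
#'   emphasizes; both are returned.
#' @param label group label.
#' @return List of class `"group_summary"`: `label`, `n`, `mean`, `sd`,
#'   `sem`, `error_mode`. `sd`/`sem` are `NA` for n = 1.
#' @export
summarize_group <- function(values, error_mode = c("sd", "sem"),
                            label = "group") {
  error_mode <- match.arg(error_mode)
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  n <- length(values)
  s <- if (n > 1L) stats::sd(values) else NA_real_
  structure(list(label = label, n = n, mean = mean(values), sd = s,
                 sem = s / sqrt(n), error_mode = error_mode),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  err <- if (x$error_mode == "sd") x$sd else x$sem
  cat(sprintf("%s: mean %.4g +/- %.4g (%s), n = %d\n",
              x$label, x$mean, err, toupper(x$error_mode), x$n))
  invisible(x)
}

#' Compare groups: ANOVA with Bonferroni-corrected pairwise t-tests
#'
#' The package's significance machinery: a one-way ANOVA omnibus test
#' followed by all pairwise two-sided equal-variance Student's t-tests
#' with Bonferroni correction over the number of pairs, or a single
#' Student's t-test for exactly two groups. Significance is flagged at
#' strict `p < alpha` (default 0.01) on the adjusted p-value.
#'
#' @param groups named list of numeric vectors, each of length >= 2.
#' @param method `"anova_bonferroni"` (>= 2 groups) or `"t_test"`
#'   (exactly 2).
#' @param alpha significance level.
#' @return List of class `"group_comparison"` with `method`, `alpha`,
#'   `omnibus` (data frame: statistic, df, p, significant; ANOVA only) and
#'   `pairwise` (data frame: comparison, statistic, p, p_adjusted,
#'   significant).
#' @export
compare_groups <- function(groups, method = c("anova_bonferroni", "t_test"),
                           alpha = 0.01) {
  method <- match.arg(method)
  stop_if_not_scalar_num(alpha, "alpha", positive = TRUE)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  k <- length(groups)
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs n >= 2", call. = FALSE)
  if (method == "t_test" && k != 2L)
    stop("t_test requires exactly 2 groups", call. = FALSE)
  if (method == "anova_bonferroni" && k < 2L)
    stop("ANOVA requires at least 2 groups", call. = FALSE)
  if (all(vapply(groups, stats::var, numeric(1)) == 0))
    stop("zero within-group variance in all groups", call. = FALSE)

  pairs <- utils::combn(names(groups), 2L, simplify = FALSE)
  m <- length(pairs)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    tt <- stats::t.test(groups[[pr[1]]], groups[[pr[2]]],
                        var.equal = TRUE)
    data.frame(comparison = paste(pr, collapse = " vs "),
               statistic = unname(tt$statistic), p = tt$p.value)
  }))
  pw$p_adjusted <- pmin(1, pw$p * if (method == "t_test") 1 else m)
  pw$significant <- pw$p_adjusted < alpha

  omnibus <- NULL
  if (method == "anova_bonferroni") {
    values <- unlist(groups, use.names = FALSE)
    fac <- factor(rep(names(groups), vapply(groups, length, integer(1))))
    ow <- stats::oneway.test(values ~ fac, var.equal = TRUE)
    omnibus <- data.frame(statistic = unname(ow$statistic),
                          df1 = unname(ow$parameter[1]),
                          df2 = unname(ow$parameter[2]),
                          p = ow$p.value,
                          significant = ow$p.value < alpha)
  }
  structure(list(method = method, alpha = alpha, omnibus = omnibus,
                 pairwise = pw),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group comparison (%s, alpha = %g)\n", x$method, x$alpha))
  if (!is.null(x$omnibus)) {
    cat(sprintf("omnibus ANOVA: F(%g, %g) = %.4g, p = %.4g%s\n",
                x$omnibus$df1, x$omnibus$df2, x$omnibus$statistic,
                x$omnibus$p, if (x$omnibus$significant) " *" else ""))
  }
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}
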