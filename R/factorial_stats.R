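# Statistical layer: log transforms, balanced 2x2x2 fixed-effects ANOVA,
# Welch t-tests and Pearson correlations. The ANOVA, t-test and correlation
# engines are stats::aov / stats::t.test / stats::cor.test; these wrappers
# add the design checks and the output layout used throughout the pipeline.

#' Log-transform positive responses
#'
#' Production rates and copy numbers are log transformed before ANOVA;
#' rates use the natural log, copy numbers conventionally log10.
#'
#' @param values Numeric vector, all > 0.
#' @param base `"e"` (natural log, default) or `"10"`.
#' @return Transformed vector.
#' @export
log_transform <- function(values, base = c("e", "10")) {
  base <- match.arg(base)
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad) > 0) {
    stop("non-positive or non-finite values at position(s): ",
         paste(bad, collapse = ", "))
  }
  if (base == "e") log(values) else log10(values)
}

#' Balanced three-factorial fixed-effects ANOVA
#'
#' Least-squares decomposition of a balanced 2x2x2 design into three main
#' effects, three two-way interactions, the three-way interaction, and
#' residual. With n replicates per cell the residual has `8(n-1)` degrees
#' of freedom (n = 3 gives the 1,16 df of the incubation experiment). In a
#' balanced design the factors are orthogonal, so type-I and type-III sums
#' of squares coincide.
#'
#' @param data Data frame containing the response and the three factor
#'   columns.
#' @param response Name of the response column.
#' @param factors Character vector of the three factor column names.
#'   Default `c("wetting", "light", "headspace")`.
#' @return Data frame of class `anova_table`: one row per term plus
#'   residuals, with `term`, `df`, `sum_sq`, `mean_sq`, `f_value`,
#'   `p_value`.
#' @export
factorial_anova <- function(data, response,
                            factors = c("wetting", "light", "headspace")) {
  if (length(factors) != 3) stop("exactly three factors are required")
  miss <- setdiff(c(response, factors), names(data))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- data[, c(response, factors)]
  if (any(!complete.cases(d))) stop("missing values in response or factors")
  for (f in factors) {
    d[[f]] <- factor(d[[f]])
    if (nlevels(d[[f]]) != 2) {
      stop("unsupported design: factor '", f, "' must have exactly 2 levels")
    }
  }
  counts <- table(d[factors])
  if (length(unique(as.vector(counts))) != 1) {
    stop("unsupported design: unbalanced cell counts (",
         paste(range(counts), collapse = "-"), " per cell)")
  }
  n_cell <- counts[[1]]
  if (n_cell < 2) stop("need >= 2 replicates per cell")

  form <- stats::as.formula(paste(response, "~", paste(factors, collapse = " * ")))
  fit <- aov(form, data = d)
  tab <- summary(fit)[[1]]
  out <- data.frame(
    term = trimws(rownames(tab)),
    df = tab[["Df"]],
    sum_sq = tab[["Sum Sq"]],
    mean_sq = tab[["Mean Sq"]],
    f_value = tab[["F value"]],
    p_value = tab[["Pr(>F)"]],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  # fully degenerate response (no variation at all): report F = 0, p = 1
  if (all(out$sum_sq == 0)) {
    term_rows <- out$term != "Residuals"
    out$f_value[term_rows] <- 0
    out$p_value[term_rows] <- 1
  }
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Satterthwaite degrees of freedom (the
#' pooled-variance variant is available via `var_equal = TRUE`). Degenerate
#' inputs with zero variance in both groups are resolved by the mean
#' comparison: equal means give p = 1, different means p = 0.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param var_equal Use the pooled-variance (Student) test instead.
#' @return List with `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
welch_t_test <- function(group_a, group_b, var_equal = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs >= 2 observations")
  }
  if (var(group_a) == 0 && var(group_b) == 0) {
    same <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    return(list(t = if (same) 0 else Inf * sign(mean(group_a) - mean(group_b)),
                df = length(group_a) + length(group_b) - 2,
                p_value = if (same) 1 else 0,
                mean_a = mean(group_a), mean_b = mean(group_b)))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Pearson product-moment correlation
#'
#' Correlation coefficient with the two-sided p-value from the t transform
#' `t = r * sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need n >= 3")
  if (var(x) == 0 || var(y) == 0) {
    stop("undefined correlation: zero variance in x or y")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}
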