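# Group-level statistics on the per-subject measure table.

#' The 12 analysis measures
#' @keywords internal
measure_columns <- function() {
  c("strength", "diversity", "zero_correlation", "k_max", "B_max", "d",
    "Ecc", "Ass", "K", "Lf", "alpha", "r_squared")
}

#' Residualise measures on age, sex and their interaction
#'
#' Replaces each measure by the residuals of an ordinary least-squares fit
#' on intercept, age, sex and age x sex, removing demographic confounding
#' before the rank tests. Residuals are mean-zero by construction. With a
#' single sex level the design is collinear and the correction is skipped
#' with a warning.
#'
#' @param table Measure table with columns `age`, `sex` and the measures.
#' @param measures Character vector of measure columns (defaults to the 12
#'   analysis measures present in the table).
#' @return The table with measures replaced by residuals.
#' @export
residualize <- function(table, measures = NULL) {
  if (is.null(measures)) measures <- intersect(measure_columns(), names(table))
  stopifnot(all(c("age", "sex") %in% names(table)), length(measures) > 0)
  sex <- factor(table$sex)
  if (nlevels(sex) < 2) {
    warning("single sex level: age/sex correction skipped")
    return(table)
  }
  age <- table$age
  for (m in measures) {
    fit <- stats::lm(table[[m]] ~ age * sex)
    table[[m]] <- unname(stats::residuals(fit))
  }
  table
}

#' Two-group rank tests with Benjamini-Hochberg correction
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test of case versus control
#' for each measure, with p-values adjusted across measures by the
#' Benjamini-Hochberg step-up rule. A measure constant across all subjects
#' gets p = 1 and is flagged.
#'
#' @param table Measure table with a `group` column (`case`/`control`) and
#'   measure columns.
#' @param measures Measure columns to test (default: the 12 analysis
#'   measures present).
#' @param sig_alpha Significance threshold used for the `significant`
#'   column (applied to adjusted p-values).
#' @return data.frame with one row per measure: `measure`, `p`, `p_adj`,
#'   `median_case`, `median_control`, `direction`, `constant`,
#'   `significant`.
#' @export
rank_tests <- function(table, measures = NULL, sig_alpha = 0.05) {
  if (is.null(measures)) measures <- intersect(measure_columns(), names(table))
  stopifnot("group" %in% names(table), length(measures) > 0)
  grp <- table$group
  if (length(unique(grp)) < 2) stop("both groups must be represented")
  res <- lapply(measures, function(m) {
    x <- table[[m]][grp == "case"]
    y <- table[[m]][grp == "control"]
    const <- stats::sd(c(x, y)) == 0 || is.na(stats::sd(c(x, y)))
    p <- if (const) 1 else
      suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                          exact = FALSE)$p.value)
    mc <- stats::median(x); mh <- stats::median(y)
    data.frame(measure = m, p = p,
               median_case = mc, median_control = mh,
               direction = if (const || mc == mh) "none" else
                 if (mc > mh) "case>control" else "case<control",
               constant = const)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < sig_alpha
  out[, c("measure", "p", "p_adj", "median_case", "median_control",
          "direction", "constant", "significant")]
}

#' Label-permutation test for a group difference
#'
#' Tests the observed absolute difference of group means against its
#' permutation distribution: subjects' values are re-assigned to groups at
#' random `B` times and the p-value is
#' `(1 + #permuted |diff| >= observed) / (B + 1)`, so the smallest
#' attainable p is `1/(B+1)`.
#'
#' @param values_case,values_control Numeric vectors of per-subject values.
#' @param B Number of permutations (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @return List with `p`, `observed`, `B`.
#' @export
permutation_test <- function(values_case, values_control, B = 10000L,
                             seed = NULL) {
  stopifnot(length(values_case) >= 1, length(values_control) >= 1)
  if (!is.null(seed)) set.seed(seed)
  obs <- abs(mean(values_case) - mean(values_control))
  pooled <- c(values_case, values_control)
  n1 <- length(values_case)
  n <- length(pooled)
  exceed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n1)
    d <- abs(mean(pooled[idx]) - mean(pooled[-idx]))
    if (d >= obs) exceed <- exceed + 1L
  }
  list(p = (1 + exceed) / (B + 1), observed = obs, B = as.integer(B))
}
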