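#' @include utils.R
NULL

.statResult <- function(test, statistic, df, p, adjusted = NA_real_,
                        method = "none", term = NA_character_) {
  data.frame(test = test, term = term, statistic = statistic,
             df1 = df[1], df2 = if (length(df) > 1) df[2] else NA_real_,
             p_value = p, adjusted_p = adjusted,
             method_of_adjustment = method, stringsAsFactors = FALSE)
}

#' Two-sample unpaired t test
#'
#' Classical two-tailed unpaired t test (pooled variance by default, with
#' the Welch unequal-variance variant behind a flag), returned as a
#' one-row result table. Numerics are delegated to [stats::t.test()].
#' Degenerate inputs: if both groups are constant with equal means the
#' statistic is 0 and p = 1; constant groups with unequal means are a
#' degenerate-input error.
#'
#' @param groupA,groupB numeric vectors, each of length >= 2, finite.
#' @param welch logical; use the unequal-variance variant (default
#'   `FALSE`, matching conventional Prism output).
#' @return One-row data.frame with columns `test`, `term`, `statistic`,
#'   `df1`, `df2`, `p_value`, `adjusted_p`, `method_of_adjustment`.
#' @examples
#' unpairedT(c(1, 2, 3), c(2, 3, 4, 5))
#' @export
unpairedT <- function(groupA, groupB, welch = FALSE) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stopf("each group needs n >= 2")
  if (any(!is.finite(groupA)) || any(!is.finite(groupB)))
    stopf("groups must be finite")
  if (var(groupA) == 0 && var(groupB) == 0) {
    if (mean(groupA) == mean(groupB))
      return(.statResult("unpaired_t", 0,
                         length(groupA) + length(groupB) - 2, 1))
    stopf("degenerate input: zero variance with unequal means")
  }
  tt <- t.test(groupA, groupB, var.equal = !welch)
  .statResult(if (welch) "welch_t" else "unpaired_t",
              unname(tt$statistic), unname(tt$parameter), tt$p.value)
}

#' Two-way ANOVA / mixed-effects model
#'
#' Main effects and interaction for a two-factor design. With no repeated
#' factor the fit is an ordinary two-way ANOVA ([stats::aov()]). Supplying
#' `repeatedOn` triggers the mixed-effects route — a subject-level random
#' intercept fitted with [lmerTest::lmer()] and Satterthwaite F tests —
#' which remains valid when repeated-measures cells are missing (e.g. a
#' subject removed mid-experiment).
#'
#' @param data data.frame in long format.
#' @param value,factorA,factorB column names (character) of the response
#'   and the two factors.
#' @param subject column name of the subject identifier (required when
#'   `repeatedOn` is given).
#' @param repeatedOn optional character; name of the repeated (within-
#'   subject) factor, enabling the mixed-effects route.
#' @return data.frame with one row per term (`factorA`, `factorB`,
#'   interaction) in the [unpairedT()] result layout.
#' @examples
#' d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:5)
#' d$y <- rnorm(nrow(d))
#' twoWayAnova(d, "y", "A", "B")
#' @export
twoWayAnova <- function(data, value, factorA, factorB, subject = NULL,
                        repeatedOn = NULL) {
  for (col in c(value, factorA, factorB, subject, repeatedOn))
    if (!col %in% names(data)) stopf("column '%s' not in data", col)
  for (f in c(factorA, factorB))
    if (length(unique(data[[f]])) < 2L)
      stopf("factor '%s' has fewer than 2 levels", f)
  d <- data.frame(y = data[[value]],
                  A = factor(data[[factorA]]), B = factor(data[[factorB]]))
  terms <- c(factorA, factorB, paste(factorA, factorB, sep = ":"))
  if (is.null(repeatedOn)) {
    fit <- aov(y ~ A * B, data = d)
    tab <- summary(fit)[[1]]
    dfRes <- tab["Residuals", "Df"]
    rows <- lapply(1:3, function(i)
      .statResult("two_way_anova", tab[i, "F value"],
                  c(tab[i, "Df"], dfRes), tab[i, "Pr(>F)"],
                  term = terms[i]))
  } else {
    if (is.null(subject))
      stopf("repeatedOn requires a subject column")
    d$subj <- factor(data[[subject]])
    fit <- lmerTest::lmer(y ~ A * B + (1 | subj), data = d)
    tab <- as.data.frame(anova(fit))  # Satterthwaite
    rows <- lapply(1:3, function(i)
      .statResult("mixed_effects_anova", tab[i, "F value"],
                  c(tab[i, "NumDF"], tab[i, "DenDF"]), tab[i, "Pr(>F)"],
                  term = terms[i]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multiple-comparison p-value adjustment
#'
#' Adjusts p values for a family of `m` comparisons. Bonferroni:
#' `min(1, m * p)`; Sidak: `1 - (1 - p)^m`; Dunnett: the many-to-one
#' adjustment `P(max_i |T_i| >= t_p)` under an equicorrelated
#' (correlation 0.5, the equal-n case) multivariate t with `df` degrees of
#' freedom, evaluated with [mvtnorm::pmvt()] — a documented approximation
#' when group sizes are unequal. Adjusted values are never smaller than
#' the input p for Bonferroni/Sidak and are non-decreasing in `m`.
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @param method `"bonferroni"`, `"sidak"` or `"dunnett"`.
#' @param m number of comparisons in the family (>= 1).
#' @param df error degrees of freedom for the Dunnett route (default
#'   `Inf`, the normal limit).
#' @return Vector of adjusted p values.
#' @examples
#' adjustP(0.01, "bonferroni", 4)  # 0.04
#' adjustP(0.01, "sidak", 4)       # ~0.0394
#' @export
adjustP <- function(p, method = c("bonferroni", "sidak", "dunnett"),
                    m, df = Inf) {
  method <- match.arg(method)
  if (m < 1) stopf("m must be >= 1")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p values must be in [0, 1]")
  m <- as.integer(m)
  switch(method,
    bonferroni = pmin(1, m * p),
    sidak = 1 - (1 - p)^m,
    dunnett = vapply(p, function(pi) {
      if (is.na(pi)) return(NA_real_)
      if (pi <= 0) return(0)
      if (pi >= 1) return(1)
      tcrit <- if (is.finite(df)) qt(1 - pi / 2, df) else qnorm(1 - pi / 2)
      corr <- matrix(0.5, m, m); diag(corr) <- 1
      inside <- mvtnorm::pmvt(lower = rep(-tcrit, m),
                              upper = rep(tcrit, m),
                              df = if (is.finite(df)) as.integer(df) else 0,
                              corr = corr)
      min(1, max(pi, 1 - as.numeric(inside)))
    }, numeric(1)))
}

#' @importFrom stats var qnorm approx
NULL
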