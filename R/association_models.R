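# Linear models relating selection pressure, expression breadth, escape
# status and sex bias. All fits are ordinary least squares with dummy-coded
# categorical terms; p values come from the t distribution with residual
# degrees of freedom (no robust errors).

# Shared OLS wrapper: complete-case fit, rank-deficiency check that names
# the collinear terms, tidy coefficient table.
fit_ols <- function(formula, data) {
  vars <- all.vars(formula)
  cc <- complete.cases(data[, vars, drop = FALSE])
  n_dropped <- sum(!cc)
  data <- data[cc, , drop = FALSE]
  # Constant predictors make the design singular before lm() would notice.
  rhs <- all.vars(formula[[3]])
  for (v in rhs) {
    if (length(unique(data[[v]])) < 2) {
      stop(sprintf("singular design: predictor '%s' is constant", v),
           call. = FALSE)
    }
  }
  fit <- lm(formula, data = data)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop(sprintf("rank-deficient design; collinear term(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  sm <- summary(fit)
  out <- tibble::tibble(
    term = rownames(sm$coefficients),
    estimate = as.numeric(sm$coefficients[, "Estimate"]),
    se = as.numeric(sm$coefficients[, "Std. Error"]),
    t = as.numeric(sm$coefficients[, "t value"]),
    p = as.numeric(sm$coefficients[, "Pr(>|t|)"])
  )
  attr(out, "n") <- nrow(data)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "r_squared") <- sm$r.squared
  attr(out, "lm") <- fit
  class(out) <- c("regression_fit", class(out))
  out
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("OLS fit: n = %d (%d dropped), R^2 = %.4f\n",
              attr(x, "n"), attr(x, "n_dropped"), attr(x, "r_squared")))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

# Reference levels mirror the reported coefficient directions: the region
# coefficient is XCR vs XAR, escape vs non-escape, male/female bias vs
# unbiased, and logical flags are TRUE vs FALSE.
encode_evolution_factors <- function(records) {
  if ("region" %in% names(records)) {
    records$region <- factor(records$region, levels = c("XAR", "XCR"))
  }
  if ("escape_status" %in% names(records)) {
    records$escape_status <- factor(records$escape_status,
                                    levels = c("non-escape", "escape"))
  }
  if ("bias" %in% names(records)) {
    records$bias <- factor(records$bias,
                           levels = intersect(
                             c("unbiased", "female", "male"),
                             unique(records$bias)))
  }
  records
}

#' Multi-covariate model of selection pressure on X-linked genes
#'
#' Fits `dnds ~ region + xy_pair + avg_expr + escape_status + disease_flag`
#' by OLS: selection pressure (macaque-human dN/dS) as a function of X-added
#' vs X-conserved region, XY-pair status, average expression level,
#' XCI-escape status, and disease-gene status. Rows with missing fields are
#' dropped and counted in the `n_dropped` attribute.
#'
#' @param records Tibble of per-gene evolution records: `dnds`, `region`
#'   (`"XAR"`/`"XCR"`), `xy_pair` (logical), `avg_expr`, `escape_status`
#'   (`"escape"`/`"non-escape"`), `disease_flag` (logical).
#' @return A `regression_fit` tibble (term, estimate, se, t, p) with `n`,
#'   `n_dropped` and `r_squared` attributes.
#' @export
fit_dnds_model <- function(records) {
  assert_columns(records, c("dnds", "region", "xy_pair", "avg_expr",
                            "escape_status", "disease_flag"),
                 "evolution records")
  records <- encode_evolution_factors(records)
  fit_ols(dnds ~ region + xy_pair + avg_expr + escape_status + disease_flag,
          records)
}

#' Multi-covariate model of expression breadth
#'
#' Fits `breadth ~ bias + dnds + avg_expr` by OLS: the number of tissues a
#' gene is expressed in (a pleiotropy proxy) as a function of sex-bias
#' category (female-biased, male-biased vs unbiased reference), dN/dS and
#' average expression. If the input contains a single bias level the bias
#' term is dropped and an intercept-plus-covariates model is fitted.
#'
#' @param records Tibble with `breadth`, `bias`, `dnds`, `avg_expr`.
#' @return A `regression_fit`.
#' @export
fit_breadth_model <- function(records) {
  assert_columns(records, c("breadth", "bias", "dnds", "avg_expr"),
                 "evolution records")
  records <- encode_evolution_factors(records)
  form <- if (nlevels(records$bias) >= 2) {
    breadth ~ bias + dnds + avg_expr
  } else {
    message("single bias level in input; bias term dropped")
    breadth ~ dnds + avg_expr
  }
  fit_ols(form, records)
}

#' Univariate OLS of one response on one predictor
#'
#' `y ~ b0 + b1 x`. For a two-level categorical or logical predictor the
#' slope equals the difference of group means exactly, which reproduces the
#' two-group comparisons (e.g. escape vs silent dN/dS, or an
#' androgen-vs-estrogen regulated gene-set flag). A constant predictor
#' raises a singular-design error.
#'
#' @param records Data frame holding both columns.
#' @param response,predictor Column names (strings).
#' @return A `regression_fit`.
#' @export
fit_univariate <- function(records, response, predictor) {
  assert_columns(records, c(response, predictor), "records")
  records <- encode_evolution_factors(records)
  fit_ols(stats::reformulate(predictor, response = response), records)
}
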