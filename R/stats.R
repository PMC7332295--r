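#' Sequential (type I) ANOVA on a linear model of per-flight kinematics
#'
#' Fits an ordinary least-squares model of a (by default log-transformed)
#' kinematic response on categorical factors in the order given, with the
#' full interaction, and decomposes the variance sequentially (R's classical
#' `anova` table). If the highest-order interaction is not significant at
#' `alpha` it is removed and the model refit with main effects only.
#' Eta-squared per term is the term's sum of squares over the total.
#'
#' @param data per-flight records (one row per flight — flights are the
#'   independent unit).
#' @param response response column name (must be positive when
#'   log-transformed).
#' @param factors character vector of predictor column names, in the
#'   sequential order wanted; categorical columns are treated as factors,
#'   numeric columns (e.g. descent angle) enter as covariates.
#' @param log_transform model `ln(response)` (default TRUE).
#' @param interaction include (and possibly drop) the interaction.
#' @param alpha significance threshold for keeping the interaction.
#' @return object of class `flight_anova`: list with `table` (term, df,
#'   sum_sq, mean_sq, statistic, p_value, eta_sq; residual row last),
#'   `model`, `dropped_interaction`, `response`, `log_transform`.
#' @export
fit_lm_sequential_anova <- function(data, response, factors,
                                    log_transform = TRUE, interaction = TRUE,
                                    alpha = 0.05) {
  stopifnot(response %in% names(data), all(factors %in% names(data)))
  d <- as.data.frame(data)
  for (f in factors) if (!is.numeric(d[[f]])) d[[f]] <- factor(d[[f]])
  for (f in factors) {
    if (is.factor(d[[f]]) && nlevels(droplevels(d[[f]])) < 2) {
      stop("factor '", f, "' has fewer than 2 levels", call. = FALSE)
    }
  }
  if (log_transform) {
    if (any(d[[response]] <= 0, na.rm = TRUE)) {
      stop("log transform requires a strictly positive response", call. = FALSE)
    }
    d$.resp <- log(d[[response]])
  } else {
    d$.resp <- d[[response]]
  }
  rhs <- if (interaction && length(factors) > 1) {
    paste(factors, collapse = " * ")
  } else {
    paste(factors, collapse = " + ")
  }
  fml <- stats::as.formula(paste(".resp ~", rhs))
  fit <- lm(fml, data = d)
  if (any(is.na(coef(fit)))) {
    stop("rank-deficient model; aliased terms: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  dropped <- FALSE
  if (interaction && length(factors) > 1) {
    a <- anova(fit)
    inter_term <- paste(factors, collapse = ":")
    p_int <- a[inter_term, "Pr(>F)"]
    if (!is.na(p_int) && p_int >= alpha) {
      fml <- stats::as.formula(paste(".resp ~", paste(factors, collapse = " + ")))
      fit <- lm(fml, data = d)
      dropped <- TRUE
    }
  }
  a <- anova(fit)
  tab <- tibble::tibble(
    term = rownames(a),
    df = a$Df,
    sum_sq = a$`Sum Sq`,
    mean_sq = a$`Mean Sq`,
    statistic = a$`F value`,
    p_value = a$`Pr(>F)`
  )
  tab$eta_sq <- tab$sum_sq / sum(tab$sum_sq)
  tab$eta_sq[tab$term == "Residuals"] <- NA_real_
  structure(
    list(table = tab, model = fit, data = d, dropped_interaction = dropped,
         response = response, factors = factors, log_transform = log_transform),
    class = "flight_anova"
  )
}

#' @export
print.flight_anova <- function(x, ...) {
  cat(sprintf("Sequential ANOVA of %s%s ~ %s%s\n",
              if (x$log_transform) "ln " else "", x$response,
              paste(x$factors, collapse = " * "),
              if (x$dropped_interaction) "  [interaction dropped]" else ""))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' Eta-squared effect sizes from an ANOVA table
#'
#' Each modelled term's sum of squares divided by the total sum of squares
#' (including residuals); values lie in `[0, 1]` and sum to at most 1.
#'
#' @param anova_fit a `flight_anova` object or its `table`.
#' @return named numeric vector of eta-squared values, one per modelled term.
#' @export
eta_squared <- function(anova_fit) {
  tab <- if (inherits(anova_fit, "flight_anova")) anova_fit$table else anova_fit
  total <- sum(tab$sum_sq)
  if (total <= 0) stop("zero total sum of squares", call. = FALSE)
  keep <- tab$term != "Residuals"
  setNames(tab$sum_sq[keep] / total, tab$term[keep])
}

#' Tukey HSD pairwise contrasts
#'
#' Studentized-range-adjusted pairwise comparisons on a fitted kinematics
#' model, via `stats::TukeyHSD` on the equivalent `aov` fit. For an
#' interaction term (e.g. species by fluid), `within` restricts the output
#' to contrasts sharing a level of that factor — the within-species
#' air-versus-water contrasts — reported in alphabetical order.
#'
#' @param anova_fit a `flight_anova`. The aov is refit with the requested
#'   term present even if the sequential fit dropped the interaction, so the
#'   contrasts are between cell means.
#' @param term model term to compare (default: the full interaction).
#' @param within optional factor name: keep only contrasts whose cells share
#'   a level of this factor.
#' @return tibble: `comparison`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(anova_fit, term = NULL, within = NULL) {
  stopifnot(inherits(anova_fit, "flight_anova"))
  factors <- anova_fit$factors
  if (is.null(term)) {
    term <- if (length(factors) > 1) paste(factors, collapse = ":") else factors
  }
  d <- anova_fit$data
  for (f in factors) {
    if (is.factor(d[[f]]) && nlevels(droplevels(d[[f]])) < 2) {
      stop("factor '", f, "' has fewer than 2 levels", call. = FALSE)
    }
  }
  rhs <- if (grepl(":", term)) paste(factors, collapse = " * ")
         else paste(factors, collapse = " + ")
  av <- aov(stats::as.formula(paste(".resp ~", rhs)), data = d)
  th <- TukeyHSD(av, which = term)[[term]]
  out <- tibble::tibble(
    comparison = rownames(th),
    diff = th[, "diff"], lwr = th[, "lwr"], upr = th[, "upr"],
    p_adj = th[, "p adj"]
  )
  if (!is.null(within) && grepl(":", term)) {
    pos <- match(within, strsplit(term, ":")[[1]])
    lvl <- function(cell) strsplit(cell, ":")[[1]][pos]
    sides <- strsplit(out$comparison, "-")
    keep <- vapply(sides, function(s) lvl(s[1]) == lvl(s[2]), logical(1))
    out <- out[keep, , drop = FALSE]
    out <- out[order(out$comparison), , drop = FALSE]
  }
  out
}

#' Welch's unequal-variance t-test
#'
#' Two-sample t statistic with the Welch-Satterthwaite fractional degrees of
#' freedom and a two-sided p-value, computed from the closed forms, with
#' Cohen's d (mean difference over the root average variance) reported
#' alongside.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param label_a,label_b names used in the comparison label.
#' @return one-row tibble: `test_name`, `comparison`, `statistic`, `df`,
#'   `p_value`, `effect_size`.
#' @export
welch_t_test <- function(group_a, group_b, label_a = "a", label_b = "b") {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  if (va + vb == 0) {
    stop("zero variance in both groups: t statistic undefined", call. = FALSE)
  }
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(tstat), df)
  d <- (mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2)
  tibble::tibble(
    test_name = "welch_t",
    comparison = paste(label_a, "-", label_b),
    statistic = tstat, df = df, p_value = p, effect_size = d
  )
}

#' Bonferroni-adjusted significance threshold
#'
#' `family_alpha / m` for `m` comparisons: with four species tested at a
#' family level of 0.05, the per-test critical p-value is 0.0125.
#'
#' @param family_alpha family-wise error rate, in (0, 1).
#' @param m number of comparisons (>= 1).
#' @return adjusted alpha.
#' @export
bonferroni_alpha <- function(family_alpha, m) {
  stopifnot(family_alpha > 0, family_alpha < 1, m >= 1)
  family_alpha / m
}

#' Bonferroni outlier test on a fitted model
#'
#' Tests the observation with the largest absolute externally studentized
#' residual: the Bonferroni-adjusted two-sided p-value is
#' `min(1, n * 2 * P(T > |r|))` on `n - p - 1` degrees of freedom. If the
#' adjusted p-value falls below `alpha`, the observation is excluded and the
#' model refit once (a single pass, not iterated to convergence).
#'
#' @param model an `lm` fit, or a `flight_anova`.
#' @param alpha exclusion threshold on the adjusted p-value.
#' @param refit refit without the flagged observation.
#' @return list: `result` (one-row tibble with `observation`, `statistic`,
#'   `df`, `p_value`, `significant`), `excluded` (row index or empty),
#'   `model` (the refit model if an outlier was excluded, else the input).
#' @export
outlier_test <- function(model, alpha = 0.05, refit = TRUE) {
  if (inherits(model, "flight_anova")) model <- model$model
  stopifnot(inherits(model, "lm"))
  n <- length(stats::residuals(model))
  p_rank <- model$rank
  df_stud <- n - p_rank - 1
  if (df_stud < 1) {
    stop("insufficient residual degrees of freedom for studentization",
         call. = FALSE)
  }
  rs <- stats::rstudent(model)
  i <- unname(which.max(abs(rs)))
  p_adj <- min(1, n * 2 * pt(-abs(rs[i]), df_stud))
  sig <- p_adj < alpha
  out_model <- model
  excluded <- integer(0)
  if (sig && refit) {
    d <- stats::model.frame(model)
    out_model <- lm(stats::formula(model), data = d[-i, , drop = FALSE])
    excluded <- i
  }
  list(
    result = tibble::tibble(
      test_name = "bonferroni_outlier", observation = i,
      statistic = unname(rs[i]), df = df_stud, p_value = p_adj,
      significant = sig
    ),
    excluded = excluded,
    model = out_model
  )
}

#' Paired Cohen's d
#'
#' Effect size for paired series: the mean of the pairwise differences over
#' their standard deviation.
#'
#' @param series_a,series_b numeric vectors of equal length (>= 2).
#' @return Cohen's d.
#' @export
cohens_d_paired <- function(series_a, series_b) {
  if (length(series_a) != length(series_b) || length(series_a) < 2) {
    stop("paired series must have equal length >= 2", call. = FALSE)
  }
  dd <- series_a - series_b
  if (all(dd == 0)) return(0)
  s <- sd(dd)
  if (!is.finite(s) || s == 0) {
    stop("zero standard deviation of differences", call. = FALSE)
  }
  mean(dd) / s
}
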