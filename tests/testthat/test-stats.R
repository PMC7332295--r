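# simulated per-flight table with configurable effects
sim_flights <- function(n_per_cell = 10, species_eff = c(0, 0.1, -0.1, 0.05),
                        fluid_eff = 0, interaction = 0, sd = 0.15, seed = 1) {
  set.seed(seed)
  sp <- c("a_species", "b_species", "c_species", "d_species")
  g <- expand.grid(species = sp, fluid = c("air", "water"),
                   rep = seq_len(n_per_cell), stringsAsFactors = FALSE)
  mu <- 1 + species_eff[match(g$species, sp)] +
    ifelse(g$fluid == "water", fluid_eff, 0) +
    ifelse(g$fluid == "water", interaction * (match(g$species, sp) - 2.5), 0)
  g$y <- exp(mu + rnorm(nrow(g), 0, sd))
  g
}

test_that("sequential sums of squares match the nested-model oracle", {
  for (seed in 1:4) {
    d <- sim_flights(n_per_cell = 6, fluid_eff = 0.3, interaction = 0.1,
                     sd = 0.2, seed = seed)
    fit <- fit_lm_sequential_anova(d, "y", c("species", "fluid"),
                                   alpha = 1)  # always keep the interaction
    # oracle: residual-SS drops along the nested sequence of models
    dd <- d
    dd$ly <- log(d$y)
    rss <- function(fml) sum(resid(lm(fml, data = dd))^2)
    ss_species <- rss(ly ~ 1) - rss(ly ~ species)
    ss_fluid <- rss(ly ~ species) - rss(ly ~ species + fluid)
    ss_int <- rss(ly ~ species + fluid) - rss(ly ~ species * fluid)
    tab <- fit$table
    expect_equal(tab$sum_sq[tab$term == "species"], ss_species, tolerance = 1e-10)
    expect_equal(tab$sum_sq[tab$term == "fluid"], ss_fluid, tolerance = 1e-10)
    expect_equal(tab$sum_sq[tab$term == "species:fluid"], ss_int, tolerance = 1e-10)
    # total SS decomposes exactly
    expect_equal(sum(tab$sum_sq), sum((dd$ly - mean(dd$ly))^2), tolerance = 1e-10)
  }
})

test_that("one balanced factor gives F equal to the squared pooled t", {
  set.seed(9)
  d <- data.frame(species = rep(c("s1", "s2"), each = 12),
                  y = exp(rnorm(24, rep(c(1, 1.4), each = 12), 0.2)))
  fit <- fit_lm_sequential_anova(d, "y", "species")
  tt <- t.test(log(y) ~ species, data = d, var.equal = TRUE)
  expect_equal(fit$table$statistic[1], unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("a zero-residual response pushes eta-squared to a total of one", {
  d <- expand.grid(species = c("s1", "s2"), fluid = c("air", "water"),
                   rep = 1:3, stringsAsFactors = FALSE)
  d$y <- exp(ifelse(d$species == "s1", 1, 2) + ifelse(d$fluid == "air", 0.5, 0))
  fit <- suppressWarnings(   # F on a perfect fit is unreliable; only SS matter
    fit_lm_sequential_anova(d, "y", c("species", "fluid"), interaction = FALSE))
  expect_equal(sum(eta_squared(fit)), 1, tolerance = 1e-9)
  expect_error(eta_squared(tibble::tibble(term = "a", sum_sq = 0)), "zero total")
})

test_that("the interaction is dropped when insignificant and kept when real", {
  d0 <- sim_flights(n_per_cell = 10, fluid_eff = 0.4, interaction = 0, seed = 3)
  f0 <- fit_lm_sequential_anova(d0, "y", c("species", "fluid"))
  expect_true(f0$dropped_interaction)
  expect_false("species:fluid" %in% f0$table$term)

  d1 <- sim_flights(n_per_cell = 20, fluid_eff = 0.4, interaction = 0.5,
                    sd = 0.1, seed = 3)
  f1 <- fit_lm_sequential_anova(d1, "y", c("species", "fluid"))
  expect_false(f1$dropped_interaction)
  expect_true("species:fluid" %in% f1$table$term)
})

test_that("Tukey HSD matches the pooled t-test at two groups", {
  set.seed(5)
  d <- data.frame(species = rep(c("s1", "s2"), each = 10),
                  y = exp(rnorm(20, rep(c(1, 1.25), each = 10), 0.2)))
  fit <- fit_lm_sequential_anova(d, "y", "species")
  tk <- tukey_hsd(fit, term = "species")
  tt <- t.test(log(y) ~ species, data = d, var.equal = TRUE)
  # studentized-range identity at k = 2: q = |t| sqrt(2)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-8)

  d$y <- rep(exp(1), 20) * rep(c(1, 1), each = 10) + rep(0:9 / 50, 2)
  fit2 <- fit_lm_sequential_anova(d, "y", "species", log_transform = FALSE)
  tk2 <- tukey_hsd(fit2, term = "species")
  expect_gt(tk2$p_adj, 0.999)
})

test_that("a strong within-species fluid effect lights up all four contrasts", {
  d <- sim_flights(n_per_cell = 10, fluid_eff = log(2), sd = 0.1, seed = 7)
  fit <- fit_lm_sequential_anova(d, "y", c("species", "fluid"))
  tk <- tukey_hsd(fit, term = "species:fluid", within = "species")
  expect_identical(nrow(tk), 4L)
  expect_true(all(tk$p_adj < 0.05))
  # alphabetical by species
  expect_identical(tk$comparison, sort(tk$comparison))
})

test_that("Welch statistic, df and p match the closed forms and stats::t.test", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  r <- welch_t_test(a, b)
  # hand evaluation: equal variances 2.5, n = 5
  se <- sqrt(2.5 / 5 + 2.5 / 5)
  expect_equal(r$statistic, (3 - 4) / se, tolerance = 1e-12)
  expect_equal(r$df, se^4 / (2 * (2.5 / 5)^2 / 4) * 1, tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pt(-1, 8), tolerance = 1e-12)
  # independent route: R's implementation agrees
  tt <- t.test(a, b, var.equal = FALSE)
  expect_equal(r$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r$df, unname(tt$parameter), tolerance = 1e-10)
  expect_equal(r$p_value, tt$p.value, tolerance = 1e-12)

  same <- welch_t_test(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(welch_t_test(c(1, 1), c(2, 2)), "zero variance")
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("Bonferroni alpha is family alpha over m", {
  expect_identical(bonferroni_alpha(0.05, 4), 0.0125)
  expect_identical(bonferroni_alpha(0.05, 1), 0.05)
  expect_identical(bonferroni_alpha(0.01, 5), 0.002)
})

test_that("outlier test flags gross outliers, controls the null, matches car", {
  set.seed(2)
  d <- data.frame(x = 1:30)
  d$y <- 2 + 0.5 * d$x + rnorm(30, 0, 0.5)
  d$y[17] <- d$y[17] + 10 * 0.5          # ten residual SDs
  m <- lm(y ~ x, data = d)
  out <- outlier_test(m)
  expect_identical(out$result$observation, 17L)
  expect_true(out$result$significant)
  expect_identical(out$excluded, 17L)
  expect_equal(length(resid(out$model)), 29L)
  # agreement with car::outlierTest on statistic and Bonferroni p
  ct <- car::outlierTest(m, cutoff = Inf, n.max = 1)
  expect_equal(out$result$statistic, unname(ct$rstudent), tolerance = 1e-10)
  expect_equal(out$result$p_value, unname(ct$bonf.p), tolerance = 1e-10)

  # null control: flag rate around or below the nominal 5 percent
  set.seed(31)
  flags <- vapply(1:400, function(i) {
    dd <- data.frame(x = 1:50, y = rnorm(50))
    outlier_test(lm(y ~ x, data = dd), refit = FALSE)$result$significant
  }, logical(1))
  expect_lt(mean(flags), 0.08)

  tiny <- lm(y ~ x, data = data.frame(x = 1:3, y = c(1, 2, 4)))
  expect_error(outlier_test(tiny), "insufficient residual")
})

test_that("paired Cohen's d behaves at its edge cases and under simulation", {
  expect_identical(cohens_d_paired(1:5, 1:5), 0)
  expect_error(cohens_d_paired(2:5, 1:4), "zero standard deviation")
  set.seed(8)
  a <- rnorm(1e4); b <- a - rnorm(1e4, 0.5, 1)
  expect_equal(cohens_d_paired(a, b), 0.5, tolerance = 0.03)
})
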