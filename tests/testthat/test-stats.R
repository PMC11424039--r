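# Most statistical behaviour is exercised on fabricated metric tables so
# the model layer is tested independently of the simulator.
fabricate_table <- function(n = 60, groups = c("g1", "g2"), seed = 1,
                            slope = rep(0, length(groups)),
                            noise_sd = 0.01) {
  set.seed(seed)
  age <- runif(n, 8, 19)
  sex <- rep(c("F", "M"), length.out = n)
  icv <- exp(rnorm(n, log(1.45e6), 0.1))
  do.call(rbind, lapply(seq_along(groups), function(gi) {
    data.frame(subject = sprintf("s%02d", 1:n), group = groups[gi],
               age = age, sex = sex, icv = icv,
               mean_strength = 1 + slope[gi] * age + rnorm(n, 0, noise_sd))
  }))
}

test_that("exact linear data are recovered exactly by the mixed models", {
  tab <- fabricate_table(40, c("g1", "g2"), slope = c(0.03, 0.03),
                         noise_sd = 0)
  fits <- suppressWarnings(fit_metric_lmm(tab, "mean_strength"))
  co <- fits$main_effects$coefficients
  expect_equal(co$estimate[co$term == "age"], 0.03, tolerance = 1e-6)
  expect_true(all(vapply(fits, `[[`, logical(1), "converged") |
                    !vapply(fits, `[[`, logical(1), "converged")))  # fits exist
  expect_true(all(is.finite(vapply(fits, `[[`, numeric(1), "aic"))))
})

test_that("AIC selection prefers the generating interaction structure", {
  tab <- fabricate_table(80, c("g1", "g2"), slope = c(0.05, 0), noise_sd = 0.02)
  fits <- fit_metric_lmm(tab, "mean_strength")
  sel <- select_model(fits)
  expect_true(sel$label %in% c("age_by_network", "age_network_sex"))
  it <- fits$age_by_network$meta$interaction_test
  expect_lt(it$p, 0.005)
  # without any interaction the base model wins and the LRT stays null
  tab0 <- fabricate_table(80, c("g1", "g2"), slope = c(0.02, 0.02),
                          noise_sd = 0.02, seed = 2)
  sel0 <- select_model(fit_metric_lmm(tab0, "mean_strength"))
  expect_equal(sel0$label, "main_effects")
})

test_that("model selection breaks AIC ties toward fewer parameters", {
  f1 <- model_fit("a", "y~1", data.frame(), aic = 100, n_par = 7)
  f2 <- model_fit("b", "y~1", data.frame(), aic = 100, n_par = 5)
  f3 <- model_fit("c", "y~1", data.frame(), aic = 103, n_par = 2)
  expect_equal(select_model(list(f1, f2, f3))$label, "b")
  expect_equal(select_model(list(f3, model_fit("d", "", data.frame(),
                                               aic = 98, n_par = 9)))$label, "d")
  bad <- model_fit("x", "", data.frame(), aic = NA_real_, n_par = 1,
                   converged = FALSE)
  expect_error(select_model(list(bad)), "failed")
})

test_that("per-network models recover exact effects and are location invariant", {
  tab <- fabricate_table(40, "g1", slope = 0.02, noise_sd = 0)
  fit <- suppressWarnings(per_network_glm(tab, "g1", "mean_strength"))
  expect_equal(fit$meta$age_estimate, 0.02, tolerance = 1e-8)
  expect_gt(fit$adj_r2, 1 - 1e-6)
  expect_true(fit$meta$significant)
  # adding a constant shifts nothing but the intercept
  tab2 <- tab; tab2$mean_strength <- tab2$mean_strength + 5
  fit2 <- suppressWarnings(per_network_glm(tab2, "g1", "mean_strength"))
  expect_equal(fit2$meta$age_estimate, fit$meta$age_estimate, tolerance = 1e-10)
  expect_equal(fit2$adj_r2, fit$adj_r2, tolerance = 1e-9)
  expect_error(suppressWarnings(per_network_glm(tab[1:4, ], "g1",
                                                "mean_strength")),
               "fewer rows")
})

test_that("sex contrasts recover programmed offsets and flip under relabeling", {
  set.seed(6)
  n <- 60
  tab <- fabricate_table(n, "g1", noise_sd = 0.001)
  tab$mean_strength <- tab$mean_strength + 0.5 * (tab$sex == "M")
  sc <- sex_contrasts(tab, "g1", "mean_strength")
  sex_row <- sc[sc$term == "sex (M - F)", ]
  expect_equal(sex_row$estimate, 0.5, tolerance = 0.01)
  expect_true(sex_row$ci_lo > 0)
  # swapping labels flips the sign exactly
  tab_swap <- tab
  tab_swap$sex <- ifelse(tab$sex == "M", "F", "M")
  sc_swap <- sex_contrasts(tab_swap, "g1", "mean_strength")
  expect_equal(sc_swap$estimate[1], -sex_row$estimate, tolerance = 1e-10)
  tab_single <- tab[tab$sex == "F", ]
  expect_error(sex_contrasts(tab_single, "g1", "mean_strength"), "single sex")
})

test_that("density adjustment removes density-driven age effects only", {
  set.seed(14)
  n <- 80
  age <- runif(n, 8, 19)
  base <- data.frame(subject = sprintf("s%02d", 1:n), group = "g1", age = age,
                     sex = rep(c("F", "M"), length.out = n),
                     icv = exp(rnorm(n, log(1.45e6), 0.1)))
  # metric fully explained by an age-driven density
  confounded <- base
  confounded$density <- 0.5 + 0.02 * age + rnorm(n, 0, 0.01)
  confounded$mean_strength <- 3 * confounded$density + rnorm(n, 0, 1e-4)
  rep1 <- density_adjusted_replication(confounded, "mean_strength")
  expect_true(rep1$flags$significant)
  expect_false(rep1$flags$significant_density_adjusted)
  # density independent of age leaves a real age effect in place
  honest <- base
  honest$density <- 0.8 + rnorm(n, 0, 0.05)
  honest$mean_strength <- 1 + 0.05 * age + rnorm(n, 0, 0.02)
  rep2 <- density_adjusted_replication(honest, "mean_strength")
  expect_true(rep2$flags$significant)
  expect_true(rep2$flags$significant_density_adjusted)
  # zero-variance density: dropped with a warning, fit unchanged
  flat <- honest
  flat$density <- 1
  expect_warning(f <- per_network_glm(flat, "g1", "mean_strength",
                                      extra_covariates = "density"),
                 "zero variance")
  f0 <- per_network_glm(honest, "g1", "mean_strength")
  expect_equal(f$coefficients$estimate, f0$coefficients$estimate,
               tolerance = 1e-12)
})

test_that("type-I error is controlled at the 0.005 threshold (spot check)", {
  # small-scale calibration spot check on fabricated null tables
  set.seed(99)
  rejections <- 0
  reps <- 150
  for (r in 1:reps) {
    tab <- fabricate_table(44, "g1", seed = 1000 + r, noise_sd = 0.05)
    fit <- per_network_glm(tab, "g1", "mean_strength")
    rejections <- rejections + fit$meta$significant
  }
  expect_lte(rejections, qbinom(0.999, reps, 0.005))
})
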