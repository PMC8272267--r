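# inferential_models: pruning, the count LMM, the activity GLMM.

test_that("prune_correlated_predictors: pairs, chains, constants, row order", {
  set.seed(12)
  n <- 400
  A <- rnorm(n)
  B <- 0.74 * A + sqrt(1 - 0.74^2) * rnorm(n)
  # designed so r(B,C) ~ 0.7 while r(A,C) ~ 0.1
  C <- -0.765 * A + 1.235 * B + 0.46 * rnorm(n)
  # verify the fixture correlations before asserting behaviour
  expect_gt(abs(cor(A, B)), 0.6)
  D <- rnorm(n)
  tab <- data.frame(A = A, B = B, C = C, D = D)
  # r(A,B) > 0.6: only the higher-priority survives
  expect_equal(prune_correlated_predictors(tab[c("A", "B")], c("A", "B")),
               "A")
  # independent predictors all retained
  expect_equal(prune_correlated_predictors(tab[c("A", "D")], c("A", "D")),
               c("A", "D"))
  # chain A-B, B-C correlated, A-C weak, priority A>B>C -> {A, C}
  expect_gt(abs(cor(B, C)), 0.6)
  expect_lt(abs(cor(A, C)), 0.6)
  expect_equal(prune_correlated_predictors(tab[c("A", "B", "C")],
                                           c("A", "B", "C")), c("A", "C"))
  # constant predictor dropped with a warning
  tab$K <- 1
  expect_warning(r <- prune_correlated_predictors(tab[c("K", "A")],
                                                  c("K", "A")), "constant")
  expect_equal(r, "A")
  # row order cannot matter
  perm <- sample(n)
  expect_equal(prune_correlated_predictors(tab[perm, c("A", "B", "C")],
                                           c("A", "B", "C")), c("A", "C"))
})

sim_counts <- function(seed, pop_offset = 0, n_ind = 24) {
  set.seed(seed)
  ind <- sprintf("i%02d", seq_len(n_ind))
  pop <- rep(c("p1", "p2"), each = n_ind / 2)
  u <- rnorm(n_ind, 0, 1)
  out <- expand.grid(individual_id = ind, season = c("spring", "fall"),
                     stringsAsFactors = FALSE)
  out$population <- pop[match(out$individual_id, ind)]
  out$count <- 4 + pop_offset * (out$population == "p2") +
    u[match(out$individual_id, ind)] + rnorm(nrow(out), 0, 1)
  out
}

test_that("count LMM recovers a population offset and is duplication-invariant", {
  d <- sim_counts(1, pop_offset = 5)
  fit <- fit_stopover_count_model(d)
  b <- fit$terms[fit$terms$name == "populationp2", ]
  expect_lt(abs(b$beta - 5), 1.96 * b$se + 1)
  expect_true("individual_id.(Intercept)" %in% names(fit$random_effect_sd))
  expect_equal(fit$n_obs, nrow(d))
  # duplicated dataset: identical point estimates
  fit2 <- fit_stopover_count_model(rbind(d, d))
  expect_equal(fit2$terms$beta, fit$terms$beta, tolerance = 1e-4)
  # single-season data drops the season term with a warning
  d_fall <- d
  d_fall$season <- "fall"
  expect_warning(f3 <- fit_stopover_count_model(d_fall), "single season")
  expect_false(any(grepl("season", f3$terms$name)))
})

test_that("count LMM type-I behaviour under zero effects", {
  hits <- 0; reps <- 40
  for (r in seq_len(reps)) {
    d <- sim_counts(100 + r, pop_offset = 0)
    fit <- fit_stopover_count_model(d)
    b <- fit$terms[fit$terms$name == "populationp2", ]
    if (abs(b$beta) <= 2 * b$se) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.8)
})

test_that("activity GLMM: aggregated binomial equals disaggregated Bernoulli", {
  d <- simulate_glmm_table(n_stopovers = 120, n_individuals = 8,
                           n_populations = 2, seed = 4)
  preds <- c("precipitation_fraction", "thermal_updraft_velocity",
             "temperature")
  agg <- suppressMessages(fit_activity_glmm(d, preds))
  # expand to hour-level 0/1 rows
  rows <- rep(seq_len(nrow(d)), d$n_daytime_h)
  dd <- d[rows, ]
  ok <- sequence(d$n_daytime_h) <= rep(d$n_active_h, d$n_daytime_h)
  dd$n_active_h <- as.integer(ok)
  dd$n_daytime_h <- 1L
  dis <- suppressMessages(fit_activity_glmm(dd, preds))
  expect_equal(agg$terms$beta, dis$terms$beta, tolerance = 1e-3)
  expect_equal(agg$terms$se, dis$terms$se, tolerance = 1e-3)
})

test_that("activity GLMM refuses single-individual data", {
  d <- simulate_glmm_table(n_stopovers = 40, n_individuals = 2,
                           n_populations = 1, seed = 5)
  d$individual_id <- "ind01"
  expect_error(fit_activity_glmm(d, "temperature"), "2 individuals")
})

test_that("zero-effect activity simulation centres estimates near zero", {
  signs <- c(0, 0, 0)
  reps <- 20
  for (r in seq_len(reps)) {
    d <- simulate_glmm_table(n_stopovers = 200, n_individuals = 12,
                             betas = c(-0.5, 0, 0, 0), seed = 300 + r)
    fit <- suppressMessages(fit_activity_glmm(
      d, c("precipitation_fraction", "thermal_updraft_velocity",
           "temperature")))
    signs <- signs + (fit$terms$beta[-1] > 0)
  }
  for (s in signs) expect_gt(s / reps, 0.15)
  for (s in signs) expect_lt(s / reps, 0.85)
})
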