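make_metrics <- function(n_per_cell = 10, boat = 0, tank = 0, sd = 0.1,
                         seed = 1) {
  set.seed(seed)
  g <- expand.grid(treatment = c("ambient", "boat"),
                   crab_condition = c("no_crab", "crab_in_box", "crab_in_tank"),
                   rep = seq_len(n_per_cell), stringsAsFactors = FALSE)
  g$mussel_size <- runif(nrow(g), 3.1, 5.4)
  g$crab_size <- runif(nrow(g), 1.5, 4.4)
  g$long_term_delta <- rnorm(nrow(g), 0, sd) +
    boat * (g$treatment == "boat") + tank * (g$crab_condition == "crab_in_tank")
  g$short_term_delta <- rnorm(nrow(g), 0, sd)
  g
}

test_that("GLM fits reproduce closed-form estimates", {
  d <- data.frame(y = c(1, 2, 3), x = c(0, 1, 2))
  f <- fit_glm(model_spec("y", "x"), d)
  expect_equal(f$coefficients$estimate, c(1, 1), tolerance = 1e-10)

  dp <- data.frame(touching_s = rep(4L, 12))
  fp <- fit_glm(model_spec("touching_s", character(), family = "poisson"), dp)
  expect_equal(fp$coefficients$estimate, log(4), tolerance = 1e-8)

  dg <- data.frame(long_term_delta = c(0.2, -0.1, 0.4, 0.05))
  fg <- fit_glm(model_spec("long_term_delta"), dg)
  expect_equal(fg$coefficients$estimate, mean(dg$long_term_delta),
               tolerance = 1e-10)
  expect_error(fit_glm(model_spec("touching_s", character(), "poisson"),
                       data.frame(touching_s = c(1.5, 2))), "integer")
})

test_that("Gaussian identity GLM equals ordinary least squares", {
  m <- make_metrics(boat = -0.1, tank = -0.2, seed = 3)
  f <- fit_glm(model_spec("long_term_delta",
                          c("sound", "crab", "mussel_size")), m)
  ols <- lm(long_term_delta ~ treatment + crab_condition + mussel_size,
            data = transform(m,
              treatment = factor(treatment, c("ambient", "boat")),
              crab_condition = factor(crab_condition,
                c("no_crab", "crab_in_box", "crab_in_tank"))))
  expect_equal(f$coefficients$estimate, unname(coef(ols)), tolerance = 1e-8)
})

test_that("reference levels are ambient and no_crab", {
  m <- make_metrics(seed = 4)
  f <- fit_glm(model_spec("long_term_delta", c("sound", "crab")), m)
  expect_setequal(f$coefficients$term,
                  c("(Intercept)", "treatmentboat", "crab_conditioncrab_in_box",
                    "crab_conditioncrab_in_tank"))
})

test_that("AICc formula, k = 0 case, and large-n limit", {
  expect_equal(aicc(-10, 3, 20), 27.5)
  expect_equal(aicc(-10, 0, 20), 20)
  expect_equal(aicc(-10, 3, 1e9), -2 * (-10) + 2 * 3, tolerance = 1e-6)
  expect_error(aicc(-10, 3, 4), "undefined")
  # against a fitted model's own bookkeeping
  m <- make_metrics(seed = 5)
  f <- fit_glm(model_spec("long_term_delta", "sound"), m)
  expect_equal(f$aicc, aicc(f$loglik, f$k, f$n))
  expect_equal(f$k, 3)  # intercept, boat, residual variance
})

test_that("candidate enumeration respects marginality", {
  full <- model_spec("long_term_delta",
                     c("sound", "crab", "sound:crab", "mussel_size", "crab_size"))
  cands <- enumerate_candidates(full)
  expect_length(cands, 20)
  labels <- vapply(cands, format, character(1))
  expect_length(unique(labels), 20)
  for (cd in cands)
    if ("sound:crab" %in% cd$terms)
      expect_true(all(c("sound", "crab") %in% cd$terms))
  expect_length(enumerate_candidates(model_spec("y", "sound")), 2)
  expect_length(enumerate_candidates(model_spec("y")), 1)
  expect_error(model_spec("y", c("sound", "sound:crab")), "marginality|requires")
})

test_that("selection ranks by AICc with parsimony tie-breaks", {
  m <- make_metrics(boat = -0.5, sd = 0.05, seed = 6)
  sel <- select_best(model_spec("long_term_delta", c("sound", "crab")), m)
  expect_equal(sel$table$delta_aicc[1], 0)
  expect_true(!is.unsorted(sel$table$aicc))
  expect_true("sound" %in% sel$best$spec$terms)

  dup <- select_best(list(model_spec("long_term_delta", "sound"),
                          model_spec("long_term_delta", "sound")), m)
  expect_equal(dup$table$aicc[1], dup$table$aicc[2])
  expect_true(dup$table$tied[2])

  single <- select_best(list(model_spec("long_term_delta", "sound")), m)
  expect_equal(nrow(single$table), 1)
  expect_equal(single$table$delta_aicc, 0)
})

test_that("selection finds a strong sound effect in most replicates", {
  hits <- 0
  for (s in 1:100) {
    m <- make_metrics(n_per_cell = 25, boat = -0.5, sd = 0.1, seed = 400 + s)
    sel <- select_best(model_spec("long_term_delta",
                                  c("sound", "crab", "sound:crab",
                                    "mussel_size", "crab_size")), m)
    if ("sound" %in% sel$best$spec$terms) hits <- hits + 1
  }
  expect_gte(hits, 80)
})

test_that("Tukey contrasts: null factor, two-level equivalence, separation", {
  m <- make_metrics(seed = 7)
  m$long_term_delta <- rep(rnorm(nrow(m) / 3, 0, 0.1), 3)  # identical groups
  f <- fit_glm(model_spec("long_term_delta", "crab"), m)
  tk <- tukey_pairwise(f, "crab_condition")
  expect_equal(nrow(tk), 3)
  expect_equal(tk$estimate, rep(0, 3), tolerance = 1e-10)
  expect_true(all(tk$p_adjusted > 0.99))

  f2 <- fit_glm(model_spec("long_term_delta", "sound"), make_metrics(seed = 8))
  tk2 <- tukey_pairwise(f2, "treatment")
  wald_p <- f2$coefficients$p_value[f2$coefficients$term == "treatmentboat"]
  # glht uses the normal reference; compare with the z-based Wald p
  z <- f2$coefficients$statistic[f2$coefficients$term == "treatmentboat"]
  expect_equal(tk2$p_adjusted, 2 * pnorm(-abs(z)), tolerance = 1e-6)
  expect_equal(tk2$p_adjusted, wald_p, tolerance = 0.02)

  expect_error(tukey_pairwise(f2, "crab_condition"), "not a term")

  hits <- 0
  for (s in 1:100) {
    m3 <- make_metrics(n_per_cell = 17, tank = 1.0, sd = 0.1, seed = 900 + s)
    t3 <- tukey_pairwise(fit_glm(model_spec("long_term_delta", "crab"), m3),
                         "crab_condition")
    sig <- t3$p_adjusted < 0.01
    names(sig) <- t3$contrast
    ok <- sig[["crab_in_tank - no_crab"]] && sig[["crab_in_tank - crab_in_box"]] &&
      !sig[["crab_in_box - no_crab"]]
    if (ok) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("per-condition sound models report the boat effect per subset", {
  m <- make_metrics(n_per_cell = 20, seed = 10)
  # boat effect only in the no-crab subset
  m$long_term_delta <- m$long_term_delta -
    0.4 * (m$treatment == "boat" & m$crab_condition == "no_crab")
  pc <- per_condition_sound_models(m)
  expect_named(pc, c("no_crab", "crab_in_box", "crab_in_tank"))
  p_no <- coef_of(pc$no_crab, "treatmentboat")
  p_box <- coef_of(pc$crab_in_box, "treatmentboat")
  expect_lt(p_no[["p_value"]], 0.001)
  expect_gt(p_box[["p_value"]], 0.05)

  # identical subsets give identical coefficients
  m2 <- make_metrics(seed = 11)
  base <- m2[m2$crab_condition == "no_crab", ]
  clones <- do.call(rbind, lapply(c("no_crab", "crab_in_box", "crab_in_tank"),
                                  function(cc) transform(base, crab_condition = cc)))
  pc2 <- per_condition_sound_models(clones)
  expect_equal(pc2$no_crab$coefficients$estimate,
               pc2$crab_in_tank$coefficients$estimate, tolerance = 1e-10)

  tiny <- make_metrics(n_per_cell = 1, seed = 12)
  expect_warning(pc3 <- per_condition_sound_models(tiny), "zero residual")
  expect_true(pc3$no_crab$zero_residual_df)
})

test_that("proximity model rejects a constant predictor", {
  m <- make_metrics(seed = 13)
  m$close_or_touching <- ifelse(m$crab_condition == "crab_in_tank", 0.5, NA)
  expect_warning(sel <- gape_vs_proximity(m), "dropping model")
  # constant predictor models are dropped; surviving best model lacks it
  expect_false("close_or_touching" %in% sel$best$spec$terms)
})
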