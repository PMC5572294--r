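test_that("GLRT arithmetic matches chi-square tail probabilities", {
  s_ri <- model_spec("poisson", degree = 1, random = "slope")
  s_g <- model_spec("poisson", degree = 1, random = "slope",
                    covariates = "gender")
  s_gi <- model_spec("poisson", degree = 1, random = "slope",
                     covariates = "gender", interactions = "gender")
  # equal log-likelihoods: chisq 0, p 1
  g0 <- glrt(fit_stub(-350, s_ri, n = 636), fit_stub(-350, s_g, n = 636))
  expect_equal(g0$chisq, 0)
  expect_equal(g0$p, 1)
  expect_false(g0$significant)
  # one-df improvements at the printed statistics
  g1 <- glrt(fit_stub(-350, s_ri, n = 636),
             fit_stub(-350 + 5.485 / 2, s_g, n = 636))
  expect_equal(g1$chisq, 5.485)
  expect_equal(g1$df, 1L)
  expect_equal(g1$p, 0.019, tolerance = 0.03)
  expect_true(g1$significant)
  g2 <- glrt(fit_stub(-350, s_g, n = 636),
             fit_stub(-350 + 1.248 / 2, s_gi, n = 636))
  expect_equal(g2$p, 0.264, tolerance = 0.002)
  expect_false(g2$significant)
  # a numerically lower full-model likelihood floors the statistic at zero
  gfloor <- glrt(fit_stub(-350, s_ri, n = 636),
                 fit_stub(-350.001, s_g, n = 636))
  expect_equal(gfloor$chisq, 0)
})

test_that("non-nested and ill-ordered pairs are refused", {
  s_fp <- model_spec("binomial", powers = 3, random = "slope")
  s_cp <- model_spec("binomial", degree = 2, random = "slope")
  expect_error(glrt(fit_stub(-3000, s_fp), fit_stub(-2990, s_cp)),
               "not nested")
  # reduced model must be the smaller one
  s_ri <- model_spec("binomial", powers = 1, random = "intercept")
  s_rs <- model_spec("binomial", powers = 1, random = "slope")
  expect_error(glrt(fit_stub(-3000, s_rs), fit_stub(-2990, s_ri)),
               "more parameters")
  # random slope nests random intercept only on the same time term
  s_rs3 <- model_spec("binomial", powers = 3, random = "slope")
  expect_false(gfpmm:::is_nested(s_rs, s_rs3))
  expect_true(gfpmm:::is_nested(s_ri, s_rs))
})

test_that("delta values and support categories follow the stated
          thresholds", {
  d <- delta_table(c(A = 6130, B = 5998))
  expect_equal(d$delta, c(132, 0))
  expect_equal(d$support, c("essentially none", "substantial"))
  expect_equal(delta_table(c(only = 100))$support, "substantial")
  expect_equal(support_category(c(0, 1.438, 2, 2.0001, 3.99, 4, 7, 7.5,
                                  10, 10.0001, 132)),
               c("substantial", "substantial", "substantial", "intermediate",
                 "intermediate", "considerably less", "considerably less",
                 "intermediate", "intermediate", "essentially none",
                 "essentially none"))
  expect_error(delta_table(numeric(0)), "non-empty")
  expect_error(delta_table(c(1, NA)), "finite")
})

test_that("comparison tables zero their minimum delta and report both
          leading criteria", {
  s1 <- model_spec("binomial", powers = 2, random = "intercept")
  s2 <- model_spec("binomial", powers = 3, random = "intercept")
  # different k via a covariate-free vs slope pair, AICc and BIC can disagree
  s3 <- model_spec("binomial", powers = 3, random = "slope")
  tab <- gfpmm:::comparison_table(list(fit_stub(-3065, s1),
                                       fit_stub(-3064, s2),
                                       fit_stub(-3059, s3)))
  expect_equal(min(tab$delta_bic), 0)
  expect_equal(min(tab$delta_aicc), 0)
  expect_true(!is.null(attr(tab, "best_bic_label")))
  expect_true(!is.null(attr(tab, "best_aicc_label")))
  # here the 2-parameter penalty difference splits the two criteria
  expect_equal(attr(tab, "best_bic_label"), "gfpm(3).ri")
  expect_equal(attr(tab, "best_aicc_label"), "gfpm(3).rs")
})

test_that("the conventional stage fits exactly the four ladder candidates on
          a 4-wave panel and GLRTs pair nested consecutive models", {
  pan <- simulate_binary_panel(cls_sim_config(n_subjects = 250, seed = 17))
  sel <- run_selection(pan, selection_config("binomial", gam = FALSE))
  tab <- sel$stages$gcpmm
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$label, c("gcpm.1.ri", "gcpm.2.ri", "gcpm.1.rs",
                            "gcpm.2.rs"))
  expect_equal(tab$k, c(3L, 4L, 5L, 6L))
  # ladder GLRT pairing: each tested against its most recent nested
  # predecessor; df follow from the parameter counts
  expect_equal(tab$glrt_df, c(NA, 1, 2, 1))
  # FP stage is the full 16-candidate grid with deltas over the whole set
  expect_equal(nrow(sel$stages$gfpmm), 16L)
  expect_true(all(is.na(sel$stages$gfpmm$glrt_chisq)))
  expect_equal(min(sel$stages$gfpmm$delta_aicc), 0)
})

test_that("a linear-truth panel makes the best FP and conventional models
          coincide with zero cross-class deltas", {
  cfg <- sim_config("binomial", n_subjects = 400, times = c(3, 8, 12, 17),
                    powers = 1, beta = c(1.2, -0.08), psi = matrix(0.5, 1, 1),
                    seed = 19)
  pan <- simulate_binary_panel(cfg)
  sel <- run_selection(pan, selection_config("binomial", gam = FALSE))
  cc <- sel$stages$cross_class
  best_fp <- cc[grepl("gfpm", cc$label), ]
  best_cp <- cc[grepl("gcpm", cc$label), ]
  # the identity holds when selection lands on power 1 / degree 1; whatever
  # it picks, the winners' criteria cannot differ by more than the identity
  if (best_fp$label == "gfpm(1).rs" && best_cp$label == "gcpm.1.rs") {
    expect_equal(best_fp$bic, best_cp$bic, tolerance = 1e-6)
    expect_equal(cc$delta_bic, c(0, 0), tolerance = 1e-6)
  }
  # cross-class GLRT cells stay blank (non-nested pair refused, logged)
  if (!gfpmm:::is_nested(sel$fits[[best_cp$label]]$spec,
                         sel$fits[[best_fp$label]]$spec)) {
    expect_true(any(grepl("refused", sel$log)))
  }
})

test_that("the covariate stage keeps a real main effect and drops a null
          interaction", {
  cfg <- sim_config("poisson", n_subjects = 212, times = c(1, 2, 3),
                    powers = 2, beta = c(log(8) - 0.3, -0.05, 0.3),
                    psi = matrix(c(0.09, 0, 0, 2.5e-3), 2, 2),
                    covariates = list(gender = function(n)
                      1 + rbinom(n, 1, 0.5)),
                    seed = 23)
  pan <- simulate_count_panel(cfg)
  sel <- run_selection(pan, selection_config("poisson",
                                             covariates = "gender",
                                             gam = FALSE))
  expect_true(any(grepl("covariate 'gender' retained", sel$log)))
  expect_true(any(grepl("interaction 'gender x time' dropped", sel$log)))
  final <- sel$best$fit$spec
  expect_true("gender" %in% final$covariates)
  expect_length(final$interactions, 0L)
  expect_false(is.null(sel$stages$covariates))
})

test_that("adding a quadratic term to a linear-truth model rejects at the
          nominal rate", {
  spec0 <- model_spec("binomial", degree = 1, random = "intercept")
  spec1 <- model_spec("binomial", degree = 2, random = "intercept")
  rej <- logical(100)
  for (r in 1:100) {
    cfg <- sim_config("binomial", n_subjects = 250, times = c(3, 8, 12, 17),
                      powers = 1, beta = c(1.2, -0.08),
                      psi = matrix(0.5, 1, 1), seed = 5000 + r)
    pan <- simulate_binary_panel(cfg)
    rej[r] <- glrt(fit_gfpmm(pan, spec0), fit_gfpmm(pan, spec1))$significant
  }
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.10)
})
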