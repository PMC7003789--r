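test_that("familywise false-positive arithmetic is exact", {
  expect_equal(expected_familywise_rate(20, 0.05), 1 - 0.95^19)
  expect_equal(round(expected_familywise_rate(20, 0.05), 4), 0.6226)
  expect_equal(expected_familywise_rate(2, 0.05), 0.05)
  expect_equal(expected_familywise_rate(7, 0), 0)
})

test_that("fit evaluation flags errors, exclusions and reversals", {
  set.seed(21)
  # tightly concentrated draws around (0, 0.55, -0.1)
  eff <- cbind(A = rnorm(4000, 0, 0.02), B = rnorm(4000, 0.55, 0.08),
               C = rnorm(4000, -0.1, 0.08))
  f <- fake_fit(eff)

  # truth matching the medians: zero errors (up to draw noise)
  tt0 <- truth_table(c(A = 0, B = 0.55, C = -0.1))
  ev0 <- evaluate_fit(f, tt0)
  expect_lt(max(abs(ev0$err_basic)), 0.01)
  expect_equal(ev0$best, "B")
  expect_equal(ev0$worst, "C")

  # truth all-zero: the A-B interval (approx [0.4, 0.7]) is a confident
  # nonzero among equally effective treatments
  tt1 <- truth_table(c(A = 0, B = 0, C = 0))
  ev1 <- evaluate_fit(f, tt1)
  ab <- ev1$contrasts[ev1$contrasts$t1 == "A" & ev1$contrasts$t2 == "B", ]
  expect_true(ab$excludes_zero && ab$truly_zero)
  expect_false(any(ev1$contrasts$reversal))

  # truth B = -0.5: same interval now has the wrong sign -> reversal
  tt2 <- truth_table(c(A = 0, B = -0.5, C = 0))
  ev2 <- evaluate_fit(f, tt2)
  ab2 <- ev2$contrasts[ev2$contrasts$t1 == "A" & ev2$contrasts$t2 == "B", ]
  expect_true(ab2$reversal)

  expect_error(evaluate_fit(f, truth_table(c(X = 0, Y = 1))),
               "different treatments")
})

test_that("aggregation follows the stated definitions", {
  mk <- function(err, excl, zero, rev, smax = 0.8, smin = 0.2) {
    structure(list(err_basic = err,
                   contrasts = data.frame(t1 = "A", t2 = "B",
                                          median = 0.3, sd = 0.1,
                                          lower = 0.1, upper = 0.5,
                                          excludes_zero = excl,
                                          true = 0, truly_zero = zero,
                                          reversal = rev),
                   sucra = c(A = smax, B = smin),
                   best = "A", worst = "B",
                   best_vs_worst_median = 0.3, best_vs_worst_sd = 0.1,
                   best_vs_ref_median = 0.3, best_vs_ref_sd = 0.1,
                   convergence_flag = FALSE),
              class = "fit_evaluation")
  }
  m1 <- aggregate_metrics(list(mk(0.3, FALSE, TRUE, FALSE)), "S", "M")
  expect_equal(m1$mae_basic, 0.3)
  expect_equal(m1$bias_basic, 0.3)
  expect_equal(m1$confident_nonzero_rate, 0)
  expect_true(is.na(m1$power))

  m2 <- aggregate_metrics(list(mk(0.1, TRUE, TRUE, FALSE),
                               mk(-0.1, FALSE, TRUE, FALSE)))
  expect_equal(m2$mae_basic, 0.1)
  expect_equal(m2$bias_basic, 0)
  expect_equal(m2$confident_nonzero_rate, 50)

  m3 <- aggregate_metrics(list(mk(0, TRUE, FALSE, TRUE),
                               mk(0, TRUE, FALSE, FALSE),
                               mk(0, FALSE, FALSE, FALSE)))
  expect_equal(m3$power, 100 * 2 / 3)
  expect_equal(m3$reversal_rate, 100 / 3)
  expect_true(is.na(m3$confident_nonzero_rate))
  expect_equal(m3$sucra_max_mean, 0.8)

  expect_error(aggregate_metrics(list()), "length")
})

test_that("run_study shares datasets across models and keeps books", {
  res <- run_study("D", c("I-flat", "III"), n_datasets = 4,
                   mcmc = mcmc_settings(2, 1200, 200), base_seed = 5,
                   keep_records = TRUE)
  expect_equal(nrow(res), 2)
  expect_equal(res$n_datasets, c(4, 4))
  expect_true(all(is.finite(res$mae_basic)))
  man <- attr(res, "manifest")
  expect_equal(man$base_seed, 5)
  expect_equal(man$models, c("I-flat", "III"))
  rec <- attr(res, "records")
  expect_equal(length(rec[["D I-flat"]]), 4)
  # the same datasets underlie both models: identical SUCRA treatment sets
  expect_identical(names(rec[["D I-flat"]][[1]]$sucra),
                   names(rec[["D III"]][[1]]$sucra))
})

test_that("model presets follow the analysis protocol", {
  a1 <- make_scenario("A.1")
  expect_equal(paper_model_spec("I-flat", a1)$priors$d_sd, 100)
  expect_equal(paper_model_spec("I-inf", a1)$priors$d_sd, 1)
  expect_equal(paper_model_spec("II", a1)$control, "1")
  expect_equal(paper_model_spec("I-flat", a1)$effects, "common")
  expect_equal(paper_model_spec("I-flat", make_scenario("B.1"))$effects,
               "random")
  expect_equal(paper_model_spec("II", make_scenario("C"))$effects, "common")
  cm <- paper_model_spec("IV", a1)$classes
  expect_equal(unname(cm$classes[c("2", "5", "6")]), c("c1", "c1", "c2"))
  expect_error(paper_model_spec("IV", make_scenario("C")), "10-treatment")
})
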