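test_that("the optimiser recovers a quadratic minimum", {
  # custom objectives exercise the search machinery in isolation
  pars2 <- tibble::tibble(
    name = c("a", "b"), init = c(1, 1), lower = c(1e-6, 1e-6),
    upper = c(1e3, 1e3), transform = "log")
  prob <- calibration_problem("B", data = NULL, correlation = NULL,
                              parameters = pars2,
                              options = list(maxit = 500,
                                             reltol = 1e-12))
  target <- c(a = 3.7, b = 0.21)
  quad <- function(theta) sum((log(theta) - log(target))^2)
  fit <- calibrate(prob, objective = quad)
  expect_equal(unname(fit$parameters$estimate), unname(target),
               tolerance = 1e-4)
  expect_lt(fit$objective, 1e-6)

  # 1-parameter problems take the bracketing path
  pars1 <- pars2[1, ]
  prob1 <- calibration_problem("B", data = NULL, correlation = NULL,
                               parameters = pars1,
                               options = list(maxit = 200))
  fit1 <- calibrate(prob1, objective = function(th) (th[["a"]] - 2)^2)
  expect_equal(fit1$parameters$estimate, 2, tolerance = 1e-5)
})

test_that("zero-iteration budgets return the initial point, flagged", {
  pars <- tibble::tibble(name = c("a", "b"), init = c(2, 5),
                         lower = 1e-6, upper = 1e3, transform = "log")
  prob <- calibration_problem("B", data = NULL, correlation = NULL,
                              parameters = pars,
                              options = list(maxit = 0))
  fit <- calibrate(prob, objective = function(th) sum(th^2))
  expect_false(fit$converged)
  expect_equal(fit$parameters$estimate, c(2, 5))
  expect_equal(fit$objective, fit$objective_init)
})

test_that("calibration is deterministic and free of caching drift", {
  pars <- tibble::tibble(name = c("a", "b"), init = c(4, 4),
                         lower = 1e-6, upper = 1e3, transform = "log")
  obj <- function(th) (th[["a"]] - 1)^2 + 3 * (th[["b"]] - 2)^2
  run <- function() {
    calibrate(calibration_problem("B", data = NULL, correlation = NULL,
                                  parameters = pars,
                                  options = list(maxit = 400)),
              objective = obj)
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$parameters$estimate, f2$parameters$estimate)
  # reported objective equals the objective re-evaluated at the estimate
  est <- stats::setNames(f1$parameters$estimate, f1$parameters$name)
  expect_identical(f1$objective, obj(est))
})

test_that("transforms keep every iterate inside the bounds", {
  pars <- tibble::tibble(
    name = c("rate", "frac"), init = c(0.01, 0.5),
    lower = c(1e-4, 0.01), upper = c(1, 0.99),
    transform = c("log", "logit"))
  seen <- new.env(); seen$bad <- 0L
  obj <- function(th) {
    if (th[["rate"]] < 1e-4 || th[["rate"]] > 1 ||
        th[["frac"]] < 0.01 || th[["frac"]] > 0.99) {
      seen$bad <- seen$bad + 1L
    }
    (log(th[["rate"]]) + 3)^2 + (th[["frac"]] - 0.4)^2
  }
  fit <- calibrate(calibration_problem("B", data = NULL,
                                       correlation = NULL,
                                       parameters = pars,
                                       options = list(maxit = 300)),
                   objective = obj)
  expect_identical(seen$bad, 0L)
  expect_equal(fit$parameters$estimate[2], 0.4, tolerance = 1e-3)
})

test_that("model objectives decompose over experiments and square errors", {
  data <- recovery_dataset()
  corr <- recovery_correlation()
  geom <- skin_geometry(n_nodes = 40)
  truth <- recovery_truth_params()

  prob_b <- calibration_problem("B", data, correlation = corr,
                                geometry = geom)
  # noise-free data generated by the model itself: objective 0 at truth
  expect_lt(model_b_objective(truth, prob_b), 1e-8)
  # and grows away from it
  expect_gt(model_b_objective(truth * 2, prob_b),
            model_b_objective(truth, prob_b))
  # decomposition: subsets add to the whole
  prob_1 <- calibration_problem("B", data[1, ], correlation = corr,
                                geometry = geom)
  prob_rest <- calibration_problem("B", data[-1, ], correlation = corr,
                                   geometry = geom)
  off <- truth * c(1.4, 1.2, 1.2, 0.7, 1.3)
  expect_equal(model_b_objective(off, prob_1) +
                 model_b_objective(off, prob_rest),
               model_b_objective(off, prob_b), tolerance = 1e-9)

  # model A: matching mass balances zero the objective; a single IVPT
  # with a 10-point error contributes 100
  data_a <- data
  prob_a0 <- calibration_problem("A", data_a, correlation = corr,
                                 geometry = geom)
  pred_a <- dermavol:::.predict_problem(prob_a0, c(u = 0.68))
  data_a$sw_mean <- pred_a$sw_pred
  data_a$sc_mean <- pred_a$sc_pred
  data_a$dd_mean <- pred_a$dd_pred
  prob_a <- calibration_problem("A", data_a, correlation = corr,
                                geometry = geom)
  expect_lt(model_a_objective(0.68, prob_a), 1e-10)
  one <- data_a[1, ]
  one$dd_mean <- one$dd_mean + 0.1 * one$dose # shift recovery by 10 pts
  prob_one <- calibration_problem("A", one, correlation = corr,
                                  geometry = geom)
  expect_equal(model_a_objective(0.68, prob_one), 100,
               tolerance = 1e-6)
  # failed simulations are penalised, not raised
  broken <- data[1, ]
  broken$dsc <- -1
  prob_bad <- calibration_problem("A", broken, correlation = corr,
                                  geometry = geom)
  expect_equal(model_a_objective(0.68, prob_bad), 1e12)
})

test_that("a reduced vehicle-parameter fit recovers the truth", {
  # single-solvent subset: free (u, eta_dep_pbs, kevap_veh_pbs)
  data <- recovery_dataset()
  pbs <- data[data$solvent == "pbs", ]
  pars <- tibble::tibble(
    name = c("u", "eta_dep_pbs", "kevap_veh_pbs"),
    init = c(1.5, 0.06, 0.011),
    lower = c(1e-3, 1e-4, 1e-6),
    upper = c(1e4, 1, 10),
    transform = c("log", "logit", "log"))
  prob <- calibration_problem("B", pbs,
                              correlation = recovery_correlation(),
                              parameters = pars,
                              geometry = skin_geometry(n_nodes = 40),
                              options = list(maxit = 500,
                                             reltol = 1e-12))
  fit <- calibrate(prob)
  truth <- recovery_truth_params()[pars$name]
  rel <- abs(fit$parameters$estimate - truth) / truth
  expect_lt(rel[["eta_dep_pbs"]], 0.05)
  expect_lt(rel[["kevap_veh_pbs"]], 0.05)
  expect_lt(rel[["u"]], 0.15)
  expect_true(fit$converged)
  # broom-style accessors
  expect_identical(tidy(fit)$estimate, fit$parameters$estimate)
  expect_true(glance(fit)$converged)
})
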