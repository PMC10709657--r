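make_expr <- function(n_feat, n_samp, seed) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_feat * n_samp), nrow = n_feat,
                dimnames = list(sprintf("g%03d", seq_len(n_feat)), NULL))
    m
  })
}

test_that("independent features all land in the predictor set", {
  # wide spacing of uncorrelated features with a strict alpha: no feature
  # should be predictable from another
  expr <- make_expr(20, 30, seed = 1)
  asg <- select_predictors(expr, alpha_sig = 1e-6)
  expect_equal(nrow(asg$predicted), 0)
  expect_setequal(asg$predictor_set, rownames(expr))
})

test_that("perfect collinearity recovers the exact slope", {
  expr <- make_expr(5, 20, seed = 2)
  expr["g002", ] <- 2 * expr["g001", ]
  asg <- select_predictors(expr, alpha_sig = 1e-4)
  pair <- asg$predicted[asg$predicted$feature %in% c("g001", "g002"), ]
  expect_equal(nrow(pair), 1) # one of the two predicted from the other
  expect_true(pair$predictor %in% c("g001", "g002"))
  slope <- if (pair$feature == "g002") 2 else 0.5
  expect_equal(pair$beta1, slope, tolerance = 1e-6)
  expect_equal(abs(pair$r), 1, tolerance = 1e-12)
  # the predictor of the pair is itself unpredicted
  expect_true(pair$predictor %in% asg$predictor_set)
})

test_that("noisy slopes are recovered within 3 standard errors", {
  set.seed(33)
  n_samp <- 50
  x <- rnorm(n_samp)
  slope <- 1
  y <- slope * x + rnorm(n_samp, sd = 0.4)
  expr <- rbind(g1 = x, g2 = y, g3 = rnorm(n_samp), g4 = rnorm(n_samp))
  asg <- select_predictors(expr, alpha_sig = 0.001)
  row <- asg$predicted[asg$predicted$feature == "g2", ]
  expect_equal(row$predictor, "g1")
  se <- summary(lm(y ~ x))$coefficients["x", "Std. Error"]
  expect_lt(abs(row$beta1 - slope), 3 * se)
  expect_equal(row$r, cor(x, y), tolerance = 1e-12)
})

test_that("constant features are excluded from predicted roles", {
  expr <- make_expr(6, 10, seed = 4)
  expr["g003", ] <- 5
  asg <- select_predictors(expr)
  expect_true("g003" %in% asg$predictor_set)
  expect_false("g003" %in% asg$predicted$feature)
  expect_error(select_predictors(expr[, 1:2]), "at least 3 samples")
})

test_that("mutual best-predictor cycles are broken deterministically", {
  expr <- make_expr(4, 15, seed = 5)
  expr["g002", ] <- expr["g001", ] + rnorm(15, sd = 0.01)
  asg <- select_predictors(expr, alpha_sig = 1e-6)
  # g001 <-> g002 would be a 2-cycle; the smaller label becomes a predictor
  expect_true("g001" %in% asg$predictor_set)
  expect_equal(asg$predicted$feature[asg$predicted$predictor == "g001"],
               "g002")
  # partition property: disjoint, covering
  expect_length(intersect(asg$predictor_set, asg$predicted$feature), 0)
  expect_setequal(c(asg$predictor_set, asg$predicted$feature),
                  rownames(expr))
})

test_that("HPP draws reduce to plain permutations when nothing is predicted", {
  vals <- withr::with_seed(6, setNames(rnorm(30), sprintf("g%03d", 1:30)))
  out <- withr::with_seed(7, hpp_permute(NULL, vals))
  expect_setequal(unname(out), unname(vals))
  expect_identical(names(out), names(vals))
  expect_false(identical(unname(out), unname(vals)))
})

test_that("prediction limits: |r| = 1 copies the predictor, |r| = 0 bootstraps", {
  vals <- setNames(as.numeric(1:10), sprintf("g%03d", 1:10))
  base <- list(predictor_set = sprintf("g%03d", 1:8),
               flavour = "pvalue", alpha_sig = 0.05)
  mk <- function(r) {
    a <- base
    a$predicted <- tibble::tibble(
      feature = c("g009", "g010"), predictor = c("g001", "g002"),
      beta1 = c(2, 2), r = c(r, r), depth = c(1L, 1L))
    a$predictor_set <- sprintf("g%03d", 1:8)
    structure(a, class = "hpp_assignment")
  }
  out1 <- withr::with_seed(8, hpp_permute(mk(1), vals))
  expect_equal(unname(out1["g009"]), unname(out1["g001"]))
  out0 <- withr::with_seed(8, hpp_permute(mk(0), vals))
  expect_true(all(out0[c("g009", "g010")] %in% vals))

  # fold-change flavour: the slope model
  fc <- mk(1); fc$flavour <- "fold_change"
  outf <- withr::with_seed(8, hpp_permute(fc, vals))
  expect_equal(unname(outf["g009"]), 2 * unname(outf["g001"]))
})

test_that("chains evaluate parents before children", {
  vals <- setNames(as.numeric(1:6), letters[1:6])
  asg <- structure(list(
    predictor_set = c("a", "b", "c"),
    predicted = tibble::tibble(
      feature = c("d", "e", "f"), predictor = c("a", "d", "e"),
      beta1 = c(2, 3, 5), r = c(1, 1, 1), depth = 1:3),
    flavour = "fold_change", alpha_sig = 0.05), class = "hpp_assignment")
  out <- withr::with_seed(9, hpp_permute(asg, vals))
  expect_equal(unname(out["e"]), 3 * 2 * unname(out["a"]))
  expect_equal(unname(out["f"]), 5 * 3 * 2 * unname(out["a"]))
})

test_that("beta method-of-moments recovers known shapes", {
  u <- ppoints(2000) # ideal uniform sample
  fit <- fit_beta_mom(u)
  expect_equal(fit$alpha, 1, tolerance = 0.01)
  expect_equal(fit$beta, 1, tolerance = 0.01)
  expect_true(fit$accepted)

  x <- withr::with_seed(10, rbeta(10000, 2, 5))
  fit2 <- fit_beta_mom(x)
  expect_equal(fit2$alpha, 2, tolerance = 0.1 * 2)
  expect_equal(fit2$beta, 5, tolerance = 0.1 * 5)
  expect_true(fit2$accepted)

  fit3 <- fit_beta_mom(rep(0.3, 50))
  expect_false(fit3$accepted)

  # a sample a beta cannot describe must be rejected by the KS gate
  bim <- c(rep(1e-6, 60), rep(1 - 1e-6, 60))
  expect_false(fit_beta_mom(bim)$accepted)
  expect_error(fit_beta_mom(runif(10)), "20")
})

test_that("adjustment scales linearly against the null threshold", {
  u <- ppoints(2000)
  fit <- fit_beta_mom(u) # threshold ~ 0.05: adjustment ~ identity
  expect_equal(adjust_pvalue(0.01, fit), 0.01, tolerance = 0.02)
  expect_equal(adjust_pvalue(1, fit), 1)

  # rejected fit: empirical fallback, exact arithmetic checkable
  skewed <- structure(list(accepted = FALSE, alpha = NA, beta = NA,
                           ks_p = 0, clamp_frac = 0,
                           sample = rep(c(0.005, 0.5), c(200, 1800))),
                      class = "beta_fit")
  # empirical 5th percentile of the sample is 0.005
  expect_equal(adjust_pvalue(1e-4, skewed), 0.05 * 1e-4 / 0.005)
  expect_equal(adjust_pvalue(0.005, skewed), 0.05)
  # monotone, capped at 1, log-space survives extreme minima
  ps <- c(1e-300, 1e-20, 1e-4, 0.01, 0.5, 1)
  adj <- vapply(ps, adjust_pvalue, numeric(1), fit = skewed)
  expect_true(all(diff(adj) >= 0))
  expect_true(all(adj <= 1))
  expect_equal(adjust_pvalue(-30000, skewed, log = TRUE),
               -30000 + log(0.05 / 0.005))
})

test_that("the degenerate HPP null matches a plain permutation null", {
  sc <- make_scenario("random", n = 200, seed = 11)
  # assignment with an empty predicted set == identity correlation structure
  asg <- structure(list(predictor_set = sc$a$labels,
                        predicted = tibble::tibble(
                          feature = character(0), predictor = character(0),
                          beta1 = numeric(0), r = numeric(0),
                          depth = integer(0)),
                        flavour = "fold_change", alpha_sig = 0.05),
                   class = "hpp_assignment")
  hpp <- null_min_logp(sc$a, sc$b, quadrants = "dd", algorithm = "grid",
                       assignment_a = asg, assignment_b = asg, R = 100,
                       seed = 12)
  plain <- null_min_logp(sc$a, sc$b, quadrants = "dd", algorithm = "grid",
                         R = 100, seed = 13)
  ks <- suppressWarnings(ks.test(hpp$log_p, plain$log_p))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted signal sits far below its permutation null", {
  sc <- make_scenario("planted", n = 500, n_overlap = 25, n_top = 40,
                      seed = 14)
  obs <- grid_search(sc$a, sc$b, "dd", step = 5)
  nul <- null_min_logp(sc$a, sc$b, quadrants = "dd", algorithm = "grid",
                       step = 5, R = 50, seed = 15)
  expect_true(all(obs$log_p < nul$log_p))
})
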