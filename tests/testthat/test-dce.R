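# manual single-attribute design used by the exhaustive-oracle tests:
# three sets covering poor-vs-average, poor-vs-good, average-vs-good
one_attr_design <- function() {
  levels <- array(NA_integer_, c(1, 3, 2, 1))
  levels[1, , 1, 1] <- c(2, 3, 3)
  levels[1, , 2, 1] <- c(1, 1, 2)
  structure(list(attributes = "x", levels = levels,
                 overlap = matrix(0, 1, 3), blocks = c(1, 2, 3)),
            class = "dce_design")
}

test_that("cost levels are the country mean shifted by +/-20%", {
  cl <- make_cost_levels(10000)
  expect_equal(unname(cl$levels), c(12000, 10000, 8000))
  expect_equal(unname(make_cost_levels(7000)$levels), c(8400, 7000, 5600))
  # worst -> best is decreasing in cost
  expect_true(all(diff(cl$levels) < 0))
  expect_error(make_cost_levels(0), "positive")
})

test_that("choice probabilities follow the binary logit on utility differences", {
  attrs <- build_core_set()$id
  zero <- partworths(rep(0, 16), attrs)
  la <- rep(1L, 8); lb <- rep(2L, 8)
  expect_equal(choice_probability(la, lb, zero), 0.5)
  # identical (overlapped) levels cancel: only differing attributes matter
  b <- partworths(rep(c(0.2, 0.7), 8), attrs)
  la <- c(3L, rep(2L, 7)); lb <- c(1L, rep(2L, 7))
  expect_equal(choice_probability(la, lb, b), plogis(0.7), tolerance = 1e-12)
  # V_A - V_B = 1 gives the logistic closed form
  b1 <- partworths(c(0.5, 1, rep(0, 14)), attrs)
  expect_equal(choice_probability(c(3L, rep(1L, 7)), rep(1L, 8), b1),
               0.7310586, tolerance = 1e-6)
  # swapping A and B complements the probability
  set.seed(2)
  brand <- partworths(rnorm(16), attrs)
  la <- sample(1:3, 8, TRUE); lb <- sample(1:3, 8, TRUE)
  expect_equal(choice_probability(la, lb, brand) +
                 choice_probability(lb, la, brand), 1, tolerance = 1e-12)
  expect_error(choice_probability(1:3, 1:3, brand), "dimension")
})

test_that("D-error is singular for fully overlapped designs and scales with replication", {
  attrs <- build_core_set()$id
  prior <- default_prior(attrs)
  # every set fully overlapped -> zero information -> +Inf, flagged
  levels <- array(2L, c(1, 6, 2, 8))
  flat <- structure(list(attributes = attrs, levels = levels,
                         overlap = matrix(8, 1, 6), blocks = rep(1:3, 2)),
                    class = "dce_design")
  de <- d_error(flat, prior)
  expect_true(is.infinite(de))
  expect_true(isTRUE(attr(de, "singular")))

  d <- small_design(seed = 3)
  e1 <- d_error(d, prior)
  # duplicating every choice set doubles I, so det^(1/p) doubles
  d2 <- d
  d2$levels <- array(c(d$levels, d$levels),
                     dim = dim(d$levels) * c(2, 1, 1, 1))
  dd <- dim(d$levels)
  for (s in seq_len(dd[1])) {
    d2$levels[s, , , ] <- d$levels[s, , , ]
    d2$levels[dd[1] + s, , , ] <- d$levels[s, , , ]
  }
  expect_equal(d_error(d2, prior), e1 / 2, tolerance = 1e-9)
  # relabelling A/B within sets leaves the D-error unchanged
  d3 <- d
  d3$levels[1, 2, , ] <- d$levels[1, 2, 2:1, ]
  d3$levels[2, 5, , ] <- d$levels[2, 5, 2:1, ]
  expect_equal(d_error(d3, prior), e1, tolerance = 1e-12)
})

test_that("optimized designs respect the overlap rule and improve greedily", {
  d <- optimize_design(seed = 17, n_subdesigns = 3, n_sets = 6, n_sweeps = 1)
  expect_true(all(d$overlap %in% 4:5))
  # no set pairs two identical alternatives (8 - overlap >= 3 attrs differ)
  dd <- dim(d$levels)
  for (s in seq_len(dd[1])) for (t in seq_len(dd[2]))
    expect_false(all(d$levels[s, t, 1, ] == d$levels[s, t, 2, ]))
  expect_lte(attr(d, "d_error"), attr(d, "d_error_initial"))
  # determinism: same seed, same design
  d2 <- optimize_design(seed = 17, n_subdesigns = 3, n_sets = 6, n_sweeps = 1)
  expect_identical(d$levels, d2$levels)
  # every coefficient carries positive information in the final design
  info <- icmcda:::.design_information(d, default_prior()$coef)
  expect_true(all(diag(info) > 0))
  expect_error(optimize_design(n_subdesigns = 2, n_sets = 6),
               "seed is mandatory")
})

test_that("design serialization round-trips losslessly", {
  d <- small_design(seed = 23)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dce_design(d, path)
  back <- read_dce_design(path)
  expect_identical(back$levels, d$levels)
  expect_equal(back$attributes, d$attributes)
  expect_equal(back$overlap, d$overlap)
  expect_equal(back$blocks, d$blocks)
})

test_that("conditional logit matches a brute-force grid-search MLE", {
  design <- one_attr_design()
  truth <- partworths(c(0.4, 0.9), "x")
  data <- simulate_dce_responses(design, truth, n_respondents = 40, seed = 31)
  fit <- fit_conditional_logit(design, data)
  # exhaustive oracle: coarse grid then 1e-3 refinement of the raw likelihood
  cm <- icmcda:::.choice_matrix(design, data)
  ll <- function(b) {
    eta <- drop(cm$X %*% b)
    sum(cm$y * eta - log1p(exp(eta)))
  }
  grid_best <- function(c1, c2) {
    best <- c(NA, NA); best_ll <- -Inf
    for (b1 in c1) for (b2 in c2) {
      v <- ll(c(b1, b2))
      if (v > best_ll) { best_ll <- v; best <- c(b1, b2) }
    }
    best
  }
  coarse <- grid_best(seq(-2, 2, 0.05), seq(-2, 2, 0.05))
  fine <- grid_best(seq(coarse[1] - 0.05, coarse[1] + 0.05, 0.001),
                    seq(coarse[2] - 0.05, coarse[2] + 0.05, 0.001))
  expect_equal(unname(fit$coef), fine, tolerance = 2e-3)
})

test_that("conditional logit agrees with an independent glm fit", {
  d <- small_design(seed = 3)
  truth <- p1_truth_beta()
  data <- simulate_dce_responses(d, truth, n_respondents = 120, seed = 13)
  fit <- fit_conditional_logit(d, data)
  cm <- icmcda:::.choice_matrix(d, data)
  ref <- suppressWarnings(stats::glm.fit(cm$X, cm$y,
                                         family = stats::binomial()))
  expect_equal(unname(fit$coef), unname(ref$coefficients), tolerance = 1e-6)
  # covariance is symmetric PSD with matching dimension
  expect_equal(fit$vcov, t(fit$vcov))
  expect_true(all(eigen(fit$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
  expect_true(fit$converged)
  expect_lt(fit$grad_norm, 1e-8)
})

test_that("null data yield small, non-significant coefficients", {
  d <- small_design(seed = 3)
  zero <- partworths(rep(0, 16), build_core_set()$id)
  data <- simulate_dce_responses(d, zero, n_respondents = 500, seed = 19)
  fit <- fit_conditional_logit(d, data)
  expect_lt(mean(abs(fit$coef)), 0.1)
  z <- abs(fit$coef) / sqrt(diag(fit$vcov))
  expect_true(all(z < qnorm(0.995)))        # none significant at 1%
  expect_lte(sum(z > qnorm(0.975)), 2)      # at most chance-level at 5%
})

test_that("estimation errors name the offending structure", {
  d <- small_design(seed = 3)
  data <- simulate_dce_responses(d, p1_truth_beta(), 50, seed = 7)
  # too few choices for the parameter count
  expect_error(fit_conditional_logit(d, data[1:10, ]), "at least 16")
  bad <- data; bad$set[1] <- 99
  expect_error(fit_conditional_logit(d, bad), "non-existent choice set")
})

test_that("prior updates trigger at the enrolment threshold", {
  d <- optimize_design(seed = 29, n_subdesigns = 2, n_sets = 9, n_sweeps = 1)
  truth <- p1_truth_beta()
  data <- simulate_dce_responses(d, truth, n_respondents = 60, seed = 37)
  below <- data[data$respondent_id <= 49, ]
  res <- update_priors(d, below, threshold = 50)
  expect_false(res$updated)
  expect_identical(res$design$levels, d$levels)

  res2 <- update_priors(d, data, threshold = 50, seed = 101)
  expect_true(res2$updated)
  expect_s3_class(res2$prior, "partworths")
  expect_lte(attr(res2$design, "d_error"),
             attr(res2$design, "d_error_initial"))
  # re-optimization under the truth as prior beats an unoptimized design
  random_design <- optimize_design(prior = truth, n_subdesigns = 2,
                                   n_sets = 9, seed = 55, n_sweeps = 0)
  optimized <- optimize_design(prior = truth, n_subdesigns = 2,
                               n_sets = 9, seed = 55, n_sweeps = 2)
  expect_lt(d_error(optimized, truth), d_error(random_design, truth))
})

test_that("weights are normalized good-level coefficients", {
  attrs <- build_core_set()$id
  equal <- partworths(rep(c(0.1, 0.6), 8), attrs)
  w <- partworths_to_weights(equal)
  expect_equal(as.numeric(w), rep(0.125, 8))
  expect_equal(attr(w, "method"), "dce")
  # doubling one attribute's good coefficient raises its weight
  b2 <- equal; b2$coef[2] <- 1.2
  w2 <- partworths_to_weights(b2)
  expect_gt(w2[[attrs[1]]], w[[attrs[1]]])
  neg <- equal; neg$coef[4] <- -0.1
  expect_error(partworths_to_weights(neg), "negative best-level")
})
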