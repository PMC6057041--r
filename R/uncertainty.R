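#' Sensitivity analysis and the CMAC
#'
#' Deterministic sensitivity analyses (criterion exclusion, weight-method
#' swap) probe structural choices; a Monte-Carlo probabilistic sensitivity
#' analysis (PSA) propagates parameter uncertainty in performance scores and
#' criteria weights simultaneously. The joint uncertainty is summarised by
#' the Conditional Multi-attribute Acceptability Curve (CMAC): for each
#' budget threshold B, the probability that the intervention has the highest
#' overall value AND its budget impact (population size times its mean total
#' cost) stays at or below B.
#'
#' @name uncertainty
NULL

#' PSA configuration
#'
#' @param n_draws Number of Monte-Carlo draws (>= 1).
#' @param seed Integer RNG seed (mandatory: draws are deterministic given it).
#' @param population_size Number of persons treated; multiplies the
#'   intervention's mean cost into a budget impact.
#' @param budget_grid Strictly increasing currency thresholds for the CMAC.
#' @param budget_basis `"intervention"` (default: budget impact =
#'   population_size x intervention mean cost) or `"incremental"`
#'   (intervention minus comparator cost).
#' @param include_costs_in_value Keep the cost criterion inside the value
#'   score while also conditioning on it (default `TRUE`, mirroring the
#'   worked example); `FALSE` drops it from the value score to avoid double
#'   counting.
#' @return A `psa_config` list.
#' @export
psa_config <- function(n_draws, seed, population_size, budget_grid,
                       budget_basis = c("intervention", "incremental"),
                       include_costs_in_value = TRUE) {
  budget_basis <- match.arg(budget_basis)
  if (n_draws < 1) stop("n_draws must be >= 1")
  if (missing(seed)) stop("seed is mandatory for the PSA")
  if (population_size < 1) stop("population_size must be positive")
  if (length(budget_grid) < 1 || is.unsorted(budget_grid, strictly = TRUE))
    stop("budget_grid must be a non-empty strictly increasing vector")
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed),
                 population_size = population_size, budget_grid = budget_grid,
                 budget_basis = budget_basis,
                 include_costs_in_value = include_costs_in_value),
            class = "psa_config")
}

#' Criterion-exclusion sensitivity analysis
#'
#' Removes one criterion (e.g. the most dominating), renormalizes the
#' remaining weights proportionally, and recomputes both alternatives'
#' overall values. Standardization is unchanged (still pairwise over the
#' remaining criteria).
#'
#' @param perf A `performance_table`.
#' @param w A `weight_vector`.
#' @param criterion_id Criterion to exclude; at least 2 must remain.
#' @return List with `with` and `without` (`value_result`s) and
#'   `excluded`.
#' @export
exclude_criterion_sa <- function(perf, w, criterion_id) {
  set <- attr(perf, "criteria")
  if (!criterion_id %in% set$id)
    stop("criterion '", criterion_id, "' not in the criteria set")
  if (nrow(set) - 1 < 2)
    stop("excluding '", criterion_id, "' would leave fewer than 2 criteria")
  base <- overall_value(standardize_table(perf), w)
  keep <- set$id[set$id != criterion_id]
  set2 <- criteria_set(as.data.frame(set)[set$id != criterion_id, ],
                       name = paste0(attr(set, "set_name"), "_minus_",
                                     criterion_id))
  perf2 <- performance_table(
    as.data.frame(perf)[perf$criterion_id != criterion_id, ],
    set2, attr(perf, "alternatives"))
  w2 <- unclass(w)[keep]
  w2 <- weight_vector(w2 / sum(w2), method = attr(w, "method"),
                      group = attr(w, "group"))
  list(with = base, without = overall_value(standardize_table(perf2), w2),
       excluded = criterion_id)
}

#' Weight-method swap sensitivity analysis
#'
#' Recomputes the value comparison under two weight sources (e.g. DCE vs
#' swing weighting) and reports whether they agree on the preferred
#' alternative.
#'
#' @param perf A `performance_table`.
#' @param w_dce,w_swing Two `weight_vector`s over the table's criteria.
#' @return List with per-source `value_result`s, preferred alternatives,
#'   and an `agreement` flag.
#' @export
weight_method_swap_sa <- function(perf, w_dce, w_swing) {
  std <- standardize_table(perf)
  v1 <- overall_value(std, w_dce)
  v2 <- overall_value(std, w_swing)
  p1 <- preferred_alternative(v1)
  p2 <- preferred_alternative(v2)
  list(sources = list(dce = v1, swing = v2),
       preferred = c(dce = p1, swing = p2),
       agreement = identical(p1, p2))
}

# truncated-normal sampler: rejection with inverse-CDF fallback
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  out <- rep(NA_real_, n)
  todo <- seq_len(n)
  for (tries in 1:20) {
    x <- stats::rnorm(length(todo), mean, sd)
    ok <- x >= lo & x <= hi
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
    if (!length(todo)) break
  }
  if (length(todo)) {  # heavy truncation: inverse CDF
    plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
    u <- stats::runif(length(todo), plo, phi)
    out[todo] <- stats::qnorm(u, mean, sd)
    out[todo] <- pmin(pmax(out[todo], lo), hi)
  }
  out
}

#' Monte-Carlo probabilistic sensitivity analysis
#'
#' Per draw: each criterion's performance mean (both alternatives) is
#' sampled from a normal centred at its estimate with its standard error,
#' truncated to the criterion's scale range; criteria weights are sampled
#' from the uncertainty model; the draw is standardized and aggregated and
#' the pair of overall values plus the drawn intervention mean cost are
#' recorded. Deterministic given `cfg$seed`.
#'
#' Weight uncertainty models (exactly one):
#' \describe{
#'   \item{`beta`}{part-worths sampled from multivariate normal
#'     (coefficients, covariance); weights recomputed per draw from the
#'     sampled good-level coefficients, negatives truncated at zero before
#'     renormalization.}
#'   \item{`swing_rankings`}{respondents' rankings resampled with
#'     replacement (bootstrap) and re-aggregated per draw.}
#'   \item{`weights`}{fixed weight vector, no weight uncertainty.}
#' }
#'
#' @param perf A `performance_table`.
#' @param cfg A `psa_config`.
#' @param beta Fitted `partworths` with covariance, or `NULL`.
#' @param weights Fixed `weight_vector`, or `NULL`.
#' @param swing_rankings Long-format rankings data frame, or `NULL`.
#' @return Data frame of class `psa_draws`: one row per draw with
#'   `value_intervention`, `value_comparator`, `cost_intervention`.
#' @export
run_psa <- function(perf, cfg, beta = NULL, weights = NULL,
                    swing_rankings = NULL) {
  stopifnot(inherits(cfg, "psa_config"))
  supplied <- c(!is.null(beta), !is.null(weights), !is.null(swing_rankings))
  if (sum(supplied) != 1)
    stop("supply exactly one of beta, weights, swing_rankings")
  set <- attr(perf, "criteria")
  alts <- attr(perf, "alternatives")
  if (!is.null(beta)) {
    if (is.null(beta$vcov)) stop("beta must carry a covariance matrix")
    ev <- eigen(beta$vcov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev)))
      stop("part-worth covariance is not positive semi-definite")
  }

  old_seed <- .Random.seed_save()
  on.exit(.Random.seed_restore(old_seed))
  set.seed(cfg$seed)

  n <- cfg$n_draws
  # pre-sample performance draws criterion-by-criterion
  perf_draw <- array(NA_real_, c(n, nrow(set), 2),
                     dimnames = list(NULL, set$id, alts))
  for (k in seq_len(nrow(set))) {
    lo <- min(set$worst[k], set$best[k]); hi <- max(set$worst[k], set$best[k])
    for (a in alts) {
      row <- perf[perf$criterion_id == set$id[k] & perf$alt == a, ]
      perf_draw[, k, a] <- .rtruncnorm(n, row$mean, row$se, lo, hi)
    }
  }
  # pre-sample weights
  w_draw <- matrix(NA_real_, n, nrow(set), dimnames = list(NULL, set$id))
  if (!is.null(weights)) {
    w_draw[] <- matrix(unclass(weights)[set$id], n, nrow(set), byrow = TRUE)
  } else if (!is.null(beta)) {
    if (!setequal(beta$attributes, set$id))
      stop("part-worth attributes do not match the criteria set")
    bs <- MASS::mvrnorm(n, beta$coef, beta$vcov)
    if (n == 1) bs <- matrix(bs, nrow = 1)
    good_idx <- seq(2, length(beta$coef), by = 2)
    good <- pmax(bs[, good_idx, drop = FALSE], 0)
    colnames(good) <- beta$attributes
    rs <- rowSums(good)
    uniform <- rs == 0
    good[uniform, ] <- 1
    w_draw[] <- (good / rowSums(good))[, set$id]
  } else {
    resp <- unique(swing_rankings$respondent_id)
    for (i in seq_len(n)) {
      pick <- sample(resp, length(resp), replace = TRUE)
      # bootstrap: duplicate sampled respondents under fresh ids
      boot <- do.call(rbind, lapply(seq_along(pick), function(j) {
        d <- swing_rankings[swing_rankings$respondent_id == pick[j], ]
        d$respondent_id <- j
        d
      }))
      wv <- aggregate_swing_weights(boot, set$id, by_group = FALSE)
      w_draw[i, ] <- unclass(wv)[set$id]
    }
  }

  value_cols <- if (cfg$include_costs_in_value) set$id
                else set$id[set$aim != "costs"]
  out <- data.frame(value_intervention = numeric(n),
                    value_comparator = numeric(n),
                    cost_intervention = numeric(n))
  cost_id <- set$id[set$direction == "cost" & set$aim == "costs"]
  if (length(cost_id) != 1)
    stop("PSA requires exactly one total-cost criterion in the set")
  for (i in seq_len(n)) {
    s_int <- numeric(0); s_comp <- numeric(0)
    for (k in seq_len(nrow(set))) {
      s <- standardize_pair(perf_draw[i, k, 1], perf_draw[i, k, 2],
                            set$direction[k])
      s_int[set$id[k]] <- s[1]; s_comp[set$id[k]] <- s[2]
    }
    wts <- w_draw[i, value_cols]
    wts <- wts / sum(wts)
    out$value_intervention[i] <- sum(wts * s_int[value_cols])
    out$value_comparator[i] <- sum(wts * s_comp[value_cols])
    ci <- perf_draw[i, cost_id, 1]
    out$cost_intervention[i] <- if (cfg$budget_basis == "incremental")
      ci - perf_draw[i, cost_id, 2] else ci
  }
  structure(out, class = c("psa_draws", "data.frame"), config = cfg)
}

#' Conditional Multi-attribute Acceptability Curve
#'
#' probability(B) = fraction of PSA draws in which the intervention has the
#' strictly higher overall value AND its budget impact
#' (population_size x drawn mean cost) is at most B. Non-decreasing in B and
#' bounded above by the unconditional preference probability, which is the
#' curve's limit as B grows.
#'
#' @param draws A `psa_draws` data frame from [run_psa()].
#' @param cfg The `psa_config` (defaults to the one stored in `draws`).
#' @return Data frame of class `cmac_curve` with columns `threshold`,
#'   `probability`; attribute `unconditional` holds the unconditional
#'   preference probability.
#' @export
cmac <- function(draws, cfg = attr(draws, "config")) {
  if (is.null(cfg)) stop("no PSA configuration available")
  if (nrow(draws) == 0) stop("empty draw matrix")
  if (length(cfg$budget_grid) == 0) stop("empty budget grid")
  preferred <- draws$value_intervention > draws$value_comparator
  impact <- cfg$population_size * draws$cost_intervention
  prob <- vapply(cfg$budget_grid,
                 function(B) mean(preferred & impact <= B), numeric(1))
  structure(data.frame(threshold = cfg$budget_grid, probability = prob),
            class = c("cmac_curve", "data.frame"),
            unconditional = mean(preferred))
}

#' @export
print.cmac_curve <- function(x, ...) {
  cat("CMAC over", nrow(x), "budget thresholds; unconditional P(preferred) =",
      round(attr(x, "unconditional"), 4), "\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Write a CMAC curve as delimited text
#'
#' @param curve A `cmac_curve`.
#' @param path File path.
#' @export
write_cmac <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# unconditional_probability: ",
                    format(attr(curve, "unconditional"), digits = 17)), con)
  utils::write.table(as.data.frame(curve), con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Plot a CMAC curve
#'
#' Base-graphics step plot of acceptance probability against the budget
#' threshold, with the unconditional preference probability as a dashed
#' asymptote.
#'
#' @param x A `cmac_curve`.
#' @param ... Passed to [plot()].
#' @export
plot.cmac_curve <- function(x, ...) {
  plot(x$threshold, x$probability, type = "s", ylim = c(0, 1),
       xlab = "Maximum budget threshold",
       ylab = "P(intervention preferred & budget impact <= threshold)",
       main = "Conditional Multi-attribute Acceptability Curve", ...)
  graphics::abline(h = attr(x, "unconditional"), lty = 2)
  invisible(x)
}
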