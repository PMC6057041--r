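#' Synthetic ground-truth data generator
#'
#' No raw study data ship with the package, so every pipeline stage is
#' exercised against simulated inputs with known ground truth: a two-arm
#' trial yielding per-criterion means and standard errors, DCE respondents
#' answering choice sets by a logistic choice rule under true part-worths,
#' and swing respondents ranking criteria by noisy true weights. All
#' generators are pure functions of (truth specification, seed).
#'
#' @name synthetic
NULL

#' Ground-truth specification
#'
#' @param set `criteria_set` the truth covers.
#' @param means Data frame `criterion_id`, `intervention`, `comparator`:
#'   true per-arm means on the natural scales.
#' @param ses Named vector of standard errors per criterion (recycled to
#'   both arms), or a single number.
#' @param beta True `partworths` driving DCE choices (or `NULL`).
#' @param weights Named list of true `weight_vector`s per stakeholder group
#'   (or `NULL`).
#' @param population_size Persons treated (budget-impact scaling).
#' @return A `truth_spec`.
#' @export
truth_spec <- function(set, means, ses = 0, beta = NULL, weights = NULL,
                       population_size = 1000) {
  stopifnot(inherits(set, "criteria_set"))
  miss <- setdiff(set$id, means$criterion_id)
  if (length(miss)) stop("means missing criteria: ", paste(miss, collapse = ", "))
  if (length(ses) == 1) ses <- stats::setNames(rep(ses, nrow(set)), set$id)
  for (k in seq_len(nrow(set))) {
    lo <- min(set$worst[k], set$best[k]); hi <- max(set$worst[k], set$best[k])
    m <- means[means$criterion_id == set$id[k], c("intervention", "comparator")]
    if (any(m < lo) || any(m > hi))
      stop("true mean for '", set$id[k], "' outside its scale range")
  }
  if (!is.null(weights))
    for (w in weights) stopifnot(abs(sum(w) - 1) < 1e-9)
  structure(list(set = set, means = means, ses = ses, beta = beta,
                 weights = weights, population_size = population_size),
            class = "truth_spec")
}

#' Worked-example truth: the hypothetical two-programme comparison
#'
#' The deterministic fixture used throughout tests and documentation: eight
#' core criteria, the hypothetical performance means of the two care
#' programmes, and the two stakeholder-group weight vectors (P1, P2). With
#' the default `ses = 0` the simulated trial reproduces these inputs
#' exactly.
#'
#' @param ses Standard errors (default 0: deterministic fixture).
#' @param population_size Persons treated.
#' @return A `truth_spec`.
#' @export
table_truth <- function(ses = 0, population_size = 1000) {
  set <- build_core_set()
  means <- data.frame(
    criterion_id = set$id,
    intervention = c(60, 70, 3, 2, 4, 4, 5, 8000),
    comparator   = c(70, 50, 4, 4, 3, 3, 3, 6000))
  truth_spec(set, means, ses = ses,
             weights = list(P1 = example_weights("P1"),
                            P2 = example_weights("P2")),
             population_size = population_size)
}

#' Hypothetical stakeholder-group weights from the worked example
#'
#' @param group `"P1"` or `"P2"`.
#' @return A `weight_vector` (provenance `method = "dce"`, hypothetical).
#' @export
example_weights <- function(group = c("P1", "P2")) {
  group <- match.arg(group)
  ids <- build_core_set()$id
  w <- switch(group,
    P1 = c(0.100, 0.150, 0.125, 0.050, 0.300, 0.100, 0.125, 0.050),
    P2 = c(0.250, 0.100, 0.100, 0.100, 0.150, 0.050, 0.050, 0.200))
  weight_vector(stats::setNames(w, ids), method = "dce", group = group)
}

#' Simulate a two-arm trial performance table
#'
#' Observed means are the true means plus normal noise with the specified
#' standard error, truncated to the criterion's scale range; SEs are copied
#' through. With `ses = 0` the truth is reproduced exactly.
#'
#' @param truth A `truth_spec`.
#' @param seed Integer RNG seed.
#' @return A `performance_table`.
#' @export
simulate_trial <- function(truth, seed) {
  stopifnot(inherits(truth, "truth_spec"))
  if (missing(seed)) stop("seed is mandatory")
  old_seed <- .Random.seed_save()
  on.exit(.Random.seed_restore(old_seed))
  set.seed(seed)
  set <- truth$set
  rows <- list()
  for (k in seq_len(nrow(set))) {
    id <- set$id[k]
    se <- truth$ses[[id]]
    lo <- min(set$worst[k], set$best[k]); hi <- max(set$worst[k], set$best[k])
    m <- truth$means[truth$means$criterion_id == id, ]
    for (a in c("intervention", "comparator")) {
      obs <- .rtruncnorm(1, m[[a]], se, lo, hi)
      rows[[length(rows) + 1]] <- data.frame(criterion_id = id, alt = a,
                                             mean = obs, se = se)
    }
  }
  performance_table(do.call(rbind, rows), set)
}

#' Simulate DCE respondents
#'
#' Each respondent is assigned one of the design's sub-designs uniformly at
#' random and answers all of its choice sets; each choice is Bernoulli with
#' the logistic choice probability under the true part-worths.
#'
#' @param design A `dce_design`.
#' @param truth A `truth_spec` with non-`NULL` `beta`, or a `partworths`.
#' @param n_respondents Number of respondents (>= 1).
#' @param seed Integer RNG seed.
#' @param group Stakeholder-group label stamped on the records.
#' @return Choice-record data frame: `respondent_id`, `group`,
#'   `sub_design`, `set`, `chosen`.
#' @export
simulate_dce_responses <- function(design, truth, n_respondents, seed,
                                   group = "P1") {
  beta <- if (inherits(truth, "partworths")) truth else truth$beta
  if (is.null(beta)) stop("truth carries no part-worths")
  if (n_respondents < 1) stop("n_respondents must be >= 1")
  if (missing(seed)) stop("seed is mandatory")
  old_seed <- .Random.seed_save()
  on.exit(.Random.seed_restore(old_seed))
  set.seed(seed)
  d <- dim(design$levels)
  sub <- sample.int(d[1], n_respondents, replace = TRUE)
  recs <- vector("list", n_respondents)
  for (r in seq_len(n_respondents)) {
    s <- sub[r]
    pA <- vapply(seq_len(d[2]), function(t)
      choice_probability(design$levels[s, t, 1, ], design$levels[s, t, 2, ],
                         beta), numeric(1))
    chosen <- ifelse(stats::runif(d[2]) < pA, "A", "B")
    recs[[r]] <- data.frame(respondent_id = r, group = group, sub_design = s,
                            set = seq_len(d[2]), chosen = chosen,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, recs)
}

#' Simulate SMARTER swing rankings
#'
#' Each respondent perturbs the true group weights with additive normal
#' noise (Thurstonian ranking model) and ranks criteria by the perturbed
#' values, descending. With `noise_sd = 0` every respondent reproduces the
#' true-weight rank order.
#'
#' @param truth A `truth_spec` with group weights, or a `weight_vector`.
#' @param n_respondents Number of respondents.
#' @param noise_sd Standard deviation of the perturbation on the weight
#'   scale (>= 0).
#' @param seed Integer RNG seed.
#' @param group Stakeholder group to draw true weights for / stamp on rows.
#' @return Long-format rankings: `respondent_id`, `group`, `rank`,
#'   `criterion_id`.
#' @export
simulate_swing_rankings <- function(truth, n_respondents, noise_sd, seed,
                                    group = "P1") {
  w <- if (inherits(truth, "weight_vector")) truth else truth$weights[[group]]
  if (is.null(w)) stop("truth carries no weights for group '", group, "'")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (missing(seed)) stop("seed is mandatory")
  old_seed <- .Random.seed_save()
  on.exit(.Random.seed_restore(old_seed))
  set.seed(seed)
  ids <- names(w)
  recs <- vector("list", n_respondents)
  for (r in seq_len(n_respondents)) {
    perceived <- unclass(w) + stats::rnorm(length(w), 0, noise_sd)
    # ties broken by the stable ordering of `order`; with continuous noise
    # ties have probability zero
    ord <- order(perceived, decreasing = TRUE)
    recs[[r]] <- data.frame(respondent_id = r, group = group,
                            rank = seq_along(ids), criterion_id = ids[ord],
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, recs)
}

#' True part-worths proportional to a weight vector
#'
#' Convenience constructor for simulations: good-level coefficient of each
#' attribute set to `scale * weight`, average-level coefficient to half of
#' it, so [partworths_to_weights()] applied to the truth returns exactly the
#' supplied weights.
#'
#' @param w A `weight_vector`.
#' @param scale Utility of a hypothetical weight-1 swing (controls choice
#'   determinism; larger = less noisy choices).
#' @return A `partworths` truth (no covariance).
#' @export
weights_to_partworths <- function(w, scale = 4) {
  good <- scale * unclass(w)
  partworths(as.vector(rbind(good / 2, good)), names(w))
}
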