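#' Discrete choice experiment engine
#'
#' Weights for the 8 core criteria are elicited with a paired-comparison DCE:
#' each choice set describes two hypothetical programmes by their level
#' (poor / average / good) on every core outcome, and respondents pick the
#' programme they prefer. Designs are D-efficient under a point prior and
#' respect a level-overlap rule (exactly 4 or 5 of the 8 attributes take
#' identical levels in both alternatives of a set, reducing task burden).
#' Part-worth utilities are estimated by conditional-logit maximum
#' likelihood; under dummy coding with the poor level as reference, the
#' "good" coefficient of an attribute is the utility of its full worst-to-
#' best swing, and relative weights are the normalized good-level
#' coefficients.
#'
#' @name dce
NULL

.LEVELS <- c("poor", "average", "good")

#' Cost attribute levels from a country mean
#'
#' The middle (average) level is the country-specific mean total health and
#' social care cost; poor and good are that mean increased and decreased by
#' 20% (a higher cost is the worse level).
#'
#' @param mean_cost Positive mean annual cost in national currency.
#' @return List with `mean_cost` and named `levels` (poor, average, good).
#' @examples
#' make_cost_levels(10000)$levels  # 12000 10000 8000
#' @export
make_cost_levels <- function(mean_cost) {
  if (length(mean_cost) != 1 || !is.finite(mean_cost) || mean_cost <= 0)
    stop("mean_cost must be a positive number")
  list(mean_cost = mean_cost,
       levels = c(poor = 1.2 * mean_cost, average = mean_cost,
                  good = 0.8 * mean_cost))
}

# Dummy coding, poor = reference: level l in 1..3 -> (average, good) indicators.
.code_level <- function(l) c(l == 2, l == 3) * 1

# Coded utility difference of a choice set: length 2*n_attr vector.
# Attribute-major order: (attr1_average, attr1_good, attr2_average, ...).
.delta_x <- function(level_a, level_b) {
  as.vector(vapply(seq_along(level_a), function(j)
    .code_level(level_a[j]) - .code_level(level_b[j]), numeric(2)))
}

.coef_names <- function(attributes)
  as.vector(t(outer(attributes, c("average", "good"), paste, sep = ":")))

#' Part-worth coefficient container
#'
#' @param coef Named numeric vector, 2 coefficients (average, good vs the
#'   poor reference) per attribute, attribute-major order.
#' @param vcov Covariance matrix (may be `NULL` for priors / truths).
#' @param logLik,converged,iterations,grad_norm Fit diagnostics.
#' @param attributes Attribute (criterion) ids.
#' @return A `partworths` object.
#' @export
partworths <- function(coef, attributes, vcov = NULL, logLik = NA_real_,
                       converged = NA, iterations = NA_integer_,
                       grad_norm = NA_real_) {
  stopifnot(length(coef) == 2 * length(attributes))
  names(coef) <- .coef_names(attributes)
  if (!is.null(vcov)) {
    stopifnot(nrow(vcov) == length(coef), ncol(vcov) == length(coef))
    if (max(abs(vcov - t(vcov))) > 1e-8) stop("covariance must be symmetric")
    dimnames(vcov) <- list(names(coef), names(coef))
  }
  structure(list(coef = coef, vcov = vcov, attributes = attributes,
                 logLik = logLik, converged = converged,
                 iterations = iterations, grad_norm = grad_norm),
            class = "partworths")
}

#' Default monotone prior part-worths
#'
#' Small positive coefficients with good > average > poor for every
#' attribute, used to seed design optimization when no literature priors are
#' supplied.
#'
#' @param attributes Attribute ids (default: the 8 core criteria).
#' @param good Good-level coefficient (average level gets half of it).
#' @return A `partworths` prior.
#' @export
default_prior <- function(attributes = build_core_set()$id, good = 0.5) {
  partworths(rep(c(good / 2, good), length(attributes)), attributes)
}

#' Probability that alternative A is chosen
#'
#' Binary logit on the utility difference: P(A) = logistic(V_A - V_B) with
#' V the sum of the level coefficients of the alternative's profile.
#' Attributes at identical levels in both alternatives cancel.
#'
#' @param level_a,level_b Integer level vectors (1 = poor, 2 = average,
#'   3 = good), one entry per attribute.
#' @param beta A `partworths` object (or bare coefficient vector).
#' @return Probability in (0, 1).
#' @export
choice_probability <- function(level_a, level_b, beta) {
  b <- if (inherits(beta, "partworths")) beta$coef else beta
  if (length(b) != 2 * length(level_a))
    stop("coefficient dimension (", length(b),
         ") does not match coded design (", 2 * length(level_a), ")")
  stats::plogis(sum(.delta_x(level_a, level_b) * b))
}

# --- design container ------------------------------------------------------

#' @export
print.dce_design <- function(x, ...) {
  cat("DCE design: ", dim(x$levels)[1], " sub-designs x ", dim(x$levels)[2],
      " choice sets, ", length(x$attributes), " attributes, 3 levels\n",
      "overlap per set in {", paste(sort(unique(as.vector(x$overlap))),
                                    collapse = ","), "}\n", sep = "")
  invisible(x)
}

.design_overlap <- function(levels) {
  # count of attributes at identical levels per (sub-design, set)
  apply(levels[, , 1, , drop = FALSE] == levels[, , 2, , drop = FALSE],
        c(1, 2), sum)
}

# random choice set with exactly `o` overlapped attributes
.random_set <- function(n_attr, o) {
  ov <- sample.int(n_attr, o)
  a <- sample.int(3, n_attr, replace = TRUE)
  b <- a
  for (j in setdiff(seq_len(n_attr), ov))
    b[j] <- sample(setdiff(1:3, a[j]), 1)
  rbind(a, b)
}

.random_design <- function(attributes, n_subdesigns, n_sets) {
  n_attr <- length(attributes)
  levels <- array(NA_integer_, c(n_subdesigns, n_sets, 2, n_attr))
  for (s in seq_len(n_subdesigns)) for (t in seq_len(n_sets)) {
    o <- sample(4:5, 1)
    levels[s, t, , ] <- .random_set(n_attr, o)
  }
  structure(list(attributes = attributes, levels = levels,
                 overlap = .design_overlap(levels),
                 blocks = rep(seq_len(3), each = n_sets / 3)),
            class = "dce_design")
}

# information matrix contribution of one choice set under a prior
.set_info <- function(level_a, level_b, b) {
  dx <- .delta_x(level_a, level_b)
  p <- stats::plogis(sum(dx * b))
  (p * (1 - p)) * tcrossprod(dx)
}

.design_information <- function(design, b) {
  p <- 2 * length(design$attributes)
  info <- matrix(0, p, p)
  d <- dim(design$levels)
  for (s in seq_len(d[1])) for (t in seq_len(d[2]))
    info <- info + .set_info(design$levels[s, t, 1, ],
                             design$levels[s, t, 2, ], b)
  info
}

#' Local D-error of a design under a point prior
#'
#' det(I(prior))^(-1/p) where I sums p(1-p) * dx dx' over every choice set
#' of every sub-design, dx the coded attribute difference and p the prior
#' choice probability; p in the exponent is the number of coefficients.
#' Lower is better. A singular information matrix (e.g. a design in which
#' some coefficient never varies) yields `+Inf` with attribute
#' `"singular"` set, never an exception.
#'
#' @param design A `dce_design`.
#' @param prior `partworths` (or coefficient vector) matching the coding.
#' @return Nonnegative scalar (possibly `+Inf`).
#' @export
d_error <- function(design, prior) {
  b <- if (inherits(prior, "partworths")) prior$coef else prior
  if (length(b) != 2 * length(design$attributes))
    stop("prior dimension does not match design coding")
  info <- .design_information(design, b)
  .d_error_from_info(info)
}

.d_error_from_info <- function(info) {
  p <- nrow(info)
  dt <- suppressWarnings(determinant(info, logarithm = TRUE))
  if (!is.finite(dt$modulus) || dt$sign <= 0 ||
      rcond(info) < 1e-12) {
    out <- Inf
    attr(out, "singular") <- TRUE
    return(out)
  }
  exp(-as.numeric(dt$modulus) / p)
}

# candidate replacements for one attribute of one set that preserve the
# overlap pattern: overlapped attribute -> common level in both alternatives;
# non-overlapped -> ordered distinct level pairs
.attr_candidates <- function(overlapped) {
  if (overlapped) {
    lapply(1:3, function(l) c(l, l))
  } else {
    pairs <- expand.grid(a = 1:3, b = 1:3)
    pairs <- pairs[pairs$a != pairs$b, ]
    lapply(seq_len(nrow(pairs)), function(i) c(pairs$a[i], pairs$b[i]))
  }
}

#' Optimize a level-overlap-constrained D-efficient DCE design
#'
#' Coordinate-exchange search: starting from a random design whose every
#' choice set has 4 or 5 overlapped attributes (drawn with equal
#' probability), repeatedly propose replacing the level assignment of a
#' single attribute within a single choice set and accept the proposal only
#' if the D-error decreases. The overlap pattern of each set is a hard
#' constraint: proposals on an overlapped attribute move both alternatives
#' together, proposals on a non-overlapped attribute keep the two levels
#' distinct. Deterministic given `seed`.
#'
#' @param prior `partworths` point prior (default [default_prior()]).
#' @param n_subdesigns,n_sets Design dimensions; `n_sets` must be divisible
#'   by 3 (sets are blocked into 3 blocks per sub-design).
#' @param seed Integer RNG seed (mandatory).
#' @param attributes Attribute ids (default: 8 core criteria).
#' @param n_sweeps Full passes of coordinate exchange.
#' @return A `dce_design` with attributes `d_error` (final) and
#'   `d_error_initial`.
#' @export
optimize_design <- function(prior = default_prior(), n_subdesigns = 10,
                            n_sets = 18, seed, attributes = NULL,
                            n_sweeps = 2) {
  if (missing(seed)) stop("seed is mandatory for design optimization")
  if (n_sets %% 3 != 0) stop("n_sets must be divisible by 3 for blocking")
  b <- if (inherits(prior, "partworths")) prior$coef else prior
  if (is.null(attributes)) {
    if (inherits(prior, "partworths")) attributes <- prior$attributes
    else attributes <- build_core_set()$id
  }
  if (length(b) != 2 * length(attributes))
    stop("prior dimension does not match attribute count")
  n_attr <- length(attributes)
  if (n_attr < 5)
    stop("overlap rule (4 or 5 overlapped attributes) needs >= 5 attributes")

  old_seed <- .Random.seed_save()
  on.exit(.Random.seed_restore(old_seed))
  set.seed(seed)

  design <- .random_design(attributes, n_subdesigns, n_sets)
  info <- .design_information(design, b)
  init_err <- .d_error_from_info(info)

  for (sweep in seq_len(n_sweeps)) {
    for (s in seq_len(n_subdesigns)) for (t in seq_len(n_sets)) {
      la <- design$levels[s, t, 1, ]; lb <- design$levels[s, t, 2, ]
      for (j in seq_len(n_attr)) {
        cur_err <- .d_error_from_info(info)
        contrib_old <- .set_info(la, lb, b)
        best <- NULL; best_err <- cur_err
        for (cand in .attr_candidates(la[j] == lb[j])) {
          if (cand[1] == la[j] && cand[2] == lb[j]) next
          la2 <- la; lb2 <- lb
          la2[j] <- cand[1]; lb2[j] <- cand[2]
          info2 <- info - contrib_old + .set_info(la2, lb2, b)
          err2 <- .d_error_from_info(info2)
          if (err2 < best_err) { best <- cand; best_err <- err2 }
        }
        if (!is.null(best)) {
          la2 <- la; lb2 <- lb
          la2[j] <- best[1]; lb2[j] <- best[2]
          info <- info - contrib_old + .set_info(la2, lb2, b)
          la <- la2; lb <- lb2
        }
      }
      design$levels[s, t, 1, ] <- la
      design$levels[s, t, 2, ] <- lb
    }
  }
  design$overlap <- .design_overlap(design$levels)
  stopifnot(all(design$overlap %in% 4:5))
  attr(design, "d_error") <- .d_error_from_info(info)
  attr(design, "d_error_initial") <- init_err
  attr(design, "seed") <- seed
  design
}

# save/restore global RNG state so package functions with their own seed do
# not perturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Serialize / read a DCE design as delimited text
#'
#' Long format: `sub_design,set,block,alternative,attribute,level` with
#' levels written as `poor` / `average` / `good`.
#'
#' @param design A `dce_design` (for writing).
#' @param path File path.
#' @return `read_dce_design()` returns a `dce_design`.
#' @export
write_dce_design <- function(design, path) {
  d <- dim(design$levels)
  grid <- expand.grid(attribute = design$attributes, alternative = c("A", "B"),
                      set = seq_len(d[2]), sub_design = seq_len(d[1]),
                      stringsAsFactors = FALSE)
  grid$level <- .LEVELS[design$levels[cbind(grid$sub_design, grid$set,
                                            match(grid$alternative, c("A", "B")),
                                            match(grid$attribute, design$attributes))]]
  grid$block <- design$blocks[grid$set]
  utils::write.csv(grid[, c("sub_design", "set", "block", "alternative",
                            "attribute", "level")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dce_design
#' @export
read_dce_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  attributes <- unique(df$attribute)
  n_sub <- max(df$sub_design); n_sets <- max(df$set)
  levels <- array(NA_integer_, c(n_sub, n_sets, 2, length(attributes)))
  levels[cbind(df$sub_design, df$set, match(df$alternative, c("A", "B")),
               match(df$attribute, attributes))] <- match(df$level, .LEVELS)
  blocks <- df$block[match(seq_len(n_sets), df$set)]
  structure(list(attributes = attributes, levels = levels,
                 overlap = .design_overlap(levels), blocks = blocks),
            class = "dce_design")
}

# --- estimation ------------------------------------------------------------

# build the utility-difference design matrix X and response y from records
.choice_matrix <- function(design, data) {
  required <- c("respondent_id", "sub_design", "set", "chosen")
  miss <- setdiff(required, names(data))
  if (length(miss)) stop("choice data missing columns: ",
                         paste(miss, collapse = ", "))
  d <- dim(design$levels)
  if (any(data$sub_design < 1 | data$sub_design > d[1]) ||
      any(data$set < 1 | data$set > d[2]))
    stop("choice record references a non-existent choice set")
  n <- nrow(data)
  p <- 2 * length(design$attributes)
  X <- matrix(0, n, p, dimnames = list(NULL, .coef_names(design$attributes)))
  # cache the 16-vector per (sub_design, set)
  key <- (data$sub_design - 1) * d[2] + data$set
  ukey <- unique(key)
  dx_cache <- matrix(0, length(ukey), p)
  for (i in seq_along(ukey)) {
    s <- (ukey[i] - 1) %/% d[2] + 1
    t <- (ukey[i] - 1) %% d[2] + 1
    dx_cache[i, ] <- .delta_x(design$levels[s, t, 1, ], design$levels[s, t, 2, ])
  }
  X[] <- dx_cache[match(key, ukey), ]
  list(X = X, y = as.numeric(data$chosen == "A"))
}

#' Fit a conditional logit to paired-choice data
#'
#' Maximum likelihood on the binary logit of utility differences, by damped
#' Newton-Raphson with step-halving (the log-likelihood never decreases
#' across accepted steps). Convergence when the gradient max-norm drops
#' below `tol`. The coefficient covariance is the inverse observed
#' information at the optimum.
#'
#' @param design `dce_design` the records refer to.
#' @param data Choice records: data frame with `respondent_id`,
#'   `sub_design`, `set`, `chosen` (`"A"` or `"B"`).
#' @param tol Gradient max-norm convergence tolerance.
#' @param max_iter Newton iteration cap.
#' @return A `partworths` fit with covariance and diagnostics.
#' @export
fit_conditional_logit <- function(design, data, tol = 1e-8, max_iter = 50) {
  cm <- .choice_matrix(design, data)
  X <- cm$X; y <- cm$y
  p <- ncol(X)
  if (nrow(X) < p)
    stop("need at least ", p, " choices to estimate ", p, " coefficients")
  never_varies <- colSums(abs(X)) == 0
  if (any(never_varies))
    stop("non-identifiable coefficients (level never varies in the data): ",
         paste(colnames(X)[never_varies], collapse = ", "))
  beta <- rep(0, p)
  ll <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  ll_old <- ll(beta)
  converged <- FALSE; it <- 0; gnorm <- Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(X, y - mu))
    gnorm <- max(abs(grad))
    if (gnorm < tol) { converged <- TRUE; break }
    W <- mu * (1 - mu)
    H <- crossprod(X * W, X)
    if (rcond(H) < 1e-14)
      stop("singular information matrix; design or data are collinear")
    step <- solve(H, grad)
    # step-halving: guarantee the log-likelihood does not decrease
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      if (ll(beta_new) >= ll_old - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10)
        stop("step-halving failed; log-likelihood surface is degenerate")
    }
    beta <- beta_new
    ll_old <- ll(beta)
    if (max(abs(beta)) > 30) {
      worst <- colnames(X)[which.max(abs(beta))]
      stop("apparent separation while estimating '", worst,
           "': coefficient diverging (|beta| > 30); ",
           "check that both alternatives are ever chosen at each level")
    }
  }
  if (!converged)
    stop("conditional logit did not converge in ", max_iter,
         " iterations (gradient max-norm ", format(gnorm, digits = 4), ")")
  mu <- stats::plogis(drop(X %*% beta))
  H <- crossprod(X * (mu * (1 - mu)), X)
  vc <- solve(H)
  vc <- (vc + t(vc)) / 2
  partworths(beta, design$attributes, vcov = vc, logLik = ll_old,
             converged = TRUE, iterations = it, grad_norm = gnorm)
}

#' Adaptive prior update after an enrolment threshold
#'
#' Once at least `threshold` respondents have answered, the part-worths are
#' refitted on the accumulated data and the design is re-optimized using the
#' refit as the new point prior. Below the threshold nothing happens and the
#' result is flagged `updated = FALSE`.
#'
#' @param design Current `dce_design`.
#' @param data Accumulated choice records.
#' @param threshold Respondent count that triggers the update.
#' @param seed Seed for the re-optimization.
#' @return List: `prior` (`partworths`), `design`, `updated` (logical).
#' @export
update_priors <- function(design, data, threshold = 50, seed = 1) {
  n_resp <- length(unique(data$respondent_id))
  if (n_resp < threshold)
    return(list(prior = NULL, design = design, updated = FALSE,
                n_respondents = n_resp))
  fit <- fit_conditional_logit(design, data)
  d <- dim(design$levels)
  new_design <- optimize_design(prior = fit, n_subdesigns = d[1],
                                n_sets = d[2], seed = seed)
  list(prior = fit, design = new_design, updated = TRUE,
       n_respondents = n_resp)
}

#' Criterion weights from fitted part-worths
#'
#' Under dummy coding with the poor level as reference, the good-level
#' coefficient of attribute j is the utility of swinging j from worst to
#' best; relative weights are these coefficients normalized to sum 1.
#'
#' @param beta A `partworths` object.
#' @param group Stakeholder-group label recorded as provenance.
#' @return A `weight_vector` with `method = "dce"`.
#' @export
partworths_to_weights <- function(beta, group = "pooled") {
  stopifnot(inherits(beta, "partworths"))
  good <- beta$coef[seq(2, length(beta$coef), by = 2)]
  if (any(good < 0)) {
    bad <- beta$attributes[good < 0]
    stop("negative best-level coefficient for: ",
         paste(bad, collapse = ", "),
         ". A 'good' level valued below 'poor' contradicts the monotone ",
         "framing of the elicitation; review coefficient signs before ",
         "deriving weights.")
  }
  if (sum(good) == 0) stop("all best-level coefficients are zero")
  weight_vector(stats::setNames(good / sum(good), beta$attributes),
                method = "dce", group = group)
}
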