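#' SMARTER swing weighting
#'
#' Respondents imagine a programme at the worst level on every criterion and
#' repeatedly name the criterion they would swing to its best level next,
#' yielding a complete ranking with no ties. Rankings are converted to
#' weights by the rank-ordered-centroid (ROC) rule and pooled across
#' respondents within and across stakeholder groups.
#'
#' @name swing_weighting
NULL

#' Rank-ordered-centroid weights
#'
#' For K ranked criteria the criterion ranked k receives
#' w_k = (1/K) * sum_{i=k}^{K} 1/i. Weights are strictly decreasing in rank
#' and sum to exactly 1.
#'
#' @param K Number of criteria (>= 1).
#' @return Numeric vector of length K, ranks 1..K.
#' @examples
#' roc_weights(2)  # 0.75 0.25
#' @export
roc_weights <- function(K) {
  if (length(K) != 1 || !is.finite(K) || K < 1 || K != floor(K))
    stop("K must be a positive integer")
  # tail-reversed cumulative harmonic sum: w_k = mean of 1/i for i >= k
  rev(cumsum(1 / seq(K, 1))) / K
}

#' Convert one swing ranking into a weight vector
#'
#' @param ranking Character vector: criterion ids in elicited order (first =
#'   swung first, i.e. most important).
#' @param criteria_ids Full id set the ranking must be a permutation of;
#'   defaults to the ranking itself.
#' @param group Stakeholder-group label recorded as provenance.
#' @param rule `"roc"` (default), `"rank_sum"` or `"rank_reciprocal"` --
#'   alternative rank-to-weight rules behind a flag.
#' @return A `weight_vector` with `method = "swing"`.
#' @export
ranking_to_weights <- function(ranking, criteria_ids = ranking,
                               group = "pooled",
                               rule = c("roc", "rank_sum", "rank_reciprocal")) {
  rule <- match.arg(rule)
  if (anyDuplicated(ranking))
    stop("ranking contains duplicates: ",
         paste(unique(ranking[duplicated(ranking)]), collapse = ", "))
  if (!setequal(ranking, criteria_ids) || length(ranking) != length(criteria_ids))
    stop("ranking is not a complete permutation of the criteria set ",
         "(missing: ", paste(setdiff(criteria_ids, ranking), collapse = ", "),
         "; extraneous: ", paste(setdiff(ranking, criteria_ids), collapse = ", "), ")")
  K <- length(ranking)
  w <- switch(rule,
    roc = roc_weights(K),
    rank_sum = (K + 1 - seq_len(K)) / sum(seq_len(K)),
    rank_reciprocal = (1 / seq_len(K)) / sum(1 / seq_len(K)))
  weight_vector(stats::setNames(w, ranking)[sort(ranking)],
                method = "swing", group = group)
}

#' Pool weight vectors
#'
#' Per-criterion arithmetic mean (or median) across vectors, renormalized to
#' sum 1. Used both to aggregate respondents within a stakeholder group and
#' to pool group-level vectors across groups.
#'
#' @param vectors List of `weight_vector`s over the same criteria.
#' @param mode `"within_group"` or `"across_groups"`; recorded in provenance.
#' @param estimator `"mean"` (SMARTER convention, default) or `"median"`.
#' @param group Label for the pooled vector.
#' @return A pooled `weight_vector`.
#' @export
pool_weights <- function(vectors, mode = c("within_group", "across_groups"),
                         estimator = c("mean", "median"), group = "pooled") {
  mode <- match.arg(mode)
  estimator <- match.arg(estimator)
  stopifnot(length(vectors) >= 1)
  ids <- sort(names(vectors[[1]]))
  for (v in vectors)
    if (!setequal(names(v), ids))
      stop("cannot pool weight vectors over mismatched criteria sets")
  mat <- vapply(vectors, function(v) unclass(v)[ids], numeric(length(ids)))
  mat <- matrix(mat, nrow = length(ids),
                dimnames = list(ids, NULL))
  agg <- apply(mat, 1, if (estimator == "mean") mean else stats::median)
  agg <- agg / sum(agg)
  method <- attr(vectors[[1]], "method")
  weight_vector(agg, method = if (is.null(method)) "manual" else method,
                group = group)
}

#' Aggregate raw swing rankings into group-level weights
#'
#' @param rankings Data frame with columns `respondent_id`, `group`, `rank`,
#'   `criterion_id` (long format, rank 1 = first swing).
#' @param criteria_ids Criteria the rankings must cover.
#' @param by_group If `TRUE` (default) return one pooled vector per
#'   stakeholder group; otherwise a single pooled vector.
#' @param rule Rank-to-weight rule, see [ranking_to_weights()].
#' @param estimator Pooling estimator, see [pool_weights()].
#' @return Named list of `weight_vector`s (by group), or one `weight_vector`.
#' @export
aggregate_swing_weights <- function(rankings, criteria_ids, by_group = TRUE,
                                    rule = "roc", estimator = "mean") {
  required <- c("respondent_id", "group", "rank", "criterion_id")
  miss <- setdiff(required, names(rankings))
  if (length(miss)) stop("rankings are missing columns: ",
                         paste(miss, collapse = ", "))
  per_resp <- split(rankings, rankings$respondent_id)
  vecs <- lapply(per_resp, function(d) {
    d <- d[order(d$rank), ]
    ranking_to_weights(d$criterion_id, criteria_ids,
                       group = d$group[1], rule = rule)
  })
  if (!by_group)
    return(pool_weights(vecs, "across_groups", estimator, group = "pooled"))
  groups <- vapply(vecs, function(v) attr(v, "group"), character(1))
  lapply(split(vecs, groups), function(vs)
    pool_weights(vs, "within_group", estimator, group = attr(vs[[1]], "group")))
}

#' Read / write swing rankings as delimited text
#'
#' Schema: `respondent_id,group,rank,criterion_id`.
#'
#' @param path File path.
#' @param rankings Long-format data frame (for writing).
#' @return `read_swing_rankings()` returns the long-format data frame.
#' @export
read_swing_rankings <- function(path) {
  if (!file.exists(path)) stop("rankings file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_swing_rankings
#' @export
write_swing_rankings <- function(rankings, path) {
  utils::write.csv(rankings, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
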