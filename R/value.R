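#' Performance standardization and overall value scores
#'
#' The value model is a weighted sum over criteria. Raw performance on each
#' criterion is first standardized to remove scale effects by pairwise vector
#' normalization: for benefit criterion j with raw scores x_aj (intervention)
#' and x_bj (comparator),
#'
#'   S_aj = x_aj / sqrt(x_aj^2 + x_bj^2)
#'
#' and for cost-direction criteria the complement 1 - x/sqrt(x_a^2 + x_b^2)
#' is taken, so that a higher standardized score is always better. The
#' overall value of an alternative is sum_j w_j * S_j with nonnegative
#' weights summing to one, hence lies in [0, 1].
#'
#' @name value_scoring
NULL

#' Build a performance table for two alternatives
#'
#' @param data Data frame with columns `criterion_id`, `alt`, `mean`, `se`.
#' @param set `criteria_set` the table must cover.
#' @param alternatives Character pair naming the intervention and comparator
#'   (in that order); must match the `alt` column.
#' @return A validated data frame of class `performance_table`.
#' @export
performance_table <- function(data, set,
                              alternatives = c("intervention", "comparator")) {
  stopifnot(length(alternatives) == 2)
  required <- c("criterion_id", "alt", "mean", "se")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("performance table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  bad_alt <- setdiff(unique(data$alt), alternatives)
  if (length(bad_alt))
    stop("unknown alternatives in table: ", paste(bad_alt, collapse = ", "))
  for (a in alternatives) {
    have <- data$criterion_id[data$alt == a]
    miss <- setdiff(set$id, have)
    if (length(miss))
      stop("alternative '", a, "' is missing criteria: ",
           paste(miss, collapse = ", "))
  }
  extra <- setdiff(unique(data$criterion_id), set$id)
  if (length(extra))
    stop("unknown criteria in table: ", paste(extra, collapse = ", "))
  if (any(data$se < 0)) stop("standard errors must be nonnegative")
  for (i in seq_len(nrow(data))) {
    cr <- set[set$id == data$criterion_id[i], ]
    lo <- min(cr$worst, cr$best); hi <- max(cr$worst, cr$best)
    if (data$mean[i] < lo || data$mean[i] > hi)
      stop("row ", i, ": mean ", data$mean[i], " for '", cr$id,
           "' outside scale range [", lo, ", ", hi, "]")
  }
  structure(as.data.frame(data), class = c("performance_table", "data.frame"),
            alternatives = alternatives, criteria = set)
}

#' Standardize one pair of raw performance scores
#'
#' Pairwise vector normalization. Benefit direction: x / ||(x_a, x_b)||.
#' Cost direction: the complement 1 - x / ||(x_a, x_b)||, so lower cost maps
#' to a higher standardized score.
#'
#' @param x_a,x_b Nonnegative raw scores of the two alternatives (not both
#'   zero).
#' @param direction `"benefit"` or `"cost"`.
#' @return Numeric pair `c(S_a, S_b)`, each in `[0, 1]`.
#' @examples
#' standardize_pair(60, 70, "benefit")   # 0.65, 0.76 at 2 dp
#' standardize_pair(8000, 6000, "cost")  # 0.20, 0.40
#' @export
standardize_pair <- function(x_a, x_b, direction = c("benefit", "cost")) {
  direction <- match.arg(direction)
  if (x_a < 0 || x_b < 0)
    stop("standardization requires nonnegative raw scores; got (",
         x_a, ", ", x_b, ")")
  nrm <- sqrt(x_a^2 + x_b^2)
  if (nrm == 0)
    stop("degenerate pair: both raw scores are zero")
  s <- c(x_a, x_b) / nrm
  if (direction == "cost") s <- 1 - s
  s
}

#' Standardize a full performance table
#'
#' Applies [standardize_pair()] criterion by criterion using the table's
#' means. Unrounded values are retained; rounding is a display concern only.
#'
#' @param perf A `performance_table`.
#' @param set `criteria_set`; defaults to the set the table was built against.
#' @return Data frame of class `standardized_table` with columns
#'   `criterion_id`, and one standardized-score column per alternative.
#' @export
standardize_table <- function(perf, set = attr(perf, "criteria")) {
  alts <- attr(perf, "alternatives")
  if (is.null(alts)) stop("perf must be a performance_table")
  miss <- setdiff(set$id, unique(perf$criterion_id))
  if (length(miss))
    stop("criteria missing from performance table: ",
         paste(miss, collapse = ", "))
  out <- data.frame(criterion_id = set$id, stringsAsFactors = FALSE)
  out[[alts[1]]] <- NA_real_
  out[[alts[2]]] <- NA_real_
  for (k in seq_len(nrow(set))) {
    j <- set$id[k]
    x_a <- perf$mean[perf$criterion_id == j & perf$alt == alts[1]]
    x_b <- perf$mean[perf$criterion_id == j & perf$alt == alts[2]]
    s <- standardize_pair(x_a, x_b, set$direction[k])
    out[[alts[1]]][k] <- s[1]
    out[[alts[2]]][k] <- s[2]
  }
  structure(out, class = c("standardized_table", "data.frame"),
            alternatives = alts, criteria = set)
}

#' Construct a weight vector with provenance
#'
#' @param weights Named nonnegative numeric vector summing to 1 (names are
#'   criterion ids).
#' @param method `"dce"`, `"swing"` or `"manual"`.
#' @param group Stakeholder-group label (one of the 5P groups, `"pooled"`,
#'   or any label for hypothetical weights).
#' @return A `weight_vector`.
#' @export
weight_vector <- function(weights, method = c("manual", "dce", "swing"),
                          group = "pooled") {
  method <- match.arg(method)
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("weights must be named by criterion id")
  if (anyDuplicated(names(weights))) stop("duplicate criterion ids in weights")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1 (got ", format(sum(weights), digits = 12), ")")
  structure(weights, class = "weight_vector", method = method, group = group)
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("Weights (method=", attr(x, "method"), ", group=", attr(x, "group"),
      ")\n", sep = "")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Aggregate standardized scores into overall value scores
#'
#' Computes the weighted contribution w_j * S_j of every criterion for each
#' alternative and sums them into the overall value score, using unrounded
#' standardized values.
#'
#' @param std A `standardized_table`.
#' @param w A `weight_vector` covering exactly the table's criteria.
#' @return A `value_result`: list with `values` (named pair of overall
#'   scores), `contributions` (data frame criterion x alternative), and the
#'   weight provenance.
#' @export
overall_value <- function(std, w) {
  alts <- attr(std, "alternatives")
  if (is.null(alts)) stop("std must be a standardized_table")
  if (!setequal(names(w), std$criterion_id))
    stop("weight vector covers ",
         paste(setdiff(names(w), std$criterion_id), collapse = ", "),
         if (length(setdiff(std$criterion_id, names(w))))
           paste(" and misses", paste(setdiff(std$criterion_id, names(w)),
                                      collapse = ", ")),
         "; criteria must match the standardized table exactly")
  ww <- unclass(w)[std$criterion_id]
  contrib <- data.frame(criterion_id = std$criterion_id,
                        stringsAsFactors = FALSE)
  for (a in alts) contrib[[a]] <- ww * std[[a]]
  values <- vapply(alts, function(a) sum(contrib[[a]]), numeric(1))
  structure(list(values = values, contributions = contrib,
                 method = attr(w, "method"), group = attr(w, "group")),
            class = "value_result")
}

#' @export
print.value_result <- function(x, ...) {
  cat("Overall value scores (weights: method=", x$method, ", group=",
      x$group, ")\n", sep = "")
  print(round(x$values, 3))
  invisible(x)
}

#' Preferred alternative of a value comparison
#'
#' @param v A `value_result` over two alternatives.
#' @param tol Values closer than this are declared a tie.
#' @return Label of the higher-valued alternative, or `"tie"`.
#' @export
preferred_alternative <- function(v, tol = 1e-12) {
  stopifnot(inherits(v, "value_result"), length(v$values) == 2)
  d <- v$values[1] - v$values[2]
  if (abs(d) <= tol) return("tie")
  names(v$values)[if (d > 0) 1 else 2]
}

#' Read / write performance tables as delimited text
#'
#' Schema: header `criterion_id,alt,mean,se`; row order irrelevant; `'.'`
#' decimal separator.
#'
#' @param path File path.
#' @param set `criteria_set` to validate against.
#' @param alternatives Character pair (intervention first).
#' @param perf A `performance_table` (for writing).
#' @return `read_performance_table()` returns a `performance_table`.
#' @export
read_performance_table <- function(path, set,
                                   alternatives = c("intervention", "comparator")) {
  if (!file.exists(path)) stop("performance table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  performance_table(df, set, alternatives)
}

#' @rdname read_performance_table
#' @export
write_performance_table <- function(perf, path) {
  utils::write.csv(as.data.frame(perf), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write weight vectors as delimited text
#'
#' Schema: comment header lines `# method: ...` and `# group: ...`, then
#' `criterion_id,weight`.
#'
#' @param path File path.
#' @param w A `weight_vector` (for writing).
#' @return `read_weights()` returns a `weight_vector`.
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) stop("weights file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key, default) {
    m <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (length(m)) trimws(sub(paste0("^#\\s*", key, ":"), "", m[1])) else default
  }
  df <- utils::read.csv(text = paste(grep("^#", lines, invert = TRUE,
                                          value = TRUE), collapse = "\n"),
                        stringsAsFactors = FALSE)
  w <- stats::setNames(df$weight, df$criterion_id)
  weight_vector(w, method = get_field("method", "manual"),
                group = get_field("group", "pooled"))
}

#' @rdname read_weights
#' @export
write_weights <- function(w, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# method: ", attr(w, "method")),
               paste0("# group: ", attr(w, "group")),
               "criterion_id,weight",
               paste(names(w), format(unclass(w), digits = 17, trim = TRUE,
                                      scientific = FALSE), sep = ",")), con)
  invisible(path)
}
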