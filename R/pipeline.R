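#' Run configuration and the end-to-end pipeline
#'
#' A run configuration (YAML) names the criteria set, the input files, the
#' stakeholder groups, seeds, PSA settings and the output directory; the
#' pipeline executes scoring, weighting, deterministic sensitivity analyses,
#' the PSA and the CMAC, and writes a machine-readable bundle plus a
#' human-readable summary. Every output is reproducible from config +
#' inputs + seeds; a manifest records seeds and input digests.
#'
#' @name io_cli
NULL

#' Read a run configuration
#'
#' @param path YAML file. Recognised keys: `criteria` (`"core"` or a
#'   programme tag), `cost_worst`/`cost_best`, `performance` (path),
#'   `weights` (named paths, e.g. `dce:`, `swing:`), `dce` (optional
#'   `design:`/`choices:` paths to refit part-worths), `sa`
#'   (`exclude:` criterion id), `psa` (`n_draws`, `seed`,
#'   `population_size`, `budget_min`, `budget_max`, `budget_steps`),
#'   `out_dir`, `rounding` (`standardized`, `values`).
#' @return A validated config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$base_dir <- dirname(normalizePath(path))
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg Config list (e.g. built in code).
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg$criteria)) cfg$criteria <- "core"
  if (is.null(cfg$performance)) stop("config must name a performance table")
  if (is.null(cfg$weights) || !length(cfg$weights))
    stop("config must name at least one weights file")
  if (is.null(cfg$out_dir)) stop("config must name out_dir")
  if (is.null(cfg$rounding)) cfg$rounding <- list(standardized = 2, values = 3)
  resolve <- function(p) {
    if (is.null(p) || is.null(cfg$base_dir) || file.exists(p)) p
    else file.path(cfg$base_dir, p)
  }
  cfg$performance <- resolve(cfg$performance)
  cfg$weights <- lapply(cfg$weights, resolve)
  if (!is.null(cfg$dce)) cfg$dce <- lapply(cfg$dce, resolve)
  for (f in c(cfg$performance, unlist(cfg$weights), unlist(cfg$dce)))
    if (!file.exists(f)) stop("input file not found: ", f)
  cfg
}

.build_set_from_config <- function(cfg) {
  args <- list()
  if (!is.null(cfg$cost_worst)) args$cost_worst <- cfg$cost_worst
  if (!is.null(cfg$cost_best)) args$cost_best <- cfg$cost_best
  if (identical(cfg$criteria, "core")) do.call(build_core_set, args)
  else do.call(build_programme_set, c(list(tag = cfg$criteria), args))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Execute the full MCDA pipeline
#'
#' Stages: load criteria and performance -> load weight sets -> standardize
#' and score under every weight set -> deterministic sensitivity analyses
#' (criterion exclusion if configured, weight-method swap when two weight
#' sets are present) -> PSA -> CMAC. Any stage failure aborts with the
#' stage name. All numeric outputs are byte-identical across reruns of the
#' same config.
#'
#' @param cfg Config list from [read_run_config()] (or built in code and
#'   passed through [validate_run_config()]).
#' @param quiet Suppress progress messages to stderr.
#' @return Invisibly, a list with every computed object (`values`,
#'   `sa`, `psa`, `cmac`, paths).
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  cfg <- validate_run_config(cfg)
  note <- function(...) if (!quiet) message("[icmcda] ", ...)
  set <- .stage("criteria", .build_set_from_config(cfg))
  perf <- .stage("performance",
                 read_performance_table(cfg$performance, set))
  note("loaded performance table: ", nrow(set), " criteria")
  weights <- .stage("weights", lapply(cfg$weights, read_weights))
  for (w in weights)
    if (!setequal(names(w), set$id))
      .stage("weights", stop("weight file does not cover the criteria set"))
  std <- standardize_table(perf)
  values <- .stage("scoring", lapply(weights, function(w)
    overall_value(std, w)))
  note("overall values: ",
       paste(names(values), vapply(values, function(v)
         paste(round(v$values, 3), collapse = "/"), character(1)),
         collapse = "; "))

  sa <- list()
  if (!is.null(cfg$sa$exclude))
    sa$exclusion <- .stage("sa", exclude_criterion_sa(
      perf, weights[[1]], cfg$sa$exclude))
  if (length(weights) >= 2)
    sa$swap <- .stage("sa", weight_method_swap_sa(
      perf, weights[[1]], weights[[2]]))

  psa_draws <- NULL; curve <- NULL
  if (!is.null(cfg$psa)) {
    p <- cfg$psa
    grid <- if (!is.null(p$budget_grid)) unlist(p$budget_grid) else
      seq(p$budget_min, p$budget_max, length.out = p$budget_steps)
    pcfg <- .stage("psa", psa_config(p$n_draws, p$seed, p$population_size,
                                     grid))
    beta <- NULL
    if (!is.null(cfg$dce)) {
      design <- .stage("psa", read_dce_design(cfg$dce$design))
      choices <- .stage("psa", utils::read.csv(cfg$dce$choices,
                                               stringsAsFactors = FALSE))
      beta <- .stage("psa", fit_conditional_logit(design, choices))
    }
    psa_draws <- .stage("psa", if (is.null(beta))
      run_psa(perf, pcfg, weights = weights[[1]])
      else run_psa(perf, pcfg, beta = beta))
    curve <- .stage("cmac", cmac(psa_draws))
    note("PSA: ", pcfg$n_draws, " draws; unconditional P(preferred) = ",
         round(attr(curve, "unconditional"), 4))
  }

  out <- .stage("write", .write_bundle(cfg, set, perf, std, weights, values,
                                       sa, psa_draws, curve))
  invisible(list(criteria = set, performance = perf, standardized = std,
                 weights = weights, values = values, sa = sa,
                 psa = psa_draws, cmac = curve, paths = out))
}

.fmt <- function(x, digits) formatC(round(x, digits), format = "f",
                                    digits = digits)

.write_bundle <- function(cfg, set, perf, std, weights, values, sa,
                          psa_draws, curve) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  alts <- attr(perf, "alternatives")
  rd_s <- cfg$rounding$standardized
  rd_v <- cfg$rounding$values

  # machine-readable per-criterion results
  res <- data.frame(criterion_id = set$id, label = set$label, aim = set$aim)
  for (a in alts) {
    res[[paste0("mean_", a)]] <- vapply(set$id, function(j)
      perf$mean[perf$criterion_id == j & perf$alt == a], numeric(1))
    res[[paste0("std_", a)]] <- std[[a]]
  }
  for (nm in names(weights)) {
    res[[paste0("weight_", nm)]] <- unclass(weights[[nm]])[set$id]
    for (a in alts)
      res[[paste0("contrib_", nm, "_", a)]] <-
        values[[nm]]$contributions[[a]]
  }
  paths$results <- file.path(cfg$out_dir, "value_breakdown.csv")
  utils::write.csv(res, paths$results, row.names = FALSE, quote = TRUE)

  # human-readable summary mirroring the worked-example layout
  lines <- c("Overall value scores", "====================", "")
  width <- max(nchar(set$label)) + 2
  hdr <- sprintf(paste0("%-", width, "s %10s %10s %10s %10s"),
                 "Criterion",
                 paste0("perf:", substr(alts[1], 1, 4)),
                 paste0("perf:", substr(alts[2], 1, 4)),
                 paste0("std:", substr(alts[1], 1, 4)),
                 paste0("std:", substr(alts[2], 1, 4)))
  lines <- c(lines, hdr)
  for (k in seq_len(nrow(set))) {
    lines <- c(lines, sprintf(
      paste0("%-", width, "s %10s %10s %10s %10s"), set$label[k],
      .fmt(res[[paste0("mean_", alts[1])]][k], rd_s),
      .fmt(res[[paste0("mean_", alts[2])]][k], rd_s),
      .fmt(std[[alts[1]]][k], rd_s), .fmt(std[[alts[2]]][k], rd_s)))
  }
  lines <- c(lines, "")
  for (nm in names(values)) {
    v <- values[[nm]]$values
    lines <- c(lines, sprintf(
      "Weights '%s' (method=%s, group=%s): value %s = %s, %s = %s -> preferred: %s",
      nm, values[[nm]]$method, values[[nm]]$group,
      alts[1], .fmt(v[1], rd_v), alts[2], .fmt(v[2], rd_v),
      preferred_alternative(values[[nm]])))
  }
  if (!is.null(sa$exclusion)) {
    v <- sa$exclusion$without$values
    lines <- c(lines, "", sprintf(
      "SA excluding '%s': value %s = %s, %s = %s -> preferred: %s",
      sa$exclusion$excluded, alts[1], .fmt(v[1], rd_v), alts[2],
      .fmt(v[2], rd_v), preferred_alternative(sa$exclusion$without)))
  }
  if (!is.null(sa$swap))
    lines <- c(lines, sprintf(
      "SA weight-method swap: preferred %s vs %s -> agreement: %s",
      sa$swap$preferred[1], sa$swap$preferred[2], sa$swap$agreement))
  if (!is.null(curve))
    lines <- c(lines, "", sprintf(
      "PSA: unconditional P(%s preferred) = %s over %d draws",
      alts[1], .fmt(attr(curve, "unconditional"), 4), nrow(psa_draws)))
  paths$summary <- file.path(cfg$out_dir, "summary.txt")
  writeLines(lines, paths$summary)

  if (!is.null(psa_draws)) {
    paths$draws <- file.path(cfg$out_dir, "psa_draws.csv")
    utils::write.csv(as.data.frame(psa_draws), paths$draws,
                     row.names = FALSE, quote = FALSE)
    paths$cmac <- file.path(cfg$out_dir, "cmac.csv")
    write_cmac(curve, paths$cmac)
  }

  inputs <- c(cfg$performance, unlist(cfg$weights), unlist(cfg$dce))
  manifest <- list(
    package = "icmcda",
    version = as.character(utils::packageVersion("icmcda")),
    criteria = if (is.null(cfg$criteria)) "core" else cfg$criteria,
    seeds = list(psa = if (!is.null(cfg$psa)) cfg$psa$seed else NULL),
    flags = list(include_costs_in_value =
                   is.null(cfg$psa$include_costs_in_value) ||
                   isTRUE(cfg$psa$include_costs_in_value)),
    inputs = as.list(tools::md5sum(inputs)))
  paths$manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  paths
}
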