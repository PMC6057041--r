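#' Outcome criteria and criteria sets
#'
#' An integrated-care MCDA evaluates two care alternatives against a set of
#' outcome criteria organised along the Triple Aim: health & well-being,
#' experience of care, and costs. Each criterion carries an explicit scale
#' range (worst and best attainable raw score) and a direction: `benefit`
#' criteria improve as the raw score rises, `cost` criteria worsen.
#'
#' A criteria set is represented as a data frame of class `criteria_set` with
#' columns `id`, `label`, `aim`, `direction`, `worst`, `best`, `set_tag`.
#'
#' @name criteria
NULL

.AIMS <- c("health_wellbeing", "experience", "costs")
.DIRECTIONS <- c("benefit", "cost")
.PROGRAMME_TAGS <- c("population_health_mgmt", "frail_elderly",
                     "palliative_oncology", "multi_life_domains")

#' Construct a single criterion record
#'
#' @param id Short unique token identifying the criterion.
#' @param label Human-readable display text.
#' @param aim Triple-Aim category: `"health_wellbeing"`, `"experience"` or
#'   `"costs"`.
#' @param direction `"benefit"` (higher raw score is better) or `"cost"`
#'   (higher raw score is worse).
#' @param worst,best Raw-scale endpoints; must differ. For cost-direction
#'   criteria `worst` is numerically the larger value.
#' @param set_tag `"core"` or one of the programme-type tags.
#' @return One-row data frame.
#' @keywords internal
criterion <- function(id, label, aim, direction, worst, best, set_tag = "core") {
  aim <- match.arg(aim, .AIMS)
  direction <- match.arg(direction, .DIRECTIONS)
  set_tag <- match.arg(set_tag, c("core", .PROGRAMME_TAGS))
  stopifnot(is.numeric(worst), is.numeric(best))
  if (worst == best) stop("criterion '", id, "': scale endpoints must differ")
  data.frame(id = id, label = label, aim = aim, direction = direction,
             worst = worst, best = best, set_tag = set_tag,
             stringsAsFactors = FALSE)
}

#' Assemble and validate a criteria set
#'
#' @param criteria Data frame with one row per criterion (columns `id`,
#'   `label`, `aim`, `direction`, `worst`, `best`, `set_tag`).
#' @param name Name of the set.
#' @return A `criteria_set` object.
#' @export
criteria_set <- function(criteria, name = "custom") {
  obj <- structure(criteria, class = c("criteria_set", "data.frame"))
  attr(obj, "set_name") <- name
  validate_criteria_set(obj)
  obj
}

#' Validate a criteria set
#'
#' Checks id uniqueness, well-formed scale ranges, and declared aims and
#' directions. Called by every constructor; exported so hand-edited catalogs
#' can be checked too.
#'
#' @param set A `criteria_set`.
#' @return The set, invisibly, if valid; otherwise an error.
#' @export
validate_criteria_set <- function(set) {
  required <- c("id", "label", "aim", "direction", "worst", "best", "set_tag")
  missing_cols <- setdiff(required, names(set))
  if (length(missing_cols))
    stop("criteria set is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(set$id))
    stop("duplicate criterion ids: ",
         paste(unique(set$id[duplicated(set$id)]), collapse = ", "))
  if (!all(set$aim %in% .AIMS))
    stop("unknown aim values: ", paste(setdiff(set$aim, .AIMS), collapse = ", "))
  if (!all(set$direction %in% .DIRECTIONS))
    stop("unknown directions: ", paste(setdiff(set$direction, .DIRECTIONS), collapse = ", "))
  if (any(set$worst == set$best))
    stop("degenerate scale range for: ",
         paste(set$id[set$worst == set$best], collapse = ", "))
  invisible(set)
}

#' Core outcome set for integrated-care evaluation
#'
#' The eight core criteria measured in every evaluation: five health &
#' well-being outcomes, two experience outcomes, and total health and social
#' care costs. Only costs run in the cost direction. Scale ranges follow the
#' worked-example performance ranges; the currency bounds of the cost
#' criterion are configurable because mean costs differ by country.
#'
#' @param cost_worst,cost_best Currency bounds of the total-cost criterion
#'   (worst = highest cost).
#' @return A `criteria_set` of 8 criteria.
#' @examples
#' core <- build_core_set()
#' subset(core, aim == "experience")$id
#' @export
build_core_set <- function(cost_worst = 8500, cost_best = 5500) {
  if (!(cost_worst > cost_best))
    stop("cost criterion: worst bound must exceed best bound (costs are bad)")
  rows <- rbind(
    criterion("physical_functioning", "Physical functioning",
              "health_wellbeing", "benefit", 0, 100),
    criterion("psychological_wellbeing", "Psychological well-being",
              "health_wellbeing", "benefit", 0, 100),
    criterion("social_participation", "Social participation & relationships",
              "health_wellbeing", "benefit", 0, 4),
    criterion("resilience", "Resilience",
              "health_wellbeing", "benefit", 1, 5),
    criterion("enjoyment_of_life", "Enjoyment of life",
              "health_wellbeing", "benefit", 0, 4),
    criterion("person_centeredness", "Person-centeredness",
              "experience", "benefit", 1, 4),
    criterion("continuity_of_care", "Continuity of care",
              "experience", "benefit", 1, 5),
    criterion("total_costs", "Total health and social care costs",
              "costs", "cost", cost_worst, cost_best)
  )
  criteria_set(rows, name = "core")
}

# Programme-type-specific supplements. Concept lists follow the published
# outcome catalog; numeric scales for these are not fixed there, so each
# defaults to a declared 0-100 scale (overridable by editing the catalog).
.programme_supplements <- function() {
  ben <- function(id, label, aim, tag) criterion(id, label, aim, "benefit", 0, 100, tag)
  cst <- function(id, label, aim, tag) criterion(id, label, aim, "cost", 100, 0, tag)
  rbind(
    ben("activation_engagement", "Activation & engagement",
        "health_wellbeing", "population_health_mgmt"),
    cst("burden_of_medication", "Burden of medication",
        "experience", "population_health_mgmt"),
    cst("acs_hospital_admissions", "Ambulatory care sensitive hospital admissions",
        "costs", "population_health_mgmt"),
    cst("hospital_readmissions", "Hospital re-admissions",
        "costs", "population_health_mgmt"),
    ben("autonomy", "Autonomy",
        "health_wellbeing", "frail_elderly"),
    cst("burden_informal_caregiving", "Burden of informal caregiving",
        "experience", "frail_elderly"),
    ben("living_at_home", "Living at home",
        "costs", "frail_elderly"),
    cst("falls_er_admissions", "Falls leading to ER or hospital admissions",
        "costs", "frail_elderly"),
    cst("mortality", "Mortality",
        "health_wellbeing", "palliative_oncology"),
    cst("pain_symptoms", "Pain and other symptoms",
        "health_wellbeing", "palliative_oncology"),
    ben("compassionate_care", "Compassionate care",
        "experience", "palliative_oncology"),
    ben("timely_access", "Timely access to care",
        "experience", "palliative_oncology"),
    ben("preferred_place_death", "Preferred place of death",
        "experience", "palliative_oncology"),
    ben("self_sufficiency", "Self-sufficiency",
        "health_wellbeing", "multi_life_domains"),
    cst("burden_informal_caregiving_mld", "Burden of informal caregiving",
        "experience", "multi_life_domains"),
    cst("justice_contacts", "Justice contacts",
        "costs", "multi_life_domains")
  )
}

#' Programme-type-specific outcome set
#'
#' Extends the core set with the supplementary outcomes defined for one of
#' the four programme types (population health management, frail elderly,
#' palliative and oncology, problems in multiple life domains). The
#' supplements' numeric scales are catalog defaults (0-100), since only the
#' outcome concepts are fixed; override by editing the exported catalog.
#'
#' @param tag One of `"population_health_mgmt"`, `"frail_elderly"`,
#'   `"palliative_oncology"`, `"multi_life_domains"`.
#' @param ... Passed to [build_core_set()] (cost bounds).
#' @return A `criteria_set` containing the core criteria followed by the
#'   programme-type supplements.
#' @export
build_programme_set <- function(tag, ...) {
  if (length(tag) != 1 || !tag %in% .PROGRAMME_TAGS)
    stop("unknown programme type '", paste(tag, collapse = ","),
         "'; valid tags: ", paste(.PROGRAMME_TAGS, collapse = ", "))
  core <- build_core_set(...)
  extra <- .programme_supplements()
  extra <- extra[extra$set_tag == tag, , drop = FALSE]
  criteria_set(rbind(as.data.frame(core), extra), name = tag)
}

#' Read / write a criteria catalog
#'
#' Catalogs are delimited text with one record per criterion
#' (`id,label,aim,direction,worst,best,set_tag`); round-trips losslessly.
#'
#' @param path File path.
#' @param set A `criteria_set` (for writing).
#' @return `read_criteria()` returns a `criteria_set`.
#' @export
read_criteria <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  criteria_set(df, name = sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_criteria
#' @export
write_criteria <- function(set, path) {
  validate_criteria_set(set)
  utils::write.csv(as.data.frame(set), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.criteria_set <- function(x, ...) {
  cat("Criteria set '", attr(x, "set_name"), "': ", nrow(x), " criteria (",
      sum(x$direction == "cost"), " cost-direction)\n", sep = "")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
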