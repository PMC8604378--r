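#' Construct a study-effect table
#'
#' Builds and validates the per-study data frame used throughout the package:
#' one row per study with a log odds ratio `y`, its within-study standard
#' error `sigma`, and descriptive metadata. Optionally carries the raw 2x2
#' counts (`a`, `b`: events/non-events in the comorbidity arm; `c`, `d`:
#' events/non-events in the monoinfection arm), in which case `y` and `sigma`
#' must agree with the values recomputed from the counts.
#'
#' @param study_label character vector of unique study labels.
#' @param y numeric vector of log odds ratios.
#' @param sigma numeric vector of within-study standard errors (> 0).
#' @param year,country,sample_size,outcome_type optional per-study metadata;
#'   `outcome_type` must be one of `"mortality"`, `"hospitalization"`,
#'   `"severe_critical"` (or `NA`).
#' @param a,b,c,d optional 2x2 counts (all four or none).
#' @param correction zero-cell rule used when checking counts against
#'   `y`/`sigma`; see [log_odds_ratio()].
#' @return A `data.frame` with class `study_effects`.
#' @seealso [comorbidity_dataset()], [log_odds_ratio()]
#' @export
study_effects <- function(study_label, y, sigma,
                          year = NA_integer_, country = NA_character_,
                          sample_size = NA_integer_, outcome_type = NA_character_,
                          a = NULL, b = NULL, c = NULL, d = NULL,
                          correction = "haldane") {
  k <- length(y)
  stopifnot(length(study_label) == k, length(sigma) == k)
  if (anyDuplicated(study_label))
    stop("study labels must be unique within a dataset", call. = FALSE)
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("all sigma values must be finite and > 0", call. = FALSE)
  ok <- is.na(outcome_type) |
    outcome_type %in% c("mortality", "hospitalization", "severe_critical")
  if (!all(ok))
    stop("invalid outcome_type: ", paste(unique(outcome_type[!ok]), collapse = ", "),
         call. = FALSE)
  df <- data.frame(
    study_label = as.character(study_label),
    year = rep_len(as.integer(year), k),
    country = rep_len(as.character(country), k),
    sample_size = rep_len(as.integer(sample_size), k),
    outcome_type = rep_len(as.character(outcome_type), k),
    y = as.numeric(y), sigma = as.numeric(sigma),
    stringsAsFactors = FALSE
  )
  counts <- list(a = a, b = b, c = c, d = d)
  given <- !vapply(counts, is.null, logical(1))
  if (any(given)) {
    if (!all(given))
      stop("either all four counts (a, b, c, d) or none must be given",
           call. = FALSE)
    df$a <- as.integer(a); df$b <- as.integer(b)
    df$c <- as.integer(c); df$d <- as.integer(d)
    eff <- log_odds_ratio(df$a, df$b, df$c, df$d, correction = correction)
    if (max(abs(eff$y - df$y)) > 1e-12 || max(abs(eff$sigma - df$sigma)) > 1e-12)
      stop("y/sigma do not match values recomputed from counts", call. = FALSE)
  }
  class(df) <- c("study_effects", "data.frame")
  df
}

#' Construct a named meta-analysis dataset
#'
#' Groups a [study_effects()] table under a comorbidity name, forming the unit
#' on which [dl_meta()], [bayes_meta()] and [bias_report()] operate.
#'
#' @param name dataset name, e.g. `"diabetes"`.
#' @param studies a `study_effects` data frame (or arguments coercible by
#'   [study_effects()]).
#' @return An object of class `comorbidity_dataset`: a list with elements
#'   `name` and `studies`.
#' @export
comorbidity_dataset <- function(name, studies) {
  if (!inherits(studies, "study_effects"))
    stop("`studies` must be a study_effects data frame", call. = FALSE)
  if (nrow(studies) < 1)
    stop("a dataset needs at least one study", call. = FALSE)
  structure(list(name = as.character(name), studies = studies),
            class = "comorbidity_dataset")
}

#' @export
print.comorbidity_dataset <- function(x, ...) {
  cat(sprintf("<comorbidity_dataset> %s: %d studies\n", x$name, nrow(x$studies)))
  print(as.data.frame(x$studies)[, c("study_label", "year", "y", "sigma")],
        row.names = FALSE)
  invisible(x)
}

# Extract (y, sigma) from a comorbidity_dataset, study_effects frame or
# plain vectors; used by every engine entry point.
resolve_effects <- function(x, sigma = NULL) {
  if (inherits(x, "comorbidity_dataset")) x <- x$studies
  if (is.data.frame(x)) {
    if (!all(c("y", "sigma") %in% names(x)))
      stop("data frame input needs columns `y` and `sigma`", call. = FALSE)
    return(list(y = x$y, sigma = x$sigma,
                labels = if ("study_label" %in% names(x)) x$study_label
                         else paste0("study_", seq_len(nrow(x)))))
  }
  if (is.null(sigma))
    stop("`sigma` must be supplied when `x` is a numeric vector", call. = FALSE)
  if (length(x) != length(sigma))
    stop("`y` and `sigma` lengths differ", call. = FALSE)
  list(y = as.numeric(x), sigma = as.numeric(sigma),
       labels = paste0("study_", seq_along(x)))
}

check_effects <- function(eff, min_k = 1, caller = "this analysis") {
  if (length(eff$y) < min_k)
    stop(sprintf("%s needs at least %d stud%s", caller, min_k,
                 if (min_k == 1) "y" else "ies"), call. = FALSE)
  if (any(!is.finite(eff$y)))
    stop("non-finite log odds ratio", call. = FALSE)
  if (any(!is.finite(eff$sigma)) || any(eff$sigma <= 0))
    stop("all sigma values must be finite and > 0", call. = FALSE)
  eff
}

# Per-study effects transcribed from the published model-summary table
# (five comorbidity groups of PLHIV versus HIV monoinfection).  `vi` is the
# within-study variance as printed; although the source table labels that
# column "sigma_i", for every row ((ci_high - ci_low) / (2 * 1.96))^2 equals
# the printed value to two decimals, identifying it as a variance.  `sigma`
# is therefore sqrt(vi).  The respiratory-disease Isernia row prints y = 0.29,
# inconsistent with its own interval (-1.13 to 5.71) whose midpoint is 2.29;
# with y = 2.29 the row reproduces that interval exactly and the group's
# published Q = 2.29 (df = 5, p = 0.807) exactly, so 2.29 is stored.
table2_rows <- function() {
  tx <- "
comorbidity|study_label|year|country|sample_size|outcome_type|y|ci_low|ci_high|vi
diabetes|Bhaskaran et al.|2021|UK|27480|mortality|3.63|2.15|5.11|0.57
diabetes|Boulle et al.|2020|South Africa|3978|mortality|2.26|1.88|2.64|0.04
diabetes|Ceballos et al.|2020|Chile|36|mortality|2.20|-0.65|5.04|2.11
diabetes|Dandachi et al.|2020|US|286|hospitalization|1.14|0.31|1.96|0.18
diabetes|Etienne et al.|2020|France|54|severe_critical|3.91|0.84|6.98|2.45
diabetes|Isernia et al.|2020|France|30|hospitalization|2.93|-0.16|6.03|2.49
diabetes|Meyerowitz et al.|2020|US|36|hospitalization|0.73|-1.21|2.68|0.98
diabetes|Pujari et al.|2021|India|86|severe_critical|1.53|-0.11|3.17|0.70
diabetes|Vizcarra et al.|2020|Spain|51|severe_critical|-0.47|-2.86|1.92|1.48
hypertension|Bhaskaran et al.|2021|UK|27480|mortality|3.02|1.55|4.50|0.57
hypertension|Ceballos et al.|2020|Chile|36|mortality|2.20|-0.42|4.81|1.78
hypertension|Dandachi et al.|2020|US|286|hospitalization|1.08|0.36|1.80|0.13
hypertension|Etienne et al.|2020|France|54|severe_critical|1.86|0.40|3.32|0.55
hypertension|Isernia et al.|2020|France|30|hospitalization|2.25|-0.84|5.34|2.49
hypertension|Meyerowitz et al.|2020|US|36|hospitalization|0.04|-1.73|1.81|0.82
hypertension|Pujari et al.|2021|India|86|severe_critical|1.56|0.16|2.96|0.51
hypertension|Vizcarra et al.|2020|Spain|51|severe_critical|0.37|-1.14|1.88|0.59
cardiovascular_disease|Ceballos et al.|2020|Chile|36|mortality|3.30|0.23|6.36|2.44
cardiovascular_disease|Dandachi et al.|2020|US|286|hospitalization|1.95|0.81|3.10|0.34
cardiovascular_disease|Etienne et al.|2020|France|54|severe_critical|1.61|0.27|2.95|0.47
cardiovascular_disease|Isernia et al.|2020|France|30|hospitalization|1.84|-1.52|5.19|2.94
cardiovascular_disease|Meyerowitz et al.|2020|US|36|hospitalization|2.40|-0.78|5.57|2.63
cardiovascular_disease|Vizcarra et al.|2020|Spain|51|severe_critical|-0.47|-2.33|1.39|0.90
respiratory_disease|Ceballos et al.|2020|Chile|36|mortality|0.75|-2.89|4.38|3.44
respiratory_disease|Dandachi et al.|2020|US|286|hospitalization|1.58|0.67|2.50|0.22
respiratory_disease|Etienne et al.|2020|France|54|severe_critical|1.20|-0.88|3.29|1.13
respiratory_disease|Isernia et al.|2020|France|30|hospitalization|2.29|-1.13|5.71|3.04
respiratory_disease|Meyerowitz et al.|2020|US|36|hospitalization|0.22|-2.14|2.58|1.45
respiratory_disease|Vizcarra et al.|2020|Spain|51|severe_critical|0.22|-2.29|2.74|1.65
chronic_kidney_disease|Bhaskaran et al.|2021|UK|27480|mortality|3.74|2.20|5.27|0.61
chronic_kidney_disease|Ceballos et al.|2020|Chile|36|mortality|2.20|-0.65|5.04|2.11
chronic_kidney_disease|Dandachi et al.|2020|US|286|hospitalization|1.58|0.67|2.50|0.22
chronic_kidney_disease|Etienne et al.|2020|France|54|severe_critical|3.46|0.33|6.60|2.56
chronic_kidney_disease|Meyerowitz et al.|2020|US|36|hospitalization|0.22|-2.14|2.58|1.45"
  df <- read.csv(text = tx, sep = "|", strip.white = TRUE,
                 stringsAsFactors = FALSE)
  df$sigma <- sqrt(df$vi)
  df
}

#' Embedded per-study evidence table
#'
#' The five comorbidity datasets (diabetes, hypertension, cardiovascular
#' disease, respiratory disease, chronic kidney disease) with each study's
#' log odds ratio of severe COVID-19 outcome (comorbidity group versus HIV
#' monoinfection) and its within-study standard error, transcribed from the
#' published model-summary table. Every downstream module consumes these.
#'
#' Each `studies` table carries, besides the standard columns, the published
#' per-study 95% CI bounds (`ci_low`, `ci_high`) and the printed
#' within-study variance `vi` (`sigma = sqrt(vi)`; the source table labels
#' the variance column "sigma_i", but it squares with the printed CIs only
#' as a variance).
#'
#' @return Named list of five [comorbidity_dataset()] objects, in the order
#'   diabetes (9 studies), hypertension (8), cardiovascular_disease (6),
#'   respiratory_disease (6), chronic_kidney_disease (5).
#' @examples
#' fix <- table2_fixture()
#' fix$diabetes$studies$y[1]        # 3.63 (largest cohort, mortality)
#' nrow(fix$chronic_kidney_disease$studies)
#' @export
table2_fixture <- function() {
  df <- table2_rows()
  split_datasets(df)
}

# One comorbidity_dataset per distinct comorbidity value, original order kept.
split_datasets <- function(df) {
  out <- list()
  for (nm in unique(df$comorbidity)) {
    sub <- df[df$comorbidity == nm, , drop = FALSE]
    st <- study_effects(sub$study_label, sub$y, sub$sigma,
                        year = sub$year, country = sub$country,
                        sample_size = sub$sample_size,
                        outcome_type = sub$outcome_type,
                        a = sub$a, b = sub$b, c = sub$c, d = sub$d)
    extra <- intersect(c("ci_low", "ci_high", "vi"), names(sub))
    for (e in extra) st[[e]] <- sub[[e]]
    out[[nm]] <- comorbidity_dataset(nm, st)
  }
  out
}

effects_cols <- c("comorbidity", "study_label", "year", "country",
                  "sample_size", "outcome_type", "log_or", "se")
counts_cols <- c("comorbidity", "study_label", "events_exposed",
                 "nonevents_exposed", "events_comparator",
                 "nonevents_comparator")

#' Read meta-analysis datasets from CSV
#'
#' Two schemas are supported. `"effects"` expects precomputed log odds
#' ratios (columns `comorbidity, study_label, year, country, sample_size,
#' outcome_type, log_or, se`); `"counts"` expects raw 2x2 counts (columns
#' `comorbidity, study_label, events_exposed, nonevents_exposed,
#' events_comparator, nonevents_comparator`), from which effects are
#' recomputed via [log_odds_ratio()]. One dataset is returned per distinct
#' comorbidity value, preserving file order.
#'
#' @param path CSV file path (UTF-8, comma-separated, header row).
#' @param schema `"effects"` or `"counts"`.
#' @param correction zero-cell rule for the counts schema.
#' @return Named list of [comorbidity_dataset()] objects.
#' @export
read_studies <- function(path, schema = c("effects", "counts"),
                         correction = "haldane") {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- if (schema == "effects") effects_cols else counts_cols
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("schema '", schema, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (schema == "effects") {
    bad <- which(!is.finite(df$se) | df$se <= 0)
    if (length(bad))
      stop("non-positive or missing se at row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    df$y <- df$log_or
    df$sigma <- df$se
  } else {
    eff <- log_odds_ratio(df$events_exposed, df$nonevents_exposed,
                          df$events_comparator, df$nonevents_comparator,
                          correction = correction)
    df$a <- df$events_exposed; df$b <- df$nonevents_exposed
    df$c <- df$events_comparator; df$d <- df$nonevents_comparator
    df$y <- eff$y
    df$sigma <- eff$sigma
    if (is.null(df$sample_size))
      df$sample_size <- df$a + df$b + df$c + df$d
    if (is.null(df$year)) df$year <- NA_integer_
    if (is.null(df$country)) df$country <- NA_character_
    if (is.null(df$outcome_type)) df$outcome_type <- NA_character_
  }
  split_datasets(df)
}

#' Write meta-analysis datasets to CSV
#'
#' Inverse of [read_studies()] for the effects schema (numeric fields are
#' written with 17 significant digits so a round-trip is lossless) or, when
#' all studies carry counts, for the counts schema.
#'
#' @param datasets a single [comorbidity_dataset()] or a list of them.
#' @param path output CSV path.
#' @param schema `"effects"` or `"counts"`.
#' @return `path`, invisibly.
#' @export
write_studies <- function(datasets, path, schema = c("effects", "counts")) {
  schema <- match.arg(schema)
  if (inherits(datasets, "comorbidity_dataset")) datasets <- list(datasets)
  rows <- lapply(datasets, function(ds) {
    st <- as.data.frame(ds$studies)
    if (schema == "effects") {
      data.frame(comorbidity = ds$name, study_label = st$study_label,
                 year = st$year, country = st$country,
                 sample_size = st$sample_size, outcome_type = st$outcome_type,
                 log_or = sprintf("%.17g", st$y), se = sprintf("%.17g", st$sigma),
                 stringsAsFactors = FALSE)
    } else {
      if (!all(c("a", "b", "c", "d") %in% names(st)))
        stop("counts schema requires 2x2 counts on every study", call. = FALSE)
      data.frame(comorbidity = ds$name, study_label = st$study_label,
                 events_exposed = st$a, nonevents_exposed = st$b,
                 events_comparator = st$c, nonevents_comparator = st$d,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
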