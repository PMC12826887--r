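# Event classification from ICD codes, outcome derivation with right
# censoring, exclusion accounting. The ICD-9/ICD-10 category map ships as a
# versioned plain-text resource (inst/extdata/icd_categories.tsv).

#' Load the ICD category mapping
#'
#' One row per listed code token; ranges are kept as printed (e.g.
#' `I21-25`, `401-405`) and expanded to prefix sets at match time.
#'
#' @param path optional path to an alternative mapping TSV with columns
#'   `category`, `icd_version`, `code`.
#' @return data.frame mapping.
#' @export
icd_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "icd_categories.tsv", package = "ppgrisk")
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "integer", "character"))
}

# expand a printed token into its prefix set:
#   "I21-25" / "I21-I23" -> I21..I25 ; "39-44" -> 39..44 ; plain code -> itself
.expand_token <- function(token) {
  token <- gsub("\\.", "", toupper(trimws(token)))
  if (!grepl("-", token)) return(token)
  parts <- strsplit(token, "-")[[1]]
  a <- parts[1]; b <- parts[2]
  letter <- sub("^([A-Z]?).*$", "\\1", a)
  num_a <- as.integer(sub("^[A-Z]?", "", a))
  num_b <- as.integer(sub("^[A-Z]?", "", b))
  width <- nchar(sub("^[A-Z]?", "", a))
  sprintf(paste0("%s%0", width, "d"), letter, num_a:num_b)
}

#' Classify an ICD code into outcome categories
#'
#' Matching is by listed prefix: a code belongs to a category when any of
#' the category's (range-expanded) tokens is a prefix of the code. A code
#' may satisfy several categories (every MI code is also CHD and CVD).
#'
#' @param code ICD code string (dots ignored, case-insensitive).
#' @param icd_version 9 or 10.
#' @param map mapping data.frame from [icd_map()].
#' @return character vector of matching categories (possibly empty).
#' @export
classify_icd <- function(code, icd_version, map = icd_map()) {
  if (!icd_version %in% c(9, 10)) stop("unknown icd_version: ", icd_version)
  code <- gsub("\\.", "", toupper(trimws(code)))
  if (!nzchar(code)) stop("empty ICD code")
  m <- map[map$icd_version == icd_version, ]
  hit <- vapply(split(m$code, m$category), function(tokens) {
    prefixes <- unlist(lapply(tokens, .expand_token))
    any(startsWith(code, prefixes))
  }, logical(1))
  names(hit)[hit]
}

#' Derive per-category outcome rows for one participant
#'
#' Time to event is `min(first qualifying hospitalization, death, loss to
#' follow-up, administrative horizon) - baseline`, in years; the event
#' indicator is 1 only when that minimum is the qualifying cause. Events are
#' administratively censored `horizon_years` after baseline; mortality is
#' censored at the fixed calendar `mortality_cutoff` when supplied. A
#' qualifying hospitalization before baseline marks the participant
#' prevalent: no outcome rows are produced (exclusion upstream). Fatal
#' qualifying events without prior hospitalization count for the death
#' outcomes only, unless `fatal_as_event = TRUE`.
#'
#' @param events data.frame with columns `icd_version`, `code`, `date`
#'   (Date), hospitalizations for one participant.
#' @param baseline_date Date of initial assessment.
#' @param death_date Date of death or `NA`.
#' @param death_codes character vector of primary-cause ICD-10 codes on the
#'   death record (empty if none).
#' @param lost_date Date lost to follow-up or `NA`.
#' @param horizon_years administrative horizon for events (default 10).
#' @param mortality_cutoff calendar censoring Date for the death outcomes
#'   (default `NULL`: the event horizon is used).
#' @param category event category the hospitalization outcome targets
#'   (default "CVD").
#' @param fatal_as_event count a qualifying death with no prior
#'   hospitalization as a hospitalization event too (default FALSE).
#' @param map ICD mapping.
#' @return data.frame with rows `CVD_event`, `CVD_death`, `all_cause_death`
#'   and columns `category`, `time_years`, `event`; zero rows with the
#'   prevalent attribute set when excluded (see [is_prevalent()]).
#' @export
derive_outcome <- function(events, baseline_date, death_date = NA,
                           death_codes = character(), lost_date = NA,
                           horizon_years = 10, mortality_cutoff = NULL,
                           category = "CVD", fatal_as_event = FALSE,
                           map = icd_map()) {
  baseline_date <- as.Date(baseline_date)
  yrs <- function(d) as.numeric(difftime(as.Date(d), baseline_date,
                                         units = "days")) / 365.25
  qualifying <- function(ev) {
    if (is.null(ev) || !nrow(ev)) return(logical(0))
    vapply(seq_len(nrow(ev)), function(i)
      category %in% classify_icd(ev$code[i], ev$icd_version[i], map),
      logical(1))
  }
  q <- qualifying(events)
  ev_times <- if (any(q)) sort(yrs(events$date[q])) else numeric(0)
  if (length(ev_times) && ev_times[1] < 0) {
    out <- data.frame(category = character(0), time_years = numeric(0),
                      event = integer(0))
    return(structure(out, prevalent = TRUE))
  }
  t_death <- if (is.na(death_date)) Inf else yrs(death_date)
  t_lost <- if (is.na(lost_date)) Inf else yrs(lost_date)
  death_is_cvd <- length(death_codes) > 0 &&
    any(vapply(death_codes, function(cd)
      category %in% classify_icd(cd, 10, map), logical(1)))

  # hospitalization event outcome
  t_first <- if (length(ev_times)) ev_times[1] else Inf
  if (fatal_as_event && death_is_cvd) t_first <- min(t_first, t_death)
  t_ev <- min(t_first, t_death, t_lost, horizon_years)
  row_event <- data.frame(category = paste0(category, "_event"),
                          time_years = t_ev,
                          event = as.integer(t_ev == t_first & is.finite(t_first)))

  # death outcomes
  t_mort_cens <- if (is.null(mortality_cutoff)) horizon_years else
    yrs(mortality_cutoff)
  t_cens <- min(t_lost, t_mort_cens)
  died <- t_death <= t_cens
  t_dth <- min(t_death, t_cens)
  row_cvddeath <- data.frame(category = paste0(category, "_death"),
                             time_years = t_dth,
                             event = as.integer(died && death_is_cvd))
  row_acd <- data.frame(category = "all_cause_death", time_years = t_dth,
                        event = as.integer(died))
  out <- rbind(row_event, row_cvddeath, row_acd)
  structure(out, prevalent = FALSE)
}

#' Was the participant flagged prevalent?
#' @param outcome result of [derive_outcome()].
#' @return logical.
#' @export
is_prevalent <- function(outcome) isTRUE(attr(outcome, "prevalent"))

#' Cohort-flow ledger from exclusion stages
#'
#' Accepts either printed stage counts (`start` plus a vector of removals)
#' or a participant table with logical exclusion columns applied in order
#' (rows already removed by an earlier stage are not counted again, so
#' overlapping stages are handled).
#'
#' @param x either a single starting count (with `removed`) or a data.frame.
#' @param removed named numeric vector of per-stage removals (counts mode).
#' @param stages character vector of logical column names in table mode,
#'   applied in order.
#' @return data.frame of class `cohort_flow` with columns `stage`,
#'   `removed`, `remaining`; attribute `kept` holds the surviving row
#'   indices in table mode.
#' @export
apply_exclusions <- function(x, removed = NULL, stages = NULL) {
  if (is.numeric(x) && length(x) == 1) {
    stopifnot(!is.null(removed))
    rem <- x - cumsum(removed)
    if (any(rem < 0)) stop("negative remaining count in cohort flow")
    out <- data.frame(stage = c("recorded", names(removed)),
                      removed = c(0, unname(removed)),
                      remaining = c(x, rem))
  } else {
    stopifnot(is.data.frame(x), !is.null(stages))
    keep <- rep(TRUE, nrow(x))
    out <- data.frame(stage = "recorded", removed = 0, remaining = nrow(x))
    for (s in stages) {
      drop <- keep & as.logical(x[[s]])
      drop[is.na(drop)] <- FALSE
      keep <- keep & !drop
      out <- rbind(out, data.frame(stage = s, removed = sum(drop),
                                   remaining = sum(keep)))
    }
    attr(out, "kept") <- which(keep)
  }
  # ledger conservation
  stopifnot(sum(out$removed) + out$remaining[nrow(out)] == out$remaining[1])
  class(out) <- c("cohort_flow", "data.frame")
  out
}

#' @export
print.cohort_flow <- function(x, ...) {
  cat("<cohort_flow>\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
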