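#' Default CSV dialect for event tables
#'
#' BORIS-style exports vary in column naming; a dialect maps logical fields to
#' the columns of a concrete file. Times are stored as seconds from trial
#' start; `time_unit` rescales on read ("s" or "min").
#'
#' @param trial_id,individual_id,time,from_zone,to_zone,flag Column names for
#'   transition tables.
#' @param start,end Column names for feeding (state event) tables.
#' @param time_unit `"s"` or `"min"`.
#' @param sep Field delimiter.
#' @return A list of class `event_dialect`.
#' @export
event_dialect <- function(trial_id = "trial_id", individual_id = "subject",
                          time = "time_s", from_zone = "from_zone",
                          to_zone = "to_zone", flag = "flag",
                          start = "start_s", end = "end_s",
                          time_unit = c("s", "min"), sep = ",") {
  time_unit <- match.arg(time_unit)
  structure(list(trial_id = trial_id, individual_id = individual_id,
                 time = time, from_zone = from_zone, to_zone = to_zone,
                 flag = flag, start = start, end = end,
                 time_unit = time_unit, sep = sep),
            class = "event_dialect")
}

.time_factor <- function(dialect) if (dialect$time_unit == "min") 60 else 1

.event_flags <- c("normal", "pretrial_escape", "startle")

.read_table <- function(source, dialect) {
  if (is.data.frame(source)) return(source)
  utils::read.csv(source, sep = dialect$sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
}

.require_columns <- function(tab, cols) {
  missing <- setdiff(unlist(cols), names(tab))
  if (length(missing))
    stop("format error: missing column(s): ", paste(missing, collapse = ", "))
}

#' Read zone-transition events
#'
#' Reads a delimited event table, maps columns through the dialect, validates
#' every row against the zone graph and trial duration, and returns events
#' sorted by trial and time (stable within ties, preserving file order — the
#' source's time resolution is taken as authoritative for ordering).
#'
#' @param source File path or data frame.
#' @param dialect An [event_dialect()].
#' @param graph A [zone_graph()] giving the admissible zone set.
#' @param trial_duration Trial length in seconds.
#' @return Data frame with columns `trial_id`, `individual_id`, `time`,
#'   `from_zone`, `to_zone`, `flag`.
#' @export
read_transition_events <- function(source, dialect = event_dialect(),
                                   graph = default_zone_graph(),
                                   trial_duration = 2400) {
  tab <- .read_table(source, dialect)
  .require_columns(tab, dialect[c("trial_id", "individual_id", "time",
                                  "from_zone", "to_zone")])
  n <- nrow(tab)
  ev <- data.frame(
    trial_id = as.character(tab[[dialect$trial_id]]),
    individual_id = as.character(tab[[dialect$individual_id]]),
    time = suppressWarnings(as.numeric(tab[[dialect$time]])) * .time_factor(dialect),
    from_zone = suppressWarnings(as.integer(tab[[dialect$from_zone]])),
    to_zone = suppressWarnings(as.integer(tab[[dialect$to_zone]])),
    flag = if (dialect$flag %in% names(tab)) as.character(tab[[dialect$flag]])
           else rep("normal", n),
    stringsAsFactors = FALSE
  )
  problems <- character(0)
  bad <- function(rows, what) {
    if (any(rows))
      problems <<- c(problems,
                     sprintf("row %d: %s", which(rows), what)[seq_len(min(sum(rows), 10))])
  }
  bad(is.na(ev$time), "unparsable time")
  bad(!is.na(ev$time) & (ev$time < 0 | ev$time > trial_duration),
      sprintf("time outside [0, %g]", trial_duration))
  bad(is.na(ev$from_zone) | is.na(ev$to_zone), "unparsable zone")
  bad(!is.na(ev$from_zone) & !(ev$from_zone %in% graph$zones), "from_zone outside zone set")
  bad(!is.na(ev$to_zone) & !(ev$to_zone %in% graph$zones), "to_zone outside zone set")
  bad(!is.na(ev$from_zone) & !is.na(ev$to_zone) & ev$from_zone == ev$to_zone,
      "from_zone equals to_zone")
  bad(!ev$flag %in% .event_flags, "unknown flag")
  if (length(problems))
    stop("invalid transition event rows:\n  ", paste(problems, collapse = "\n  "))
  dup <- duplicated(ev[c("trial_id", "individual_id", "time", "from_zone", "to_zone")])
  if (any(dup))
    warning(sum(dup), " duplicate event row(s) kept")
  ev[order(ev$trial_id, ev$time), , drop = FALSE] -> ev
  rownames(ev) <- NULL
  ev
}

#' Write zone-transition events
#'
#' Lossless inverse of [read_transition_events()] for the same dialect.
#'
#' @param events Validated event data frame.
#' @param path Output file path.
#' @param dialect An [event_dialect()].
#' @export
write_events <- function(events, path, dialect = event_dialect()) {
  out <- data.frame(
    events$trial_id, events$individual_id,
    events$time / .time_factor(dialect),
    events$from_zone, events$to_zone, events$flag,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  names(out) <- unlist(dialect[c("trial_id", "individual_id", "time",
                                 "from_zone", "to_zone", "flag")])
  utils::write.table(out, path, sep = dialect$sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Apply the exclusion rules to an event list
#'
#' Pre-trial escapes are removed entirely; startle/pushed transits are kept
#' (they still move the animal, so occupancy needs them) but marked ineligible
#' as following interactions via a `follow_eligible` column. Removal counts
#' are attached as attribute `filter_counts`.
#'
#' @param events Validated transition events.
#' @return Filtered events with a `follow_eligible` column.
#' @export
filter_events <- function(events) {
  pre <- events$flag == "pretrial_escape"
  out <- events[!pre, , drop = FALSE]
  out$follow_eligible <- out$flag != "startle"
  rownames(out) <- NULL
  attr(out, "filter_counts") <- c(pretrial_escape = sum(pre),
                                  startle = sum(!out$follow_eligible))
  out
}

#' Read feeding (state) events
#'
#' Feeding bouts at the food patch, with start and end times. Parsed and
#' summarized for the descriptive stage; the diffusion trait itself is
#' target-zone discovery, not feeding.
#'
#' @inheritParams read_transition_events
#' @return Data frame with columns `trial_id`, `individual_id`, `start`, `end`.
#' @export
read_feeding_events <- function(source, dialect = event_dialect(),
                                trial_duration = 2400) {
  tab <- .read_table(source, dialect)
  .require_columns(tab, dialect[c("trial_id", "individual_id", "start", "end")])
  fe <- data.frame(
    trial_id = as.character(tab[[dialect$trial_id]]),
    individual_id = as.character(tab[[dialect$individual_id]]),
    start = suppressWarnings(as.numeric(tab[[dialect$start]])) * .time_factor(dialect),
    end = suppressWarnings(as.numeric(tab[[dialect$end]])) * .time_factor(dialect),
    stringsAsFactors = FALSE
  )
  ok <- !is.na(fe$start) & !is.na(fe$end) & fe$start >= 0 &
    fe$start < fe$end & fe$end <= trial_duration
  if (!all(ok))
    stop("invalid feeding event rows: ",
         paste(which(!ok)[seq_len(min(10, sum(!ok)))], collapse = ", "))
  fe <- fe[order(fe$trial_id, fe$start), , drop = FALSE]
  rownames(fe) <- NULL
  fe
}

#' Write feeding events
#' @inheritParams write_events
#' @export
write_feeding_events <- function(events, path, dialect = event_dialect()) {
  out <- data.frame(events$trial_id, events$individual_id,
                    events$start / .time_factor(dialect),
                    events$end / .time_factor(dialect),
                    stringsAsFactors = FALSE)
  names(out) <- unlist(dialect[c("trial_id", "individual_id", "start", "end")])
  utils::write.table(out, path, sep = dialect$sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read collective metadata
#'
#' One row per collective member: trial id, collective type (`C` = all naive,
#' `S` = contains tutors), individual id, treatment (`control` or
#' `spirulina`).
#'
#' @inheritParams read_transition_events
#' @return Data frame with columns `trial_id`, `collective_type`,
#'   `individual_id`, `treatment`.
#' @export
read_collective_meta <- function(source, dialect = event_dialect()) {
  tab <- .read_table(source, dialect)
  .require_columns(tab, list("trial_id", "collective_type", "individual_id",
                             "treatment"))
  meta <- data.frame(trial_id = as.character(tab$trial_id),
                     collective_type = as.character(tab$collective_type),
                     individual_id = as.character(tab$individual_id),
                     treatment = as.character(tab$treatment),
                     stringsAsFactors = FALSE)
  if (!all(meta$collective_type %in% c("C", "S")))
    stop("collective_type must be 'C' or 'S'")
  if (!all(meta$treatment %in% c("control", "spirulina")))
    stop("treatment must be 'control' or 'spirulina'")
  bad <- unique(meta$trial_id[meta$collective_type == "C" &
                                meta$treatment == "spirulina"])
  if (length(bad))
    stop("C collectives cannot contain spirulina members: ",
         paste(bad, collapse = ", "))
  meta
}
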