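# Event-log ingest: parsing, validation, day filtering and count matrices.
#
# Two sampling protocols coexist in one log: all-occurrence records of
# affiliative/agonistic interactions, and instantaneous scan samples of
# proximity (sitting close / same branch). The two must never be pooled
# into one matrix because their units differ (events vs scans).

BEHAVIOURS <- c("physical_contact", "share", "agonistic", "sit_close", "same_branch")
SCAN_BEHAVIOURS <- c("sit_close", "same_branch")
RECORD_KINDS <- c("all_occurrence", "scan")

#' Construct an event log
#'
#' Bundles a group's individual attribute table and its time-stamped dyadic
#' interaction records, validating identities and the sampling-protocol
#' vocabulary.
#'
#' @param individuals Tibble/data frame with columns `id`, `sex` (`"F"`/`"M"`),
#'   `age_class` (`"juvenile"`/`"subadult"`), `kin_group` (integer or `NA`),
#'   `trained` (logical; the seeded demonstrator).
#' @param events Tibble/data frame with columns `day` (Date or ISO-8601
#'   string), `actor`, `receiver`, `behaviour` (one of `physical_contact`,
#'   `share`, `agonistic`, `sit_close`, `same_branch`), `record_kind`
#'   (`all_occurrence` or `scan`).
#' @param group_id Character label for the group.
#' @param excluded_days Dates already removed from the log (e.g. trial days).
#' @return An object of class `event_log`.
#' @export
event_log <- function(individuals, events, group_id = "group",
                      excluded_days = as.Date(character())) {
  individuals <- tibble::as_tibble(individuals)
  events <- tibble::as_tibble(events)
  req_ind <- c("id", "sex", "age_class", "kin_group", "trained")
  req_ev <- c("day", "actor", "receiver", "behaviour", "record_kind")
  miss <- setdiff(req_ind, names(individuals))
  if (length(miss)) abort(sprintf("attribute table is missing column(s): %s", toString(miss)))
  miss <- setdiff(req_ev, names(events))
  if (length(miss)) abort(sprintf("event table is missing column(s): %s", toString(miss)))

  individuals$id <- as.character(individuals$id)
  if (anyDuplicated(individuals$id)) abort("individual ids must be unique within a group")
  if (!all(individuals$sex %in% c("F", "M"))) abort("sex must be 'F' or 'M'")
  if (!all(individuals$age_class %in% c("juvenile", "subadult"))) {
    abort("age_class must be 'juvenile' or 'subadult'")
  }
  individuals$trained <- as.logical(individuals$trained)

  events$day <- as.Date(events$day)
  events$actor <- as.character(events$actor)
  events$receiver <- as.character(events$receiver)

  bad <- which(!(events$behaviour %in% BEHAVIOURS))
  if (length(bad)) {
    abort(sprintf("row %d: unknown behaviour '%s'; accepted categories: %s",
                  bad[1], events$behaviour[bad[1]], toString(BEHAVIOURS)))
  }
  bad <- which(!(events$record_kind %in% RECORD_KINDS))
  if (length(bad)) {
    abort(sprintf("row %d: unknown record_kind '%s'; accepted: %s",
                  bad[1], events$record_kind[bad[1]], toString(RECORD_KINDS)))
  }
  bad <- which(events$actor == events$receiver)
  if (length(bad)) {
    abort(sprintf("row %d: actor equals receiver ('%s')", bad[1], events$actor[bad[1]]))
  }
  ids <- individuals$id
  bad <- which(!(events$actor %in% ids) | !(events$receiver %in% ids))
  if (length(bad)) {
    abort(sprintf("row %d: unknown individual id '%s'", bad[1],
                  setdiff(c(events$actor[bad[1]], events$receiver[bad[1]]), ids)[1]))
  }
  # protocol consistency: proximity comes from scans, interactions from
  # all-occurrence sampling
  is_scan_behaviour <- events$behaviour %in% SCAN_BEHAVIOURS
  bad <- which(is_scan_behaviour & events$record_kind != "scan")
  if (length(bad)) abort(sprintf("row %d: proximity behaviours must have record_kind 'scan'", bad[1]))
  bad <- which(!is_scan_behaviour & events$record_kind != "all_occurrence")
  if (length(bad)) abort(sprintf("row %d: interaction behaviours must have record_kind 'all_occurrence'", bad[1]))

  structure(
    list(group_id = group_id, individuals = individuals, events = events,
         excluded_days = as.Date(excluded_days)),
    class = "event_log"
  )
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log '%s': %d individuals, %d events, %d excluded days>\n",
              x$group_id, nrow(x$individuals), nrow(x$events),
              length(x$excluded_days)))
  invisible(x)
}

#' Read an event log and attribute table from CSV
#'
#' @param path CSV of events with header
#'   `day,actor,receiver,behaviour,record_kind` (`day` ISO-8601).
#' @param attribute_path CSV of individuals with header
#'   `id,sex,age_class,kin_group,trained`.
#' @param group_id Group label attached to the log.
#' @return An [event_log()].
#' @export
read_event_log <- function(path, attribute_path, group_id = "group") {
  events <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(.default = readr::col_character(),
                                                    day = readr::col_date()))
  individuals <- readr::read_csv(attribute_path, show_col_types = FALSE,
                                 col_types = readr::cols(id = readr::col_character(),
                                                         sex = readr::col_character(),
                                                         age_class = readr::col_character(),
                                                         kin_group = readr::col_integer(),
                                                         trained = readr::col_logical()))
  event_log(individuals, events, group_id = group_id)
}

#' Write an event log back to CSV
#'
#' Emits the same dialect [read_event_log()] accepts.
#' @param log An [event_log()].
#' @param path,attribute_path Output CSV paths.
#' @return `log`, invisibly.
#' @export
write_event_log <- function(log, path, attribute_path) {
  readr::write_csv(log$events, path)
  readr::write_csv(log$individuals, attribute_path)
  invisible(log)
}

#' Drop events on excluded days
#'
#' Interaction data collected while diffusion trials were in session must be
#' excluded so the task itself cannot shape the social networks.
#'
#' @param log An [event_log()].
#' @param excluded Vector of dates to drop.
#' @return The filtered `event_log`, with `excluded_days` recorded.
#' @export
filter_days <- function(log, excluded) {
  excluded <- as.Date(excluded)
  keep <- !(log$events$day %in% excluded)
  log$events <- log$events[keep, , drop = FALSE]
  log$excluded_days <- sort(unique(c(log$excluded_days, excluded)))
  log
}

#' Aggregate events into a dyadic count matrix
#'
#' Cell (i, j) counts events with actor i and receiver j whose behaviour is
#' in `behaviours`. Undirected aggregation counts each record toward both
#' orientations (scan co-occurrences have no meaningful direction).
#' All-occurrence and scan records must not be pooled in one call.
#'
#' @param log An [event_log()].
#' @param behaviours Character subset of the behaviour vocabulary.
#' @param directed Count actor to receiver (`TRUE`) or symmetrically (`FALSE`).
#' @return Integer matrix with individual ids as dimnames.
#' @export
count_matrix <- function(log, behaviours, directed = TRUE) {
  if (!length(behaviours)) abort("`behaviours` must be a nonempty set")
  unknown <- setdiff(behaviours, BEHAVIOURS)
  if (length(unknown)) {
    abort(sprintf("unknown behaviour(s): %s; accepted: %s",
                  toString(unknown), toString(BEHAVIOURS)))
  }
  kinds <- unique(ifelse(behaviours %in% SCAN_BEHAVIOURS, "scan", "all_occurrence"))
  if (length(kinds) > 1) {
    abort("cannot pool all-occurrence and scan behaviours in one count matrix")
  }
  ids <- log$individuals$id
  n <- length(ids)
  M <- matrix(0L, n, n, dimnames = list(ids, ids))
  ev <- log$events[log$events$behaviour %in% behaviours, , drop = FALSE]
  if (nrow(ev)) {
    idx <- cbind(match(ev$actor, ids), match(ev$receiver, ids))
    tab <- table(factor(idx[, 1], levels = seq_len(n)),
                 factor(idx[, 2], levels = seq_len(n)))
    M <- M + matrix(as.integer(tab), n, n, dimnames = list(ids, ids))
    if (!directed) M <- M + t(M)
  }
  diag(M) <- 0L
  M
}
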