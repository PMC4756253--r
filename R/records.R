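# Patient records: blood-pressure log, medication schedules and intake
# log, adherence summaries, reminders, and file import/export. Persistence
# is a single JSON document per patient; timestamps are timezone-naive
# local times (single-user device semantics), stored as ISO-8601 and
# handled internally as UTC POSIXct for determinism.

parse_ts <- function(x, what = "timestamp") {
  if (inherits(x, "POSIXct")) return(as.POSIXct(format(x), tz = "UTC"))
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  if (any(is.na(out))) stopf("cannot parse %s: %s", what, x)
  out
}

iso_ts <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' Create an empty patient record store
#'
#' The store holds the blood-pressure log, medication schedules, the
#' medication-intake log and hospital-visit dates for one patient.
#'
#' @return An object of class `hma_store`.
#' @export
record_store <- function() {
  structure(list(
    bp = data.frame(timestamp = as.POSIXct(character(0), tz = "UTC"),
                    systolic = numeric(0), diastolic = numeric(0),
                    note = character(0), stringsAsFactors = FALSE),
    schedules = list(),
    intakes = data.frame(drug_name = character(0),
                         slot = as.POSIXct(character(0), tz = "UTC"),
                         taken = logical(0),
                         taken_at = as.POSIXct(character(0), tz = "UTC"),
                         stringsAsFactors = FALSE),
    visits = data.frame(due_at = as.POSIXct(character(0), tz = "UTC"),
                        label = character(0), stringsAsFactors = FALSE)
  ), class = "hma_store")
}

#' Append a blood-pressure reading
#'
#' @param store An [record_store()] object.
#' @param timestamp POSIXct or ISO-8601 string.
#' @param systolic,diastolic Pressures in mmHg (systolic > diastolic > 0).
#' @param note Optional free-text note.
#' @return The updated store.
#' @export
add_bp_record <- function(store, timestamp, systolic, diastolic, note = NA) {
  stopifnot(inherits(store, "hma_store"))
  if (!is_scalar_number(systolic) || !is_scalar_number(diastolic) ||
      diastolic <= 0 || systolic <= diastolic)
    stopf("blood pressure must satisfy systolic > diastolic > 0")
  store$bp <- rbind(store$bp, data.frame(
    timestamp = parse_ts(timestamp), systolic = systolic,
    diastolic = diastolic, note = as.character(note),
    stringsAsFactors = FALSE))
  store
}

#' Define a medication schedule
#'
#' @param drug_name Drug name.
#' @param dose_times Character vector of unique clock times (`"HH:MM"`);
#'   its length is the number of doses per day.
#' @param start_date,end_date Schedule activity window (Date or
#'   `"YYYY-MM-DD"`); `end_date` may be `NA` for an open-ended schedule.
#' @return An object of class `hma_schedule`.
#' @export
medication_schedule <- function(drug_name, dose_times, start_date,
                                end_date = NA) {
  if (!all(grepl("^\\d{2}:\\d{2}$", dose_times)))
    stopf("dose_times must be 'HH:MM' strings")
  if (anyDuplicated(dose_times)) stopf("dose_times must be unique")
  structure(list(
    drug_name = as.character(drug_name),
    doses_per_day = length(dose_times),
    dose_times = sort(dose_times),
    start_date = as.Date(start_date),
    end_date = if (length(end_date) == 1L && is.na(end_date)) NA else
      as.Date(end_date)
  ), class = "hma_schedule")
}

#' @rdname medication_schedule
#' @param store A record store.
#' @param schedule An `hma_schedule`.
#' @export
add_schedule <- function(store, schedule) {
  stopifnot(inherits(store, "hma_store"), inherits(schedule, "hma_schedule"))
  store$schedules[[length(store$schedules) + 1L]] <- schedule
  store
}

#' Record a medication intake (or a missed dose)
#'
#' @param store A record store.
#' @param drug_name Drug name matching a schedule.
#' @param slot Scheduled date-time of the dose.
#' @param taken Whether the dose was taken.
#' @param taken_at When it was taken; required iff `taken` (defaults to
#'   the slot time).
#' @return The updated store.
#' @export
record_intake <- function(store, drug_name, slot, taken = TRUE,
                          taken_at = NULL) {
  stopifnot(inherits(store, "hma_store"))
  slot <- parse_ts(slot, "slot")
  if (taken) {
    taken_at <- if (is.null(taken_at)) slot else parse_ts(taken_at, "taken_at")
  } else {
    if (!is.null(taken_at)) stopf("taken_at must be absent when taken = FALSE")
    taken_at <- as.POSIXct(NA, tz = "UTC")
  }
  store$intakes <- rbind(store$intakes, data.frame(
    drug_name = as.character(drug_name), slot = slot, taken = taken,
    taken_at = taken_at, stringsAsFactors = FALSE))
  store
}

#' Add a hospital-visit calendar entry
#' @param store A record store.
#' @param due_at Visit date-time.
#' @param label Short description.
#' @return The updated store.
#' @export
add_visit <- function(store, due_at, label = "hospital visit") {
  stopifnot(inherits(store, "hma_store"))
  store$visits <- rbind(store$visits, data.frame(
    due_at = parse_ts(due_at, "due_at"), label = as.character(label),
    stringsAsFactors = FALSE))
  store
}

#' Expand a schedule into scheduled dose slots over a date window
#'
#' A continuous once-daily schedule over 28 days yields 28 slots; in
#' general the slot count is (active days) x (doses per day).
#'
#' @param schedule An `hma_schedule`.
#' @param from,to Window bounds (Date, inclusive).
#' @return POSIXct vector of scheduled slots, sorted.
#' @export
expand_slots <- function(schedule, from, to) {
  stopifnot(inherits(schedule, "hma_schedule"))
  from <- max(as.Date(from), schedule$start_date)
  to <- as.Date(to)
  if (length(schedule$end_date) == 1L && !is.na(schedule$end_date))
    to <- min(to, schedule$end_date)
  if (from > to) return(as.POSIXct(character(0), tz = "UTC"))
  days <- seq(from, to, by = "day")
  slots <- as.POSIXct(outer(as.character(days), schedule$dose_times,
                            paste), tz = "UTC", format = "%Y-%m-%d %H:%M")
  sort(slots)
}

#' Medication adherence rate over a window
#'
#' The rate is taken slots divided by scheduled slots, as a percentage
#' rounded to one decimal. A scheduled slot counts as taken when an
#' intake record for the same drug and slot is marked taken within the
#' grace window of the slot time. Adherence pools across drugs by
#' default; a per-drug breakdown is always returned.
#'
#' @param x A record store, or an `hma_schedule`/list of schedules.
#' @param intakes Intake log data frame (taken from the store when `x` is
#'   a store).
#' @param from,to Reporting window (Date, inclusive).
#' @param grace_hours Half-width of the on-time window around a slot
#'   (default 6 h).
#' @return An object of class `hma_adherence`: list with `rate` (percent,
#'   one decimal), `taken`, `scheduled` and `per_drug`.
#' @examples
#' st <- record_store()
#' st <- add_schedule(st, medication_schedule("amlodipine", "09:00",
#'                                            "2026-01-01"))
#' st <- record_intake(st, "amlodipine", "2026-01-01T09:00")
#' adherence_rate(st, from = "2026-01-01", to = "2026-01-07")$scheduled  # 7
#' @export
adherence_rate <- function(x, intakes = NULL, from, to, grace_hours = 6) {
  if (inherits(x, "hma_store")) {
    schedules <- x$schedules
    intakes <- x$intakes
  } else if (inherits(x, "hma_schedule")) {
    schedules <- list(x)
  } else {
    schedules <- x
  }
  if (as.Date(from) > as.Date(to)) stopf("empty reporting window")
  per <- lapply(schedules, function(sch) {
    slots <- expand_slots(sch, from, to)
    rel <- intakes[intakes$drug_name == sch$drug_name & intakes$taken, ,
                   drop = FALSE]
    taken <- vapply(slots, function(s) {
      any(rel$slot == s &
            abs(as.numeric(rel$taken_at) - as.numeric(s)) <=
            grace_hours * 3600)
    }, logical(1))
    data.frame(drug_name = sch$drug_name, scheduled = length(slots),
               taken = sum(taken), stringsAsFactors = FALSE)
  })
  per <- if (length(per) > 0) do.call(rbind, per) else
    data.frame(drug_name = character(0), scheduled = integer(0),
               taken = integer(0), stringsAsFactors = FALSE)
  scheduled <- sum(per$scheduled)
  if (scheduled == 0L)
    stopf("no scheduled doses in window %s..%s; adherence is undefined",
          from, to)
  taken <- sum(per$taken)
  per$rate <- ifelse(per$scheduled > 0,
                     round(100 * per$taken / per$scheduled, 1), NA_real_)
  structure(list(rate = round(100 * taken / scheduled, 1),
                 taken = taken, scheduled = scheduled, per_drug = per),
            class = "hma_adherence")
}

#' @export
print.hma_adherence <- function(x, ...) {
  cat(sprintf("adherence %.1f%% (%d/%d slots)\n", x$rate, x$taken,
              x$scheduled))
  invisible(x)
}

#' Upcoming alerts within a horizon
#'
#' Returns medication-time, hospital-visit and monthly lifestyle-prompt
#' alerts due strictly after `now` and no later than `now + horizon`,
#' sorted by due time. The lifestyle prompt fires once a month on a
#' configured day.
#'
#' @param store A record store.
#' @param now Current time (POSIXct or ISO string).
#' @param horizon_hours Look-ahead horizon in hours.
#' @param lifestyle_day Day of month of the lifestyle data prompt.
#' @param lifestyle_time Clock time of the prompt (`"HH:MM"`).
#' @return Data frame with columns `kind`, `due_at`, `message`.
#' @export
due_alerts <- function(store, now, horizon_hours,
                       lifestyle_day = 1, lifestyle_time = "09:00") {
  stopifnot(inherits(store, "hma_store"))
  now <- parse_ts(now, "now")
  end <- now + horizon_hours * 3600
  out <- list()
  for (sch in store$schedules) {
    slots <- expand_slots(sch, as.Date(now) - 1, as.Date(end) + 1)
    slots <- slots[slots > now & slots <= end]
    if (length(slots) > 0)
      out[[length(out) + 1L]] <- data.frame(
        kind = "medication_time", due_at = slots,
        message = paste0("Time to take ", sch$drug_name),
        stringsAsFactors = FALSE)
  }
  vis <- store$visits[store$visits$due_at > now & store$visits$due_at <= end, ,
                      drop = FALSE]
  if (nrow(vis) > 0)
    out[[length(out) + 1L]] <- data.frame(
      kind = "hospital_visit", due_at = vis$due_at,
      message = vis$label, stringsAsFactors = FALSE)
  months <- unique(format(seq(as.Date(now), as.Date(end), by = "day"), "%Y-%m"))
  prompts <- as.POSIXct(paste0(months, "-", sprintf("%02d", lifestyle_day),
                               " ", lifestyle_time),
                        tz = "UTC", format = "%Y-%m-%d %H:%M")
  prompts <- prompts[!is.na(prompts) & prompts > now & prompts <= end]
  if (length(prompts) > 0)
    out[[length(out) + 1L]] <- data.frame(
      kind = "monthly_lifestyle_prompt", due_at = prompts,
      message = "Monthly prompt: please enter your lifestyle data",
      stringsAsFactors = FALSE)
  out <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(kind = character(0),
               due_at = as.POSIXct(character(0), tz = "UTC"),
               message = character(0), stringsAsFactors = FALSE)
  out[order(out$due_at, out$kind), , drop = FALSE]
}

store_to_list <- function(store) {
  list(
    bp = data.frame(timestamp = iso_ts(store$bp$timestamp),
                    systolic = store$bp$systolic,
                    diastolic = store$bp$diastolic,
                    note = store$bp$note, stringsAsFactors = FALSE),
    schedules = lapply(store$schedules, function(s) list(
      drug_name = s$drug_name, doses_per_day = s$doses_per_day,
      dose_times = s$dose_times, start_date = as.character(s$start_date),
      end_date = if (length(s$end_date) == 1L && is.na(s$end_date))
        NA_character_ else as.character(s$end_date))),
    intakes = data.frame(drug_name = store$intakes$drug_name,
                         slot = iso_ts(store$intakes$slot),
                         taken = store$intakes$taken,
                         taken_at = ifelse(store$intakes$taken,
                                           iso_ts(store$intakes$taken_at),
                                           NA_character_),
                         stringsAsFactors = FALSE),
    visits = data.frame(due_at = iso_ts(store$visits$due_at),
                        label = store$visits$label, stringsAsFactors = FALSE)
  )
}

store_from_list <- function(x) {
  st <- record_store()
  if (length(x$bp$timestamp %||% character(0)) > 0) {
    st$bp <- data.frame(timestamp = parse_ts(x$bp$timestamp),
                        systolic = as.numeric(x$bp$systolic),
                        diastolic = as.numeric(x$bp$diastolic),
                        note = as.character(x$bp$note),
                        stringsAsFactors = FALSE)
  }
  st$schedules <- lapply(x$schedules %||% list(), function(s)
    medication_schedule(s$drug_name, unlist(s$dose_times), s$start_date,
                        if (is.null(s$end_date) || is.na(s$end_date)) NA
                        else s$end_date))
  if (length(x$intakes$drug_name %||% character(0)) > 0) {
    taken <- as.logical(x$intakes$taken)
    st$intakes <- data.frame(
      drug_name = as.character(x$intakes$drug_name),
      slot = parse_ts(x$intakes$slot),
      taken = taken,
      taken_at = as.POSIXct(ifelse(taken, x$intakes$taken_at,
                                   NA_character_),
                            tz = "UTC", format = "%Y-%m-%dT%H:%M:%S"),
      stringsAsFactors = FALSE)
  }
  if (length(x$visits$due_at %||% character(0)) > 0) {
    st$visits <- data.frame(due_at = parse_ts(x$visits$due_at),
                            label = as.character(x$visits$label),
                            stringsAsFactors = FALSE)
  }
  st
}

#' Export and re-import a record store
#'
#' `export_data()` writes the store either as a single JSON document or
#' as a directory of CSV files (comma-separated, UTF-8, header row) — the
#' file counterpart of the app's "send data" function. `import_data()`
#' reads either format back; a round-trip reproduces the store
#' field-for-field.
#'
#' @param store A record store.
#' @param format `"json"` or `"csv"`.
#' @param destination Output file (json) or directory (csv).
#' @return `export_data()` returns `destination` invisibly;
#'   `import_data()` returns an `hma_store`.
#' @export
export_data <- function(store, format = c("json", "csv"), destination) {
  stopifnot(inherits(store, "hma_store"))
  format <- match.arg(format)
  x <- store_to_list(store)
  if (format == "json") {
    jsonlite::write_json(x, destination, auto_unbox = TRUE, na = "null",
                         pretty = TRUE, digits = NA)
  } else {
    dir.create(destination, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(x$bp, file.path(destination, "bp.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    sched <- do.call(rbind, lapply(x$schedules, function(s) data.frame(
      drug_name = s$drug_name, doses_per_day = s$doses_per_day,
      dose_times = paste(s$dose_times, collapse = ";"),
      start_date = s$start_date, end_date = s$end_date,
      stringsAsFactors = FALSE)))
    if (is.null(sched))
      sched <- data.frame(drug_name = character(0),
                          doses_per_day = integer(0),
                          dose_times = character(0),
                          start_date = character(0),
                          end_date = character(0), stringsAsFactors = FALSE)
    utils::write.csv(sched, file.path(destination, "schedules.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    utils::write.csv(x$intakes, file.path(destination, "intakes.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    utils::write.csv(x$visits, file.path(destination, "visits.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(destination)
}

#' @rdname export_data
#' @param path A JSON file or CSV directory written by `export_data()`.
#' @export
import_data <- function(path) {
  if (dir.exists(path)) {
    rd <- function(f, colClasses = NA) {
      p <- file.path(path, f)
      if (!file.exists(p)) stopf("missing export file: %s", p)
      utils::read.csv(p, stringsAsFactors = FALSE, colClasses = colClasses)
    }
    sched <- rd("schedules.csv", colClasses = "character")
    x <- list(
      bp = rd("bp.csv"),
      schedules = if (nrow(sched) == 0) list() else
        lapply(seq_len(nrow(sched)), function(i) list(
          drug_name = sched$drug_name[i],
          doses_per_day = as.integer(sched$doses_per_day[i]),
          dose_times = strsplit(sched$dose_times[i], ";")[[1]],
          start_date = sched$start_date[i],
          end_date = if (sched$end_date[i] %in% c(NA, "", "NA")) NA
          else sched$end_date[i])),
      intakes = rd("intakes.csv"),
      visits = rd("visits.csv"))
    return(store_from_list(x))
  }
  if (!file.exists(path)) stopf("no such export: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = TRUE)
  ## schedules must stay a list of records, not be simplified to a table
  x$schedules <- jsonlite::read_json(path, simplifyVector = FALSE)$schedules
  store_from_list(x)
}

#' Recent blood-pressure readings and adherence sparkline data
#'
#' Returns the most recent `n` blood-pressure readings, newest first;
#' readings sharing a timestamp are ordered by insertion (later-inserted
#' treated as newer). Also returns per-day scheduled/taken dose counts
#' for the 7 days ending at `as_of`, suitable for a sparkline.
#'
#' @param store A record store.
#' @param n Number of readings to return (fewer are returned if the log
#'   is shorter).
#' @param as_of Reference time; defaults to the newest timestamp in the
#'   store (or the current time for an empty store).
#' @param grace_hours Grace window passed to the adherence matcher.
#' @return List with `bp` (data frame, newest first) and `adherence_by_day`.
#' @export
recent_summary <- function(store, n, as_of = NULL, grace_hours = 6) {
  stopifnot(inherits(store, "hma_store"), n >= 1)
  bp <- store$bp
  if (nrow(bp) > 0) {
    idx <- order(bp$timestamp, seq_len(nrow(bp)), decreasing = TRUE)
    bp <- bp[idx[seq_len(min(n, nrow(bp)))], , drop = FALSE]
    rownames(bp) <- NULL
  }
  if (is.null(as_of)) {
    cand <- c(store$bp$timestamp, store$intakes$slot)
    as_of <- if (length(cand) > 0) max(cand) else Sys.time()
  } else {
    as_of <- parse_ts(as_of, "as_of")
  }
  days <- seq(as.Date(as_of) - 6, as.Date(as_of), by = "day")
  spark <- do.call(rbind, lapply(days, function(d) {
    res <- tryCatch(
      adherence_rate(store, from = d, to = d, grace_hours = grace_hours),
      error = function(e) NULL)
    data.frame(date = d,
               scheduled = if (is.null(res)) 0L else res$scheduled,
               taken = if (is.null(res)) 0L else res$taken)
  }))
  list(bp = bp, adherence_by_day = spark)
}
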