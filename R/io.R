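#' Read a day-level time-use CSV
#'
#' Wide format, one row per participant-day: columns `id`, `day_type`
#' (`weekday`/`weekend`) and the seven activity parts in min/day. Rows
#' failing validation (unknown day type, negative or missing durations,
#' all-zero compositions) are dropped with a per-row report attached as
#' attribute `"dropped"` and summarised in a message.
#'
#' @param path Path to the CSV file.
#' @return Data frame of valid rows; attribute `dropped` is a data frame
#'   with columns `row` and `reason`.
#' @export
read_timeuse_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("id", "day_type", activity_parts())
  miss <- setdiff(needed, names(raw))
  if (length(miss))
    stop("time-use CSV is missing column(s): ", paste(miss, collapse = ", "))
  reasons <- character(0); rows <- integer(0)
  flag <- function(idx, why) {
    rows <<- c(rows, idx); reasons <<- c(reasons, why)
  }
  part_mat <- suppressWarnings(
    vapply(activity_parts(), function(p) as.numeric(raw[[p]]), numeric(nrow(raw))))
  if (nrow(raw) == 1L) part_mat <- matrix(part_mat, nrow = 1L,
                                          dimnames = list(NULL, activity_parts()))
  for (i in seq_len(nrow(raw))) {
    v <- part_mat[i, ]
    if (!(raw$day_type[i] %in% c("weekday", "weekend")))
      flag(i, "invalid day_type")
    else if (any(!is.finite(v))) flag(i, "missing or non-numeric duration")
    else if (any(v < 0)) flag(i, "negative duration")
    else if (sum(v) == 0) flag(i, "all-zero composition")
  }
  keep <- setdiff(seq_len(nrow(raw)), rows)
  out <- raw[keep, needed]
  for (p in activity_parts()) out[[p]] <- as.numeric(out[[p]])
  if (length(rows))
    message("read_timeuse_csv: dropped ", length(rows), " of ", nrow(raw),
            " rows (", paste(unique(reasons), collapse = "; "), ")")
  attr(out, "dropped") <- data.frame(row = rows, reason = reasons,
                                     stringsAsFactors = FALSE)
  out
}

#' Weekly compositions per participant from day-level data
#'
#' Applies [weighted_weekly_composition()] (5:2 weekday:weekend weighting)
#' within each participant. Participants missing either day type are
#' dropped and reported via the `"dropped"` attribute.
#'
#' @param data Day-level data frame as returned by [read_timeuse_csv()].
#' @param total Closure constant (default 1440).
#' @return Matrix of weekly compositions, one row per retained participant
#'   (rownames are ids).
#' @export
participant_weekly <- function(data, total = 1440) {
  ids <- unique(data$id)
  out <- list(); dropped <- character(0)
  for (pid in ids) {
    rows <- data[data$id == pid, , drop = FALSE]
    res <- tryCatch(
      weighted_weekly_composition(rows[, activity_parts()], rows$day_type,
                                  total = total),
      error = function(e) conditionMessage(e))
    if (is.character(res)) dropped <- c(dropped, as.character(pid))
    else out[[as.character(pid)]] <- unclass(res)[seq_len(7L)]
  }
  if (length(dropped))
    message("participant_weekly: dropped ", length(dropped),
            " participant(s) missing a day type")
  m <- do.call(rbind, out)
  attr(m, "dropped") <- dropped
  m
}
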