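#' Assign diel period from an instant
#'
#' Day runs from `day_start` (inclusive) to `night_start` (exclusive) on the
#' local clock; everything else is night. The defaults (07:00/19:00) suit a
#' near-equatorial site with a roughly 12-hour cycle; no ephemeris is
#' computed.
#'
#' @param t `POSIXct` vector.
#' @param tz Local zone for the clock reading (e.g. `"Etc/GMT-6"` for
#'   UTC+06:00).
#' @param day_start,night_start `"HH:MM"` strings.
#' @return Character vector, `"day"` or `"night"`.
#' @export
assign_diel <- function(t, tz = "Etc/GMT-6",
                        day_start = "07:00", night_start = "19:00") {
  mins <- function(hm) {
    p <- as.integer(strsplit(hm, ":", fixed = TRUE)[[1L]])
    p[1L] * 60L + p[2L]
  }
  d0 <- mins(day_start); n0 <- mins(night_start)
  local_min <- as.integer(format(t, "%H", tz = tz)) * 60L +
    as.integer(format(t, "%M", tz = tz))
  ifelse(local_min >= d0 & local_min < n0, "day", "night")
}

#' Assign season from an instant
#'
#' The site has distinct Indian Ocean wet (October–March) and dry
#' (April–September) seasons; the month is read on the local clock.
#'
#' @param t `POSIXct` vector.
#' @param tz Local zone.
#' @param wet_months Integer months counted as wet season.
#' @return Character vector, `"wet"` or `"dry"`.
#' @export
assign_season <- function(t, tz = "Etc/GMT-6",
                          wet_months = c(10L, 11L, 12L, 1L, 2L, 3L)) {
  m <- as.integer(format(t, "%m", tz = tz))
  ifelse(m %in% wet_months, "wet", "dry")
}

#' Build the modelling table from labelled movements
#'
#' Attaches the covariates and grouping factors the inference module needs:
#' species, sex, log total length, diel period and season (both derived from
#' the movement's *start* instant — the departure detection, when the
#' behavioural decision is made), plus `tag_id` and a movement receiver as
#' crossed grouping factors. For transitions the receiver factor defaults to
#' the destination (arrival) receiver; set `receiver_role = "origin"` to use
#' departure instead. Rows with missing sex or size are dropped with a
#' logged count.
#'
#' @param labelled Output of [classify_movements()].
#' @param individuals Tag metadata from [read_individuals()].
#' @param tz Local zone for diel/season assignment.
#' @param receiver_role `"destination"` (default) or `"origin"`.
#' @param day_start,night_start,wet_months Passed to [assign_diel()] and
#'   [assign_season()].
#' @return `data.table` with columns `label`, `species`, `sex`, `log_size`,
#'   `diel`, `season`, `tag_id`, `receiver_id` (all complete).
#' @export
build_model_table <- function(labelled, individuals, tz = "Etc/GMT-6",
                              receiver_role = c("destination", "origin"),
                              day_start = "07:00", night_start = "19:00",
                              wet_months = c(10L, 11L, 12L, 1L, 2L, 3L)) {
  receiver_role <- match.arg(receiver_role)
  mv <- as.data.table(labelled)
  ind <- as.data.table(individuals)
  mv[ind, `:=`(sex = i.sex, total_length_cm = i.total_length_cm),
     on = "tag_id"]
  out <- data.table(
    label = as.integer(mv$label),
    species = mv$species,
    sex = mv$sex,
    log_size = log(mv$total_length_cm),
    diel = assign_diel(mv$t_start, tz, day_start, night_start),
    season = assign_season(mv$t_start, tz, wet_months),
    tag_id = mv$tag_id,
    receiver_id = if (receiver_role == "destination") mv$dest_receiver
                  else mv$origin_receiver
  )
  ok <- !is.na(out$sex) & nzchar(out$sex) & out$sex != "unknown" &
    is.finite(out$log_size)
  if (any(!ok))
    message(sum(!ok), " movement(s) dropped for missing sex/size metadata")
  out[ok][]
}
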