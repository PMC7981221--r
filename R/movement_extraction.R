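#' Great-circle distance matrix between receivers
#'
#' Haversine distances (Earth radius 6,371,000 m) between receiver mooring
#' coordinates. Depth is ignored: at array scale (receivers kilometres apart
#' in tens of metres of water) the surface geodesic is the relevant distance.
#'
#' @param receivers Output of [read_receivers()].
#' @return A symmetric numeric matrix in metres with receiver ids as dimnames.
#' @export
#' @examples
#' rec <- data.frame(receiver_id = c("a", "b"),
#'                   latitude = c(0, 0), longitude = c(0, 1))
#' interreceiver_distances(rec)["a", "b"]  # ~111195 m
interreceiver_distances <- function(receivers) {
  receivers <- as.data.table(receivers)
  if (nrow(receivers) < 1L) stop("need at least one receiver")
  p <- as.matrix(receivers[, .(longitude, latitude)])
  d <- geosphere::distm(p, p, fun = geosphere::distHaversine)
  # distHaversine's default radius is 6378137; rescale to the 6371 km sphere
  d <- d * (6371000 / 6378137)
  dimnames(d) <- list(receivers$receiver_id, receivers$receiver_id)
  d
}

#' Build movement events from consecutive detections
#'
#' A detection gap is the time between two consecutive detections of the same
#' individual. Each gap becomes one movement event: a *recursion* if both
#' detections are at the same receiver (the animal left detection range and
#' returned — a self-loop in the movement network), a *transition* if they
#' are at different receivers. Individuals with fewer than two detections
#' yield no events. Zero-duration gaps (clock collisions) are dropped with a
#' warning: they carry no duration information and would break the
#' log-transform and RDET downstream.
#'
#' @param detections Detections sorted by `(tag_id, timestamp)` as produced
#'   by [read_detections()].
#' @return A `data.table` of movements: `tag_id`, `kind`
#'   (`recursion`/`transition`), `origin_receiver`, `dest_receiver`,
#'   `t_start`, `t_end`, `gap_s`.
#' @export
extract_movements <- function(detections) {
  det <- as.data.table(detections)
  setorder(det, tag_id, timestamp)
  mv <- det[, {
    n <- .N
    if (n < 2L) {
      list(origin_receiver = character(0), dest_receiver = character(0),
           t_start = timestamp[0], t_end = timestamp[0], gap_s = numeric(0))
    } else {
      list(origin_receiver = receiver_id[-n], dest_receiver = receiver_id[-1L],
           t_start = timestamp[-n], t_end = timestamp[-1L],
           gap_s = as.numeric(difftime(timestamp[-1L], timestamp[-n],
                                       units = "secs")))
    }
  }, by = tag_id]
  nzero <- sum(mv$gap_s <= 0)
  if (nzero > 0L) {
    warning(nzero, " zero-duration gap(s) (simultaneous detections) dropped")
    mv <- mv[gap_s > 0]
  }
  mv[, kind := fifelse(origin_receiver == dest_receiver,
                       "recursion", "transition")]
  setcolorder(mv, c("tag_id", "kind", "origin_receiver", "dest_receiver",
                    "t_start", "t_end", "gap_s"))
  mv[]
}

#' Remove short recursions
#'
#' Recursions shorter than `min_gap_s` (default six minutes, i.e. a minimum
#' of two nominal transmission intervals) are removed: such gaps are more
#' plausibly a missed detection of an animal that never left range than a
#' genuine departure and return. The rule is strict — a gap of exactly
#' `min_gap_s` is retained. Transitions are untouched; a detection at a
#' different receiver is already evidence of movement.
#'
#' @param movements Output of [extract_movements()].
#' @param min_gap_s Minimum recursion gap in seconds (default 360).
#' @return Filtered movements; attribute `removed` holds the drop count.
#' @export
filter_recursions <- function(movements, min_gap_s = 360) {
  mv <- as.data.table(movements)
  drop <- mv$kind == "recursion" & mv$gap_s < min_gap_s
  out <- mv[!drop]
  message(sum(drop), " recursion(s) under ", min_gap_s, " s removed")
  setattr(out, "removed", sum(drop))
  out
}

#' Compute RDET (relative deviation from expected time) for transitions
#'
#' The expected transit time between two receivers is the straight-line
#' distance divided by the species' minimum sustainable swim speed; RDET is
#' expected time over observed time. RDET > 1 means faster than expected,
#' RDET < 1 slower/more tortuous. Recursions pass through unchanged. The
#' individual's species is attached to every movement as a side effect (it is
#' needed for per-species thresholds downstream).
#'
#' @param movements Output of [extract_movements()] or [filter_recursions()].
#' @param distances Matrix from [interreceiver_distances()].
#' @param individuals Tag metadata from [read_individuals()] (supplies the
#'   species of each tag).
#' @param species_params `data.frame` with columns `species` and
#'   `swim_speed_m_s`; defaults to the two study species (gray reef 0.69 m/s,
#'   silvertip 0.73 m/s).
#' @return Movements with added columns `species`, `distance_m`,
#'   `expected_s`, `rdet` (the last three `NA` for recursions).
#' @export
compute_rdet <- function(movements, distances, individuals,
                         species_params = default_species_params()) {
  mv <- as.data.table(movements)
  ind <- as.data.table(individuals)
  sp <- as.data.table(species_params)
  mv[ind, species := i.species, on = "tag_id"]
  if (anyNA(mv$species))
    stop("movement tag(s) without species metadata: ",
         paste(unique(mv$tag_id[is.na(mv$species)]), collapse = ", "))
  mv[sp, swim_speed_m_s := i.swim_speed_m_s, on = "species"]
  if (anyNA(mv$swim_speed_m_s))
    stop("no swim speed for species: ",
         paste(setdiff(unique(mv$species), sp$species), collapse = ", "))
  tr <- mv$kind == "transition"
  miss <- tr & (!(mv$origin_receiver %in% rownames(distances)) |
                  !(mv$dest_receiver %in% colnames(distances)))
  if (any(miss))
    stop("transition receiver(s) missing from distance matrix: ",
         paste(unique(c(mv$origin_receiver[miss], mv$dest_receiver[miss])),
               collapse = ", "))
  mv[, distance_m := NA_real_]
  mv[, expected_s := NA_real_]
  mv[, rdet := NA_real_]
  if (any(tr)) {
    d <- distances[cbind(mv$origin_receiver[tr], mv$dest_receiver[tr])]
    if (any(d <= 0))
      stop("zero distance between distinct receivers ",
           "(array must have non-overlapping stations)")
    mv[tr, distance_m := d]
    mv[tr, expected_s := distance_m / swim_speed_m_s]
    mv[tr, rdet := expected_s / gap_s]
  }
  mv[, swim_speed_m_s := NULL]
  mv[]
}

#' Remove implausibly fast transitions
#'
#' Transitions with RDET above `rdet_max` (default 5, i.e. five times the
#' species' sustainable speed) are removed as likely false detections. The
#' rule is strict: RDET of exactly `rdet_max` is retained. Slow transitions
#' are never removed — tortuous movement is data, not noise.
#'
#' @param movements Output of [compute_rdet()].
#' @param rdet_max RDET ceiling (default 5).
#' @return Filtered movements; attribute `removed` holds the drop count.
#' @export
filter_transitions <- function(movements, rdet_max = 5) {
  mv <- as.data.table(movements)
  drop <- mv$kind == "transition" & !is.na(mv$rdet) & mv$rdet > rdet_max
  out <- mv[!drop]
  message(sum(drop), " transition(s) with RDET > ", rdet_max, " removed")
  setattr(out, "removed", sum(drop))
  out
}

#' Default species swim-speed table
#'
#' Minimum sustainable swim speeds used for expected transit times:
#' 0.69 m/s for gray reef sharks and 0.73 m/s for silvertip sharks.
#'
#' @return `data.table` with columns `species`, `swim_speed_m_s`.
#' @export
default_species_params <- function() {
  data.table(species = c("gray_reef", "silvertip"),
             swim_speed_m_s = c(0.69, 0.73))
}
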