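#' Read and validate a detections table
#'
#' Detections are presence-only records: one row per decoded transmission of
#' a tagged individual at a receiver. Rows are sorted by `(tag_id, timestamp)`
#' on the way in; timestamps are parsed in `tz` and stored as UTC `POSIXct`.
#' Exact duplicate rows are kept (with a warning): the only detection-thinning
#' step the method defines is the recursion minimum-gap filter, applied later
#' and explicitly.
#'
#' @param path CSV file with at least the three mapped columns.
#' @param tz Zone the timestamps are recorded in (default `"UTC"`).
#' @param col_map Named list mapping canonical names `tag_id`, `receiver_id`,
#'   `timestamp` to the file's column names.
#' @return A `data.table` with columns `tag_id`, `receiver_id` (character)
#'   and `timestamp` (`POSIXct`, UTC), sorted by tag then time.
#' @export
read_detections <- function(path, tz = "UTC",
                            col_map = list(tag_id = "tag_id",
                                           receiver_id = "receiver_id",
                                           timestamp = "timestamp")) {
  dt <- read_mapped_csv(path, col_map, c("tag_id", "receiver_id", "timestamp"))
  if (nrow(dt) == 0L) stop("empty detections file: ", path)
  ts <- parse_timestamps(dt$timestamp, tz)
  bad <- which(is.na(ts))
  if (length(bad) > 0L) {
    stop("unparseable timestamp(s) in ", path, " at data row(s): ",
         paste(head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "")
  }
  attr(ts, "tzone") <- "UTC"
  out <- data.table(tag_id = as.character(dt$tag_id),
                    receiver_id = as.character(dt$receiver_id),
                    timestamp = ts)
  if (any(!nzchar(out$tag_id)) || any(!nzchar(out$receiver_id)))
    stop("empty tag_id or receiver_id in ", path)
  ndup <- nrow(out) - nrow(unique(out))
  if (ndup > 0L)
    warning(ndup, " exact duplicate detection row(s) retained in ", path)
  setorder(out, tag_id, timestamp)
  message("read ", nrow(out), " detections from ", path)
  out[]
}

#' Read and validate a receiver table
#'
#' @param path CSV with receiver id and WGS84 coordinates in decimal degrees.
#' @param col_map Named list mapping `receiver_id`, `latitude`, `longitude`.
#' @return A `data.table` with one validated row per receiver.
#' @export
read_receivers <- function(path,
                           col_map = list(receiver_id = "receiver_id",
                                          latitude = "latitude",
                                          longitude = "longitude")) {
  dt <- read_mapped_csv(path, col_map, c("receiver_id", "latitude", "longitude"))
  out <- data.table(receiver_id = as.character(dt$receiver_id),
                    latitude = as.numeric(dt$latitude),
                    longitude = as.numeric(dt$longitude))
  bad_lat <- which(is.na(out$latitude) | abs(out$latitude) > 90)
  bad_lon <- which(is.na(out$longitude) | abs(out$longitude) > 180)
  if (length(bad_lat) > 0L)
    stop("latitude out of [-90, 90] at row(s): ", paste(bad_lat, collapse = ", "))
  if (length(bad_lon) > 0L)
    stop("longitude out of [-180, 180] at row(s): ", paste(bad_lon, collapse = ", "))
  if (anyDuplicated(out$receiver_id))
    stop("duplicate receiver_id(s): ",
         paste(unique(out$receiver_id[duplicated(out$receiver_id)]), collapse = ", "))
  out[]
}

#' Read and validate a tag-metadata table
#'
#' One row per tagged individual: species, sex (`F`/`M`/`unknown`) and total
#' length in centimetres (log-transformed downstream as the size covariate).
#'
#' @param path CSV file.
#' @param col_map Named list mapping `tag_id`, `species`, `sex`,
#'   `total_length_cm`.
#' @return A `data.table` with one validated row per individual.
#' @export
read_individuals <- function(path,
                             col_map = list(tag_id = "tag_id",
                                            species = "species",
                                            sex = "sex",
                                            total_length_cm = "total_length_cm")) {
  dt <- read_mapped_csv(path, col_map,
                        c("tag_id", "species", "sex", "total_length_cm"))
  out <- data.table(tag_id = as.character(dt$tag_id),
                    species = as.character(dt$species),
                    sex = as.character(dt$sex),
                    total_length_cm = as.numeric(dt$total_length_cm))
  if (anyDuplicated(out$tag_id))
    stop("duplicate tag_id(s): ",
         paste(unique(out$tag_id[duplicated(out$tag_id)]), collapse = ", "))
  if (any(!is.na(out$total_length_cm) & out$total_length_cm <= 0))
    stop("total_length_cm must be positive where present")
  out[]
}

#' Keep only detections from known tags
#'
#' Detections whose tag id does not appear in the metadata table are removed
#' (they may be stray code collisions or animals tagged by other programmes);
#' the removed count is logged.
#'
#' @param detections Output of [read_detections()].
#' @param individuals Output of [read_individuals()].
#' @return Filtered detections, attribute `removed` holding the drop count.
#' @export
filter_known_tags <- function(detections, individuals) {
  keep <- detections$tag_id %in% individuals$tag_id
  removed <- sum(!keep)
  out <- detections[keep]
  message(removed, " detection(s) from unknown tags removed; ",
          nrow(out), " retained")
  if (nrow(out) == 0L) warning("no detections from known tags remain")
  setattr(out, "removed", removed)
  out
}

#' Write a pipeline table to CSV
#'
#' Timestamps are serialised as `"%Y-%m-%d %H:%M:%S"` UTC so a written table
#' re-read with the matching reader round-trips at 1-second precision and the
#' bytes are reproducible.
#'
#' @param x A `data.frame`/`data.table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  x <- as.data.table(x)[, lapply(.SD, function(col) {
    if (inherits(col, "POSIXct"))
      format(col, "%Y-%m-%d %H:%M:%S", tz = "UTC")
    else col
  })]
  fwrite(x, path)
  invisible(path)
}

# row-level parsing: a malformed timestamp becomes NA (reported with its
# row number by the caller) instead of aborting the whole read
#' @noRd
parse_timestamps <- function(x, tz) {
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%d %H:%M", "%Y/%m/%d %H:%M:%OS")
  res <- rep(NA_real_, length(x))
  for (f in fmts) {
    idx <- which(is.na(res))
    if (length(idx) == 0L) break
    cand <- as.POSIXct(x[idx], tz = tz, format = f)
    ok <- !is.na(cand)
    res[idx[ok]] <- as.numeric(cand[ok])
  }
  .POSIXct(res, tz = "UTC")
}

#' @noRd
read_mapped_csv <- function(path, col_map, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread(path, colClasses = "character")
  missing_keys <- setdiff(required, names(col_map))
  if (length(missing_keys) > 0L)
    stop("col_map lacks: ", paste(missing_keys, collapse = ", "))
  src <- unlist(col_map[required])
  absent <- setdiff(src, names(dt))
  if (length(absent) > 0L)
    stop("column(s) not in ", path, ": ", paste(absent, collapse = ", "))
  out <- dt[, src, with = FALSE]
  setnames(out, src, required)
  out
}
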