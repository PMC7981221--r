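# Shared fixtures: tiny CSV builders, a brute-force Fisher oracle, and a
# cached small simulated pipeline run reused across test files.

write_fixture_csv <- function(lines, dir = tempdir()) {
  path <- tempfile(tmpdir = dir, fileext = ".csv")
  writeLines(lines, path)
  path
}

detections_csv <- function(rows) {
  write_fixture_csv(c("tag_id,receiver_id,timestamp", rows))
}

receivers_csv <- function(rows) {
  write_fixture_csv(c("receiver_id,latitude,longitude", rows))
}

individuals_csv <- function(rows) {
  write_fixture_csv(c("tag_id,species,sex,total_length_cm", rows))
}

# exhaustive search over all contiguous k-partitions of sorted values;
# independent of the DP in fisher_breaks
brute_force_breaks <- function(values, k = 2L) {
  x <- sort(values)
  n <- length(x)
  sse <- function(v) sum((v - mean(v))^2)
  cuts <- utils::combn(n - 1L, k - 1L, simplify = FALSE)
  best <- Inf
  best_bounds <- NULL
  for (cut in cuts) {
    starts <- c(1L, cut + 1L)
    ends <- c(cut, n)
    obj <- sum(vapply(seq_len(k), function(i) sse(x[starts[i]:ends[i]]), 0))
    if (obj < best) {
      best <- obj
      best_bounds <- x[cut]
    }
  }
  attr(best_bounds, "objective") <- best
  best_bounds
}

# small two-species detection set with hand-computable movements
tiny_detections <- function() {
  base <- as.POSIXct("2016-03-05 02:00:00", tz = "UTC")
  data.table::data.table(
    tag_id = c("A", "A", "A", "B", "B"),
    receiver_id = c("R1", "R1", "R2", "R2", "R2"),
    timestamp = base + c(0, 100, 1000, 50, 500)
  )
}

tiny_individuals <- function() {
  data.table::data.table(
    tag_id = c("A", "B"),
    species = c("gray_reef", "silvertip"),
    sex = c("F", "M"),
    total_length_cm = c(100, 120)
  )
}

# one small end-to-end simulated run, computed once per test session
small_run_cache <- new.env(parent = emptyenv())

small_sim_config <- function(seed = 11L) {
  sim_config(
    seed = seed,
    species = list(
      gray_reef = list(n = 7L, swim_speed_m_s = 0.69, size_mean_cm = 119.15,
                       size_sd_cm = 18.07, prop_female = 0.75),
      silvertip = list(n = 6L, swim_speed_m_s = 0.73, size_mean_cm = 123.56,
                       size_sd_cm = 19.14, prop_female = 0.59)
    ),
    window = list(start = "2016-03-20", days = 14L)
  )
}

small_pipeline_run <- function() {
  if (!is.null(small_run_cache$res)) return(small_run_cache)
  dir <- file.path(tempdir(), "telegaps-small-run")
  sim <- simulate_telemetry(small_sim_config())
  suppressMessages(write_sim_bundle(sim, dir))
  cfg <- default_config()
  cfg$paths <- list(detections = file.path(dir, "detections.csv"),
                    receivers = file.path(dir, "receivers.csv"),
                    individuals = file.path(dir, "individuals.csv"),
                    output_dir = file.path(dir, "out"))
  res <- suppressWarnings(suppressMessages(
    run_gap_analysis(cfg, write_outputs = TRUE)))
  small_run_cache$sim <- sim
  small_run_cache$cfg <- cfg
  small_run_cache$res <- res
  small_run_cache
}
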