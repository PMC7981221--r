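test_that("haversine distances match the closed form on the 6371 km sphere", {
  rec <- data.frame(receiver_id = c("a", "b", "c"),
                    latitude = c(0, 0, 12.5), longitude = c(0, 1, -3.2))
  d <- interreceiver_distances(rec)
  # one degree of longitude on the equator: 2*pi*6371000/360
  expect_equal(d["a", "b"], 2 * pi * 6371000 / 360, tolerance = 1 / 111195)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_equal(d, t(d))
})

test_that("consecutive detections become recursion/transition events", {
  mv <- suppressWarnings(extract_movements(tiny_detections()))
  a <- mv[tag_id == "A"]
  expect_equal(a$kind, c("recursion", "transition"))
  expect_equal(a$gap_s, c(100, 900))
  expect_equal(a$origin_receiver, c("R1", "R1"))
  expect_equal(a$dest_receiver, c("R1", "R2"))
  # tags never mix: B's single gap is its own recursion
  expect_equal(mv[tag_id == "B", gap_s], 450)
})

test_that("movement counts are n-1 per individual and degenerate inputs vanish", {
  base <- as.POSIXct("2016-01-01", tz = "UTC")
  for (n in c(1L, 2L, 7L)) {
    det <- data.table::data.table(
      tag_id = "X", receiver_id = sample(c("R1", "R2"), n, replace = TRUE),
      timestamp = base + cumsum(runif(n, 60, 600)))
    expect_equal(nrow(extract_movements(det)), max(n - 1L, 0L))
  }
})

test_that("simultaneous detections are dropped with a warning", {
  base <- as.POSIXct("2016-01-01", tz = "UTC")
  det <- data.table::data.table(tag_id = "X",
                                receiver_id = c("R1", "R2", "R1"),
                                timestamp = base + c(0, 0, 500))
  expect_warning(mv <- extract_movements(det), "zero-duration")
  expect_equal(nrow(mv), 1L)
})

test_that("recursion filter is strict and leaves transitions alone", {
  mv <- data.table::data.table(
    tag_id = "X",
    kind = c("recursion", "recursion", "transition"),
    origin_receiver = c("R1", "R1", "R1"),
    dest_receiver = c("R1", "R1", "R2"),
    t_start = as.POSIXct("2016-01-01", tz = "UTC"),
    t_end = as.POSIXct("2016-01-01", tz = "UTC") + c(300, 360, 10),
    gap_s = c(300, 360, 10))
  out <- suppressMessages(filter_recursions(mv))
  expect_equal(out$gap_s, c(360, 10))   # 300 s removed, 360 s kept, transition kept
})

test_that("RDET follows expected/observed with the species swim speed", {
  base <- as.POSIXct("2016-01-01", tz = "UTC")
  det <- data.table::data.table(
    tag_id = "A", receiver_id = c("R1", "R2"),
    timestamp = base + c(0, 6000))
  mv <- extract_movements(det)
  dmat <- matrix(c(0, 2070, 2070, 0), 2,
                 dimnames = list(c("R1", "R2"), c("R1", "R2")))
  out <- compute_rdet(mv, dmat, tiny_individuals())
  expect_equal(out$expected_s, 2070 / 0.69)   # 3000 s
  expect_equal(out$rdet, 0.5)

  # halving observed time doubles RDET
  det2 <- data.table::data.table(tag_id = "A", receiver_id = c("R1", "R2"),
                                 timestamp = base + c(0, 3000))
  out2 <- compute_rdet(extract_movements(det2), dmat, tiny_individuals())
  expect_equal(out2$rdet, 1)
})

test_that("RDET errors on missing metadata and overlapping stations", {
  base <- as.POSIXct("2016-01-01", tz = "UTC")
  det <- data.table::data.table(tag_id = "A", receiver_id = c("R1", "R2"),
                                timestamp = base + c(0, 6000))
  mv <- extract_movements(det)
  dmat0 <- matrix(0, 2, 2, dimnames = list(c("R1", "R2"), c("R1", "R2")))
  expect_error(compute_rdet(mv, dmat0, tiny_individuals()), "zero distance")
  expect_error(
    compute_rdet(mv, dmat0, data.table::data.table(
      tag_id = "Z", species = "gray_reef", sex = "F", total_length_cm = 90)),
    "without species")
})

test_that("transition filter is strict at the RDET ceiling", {
  mv <- data.table::data.table(
    tag_id = "X", kind = "transition",
    origin_receiver = "R1", dest_receiver = "R2",
    t_start = as.POSIXct("2016-01-01", tz = "UTC"),
    t_end = as.POSIXct("2016-01-01", tz = "UTC") + 10,
    gap_s = 10, species = "gray_reef", distance_m = 1,
    expected_s = 1, rdet = c(5.2, 5.0, 0.01))
  out <- suppressMessages(filter_transitions(mv))
  expect_equal(out$rdet, c(5.0, 0.01))
})

test_that("filters are idempotent and commute", {
  run <- small_pipeline_run()
  mv <- suppressWarnings(extract_movements(
    suppressMessages(read_detections(run$cfg$paths$detections))))
  dmat <- interreceiver_distances(run$sim$receivers)
  mv <- compute_rdet(mv, dmat, run$sim$individuals)
  ab <- suppressMessages(filter_transitions(filter_recursions(mv)))
  ba <- suppressMessages(filter_recursions(filter_transitions(mv)))
  data.table::setkey(ab, NULL); data.table::setkey(ba, NULL)
  expect_equal(as.data.frame(ab), as.data.frame(ba), ignore_attr = TRUE)
  again <- suppressMessages(filter_transitions(filter_recursions(ab)))
  expect_equal(as.data.frame(again), as.data.frame(ab), ignore_attr = TRUE)
})

test_that("RDET is invariant to the time unit when units stay consistent", {
  # distance in km and speed in km/s give the same RDET as metres and m/s
  base <- as.POSIXct("2016-01-01", tz = "UTC")
  det <- data.table::data.table(tag_id = "A", receiver_id = c("R1", "R2"),
                                timestamp = base + c(0, 7200))
  mv <- extract_movements(det)
  dmat_m <- matrix(c(0, 2070, 2070, 0), 2,
                   dimnames = list(c("R1", "R2"), c("R1", "R2")))
  sp_m <- data.frame(species = "gray_reef", swim_speed_m_s = 0.69)
  sp_km <- data.frame(species = "gray_reef", swim_speed_m_s = 0.69 / 1000)
  r1 <- compute_rdet(mv, dmat_m, tiny_individuals(), sp_m)$rdet
  r2 <- compute_rdet(mv, dmat_m / 1000, tiny_individuals(), sp_km)$rdet
  expect_equal(r1, r2)
})
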