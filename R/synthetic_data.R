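#' Simulation configuration
#'
#' Builds the full configuration for the synthetic telemetry generator, an
#' atoll-like receiver array monitored array of two-state movers. Defaults
#' emulate the study system: ring array with ~2.15 km nearest-neighbour
#' spacing (admissible range 0.55–4.57 km), tags with a nominal 60–180 s
#' random delay, per-transmission detection probability 0.5 within a 500 m
#' range, two shark species with distinct swim speeds and size
#' distributions, and a two-state (restricted / out-of-range) movement
#' process whose excursion probability follows a logistic model in species,
#' diel period and season with individual and receiver random intercepts
#' (coefficient defaults carry the fitted sign pattern: positive silvertip,
#' night and wet-season effects; random-intercept SDs `sqrt(0.43)`).
#'
#' State-dependent durations are log-normal: recursion gaps with median 18
#' min (restricted) vs 240 min (excursion), and transition RDET with median
#' 0.7 (restricted, near-direct) vs 0.05 (excursion) — mode ratios above 10,
#' i.e. clearly separated behavioural states.
#'
#' @param seed Integer seed; every random draw in the simulator flows from
#'   it.
#' @param ... Named overrides merged over the defaults (nested lists are
#'   merged recursively).
#' @return A nested configuration list.
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, window = list(days = 5))
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    array = list(n_receivers = 24L, layout = "ring", spacing_km = 2.15,
                 center_lat = -7.3, center_lon = 72.4,
                 nn_range_km = c(0.55, 4.57)),
    species = list(
      gray_reef = list(n = 14L, swim_speed_m_s = 0.69,
                       size_mean_cm = 119.15, size_sd_cm = 18.07,
                       prop_female = 76 / 102),
      silvertip = list(n = 11L, swim_speed_m_s = 0.73,
                       size_mean_cm = 123.56, size_sd_cm = 19.14,
                       prop_female = 44 / 75)
    ),
    tag_delay_s = c(60, 180),
    detection_prob = 0.5,
    detection_range_m = 500,
    # straddles the dry/wet boundary so season varies within the window
    window = list(start = "2016-03-01", days = 45L),
    residence = list(meanlog = log(90 * 60), sdlog = 0.8),
    state_model = list(beta0 = -0.475,
                       beta_species = c(gray_reef = 0, silvertip = 0.449),
                       beta_night = 0.179, beta_wet = 0.159,
                       sigma_tag = sqrt(0.43), sigma_receiver = sqrt(0.43)),
    movement = list(p_transition = 0.5, neighbor_radius_km = 5),
    durations = list(
      recursion = list(restricted_meanlog = log(18 * 60),
                       excursion_meanlog = log(240 * 60), sdlog = 0.6),
      transition_rdet = list(restricted_meanlog = log(0.7),
                             excursion_meanlog = log(0.05), sdlog = 0.4)
    ),
    timezone = "Etc/GMT-6"
  )
  modifyList(cfg, list(...))
}

#' Generate a synthetic receiver array
#'
#' Places `n_receivers` on a ring (or square grid) whose adjacent spacing is
#' `spacing_km`, around the configured centre, and verifies that every
#' nearest-neighbour distance falls inside the admissible range. The layout
#' is deterministic given the configuration.
#'
#' @param config From [sim_config()].
#' @return `data.table` of `receiver_id`, `latitude`, `longitude`.
#' @export
generate_array <- function(config) {
  a <- config$array
  n <- as.integer(a$n_receivers)
  if (n < 2L) stop("need at least two receivers")
  km_per_deg <- 111.195  # great-circle, R = 6371 km
  if (a$layout == "ring") {
    # chord between adjacent ring points equals the requested spacing
    radius_km <- a$spacing_km / (2 * sin(pi / n))
    theta <- 2 * pi * (seq_len(n) - 1L) / n
    lat <- a$center_lat + (radius_km * sin(theta)) / km_per_deg
    lon <- a$center_lon + (radius_km * cos(theta)) /
      (km_per_deg * cos(a$center_lat * pi / 180))
  } else if (a$layout == "grid") {
    side <- ceiling(sqrt(n))
    ij <- expand.grid(i = seq_len(side), j = seq_len(side))[seq_len(n), ]
    lat <- a$center_lat + (ij$i - (side + 1) / 2) * a$spacing_km / km_per_deg
    lon <- a$center_lon + (ij$j - (side + 1) / 2) * a$spacing_km /
      (km_per_deg * cos(a$center_lat * pi / 180))
  } else stop("unknown layout: ", a$layout)
  rec <- data.table(receiver_id = sprintf("R%02d", seq_len(n)),
                    latitude = lat, longitude = lon)
  d <- interreceiver_distances(rec) / 1000
  diag(d) <- Inf
  nn <- apply(d, 1L, min)
  if (any(nn < a$nn_range_km[1L]) || any(nn > a$nn_range_km[2L]))
    stop("infeasible spacing: nearest-neighbour distances ",
         sprintf("%.2f-%.2f km", min(nn), max(nn)),
         " outside [", a$nn_range_km[1L], ", ", a$nn_range_km[2L], "] km")
  rec[]
}

#' Simulate a telemetry study with known ground truth
#'
#' Each individual alternates residence bouts at a receiver (transmissions
#' at the nominal tag delay, thinned by the detection probability) with
#' movements. Each movement draws its true state (restricted vs
#' out-of-range) from the logistic state model evaluated at the departure
#' instant, its duration from the state's log-normal (recursions directly;
#' transitions via a state-dependent RDET, so duration =
#' expected-time / RDET), and its endpoint — the same receiver for
#' recursions, a uniformly chosen receiver within the neighbour radius for
#' transitions. Every movement is recorded in the ground-truth table whether
#' or not its bracketing detections survive thinning.
#'
#' @param config From [sim_config()].
#' @return List with `detections`, `receivers`, `individuals` (the three
#'   pipeline input tables), `truth` (`tag_id`, `t_start`, `t_end`, `kind`,
#'   `origin_receiver`, `dest_receiver`, `state` 0/1), and `params` (drawn
#'   random intercepts and the true coefficient vector).
#' @export
simulate_telemetry <- function(config = sim_config()) {
  set.seed(config$seed)
  receivers <- generate_array(config)
  dmat <- interreceiver_distances(receivers)
  n_recv <- nrow(receivers)
  sm <- config$state_model
  tz <- config$timezone

  # individuals
  sp_names <- names(config$species)
  ind <- rbindlist(lapply(sp_names, function(s) {
    p <- config$species[[s]]
    nn <- as.integer(p$n)
    code <- toupper(substr(gsub("[^a-z]", "", s), 1L, 2L))
    data.table(tag_id = sprintf("%s%03d", code, seq_len(nn)), species = s,
               sex = fifelse(runif(nn) < p$prop_female, "F", "M"),
               total_length_cm = round(pmax(
                 rnorm(nn, p$size_mean_cm, p$size_sd_cm), 40), 1))
  }))
  u_tag <- rnorm(nrow(ind), 0, sm$sigma_tag)
  names(u_tag) <- ind$tag_id
  u_recv <- rnorm(n_recv, 0, sm$sigma_receiver)
  names(u_recv) <- receivers$receiver_id

  t0 <- as.POSIXct(paste(config$window$start, "00:00:00"), tz = "UTC")
  t_end <- t0 + config$window$days * 86400
  delay <- config$tag_delay_s
  p_det <- config$detection_prob
  dur <- config$durations
  neighbors <- lapply(seq_len(n_recv), function(i) {
    j <- which(dmat[i, ] > 0 & dmat[i, ] <= config$movement$neighbor_radius_km * 1000)
    receivers$receiver_id[j]
  })
  names(neighbors) <- receivers$receiver_id

  det_list <- list()
  truth_list <- list()
  for (i in seq_len(nrow(ind))) {
    tag <- ind$tag_id[i]
    spec <- ind$species[i]
    speed <- config$species[[spec]]$swim_speed_m_s
    beta_sp <- sm$beta_species[[spec]]
    recv <- sample(receivers$receiver_id, 1L)
    t <- t0 + runif(1L, 0, 3600)
    dets <- vector("list", 2048L)
    truths <- vector("list", 1024L)
    nd <- 0L; nt <- 0L
    while (t < t_end) {
      # residence bout: pings at the nominal delay, thinned
      bout <- rlnorm(1L, config$residence$meanlog, config$residence$sdlog)
      n_ping <- ceiling(bout / delay[1L]) + 1L
      gaps <- runif(n_ping, delay[1L], delay[2L])
      ping <- t + cumsum(gaps)
      ping <- ping[ping <= t + bout]
      ping <- ping[runif(length(ping)) < p_det]
      if (length(ping) > 0L) {
        nd <- nd + 1L
        dets[[nd]] <- data.table(receiver_id = recv, timestamp = ping)
      }
      t_depart <- t + bout
      if (t_depart >= t_end) break
      # movement: true state from the logistic model at departure
      night <- assign_diel(t_depart, tz) == "night"
      wet <- assign_season(t_depart, tz) == "wet"
      eta <- sm$beta0 + beta_sp + sm$beta_night * night + sm$beta_wet * wet +
        u_tag[[tag]] + u_recv[[recv]]
      state <- rbinom(1L, 1L, plogis(eta))
      is_transition <- runif(1L) < config$movement$p_transition &&
        length(neighbors[[recv]]) > 0L
      if (is_transition) {
        dest <- sample(neighbors[[recv]], 1L)
        rd <- rlnorm(1L, if (state == 1L) dur$transition_rdet$excursion_meanlog
                         else dur$transition_rdet$restricted_meanlog,
                     dur$transition_rdet$sdlog)
        move_dur <- (dmat[recv, dest] / speed) / rd
      } else {
        dest <- recv
        move_dur <- rlnorm(1L, if (state == 1L) dur$recursion$excursion_meanlog
                               else dur$recursion$restricted_meanlog,
                           dur$recursion$sdlog)
      }
      nt <- nt + 1L
      truths[[nt]] <- data.table(
        t_start = t_depart, t_end = t_depart + move_dur,
        kind = if (is_transition) "transition" else "recursion",
        origin_receiver = recv, dest_receiver = dest, state = state)
      t <- t_depart + move_dur
      recv <- dest
    }
    if (nd > 0L) {
      dd <- rbindlist(dets[seq_len(nd)])
      dd[, tag_id := tag]
      det_list[[length(det_list) + 1L]] <- dd
    }
    if (nt > 0L) {
      tt <- rbindlist(truths[seq_len(nt)])
      tt[, tag_id := tag]
      truth_list[[length(truth_list) + 1L]] <- tt
    }
  }
  detections <- rbindlist(det_list)
  detections[, timestamp := as.POSIXct(round(as.numeric(timestamp)),
                                       origin = "1970-01-01", tz = "UTC")]
  setcolorder(detections, c("tag_id", "receiver_id", "timestamp"))
  setorder(detections, tag_id, timestamp)
  truth <- rbindlist(truth_list)
  setcolorder(truth, c("tag_id", "t_start", "t_end", "kind",
                       "origin_receiver", "dest_receiver", "state"))
  setorder(truth, tag_id, t_start)
  list(detections = detections[], receivers = receivers,
       individuals = ind[], truth = truth[],
       params = list(u_tag = u_tag, u_receiver = u_recv, beta = sm))
}

#' Write a simulated bundle to CSV files
#'
#' Emits the exact three-table input contract of the ingest module plus the
#' ground-truth table, with deterministic formatting: identical config and
#' seed give byte-identical files.
#'
#' @param sim Output of [simulate_telemetry()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_sim_bundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(detections = file.path(dir, "detections.csv"),
             receivers = file.path(dir, "receivers.csv"),
             individuals = file.path(dir, "individuals.csv"),
             truth = file.path(dir, "truth.csv"))
  write_table_csv(sim$detections, paths["detections"])
  write_table_csv(sim$receivers, paths["receivers"])
  write_table_csv(sim$individuals, paths["individuals"])
  write_table_csv(sim$truth, paths["truth"])
  invisible(paths)
}

#' Compare pipeline output against simulated ground truth
#'
#' Matches every labelled movement to the ground-truth movements its
#' detection gap spans (the observed gap runs from the last detection before
#' departure to the first after arrival, so each true movement interval is
#' contained in exactly one observed gap). A gap containing no true movement
#' is a within-bout recursion (missed detections) and is truly restricted; a
#' gap spanning several true movements (a fully undetected bout between
#' them) is truly out-of-range if any component was. Reports the label
#' confusion matrix and accuracy, and — when thresholds and a fitted model
#' are supplied — threshold position relative to the generator's duration
#' modes and fixed-effect recovery.
#'
#' @param labelled Output of [classify_movements()].
#' @param truth Ground-truth table from [simulate_telemetry()].
#' @param config The generator's [sim_config()] (for modes and true betas).
#' @param thresholds Optional [movement_thresholds()] output.
#' @param coefficients Optional [coef_table()]-style table for fixed-effect
#'   recovery (bias and CI coverage of the true values).
#' @return List: `confusion` (2x2 table truth x label), `accuracy`, `n`,
#'   and optionally `threshold_report` and `coef_recovery`.
#' @export
evaluate_recovery <- function(labelled, truth, config,
                              thresholds = NULL, coefficients = NULL) {
  lab <- as.data.table(labelled)
  tru <- as.data.table(truth)
  if (length(intersect(lab$tag_id, tru$tag_id)) == 0L)
    stop("no overlap between pipeline tags and ground-truth tags")
  tol <- 1.5  # s; detection timestamps are rounded to whole seconds
  lab[, truth_label := {
    res <- integer(.N)
    for (tg in unique(tag_id)) {
      li <- which(tag_id == tg)
      ti <- tru[tag_id == tg]
      s <- as.numeric(ti$t_start); e <- as.numeric(ti$t_end)
      ls <- as.numeric(t_start[li]); le <- as.numeric(t_end[li])
      for (j in seq_along(li)) {
        inside <- s >= ls[j] - tol & e <= le[j] + tol
        res[li[j]] <- if (any(inside)) max(ti$state[inside]) else 0L
      }
    }
    res
  }]
  confusion <- table(truth = factor(lab$truth_label, levels = 0:1),
                     label = factor(lab$label, levels = 0:1))
  out <- list(confusion = confusion,
              accuracy = mean(lab$truth_label == lab$label),
              n = nrow(lab))
  if (!is.null(thresholds)) {
    dr <- config$durations
    out$threshold_report <- list(
      recursion_modes_min = exp(c(dr$recursion$restricted_meanlog,
                                  dr$recursion$excursion_meanlog)) / 60,
      rdet_modes = exp(c(dr$transition_rdet$excursion_meanlog,
                         dr$transition_rdet$restricted_meanlog)),
      thresholds = as.data.table(thresholds))
  }
  if (!is.null(coefficients)) {
    sm <- config$state_model
    truth_beta <- c("(Intercept)" = sm$beta0,
                    setNames(sm$beta_species[-1L],
                             paste0("species", names(sm$beta_species)[-1L])),
                    dielnight = sm$beta_night, seasonwet = sm$beta_wet)
    ct <- as.data.table(coefficients)
    ct <- ct[term %in% names(truth_beta)]
    ct[, truth := truth_beta[term]]
    ct[, bias := estimate - truth]
    ct[, covered := truth >= ci_lower & truth <= ci_upper]
    out$coef_recovery <- ct[]
  }
  out
}

#' Simulate a modelling table directly from the logistic state model
#'
#' Bypasses the telemetry layer: draws labelled movements straight from
#' `logit P(out_of_range) = b0 + b_species + b_night + b_wet + u_tag +
#' u_receiver`, with balanced random covariates. Used for parameter-recovery
#' studies of the inference stage, where the quantity of interest is the
#' mixed model itself rather than the detection process.
#'
#' @param n_per_species Named integer vector of individuals per species.
#' @param movements_per_ind Movements per individual.
#' @param n_receivers Number of receiver levels.
#' @param beta Named list: `beta0`, `beta_species` (named, first entry the
#'   baseline 0), `beta_night`, `beta_wet`.
#' @param sigma_tag,sigma_receiver Random-intercept SDs.
#' @param seed RNG seed.
#' @return List: `table` (a [build_model_table()]-shaped `data.table`) and
#'   `params` (true intercepts and coefficients).
#' @export
simulate_model_table <- function(n_per_species = c(gray_reef = 75L, silvertip = 75L),
                                 movements_per_ind = 30L,
                                 n_receivers = 15L,
                                 beta = list(beta0 = -0.475,
                                             beta_species = c(gray_reef = 0,
                                                              silvertip = 0.449),
                                             beta_night = 0.179,
                                             beta_wet = 0.159),
                                 sigma_tag = sqrt(0.43),
                                 sigma_receiver = sqrt(0.43),
                                 seed = 1L) {
  set.seed(seed)
  n_ind <- sum(n_per_species)
  tags <- sprintf("T%03d", seq_len(n_ind))
  species <- rep(names(n_per_species), n_per_species)
  u_tag <- rnorm(n_ind, 0, sigma_tag)
  u_recv <- rnorm(n_receivers, 0, sigma_receiver)
  recv_ids <- sprintf("R%02d", seq_len(n_receivers))
  n <- n_ind * movements_per_ind
  idx <- rep(seq_len(n_ind), each = movements_per_ind)
  ridx <- sample.int(n_receivers, n, replace = TRUE)
  diel <- sample(c("day", "night"), n, replace = TRUE)
  season <- sample(c("dry", "wet"), n, replace = TRUE)
  sex <- rep(sample(c("F", "M"), n_ind, replace = TRUE), each = movements_per_ind)
  log_size <- rep(log(pmax(rnorm(n_ind, 120, 18), 40)), each = movements_per_ind)
  eta <- beta$beta0 + beta$beta_species[species[idx]] +
    beta$beta_night * (diel == "night") + beta$beta_wet * (season == "wet") +
    u_tag[idx] + u_recv[ridx]
  tab <- data.table(label = rbinom(n, 1L, plogis(eta)),
                    species = species[idx], sex = sex, log_size = log_size,
                    diel = diel, season = season,
                    tag_id = tags[idx], receiver_id = recv_ids[ridx])
  list(table = tab[],
       params = list(beta = beta, u_tag = setNames(u_tag, tags),
                     u_receiver = setNames(u_recv, recv_ids)))
}
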