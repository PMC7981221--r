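#' Fisher optimal 1-D partition (exact dynamic programming)
#'
#' Partitions sorted values into `k` contiguous classes minimising the total
#' within-class sum of squared deviations from class means (Fisher's exact
#' algorithm — the optimisation behind "natural breaks" classification).
#' Unlike heuristics such as k-means on 1-D data, the dynamic programme is
#' exact: no other contiguous partition has a lower objective.
#'
#' Ties are collapsed to weighted unique values first, which leaves the
#' optimum unchanged and keeps the cost at `O(u)` for `k = 2` and
#' `O(k u^2)` otherwise (`u` = number of unique values).
#'
#' @param values Finite numeric vector, length >= `k`.
#' @param k Number of classes (default 2).
#' @return Sorted numeric vector of the `k - 1` internal boundaries, each
#'   reported as the maximum value of its lower class. Attribute `objective`
#'   carries the minimised within-class sum of squares.
#' @export
#' @examples
#' fisher_breaks(c(0.9, 1.0, 1.1, 9.8, 10.0, 10.2), k = 2)  # 1.1
fisher_breaks <- function(values, k = 2L) {
  x <- as.numeric(values)
  if (any(!is.finite(x))) stop("values must be finite")
  n <- length(x)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("need at least k values (n = ", n, ", k = ", k, ")")
  x <- sort(x)
  u <- unique(x)
  if (length(u) == 1L) {
    warning("all values identical; degenerate boundary")
    out <- rep(u, k - 1L)
    attr(out, "objective") <- 0
    return(out)
  }
  w <- tabulate(match(x, u))
  m <- length(u)
  cw <- cumsum(w)
  cs <- cumsum(w * u)
  cs2 <- cumsum(w * u^2)
  # within-class SSE of u[i..j]
  sse <- function(i, j) {
    W <- cw[j] - if (i > 1L) cw[i - 1L] else 0
    S <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    S2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    S2 - S^2 / W
  }
  if (k == 2L) {
    best <- Inf; split <- 1L
    for (i in seq_len(m - 1L)) {
      obj <- sse(1L, i) + sse(i + 1L, m)
      if (obj < best) { best <- obj; split <- i }
    }
    out <- u[split]
    attr(out, "objective") <- best
    return(out)
  }
  if (k > m) stop("k exceeds the number of distinct values")
  # D[c, j]: optimal SSE for u[1..j] in c classes; B[c, j]: last class start
  D <- matrix(Inf, k, m)
  B <- matrix(1L, k, m)
  for (j in seq_len(m)) D[1L, j] <- sse(1L, j)
  for (cl in 2L:k) {
    for (j in cl:m) {
      for (i in cl:j) {
        obj <- D[cl - 1L, i - 1L] + sse(i, j)
        if (obj < D[cl, j]) { D[cl, j] <- obj; B[cl, j] <- i }
      }
    }
  }
  bounds <- numeric(k - 1L)
  j <- m
  for (cl in k:2L) {
    i <- B[cl, j]
    bounds[cl - 1L] <- u[i - 1L]
    j <- i - 1L
  }
  attr(bounds, "objective") <- D[k, m]
  bounds
}

#' Per-species recursion threshold
#'
#' Retained recursion gaps for one species are natural-log-transformed (gap
#' durations are strongly right-skewed), split into two classes by
#' [fisher_breaks()], and the single internal boundary is back-transformed
#' and returned in minutes. Gaps above the threshold are interpreted as
#' out-of-range excursions; at or below, restricted on-reef movement.
#'
#' @param movements Filtered movements carrying a `species` column
#'   (see [compute_rdet()]).
#' @param species Species name.
#' @return Threshold in minutes (full precision; round only for display).
#' @export
recursion_threshold <- function(movements, species) {
  mv <- as.data.table(movements)
  want <- species
  g <- mv[kind == "recursion" & species == want][["gap_s"]]
  if (length(g) < 2L)
    stop("need >= 2 retained recursions for species ", species)
  b <- fisher_breaks(log(g), k = 2L)
  exp(b[1L]) / 60
}

#' Per-species transition RDET threshold
#'
#' As [recursion_threshold()] but on log RDET of retained transitions; the
#' boundary is returned on the original RDET scale. Transitions *below* the
#' threshold (much slower than a direct swim) are interpreted as
#' out-of-range.
#'
#' @inheritParams recursion_threshold
#' @return RDET threshold (dimensionless).
#' @export
transition_threshold <- function(movements, species) {
  mv <- as.data.table(movements)
  want <- species
  r <- mv[kind == "transition" & species == want][["rdet"]]
  r <- r[!is.na(r)]
  if (length(r) < 2L)
    stop("need >= 2 retained transitions for species ", species)
  b <- fisher_breaks(log(r), k = 2L)
  exp(b[1L])
}

#' Classification thresholds for every species present
#'
#' @param movements Filtered movements with `species`, from the extraction
#'   chain.
#' @return `data.table` with one row per species: `species`,
#'   `recursion_threshold_min`, `transition_rdet_threshold`.
#' @export
movement_thresholds <- function(movements) {
  mv <- as.data.table(movements)
  out <- data.table(species = sort(unique(mv$species)))
  out[, recursion_threshold_min :=
        vapply(species, function(s) recursion_threshold(mv, s), 0)]
  out[, transition_rdet_threshold :=
        vapply(species, function(s) transition_threshold(mv, s), 0)]
  out[]
}

#' Label movements as restricted (0) or out-of-range (1)
#'
#' Recursions are out-of-range when the gap in minutes strictly exceeds the
#' species' recursion threshold; transitions when RDET is strictly below the
#' species' RDET threshold. Ties go to "restricted" — the conservative
#' choice, consistent with thresholds deliberately loose enough that a
#' tortuous on-reef movement still counts as restricted.
#'
#' @param movements Filtered movements with `species`.
#' @param thresholds Output of [movement_thresholds()].
#' @return Movements with an added integer `label` column
#'   (restricted = 0, out_of_range = 1).
#' @export
classify_movements <- function(movements, thresholds) {
  mv <- as.data.table(movements)
  th <- as.data.table(thresholds)
  missing_sp <- setdiff(unique(mv$species), th$species)
  if (length(missing_sp) > 0L)
    stop("no thresholds for species: ", paste(missing_sp, collapse = ", "))
  mv[th, `:=`(recursion_threshold_min = i.recursion_threshold_min,
              transition_rdet_threshold = i.transition_rdet_threshold),
     on = "species"]
  mv[, label := fifelse(kind == "recursion",
                        as.integer(gap_s / 60 > recursion_threshold_min),
                        as.integer(rdet < transition_rdet_threshold))]
  mv[, c("recursion_threshold_min", "transition_rdet_threshold") := NULL]
  mv[]
}
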