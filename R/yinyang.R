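#' Classify a point of the Yin-Yang figure
#'
#' Deterministic label from the standard yin-yang construction on the disc
#' of radius `r_big` centered at `(r_big, r_big)`: two small "dot" circles
#' of radius `r_small` centered at `(0.5 r_big, r_big)` and
#' `(1.5 r_big, r_big)`, and two interlocking half-discs of radius
#' `0.5 r_big`. Dot-circle membership is decided before the yin/yang
#' halves. The geometry constants are frozen to the dataset's public
#' definition (defaults give the unit square).
#'
#' @param x,y Coordinates (vectorized). Points must lie inside the outer
#'   circle; points outside raise an error (the sampler guarantees this).
#' @param r_small Dot-circle radius. Default 0.1.
#' @param r_big Outer radius. Default 0.5.
#' @return Character vector of labels among `"yin"`, `"yang"`, `"dot"`.
#' @export
classify_point <- function(x, y, r_small = 0.1, r_big = 0.5) {
  if (any((x - r_big)^2 + (y - r_big)^2 > r_big^2 + 1e-12))
    stop("point outside the outer circle: resample", call. = FALSE)
  d_right <- sqrt((x - 1.5 * r_big)^2 + (y - r_big)^2)
  d_left  <- sqrt((x - 0.5 * r_big)^2 + (y - r_big)^2)
  crit1 <- d_right <= r_small
  crit2 <- d_left > r_small & d_left <= 0.5 * r_big
  crit3 <- y > r_big & d_right > 0.5 * r_big
  is_yin <- crit1 | crit2 | crit3
  is_dot <- d_right < r_small | d_left < r_small
  ifelse(is_dot, "dot", ifelse(is_yin, "yin", "yang"))
}

#' Sample a class-balanced Yin-Yang dataset
#'
#' Rejection-samples points uniformly on the outer disc, cycling through
#' the three classes as per-sample goals so that class counts are balanced
#' up to rounding (`n = 999` gives exactly 333 per class). Reproducible for
#' a fixed seed.
#'
#' @param n Number of samples.
#' @param seed Optional integer seed for the sampler's RNG stream.
#' @param r_small,r_big Geometry constants, see [classify_point()].
#' @return A data frame with columns `x`, `y` (in `[0, 2 r_big]`) and
#'   `label` (character).
#' @export
sample_yinyang <- function(n, seed = NULL, r_small = 0.1, r_big = 0.5) {
  stopifnot(n > 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  classes <- c("yin", "yang", "dot")
  goals <- classes[((seq_len(n) - 1L) %% 3L) + 1L]
  xs <- numeric(n); ys <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      p <- stats::runif(2, 0, 2 * r_big)
      if ((p[1] - r_big)^2 + (p[2] - r_big)^2 > r_big^2) next
      if (classify_point(p[1], p[2], r_small, r_big) == goals[i]) break
    }
    xs[i] <- p[1]; ys[i] <- p[2]
  }
  data.frame(x = xs, y = ys, label = goals, stringsAsFactors = FALSE)
}

#' Encode coordinates as four input spike times
#'
#' The two coordinates and their mirrored values are mapped linearly to
#' spike times, `t = t0 + span * (x, y, 1 - x, 1 - y)`: a larger coordinate
#' spikes later while its mirror spikes earlier. The span is the time
#' difference between the earliest and latest possible input spikes (units
#' of `tau_s`). No bias/reference spike is added: the network has exactly
#' four input neurons.
#'
#' @param xy A data frame with columns `x`, `y` (in the unit square) or a
#'   length-2 numeric vector.
#' @param span Temporal span of the encoding. Must be positive.
#' @param t0 Time of the earliest possible spike. Default 0.
#' @return An `n x 4` matrix of spike times (columns: x, y, 1-x, 1-y).
#' @export
encode_spikes <- function(xy, span = 2, t0 = 0) {
  stopifnot(span > 0)
  if (is.data.frame(xy)) {
    x <- xy$x; y <- xy$y
  } else {
    x <- xy[1]; y <- xy[2]
  }
  cbind(t0 + span * x, t0 + span * y,
        t0 + span * (1 - x), t0 + span * (1 - y))
}

#' Generate an encoded Yin-Yang dataset
#'
#' Convenience wrapper combining [sample_yinyang()] and [encode_spikes()].
#'
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param span,t0 Encoding parameters, see [encode_spikes()].
#' @param r_small,r_big Geometry constants.
#' @return A list with `times` (`n x 4` spike-time matrix), `labels`
#'   (integer class index: 1 = yin, 2 = yang, 3 = dot), and `points` (the
#'   raw data frame).
#' @export
yinyang_dataset <- function(n, seed = NULL, span = 2, t0 = 0,
                            r_small = 0.1, r_big = 0.5) {
  pts <- sample_yinyang(n, seed = seed, r_small = r_small, r_big = r_big)
  list(times = encode_spikes(pts, span = span, t0 = t0),
       labels = match(pts$label, c("yin", "yang", "dot")),
       points = pts)
}
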