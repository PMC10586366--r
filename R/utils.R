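# Internal helpers: seed streams, 365-day calendar, small planar geometry.

# Named RNG sub-streams derived from one master seed, so that one component's
# draws do not shift another component's (application dates vs wind vs
# generator). Offsets are fixed per component name.
.stream_offsets <- c(
  generator   = 101L,
  application = 211L,
  wind        = 307L,
  hydrology   = 401L
)

#' Derive a component sub-seed from a master seed
#'
#' A single master seed spawns named per-component seeds so that component
#' level reproducibility holds when other components change.
#'
#' @param seed master integer seed
#' @param stream component name, one of `"generator"`, `"application"`,
#'   `"wind"`, `"hydrology"`
#' @return an integer seed below 2^31
#' @export
derive_seed <- function(seed, stream) {
  if (!stream %in% names(.stream_offsets)) {
    stop("unknown RNG stream: ", stream)
  }
  off <- .stream_offsets[[stream]]
  # simple LCG-style mix kept inside 31 bits
  as.integer((as.double(seed) * 48271 + off * 65537) %% 2147483647)
}

# Evaluate expr under a local RNG state seeded for a component stream,
# restoring the caller's .Random.seed afterwards.
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, stream))
  expr
}

## ---- 365-day calendar ------------------------------------------------------

# All simulation years have 365 days / 8760 hours; month lengths are the
# non-leap ones. Keeps annual windows and whole-year survival windows exact.
HOURS_PER_YEAR <- 8760L
DAYS_PER_YEAR <- 365L

.month_days <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
.month_start_doy <- c(0L, cumsum(.month_days))[1:12] + 1L

# day-of-year (1..365) for "MM-DD"
doy_from_mmdd <- function(mmdd) {
  parts <- strsplit(mmdd, "-", fixed = TRUE)
  vapply(parts, function(p) {
    m <- as.integer(p[1]); d <- as.integer(p[2])
    if (is.na(m) || is.na(d) || m < 1 || m > 12 || d < 1 || d > .month_days[m]) {
      stop("invalid month-day string; expected 'MM-DD'")
    }
    .month_start_doy[m] + d - 1L
  }, integer(1))
}

# ISO-8601 timestamp for a simulated hour (0-based within the run)
format_sim_hour <- function(hour0, base_year = 2001L) {
  yr <- base_year + hour0 %/% HOURS_PER_YEAR
  hoy <- hour0 %% HOURS_PER_YEAR
  doy <- hoy %/% 24L
  hh <- hoy %% 24L
  m <- findInterval(doy + 1L, .month_start_doy)
  d <- doy + 1L - .month_start_doy[m] + 1L
  sprintf("%04d-%02d-%02dT%02d:00:00", yr, m, d, hh)
}

## ---- planar geometry (projected metric coordinates) ------------------------

# distance from points (px,py) to segment (x1,y1)-(x2,y2)
.point_segment_dist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  L2 <- dx * dx + dy * dy
  t <- if (L2 == 0) 0 else pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / L2))
  sqrt((x1 + t * dx - px)^2 + (y1 + t * dy - py)^2)
}

# minimum distance between a point and a polyline (n x 2 matrix)
point_polyline_distance <- function(p, line) {
  n <- nrow(line)
  if (n == 1) return(sqrt(sum((p - line[1, ])^2)))
  min(.point_segment_dist(p[1], p[2],
                          line[-n, 1], line[-n, 2],
                          line[-1, 1], line[-1, 2]))
}

# nearest point on a polyline to p
nearest_point_on_polyline <- function(p, line) {
  n <- nrow(line)
  if (n == 1) return(line[1, ])
  best <- NULL; bestd <- Inf
  for (i in seq_len(n - 1)) {
    a <- line[i, ]; b <- line[i + 1, ]
    d2 <- sum((b - a)^2)
    t <- if (d2 == 0) 0 else max(0, min(1, sum((p - a) * (b - a)) / d2))
    q <- a + t * (b - a)
    dd <- sum((q - p)^2)
    if (dd < bestd) { bestd <- dd; best <- q }
  }
  best
}

# minimum distance between polygon boundary (closed ring, n x 2) and polyline
polygon_polyline_distance <- function(ring, line) {
  # sample: exact segment-segment distance
  segs_a <- cbind(ring, rbind(ring[-1, , drop = FALSE], ring[1, , drop = FALSE]))
  nb <- nrow(line)
  if (nb == 1) {
    return(min(.point_segment_dist(line[1, 1], line[1, 2],
                                   segs_a[, 1], segs_a[, 2], segs_a[, 3], segs_a[, 4])))
  }
  segs_b <- cbind(line[-nb, , drop = FALSE], line[-1, , drop = FALSE])
  dmin <- Inf
  for (i in seq_len(nrow(segs_a))) {
    a1 <- segs_a[i, 1:2]; a2 <- segs_a[i, 3:4]
    for (j in seq_len(nrow(segs_b))) {
      b1 <- segs_b[j, 1:2]; b2 <- segs_b[j, 3:4]
      dmin <- min(dmin, .segment_segment_dist(a1, a2, b1, b2))
      if (dmin == 0) return(0)
    }
  }
  dmin
}

.segment_segment_dist <- function(a1, a2, b1, b2) {
  if (.segments_intersect(a1, a2, b1, b2)) return(0)
  min(
    .point_segment_dist(a1[1], a1[2], b1[1], b1[2], b2[1], b2[2]),
    .point_segment_dist(a2[1], a2[2], b1[1], b1[2], b2[1], b2[2]),
    .point_segment_dist(b1[1], b1[2], a1[1], a1[2], a2[1], a2[2]),
    .point_segment_dist(b2[1], b2[2], a1[1], a1[2], a2[1], a2[2])
  )
}

.segments_intersect <- function(a1, a2, b1, b2) {
  cr <- function(o, p, q) (p[1] - o[1]) * (q[2] - o[2]) - (p[2] - o[2]) * (q[1] - o[1])
  d1 <- cr(b1, b2, a1); d2 <- cr(b1, b2, a2)
  d3 <- cr(a1, a2, b1); d4 <- cr(a1, a2, b2)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on <- function(o, p, q) {
    min(o[1], p[1]) <= q[1] && q[1] <= max(o[1], p[1]) &&
      min(o[2], p[2]) <= q[2] && q[2] <= max(o[2], p[2])
  }
  (d1 == 0 && on(b1, b2, a1)) || (d2 == 0 && on(b1, b2, a2)) ||
    (d3 == 0 && on(a1, a2, b1)) || (d4 == 0 && on(a1, a2, b2))
}

# polygon area (shoelace, ring not necessarily closed) and centroid
polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_centroid <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

# compass bearing (degrees, 0 = north, clockwise) from p to q
bearing_deg <- function(p, q) {
  (atan2(q[1] - p[1], q[2] - p[2]) * 180 / pi) %% 360
}

# smallest absolute angular difference in degrees
angle_diff_deg <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}
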