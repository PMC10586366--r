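# Landscape-scale risk characterisation end points: annual peak
# concentration (PECmax) tables, pooled percentiles, spatiotemporal rank
# matrices, exceedance fractions, and worst-year LP50 category maps.

#' Annual maximum of hourly averaged concentrations (PECmax)
#'
#' @param field a `concentration_field` covering whole assessment years
#' @return a `pec_table` data.frame: `reach_id`, `year`, `pec_max` (ug/L),
#'   and `below_floor` flag for values under the reporting floor
#' @param floor_conc reporting floor (ug/L, default 1e-6); values below it
#'   are kept but flagged
#' @export
pec_max <- function(field, floor_conc = 1e-6) {
  hpy <- field$hours_per_year
  if (ncol(field$cw) %% hpy != 0) stop("field must cover whole years")
  n_years <- ncol(field$cw) %/% hpy
  out <- do.call(rbind, lapply(seq_len(n_years), function(y) {
    block <- field$cw[, ((y - 1) * hpy + 1):(y * hpy), drop = FALSE]
    data.frame(reach_id = field$reach_ids, year = y,
               pec_max = apply(block, 1, max), stringsAsFactors = FALSE)
  }))
  out$below_floor <- out$pec_max < floor_conc
  rownames(out) <- NULL
  class(out) <- c("pec_table", "data.frame")
  out
}

#' Overall pooled percentile of a reach-by-year table
#'
#' Pools all reach x year values and returns the requested percentile.
#' Two estimators are exposed: `"interpolated"` (linear interpolation
#' between order statistics, the default) and `"count"` (empirical
#' inverse-CDF, type 1). For LP50 tables, sentinel entries
#' (`NO_EXPOSURE`, `ABOVE_CUTOFF`) are treated as better-than-any-finite
#' values: they are placed above the cutoff so that low percentiles of
#' LP50 are driven by the finite (at-risk) values.
#'
#' @param table a `pec_table` or `lp50_table`
#' @param p percentile in `[0, 100]`
#' @param estimator `"interpolated"` or `"count"`
#' @param sentinel_value value substituted for sentinels in LP50 tables
#'   (default `Inf`)
#' @return scalar percentile value
#' @export
overall_percentile <- function(table, p, estimator = c("interpolated", "count"),
                               sentinel_value = Inf) {
  estimator <- match.arg(estimator)
  if (inherits(table, "lp50_table")) {
    v <- ifelse(table$sentinel == "none", table$lp50, sentinel_value)
  } else if (inherits(table, "pec_table")) {
    v <- table$pec_max
  } else {
    v <- as.numeric(table)
  }
  v <- v[!is.na(v)]
  if (!length(v) || all(!is.finite(v))) {
    stop("overall_percentile: no finite values to pool")
  }
  type <- if (estimator == "interpolated") 7 else 1
  # keep infinite sentinels out of the interpolation arithmetic
  huge <- 1e300
  q <- unname(stats::quantile(pmin(v, huge), p / 100, type = type,
                              names = FALSE))
  if (q > huge / 2) Inf else q
}

#' Spatiotemporal rank matrix
#'
#' Columns are reaches, rows are years. For exposure (`direction =
#' "exposure"`, PECmax): within each column years are sorted ascending from
#' the top, so each reach's maximum sits at the bottom; columns are then
#' sorted descending by their largest value, putting the highest PECmax in
#' the bottom-left corner. For effects (`direction = "effect"`, LP50):
#' within each column years are sorted so the lowest LP50 is at the
#' bottom, and columns ascending by their smallest value, putting the
#' lowest LP50 bottom-left. Sentinels rank as better than any finite value
#' (finite < ABOVE_CUTOFF < NO_EXPOSURE on the risk scale) and are
#' reported in the sentinel mask.
#'
#' Ties between columns are broken by reach id (lexicographic).
#'
#' @param table a `pec_table` or `lp50_table` (one species/variant slice)
#' @param direction `"exposure"` or `"effect"`
#' @return a `rank_matrix`: list with `values` (years x reaches, row 1 =
#'   top), `reach_order`, `sentinel` (character matrix mask)
#' @export
build_rank_matrix <- function(table, direction = c("exposure", "effect")) {
  direction <- match.arg(direction)
  if (direction == "exposure") {
    val <- table$pec_max; sent <- rep("none", nrow(table))
  } else {
    if (!all(c("lp50", "sentinel") %in% names(table))) {
      stop("effect direction requires an lp50_table")
    }
    if (length(unique(paste(table$species, table$variant))) > 1) {
      stop("rank matrix requires a single species x variant slice")
    }
    val <- table$lp50; sent <- table$sentinel
  }
  ids <- sort(unique(table$reach_id))
  years <- sort(unique(table$year))
  ny <- length(years)
  # sort key: effect sentinels above the cutoff, ABOVE_CUTOFF < NO_EXPOSURE
  key <- val
  key[sent == "ABOVE_CUTOFF"] <- Inf
  key[sent == "NO_EXPOSURE"] <- Inf
  rank2 <- ifelse(sent == "NO_EXPOSURE", 2, ifelse(sent == "ABOVE_CUTOFF", 1, 0))

  vmat <- matrix(NA_real_, ny, length(ids), dimnames = list(years, ids))
  smat <- matrix("none", ny, length(ids), dimnames = list(years, ids))
  for (j in seq_along(ids)) {
    sel <- table$reach_id == ids[j]
    kj <- key[sel]; vj <- val[sel]; sj <- sent[sel]; r2 <- rank2[sel]
    if (length(kj) != ny) stop("table must be complete (every reach x year)")
    if (direction == "exposure") {
      o <- order(kj) # ascending; max at bottom
    } else {
      o <- order(-kj, -r2) # lowest LP50 at bottom, worst sentinel above
    }
    vmat[, j] <- vj[o]; smat[, j] <- sj[o]
  }
  # column order
  if (direction == "exposure") {
    colkey <- apply(vmat, 2, max)
    jo <- order(-colkey, ids)
  } else {
    ck <- key
    colmin <- vapply(seq_along(ids), function(j) {
      sel <- table$reach_id == ids[j]
      min(ck[sel])
    }, numeric(1))
    jo <- order(colmin, ids)
  }
  structure(list(values = vmat[, jo, drop = FALSE],
                 sentinel = smat[, jo, drop = FALSE],
                 reach_order = ids[jo],
                 direction = direction),
            class = "rank_matrix")
}

#' Fraction of reaches exceeding (or below) a bound in at most a fraction
#' of years
#'
#' For exposure matrices: the fraction of reaches whose value exceeds
#' `bound` in at least one year and in at most `at_most_years` of the
#' assessment years. For effect matrices the criterion is values BELOW the
#' bound (a small LP50 is the risk). `at_most_years = 1` gives the plain
#' fraction of reaches ever exceeding.
#'
#' @param matrix a `rank_matrix`
#' @param bound finite threshold value
#' @param at_most_years fraction of years in `[0, 1]`
#' @return fraction of reaches in `[0, 1]`
#' @export
fraction_exceeding <- function(matrix, bound, at_most_years = 1) {
  stopifnot(is.finite(bound))
  v <- matrix$values
  hit <- if (matrix$direction == "exposure") {
    v > bound
  } else {
    ok <- matrix$sentinel == "none" & !is.na(v)
    ok & v < bound
  }
  cnt <- colSums(hit, na.rm = TRUE)
  ny <- nrow(v)
  mean(cnt >= 1 & cnt <= at_most_years * ny)
}

#' LP50 category map for the worst (lower-percentile) year
#'
#' For each reach, takes the year at the given lower percentile of its
#' LP50 values (the 5th percentile of 20 years is the worst year) using
#' the risk ordering finite < ABOVE_CUTOFF < NO_EXPOSURE, then bins it
#' into the categories `<1`, `1-10`, `10-100`, `100-1e5` (left-closed
#' bins), `effect-free` (above the cutoff) and `no-exposure`.
#'
#' @param table an `lp50_table` slice (one species x variant)
#' @param year_percentile lower percentile of years (default 5)
#' @param cutoff LP50 cutoff used for the effect-free class
#' @return a `category_map` data.frame: `reach_id`, `lp50_worst`,
#'   `category`
#' @export
categorize_lp50 <- function(table, year_percentile = 5, cutoff = 1e5) {
  if (length(unique(paste(table$species, table$variant))) > 1) {
    stop("category map requires a single species x variant slice")
  }
  ids <- sort(unique(table$reach_id))
  ny <- length(unique(table$year))
  # index of the percentile year among sorted (worst-first) years
  k <- max(1L, ceiling(year_percentile / 100 * ny))
  out <- do.call(rbind, lapply(ids, function(id) {
    sel <- table$reach_id == id
    v <- table$lp50[sel]; s <- table$sentinel[sel]
    key <- ifelse(s == "none", v, ifelse(s == "ABOVE_CUTOFF", Inf, Inf))
    r2 <- ifelse(s == "NO_EXPOSURE", 2, ifelse(s == "ABOVE_CUTOFF", 1, 0))
    o <- order(key, r2) # worst (smallest LP50) first; finite beats sentinels
    vi <- v[o][k]; si <- s[o][k]
    cat <- if (si == "NO_EXPOSURE") "no-exposure"
           else if (si == "ABOVE_CUTOFF" || (!is.na(vi) && vi >= cutoff)) "effect-free"
           else if (vi < 1) "<1"
           else if (vi < 10) "1-10"
           else if (vi < 100) "10-100"
           else "100-1e5"
    data.frame(reach_id = id,
               lp50_worst = if (si == "none") vi else NA_real_,
               category = cat, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$category <- factor(out$category,
                         levels = c("<1", "1-10", "10-100", "100-1e5",
                                    "effect-free", "no-exposure"))
  class(out) <- c("category_map", "data.frame")
  out
}

#' Heatmap of a rank matrix
#'
#' Simple base-graphics rendering of the spatiotemporal percentile plot:
#' reach columns against year rows, on a log colour scale, with sentinel
#' cells shown in grey. Optional reporting aid, not part of the numeric
#' contract.
#'
#' @param x a `rank_matrix`
#' @param main plot title
#' @param ... passed to [graphics::image()]
#' @export
plot.rank_matrix <- function(x, main = NULL, ...) {
  v <- x$values
  lv <- log10(pmax(v, 1e-12))
  lv[x$sentinel != "none"] <- NA
  graphics::image(x = seq_len(ncol(v)), y = seq_len(nrow(v)),
                  z = t(lv)[, nrow(v):1, drop = FALSE],
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "reaches (ranked)", ylab = "years (ranked)",
                  main = main %||% paste("rank matrix:", x$direction), ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
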