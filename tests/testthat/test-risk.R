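# helpers to build tables directly
make_pec_table <- function(values) {
  # values: reaches x years matrix with reach ids as rownames
  df <- do.call(rbind, lapply(seq_len(ncol(values)), function(y) {
    data.frame(reach_id = rownames(values), year = y,
               pec_max = values[, y], stringsAsFactors = FALSE)
  }))
  df$below_floor <- df$pec_max < 1e-6
  rownames(df) <- NULL
  class(df) <- c("pec_table", "data.frame")
  df
}

make_lp50_table <- function(values, sentinels = NULL) {
  df <- do.call(rbind, lapply(seq_len(ncol(values)), function(y) {
    data.frame(reach_id = rownames(values), year = y, species = "sp",
               variant = "IT", lp50 = values[, y], stringsAsFactors = FALSE)
  }))
  df$sentinel <- if (is.null(sentinels)) "none" else as.vector(sentinels)
  df$lp50[df$sentinel != "none"] <- NA_real_
  rownames(df) <- NULL
  class(df) <- c("lp50_table", "data.frame")
  df
}

test_that("pec_max equals a brute-force scan over the hour axis", {
  set.seed(61)
  hpy <- 8760
  cw <- matrix(rexp(3 * 2 * hpy, 100), nrow = 3)
  rownames(cw) <- c("a", "b", "c")
  field <- structure(list(cw = cw, reach_ids = c("a", "b", "c"), n_years = 2,
                          hours_per_year = hpy),
                     class = "concentration_field")
  tab <- pec_max(field)
  for (y in 1:2) {
    for (i in 1:3) {
      expect_equal(tab$pec_max[tab$year == y][i],
                   max(cw[i, ((y - 1) * hpy + 1):(y * hpy)]))
    }
  }
  # constant field: pec_max equals the constant
  fieldc <- structure(list(cw = matrix(0.25, 2, hpy,
                                       dimnames = list(c("x", "y"), NULL)),
                           reach_ids = c("x", "y"), n_years = 1,
                           hours_per_year = hpy),
                      class = "concentration_field")
  expect_true(all(pec_max(fieldc)$pec_max == 0.25))
})

test_that("overall percentile: order-statistics arithmetic, edges, monotonicity", {
  v <- matrix(1:100, nrow = 10, dimnames = list(paste0("r", 1:10), NULL))
  tab <- make_pec_table(v)
  expect_equal(overall_percentile(tab, 90), 90.1) # interpolated estimator
  expect_equal(overall_percentile(tab, 100), 100) # maximum
  single <- make_pec_table(matrix(7, 1, 1, dimnames = list("r", NULL)))
  expect_equal(overall_percentile(single, 13), 7)
  expect_equal(overall_percentile(single, 95), 7)
  ps <- seq(0, 100, by = 5)
  qs <- vapply(ps, function(p) overall_percentile(tab, p), numeric(1))
  expect_true(all(diff(qs) >= 0))
  # invariant to reach ordering
  tab2 <- tab[sample(nrow(tab)), ]
  class(tab2) <- class(tab)
  expect_equal(overall_percentile(tab2, 37), overall_percentile(tab, 37))
  # count-based estimator stays on observed values
  expect_true(overall_percentile(tab, 90, estimator = "count") %in% 1:100)
  # sentinel-only input errors
  allsent <- make_lp50_table(matrix(1, 1, 1, dimnames = list("r", NULL)),
                             sentinels = "NO_EXPOSURE")
  expect_error(overall_percentile(allsent, 10), "no finite")
})

test_that("exposure rank matrix sorts years ascending and columns by max", {
  v <- matrix(c(5, 1, 3, 2, 0, 0), nrow = 2,
              dimnames = list(NULL, c("r1", "r2", "r3")))
  # per-reach year values: r1 (5,1), r2 (3,2), r3 (0,0)
  tab <- make_pec_table(t(v)) # transpose to reaches x years
  rm <- build_rank_matrix(tab, "exposure")
  expect_equal(rm$reach_order, c("r1", "r2", "r3"))
  expect_equal(rm$values[, 1], c("1" = 1, "2" = 5)) # top -> bottom ascending
  expect_equal(rm$values[, 2], c("1" = 2, "2" = 3))
  # 1x1 matrix
  one <- make_pec_table(matrix(4, 1, 1, dimnames = list("solo", NULL)))
  rm1 <- build_rank_matrix(one, "exposure")
  expect_equal(dim(rm1$values), c(1, 1))
  # tie case: equal columns fall back to reach-id order
  tie <- make_pec_table(matrix(2, 3, 2, dimnames = list(c("b", "a", "c"), NULL)))
  rmt <- build_rank_matrix(tie, "exposure")
  expect_equal(rmt$reach_order, c("a", "b", "c"))
})

test_that("rank-matrix columns are permutations of the input (property)", {
  set.seed(71)
  for (k in 1:20) {
    nr <- sample(1:6, 1); ny <- sample(1:6, 1)
    v <- matrix(round(runif(nr * ny, 0, 10), 2), nr,
                dimnames = list(paste0("r", seq_len(nr)), NULL))
    tab <- make_pec_table(v)
    rm <- build_rank_matrix(tab, "exposure")
    for (id in rownames(v)) {
      expect_equal(sort(unname(rm$values[, which(rm$reach_order == id)])),
                   sort(unname(v[id, ])))
    }
    # column order: non-increasing column maxima
    cmax <- apply(rm$values, 2, max)
    expect_true(all(diff(cmax) <= 1e-12))
    # within-column ascending (max at the bottom row)
    for (j in seq_len(ncol(rm$values))) {
      expect_true(all(diff(rm$values[, j]) >= -1e-12))
    }
  }
})

test_that("effect rank matrix puts lowest LP50 bottom-left with sentinels on top", {
  v <- matrix(c(50, 2, NA, NA, 1000, 20), nrow = 2,
              dimnames = list(NULL, c("rA", "rB", "rC")))
  sent <- matrix(c("none", "none", "NO_EXPOSURE", "ABOVE_CUTOFF",
                   "none", "none"), nrow = 2)
  tab <- make_lp50_table(t(v), sentinels = t(sent))
  rm <- build_rank_matrix(tab, "effect")
  # rA has the lowest LP50 (2) -> leftmost; bottom row = worst year
  expect_equal(rm$reach_order[1], "rA")
  expect_equal(unname(rm$values[2, 1]), 2) # bottom = lowest
  expect_equal(unname(rm$values[1, 1]), 50)
  # all-sentinel reach ranks last
  expect_equal(rm$reach_order[3], "rB")
  expect_equal(rm$sentinel[1, 3], "NO_EXPOSURE") # worse sentinel on top
  expect_equal(rm$sentinel[2, 3], "ABOVE_CUTOFF")
})

test_that("fraction_exceeding equals an exhaustive double-loop oracle up to 6x6", {
  oracle <- function(values, bound, at_most, direction) {
    # values: years x reaches
    ny <- nrow(values)
    cnt <- 0
    for (j in seq_len(ncol(values))) {
      hits <- 0
      for (i in seq_len(ny)) {
        hit <- if (direction == "exposure") values[i, j] > bound
               else values[i, j] < bound
        if (!is.na(hit) && hit) hits <- hits + 1
      }
      if (hits >= 1 && hits <= at_most * ny) cnt <- cnt + 1
    }
    cnt / ncol(values)
  }
  set.seed(81)
  for (nr in 1:6) {
    for (ny in 1:6) {
      v <- matrix(sample(0:8, nr * ny, replace = TRUE), nrow = nr,
                  dimnames = list(paste0("r", seq_len(nr)), NULL))
      tab <- make_pec_table(v)
      rm <- build_rank_matrix(tab, "exposure")
      for (bound in c(-1, 2.5, 4, 8.5)) {
        for (am in c(0.25, 0.5, 1)) {
          expect_equal(fraction_exceeding(rm, bound, am),
                       oracle(rm$values, bound, am, "exposure"),
                       label = sprintf("%dx%d bound %.1f am %.2f", nr, ny, bound, am))
        }
      }
    }
  }
  # toy case from the exposure matrix above, by hand: bound 2.5, half the years
  v <- matrix(c(5, 1, 3, 2, 0, 0), nrow = 2,
              dimnames = list(NULL, c("r1", "r2", "r3")))
  rm <- build_rank_matrix(make_pec_table(t(v)), "exposure")
  expect_equal(fraction_exceeding(rm, 2.5, 0.5), 2 / 3)
  # bound above everything: nothing exceeds
  expect_equal(fraction_exceeding(rm, 99, 1), 0)
})

test_that("worst-year LP50 categories: binning, sentinels, mixed ordering", {
  # 20 finite years: category of the minimum (5th percentile of 20 = worst)
  vals <- matrix(seq(5, 100, length.out = 20), 1,
                 dimnames = list("r1", NULL))
  tab <- make_lp50_table(vals)
  cm <- categorize_lp50(tab)
  expect_equal(as.character(cm$category), "1-10") # min = 5
  expect_equal(cm$lp50_worst, 5)
  # all NO_EXPOSURE
  tabne <- make_lp50_table(matrix(1, 1, 3, dimnames = list("r", NULL)),
                           sentinels = matrix("NO_EXPOSURE", 1, 3))
  expect_equal(as.character(categorize_lp50(tabne)$category), "no-exposure")
  # mixed sentinels and finite values: the finite worst year wins
  tabmix <- make_lp50_table(
    matrix(c(NA, 150, NA), 1, 3, dimnames = list("r", NULL)),
    sentinels = matrix(c("NO_EXPOSURE", "none", "ABOVE_CUTOFF"), 1, 3))
  cmix <- categorize_lp50(tabmix)
  expect_equal(as.character(cmix$category), "100-1e5")
  # boundary convention: left-closed bins
  for (pair in list(c(1, "1-10"), c(10, "10-100"), c(100, "100-1e5"),
                    c(0.99, "<1"), c(1e5, "effect-free"))) {
    t1 <- make_lp50_table(matrix(as.numeric(pair[1]), 1, 1,
                                 dimnames = list("r", NULL)))
    expect_equal(as.character(categorize_lp50(t1)$category), pair[2],
                 label = pair[1])
  }
})
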