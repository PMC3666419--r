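# Published reference grids of expected SNV counts (theta = 13,333), as
# printed: 15 sample sizes x 8 design/filter columns, NA where the grid
# leaves a cell blank. Printed values carry two decimals, so computed cells
# are compared with absolute tolerance 0.02.

reference_grid_rows <- c(1, 2, 3, 4, 5, 10, 11, 13, 20, 21, 23, 50, 51, 53, 100)

make_reference_grid <- function(cells) {
  m <- matrix(cells, ncol = 8, byrow = TRUE)
  colnames(m) <- paste0("col", 1:8)
  rownames(m) <- reference_grid_rows
  m
}

# Unrelated, dominant.
reference_grid_2 <- make_reference_grid(c(
  19999.50,      NA,       NA,      NA,      NA,      NA,     NA,     NA,
  12221.92,      NA,       NA, 7777.58, 7777.58,      NA,     NA,     NA,
   9333.10,      NA,       NA,      NA, 2888.82,      NA,     NA,     NA,
   7761.71,      NA,       NA, 1317.43, 1571.39,      NA,     NA,     NA,
   6751.15,      NA, 11803.94,      NA, 1010.56,      NA,     NA,     NA,
   4450.20, 7292.89,  9899.74,   12.68,  284.27,      NA,     NA, 487.69,
   4209.42,      NA,       NA,      NA,  240.77, 1325.27,     NA,     NA,
   3821.65,      NA,       NA,      NA,  180.60,      NA, 111.07,     NA,
   2992.04, 6220.39,  8915.41,    0.01,   87.51,      NA,     NA,  28.51,
   2911.32,      NA,       NA,      NA,   80.72,  944.79,     NA,     NA,
   2767.09,      NA,       NA,      NA,   69.48,      NA,  45.77,     NA,
   1808.56, 5540.39,  8311.92,      NA,   19.82,      NA,     NA,   0.02,
   1789.36,      NA,       NA,      NA,      NA,  736.85,     NA,     NA,
   1752.68,      NA,       NA,      NA,      NA,      NA,  21.74,     NA,
   1249.75, 5306.36,  8108.38,      NA,      NA,      NA,     NA,     NA))

# Unrelated, recessive.
reference_grid_3 <- make_reference_grid(c(
  6666.50,      NA,      NA,      NA,      NA,     NA,    NA,     NA,
  3333.25,      NA,      NA, 3333.25, 3333.25,     NA,    NA,     NA,
  2222.17,      NA,      NA,      NA, 1111.08,     NA,    NA,     NA,
  1666.63,      NA,      NA,  555.54,  555.54,     NA,    NA,     NA,
  1333.30,      NA, 2999.93,      NA,  333.33,     NA,    NA,     NA,
   666.65, 1407.37, 2240.68,    5.29,   74.07,     NA,    NA, 203.70,
   606.05,      NA,      NA,      NA,   60.60, 422.55,    NA,     NA,
   512.81,      NA,      NA,      NA,   42.73,     NA, 41.83,     NA,
   333.33, 1054.55, 1863.36,    0.00,   17.54,     NA,    NA,  11.86,
   317.45,      NA,      NA,      NA,   15.87, 276.10,    NA,     NA,
   289.85,      NA,      NA,      NA,   13.17,     NA, 15.73,     NA,
   133.33,  843.18, 1637.71,      NA,    2.72,     NA,    NA,   0.01,
   130.72,      NA,      NA,      NA,      NA, 199.84,    NA,     NA,
   125.78,      NA,      NA,      NA,      NA,     NA,  6.80,     NA,
    66.67,  772.77, 1562.62,      NA,      NA,     NA,    NA,     NA))

# Full-sibs, dominant.
reference_grid_4 <- make_reference_grid(c(
  19999.50,       NA,       NA,      NA,      NA,     NA,     NA,     NA,
  15832.94,       NA,       NA, 4166.56, 4166.56,     NA,     NA,     NA,
  13541.33,       NA,       NA,      NA, 2291.61,     NA,     NA,     NA,
  12239.28,       NA,       NA,  989.56, 1302.05,     NA,     NA,     NA,
  11471.07,       NA, 15312.12,      NA,  768.21,     NA,     NA,     NA,
  10263.05, 11227.51, 13064.81,   14.05,   96.45,     NA,     NA, 512.68,
  10193.97,       NA,       NA,      NA,   69.08, 948.55,     NA,     NA,
  10106.96,       NA,       NA,      NA,   36.82,     NA, 127.64,     NA,
  10013.86, 10408.02, 11922.23,    0.01,    4.71,     NA,     NA,  40.85,
  10010.33,       NA,       NA,      NA,    3.53, 500.32,     NA,     NA,
  10005.70,       NA,       NA,      NA,    1.98,     NA,  38.66,     NA,
   9999.75, 10031.07, 11165.22,      NA,    0.00,     NA,     NA,   0.06,
   9999.75,       NA,       NA,      NA,      NA, 291.41,     NA,     NA,
   9999.75,       NA,       NA,      NA,      NA,     NA,  18.23,     NA,
   9999.75, 10000.36, 10661.20,      NA,      NA,     NA,     NA,     NA))

# Full-sibs, recessive.
reference_grid_5 <- make_reference_grid(c(
  6666.50,      NA,      NA,      NA,      NA,     NA,    NA,     NA,
  4722.10,      NA,      NA, 1944.40, 1944.40,     NA,    NA,     NA,
  3958.23,      NA,      NA,      NA,  763.87,     NA,    NA,     NA,
  3628.38,      NA,      NA,  434.02,  329.85,     NA,    NA,     NA,
  3476.48,      NA, 4236.01,      NA,  151.91,     NA,    NA,     NA,
  3337.59, 3381.12, 3578.15,    5.37,    4.35,     NA,    NA, 200.19,
  3335.42,      NA,      NA,      NA,    2.17, 122.91,    NA,     NA,
  3333.79,      NA,      NA,      NA,    0.54,     NA, 31.16,     NA,
  3333.25, 3334.14, 3359.51,    0.00,    0.00,     NA,    NA,  14.26,
  3333.25,      NA,      NA,      NA,    0.00,  13.13,    NA,     NA,
  3333.25,      NA,      NA,      NA,    0.00,     NA,  3.28,     NA,
  3333.25, 3333.25, 3333.30,      NA,    0.00,     NA,    NA,   0.02,
  3333.25,      NA,      NA,      NA,      NA,   0.03,    NA,     NA,
  3333.25,      NA,      NA,      NA,      NA,     NA,  0.01,     NA,
  3333.25, 3333.25, 3333.25,      NA,      NA,     NA,    NA,     NA))

reference_grids <- list("2" = reference_grid_2, "3" = reference_grid_3,
                        "4" = reference_grid_4, "5" = reference_grid_5)

# Compare a reproduce_table() result against a printed grid: identical NA
# pattern, defined cells within 0.02 absolute.
expect_grid_match <- function(computed, printed, tol = 0.02) {
  vals <- as.matrix(computed[, -1L])
  expect_identical(unname(is.na(vals)), unname(is.na(printed)))
  ok <- !is.na(printed)
  expect_lt(max(abs(vals[ok] - printed[ok])), tol)
}
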