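th <- 13333

test_that("mating-type table carries the correct rates and offspring laws", {
  mt <- mating_type_expectations(th)
  expect_identical(mt$label, c("RRxRA", "RRxAA", "RAxRA", "RAxAA", "AAxAA"))
  expect_equal(mt$snv_weight, th * c(1, 1 / 6, 1 / 3, 1 / 3, 1 / 4))
  expect_equal(unlist(mt[mt$label == "RAxRA", c("p_rr", "p_ra", "p_aa")],
                      use.names = FALSE), c(1 / 4, 1 / 2, 1 / 4))
  expect_equal(mt$snv_weight[mt$label == "AAxAA"], 3333.25)
  ## offspring distributions are proper; rates sum to the 4-haploid
  ## spectrum total theta * H_4
  expect_equal(mt$p_rr + mt$p_ra + mt$p_aa, rep(1, 5))
  expect_equal(sum(mt$snv_weight), th * (1 + 1 / 2 + 1 / 3 + 1 / 4))
})

test_that("sib configuration expectations match published values", {
  expect_equal(expected_sib_config(0, 0, 2, th), 4722.10,
               tolerance = 0.02 / 4722.10)
  expect_equal(expected_sib_config(0, 0, 1, th), 6666.50)
  ## one sib carrying at least one alternative allele: theta * H_2
  expect_equal(expected_sib_config(0, 1, 0, th) +
                 expected_sib_config(0, 0, 1, th), 19999.50)
  expect_error(expected_sib_config(0, 0, 0, th), "sib")
})

test_that("sib configuration expectations sum to theta * H_4 for every N", {
  for (n in 1:6) {
    cfg <- snvexpect:::sib_compositions(n)
    total <- sum(expected_sib_config(cfg[, "n_rr"], cfg[, "n_ra"],
                                     cfg[, "n_aa"], th))
    expect_equal(total, th * (1 + 1 / 2 + 1 / 3 + 1 / 4), tolerance = 1e-12)
  }
})

test_that("stringent sib filters plateau at 3*theta/4 and theta/4", {
  expect_equal(expected_sib_filtered_no_controls(100, "dominant", 100, th),
               3 * th / 4, tolerance = 0.02 / 9999.75)
  expect_equal(expected_sib_filtered_no_controls(50, "recessive", 50, th),
               th / 4, tolerance = 0.02 / 3333.25)
  ## plateau reached from above
  v <- vapply(c(10, 20, 50), function(n)
    expected_sib_filtered_no_controls(n, "dominant", n, th), numeric(1))
  expect_true(all(diff(v) <= 0))
  expect_gte(v[3], 3 * th / 4)
})

test_that("a single sib is a single random diploid (unrelated N=1)", {
  ## equivalence holds for every filter demanding at least one carrier;
  ## with no filter at all the sib total counts all sites segregating in
  ## the four parental haplotypes (theta * H_4), including those at which
  ## the one sampled sib happens to be RR, whereas the unrelated total
  ## counts sites visible in the sampled exome (theta * H_2)
  for (mode in c("dominant", "recessive")) {
    expect_equal(expected_sib_filtered_no_controls(1, mode, 1, th),
                 expected_filtered_no_controls(1, mode, 1, th),
                 tolerance = 1e-12)
  }
  expect_equal(expected_sib_filtered_no_controls(1, "dominant", 0, th),
               th * sum(1 / (1:4)), tolerance = 1e-12)
})

test_that("split sib configurations obey the pooling identity", {
  ## a degenerate control group changes nothing
  for (cfg in list(c(2, 0, 1), c(0, 1, 2), c(1, 1, 1))) {
    expect_equal(expected_sib_split_config(cfg, c(0, 0, 0), th),
                 expected_sib_config(cfg[1], cfg[2], cfg[3], th),
                 tolerance = 1e-12)
  }
  ## both sibs AA, split 1 affected / 1 control: equals the pooled (0,0,2)
  ## configuration since all multinomial coefficients are 1
  expect_equal(expected_sib_split_config(c(0, 0, 1), c(0, 0, 1), th),
               expected_sib_config(0, 0, 2, th), tolerance = 1e-12)
  ## summing a pooled configuration over all affected/control splits
  ## recovers the pooled expectation times the number of orderings mass
  for (n_aff in 1:3) {
    for (n_con in 1:3) {
      pooled <- snvexpect:::sib_compositions(n_aff + n_con)
      for (j in seq_len(nrow(pooled))) {
        target <- pooled[j, ]
        splits <- 0
        cfg_a <- snvexpect:::sib_compositions(n_aff)
        for (k in seq_len(nrow(cfg_a))) {
          ctrl <- target - cfg_a[k, ]
          if (any(ctrl < 0) || sum(ctrl) != n_con) next
          if (sum(cfg_a[k, ]) != n_aff) next
          splits <- splits + expected_sib_split_config(cfg_a[k, ], ctrl, th)
        }
        expect_equal(unname(splits),
                     unname(expected_sib_config(target[1], target[2],
                                                target[3], th)),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("sib case/control filtering matches published spot values", {
  expect_equal(expected_sib_filtered_casecontrol(10, 10, "dominant", 8, 2, th),
               40.85, tolerance = 0.02 / 40.85)
  expect_equal(expected_sib_filtered_casecontrol(9, 1, "dominant", 9, 0, th),
               96.45, tolerance = 0.02 / 96.45)
  ## Na=1/Nc=1 recessive stringent cell: theta * 7/48
  expect_equal(expected_sib_filtered_casecontrol(1, 1, "recessive", 1, 0, th),
               1944.40, tolerance = 0.02 / 1944.40)
  ## the published grid prints 200.19 for this design (the running-text
  ## variant 200.09 is a known internal inconsistency of the source)
  expect_equal(expected_sib_filtered_casecontrol(5, 5, "recessive", 4, 1, th),
               200.19, tolerance = 0.02 / 200.19)
  ## zero controls reduce to the no-control path
  for (mode in c("dominant", "recessive")) {
    expect_equal(expected_sib_filtered_casecontrol(4, 0, mode, 3, 0, th),
                 expected_sib_filtered_no_controls(4, mode, 3, th),
                 tolerance = 1e-12)
  }
  expect_warning(out <- expected_sib_filtered_casecontrol(2, 2, "dominant",
                                                          3, 0, th),
                 "no site can pass")
  expect_identical(out, 0)
})

test_that("sib filters are monotone in the thresholds", {
  for (mode in c("dominant", "recessive")) {
    v <- vapply(0:4, function(x)
      expected_sib_filtered_no_controls(4, mode, x, th), numeric(1))
    expect_true(all(diff(v) <= 1e-9))
    w <- vapply(0:3, function(y)
      expected_sib_filtered_casecontrol(4, 3, mode, 3, y, th), numeric(1))
    expect_true(all(diff(w) >= -1e-9))
  }
})

test_that("ordered-genotype enumeration reproduces sib filtered sums", {
  cases <- list(
    list(n_a = 3L, n_c = 0L, mode = "dominant", x = 2L, y = 0L),
    list(n_a = 2L, n_c = 0L, mode = "recessive", x = 2L, y = 0L),
    list(n_a = 2L, n_c = 1L, mode = "recessive", x = 1L, y = 0L),
    list(n_a = 2L, n_c = 2L, mode = "dominant", x = 2L, y = 1L)
  )
  for (cs in cases) {
    got <- expected_sib_filtered_casecontrol(cs$n_a, cs$n_c, cs$mode,
                                             cs$x, cs$y, th)
    want <- oracle_fullsib(cs$n_a, cs$n_c, cs$mode, cs$x, cs$y, th)
    expect_equal(got, want, tolerance = 1e-9)
  }
})
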