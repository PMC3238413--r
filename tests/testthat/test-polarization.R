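# Outgroup polarity coding, gene classification and DEA detection.

# small fixture: one gene per interesting pattern, outgroup O1..O3
fixture_matrix <- function() {
  vals <- rbind(
    inside  = c(5, 6, 7,  6, 6.5),  # ingroup inside the range
    above   = c(5, 6, 7,  9, 6),    # one ingroup value above
    below   = c(5, 6, 7,  3, 6),    # one below
    straddle = c(5, 6, 7, 9, 3),    # above and below: DEA
    boundary = c(5, 6, 7,  5, 7))   # values on the closed boundary
  colnames(vals) <- c("O1", "O2", "O3", "I1", "I2")
  expression_matrix(vals)
}

fixture_design <- function(em) build_design(c("O1", "O2", "O3"),
                                            c("I1", "I2"), em)

test_that("outgroup profile is the per-gene min-max with tolerance widening", {
  em <- fixture_matrix()
  d <- fixture_design(em)
  prof <- outgroup_profile(em, d)
  expect_equal(unname(prof$lo["inside"]), 5)
  expect_equal(unname(prof$hi["inside"]), 7)
  expect_true(all(prof$usable))

  # degenerate two-point interval
  em2 <- expression_matrix(rbind(g = c(4, 4, 5)),
                           sample_ids = c("O1", "O2", "I1"))
  p2 <- outgroup_profile(em2, build_design(c("O1", "O2"), "I1", em2))
  expect_equal(unname(p2$lo["g"]), 4)
  expect_equal(unname(p2$hi["g"]), 4)

  # tolerance 0.1 on [5, 7]: width 2, effective [4.8, 7.2]
  e <- expclad:::effective_interval(5, 7, 0.1)
  expect_equal(e$lo, 4.8)
  expect_equal(e$hi, 7.2)
  em3 <- expression_matrix(rbind(g = c(5, 7, 7.1, 7.3)),
                           sample_ids = c("O1", "O2", "I1", "I2"))
  d3 <- build_design(c("O1", "O2"), c("I1", "I2"), em3)
  pol3 <- polarize(em3, outgroup_profile(em3, d3, tolerance = 0.1), d3)
  expect_equal(unname(pol3$states["g", c("I1", "I2")]),
               c(expclad:::ST_ANC, expclad:::ST_OVER))
})

test_that("ingroup values code over/under/ancestral with closed boundaries", {
  em <- fixture_matrix()
  d <- fixture_design(em)
  pol <- polarize(em, outgroup_profile(em, d), d)
  s <- pol$states
  expect_equal(unname(s["inside", c("I1", "I2")]), c(0L, 0L))
  expect_equal(unname(s["above", "I1"]), expclad:::ST_OVER)
  expect_equal(unname(s["below", "I1"]), expclad:::ST_UNDER)
  expect_equal(unname(s["straddle", c("I1", "I2")]),
               c(expclad:::ST_OVER, expclad:::ST_UNDER))
  # ties at lo/hi are ancestral (closed interval)
  expect_equal(unname(s["boundary", c("I1", "I2")]), c(0L, 0L))
})

test_that("missing ingroup values at usable genes code derived_absent", {
  vals <- rbind(g1 = c(5, 6, NA, 6), g2 = c(5, 6, 4, NA))
  colnames(vals) <- c("O1", "O2", "I1", "I2")
  em <- expression_matrix(vals)
  d <- build_design(c("O1", "O2"), c("I1", "I2"), em)
  pol <- polarize(em, outgroup_profile(em, d), d)
  expect_equal(unname(pol$states["g1", "I1"]), expclad:::ST_ABSENT)
  expect_equal(unname(pol$states["g2", "I2"]), expclad:::ST_ABSENT)
  # derived_absent contributes 1 to the binary view
  expect_equal(unname(binary_view(pol)["g1", "I1"]), 1L)
})

test_that("genes unusable in the outgroup are excluded and coded ancestral", {
  vals <- rbind(ok = c(5, 6, 9), bad = c(5, NA, 9))
  colnames(vals) <- c("O1", "O2", "I1")
  em <- expression_matrix(vals)
  d <- build_design(c("O1", "O2"), "I1", em)
  prof <- outgroup_profile(em, d)
  expect_false(prof$usable[["bad"]])
  pol <- polarize(em, prof, d)
  expect_identical(pol$excluded_genes, "bad")
  expect_equal(unname(pol$states["bad", ]), rep(0L, 3))
  expect_equal(unname(pol$states["ok", "I1"]), expclad:::ST_OVER)

  # all-missing outgroup is an error
  vals2 <- rbind(g = c(NA, NA, 1))
  colnames(vals2) <- c("O1", "O2", "I1")
  em2 <- expression_matrix(vals2)
  expect_error(outgroup_profile(em2, build_design(c("O1", "O2"), "I1", em2)),
               "empty outgroup")
})

test_that("leave-one-out coding lets extreme outgroup samples go derived", {
  # outgroup {5, 6, 7}: the sample holding 7 is coded against [5, 6]
  vals <- rbind(g = c(5, 6, 7, 6))
  colnames(vals) <- c("O1", "O2", "O3", "I1")
  em <- expression_matrix(vals)
  d <- build_design(c("O1", "O2", "O3"), "I1", em)
  pol <- polarize(em, outgroup_profile(em, d), d, leave_one_out = TRUE)
  expect_equal(unname(pol$states["g", "O3"]), expclad:::ST_OVER)
  expect_equal(unname(pol$states["g", "O1"]), expclad:::ST_UNDER)
  expect_equal(unname(pol$states["g", "O2"]), 0L)

  # tied extremes survive leave-one-out
  vals2 <- rbind(g = c(7, 7, 5, 6))
  colnames(vals2) <- c("O1", "O2", "O3", "I1")
  em2 <- expression_matrix(vals2)
  d2 <- build_design(c("O1", "O2", "O3"), "I1", em2)
  pol2 <- polarize(em2, outgroup_profile(em2, d2), d2, leave_one_out = TRUE)
  expect_equal(unname(pol2$states["g", "O1"]), 0L)
  expect_equal(unname(pol2$states["g", "O2"]), 0L)
})

test_that("without leave-one-out, outgroup samples never code derived", {
  set.seed(42)
  for (rep in 1:10) {
    ng <- 50
    vals <- matrix(rnorm(ng * 8), ng,
                   dimnames = list(sprintf("g%02d", 1:ng),
                                   c(sprintf("O%d", 1:5), sprintf("I%d", 1:3))))
    vals[sample(length(vals), 30)] <- NA  # arbitrary missingness
    em <- expression_matrix(vals)
    d <- build_design(sprintf("O%d", 1:5), sprintf("I%d", 1:3), em)
    prof <- outgroup_profile(em, d)
    pol <- polarize(em, prof, d, leave_one_out = FALSE)
    expect_true(all(pol$states[, d$outgroup] == expclad:::ST_ANC))
  }
})

test_that("derived calls shrink monotonically as tolerance grows", {
  set.seed(7)
  vals <- matrix(rlnorm(100 * 9, 4, 0.5), 100,
                 dimnames = list(sprintf("g%03d", 1:100),
                                 c(sprintf("O%d", 1:4), sprintf("I%d", 1:5))))
  em <- expression_matrix(vals)
  d <- build_design(sprintf("O%d", 1:4), sprintf("I%d", 1:5), em)
  tols <- c(0, 0.05, 0.2, 0.5)
  derived <- lapply(tols, function(t) {
    pol <- polarize(em, outgroup_profile(em, d, t), d)
    which(pol$states != 0L)
  })
  for (i in seq_along(tols)[-1])
    expect_true(all(derived[[i]] %in% derived[[i - 1]]))
})

test_that("gene classes partition genes and match their defining patterns", {
  # ZC3H15-like pattern: 1 over, 5 under, 4 unchanged over 10 ingroup samples
  states <- matrix(0L, 3, 12,
                   dimnames = list(c("zc3h15", "quiet", "lcn2"),
                                   c("O1", "O2", sprintf("I%d", 1:10))))
  states["zc3h15", c("I1")] <- expclad:::ST_OVER
  states["zc3h15", sprintf("I%d", 2:6)] <- expclad:::ST_UNDER
  states["lcn2", sprintf("I%d", 1:4)] <- expclad:::ST_OVER
  pol <- structure(list(states = states, outgroup = c("O1", "O2"),
                        ingroup = sprintf("I%d", 1:10),
                        excluded_genes = character(), tolerance = 0,
                        leave_one_out = FALSE),
                   class = "polarity_matrix")
  cls <- classify_genes(pol)
  expect_identical(cls$class[cls$gene_id == "zc3h15"], "dea")
  expect_identical(cls$class[cls$gene_id == "quiet"], "unchanged")
  expect_identical(cls$class[cls$gene_id == "lcn2"], "overexpressed")
  expect_equal(cls[cls$gene_id == "zc3h15", c("n_over", "n_under",
                                              "n_ancestral", "n_absent")],
               data.frame(n_over = 1, n_under = 5, n_ancestral = 4,
                          n_absent = 0, row.names = 1L))
})

test_that("classification is exhaustive and mutually exclusive on random polarity", {
  set.seed(13)
  for (rep in 1:5) {
    states <- matrix(sample(0:3, 200 * 6, replace = TRUE,
                            prob = c(0.7, 0.1, 0.1, 0.1)), 200,
                     dimnames = list(sprintf("g%03d", 1:200),
                                     sprintf("I%d", 1:6)))
    pol <- structure(list(states = states, outgroup = character(),
                          ingroup = sprintf("I%d", 1:6),
                          excluded_genes = character(), tolerance = 0,
                          leave_one_out = FALSE),
                     class = "polarity_matrix")
    cls <- classify_genes(pol)
    expect_true(all(cls$class %in% c("unchanged", "overexpressed",
                                     "underexpressed", "dea", "unmeasurable")))
    # invariants define each class uniquely
    with(cls, {
      expect_true(all((class == "dea") == (n_over >= 1 & n_under >= 1)))
      expect_true(all((class == "overexpressed") == (n_over >= 1 & n_under == 0)))
      expect_true(all((class == "underexpressed") == (n_under >= 1 & n_over == 0)))
      expect_true(all((class == "unchanged") ==
                        (n_over == 0 & n_under == 0 & n_absent == 0)))
      expect_true(all((class == "unmeasurable") ==
                        (n_absent >= 1 & n_over == 0 & n_under == 0)))
    })
  }
})

test_that("DEA detection agrees with a brute-force scan", {
  set.seed(29)
  states <- matrix(sample(0:3, 500 * 8, replace = TRUE,
                          prob = c(0.8, 0.08, 0.08, 0.04)), 500,
                   dimnames = list(sprintf("g%03d", 1:500),
                                   sprintf("I%d", 1:8)))
  pol <- structure(list(states = states, outgroup = character(),
                        ingroup = sprintf("I%d", 1:8),
                        excluded_genes = character(), tolerance = 0,
                        leave_one_out = FALSE),
                   class = "polarity_matrix")
  brute <- sort(rownames(states)[apply(states, 1, function(r)
    any(r == expclad:::ST_OVER) && any(r == expclad:::ST_UNDER))])
  expect_identical(detect_dea(pol), brute)

  # values straddling the interval on both sides are DEA
  em <- fixture_matrix()
  d <- fixture_design(em)
  pol2 <- polarize(em, outgroup_profile(em, d), d)
  expect_identical(detect_dea(pol2), "straddle")
})

test_that("polarity TSV export round-trips through the package reader", {
  em <- fixture_matrix()
  d <- fixture_design(em)
  pol <- polarize(em, outgroup_profile(em, d), d)
  path <- tempfile()
  write_polarity(pol, path)
  back <- read_polarity(path, outgroup = pol$outgroup, ingroup = pol$ingroup)
  expect_identical(back$states, pol$states)
})
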