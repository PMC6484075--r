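test_that("present-mean divides by the number of present samples", {
  expect_equal(present_mean(c(5, 5, 5)), 5)
  expect_equal(present_mean(c(4, 0, 2)), 3)
  expect_error(present_mean(c(0, 0)), "absent")
  set.seed(41)
  for (i in 1:20) {
    x <- abs(rnorm(20)) * rbinom(20, 1, 0.7)
    if (all(x == 0)) next
    expect_equal(present_mean(x), sum(x) / sum(x > 0))
  }
})

test_that("the coefficient of variation couples all-sample deviations to the present-mean", {
  expect_equal(present_cv(c(1, 1, 1)), 0)
  expect_equal(present_cv(c(2, 4)), sqrt(2) / 3)
  # zeros enter the deviations but not the mean's denominator
  expect_equal(present_cv(c(2, 0, 4)), sqrt(5.5) / 3)
  expect_error(present_cv(5), "2 samples")
})

test_that("abundance classes follow the 1% / 0.1% mean cut-offs", {
  v <- rbind(ha = rep(0.02, 10), la = rep(0.005, 10), ra = rep(2e-4, 10),
             ha_edge = rep(0.01, 10), la_edge = rep(0.001, 10),
             gone = rep(0, 10))
  tab <- abundance_table(v)
  cls <- abundance_class(tab)
  expect_equal(as.character(cls),
               c("HA", "LA", "RA", "LA", "LA", "RA"))
})

test_that("core taxa are present in every sample", {
  v <- rbind(core = runif(10, 0.1, 1), sometimes = c(0, runif(9)),
             never = rep(0, 10))
  tab <- abundance_table(v)
  expect_equal(as.character(presence_class(tab)),
               c("Core", "Ncore", "Ncore"))
})

test_that("stability classes combine the F test with the CV rule", {
  set.seed(7)
  same <- rnorm(12, 10, 1)
  st <- stability_class(same, same)
  expect_equal(as.character(st$class), "NC")
  expect_equal(st$f_test_p, 1)
  # high variance before, near-constant after
  st_bs <- stability_class(rnorm(12, 10, 4), rnorm(15, 10, 0.3))
  expect_equal(as.character(st_bs$class), "BS")
  st_bv <- stability_class(rnorm(12, 10, 0.3), rnorm(15, 10, 4))
  expect_equal(as.character(st_bv$class), "BV")
  # the F p-value agrees with the reference implementation
  b <- rnorm(12, 5, 2); a <- rnorm(15, 5, 1)
  expect_equal(st_f <- stability_class(b, a)$f_test_p,
               var.test(b, a)$p.value, tolerance = 1e-12)
  # degenerate windows
  both0 <- stability_class(rep(3, 12), rep(5, 15))
  expect_equal(as.character(both0$class), "NC")
  expect_equal(both0$f_test_p, 1)
  one0 <- stability_class(rnorm(12, 10, 2), rep(5, 15))
  expect_equal(one0$f_test_p, 0)
  expect_equal(as.character(one0$class), "BS")
  absent <- stability_class(rep(0, 12), rnorm(15, 5, 1))
  expect_equal(as.character(absent$class), "NC")
  expect_true("window_absent" %in% absent$flags)
})

test_that("induced and repressed responses need strict convexity", {
  expect_equal(as.character(
    response_class(rep(0.01, 12), rep(0.03, 3), rep(0.01, 15))$response),
    "induced")
  expect_equal(as.character(
    response_class(rep(0.03, 12), rep(0.01, 3), rep(0.02, 15))$response),
    "repressed")
  expect_equal(as.character(
    response_class(rep(0.01, 12), rep(0.01, 3), rep(0.01, 15))$response),
    "neither")
  ab <- response_class(rep(0, 12), rep(0.01, 3), rep(0.01, 15))
  expect_equal(as.character(ab$response), "neither")
  expect_true("response_window_absent" %in% ab$flags)
})

test_that("classify_all matches the brute-force oracle on random tables", {
  set.seed(99)
  for (rep_i in 1:10) {
    v <- random_table(30, 30)
    tab <- abundance_table(v)
    design <- phase_design(1:12, 13:15, 16:30, 30)
    got <- classify_all(tab, design)
    want <- oracle_classify_table(v, 1:12, 13:15, 16:30)
    expect_identical(as.character(got$abundance_class), want$abundance)
    expect_identical(as.character(got$presence_class), want$presence)
    expect_identical(as.character(got$stability_class), want$stability)
    expect_identical(as.character(got$response), want$response)
  }
})

test_that("every taxon receives one label per axis and the crosstab sums to N", {
  set.seed(5)
  tab <- abundance_table(random_table(40, 30))
  cls <- classify_all(tab, phase_design(1:12, 13:15, 16:30, 30))
  expect_false(anyNA(cls$abundance_class))
  expect_false(anyNA(cls$presence_class))
  expect_false(anyNA(cls$stability_class))
  expect_false(anyNA(cls$response))
  expect_equal(sum(attr(cls, "crosstab")), 40)
})

test_that("stability and response labels ignore within-phase sample order and overall scale", {
  set.seed(17)
  v <- random_table(25, 30)
  design <- phase_design(1:12, 13:15, 16:30, 30)
  base <- classify_all(abundance_table(v), design)
  perm <- c(sample(1:12), sample(13:15), sample(16:30))
  shuffled <- classify_all(abundance_table(v[, perm]), design)
  expect_identical(shuffled$stability_class, base$stability_class)
  expect_identical(shuffled$response, base$response)
  expect_identical(shuffled$presence_class, base$presence_class)
  scaled <- classify_all(abundance_table(v * 3), design)
  expect_identical(scaled$stability_class, base$stability_class)
  expect_identical(scaled$response, base$response)
})

test_that("sparse non-core taxa get flagged under the prevalence rule", {
  x <- numeric(30)
  x[c(2, 14, 20)] <- 0.01          # 1 present before, 1 during, 1 after
  y <- numeric(30)
  y[c(1:4, 16:20)] <- 0.01         # 4 before, 5 after
  v <- rbind(sparse = x, prevalent = y, core = runif(30, 0.1, 1))
  cls <- classify_all(abundance_table(v), phase_design(1:12, 13:15, 16:30, 30))
  expect_true(grepl("low_prevalence", cls$flags[1]))
  expect_false(grepl("low_prevalence", cls$flags[2]))
})

test_that("group property aggregation matches set-union and simulation expectations", {
  cls <- data.frame(
    taxon = sprintf("t%02d", 1:40),
    abundance_class = factor(rep(c("HA", "LA"), each = 20),
                             levels = c("HA", "LA", "RA")),
    presence_class = factor("Core", levels = c("Core", "Ncore")),
    stability_class = factor(rep(c("BS", "BV"), 20),
                             levels = c("BS", "BV", "NC")),
    response = factor("neither", levels = c("induced", "repressed", "neither")),
    stringsAsFactors = FALSE)
  set.seed(12)
  ann <- data.frame(
    taxon = cls$taxon,
    gc_percent = ifelse(cls$stability_class == "BV", rnorm(40, 60, 1),
                        rnorm(40, 50, 1)),
    genome_size_mb = runif(40, 2, 5),
    pathways = I(c(list(c("p1", "p2")), list(c("p2", "p3")),
                   rep(list(character(0)), 38))),
    stringsAsFactors = FALSE)
  agg <- aggregate_properties(cls, ann)
  ss <- agg$stability_summary
  expect_gt(ss$gc_percent_mean[ss$stability_class == "BV"],
            ss$gc_percent_mean[ss$stability_class == "BS"])
  tst <- agg$stability_tests
  row <- tst[tst$metric == "gc_percent" & tst$group1 == "BS" &
             tst$group2 == "BV", ]
  expect_lt(row$t_p, 0.01)   # one-tailed: BV exceeds BS
  # pathway union: both HA taxa carry {p1,p2} and {p2,p3}
  ab <- agg$abundance_summary
  expect_equal(ab$n_distinct_pathways[ab$abundance_class == "HA"], 3)
  # groups too small for a test are flagged, not errored
  nc_row <- tst[tst$group2 == "NC" & tst$metric == "gc_percent", ]
  expect_true(all(nc_row$flags == "too_few_annotated"))
})
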