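test_that("the gLV fit recovers parameters exactly from noiseless data", {
  # single member following the discrete logistic map
  r <- 0.5; a <- -0.5; x <- numeric(25); x[1] <- 0.1
  for (k in 1:24) x[k + 1] <- x[k] * exp(r + a * x[k])
  fit <- fit_glv(matrix(x, 1), lambda = 0, epsilon = 0)
  expect_equal(unname(fit$r), r, tolerance = 1e-8)
  expect_equal(unname(fit$A[1, 1]), a, tolerance = 1e-8)
  # five members, known matrix, forty points
  sc <- glv_scenario(n_taxa = 5, n_before = 40, n_during = 0, n_after = 2,
                     noise = "none", sigma_process = 0,
                     disturbance = FALSE, seed = 8)
  sim <- simulate_glv(sc)
  fit5 <- fit_glv(sim$truth$raw[, 1:40], lambda = 0, epsilon = 0,
                  times = 1:40)
  expect_lt(max(abs(fit5$A - sc$A)), 1e-6)
  expect_lt(max(abs(fit5$r - sc$r)), 1e-6)
})

test_that("a constant series yields a null model under ridge", {
  v <- matrix(0.2, 4, 10, dimnames = list(paste0("t", 1:4), NULL))
  fit <- fit_glv(v, lambda = 1e-3, epsilon = 1e-6)
  expect_equal(max(abs(fit$A)), 0, tolerance = 1e-12)
  expect_equal(max(abs(fit$r)), 0, tolerance = 1e-12)
})

test_that("fit pre-conditions are enforced", {
  v <- matrix(runif(20, 0.1, 1), 4, 5)
  expect_error(fit_glv(v[, 1:2]), "3 time points")
  expect_error(fit_glv(v, lambda = 0), "N \\+ 2")
  v0 <- v; v0[1, 2] <- 0
  expect_error(fit_glv(rbind(v0[1, ], v0[1, ]), lambda = 1e-3, epsilon = 0),
               "strictly positive")
  expect_error(fit_glv(v, times = c(1, 2, 2, 3, 4)), "strictly increasing")
})

test_that("ensembles are deterministic under a fixed seed", {
  set.seed(1)
  tab <- abundance_table(random_table(8, 20, zero_frac = 0))
  e1 <- ensemble_infer(tab, R = 50, seed = 77)
  e2 <- ensemble_infer(tab, R = 50, seed = 77)
  expect_identical(e1, e2)
  e3 <- ensemble_infer(tab, R = 50, seed = 78)
  expect_false(identical(e1$n_present, e3$n_present))
})

test_that("full-community subsampling includes every pair in every replicate", {
  set.seed(4)
  tab <- abundance_table(random_table(6, 15, zero_frac = 0))
  ens <- ensemble_infer(tab, R = 25, f = 1, seed = 5)
  expect_true(all(ens$n_present == 25))
  expect_error(ensemble_infer(tab, R = 5, f = 0.2), "must be >= 2")
})

test_that("consensus reliability follows the binomial closed forms", {
  N <- 3
  members <- paste0("t", 1:N)
  mk <- function(n_pos, n_neg, n = 100) {
    m0 <- matrix(0, N, N, dimnames = list(members, members))
    np <- m0 + n
    pos <- m0; pos[1, 2] <- n_pos
    neg <- m0; neg[1, 2] <- n_neg
    st <- m0; st[1, 2] <- if (n_pos >= n_neg) 0.5 else -0.5
    structure(list(members = members, n_present = np, n_pos = pos,
                   n_neg = neg, strength_mean = st, R = n, f = 0.9,
                   seed = 1), class = "interaction_ensemble")
  }
  expect_equal(sign_consensus_pvalue(100, 100, 0.9), 0.9^100,
               tolerance = 1e-12)
  # k = 100/100 negative: reliable under the exact test
  got <- consensus_edges(mk(0, 100), mode = "test", p0 = 0.9, alpha = 0.05)
  got <- got[got$source == "t2" & got$target == "t1", ]
  expect_equal(got$sign, -1)
  expect_equal(got$p_value, 0.9^100, tolerance = 1e-12)
  # k = 85/100: reliable in neither mode
  expect_equal(nrow(consensus_edges(mk(85, 0), mode = "test")), 0)
  expect_equal(nrow(consensus_edges(mk(85, 0), mode = "threshold")), 0)
  # k = 95/100: threshold passes, exact test does not
  expect_equal(nrow(consensus_edges(mk(95, 0), mode = "threshold")), 1)
  expect_equal(nrow(consensus_edges(mk(95, 0), mode = "test")), 0)
})

test_that("the exact test is never more permissive than the threshold rule", {
  set.seed(55)
  for (i in 1:200) {
    n <- sample(20:200, 1)
    k <- rbinom(1, n, runif(1, 0.7, 1))
    test_ok <- sign_consensus_pvalue(k, n, 0.9) <= 0.05
    thr_ok <- k / n > 0.9
    if (test_ok) expect_true(thr_ok)
  }
})

test_that("strength filtering keeps the strongest fraction with a stable tie policy", {
  set.seed(6)
  pairs <- data.frame(
    source = sprintf("s%02d", 1:20), target = sprintf("t%02d", 1:20),
    sign = sample(c(-1, 1), 20, TRUE), strength = rnorm(20),
    n_pos = 90, n_neg = 5, n_present = 100, proportion = 0.9,
    p_value = 0.01, stringsAsFactors = FALSE)
  net <- strength_filter(pairs, top_frac = 0.1)
  expect_equal(nrow(net$edges), 2)
  want <- pairs[order(-abs(pairs$strength))[1:2], c("source", "target")]
  expect_setequal(paste(net$edges$source, net$edges$target),
                  paste(want$source, want$target))
  # all-equal strengths: lexicographic (source, target) decides, stably
  pairs$strength <- 1
  n1 <- strength_filter(pairs, top_frac = 0.25)
  n2 <- strength_filter(pairs[sample(20), ], top_frac = 0.25)
  expect_equal(n1$edges[order(n1$edges$source), "source"],
               n2$edges[order(n2$edges$source), "source"])
  expect_warning(empty <- strength_filter(pairs[0, ]), "no reliable pairs")
  expect_equal(nrow(empty$edges), 0)
})

test_that("phase networks are invariant to taxon row order", {
  sc <- glv_scenario(n_taxa = 8, n_before = 15, n_during = 2, n_after = 15,
                     seed = 12)
  sim <- simulate_glv(sc)
  net1 <- infer_network(sim$table, sim$design, phase = "before", R = 50,
                        seed = 3)
  perm <- sample(8)
  tab2 <- abundance_table(sim$table$values[perm, ],
                          times = sim$table$times)
  net2 <- infer_network(tab2, sim$design, phase = "before", R = 50, seed = 3)
  key <- function(n) sort(paste(n$edges$source, n$edges$target, n$edges$sign))
  expect_identical(key(net1), key(net2))
})

test_that("a constant phase window produces an empty or near-empty network", {
  v <- matrix(rep(c(0.5, 0.3, 0.2), 12), nrow = 3,
              dimnames = list(paste0("t", 1:3), NULL))
  tab <- abundance_table(v)
  design <- phase_design(1:6, 7:8, 9:12, 12)
  net <- suppressWarnings(infer_network(tab, design, phase = "before",
                                        R = 30, f = 1, seed = 2))
  expect_lte(nrow(net$edges), 1)
})

test_that("added observation noise does not improve sign recovery", {
  recov <- sapply(c(0.02, 0.1, 0.3), function(sig) {
    hits <- sapply(1:6, function(s) {
      sc <- glv_scenario(n_taxa = 8, n_before = 25, n_during = 2,
                         n_after = 5, sigma = sig, seed = s)
      sim <- simulate_glv(sc)
      net <- infer_network(sim$table, sim$design, phase = "before",
                           R = 60, seed = s)
      ed <- net$edges
      if (nrow(ed) == 0) return(0)
      tru <- sc$A[cbind(match(ed$target, sc$members),
                        match(ed$source, sc$members))]
      sum(sign(tru) == ed$sign & tru != 0)
    })
    mean(hits)
  })
  # monotone within Monte-Carlo slack: the noisiest setting must not beat
  # the cleanest by more than one edge on average
  expect_lte(recov[3], recov[1] + 1)
})
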