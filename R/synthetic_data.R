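#' Define a synthetic gLV disturbance scenario
#'
#' Builds the ground-truth parameters for a generalized Lotka-Volterra
#' community observed through a press disturbance. Off-diagonal
#' interactions are sparse and signed with magnitudes drawn uniformly
#' from `magnitude_range`; self-interactions are negative, drawn from
#' `aii_range`, strong enough (for random interaction matrices of this
#' density) to keep the community dynamically stable without making the
#' abundances relax so fast that the time series loses information. The
#' community equilibrium `x*` is drawn on an absolute abundance scale of
#' order one (`equilibrium_range`) and growth rates are solved from
#' `r = -A x*`, so `x*` is an exact fixed point; the emitted table is
#' closed to proportions at observation time. Environmental stochasticity
#' (`sigma_process`, multiplicative per-capita noise in the dynamics)
#' keeps the community fluctuating around its equilibrium the way real
#' reactor communities do — without it a deterministic gLV settles onto
#' its fixed point and the series carries no interaction signal. During
#' the disturbance window a fraction of members has its growth rate
#' shifted (a press disturbance on growth), after which the original
#' parameters resume.
#'
#' Random parameter draws occasionally produce communities whose
#' positive-feedback loops blow up; draws are rejected and redrawn (up to
#' `max_tries`, deterministically in the seed) until a probe simulation
#' stays bounded, mirroring the fact that observable communities are the
#' persistent ones.
#'
#' @param n_taxa community size (default 15).
#' @param n_before,n_during,n_after samples per phase (default 12/3/15,
#'   the fixture design mirrored throughout the package).
#' @param density probability of a non-zero off-diagonal interaction
#'   (default 0.3).
#' @param magnitude_range range of absolute off-diagonal interaction
#'   strengths, per unit abundance per day (default 0.2 to 1).
#' @param aii_range range of absolute self-interaction strengths
#'   (default 1 to 2; the spread gives the community a mixture of fast-
#'   and slow-relaxing members, which enriches the excitation spectrum of
#'   the time series).
#' @param equilibrium_range range of per-taxon equilibrium abundances on
#'   the latent absolute scale (default 0.5 to 0.9).
#' @param noise observation-noise model: `"lognormal"` (multiplicative,
#'   sd `sigma` on the log scale), `"multinomial"` (count sampling at
#'   `depth` reads) or `"none"`.
#' @param sigma lognormal observation-noise sd (default 0.05).
#' @param depth multinomial sequencing depth (default 10000).
#' @param sigma_process environmental-stochasticity sd per step in the
#'   dynamics (default 0.1); 0 gives fully deterministic dynamics.
#' @param x0_spread lognormal spread of the initial state around the
#'   equilibrium (default 0.4).
#' @param disturbance apply the growth-rate override inside the during
#'   window.
#' @param disturb_frac fraction of members whose growth rate is shifted
#'   (default 0.5).
#' @param disturb_shift range of absolute growth-rate shifts (default
#'   0.3 to 0.8 per day, sign random).
#' @param times observation days (default unit spacing).
#' @param r,A,x0 explicit parameter overrides; generated when `NULL`.
#' @param max_tries stability redraw budget (default 50).
#' @param seed integer seed.
#' @return object of class `glv_scenario`.
#' @export
glv_scenario <- function(n_taxa = 15, n_before = 12, n_during = 3,
                         n_after = 15, density = 0.3,
                         magnitude_range = c(0.2, 1),
                         aii_range = c(1, 2),
                         equilibrium_range = c(0.5, 0.9),
                         noise = c("lognormal", "multinomial", "none"),
                         sigma = 0.05, depth = 1e4, sigma_process = 0.1,
                         x0_spread = 0.4, disturbance = TRUE,
                         disturb_frac = 0.5, disturb_shift = c(0.3, 0.8),
                         times = NULL, r = NULL, A = NULL, x0 = NULL,
                         max_tries = 50, seed = 1) {
  noise <- match.arg(noise)
  N <- n_taxa
  T_len <- n_before + n_during + n_after
  if (is.null(times)) times <- seq_len(T_len)
  if (length(times) != T_len) stop("times length must equal total samples")
  during <- if (n_during > 0) n_before + seq_len(n_during) else integer(0)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  fixed <- !is.null(A) && !is.null(r) && !is.null(x0)
  for (try in seq_len(max_tries) - 1L) {
    draw_seed <- as.integer(seed) + 100000L * try
    set.seed(draw_seed)
    A_try <- A
    if (is.null(A_try)) {
      A_try <- matrix(0, N, N)
      off <- which(row(A_try) != col(A_try))
      live <- off[stats::runif(length(off)) < density]
      A_try[live] <- stats::runif(length(live), magnitude_range[1],
                                  magnitude_range[2]) *
        sample(c(-1, 1), length(live), replace = TRUE)
      diag(A_try) <- -stats::runif(N, aii_range[1], aii_range[2])
    }
    xstar <- stats::runif(N, equilibrium_range[1], equilibrium_range[2])
    r_try <- if (is.null(r)) as.numeric(-A_try %*% xstar) else r
    x0_try <- if (is.null(x0)) {
      xstar * exp(stats::rnorm(N, 0, x0_spread))
    } else x0
    r_dist <- r_try
    A_dist <- A_try
    if (disturbance && n_during > 0) {
      hit <- sample.int(N, max(1, round(disturb_frac * N)))
      r_dist[hit] <- r_try[hit] +
        stats::runif(length(hit), disturb_shift[1], disturb_shift[2]) *
        sample(c(-1, 1), length(hit), replace = TRUE)
    }
    probe <- .glv_run(x0_try, r_try, A_try, r_dist, A_dist, times, during,
                      sigma_process, process_seed = draw_seed + 333L,
                      guard = 1e4)
    if (probe$ok || fixed) break
    if (try == max_tries - 1L) {
      stop("no dynamically stable parameter draw in ", max_tries, " tries")
    }
  }
  members <- sprintf("taxon%02d", seq_len(N))
  dimnames(A_try) <- dimnames(A_dist) <- list(members, members)
  names(r_try) <- names(r_dist) <- names(x0_try) <- members
  structure(list(n_taxa = N, members = members,
                 n_before = n_before, n_during = n_during,
                 n_after = n_after, times = times,
                 r = r_try, A = A_try, r_dist = r_dist, A_dist = A_dist,
                 x0 = x0_try, noise = noise, sigma = sigma, depth = depth,
                 sigma_process = sigma_process,
                 process_seed = draw_seed + 333L, seed = seed),
            class = "glv_scenario")
}

# iterate the discrete gLV map with optional multiplicative process noise;
# guard aborts on divergence (ok = FALSE) without raising
.glv_run <- function(x0, r, A, r_dist, A_dist, times, during,
                     sigma_process, process_seed, guard = 1e6) {
  N <- length(x0)
  T_len <- length(times)
  dt <- diff(times)
  floor_eps <- 1e-10
  eta <- if (sigma_process > 0) {
    old_seed <- .save_rng()
    on.exit(.restore_rng(old_seed))
    set.seed(as.integer(process_seed))
    matrix(stats::rnorm(N * (T_len - 1), 0, sigma_process), N, T_len - 1)
  } else {
    matrix(0, N, T_len - 1)
  }
  raw <- matrix(NA_real_, N, T_len)
  x <- pmax(x0, floor_eps)
  raw[, 1] <- x
  for (k in seq_len(T_len - 1)) {
    in_dist <- (k + 1) %in% during
    r_k <- if (in_dist) r_dist else r
    A_k <- if (in_dist) A_dist else A
    x <- x * exp(dt[k] * (r_k + as.numeric(A_k %*% x)) + eta[, k])
    if (any(!is.finite(x)) || any(x > guard)) {
      return(list(ok = FALSE, raw = raw, step = k + 1))
    }
    x <- pmax(x, floor_eps)
    raw[, k + 1] <- x
  }
  list(ok = TRUE, raw = raw, step = T_len)
}

#' Simulate a compositional abundance time series from a gLV scenario
#'
#' Iterates the discrete gLV map
#' `x[k+1] = x[k] * exp(dt_k * (r + A x[k]))`, switching to the
#' disturbance parameters inside the during window; applies the
#' scenario's observation noise; clips the state at a small positive
#' floor; and closes each observed column to proportions. The returned
#' ground truth includes the raw (pre-noise, pre-closure) trajectories:
#' closure introduces a shared per-step offset in the log-ratio
#' regression, so exact parameter recovery is only defined on the raw
#' trajectories.
#'
#' @param scenario a [glv_scenario()].
#' @param close close observed columns to proportions (default `TRUE`).
#' @return list with `table` (an [abundance_table()]), `design` (a
#'   [phase_design()]) and `truth` (list: `r`, `A`, `r_dist`, `A_dist`,
#'   `x0`, `raw` trajectories, `scenario`).
#' @export
simulate_glv <- function(scenario, close = TRUE) {
  stopifnot(inherits(scenario, "glv_scenario"))
  N <- scenario$n_taxa
  T_len <- scenario$n_before + scenario$n_during + scenario$n_after
  during <- if (scenario$n_during > 0) {
    scenario$n_before + seq_len(scenario$n_during)
  } else integer(0)
  run <- .glv_run(scenario$x0, scenario$r, scenario$A, scenario$r_dist,
                  scenario$A_dist, scenario$times, during,
                  scenario$sigma_process, scenario$process_seed,
                  guard = 1e6)
  if (!run$ok) {
    stop("unstable scenario: abundances diverged at step ", run$step)
  }
  raw <- run$raw
  rownames(raw) <- scenario$members
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(as.integer(scenario$seed) + 7919L)
  obs <- raw
  if (scenario$noise == "lognormal") {
    obs <- obs * exp(matrix(stats::rnorm(N * T_len, 0, scenario$sigma),
                            N, T_len))
  } else if (scenario$noise == "multinomial") {
    for (k in seq_len(T_len)) {
      p <- obs[, k] / sum(obs[, k])
      obs[, k] <- as.numeric(stats::rmultinom(1, scenario$depth, p)) /
        scenario$depth
    }
  }
  if (close) {
    cs <- colSums(obs)
    if (any(cs == 0)) stop("unstable scenario: empty observed sample")
    obs <- sweep(obs, 2, cs, "/")
  }
  samples <- sprintf("T%02d", seq_len(T_len))
  colnames(obs) <- samples
  tab <- abundance_table(obs, taxa = scenario$members, samples = samples,
                         times = scenario$times)
  design <- phase_design(seq_len(scenario$n_before), during,
                         (scenario$n_before + scenario$n_during) +
                           seq_len(scenario$n_after),
                         n_samples = T_len)
  list(table = tab, design = design,
       truth = list(r = scenario$r, A = scenario$A,
                    r_dist = scenario$r_dist, A_dist = scenario$A_dist,
                    x0 = scenario$x0, raw = raw, scenario = scenario))
}

#' Export ground-truth interactions as an edge table
#'
#' Converts the non-zero off-diagonal entries of a true interaction
#' matrix to the same edge schema as inferred networks (`source` acts on
#' `target`), enabling direct set comparison with [consensus_edges()] /
#' [strength_filter()] output.
#'
#' @param A true interaction matrix (`A[i, j]` = effect of j on i).
#' @param members taxon ids (defaults to the matrix dimnames).
#' @return data frame with `source`, `target`, `sign`, `strength`.
#' @export
glv_truth_edges <- function(A, members = rownames(A)) {
  if (is.null(members)) members <- paste0("taxon", seq_len(nrow(A)))
  idx <- which(A != 0 & row(A) != col(A), arr.ind = TRUE)
  data.frame(source = members[idx[, "col"]],
             target = members[idx[, "row"]],
             sign = sign(A[idx]),
             strength = A[idx],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Default classification fixture specification
#'
#' A compact specification table of focal taxa whose target labels span
#' the classification scheme: core and non-core members at high, low and
#' rare abundance, stable (BS), variable (BV) and unchanged (NC) patterns,
#' and induced / repressed / flat disturbance responses. BS/BV taxa use a
#' before:after variance ratio of 10, large enough for the variance F test
#' to detect at the default 12/15 window sizes with high power.
#'
#' @param n_per_cell focal taxa per specification row template (default 4).
#' @return data frame consumed by [make_classification_fixture()], with
#'   columns `taxon`, `mean_before`, `mean_during`, `mean_after`,
#'   `cv_before`, `cv_after`, `n_absent_before`, `n_absent_during`,
#'   `n_absent_after` and the `target_*` label columns.
#' @export
fixture_spec <- function(n_per_cell = 4) {
  base_cv <- 0.25
  hi_cv <- 0.7
  lo_cv <- hi_cv / sqrt(10)   # variance ratio 10
  tmpl <- list(
    list("Core", "HA", "NC", "neither", 0.02, 0.02, 0.02, base_cv, base_cv, 0, 0, 0),
    list("Core", "HA", "BS", "neither", 0.02, 0.02, 0.02, hi_cv, lo_cv, 0, 0, 0),
    list("Core", "HA", "BV", "neither", 0.02, 0.02, 0.02, lo_cv, hi_cv, 0, 0, 0),
    list("Core", "HA", "NC", "induced", 0.015, 0.045, 0.015, base_cv, base_cv, 0, 0, 0),
    list("Core", "HA", "NC", "repressed", 0.02, 0.005, 0.02, base_cv, base_cv, 0, 0, 0),
    list("Core", "LA", "NC", "neither", 0.005, 0.005, 0.005, base_cv, base_cv, 0, 0, 0),
    list("Core", "LA", "BS", "neither", 0.005, 0.005, 0.005, hi_cv, lo_cv, 0, 0, 0),
    list("Core", "LA", "BV", "induced", 0.004, 0.012, 0.004, lo_cv, hi_cv, 0, 0, 0),
    list("Core", "RA", "NC", "neither", 5e-4, 5e-4, 5e-4, base_cv, base_cv, 0, 0, 0),
    list("Ncore", "RA", "NC", "neither", 5e-4, 5e-4, 5e-4, base_cv, base_cv, 4, 0, 5),
    list("Ncore", "RA", "BS", "neither", 5e-4, 5e-4, 5e-4, hi_cv, lo_cv, 3, 0, 4),
    list("Ncore", "RA", "BV", "neither", 5e-4, 5e-4, 5e-4, lo_cv, hi_cv, 3, 0, 4)
  )
  rows <- lapply(seq_along(tmpl), function(i) {
    t <- tmpl[[i]]
    data.frame(
      template = i,
      target_presence_class = t[[1]], target_abundance_class = t[[2]],
      target_stability_class = t[[3]], target_response = t[[4]],
      mean_before = t[[5]], mean_during = t[[6]], mean_after = t[[7]],
      cv_before = t[[8]], cv_after = t[[9]],
      n_absent_before = t[[10]], n_absent_during = t[[11]],
      n_absent_after = t[[12]],
      stringsAsFactors = FALSE)
  })
  spec <- do.call(rbind, rows[rep(seq_along(rows), each = n_per_cell)])
  spec$taxon <- sprintf("focal%03d", seq_len(nrow(spec)))
  spec[, c("taxon", setdiff(colnames(spec), "taxon"))]
}

# direct application of the classification formulas to one pre-closure
# abundance row; intentionally plain arithmetic, kept separate from
# classify_all so fixtures carry labels derived straight from the
# definitions
.fixture_labels <- function(x, design, alpha = 0.05) {
  b <- x[design$before]; d <- x[design$during]; a <- x[design$after]
  mean_all <- mean(x)
  abundance <- if (mean_all > 0.01) "HA" else if (mean_all >= 0.001) "LA" else "RA"
  presence <- if (all(x > 0)) "Core" else "Ncore"
  pmean <- function(w) sum(w) / sum(w > 0)
  wcv <- function(w) {
    m <- pmean(w)
    sqrt(sum((w - m)^2) / (length(w) - 1)) / m
  }
  if (all(b == 0) || all(a == 0)) {
    stability <- "NC"
  } else {
    vb <- stats::var(b); va <- stats::var(a)
    p <- if (vb == 0 && va == 0) 1 else if (vb == 0 || va == 0) 0 else {
      pp <- stats::pf(vb / va, length(b) - 1, length(a) - 1)
      min(1, 2 * min(pp, 1 - pp))
    }
    stability <- if (p > alpha) "NC" else if (wcv(b) >= wcv(a)) "BS" else "BV"
  }
  if (length(d) == 0 || all(b == 0) || all(d == 0) || all(a == 0)) {
    response <- "neither"
  } else {
    mb <- pmean(b); md <- pmean(d); ma <- pmean(a)
    response <- if (md > mb && md > ma) "induced"
                else if (md < mb && md < ma) "repressed" else "neither"
  }
  c(abundance_class = abundance, presence_class = presence,
    stability_class = stability, response = response)
}

#' Generate a classification fixture with known labels
#'
#' Draws each focal taxon's window values from normal distributions with
#' the specified window means and coefficients of variation (clipped at a
#' small positive floor so presence is preserved), zeroes out the
#' requested number of randomly placed samples per window for non-core
#' taxa, adds rare filler taxa and a high-abundance baseline taxon so
#' pre-closure column sums are close to 1, computes the ground-truth
#' labels by direct application of the classification formulas to the
#' pre-closure values, and finally closes columns to proportions.
#'
#' @param spec specification data frame (see [fixture_spec()]).
#' @param design a [phase_design()]; defaults to 12/3/15.
#' @param n_filler number of rare filler taxa (default 40).
#' @param seed integer seed.
#' @return list with `table` (closed [abundance_table()]), `design`,
#'   `truth` (data frame of per-focal-taxon labels) and `spec`.
#' @export
make_classification_fixture <- function(spec, design = NULL, n_filler = 40,
                                        seed = 1) {
  if (is.null(design)) {
    design <- phase_design(1:12, 13:15, 16:30, n_samples = 30)
  }
  if ("target_presence_class" %in% colnames(spec)) {
    masked <- spec$n_absent_before + spec$n_absent_during +
      spec$n_absent_after > 0
    bad <- spec$target_presence_class == "Core" & masked
    if (any(bad)) {
      stop("unsatisfiable spec: Core taxa cannot carry absence masks (",
           paste(spec$taxon[bad], collapse = ", "), ")")
    }
  }
  wins <- list(before = design$before, during = design$during,
               after = design$after)
  for (w in names(wins)) {
    nab <- spec[[paste0("n_absent_", w)]]
    if (any(nab > length(wins[[w]]))) {
      stop("unsatisfiable spec: more absences than samples in the ", w,
           " window")
    }
  }
  T_len <- length(design$before) + length(design$during) +
    length(design$after)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(as.integer(seed))
  n_focal <- nrow(spec)
  vals <- matrix(0, n_focal + n_filler + 1, T_len)
  floor_pos <- 1e-8
  for (i in seq_len(n_focal)) {
    x <- numeric(T_len)
    for (w in names(wins)) {
      idx <- wins[[w]]
      if (!length(idx)) next
      m <- spec[[paste0("mean_", w)]][i]
      cv <- if (w == "during") 0.15 else spec[[paste0("cv_", w)]][i]
      x[idx] <- pmax(stats::rnorm(length(idx), m, cv * m), floor_pos)
      nab <- spec[[paste0("n_absent_", w)]][i]
      if (nab > 0) x[sample(idx, nab)] <- 0
    }
    vals[i, ] <- x
  }
  filler <- matrix(pmax(stats::rnorm(n_filler * T_len, 2e-4, 5e-5),
                        floor_pos), n_filler, T_len)
  vals[n_focal + seq_len(n_filler), ] <- filler
  # baseline taxon absorbs the remaining mass so closure is near-identity
  remainder <- pmax(1 - colSums(vals), 0.05)
  vals[n_focal + n_filler + 1, ] <- remainder *
    exp(stats::rnorm(T_len, 0, 0.02))
  taxa <- c(spec$taxon, sprintf("filler%03d", seq_len(n_filler)),
            "baseline001")
  truth <- do.call(rbind, lapply(seq_len(n_focal), function(i) {
    lbl <- .fixture_labels(vals[i, ], design)
    data.frame(taxon = taxa[i], t(lbl), stringsAsFactors = FALSE)
  }))
  tab <- abundance_table(vals, taxa = taxa,
                         samples = sprintf("T%02d", seq_len(T_len)),
                         normalize = TRUE)
  list(table = tab, design = design, truth = truth, spec = spec)
}
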