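#' Fit a discrete-time generalized Lotka-Volterra model by ridge regression
#'
#' The engine behind the interaction-network inference. For the discrete
#' gLV map `x[i,k+1] = x[i,k] * exp(dt_k * (r_i + sum_j a_ij x[j,k]))`,
#' the per-step log-ratio `y[i,k] = log((x[i,k+1] + eps) / (x[i,k] + eps)) / dt_k`
#' is linear in the abundances, so each target taxon i is regressed on an
#' intercept (growth rate `r_i`) plus the abundances of every member
#' (interaction coefficients `a_ij`, effect of j on i). A ridge penalty
#' `lambda` on all coefficients except the intercept stabilizes the fit
#' when time points are scarce relative to members; `lambda = 0` gives the
#' ordinary least-squares fit and requires at least `N + 2` time points.
#'
#' @param table an [abundance_table()] (or plain taxa-by-samples matrix)
#'   covering one time window; abundances must be non-negative.
#' @param lambda ridge penalty (default 1e-3); must be > 0 when the
#'   window is shorter than `N + 2` points.
#' @param epsilon pseudocount added inside the log ratio (default 1e-6);
#'   use 0 for strictly positive data when exact recovery matters.
#' @param times observation times; taken from the table when present,
#'   otherwise unit spacing is assumed.
#' @return object of class `glv_fit`: list with `members`, `r` (growth
#'   vector), `A` (N x N interaction matrix, `A[i, j]` = effect of j on
#'   i), `lambda`, `epsilon`.
#' @export
fit_glv <- function(table, lambda = 1e-3, epsilon = 1e-6, times = NULL) {
  if (inherits(table, "abundance_table")) {
    v <- table$values
    if (is.null(times)) times <- table$times
  } else {
    v <- as.matrix(table)
  }
  N <- nrow(v); T_len <- ncol(v)
  if (T_len < 3) stop("need at least 3 time points")
  if (is.null(times)) times <- seq_len(T_len)
  if (length(times) != T_len) stop("times length must match samples")
  dt <- diff(times)
  if (any(dt <= 0)) stop("times must be strictly increasing for gLV fitting")
  if (any(v < 0)) stop("abundances must be non-negative")
  if (lambda == 0 && T_len < N + 2) {
    stop("unpenalized fit needs >= N + 2 time points; set lambda > 0")
  }
  if (epsilon == 0 && any(v == 0)) {
    stop("epsilon = 0 requires strictly positive abundances")
  }
  Y <- t(log((v[, -1, drop = FALSE] + epsilon) /
             (v[, -T_len, drop = FALSE] + epsilon)) /
         matrix(dt, N, T_len - 1, byrow = TRUE))      # (T-1) x N
  if (any(!is.finite(Y))) stop("non-finite log-ratio response")
  X <- cbind(1, t(v[, -T_len, drop = FALSE]))          # (T-1) x (N+1)
  if (lambda == 0) {
    B <- qr.coef(qr(X), Y)
    if (anyNA(B)) stop("design is rank deficient; set lambda > 0")
  } else {
    D <- diag(c(0, rep(lambda, N)), N + 1)
    B <- solve(crossprod(X) + D, crossprod(X, Y))
  }
  members <- rownames(v)
  if (is.null(members)) members <- paste0("taxon", seq_len(N))
  A <- t(B[-1, , drop = FALSE])                        # N x N, A[i,j]
  dimnames(A) <- list(members, members)
  structure(list(members = members, r = stats::setNames(B[1, ], members),
                 A = A, lambda = lambda, epsilon = epsilon),
            class = "glv_fit")
}

#' Subsampling ensemble of gLV fits
#'
#' Runs `R` replicate fits; each replicate draws a uniform random subset
#' of `floor(f * N)` members without replacement, fits the gLV model on
#' the sub-table, and tallies for every ordered pair the sign and
#' strength of the fitted interaction coefficient. Coefficients with
#' |a| < 1e-12 count as neither positive nor negative. Fully seeded and
#' reproducible.
#'
#' By default the subsampled table is fitted as-is: re-closing it to
#' proportions (`renormalize = TRUE`) makes every column sum to exactly
#' one, which is exactly collinear with the regression intercept and
#' leaves each row of the interaction matrix identified only up to an
#' additive shift; that degeneracy inflates spurious coefficients. The
#' option is provided for users who want every replicate fitted on a
#' strictly compositional design.
#'
#' @param table an [abundance_table()] restricted to one time window.
#' @param R number of replicates (default 1000).
#' @param f member subsample fraction (default 0.9); `floor(f * N)` must
#'   be >= 2.
#' @param lambda,epsilon passed to [fit_glv()].
#' @param seed integer seed for the subsampling stream.
#' @param renormalize re-close subsampled columns to proportions.
#' @return object of class `interaction_ensemble`: list of N x N matrices
#'   `n_present`, `n_pos`, `n_neg`, `strength_mean` plus `members`, `R`,
#'   `f`, `seed`.
#' @export
ensemble_infer <- function(table, R = 1000, f = 0.9, lambda = 1e-3,
                           epsilon = 1e-6, seed = 1, renormalize = FALSE) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values
  N <- nrow(v)
  if (N < 3) stop("ensemble inference needs at least 3 members")
  m <- floor(f * N)
  if (m < 2) stop("subsample size floor(f * N) must be >= 2")
  n_present <- n_pos <- n_neg <- strength_sum <- matrix(
    0, N, N, dimnames = list(table$taxa, table$taxa))
  zero_tol <- 1e-12
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(as.integer(seed))
  for (rep_i in seq_len(R)) {
    idx <- sort(sample.int(N, m))
    sub <- v[idx, , drop = FALSE]
    if (renormalize) {
      cs <- colSums(sub)
      if (any(cs == 0)) stop("subsample has an empty sample column")
      sub <- sweep(sub, 2, cs, "/")
    }
    fit <- fit_glv(sub, lambda = lambda, epsilon = epsilon,
                   times = table$times)
    A <- fit$A
    n_present[idx, idx] <- n_present[idx, idx] + 1
    n_pos[idx, idx] <- n_pos[idx, idx] + (A > zero_tol)
    n_neg[idx, idx] <- n_neg[idx, idx] + (A < -zero_tol)
    strength_sum[idx, idx] <- strength_sum[idx, idx] + A
  }
  strength_mean <- strength_sum / n_present
  strength_mean[n_present == 0] <- NA_real_
  structure(list(members = table$taxa, n_present = n_present,
                 n_pos = n_pos, n_neg = n_neg,
                 strength_mean = strength_mean,
                 R = R, f = f, seed = seed),
            class = "interaction_ensemble")
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' One-sided exact binomial tail P(X >= k | n, p0)
#'
#' Used by the sign-consensus test: the probability of observing at least
#' `k` same-sign calls out of `n` if the true per-replicate sign
#' probability were only `p0`.
#'
#' @param k observed count of same-sign calls.
#' @param n number of replicates containing the pair.
#' @param p0 null sign proportion (default 0.9).
#' @return upper-tail probability.
#' @export
sign_consensus_pvalue <- function(k, n, p0 = 0.9) {
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Extract reliable signed pairs from an ensemble
#'
#' For each ordered pair (target <- source) and each sign, the tally `k`
#' out of the `n` replicates containing both members is assessed either by
#' an exact one-sided binomial test against the null proportion `p0`
#' (`mode = "test"`: reliable iff P(X >= k | n, p0) <= alpha) or by a
#' plain proportion cut-off (`mode = "threshold"`: reliable iff
#' k / n > p0). At most one sign can pass for p0 >= 0.5; the pair is
#' assigned that sign with strength `strength_mean`. Self-pairs are
#' excluded unless `include_self = TRUE`.
#'
#' @param ensemble an `interaction_ensemble` from [ensemble_infer()].
#' @param p0 null/threshold sign proportion (default 0.9).
#' @param mode `"threshold"` (plain cut-off) or `"test"` (exact binomial).
#' @param alpha level of the binomial test (mode `"test"` only).
#' @param include_self keep self-interaction pairs.
#' @return data frame of reliable pairs: `source`, `target`, `sign`
#'   (+1/-1), `strength`, `n_pos`, `n_neg`, `n_present`, `proportion`,
#'   `p_value`.
#' @export
consensus_edges <- function(ensemble, p0 = 0.9,
                            mode = c("threshold", "test"), alpha = 0.05,
                            include_self = FALSE) {
  stopifnot(inherits(ensemble, "interaction_ensemble"))
  mode <- match.arg(mode)
  N <- length(ensemble$members)
  rows <- list()
  for (i in seq_len(N)) {       # target
    for (j in seq_len(N)) {     # source
      if (i == j && !include_self) next
      n <- ensemble$n_present[i, j]
      if (n == 0) next
      for (s in c(1, -1)) {
        k <- if (s > 0) ensemble$n_pos[i, j] else ensemble$n_neg[i, j]
        p_val <- sign_consensus_pvalue(k, n, p0)
        ok <- if (mode == "test") p_val <= alpha else k / n > p0
        if (ok) {
          rows[[length(rows) + 1]] <- data.frame(
            source = ensemble$members[j], target = ensemble$members[i],
            sign = s, strength = ensemble$strength_mean[i, j],
            n_pos = ensemble$n_pos[i, j], n_neg = ensemble$n_neg[i, j],
            n_present = n, proportion = k / n, p_value = p_val,
            stringsAsFactors = FALSE)
          break  # the other sign cannot also pass for p0 >= 0.5
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(source = character(0), target = character(0),
                      sign = numeric(0), strength = numeric(0),
                      n_pos = numeric(0), n_neg = numeric(0),
                      n_present = numeric(0), proportion = numeric(0),
                      p_value = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Construct a signed directed network
#'
#' @param edges data frame with at least `source`, `target`, `sign`,
#'   `strength` columns.
#' @param nodes optional data frame with a `taxon` column plus
#'   annotations; defaults to the taxa incident to the edges.
#' @return object of class `signed_network`: list with `nodes`, `edges`.
#' @export
signed_network <- function(edges, nodes = NULL) {
  need <- c("source", "target", "sign", "strength")
  miss <- setdiff(need, colnames(edges))
  if (length(miss)) stop("edge table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(edges) && !all(edges$sign %in% c(-1, 1))) {
    stop("edge sign must be +1 or -1")
  }
  if (is.null(nodes)) {
    nodes <- data.frame(taxon = sort(unique(c(edges$source, edges$target))),
                        stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("signed_network: %d nodes, %d edges (%d positive, %d negative)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign > 0), sum(x$edges$sign < 0)))
  invisible(x)
}

#' Convert a signed network to an igraph object
#'
#' @param network a [signed_network].
#' @return an [igraph::igraph] directed graph with edge attributes `sign`
#'   and `strength`.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "signed_network"))
  vert <- network$nodes
  colnames(vert)[colnames(vert) == "taxon"] <- "name"
  vert <- vert[!vapply(vert, is.list, logical(1))]
  igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                vertices = vert)
}

#' Keep the strongest reliable pairs
#'
#' Ranks reliable pairs by absolute mean strength (descending) and keeps
#' the top `ceiling(top_frac * count)`. Ties at the cut are broken
#' deterministically by lexicographic (source, target) order, so the kept
#' set is stable across runs and platforms.
#'
#' @param pairs data frame of reliable pairs from [consensus_edges()].
#' @param top_frac fraction kept (default 0.1).
#' @param nodes optional node table forwarded to [signed_network()].
#' @return a [signed_network] of the retained edges.
#' @export
strength_filter <- function(pairs, top_frac = 0.1, nodes = NULL) {
  if (nrow(pairs) == 0) {
    warning("no reliable pairs: returning an empty network")
    return(signed_network(pairs[, c("source", "target", "sign", "strength")],
                          nodes = nodes))
  }
  ord <- order(-abs(pairs$strength), pairs$source, pairs$target)
  keep <- ord[seq_len(ceiling(top_frac * nrow(pairs)))]
  signed_network(pairs[sort(keep), , drop = FALSE], nodes = nodes)
}

#' Infer the interaction network of one phase
#'
#' Composition of the full inference chain on the chosen phase window:
#' drop taxa absent throughout the window, run the subsampling ensemble
#' ([ensemble_infer()]), collect sign-consensus pairs
#' ([consensus_edges()]) and keep the strongest fraction
#' ([strength_filter()]).
#'
#' @param table an [abundance_table()].
#' @param design a [phase_design()].
#' @param phase `"before"` or `"after"`.
#' @param R,f,lambda,epsilon,seed,renormalize see [ensemble_infer()].
#' @param p0,mode,alpha see [consensus_edges()].
#' @param top_frac see [strength_filter()].
#' @return a [signed_network] tagged with attribute `"phase"`.
#' @export
infer_network <- function(table, design, phase = c("before", "after"),
                          R = 1000, f = 0.9, p0 = 0.9,
                          mode = c("threshold", "test"), alpha = 0.05,
                          top_frac = 0.1, lambda = 1e-3, epsilon = 1e-6,
                          seed = 1, renormalize = FALSE) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(design, "phase_design"))
  phase <- match.arg(phase)
  mode <- match.arg(mode)
  idx <- design[[phase]]
  v <- table$values[, idx, drop = FALSE]
  present <- rowSums(v) > 0
  win <- abundance_table(v[present, , drop = FALSE],
                         taxa = table$taxa[present],
                         samples = table$samples[idx],
                         times = table$times[idx])
  ens <- ensemble_infer(win, R = R, f = f, lambda = lambda,
                        epsilon = epsilon, seed = seed,
                        renormalize = renormalize)
  pairs <- consensus_edges(ens, p0 = p0, mode = mode, alpha = alpha)
  net <- strength_filter(pairs, top_frac = top_frac)
  attr(net, "phase") <- phase
  net
}
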