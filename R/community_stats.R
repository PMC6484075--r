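#' Shannon diversity of one sample
#'
#' Natural-log Shannon entropy H = -sum(p * ln p) over the taxa present in
#' the sample, with proportions renormalized over the non-zero entries.
#' Computed through [vegan::diversity()].
#'
#' @param column numeric vector of abundances for one sample.
#' @return diversity in nats.
#' @examples
#' shannon_index(rep(1 / 100, 100)) # log(100)
#' @export
shannon_index <- function(column) {
  if (length(column) == 0 || all(column == 0)) {
    stop("empty sample: no positive abundances")
  }
  as.numeric(vegan::diversity(column, index = "shannon"))
}

#' Richness of one sample
#'
#' Number of taxa with positive abundance.
#'
#' @inheritParams shannon_index
#' @return integer count.
#' @export
richness <- function(column) {
  as.integer(vegan::specnumber(column))
}

#' Archaeal fraction of one sample
#'
#' Summed abundance of taxa annotated with domain Archaea divided by the
#' total abundance of the sample.
#'
#' @param column named numeric vector of abundances (names are taxon ids),
#'   or unnamed with `taxa` supplied.
#' @param annotations annotation data frame with `taxon` and `domain`
#'   columns.
#' @param taxa taxon ids matching `column` when it is unnamed.
#' @return proportion in \[0, 1\]; `NA` with a warning when no taxon of
#'   the sample carries a domain annotation.
#' @export
archaeal_fraction <- function(column, annotations, taxa = names(column)) {
  if (is.null(taxa)) stop("taxon ids required (name the column or pass taxa)")
  dom <- annotations$domain[match(taxa, annotations$taxon)]
  if (all(is.na(dom))) {
    warning("no domain annotation available for this sample")
    return(NA_real_)
  }
  tot <- sum(column)
  if (tot == 0) stop("empty sample")
  sum(column[!is.na(dom) & dom == "Archaea"]) / tot
}

#' PCA of samples over standardized taxon abundances
#'
#' Transposes the table so samples are observations and taxa features,
#' z-scores each taxon (sample standard deviation, `n - 1`), removes
#' zero-variance taxa beforehand (with a warning naming them), and
#' performs PCA via [stats::prcomp()]. Component signs are fixed so that
#' the largest-magnitude loading of each component is positive, making
#' scores reproducible across platforms.
#'
#' @param table an [abundance_table()] with at least two samples.
#' @return list with `scores` (samples x components), `loadings`
#'   (taxa x components), `explained` (variance fractions, non-increasing
#'   and summing to 1) and `dropped` (zero-variance taxa).
#' @export
pca_scores <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (length(table$samples) < 2) stop("PCA needs at least 2 samples")
  X <- t(table$values)
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning("dropping zero-variance taxa: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) == 0) stop("no taxon varies across samples")
  pr <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  for (k in seq_len(ncol(pr$rotation))) {
    j <- which.max(abs(pr$rotation[, k]))
    if (pr$rotation[j, k] < 0) {
      pr$rotation[, k] <- -pr$rotation[, k]
      pr$x[, k] <- -pr$x[, k]
    }
  }
  list(scores = pr$x,
       loadings = pr$rotation,
       explained = pr$sdev^2 / sum(pr$sdev^2),
       dropped = dropped)
}

#' Two-phase comparison: F test for variances, then a one-tailed t test
#'
#' First applies a two-sided F test for equality of the before and after
#' variances at level `alpha`. When the variances do not differ
#' (p > alpha) a pooled-variance two-sample t test is used; otherwise an
#' unequal-variance (Welch-Satterthwaite) t test. The t test is one-tailed
#' in the direction stated by the caller: `direction = "greater"` tests
#' whether the after mean exceeds the before mean, `"less"` the opposite.
#' The direction is a scientific choice per metric and is never inferred
#' from the data.
#'
#' @param before,after numeric vectors, length >= 2 each.
#' @param alpha level of the variance pre-test (default 0.05).
#' @param direction `"greater"` or `"less"`, alternative for the after
#'   mean relative to the before mean.
#' @return object of class `phase_comparison`: list with `before_mean`,
#'   `before_sem`, `after_mean`, `after_sem`, `f_p`, `t_p`,
#'   `variance_mode` ("pooled" or "unequal"), `direction`, `flags`.
#' @export
two_phase_test <- function(before, after, alpha = 0.05,
                           direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(before) < 2 || length(after) < 2) {
    stop("both phases need >= 2 values")
  }
  flags <- character(0)
  f_p <- .f_test_p(before, after)
  mode <- if (f_p > alpha) "pooled" else "unequal"
  vb <- stats::var(before); va <- stats::var(after)
  if (vb == 0 && va == 0) {
    d <- mean(after) - mean(before)
    if (d == 0) {
      t_p <- 0.5
      flags <- c(flags, "degenerate_equal_constants")
    } else {
      # both phases constant but different: the ordering is certain
      t_p <- if ((direction == "greater") == (d > 0)) 0 else 1
      flags <- c(flags, "degenerate_constant_phases")
    }
  } else {
    t_p <- stats::t.test(after, before, alternative = direction,
                         var.equal = (mode == "pooled"))$p.value
  }
  structure(list(
    before_mean = mean(before), before_sem = stats::sd(before) / sqrt(length(before)),
    after_mean = mean(after), after_sem = stats::sd(after) / sqrt(length(after)),
    f_p = f_p, t_p = t_p, variance_mode = mode, direction = direction,
    flags = flags
  ), class = "phase_comparison")
}

#' @export
print.phase_comparison <- function(x, ...) {
  cat(sprintf("before %.4g +/- %.4g | after %.4g +/- %.4g\n",
              x$before_mean, x$before_sem, x$after_mean, x$after_sem))
  cat(sprintf("F p = %.4g (%s variance); one-tailed t p = %.4g (%s)\n",
              x$f_p, x$variance_mode, x$t_p, x$direction))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ";"), "\n")
  invisible(x)
}

#' Correlation of a member's abundance with an abiotic series
#'
#' Pearson (default) or Spearman correlation between a taxon abundance
#' series and an abiotic measurement series such as biogas production.
#'
#' @param member numeric abundance series.
#' @param abiotic numeric abiotic series of the same length (>= 3 points).
#' @param method `"pearson"` or `"spearman"`.
#' @return correlation coefficient; `NA` with a warning when either
#'   series has zero variance.
#' @export
abiotic_correlation <- function(member, abiotic,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(member) != length(abiotic)) stop("series lengths differ")
  if (length(member) < 3) stop("need at least 3 paired points")
  if (stats::sd(member) == 0 || stats::sd(abiotic) == 0) {
    warning("zero-variance series: correlation undefined")
    return(NA_real_)
  }
  stats::cor(member, abiotic, method = method)
}

#' Per-sample community summary
#'
#' Shannon diversity and richness for every sample of a table, plus the
#' archaeal fraction when domain annotations are supplied.
#'
#' @param table an [abundance_table()].
#' @param annotations optional annotation data frame with a `domain`
#'   column.
#' @return data frame with one row per sample.
#' @export
community_summary <- function(table, annotations = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values
  out <- data.frame(
    sample = table$samples,
    time = table$times,
    shannon = apply(v, 2, shannon_index),
    richness = apply(v, 2, richness),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(annotations) && "domain" %in% colnames(annotations)) {
    out$archaeal_fraction <- apply(v, 2, archaeal_fraction,
                                   annotations = annotations,
                                   taxa = table$taxa)
  }
  out
}
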