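#' Present-mean of an abundance series
#'
#' Mean abundance over the samples in which the taxon is present: the sum
#' of the series divided by the number of strictly positive entries. This
#' is the mean used by the coefficient of variation and by the
#' induced/repressed comparison, where zeros mark absence rather than a
#' measured abundance of zero.
#'
#' @param series numeric vector of relative abundances over a time window.
#' @return the present-mean (a proportion).
#' @examples
#' present_mean(c(4, 0, 2)) # 6 / 2 = 3
#' @export
present_mean <- function(series) {
  n_present <- sum(series > 0)
  if (n_present == 0) stop("taxon absent in window: all entries are zero")
  sum(series) / n_present
}

#' Coefficient of variation about the present-mean
#'
#' Sample standard deviation of the full series (denominator `T - 1`,
#' deviations taken from the present-mean and summed over all entries,
#' zeros included), divided by the present-mean.
#'
#' @param series numeric vector, length >= 2, with at least one positive
#'   entry.
#' @return dimensionless coefficient of variation (>= 0).
#' @examples
#' present_cv(c(2, 0, 4)) # sqrt(5.5) / 3
#' @export
present_cv <- function(series) {
  T_len <- length(series)
  if (T_len < 2) stop("window must contain at least 2 samples")
  pm <- present_mean(series)
  sqrt(sum((series - pm)^2) / (T_len - 1)) / pm
}

#' Abundance-level class of a taxon
#'
#' High-abundance (HA) taxa average more than 1% of the community across
#' all time samples; low-abundance (LA) taxa average between 0.1% and 1%
#' (closed interval); the rest are rare (RA). The average here is the plain
#' arithmetic mean over all samples, zeros included, since the criterion
#' concerns the share of total sequences.
#'
#' @param table an [abundance_table()] of proportions.
#' @param taxon taxon identifier, or `NULL` to classify every taxon.
#' @param ha_threshold,la_threshold proportion cut-offs (defaults 1% and
#'   0.1%).
#' @return factor with levels HA, LA, RA.
#' @export
abundance_class <- function(table, taxon = NULL, ha_threshold = 0.01,
                            la_threshold = 0.001) {
  stopifnot(inherits(table, "abundance_table"))
  rows <- if (is.null(taxon)) table$taxa else taxon
  miss <- setdiff(rows, table$taxa)
  if (length(miss)) stop("unknown taxon: ", paste(miss, collapse = ", "))
  m <- rowMeans(table$values[rows, , drop = FALSE])
  cls <- ifelse(m > ha_threshold, "HA",
                ifelse(m >= la_threshold, "LA", "RA"))
  factor(stats::setNames(cls, rows), levels = c("HA", "LA", "RA"))
}

#' Temporal presence class of a taxon
#'
#' Core taxa are present (abundance > 0) in every time sample; all others
#' are non-core (Ncore).
#'
#' @inheritParams abundance_class
#' @return factor with levels Core, Ncore.
#' @export
presence_class <- function(table, taxon = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  rows <- if (is.null(taxon)) table$taxa else taxon
  miss <- setdiff(rows, table$taxa)
  if (length(miss)) stop("unknown taxon: ", paste(miss, collapse = ", "))
  core <- apply(table$values[rows, , drop = FALSE] > 0, 1, all)
  factor(stats::setNames(ifelse(core, "Core", "Ncore"), rows),
         levels = c("Core", "Ncore"))
}

# two-sided F p-value for equality of two variances, with the degenerate
# cases resolved by inspection rather than through the F distribution
.f_test_p <- function(before, after) {
  vb <- stats::var(before); va <- stats::var(after)
  if (vb == 0 && va == 0) return(1)
  if (vb == 0 || va == 0) return(0)
  f <- vb / va
  p <- stats::pf(f, length(before) - 1, length(after) - 1)
  min(1, 2 * min(p, 1 - p))
}

#' Abundance-stability class across a disturbance
#'
#' Compares the before- and after-disturbance windows by a two-sided F
#' test for equality of variances at level `alpha`. Taxa whose variances
#' do not differ are "no change" (NC). Otherwise the coefficient of
#' variation (about the window present-mean) decides: before-stable (BS)
#' when the before-window CV is at least the after-window CV — the taxon
#' was the more variable one before — and before-variable (BV) when the
#' after-window CV is larger.
#'
#' Degenerate windows are resolved by inspection: zero variance in both
#' windows means equal variances (NC, p = 1); zero variance in exactly one
#' window means trivially unequal variances (BS/BV by the CV rule, p = 0
#' recorded). A window with no presence at all cannot be assessed: the
#' taxon is flagged `window_absent` and labelled NC.
#'
#' @param before_series,after_series numeric abundance vectors, length
#'   >= 2 each.
#' @param alpha significance level of the F test (default 0.05).
#' @return list with `class` (factor BS/BV/NC), `f_test_p`, `cv_before`,
#'   `cv_after`, `flags` (character vector).
#' @export
stability_class <- function(before_series, after_series, alpha = 0.05) {
  if (length(before_series) < 2 || length(after_series) < 2) {
    stop("both windows need >= 2 samples")
  }
  flags <- character(0)
  if (all(before_series == 0) || all(after_series == 0)) {
    return(list(class = factor("NC", levels = c("BS", "BV", "NC")),
                f_test_p = NA_real_, cv_before = NA_real_,
                cv_after = NA_real_, flags = "window_absent"))
  }
  cvb <- present_cv(before_series)
  cva <- present_cv(after_series)
  p <- .f_test_p(before_series, after_series)
  cls <- if (p > alpha) "NC" else if (cvb >= cva) "BS" else "BV"
  list(class = factor(cls, levels = c("BS", "BV", "NC")),
       f_test_p = p, cv_before = cvb, cv_after = cva, flags = flags)
}

#' Disturbance-response class (induced / repressed)
#'
#' A taxon is induced when its present-mean abundance during the
#' disturbance window strictly exceeds both the before- and after-window
#' present-means (a convex pattern across the three windows), repressed
#' when it falls strictly below both (concave), and neither otherwise.
#' Ties fail the strict inequalities. A taxon absent throughout any of the
#' three windows is "neither", flagged `response_window_absent`.
#'
#' @param before,during,after numeric abundance vectors for the three
#'   windows; `during` must be non-empty.
#' @return list with `response` (factor induced/repressed/neither) and
#'   `flags`.
#' @export
response_class <- function(before, during, after) {
  if (length(during) == 0) stop("during window is empty")
  if (all(before == 0) || all(during == 0) || all(after == 0)) {
    return(list(response = factor("neither",
                                  levels = c("induced", "repressed", "neither")),
                flags = "response_window_absent"))
  }
  m_b <- present_mean(before); m_d <- present_mean(during)
  m_a <- present_mean(after)
  resp <- if (m_d > m_b && m_d > m_a) "induced"
          else if (m_d < m_b && m_d < m_a) "repressed"
          else "neither"
  list(response = factor(resp, levels = c("induced", "repressed", "neither")),
       flags = character(0))
}

#' Classify every taxon of an abundance table
#'
#' Applies the three categorical axes — abundance level (HA/LA/RA),
#' temporal presence (Core/Ncore) and before/after stability (BS/BV/NC) —
#' plus the induced/repressed disturbance response to every taxon, and
#' attaches the presence-by-abundance-by-stability cross-tabulation as the
#' `"crosstab"` attribute.
#'
#' Non-core taxa additionally get a `low_prevalence` flag when present in
#' fewer than `ncore_min_presence` samples of both the before and the
#' after window; such sparse members are usually excluded from per-class
#' displays.
#'
#' @param table an [abundance_table()] of proportions.
#' @param design a [phase_design()].
#' @param alpha significance level for the variance F test.
#' @param ha_threshold,la_threshold abundance-class cut-offs.
#' @param ncore_min_presence prevalence floor for non-core taxa (default
#'   3); set to 0 to disable.
#' @return data frame with columns `taxon`, `abundance_class`,
#'   `presence_class`, `stability_class`, `response`, `present_mean`,
#'   `mean_all`, `cv_before`, `cv_after`, `f_test_p`, `flags`; attribute
#'   `"crosstab"` holds the class-count table.
#' @export
classify_all <- function(table, design, alpha = 0.05, ha_threshold = 0.01,
                         la_threshold = 0.001, ncore_min_presence = 3) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(design, "phase_design"))
  v <- table$values
  n <- nrow(v)
  ab <- abundance_class(table, ha_threshold = ha_threshold,
                        la_threshold = la_threshold)
  pr <- presence_class(table)
  stab <- character(n); resp <- character(n)
  pm <- cvb <- cva <- fp <- rep(NA_real_, n)
  flags <- character(n)
  for (i in seq_len(n)) {
    x <- v[i, ]
    fl <- character(0)
    pm[i] <- if (any(x > 0)) present_mean(x) else NA_real_
    if (is.na(pm[i])) fl <- c(fl, "absent")
    st <- stability_class(x[design$before], x[design$after], alpha = alpha)
    stab[i] <- as.character(st$class)
    cvb[i] <- st$cv_before; cva[i] <- st$cv_after; fp[i] <- st$f_test_p
    fl <- c(fl, st$flags)
    if (length(design$during)) {
      rs <- response_class(x[design$before], x[design$during],
                           x[design$after])
      resp[i] <- as.character(rs$response)
      fl <- c(fl, rs$flags)
    } else {
      resp[i] <- "neither"
      fl <- c(fl, "no_during_window")
    }
    if (pr[i] == "Ncore" && ncore_min_presence > 0) {
      if (sum(x[design$before] > 0) < ncore_min_presence &&
          sum(x[design$after] > 0) < ncore_min_presence) {
        fl <- c(fl, "low_prevalence")
      }
    }
    flags[i] <- paste(fl, collapse = ";")
  }
  out <- data.frame(
    taxon = table$taxa,
    abundance_class = factor(ab, levels = c("HA", "LA", "RA")),
    presence_class = factor(pr, levels = c("Core", "Ncore")),
    stability_class = factor(stab, levels = c("BS", "BV", "NC")),
    response = factor(resp, levels = c("induced", "repressed", "neither")),
    present_mean = pm,
    mean_all = rowMeans(v),
    cv_before = cvb,
    cv_after = cva,
    f_test_p = fp,
    flags = flags,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "crosstab") <- table(presence = out$presence_class,
                                 abundance = out$abundance_class,
                                 stability = out$stability_class)
  out
}

#' Aggregate genomic properties and pathways by class
#'
#' Per stability class (BS/BV/NC): number of annotated members and
#' mean +/- SEM of GC percent and genome size, with pairwise
#' [two_phase_test()] comparisons between classes per metric. Per
#' abundance class (HA/LA/RA): member count and the number of distinct
#' pathway identifiers in the union over member taxa. Taxa lacking an
#' annotation are excluded metric by metric; groups with fewer than two
#' annotated members are reported but their tests are skipped with a flag.
#'
#' @param classification data frame from [classify_all()].
#' @param annotations annotation data frame (see [read_annotations()]).
#' @return list with data frames `stability_summary`, `stability_tests`
#'   and `abundance_summary`.
#' @export
aggregate_properties <- function(classification, annotations) {
  annotations <- validate_annotations(annotations)
  merged <- merge(classification, annotations, by = "taxon", all.x = TRUE)
  metrics <- intersect(c("gc_percent", "genome_size_mb"), colnames(merged))

  lv <- c("BS", "BV", "NC")
  summ <- do.call(rbind, lapply(lv, function(g) {
    sub <- merged[merged$stability_class == g, , drop = FALSE]
    row <- data.frame(stability_class = g, n_taxa = nrow(sub))
    for (m in metrics) {
      vals <- sub[[m]][!is.na(sub[[m]])]
      row[[paste0(m, "_n")]] <- length(vals)
      row[[paste0(m, "_mean")]] <- if (length(vals)) mean(vals) else NA_real_
      row[[paste0(m, "_sem")]] <- if (length(vals) > 1) {
        stats::sd(vals) / sqrt(length(vals))
      } else NA_real_
    }
    row
  }))

  pairs <- utils::combn(lv, 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(p) {
    do.call(rbind, lapply(metrics, function(m) {
      g1 <- merged[[m]][merged$stability_class == p[1] & !is.na(merged[[m]])]
      g2 <- merged[[m]][merged$stability_class == p[2] & !is.na(merged[[m]])]
      if (length(g1) < 2 || length(g2) < 2) {
        return(data.frame(metric = m, group1 = p[1], group2 = p[2],
                          f_p = NA_real_, t_p = NA_real_,
                          variance_mode = NA_character_,
                          flags = "too_few_annotated"))
      }
      tp <- two_phase_test(g1, g2, direction = "greater")
      data.frame(metric = m, group1 = p[1], group2 = p[2],
                 f_p = tp$f_p, t_p = tp$t_p,
                 variance_mode = tp$variance_mode,
                 flags = paste(tp$flags, collapse = ";"))
    }))
  }))

  has_pw <- "pathways" %in% colnames(merged)
  ab_summ <- do.call(rbind, lapply(c("HA", "LA", "RA"), function(g) {
    sub <- merged[merged$abundance_class == g, , drop = FALSE]
    npw <- if (has_pw) {
      length(unique(unlist(sub$pathways)))
    } else NA_integer_
    data.frame(abundance_class = g, n_taxa = nrow(sub),
               n_distinct_pathways = npw)
  }))

  list(stability_summary = summ, stability_tests = tests,
       abundance_summary = ab_summ)
}
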