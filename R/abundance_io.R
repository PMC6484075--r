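#' Construct an abundance table
#'
#' An `abundance_table` holds a taxon-by-sample matrix of relative
#' abundances together with per-sample observation times (days). Taxa are
#' rows, samples are columns. All-zero taxa are retained: absence carries
#' information for the presence (core/non-core) classification.
#'
#' @param values numeric matrix, taxa in rows, samples in columns. Must be
#'   non-negative with no missing values (absence is coded as 0).
#' @param taxa character vector of unique taxon identifiers; defaults to
#'   `rownames(values)`.
#' @param samples character vector of unique sample identifiers; defaults
#'   to `colnames(values)`.
#' @param times numeric vector of per-sample observation times in days,
#'   non-decreasing; defaults to `1:ncol(values)`.
#' @param normalize if `TRUE`, rescale each sample column to sum to 1.
#'   Percent-scaled input (columns summing to ~100) is handled by the same
#'   rescaling.
#' @param tol tolerance used when checking that columns sum to 1.
#' @return an object of class `abundance_table`: a list with elements
#'   `values` (matrix with dimnames), `taxa`, `samples`, `times`.
#' @examples
#' m <- matrix(c(0.6, 0.4, 0.3, 0.7), nrow = 2,
#'             dimnames = list(c("fam_A", "fam_B"), c("T1", "T2")))
#' tab <- abundance_table(m)
#' @export
abundance_table <- function(values, taxa = rownames(values),
                            samples = colnames(values), times = NULL,
                            normalize = FALSE, tol = 1e-6) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("abundance values must be numeric")
  }
  if (is.null(taxa)) taxa <- paste0("taxon", seq_len(nrow(values)))
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(values)))
  taxa <- as.character(taxa)
  samples <- as.character(samples)
  if (length(taxa) != nrow(values)) stop("taxa length must match rows")
  if (length(samples) != ncol(values)) stop("samples length must match columns")
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon ids: ", paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids: ", paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  if (anyNA(values)) stop("missing values are not permitted; code absence as 0")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at taxon '%s', sample '%s'",
                 taxa[bad[1]], samples[bad[2]]))
  }
  if (is.null(times)) times <- seq_len(ncol(values))
  times <- as.numeric(times)
  if (length(times) != ncol(values)) stop("times length must match samples")
  if (is.unsorted(times)) stop("sample times must be non-decreasing")
  if (normalize) {
    cs <- colSums(values)
    if (any(cs == 0)) {
      stop("empty sample: column '", samples[which(cs == 0)[1]],
           "' sums to zero and cannot be normalized")
    }
    values <- sweep(values, 2, cs, "/")
  }
  dimnames(values) <- list(taxa, samples)
  structure(list(values = values, taxa = taxa, samples = samples,
                 times = times),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d taxa x %d samples (days %g-%g)\n",
              length(x$taxa), length(x$samples),
              min(x$times), max(x$times)))
  cs <- colSums(x$values)
  cat(sprintf("column sums in [%.4g, %.4g]\n", min(cs), max(cs)))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Read an abundance table from delimited text
#'
#' Expects taxa in rows and samples in columns: the first column holds
#' taxon identifiers and the header row holds sample identifiers. An
#' optional second header row labelled `time`, `times`, `day` or `days`
#' (case-insensitive, in the first column) supplies per-sample observation
#' days. The mothur-style "shared" layout (`label`, `Group`, `numOtus`
#' prefix columns, samples in rows) is supported via `dialect = "shared"`;
#' its counts are converted to proportions.
#'
#' @param path path to a TSV (default) or CSV file; `.csv` extension
#'   selects comma separation.
#' @param normalize rescale columns to sum to 1 (see [abundance_table()]).
#'   Always applied for the "shared" dialect.
#' @param dialect `"plain"` (taxa x samples) or `"shared"` (mothur shared
#'   file).
#' @param sep field separator; inferred from the file extension when `NULL`.
#' @return an [abundance_table()].
#' @export
read_abundance_table <- function(path, normalize = FALSE,
                                 dialect = c("plain", "shared"), sep = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "")
  if (dialect == "shared") {
    return(.read_shared(raw))
  }
  ids <- raw[[1]]
  times <- NULL
  if (nrow(raw) > 0 && tolower(ids[1]) %in% c("time", "times", "day", "days")) {
    times <- suppressWarnings(as.numeric(raw[1, -1]))
    if (anyNA(times)) stop("non-numeric entry in the time header row")
    raw <- raw[-1, , drop = FALSE]
    ids <- raw[[1]]
  }
  body <- raw[, -1, drop = FALSE]
  values <- matrix(NA_real_, nrow(body), ncol(body))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                   ids[i], colnames(body)[j], body[[j]][i]))
    }
    values[, j] <- v
  }
  abundance_table(values, taxa = ids, samples = colnames(body),
                  times = times, normalize = normalize)
}

# mothur shared layout: rows are samples, prefix columns label/Group/numOtus
.read_shared <- function(raw) {
  cn <- tolower(colnames(raw))
  drop <- cn %in% c("label", "group", "numotus")
  if (!"group" %in% cn) stop("shared dialect requires a 'Group' column")
  groups <- raw[[which(cn == "group")[1]]]
  body <- raw[, !drop, drop = FALSE]
  values <- t(vapply(seq_len(nrow(body)), function(i) {
    v <- suppressWarnings(as.numeric(unlist(body[i, ])))
    if (anyNA(v)) stop("non-numeric count in shared file, row ", groups[i])
    v
  }, numeric(ncol(body))))
  abundance_table(t(values), taxa = colnames(body), samples = groups,
                  normalize = TRUE)
}

#' Construct a phase design
#'
#' A `phase_design` partitions the ordered time samples into contiguous
#' `before`, `during` and `after` windows around a press disturbance.
#' The before and after windows need at least two samples each because the
#' stability classification compares window variances.
#'
#' @param before,during,after integer vectors of sample indices. `during`
#'   may be empty (the disturbance-response classification is then skipped).
#' @param n_samples total number of samples the design must cover.
#' @return an object of class `phase_design` with elements `before`,
#'   `during`, `after`.
#' @export
phase_design <- function(before, during, after, n_samples) {
  before <- as.integer(before); during <- as.integer(during)
  after <- as.integer(after)
  all_idx <- c(before, during, after)
  if (anyDuplicated(all_idx)) stop("phases overlap")
  if (!setequal(all_idx, seq_len(n_samples))) {
    stop("phases must cover all ", n_samples, " samples exactly")
  }
  chk_contig <- function(v, nm) {
    if (length(v) && !identical(v, seq(min(v), max(v)))) {
      stop("phase '", nm, "' is not contiguous")
    }
  }
  chk_contig(before, "before"); chk_contig(during, "during")
  chk_contig(after, "after")
  if (length(before) && length(during) && max(before) > min(during)) {
    stop("phases out of temporal order: before must precede during")
  }
  if (length(during) && length(after) && max(during) > min(after)) {
    stop("phases out of temporal order: during must precede after")
  }
  if (length(before) && length(after) && max(before) > min(after)) {
    stop("phases out of temporal order: before must precede after")
  }
  if (length(before) < 2) stop("before window needs >= 2 samples")
  if (length(after) < 2) stop("after window needs >= 2 samples")
  structure(list(before = before, during = during, after = after),
            class = "phase_design")
}

#' @export
print.phase_design <- function(x, ...) {
  cat(sprintf("phase_design: before %d | during %d | after %d samples\n",
              length(x$before), length(x$during), length(x$after)))
  invisible(x)
}

#' Read or parse a phase design
#'
#' Accepts (i) a compact range string such as
#' `"before=1..12, during=13..15, after=16..30"`, (ii) a list with
#' `before`/`during`/`after` index vectors, or (iii) a path to a two-column
#' delimited file mapping sample id to phase name.
#'
#' @param spec range string, list, or file path.
#' @param table the [abundance_table()] the design applies to.
#' @return a [phase_design()].
#' @examples
#' m <- matrix(runif(60), nrow = 2)
#' tab <- abundance_table(m, normalize = TRUE)
#' read_phase_design("before=1..12, during=13..15, after=16..30", tab)
#' @export
read_phase_design <- function(spec, table) {
  stopifnot(inherits(table, "abundance_table"))
  n <- length(table$samples)
  if (is.list(spec)) {
    idx <- spec
  } else if (is.character(spec) && length(spec) == 1 && file.exists(spec)) {
    sep <- if (grepl("\\.csv$", spec, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(spec, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    pos <- match(df[[1]], table$samples)
    if (anyNA(pos)) stop("design file names unknown samples: ",
                         paste(df[[1]][is.na(pos)], collapse = ", "))
    ph <- tolower(df[[2]])
    idx <- list(before = pos[ph == "before"], during = pos[ph == "during"],
                after = pos[ph == "after"])
  } else if (is.character(spec) && length(spec) == 1) {
    idx <- .parse_phase_string(spec)
  } else {
    stop("unrecognized phase design specification")
  }
  for (nm in c("before", "during", "after")) {
    if (is.null(idx[[nm]])) idx[[nm]] <- integer(0)
  }
  phase_design(idx$before, idx$during, idx$after, n_samples = n)
}

.parse_phase_string <- function(s) {
  parts <- strsplit(gsub("[[:space:]]", "", s), ",")[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, "=")[[1]]
    if (length(kv) != 2 || !kv[1] %in% c("before", "during", "after")) {
      stop("cannot parse phase segment '", p, "'")
    }
    rng <- strsplit(kv[2], "\\.\\.")[[1]]
    if (length(rng) == 1) {
      out[[kv[1]]] <- as.integer(rng)
    } else if (length(rng) == 2) {
      out[[kv[1]]] <- seq(as.integer(rng[1]), as.integer(rng[2]))
    } else {
      stop("cannot parse range '", kv[2], "'")
    }
  }
  out
}

#' Read a per-taxon annotation table
#'
#' Recognized columns (all optional except `taxon`): `gc_percent`,
#' `genome_size_mb`, `genes`, `proteins`, `pathway_category` (one of
#' hydrolysis, acidogenesis, acetogenesis, methanogenesis, combined,
#' desulfurization, none), `domain` (Bacteria or Archaea) and `pathways`
#' (semicolon-separated pathway identifiers). Unknown fields stay `NA`:
#' missingness is explicit, never coded as zero.
#'
#' @param path delimited text file with a `taxon` column.
#' @return a data frame with one row per taxon and a `pathways`
#'   list-column of character vectors.
#' @export
read_annotations <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"taxon" %in% colnames(df)) stop("annotation table needs a 'taxon' column")
  if (anyDuplicated(df$taxon)) stop("duplicate taxon ids in annotations")
  validate_annotations(df)
}

#' @rdname read_annotations
#' @param df a data frame already holding annotation columns.
#' @export
validate_annotations <- function(df) {
  if ("gc_percent" %in% colnames(df)) {
    bad <- !is.na(df$gc_percent) & (df$gc_percent <= 0 | df$gc_percent >= 100)
    if (any(bad)) stop("gc_percent outside (0,100) for: ",
                       paste(df$taxon[bad], collapse = ", "))
  }
  if ("genome_size_mb" %in% colnames(df)) {
    bad <- !is.na(df$genome_size_mb) & df$genome_size_mb <= 0
    if (any(bad)) stop("genome_size_mb must be positive")
  }
  if ("pathway_category" %in% colnames(df)) {
    ok <- c("hydrolysis", "acidogenesis", "acetogenesis", "methanogenesis",
            "combined", "desulfurization", "none", NA)
    bad <- !df$pathway_category %in% ok
    if (any(bad)) stop("unknown pathway_category: ",
                       paste(unique(df$pathway_category[bad]), collapse = ", "))
  }
  if ("domain" %in% colnames(df)) {
    bad <- !df$domain %in% c("Bacteria", "Archaea", NA)
    if (any(bad)) stop("domain must be Bacteria or Archaea")
  }
  if ("pathways" %in% colnames(df) && !is.list(df$pathways)) {
    df$pathways <- lapply(strsplit(as.character(df$pathways), ";"), function(p) {
      p <- trimws(p)
      p[nzchar(p) & !is.na(p)]
    })
  }
  df
}

#' Write analysis artifacts to a directory
#'
#' Writes the classification TSV (one row per taxon), per-network edge
#' lists as CSV (columns `source`, `target`, `sign`, `strength`, `n_pos`,
#' `n_neg`, `n_present`), GraphML exports of the same networks, optional
#' summary tables, and a JSON run manifest.
#'
#' @param dir output directory (created if missing).
#' @param classification data frame from [classify_all()], or `NULL`.
#' @param networks named list of [signed_network] objects, or `NULL`;
#'   names become file tags, e.g. `network_before_edges.csv`.
#' @param summaries named list of data frames written as TSV, or `NULL`.
#' @param manifest list written as `manifest.json`, or `NULL`.
#' @return invisibly, the character vector of files written.
#' @export
write_results <- function(dir, classification = NULL, networks = NULL,
                          summaries = NULL, manifest = NULL) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  if (file.access(dir, 2) != 0) stop("output directory not writable: ", dir)
  written <- character(0)
  if (!is.null(classification)) {
    f <- file.path(dir, "classification.tsv")
    utils::write.table(classification, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, f)
  }
  for (nm in names(networks)) {
    net <- networks[[nm]]
    f <- file.path(dir, sprintf("network_%s_edges.csv", nm))
    write_edge_csv(net, f)
    g <- file.path(dir, sprintf("network_%s.graphml", nm))
    igraph::write_graph(as_igraph(net), g, format = "graphml")
    written <- c(written, f, g)
  }
  for (nm in names(summaries)) {
    f <- file.path(dir, sprintf("%s.tsv", nm))
    utils::write.table(summaries[[nm]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, f)
  }
  if (!is.null(manifest)) {
    f <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    written <- c(written, f)
  }
  invisible(written)
}

#' Write or read a signed edge list as CSV
#'
#' @param network a [signed_network] object.
#' @param path CSV path.
#' @export
write_edge_csv <- function(network, path) {
  stopifnot(inherits(network, "signed_network"))
  cols <- c("source", "target", "sign", "strength", "n_pos", "n_neg",
            "n_present")
  ed <- network$edges
  for (cl in cols) if (!cl %in% colnames(ed)) ed[[cl]] <- NA
  utils::write.table(ed[, cols, drop = FALSE], path, sep = ",",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_csv
#' @export
read_edge_csv <- function(path) {
  ed <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE)
  signed_network(ed)
}
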