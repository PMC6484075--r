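#' Default pipeline configuration
#'
#' Every threshold defaults to the study's stated value: classification
#' alpha 0.05, high-abundance cut-off 1%, low-abundance cut-off 0.1%,
#' member subsample fraction 0.9 over 1000 ensemble replicates, sign
#' consensus proportion 0.9, and retention of the strongest 10% of
#' reliable interaction pairs.
#'
#' @param ... named overrides of any config entry (nested entries via
#'   `ensemble = list(R = 200)` merge into the defaults).
#' @return a named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    table = NULL,            # path to an abundance table, or NULL to simulate
    design = "before=1..12, during=13..15, after=16..30",
    annotations = NULL,
    normalize = TRUE,
    alpha = 0.05,
    ha_threshold = 0.01,
    la_threshold = 0.001,
    ncore_min_presence = 3,
    stats_direction = "greater",
    ensemble = list(R = 1000, f = 0.9, p0 = 0.9, mode = "threshold",
                    alpha = 0.05, top_frac = 0.1, lambda = 1e-3,
                    epsilon = 1e-6),
    simulate = list(n_taxa = 15, n_before = 12, n_during = 3,
                    n_after = 15, noise = "lognormal", sigma = 0.05),
    seed = 1,
    out = "disturbnet_results"
  )
  .merge_config(cfg, list(...))
}

.merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration file
#'
#' YAML or JSON; entries missing from the file keep their defaults.
#'
#' @param path configuration file path.
#' @return validated config list.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(.merge_config(default_config(), cfg))
}

#' Validate a pipeline configuration
#'
#' @param cfg config list (see [default_config()]).
#' @return the config, invisibly errors on invalid entries.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg, call. = FALSE)
  chk(is.numeric(cfg$alpha) && cfg$alpha > 0 && cfg$alpha < 1,
      "alpha must be in (0,1)")
  chk(cfg$ha_threshold > cfg$la_threshold,
      "ha_threshold must exceed la_threshold")
  e <- cfg$ensemble
  chk(e$f > 0 && e$f <= 1, "ensemble f must be in (0,1]")
  chk(e$R >= 1, "ensemble R must be >= 1")
  chk(e$p0 > 0.5 && e$p0 < 1, "ensemble p0 must be in (0.5,1)")
  chk(e$mode %in% c("threshold", "test"), "ensemble mode unknown")
  chk(e$top_frac > 0 && e$top_frac <= 1, "top_frac must be in (0,1]")
  chk(e$lambda >= 0, "lambda must be >= 0")
  chk(e$epsilon >= 0, "epsilon must be >= 0")
  chk(is.numeric(cfg$seed), "seed must be numeric")
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates classify, community statistics, network inference on the
#' before and after windows, topological comparison and artifact writing.
#' Inputs are read from the configured paths, or generated from the
#' default synthetic scenario when no table path is given. All artifacts
#' plus a reproducibility manifest (config echo, seed, stage timings,
#' input hashes, package version) are written to `cfg$out`.
#'
#' @param cfg configuration list from [default_config()] /
#'   [read_config()].
#' @param log write stage-tagged progress lines to stderr.
#' @return list with `classification`, `summary`, `phase_tests`,
#'   `networks` (before/after [signed_network]s), `topology`, `niche`,
#'   `files`, `manifest`.
#' @export
run_pipeline <- function(cfg = default_config(), log = TRUE) {
  cfg <- validate_config(cfg)
  say <- function(stage, ...) {
    if (log) message(sprintf("[disturbnet:%s] %s", stage, sprintf(...)))
  }
  timings <- list()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  # --- inputs ----------------------------------------------------------
  if (!is.null(cfg$table)) {
    say("input", "reading abundance table %s", cfg$table)
    tab <- read_abundance_table(cfg$table, normalize = cfg$normalize)
    input_hash <- unname(tools::md5sum(cfg$table))
    truth <- NULL
  } else {
    say("input", "simulating default gLV scenario (seed %d)", cfg$seed)
    sim <- do.call(glv_scenario, c(cfg$simulate, list(seed = cfg$seed)))
    simd <- simulate_glv(sim)
    tab <- simd$table
    truth <- simd$truth
    input_hash <- "synthetic"
    cfg$design <- list(before = simd$design$before,
                       during = simd$design$during,
                       after = simd$design$after)
  }
  design <- read_phase_design(cfg$design, tab)
  ann <- if (!is.null(cfg$annotations)) read_annotations(cfg$annotations)
  timings$input <- tic() - t0

  # --- classification --------------------------------------------------
  t1 <- tic()
  say("classify", "classifying %d taxa", length(tab$taxa))
  cls <- classify_all(tab, design, alpha = cfg$alpha,
                      ha_threshold = cfg$ha_threshold,
                      la_threshold = cfg$la_threshold,
                      ncore_min_presence = cfg$ncore_min_presence)
  timings$classify <- tic() - t1

  # --- community statistics -------------------------------------------
  t2 <- tic()
  summ <- community_summary(tab, annotations = ann)
  phase_tests <- lapply(c(shannon = "shannon", richness = "richness"),
    function(metric) {
      two_phase_test(summ[[metric]][design$before],
                     summ[[metric]][design$after],
                     alpha = cfg$alpha, direction = cfg$stats_direction)
    })
  pca <- pca_scores(tab)
  timings$stats <- tic() - t2

  # --- network inference ----------------------------------------------
  t3 <- tic()
  e <- cfg$ensemble
  nets <- list()
  for (ph in c("before", "after")) {
    say("infer", "ensemble inference on the %s window (R=%d, f=%.2f)",
        ph, e$R, e$f)
    nets[[ph]] <- infer_network(tab, design, phase = ph, R = e$R, f = e$f,
                                p0 = e$p0, mode = e$mode, alpha = e$alpha,
                                top_frac = e$top_frac, lambda = e$lambda,
                                epsilon = e$epsilon,
                                seed = cfg$seed + match(ph, c("before", "after")))
  }
  timings$infer <- tic() - t3

  # --- topology --------------------------------------------------------
  t4 <- tic()
  topo <- rbind(node_topology(nets$before, "before"),
                node_topology(nets$after, "after"))
  niche <- compare_networks(nets$before, nets$after)
  if (!is.null(ann) && "pathway_category" %in% colnames(ann)) {
    for (ph in c("before", "after")) {
      ov <- overlay_pathways(nets[[ph]], ann, niche = niche)
      nets[[ph]] <- ov$network
    }
  }
  timings$topology <- tic() - t4

  # --- artifacts -------------------------------------------------------
  t5 <- tic()
  summaries <- list(community_summary = summ, topology = topo,
                    niche = niche,
                    pca_scores = data.frame(sample = rownames(pca$scores),
                                            pca$scores, row.names = NULL))
  manifest <- list(
    package = "disturbnet",
    version = as.character(utils::packageVersion("disturbnet")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out")],
    input_hash = input_hash,
    timings = timings
  )
  files <- write_results(cfg$out, classification = cls, networks = nets,
                         summaries = summaries, manifest = manifest)
  say("write", "wrote %d files to %s", length(files), cfg$out)

  invisible(list(classification = cls, summary = summ,
                 phase_tests = phase_tests, pca = pca, networks = nets,
                 topology = topo, niche = niche, truth = truth,
                 files = files, manifest = manifest))
}
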