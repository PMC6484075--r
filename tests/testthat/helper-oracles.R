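# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (plain loops, textbook formulas) and separate from
# the package implementation.

# --- classification oracle -------------------------------------------

# one taxon, plain loops over the defining formulas
oracle_classify_taxon <- function(x, before, during, after, alpha = 0.05,
                                  ha = 0.01, la = 0.001) {
  n <- length(x)
  m_all <- sum(x) / n
  abundance <- if (m_all > ha) "HA" else if (m_all >= la) "LA" else "RA"
  presence <- "Core"
  for (k in seq_len(n)) if (x[k] <= 0) presence <- "Ncore"
  pmean <- function(w) {
    s <- 0; np <- 0
    for (v in w) { s <- s + v; if (v > 0) np <- np + 1 }
    if (np == 0) return(NA_real_)
    s / np
  }
  wcv <- function(w) {
    m <- pmean(w)
    ss <- 0
    for (v in w) ss <- ss + (v - m)^2
    sqrt(ss / (length(w) - 1)) / m
  }
  b <- x[before]; d <- x[during]; a <- x[after]
  if (is.na(pmean(b)) || is.na(pmean(a))) {
    stability <- "NC"
  } else {
    vb <- sum((b - mean(b))^2) / (length(b) - 1)
    va <- sum((a - mean(a))^2) / (length(a) - 1)
    if (vb == 0 && va == 0) {
      p <- 1
    } else if (vb == 0 || va == 0) {
      p <- 0
    } else {
      pp <- pf(vb / va, length(b) - 1, length(a) - 1)
      p <- min(1, 2 * min(pp, 1 - pp))
    }
    stability <- if (p > alpha) "NC" else if (wcv(b) >= wcv(a)) "BS" else "BV"
  }
  if (length(d) == 0 || is.na(pmean(b)) || is.na(pmean(d)) ||
      is.na(pmean(a))) {
    response <- "neither"
  } else {
    mb <- pmean(b); md <- pmean(d); ma <- pmean(a)
    response <- if (md > mb && md > ma) "induced"
                else if (md < mb && md < ma) "repressed" else "neither"
  }
  list(abundance = abundance, presence = presence, stability = stability,
       response = response)
}

oracle_classify_table <- function(v, before, during, after, alpha = 0.05) {
  out <- data.frame(taxon = rownames(v), abundance = NA_character_,
                    presence = NA_character_, stability = NA_character_,
                    response = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(v))) {
    o <- oracle_classify_taxon(v[i, ], before, during, after, alpha)
    out$abundance[i] <- o$abundance
    out$presence[i] <- o$presence
    out$stability[i] <- o$stability
    out$response[i] <- o$response
  }
  out
}

# random abundance table with zeros, closed columns
random_table <- function(n_taxa, n_samples, zero_frac = 0.2) {
  v <- matrix(abs(rnorm(n_taxa * n_samples)), n_taxa, n_samples)
  v[runif(length(v)) < zero_frac] <- 0
  keep <- colSums(v) > 0
  if (!all(keep)) v[1, !keep] <- 1
  v <- sweep(v, 2, colSums(v), "/")
  rownames(v) <- sprintf("tax%03d", seq_len(n_taxa))
  colnames(v) <- sprintf("S%03d", seq_len(n_samples))
  v
}

# --- betweenness oracle ----------------------------------------------

# all-shortest-paths accumulation from the adjacency matrix: shortest
# path lengths and counts via matrix powers, then the defining triple sum
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  diag(dist) <- 0
  diag(sigma) <- 1
  walk <- diag(1, n)
  for (len in seq_len(n - 1)) {
    walk <- walk %*% adj
    newly <- is.infinite(dist) & walk > 0
    diag(newly) <- FALSE
    dist[newly] <- len
    sigma[newly] <- walk[newly]
  }
  btw <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || is.infinite(dist[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(dist[s, v]) && is.finite(dist[v, t]) &&
          dist[s, v] + dist[v, t] == dist[s, t]) {
        btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  btw
}

# signed_network from a 0/1 adjacency (edge i -> j where adj[i, j] == 1)
adj_to_network <- function(adj, nodes = paste0("n", seq_len(nrow(adj)))) {
  idx <- which(adj != 0, arr.ind = TRUE)
  edges <- data.frame(source = nodes[idx[, 1]], target = nodes[idx[, 2]],
                      sign = 1, strength = 1, stringsAsFactors = FALSE)
  signed_network(edges, nodes = data.frame(taxon = nodes,
                                           stringsAsFactors = FALSE))
}
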