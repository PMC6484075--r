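#' In-degree centrality
#'
#' Number of distinct incoming directed edges a node receives. Edge signs
#' are ignored: positive and negative interactions both count, matching
#' how received interactions are tallied when comparing the two phase
#' networks.
#'
#' @param network a [signed_network].
#' @param node taxon id, or `NULL` for all nodes.
#' @return named integer vector (or a single count).
#' @export
node_in_degree <- function(network, node = NULL) {
  g <- as_igraph(network)
  deg <- igraph::degree(g, mode = "in", loops = FALSE)
  if (is.null(node)) return(deg)
  if (!node %in% names(deg)) stop("unknown node: ", node)
  deg[[node]]
}

#' Betweenness centrality
#'
#' Directed, unweighted, unnormalized betweenness: for node v, the sum
#' over ordered pairs (s, t) with s != t != v of the fraction of shortest
#' s-t paths that pass through v. Computed by igraph's Brandes
#' accumulation. A `normalized` flag divides by (n-1)(n-2), the number of
#' ordered pairs a node could bridge.
#'
#' @param network a [signed_network].
#' @param node taxon id, or `NULL` for all nodes.
#' @param normalized divide by (n-1)(n-2).
#' @return named numeric vector (or a single value).
#' @export
node_betweenness <- function(network, node = NULL, normalized = FALSE) {
  g <- as_igraph(network)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  btw <- igraph::betweenness(g, directed = TRUE, normalized = FALSE)
  if (normalized) {
    n <- igraph::vcount(g)
    if (n > 2) btw <- btw / ((n - 1) * (n - 2))
  }
  if (is.null(node)) return(btw)
  if (!node %in% names(btw)) stop("unknown node: ", node)
  btw[[node]]
}

#' Per-node topology table of one network
#'
#' @param network a [signed_network].
#' @param tag label stored in the `network` column (e.g. "before").
#' @return data frame with `taxon`, `in_degree`, `betweenness`, `network`.
#' @export
node_topology <- function(network, tag = NA_character_) {
  deg <- node_in_degree(network)
  btw <- node_betweenness(network)
  data.frame(taxon = names(deg),
             in_degree = as.integer(deg),
             betweenness = as.numeric(btw[names(deg)]),
             network = tag,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare two phase networks by in-degree centrality
#'
#' For each taxon present in either network the in-degree is computed in
#' both. The default comparator labels a taxon `A` when its in-degree is
#' strictly larger in `netA` (taxa absent from a network rank below any
#' present taxon), `B` when strictly larger in `netB`, `star` when present
#' in both with equal positive in-degree, and `none` otherwise. The rule
#' is pluggable: supply any function of two in-degrees (NA = absent)
#' returning one of "A", "B", "star", "none".
#'
#' @param netA,netB [signed_network] objects (e.g. before and after a
#'   disturbance).
#' @param comparator optional replacement rule `function(dA, dB)`.
#' @return data frame with `taxon`, `in_degree_A`, `in_degree_B`
#'   (NA = absent) and `niche` (factor A/B/star/none).
#' @export
compare_networks <- function(netA, netB, comparator = NULL) {
  degA <- node_in_degree(netA)
  degB <- node_in_degree(netB)
  taxa <- sort(union(names(degA), names(degB)))
  dA <- degA[taxa]; dB <- degB[taxa]
  names(dA) <- names(dB) <- taxa
  if (is.null(comparator)) comparator <- .default_niche_rule
  niche <- vapply(taxa, function(tx) comparator(dA[[tx]], dB[[tx]]),
                  character(1))
  data.frame(taxon = taxa,
             in_degree_A = as.integer(dA),
             in_degree_B = as.integer(dB),
             niche = factor(niche, levels = c("A", "B", "star", "none")),
             stringsAsFactors = FALSE, row.names = NULL)
}

.default_niche_rule <- function(dA, dB) {
  inA <- !is.na(dA); inB <- !is.na(dB)
  if (inA && inB) {
    if (dA > dB) return("A")
    if (dB > dA) return("B")
    if (dA > 0) return("star")
    return("none")
  }
  if (inA) return("A")
  if (inB) return("B")
  "none"
}

#' Overlay pathway annotations on a network
#'
#' Attaches the `pathway_category` annotation to every node (category
#' "none" when unannotated) and summarizes, per category, the node count
#' and the count of niche-holding members when a [compare_networks()]
#' table is supplied.
#'
#' @param network a [signed_network].
#' @param annotations annotation data frame with `taxon` and
#'   `pathway_category` columns.
#' @param niche optional data frame from [compare_networks()].
#' @return list with `network` (nodes annotated) and `summary` (per
#'   category counts).
#' @export
overlay_pathways <- function(network, annotations, niche = NULL) {
  stopifnot(inherits(network, "signed_network"))
  nodes <- network$nodes
  cat_col <- annotations$pathway_category[match(nodes$taxon,
                                                annotations$taxon)]
  cat_col[is.na(cat_col)] <- "none"
  nodes$pathway_category <- cat_col
  network$nodes <- nodes
  summary_df <- as.data.frame(table(pathway_category = cat_col),
                              stringsAsFactors = FALSE)
  colnames(summary_df)[2] <- "n_nodes"
  if (!is.null(niche)) {
    holds <- niche$taxon[niche$niche %in% c("A", "B", "star")]
    summary_df$n_niche_holders <- vapply(summary_df$pathway_category,
      function(pc) sum(nodes$taxon[cat_col == pc] %in% holds), integer(1))
  }
  list(network = network, summary = summary_df)
}
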