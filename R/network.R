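#' Construct a trade network
#'
#' A directed network of traders in which an edge `u -> v` means "`u` requests
#' fish from / buys from `v`" (the opposite of the flow of fish). Trader type
#' is determined by out-degree: a *dealer* has at least one buying relationship
#' (out-degree >= 1); a *seller* only sells the fish it obtains from its own
#' fishers (out-degree 0). The object wraps an [igraph::graph] with vertex
#' attributes `name` and `type`.
#'
#' @param n Number of traders. Vertices are named `"T01"`, `"T02"`, ...
#' @param edges Two-column matrix (or empty) of integer vertex indices
#'   `(from, to)`; `from` buys from `to`. No self-loops, no duplicates.
#' @return An object of class `trade_network`.
#' @seealso [make_absent()], [make_pairs_across()], [make_fully_connected()],
#'   [make_erdos_renyi()], [make_motif_biased()], [read_edge_list()]
#' @export
trade_network <- function(n, edges = matrix(integer(), ncol = 2)) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer", call. = FALSE)
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) != 2L)
    stop("`edges` must have two columns (from, to)", call. = FALSE)
  storage.mode(edges) <- "integer"
  if (length(edges)) {
    if (any(is.na(edges)) || any(edges < 1L) || any(edges > n))
      stop("edge endpoints must be vertex indices in 1..n", call. = FALSE)
    if (any(edges[, 1L] == edges[, 2L]))
      stop("self-loops are not allowed", call. = FALSE)
    key <- (edges[, 1L] - 1L) * n + edges[, 2L]
    if (anyDuplicated(key))
      stop("duplicate edges are not allowed", call. = FALSE)
  }
  g <- igraph::make_empty_graph(n = n, directed = TRUE)
  igraph::V(g)$name <- sprintf("T%02d", seq_len(n))
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::V(g)$type <- ifelse(
    igraph::degree(g, mode = "out") > 0, "dealer", "seller"
  )
  structure(list(graph = g), class = "trade_network")
}

#' @export
print.trade_network <- function(x, ...) {
  ty <- trader_types(x)
  cat(sprintf(
    "<trade_network> %d traders (%d dealers, %d sellers), %d directed edges\n",
    n_traders(x), sum(ty == "dealer"), sum(ty == "seller"), n_edges(x)
  ))
  ra <- attr(x, "regions")
  if (!is.null(ra)) cat("  bundled region assignment present\n")
  invisible(x)
}

#' Number of traders / edges in a trade network
#' @param net A [trade_network()].
#' @return Integer count.
#' @export
n_traders <- function(net) {
  stopifnot(inherits(net, "trade_network"))
  igraph::vcount(net$graph)
}

#' @rdname n_traders
#' @export
n_edges <- function(net) {
  stopifnot(inherits(net, "trade_network"))
  igraph::ecount(net$graph)
}

#' Trader types, names, degrees and edges
#'
#' Accessors for the node and edge data of a [trade_network()]. Types are
#' always derived from out-degree (`dealer` iff out-degree >= 1).
#'
#' @param net A [trade_network()].
#' @return `trader_types()`: character vector (`"dealer"`/`"seller"`) named by
#'   trader; `trader_names()`: character vector; `out_degree()`: named integer
#'   vector; `edge_matrix()`: two-column integer matrix of vertex indices
#'   `(from, to)`.
#' @export
trader_types <- function(net) {
  stopifnot(inherits(net, "trade_network"))
  stats::setNames(igraph::V(net$graph)$type, igraph::V(net$graph)$name)
}

#' @rdname trader_types
#' @export
trader_names <- function(net) {
  stopifnot(inherits(net, "trade_network"))
  igraph::V(net$graph)$name
}

#' @rdname trader_types
#' @export
out_degree <- function(net) {
  stopifnot(inherits(net, "trade_network"))
  stats::setNames(
    as.integer(igraph::degree(net$graph, mode = "out")),
    igraph::V(net$graph)$name
  )
}

#' @rdname trader_types
#' @export
edge_matrix <- function(net) {
  stopifnot(inherits(net, "trade_network"))
  em <- igraph::as_edgelist(net$graph, names = FALSE)
  storage.mode(em) <- "integer"
  colnames(em) <- c("from", "to")
  em
}

#' Network without trade relationships (only sellers)
#'
#' The reference structure for the "absence of a trade network" experiment:
#' `n` isolated traders, all sellers.
#'
#' @param n Number of traders; must be even so the two regions can hold equal
#'   numbers.
#' @return A [trade_network()] with zero edges.
#' @export
make_absent <- function(n = 16L) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L || n %% 2L != 0L)
    stop("`n` must be an even integer >= 2", call. = FALSE)
  trade_network(n)
}

#' Pair-wise network connecting traders from different regions
#'
#' Every trader has exactly one buying relationship, reciprocated, and the
#' partner is always in the other region: `n/2` reciprocal cross-region dyads.
#' All traders are dealers. Because the structure is defined relative to the
#' regions, the returned network carries its own balanced region assignment
#' (attribute `"regions"`), which [run_simulation()] reuses instead of drawing
#' a random one; its direction-adapted E-I index is 0.5 by construction.
#'
#' @param n Number of traders, divisible by 4 (so each region holds an even
#'   number of dealers).
#' @return A [trade_network()] with a bundled region assignment.
#' @export
make_pairs_across <- function(n = 16L) {
  n <- as.integer(n)
  if (is.na(n) || n < 4L || n %% 4L != 0L)
    stop("`n` must be a positive multiple of 4", call. = FALSE)
  half <- n %/% 2L
  a <- seq_len(half)          # region 1
  b <- half + seq_len(half)   # region 2 partner of a[i] is b[i]
  edges <- rbind(cbind(a, b), cbind(b, a))
  net <- trade_network(n, edges)
  regions <- rep(c(1L, 2L), each = half)
  names(regions) <- trader_names(net)
  attr(net, "regions") <- regions
  net
}

#' Fully connected trade network
#'
#' Every ordered pair of distinct traders is an edge: all `n(n-1)` buying
#' relationships exist and every trader is a dealer. The "highly connected"
#' experiment structure.
#'
#' @param n Number of traders (>= 2).
#' @return A [trade_network()].
#' @export
make_fully_connected <- function(n = 16L) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be an integer >= 2", call. = FALSE)
  from <- rep(seq_len(n), each = n)
  to <- rep(seq_len(n), times = n)
  keep <- from != to
  trade_network(n, cbind(from[keep], to[keep]))
}

# all permitted ordered pairs (u, v): u in `dealers`, v != u
permitted_pairs <- function(n, dealers) {
  from <- rep(dealers, each = n)
  to <- rep(seq_len(n), times = length(dealers))
  keep <- from != to
  cbind(from = from[keep], to = to[keep])
}

#' Erdős–Rényi random trade network with a seller constraint
#'
#' Draws exactly `n_edges` directed edges uniformly at random among the
#' ordered pairs whose source is one of the `ceiling(dealer_fraction * n)`
#' designated buying-capable traders (designated uniformly at random); the
#' remaining traders are sellers and receive no out-edges. Trader types in the
#' result are re-derived from realized out-degree, so a designated
#' buying-capable trader that happens to draw no out-edge is a seller.
#'
#' @param n Number of traders.
#' @param n_edges Exact number of directed edges to place.
#' @param dealer_fraction Fraction of traders permitted to have out-edges.
#' @return A [trade_network()]. Uses the current RNG stream; set a seed for
#'   reproducibility.
#' @export
make_erdos_renyi <- function(n = 16L, n_edges, dealer_fraction = 1) {
  n <- as.integer(n)
  n_edges <- as.integer(n_edges)
  if (is.na(n) || n < 2L) stop("`n` must be an integer >= 2", call. = FALSE)
  if (is.na(n_edges) || n_edges < 0L)
    stop("`n_edges` must be a non-negative integer", call. = FALSE)
  if (!is.numeric(dealer_fraction) || dealer_fraction < 0 || dealer_fraction > 1)
    stop("`dealer_fraction` must lie in [0, 1]", call. = FALSE)
  d <- as.integer(ceiling(dealer_fraction * n))
  if (n_edges > d * (n - 1L))
    stop(sprintf(
      "infeasible: %d edges requested but only %d permitted pairs (%d buying-capable traders)",
      n_edges, d * (n - 1L), d
    ), call. = FALSE)
  if (n_edges == 0L) return(trade_network(n))
  dealers <- sort(sample.int(n, d))
  pairs <- permitted_pairs(n, dealers)
  pick <- sample.int(nrow(pairs), n_edges)
  trade_network(n, pairs[pick, , drop = FALSE])
}

#' Motif-biased random trade network
#'
#' Sequential random edge placement biased toward two motifs observed in
#' empirical fish trade networks: reciprocity of trade relationships and
#' centralization of buying relationships. Starting from the same permitted
#' pair set as [make_erdos_renyi()], edges are placed one at a time; a
#' candidate edge `(u, v)` is drawn with probability proportional to
#' `(1 + reciprocity_weight)^[edge (v,u) already placed] *
#'  (1 + centralization_weight)^outdeg(u)`.
#' With both weights 0 the generator is distributionally identical to
#' [make_erdos_renyi()].
#'
#' @inheritParams make_erdos_renyi
#' @param reciprocity_weight Non-negative bias toward closing reciprocal
#'   dyads.
#' @param centralization_weight Non-negative bias toward concentrating buying
#'   relationships on already-active buyers.
#' @return A [trade_network()].
#' @export
make_motif_biased <- function(n = 16L, n_edges, dealer_fraction = 1,
                              reciprocity_weight = 0,
                              centralization_weight = 0) {
  n <- as.integer(n)
  n_edges <- as.integer(n_edges)
  if (is.na(n) || n < 2L) stop("`n` must be an integer >= 2", call. = FALSE)
  if (is.na(n_edges) || n_edges < 0L)
    stop("`n_edges` must be a non-negative integer", call. = FALSE)
  if (!is.numeric(reciprocity_weight) || reciprocity_weight < 0 ||
      !is.numeric(centralization_weight) || centralization_weight < 0)
    stop("motif weights must be non-negative", call. = FALSE)
  if (!is.numeric(dealer_fraction) || dealer_fraction < 0 || dealer_fraction > 1)
    stop("`dealer_fraction` must lie in [0, 1]", call. = FALSE)
  d <- as.integer(ceiling(dealer_fraction * n))
  if (n_edges > d * (n - 1L))
    stop("infeasible edge count for the permitted pair set", call. = FALSE)
  if (n_edges == 0L) return(trade_network(n))
  dealers <- sort(sample.int(n, d))
  pairs <- permitted_pairs(n, dealers)
  m <- nrow(pairs)
  placed <- matrix(FALSE, n, n)
  outdeg <- integer(n)
  avail <- rep(TRUE, m)
  chosen <- integer(n_edges)
  for (k in seq_len(n_edges)) {
    idx <- which(avail)
    u <- pairs[idx, 1L]
    v <- pairs[idx, 2L]
    w <- (1 + reciprocity_weight)^(placed[cbind(v, u)]) *
      (1 + centralization_weight)^outdeg[u]
    pick <- idx[sample.int(length(idx), 1L, prob = w)]
    chosen[k] <- pick
    avail[pick] <- FALSE
    placed[pairs[pick, 1L], pairs[pick, 2L]] <- TRUE
    outdeg[pairs[pick, 1L]] <- outdeg[pairs[pick, 1L]] + 1L
  }
  trade_network(n, pairs[chosen, , drop = FALSE])
}

#' Randomly allocate traders between the two regions
#'
#' Uniformly random balanced assignment of traders to regions 1 and 2 with
#' `traders_per_region` traders each, maintaining equal proportions of the two
#' trader types in each region. The dealer count must therefore be even (add
#' or drop one isolated seller otherwise).
#'
#' @param net A [trade_network()] with `2 * traders_per_region` traders.
#' @param traders_per_region Traders per region.
#' @return Named integer vector of regions (1 or 2), one per trader.
#' @export
assign_regions <- function(net, traders_per_region = n_traders(net) %/% 2L) {
  stopifnot(inherits(net, "trade_network"))
  n <- n_traders(net)
  traders_per_region <- as.integer(traders_per_region)
  if (n != 2L * traders_per_region)
    stop("network must have exactly 2 * traders_per_region traders", call. = FALSE)
  ty <- trader_types(net)
  dealers <- which(ty == "dealer")
  sellers <- which(ty == "seller")
  if (length(dealers) %% 2L != 0L)
    stop("dealer count is odd; balanced region allocation is impossible ",
         "(add or remove one isolated seller)", call. = FALSE)
  if (length(sellers) %% 2L != 0L)
    stop("seller count is odd; balanced region allocation is impossible", call. = FALSE)
  regions <- integer(n)
  half_d <- length(dealers) %/% 2L
  half_s <- length(sellers) %/% 2L
  d1 <- if (half_d > 0L) dealers[sample.int(length(dealers), half_d)] else integer()
  s1 <- if (half_s > 0L) sellers[sample.int(length(sellers), half_s)] else integer()
  regions[] <- 2L
  regions[c(d1, s1)] <- 1L
  names(regions) <- trader_names(net)
  regions
}

#' Direction-adapted E-I (external-internal) index
#'
#' Spatial connectivity of the focal region's traders, adapted for directed
#' buying relationships:
#' `E.I. = (external out-links - internal out-links) / total links`,
#' where the numerator counts the out-edges of focal-region traders that cross
#' into the other region minus those that stay within the focal region, and
#' the denominator is, by the literal formula, the total number of links in
#' the whole network (`denominator = "all"`). The alternative normalisation by
#' the focal region's out-links only is available as
#' `denominator = "focal_out"`. The index lies in `[-1, 1]`.
#'
#' @param net A [trade_network()] with at least one edge.
#' @param regions Named or plain integer vector of regions (1/2) per trader.
#' @param focal_region Region whose out-links are counted (default 1, the
#'   region exposed to seasonality in the experiments).
#' @param denominator `"all"` (total links in the network, default) or
#'   `"focal_out"` (the focal region's out-links).
#' @return The E-I index.
#' @export
ei_index <- function(net, regions, focal_region = 1L,
                     denominator = c("all", "focal_out")) {
  stopifnot(inherits(net, "trade_network"))
  denominator <- match.arg(denominator)
  em <- edge_matrix(net)
  if (nrow(em) == 0L)
    stop("E-I index is undefined for a network with no edges", call. = FALSE)
  regions <- as.integer(regions)
  if (length(regions) != n_traders(net) || any(!regions %in% c(1L, 2L)))
    stop("`regions` must give region 1 or 2 for every trader", call. = FALSE)
  focal_region <- as.integer(focal_region)
  from_focal <- regions[em[, 1L]] == focal_region
  external <- sum(from_focal & regions[em[, 2L]] != focal_region)
  internal <- sum(from_focal & regions[em[, 2L]] == focal_region)
  denom <- switch(denominator, all = nrow(em), focal_out = sum(from_focal))
  if (denom == 0L)
    stop("E-I index is undefined: focal region has no out-links", call. = FALSE)
  (external - internal) / denom
}
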