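# The coevolution network: nodes are kept reference positions, edges are
# significant MI z-scores; cumulative MI, proximity MI, percentile bands,
# filters and neighborhoods.

# percentile bands over retained-edge z values; ties promote upward
.bands <- function(z) {
  if (!length(z)) return(character(0))
  q95 <- stats::quantile(z, 0.95, names = FALSE, type = 7)
  q70 <- stats::quantile(z, 0.70, names = FALSE, type = 7)
  ifelse(z >= q95, "top5", ifelse(z >= q70, "mid70_95", "low"))
}

#' Build the coevolution network from score matrices
#'
#' Edges are exactly the pairs with `z > threshold` (strict inequality).
#' Isolated positions remain as nodes: they still carry conservation. When a
#' conservation profile and/or a structure map + distance matrix are given,
#' node KL, pMI, PDB numbering, secondary structure and edge spatial
#' distances are annotated.
#'
#' @param scores a [permutation_zscores()] result
#' @param threshold z-score retention threshold (default 6.5, strict `>`)
#' @param conservation optional [kl_conservation()] result
#' @param map optional [map_alignment_to_structure()] result
#' @param distances optional [min_distances()] matrix (required with `map`)
#' @param structure optional [read_structure()] result (secondary structure)
#' @param radius pMI neighborhood radius in Angstrom (default 5, inclusive)
#' @param include_self include the residue's own cMI in its pMI average
#'   (default `FALSE`)
#' @return an object of class `coevo_network` with data.frames `nodes`
#'   (`position`, `aa`, `label`, `kl`, `cmi`, `pmi`, `secondary`) and `edges`
#'   (`position_i`, `position_j`, `z`, `band`, `distance`, `separation`)
#' @export
build_network <- function(scores, threshold = 6.5, conservation = NULL,
                          map = NULL, distances = NULL, structure = NULL,
                          radius = 5, include_self = FALSE) {
  stopifnot(inherits(scores, "score_matrices"))
  pos <- scores$positions
  n <- length(pos)

  z <- scores$z
  ut <- which(upper.tri(z) & !is.na(z) & z > threshold, arr.ind = TRUE)
  edges <- data.frame(
    position_i = pos[ut[, 1]],
    position_j = pos[ut[, 2]],
    z = z[ut],
    band = rep(NA_character_, nrow(ut)),
    distance = rep(NA_real_, nrow(ut)),
    separation = abs(pos[ut[, 2]] - pos[ut[, 1]]),
    stringsAsFactors = FALSE
  )
  if (nrow(edges)) edges$band <- .bands(edges$z)

  nodes <- data.frame(
    position = pos,
    aa = scores$ref_aa,
    label = as.character(pos),
    kl = NA_real_,
    cmi = 0,
    pmi = NA_real_,
    secondary = NA_character_,
    stringsAsFactors = FALSE
  )
  if (!is.null(conservation)) {
    nodes$kl <- conservation$kl[match(pos, conservation$positions)]
  }

  # cMI: sum of retained-edge z incident to each node
  if (nrow(edges)) {
    inc <- tapply(c(edges$z, edges$z),
                  c(edges$position_i, edges$position_j), sum)
    hit <- match(nodes$position, as.integer(names(inc)))
    nodes$cmi <- ifelse(is.na(hit), 0, inc[hit])
  }

  net <- structure(
    list(nodes = nodes, edges = edges, threshold = threshold,
         radius = radius, has_structure = !is.null(map)),
    class = "coevo_network"
  )

  if (!is.null(map)) {
    if (is.null(distances)) {
      stop("'distances' is required when a structure map is given",
           call. = FALSE)
    }
    m <- match(nodes$position, map$pairs$ref_pos)
    net$nodes$label <- ifelse(is.na(m), nodes$label,
                              map$pairs$pdb_label[m])
    net$nodes$res_index <- map$pairs$res_index[m]
    if (!is.null(structure)) {
      net$nodes$secondary <-
        structure$residues$secondary[map$pairs$res_index[m]]
    }
    # edge spatial distances
    ei <- map$pairs$res_index[match(edges$position_i, map$pairs$ref_pos)]
    ej <- map$pairs$res_index[match(edges$position_j, map$pairs$ref_pos)]
    ok <- !is.na(ei) & !is.na(ej)
    if (any(ok)) net$edges$distance[ok] <- distances[cbind(ei[ok], ej[ok])]
    net$nodes$pmi <- proximity_mi(net, map, distances, radius = radius,
                                  include_self = include_self)
  }
  net
}

#' @export
print.coevo_network <- function(x, ...) {
  cat("Coevolution network: ", nrow(x$nodes), " positions, ", nrow(x$edges),
      " edges (z > ", x$threshold, ")\n", sep = "")
  if (nrow(x$edges)) {
    cat("  bands: ", sum(x$edges$band == "top5"), " top5, ",
        sum(x$edges$band == "mid70_95"), " mid70_95, ",
        sum(x$edges$band == "low"), " low\n", sep = "")
  }
  invisible(x)
}

#' Cumulative mutual information per node
#'
#' `cMI(i)` is the sum of z-scores over the retained edges incident to
#' position i; 0 for isolated nodes. Recomputed from the network's edge
#' table.
#'
#' @param network a [build_network()] result
#' @return numeric vector named by position
#' @export
cumulative_mi <- function(network) {
  stopifnot(inherits(network, "coevo_network"))
  out <- stats::setNames(rep(0, nrow(network$nodes)),
                         network$nodes$position)
  e <- network$edges
  if (nrow(e)) {
    inc <- tapply(c(e$z, e$z), c(e$position_i, e$position_j), sum)
    out[names(inc)] <- inc
  }
  out
}

#' Proximity mutual information per node
#'
#' `pMI(i)` is the mean cMI over mapped residues j != i whose minimum
#' heavy-atom distance to i is at most `radius` Angstrom. Missing for
#' unmapped positions and positions with no neighbor in range.
#'
#' @param network a [build_network()] result
#' @param map a [map_alignment_to_structure()] result
#' @param distances a [min_distances()] matrix
#' @param radius neighborhood radius in Angstrom (default 5, inclusive)
#' @param include_self also average in the residue's own cMI
#' @return numeric vector named by position (`NA` where undefined)
#' @export
proximity_mi <- function(network, map, distances, radius = 5,
                         include_self = FALSE) {
  stopifnot(inherits(network, "coevo_network"),
            inherits(map, "seqstruct_map"))
  nodes <- network$nodes
  cmi <- stats::setNames(nodes$cmi, nodes$position)
  res <- map$pairs$res_index[match(nodes$position, map$pairs$ref_pos)]
  out <- stats::setNames(rep(NA_real_, nrow(nodes)), nodes$position)
  mapped <- which(!is.na(res))
  for (k in mapped) {
    d <- distances[res[k], res[mapped]]
    nb <- mapped[!is.na(d) & d <= radius]
    if (!include_self) nb <- setdiff(nb, k)
    if (length(nb)) out[k] <- mean(cmi[nb])
  }
  out
}

#' Percentile bands of retained edges
#'
#' Bands over the retained-edge z values: `top5` for z at or above the 95th
#' percentile, `mid70_95` for the 70th-95th band, `low` otherwise
#' (linear-interpolation quantiles; ties promote upward, so a single edge or
#' all-equal edges are `top5`).
#'
#' @param network a [build_network()] result
#' @return character vector, one band per edge
#' @export
percentile_bands <- function(network) {
  stopifnot(inherits(network, "coevo_network"))
  .bands(network$edges$z)
}

# range test helper: NA attribute fails any explicit range
.in_range <- function(x, range) {
  if (is.null(range)) return(rep(TRUE, length(x)))
  if (length(range) == 1) range <- c(range, Inf)
  !is.na(x) & x >= range[1] & x <= range[2]
}

#' Filter a coevolution network
#'
#' Node criteria (`kl`, `cmi`, `pmi`) select nodes; edges survive iff both
#' endpoints survive and the edge criteria (`z`, `distance`, `separation`)
#' hold. Each criterion is `c(min, max)` (a single value means `c(value,
#' Inf)`); nodes/edges with a missing attribute fail an explicit range.
#' `top_n` is applied last: it keeps the N highest-z edges and their
#' endpoints. Contradictory ranges yield an empty sub-network, not an error.
#'
#' @param network a [build_network()] result
#' @param kl,cmi,pmi node attribute ranges
#' @param z,distance,separation edge attribute ranges
#' @param top_n keep only the N highest-z edges and their endpoints
#' @return the filtered `coevo_network`
#' @export
filter_network <- function(network, kl = NULL, cmi = NULL, pmi = NULL,
                           z = NULL, distance = NULL, separation = NULL,
                           top_n = NULL) {
  stopifnot(inherits(network, "coevo_network"))
  nodes <- network$nodes
  keep_node <- .in_range(nodes$kl, kl) &
    .in_range(nodes$cmi, cmi) &
    .in_range(nodes$pmi, pmi)
  nodes <- nodes[keep_node, , drop = FALSE]
  e <- network$edges
  keep_edge <- e$position_i %in% nodes$position &
    e$position_j %in% nodes$position &
    .in_range(e$z, z) &
    .in_range(e$distance, distance) &
    .in_range(e$separation, separation)
  e <- e[keep_edge, , drop = FALSE]
  if (!is.null(top_n) && nrow(e) > top_n) {
    e <- e[order(-e$z)[seq_len(top_n)], , drop = FALSE]
  }
  if (!is.null(top_n)) {
    nodes <- nodes[nodes$position %in% c(e$position_i, e$position_j), ,
                   drop = FALSE]
  }
  network$nodes <- nodes
  network$edges <- e
  network
}

.network_igraph <- function(network) {
  igraph::graph_from_data_frame(
    data.frame(from = as.character(network$edges$position_i),
               to = as.character(network$edges$position_j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(network$nodes$position))
  )
}

#' Neighborhood of a node
#'
#' `first_neighbors` keeps the node, its adjacent nodes and the connecting
#' edges; `connected_component` keeps the node's maximal connected subgraph.
#'
#' @param network a [build_network()] result
#' @param node reference position of the node
#' @param mode `"first_neighbors"` or `"connected_component"`
#' @return the sub-`coevo_network`
#' @export
neighborhood <- function(network, node,
                         mode = c("first_neighbors", "connected_component")) {
  mode <- match.arg(mode)
  stopifnot(inherits(network, "coevo_network"))
  if (!node %in% network$nodes$position) {
    stop("unknown node: ", node, call. = FALSE)
  }
  e <- network$edges
  if (mode == "first_neighbors") {
    touch <- e$position_i == node | e$position_j == node
    keep_pos <- unique(c(node, e$position_i[touch], e$position_j[touch]))
    e <- e[touch, , drop = FALSE]
  } else {
    g <- .network_igraph(network)
    comp <- igraph::components(g)
    cid <- comp$membership[as.character(node)]
    keep_pos <- as.integer(names(comp$membership)[comp$membership == cid])
    e <- e[e$position_i %in% keep_pos & e$position_j %in% keep_pos, ,
           drop = FALSE]
  }
  network$nodes <- network$nodes[network$nodes$position %in% keep_pos, ,
                                 drop = FALSE]
  network$edges <- e
  network
}
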