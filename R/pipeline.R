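# End-to-end orchestration: MSA -> weights -> MI z-scores -> conservation ->
# (structure) -> network -> bundle; returns a classed analysis object.

.stage <- function(name, expr, timings, verbose) {
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  dt <- proc.time()[["elapsed"]] - t0
  timings[[name]] <- dt
  if (verbose) message(sprintf("[%s] %.2fs", name, dt))
  list(value = value, timings = timings)
}

#' Run the full coevolution analysis pipeline
#'
#' Reads (or accepts) an alignment, sets the reference, masks gappy columns,
#' computes redundancy weights, permutation MI z-scores, KL conservation and
#' — when a structure is supplied — the residue distance matrix, the
#' Smith-Waterman sequence/structure map and proximity MI; builds the
#' coevolution and distance networks; optionally writes the result bundle.
#'
#' @param msa path to an alignment file, or an [alignment] object
#' @param format alignment format (see [read_msa()])
#' @param reference reference sequence identifier (default: first sequence)
#' @param pdb optional path to a PDB structure file
#' @param chain chain identifier within `pdb` (default: first chain)
#' @param out optional output directory; when given, [bundle_results()] is
#'   invoked
#' @param identity_threshold sequence clustering identity cutoff
#' @param pseudocount additive low-count correction per joint cell
#' @param n_permutations permutation replicates for the z-score null
#' @param seed RNG seed for the permutation null
#' @param max_gap_fraction column gap-fraction threshold
#' @param z_threshold edge retention threshold (strict `>`)
#' @param distance_cutoff distance-network edge cutoff in Angstrom (strict `<`)
#' @param radius pMI neighborhood radius in Angstrom (inclusive)
#' @param null permutation null: `"per-pair"` or `"pooled"`
#' @param background `"blosum62"`, `"uniform"`, or 20 frequencies
#' @param verbose log stage timings
#' @return an object of class `coevomap` bundling every intermediate result:
#'   `alignment`, `mask`, `weights`, `scores`, `conservation`, `structure`,
#'   `map`, `distances`, `network`, `dist_net`, `params`, `timings`
#' @export
run_pipeline <- function(msa, format = "auto", reference = NULL, pdb = NULL,
                         chain = NULL, out = NULL,
                         identity_threshold = 0.62, pseudocount = 0.05,
                         n_permutations = 100, seed = 1729L,
                         max_gap_fraction = 0.5, z_threshold = 6.5,
                         distance_cutoff = 5, radius = 5,
                         null = "per-pair", background = "blosum62",
                         verbose = TRUE) {
  timings <- list()
  if (is.character(background)) {
    background <- background_frequencies(background)
  }

  st <- .stage("msa_io", {
    aln <- if (inherits(msa, "alignment")) msa else read_msa(msa, format)
    aln <- set_reference(aln, reference)
    list(alignment = aln, mask = mask_columns(aln, max_gap_fraction))
  }, timings, verbose); timings <- st$timings
  alignment <- st$value$alignment
  mask <- st$value$mask

  st <- .stage("weighting",
               cluster_weights(alignment, identity_threshold),
               timings, verbose); timings <- st$timings
  weights <- st$value

  st <- .stage("mi_engine",
               permutation_zscores(alignment, mask, weights, pseudocount,
                                   n_permutations, seed, null),
               timings, verbose); timings <- st$timings
  scores <- st$value

  st <- .stage("conservation",
               kl_conservation(alignment, mask, weights, background,
                               pseudocount),
               timings, verbose); timings <- st$timings
  conservation <- st$value

  struct <- map <- distances <- dist_net <- NULL
  if (!is.null(pdb)) {
    st <- .stage("structure_map", {
      s <- read_structure(pdb, chain)
      d <- min_distances(s)
      m <- map_alignment_to_structure(alignment, mask, s)
      list(structure = s, distances = d, map = m,
           dist_net = distance_network(d, distance_cutoff))
    }, timings, verbose); timings <- st$timings
    struct <- st$value$structure
    distances <- st$value$distances
    map <- st$value$map
    dist_net <- st$value$dist_net
  }

  st <- .stage("coevo_network",
               build_network(scores, z_threshold, conservation, map,
                             distances, struct, radius),
               timings, verbose); timings <- st$timings
  network <- st$value

  result <- structure(
    list(alignment = alignment, mask = mask, weights = weights,
         scores = scores, conservation = conservation, structure = struct,
         map = map, distances = distances, network = network,
         dist_net = dist_net,
         params = list(identity_threshold = identity_threshold,
                       pseudocount = pseudocount,
                       n_permutations = n_permutations, seed = seed,
                       max_gap_fraction = max_gap_fraction,
                       z_threshold = z_threshold,
                       distance_cutoff = distance_cutoff, radius = radius,
                       null = null),
         timings = timings),
    class = "coevomap"
  )
  if (!is.null(out)) {
    st <- .stage("reporting", bundle_results(result, out), timings, verbose)
    result$timings <- st$timings
    result$bundle <- st$value
  }
  result
}

#' @export
print.coevomap <- function(x, ...) {
  cat("Coevolution analysis (", length(x$alignment$seq), " sequences x ",
      x$alignment$n_columns, " columns, ", sum(x$mask$keep),
      " kept positions)\n", sep = "")
  cat("  ", nrow(x$network$edges), " retained edges (z > ",
      x$params$z_threshold, ", ", x$params$n_permutations,
      " permutations, seed ", x$params$seed, ")\n", sep = "")
  if (!is.null(x$structure)) {
    cat("  structure: chain ", x$structure$chain_id,
        sprintf(", coverage %.0f%%\n", 100 * x$map$coverage), sep = "")
  }
  invisible(x)
}

#' @export
summary.coevomap <- function(object, n_top = 10, ...) {
  e <- object$network$edges
  top_edges <- if (nrow(e)) {
    e[order(-e$z)[seq_len(min(n_top, nrow(e)))], , drop = FALSE]
  } else e
  nodes <- object$network$nodes
  hubs <- nodes[order(-nodes$cmi)[seq_len(min(n_top, nrow(nodes)))], ,
                drop = FALSE]
  out <- list(n_sequences = length(object$alignment$seq),
              n_positions = nrow(nodes), n_edges = nrow(e),
              top_edges = top_edges, hubs = hubs,
              params = object$params)
  class(out) <- "summary.coevomap"
  out
}

#' @export
print.summary.coevomap <- function(x, ...) {
  cat("Coevolution analysis summary\n")
  cat("  sequences: ", x$n_sequences, "; positions: ", x$n_positions,
      "; edges: ", x$n_edges, "\n", sep = "")
  if (nrow(x$top_edges)) {
    cat("\nTop edges by z-score:\n")
    print(x$top_edges, row.names = FALSE)
  }
  cat("\nTop positions by cumulative MI:\n")
  print(x$hubs[, c("position", "aa", "kl", "cmi", "pmi")], row.names = FALSE)
  invisible(x)
}

#' @export
plot.coevomap <- function(x, ...) {
  .draw_circos_base(circos_layout(x$network))
  invisible(x)
}
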