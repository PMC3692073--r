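# Sequence redundancy weights from single-linkage identity clustering.

#' Pairwise sequence identity
#'
#' Fraction of positions with identical residues, counted over positions
#' where neither sequence has a gap. Returns 0 when no such positions exist.
#'
#' @param a,b aligned residue strings of equal length
#' @return identity fraction in \[0, 1\]
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("sequences have different lengths (", nchar(a), " vs ", nchar(b),
         ")", call. = FALSE)
  }
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  ok <- ca != "-" & cb != "-"
  if (!any(ok)) return(0)
  sum(ca[ok] == cb[ok]) / sum(ok)
}

# full identity matrix, vectorized over columns
.identity_matrix <- function(alignment) {
  chars <- do.call(rbind, strsplit(alignment$seq, "", fixed = TRUE))
  n <- nrow(chars)
  match_count <- matrix(0, n, n)
  denom <- matrix(0, n, n)
  for (c in seq_len(ncol(chars))) {
    nongap <- chars[, c] != "-"
    both <- outer(nongap, nongap, "&")
    denom <- denom + both
    eq <- outer(chars[, c], chars[, c], "==") & both
    match_count <- match_count + eq
  }
  idm <- ifelse(denom > 0, match_count / denom, 0)
  diag(idm) <- 1
  idm
}

#' Sequence weights from single-linkage identity clustering
#'
#' Sequences are clustered by single linkage under the relation
#' identity >= `identity_threshold`; each sequence is weighted 1/(its cluster
#' size), so every cluster contributes unit total weight to frequency
#' estimates. Single linkage (transitive closure) makes the result invariant
#' to sequence order.
#'
#' @param alignment an [alignment] object
#' @param identity_threshold clustering identity cutoff in (0, 1]
#' @return an object of class `seq_weights` with fields `weight`, `cluster_id`
#'   (both named by sequence identifier) and `identity_threshold`
#' @export
cluster_weights <- function(alignment, identity_threshold = 0.62) {
  stopifnot(inherits(alignment, "alignment"))
  if (identity_threshold <= 0 || identity_threshold > 1) {
    stop("identity_threshold must be in (0, 1]", call. = FALSE)
  }
  idm <- .identity_matrix(alignment)
  adj <- idm >= identity_threshold
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  cluster_id <- as.integer(comp$membership)
  size <- as.integer(comp$csize)[cluster_id]
  weight <- 1 / size
  structure(
    list(weight = stats::setNames(weight, alignment$id),
         cluster_id = stats::setNames(cluster_id, alignment$id),
         identity_threshold = identity_threshold),
    class = "seq_weights"
  )
}

#' @export
print.seq_weights <- function(x, ...) {
  cat("Sequence weights: ", length(x$weight), " sequences in ",
      max(x$cluster_id), " clusters (identity >= ",
      x$identity_threshold, ")\n", sep = "")
  invisible(x)
}

# accept either a seq_weights object or a bare numeric vector; normalized to
# mean 1 so the balance against the additive pseudocount does not depend on
# the arbitrary scale of the weights (frequencies are then exactly invariant
# to rescaling all weights)
.weight_vector <- function(weights, n) {
  w <- if (inherits(weights, "seq_weights")) weights$weight else weights
  w <- as.numeric(w)
  if (length(w) != n) {
    stop("weights must have one entry per sequence (", n, ")", call. = FALSE)
  }
  if (any(w < 0) || all(w == 0)) {
    stop("weights must be nonnegative and not all zero", call. = FALSE)
  }
  unname(w * (length(w) / sum(w)))
}
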