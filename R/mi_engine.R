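# Weighted pair frequencies, mutual information, average product correction
# and the column-permutation z-score null.

.check_kept <- function(mask, i, j) {
  if (i == j) stop("column pair must have i != j", call. = FALSE)
  if (!mask$keep[i] || !mask$keep[j]) {
    stop("columns ", i, ", ", j, " must both be kept by the mask",
         call. = FALSE)
  }
}

#' Weighted pair-frequency table for one column pair
#'
#' Each sequence whose residues at columns `i` and `j` are both standard
#' amino acids contributes its weight to the corresponding cell of a 20x20
#' joint table (gaps and `X` are skipped). The pseudocount `lambda` is added
#' to every cell (low-count correction) before normalization; marginals are
#' the row/column sums of the joint.
#'
#' @param alignment an [alignment] object
#' @param mask a [mask_columns()] result
#' @param weights a [cluster_weights()] result or numeric vector
#' @param i,j alignment column indices (1-based), both kept, `i != j`
#' @param pseudocount additive pseudocount per joint cell (default 0.05)
#' @return an object of class `pair_freq` with fields `joint` (20x20),
#'   `marginal_i`, `marginal_j`, `pseudocount`, `effective_count`
#' @export
pair_frequencies <- function(alignment, mask, weights, i, j,
                             pseudocount = 0.05) {
  .check_kept(mask, i, j)
  w <- .weight_vector(weights, length(alignment$seq))
  code <- encode_alignment(alignment, c(i, j))
  ok <- code[, 1] > 0L & code[, 2] > 0L
  if (sum(ok) < 2L) {
    stop("degenerate pair (", i, ", ", j, "): fewer than 2 sequences ",
         "contribute", call. = FALSE)
  }
  aa <- aa_alphabet()
  joint <- matrix(pseudocount, 20, 20, dimnames = list(aa, aa))
  for (s in which(ok)) {
    joint[code[s, 1], code[s, 2]] <- joint[code[s, 1], code[s, 2]] + w[s]
  }
  joint <- joint / sum(joint)
  structure(
    list(joint = joint,
         marginal_i = rowSums(joint),
         marginal_j = colSums(joint),
         pseudocount = pseudocount,
         effective_count = sum(w[ok])),
    class = "pair_freq"
  )
}

#' Mutual information of a pair-frequency table
#'
#' \eqn{\sum_{a,b} p_{ij}(a,b) \ln[p_{ij}(a,b) / (p_i(a) p_j(b))]} in nats;
#' zero-probability cells contribute 0.
#'
#' @param table a [pair_frequencies()] result
#' @return mutual information in nats
#' @export
mutual_information <- function(table) {
  stopifnot(inherits(table, "pair_freq"))
  p <- table$joint
  e <- outer(table$marginal_i, table$marginal_j)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / e[nz]))
}

# internal: MI matrix from an already-encoded column block
.mi_matrix_code <- function(code, w, pseudocount) {
  mi_matrix_cpp(code, w, pseudocount)
}

#' Mutual information matrix over kept columns
#'
#' Computes [mutual_information()] for every pair of kept columns (fast
#' compiled path). Degenerate pairs (fewer than 2 contributing sequences) are
#' reported as `NA` and propagate as missing through downstream corrections.
#'
#' @inheritParams pair_frequencies
#' @return symmetric matrix over kept columns with `NA` diagonal; dimnames
#'   are reference positions, attribute `columns` holds the alignment column
#'   indices
#' @export
mi_matrix <- function(alignment, mask, weights, pseudocount = 0.05) {
  stopifnot(inherits(alignment, "alignment"), inherits(mask, "column_mask"))
  w <- .weight_vector(weights, length(alignment$seq))
  cols <- which(mask$keep)
  if (length(cols) < 2L) stop("need at least 2 kept columns", call. = FALSE)
  code <- encode_alignment(alignment, cols)
  mi <- .mi_matrix_code(code, w, pseudocount)
  pos <- mask$ref_position[cols]
  dimnames(mi) <- list(pos, pos)
  attr(mi, "columns") <- cols
  mi
}

#' Average product correction (APC)
#'
#' Subtracts the background term `mean_i * mean_j / mean_all` from each MI
#' entry, where `mean_i` is the mean over defined off-diagonal entries of row
#' i and `mean_all` the mean over all defined off-diagonal entries. This
#' suppresses shared phylogenetic/entropic signal.
#'
#' @param mi symmetric MI matrix (e.g. from [mi_matrix()]); `NA` entries are
#'   excluded from means and stay `NA`
#' @return corrected symmetric matrix of the same shape
#' @export
apc_correct <- function(mi) {
  stopifnot(is.matrix(mi), nrow(mi) == ncol(mi))
  m <- mi
  diag(m) <- NA
  row_mean <- rowMeans(m, na.rm = TRUE)
  mean_all <- mean(m[upper.tri(m)], na.rm = TRUE)
  if (is.nan(mean_all) || mean_all == 0) {
    warning("mean MI is zero; APC returns the input unchanged")
    return(mi)
  }
  corrected <- m - outer(row_mean, row_mean) / mean_all
  corrected[is.na(m)] <- NA
  diag(corrected) <- NA
  matrix(corrected, nrow(mi), ncol(mi), dimnames = dimnames(mi))
}

# shuffle residues within every column (preserves column compositions,
# destroys inter-column correlation)
.shuffle_columns <- function(code) {
  n <- nrow(code)
  for (c in seq_len(ncol(code))) {
    code[, c] <- code[sample.int(n), c]
  }
  code
}

#' Permutation z-scores for APC-corrected mutual information
#'
#' For each permutation replicate the residues within every kept column are
#' shuffled independently across sequences (gaps travel with residues), the
#' full APC-corrected MI matrix is recomputed, and the observed corrected MI
#' is standardized against the null: `z = (obs - mean_null) / sd_null`. With
#' `null = "per-pair"` (default) each pair gets its own null moments; with
#' `"pooled"` moments are pooled over all defined pairs and replicates. Pairs
#' whose null spread is zero (e.g. fully conserved columns) get `z = 0` and
#' are flagged degenerate. Deterministic for a fixed `seed`.
#'
#' @inheritParams pair_frequencies
#' @param n_permutations number of shuffled replicates (>= 2; default 100)
#' @param seed RNG seed (default 1729)
#' @param null `"per-pair"` or `"pooled"` null moments
#' @return an object of class `score_matrices`: `mi_raw`, `mi_apc`, `z`
#'   (symmetric matrices over kept columns), `degenerate` (logical matrix),
#'   `mean_mi`, `n_permutations`, `seed`, `null`, `positions` (reference
#'   position per kept column), `ref_aa` (reference residue per kept column)
#' @export
permutation_zscores <- function(alignment, mask, weights, pseudocount = 0.05,
                                n_permutations = 100, seed = 1729L,
                                null = c("per-pair", "pooled")) {
  null <- match.arg(null)
  stopifnot(inherits(alignment, "alignment"), inherits(mask, "column_mask"))
  if (n_permutations < 2) stop("n_permutations must be >= 2", call. = FALSE)
  w <- .weight_vector(weights, length(alignment$seq))
  cols <- which(mask$keep)
  code <- encode_alignment(alignment, cols)

  mi_raw <- .mi_matrix_code(code, w, pseudocount)
  mi_apc <- apc_correct(mi_raw)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  m <- length(cols)
  s1 <- matrix(0, m, m)
  s2 <- matrix(0, m, m)
  n_def <- matrix(0L, m, m)
  for (r in seq_len(n_permutations)) {
    perm <- .shuffle_columns(code)
    null_apc <- apc_correct(.mi_matrix_code(perm, w, pseudocount))
    def <- !is.na(null_apc)
    v <- ifelse(def, null_apc, 0)
    s1 <- s1 + v
    s2 <- s2 + v * v
    n_def <- n_def + def
  }

  if (null == "per-pair") {
    null_mean <- ifelse(n_def > 0, s1 / n_def, NA)
    null_var <- ifelse(n_def > 1,
                       pmax(0, (s2 - s1^2 / pmax(n_def, 1)) / (n_def - 1)),
                       NA)
    null_sd <- sqrt(null_var)
  } else {
    off <- upper.tri(s1)
    n_tot <- sum(n_def[off])
    g1 <- sum(s1[off]); g2 <- sum(s2[off])
    gm <- g1 / n_tot
    gsd <- sqrt(max(0, (g2 - g1^2 / n_tot) / (n_tot - 1)))
    null_mean <- matrix(gm, m, m)
    null_sd <- matrix(gsd, m, m)
  }

  z <- (mi_apc - null_mean) / null_sd
  degenerate <- !is.na(mi_apc) & !is.na(null_sd) & null_sd == 0
  z[degenerate] <- 0
  z[is.na(mi_apc)] <- NA
  diag(z) <- NA
  pos <- mask$ref_position[cols]
  dimnames(z) <- dimnames(mi_raw) <- dimnames(mi_apc) <-
    dimnames(degenerate) <- list(pos, pos)
  ref_chars <- strsplit(alignment$seq[alignment$reference_row], "",
                        fixed = TRUE)[[1]]
  structure(
    list(mi_raw = mi_raw, mi_apc = mi_apc, z = z, degenerate = degenerate,
         mean_mi = mean(mi_raw[upper.tri(mi_raw)], na.rm = TRUE),
         n_permutations = n_permutations, seed = as.integer(seed),
         null = null, positions = pos, columns = cols,
         ref_aa = ref_chars[cols]),
    class = "score_matrices"
  )
}

#' @export
print.score_matrices <- function(x, ...) {
  cat("MI score matrices over ", length(x$positions), " kept positions (",
      x$n_permutations, " permutations, ", x$null, " null, seed ", x$seed,
      ")\n", sep = "")
  zz <- x$z[upper.tri(x$z)]
  cat("  z-score range: ", round(min(zz, na.rm = TRUE), 2), " .. ",
      round(max(zz, na.rm = TRUE), 2), "\n", sep = "")
  invisible(x)
}

#' Significant-pair table from score matrices
#'
#' One row per kept pair with z above `threshold` (strict), the raw output
#' table format of the analysis.
#'
#' @param scores a [permutation_zscores()] result
#' @param threshold z-score retention threshold (default 6.5)
#' @param all if `TRUE`, dump every defined pair regardless of threshold
#' @return data.frame with `position_i`, `position_j`, `z`
#' @export
zscore_table <- function(scores, threshold = 6.5, all = FALSE) {
  stopifnot(inherits(scores, "score_matrices"))
  z <- scores$z
  ut <- which(upper.tri(z), arr.ind = TRUE)
  zv <- z[ut]
  keep <- if (all) !is.na(zv) else !is.na(zv) & zv > threshold
  data.frame(
    position_i = scores$positions[ut[keep, 1]],
    position_j = scores$positions[ut[keep, 2]],
    z = zv[keep]
  )
}
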