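# Per-column Kullback-Leibler conservation and enrichment/depletion logos.

# weighted, pseudocounted amino-acid frequencies per kept column;
# columns with no standard residue get an all-NA row
.column_frequencies <- function(alignment, mask, weights, pseudocount) {
  w <- .weight_vector(weights, length(alignment$seq))
  cols <- which(mask$keep)
  code <- encode_alignment(alignment, cols)
  freq <- matrix(NA_real_, length(cols), 20,
                 dimnames = list(mask$ref_position[cols], aa_alphabet()))
  for (k in seq_along(cols)) {
    ok <- code[, k] > 0L
    if (!any(ok)) next
    counts <- rep(pseudocount, 20)
    for (s in which(ok)) counts[code[s, k]] <- counts[code[s, k]] + w[s]
    freq[k, ] <- counts / sum(counts)
  }
  attr(freq, "columns") <- cols
  freq
}

.check_background <- function(background) {
  if (length(background) != 20 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6) {
    stop("background must be 20 strictly positive frequencies summing to 1",
         call. = FALSE)
  }
  if (!is.null(names(background))) background <- background[aa_alphabet()]
  unname(background)
}

#' Kullback-Leibler conservation per kept column
#'
#' For each kept column, the KL divergence (nats) of its weighted,
#' pseudocounted amino-acid distribution from a background distribution:
#' \eqn{KL(c) = \sum_a p_c(a) \ln[p_c(a)/q(a)]}. High values mark conserved
#' positions. Gaps and unknowns are excluded from the column distribution.
#'
#' @inheritParams pair_frequencies
#' @param background 20 strictly positive frequencies summing to 1
#'   (default [background_frequencies()] `"blosum62"`)
#' @return an object of class `conservation_profile` with fields `kl`
#'   (named by reference position; `NA` for columns with no standard
#'   residues), `frequencies` (kept columns x 20), `background`,
#'   `positions`, `columns`
#' @export
kl_conservation <- function(alignment, mask, weights,
                            background = background_frequencies(),
                            pseudocount = 0.05) {
  stopifnot(inherits(alignment, "alignment"), inherits(mask, "column_mask"))
  q <- .check_background(background)
  freq <- .column_frequencies(alignment, mask, weights, pseudocount)
  kl <- apply(freq, 1, function(p) {
    if (anyNA(p)) return(NA_real_)
    nz <- p > 0
    sum(p[nz] * log(p[nz] / q[nz]))
  })
  structure(
    list(kl = kl, frequencies = freq,
         background = stats::setNames(q, aa_alphabet()),
         positions = as.integer(rownames(freq)),
         columns = attr(freq, "columns")),
    class = "conservation_profile"
  )
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("KL conservation over ", length(x$kl), " positions; range ",
      round(min(x$kl, na.rm = TRUE), 3), " .. ",
      round(max(x$kl, na.rm = TRUE), 3), " nats\n", sep = "")
  invisible(x)
}

#' Enrichment/depletion logo data for selected columns
#'
#' Per selected column and amino acid, the signed KL contribution
#' \eqn{p_c(a) \ln[p_c(a)/q(a)]}: positive terms are enrichments relative to
#' the background, negative terms depletions. Summing a column's terms gives
#' its KL conservation. Raw frequencies are attached for single-position
#' displays.
#'
#' @inheritParams kl_conservation
#' @param columns alignment column indices (1-based, all kept), in display
#'   order
#' @return an object of class `logo_data`: `terms` and `frequencies` matrices
#'   (selected columns x 20, rows named by reference position)
#' @export
logo_data <- function(alignment, mask, weights, columns,
                      background = background_frequencies(),
                      pseudocount = 0.05) {
  stopifnot(inherits(alignment, "alignment"), inherits(mask, "column_mask"))
  if (length(columns) == 0) stop("empty column selection", call. = FALSE)
  if (!all(mask$keep[columns])) {
    stop("all selected columns must be kept by the mask", call. = FALSE)
  }
  q <- .check_background(background)
  freq_all <- .column_frequencies(alignment, mask, weights, pseudocount)
  idx <- match(columns, attr(freq_all, "columns"))
  freq <- freq_all[idx, , drop = FALSE]
  terms <- freq
  for (k in seq_len(nrow(freq))) {
    p <- freq[k, ]
    t <- ifelse(p > 0, p * log(p / q), 0)
    terms[k, ] <- t
  }
  structure(
    list(terms = terms, frequencies = freq,
         positions = as.integer(rownames(freq)), columns = columns),
    class = "logo_data"
  )
}
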