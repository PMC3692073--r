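# Synthetic alignments with planted covarying pairs, and toy PDB files.

#' Generate a synthetic alignment with planted covarying column pairs
#'
#' Independent columns are drawn from `background`. Each planted pair follows
#' a two-state coupled model: with probability `coupling` the pair takes one
#' of the states (A,D) or (C,E) (equiprobable, fully correlated; standard
#' residues only, since B is not a standard amino-acid code), otherwise the
#' two columns draw independently and uniformly from \{A,C\} and \{D,E\}.
#' Marginals are thus 50/50 regardless of coupling, and at coupling 1 the
#' pair's mutual information is exactly ln 2. Conserved columns place a
#' dominant residue at the stated frequency, the remainder drawn from the
#' background. Gaps are injected uniformly at `gap_rate`. Deterministic per
#' `seed`.
#'
#' @param n_sequences number of sequences (default 200)
#' @param n_columns number of columns (default 30)
#' @param planted_pairs data.frame with columns `i`, `j`, `coupling` (or a
#'   list of `c(i, j, coupling)` triples); pairs must be disjoint
#' @param conservation_columns data.frame with columns `column`, `aa`,
#'   `frequency`
#' @param background 20 frequencies (default uniform)
#' @param gap_rate per-cell gap probability (default 0)
#' @param seed RNG seed
#' @return list with `alignment` (an [alignment]; first row is the
#'   reference) and `truth` (the planted-pair data.frame)
#' @export
generate_msa <- function(n_sequences = 200, n_columns = 30,
                         planted_pairs = NULL, conservation_columns = NULL,
                         background = NULL, gap_rate = 0, seed = 1L) {
  if (is.list(planted_pairs) && !is.data.frame(planted_pairs)) {
    planted_pairs <- do.call(rbind, lapply(planted_pairs, function(p) {
      data.frame(i = p[1], j = p[2], coupling = p[3])
    }))
  }
  if (is.null(planted_pairs)) {
    planted_pairs <- data.frame(i = integer(0), j = integer(0),
                                coupling = numeric(0))
  }
  if (nrow(planted_pairs)) {
    idx <- c(planted_pairs$i, planted_pairs$j)
    if (any(idx < 1 | idx > n_columns)) {
      stop("planted column index out of range", call. = FALSE)
    }
    if (anyDuplicated(idx)) {
      stop("planted pairs must use disjoint columns", call. = FALSE)
    }
    if (any(planted_pairs$coupling < 0 | planted_pairs$coupling > 1)) {
      stop("coupling must be in [0, 1]", call. = FALSE)
    }
  }
  aa <- aa_alphabet()
  if (is.null(background)) background <- rep(1 / 20, 20)
  background <- .check_background(background)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  chars <- matrix(sample(aa, n_sequences * n_columns, replace = TRUE,
                         prob = background),
                  n_sequences, n_columns)
  for (k in seq_len(nrow(planted_pairs))) {
    i <- planted_pairs$i[k]; j <- planted_pairs$j[k]
    cpl <- planted_pairs$coupling[k]
    coupled <- stats::runif(n_sequences) < cpl
    state <- sample(c(1L, 2L), n_sequences, replace = TRUE)
    chars[, i] <- ifelse(coupled,
                         c("A", "C")[state],
                         sample(c("A", "C"), n_sequences, replace = TRUE))
    chars[, j] <- ifelse(coupled,
                         c("D", "E")[state],
                         sample(c("D", "E"), n_sequences, replace = TRUE))
  }
  if (!is.null(conservation_columns)) {
    for (k in seq_len(nrow(conservation_columns))) {
      c0 <- conservation_columns$column[k]
      dom <- stats::runif(n_sequences) < conservation_columns$frequency[k]
      bg <- sample(aa, n_sequences, replace = TRUE, prob = background)
      chars[, c0] <- ifelse(dom, conservation_columns$aa[k], bg)
    }
  }
  if (gap_rate > 0) {
    chars[matrix(stats::runif(length(chars)) < gap_rate,
                 nrow(chars))] <- "-"
  }
  ids <- sprintf("seq_%03d", seq_len(n_sequences))
  aln <- new_alignment(ids, apply(chars, 1, paste, collapse = ""))
  list(alignment = aln, truth = planted_pairs)
}

# ideal alpha-helix CA trace: radius 2.3 A, rise 1.5 A, 100 degrees/residue
.helix_coords <- function(n) {
  t <- (seq_len(n) - 1) * 100 * pi / 180
  cbind(x = 2.3 * cos(t), y = 2.3 * sin(t), z = 1.5 * (seq_len(n) - 1))
}

#' Write a toy CA-only PDB file
#'
#' A single chain of CA atoms with exact coordinates: `"line"` places them
#' collinearly at `spacing` Angstrom, `"helix"` on an ideal alpha-helix
#' (radius 2.3 A, rise 1.5 A, 100 degrees per residue; `spacing` ignored).
#'
#' @param n_residues number of residues (>= 2)
#' @param geometry `"line"` or `"helix"`
#' @param spacing inter-CA distance for `"line"` (default 3.8)
#' @param path output path (default a tempfile)
#' @param sequence optional one-letter residue sequence (recycled/truncated
#'   to `n_residues`; default poly-alanine)
#' @param chain chain identifier (default `"A"`)
#' @return the output path, invisibly
#' @export
generate_toy_pdb <- function(n_residues, geometry = c("line", "helix"),
                             spacing = 3.8, path = tempfile(fileext = ".pdb"),
                             sequence = NULL, chain = "A") {
  geometry <- match.arg(geometry)
  if (n_residues < 2) stop("n_residues must be >= 2", call. = FALSE)
  coords <- switch(geometry,
    line = cbind(x = (seq_len(n_residues) - 1) * spacing, y = 0, z = 0),
    helix = .helix_coords(n_residues)
  )
  if (is.null(sequence)) {
    aa1 <- rep("A", n_residues)
  } else {
    aa1 <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
    aa1 <- rep_len(aa1, n_residues)
  }
  aa3 <- names(.aa3to1)[match(aa1, .aa3to1)]
  aa3[is.na(aa3)] <- "UNK"
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n_residues), aa3, chain, seq_len(n_residues),
    coords[, 1], coords[, 2], coords[, 3]
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
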