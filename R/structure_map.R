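# PDB chain parsing, minimum heavy-atom distances, the distance network and
# Smith-Waterman mapping of alignment positions onto structure residues.

.pdb_field <- function(lines, from, to) trimws(substr(lines, from, to))

# element-based, with atom-name fallback: strip leading digits, first letter H
.is_hydrogen <- function(element, name) {
  el <- toupper(element)
  has_el <- nzchar(el)
  byname <- grepl("^H", sub("^[0-9]+", "", toupper(name)))
  ifelse(has_el, el %in% c("H", "D"), byname)
}

#' Read one chain of a PDB-format structure
#'
#' Parses ATOM records of the first model only. Alternate locations keep the
#' highest-occupancy conformer (first on ties). Hydrogens are retained in
#' storage but flagged, and excluded from distance computation. HELIX/SHEET
#' header records populate per-residue secondary-structure labels; residues
#' not covered are `"coil"`.
#'
#' @param path path to a PDB file
#' @param chain chain identifier; `NULL` takes the first chain encountered
#' @return an object of class `structure_model`: `chain_id`, `residues`
#'   (data.frame: `number`, `icode`, `label`, `aa` one-letter, `secondary`),
#'   `atoms` (data.frame: `res` residue index, `name`, `element`, `x`, `y`,
#'   `z`, `occupancy`, `hydrogen`)
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)

  # first model only
  model_start <- grep("^MODEL", lines)
  if (length(model_start)) {
    model_end <- grep("^ENDMDL", lines)
    end <- if (length(model_end)) model_end[1] else length(lines)
    body <- lines[(model_start[1] + 1L):(end - 1L)]
    header <- lines[seq_len(model_start[1] - 1L)]
  } else {
    body <- lines
    header <- lines
  }

  atom <- body[startsWith(body, "ATOM  ")]
  if (!length(atom)) stop("no ATOM records in ", path, call. = FALSE)

  chains <- substr(atom, 22, 22)
  available <- unique(chains)
  if (is.null(chain)) chain <- available[1]
  if (!chain %in% available) {
    stop("chain ", dQuote(chain), " not found; available: ",
         paste(available, collapse = ", "), call. = FALSE)
  }
  atom <- atom[chains == chain]

  df <- data.frame(
    name = .pdb_field(atom, 13, 16),
    altloc = substr(atom, 17, 17),
    resname = .pdb_field(atom, 18, 20),
    number = as.integer(.pdb_field(atom, 23, 26)),
    icode = trimws(substr(atom, 27, 27)),
    x = as.numeric(.pdb_field(atom, 31, 38)),
    y = as.numeric(.pdb_field(atom, 39, 46)),
    z = as.numeric(.pdb_field(atom, 47, 54)),
    occupancy = suppressWarnings(as.numeric(.pdb_field(atom, 55, 60))),
    element = .pdb_field(atom, 77, 78),
    stringsAsFactors = FALSE
  )
  df$occupancy[is.na(df$occupancy)] <- 1

  # altloc: per (residue, atom name) keep the highest-occupancy conformer,
  # then restore file order
  key <- paste(df$number, df$icode, df$name)
  df$.row <- seq_len(nrow(df))
  ord <- order(key, -df$occupancy, df$.row)
  df <- df[ord, ][!duplicated(key[ord]), ]
  df <- df[order(df$.row), ]

  reskey <- paste(df$number, df$icode)
  res_index <- match(reskey, unique(reskey))
  first <- !duplicated(res_index)
  residues <- data.frame(
    number = df$number[first],
    icode = df$icode[first],
    label = paste0(df$number[first], df$icode[first]),
    aa = unname(ifelse(df$resname[first] %in% names(.aa3to1),
                       .aa3to1[df$resname[first]], "X")),
    secondary = "coil",
    stringsAsFactors = FALSE
  )

  # secondary structure from header HELIX/SHEET records (this chain only)
  helix <- header[startsWith(header, "HELIX ")]
  for (h in helix) {
    if (substr(h, 20, 20) != chain) next
    from <- suppressWarnings(as.integer(trimws(substr(h, 22, 25))))
    to <- suppressWarnings(as.integer(trimws(substr(h, 34, 37))))
    if (!is.na(from) && !is.na(to)) {
      residues$secondary[residues$number >= from & residues$number <= to] <-
        "helix"
    }
  }
  sheet <- header[startsWith(header, "SHEET ")]
  for (s in sheet) {
    if (substr(s, 22, 22) != chain) next
    from <- suppressWarnings(as.integer(trimws(substr(s, 23, 26))))
    to <- suppressWarnings(as.integer(trimws(substr(s, 34, 37))))
    if (!is.na(from) && !is.na(to)) {
      residues$secondary[residues$number >= from & residues$number <= to] <-
        "sheet"
    }
  }

  atoms <- data.frame(
    res = res_index,
    name = df$name,
    element = df$element,
    x = df$x, y = df$y, z = df$z,
    occupancy = df$occupancy,
    hydrogen = .is_hydrogen(df$element, df$name),
    stringsAsFactors = FALSE
  )
  structure(
    list(chain_id = chain, residues = residues, atoms = atoms, path = path),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat("Structure chain ", x$chain_id, ": ", nrow(x$residues), " residues, ",
      nrow(x$atoms), " atoms (", sum(!x$atoms$hydrogen), " heavy)\n",
      sep = "")
  invisible(x)
}

#' Minimum heavy-atom inter-residue distances
#'
#' Entry (r, s) is the minimum Euclidean distance (Angstrom) over all pairs
#' of non-hydrogen atoms of residues r and s. Residues with no heavy atom get
#' an all-`NA` row/column. Diagonal is 0.
#'
#' @param structure a [read_structure()] result
#' @return symmetric distance matrix with residue labels as dimnames
#' @export
min_distances <- function(structure) {
  stopifnot(inherits(structure, "structure_model"))
  res <- structure$residues
  n <- nrow(res)
  if (n < 2) stop("need at least 2 residues", call. = FALSE)
  heavy <- structure$atoms[!structure$atoms$hydrogen, , drop = FALSE]
  out <- matrix(NA_real_, n, n, dimnames = list(res$label, res$label))
  if (nrow(heavy)) {
    coords <- as.matrix(heavy[, c("x", "y", "z")])
    d <- as.matrix(stats::dist(coords))
    grp <- heavy$res
    present <- sort(unique(grp))
    for (r in present) {
      rows <- d[grp == r, , drop = FALSE]
      colmin <- apply(rows, 2, min)
      out[r, present] <- tapply(colmin, grp, min)[as.character(present)]
    }
    out[present, present] <- pmin(out[present, present],
                                  t(out[present, present]))
    out[cbind(present, present)] <- 0
  }
  out
}

#' Map alignment positions onto structure residues (Smith-Waterman)
#'
#' Locally aligns the ungapped reference sequence against the chain's
#' one-letter sequence (BLOSUM62, gap open 10, extend 0.5 by default);
#' matched positions define a one-to-one, order-preserving map between kept
#' alignment columns and structure residues, reported with PDB author
#' numbering.
#'
#' @param alignment an [alignment] object
#' @param mask a [mask_columns()] result
#' @param structure a [read_structure()] result
#' @param gap_opening,gap_extension Smith-Waterman gap penalties
#' @return an object of class `seqstruct_map`: `pairs` (data.frame: `column`
#'   alignment column, `ref_pos`, `res_index`, `pdb_number`, `pdb_label`),
#'   `coverage` (fraction of reference residues mapped)
#' @export
map_alignment_to_structure <- function(alignment, mask, structure,
                                       gap_opening = 10,
                                       gap_extension = 0.5) {
  stopifnot(inherits(alignment, "alignment"),
            inherits(structure, "structure_model"))
  ref <- gsub("-", "", alignment$seq[alignment$reference_row], fixed = TRUE)
  chainseq <- paste(structure$residues$aa, collapse = "")
  if (!nzchar(ref) || !nzchar(chainseq)) {
    stop("empty reference or chain sequence", call. = FALSE)
  }
  blosum62 <- get(utils::data("BLOSUM62", package = "Biostrings",
                              envir = environment()))
  pa <- Biostrings::pairwiseAlignment(
    ref, chainseq, type = "local", substitutionMatrix = blosum62,
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ri <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  si <- Biostrings::start(Biostrings::subject(pa)) - 1L
  ref_pos <- integer(0); res_index <- integer(0)
  for (k in seq_along(p)) {
    if (p[k] != "-") ri <- ri + 1L
    if (s[k] != "-") si <- si + 1L
    if (p[k] != "-" && s[k] != "-") {
      ref_pos <- c(ref_pos, ri)
      res_index <- c(res_index, si)
    }
  }
  if (!length(ref_pos)) stop("no aligned residue pairs between reference ",
                             "and structure", call. = FALSE)
  coverage <- length(ref_pos) / nchar(ref)
  if (coverage < 0.3) {
    warning(sprintf("low structure coverage: %.0f%% of reference residues",
                    100 * coverage))
  }
  column <- match(ref_pos, mask$ref_position)
  keep <- !is.na(column)
  pairs <- data.frame(
    column = column[keep],
    ref_pos = ref_pos[keep],
    res_index = res_index[keep],
    pdb_number = structure$residues$number[res_index[keep]],
    pdb_label = structure$residues$label[res_index[keep]],
    stringsAsFactors = FALSE
  )
  structure(list(pairs = pairs, coverage = coverage,
                 chain_id = structure$chain_id),
            class = "seqstruct_map")
}

#' @export
print.seqstruct_map <- function(x, ...) {
  cat("Sequence-structure map: ", nrow(x$pairs), " kept positions on chain ",
      x$chain_id, sprintf(" (coverage %.0f%%)\n", 100 * x$coverage), sep = "")
  invisible(x)
}

#' Residue distance network
#'
#' Edges connect residues whose minimum heavy-atom distance is strictly below
#' `cutoff` (Angstrom).
#'
#' @param dist a [min_distances()] matrix
#' @param cutoff distance threshold in Angstrom (default 5)
#' @return an object of class `distance_network`: `edges` (data.frame: `i`,
#'   `j` residue indices, `label_i`, `label_j`, `distance`), `n_residues`,
#'   `labels`, `cutoff`
#' @export
distance_network <- function(dist, cutoff = 5) {
  stopifnot(is.matrix(dist), nrow(dist) == ncol(dist))
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  ut <- which(upper.tri(dist) & !is.na(dist) & dist < cutoff, arr.ind = TRUE)
  labels <- rownames(dist)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(dist)))
  structure(
    list(edges = data.frame(i = ut[, 1], j = ut[, 2],
                            label_i = labels[ut[, 1]],
                            label_j = labels[ut[, 2]],
                            distance = dist[ut],
                            stringsAsFactors = FALSE),
         n_residues = nrow(dist), labels = labels, cutoff = cutoff),
    class = "distance_network"
  )
}

#' @export
print.distance_network <- function(x, ...) {
  cat("Distance network: ", x$n_residues, " residues, ", nrow(x$edges),
      " contacts < ", x$cutoff, " A\n", sep = "")
  invisible(x)
}
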