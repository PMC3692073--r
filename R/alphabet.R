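# Amino-acid alphabet and encodings shared across modules.

#' The 20 standard amino acids (one-letter, alphabetical)
#' @keywords internal
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# three-letter -> one-letter for PDB residue names; anything else maps to X
.aa3to1 <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
  GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
  MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
  SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y"
)

#' Encode an alignment as an integer matrix
#'
#' Rows are sequences, columns alignment columns; standard amino acids are
#' coded 1..20 in the order of [aa_alphabet()], gaps (`-`) and unknowns (`X`)
#' are coded 0 and are skipped by all frequency computations.
#'
#' @param alignment an [alignment] object
#' @param columns optional integer vector of alignment columns to keep
#' @return integer matrix, n_sequences x length(columns)
#' @keywords internal
encode_alignment <- function(alignment, columns = NULL) {
  chars <- do.call(rbind, strsplit(alignment$seq, "", fixed = TRUE))
  if (!is.null(columns)) chars <- chars[, columns, drop = FALSE]
  code <- match(chars, aa_alphabet())
  code[is.na(code)] <- 0L
  matrix(as.integer(code), nrow = nrow(chars))
}

#' Background amino-acid frequency distributions
#'
#' `"blosum62"` gives the amino-acid frequencies underlying the BLOSUM62
#' substitution matrix (the default background for the Kullback-Leibler
#' conservation score); `"uniform"` gives 1/20 per residue.
#'
#' @param type `"blosum62"` or `"uniform"`
#' @return named numeric vector of length 20 summing to 1
#' @export
background_frequencies <- function(type = c("blosum62", "uniform")) {
  type <- match.arg(type)
  aa <- aa_alphabet()
  if (type == "uniform") {
    return(stats::setNames(rep(1 / 20, 20), aa))
  }
  q <- c(
    A = 0.0742, C = 0.0246, D = 0.0536, E = 0.0543, F = 0.0473,
    G = 0.0741, H = 0.0262, I = 0.0679, K = 0.0582, L = 0.0989,
    M = 0.0249, N = 0.0448, P = 0.0387, Q = 0.0342, R = 0.0517,
    S = 0.0570, T = 0.0508, V = 0.0729, W = 0.0132, Y = 0.0322
  )
  q[aa] / sum(q)
}
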