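# Fixture builders: everything is generated in code at test time.

tiny_alignment <- function() {
  new_alignment(
    id = c("refseq", "homolog1", "homolog2", "homolog3"),
    seq = c("ACDEFGHIKL", "ACDEFGHIKL", "ACDWFGHIKV", "GCDWFGHIKV")
  )
}

random_alignment <- function(n_seq, n_col, seed, gap_rate = 0) {
  set.seed(seed)
  chars <- matrix(sample(ALPHA, n_seq * n_col, replace = TRUE), n_seq, n_col)
  if (gap_rate > 0) {
    gaps <- matrix(runif(n_seq * n_col) < gap_rate, n_seq, n_col)
    gaps[1, ] <- FALSE  # keep the reference gapless
    chars[gaps] <- "-"
  }
  new_alignment(sprintf("s%02d", seq_len(n_seq)),
                apply(chars, 1, paste, collapse = ""))
}

write_fasta_text <- function(ids, seqs, path = tempfile(fileext = ".fa")) {
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

write_clustal_text <- function(ids, seqs,
                               path = tempfile(fileext = ".aln")) {
  writeLines(c(
    "CLUSTAL W (1.82) multiple sequence alignment", "", "",
    sprintf("%-16s%s", ids, seqs),
    sprintf("%-16s%s", "", strrep("*", nchar(seqs[1])))
  ), path)
  path
}

write_phylip_text <- function(ids, seqs,
                              path = tempfile(fileext = ".phy")) {
  writeLines(c(
    sprintf(" %d %d", length(ids), nchar(seqs[1])),
    sprintf("%-10s %s", ids, seqs)
  ), path)
  path
}

write_nexus_text <- function(ids, seqs,
                             path = tempfile(fileext = ".nex")) {
  writeLines(c(
    "#NEXUS", "BEGIN DATA;",
    sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", length(ids), nchar(seqs[1])),
    "FORMAT DATATYPE=PROTEIN GAP=- MISSING=?;", "MATRIX",
    paste(ids, seqs), ";", "END;"
  ), path)
  path
}

write_pir_text <- function(ids, seqs, path = tempfile(fileext = ".pir")) {
  writeLines(unlist(lapply(seq_along(ids), function(k) {
    c(paste0(">P1;", ids[k]), paste0(ids[k], " description"),
      paste0(seqs[k], "*"))
  })), path)
  path
}

# hand-built PDB text: atoms is a data.frame with name, resname, resnum,
# x, y, z, element (and optional chain, occupancy)
write_pdb_text <- function(atoms, path = tempfile(fileext = ".pdb"),
                           header = character(0)) {
  chain <- if (is.null(atoms$chain)) rep("A", nrow(atoms)) else atoms$chain
  occ <- if (is.null(atoms$occ)) rep(1, nrow(atoms)) else atoms$occ
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f  0.00          %2s",
    seq_len(nrow(atoms)),
    ifelse(nchar(atoms$name) < 4, paste0(" ", atoms$name), atoms$name),
    atoms$resname, chain, atoms$resnum, atoms$x, atoms$y, atoms$z, occ,
    atoms$element
  )
  writeLines(c(header, lines, "END"), path)
  path
}

# random small structure: n residues, 1-3 heavy atoms plus an occasional H
random_structure <- function(n_res, seed) {
  set.seed(seed)
  rows <- list()
  for (r in seq_len(n_res)) {
    center <- runif(3, -10, 10)
    n_at <- sample(1:3, 1)
    for (a in seq_len(n_at)) {
      rows[[length(rows) + 1]] <- data.frame(
        name = c("CA", "CB", "CG")[a], resname = "ALA", resnum = r,
        x = center[1] + rnorm(1, 0, 0.8),
        y = center[2] + rnorm(1, 0, 0.8),
        z = center[3] + rnorm(1, 0, 0.8), element = "C"
      )
    }
    if (runif(1) < 0.5) {
      rows[[length(rows) + 1]] <- data.frame(
        name = "HA", resname = "ALA", resnum = r,
        x = center[1], y = center[2], z = center[3], element = "H"
      )
    }
  }
  read_structure(write_pdb_text(do.call(rbind, rows)))
}

# a score_matrices object with prescribed z values (upper-triangle order)
fake_scores <- function(z_values, n_pos = NULL) {
  if (is.null(n_pos)) {
    n_pos <- ceiling((1 + sqrt(1 + 8 * length(z_values))) / 2)
  }
  z <- matrix(NA_real_, n_pos, n_pos)
  ut <- which(upper.tri(z))
  z[ut[seq_along(z_values)]] <- z_values
  z[lower.tri(z)] <- t(z)[lower.tri(z)]
  pos <- seq_len(n_pos)
  dimnames(z) <- list(pos, pos)
  structure(
    list(mi_raw = z, mi_apc = z, z = z,
         degenerate = matrix(FALSE, n_pos, n_pos),
         mean_mi = mean(z, na.rm = TRUE), n_permutations = 2L, seed = 1L,
         null = "per-pair", positions = pos, columns = pos,
         ref_aa = rep("A", n_pos)),
    class = "score_matrices"
  )
}
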