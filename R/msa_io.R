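# Reading, validating and masking multiple sequence alignments.

#' Construct a validated alignment object
#'
#' Residues are uppercased, `.` is normalized to the gap character `-`, and
#' any character that is neither a standard amino acid nor a gap is mapped to
#' the unknown code `X`. Duplicate identifiers are disambiguated by appending
#' an ordinal suffix (with a warning).
#'
#' @param id character vector of sequence identifiers
#' @param seq character vector of aligned residue strings (equal lengths)
#' @param reference_row index of the reference sequence (default 1)
#' @return an object of class `alignment` with fields `id`, `seq`,
#'   `n_columns`, `reference_row`
#' @export
new_alignment <- function(id, seq, reference_row = 1L) {
  if (length(id) != length(seq)) {
    stop("'id' and 'seq' must have the same length", call. = FALSE)
  }
  if (length(seq) < 2L) {
    stop("an alignment needs at least 2 sequences, got ", length(seq),
         call. = FALSE)
  }
  id <- unname(as.character(id))
  seq <- unname(toupper(seq))
  seq <- gsub(".", "-", seq, fixed = TRUE)
  # anything outside the 20 standard codes and '-' becomes 'X'
  seq <- gsub("[^ACDEFGHIKLMNPQRSTVWY-]", "X", seq)
  lens <- nchar(seq)
  if (length(unique(lens)) != 1L) {
    bad <- id[lens != stats::median(lens)]
    stop("sequences have unequal lengths: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (lens[1] < 2L) {
    stop("alignment must have at least 2 columns", call. = FALSE)
  }
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    warning("duplicate identifiers disambiguated with ordinal suffixes: ",
            paste(dup, collapse = ", "), call. = FALSE)
    id <- make.unique(id, sep = "_")
  }
  reference_row <- as.integer(reference_row)
  if (reference_row < 1L || reference_row > length(seq)) {
    stop("reference_row out of range", call. = FALSE)
  }
  structure(
    list(id = id, seq = seq, n_columns = unname(lens[1]),
         reference_row = reference_row),
    class = "alignment"
  )
}

#' @export
print.alignment <- function(x, ...) {
  cat("Protein alignment: ", length(x$seq), " sequences x ", x$n_columns,
      " columns (reference: ", x$id[x$reference_row], ")\n", sep = "")
  invisible(x)
}

.sniff_format <- function(path) {
  head <- readLines(path, n = 5L, warn = FALSE)
  head <- head[nzchar(trimws(head))]
  if (!length(head)) stop("empty file: ", path, call. = FALSE)
  first <- head[1]
  if (grepl("^>P1;", first)) return("pir")
  if (startsWith(first, ">")) return("fasta")
  if (grepl("^CLUSTAL", first, ignore.case = TRUE)) return("clustal")
  if (grepl("^#NEXUS", first, ignore.case = TRUE)) return("nexus")
  if (grepl("^\\s*\\d+\\s+\\d+\\s*$", first)) return("phylip")
  stop("cannot determine alignment format; first line: ", dQuote(first),
       call. = FALSE)
}

.read_fasta_records <- function(path) {
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      first <- readLines(path, n = 1L, warn = FALSE)
      stop("not parseable as FASTA (", conditionMessage(e),
           "); first line: ", dQuote(first), call. = FALSE)
    }
  )
  # keep only the first whitespace-delimited token of the description
  ids <- sub("\\s.*$", "", names(set))
  list(id = ids, seq = as.character(set))
}

.read_pir_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^>..;", lines)
  if (!length(starts)) {
    stop("not parseable as PIR; first line: ",
         dQuote(lines[1]), call. = FALSE)
  }
  ends <- c(starts[-1] - 1L, length(lines))
  id <- character(0); seq <- character(0)
  for (k in seq_along(starts)) {
    id[k] <- sub("^>..;", "", lines[starts[k]])
    # line after the header is the description line; sequence follows,
    # terminated by '*'
    body <- lines[(starts[k] + 2L):ends[k]]
    s <- gsub("\\s", "", paste(body, collapse = ""))
    seq[k] <- sub("\\*.*$", "", s)
  }
  list(id = id, seq = seq)
}

.read_msa_biostrings <- function(path, format) {
  aln <- tryCatch(
    Biostrings::readAAMultipleAlignment(path, format = format),
    error = function(e) {
      first <- readLines(path, n = 1L, warn = FALSE)
      stop("not parseable as ", format, " (", conditionMessage(e),
           "); first line: ", dQuote(first), call. = FALSE)
    }
  )
  set <- as.character(aln)
  list(id = names(set), seq = unname(set))
}

.read_nexus_records <- function(path) {
  recs <- tryCatch(
    ape::read.nexus.data(path),
    error = function(e) {
      first <- readLines(path, n = 1L, warn = FALSE)
      stop("not parseable as NEXUS (", conditionMessage(e),
           "); first line: ", dQuote(first), call. = FALSE)
    }
  )
  list(id = names(recs),
       seq = vapply(recs, paste, "", collapse = ""))
}

#' Read a multiple sequence alignment
#'
#' Supports FASTA, ClustalW, Phylip, Nexus and PIR. With `format = "auto"`
#' the format is sniffed from the leading bytes (`>` FASTA, `>P1;` PIR,
#' `CLUSTAL` header, `#NEXUS` header, numeric header Phylip). The first
#' sequence becomes the reference; see [set_reference()].
#'
#' @param path path to the alignment file
#' @param format one of `"auto"`, `"fasta"`, `"clustal"`, `"phylip"`,
#'   `"nexus"`, `"pir"`
#' @return an [alignment] object
#' @export
read_msa <- function(path,
                     format = c("auto", "fasta", "clustal", "phylip",
                                "nexus", "pir")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- .sniff_format(path)
  recs <- switch(format,
    fasta   = .read_fasta_records(path),
    pir     = .read_pir_records(path),
    clustal = .read_msa_biostrings(path, "clustal"),
    phylip  = .read_msa_biostrings(path, "phylip"),
    nexus   = .read_nexus_records(path)
  )
  new_alignment(recs$id, recs$seq)
}

#' Write an alignment as FASTA
#'
#' @param alignment an [alignment] object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_msa <- function(alignment, path) {
  set <- Biostrings::BStringSet(stats::setNames(alignment$seq, alignment$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Select the reference sequence of an alignment
#'
#' With no identifier the first sequence is used. Otherwise the identifier is
#' matched exactly first, then as a unique prefix.
#'
#' @param alignment an [alignment] object
#' @param identifier sequence identifier (or `NULL` for the first sequence)
#' @return the alignment with `reference_row` set
#' @export
set_reference <- function(alignment, identifier = NULL) {
  stopifnot(inherits(alignment, "alignment"))
  if (is.null(identifier) || !nzchar(identifier)) {
    alignment$reference_row <- 1L
    return(alignment)
  }
  hit <- which(alignment$id == identifier)
  if (length(hit) == 0L) {
    hit <- which(startsWith(alignment$id, identifier))
  }
  if (length(hit) == 0L) {
    stop("no sequence matches identifier ", dQuote(identifier), call. = FALSE)
  }
  if (length(hit) > 1L) {
    stop("identifier ", dQuote(identifier), " is ambiguous; candidates: ",
         paste(alignment$id[hit], collapse = ", "), call. = FALSE)
  }
  alignment$reference_row <- hit
  alignment
}

#' Mask alignment columns by gap content
#'
#' A column is kept iff its gap fraction is at most `max_gap_fraction` AND the
#' reference sequence has a residue (non-gap) there: all reporting is indexed
#' by reference positions, so reference-gap columns cannot be labeled.
#'
#' @param alignment an [alignment] object
#' @param max_gap_fraction maximum tolerated fraction of gaps per column
#' @return an object of class `column_mask` with fields `keep` (logical per
#'   column), `gap_fraction`, and `ref_position` (1-based index into the
#'   ungapped reference sequence, `NA` where not kept)
#' @export
mask_columns <- function(alignment, max_gap_fraction = 0.5) {
  stopifnot(inherits(alignment, "alignment"))
  if (max_gap_fraction < 0 || max_gap_fraction > 1) {
    stop("max_gap_fraction must be in [0, 1]", call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(alignment$seq, "", fixed = TRUE))
  gap_fraction <- colMeans(chars == "-")
  ref <- chars[alignment$reference_row, ]
  ref_nongap <- ref != "-"
  keep <- gap_fraction <= max_gap_fraction & ref_nongap
  ref_position <- rep(NA_integer_, alignment$n_columns)
  ref_position[ref_nongap] <- seq_len(sum(ref_nongap))
  ref_position[!keep] <- NA_integer_
  if (sum(keep) < 2L) {
    stop("fewer than 2 columns survive gap masking (threshold ",
         max_gap_fraction, "): degenerate alignment", call. = FALSE)
  }
  structure(
    list(keep = keep, gap_fraction = gap_fraction,
         ref_position = ref_position,
         max_gap_fraction = max_gap_fraction),
    class = "column_mask"
  )
}

#' @export
print.column_mask <- function(x, ...) {
  cat("Column mask: ", sum(x$keep), "/", length(x$keep),
      " columns kept (gap threshold ", x$max_gap_fraction, ")\n", sep = "")
  invisible(x)
}
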