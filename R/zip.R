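# Minimal store-only ZIP writer. The runtime image ships no `zip` binary and
# no zip-creating R package, so the result bundle is assembled as an
# uncompressed ZIP container (readable by any unzip implementation).

.crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      for (n in 0:255) {
        c <- n
        for (k in 1:8) {
          c <- if (bitwAnd(c, 1L) != 0L) {
            bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1))
          } else {
            bitwShiftR(bitwAnd(c, -2L), 1)
          }
        }
        t[n + 1] <- c
      }
      tab <<- t
    }
    tab
  }
})

.crc32 <- function(bytes) {
  tab <- .crc32_table()
  crc <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(crc, b), 255L)
    crc <- bitwXor(bitwShiftR(bitwAnd(crc, -256L), 8), tab[idx + 1])
  }
  bitwXor(crc, -1L)
}

.le_bytes <- function(x, n) {
  out <- raw(n)
  for (k in seq_len(n)) {
    out[k] <- as.raw(bitwAnd(x, 255L))
    x <- bitwShiftR(bitwAnd(x, -256L), 8)
  }
  out
}

#' Write a store-only ZIP archive
#'
#' @param zipfile output path
#' @param files paths of files to include
#' @param root directory against which archive member names are relativized
#' @return `zipfile`, invisibly
#' @keywords internal
write_zip <- function(zipfile, files, root = dirname(zipfile)) {
  con <- file(zipfile, "wb")
  on.exit(close(con))
  central <- list()
  offset <- 0L
  root <- normalizePath(root)
  for (f in files) {
    name <- sub("^/", "", sub(root, "", normalizePath(f), fixed = TRUE))
    data <- readBin(f, "raw", file.info(f)$size)
    crc <- .crc32(data)
    nm <- charToRaw(name)
    local_hdr <- c(
      .le_bytes(0x04034b50L, 4), .le_bytes(20L, 2), .le_bytes(0L, 2),
      .le_bytes(0L, 2),  # method 0 = store
      .le_bytes(0L, 2), .le_bytes(0L, 2),  # time, date
      .le_bytes(crc, 4),
      .le_bytes(length(data), 4), .le_bytes(length(data), 4),
      .le_bytes(length(nm), 2), .le_bytes(0L, 2)
    )
    writeBin(local_hdr, con)
    writeBin(nm, con)
    if (length(data)) writeBin(data, con)
    central[[length(central) + 1]] <- list(
      name = nm, crc = crc, size = length(data), offset = offset
    )
    offset <- offset + length(local_hdr) + length(nm) + length(data)
  }
  cd_start <- offset
  cd_size <- 0L
  for (e in central) {
    hdr <- c(
      .le_bytes(0x02014b50L, 4), .le_bytes(20L, 2), .le_bytes(20L, 2),
      .le_bytes(0L, 2), .le_bytes(0L, 2),
      .le_bytes(0L, 2), .le_bytes(0L, 2),
      .le_bytes(e$crc, 4),
      .le_bytes(e$size, 4), .le_bytes(e$size, 4),
      .le_bytes(length(e$name), 2), .le_bytes(0L, 2), .le_bytes(0L, 2),
      .le_bytes(0L, 2), .le_bytes(0L, 2), .le_bytes(0L, 4),
      .le_bytes(e$offset, 4)
    )
    writeBin(hdr, con)
    writeBin(e$name, con)
    cd_size <- cd_size + length(hdr) + length(e$name)
  }
  eocd <- c(
    .le_bytes(0x06054b50L, 4), .le_bytes(0L, 2), .le_bytes(0L, 2),
    .le_bytes(length(central), 2), .le_bytes(length(central), 2),
    .le_bytes(cd_size, 4), .le_bytes(cd_start, 4), .le_bytes(0L, 2)
  )
  writeBin(eocd, con)
  invisible(zipfile)
}
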