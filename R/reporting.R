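# Circos-style circular summary, static network figures, Cytoscape exports
# and the downloadable result bundle.

# conservation color scale: red (highest) -> cyan (lowest), linear over the
# observed range; NA -> grey
.conservation_colors <- function(kl) {
  out <- rep("#bbbbbb", length(kl))
  ok <- !is.na(kl)
  if (!any(ok)) return(out)
  rng <- range(kl[ok])
  t <- if (diff(rng) > 0) (kl[ok] - rng[1]) / diff(rng) else rep(1, sum(ok))
  out[ok] <- grDevices::rgb(t, 1 - t, 1 - t)
  out
}

.band_colors <- c(top5 = "#cc0000", mid70_95 = "#000000", low = "#999999")

# all geometry for the circular summary; both renderers consume this, so the
# figure is a pure function of the network object
circos_layout <- function(network) {
  stopifnot(inherits(network, "coevo_network"))
  nodes <- network$nodes[order(network$nodes$position), , drop = FALSE]
  n <- nrow(nodes)
  if (n == 0) stop("network has no positions to draw", call. = FALSE)
  theta <- pi / 2 - 2 * pi * (seq_len(n) - 0.5) / n  # clockwise from top
  half <- pi / n * 0.8                               # half-wedge width

  cmi_max <- max(nodes$cmi, 0)
  pmi <- ifelse(is.na(nodes$pmi), 0, nodes$pmi)
  pmi_max <- max(pmi, 0)
  e <- network$edges
  ei <- match(e$position_i, nodes$position)
  ej <- match(e$position_j, nodes$position)
  list(
    n = n,
    positions = nodes$position,
    labels = paste0(nodes$aa, nodes$label),
    theta = theta,
    half = half,
    r_label = 1.02,
    r_cons = c(0.86, 0.93),
    r_cmi = 0.70,                       # base; bars face outward to 0.84
    cmi_frac = if (cmi_max > 0) nodes$cmi / cmi_max else rep(0, n),
    r_pmi = 0.68,                       # base; bars face inward to 0.54
    pmi_frac = if (pmi_max > 0) pmi / pmi_max else rep(0, n),
    r_chord = 0.52,
    cons_col = .conservation_colors(nodes$kl),
    chords = data.frame(
      i = ei, j = ej, band = e$band,
      col = unname(.band_colors[e$band]),
      stringsAsFactors = FALSE
    )
  )
}

.pol <- function(r, th) c(r * cos(th), r * sin(th))

.svg_num <- function(x) formatC(100 * x, format = "f", digits = 2)

# hand-emitted SVG: structured elements (pos-label groups, cons-box rects,
# cmi/pmi bars, chord paths with band classes) that downstream checks can
# count
.circos_svg <- function(geom) {
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<svg xmlns="http://www.w3.org/2000/svg" width="640" ',
           'height="640" viewBox="-115 -115 230 230">'),
    '<rect x="-115" y="-115" width="230" height="230" fill="white"/>'
  )
  for (k in seq_len(geom$n)) {
    th <- geom$theta[k]
    deg <- -th * 180 / pi
    rot <- if (cos(th) < 0) deg + 180 else deg
    anchor <- if (cos(th) < 0) "end" else "start"
    p <- .pol(geom$r_label, th)
    out <- c(out, paste0(
      '<g class="pos-label"><text x="', .svg_num(p[1]), '" y="',
      .svg_num(p[2]), '" font-size="3" text-anchor="', anchor,
      '" transform="rotate(', formatC(rot, format = "f", digits = 2), " ",
      .svg_num(p[1]), " ", .svg_num(p[2]), ')">', geom$labels[k],
      "</text></g>"
    ))
  }
  wedge <- function(r0, r1, th, half, col, class) {
    a <- .pol(r0, th - half); b <- .pol(r1, th - half)
    c2 <- .pol(r1, th + half); d <- .pol(r0, th + half)
    paste0('<path class="', class, '" d="M', .svg_num(a[1]), ",",
           .svg_num(a[2]), " L", .svg_num(b[1]), ",", .svg_num(b[2]),
           " L", .svg_num(c2[1]), ",", .svg_num(c2[2]), " L",
           .svg_num(d[1]), ",", .svg_num(d[2]), ' Z" fill="', col,
           '" stroke="none"/>')
  }
  for (k in seq_len(geom$n)) {
    out <- c(out, wedge(geom$r_cons[1], geom$r_cons[2], geom$theta[k],
                        geom$half, geom$cons_col[k], "cons-box"))
  }
  for (k in seq_len(geom$n)) {   # cMI histogram, facing outward
    h <- geom$cmi_frac[k] * 0.14
    out <- c(out, wedge(geom$r_cmi, geom$r_cmi + h, geom$theta[k],
                        geom$half * 0.9, "#1f77b4", "cmi-bar"))
  }
  for (k in seq_len(geom$n)) {   # pMI histogram, facing inward
    h <- geom$pmi_frac[k] * 0.14
    out <- c(out, wedge(geom$r_pmi - h, geom$r_pmi, geom$theta[k],
                        geom$half * 0.9, "#ff7f0e", "pmi-bar"))
  }
  ch <- geom$chords
  for (k in seq_len(nrow(ch))) {
    a <- .pol(geom$r_chord, geom$theta[ch$i[k]])
    b <- .pol(geom$r_chord, geom$theta[ch$j[k]])
    out <- c(out, paste0(
      '<path class="chord chord-', ch$band[k], '" d="M', .svg_num(a[1]),
      ",", .svg_num(a[2]), " Q0,0 ", .svg_num(b[1]), ",", .svg_num(b[2]),
      '" fill="none" stroke="', ch$col[k], '" stroke-width="0.4" ',
      'opacity="0.7"/>'
    ))
  }
  c(out, "</svg>")
}

# same geometry drawn with base graphics (for PNG and plot())
.draw_circos_base <- function(geom) {
  op <- graphics::par(mar = c(0.5, 0.5, 0.5, 0.5))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(c(-1.18, 1.18), c(-1.18, 1.18), asp = 1)
  wedge <- function(r0, r1, th, half, col) {
    a <- seq(th - half, th + half, length.out = 8)
    graphics::polygon(c(r0 * cos(a), r1 * cos(rev(a))),
                      c(r0 * sin(a), r1 * sin(rev(a))),
                      col = col, border = NA)
  }
  for (k in seq_len(geom$n)) {
    th <- geom$theta[k]
    deg <- th * 180 / pi
    flip <- cos(th) < 0
    p <- .pol(geom$r_label, th)
    cex <- max(0.25, min(0.7, 28 / geom$n))
    graphics::text(p[1], p[2], geom$labels[k],
                   srt = if (flip) deg + 180 else deg,
                   adj = if (flip) 1 else 0, cex = cex)
    wedge(geom$r_cons[1], geom$r_cons[2], th, geom$half, geom$cons_col[k])
    wedge(geom$r_cmi, geom$r_cmi + geom$cmi_frac[k] * 0.14, th,
          geom$half * 0.9, "#1f77b4")
    wedge(geom$r_pmi - geom$pmi_frac[k] * 0.14, geom$r_pmi, th,
          geom$half * 0.9, "#ff7f0e")
  }
  ch <- geom$chords
  for (k in seq_len(nrow(ch))) {
    a <- .pol(geom$r_chord, geom$theta[ch$i[k]])
    b <- .pol(geom$r_chord, geom$theta[ch$j[k]])
    graphics::xspline(c(a[1], 0, b[1]), c(a[2], 0, b[2]), shape = 1,
                      open = TRUE, border = ch$col[k], lwd = 1)
  }
  invisible(NULL)
}

#' Render the circular (circos-style) summary
#'
#' Tracks, outer to inner: position labels (reference amino acid + number, or
#' PDB numbering when a structure is mapped), conservation boxes colored red
#' (highest KL) to cyan (lowest), the cMI histogram facing outward, the pMI
#' histogram facing inward, and central chords connecting retained edges
#' colored by percentile band (red top 5%, black 70-95%, gray rest).
#'
#' @param network a [build_network()] result with at least one position
#' @param out output path prefix; `<out>.svg` and `<out>.png` are written
#' @param formats subset of `c("svg", "png")`
#' @param png_size PNG width/height in pixels
#' @return named character vector of written paths, invisibly
#' @export
render_circos <- function(network, out, formats = c("svg", "png"),
                          png_size = 1200) {
  geom <- circos_layout(network)
  paths <- character(0)
  if ("svg" %in% formats) {
    svg_path <- paste0(out, ".svg")
    writeLines(.circos_svg(geom), svg_path)
    paths["svg"] <- svg_path
  }
  if ("png" %in% formats) {
    png_path <- paste0(out, ".png")
    grDevices::png(png_path, width = png_size, height = png_size, res = 150)
    .draw_circos_base(geom)
    grDevices::dev.off()
    paths["png"] <- png_path
  }
  invisible(paths)
}

.attribute_colors <- function(nodes, color_by) {
  if (color_by == "secondary") {
    pal <- c(helix = "#d62728", sheet = "#ffbf00", coil = "#aaaaaa")
    col <- pal[nodes$secondary]
    col[is.na(col)] <- "#aaaaaa"
    return(unname(col))
  }
  v <- switch(color_by, conservation = nodes$kl, cmi = nodes$cmi,
              pmi = nodes$pmi,
              stop("unknown node color attribute: ", dQuote(color_by),
                   "; use conservation, cmi, pmi or secondary",
                   call. = FALSE))
  .conservation_colors(v)
}

#' Render static network figures
#'
#' Draws the MI network (and the distance network, when given) with a
#' deterministic force-directed layout; node colors follow the selected
#' attribute on the red (high) to cyan (low) scale.
#'
#' @param network a [build_network()] result
#' @param dist_net optional [distance_network()] result
#' @param out_dir output directory
#' @param color_by node color attribute: `"conservation"`, `"cmi"`, `"pmi"`
#'   or `"secondary"`
#' @param seed layout seed
#' @return character vector of written paths, invisibly
#' @export
render_networks <- function(network, dist_net = NULL, out_dir,
                            color_by = "conservation", seed = 1L) {
  stopifnot(inherits(network, "coevo_network"))
  cols <- .attribute_colors(network$nodes, color_by)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  g <- .network_igraph(network)
  set.seed(seed)
  lay <- igraph::layout_with_fr(g)
  p <- file.path(out_dir, "mi_network.png")
  grDevices::png(p, width = 1000, height = 1000, res = 130)
  op <- graphics::par(mar = c(0.5, 0.5, 2, 0.5))
  plot(g, layout = lay, vertex.color = cols, vertex.size = 6,
       vertex.label.cex = 0.5, vertex.label.color = "black",
       main = paste("MI network (node color:", color_by, ")"))
  graphics::par(op)
  grDevices::dev.off()
  paths <- c(paths, p)

  if (!is.null(dist_net)) {
    gd <- igraph::graph_from_data_frame(
      data.frame(from = dist_net$edges$label_i,
                 to = dist_net$edges$label_j),
      directed = FALSE,
      vertices = data.frame(name = dist_net$labels)
    )
    set.seed(seed)
    layd <- igraph::layout_with_fr(gd)
    p <- file.path(out_dir, "distance_network.png")
    grDevices::png(p, width = 1000, height = 1000, res = 130)
    op <- graphics::par(mar = c(0.5, 0.5, 2, 0.5))
    plot(gd, layout = layd, vertex.color = "#88ccee", vertex.size = 6,
         vertex.label.cex = 0.5, vertex.label.color = "black",
         main = paste0("Distance network (< ", dist_net$cutoff, " A)"))
    graphics::par(op)
    grDevices::dev.off()
    paths <- c(paths, p)
  }
  invisible(paths)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write SIF and attribute files for desktop Cytoscape
#'
#' @param network a [build_network()] result
#' @param dir output directory
#' @param prefix file-name prefix
#' @return character vector of written paths, invisibly
#' @export
write_network_files <- function(network, dir, prefix = "mi_network") {
  stopifnot(inherits(network, "coevo_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  e <- network$edges
  sif <- if (nrow(e)) paste(e$position_i, "mi", e$position_j) else character(0)
  isolated <- setdiff(network$nodes$position,
                      c(e$position_i, e$position_j))
  sif <- c(sif, as.character(isolated))
  sif_path <- file.path(dir, paste0(prefix, ".sif"))
  writeLines(sif, sif_path)
  nodes_path <- .write_tsv(network$nodes,
                           file.path(dir, paste0(prefix, "_nodes.tsv")))
  edges_path <- .write_tsv(e, file.path(dir, paste0(prefix, "_edges.tsv")))
  invisible(c(sif_path, nodes_path, edges_path))
}

#' Rebuild a coevolution network from bundled tables
#'
#' Inverse of the bundle's node/edge tables, used by the `filter` and `plot`
#' CLI subcommands to operate on saved results.
#'
#' @param nodes,edges data.frames in the bundle's `nodes.tsv` / `edges.tsv`
#'   layout
#' @param threshold the retention threshold the tables were built with
#' @return a `coevo_network`
#' @export
network_from_tables <- function(nodes, edges, threshold = 6.5) {
  structure(
    list(nodes = nodes, edges = edges, threshold = threshold,
         radius = NA_real_, has_structure = any(!is.na(nodes$pmi))),
    class = "coevo_network"
  )
}

#' Assemble the downloadable result bundle
#'
#' Writes every artifact of a pipeline run into `out_dir` — processed MSA
#' (FASTA), sequence weights, retained z-score table, node/edge tables,
#' conservation and logo matrices, circos SVG+PNG, static network images,
#' SIF + attribute files — plus a JSON run manifest (parameters, seed,
#' versions, present and missing items), and packs everything into
#' `bundle.zip`. Partial results bundle what exists; the manifest records
#' what is absent.
#'
#' @param result a [run_pipeline()] result (class `coevomap`)
#' @param out_dir output directory (created if needed)
#' @return path of the written zip file, invisibly
#' @export
bundle_results <- function(result, out_dir) {
  stopifnot(inherits(result, "coevomap"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  missing <- character(0)
  add <- function(name, path) {
    files[[name]] <<- path
  }

  add("msa", write_msa(result$alignment, file.path(out_dir, "msa.fasta")))
  add("weights", .write_tsv(
    data.frame(identifier = names(result$weights$weight),
               weight = unname(result$weights$weight)),
    file.path(out_dir, "weights.tsv")
  ))
  add("zscores", .write_tsv(zscore_table(result$scores, result$params$z_threshold),
                            file.path(out_dir, "zscores.tsv")))
  add("conservation", .write_tsv(
    data.frame(position = result$conservation$positions,
               kl = unname(result$conservation$kl)),
    file.path(out_dir, "conservation.tsv")
  ))
  logo <- logo_data(result$alignment, result$mask, result$weights,
                    columns = result$conservation$columns,
                    background = result$conservation$background,
                    pseudocount = result$params$pseudocount)
  add("logo", .write_tsv(
    cbind(position = logo$positions, as.data.frame(logo$terms)),
    file.path(out_dir, "logo_matrix.tsv")
  ))

  net_files <- write_network_files(result$network, out_dir, "mi_network")
  add("sif", net_files[1]); add("nodes", net_files[2])
  add("edges", net_files[3])

  circos <- render_circos(result$network, file.path(out_dir, "circos"))
  add("circos_svg", circos[["svg"]]); add("circos_png", circos[["png"]])

  imgs <- render_networks(result$network, result$dist_net, out_dir)
  add("mi_network_png", imgs[1])
  if (!is.null(result$dist_net)) {
    add("distance_network_png", imgs[2])
    dn <- result$dist_net
    sifd <- file.path(out_dir, "distance_network.sif")
    writeLines(if (nrow(dn$edges))
      paste(dn$edges$label_i, "dist", dn$edges$label_j) else character(0),
      sifd)
    add("distance_sif", sifd)
  } else {
    missing <- c(missing, "pmi", "distance_network")
  }

  manifest <- list(
    package = "coevomap",
    version = as.character(utils::packageVersion("coevomap")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    parameters = result$params,
    n_sequences = length(result$alignment$seq),
    n_positions = nrow(result$network$nodes),
    n_edges = nrow(result$network$edges),
    files = lapply(files, basename),
    missing = as.list(missing)
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  zip_path <- file.path(out_dir, "bundle.zip")
  write_zip(zip_path, c(unlist(files), manifest_path), root = out_dir)
  invisible(zip_path)
}
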