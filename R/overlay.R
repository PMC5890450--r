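#' @title Omics data overlay
#' @description
#' Tools to import omics tables keyed by HUGO gene symbol, aggregate them
#' over sample groups and protein families, and visualise them on a laid-
#' out map view: map staining (a smooth background colour field showing
#' large-scale trends), glyphs (small shapes flagging discrete events such
#' as mutations), and per-entity barplots/heatmaps sharing one colour
#' scale across the map. Matching between data and map is by HUGO symbol
#' only; probe or transcript mapping is upstream of this tool.
#' @name omics-overlay
NULL

#' Create an overlay dataset
#'
#' @param values numeric matrix, rows = HUGO gene symbols (rownames,
#'   upper-cased, unique), columns = samples (colnames). Discrete data
#'   (e.g. mutation flags) use 0/1 values.
#' @param groups optional named character vector, sample -> group label,
#'   covering a subset of the samples.
#' @param families optional named list, family name -> character vector of
#'   HUGO symbols.
#' @return An object of class `overlay_dataset`.
#' @export
overlay_dataset <- function(values, groups = NULL, families = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have gene-symbol rownames")
  rownames(values) <- toupper(trimws(rownames(values)))
  if (anyDuplicated(rownames(values))) stop("duplicate gene rows")
  if (!is.null(groups)) {
    groups <- stats::setNames(as.character(groups), names(groups))
    extra <- setdiff(names(groups), colnames(values))
    if (length(extra)) stop("group labels for unknown sample(s): ",
                            paste(extra, collapse = ", "))
  }
  if (!is.null(families))
    families <- lapply(families, function(f) unique(toupper(trimws(f))))
  structure(list(values = values, groups = groups, families = families),
            class = "overlay_dataset")
}

#' @export
print.overlay_dataset <- function(x, ...) {
  cat(sprintf("<overlay_dataset> %d genes x %d samples; %d group(s), %d family(ies)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$groups)), length(x$families)))
  invisible(x)
}

#' Read an omics matrix from TSV
#'
#' First column = HUGO symbols, header row = sample ids.
#' @param path TSV file path.
#' @return An [overlay_dataset()] without groups/families.
#' @export
read_omics <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  overlay_dataset(m)
}

#' Read a sample-group definition TSV (columns: sample, group)
#' @param path TSV file path.
#' @return named character vector sample -> group.
#' @export
read_groups <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Read protein families from a GMT file
#' @param path GMT file path.
#' @return named list family -> HUGO symbols.
#' @export
read_families <- function(path) {
  rows <- strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE)
  rows <- rows[lengths(rows) >= 3]
  stats::setNames(lapply(rows, function(r) unlist(r[-(1:2)])),
                  vapply(rows, `[[`, character(1), 1))
}

stat_fun <- function(stat) {
  switch(stat, MEAN = function(x) mean(x, na.rm = TRUE),
         MEDIAN = function(x) stats::median(x, na.rm = TRUE),
         stop("unknown stat: ", stat))
}

#' Aggregate over sample groups and/or protein families
#'
#' `GROUP`: one column per group, the NA-skipping mean/median over member
#' samples. `FAMILY`: one row per family, aggregated over the family's
#' genes present in the matrix. `GROUP_AND_FAMILY` applies both. A group
#' or family left empty after NA removal yields an NA cell with a warning.
#' Row and column order is deterministic (sorted).
#'
#' @param data an [overlay_dataset()].
#' @param by `"GROUP"`, `"FAMILY"` or `"GROUP_AND_FAMILY"`.
#' @param stat `"MEAN"` or `"MEDIAN"`.
#' @return A new [overlay_dataset()] with aggregated values.
#' @export
aggregate_overlay <- function(data, by = c("GROUP", "FAMILY", "GROUP_AND_FAMILY"),
                              stat = c("MEAN", "MEDIAN")) {
  by <- match.arg(by); stat <- match.arg(stat)
  f <- stat_fun(stat)
  m <- data$values
  if (by %in% c("GROUP", "GROUP_AND_FAMILY")) {
    if (is.null(data$groups)) stop("no sample groups defined")
    gl <- sort(unique(data$groups))
    m2 <- matrix(NA_real_, nrow(m), length(gl),
                 dimnames = list(rownames(m), gl))
    for (g in gl) {
      cols <- names(data$groups)[data$groups == g]
      for (i in seq_len(nrow(m))) {
        v <- m[i, cols]
        if (all(is.na(v))) {
          warning("group ", g, " has no non-NA value for gene ", rownames(m)[i])
        } else m2[i, g] <- f(v)
      }
    }
    m <- m2
  }
  if (by %in% c("FAMILY", "GROUP_AND_FAMILY")) {
    if (is.null(data$families)) stop("no protein families defined")
    fam <- data$families[sort(names(data$families))]
    m3 <- matrix(NA_real_, length(fam), ncol(m),
                 dimnames = list(names(fam), colnames(m)))
    for (fn in names(fam)) {
      genes <- intersect(fam[[fn]], rownames(m))
      for (j in seq_len(ncol(m))) {
        v <- m[genes, j]
        if (length(genes) == 0L || all(is.na(v))) {
          warning("family ", fn, " is empty after NA removal (column ",
                  colnames(m)[j], ")")
        } else m3[fn, j] <- f(v)
      }
    }
    m <- m3
  }
  overlay_dataset(m[sort(rownames(m)), , drop = FALSE],
                  groups = NULL, families = data$families)
}

#' Define a diverging colour scale
#'
#' @param vmin,vmid,vmax domain of the scale (`vmin < vmax`); values are
#'   clamped to the domain.
#' @param low,mid,high colours interpolated across the domain.
#' @param na_col colour for missing values.
#' @return An object of class `color_scale`; callable via [scale_colors()].
#' @export
color_scale <- function(vmin = -1, vmid = 0, vmax = 1,
                        low = "#2166AC", mid = "#F7F7F7", high = "#B2182B",
                        na_col = "#BBBBBB") {
  stopifnot(vmin < vmax)
  structure(list(vmin = vmin, vmid = vmid, vmax = vmax,
                 low = low, mid = mid, high = high, na_col = na_col),
            class = "color_scale")
}

#' Map values to colours through a [color_scale()]
#' @param scale a [color_scale()].
#' @param x numeric vector.
#' @return character vector of hex colours.
#' @export
scale_colors <- function(scale, x) {
  ramp_lo <- grDevices::colorRamp(c(scale$low, scale$mid))
  ramp_hi <- grDevices::colorRamp(c(scale$mid, scale$high))
  out <- rep(scale$na_col, length(x))
  ok <- !is.na(x)
  xv <- pmin(pmax(x[ok], scale$vmin), scale$vmax)
  cols <- vapply(xv, function(v) {
    rgbv <- if (v <= scale$vmid)
      ramp_lo((v - scale$vmin) / max(scale$vmid - scale$vmin, .Machine$double.eps))
    else
      ramp_hi((v - scale$vmid) / max(scale$vmax - scale$vmid, .Machine$double.eps))
    grDevices::rgb(rgbv[1], rgbv[2], rgbv[3], maxColorValue = 255)
  }, character(1))
  out[ok] <- cols
  out
}

# positions (entity centres) on the view carrying each gene symbol;
# complexes count through their flattened members
symbol_anchors <- function(view) {
  out <- list()
  for (e in view$entities) {
    syms <- flatten_symbols(e$id, view)
    for (s in syms)
      out[[length(out) + 1L]] <- data.frame(
        gene = s, entity_id = e$id, x = e$x + e$w / 2, y = e$y + e$h / 2,
        bx = e$x, by = e$y, bw = e$w, bh = e$h, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(gene = character(), entity_id = character(),
                                      x = numeric(), y = numeric(),
                                      bx = numeric(), by = numeric(),
                                      bw = numeric(), bh = numeric()))
  do.call(rbind, out)
}

overlay_report <- function(data_genes, matched_genes) {
  matched <- intersect(data_genes, matched_genes)
  list(n_genes = length(data_genes), n_matched = length(matched),
       n_ignored = length(data_genes) - length(matched),
       ignored = sort(setdiff(data_genes, matched_genes)))
}

#' Map staining: smooth background colour field
#'
#' Attaches each gene's value to every entity position carrying that HUGO
#' symbol (complexes included) and computes a background field over the
#' canvas by Gaussian-kernel-weighted (Nadaraya-Watson) averaging of the
#' attached values, to be rendered under the map at reduced opacity.
#' Genes absent from the map are ignored and counted in the report. The
#' field is invariant under permutation of entity enumeration order.
#'
#' @param view a laid-out [signalling_map()] view.
#' @param data an [overlay_dataset()] with exactly one value column.
#' @param scale a [color_scale()].
#' @param bandwidth kernel bandwidth in pixels; default 5% of the canvas
#'   diagonal.
#' @param resolution number of grid cells along the larger canvas side.
#' @return An object of class `staining_layer`: `field` (numeric matrix,
#'   rows = y cells), `weight` (total kernel mass per cell, used as
#'   rendering opacity so the stain fades away from any data anchor),
#'   `colors` (hex matrix), grid axes, and `report`
#'   (`n_genes`, `n_matched`, `n_ignored`; matched + ignored = total).
#' @export
map_staining <- function(view, data, scale = NULL, bandwidth = NULL,
                         resolution = 64L) {
  stopifnot(inherits(data, "overlay_dataset"))
  if (ncol(data$values) != 1L) stop("map staining needs exactly one value column")
  vals <- stats::setNames(data$values[, 1], rownames(data$values))
  anchors <- symbol_anchors(view)
  anchors <- anchors[anchors$gene %in% rownames(data$values), , drop = FALSE]
  anchors$value <- vals[anchors$gene]
  anchors <- anchors[!is.na(anchors$value), , drop = FALSE]
  report <- overlay_report(rownames(data$values), unique(symbol_anchors(view)$gene))
  if (is.null(bandwidth))
    bandwidth <- 0.05 * sqrt(view$width^2 + view$height^2)
  if (is.null(scale)) {
    rng <- suppressWarnings(range(vals, na.rm = TRUE, finite = TRUE))
    if (!all(is.finite(rng))) rng <- c(-1, 1)
    half <- max(abs(rng), .Machine$double.eps)
    scale <- color_scale(vmin = -half, vmid = 0, vmax = half)
  }
  nx <- max(2L, round(resolution * view$width /
                        max(view$width, view$height)))
  ny <- max(2L, round(resolution * view$height /
                        max(view$width, view$height)))
  gx <- seq(0, view$width, length.out = nx)
  gy <- seq(0, view$height, length.out = ny)
  field <- matrix(NA_real_, nrow = ny, ncol = nx)
  weight <- matrix(0, nrow = ny, ncol = nx)  # total kernel mass: fades the
  if (nrow(anchors)) {                       # stain away from any data anchor
    for (iy in seq_len(ny)) {
      dx2 <- outer(anchors$x, gx, function(ax, g) (ax - g)^2)
      d2 <- dx2 + (anchors$y - gy[iy])^2
      w <- exp(-d2 / (2 * bandwidth^2))
      sw <- colSums(w)
      weight[iy, ] <- sw
      field[iy, ] <- ifelse(sw > 0, colSums(w * anchors$value) / sw, NA_real_)
    }
  } else {
    warning("no data values could be attached to the map; NA-colour layer")
  }
  structure(list(field = field, weight = weight,
                 colors = matrix(scale_colors(scale, field),
                                 nrow = ny, ncol = nx),
                 x = gx, y = gy, scale = scale, bandwidth = bandwidth,
                 anchors = anchors, report = report),
            class = "staining_layer")
}

#' @export
print.staining_layer <- function(x, ...) {
  cat(sprintf("<staining_layer> %dx%d field, bandwidth %.1f px; %d/%d genes matched\n",
              ncol(x$field), nrow(x$field), x$bandwidth,
              x$report$n_matched, x$report$n_genes))
  invisible(x)
}

#' Place glyphs for discrete data
#'
#' One glyph (default a triangle) is anchored at the bounding-box corner
#' of each entity carrying a gene flagged in the dataset; several glyphs
#' at one entity (one per flagged data column) are stacked horizontally.
#' Placement is deterministic. Unknown gene symbols are skipped and
#' reported.
#'
#' @param view a laid-out [signalling_map()] view.
#' @param data an [overlay_dataset()] of 0/1 flags (e.g. gene x
#'   sample-group mutation indicators).
#' @param glyph_spec list binding channels: `shape` (R plotting symbol,
#'   default 25 = down triangle), `size` (cex), `colors` (named by data
#'   column, recycled).
#' @return An object of class `glyph_layer`: data frame `glyphs` (one row
#'   per placed glyph: entity_id, gene, column, x, y, shape, size, color)
#'   and `report`.
#' @export
place_glyphs <- function(view, data,
                         glyph_spec = list(shape = 25, size = 1,
                                           colors = "#D95F02")) {
  stopifnot(inherits(data, "overlay_dataset"))
  anchors <- symbol_anchors(view)
  report <- overlay_report(rownames(data$values), unique(anchors$gene))
  cols <- rep(glyph_spec$colors %||% "#D95F02", length.out = ncol(data$values))
  names(cols) <- colnames(data$values)
  rows <- list()
  anchors <- anchors[order(anchors$gene, anchors$entity_id), , drop = FALSE]
  for (i in seq_len(nrow(anchors))) {
    g <- anchors$gene[i]
    if (!g %in% rownames(data$values)) next
    flagged <- colnames(data$values)[!is.na(data$values[g, ]) &
                                       data$values[g, ] > 0]
    for (k in seq_along(flagged)) {
      rows[[length(rows) + 1L]] <- data.frame(
        entity_id = anchors$entity_id[i], gene = g, column = flagged[k],
        x = anchors$bx[i] + (k - 1) * 10, y = anchors$by[i],
        shape = glyph_spec$shape %||% 25, size = glyph_spec$size %||% 1,
        color = unname(cols[flagged[k]]), stringsAsFactors = FALSE)
    }
  }
  glyphs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(entity_id = character(), gene = character(), column = character(),
               x = numeric(), y = numeric(), shape = numeric(), size = numeric(),
               color = character())
  # one stack per entity: glyphs of the same entity keep distinct x slots
  structure(list(glyphs = glyphs, report = report), class = "glyph_layer")
}

#' Miniature per-entity charts
#'
#' Builds one miniature barplot or heatmap strip per matching entity, one
#' bar/cell per data column, with a single shared axis/colour scale across
#' the whole map so charts are comparable.
#'
#' @param view a laid-out [signalling_map()] view.
#' @param data an [overlay_dataset()] with at least one column.
#' @param kind `"BARPLOT"` or `"HEATMAP"`.
#' @param scale optional [color_scale()]; derived from the data range by
#'   default.
#' @return An object of class `chart_layer`: list `charts` (per entity:
#'   entity_id, gene, values, colors, ylim) with identical `ylim` across
#'   charts, the `scale`, and `report`.
#' @export
entity_charts <- function(view, data, kind = c("BARPLOT", "HEATMAP"),
                          scale = NULL) {
  kind <- match.arg(kind)
  stopifnot(ncol(data$values) >= 1L)
  anchors <- symbol_anchors(view)
  report <- overlay_report(rownames(data$values), unique(anchors$gene))
  rng <- range(data$values, na.rm = TRUE, finite = TRUE)
  if (!all(is.finite(rng))) rng <- c(0, 1)
  if (is.null(scale)) {
    half <- max(abs(rng), .Machine$double.eps)
    scale <- color_scale(vmin = -half, vmid = 0, vmax = half)
  }
  ylim <- c(min(0, rng[1]), max(0, rng[2]))
  anchors <- anchors[anchors$gene %in% rownames(data$values), , drop = FALSE]
  anchors <- anchors[order(anchors$entity_id, anchors$gene), , drop = FALSE]
  charts <- lapply(seq_len(nrow(anchors)), function(i) {
    v <- data$values[anchors$gene[i], ]
    list(entity_id = anchors$entity_id[i], gene = anchors$gene[i],
         kind = kind, values = v, colors = scale_colors(scale, v),
         x = anchors$bx[i], y = anchors$by[i], ylim = ylim)
  })
  structure(list(charts = charts, kind = kind, scale = scale, ylim = ylim,
                 report = report), class = "chart_layer")
}

#' Render a view with overlay layers to a PNG
#'
#' Draws the staining field (at reduced opacity) under the map, then the
#' map itself, then glyphs and miniature charts.
#'
#' @param view a laid-out [signalling_map()] view.
#' @param path output PNG path.
#' @param staining optional [map_staining()] result.
#' @param glyphs optional [place_glyphs()] result.
#' @param charts optional [entity_charts()] result.
#' @param modules optional [module_set()] for background shapes.
#' @return `path`, invisibly.
#' @export
render_overlay_png <- function(view, path, staining = NULL, glyphs = NULL,
                               charts = NULL, modules = NULL) {
  grDevices::png(path, width = max(256, ceiling(view$width)),
                 height = max(256, ceiling(view$height)), type = "cairo")
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot(NA, xlim = c(0, view$width), ylim = c(view$height, 0),
                 xlab = "", ylab = "", axes = FALSE, asp = NA)
  if (!is.null(staining)) {
    nx <- length(staining$x); ny <- length(staining$y)
    wmax <- max(staining$weight, 1e-12)
    dx <- view$width / nx; dy <- view$height / ny
    for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
      alpha <- 0.45 * staining$weight[iy, ix] / wmax
      graphics::rect((ix - 1) * dx, iy * dy, ix * dx, (iy - 1) * dy,
                     col = grDevices::adjustcolor(staining$colors[iy, ix],
                                                  alpha.f = alpha),
                     border = NA)
    }
  }
  draw_view(view, modules)
  if (!is.null(glyphs) && nrow(glyphs$glyphs)) {
    g <- glyphs$glyphs
    graphics::points(g$x, g$y, pch = g$shape, bg = g$color, col = "#333333",
                     cex = g$size)
  }
  if (!is.null(charts)) {
    for (ch in charts$charts) {
      wbar <- 8; hmax <- 24
      for (j in seq_along(ch$values)) {
        v <- ch$values[j]
        if (is.na(v)) next
        x0 <- ch$x + (j - 1) * wbar
        if (ch$kind == "BARPLOT") {
          hh <- hmax * (v - ch$ylim[1]) / max(diff(ch$ylim), .Machine$double.eps)
          graphics::rect(x0, ch$y, x0 + wbar, ch$y - hh,
                         col = ch$colors[j], border = "#333333")
        } else {
          graphics::rect(x0, ch$y, x0 + wbar, ch$y - 8,
                         col = ch$colors[j], border = NA)
        }
      }
    }
  }
  invisible(path)
}
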