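#' @title Semantic zooming and tile pyramid rendering
#' @description
#' Instead of pure geometric scaling, a map is explored through a small
#' number of progressively pruned views: a top level showing module
#' background shapes and the backbone structure, an intermediate level
#' showing canonical pathways, and a detailed level showing everything.
#' Each view is rasterised into a Google-Maps-style pyramid of 256-pixel
#' PNG tiles: level 0 renders the native canvas, each deeper level doubles
#' the resolution (documented in the index file to avoid dialect
#' confusion).
#' @name semantic-zoom
NULL

TILE_SIZE <- 256L

#' Define a zoom policy
#'
#' @param levels list of level specs, each a list with `name` and `rule`
#'   (one of `"MODULE_BACKGROUNDS_AND_BACKBONE"`, `"CANONICAL_PATHWAYS"`,
#'   `"FULL_DETAIL"`), plus rule parameters `k` (backbone participation-
#'   degree threshold) or `canonical_tag` (annotation note marking
#'   canonical-pathway membership). At least two levels; the last must be
#'   `FULL_DETAIL`.
#' @return An object of class `zoom_policy`.
#' @export
zoom_policy <- function(levels = default_zoom_levels()) {
  stopifnot(length(levels) >= 2L)
  rules <- vapply(levels, `[[`, character(1), "rule")
  ok <- c("MODULE_BACKGROUNDS_AND_BACKBONE", "CANONICAL_PATHWAYS", "FULL_DETAIL")
  if (!all(rules %in% ok)) stop("unknown visibility rule(s): ",
                                paste(setdiff(rules, ok), collapse = ", "))
  if (rules[length(rules)] != "FULL_DETAIL")
    stop("the last zoom level must be FULL_DETAIL")
  structure(list(levels = levels), class = "zoom_policy")
}

#' Default three-level policy
#'
#' Top level: module backgrounds plus backbone entities (participation
#' degree >= `k` or an explicit `backbone` annotation note). Middle level:
#' entities/reactions carrying the canonical tag. Last level: full detail.
#' Three levels match the recommended three-to-four zoom levels; the count
#' is configurable and unlimited in principle.
#'
#' @param k backbone participation-degree threshold (default 4).
#' @param canonical_tag annotation note naming canonical-pathway
#'   membership (default `"canonical"`).
#' @return list of level specs for [zoom_policy()].
#' @export
default_zoom_levels <- function(k = 4L, canonical_tag = "canonical") {
  list(list(name = "backbone", rule = "MODULE_BACKGROUNDS_AND_BACKBONE", k = k),
       list(name = "canonical", rule = "CANONICAL_PATHWAYS",
            canonical_tag = canonical_tag),
       list(name = "detail", rule = "FULL_DETAIL"))
}

has_note <- function(e, note) note %in% e$annotation$notes

#' Prune a map to one zoom level
#'
#' Applies the level's visibility rule and drops every reaction that lost
#' a participant (pruning never reroutes: a retained reaction keeps all
#' its participants or is dropped entirely). `FULL_DETAIL` is the
#' identity.
#'
#' @param map a [signalling_map()].
#' @param level_spec one element of a [zoom_policy()]'s `levels`.
#' @return The pruned view, a [signalling_map()].
#' @export
prune <- function(map, level_spec) {
  rule <- level_spec$rule
  if (rule == "FULL_DETAIL") return(map)
  keep <- if (rule == "MODULE_BACKGROUNDS_AND_BACKBONE") {
    k <- level_spec$k %||% 4L
    deg <- participation_degree(map)
    names(map$entities)[deg >= k |
                          vapply(map$entities, has_note, logical(1), "backbone")]
  } else {  # CANONICAL_PATHWAYS
    tag <- level_spec$canonical_tag %||% "canonical"
    names(map$entities)[vapply(map$entities, has_note, logical(1), tag)]
  }
  # keep complex members of kept complexes so the boxes stay meaningful
  repeat {
    more <- setdiff(unique(unlist(lapply(map$entities[keep], `[[`, "members"))), keep)
    if (!length(more)) break
    keep <- c(keep, more)
  }
  rx_ids <- names(map$reactions)[vapply(map$reactions, function(r) {
    all(unique(c(r$reactants, r$products, names(r$regulators))) %in% keep)
  }, logical(1))]
  induced_submap(map, keep, rx_ids, name = paste0(map$name, "@", level_spec$name))
}

#' Generate the per-level views of a map
#'
#' Applies [prune()] level by level and, by default, enforces monotone
#' detail: the entity (and reaction) set of each level is unioned with all
#' shallower levels' sets, so every element visible at level `i` stays
#' visible at level `i + 1`.
#'
#' @param map a [signalling_map()].
#' @param policy a [zoom_policy()].
#' @param enforce_containment union each level with the previous ones
#'   (default `TRUE`).
#' @return named list of views, one [signalling_map()] per level.
#' @export
zoom_views <- function(map, policy = zoom_policy(), enforce_containment = TRUE) {
  views <- list()
  prev_e <- character(); prev_r <- character()
  for (spec in policy$levels) {
    v <- prune(map, spec)
    if (enforce_containment) {
      keep_e <- union(names(v$entities), prev_e)
      keep_r <- union(names(v$reactions), prev_r)
      v <- induced_submap(map, keep_e, keep_r,
                          name = paste0(map$name, "@", spec$name))
      prev_e <- keep_e; prev_r <- keep_r
    }
    views[[spec$name]] <- v
  }
  views
}

#' Tile grid size at one level
#'
#' Level `L` renders the canvas at `2^L` times the native resolution and
#' cuts it into 256-px tiles: `ceil(W * 2^L / 256) * ceil(H * 2^L / 256)`
#' tiles.
#'
#' @param width,height canvas size in pixels.
#' @param level zero-based level index.
#' @return integer vector `c(nx, ny)`.
#' @export
tile_grid <- function(width, height, level) {
  s <- 2^level
  c(nx = as.integer(ceiling(width * s / TILE_SIZE)),
    ny = as.integer(ceiling(height * s / TILE_SIZE)))
}

entity_fill <- function(cls) {
  switch(cls,
         PROTEIN = "#CCFFCC", GENE = "#FFFF66", RNA = "#66CCFF",
         ANTISENSE_RNA = "#99CCFF", SIMPLE_MOLECULE = "#FFCC99",
         ION = "#FFCCCC", DRUG = "#FF9999", PHENOTYPE = "#CC99FF",
         COMPLEX = "#E0E0E0", "#FFFFFF")
}

# draw one view into the currently open device, device user coordinates
# assumed to be map pixels (x right, y down)
draw_view <- function(view, modules = NULL, markers = NULL) {
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  if (!is.null(modules)) {
    pal <- grDevices::hcl.colors(max(1L, length(modules$modules)), "Pastel 1")
    i <- 0L
    for (m in modules$modules) {
      i <- i + 1L
      ents <- view$entities[intersect(m$entity_ids, names(view$entities))]
      if (!length(ents)) next
      xs <- vapply(ents, `[[`, numeric(1), "x")
      ys <- vapply(ents, `[[`, numeric(1), "y")
      ws <- vapply(ents, `[[`, numeric(1), "w")
      hs <- vapply(ents, `[[`, numeric(1), "h")
      graphics::rect(min(xs) - 10, max(ys + hs) + 10, max(xs + ws) + 10,
                     min(ys) - 10, col = pal[i], border = NA)
    }
  }
  for (cm in view$compartments)
    graphics::rect(cm$x, cm$y + cm$h, cm$x + cm$w, cm$y,
                   border = "#888888", lwd = 2)
  for (r in view$reactions) {
    ids <- c(r$reactants, r$products, names(r$regulators))
    ids <- ids[ids %in% names(view$entities)]
    if (length(ids) < 2) next
    cx <- vapply(view$entities[ids], function(e) e$x + e$w / 2, numeric(1))
    cy <- vapply(view$entities[ids], function(e) e$y + e$h / 2, numeric(1))
    graphics::lines(cx, cy, col = "#555555")
  }
  for (e in view$entities) {
    graphics::rect(e$x, e$y + e$h, e$x + e$w, e$y,
                   col = entity_fill(e$entity_class), border = "#333333")
    graphics::text(e$x + e$w / 2, e$y + e$h / 2, e$name, cex = 0.5)
  }
  if (!is.null(markers) && nrow(markers)) {
    for (i in seq_len(nrow(markers))) {
      e <- view$entities[[markers$entity_id[i]]]
      if (is.null(e)) next
      graphics::points(e$x + e$w / 2, e$y + e$h / 2, pch = 25,
                       bg = "#FF0000", col = "#800000", cex = 1.2)
      graphics::text(e$x + e$w / 2, e$y - 4, markers$label[i], cex = 0.5,
                     col = "#800000")
    }
  }
}

render_one_tile <- function(path, view, W, H, level, tx, ty, modules, markers) {
  s <- 2^level
  x0 <- tx * TILE_SIZE / s
  y0 <- ty * TILE_SIZE / s
  x1 <- x0 + TILE_SIZE / s
  y1 <- y0 + TILE_SIZE / s
  grDevices::png(path, width = TILE_SIZE, height = TILE_SIZE, type = "cairo")
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot(NA, xlim = c(x0, x1), ylim = c(y1, y0), xlab = "", ylab = "",
                 axes = FALSE, asp = NA)
  graphics::rect(x0, y1, x1, y0, col = "#FFFFFF", border = NA)
  draw_view(view, modules, markers)
}

#' Render a tile pyramid
#'
#' Writes deterministic PNG tiles under `out_dir/tiles/<level>/<x>_<y>.png`
#' (fixed fonts and colours; two renders of the same input are
#' byte-identical), an `index.json` naming the levels, grid sizes and the
#' coordinate dialect, and a minimal static `map.html` shell with a zoom
#' bar. All levels share the canvas of the deepest (full-detail) view.
#'
#' @param views list of per-level views from [zoom_views()] (one per
#'   policy level).
#' @param policy the [zoom_policy()] that produced them.
#' @param out_dir output directory (created if needed).
#' @param modules optional [module_set()] used to paint module background
#'   shapes on the top (backbone) level.
#' @param markers optional data frame with columns `entity_id`, `label`;
#'   a marker is drawn at the entity centre at every level where the
#'   entity is visible.
#' @return An object of class `tile_pyramid`: per-level grids and the tile
#'   count, satisfying `tiles(L) = ceil(W*2^L/256) * ceil(H*2^L/256)`.
#' @export
render_tiles <- function(views, policy, out_dir, modules = NULL,
                         markers = NULL) {
  stopifnot(length(views) == length(policy$levels))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  W <- views[[length(views)]]$width
  H <- views[[length(views)]]$height
  index <- list(tile_size = TILE_SIZE,
                coordinate_dialect = "level 0 = native canvas; each deeper level doubles the resolution",
                canvas = list(width = W, height = H),
                levels = list())
  total <- 0L
  for (L in seq_along(views) - 1L) {
    view <- views[[L + 1L]]
    view$width <- W; view$height <- H
    g <- tile_grid(W, H, L)
    dir.create(file.path(out_dir, "tiles", L), recursive = TRUE,
               showWarnings = FALSE)
    for (ty in seq_len(g["ny"]) - 1L) for (tx in seq_len(g["nx"]) - 1L) {
      render_one_tile(file.path(out_dir, "tiles", L,
                                sprintf("%d_%d.png", tx, ty)),
                      view, W, H, L, tx, ty,
                      if (L == 0L) modules, markers)
    }
    index$levels[[L + 1L]] <- list(level = L, name = policy$levels[[L + 1L]]$name,
                                   nx = unname(g["nx"]), ny = unname(g["ny"]),
                                   n_tiles = unname(g["nx"] * g["ny"]))
    total <- total + g["nx"] * g["ny"]
  }
  jsonlite::write_json(index, file.path(out_dir, "index.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(pyramid_html(index), file.path(out_dir, "map.html"),
             useBytes = TRUE)
  structure(list(out_dir = out_dir, tile_size = TILE_SIZE,
                 levels = index$levels, n_tiles = as.integer(total)),
            class = "tile_pyramid")
}

#' @export
print.tile_pyramid <- function(x, ...) {
  cat(sprintf("<tile_pyramid> %d level(s), %d tiles in %s\n",
              length(x$levels), x$n_tiles, x$out_dir))
  invisible(x)
}

pyramid_html <- function(index) {
  lv <- vapply(index$levels, function(l)
    sprintf("<option value=\"%d\">%s</option>", l$level, l$name), character(1))
  c("<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"><title>map</title>",
    "<style>#tiles{position:relative}#tiles img{position:absolute}</style>",
    "</head><body>",
    "<label>zoom <select id=\"zoom\">", lv, "</select></label>",
    "<div id=\"tiles\"></div>",
    "<script>",
    sprintf("var index=%s;", jsonlite::toJSON(index, auto_unbox = TRUE)),
    "function show(L){var l=index.levels[L],d=document.getElementById('tiles');d.innerHTML='';",
    "for(var y=0;y<l.ny;y++)for(var x=0;x<l.nx;x++){var i=document.createElement('img');",
    "i.src='tiles/'+L+'/'+x+'_'+y+'.png';i.style.left=(x*index.tile_size)+'px';",
    "i.style.top=(y*index.tile_size)+'px';d.appendChild(i);}}",
    "document.getElementById('zoom').addEventListener('change',function(){show(+this.value);});",
    "show(0);",
    "</script></body></html>")
}
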