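#' @title Hierarchical layer/module structure
#' @description
#' Comprehensive maps are decomposed into hierarchically organised units:
#' layers group functional modules with similar roles (e.g. a repair-
#' machinery layer, a checkpoint layer, a cell-cycle layer), and each
#' functional module can exist both as part of the global map and as an
#' independent sub-map with its own compact layout. Membership is driven
#' by the machine-readable module tags in entity annotations, not by
#' geometry.
#' @name hierarchy
NULL

#' Create a module
#'
#' @param name module name (unique within a [module_set()]).
#' @param layer name of the layer this module belongs to.
#' @param entity_ids,reaction_ids character vectors of member ids.
#' @return An object of class `map_module`.
#' @export
map_module <- function(name, layer = "_default", entity_ids = character(),
                       reaction_ids = character()) {
  structure(list(name = as.character(name), layer = as.character(layer),
                 entity_ids = sort(unique(as.character(entity_ids))),
                 reaction_ids = sort(unique(as.character(reaction_ids)))),
            class = "map_module")
}

#' Create a module set
#'
#' @param modules list of [map_module()] objects; names must be unique.
#' @param layers ordered character vector of layer names; defaults to the
#'   distinct layers of `modules` in order of appearance.
#' @return An object of class `module_set`.
#' @export
module_set <- function(modules = list(), layers = NULL) {
  nms <- vapply(modules, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate module names")
  names(modules) <- nms
  mlayers <- unique(vapply(modules, `[[`, character(1), "layer"))
  if (is.null(layers)) layers <- mlayers
  if (length(setdiff(mlayers, layers)))
    stop("module layer(s) missing from the layer list: ",
         paste(setdiff(mlayers, layers), collapse = ", "))
  structure(list(layers = as.character(layers), modules = modules),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("<module_set> %d modules in %d layer(s)\n",
              length(x$modules), length(x$layers)))
  invisible(x)
}

#' Derive the module decomposition from annotation tags
#'
#' One module per distinct module tag found in entity annotations; an
#' entity tagged in several modules belongs to all of them. A reaction
#' belongs to every module containing at least one of its participants.
#' Entities carrying no module tag fall into the reserved module
#' `"_untagged"`.
#'
#' @param map a [signalling_map()].
#' @param layers optional named character vector, module name -> layer
#'   name, for modules whose layer is known (e.g. from the fixture truth
#'   record); unmapped modules land in layer `"_default"`.
#' @return A [module_set()].
#' @export
modules_from_tags <- function(map, layers = NULL) {
  membership <- list()
  for (e in map$entities) {
    tags <- e$annotation$module_tags
    mods <- tags$module[!is.na(tags$module)]
    if (length(mods) == 0L) mods <- "_untagged"
    for (m in mods) membership[[m]] <- c(membership[[m]], e$id)
  }
  modules <- lapply(sort(names(membership)), function(mn) {
    ents <- unique(membership[[mn]])
    rxs <- names(map$reactions)[vapply(map$reactions, function(r) {
      any(unique(c(r$reactants, r$products, names(r$regulators))) %in% ents)
    }, logical(1))]
    map_module(mn,
               layer = if (!is.null(layers) && mn %in% names(layers))
                 layers[[mn]] else "_default",
               entity_ids = ents, reaction_ids = rxs)
  })
  ms <- module_set(modules)
  ms
}

#' Extract a module as an independent sub-map
#'
#' The extracted map contains the module's entities (closure: complex
#' members are pulled in), the reactions whose participants lie inside
#' that closure, and unchanged annotations, then receives a fresh compact
#' layout. The reaction/entity topology is the induced subgraph of the
#' parent map; extraction never invents edges.
#'
#' @param map a [signalling_map()] .
#' @param module_name name of a module of `module_set`.
#' @param module_set a [module_set()]; defaults to [modules_from_tags()]
#'   of `map`.
#' @param strict if `TRUE` (default) keep only reactions all of whose
#'   participants are inside the closure; if `FALSE`, keep reactions with
#'   at least one member participant, restricted to the closure.
#' @param seed layout seed passed to [relayout()].
#' @return A [signalling_map()].
#' @export
extract_module_map <- function(map, module_name, module_set = NULL,
                               strict = TRUE, seed = 1L) {
  if (is.null(module_set)) module_set <- modules_from_tags(map)
  mod <- module_set$modules[[module_name]]
  if (is.null(mod)) stop("unknown module: ", module_name)
  closure <- mod$entity_ids
  repeat {
    more <- unique(unlist(lapply(map$entities[closure], `[[`, "members")))
    more <- setdiff(more, closure)
    if (length(more) == 0L) break
    closure <- c(closure, more)
  }
  rx_ids <- names(map$reactions)[vapply(map$reactions, function(r) {
    parts <- unique(c(r$reactants, r$products, names(r$regulators)))
    if (strict) all(parts %in% closure) else any(parts %in% mod$entity_ids)
  }, logical(1))]
  sub <- induced_submap(map, closure, rx_ids,
                        name = paste0(map$name, "_", module_name),
                        keep_canvas = FALSE)
  relayout(sub, seed = seed)
}

#' Deterministic force-directed relayout
#'
#' Computes a Fruchterman-Reingold layout of the entity graph (entities
#' linked when they share a reaction or a complex), then snaps entities to
#' a collision-free grid preserving the layout's relative ordering, so no
#' two bounding boxes overlap. The topology is untouched; the same seed
#' always yields identical coordinates.
#'
#' @param map a [signalling_map()].
#' @param seed integer random seed for the layout.
#' @return The map with new entity coordinates and a canvas just large
#'   enough to contain them.
#' @export
relayout <- function(map, seed = 1L) {
  n <- length(map$entities)
  if (n == 0L) return(map)
  ids <- names(map$entities)
  if (n == 1L) {
    e <- map$entities[[1]]
    map$entities[[1]]$x <- (map$width - e$w) / 2
    map$entities[[1]]$y <- (map$height - e$h) / 2
    return(map)
  }
  edges <- character(0)
  for (r in map$reactions) {
    parts <- unique(c(r$reactants, r$products, names(r$regulators)))
    if (length(parts) >= 2)
      for (i in seq_len(length(parts) - 1))
        edges <- c(edges, parts[i], parts[i + 1])
  }
  for (e in map$entities) for (m in e$members) edges <- c(edges, e$id, m)
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(ids)
  if (length(edges)) g <- g + igraph::edges(edges)
  xy <- withr_seed(seed, igraph::layout_with_fr(g, niter = 200))
  # snap to a grid sized by the largest box: collision-free by construction
  cw <- max(vapply(map$entities, `[[`, numeric(1), "w")) + 30
  ch <- max(vapply(map$entities, `[[`, numeric(1), "h")) + 30
  ncol_grid <- max(1L, ceiling(sqrt(n)))
  # order cells by layout position (row-major sweep of the fr coordinates)
  ord <- order(xy[, 2], xy[, 1])
  cells <- integer(n)
  cells[ord] <- seq_len(n) - 1L
  # within each row, keep the fr x-order
  for (row in unique(cells %/% ncol_grid)) {
    in_row <- which(cells %/% ncol_grid == row)
    in_row <- in_row[order(xy[in_row, 1])]
    cells[in_row] <- row * ncol_grid + seq_along(in_row) - 1L
  }
  for (i in seq_len(n)) {
    map$entities[[i]]$x <- (cells[i] %% ncol_grid) * cw + 15
    map$entities[[i]]$y <- (cells[i] %/% ncol_grid) * ch + 15
  }
  map$width <- max(256, ncol_grid * cw)
  map$height <- max(256, ceiling(n / ncol_grid) * ch)
  validate_map(map)
  map
}

# run code under a fixed RNG state without disturbing the caller's RNG
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

# identity key used when merging maps and de-duplicating reactions:
# HUGO symbol for proteins/genes/RNAs, CHEBI-style id (or name) for small
# molecules, member-set key for complexes, class+name otherwise.
entity_key <- function(e, map) {
  cls <- e$entity_class
  if (cls %in% c("PROTEIN", "GENE", "RNA", "ANTISENSE_RNA") &&
      !is.null(e$hugo) && nzchar(e$hugo))
    return(paste0(cls, ":", e$hugo, ":", paste(sort(e$modifications), collapse = ",")))
  if (cls %in% c("SIMPLE_MOLECULE", "ION", "DRUG")) {
    # chemical identity is the CHEBI-style id (fallback: name), class-free:
    # the same chemical drawn with two classes is a curation conflict that
    # merge_maps must surface, not silently duplicate
    chebi <- if ("CHEBI" %in% names(e$annotation$identifiers))
      e$annotation$identifiers[["CHEBI"]]
    key <- if (!is.null(chebi) && nzchar(chebi)) chebi else toupper(e$name)
    return(paste0("CHEM:", key))
  }
  if (cls == "COMPLEX") {
    mk <- sort(vapply(e$members, function(m) entity_key(map$entities[[m]], map),
                      character(1)))
    return(paste0("COMPLEX:{", paste(mk, collapse = "+"), "}"))
  }
  paste0(cls, ":", toupper(e$name))
}

merge_annotations <- function(a, b) {
  ids <- a$identifiers
  for (ns in names(b$identifiers))
    if (!ns %in% names(ids)) ids[[ns]] <- b$identifiers[[ns]]
  refs <- a$references
  seen <- vapply(refs, `[[`, character(1), "identifier")
  for (r in b$references) if (!r$identifier %in% seen) {
    refs[[length(refs) + 1L]] <- r
    seen <- c(seen, r$identifier)
  }
  annotation(identifiers = ids,
             module_tags = rbind(a$module_tags, b$module_tags),
             references = refs,
             confidence = a$confidence %||% b$confidence,
             notes = union(a$notes, b$notes))
}

#' Merge two maps by standard identifiers
#'
#' Entities with the same identity key (HUGO symbol for proteins, genes
#' and RNAs; CHEBI-style identifier for small molecules; member sets for
#' complexes) are unified: identifiers and module tags are unioned and
#' references de-duplicated by identifier. Reactions are de-duplicated by
#' (class, reactant set, product set, regulator set) over identity keys.
#' The second map's coordinates are offset to a free canvas region right
#' of the first map.
#'
#' @param a,b two [signalling_map()] objects passing [validate_map()].
#' @return The merged [signalling_map()].
#' @export
merge_maps <- function(a, b) {
  validate_map(a); validate_map(b)
  margin <- 40
  dx <- if (length(b$entities)) a$width + margin else 0
  key_of_a <- vapply(a$entities, entity_key, character(1), map = a)
  ents <- a$entities
  id_map <- stats::setNames(names(b$entities), names(b$entities))  # b id -> merged id
  # complexes must be processed after their members: order by member depth
  depth <- function(map, id) {
    e <- map$entities[[id]]
    if (length(e$members) == 0L) 0L
    else 1L + max(vapply(e$members, depth, integer(1), map = map))
  }
  b_ord <- names(b$entities)[order(vapply(names(b$entities), depth, integer(1),
                                          map = b))]
  for (bid in b_ord) {
    be <- b$entities[[bid]]
    bkey <- entity_key(be, b)
    hit <- names(key_of_a)[key_of_a == bkey]
    if (length(hit)) {
      tgt <- hit[1]
      if (ents[[tgt]]$entity_class != be$entity_class)
        stop("merge conflict for identity key ", bkey, ": classes ",
             ents[[tgt]]$entity_class, " vs ", be$entity_class)
      ents[[tgt]]$annotation <- merge_annotations(ents[[tgt]]$annotation,
                                                  be$annotation)
      id_map[[bid]] <- tgt
    } else {
      nid <- bid
      while (nid %in% names(ents)) nid <- paste0(nid, "_b")
      be$id <- nid
      be$x <- be$x + dx
      be$members <- unname(id_map[be$members])
      be$compartment <- NULL  # compartment geometry is not merged
      ents[[nid]] <- be
      key_of_a[[nid]] <- bkey
      id_map[[bid]] <- nid
    }
  }
  rx_key <- function(r, keys) {
    paste(r$reaction_class,
          paste(sort(keys[r$reactants]), collapse = "+"),
          paste(sort(keys[r$products]), collapse = "+"),
          paste(sort(paste0(keys[names(r$regulators)], "=", r$regulators)),
                collapse = "+"),
          sep = "|")
  }
  merged_keys <- vapply(ents, entity_key, character(1),
                        map = list(entities = ents))
  rxs <- a$reactions
  seen_rx <- vapply(rxs, rx_key, character(1), keys = merged_keys)
  for (r in b$reactions) {
    r$reactants <- unname(id_map[r$reactants])
    r$products <- unname(id_map[r$products])
    names(r$regulators) <- unname(id_map[names(r$regulators)])
    k <- rx_key(r, merged_keys)
    if (k %in% seen_rx) next
    nid <- r$id
    while (nid %in% names(rxs)) nid <- paste0(nid, "_b")
    r$id <- nid
    rxs[[nid]] <- r
    seen_rx <- c(seen_rx, k)
  }
  signalling_map(name = paste0(a$name, "+", b$name),
                 entities = unname(ents), reactions = unname(rxs),
                 compartments = unname(a$compartments),
                 width = max(a$width, dx + b$width),
                 height = max(a$height, b$height))
}
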