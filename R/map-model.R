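#' @title In-memory model of a process-description signalling map
#' @description
#' A signalling map is a bipartite reaction network: typed molecular
#' entities (proteins, genes, RNAs, small molecules, drugs, phenotypes,
#' complexes, ...) connected by typed reactions (state transitions,
#' translation, transcription, association, dissociation, transport,
#' degradation) that may carry regulators (catalysis, inhibition,
#' modulation, trigger, physical stimulation). Coordinates are pixels of the
#' most detailed zoom level, origin top-left, x rightwards, y downwards;
#' an entity's position is the top-left corner of its bounding box.
#' @name map-model
NULL

ENTITY_CLASSES <- c("PROTEIN", "GENE", "RNA", "ANTISENSE_RNA",
                    "SIMPLE_MOLECULE", "ION", "DRUG", "PHENOTYPE",
                    "COMPLEX", "UNKNOWN")
REGULATION_CLASSES <- c("CATALYSIS", "INHIBITION", "MODULATION", "TRIGGER",
                        "PHYSICAL_STIMULATION")
REACTION_CLASSES <- c("STATE_TRANSITION", "TRANSLATION", "TRANSCRIPTION",
                      "ASSOCIATION", "DISSOCIATION", "TRANSPORT",
                      "DEGRADATION", "UNKNOWN")

#' Supported vocabulary
#'
#' The entity, reaction and regulation class vocabularies of the data model.
#' @return character vector of class names.
#' @export
#' @rdname vocabulary
entity_classes <- function() ENTITY_CLASSES

#' @export
#' @rdname vocabulary
reaction_classes <- function() REACTION_CLASSES

#' @export
#' @rdname vocabulary
regulation_classes <- function() REGULATION_CLASSES

#' Create a map entity
#'
#' @param id unique opaque identifier within the map.
#' @param name display label (defaults to `id`).
#' @param entity_class one of [entity_classes()].
#' @param hugo optional standard gene symbol (upper-cased); identity key for
#'   proteins/genes/RNAs during merging and scoring.
#' @param modifications character vector of state marks
#'   (e.g. `"phosphorylated"`). Drawn species with different modification
#'   states remain distinct entities but collapse to one symbol for scoring
#'   and overlay.
#' @param compartment optional compartment id.
#' @param x,y top-left corner of the bounding box, in pixels.
#' @param w,h bounding box size in pixels.
#' @param members character vector of member entity ids; non-empty iff
#'   `entity_class == "COMPLEX"`.
#' @param annotation a [annotation()] object.
#' @return An object of class `map_entity`.
#' @export
map_entity <- function(id, name = id, entity_class = "PROTEIN", hugo = NULL,
                       modifications = character(), compartment = NULL,
                       x = 0, y = 0, w = 80, h = 40,
                       members = character(), annotation = pathmapr::annotation()) {
  id <- as.character(id)
  stopifnot(length(id) == 1L, nzchar(id))
  entity_class <- match.arg(entity_class, ENTITY_CLASSES)
  if (length(members) > 0L && entity_class != "COMPLEX")
    stop("only COMPLEX entities may have members (entity ", id, ")")
  if (entity_class == "COMPLEX" && length(members) == 0L)
    stop("COMPLEX entity ", id, " must have at least one member")
  pos <- c(x, y, w, h)
  if (any(!is.finite(pos)) || any(pos < 0))
    stop("position/size must be finite and non-negative (entity ", id, ")")
  if (!is.null(hugo)) hugo <- toupper(trimws(as.character(hugo)))
  # keep the HUGO symbol and the Identifiers annotation section in sync so
  # the canonical XML round-trip is lossless in both directions
  ann_hugo <- if ("HUGO" %in% names(annotation$identifiers))
    annotation$identifiers[["HUGO"]]
  if (is.null(hugo) && !is.null(ann_hugo)) hugo <- toupper(ann_hugo)
  if (!is.null(hugo) && !identical(ann_hugo, hugo)) {
    ids2 <- annotation$identifiers
    ids2[["HUGO"]] <- hugo
    annotation <- pathmapr::annotation(ids2, annotation$module_tags,
                                       annotation$references,
                                       annotation$confidence, annotation$notes)
  }
  structure(list(id = id, name = as.character(name),
                 entity_class = entity_class, hugo = hugo,
                 modifications = as.character(modifications),
                 compartment = compartment,
                 x = as.numeric(x), y = as.numeric(y),
                 w = as.numeric(w), h = as.numeric(h),
                 members = as.character(members),
                 annotation = annotation),
            class = "map_entity")
}

#' Create a reaction
#'
#' A reaction is a typed hyperedge connecting reactant, product and
#' regulator entities. `DEGRADATION` reactions may have empty products;
#' every other class needs at least one product or reactant overall.
#'
#' @param id unique reaction identifier.
#' @param reaction_class one of [reaction_classes()].
#' @param reactants,products character vectors of entity ids.
#' @param regulators named character vector: names are entity ids, values
#'   are regulation classes (see [regulation_classes()]).
#' @param annotation a [annotation()] object.
#' @return An object of class `map_reaction`.
#' @export
map_reaction <- function(id, reaction_class = "STATE_TRANSITION",
                         reactants = character(), products = character(),
                         regulators = character(),
                         annotation = pathmapr::annotation()) {
  id <- as.character(id)
  stopifnot(length(id) == 1L, nzchar(id))
  reaction_class <- match.arg(reaction_class, REACTION_CLASSES)
  if (length(regulators) && is.null(names(regulators)))
    stop("regulators must be a named vector (entity id -> regulation class)")
  regulators <- vapply(as.character(regulators), match.arg,
                       character(1), REGULATION_CLASSES) |>
    stats::setNames(names(regulators))
  if (length(regulators))
    regulators <- regulators[order(names(regulators))]  # canonical order
  if (length(reactants) + length(products) == 0L)
    stop("reaction ", id, ": reactants and products cannot both be empty")
  if (reaction_class != "DEGRADATION" && length(products) == 0L)
    stop("reaction ", id, ": products may be empty only for DEGRADATION")
  structure(list(id = id, reaction_class = reaction_class,
                 reactants = as.character(reactants),
                 products = as.character(products),
                 regulators = regulators, annotation = annotation),
            class = "map_reaction")
}

#' Create a compartment
#'
#' @param id unique compartment id.
#' @param name display name (e.g. cytosol, nucleus, mitochondria).
#' @param x,y,w,h bounding box in map pixels.
#' @return An object of class `map_compartment`.
#' @export
map_compartment <- function(id, name = id, x = 0, y = 0, w = 0, h = 0) {
  structure(list(id = as.character(id), name = as.character(name),
                 x = as.numeric(x), y = as.numeric(y),
                 w = as.numeric(w), h = as.numeric(h)),
            class = "map_compartment")
}

#' Assemble a signalling map
#'
#' @param name map name ("one biological function per map").
#' @param entities list of [map_entity()] objects.
#' @param reactions list of [map_reaction()] objects.
#' @param compartments list of [map_compartment()] objects.
#' @param width,height canvas size in pixels; if `NULL`, grown to fit all
#'   entity boxes (minimum 256).
#' @param module_set optional [module_set()] decomposition.
#' @param validate run [validate_map()] (default `TRUE`).
#' @return An object of class `signalling_map`.
#' @export
signalling_map <- function(name = "map", entities = list(),
                           reactions = list(), compartments = list(),
                           width = NULL, height = NULL, module_set = NULL,
                           validate = TRUE) {
  ids <- vapply(entities, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate entity ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(entities) <- ids
  rids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(rids)) stop("duplicate reaction ids")
  names(reactions) <- rids
  cids <- vapply(compartments, `[[`, character(1), "id")
  if (anyDuplicated(cids)) stop("duplicate compartment ids")
  names(compartments) <- cids
  if (is.null(width) || is.null(height)) {
    xmax <- if (length(entities))
      max(vapply(entities, function(e) e$x + e$w, numeric(1))) else 0
    ymax <- if (length(entities))
      max(vapply(entities, function(e) e$y + e$h, numeric(1))) else 0
    width <- width %||% max(256, ceiling(xmax))
    height <- height %||% max(256, ceiling(ymax))
  }
  m <- structure(list(name = as.character(name),
                      width = as.numeric(width), height = as.numeric(height),
                      entities = entities, reactions = reactions,
                      compartments = compartments, module_set = module_set),
                 class = "signalling_map")
  if (validate) validate_map(m)
  m
}

#' Check the structural invariants of a map
#'
#' Verifies referential integrity (reaction participants, complex members
#' and compartment references all resolve), acyclicity of complex
#' membership, and that the canvas contains every entity box.
#'
#' @param map a [signalling_map()].
#' @return `map`, invisibly; errors on the first violated invariant.
#' @export
validate_map <- function(map) {
  stopifnot(inherits(map, "signalling_map"))
  ids <- names(map$entities)
  for (r in map$reactions) {
    refs <- c(r$reactants, r$products, names(r$regulators))
    bad <- setdiff(refs, ids)
    if (length(bad))
      stop("reaction ", r$id, " references unknown entity id(s): ",
           paste(bad, collapse = ", "))
  }
  for (e in map$entities) {
    bad <- setdiff(e$members, ids)
    if (length(bad))
      stop("complex ", e$id, " references unknown member id(s): ",
           paste(bad, collapse = ", "))
    if (!is.null(e$compartment) && !e$compartment %in% names(map$compartments))
      stop("entity ", e$id, " references unknown compartment ", e$compartment)
  }
  # member graph must be acyclic
  state <- new.env(parent = emptyenv())
  visit <- function(id, stack) {
    if (id %in% stack) stop("complex membership cycle involving ", id)
    key <- paste0("v", id)
    if (isTRUE(state[[key]])) return(invisible())
    for (m in map$entities[[id]]$members) visit(m, c(stack, id))
    assign(key, TRUE, envir = state)
  }
  for (id in ids) visit(id, character())
  for (e in map$entities) {
    if (e$x + e$w > map$width + 1e-6 || e$y + e$h > map$height + 1e-6)
      stop("entity ", e$id, " extends beyond the canvas")
  }
  invisible(map)
}

#' @export
print.signalling_map <- function(x, ...) {
  cat(sprintf("<signalling_map> %s: %d entities, %d reactions, %d compartments, canvas %gx%g\n",
              x$name, length(x$entities), length(x$reactions),
              length(x$compartments), x$width, x$height))
  invisible(x)
}

#' @export
print.map_entity <- function(x, ...) {
  cat(sprintf("<map_entity> %s [%s]%s at (%g,%g) %gx%g\n", x$id,
              x$entity_class,
              if (!is.null(x$hugo)) paste0(" ", x$hugo) else "",
              x$x, x$y, x$w, x$h))
  invisible(x)
}

# flatten a complex into its protein-member HUGO symbols (recursive);
# used for scoring, GMT export and overlay matching
flatten_proteins <- function(entity_id, map, seen = character()) {
  if (entity_id %in% seen) return(character())
  e <- map$entities[[entity_id]]
  if (is.null(e)) stop("dangling entity id: ", entity_id)
  if (e$entity_class == "COMPLEX") {
    unique(unlist(lapply(e$members, flatten_proteins, map = map,
                         seen = c(seen, entity_id))))
  } else if (e$entity_class == "PROTEIN" && !is.null(e$hugo) && nzchar(e$hugo)) {
    e$hugo
  } else character()
}

# all HUGO symbols attached to an entity, proteins or genes/RNAs included;
# complexes flattened. Used by GMT export and omics overlay.
flatten_symbols <- function(entity_id, map, seen = character()) {
  if (entity_id %in% seen) return(character())
  e <- map$entities[[entity_id]]
  if (is.null(e)) stop("dangling entity id: ", entity_id)
  if (e$entity_class == "COMPLEX") {
    unique(unlist(lapply(e$members, flatten_symbols, map = map,
                         seen = c(seen, entity_id))))
  } else if (!is.null(e$hugo) && nzchar(e$hugo)) e$hugo else character()
}

#' Proteins participating in a reaction
#'
#' Returns the HUGO symbols of every protein-class participant of a
#' reaction (reactants, products and regulators). Complex participants are
#' recursively decomposed into their protein members; entities without a
#' HUGO symbol are omitted. This participant set is the input of the
#' functional-proximity confidence score.
#'
#' @param reaction a [map_reaction()] belonging to `map`.
#' @param map the [signalling_map()].
#' @return character vector (a set) of HUGO symbols; possibly empty.
#' @export
participant_proteins <- function(reaction, map) {
  stopifnot(inherits(reaction, "map_reaction"), inherits(map, "signalling_map"))
  ids <- unique(c(reaction$reactants, reaction$products,
                  names(reaction$regulators)))
  sort(unique(unlist(lapply(ids, flatten_proteins, map = map))))
}

#' Neighbourhood sub-map of an entity
#'
#' Breadth-first exploration of the bipartite entity-reaction graph: a
#' reaction links all of its participants, and the neighbourhood of radius
#' `r` contains every entity reachable through at most `r` reactions.
#' Radius 0 returns the entity alone. Supports step-wise enlargement of the
#' highlighted neighbourhood around a species of interest.
#'
#' @param map a [signalling_map()].
#' @param entity_id starting entity id.
#' @param radius integer >= 0.
#' @return The induced sub-map (a [signalling_map()]): kept reactions are
#'   those crossed by the search, restricted to kept participants.
#' @export
neighbourhood <- function(map, entity_id, radius) {
  stopifnot(inherits(map, "signalling_map"))
  if (!entity_id %in% names(map$entities))
    stop("unknown entity id: ", entity_id)
  radius <- as.integer(radius)
  stopifnot(radius >= 0L)
  kept <- entity_id
  kept_rx <- character()
  frontier <- entity_id
  r <- 0L
  while (r < radius && length(frontier)) {
    nxt <- character()
    for (rx in map$reactions) {
      parts <- unique(c(rx$reactants, rx$products, names(rx$regulators)))
      if (any(frontier %in% parts)) {
        kept_rx <- union(kept_rx, rx$id)
        nxt <- union(nxt, setdiff(parts, kept))
      }
    }
    kept <- union(kept, nxt)
    frontier <- nxt
    r <- r + 1L
  }
  induced_submap(map, kept, kept_rx, name = paste0(map$name, "_nbhd_", entity_id))
}

# induced sub-map over an entity id set; reactions restricted to those in
# rx_ids with at least one kept participant, participants filtered to kept.
# Complex members outside the kept set are dropped from member lists (and
# the complex demoted to UNKNOWN if all members vanish is avoided by keeping
# members that are kept only).
induced_submap <- function(map, keep_ids, rx_ids = NULL, name = map$name,
                           keep_canvas = TRUE) {
  keep_ids <- intersect(names(map$entities), keep_ids)
  ents <- lapply(map$entities[keep_ids], function(e) {
    e$members <- intersect(e$members, keep_ids)
    if (e$entity_class == "COMPLEX" && length(e$members) == 0L)
      e$entity_class <- "UNKNOWN"
    e
  })
  rxs <- list()
  cand <- if (is.null(rx_ids)) map$reactions else map$reactions[rx_ids]
  for (rx in cand) {
    rx$reactants <- intersect(rx$reactants, keep_ids)
    rx$products <- intersect(rx$products, keep_ids)
    rx$regulators <- rx$regulators[names(rx$regulators) %in% keep_ids]
    if (length(rx$reactants) + length(rx$products) > 0L)
      rxs[[rx$id]] <- rx
  }
  comp_ids <- unique(unlist(lapply(ents, `[[`, "compartment")))
  signalling_map(name = name, entities = ents, reactions = unname(rxs),
                 compartments = unname(map$compartments[intersect(names(map$compartments), comp_ids)]),
                 width = if (keep_canvas) map$width,
                 height = if (keep_canvas) map$height,
                 validate = FALSE)
}

# participation degree: number of reactions in which an entity participates
participation_degree <- function(map) {
  deg <- stats::setNames(integer(length(map$entities)), names(map$entities))
  for (rx in map$reactions) {
    parts <- unique(c(rx$reactants, rx$products, names(rx$regulators)))
    deg[parts] <- deg[parts] + 1L
  }
  deg
}
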