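#' @title CellDesigner-flavoured SBML input/output
#' @description
#' Reads the CellDesigner dialect of SBML Level 2 into a
#' [signalling_map()] and writes a canonical, byte-stable XML round-trip
#' format in the same dialect, plus SIF and GMT exporters. The supported
#' dialect subset is exactly the data-model vocabulary: species classes
#' PROTEIN/GENE/RNA/ANTISENSE_RNA/SIMPLE_MOLECULE/ION/DRUG/PHENOTYPE/
#' COMPLEX, and modification types mapping to the five regulation classes.
#' Unknown constructs are skipped, never fatal, and listed in the dialect
#' report.
#' @name celldesigner-io
NULL

SBML_NS <- "http://www.sbml.org/sbml/level2"
CD_NS <- "http://www.sbml.org/2001/ns/celldesigner"

#' Read a CellDesigner SBML file
#'
#' Species become entities (class from the CellDesigner species-class
#' annotation, layout from the species alias bounds, complex membership
#' from the alias nesting); reactions map their CellDesigner modification
#' types onto the regulation vocabulary; notes blocks are parsed with
#' [parse_annotation()]. Plain SBML without the CellDesigner extension is
#' read with UNKNOWN entity classes and a report warning.
#'
#' @param path path to an XML file with an `sbml` root.
#' @return list with elements `map` (a [signalling_map()]) and `report`
#'   (a `dialect_report`: parsed counts plus a data frame of skipped
#'   constructs with reasons). `parsed + skipped` accounts for every
#'   species and reaction element in the document.
#' @export
read_celldesigner <- function(path) {
  doc <- xml2::read_xml(path)  # malformed XML errors carry the line number
  if (xml2::xml_name(doc) != "sbml") stop("not an SBML document: root is <",
                                          xml2::xml_name(doc), ">")
  ns <- c(s = SBML_NS, cd = CD_NS)
  has_cd <- length(xml2::xml_find_all(doc, ".//cd:extension", ns)) > 0
  model <- xml2::xml_find_first(doc, "./s:model", ns)
  if (inherits(model, "xml_missing"))
    model <- xml2::xml_find_first(doc, "./model")  # namespace-less fallback
  skipped <- data.frame(element = character(), reason = character(),
                        stringsAsFactors = FALSE)
  skip <- function(el, why) {
    skipped <<- rbind(skipped, data.frame(element = el, reason = why))
  }
  if (!has_cd) skip("celldesigner:extension",
                    "no CellDesigner extension; classes set to UNKNOWN")

  map_name <- attr_or(xml2::xml_attr(model, "id"), "map")
  disp <- xml2::xml_find_first(model, ".//cd:modelDisplay", ns)
  W <- H <- NULL
  if (!inherits(disp, "xml_missing")) {
    W <- as.numeric(xml2::xml_attr(disp, "sizeX"))
    H <- as.numeric(xml2::xml_attr(disp, "sizeY"))
  }

  # species aliases: layout boxes + complex nesting
  alias_nodes <- xml2::xml_find_all(model, ".//cd:speciesAlias | .//cd:complexSpeciesAlias", ns)
  bounds <- list(); parent_alias <- character(); alias_species <- character()
  for (a in alias_nodes) {
    aid <- xml2::xml_attr(a, "id")
    sp <- xml2::xml_attr(a, "species")
    b <- xml2::xml_find_first(a, "./cd:bounds", ns)
    alias_species[[aid]] <- sp
    if (!inherits(b, "xml_missing"))
      bounds[[sp]] <- as.numeric(c(xml2::xml_attr(b, "x"), xml2::xml_attr(b, "y"),
                                   xml2::xml_attr(b, "w"), xml2::xml_attr(b, "h")))
    pa <- xml2::xml_attr(a, "complexSpeciesAlias")
    if (!is.na(pa)) parent_alias[[aid]] <- pa
  }

  notes_text <- function(node) {
    nn <- xml2::xml_find_first(node, "./s:notes", ns)
    if (inherits(nn, "xml_missing")) nn <- xml2::xml_find_first(node, "./notes")
    if (inherits(nn, "xml_missing")) return("")
    xml2::xml_text(nn)
  }

  # the id "default" is reserved for "no compartment" and never surfaced
  comp_nodes <- xml2::xml_find_all(model, "./s:listOfCompartments/s:compartment", ns)
  compartments <- lapply(comp_nodes, function(cn) {
    cid <- xml2::xml_attr(cn, "id")
    if (identical(cid, "default")) return(NULL)
    map_compartment(cid,
                    name = attr_or(xml2::xml_attr(cn, "name"), cid),
                    x = as_num0(xml2::xml_attr(cn, "x")),
                    y = as_num0(xml2::xml_attr(cn, "y")),
                    w = as_num0(xml2::xml_attr(cn, "w")),
                    h = as_num0(xml2::xml_attr(cn, "h")))
  })
  compartments <- compartments[!vapply(compartments, is.null, logical(1))]
  comp_ids <- vapply(compartments, `[[`, character(1), "id")

  sp_nodes <- xml2::xml_find_all(model, "./s:listOfSpecies/s:species", ns)
  entities <- list()
  n_parsed_sp <- 0L
  for (sn in sp_nodes) {
    sid <- xml2::xml_attr(sn, "id")
    if (is.na(sid)) { skip("species", "missing id attribute"); next }
    cls_node <- xml2::xml_find_first(sn, ".//cd:speciesIdentity/cd:class", ns)
    cls <- if (inherits(cls_node, "xml_missing")) NA_character_
           else toupper(xml2::xml_text(cls_node))
    if (is.na(cls)) {
      cls <- "UNKNOWN"
      if (has_cd) skip(paste0("species:", sid), "no species class annotation")
    } else if (!cls %in% ENTITY_CLASSES) {
      skip(paste0("species:", sid),
           paste0("unsupported species class '", cls, "' mapped to UNKNOWN"))
      cls <- "UNKNOWN"
    }
    mods <- xml2::xml_attr(
      xml2::xml_find_all(sn, ".//cd:listOfModifications/cd:modification", ns),
      "state")
    ann <- parse_annotation(notes_text(sn))
    hugo <- if ("HUGO" %in% names(ann$identifiers)) ann$identifiers[["HUGO"]]
    b <- bounds[[sid]] %||% c(0, 0, 80, 40)
    comp <- xml2::xml_attr(sn, "compartment")
    if (is.na(comp) || !comp %in% comp_ids) comp <- NULL
    # members resolved after all aliases are known
    entities[[sid]] <- list(id = sid,
                            name = attr_or(xml2::xml_attr(sn, "name"), sid),
                            class = cls, hugo = hugo, mods = mods,
                            comp = comp, b = b, ann = ann)
    n_parsed_sp <- n_parsed_sp + 1L
  }

  # complex membership: alias -> parent complex alias -> parent species
  members <- lapply(stats::setNames(nm = names(entities)), function(x) character())
  for (aid in names(parent_alias)) {
    child_sp <- alias_species[[aid]]
    parent_sp <- alias_species[[parent_alias[[aid]]]]
    if (!is.null(child_sp) && !is.null(parent_sp) &&
        child_sp %in% names(entities) && parent_sp %in% names(entities)) {
      members[[parent_sp]] <- union(members[[parent_sp]], child_sp)
    } else skip(paste0("speciesAlias:", aid), "unresolved complex nesting")
  }

  ents <- lapply(names(entities), function(sid) {
    e <- entities[[sid]]
    cls <- e$class
    mem <- members[[sid]]
    if (cls == "COMPLEX" && length(mem) == 0L) {
      skip(paste0("species:", sid), "COMPLEX without members mapped to UNKNOWN")
      cls <- "UNKNOWN"
    }
    if (cls != "COMPLEX") mem <- character()
    map_entity(sid, name = e$name, entity_class = cls, hugo = e$hugo,
               modifications = e$mods, compartment = e$comp,
               x = e$b[1], y = e$b[2], w = e$b[3], h = e$b[4],
               members = mem, annotation = e$ann)
  })

  rx_nodes <- xml2::xml_find_all(model, "./s:listOfReactions/s:reaction", ns)
  reactions <- list()
  n_parsed_rx <- 0L
  known_ids <- vapply(ents, `[[`, character(1), "id")
  for (rn in rx_nodes) {
    rid <- xml2::xml_attr(rn, "id")
    rt_node <- xml2::xml_find_first(rn, ".//cd:reactionType", ns)
    rclass <- if (inherits(rt_node, "xml_missing")) "UNKNOWN"
              else toupper(xml2::xml_text(rt_node))
    if (!rclass %in% REACTION_CLASSES) {
      skip(paste0("reaction:", rid),
           paste0("unsupported reaction type '", rclass, "' mapped to UNKNOWN"))
      rclass <- "UNKNOWN"
    }
    sp_of <- function(xp) xml2::xml_attr(xml2::xml_find_all(rn, xp, ns), "species")
    reactants <- sp_of("./s:listOfReactants/s:speciesReference")
    products <- sp_of("./s:listOfProducts/s:speciesReference")
    regs <- character()
    for (mn in xml2::xml_find_all(rn, ".//cd:listOfModification/cd:modification", ns)) {
      typ <- toupper(xml2::xml_attr(mn, "type"))
      who <- xml2::xml_attr(mn, "modifiers")
      if (typ %in% REGULATION_CLASSES && !is.na(who)) {
        for (w in strsplit(who, ",", fixed = TRUE)[[1]]) regs[[trimws(w)]] <- typ
      } else {
        skip(paste0("reaction:", rid),
             paste0("unsupported modification type '", typ, "'"))
      }
    }
    # plain-SBML modifiers without a CellDesigner type default to MODULATION
    plain_mod <- sp_of("./s:listOfModifiers/s:modifierSpeciesReference")
    for (w in setdiff(plain_mod, names(regs))) regs[[w]] <- "MODULATION"
    bad <- setdiff(c(reactants, products, names(regs)), known_ids)
    if (length(bad)) {
      skip(paste0("reaction:", rid),
           paste0("unknown participant id(s): ", paste(bad, collapse = ",")))
      next
    }
    if (length(reactants) + length(products) == 0L) {
      skip(paste0("reaction:", rid), "no reactants or products")
      next
    }
    if (rclass != "DEGRADATION" && length(products) == 0L) rclass <- "DEGRADATION"
    reactions[[rid]] <- map_reaction(rid, reaction_class = rclass,
                                     reactants = reactants, products = products,
                                     regulators = regs,
                                     annotation = parse_annotation(notes_text(rn)))
    n_parsed_rx <- n_parsed_rx + 1L
  }

  map <- signalling_map(name = map_name, entities = ents,
                        reactions = unname(reactions),
                        compartments = compartments,
                        width = W, height = H)
  report <- structure(list(n_species = n_parsed_sp,
                           n_reactions = n_parsed_rx,
                           n_compartments = length(compartments),
                           skipped = skipped),
                      class = "dialect_report")
  list(map = map, report = report)
}

as_num0 <- function(x) { v <- suppressWarnings(as.numeric(x)); if (is.na(v)) 0 else v }

attr_or <- function(v, default) if (is.null(v) || is.na(v)) default else v

#' @export
print.dialect_report <- function(x, ...) {
  cat(sprintf("<dialect_report> %d species, %d reactions, %d compartments; %d skipped construct(s)\n",
              x$n_species, x$n_reactions, x$n_compartments, nrow(x$skipped)))
  if (nrow(x$skipped)) print(x$skipped)
  invisible(x)
}

#' Write a map as canonical CellDesigner-dialect XML
#'
#' The writer emits elements and attributes in a fixed, sorted order so the
#' output is byte-stable and usable as a golden file;
#' `read_celldesigner(write_celldesigner(map))` reproduces the map
#' field-for-field.
#'
#' @param map a [signalling_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_celldesigner <- function(map, path) {
  validate_map(map)
  esc <- function(x) html_escape(as.character(x))
  num <- function(x) format(x, trim = TRUE, scientific = FALSE)
  ln <- character()
  add <- function(...) ln <<- c(ln, paste0(...))
  add('<?xml version="1.0" encoding="UTF-8"?>')
  add(sprintf('<sbml xmlns="%s" xmlns:celldesigner="%s" level="2" version="4">',
              SBML_NS, CD_NS))
  add(sprintf('<model id="%s">', esc(map$name)))
  add('<annotation><celldesigner:extension>')
  add(sprintf('<celldesigner:modelDisplay sizeX="%s" sizeY="%s"/>',
              num(map$width), num(map$height)))
  ord <- sort(names(map$entities))
  # one alias per (species, parent-complex) pair, CellDesigner style: a
  # species drawn inside several complexes has several aliases
  parents_of <- function(id)
    ord[vapply(map$entities[ord], function(p) id %in% p$members, logical(1))]
  bounds_of <- function(e) sprintf('<celldesigner:bounds h="%s" w="%s" x="%s" y="%s"/>',
                                   num(e$h), num(e$w), num(e$x), num(e$y))
  add('<celldesigner:listOfSpeciesAliases>')
  for (id in ord) {
    e <- map$entities[[id]]
    if (e$entity_class == "COMPLEX") next
    parents <- parents_of(id)
    if (length(parents) == 0L) {
      add(sprintf('<celldesigner:speciesAlias id="sa_%s" species="%s">',
                  esc(id), esc(id)), bounds_of(e), '</celldesigner:speciesAlias>')
    } else for (p in parents) {
      add(sprintf('<celldesigner:speciesAlias complexSpeciesAlias="csa_%s" id="sa_%s__%s" species="%s">',
                  esc(p), esc(id), esc(p), esc(id)),
          bounds_of(e), '</celldesigner:speciesAlias>')
    }
  }
  add('</celldesigner:listOfSpeciesAliases>')
  add('<celldesigner:listOfComplexSpeciesAliases>')
  for (id in ord) {
    e <- map$entities[[id]]
    if (e$entity_class != "COMPLEX") next
    # a complex keeps a single alias (its members point at it); nesting is
    # recorded through the parent attribute of that alias
    parents <- parents_of(id)
    pa <- if (length(parents)) sprintf(' complexSpeciesAlias="csa_%s"', esc(parents[1])) else ""
    add(sprintf('<celldesigner:complexSpeciesAlias%s id="csa_%s" species="%s">',
                pa, esc(id), esc(id)), bounds_of(e),
        '</celldesigner:complexSpeciesAlias>')
  }
  add('</celldesigner:listOfComplexSpeciesAliases>')
  add('</celldesigner:extension></annotation>')
  add('<listOfCompartments>')
  add('<compartment id="default"/>')  # reserved: entities without compartment
  for (cid in sort(names(map$compartments))) {
    cm <- map$compartments[[cid]]
    add(sprintf('<compartment h="%s" id="%s" name="%s" w="%s" x="%s" y="%s"/>',
                num(cm$h), esc(cm$id), esc(cm$name), num(cm$w), num(cm$x), num(cm$y)))
  }
  add('</listOfCompartments>')
  add('<listOfSpecies>')
  for (id in ord) {
    e <- map$entities[[id]]
    ann <- e$annotation  # HUGO is kept in sync by the map_entity constructor
    comp <- if (!is.null(e$compartment)) e$compartment else "default"
    add(sprintf('<species compartment="%s" id="%s" name="%s">',
                esc(comp), esc(e$id), esc(e$name)))
    add('<annotation><celldesigner:extension><celldesigner:speciesIdentity>')
    add(sprintf('<celldesigner:class>%s</celldesigner:class>', e$entity_class))
    if (length(e$modifications)) {
      add('<celldesigner:listOfModifications>')
      for (m in e$modifications)
        add(sprintf('<celldesigner:modification state="%s"/>', esc(m)))
      add('</celldesigner:listOfModifications>')
    }
    add('</celldesigner:speciesIdentity></celldesigner:extension></annotation>')
    txt <- serialise_annotation(ann)
    if (nzchar(txt))
      add('<notes><body xmlns="http://www.w3.org/1999/xhtml">', esc(txt),
          '</body></notes>')
    add('</species>')
  }
  add('</listOfSpecies>')
  add('<listOfReactions>')
  for (rid in sort(names(map$reactions))) {
    r <- map$reactions[[rid]]
    add(sprintf('<reaction id="%s" reversible="false">', esc(r$id)))
    add('<annotation><celldesigner:extension>')
    add(sprintf('<celldesigner:reactionType>%s</celldesigner:reactionType>',
                r$reaction_class))
    if (length(r$regulators)) {
      add('<celldesigner:listOfModification>')
      for (i in order(names(r$regulators)))
        add(sprintf('<celldesigner:modification modifiers="%s" type="%s"/>',
                    esc(names(r$regulators)[i]), r$regulators[[i]]))
      add('</celldesigner:listOfModification>')
    }
    add('</celldesigner:extension></annotation>')
    txt <- serialise_annotation(r$annotation)
    if (nzchar(txt))
      add('<notes><body xmlns="http://www.w3.org/1999/xhtml">', esc(txt),
          '</body></notes>')
    if (length(r$reactants)) {
      add('<listOfReactants>')
      for (s in r$reactants)
        add(sprintf('<speciesReference species="%s"/>', esc(s)))
      add('</listOfReactants>')
    }
    if (length(r$products)) {
      add('<listOfProducts>')
      for (s in r$products)
        add(sprintf('<speciesReference species="%s"/>', esc(s)))
      add('</listOfProducts>')
    }
    if (length(r$regulators)) {
      add('<listOfModifiers>')
      for (s in sort(names(r$regulators)))
        add(sprintf('<modifierSpeciesReference species="%s"/>', esc(s)))
      add('</listOfModifiers>')
    }
    add('</reaction>')
  }
  add('</listOfReactions>')
  add('</model>')
  add('</sbml>')
  writeLines(ln, path, useBytes = TRUE)
  invisible(path)
}

#' Export a map as SIF (simple interaction format)
#'
#' Each reaction is expanded into binary relations: one
#' `reactant <TAB> reaction_class <TAB> product` line per reactant-product
#' pair and one `regulator <TAB> regulation_class <TAB> product` line per
#' regulator-product pair. Degradation reactions without products target
#' the reserved sink token `__degraded__`. Lines are written in
#' deterministic lexicographic order.
#'
#' @param map a [signalling_map()] passing [validate_map()].
#' @param path output file path.
#' @return number of lines written.
#' @export
write_sif <- function(map, path) {
  validate_map(map)
  lines <- character()
  for (r in map$reactions) {
    prods <- r$products
    if (length(prods) == 0L) prods <- "__degraded__"
    for (a in r$reactants) for (b in prods)
      lines <- c(lines, paste(a, r$reaction_class, b, sep = "\t"))
    for (i in seq_along(r$regulators)) for (b in prods)
      lines <- c(lines, paste(names(r$regulators)[i], r$regulators[[i]], b,
                              sep = "\t"))
  }
  lines <- sort(lines)
  writeLines(lines, path, useBytes = TRUE)
  length(lines)
}

#' Export a module decomposition as a GMT gene-set file
#'
#' One line per module: `name <TAB> description <TAB> gene1 <TAB> ...`.
#' Genes are the de-duplicated HUGO symbols of the module's entities with
#' complexes flattened into members; the description column carries the
#' module's layer name (or `"NA"`). Lines are sorted by module name.
#'
#' @param module_set a [module_set()].
#' @param map the parent [signalling_map()].
#' @param path output file path.
#' @return number of lines written.
#' @export
write_gmt <- function(module_set, map, path) {
  stopifnot(inherits(module_set, "module_set"))
  lines <- character()
  for (m in module_set$modules) {
    bad <- setdiff(m$entity_ids, names(map$entities))
    if (length(bad))
      stop("module ", m$name, " references missing entity id(s): ",
           paste(bad, collapse = ", "))
    genes <- sort(unique(unlist(lapply(m$entity_ids, flatten_symbols, map = map))))
    desc <- if (is.null(m$layer) || is.na(m$layer)) "NA" else m$layer
    lines <- c(lines, paste(c(m$name, desc, genes), collapse = "\t"))
  }
  lines <- lines[order(vapply(strsplit(lines, "\t"), `[[`, character(1), 1))]
  writeLines(lines, path, useBytes = TRUE)
  length(lines)
}
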