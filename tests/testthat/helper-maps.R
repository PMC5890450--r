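# small in-code builders shared across test files

# A --r1--> B --r2--> C, all proteins with HUGO = their name
chain_map <- function() {
  signalling_map("chain",
    entities = list(
      map_entity("e1", name = "A", hugo = "A", x = 10, y = 10),
      map_entity("e2", name = "B", hugo = "B", x = 120, y = 10),
      map_entity("e3", name = "C", hugo = "C", x = 230, y = 10)),
    reactions = list(
      map_reaction("r1", reactants = "e1", products = "e2"),
      map_reaction("r2", reactants = "e2", products = "e3")))
}

# complex C = {P1, P2} as reactant, P3 as product
complex_map <- function() {
  signalling_map("cx",
    entities = list(
      map_entity("p1", hugo = "P1", x = 0, y = 0),
      map_entity("p2", hugo = "P2", x = 90, y = 0),
      map_entity("cplx", entity_class = "COMPLEX", members = c("p1", "p2"),
                 x = 0, y = 60, w = 120, h = 60),
      map_entity("p3", hugo = "P3", x = 200, y = 60)),
    reactions = list(
      map_reaction("r1", reactants = "cplx", products = "p3")))
}

path_ppi <- function(symbols) {
  n <- length(symbols)
  ppi_network(cbind(symbols[-n], symbols[-1]))
}

# canonical form for field-for-field map comparison (sorted, order-free)
norm_map <- function(map) {
  ord <- sort(names(map$entities))
  ents <- lapply(map$entities[ord], function(e) {
    e$members <- sort(e$members)
    e
  })
  rxs <- lapply(map$reactions[sort(names(map$reactions))], function(r) {
    r$reactants <- sort(r$reactants)
    r$products <- sort(r$products)
    r
  })
  list(name = map$name, width = map$width, height = map$height,
       entities = ents, reactions = rxs,
       compartments = map$compartments[sort(names(map$compartments))])
}

expect_map_equal <- function(a, b) {
  expect_equal(norm_map(a), norm_map(b))
}

# deterministic random annotation generator for round-trip properties
random_annotation <- function() {
  ns <- sample(c("HUGO", "UNIPROT", "ENTREZ", "CHEBI"), sample(0:3, 1))
  ids <- if (length(ns))
    stats::setNames(paste0("ID", seq_along(ns)), ns) else character()
  ntag <- sample(0:2, 1)
  tags <- if (ntag > 0)
    data.frame(map = paste0("m", seq_len(ntag)),
               module = ifelse(stats::runif(ntag) < 0.5, NA_character_,
                               paste0("mod", seq_len(ntag))))
  else data.frame(map = character(), module = character())
  refs <- lapply(seq_len(sample(0:3, 1)), function(i)
    reference(paste0("1234", i),
              kind = sample(c("ORIGINAL", "REVIEW"), 1)))
  conf <- if (stats::runif(1) < 0.5)
    list(ref = sample(0:5, 1), func = sample(0:5, 1))
  annotation(identifiers = ids, module_tags = tags, references = refs,
             confidence = conf,
             notes = if (stats::runif(1) < 0.5) c("backbone", "a free note"))
}
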