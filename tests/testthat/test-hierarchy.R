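tagged <- function(id, mod, hugo = toupper(id), x = 0, y = 0) {
  map_entity(id, hugo = hugo, x = x, y = y,
             annotation = annotation(module_tags = data.frame(
               map = "toy", module = mod)))
}

test_that("modules_from_tags builds one module per distinct tag", {
  # the 10 + 4 + 4 composition yields exactly 18 modules
  f <- make_fixture_map(fixture_spec(seed = 1))
  ms <- modules_from_tags(f$map, layers = f$truth$layers)
  expect_length(ms$modules, 18)
  expect_setequal(names(ms$modules), f$truth$modules)
  expect_setequal(ms$layers, c("repair_machinery", "cell_cycle", "checkpoints"))

  # a map with no tags collapses into the reserved module
  m <- signalling_map("plain", entities = list(map_entity("a"), map_entity("b", x = 100)),
                      reactions = list(map_reaction("r", reactants = "a", products = "b")))
  ms2 <- modules_from_tags(m)
  expect_length(ms2$modules, 1)
  expect_setequal(ms2$modules[["_untagged"]]$entity_ids, c("a", "b"))
  expect_setequal(ms2$modules[["_untagged"]]$reaction_ids, "r")

  # an entity tagged in two modules appears in both entity sets
  e2 <- map_entity("shared", hugo = "SH", x = 200,
                   annotation = annotation(module_tags = data.frame(
                     map = "toy", module = c("M1", "M2"))))
  m3 <- signalling_map("multi", entities = list(tagged("a", "M1"), e2))
  ms3 <- modules_from_tags(m3)
  expect_true("shared" %in% ms3$modules[["M1"]]$entity_ids)
  expect_true("shared" %in% ms3$modules[["M2"]]$entity_ids)

  # size identity: sum of module sizes >= entity count, equal iff no multi-tag
  sizes3 <- sum(lengths(lapply(ms3$modules, `[[`, "entity_ids")))
  expect_equal(sizes3, length(m3$entities) + 1)  # one entity double-tagged
  sizes2 <- sum(lengths(lapply(ms2$modules, `[[`, "entity_ids")))
  expect_equal(sizes2, length(m$entities))
})

test_that("extract_module_map induces the tagged sub-map with a fresh layout", {
  # 5 entities / 3 reactions planted in module M
  ents <- lapply(1:5, function(i) tagged(paste0("e", i), "M", x = i * 100))
  rxs <- lapply(1:3, function(i)
    map_reaction(paste0("r", i), reactants = paste0("e", i),
                 products = paste0("e", i + 1)))
  other <- tagged("z", "OTHER", x = 700)
  m <- signalling_map("parent", entities = c(ents, list(other)),
                      reactions = c(rxs, list(
                        map_reaction("rz", reactants = "e5", products = "z"))))
  sub <- extract_module_map(m, "M")
  expect_length(sub$entities, 5)
  expect_length(sub$reactions, 3)  # strict rule drops the boundary reaction rz
  expect_true(all(names(sub$reactions) %in% names(m$reactions)))
  expect_true(sub$width * sub$height <= m$width * m$height)

  # loose rule keeps the boundary reaction, restricted to the closure
  sub_loose <- extract_module_map(m, "M", strict = FALSE)
  expect_length(sub_loose$reactions, 4)

  expect_error(extract_module_map(m, "NOPE"), "unknown module")

  # extracting _untagged from an untagged map preserves the topology
  plain <- signalling_map("plain", entities = list(
    map_entity("a"), map_entity("b", x = 100)),
    reactions = list(map_reaction("r", reactants = "a", products = "b")))
  iso <- extract_module_map(plain, "_untagged")
  expect_setequal(names(iso$entities), names(plain$entities))
  expect_setequal(names(iso$reactions), names(plain$reactions))

  # an entity shared by two modules keeps identical annotation in both maps
  shared <- map_entity("s", hugo = "SH", x = 300,
                       annotation = annotation(
                         module_tags = data.frame(map = "toy", module = c("M1", "M2")),
                         references = list(reference("77", "REVIEW"))))
  m2 <- signalling_map("two", entities = list(tagged("a", "M1"), tagged("b", "M2", x = 100), shared))
  s1 <- extract_module_map(m2, "M1")
  s2 <- extract_module_map(m2, "M2")
  expect_equal(s1$entities[["s"]]$annotation, s2$entities[["s"]]$annotation)
})

test_that("relayout is deterministic and produces no overlapping boxes", {
  f <- make_fixture_map(fixture_spec(seed = 2, n_modules = 5))
  a <- relayout(f$map, seed = 10)
  b <- relayout(f$map, seed = 10)
  expect_equal(lapply(a$entities, function(e) c(e$x, e$y)),
               lapply(b$entities, function(e) c(e$x, e$y)))
  # topology unchanged
  expect_identical(names(a$entities), names(f$map$entities))
  expect_identical(names(a$reactions), names(f$map$reactions))
  # O(n^2) overlap census over all bounding-box pairs
  boxes <- t(vapply(a$entities, function(e) c(e$x, e$y, e$w, e$h), numeric(4)))
  n <- nrow(boxes)
  overlaps <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (boxes[i, 1] < boxes[j, 1] + boxes[j, 3] &&
        boxes[j, 1] < boxes[i, 1] + boxes[i, 3] &&
        boxes[i, 2] < boxes[j, 2] + boxes[j, 4] &&
        boxes[j, 2] < boxes[i, 2] + boxes[i, 4]) overlaps <- overlaps + 1L
  }
  expect_equal(overlaps, 0L)

  # single entity is centred
  single <- signalling_map("one", entities = list(map_entity("a", w = 80, h = 40)),
                           width = 400, height = 300)
  cs <- relayout(single, seed = 1)
  expect_equal(cs$entities[["a"]]$x, (400 - 80) / 2)
  expect_equal(cs$entities[["a"]]$y, (300 - 40) / 2)
})

test_that("merge_maps unifies entities by identity key", {
  empty <- signalling_map("empty")
  m <- chain_map()
  merged0 <- merge_maps(m, empty)
  expect_map_equal_topology <- function(a, b) {
    expect_setequal(names(a$entities), names(b$entities))
    expect_setequal(names(a$reactions), names(b$reactions))
  }
  expect_map_equal_topology(merged0, m)

  # two maps sharing TP53: one merged entity, module tags unioned
  mk <- function(mod, id) signalling_map(mod, entities = list(
    map_entity(id, name = "TP53", hugo = "TP53",
               annotation = annotation(module_tags = data.frame(
                 map = mod, module = paste0(mod, "_mod"))))))
  ab <- merge_maps(mk("a", "x1"), mk("b", "x2"))
  expect_length(ab$entities, 1)
  expect_equal(nrow(ab$entities[[1]]$annotation$module_tags), 2)

  # merge(a, a) is isomorphic to a: de-duplication of entities and reactions
  aa <- merge_maps(m, m)
  expect_length(aa$entities, length(m$entities))
  expect_length(aa$reactions, length(m$reactions))

  # commutative up to layout: same identity keys and reaction count
  f1 <- make_fixture_map(fixture_spec(seed = 3, n_modules = 2))$map
  f2 <- chain_map()
  k <- function(mm) sort(vapply(mm$entities, pathmapr:::entity_key,
                                character(1), map = mm))
  m12 <- merge_maps(f1, f2); m21 <- merge_maps(f2, f1)
  expect_identical(k(m12), k(m21))
  expect_equal(length(m12$reactions), length(m21$reactions))

  # conflicting classes for one identity key raise a merge conflict
  g1 <- signalling_map("g1", entities = list(map_entity("u", name = "GLC")))
  g2 <- signalling_map("g2", entities = list(
    map_entity("v", name = "GLC", entity_class = "SIMPLE_MOLECULE")))
  p1 <- signalling_map("p1", entities = list(
    map_entity("w", name = "GLC", entity_class = "SIMPLE_MOLECULE",
               annotation = annotation(identifiers = c(CHEBI = "CHEBI:1")))))
  p2 <- signalling_map("p2", entities = list(
    map_entity("q", name = "OTHER", entity_class = "ION",
               annotation = annotation(identifiers = c(CHEBI = "CHEBI:1")))))
  expect_error(merge_maps(p1, p2), "conflict")
  # same name, different class namespaces do not collide
  expect_length(merge_maps(g1, g2)$entities, 2)
})
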