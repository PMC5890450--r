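test_that("read_celldesigner parses a generated dialect file with exact counts", {
  # 3 free proteins, 1 complex of 2 (one member its own species), 2 reactions
  # -> 5 species elements -> 5 entities, the complex counted once
  m <- signalling_map("five", entities = list(
    map_entity("p1", hugo = "AA"), map_entity("p2", hugo = "BB", x = 100),
    map_entity("p3", hugo = "CC", x = 200),
    map_entity("p4", hugo = "DD", x = 300),
    map_entity("cx", entity_class = "COMPLEX", members = c("p1", "p4"),
               y = 80, w = 120, h = 60)),
    reactions = list(
      map_reaction("r1", reactants = "p1", products = "p2"),
      map_reaction("r2", reaction_class = "ASSOCIATION",
                   reactants = c("p1", "p4"), products = "cx")))
  path <- withr::local_tempfile(fileext = ".xml")
  write_celldesigner(m, path)
  res <- read_celldesigner(path)
  expect_length(res$map$entities, 5)
  expect_length(res$map$reactions, 2)
  expect_equal(res$report$n_species, 5)
  expect_equal(res$report$n_reactions, 2)
  expect_equal(nrow(res$report$skipped), 0)
  expect_setequal(res$map$entities[["cx"]]$members, c("p1", "p4"))
})

test_that("empty model and plain SBML degrade gracefully", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(sprintf('<sbml xmlns="%s"><model id="empty"/></sbml>',
                     "http://www.sbml.org/sbml/level2"), path)
  res <- read_celldesigner(path)
  expect_length(res$map$entities, 0)
  expect_length(res$map$reactions, 0)
  # no CellDesigner extension -> warning entry in the report
  expect_true(any(grepl("CellDesigner", res$report$skipped$reason)))

  writeLines(c('<sbml xmlns="http://www.sbml.org/sbml/level2"><model id="m">',
               '<listOfSpecies><species id="s1" name="X"/></listOfSpecies>',
               '</model></sbml>'), path)
  res2 <- read_celldesigner(path)
  expect_equal(res2$map$entities[["s1"]]$entity_class, "UNKNOWN")

  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model>", bad)
  expect_error(read_celldesigner(bad))
  notsbml <- withr::local_tempfile(fileext = ".xml")
  writeLines("<foo/>", notsbml)
  expect_error(read_celldesigner(notsbml), "SBML")
})

test_that("an unsupported construct is skipped and reported, map unchanged", {
  m <- chain_map()
  path <- withr::local_tempfile(fileext = ".xml")
  write_celldesigner(m, path)
  base <- read_celldesigner(path)
  # inject a species element without an id: unparseable, must be skipped
  doc <- readLines(path)
  doc <- sub("<listOfSpecies>", '<listOfSpecies><species name="mystery"/>',
             doc, fixed = TRUE)
  path2 <- withr::local_tempfile(fileext = ".xml")
  writeLines(doc, path2)
  res <- read_celldesigner(path2)
  expect_map_equal(res$map, base$map)
  expect_equal(nrow(res$report$skipped), nrow(base$report$skipped) + 1)
})

test_that("canonical XML round-trip is the identity on fixture maps", {
  for (seed in c(1, 9)) {
    f <- make_fixture_map(fixture_spec(seed = seed, n_modules = 5))
    path <- withr::local_tempfile(fileext = ".xml")
    write_celldesigner(f$map, path)
    back <- read_celldesigner(path)$map
    expect_map_equal(back, f$map)
    # writing the re-read map reproduces the file byte-for-byte
    path2 <- withr::local_tempfile(fileext = ".xml")
    write_celldesigner(back, path2)
    expect_identical(readLines(path2), readLines(path))
  }
  # maps with compartments, modifications and scored annotations round-trip too
  m <- signalling_map("rich",
    entities = list(
      map_entity("a", hugo = "A", modifications = c("phosphorylated", "ub"),
                 compartment = "nuc",
                 annotation = annotation(
                   identifiers = c(UNIPROT = "P1"),
                   references = list(reference("11", "REVIEW"), reference("12")),
                   confidence = list(ref = 4L, func = 2L),
                   notes = "canonical")),
      map_entity("b", hugo = "B", x = 100, compartment = "nuc")),
    reactions = list(map_reaction("r", reactants = "a", products = "b",
                                  regulators = c(b = "INHIBITION"))),
    compartments = list(map_compartment("nuc", "nucleus", 0, 0, 250, 120)))
  path <- withr::local_tempfile(fileext = ".xml")
  write_celldesigner(m, path)
  expect_map_equal(read_celldesigner(path)$map, m)
})

test_that("parsing survives dropping any optional XML subtree", {
  f <- make_fixture_map(fixture_spec(seed = 2, n_modules = 3))
  path <- withr::local_tempfile(fileext = ".xml")
  write_celldesigner(f$map, path)
  doc <- xml2::read_xml(path)
  optional <- xml2::xml_find_all(
    doc, "//*[local-name()='notes' or local-name()='bounds' or
              local-name()='speciesIdentity' or local-name()='listOfModification'
              or local-name()='listOfModifiers' or local-name()='modelDisplay']")
  set.seed(5)
  for (i in sample(seq_along(optional), min(12, length(optional)))) {
    doc_i <- xml2::read_xml(path)
    all_i <- xml2::xml_find_all(
      doc_i, "//*[local-name()='notes' or local-name()='bounds' or
                local-name()='speciesIdentity' or local-name()='listOfModification'
                or local-name()='listOfModifiers' or local-name()='modelDisplay']")
    xml2::xml_remove(all_i[[i]])
    mut <- withr::local_tempfile(fileext = ".xml")
    xml2::write_xml(doc_i, mut)
    expect_no_error(read_celldesigner(mut))
  }
})

test_that("write_sif expands reactions into binary relations", {
  path <- withr::local_tempfile()
  # A -> B with catalyst C: 2 lines
  m <- signalling_map("s", entities = list(
    map_entity("A"), map_entity("B", x = 100), map_entity("C", y = 60)),
    reactions = list(map_reaction("r", reactants = "A", products = "B",
                                  regulators = c(C = "CATALYSIS"))))
  expect_equal(write_sif(m, path), 2)
  expect_setequal(readLines(path),
                  c("A\tSTATE_TRANSITION\tB", "C\tCATALYSIS\tB"))

  # association A + B -> AB, no regulators: 2 lines
  m2 <- signalling_map("s2", entities = list(
    map_entity("A"), map_entity("B", x = 100),
    map_entity("AB", entity_class = "COMPLEX", members = c("A", "B"), y = 80)),
    reactions = list(map_reaction("r", reaction_class = "ASSOCIATION",
                                  reactants = c("A", "B"), products = "AB")))
  expect_equal(write_sif(m2, path), 2)

  # empty map: 0 lines
  expect_equal(write_sif(signalling_map("e"), path), 0)

  # degradation uses the reserved sink token
  m3 <- signalling_map("d", entities = list(map_entity("A")),
    reactions = list(map_reaction("rd", reaction_class = "DEGRADATION",
                                  reactants = "A")))
  expect_equal(write_sif(m3, path), 1)
  expect_equal(readLines(path), "A\tDEGRADATION\t__degraded__")
})

test_that("SIF line count matches the brute-force expansion formula", {
  for (seed in c(4, 8)) {
    f <- make_fixture_map(fixture_spec(seed = seed, n_modules = 6))
    expected <- sum(vapply(f$map$reactions, function(r) {
      np <- max(1L, length(r$products))  # degradation sink counts as one target
      length(r$reactants) * np + length(r$regulators) * np
    }, numeric(1)))
    path <- withr::local_tempfile()
    expect_equal(write_sif(f$map, path), expected)
    expect_equal(length(readLines(path)), expected)
    # deterministic lexicographic order
    expect_identical(readLines(path), sort(readLines(path)))
  }
})

test_that("write_gmt flattens complexes and de-duplicates genes", {
  path <- withr::local_tempfile()
  # 18-module fixture -> 18 GMT lines
  f <- make_fixture_map(fixture_spec(seed = 1))
  ms <- modules_from_tags(f$map, layers = f$truth$layers)
  expect_equal(write_gmt(ms, f$map, path), 18)
  lines <- readLines(path)
  expect_equal(length(lines), 18)
  # description column is the layer name
  first <- strsplit(lines[1], "\t")[[1]]
  expect_true(first[2] %in% c("repair_machinery", "cell_cycle", "checkpoints"))

  # empty module set -> 0 lines
  expect_equal(write_gmt(module_set(), signalling_map("e"), path), 0)

  # a gene present both free and inside a complex appears once per module line
  m <- signalling_map("dup", entities = list(
    map_entity("p1", hugo = "G1",
               annotation = annotation(module_tags = data.frame(map = "m", module = "M1"))),
    map_entity("p1b", hugo = "G1", x = 100,
               annotation = annotation(module_tags = data.frame(map = "m", module = "M1"))),
    map_entity("cx", entity_class = "COMPLEX", members = "p1", y = 80,
               annotation = annotation(module_tags = data.frame(map = "m", module = "M1")))))
  expect_equal(write_gmt(modules_from_tags(m), m, path), 1)
  genes <- strsplit(readLines(path), "\t")[[1]][-(1:2)]
  expect_identical(genes, "G1")

  # module referencing a missing entity id errors
  bad <- module_set(list(map_module("M", entity_ids = "ghost")))
  expect_error(write_gmt(bad, m, path), "missing entity")
})
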