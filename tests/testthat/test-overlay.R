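mini_data <- function() {
  m <- matrix(c(2, 4, 1, 3), nrow = 2, byrow = TRUE,
              dimnames = list(c("G1", "G2"), c("s1", "s2")))
  overlay_dataset(m, groups = c(s1 = "G", s2 = "G"))
}

test_that("overlay_dataset validates its inputs", {
  expect_error(overlay_dataset(matrix(1:4, 2)), "rownames")
  m <- matrix(1:4, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  expect_error(overlay_dataset(m), "duplicate")
  m2 <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(overlay_dataset(m2, groups = c(zz = "G")), "unknown sample")
  d <- overlay_dataset(m2)
  expect_identical(rownames(d$values), c("G1", "G2"))  # upper-cased
})

test_that("aggregate_overlay computes NA-skipping group and family stats", {
  d <- mini_data()
  a <- aggregate_overlay(d, "GROUP", "MEAN")
  expect_equal(unname(a$values["G1", "G"]), 3.0)  # mean(2, 4)

  # one sample per group: aggregation is the identity on values
  d2 <- overlay_dataset(d$values, groups = c(s1 = "A", s2 = "B"))
  a2 <- aggregate_overlay(d2, "GROUP", "MEAN")
  expect_equal(unname(a2$values[, "A"]), unname(d$values[, "s1"]))
  expect_equal(unname(a2$values[, "B"]), unname(d$values[, "s2"]))

  # family median skips genes missing from the matrix and NA values
  m <- matrix(c(1, 3, NA), ncol = 1,
              dimnames = list(c("G1", "G2", "G3"), "s"))
  d3 <- overlay_dataset(m, families = list(F1 = c("G1", "G2", "G_ABSENT")))
  a3 <- aggregate_overlay(d3, "FAMILY", "MEDIAN")
  expect_equal(unname(a3$values["F1", "s"]), 2.0)

  # empty group after NA removal: NA cell plus warning
  m4 <- matrix(NA_real_, 1, 1, dimnames = list("G1", "s1"))
  d4 <- overlay_dataset(m4, groups = c(s1 = "A"))
  expect_warning(a4 <- aggregate_overlay(d4, "GROUP", "MEAN"), "no non-NA")
  expect_true(is.na(a4$values["G1", "A"]))
})

stained_map <- function() {
  signalling_map("st", entities = list(
    map_entity("a", hugo = "GA", x = 40, y = 40),
    map_entity("b", hugo = "GB", x = 400, y = 300),
    map_entity("cx", entity_class = "COMPLEX", members = "a", x = 40, y = 160)),
    width = 512, height = 400)
}

test_that("map_staining produces a Nadaraya-Watson field with a report", {
  m <- stained_map()
  one <- overlay_dataset(matrix(c(2, 2, 5), ncol = 1,
                                dimnames = list(c("GA", "GB", "GZ"), "v")))
  st <- map_staining(m, one)
  # reconciliation: matched + ignored = total
  expect_equal(st$report$n_genes, 3)
  expect_equal(st$report$n_matched, 2)
  expect_equal(st$report$n_ignored, 1)
  expect_equal(st$report$ignored, "GZ")

  # uniform value everywhere -> constant colour field
  unif <- overlay_dataset(matrix(c(3, 3), ncol = 1,
                                 dimnames = list(c("GA", "GB"), "v")))
  stu <- map_staining(m, unif)
  expect_true(all(abs(stu$field - 3) < 1e-9))
  expect_equal(length(unique(as.vector(stu$colors))), 1)

  # single stained entity: field constant, kernel weight strictly decreasing
  # with distance from the anchor along a sampled row
  solo <- overlay_dataset(matrix(7, 1, 1, dimnames = list("GB", "v")))
  sts <- map_staining(m, solo)
  iy <- which.min(abs(sts$y - (300 + 20)))   # row through the anchor
  ix0 <- which.min(abs(sts$x - (400 + 40)))  # column of the anchor centre
  right <- sts$weight[iy, ix0:length(sts$x)]
  expect_true(all(diff(right) < 0))
  expect_true(all(abs(sts$field - 7) < 1e-9))

  # invariant under permutation of entity enumeration order
  m_perm <- m
  m_perm$entities <- m_perm$entities[c(3, 1, 2)]
  expect_equal(map_staining(m_perm, one)$field, st$field)

  # all-NA data: NA-colour layer and a warning
  nas <- overlay_dataset(matrix(NA_real_, 1, 1, dimnames = list("GA", "v")))
  expect_warning(stn <- map_staining(m, nas), "NA")
  expect_true(all(is.na(stn$field)))
  expect_true(all(stn$colors == stn$scale$na_col))
})

test_that("opposite-sign regions stain with opposite mean field signs", {
  # two gene clusters on disjoint map regions with opposite planted signs
  left <- lapply(1:4, function(i)
    map_entity(paste0("l", i), hugo = paste0("L", i), x = 30, y = 30 + i * 40))
  right <- lapply(1:4, function(i)
    map_entity(paste0("r", i), hugo = paste0("R", i), x = 900, y = 30 + i * 40))
  m <- signalling_map("two_regions", entities = c(left, right),
                      width = 1000, height = 300)
  vals <- matrix(c(rep(-2, 4), rep(2, 4)), ncol = 1,
                 dimnames = list(c(paste0("L", 1:4), paste0("R", 1:4)), "v"))
  st <- map_staining(m, overlay_dataset(vals))
  left_cols <- st$x < 200; right_cols <- st$x > 800
  expect_lt(mean(st$field[, left_cols]), 0)
  expect_gt(mean(st$field[, right_cols]), 0)
})

test_that("place_glyphs anchors one glyph per flagged gene occurrence", {
  m <- stained_map()
  flag1 <- overlay_dataset(matrix(1, 1, 1, dimnames = list("GB", "mut")))
  g1 <- place_glyphs(m, flag1)
  expect_equal(nrow(g1$glyphs), 1)
  expect_equal(g1$glyphs$shape, 25)  # triangle

  # empty mutation list: no glyphs
  g0 <- place_glyphs(m, overlay_dataset(
    matrix(0, 1, 1, dimnames = list("GB", "mut"))))
  expect_equal(nrow(g0$glyphs), 0)

  # gene present at 3 map locations (free, duplicate, inside complex) -> 3 glyphs
  m3 <- signalling_map("multi", entities = list(
    map_entity("a1", hugo = "GX", x = 0),
    map_entity("a2", hugo = "GX", x = 200),
    map_entity("cx", entity_class = "COMPLEX", members = "a1", x = 0, y = 100)))
  g3 <- place_glyphs(m3, overlay_dataset(
    matrix(1, 1, 1, dimnames = list("GX", "mut"))))
  expect_equal(nrow(g3$glyphs), 3)
  # deterministic placement
  expect_identical(g3$glyphs,
                   place_glyphs(m3, overlay_dataset(
                     matrix(1, 1, 1, dimnames = list("GX", "mut"))))$glyphs)
  # unknown symbols are skipped and reported
  gz <- place_glyphs(m, overlay_dataset(
    matrix(1, 1, 1, dimnames = list("NOPE", "mut"))))
  expect_equal(nrow(gz$glyphs), 0)
  expect_equal(gz$report$n_ignored, 1)
  # glyphs at one entity stack horizontally at distinct x offsets
  two <- overlay_dataset(matrix(c(1, 1), 1, 2,
                                dimnames = list("GB", c("c1", "c2"))))
  g2 <- place_glyphs(m, two)
  expect_equal(nrow(g2$glyphs), 2)
  expect_false(g2$glyphs$x[1] == g2$glyphs$x[2])
})

test_that("entity_charts share one axis across the map", {
  m <- stained_map()
  vals <- matrix(c(1, 5, -2, 3), 2, 2,
                 dimnames = list(c("GA", "GB"), c("grpA", "grpB")))
  ch <- entity_charts(m, overlay_dataset(vals), "BARPLOT")
  expect_true(length(ch$charts) >= 2)
  for (c1 in ch$charts) {
    expect_length(c1$values, 2)      # one bar per column
    expect_equal(c1$ylim, ch$ylim)   # shared axis limits
  }
  # all-equal values give all-equal bars
  eqv <- matrix(2, 2, 2, dimnames = list(c("GA", "GB"), c("a", "b")))
  che <- entity_charts(m, overlay_dataset(eqv), "BARPLOT")
  expect_true(all(vapply(che$charts, function(x)
    length(unique(x$values)) == 1, logical(1))))
})

test_that("render_overlay_png composes all layers into a file", {
  m <- stained_map()
  one <- overlay_dataset(matrix(c(1, -1), ncol = 1,
                                dimnames = list(c("GA", "GB"), "v")))
  st <- map_staining(m, one)
  gl <- place_glyphs(m, overlay_dataset(
    matrix(1, 1, 1, dimnames = list("GA", "mut"))))
  ch <- entity_charts(m, one, "HEATMAP")
  path <- withr::local_tempfile(fileext = ".png")
  render_overlay_png(m, path, staining = st, glyphs = gl, charts = ch)
  expect_true(file.size(path) > 0)
})
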