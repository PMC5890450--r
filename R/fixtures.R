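#' @title Deterministic synthetic fixtures
#' @description
#' Generators for toy signalling maps, PPI networks and omics tables with
#' known ground truth, written to real on-disk files in the external
#' formats (CellDesigner XML, SIF, TSV, GMT) so the I/O code paths are
#' exercised end to end. The default map emulates the hierarchical
#' composition of a comprehensive DNA-repair-style map: 18 functional
#' modules (10 repair mechanisms + 4 cell-cycle phases + 4 checkpoints)
#' arranged in three layers. Every fixture is reproducible from
#' (spec, seed) alone, and the truth record lists each downstream expected
#' quantity.
#' @name fixtures
NULL

default_module_plan <- function() {
  data.frame(
    module = c("BER", "NER", "MMR", "HR", "NHEJ", "ALT_NHEJ", "SSA", "TLS",
               "FA", "DR",
               "G1", "S", "G2", "M",
               "G1S_CHECKPOINT", "INTRA_S_CHECKPOINT", "G2M_CHECKPOINT",
               "SAC"),
    layer = c(rep("repair_machinery", 10), rep("cell_cycle", 4),
              rep("checkpoints", 4)),
    stringsAsFactors = FALSE)
}

#' Fixture specification
#'
#' Defaults encode the stated world the fixtures emulate: an 18-module
#' map (ten repair mechanisms, four cell-cycle phases, four checkpoints),
#' a modest PPI graph with planted distances, and a two-group omics
#' contrast with 50 samples per group.
#'
#' @param seed integer master seed.
#' @param n_modules number of modules (default 18, named after the
#'   default composition; beyond 18 modules get generic names).
#' @param entities_per_module proteins drawn per module (default 4).
#' @param complex_fraction fraction of modules that also receive one
#'   two-member complex (default 0.25).
#' @param ppi list: `n_nodes`, `model` (`"path"`, `"ring"`, `"complete"`,
#'   `"er"`), `p` (ER edge probability), `plant_disconnected` (add an
#'   isolated component).
#' @param omics list: `n_samples` per group (default 50), `effect` planted
#'   group-mean shift (default 2), `na_fraction` (default 0.05),
#'   `n_genes` extra unshifted genes.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_modules = 18L, entities_per_module = 4L,
                         complex_fraction = 0.25,
                         ppi = list(), omics = list()) {
  stopifnot(n_modules >= 0, entities_per_module >= 0,
            complex_fraction >= 0, complex_fraction <= 1)
  ppi <- utils::modifyList(list(n_nodes = 12L, model = "path", p = 0.2,
                                plant_disconnected = FALSE), ppi)
  omics <- utils::modifyList(list(n_samples = 50L, effect = 2, na_fraction = 0.05,
                                  n_genes = 20L), omics)
  structure(list(seed = as.integer(seed), n_modules = as.integer(n_modules),
                 entities_per_module = as.integer(entities_per_module),
                 complex_fraction = complex_fraction, ppi = ppi, omics = omics),
            class = "fixture_spec")
}

fixture_gene <- function(i) sprintf("GENE%03d", i)

#' Generate a toy CellDesigner map with known truth
#'
#' Builds `n_modules` modules, each a chain of reactions over
#' `entities_per_module` tagged proteins, with one hub protein per layer
#' wired into every module of that layer (planted high participation
#' degree), optional two-member complexes, and canonical-pathway notes on
#' the first entity of each module. The map is written as
#' CellDesigner-dialect XML.
#'
#' @param spec a [fixture_spec()].
#' @param path output XML path; `NULL` keeps the map in memory only.
#' @return list with `map` (the [signalling_map()]), `path`, and `truth`:
#'   module names and layers, entity/reaction/complex counts, hub ids and
#'   their planted degrees, per-module membership, canonical entity ids.
#' @export
make_fixture_map <- function(spec = fixture_spec(), path = NULL) {
  plan <- default_module_plan()
  n <- spec$n_modules
  if (n <= nrow(plan)) plan <- plan[seq_len(n), , drop = FALSE] else {
    extra <- n - nrow(plan)
    plan <- rbind(plan, data.frame(
      module = sprintf("MODULE_%02d", seq_len(extra)),
      layer = "extra", stringsAsFactors = FALSE))
  }
  ents <- list(); rxs <- list(); gene_i <- 0L
  layers_of <- stats::setNames(plan$layer, plan$module)
  membership <- list(); canonical_ids <- character()
  hub_ids <- character()
  mk_tag <- function(module) data.frame(map = "toy_map", module = module,
                                        stringsAsFactors = FALSE)
  complex_modules <- if (n > 0)
    seq_len(n)[seq_len(n) %% max(1L, round(1 / max(spec$complex_fraction, 1e-9))) == 1L &
                 spec$complex_fraction > 0]
  else integer()
  withr_seed(spec$seed, {
    for (mi in seq_len(n)) {
      mod <- plan$module[mi]
      ids <- character()
      for (j in seq_len(spec$entities_per_module)) {
        gene_i <- gene_i + 1L
        id <- sprintf("e_%s_%d", mod, j)
        note <- if (j == 1L) "canonical" else character()
        ents[[id]] <- map_entity(
          id, name = fixture_gene(gene_i), hugo = fixture_gene(gene_i),
          x = ((mi - 1) %% 6) * 320 + (j - 1) * 40,
          y = ((mi - 1) %/% 6) * 280 + (j - 1) * 50,
          w = 70, h = 30,
          annotation = annotation(module_tags = mk_tag(mod),
                                  references = list(reference(paste0("70", gene_i))),
                                  notes = note))
        if (j == 1L) canonical_ids <- c(canonical_ids, id)
        ids <- c(ids, id)
      }
      # chain reactions through the module
      for (j in seq_len(max(0L, length(ids) - 1L))) {
        rid <- sprintf("r_%s_%d", mod, j)
        rxs[[rid]] <- map_reaction(
          rid, reactants = ids[j], products = ids[j + 1],
          annotation = annotation(references = list(
            reference(sprintf("80%03d%02d", mi, j), kind = "REVIEW"))))
      }
      membership[[mod]] <- ids
      if (mi %in% complex_modules && length(ids) >= 2) {
        cid <- sprintf("cx_%s", mod)
        ents[[cid]] <- map_entity(
          cid, name = paste0(mod, "_complex"), entity_class = "COMPLEX",
          members = ids[1:2],
          x = ((mi - 1) %% 6) * 320 + 160, y = ((mi - 1) %/% 6) * 280 + 160,
          w = 90, h = 60,
          annotation = annotation(module_tags = mk_tag(mod),
                                  references = list(reference(paste0("90", mi),
                                                              kind = "REVIEW"))))
        membership[[mod]] <- c(membership[[mod]], cid)
        rid <- sprintf("r_%s_cx", mod)
        rxs[[rid]] <- map_reaction(rid, reaction_class = "ASSOCIATION",
                                   reactants = ids[1:2], products = cid)
      }
    }
    # one hub per layer, wired into every module of its layer as a catalyst
    for (ly in unique(plan$layer)) {
      mods <- plan$module[plan$layer == ly]
      first_rx <- sprintf("r_%s_1", mods)
      first_rx <- first_rx[first_rx %in% names(rxs)]
      if (!length(first_rx)) next
      gene_i <- gene_i + 1L
      hid <- sprintf("hub_%s", ly)
      ents[[hid]] <- map_entity(
        hid, name = fixture_gene(gene_i), hugo = fixture_gene(gene_i),
        x = 20, y = 20 + 60 * length(hub_ids), w = 70, h = 30,
        annotation = annotation(
          module_tags = do.call(rbind, lapply(mods, mk_tag)),
          notes = c("backbone", "canonical")))
      for (rid in first_rx) {
        regs <- rxs[[rid]]$regulators
        regs[[hid]] <- "CATALYSIS"
        rxs[[rid]] <- map_reaction(rxs[[rid]]$id, rxs[[rid]]$reaction_class,
                                   rxs[[rid]]$reactants, rxs[[rid]]$products,
                                   regs, rxs[[rid]]$annotation)
      }
      hub_ids <- c(hid, hub_ids)
      hub_ids <- sort(hub_ids)
    }
  })
  map <- signalling_map(name = "toy_map", entities = unname(ents),
                        reactions = unname(rxs))
  deg <- participation_degree(map)
  truth <- list(modules = plan$module, layers = layers_of,
                n_modules = n,
                n_entities = length(ents), n_reactions = length(rxs),
                n_complexes = sum(vapply(ents, function(e)
                  e$entity_class == "COMPLEX", logical(1))),
                membership = membership,
                hub_ids = hub_ids, hub_degrees = deg[hub_ids],
                canonical_ids = sort(c(canonical_ids, hub_ids)),
                genes = vapply(ents, function(e) e$hugo %||% NA_character_,
                               character(1)))
  if (!is.null(path)) write_celldesigner(map, path)
  list(map = map, path = path, truth = truth)
}

#' Generate a PPI network with planted distances
#'
#' Path graphs give exact distances 1..n-1 between numbered nodes, rings
#' and complete graphs their closed-form distances, and Erdős–Rényi
#' graphs random topology; a disconnected pair can be planted on demand.
#' Truth distances are computed by BFS at generation time.
#'
#' @param spec a [fixture_spec()] (fields under `spec$ppi`).
#' @param path output SIF path; `NULL` keeps the network in memory.
#' @param symbols node names; defaults to `GENE001..`.
#' @return list with `ppi` (a [ppi_network()]), `path`, and `truth`:
#'   the edge list, the full BFS distance matrix (`Inf` = disconnected)
#'   and, if planted, the disconnected pair.
#' @export
make_fixture_ppi <- function(spec = fixture_spec(), path = NULL,
                             symbols = NULL) {
  n <- spec$ppi$n_nodes
  if (is.null(symbols)) symbols <- vapply(seq_len(n), fixture_gene, character(1))
  stopifnot(length(symbols) == n)
  edges <- switch(spec$ppi$model,
    path = if (n >= 2) cbind(symbols[-n], symbols[-1]),
    ring = if (n >= 3) rbind(cbind(symbols[-n], symbols[-1]),
                             c(symbols[n], symbols[1]))
           else if (n == 2) cbind(symbols[1], symbols[2]),
    complete = if (n >= 2) t(utils::combn(symbols, 2)),
    er = withr_seed(spec$seed, {
      all_pairs <- t(utils::combn(symbols, 2))
      keep <- stats::runif(nrow(all_pairs)) < spec$ppi$p
      # keep the graph non-empty for degenerate draws
      if (!any(keep)) keep[1] <- TRUE
      all_pairs[keep, , drop = FALSE]
    }),
    stop("unknown ppi model: ", spec$ppi$model))
  if (is.null(edges)) edges <- matrix(character(), ncol = 2)
  disconnected_pair <- NULL
  if (isTRUE(spec$ppi$plant_disconnected)) {
    iso <- c("ISOLATED1", "ISOLATED2")
    edges <- rbind(edges, iso)
    disconnected_pair <- c(symbols[1], iso[1])
  }
  ppi <- ppi_network(edges, provenance = paste0("fixture:", spec$ppi$model))
  D <- igraph::distances(ppi$graph)
  if (!is.null(path)) {
    lines <- sort(paste(edges[, 1], "pp", edges[, 2], sep = "\t"))
    writeLines(lines, path, useBytes = TRUE)
  }
  list(ppi = ppi, path = path,
       truth = list(edges = edges, distances = D,
                    disconnected_pair = disconnected_pair))
}

#' Generate a two-group omics table with planted effects
#'
#' Gaussian values (sd 1) for `n_genes` genes over two sample groups, A
#' and B, with a planted mean shift: genes of the shifted set are centred
#' at `-effect/2` in group A and `+effect/2` in group B (emulating an
#' expression contrast between two disease classes); the remaining genes
#' are centred at 0 in both. A chosen gene subset carries binary mutation
#' flags in group A. Missing values are injected at the specified rate.
#'
#' @param spec a [fixture_spec()] (fields under `spec$omics`; `seed` used).
#' @param dir output directory for `expression.tsv`, `groups.tsv`,
#'   `mutations.tsv`; `NULL` keeps data in memory.
#' @param genes gene symbols; defaults to `GENE001..`; the first quarter
#'   (at least one) is the shifted set.
#' @return list with `data` (an [overlay_dataset()] with groups),
#'   `mutations` (an [overlay_dataset()] of per-group flags), `paths`,
#'   and `truth`: planted means per group, shifted gene set, mutated
#'   genes, NA fraction.
#' @export
make_fixture_omics <- function(spec = fixture_spec(), dir = NULL,
                               genes = NULL) {
  o <- spec$omics
  if (is.null(genes))
    genes <- vapply(seq_len(o$n_genes), fixture_gene, character(1))
  ns <- o$n_samples
  shifted <- genes[seq_len(max(1L, length(genes) %/% 4L))]
  samples <- c(sprintf("A%02d", seq_len(ns)), sprintf("B%02d", seq_len(ns)))
  groups <- stats::setNames(rep(c("A", "B"), each = ns), samples)
  mu <- matrix(0, length(genes), 2, dimnames = list(genes, c("A", "B")))
  mu[shifted, "A"] <- -o$effect / 2
  mu[shifted, "B"] <- +o$effect / 2
  vals <- withr_seed(spec$seed + 1L, {
    m <- matrix(stats::rnorm(length(genes) * length(samples)),
                length(genes), length(samples),
                dimnames = list(genes, samples))
    m <- m + mu[, groups[samples]]
    if (o$na_fraction > 0) {
      nas <- stats::runif(length(m)) < o$na_fraction
      m[nas] <- NA_real_
    }
    m
  })
  mut_genes <- shifted[seq_len(max(1L, length(shifted) %/% 2L))]
  mut <- matrix(0, length(genes), 2, dimnames = list(genes, c("A", "B")))
  mut[mut_genes, "A"] <- 1
  data <- overlay_dataset(vals, groups = groups)
  mutations <- overlay_dataset(mut)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(expression = file.path(dir, "expression.tsv"),
                  groups = file.path(dir, "groups.tsv"),
                  mutations = file.path(dir, "mutations.tsv"))
    write_tsv_matrix(vals, paths$expression)
    utils::write.table(data.frame(sample = samples, group = groups[samples]),
                       paths$groups, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    write_tsv_matrix(mut, paths$mutations)
  }
  list(data = data, mutations = mutations, paths = paths,
       truth = list(group_means = mu, shifted_genes = shifted,
                    mutated_genes = mut_genes, na_fraction = o$na_fraction,
                    effect = o$effect))
}

write_tsv_matrix <- function(m, path) {
  df <- data.frame(GENE = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
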