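#' @title REF and FUNC confidence scores
#' @description
#' Two integer confidence scores, both ranging 0 (undefined) to 5 (high
#' confidence), evaluate the reliability of reactions and protein
#' complexes on a map. The reference score REF weighs the publications in
#' the annotation (1 point per original article, 3 per review, capped at
#' 5). The functional-proximity score FUNC reflects the average shortest-
#' path distance in an external protein-protein interaction (PPI) network
#' between all proteins participating in a reaction: all participants
#' adjacent (distance 1) scores 5, a pair 2 (3, 4) edges apart scores
#' 4 (3, 2), and participants in different components score 0.
#' @name confidence
NULL

#' Build a PPI network from an edge list
#'
#' @param edges two-column matrix/data frame of interacting gene symbols,
#'   or a character vector path handled by [read_ppi()]. Symbols are
#'   upper-cased and trimmed; self-loops and duplicate edges are dropped.
#' @param provenance free-text provenance label (e.g. the source database).
#' @return An object of class `ppi_network` wrapping an undirected simple
#'   igraph graph.
#' @export
ppi_network <- function(edges, provenance = "user-supplied") {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2, byrow = TRUE)
  stopifnot(ncol(edges) >= 2)
  a <- toupper(trimws(as.character(edges[, 1])))
  b <- toupper(trimws(as.character(edges[, ncol(edges)])))
  keep <- a != b & nzchar(a) & nzchar(b)
  g <- igraph::graph_from_edgelist(cbind(a[keep], b[keep]), directed = FALSE)
  g <- igraph::simplify(g)
  structure(list(graph = g, provenance = as.character(provenance)),
            class = "ppi_network")
}

#' Read a PPI network from a SIF-style file
#'
#' Accepts 2-column (`A<TAB>B`) or 3-column (`A<TAB>relation<TAB>B`)
#' tab-separated files; the network is undirected and de-duplicated.
#'
#' @param path file path.
#' @param provenance provenance label recorded on the network (defaults to
#'   the file name).
#' @return A [ppi_network()].
#' @export
read_ppi <- function(path, provenance = basename(path)) {
  rows <- strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE)
  rows <- rows[lengths(rows) >= 2]
  el <- t(vapply(rows, function(r) c(r[[1]], r[[length(r)]]), character(2)))
  ppi_network(el, provenance = provenance)
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d proteins, %d interactions (%s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$provenance))
  invisible(x)
}

#' Reference confidence score (REF)
#'
#' `raw = 1 * n_original + 3 * n_review`, capped at 5; an empty reference
#' list scores 0 (undefined confidence). Two reviews therefore reach the
#' maximal REF = 5.
#'
#' @param references list of [reference()] objects.
#' @param breakdown return the breakdown alongside the score.
#' @return integer in 0..5, or (with `breakdown = TRUE`) a list with
#'   `score`, `n_original`, `n_review`, `raw_weight`.
#' @export
ref_score <- function(references, breakdown = FALSE) {
  kinds <- vapply(references, `[[`, character(1), "kind")
  n_orig <- sum(kinds == "ORIGINAL")
  n_rev <- sum(kinds == "REVIEW")
  raw <- n_orig + 3L * n_rev
  score <- if (length(references) == 0L) 0L else min(5L, raw)
  if (!breakdown) return(as.integer(score))
  list(score = as.integer(score), n_original = n_orig, n_review = n_rev,
       raw_weight = raw)
}

#' Shortest-path distance between two proteins in the PPI network
#'
#' @param a,b HUGO symbols (case-insensitive).
#' @param ppi a [ppi_network()].
#' @return non-negative integer path length (`0` iff `a == b`), or the
#'   string `"DISCONNECTED"` if both symbols are present but in different
#'   components, or `"ABSENT"` if either symbol is not a network node.
#' @export
ppi_distance <- function(a, b, ppi) {
  stopifnot(inherits(ppi, "ppi_network"))
  a <- toupper(trimws(a)); b <- toupper(trimws(b))
  nodes <- igraph::V(ppi$graph)$name
  if (!(a %in% nodes) || !(b %in% nodes)) return("ABSENT")
  if (a == b) return(0L)
  d <- igraph::distances(ppi$graph, v = a, to = b)[1, 1]
  if (is.infinite(d)) "DISCONNECTED" else as.integer(d)
}

round_half_up <- function(x) floor(x + 0.5)

# core FUNC rule given a vector of participant symbols
func_score_symbols <- function(symbols, ppi, breakdown = FALSE) {
  symbols <- sort(unique(toupper(trimws(symbols))))
  mk <- function(score, dists, mean_d) {
    if (!breakdown) return(as.integer(score))
    list(score = as.integer(score), pair_distances = dists, mean_distance = mean_d)
  }
  if (length(symbols) < 2L) return(mk(0L, list(), "undefined"))
  pairs <- utils::combn(symbols, 2L, simplify = FALSE)
  dists <- lapply(pairs, function(p) ppi_distance(p[1], p[2], ppi))
  names(dists) <- vapply(pairs, paste, character(1), collapse = "|")
  if (any(vapply(dists, identical, logical(1), "ABSENT")))
    return(mk(0L, dists, "undefined"))
  if (any(vapply(dists, identical, logical(1), "DISCONNECTED")))
    return(mk(0L, dists, "disconnected"))
  dbar <- mean(unlist(dists))
  score <- max(1L, min(5L, 6L - round_half_up(dbar)))
  mk(score, dists, dbar)
}

#' Functional-proximity confidence score (FUNC)
#'
#' Collects the protein participants of a reaction with
#' [participant_proteins()] (complexes flattened to their protein members)
#' and scores their mutual proximity in the PPI network: with fewer than
#' two participants or any symbol absent from the network the score is 0
#' (undefined); with any pair in different components it is 0
#' (disconnected); otherwise the mean over all unordered pairwise
#' shortest-path distances `d` gives `clamp(6 - round_half_up(d), 1, 5)`,
#' so distance 1 scores 5, 2 scores 4, 3 scores 3, 4 scores 2 and any
#' remoter but connected set scores 1.
#'
#' @param reaction a [map_reaction()] belonging to `map`.
#' @param map the [signalling_map()].
#' @param ppi a [ppi_network()].
#' @param breakdown return pair distances and mean distance too.
#' @return integer in 0..5, or a breakdown list.
#' @export
func_score <- function(reaction, map, ppi, breakdown = FALSE) {
  func_score_symbols(participant_proteins(reaction, map), ppi, breakdown)
}

#' Score every reaction and complex of a map
#'
#' Writes a REF/FUNC confidence entry into the annotation of every
#' reaction and every COMPLEX entity: FUNC from the flattened protein
#' participants (members, for a complex), REF from the reaction's or
#' complex's own references. Idempotent: re-running overwrites the same
#' values.
#'
#' @param map a [signalling_map()].
#' @param ppi a [ppi_network()].
#' @return list with `map` (the scored map) and `scores` (a data frame:
#'   id, kind, ref, func, n_original, n_review, mean_distance).
#' @export
score_map <- function(map, ppi) {
  rows <- list()
  set_conf <- function(ann, ref, func) {
    annotation(ann$identifiers, ann$module_tags, ann$references,
               list(ref = ref, func = func), ann$notes)
  }
  for (rid in names(map$reactions)) {
    r <- map$reactions[[rid]]
    rb <- ref_score(r$annotation$references, breakdown = TRUE)
    fb <- func_score(r, map, ppi, breakdown = TRUE)
    map$reactions[[rid]]$annotation <- set_conf(r$annotation, rb$score, fb$score)
    rows[[length(rows) + 1L]] <- data.frame(
      id = rid, kind = "reaction", ref = rb$score, func = fb$score,
      n_original = rb$n_original, n_review = rb$n_review,
      mean_distance = as.character(fb$mean_distance))
  }
  for (eid in names(map$entities)) {
    e <- map$entities[[eid]]
    if (e$entity_class != "COMPLEX") next
    rb <- ref_score(e$annotation$references, breakdown = TRUE)
    fb <- func_score_symbols(unlist(lapply(e$members, flatten_proteins, map = map)),
                             ppi, breakdown = TRUE)
    map$entities[[eid]]$annotation <- set_conf(e$annotation, rb$score, fb$score)
    rows[[length(rows) + 1L]] <- data.frame(
      id = eid, kind = "complex", ref = rb$score, func = fb$score,
      n_original = rb$n_original, n_review = rb$n_review,
      mean_distance = as.character(fb$mean_distance))
  }
  scores <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), kind = character(), ref = integer(),
               func = integer(), n_original = integer(), n_review = integer(),
               mean_distance = character())
  rownames(scores) <- NULL
  list(map = map, scores = scores)
}
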