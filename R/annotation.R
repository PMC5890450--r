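#' Structured entity annotation
#'
#' Entities and reactions carry a structured annotation with four sections:
#' `Identifiers` (standard identifiers keyed by namespace, e.g. HUGO,
#' UNIPROT, ENTREZ, CHEBI), `Maps_Modules` (tags naming the maps and
#' functional modules where the entity participates), `References`
#' (publications supporting the depicted interaction) and `Confidence`
#' (the two integer confidence scores, REF and FUNC). Free-text curator
#' notes are preserved verbatim.
#'
#' @param identifiers named character vector, namespace -> identifier
#'   (e.g. `c(HUGO = "BRCA1")`). Namespaces are upper-cased.
#' @param module_tags data frame with columns `map` and `module`; `module`
#'   may be `NA` for a map-level tag. Duplicate tags are dropped.
#' @param references list of [reference()] objects.
#' @param confidence `NULL`, or a list with integer elements `ref` and
#'   `func`, each in 0..5 (`NA` allowed for a not-yet-computed score).
#' @param notes character vector of free-text note lines.
#' @return An object of class `map_annotation`.
#' @export
annotation <- function(identifiers = character(), module_tags = empty_tags(),
                       references = list(), confidence = NULL,
                       notes = character()) {
  identifiers <- as.character(identifiers) |>
    stats::setNames(toupper(names(identifiers) %||% character()))
  if (!is.data.frame(module_tags)) stop("module_tags must be a data frame")
  module_tags <- normalise_tags(module_tags)
  stopifnot(all(vapply(references, inherits, logical(1), "map_reference")))
  if (!is.null(confidence)) {
    confidence <- list(ref = as.integer(confidence$ref),
                       func = as.integer(confidence$func))
    ok <- function(s) is.na(s) || (s >= 0L && s <= 5L)
    if (!ok(confidence$ref) || !ok(confidence$func))
      stop("confidence scores must be integers in [0, 5]")
  }
  structure(list(identifiers = identifiers, module_tags = module_tags,
                 references = references, confidence = confidence,
                 notes = as.character(notes)),
            class = "map_annotation")
}

empty_tags <- function() {
  data.frame(map = character(), module = character(),
             stringsAsFactors = FALSE)
}

normalise_tags <- function(tags) {
  tags <- data.frame(map = as.character(tags$map),
                     module = as.character(tags$module),
                     stringsAsFactors = FALSE)
  tags <- unique(tags)
  tags <- tags[order(tags$map, tags$module, na.last = TRUE), , drop = FALSE]
  rownames(tags) <- NULL
  tags
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Literature reference
#'
#' A single supporting publication. Review articles weigh more than original
#' research articles when the REF confidence score is computed (3 points vs
#' 1 point).
#'
#' @param identifier PubMed-style identifier (non-empty string).
#' @param kind `"ORIGINAL"` or `"REVIEW"`.
#' @param note optional free-text curator note attached to this reference.
#' @return An object of class `map_reference`.
#' @export
reference <- function(identifier, kind = c("ORIGINAL", "REVIEW"), note = NULL) {
  identifier <- as.character(identifier)
  if (length(identifier) != 1L || !nzchar(identifier))
    stop("reference identifier must be a non-empty string")
  kind <- match.arg(kind)
  structure(list(identifier = identifier, kind = kind,
                 note = if (!is.null(note)) as.character(note)),
            class = "map_reference")
}

# ---------------------------------------------------------------------------
# Annotation dialect: plain-text serialisation used inside CellDesigner
# notes blocks. Section headers are case-insensitive and order-free; lines
# that match no known grammar are preserved as notes.
# ---------------------------------------------------------------------------

#' Parse the plain-text annotation dialect
#'
#' Recognised constructs, grouped under the (case-insensitive) section
#' headers `Identifiers:`, `Maps_Modules:`, `References:`, `Confidence:`:
#' \itemize{
#'   \item `NAMESPACE:id` identifier lines (e.g. `HUGO:BRCA1`)
#'   \item `MAP:<map>` and `MODULE:<map>:<module>` tags
#'   \item `PMID:<id>` reference lines, optionally suffixed `[review]`
#'   \item `REF=<0-5>` / `FUNC=<0-5>` confidence lines
#' }
#' Unknown lines are kept verbatim in `notes`; malformed tag lines are
#' reported via a warning but never dropped silently. Missing sections
#' yield empty fields.
#'
#' @param text character scalar (may contain newlines) or vector of lines.
#' @return A [annotation()] object.
#' @export
parse_annotation <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  ids <- character(); tags <- empty_tags(); refs <- list()
  conf_ref <- NA_integer_; conf_func <- NA_integer_; have_conf <- FALSE
  notes <- character()
  section <- NA_character_
  sections <- c("identifiers", "maps_modules", "references", "confidence")
  for (ln in lines) {
    hdr <- tolower(sub(":\\s*$", "", ln))
    if (grepl(":\\s*$", ln) && hdr %in% sections) { section <- hdr; next }
    if (grepl("^MAP:", ln)) {
      nm <- sub("^MAP:", "", ln)
      if (nzchar(nm)) {
        tags <- rbind(tags, data.frame(map = nm, module = NA_character_))
      } else {
        warning("malformed tag line kept as note: ", ln)
        notes <- c(notes, ln)
      }
      next
    }
    if (grepl("^MODULE:", ln)) {
      parts <- strsplit(sub("^MODULE:", "", ln), ":", fixed = TRUE)[[1]]
      if (length(parts) == 2L && all(nzchar(parts))) {
        tags <- rbind(tags, data.frame(map = parts[1], module = parts[2]))
      } else {
        warning("malformed tag line kept as note: ", ln)
        notes <- c(notes, ln)
      }
      next
    }
    if (grepl("^PMID:", ln)) {
      body <- sub("^PMID:\\s*", "", ln)
      kind <- if (grepl("\\[review\\]\\s*$", body, ignore.case = TRUE))
        "REVIEW" else "ORIGINAL"
      id <- trimws(sub("\\[review\\]\\s*$", "", body, ignore.case = TRUE))
      if (nzchar(id)) { refs[[length(refs) + 1L]] <- reference(id, kind); next }
    }
    if (grepl("^REF\\s*=\\s*[0-5]$", ln)) {
      conf_ref <- as.integer(sub("^REF\\s*=\\s*", "", ln)); have_conf <- TRUE
      next
    }
    if (grepl("^FUNC\\s*=\\s*[0-5]$", ln)) {
      conf_func <- as.integer(sub("^FUNC\\s*=\\s*", "", ln)); have_conf <- TRUE
      next
    }
    if (identical(section, "identifiers") && grepl("^[A-Za-z][A-Za-z0-9_]*:.+$", ln)) {
      ns <- toupper(sub(":.*$", "", ln))
      ids[[ns]] <- sub("^[^:]+:", "", ln)
      next
    }
    notes <- c(notes, ln)
  }
  annotation(identifiers = ids, module_tags = tags, references = refs,
             confidence = if (have_conf) list(ref = conf_ref, func = conf_func),
             notes = notes)
}

#' Serialise an annotation to the plain-text dialect
#'
#' Inverse of [parse_annotation()]: sections are emitted in the fixed order
#' Identifiers, Maps_Modules, References, Confidence, followed by note
#' lines, so that `parse_annotation(serialise_annotation(a))` reproduces
#' `a` exactly.
#'
#' @param ann a [annotation()] object.
#' @return character scalar.
#' @export
serialise_annotation <- function(ann) {
  stopifnot(inherits(ann, "map_annotation"))
  out <- character()
  if (length(ann$identifiers)) {
    out <- c(out, "Identifiers:",
             paste0(names(ann$identifiers), ":", ann$identifiers))
  }
  if (nrow(ann$module_tags)) {
    t <- ann$module_tags
    out <- c(out, "Maps_Modules:",
             ifelse(is.na(t$module), paste0("MAP:", t$map),
                    paste0("MODULE:", t$map, ":", t$module)))
  }
  if (length(ann$references)) {
    out <- c(out, "References:",
             vapply(ann$references, function(r) {
               paste0("PMID:", r$identifier,
                      if (r$kind == "REVIEW") " [review]" else "")
             }, character(1)))
  }
  if (!is.null(ann$confidence)) {
    out <- c(out, "Confidence:")
    if (!is.na(ann$confidence$ref))
      out <- c(out, paste0("REF=", ann$confidence$ref))
    if (!is.na(ann$confidence$func))
      out <- c(out, paste0("FUNC=", ann$confidence$func))
  }
  out <- c(out, ann$notes)
  paste(out, collapse = "\n")
}

# default table of hyperlink templates, namespace -> sprintf template
default_url_templates <- function() {
  c(HUGO   = "https://www.genenames.org/tools/search/#!/?query=%s",
    UNIPROT = "https://www.uniprot.org/uniprotkb/%s",
    ENTREZ = "https://www.ncbi.nlm.nih.gov/gene/%s",
    CHEBI  = "https://www.ebi.ac.uk/chebi/searchId.do?chebiId=%s",
    PMID   = "https://pubmed.ncbi.nlm.nih.gov/%s/")
}

five_stars <- function(score) {
  if (is.null(score) || is.na(score)) return("")
  paste0(strrep("★", score), strrep("☆", 5L - score))
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render an entity annotation post
#'
#' Produces a self-contained static HTML page for one entity: the four
#' annotation sections in fixed order, a hyperlink per identifier whose
#' namespace appears in the URL template table (unknown namespaces are shown
#' without a link), one anchor per module tag and a five-star rendering of
#' each confidence score. Output is a pure function of the entity, so
#' identical input gives byte-identical output.
#'
#' @param entity a [map_entity()].
#' @param url_templates named character vector of sprintf-style templates,
#'   namespace -> URL; defaults cover HUGO/UNIPROT/ENTREZ/CHEBI/PMID.
#' @return character scalar containing an HTML document.
#' @export
render_post <- function(entity, url_templates = default_url_templates()) {
  stopifnot(inherits(entity, "map_entity"))
  ann <- entity$annotation
  li <- function(x) paste0("  <li>", x, "</li>")
  id_items <- character()
  if (length(ann$identifiers)) {
    ns <- names(ann$identifiers)
    id_items <- vapply(seq_along(ns), function(i) {
      v <- html_escape(ann$identifiers[[i]])
      if (ns[i] %in% names(url_templates)) {
        url <- sprintf(url_templates[[ns[i]]], ann$identifiers[[i]])
        li(sprintf("%s: <a href=\"%s\">%s</a>", ns[i], html_escape(url), v))
      } else li(sprintf("%s: %s", ns[i], v))
    }, character(1))
  }
  tag_items <- character()
  if (nrow(ann$module_tags)) {
    t <- ann$module_tags
    lab <- ifelse(is.na(t$module), t$map, paste0(t$map, ":", t$module))
    anchor <- gsub("[^A-Za-z0-9_]", "_", lab)
    tag_items <- li(sprintf("<a class=\"module-anchor\" href=\"#%s\">%s</a>",
                            anchor, html_escape(lab)))
  }
  ref_items <- character()
  if (length(ann$references)) {
    ref_items <- vapply(ann$references, function(r) {
      v <- html_escape(r$identifier)
      lnk <- if ("PMID" %in% names(url_templates))
        sprintf("<a href=\"%s\">PMID:%s</a>",
                html_escape(sprintf(url_templates[["PMID"]], r$identifier)), v)
      else paste0("PMID:", v)
      li(paste0(lnk, if (r$kind == "REVIEW") " [review]" else ""))
    }, character(1))
  }
  conf_items <- character()
  if (!is.null(ann$confidence)) {
    if (!is.na(ann$confidence$ref))
      conf_items <- c(conf_items, li(sprintf(
        "REF: <span class=\"stars\">%s</span>", five_stars(ann$confidence$ref))))
    if (!is.na(ann$confidence$func))
      conf_items <- c(conf_items, li(sprintf(
        "FUNC: <span class=\"stars\">%s</span>", five_stars(ann$confidence$func))))
  }
  section <- function(title, items) {
    c(sprintf("<h2>%s</h2>", title), "<ul>", items, "</ul>")
  }
  paste(c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\">",
          sprintf("<title>%s</title>", html_escape(entity$name)),
          "</head><body>",
          sprintf("<h1>%s</h1>", html_escape(entity$name)),
          section("Identifiers", id_items),
          section("Maps_Modules", tag_items),
          section("References", ref_items),
          section("Confidence", conf_items),
          if (length(ann$notes))
            c("<h2>Notes</h2>", "<pre>",
              html_escape(ann$notes), "</pre>"),
          "</body></html>"),
        collapse = "\n")
}
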