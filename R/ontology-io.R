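#' Construct an ontology object
#'
#' An ontology bundles a class table and an axiom table. Classes carry a
#' CURIE-style identifier (`"GO:0005634"`), an optional label and an optional
#' textual definition. Axioms are either plain subclass axioms
#' (`subject SubClassOf object`) or subclass axioms whose superclass is an
#' existential restriction (`subject SubClassOf relation some object`), and
#' each is marked `asserted` or `inferred`.
#'
#' @param classes Tibble with columns `id`, `label`, `definition` (character;
#'   `label`/`definition` may be `NA`).
#' @param axioms Tibble with columns `subject`, `kind` (one of `"subclass"`,
#'   `"subclass_existential"`), `relation` (`NA` for plain subclass axioms),
#'   `object`, `provenance` (`"asserted"` or `"inferred"`).
#' @param source_tag Short name for the ontology, e.g. `"GO"` or `"MERGED"`.
#' @return An object of class `ontology`.
#' @export
ontology <- function(classes, axioms, source_tag = "ONT") {
  classes <- tibble::as_tibble(classes)
  axioms <- tibble::as_tibble(axioms)
  for (col in c("label", "definition")) {
    if (!col %in% names(classes)) classes[[col]] <- NA_character_
  }
  if (nrow(axioms) == 0L) {
    axioms <- tibble::tibble(
      subject = character(), kind = character(), relation = character(),
      object = character(), provenance = character()
    )
  }
  if (!"relation" %in% names(axioms)) axioms$relation <- NA_character_
  if (!"provenance" %in% names(axioms)) axioms$provenance <- "asserted"
  classes <- classes[, c("id", "label", "definition")]
  axioms <- dplyr::distinct(
    axioms[, c("subject", "kind", "relation", "object", "provenance")]
  )
  obj <- structure(
    list(classes = classes, axioms = axioms, source_tag = source_tag),
    class = "ontology"
  )
  validate_ontology(obj)
  obj
}

validate_ontology <- function(x) {
  ids <- x$classes$id
  if (any(is.na(ids) | ids == "")) {
    stop("ontology contains empty class ids", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop(
      "duplicate class ids: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  endpoints <- unique(c(x$axioms$subject, x$axioms$object))
  missing <- setdiff(endpoints, ids)
  if (length(missing) > 0L) {
    stop(
      "axiom endpoints not declared as classes: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  plain <- x$axioms$kind == "subclass"
  if (any(!is.na(x$axioms$relation[plain]))) {
    stop("plain subclass axioms must not carry a relation", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.ontology <- function(x, ...) {
  n_inf <- sum(x$axioms$provenance == "inferred")
  cat(
    sprintf(
      "<ontology '%s'> %d classes, %d axioms (%d inferred)\n",
      x$source_tag, nrow(x$classes), nrow(x$axioms), n_inf
    )
  )
  invisible(x)
}

# "GO_0005634" and "GO:0005634" are both accepted on input; colon form is
# canonical in memory.
canonical_curie <- function(x) {
  has_colon <- grepl(":", x, fixed = TRUE)
  x[!has_colon] <- sub("_", ":", x[!has_colon])
  x
}

#' Parse an ontology file
#'
#' Reads an ontology from OBO format 1.2 or from a subset of OWL functional
#' syntax. The OBO reader understands `[Term]` stanzas with `id`, `name`,
#' `def`, `is_a` and `relationship` tags. The OWL reader understands
#' `Declaration(Class(...))`, `SubClassOf` between named classes, and
#' `SubClassOf` with a single `ObjectSomeValuesFrom` filler; any other axiom
#' is skipped with a counted warning. All parsed axioms are marked
#' `asserted`.
#'
#' @param path Path to the ontology file.
#' @param format `"obo"` or `"owl-functional"`; `NULL` guesses from the file
#'   extension (`.obo` vs `.owl`/`.ofn`).
#' @param source_tag Short ontology name recorded on the result; defaults to
#'   the file stem.
#' @return An [ontology] object.
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c(
#'   "format-version: 1.2", "",
#'   "[Term]", "id: T:1", "name: root", "",
#'   "[Term]", "id: T:2", "name: child", "is_a: T:1"
#' ), obo)
#' read_ontology(obo)
#' @export
read_ontology <- function(path, format = NULL, source_tag = NULL) {
  if (!file.exists(path)) {
    stop("cannot read ontology file: ", path, call. = FALSE)
  }
  if (is.null(format)) {
    format <- if (grepl("\\.(owl|ofn)$", path)) "owl-functional" else "obo"
  }
  format <- match.arg(format, c("obo", "owl-functional"))
  if (is.null(source_tag)) {
    source_tag <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "obo") {
    parse_obo_lines(lines, source_tag)
  } else {
    parse_ofn_lines(lines, source_tag)
  }
}

parse_obo_lines <- function(lines, source_tag) {
  # strip trailing "! ..." comments (not inside quoted defs) and whitespace
  stanza_starts <- grep("^\\[", lines)
  term_starts <- grep("^\\[Term\\]\\s*$", lines)

  classes <- list()
  axioms <- list()
  for (s in term_starts) {
    nxt <- stanza_starts[stanza_starts > s]
    end <- if (length(nxt) > 0L) min(nxt) - 1L else length(lines)
    body <- lines[(s + 1L):end]
    body <- body[nzchar(trimws(body))]
    tags <- sub("^([A-Za-z_]+):.*$", "\\1", body)
    vals <- trimws(sub("^[A-Za-z_]+:", "", body))
    bad <- !grepl("^[A-Za-z_]+:", body)
    if (any(bad)) {
      stop(
        "malformed OBO stanza near line ", s + which(bad)[1L],
        ": ", body[bad][1L],
        call. = FALSE
      )
    }
    id <- vals[tags == "id"][1L]
    if (is.na(id) || !nzchar(id)) {
      stop("OBO [Term] stanza at line ", s, " lacks an id", call. = FALSE)
    }
    if (isTRUE(vals[tags == "is_obsolete"][1L] == "true")) next
    id <- canonical_curie(id)
    label <- vals[tags == "name"][1L]
    def <- vals[tags == "def"][1L]
    if (!is.na(def)) def <- sub('^"(.*)".*$', "\\1", def)
    classes[[length(classes) + 1L]] <-
      tibble::tibble(id = id, label = label, definition = def)
    for (v in vals[tags == "is_a"]) {
      parent <- canonical_curie(strip_obo_comment(v))
      axioms[[length(axioms) + 1L]] <- tibble::tibble(
        subject = id, kind = "subclass", relation = NA_character_,
        object = parent, provenance = "asserted"
      )
    }
    for (v in vals[tags == "relationship"]) {
      parts <- strsplit(strip_obo_comment(v), "\\s+")[[1L]]
      if (length(parts) != 2L) {
        stop("malformed relationship tag in stanza at line ", s, ": ", v,
             call. = FALSE)
      }
      axioms[[length(axioms) + 1L]] <- tibble::tibble(
        subject = id, kind = "subclass_existential", relation = parts[1L],
        object = canonical_curie(parts[2L]), provenance = "asserted"
      )
    }
  }
  classes <- if (length(classes)) dplyr::bind_rows(classes) else
    tibble::tibble(id = character(), label = character(),
                   definition = character())
  classes <- dplyr::distinct(classes, .data$id, .keep_all = TRUE)
  axioms <- if (length(axioms)) dplyr::bind_rows(axioms) else NULL
  ontology(classes, axioms %||% tibble::tibble(), source_tag)
}

strip_obo_comment <- function(x) trimws(sub("\\s*!.*$", "", x))

parse_ofn_lines <- function(lines, source_tag) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lines <- lines[!grepl("^(Prefix|Ontology\\(|\\)$)", lines)]

  ids <- character()
  labels <- list()
  axioms <- list()
  skipped <- 0L

  name1 <- "([A-Za-z0-9_:.<>/#-]+)"
  re_decl <- paste0("^Declaration\\(Class\\(", name1, "\\)\\)$")
  re_sub <- paste0("^SubClassOf\\(", name1, " ", name1, "\\)$")
  re_some <- paste0(
    "^SubClassOf\\(", name1, " ObjectSomeValuesFrom\\(", name1, " ", name1,
    "\\)\\)$"
  )
  re_label <- paste0(
    '^AnnotationAssertion\\(rdfs:label ', name1, ' "(.*)"\\)$'
  )

  for (ln in lines) {
    if (grepl(re_decl, ln)) {
      ids <- c(ids, canonical_curie(sub(re_decl, "\\1", ln)))
    } else if (grepl(re_some, ln)) {
      axioms[[length(axioms) + 1L]] <- tibble::tibble(
        subject = canonical_curie(sub(re_some, "\\1", ln)),
        kind = "subclass_existential",
        relation = sub(re_some, "\\2", ln),
        object = canonical_curie(sub(re_some, "\\3", ln)),
        provenance = "asserted"
      )
    } else if (grepl(re_sub, ln)) {
      axioms[[length(axioms) + 1L]] <- tibble::tibble(
        subject = canonical_curie(sub(re_sub, "\\1", ln)),
        kind = "subclass", relation = NA_character_,
        object = canonical_curie(sub(re_sub, "\\2", ln)),
        provenance = "asserted"
      )
    } else if (grepl(re_label, ln)) {
      labels[[canonical_curie(sub(re_label, "\\1", ln))]] <-
        sub(re_label, "\\2", ln)
    } else {
      skipped <- skipped + 1L
    }
  }
  if (skipped > 0L) {
    warning(
      skipped, " OWL axiom(s) outside the supported subset were skipped",
      call. = FALSE
    )
  }
  ids <- unique(ids)
  classes <- tibble::tibble(
    id = ids,
    label = vapply(
      ids, function(i) labels[[i]] %||% NA_character_, character(1)
    ),
    definition = NA_character_
  )
  axioms <- if (length(axioms)) dplyr::bind_rows(axioms) else tibble::tibble()
  ontology(classes, axioms, source_tag)
}

#' Write an ontology to OBO format
#'
#' Emits one `[Term]` stanza per class with `is_a` lines for plain subclass
#' axioms and `relationship` lines for existential axioms. Only asserted
#' axioms are written; a file written and re-read yields the same class and
#' asserted-axiom set.
#'
#' @param x An [ontology].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(x, path) {
  stopifnot(inherits(x, "ontology"))
  ax <- x$axioms[x$axioms$provenance == "asserted", ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2",
               paste0("ontology: ", tolower(x$source_tag))), con)
  for (i in seq_len(nrow(x$classes))) {
    cl <- x$classes[i, ]
    out <- c("", "[Term]", paste0("id: ", cl$id))
    if (!is.na(cl$label)) out <- c(out, paste0("name: ", cl$label))
    if (!is.na(cl$definition)) {
      out <- c(out, sprintf('def: "%s" []', cl$definition))
    }
    mine <- ax[ax$subject == cl$id, ]
    plain <- mine[mine$kind == "subclass", ]
    exis <- mine[mine$kind == "subclass_existential", ]
    if (nrow(plain)) out <- c(out, paste0("is_a: ", sort(plain$object)))
    if (nrow(exis)) {
      ord <- order(exis$relation, exis$object)
      out <- c(out, paste0("relationship: ", exis$relation[ord], " ",
                           exis$object[ord]))
    }
    writeLines(out, con)
  }
  invisible(path)
}
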