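#' Read a gene annotation table
#'
#' Annotations are GAF-like TSVs with a header and the columns `gene_id`,
#' `class_id`, `source_tag`; lines starting with `#` are comments. Class ids
#' are normalised to CURIE colon form.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `gene_id`, `class_id`, `source_tag`.
#' @export
read_annotations <- function(path) {
  df <- readr::read_tsv(
    path, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  required <- c("gene_id", "class_id", "source_tag")
  if (!all(required %in% names(df))) {
    stop(
      "annotation table must have columns ",
      paste(required, collapse = ", "),
      call. = FALSE
    )
  }
  df |>
    dplyr::mutate(class_id = canonical_curie(.data$class_id)) |>
    dplyr::select(dplyr::all_of(required))
}

#' Write a gene annotation table
#'
#' @param annotations Tibble with columns `gene_id`, `class_id`,
#'   `source_tag`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(
    annotations[, c("gene_id", "class_id", "source_tag")], path
  )
  invisible(path)
}

# Class ids become single tokens by rendering in underscore form.
token_form <- function(id) sub(":", "_", id, fixed = TRUE)

#' Render one axiom as a corpus sentence
#'
#' Plain subclass axioms become the three tokens
#' `subject SubClassOf object`; existential axioms become the five tokens
#' `subject SubClassOf relation some object`. Class ids are rendered in
#' underscore form so that each id is a single whitespace-free token.
#'
#' @param axiom A one-row data frame (or list) with fields `subject`, `kind`,
#'   `relation`, `object`.
#' @return Character vector of tokens.
#' @export
render_axiom <- function(axiom) {
  if (axiom$kind == "subclass") {
    c(token_form(axiom$subject), "SubClassOf", token_form(axiom$object))
  } else {
    c(token_form(axiom$subject), "SubClassOf", axiom$relation, "some",
      token_form(axiom$object))
  }
}

#' Build the sentence corpus for embedding training
#'
#' The corpus interleaves three kinds of sentences, in deterministic order
#' (axioms, then class metadata, then gene associations, each sorted):
#' * one sentence per axiom (`subject SubClassOf ...`), optionally including
#'   inferred axioms,
#' * one metadata sentence per labelled class (`class_id label
#'   <label tokens>`), lower-cased and whitespace-tokenised,
#' * one association sentence `gene_id hasAnnotation class_id` per
#'   annotation record.
#'
#' Gene identifiers therefore occur in the corpus exactly as often as the
#' gene is annotated.
#'
#' @param ontology An [ontology]; every annotation class id must resolve in
#'   it.
#' @param annotations Tibble with columns `gene_id`, `class_id` (and
#'   optionally `source_tag`), as from [read_annotations()]. May have zero
#'   rows.
#' @param include_metadata Include class-label metadata sentences
#'   (default `TRUE`).
#' @param include_inferred Include inferred axioms (default `TRUE`).
#' @return An object of class `corpus`: a list with `sentences` (list of
#'   token vectors) and `counts` (named tally of `axiom`, `metadata`,
#'   `association` sentences).
#' @export
build_corpus <- function(ontology, annotations = NULL,
                         include_metadata = TRUE, include_inferred = TRUE) {
  stopifnot(inherits(ontology, "ontology"))
  if (is.null(annotations)) {
    annotations <- tibble::tibble(gene_id = character(),
                                  class_id = character())
  }
  unknown <- setdiff(annotations$class_id, ontology$classes$id)
  if (length(unknown) > 0L) {
    stop(
      "annotations reference unknown class id(s): ",
      paste(sort(unknown), collapse = ", "),
      call. = FALSE
    )
  }

  ax <- ontology$axioms
  if (!include_inferred) ax <- ax[ax$provenance == "asserted", ]
  ax <- ax[order(ax$subject, ax$kind, ax$object,
                 ax$relation, method = "radix"), ]
  axiom_sentences <- lapply(seq_len(nrow(ax)), function(i) {
    render_axiom(ax[i, ])
  })

  metadata_sentences <- list()
  if (include_metadata) {
    lab <- ontology$classes[!is.na(ontology$classes$label), ]
    lab <- lab[order(lab$id, method = "radix"), ]
    metadata_sentences <- lapply(seq_len(nrow(lab)), function(i) {
      c(token_form(lab$id[i]), "label",
        strsplit(tolower(lab$label[i]), "\\s+")[[1L]])
    })
  }

  ann <- annotations[order(annotations$gene_id, annotations$class_id,
                           method = "radix"), ]
  association_sentences <- purrr::map2(
    ann$gene_id, ann$class_id,
    function(g, cl) c(g, "hasAnnotation", token_form(cl))
  )

  structure(
    list(
      sentences = c(axiom_sentences, metadata_sentences,
                    association_sentences),
      counts = c(
        axiom = length(axiom_sentences),
        metadata = length(metadata_sentences),
        association = length(association_sentences)
      )
    ),
    class = "corpus"
  )
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf(
    "<corpus> %d sentences (axiom %d, metadata %d, association %d)\n",
    length(x$sentences), x$counts[["axiom"]], x$counts[["metadata"]],
    x$counts[["association"]]
  ))
  invisible(x)
}

#' Write a corpus as plain text, one sentence per line
#'
#' @param corpus A `corpus` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  writeLines(vapply(corpus$sentences, paste, character(1), collapse = " "),
             path, useBytes = TRUE)
  invisible(path)
}
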