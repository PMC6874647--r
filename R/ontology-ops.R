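#' Transitive closure over plain subclass axioms
#'
#' Adds every transitively entailed plain subclass axiom to the ontology,
#' marked `inferred`. Reasoning is structural: only `subclass` axioms
#' participate; existential restrictions are carried along unchanged.
#' Reflexive axioms (`A SubClassOf A`) are never added, and asserted axioms
#' are left untouched.
#'
#' @param x An [ontology] whose plain-subclass graph is acyclic.
#' @return A copy of `x` with the inferred axioms appended.
#' @examples
#' o <- ontology(
#'   tibble::tibble(id = c("T:1", "T:2", "T:3")),
#'   tibble::tibble(subject = c("T:3", "T:2"), kind = "subclass",
#'                  object = c("T:2", "T:1"))
#' )
#' infer_subclass_closure(o)$axioms
#' @export
infer_subclass_closure <- function(x) {
  stopifnot(inherits(x, "ontology"))
  asserted <- x$axioms[x$axioms$provenance == "asserted", ]
  plain <- asserted[asserted$kind == "subclass", ]
  if (nrow(plain) == 0L) {
    x$axioms <- asserted
    return(x)
  }
  g <- igraph::graph_from_data_frame(
    plain[, c("subject", "object")],
    directed = TRUE,
    vertices = x$classes$id
  )
  if (!igraph::is_dag(g)) {
    cyc <- find_subclass_cycle(plain)
    stop(
      "subclass axioms contain a cycle: ",
      paste(cyc, collapse = " -> "),
      call. = FALSE
    )
  }
  d <- igraph::distances(g, mode = "out")
  reach <- which(is.finite(d) & d > 0, arr.ind = TRUE)
  ids <- igraph::V(g)$name
  entailed <- tibble::tibble(
    subject = ids[reach[, 1L]],
    kind = "subclass",
    relation = NA_character_,
    object = ids[reach[, 2L]],
    provenance = "inferred"
  )
  new <- dplyr::anti_join(
    entailed, plain, by = c("subject", "kind", "object")
  )
  x$axioms <- dplyr::bind_rows(asserted, new)
  x
}

# Locate one directed cycle in the subclass edge list (for the error message).
find_subclass_cycle <- function(plain) {
  adj <- split(plain$object, plain$subject)
  state <- new.env(parent = emptyenv())
  path <- character()
  visit <- function(v) {
    st <- state[[v]] %||% 0L
    if (st == 1L) {
      i <- match(v, path)
      return(c(path[i:length(path)], v))
    }
    if (st == 2L) return(NULL)
    state[[v]] <- 1L
    path <<- c(path, v)
    for (w in adj[[v]] %||% character()) {
      res <- visit(w)
      if (!is.null(res)) return(res)
    }
    path <<- path[-length(path)]
    state[[v]] <- 2L
    NULL
  }
  for (v in unique(plain$subject)) {
    res <- visit(v)
    if (!is.null(res)) return(res)
  }
  character()
}

#' Merge ontologies into one
#'
#' Classes are unioned by id (the label and definition of the first
#' occurrence win; a conflicting later label raises a warning) and axioms are
#' deduplicated. The result carries `source_tag = "MERGED"`.
#'
#' @param parts A non-empty list of [ontology] objects.
#' @return A merged [ontology].
#' @export
merge_ontologies <- function(parts) {
  if (!is.list(parts) || length(parts) == 0L ||
      !all(vapply(parts, inherits, logical(1), "ontology"))) {
    stop("`parts` must be a non-empty list of ontology objects",
         call. = FALSE)
  }
  classes <- dplyr::bind_rows(lapply(parts, `[[`, "classes"))
  conflicts <- classes |>
    dplyr::filter(!is.na(.data$label)) |>
    dplyr::distinct(.data$id, .data$label) |>
    dplyr::count(.data$id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(conflicts) > 0L) {
    warning(
      "conflicting labels for class(es) ",
      paste(conflicts$id, collapse = ", "),
      "; keeping the first occurrence",
      call. = FALSE
    )
  }
  classes <- dplyr::distinct(classes, .data$id, .keep_all = TRUE)
  axioms <- dplyr::bind_rows(lapply(parts, `[[`, "axioms"))
  ontology(classes, axioms, source_tag = "MERGED")
}
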