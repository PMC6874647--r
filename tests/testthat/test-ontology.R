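test_that("OBO parsing maps stanzas to classes and axioms", {
  path <- withr::local_tempfile(fileext = ".obo")
  write_toy_obo(path)
  ont <- read_ontology(path, "obo", source_tag = "TOY")

  expect_s3_class(ont, "ontology")
  expect_equal(ont$classes$id, c("T:1", "T:2", "T:3"))
  expect_equal(ont$classes$label[ont$classes$id == "T:3"], "nucleus")

  plain <- ont$axioms[ont$axioms$kind == "subclass", ]
  expect_equal(nrow(plain), 2L)
  expect_true(any(plain$subject == "T:2" & plain$object == "T:1"))

  exis <- ont$axioms[ont$axioms$kind == "subclass_existential", ]
  expect_equal(exis$relation, "part_of")
  expect_equal(exis$object, "T:1")
  expect_true(all(ont$axioms$provenance == "asserted"))
})

test_that("OBO parser reports malformed stanzas and unknown references", {
  bad <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: T:1", "no-colon-here"), bad)
  expect_error(read_ontology(bad, "obo"), "malformed")

  dangling <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: T:1", "is_a: T:9"), dangling)
  expect_error(read_ontology(dangling, "obo"), "T:9")

  expect_error(read_ontology("/nonexistent/x.obo"), "cannot read")
})

test_that("underscore CURIEs are normalised to colon form", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "[Term]", "id: GO_0000001", "",
    "[Term]", "id: GO:0000002", "is_a: GO_0000001"
  ), path)
  ont <- read_ontology(path, "obo")
  expect_setequal(ont$classes$id, c("GO:0000001", "GO:0000002"))
  expect_equal(ont$axioms$object, "GO:0000001")
})

test_that("OWL functional-syntax subset parses and skips the rest", {
  path <- withr::local_tempfile(fileext = ".ofn")
  writeLines(c(
    "Prefix(:=<http://example.org/>)",
    "Ontology(<http://example.org/toy>",
    "Declaration(Class(A:1))",
    "Declaration(Class(A:2))",
    "Declaration(Class(A:3))",
    "SubClassOf(A:2 A:1)",
    "SubClassOf(A:3 ObjectSomeValuesFrom(part_of A:1))",
    "EquivalentClasses(A:2 A:3)",
    ")"
  ), path)
  expect_warning(ont <- read_ontology(path, "owl-functional", "OWLTOY"),
                 "skipped")
  expect_equal(nrow(ont$classes), 3L)
  expect_equal(sum(ont$axioms$kind == "subclass"), 1L)
  exis <- ont$axioms[ont$axioms$kind == "subclass_existential", ]
  expect_equal(exis$subject, "A:3")
  expect_equal(exis$relation, "part_of")
})

test_that("subclass closure adds exactly the transitive entailments", {
  chain <- dag_ontology(
    tibble::tibble(subject = c("N:01", "N:02"), object = c("N:02", "N:03")),
    3L
  )
  closed <- infer_subclass_closure(chain)
  inferred <- closed$axioms[closed$axioms$provenance == "inferred", ]
  expect_equal(nrow(inferred), 1L)
  expect_equal(inferred$subject, "N:01")
  expect_equal(inferred$object, "N:03")

  # single axiom entails nothing new
  single <- dag_ontology(
    tibble::tibble(subject = "N:01", object = "N:02"), 2L
  )
  expect_equal(nrow(infer_subclass_closure(single)$axioms), 1L)

  # diamond: the top is entailed exactly once
  diamond <- dag_ontology(
    tibble::tibble(subject = c("N:01", "N:01", "N:02", "N:03"),
                   object = c("N:02", "N:03", "N:04", "N:04")),
    4L
  )
  closed <- infer_subclass_closure(diamond)
  top <- closed$axioms[closed$axioms$subject == "N:01" &
                         closed$axioms$object == "N:04", ]
  expect_equal(nrow(top), 1L)
  expect_equal(top$provenance, "inferred")
  expect_false(any(closed$axioms$subject == closed$axioms$object))
})

test_that("closure is idempotent and matches brute-force reachability", {
  withr::local_seed(42)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    edges <- random_dag_edges(n)
    if (nrow(edges) == 0L) next
    ont <- dag_ontology(edges, n)
    closed <- infer_subclass_closure(ont)

    got <- closed$axioms[closed$axioms$kind == "subclass",
                         c("subject", "object")]
    got <- dplyr::arrange(got, subject, object)
    expect_equal(got, oracle_reachability(edges), ignore_attr = TRUE)

    twice <- infer_subclass_closure(closed)
    expect_setequal(
      paste(twice$axioms$subject, twice$axioms$object,
            twice$axioms$provenance),
      paste(closed$axioms$subject, closed$axioms$object,
            closed$axioms$provenance)
    )
  }
})

test_that("subclass cycles are rejected with the cycle named", {
  cyc <- dag_ontology(
    tibble::tibble(subject = c("N:01", "N:02", "N:03"),
                   object = c("N:02", "N:03", "N:01")),
    3L
  )
  expect_error(infer_subclass_closure(cyc), "N:01.*N:01|cycle")
})

test_that("merging unions classes and deduplicates axioms", {
  a <- ontology(
    tibble::tibble(id = c("A:1", "A:2", "A:3")),
    tibble::tibble(subject = "A:2", kind = "subclass", object = "A:1",
                   provenance = "asserted"),
    "A"
  )
  b <- ontology(
    tibble::tibble(id = c("B:1", "B:2", "B:3")),
    tibble::tibble(subject = "B:2", kind = "subclass", object = "B:1",
                   provenance = "asserted"),
    "B"
  )
  merged <- merge_ontologies(list(a, b))
  expect_equal(nrow(merged$classes), 6L)
  expect_equal(merged$source_tag, "MERGED")

  # shared class id and identical axiom each appear once
  b2 <- ontology(
    tibble::tibble(id = c("A:1", "A:2")),
    tibble::tibble(subject = "A:2", kind = "subclass", object = "A:1",
                   provenance = "asserted"),
    "B"
  )
  merged2 <- merge_ontologies(list(a, b2))
  expect_equal(sum(merged2$classes$id == "A:1"), 1L)
  expect_equal(nrow(merged2$axioms), 1L)

  expect_error(merge_ontologies(list()), "non-empty")

  conflict <- ontology(
    tibble::tibble(id = "A:1", label = "other name"),
    tibble::tibble(),
    "C"
  )
  lab_a <- ontology(
    tibble::tibble(id = "A:1", label = "first name"), tibble::tibble(), "A"
  )
  expect_warning(m3 <- merge_ontologies(list(lab_a, conflict)),
                 "conflicting")
  expect_equal(m3$classes$label, "first name")
})

test_that("OBO write/parse round trip preserves classes and axioms", {
  ont <- toy_ontology()
  path <- withr::local_tempfile(fileext = ".obo")
  write_obo(ont, path)
  back <- read_ontology(path, "obo", source_tag = "TOY")
  expect_setequal(back$classes$id, ont$classes$id)
  expect_setequal(
    paste(back$axioms$subject, back$axioms$kind, back$axioms$object),
    paste(ont$axioms$subject, ont$axioms$kind, ont$axioms$object)
  )
})
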