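# Shared fixtures. Expensive full-scale pipeline runs are computed once per
# session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

toy_ontology <- function() {
  ontology(
    tibble::tibble(
      id = c("T:1", "T:2", "T:3", "T:4"),
      label = c("root", "organelle", "nucleus", NA)
    ),
    tibble::tibble(
      subject = c("T:2", "T:3", "T:4"),
      kind = c("subclass", "subclass", "subclass_existential"),
      relation = c(NA, NA, "part_of"),
      object = c("T:1", "T:2", "T:2"),
      provenance = "asserted"
    ),
    source_tag = "TOY"
  )
}

write_toy_obo <- function(path) {
  writeLines(c(
    "format-version: 1.2",
    "",
    "[Term]",
    "id: T:1",
    "name: root",
    "",
    "[Term]",
    "id: T:2",
    "name: organelle",
    "is_a: T:1 ! root",
    "",
    "[Term]",
    "id: T:3",
    "name: nucleus",
    "is_a: T:2",
    "relationship: part_of T:1"
  ), path)
  path
}

# Full-scale synthetic study at generator defaults (500 genes), with
# embeddings trained at the package's default parameters. Used by the
# pipeline-level and acceptance tests.
full_study <- function(strength = 0.9, seed = 7L) {
  cached(sprintf("study_%s_%d", strength, seed), {
    cfg <- synthetic_config(signal_strength = strength, seed = seed)
    gd <- generate_gene_data(cfg)
    onts <- lapply(
      stats::setNames(toupper(cfg$sources), toupper(cfg$sources)),
      function(s) generate_ontology(cfg, s)
    )
    tables <- train_all_embeddings(onts, gd$annotations,
                                   embedding_params(seed = seed))
    list(config = cfg, data = gd, ontologies = onts, tables = tables)
  })
}

full_cv <- function(mode = "union", strength = 0.9, seed = 7L) {
  cached(sprintf("cv_%s_%s_%d", mode, strength, seed), {
    st <- full_study(strength, seed)
    features <- build_representation(mode, st$tables, st$data$annotations)
    cross_validate(features, st$data$labels, model_config(), k = 10L,
                   seed = seed)
  })
}
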