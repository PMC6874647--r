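small_config <- function(...) {
  synthetic_config(
    n_classes_per_ontology = 13L, dag_branching = 3L, n_genes = 60L,
    n_cancer_types = 3L, driver_fraction = 0.2,
    annotations_per_gene = 9L, seed = 13L, ...
  )
}

test_that("generated ontology is a labelled tree plus existential extras", {
  cfg <- synthetic_config(n_classes_per_ontology = 10L, dag_branching = 2L,
                          seed = 1L)
  ont <- generate_ontology(cfg, "GO")
  expect_equal(nrow(ont$classes), 10L)
  plain <- ont$axioms[ont$axioms$kind == "subclass", ]
  expect_equal(nrow(plain), 9L)  # tree: n - 1 edges
  expect_true(all(!is.na(ont$classes$label)))
  exis <- ont$axioms[ont$axioms$kind == "subclass_existential", ]
  expect_equal(nrow(exis), round(0.1 * 9))
  # acyclic by construction
  expect_no_error(infer_subclass_closure(ont))
})

test_that("generated ontology round-trips through its OBO file", {
  cfg <- small_config()
  ont <- generate_ontology(cfg, "MP")
  path <- withr::local_tempfile(fileext = ".obo")
  write_obo(ont, path)
  back <- read_ontology(path, "obo", "MP")
  expect_setequal(back$classes$id, ont$classes$id)
  expect_setequal(
    paste(back$axioms$subject, back$axioms$kind, back$axioms$relation,
          back$axioms$object),
    paste(ont$axioms$subject, ont$axioms$kind, ont$axioms$relation,
          ont$axioms$object)
  )
})

test_that("generators are deterministic and regenerated files are identical", {
  cfg <- small_config()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_study(cfg, d1)
  simulate_study(cfg, d2)
  for (f in list.files(d1)) {
    if (f == "manifest.json") next  # embeds absolute paths
    expect_identical(
      unname(tools::md5sum(file.path(d1, f))),
      unname(tools::md5sum(file.path(d2, f))),
      info = f
    )
  }
  ont1 <- generate_ontology(cfg, "GO")
  ont2 <- generate_ontology(cfg, "GO")
  expect_identical(ont1, ont2)
})

test_that("driver fraction, holdout split and per-type counts are as configured", {
  cfg <- synthetic_config(seed = 3L)
  gd <- generate_gene_data(cfg)
  all_drivers <- union(gd$labels$gene_id, gd$holdout$gene_id)
  expect_equal(length(all_drivers), round(0.16 * 500))
  # held-out novel drivers are disjoint from the labelled ones
  expect_length(intersect(gd$labels$gene_id, gd$holdout$gene_id), 0L)
  expect_equal(nrow(gd$holdout) / length(all_drivers), 0.2,
               tolerance = 0.15)
  counts <- table(gd$labels$cancer_type)
  expect_equal(length(counts), 6L)
  expect_lte(max(counts) - min(counts), 2L)  # round-robin minus holdout
  expect_true(all(counts >= 10L))            # enough for 10-fold CV
  expect_equal(nrow(gd$annotations), 500L * 30L)
})

test_that("signal strength biases driver annotations into their subtree", {
  cfg <- small_config(signal_strength = 0.9)
  gd <- generate_gene_data(cfg)
  # fraction of driver annotations (in the type's signal source) inside
  # the designated subtree
  in_subtree_fraction <- function(gd) {
    joined <- dplyr::inner_join(gd$annotations, gd$labels, by = "gene_id",
                                relationship = "many-to-many")
    sig <- dplyr::semi_join(
      joined, dplyr::distinct(gd$subtrees, cancer_type, source_tag),
      by = c("cancer_type", "source_tag")
    )
    hits <- dplyr::inner_join(
      sig, gd$subtrees,
      by = c("cancer_type", "source_tag", "class_id")
    )
    nrow(hits) / nrow(sig)
  }
  expect_gt(in_subtree_fraction(gd), 0.85)

  # null generator: subtree occupancy matches its uniform share
  cfg0 <- small_config(signal_strength = 0)
  gd0 <- generate_gene_data(cfg0)
  share <- nrow(dplyr::distinct(gd0$subtrees, class_id,
                                .keep_all = TRUE)) /
    (cfg0$n_classes_per_ontology * cfg0$n_cancer_types)
  expect_lt(in_subtree_fraction(gd0), 0.5)
})

test_that("generated network upgrades driver pairs and never self-loops", {
  cfg <- synthetic_config(n_genes = 150L, seed = 9L)
  gd <- generate_gene_data(cfg)
  net <- generate_network(gd$genes, gd$labels, cfg)
  expect_true(all(net$edges$gene_a != net$edges$gene_b))

  drivers <- unique(gd$labels$gene_id)
  n_d <- length(drivers)
  dd_possible <- choose(n_d, 2)
  dd_edges <- sum(net$edges$gene_a %in% drivers &
                    net$edges$gene_b %in% drivers)
  bg_possible <- choose(length(gd$genes), 2) - dd_possible
  bg_edges <- nrow(net$edges) - dd_edges
  expect_gt(dd_edges / dd_possible, bg_edges / bg_possible)

  # null network: no enrichment beyond sampling noise
  cfg0 <- synthetic_config(n_genes = 150L, p_within = 0.02, seed = 9L)
  net0 <- generate_network(gd$genes, gd$labels, cfg0)
  expect_lt(
    sum(net0$edges$gene_a %in% drivers & net0$edges$gene_b %in% drivers) /
      dd_possible,
    0.06
  )
})

test_that("variant scores shift in each tool's deleterious direction", {
  cfg <- small_config(variant_shift = 2)
  gd <- generate_gene_data(cfg)
  drivers <- unique(gd$labels$gene_id)
  v <- generate_variants(gd$genes, drivers, cfg)
  drv <- v$gene_id %in% drivers

  # higher_worse tool shifts up, lower_worse tool shifts down
  expect_gt(mean(v$CADD[drv]) - mean(v$CADD[!drv]), 1)
  expect_lt(mean(v$SIFT[drv]) - mean(v$SIFT[!drv]), -1)

  expect_equal(mean(v$coding_flag), 0.9, tolerance = 0.1)
  expect_equal(mean(is.na(v$allele_frequency)), 0.3, tolerance = 0.12)

  # null shift: no separation
  cfg0 <- small_config(variant_shift = 0)
  v0 <- generate_variants(gd$genes, drivers, cfg0)
  expect_lt(abs(mean(v0$CADD[v0$gene_id %in% drivers]) -
                  mean(v0$CADD[!v0$gene_id %in% drivers])), 0.3)
})

test_that("simulated study files parse through every reader", {
  cfg <- small_config()
  dir <- withr::local_tempdir()
  sim <- simulate_study(cfg, dir)
  for (s in c("cmpo", "go", "mp")) {
    ont <- read_ontology(file.path(dir, paste0(s, ".obo")), "obo",
                         toupper(s))
    expect_s3_class(ont, "ontology")
  }
  ann <- read_annotations(file.path(dir, "annotations.tsv"))
  expect_equal(nrow(ann), nrow(sim$annotations))
  labs <- read_labels(file.path(dir, "labels.tsv"))
  expect_equal(nrow(labs), nrow(sim$labels))
  net <- read_network(file.path(dir, "network.tsv"))
  expect_equal(net$edges, sim$network$edges)
  mut <- read_mutations(file.path(dir, "mutations.tsv"))
  expect_equal(nrow(mut), cfg$n_genes)
  v <- read_variants(file.path(dir, "variants.tsv"))
  expect_equal(nrow(v), cfg$n_genes * cfg$variants_per_gene)
  expect_true(file.exists(file.path(dir, "manifest.json")))
})

test_that("infeasible configurations are rejected", {
  expect_error(synthetic_config(p_within = 0.01, p_background = 0.5))
  expect_error(synthetic_config(signal_strength = 2))
  expect_error(
    generate_gene_data(synthetic_config(n_classes_per_ontology = 4L,
                                        n_cancer_types = 20L)),
    "at most"
  )
})
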