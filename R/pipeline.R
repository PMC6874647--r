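#' Train all per-source and merged-ontology embeddings
#'
#' For each annotation source: the source ontology is closed under subclass
#' entailment, rendered into a corpus together with that source's gene
#' associations, and embedded. Additionally the ontologies are merged into
#' one and embedded with the pooled annotations, giving the `"MERGED"`
#' table used by the union representation.
#'
#' @param ontologies Named list of [ontology] objects, keyed by source tag.
#' @param annotations Tibble with `gene_id`, `class_id`, `source_tag`.
#' @param params An [embedding_params()]; each source derives its own
#'   training seed from `params$seed`.
#' @param include_metadata,include_inferred Corpus construction flags, see
#'   [build_corpus()].
#' @return Named list of `embedding_table`s (source tags plus `"MERGED"`).
#' @export
train_all_embeddings <- function(ontologies, annotations,
                                 params = embedding_params(),
                                 include_metadata = TRUE,
                                 include_inferred = TRUE) {
  stopifnot(is.list(ontologies), !is.null(names(ontologies)))
  one <- function(ont, ann, salt) {
    closed <- infer_subclass_closure(ont)
    corpus <- build_corpus(closed, ann, include_metadata, include_inferred)
    p <- params
    p$seed <- derive_seed(params$seed, paste0("embed:", salt))
    train_embeddings(corpus, p, entity_tokens = unique(ann$gene_id))
  }
  tables <- lapply(names(ontologies), function(s) {
    one(ontologies[[s]], annotations[annotations$source_tag == s, ], s)
  })
  names(tables) <- names(ontologies)
  merged <- merge_ontologies(unname(ontologies))
  tables[["MERGED"]] <- one(merged, annotations, "MERGED")
  tables
}

#' Read a corpus written by [write_corpus()]
#'
#' Sentence categories are recovered from the relation token (second
#' position): `SubClassOf` axioms, `label` metadata, `hasAnnotation`
#' associations.
#'
#' @param path Path to a one-sentence-per-line text file.
#' @return A `corpus` object.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sentences <- strsplit(lines, " ", fixed = TRUE)
  rel <- vapply(sentences, function(s) s[2L], character(1))
  structure(
    list(
      sentences = sentences,
      counts = c(
        axiom = sum(rel == "SubClassOf"),
        metadata = sum(rel == "label"),
        association = sum(rel == "hasAnnotation")
      )
    ),
    class = "corpus"
  )
}

pipeline_subcommands <- c("simulate", "build-corpus", "embed",
                          "train-eval", "predict", "validate")

#' Run one workflow subcommand
#'
#' Orchestrates the end-to-end workflow: `simulate` writes a synthetic
#' study, `build-corpus` renders per-source and merged corpora, `embed`
#' trains the embeddings, `train-eval` cross-validates the per-type
#' classifiers for the configured representation mode, `predict` calls
#' novel candidates, and `validate` runs the three validation statistics
#' (mutation frequency, network permutation, pathogenicity enrichment) and
#' writes one JSON report. Every subcommand writes a machine-readable run
#' log (config echo, seed, artifact checksums) next to its artifacts, and
#' removes partial outputs on failure.
#'
#' @param name One of `simulate`, `build-corpus`, `embed`, `train-eval`,
#'   `predict`, `validate`.
#' @param config Nested configuration list (see the package vignette), as
#'   read from YAML/JSON by [read_run_config()]. Must at least contain
#'   `output_dir`; `seed` defaults to 1.
#' @return Invisibly, a list of artifact paths written.
#' @export
run_subcommand <- function(name, config) {
  name <- match.arg(name, pipeline_subcommands)
  if (is.null(config$output_dir)) {
    stop("config must specify `output_dir`", call. = FALSE)
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  config$seed <- config$seed %||% 1L
  written <- character()
  note <- function(p) {
    written <<- c(written, p)
    p
  }
  fn <- switch(
    name,
    "simulate" = pipeline_simulate,
    "build-corpus" = pipeline_build_corpus,
    "embed" = pipeline_embed,
    "train-eval" = pipeline_train_eval,
    "predict" = pipeline_predict,
    "validate" = pipeline_validate
  )
  result <- tryCatch(
    fn(config, note),
    error = function(e) {
      unlink(written)
      stop("subcommand '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  log_path <- file.path(config$output_dir,
                        paste0("runlog_", gsub("-", "_", name), ".json"))
  jsonlite::write_json(
    list(
      subcommand = name,
      config = config,
      seed = config$seed,
      artifacts = lapply(written, function(p) {
        list(path = p, md5 = unname(tools::md5sum(p)))
      }),
      summary = result
    ),
    log_path, auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE
  )
  invisible(c(written, log_path))
}

#' Read a workflow configuration file
#'
#' @param path YAML (or JSON) configuration file.
#' @return Configuration list for [run_subcommand()].
#' @export
read_run_config <- function(path) {
  if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

pipeline_simulate <- function(config, note) {
  args <- config$synthetic %||% list()
  args$seed <- args$seed %||% config$seed
  cfg <- do.call(synthetic_config, args)
  sim <- simulate_study(cfg, config$output_dir)
  for (f in sim$manifest$files) note(f$path)
  note(file.path(config$output_dir, "manifest.json"))
  list(
    n_genes = length(sim$genes),
    n_drivers = length(unique(sim$labels$gene_id)),
    n_annotations = nrow(sim$annotations),
    n_edges = nrow(sim$network$edges)
  )
}

pipeline_load_ontologies <- function(config) {
  specs <- config$ontologies
  if (is.null(specs)) {
    # default to the OBO files a `simulate` run wrote
    obo <- list.files(config$output_dir, pattern = "\\.obo$",
                      full.names = TRUE)
    if (length(obo) == 0L) stop("no ontologies configured or found")
    specs <- lapply(obo, function(p) {
      list(path = p, source_tag = toupper(sub("\\.obo$", "", basename(p))))
    })
  }
  onts <- lapply(specs, function(sp) {
    read_ontology(sp$path, sp$format %||% NULL, sp$source_tag)
  })
  names(onts) <- vapply(specs, `[[`, character(1), "source_tag")
  onts
}

pipeline_annotations_path <- function(config) {
  config$annotations %||% file.path(config$output_dir, "annotations.tsv")
}

pipeline_build_corpus <- function(config, note) {
  onts <- pipeline_load_ontologies(config)
  ann <- read_annotations(pipeline_annotations_path(config))
  include_metadata <- config$include_metadata %||% TRUE
  include_inferred <- config$include_inferred %||% TRUE
  counts <- list()
  emit <- function(ont, ann_sub, tag) {
    closed <- infer_subclass_closure(ont)
    corpus <- build_corpus(closed, ann_sub, include_metadata,
                           include_inferred)
    p <- note(file.path(config$output_dir,
                        paste0("corpus_", tag, ".txt")))
    write_corpus(corpus, p)
    counts[[tag]] <<- as.list(corpus$counts)
  }
  for (s in names(onts)) emit(onts[[s]], ann[ann$source_tag == s, ], s)
  emit(merge_ontologies(unname(onts)), ann, "MERGED")
  counts
}

pipeline_embedding_params <- function(config) {
  args <- config$embedding %||% list()
  args$seed <- args$seed %||% config$seed
  do.call(embedding_params, args)
}

pipeline_embed <- function(config, note) {
  params <- pipeline_embedding_params(config)
  ann <- read_annotations(pipeline_annotations_path(config))
  corpora <- list.files(config$output_dir, pattern = "^corpus_.*\\.txt$",
                        full.names = TRUE)
  if (length(corpora) == 0L) {
    stop("no corpus files in output_dir; run build-corpus first")
  }
  sizes <- list()
  for (path in corpora) {
    tag <- sub("^corpus_(.*)\\.txt$", "\\1", basename(path))
    corpus <- read_corpus(path)
    entity <- if (tag == "MERGED") unique(ann$gene_id) else
      unique(ann$gene_id[ann$source_tag == tag])
    p <- params
    p$seed <- derive_seed(params$seed, paste0("embed:", tag))
    table <- train_embeddings(corpus, p, entity_tokens = entity)
    out <- note(file.path(config$output_dir,
                          paste0("embeddings_", tag, ".txt")))
    write_embeddings(table, out)
    sizes[[tag]] <- nrow(table$vectors)
  }
  sizes
}

pipeline_load_tables <- function(config) {
  files <- list.files(config$output_dir, pattern = "^embeddings_.*\\.txt$",
                      full.names = TRUE)
  if (length(files) == 0L) {
    stop("no embedding tables in output_dir; run embed first")
  }
  tables <- lapply(files, read_embeddings)
  names(tables) <- sub("^embeddings_(.*)\\.txt$", "\\1", basename(files))
  tables
}

pipeline_features <- function(config) {
  tables <- pipeline_load_tables(config)
  ann <- read_annotations(pipeline_annotations_path(config))
  build_representation(config$mode %||% "union", tables, ann)
}

pipeline_model_config <- function(config) {
  args <- config$model %||% list()
  args$seed <- args$seed %||% config$seed
  do.call(model_config, args)
}

pipeline_labels_path <- function(config) {
  config$labels %||% file.path(config$output_dir, "labels.tsv")
}

pipeline_train_eval <- function(config, note) {
  features <- pipeline_features(config)
  labels <- read_labels(pipeline_labels_path(config))
  cv <- cross_validate(
    features, labels, pipeline_model_config(config),
    k = config$k %||% 10L, seed = config$seed,
    threshold = config$threshold %||% 0.5
  )
  metrics_path <- note(file.path(config$output_dir, "metrics.json"))
  jsonlite::write_json(
    list(
      mode = attr(features, "mode"),
      pooled = cv$pooled,
      folds = cv$folds,
      glance = glance(cv)
    ),
    metrics_path, auto_unbox = TRUE, pretty = TRUE, digits = NA,
    dataframe = "rows"
  )
  roc <- dplyr::bind_cols(
    tibble::tibble(curve = "overall"),
    roc_points(cv$scores$score, cv$scores$label)
  )
  pr <- dplyr::bind_cols(
    tibble::tibble(curve = "overall"),
    pr_points(cv$scores$score, cv$scores$label)
  )
  readr::write_tsv(roc, note(file.path(config$output_dir, "roc.tsv")))
  readr::write_tsv(pr, note(file.path(config$output_dir, "pr.tsv")))
  as.list(glance(cv))
}

pipeline_predict <- function(config, note) {
  features <- pipeline_features(config)
  labels <- read_labels(pipeline_labels_path(config))
  models <- train_driver_models(features, labels,
                                pipeline_model_config(config),
                                seed = config$seed)
  candidates <- predict_candidates(models, features, labels,
                                   threshold = config$threshold %||% 0.5)
  readr::write_tsv(candidates,
                   note(file.path(config$output_dir, "candidates.tsv")))
  list(n_candidates = nrow(candidates),
       n_candidate_genes = length(unique(candidates$gene_id)))
}

pipeline_validate <- function(config, note) {
  labels <- read_labels(pipeline_labels_path(config))
  cand_path <- config$candidates %||%
    file.path(config$output_dir, "candidates.tsv")
  candidates <- readr::read_tsv(cand_path, show_col_types = FALSE)
  known <- unique(labels$gene_id)
  cand_genes <- setdiff(unique(candidates$gene_id), known)

  mutations <- read_mutations(
    config$mutations %||% file.path(config$output_dir, "mutations.tsv")
  )
  network <- read_network(
    config$network %||% file.path(config$output_dir, "network.tsv")
  )
  variants <- read_variants(
    config$variants %||% file.path(config$output_dir, "variants.tsv")
  )

  freq <- mutation_frequency(
    stats::setNames(mutations$mutation_count, mutations$gene_id),
    stats::setNames(mutations$gene_length, mutations$gene_id)
  )
  nondriver <- setdiff(freq$gene_id, c(known, cand_genes))
  mut_test <- welch_t_test_one_tailed(
    freq$frequency[freq$gene_id %in% cand_genes],
    freq$frequency[freq$gene_id %in% nondriver],
    "a_greater"
  )

  perm_args <- config$permutation %||% list()
  perm_args$seed <- perm_args$seed %||% config$seed
  net_test <- network_permutation_test(
    network, intersect(cand_genes, network$nodes), known,
    do.call(permutation_config, perm_args)
  )

  coding <- filter_coding_variants(variants)
  rare <- filter_rare_variants(coding,
                               config$af_threshold %||% 0.01)
  enrich <- pathogenicity_enrichment(rare, cand_genes,
                                     intersect(nondriver, rare$gene_id))

  report <- list(
    mutation_frequency = as.list(tidy(mut_test)),
    network_permutation = as.list(
      tidy(net_test)
    ),
    pathogenicity = tidy_enrichment(enrich)
  )
  path <- note(file.path(config$output_dir, "validation.json"))
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, dataframe = "rows")
  list(
    mutation_p = mut_test$p_value,
    network_observed = net_test$statistic,
    network_null_mean = net_test$null_summary$mean,
    network_empirical_p = net_test$null_summary$empirical_p,
    pathogenicity_p = lapply(enrich, `[[`, "p_value")
  )
}
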