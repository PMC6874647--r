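#' Synthetic study configuration
#'
#' Parameters of the fully self-contained toy study the generators emulate:
#' a rooted-DAG ontology per annotation source, gene annotations with a
#' planted driver signature, a driver-enriched interaction network,
#' driver-elevated mutation counts, and driver-shifted variant pathogenicity
#' scores.
#'
#' The driver signal is planted through annotation bias only: each cancer
#' type is assigned a designated subtree in one of the ontologies
#' (round-robin across sources, so the sources carry complementary signal),
#' and a driver gene draws each annotation record in that source from its
#' type's subtree with probability `signal_strength`, otherwise uniformly.
#' `signal_strength = 0` yields an exact null dataset.
#'
#' @param n_classes_per_ontology Classes per generated ontology (default
#'   20).
#' @param dag_branching Tree branching factor (default 3).
#' @param n_genes Number of genes (default 500).
#' @param n_cancer_types Number of cancer types (default 6); must not
#'   exceed the number of designated subtrees available.
#' @param driver_fraction Fraction of genes that are drivers (default
#'   0.16).
#' @param holdout_fraction Fraction of driver genes withheld from the label
#'   table (default 0.2). Held-out drivers carry the full driver signature
#'   (annotation bias, network edges, elevated mutations, shifted variant
#'   scores) but are unlabelled, emulating the novel drivers the classifier
#'   is meant to discover and the validation statistics to confirm.
#' @param signal_strength Probability in `[0, 1]` that a driver's
#'   annotation in its signal source is drawn from the designated subtree
#'   (default 0.9).
#' @param annotations_per_gene Annotation records per gene, split uniformly
#'   across sources (default 30, comparable to the typical per-gene
#'   annotation count of well-covered human genes).
#' @param p_within Edge probability between two driver genes (default 0.2).
#' @param p_background Background edge probability (default 0.001); must not
#'   exceed `p_within`.
#' @param variant_shift Mean shift of pathogenicity scores in
#'   driver/candidate genes, recycled over tools or a named per-tool vector
#'   (default 2).
#' @param variants_per_gene Variant records per gene (default 3).
#' @param mutation_rate_background,mutation_rate_driver Per-base Poisson
#'   mutation rates for non-driver and driver/candidate genes (defaults
#'   1e-4 and 3e-4).
#' @param sources Source tags of the generated ontologies (default
#'   `c("CMPO", "GO", "MP")`).
#' @param seed Master seed; all generators are deterministic under it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_classes_per_ontology = 20L,
                             dag_branching = 3L,
                             n_genes = 500L,
                             n_cancer_types = 6L,
                             driver_fraction = 0.16,
                             holdout_fraction = 0.2,
                             signal_strength = 0.9,
                             annotations_per_gene = 30L,
                             p_within = 0.2,
                             p_background = 0.001,
                             variant_shift = 2,
                             variants_per_gene = 3L,
                             mutation_rate_background = 1e-4,
                             mutation_rate_driver = 3e-4,
                             sources = c("CMPO", "GO", "MP"),
                             seed = 1L) {
  stopifnot(
    n_classes_per_ontology >= 2, dag_branching >= 1, n_genes >= 1,
    n_cancer_types >= 1, driver_fraction >= 0, driver_fraction <= 1,
    holdout_fraction >= 0, holdout_fraction < 1,
    signal_strength >= 0, signal_strength <= 1, annotations_per_gene >= 1,
    p_within >= 0, p_within <= 1, p_background >= 0, p_background <= 1,
    p_within >= p_background, variants_per_gene >= 1,
    mutation_rate_background > 0, mutation_rate_driver > 0,
    length(sources) >= 1
  )
  structure(
    list(
      n_classes_per_ontology = as.integer(n_classes_per_ontology),
      dag_branching = as.integer(dag_branching),
      n_genes = as.integer(n_genes),
      n_cancer_types = as.integer(n_cancer_types),
      driver_fraction = driver_fraction,
      holdout_fraction = holdout_fraction,
      signal_strength = signal_strength,
      annotations_per_gene = as.integer(annotations_per_gene),
      p_within = p_within, p_background = p_background,
      variant_shift = variant_shift,
      variants_per_gene = as.integer(variants_per_gene),
      mutation_rate_background = mutation_rate_background,
      mutation_rate_driver = mutation_rate_driver,
      sources = sources,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Generate a synthetic ontology
#'
#' Builds a rooted tree of `n_classes_per_ontology` classes with the
#' configured branching factor; roughly 10% of the non-root classes
#' additionally carry one `part_of` existential axiom to a random class.
#' Every class gets an auto-generated label.
#'
#' @param config A [synthetic_config()].
#' @param source_tag Tag (and id prefix) for the generated ontology.
#' @return An [ontology].
#' @export
generate_ontology <- function(config, source_tag) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_classes_per_ontology
  b <- config$dag_branching
  ids <- sprintf("%s:%04d", toupper(source_tag), seq_len(n))
  classes <- tibble::tibble(
    id = ids,
    label = paste(tolower(source_tag), "class", seq_len(n)),
    definition = NA_character_
  )
  parent <- function(i) (i - 2L) %/% b + 1L
  subj <- seq(2L, length.out = max(n - 1L, 0L))
  axioms <- tibble::tibble(
    subject = ids[subj], kind = "subclass", relation = NA_character_,
    object = ids[vapply(subj, parent, integer(1))], provenance = "asserted"
  )
  extra <- with_local_seed(derive_seed(config$seed, paste0("ont:", source_tag)), {
    k <- max(0L, round(0.1 * (n - 1L)))
    if (k == 0L) return(NULL)
    who <- sample(subj, k)
    tibble::tibble(
      subject = ids[who], kind = "subclass_existential",
      relation = "part_of",
      object = ids[vapply(who, function(i) {
        sample(setdiff(seq_len(n), i), 1L)
      }, integer(1))],
      provenance = "asserted"
    )
  })
  ontology(classes, dplyr::bind_rows(axioms, extra), toupper(source_tag))
}

# Depth of each node in the generated tree (root = 0).
tree_depths <- function(n, b) {
  depth <- integer(n)
  for (i in seq_len(n)[-1]) depth[i] <- depth[(i - 2L) %/% b + 1L] + 1L
  depth
}

# Designated subtree classes per cancer type, round-robin across sources so
# each source carries the signal of roughly 1/|sources| of the types.
designate_subtrees <- function(config) {
  n <- config$n_classes_per_ontology
  b <- config$dag_branching
  depth <- tree_depths(n, b)
  roots <- which(depth == 2L)
  if (length(roots) == 0L) roots <- which(depth == max(depth))
  n_src <- length(config$sources)
  per_src <- ceiling(config$n_cancer_types / n_src)
  if (per_src > length(roots)) {
    stop(
      "config supports at most ", length(roots) * n_src,
      " cancer types (one designated subtree each); requested ",
      config$n_cancer_types,
      call. = FALSE
    )
  }
  children <- split(seq_len(n)[-1], vapply(seq_len(n)[-1], function(i) {
    (i - 2L) %/% b + 1L
  }, integer(1)))
  descendants <- function(r) {
    out <- r
    frontier <- r
    while (length(frontier) > 0L) {
      nxt <- unlist(children[as.character(frontier)], use.names = FALSE)
      out <- c(out, nxt)
      frontier <- nxt
    }
    out
  }
  purrr::map_dfr(seq_len(config$n_cancer_types), function(t) {
    src <- config$sources[(t - 1L) %% n_src + 1L]
    root <- roots[(t - 1L) %/% n_src + 1L]
    tibble::tibble(
      cancer_type = sprintf("T%02d", t),
      source_tag = toupper(src),
      class_id = sprintf("%s:%04d", toupper(src), descendants(root))
    )
  })
}

#' Generate gene annotations and driver labels with a planted signature
#'
#' Drivers (`driver_fraction` of genes, types dealt round-robin so every
#' type has a comparable positive count) draw annotation records in their
#' type's designated source from that type's subtree with probability
#' `signal_strength`; all other records are uniform over the source's
#' classes.
#'
#' @param config A [synthetic_config()].
#' @return List with `annotations` (tibble `gene_id`, `class_id`,
#'   `source_tag`), `labels` (tibble `gene_id`, `cancer_type` — labelled
#'   drivers only), `holdout` (same shape; the withheld novel drivers),
#'   `genes` (character vector of all gene ids) and `subtrees` (the
#'   designated subtree classes per type).
#' @export
generate_gene_data <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  subtrees <- designate_subtrees(config)
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  types <- sprintf("T%02d", seq_len(config$n_cancer_types))
  n_src <- length(config$sources)
  src_tags <- toupper(config$sources)
  class_pool <- lapply(stats::setNames(src_tags, src_tags), function(s) {
    sprintf("%s:%04d", s, seq_len(config$n_classes_per_ontology))
  })

  with_local_seed(derive_seed(config$seed, "genes"), {
    n_driver <- round(config$driver_fraction * config$n_genes)
    driver_genes <- sort(sample(genes, n_driver))
    assignment <- tibble::tibble(
      gene_id = sample(driver_genes),
      cancer_type = rep_len(types, n_driver)
    )
    # hold out a fraction of drivers per type: they keep the full driver
    # signature but are absent from the label table
    held <- assignment |>
      dplyr::group_by(.data$cancer_type) |>
      dplyr::group_modify(function(df, key) {
        df[seq_len(round(config$holdout_fraction * nrow(df))), ]
      }) |>
      dplyr::ungroup() |>
      dplyr::select(dplyr::all_of(c("gene_id", "cancer_type")))
    labels <- dplyr::anti_join(assignment, held, by = "gene_id") |>
      dplyr::arrange(.data$gene_id)
    holdout <- dplyr::arrange(held, .data$gene_id)

    gene_type <- stats::setNames(assignment$cancer_type,
                                 assignment$gene_id)
    ann <- purrr::map_dfr(genes, function(g) {
      src <- sample(src_tags, config$annotations_per_gene, replace = TRUE)
      type <- gene_type[g]
      cls <- vapply(src, function(s) {
        pool <- class_pool[[s]]
        if (!is.na(type)) {
          sub <- subtrees$class_id[subtrees$cancer_type == type &
                                     subtrees$source_tag == s]
          if (length(sub) > 0L &&
              stats::runif(1) < config$signal_strength) {
            pool <- sub
          }
        }
        sample(pool, 1L)
      }, character(1))
      tibble::tibble(gene_id = g, class_id = cls, source_tag = src)
    })
    list(annotations = ann, labels = labels, holdout = holdout,
         genes = genes, subtrees = subtrees)
  })
}

#' Generate a driver-enriched interaction network
#'
#' Erdős–Rényi background at `p_background` with driver–driver pairs
#' upgraded to `p_within`. All genes become nodes; self-loops never occur.
#'
#' @param genes Character vector of all gene ids (network nodes).
#' @param driver_genes Driver genes (labelled plus held-out novel drivers);
#'   a tibble with a `gene_id` column is also accepted.
#' @param config A [synthetic_config()].
#' @return An `interaction_network`.
#' @export
generate_network <- function(genes, driver_genes, config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.data.frame(driver_genes)) driver_genes <- driver_genes$gene_id
  drivers <- unique(driver_genes)
  pairs <- utils::combn(genes, 2L)
  both_driver <- pairs[1L, ] %in% drivers & pairs[2L, ] %in% drivers
  p <- ifelse(both_driver, config$p_within, config$p_background)
  keep <- with_local_seed(derive_seed(config$seed, "network"), {
    stats::runif(length(p)) < p
  })
  interaction_network(
    tibble::tibble(gene_a = pairs[1L, keep], gene_b = pairs[2L, keep]),
    nodes = genes
  )
}

#' Generate per-gene somatic mutation counts and lengths
#'
#' Gene lengths are uniform on 5–100 kb; mutation counts are Poisson with a
#' per-base rate of `mutation_rate_driver` for driver or candidate genes
#' and `mutation_rate_background` otherwise.
#'
#' @param genes All gene ids.
#' @param elevated_genes Genes with the elevated rate (drivers and/or
#'   candidates).
#' @param config A [synthetic_config()].
#' @return Tibble `gene_id`, `mutation_count`, `gene_length`.
#' @export
generate_mutations <- function(genes, elevated_genes, config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(derive_seed(config$seed, "mutations"), {
    len <- round(stats::runif(length(genes), 5e3, 1e5))
    rate <- ifelse(genes %in% elevated_genes,
                   config$mutation_rate_driver,
                   config$mutation_rate_background)
    tibble::tibble(
      gene_id = genes,
      mutation_count = stats::rpois(length(genes), len * rate),
      gene_length = len
    )
  })
}

#' Generate variant records with driver-shifted pathogenicity scores
#'
#' Each gene receives `variants_per_gene` variants. Tool scores are
#' standard normal for background genes and shifted by `variant_shift` for
#' genes in `shifted_genes` — with the sign flipped for `lower_worse`
#' tools, so that shifted genes always look *more deleterious* under each
#' tool's own convention. 90% of variants are coding; allele frequency is
#' missing for 30% of variants and Beta(0.5, 10)-distributed otherwise.
#'
#' @param genes All gene ids.
#' @param shifted_genes Genes whose variants carry the pathogenicity shift
#'   (drivers and/or predicted candidates).
#' @param config A [synthetic_config()].
#' @param orientations Tool orientation map (default
#'   [default_orientations()]); generated tools are its names.
#' @return Tibble with `gene_id`, `variant_id`, `coding_flag`,
#'   `allele_frequency`, and one numeric column per tool.
#' @export
generate_variants <- function(genes, shifted_genes, config,
                              orientations = default_orientations()) {
  stopifnot(inherits(config, "synthetic_config"))
  tools <- names(orientations)
  shift <- config$variant_shift
  if (is.null(names(shift))) {
    shift <- stats::setNames(rep_len(shift, length(tools)), tools)
  }
  with_local_seed(derive_seed(config$seed, "variants"), {
    gene_id <- rep(genes, each = config$variants_per_gene)
    n <- length(gene_id)
    shifted <- gene_id %in% shifted_genes
    out <- tibble::tibble(
      gene_id = gene_id,
      variant_id = sprintf("var%05d", seq_len(n)),
      coding_flag = stats::runif(n) < 0.9,
      allele_frequency = ifelse(stats::runif(n) < 0.3, NA_real_,
                                stats::rbeta(n, 0.5, 10))
    )
    for (tool in tools) {
      mu <- ifelse(shifted, shift[[tool]], 0)
      if (orientations[[tool]] == "lower_worse") mu <- -mu
      out[[tool]] <- stats::rnorm(n, mean = mu)
    }
    out
  })
}

#' Read / write a variant table as TSV
#'
#' @param path TSV path; must carry `gene_id`, `variant_id`, `coding_flag`,
#'   `allele_frequency` plus tool score columns.
#' @return Tibble of variant records.
#' @export
read_variants <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  required <- c("gene_id", "variant_id", "coding_flag", "allele_frequency")
  if (!all(required %in% names(df))) {
    stop("variant table must have columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  df$coding_flag <- as.logical(df$coding_flag)
  df
}

#' @rdname read_variants
#' @param variants Tibble of variant records.
#' @export
write_variants <- function(variants, path) {
  readr::write_tsv(variants, path)
  invisible(path)
}

#' Simulate a complete study into a directory
#'
#' Runs every generator under one config, writes all files in the dialects
#' the readers consume (OBO ontologies, annotation/label/network/mutation
#' TSVs, variant TSV), and records a `manifest.json` with the config, file
#' paths and md5 checksums.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects and the manifest.
#' @export
simulate_study <- function(config = synthetic_config(), dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ontologies <- lapply(
    stats::setNames(toupper(config$sources), toupper(config$sources)),
    function(s) generate_ontology(config, s)
  )
  gd <- generate_gene_data(config)
  drivers <- unique(c(gd$labels$gene_id, gd$holdout$gene_id))
  network <- generate_network(gd$genes, drivers, config)
  mutations <- generate_mutations(gd$genes, drivers, config)
  variants <- generate_variants(gd$genes, drivers, config)

  paths <- list()
  for (s in names(ontologies)) {
    paths[[paste0("ontology_", s)]] <-
      write_obo(ontologies[[s]], file.path(dir, paste0(tolower(s), ".obo")))
  }
  paths$annotations <-
    write_annotations(gd$annotations, file.path(dir, "annotations.tsv"))
  paths$labels <- write_labels(gd$labels, file.path(dir, "labels.tsv"))
  # synthetic ground truth for the withheld novel drivers
  paths$holdout <- write_labels(
    gd$holdout, file.path(dir, "synthetic_holdout_truth.tsv")
  )
  paths$network <- write_network(network, file.path(dir, "network.tsv"))
  paths$mutations <- {
    readr::write_tsv(mutations, file.path(dir, "mutations.tsv"))
    file.path(dir, "mutations.tsv")
  }
  paths$variants <- write_variants(variants, file.path(dir, "variants.tsv"))

  manifest <- list(
    config = unclass(config),
    files = lapply(paths, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(
    ontologies = ontologies, annotations = gd$annotations,
    labels = gd$labels, holdout = gd$holdout, genes = gd$genes,
    subtrees = gd$subtrees, network = network, mutations = mutations,
    variants = variants, manifest = manifest
  ))
}
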