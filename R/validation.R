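#' Read an interaction network edge list
#'
#' STRING-like TSV with two gene-id columns (`gene_a`, `gene_b`, or the
#' first two columns of a headerless file); an optional numeric `score`
#' column can be thresholded. Self-loops are dropped and edges are stored
#' unordered and deduplicated.
#'
#' @param path Path to the TSV.
#' @param min_score If the file carries a `score` column, keep only edges
#'   with `score >= min_score` (default `NULL`: keep all).
#' @return An `interaction_network`: list with `nodes` (character vector)
#'   and `edges` (tibble `gene_a`, `gene_b`).
#' @export
read_network <- function(path, min_score = NULL) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(df))) {
    names(df)[1:2] <- c("gene_a", "gene_b")
  }
  if (!is.null(min_score) && "score" %in% names(df)) {
    df <- df[df$score >= min_score, ]
  }
  interaction_network(df[, c("gene_a", "gene_b")])
}

#' Construct an interaction network
#'
#' @param edges Tibble/data frame with columns `gene_a`, `gene_b`.
#' @param nodes Optional character vector of nodes (defaults to the edge
#'   endpoints); isolated nodes may be listed here.
#' @return An `interaction_network` object.
#' @export
interaction_network <- function(edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)[, c("gene_a", "gene_b")]
  edges <- edges[edges$gene_a != edges$gene_b, ]
  # canonical unordered form
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  edges <- dplyr::distinct(tibble::tibble(gene_a = a, gene_b = b))
  endpoint_nodes <- unique(c(edges$gene_a, edges$gene_b))
  if (is.null(nodes)) {
    nodes <- endpoint_nodes
  } else if (!all(endpoint_nodes %in% nodes)) {
    stop("edge endpoints missing from `nodes`", call. = FALSE)
  }
  structure(
    list(nodes = sort(unique(nodes)), edges = edges),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Write a network edge list as TSV
#'
#' @param network An `interaction_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  readr::write_tsv(network$edges, path)
  invisible(path)
}

#' Per-gene somatic mutation frequency
#'
#' Frequency is the recorded somatic mutation count divided by the gene
#' length in bases. Whether the supplied length is the CDS length or the
#' genomic span is the caller's choice; the frequency is interpreted
#' relative to whichever was given.
#'
#' @param mutation_counts Named numeric vector (or tibble with `gene_id`,
#'   `mutation_count`) of per-gene mutation counts.
#' @param gene_lengths Named numeric vector (or tibble with `gene_id`,
#'   `gene_length`) of positive gene lengths; must cover every counted
#'   gene.
#' @return Tibble with columns `gene_id`, `mutation_count`, `gene_length`,
#'   `frequency`.
#' @export
mutation_frequency <- function(mutation_counts, gene_lengths) {
  if (is.data.frame(mutation_counts)) {
    mutation_counts <- stats::setNames(mutation_counts$mutation_count,
                                       mutation_counts$gene_id)
  }
  if (is.data.frame(gene_lengths)) {
    gene_lengths <- stats::setNames(gene_lengths$gene_length,
                                    gene_lengths$gene_id)
  }
  genes <- names(mutation_counts)
  len <- gene_lengths[genes]
  bad <- genes[is.na(len) | len <= 0]
  if (length(bad) > 0L) {
    stop(
      "missing or non-positive gene length for: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  stopifnot(all(mutation_counts >= 0))
  tibble::tibble(
    gene_id = genes,
    mutation_count = as.numeric(mutation_counts),
    gene_length = as.numeric(len),
    frequency = as.numeric(mutation_counts) / as.numeric(len)
  )
}

#' Read a mutation count table
#'
#' @param path TSV with header columns `gene_id`, `mutation_count`,
#'   `gene_length`.
#' @return Tibble with those columns.
#' @export
read_mutations <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  required <- c("gene_id", "mutation_count", "gene_length")
  if (!all(required %in% names(df))) {
    stop("mutation table must have columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  df[, required]
}

#' Number of sampled genes adjacent to a known driver
#'
#' Counts how many of the `sampled` genes have at least one network edge to
#' any gene in `known_drivers`. Adjacency, not membership: a sampled gene
#' that is itself a driver but has no driver neighbour contributes 0.
#'
#' @param network An `interaction_network`.
#' @param sampled Character vector of sampled genes, all present in the
#'   network.
#' @param known_drivers Character vector of known driver genes.
#' @return Integer count.
#' @export
connection_count <- function(network, sampled, known_drivers) {
  missing <- setdiff(sampled, network$nodes)
  if (length(missing) > 0L) {
    stop("sampled gene(s) absent from network: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  adj <- driver_adjacent_nodes(network, known_drivers)
  sum(sampled %in% adj)
}

driver_adjacent_nodes <- function(network, known_drivers) {
  e <- network$edges
  unique(c(e$gene_a[e$gene_b %in% known_drivers],
           e$gene_b[e$gene_a %in% known_drivers]))
}

#' Permutation-test configuration
#'
#' @param n_permutations Number of random node samples (default 10000).
#' @param sample_size Nodes drawn per sample; defaults at test time to the
#'   number of candidate genes.
#' @param seed Integer seed.
#' @param exclude_drivers Drop known drivers from the sampling frame
#'   (default `TRUE`; candidate genes are non-drivers by construction, so
#'   the null resamples from the same frame).
#' @return A list of class `permutation_config`.
#' @export
permutation_config <- function(n_permutations = 10000L, sample_size = NULL,
                               seed = 1L, exclude_drivers = TRUE) {
  stopifnot(n_permutations >= 1)
  structure(
    list(
      n_permutations = as.integer(n_permutations),
      sample_size = if (is.null(sample_size)) NULL else
        as.integer(sample_size),
      seed = as.integer(seed),
      exclude_drivers = isTRUE(exclude_drivers)
    ),
    class = "permutation_config"
  )
}

#' Network-module permutation test for candidate driver genes
#'
#' Tests whether predicted candidate driver genes are connected to known
#' driver genes more often than random gene sets of the same size. The
#' observed statistic is [connection_count()] of the candidates; the null
#' distribution is the connection count over `n_permutations` uniform node
#' samples of `sample_size` genes. Two p-values are reported: the empirical
#' permutation p-value `(1 + #{null >= observed}) / (1 + n_permutations)`,
#' and a one-tailed one-sample t-test of the null draws against the
#' observed value (the style of summary often quoted for this comparison).
#'
#' @param network An `interaction_network`.
#' @param candidates Character vector of candidate genes, all in the
#'   network.
#' @param known_drivers Character vector of known driver genes.
#' @param config A [permutation_config()]; `sample_size` defaults to
#'   `length(candidates)`.
#' @return A `test_result` whose `statistic` is the observed connection
#'   count; `null_summary` carries the null mean/sd, the empirical p-value,
#'   and the full vector of null draws.
#' @export
network_permutation_test <- function(network, candidates, known_drivers,
                                     config = permutation_config()) {
  stopifnot(inherits(config, "permutation_config"))
  observed <- connection_count(network, candidates, known_drivers)
  frame <- network$nodes
  if (config$exclude_drivers) {
    frame <- setdiff(frame, known_drivers)
  }
  m <- config$sample_size %||% length(candidates)
  if (m > length(frame)) {
    stop("sample_size ", m, " exceeds the ", length(frame),
         " nodes in the sampling frame", call. = FALSE)
  }
  adj <- driver_adjacent_nodes(network, known_drivers)
  in_adj <- frame %in% adj
  null_draws <- with_local_seed(config$seed, {
    vapply(seq_len(config$n_permutations), function(i) {
      sum(in_adj[sample.int(length(frame), m)])
    }, numeric(1))
  })
  empirical_p <- (1 + sum(null_draws >= observed)) /
    (1 + config$n_permutations)
  null_sd <- stats::sd(null_draws)
  # one-sample t of the null draws against the observed count
  t_p <- if (null_sd == 0) {
    if (mean(null_draws) >= observed) 1 else 0
  } else {
    t_stat <- (mean(null_draws) - observed) /
      (null_sd / sqrt(config$n_permutations))
    stats::pt(t_stat, config$n_permutations - 1)
  }
  new_test_result(
    "network_permutation", observed, t_p,
    direction = "candidates more driver-connected than random samples",
    n_group_a = length(candidates), n_group_b = config$n_permutations,
    null_summary = list(
      mean = mean(null_draws), sd = null_sd,
      empirical_p = empirical_p, draws = null_draws
    )
  )
}

#' Variant filters
#'
#' `filter_coding_variants()` keeps variants whose `coding_flag` is `TRUE`;
#' records with a missing flag are treated as non-coding and dropped (a
#' message reports how many). `filter_rare_variants()` keeps variants with
#' population allele frequency below `af_threshold`; a missing allele
#' frequency is kept (novel-variant convention).
#'
#' @param variants Tibble of variant records with columns `gene_id`,
#'   `variant_id`, `coding_flag`, `allele_frequency`, and one numeric score
#'   column per pathogenicity tool.
#' @return The filtered tibble.
#' @export
filter_coding_variants <- function(variants) {
  flag <- variants$coding_flag
  n_missing <- sum(is.na(flag))
  if (n_missing > 0L) {
    message(n_missing,
            " variant(s) without a coding flag treated as non-coding")
  }
  variants[!is.na(flag) & flag, ]
}

#' @rdname filter_coding_variants
#' @param af_threshold Allele-frequency cutoff in (0, 1); default 0.01.
#' @export
filter_rare_variants <- function(variants, af_threshold = 0.01) {
  stopifnot(af_threshold > 0, af_threshold < 1)
  af <- variants$allele_frequency
  variants[is.na(af) | af < af_threshold, ]
}

#' Default pathogenicity-score orientations
#'
#' Whether a larger score means more damaging differs by tool: SIFT and
#' FATHMM report lower scores for more deleterious variants; PolyPhen-2,
#' MutationAssessor, MutationTaster, CADD and VEST3 report higher scores.
#'
#' @return Named character vector mapping tool name to `"higher_worse"` or
#'   `"lower_worse"`.
#' @export
default_orientations <- function() {
  c(
    SIFT = "lower_worse",
    PolyPhen2 = "higher_worse",
    MutationAssessor = "higher_worse",
    MutationTaster = "higher_worse",
    CADD = "higher_worse",
    VEST3 = "higher_worse",
    FATHMM = "lower_worse"
  )
}

#' Per-tool pathogenicity-score enrichment in candidate driver genes
#'
#' For every pathogenicity tool with scores in the variant table, runs a
#' one-tailed Mann-Whitney U test that variants in candidate driver genes
#' are scored *more deleterious* than variants in the comparison genes. The
#' alternative direction follows each tool's orientation: for
#' `higher_worse` tools candidate scores are tested as stochastically
#' greater, for `lower_worse` tools as stochastically smaller.
#'
#' @param variants Tibble of (already coding-filtered) variant records; tool
#'   scores in columns named after the tools.
#' @param candidate_genes,comparison_genes Disjoint gene sets.
#' @param orientations Named orientation map; defaults to
#'   [default_orientations()].
#' @return Named list of `test_result`s, one per tool with at least two
#'   scored variants in each group; tools with fewer are skipped with a
#'   warning.
#' @export
pathogenicity_enrichment <- function(variants, candidate_genes,
                                     comparison_genes,
                                     orientations = default_orientations()) {
  if (length(intersect(candidate_genes, comparison_genes)) > 0L) {
    stop("candidate and comparison gene sets must be disjoint",
         call. = FALSE)
  }
  tools <- intersect(names(orientations), names(variants))
  out <- list()
  for (tool in tools) {
    a <- variants[[tool]][variants$gene_id %in% candidate_genes]
    b <- variants[[tool]][variants$gene_id %in% comparison_genes]
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) {
      warning("tool ", tool, " has fewer than 2 scored variants in a ",
              "group; skipped", call. = FALSE)
      next
    }
    alt <- if (orientations[[tool]] == "lower_worse") "a_less" else
      "a_greater"
    res <- mann_whitney_one_tailed(a, b, alt)
    res$test_name <- paste0("pathogenicity_", tool)
    out[[tool]] <- res
  }
  out
}

#' Tidy a list of per-tool enrichment results
#'
#' @param results Named list of `test_result`s from
#'   [pathogenicity_enrichment()].
#' @return Tibble with one row per tool.
#' @export
tidy_enrichment <- function(results) {
  purrr::map_dfr(names(results), function(tool) {
    dplyr::bind_cols(tibble::tibble(tool = tool), tidy(results[[tool]]))
  })
}
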