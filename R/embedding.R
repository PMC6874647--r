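#' Embedding training parameters
#'
#' Defaults follow the selected configuration of the workflow: skip-gram
#' model, embedding size 100, context window 5, minimum token count 5.
#' Because ontology axiom sentences are short (3 tokens for a plain subclass
#' axiom, rarely more than 10), a window of 5 always spans a whole axiom
#' sentence.
#'
#' @param dim Embedding dimensionality (default 100).
#' @param window Maximum context window (default 5).
#' @param min_count Minimum corpus frequency for a token to receive a vector
#'   (default 5). Entity tokens passed to [train_embeddings()] are exempt.
#' @param model Embedding objective; only `"skip-gram"` is supported.
#' @param epochs Training passes over the corpus (default 50). The
#'   word2vec default of 5 passes assumes corpora of millions of tokens;
#'   the corpora this package trains on are orders of magnitude smaller,
#'   so more passes are needed before gene vectors reflect their
#'   annotation structure.
#' @param negative Negative samples per positive pair (default 5).
#' @param sample Frequent-token subsampling threshold (default 1e-3, the
#'   word2vec default); 0 disables subsampling. Without it the ubiquitous
#'   relation tokens (`hasAnnotation`, `SubClassOf`) dominate every
#'   context.
#' @param learning_rate Initial learning rate, linearly decayed (default
#'   0.025).
#' @param seed Integer seed; training is single-threaded and bit-for-bit
#'   reproducible under a fixed seed.
#' @return A list of class `embedding_params`.
#' @export
embedding_params <- function(dim = 100L, window = 5L, min_count = 5L,
                             model = "skip-gram", epochs = 50L,
                             negative = 5L, sample = 1e-3,
                             learning_rate = 0.025, seed = 1L) {
  model <- match.arg(model, "skip-gram")
  stopifnot(dim >= 1, window >= 1, min_count >= 1, epochs >= 1,
            negative >= 1, sample >= 0, learning_rate > 0)
  structure(
    list(
      dim = as.integer(dim), window = as.integer(window),
      min_count = as.integer(min_count), model = model,
      epochs = as.integer(epochs), negative = as.integer(negative),
      sample = sample, learning_rate = learning_rate,
      seed = as.integer(seed)
    ),
    class = "embedding_params"
  )
}

#' Train skip-gram embeddings on a corpus
#'
#' Trains word2vec-style skip-gram vectors with negative sampling over the
#' corpus sentences. The vocabulary contains every token whose corpus
#' frequency is at least `min_count`, plus every `entity_tokens` member that
#' occurs at all — genes are kept regardless of frequency so that a gene
#' with few annotations still receives a vector.
#'
#' @param corpus A `corpus` from [build_corpus()].
#' @param params An [embedding_params()] object.
#' @param entity_tokens Character vector of tokens (gene ids) exempt from
#'   the minimum-count threshold.
#' @return An `embedding_table`: a list with `vectors` (numeric matrix, one
#'   row per token) and `params`.
#' @export
train_embeddings <- function(corpus, params = embedding_params(),
                             entity_tokens = character()) {
  stopifnot(inherits(corpus, "corpus"), inherits(params, "embedding_params"))
  if (length(corpus$sentences) == 0L) {
    stop("corpus is empty", call. = FALSE)
  }
  tokens <- unlist(corpus$sentences, use.names = FALSE)
  freq <- table(tokens)
  keep <- names(freq)[freq >= params$min_count |
                        names(freq) %in% entity_tokens]
  # fixed vocabulary order: frequency-descending, id as tie-break
  keep <- keep[order(-as.integer(freq[keep]), keep, method = "radix")]
  if (length(keep) == 0L) {
    stop("no token reaches min_count and no entity token occurs",
         call. = FALSE)
  }
  vocab <- stats::setNames(seq_along(keep), keep)
  sentences <- lapply(corpus$sentences, function(s) {
    idx <- vocab[s]
    as.integer(idx[!is.na(idx)] - 1L)
  })
  sentences <- sentences[lengths(sentences) >= 2L]
  mat <- sgns_train_cpp(
    sentences, length(keep), as.numeric(freq[keep]),
    params$dim, params$window, params$negative, params$epochs,
    params$learning_rate, params$sample, params$seed
  )
  rownames(mat) <- keep
  structure(list(vectors = mat, params = params), class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d tokens x %d dimensions\n",
              nrow(x$vectors), ncol(x$vectors)))
  invisible(x)
}

#' Write embeddings in word2vec text format
#'
#' First line `N dim`, then one line per token: the token followed by its
#' vector components, space-separated.
#'
#' @param table An `embedding_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(table, path) {
  m <- table$vectors
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(m), ncol(m)), con)
  lines <- vapply(seq_len(nrow(m)), function(i) {
    paste(rownames(m)[i],
          paste(sprintf("%.17g", m[i, ]), collapse = " "))
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read embeddings from word2vec text format
#'
#' @param path Path to a file written by [write_embeddings()] (or any
#'   word2vec text-format file).
#' @param params Optional [embedding_params()] to attach; dimensions must
#'   agree with the file header.
#' @return An `embedding_table`.
#' @export
read_embeddings <- function(path, params = NULL) {
  lines <- readLines(path, warn = FALSE)
  header <- as.integer(strsplit(lines[1L], " ")[[1L]])
  n <- header[1L]
  d <- header[2L]
  parts <- strsplit(lines[1L + seq_len(n)], " ", fixed = TRUE)
  toks <- vapply(parts, `[[`, character(1), 1L)
  m <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1L])))
  stopifnot(ncol(m) == d)
  rownames(m) <- toks
  if (is.null(params)) {
    params <- embedding_params(dim = d)
  } else {
    stopifnot(params$dim == d)
  }
  structure(list(vectors = m, params = params), class = "embedding_table")
}

#' Assemble a gene feature matrix for one representation mode
#'
#' Five representations are supported: one per annotation source (the gene's
#' vector from the embedding trained on that single ontology), the
#' *intersection* (vectors from all single-source tables concatenated, for
#' genes annotated in every source), and the *union* (the gene's vector from
#' the embedding trained on the merged ontology, for genes annotated in at
#' least one source).
#'
#' @param mode A source tag (e.g. `"CMPO"`), `"intersection"`, or `"union"`.
#' @param tables Named list of `embedding_table`s: one per source tag, plus
#'   `"MERGED"` for the union mode.
#' @param annotations Tibble with `gene_id`, `class_id`, `source_tag` rows
#'   covering all sources.
#' @param sources Character vector fixing the source order for intersection
#'   concatenation; defaults to the sorted source tags present in
#'   `annotations`.
#' @return A `gene_features` tibble: `gene_id` plus `f1..fp` numeric feature
#'   columns, with attributes `mode` and `feature_dim`.
#' @export
build_representation <- function(mode, tables, annotations,
                                 sources = NULL) {
  stopifnot(is.list(tables))
  if (is.null(sources)) {
    sources <- sort(unique(annotations$source_tag))
  }
  single_genes <- function(src) {
    tab <- tables[[src]]
    if (is.null(tab)) {
      stop("mode '", mode, "' requires an embedding table for source '",
           src, "'", call. = FALSE)
    }
    genes <- unique(annotations$gene_id[annotations$source_tag == src])
    sort(intersect(genes, rownames(tab$vectors)))
  }

  if (mode == "intersection") {
    gene_sets <- lapply(sources, single_genes)
    genes <- sort(Reduce(intersect, gene_sets))
    mat <- do.call(cbind, lapply(sources, function(src) {
      tables[[src]]$vectors[genes, , drop = FALSE]
    }))
  } else if (mode == "union") {
    tab <- tables[["MERGED"]]
    if (is.null(tab)) {
      stop("mode 'union' requires an embedding table named 'MERGED' ",
           "trained on the merged ontology", call. = FALSE)
    }
    genes <- sort(intersect(unique(annotations$gene_id),
                            rownames(tab$vectors)))
    mat <- tab$vectors[genes, , drop = FALSE]
  } else {
    if (!mode %in% sources) {
      stop("unknown representation mode '", mode, "'; expected one of ",
           paste(c(sources, "intersection", "union"), collapse = ", "),
           call. = FALSE)
    }
    genes <- single_genes(mode)
    mat <- tables[[mode]]$vectors[genes, , drop = FALSE]
  }

  p <- ncol(mat)
  colnames(mat) <- paste0("f", seq_len(p))
  out <- dplyr::bind_cols(tibble::tibble(gene_id = genes),
                          tibble::as_tibble(mat))
  attr(out, "mode") <- mode
  attr(out, "feature_dim") <- p
  class(out) <- c("gene_features", class(out))
  out
}

#' Extract the numeric feature matrix from a `gene_features` tibble
#'
#' @param features A `gene_features` tibble from [build_representation()].
#' @return Numeric matrix with gene ids as row names.
#' @export
features_matrix <- function(features) {
  m <- as.matrix(features[, setdiff(names(features), "gene_id")])
  rownames(m) <- features$gene_id
  storage.mode(m) <- "double"
  m
}
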