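# A small corpus with two gene groups annotated to disjoint class sets,
# used across the embedding tests.
two_group_corpus <- function(n_per_group = 100L, ann_per_gene = 10L,
                             seed = 11L) {
  withr::with_seed(seed, {
    g_a <- sprintf("GA%03d", seq_len(n_per_group))
    g_b <- sprintf("GB%03d", seq_len(n_per_group))
    cls_a <- sprintf("CA_%d", 1:5)
    cls_b <- sprintf("CB_%d", 1:5)
    mk <- function(genes, cls) {
      unlist(lapply(genes, function(g) {
        lapply(seq_len(ann_per_gene),
               function(i) c(g, "hasAnnotation", sample(cls, 1L)))
      }), recursive = FALSE)
    }
    sentences <- c(mk(g_a, cls_a), mk(g_b, cls_b))
    list(
      corpus = structure(
        list(sentences = sentences,
             counts = c(axiom = 0L, metadata = 0L,
                        association = length(sentences))),
        class = "corpus"
      ),
      genes_a = g_a, genes_b = g_b
    )
  })
}

test_that("vocabulary obeys min_count with entity exemption", {
  sentences <- c(
    rep(list(c("G1", "hasAnnotation", "C_common")), 6L),
    rep(list(c("G2", "hasAnnotation", "C_rare")), 4L)
  )
  corpus <- structure(
    list(sentences = sentences,
         counts = c(axiom = 0L, metadata = 0L, association = 10L)),
    class = "corpus"
  )
  tab <- train_embeddings(
    corpus, embedding_params(dim = 8L, epochs = 2L, seed = 1L),
    entity_tokens = c("G1", "G2")
  )
  toks <- rownames(tab$vectors)
  expect_true("C_common" %in% toks)       # frequency 6 >= 5
  expect_false("C_rare" %in% toks)        # frequency 4 < 5, not an entity
  expect_true(all(c("G1", "G2") %in% toks))  # entities exempt
  expect_equal(ncol(tab$vectors), 8L)
  expect_true(all(is.finite(tab$vectors)))
})

test_that("default parameters carry the published embedding configuration", {
  p <- embedding_params()
  expect_equal(p$dim, 100L)
  expect_equal(p$window, 5L)
  expect_equal(p$min_count, 5L)
  expect_equal(p$model, "skip-gram")
})

test_that("training is deterministic under a fixed seed", {
  tg <- two_group_corpus(20L, 5L)
  params <- embedding_params(dim = 16L, epochs = 3L, seed = 99L)
  t1 <- train_embeddings(tg$corpus, params,
                         entity_tokens = c(tg$genes_a, tg$genes_b))
  t2 <- train_embeddings(tg$corpus, params,
                         entity_tokens = c(tg$genes_a, tg$genes_b))
  expect_identical(t1$vectors, t2$vectors)

  t3 <- train_embeddings(tg$corpus,
                         embedding_params(dim = 16L, epochs = 3L,
                                          seed = 100L),
                         entity_tokens = c(tg$genes_a, tg$genes_b))
  expect_false(identical(t1$vectors, t3$vectors))
})

test_that("empty corpus is rejected", {
  empty <- structure(
    list(sentences = list(),
         counts = c(axiom = 0L, metadata = 0L, association = 0L)),
    class = "corpus"
  )
  expect_error(train_embeddings(empty), "empty")
})

test_that("genes sharing annotation classes are closer than disjoint genes", {
  tg <- two_group_corpus(100L, 10L)
  tab <- train_embeddings(
    tg$corpus, embedding_params(dim = 50L, epochs = 30L, seed = 5L),
    entity_tokens = c(tg$genes_a, tg$genes_b)
  )
  v <- tab$vectors[c(tg$genes_a, tg$genes_b), ]
  v <- v / sqrt(rowSums(v^2))
  sim <- v %*% t(v)
  n <- length(tg$genes_a)
  within_a <- sim[1:n, 1:n][upper.tri(sim[1:n, 1:n])]
  across <- sim[1:n, (n + 1):(2 * n)]
  expect_gt(mean(within_a), mean(across))
})

test_that("word2vec text serialization round-trips", {
  tg <- two_group_corpus(10L, 5L)
  tab <- train_embeddings(tg$corpus,
                          embedding_params(dim = 12L, epochs = 2L,
                                           seed = 1L),
                          entity_tokens = c(tg$genes_a, tg$genes_b))
  path <- withr::local_tempfile(fileext = ".txt")
  write_embeddings(tab, path)
  header <- strsplit(readLines(path, n = 1L), " ")[[1L]]
  expect_equal(as.integer(header), c(nrow(tab$vectors), 12L))
  back <- read_embeddings(path)
  expect_equal(back$vectors, tab$vectors, tolerance = 1e-12)
})

# Shared fixture for the representation-mode tests: three tiny sources with
# explicitly controlled gene coverage.
mode_fixture <- function() {
  mk_table <- function(genes, dim, seed) {
    m <- matrix(stats::rnorm(length(genes) * dim), length(genes), dim)
    rownames(m) <- genes
    structure(list(vectors = m, params = embedding_params(dim = dim)),
              class = "embedding_table")
  }
  withr::with_seed(3L, {
    # G1: all three sources; G2: CMPO only; G3: GO+MP; G4: unannotated
    ann <- tibble::tibble(
      gene_id = c("G1", "G1", "G1", "G2", "G3", "G3"),
      class_id = "X:1",
      source_tag = c("CMPO", "GO", "MP", "CMPO", "GO", "MP")
    )
    tables <- list(
      CMPO = mk_table(c("G1", "G2"), 4L, 1L),
      GO = mk_table(c("G1", "G3"), 4L, 2L),
      MP = mk_table(c("G1", "G3"), 4L, 3L),
      MERGED = mk_table(c("G1", "G2", "G3"), 4L, 4L)
    )
    list(ann = ann, tables = tables)
  })
}

test_that("representation modes select the documented gene sets", {
  fx <- mode_fixture()
  inter <- build_representation("intersection", fx$tables, fx$ann)
  expect_equal(inter$gene_id, "G1")
  expect_equal(attr(inter, "feature_dim"), 12L)  # 3 x 4 concatenated

  un <- build_representation("union", fx$tables, fx$ann)
  expect_setequal(un$gene_id, c("G1", "G2", "G3"))
  expect_equal(attr(un, "feature_dim"), 4L)

  cmpo <- build_representation("CMPO", fx$tables, fx$ann)
  expect_setequal(cmpo$gene_id, c("G1", "G2"))

  # G2 (CMPO-only) is excluded from intersection, included in union
  expect_false("G2" %in% inter$gene_id)
  expect_true("G2" %in% un$gene_id)
  # unannotated G4 appears nowhere
  expect_false("G4" %in% un$gene_id)

  # gene-count ordering: intersection <= each single <= union
  singles <- vapply(c("CMPO", "GO", "MP"), function(m) {
    nrow(build_representation(m, fx$tables, fx$ann))
  }, numeric(1))
  expect_true(all(nrow(inter) <= singles))
  expect_true(all(singles <= nrow(un)))
})

test_that("missing tables for a mode raise a configuration error", {
  fx <- mode_fixture()
  expect_error(
    build_representation("intersection", fx$tables[c("CMPO", "GO")],
                         fx$ann),
    "requires an embedding table"
  )
  expect_error(
    build_representation("union", fx$tables[c("CMPO", "GO", "MP")],
                         fx$ann),
    "MERGED"
  )
  expect_error(
    build_representation("bogus", fx$tables, fx$ann),
    "unknown representation mode"
  )
})

test_that("intersection concatenates in fixed source order", {
  fx <- mode_fixture()
  inter <- build_representation("intersection", fx$tables, fx$ann)
  m <- features_matrix(inter)
  expect_equal(unname(m["G1", 1:4]),
               unname(fx$tables$CMPO$vectors["G1", ]))
  expect_equal(unname(m["G1", 5:8]),
               unname(fx$tables$GO$vectors["G1", ]))
  expect_equal(unname(m["G1", 9:12]),
               unname(fx$tables$MP$vectors["G1", ]))
})
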