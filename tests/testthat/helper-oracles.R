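# Independent oracles used to cross-check the package implementations.
# These deliberately use brute-force strategies, not the code paths they
# verify.

# Exhaustive pairwise AUC: P(score+ > score-) + 0.5 P(score+ = score-).
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Reachability by exhaustive path enumeration over a subclass edge list
# (tibble with subject/object columns). Returns a tibble of all entailed
# (subject, object) pairs, excluding reflexive ones.
oracle_reachability <- function(edges) {
  nodes <- unique(c(edges$subject, edges$object))
  reach_from <- function(v, seen = character()) {
    nxt <- setdiff(edges$object[edges$subject == v], seen)
    out <- nxt
    for (w in nxt) {
      out <- union(out, reach_from(w, c(seen, nxt)))
    }
    out
  }
  pairs <- list()
  for (v in nodes) {
    for (w in setdiff(reach_from(v), v)) {
      pairs[[length(pairs) + 1L]] <- c(v, w)
    }
  }
  if (length(pairs) == 0L) {
    return(tibble::tibble(subject = character(), object = character()))
  }
  m <- do.call(rbind, pairs)
  dplyr::arrange(tibble::tibble(subject = m[, 1L], object = m[, 2L]),
                 subject, object)
}

# Random DAG edge list on n nodes: edges only from higher to lower index,
# so acyclicity is guaranteed by construction.
random_dag_edges <- function(n, p = 0.3) {
  ids <- sprintf("N:%02d", seq_len(n))
  pairs <- utils::combn(n, 2L)
  keep <- stats::runif(ncol(pairs)) < p
  tibble::tibble(
    subject = ids[pairs[2L, keep]],
    object = ids[pairs[1L, keep]]
  )
}

dag_ontology <- function(edges, n) {
  ids <- sprintf("N:%02d", seq_len(n))
  ontology(
    tibble::tibble(id = ids),
    tibble::tibble(subject = edges$subject, kind = "subclass",
                   object = edges$object, provenance = "asserted")
  )
}

# Exact one-tailed Mann-Whitney p-value by enumerating every assignment of
# the pooled values to the two groups and comparing pairwise-win U
# statistics (independent of the rank-sum path used by the package).
oracle_mw_p <- function(a, b, alternative = "a_greater") {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(x, y) {
    total <- 0
    for (p in x) for (q in y) total <- total + (p > q) + 0.5 * (p == q)
    total
  }
  obs <- u_of(a, b)
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2L, function(idx) {
    u_of(pooled[idx], pooled[-idx])
  })
  if (alternative == "a_greater") mean(us >= obs) else mean(us <= obs)
}

# Exact null mean of the network connection count by enumerating every
# possible sample of the given size from the frame.
oracle_null_mean <- function(frame, adjacent, size) {
  combos <- utils::combn(length(frame), size)
  mean(apply(combos, 2L, function(idx) sum(frame[idx] %in% adjacent)))
}
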