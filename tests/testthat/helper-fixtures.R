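# Hand-built graphs and independent brute-force oracles used across tests.
# Oracles deliberately share no code with the package internals: closures
# come from boolean matrix powers, similarities from naive double loops.

mk_graph <- function(ids, child = character(), parent = character(),
                     domain = "X", obsolete = rep(FALSE, length(ids))) {
  ontology(
    tibble::tibble(id = ids, name = ids, domain = domain, obsolete = obsolete),
    tibble::tibble(child = child, parent = parent, relation = "is_a")
  )
}

chain_graph <- function(domain = "X") {
  # r <- a <- b
  mk_graph(c("X:r", "X:a", "X:b"),
           child = c("X:a", "X:b"), parent = c("X:r", "X:a"),
           domain = domain)
}

diamond_graph <- function() {
  # r <- {a, b} <- c
  mk_graph(c("X:r", "X:a", "X:b", "X:c"),
           child = c("X:a", "X:b", "X:c", "X:c"),
           parent = c("X:r", "X:r", "X:a", "X:b"))
}

mk_corpus <- function(df, ontologies) {
  annotation_corpus(df, ontologies)
}

# --- independent closure oracle: boolean reachability by matrix powers ----

oracle_closures <- function(graph) {
  ids <- names(graph$anc)
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  diag(A) <- TRUE
  for (row in seq_len(nrow(graph$edges))) {
    A[graph$edges$child[[row]], graph$edges$parent[[row]]] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  A   # A[i, j] TRUE iff j is a (reflexive) ancestor of i
}

oracle_ancestors <- function(graph, term) {
  A <- oracle_closures(graph)
  colnames(A)[A[term, ]]
}

oracle_mica <- function(graph, ic, t1, t2) {
  A <- oracle_closures(graph)
  common <- colnames(A)[A[t1, ] & A[t2, ]]
  if (length(common) == 0) return(list(term = NA_character_, ic = 0))
  vals <- vapply(common, function(t) {
    v <- ic$ic[[t]]
    if (is.null(v) || is.na(v)) 0 else v
  }, 1)
  best <- max(vals)
  list(term = min(common[vals == best]), ic = best)
}

# --- naive groupwise oracles ----------------------------------------------

oracle_term_resnik <- function(graph, ic, t1, t2, normalize = TRUE) {
  v <- oracle_mica(graph, ic, t1, t2)$ic
  if (!normalize) return(v)
  if (ic$ic_max == 0) 0 else v / ic$ic_max
}

oracle_term_lin <- function(graph, ic, t1, t2) {
  lk <- function(t) { v <- ic$ic[[t]]; if (is.null(v) || is.na(v)) 0 else v }
  denom <- lk(t1) + lk(t2)
  if (denom == 0) return(0)
  2 * oracle_mica(graph, ic, t1, t2)$ic / denom
}

oracle_bma <- function(termsim, A, B) {
  fwd <- vapply(A, function(a) max(vapply(B, function(b) termsim(a, b), 1)), 1)
  bwd <- vapply(B, function(b) max(vapply(A, function(a) termsim(a, b), 1)), 1)
  (mean(fwd) + mean(bwd)) / 2
}

oracle_set_closure <- function(graph, terms) {
  A <- oracle_closures(graph)
  unique(unlist(lapply(terms, function(t) colnames(A)[A[t, ]])))
}

oracle_simui <- function(graph, A, B) {
  ca <- oracle_set_closure(graph, A)
  cb <- oracle_set_closure(graph, B)
  length(intersect(ca, cb)) / length(union(ca, cb))
}

oracle_simgic <- function(graph, ic, A, B) {
  lk <- function(ts) sum(vapply(ts, function(t) {
    v <- ic$ic[[t]]
    if (is.null(v) || is.na(v)) 0 else v
  }, 1))
  ca <- oracle_set_closure(graph, A)
  cb <- oracle_set_closure(graph, B)
  denom <- lk(union(ca, cb))
  if (denom == 0) return(if (setequal(ca, cb)) 1 else 0)
  lk(intersect(ca, cb)) / denom
}

# --- random instances for property tests ----------------------------------

# random connected DAG, independent of the package's generator
rand_dag <- function(n, domain = "X") {
  ids <- sprintf("%s:%02d", domain, seq_len(n))
  child <- character(0); parent <- character(0)
  if (n > 1) {
    for (j in 2:n) {
      ps <- sample(seq_len(j - 1), sample(1:min(2, j - 1), 1))
      child <- c(child, rep(ids[[j]], length(ps)))
      parent <- c(parent, ids[ps])
    }
  }
  mk_graph(ids, child, parent, domain = domain)
}

# random IC table, monotone non-decreasing from parent to child as every
# real (corpus or intrinsic) IC table is
rand_ic <- function(graph) {
  ids <- names(graph$anc)
  parents_of <- split(graph$edges$parent, graph$edges$child)
  v <- stats::setNames(rep(NA_real_, length(ids)), ids)
  v[graph$roots] <- 0
  while (anyNA(v)) {
    for (id in ids[is.na(v)]) {
      ps <- parents_of[[id]]
      if (!anyNA(v[ps])) v[[id]] <- max(v[ps]) + round(stats::runif(1), 3)
    }
  }
  ic_table(v, source = "intrinsic")
}

sample_upto <- function(x, max_size, replace = FALSE) {
  sample(x, sample(seq_len(min(max_size, length(x))), 1), replace = replace)
}

rand_sim_matrix <- function(m) {
  ids <- sprintf("r%02d", seq_len(m))
  s <- matrix(stats::runif(m * m), m, m, dimnames = list(ids, ids))
  s <- (s + t(s)) / 2
  diag(s) <- 1
  structure(list(scores = s, setting = setting_spec("integrative"),
                 measure = measure_spec("simui")),
            class = "similarity_matrix")
}

# --- independent multi-label metric oracle (explicit per-resource loops) ---

oracle_metrics <- function(scores, truth) {
  m <- nrow(scores); L <- ncol(scores)
  # deterministic ranking: descending score, ties by column (label id) order
  rank_of <- function(v) {
    ord <- order(-v, seq_along(v))
    r <- integer(L); r[ord] <- seq_len(L); r
  }
  h <- o <- cv <- rl <- ap <- numeric(m)
  for (i in seq_len(m)) {
    r <- rank_of(scores[i, ])
    tr <- which(truth[i, ] == 1); fa <- which(truth[i, ] == 0)
    pred <- which(scores[i, ] > 0.5)
    h[i] <- (length(setdiff(pred, tr)) + length(setdiff(tr, pred))) / L
    o[i] <- as.numeric(!(which(r == 1) %in% tr))
    cv[i] <- max(r[tr]) - 1
    rl[i] <- if (length(fa) == 0) 0 else {
      wrong <- 0
      for (a in tr) for (b in fa) if (r[a] > r[b]) wrong <- wrong + 1
      wrong / (length(tr) * length(fa))
    }
    prec <- vapply(tr, function(a) sum(r[tr] <= r[a]) / r[a], 1)
    ap[i] <- mean(prec)
  }
  c(hamming_loss = mean(h), one_error = mean(o), coverage = mean(cv),
    ranking_loss = mean(rl), average_precision = mean(ap))
}

# --- independent ML-KNN oracle (direct enumeration of the estimator) ------

oracle_mlknn <- function(sim, truth, k, s = 1) {
  ids <- rownames(sim)
  m <- length(ids)
  nb <- lapply(seq_len(m), function(i) {
    others <- setdiff(seq_len(m), i)
    others[order(-sim[i, others], ids[others])][seq_len(k)]
  })
  out <- matrix(NA_real_, m, ncol(truth), dimnames = dimnames(truth))
  for (l in seq_len(ncol(truth))) {
    y <- truth[, l]
    cnt <- vapply(seq_len(m), function(i) sum(y[nb[[i]]]), 0)
    prior <- (s + sum(y)) / (2 * s + m)
    c1 <- vapply(0:k, function(j) sum(y == 1 & cnt == j), 0)
    c0 <- vapply(0:k, function(j) sum(y == 0 & cnt == j), 0)
    for (i in seq_len(m)) {
      num <- prior * (s + c1[[cnt[[i]] + 1]]) / (s * (k + 1) + sum(c1))
      den <- num + (1 - prior) *
        (s + c0[[cnt[[i]] + 1]]) / (s * (k + 1) + sum(c0))
      out[i, l] <- num / den
    }
  }
  out
}
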