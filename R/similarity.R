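#' Measure and setting specifications
#'
#' A `measure_spec` picks one of the four groupwise single-ontology
#' similarity measures; a `setting_spec` picks how that measure is lifted
#' across annotation domains.
#'
#' Settings:
#' * `baseline` — the measure restricted to one domain's annotations
#'   (requires `baseline_domain`);
#' * `aggregative_raw` — per-domain scores averaged with equal weights over
#'   the domains where both resources are annotated;
#' * `aggregative_weighted` — same domains, each weighted by the two
#'   resources' combined annotation count in that domain;
#' * `integrative` — the measure applied once to the full annotation sets
#'   against the merged multi-domain ontology.
#'
#' @param groupwise One of `"resnik_bma"`, `"lin_bma"`, `"simui"`,
#'   `"simgic"`.
#' @param normalize_resnik Divide Resnik term scores by the ontology's
#'   maximum IC so values are commensurable across domains (default `TRUE`).
#' @return A `measure_spec` / `setting_spec` list.
#' @export
measure_spec <- function(groupwise = c("resnik_bma", "lin_bma", "simui", "simgic"),
                         normalize_resnik = TRUE) {
  groupwise <- match.arg(groupwise)
  structure(list(groupwise = groupwise, normalize_resnik = normalize_resnik),
            class = "measure_spec")
}

#' @rdname measure_spec
#' @param mode One of `"baseline"`, `"aggregative_raw"`,
#'   `"aggregative_weighted"`, `"integrative"`.
#' @param baseline_domain Domain tag; required iff `mode = "baseline"`.
#' @export
setting_spec <- function(mode = c("baseline", "aggregative_raw",
                                  "aggregative_weighted", "integrative"),
                         baseline_domain = NULL) {
  mode <- match.arg(mode)
  if (mode == "baseline" && is.null(baseline_domain)) {
    stop("baseline setting needs `baseline_domain`", call. = FALSE)
  }
  if (mode != "baseline" && !is.null(baseline_domain)) {
    stop("`baseline_domain` only applies to the baseline setting", call. = FALSE)
  }
  structure(list(mode = mode, baseline_domain = baseline_domain),
            class = "setting_spec")
}

setting_label <- function(setting) {
  if (setting$mode == "baseline") {
    paste0("baseline:", setting$baseline_domain)
  } else {
    setting$mode
  }
}

#' Term-level Resnik similarity
#'
#' The IC of the most informative common ancestor; optionally normalized by
#' the table's maximum IC so scores lie in `[0, 1]`.
#'
#' @param graph An [ontology].
#' @param ic An [ic_table].
#' @param t1,t2 Term ids.
#' @param normalize Divide by `ic$ic_max` (0 when `ic_max` is 0).
#' @return A non-negative number.
#' @export
sim_term_resnik <- function(graph, ic, t1, t2, normalize = TRUE) {
  v <- mica(graph, ic, t1, t2)$ic
  if (normalize) {
    if (ic$ic_max == 0) 0 else v / ic$ic_max
  } else {
    v
  }
}

#' Term-level Lin similarity
#'
#' `2 * IC(MICA) / (IC(t1) + IC(t2))`, defined as 0 when the denominator is
#' 0; equals 1 for a term compared with itself whenever its IC is positive.
#'
#' @inheritParams sim_term_resnik
#' @return A number in `[0, 1]`.
#' @export
sim_term_lin <- function(graph, ic, t1, t2) {
  denom <- sum(ic_of(ic, resolve_term(graph, c(t1, t2))))
  if (denom == 0) return(0)
  2 * mica(graph, ic, t1, t2)$ic / denom
}

#' Groupwise best-match-average similarity
#'
#' Averages, symmetrically in both directions, each term's best match in the
#' other set:
#' `0.5 * (mean_a max_b s(a,b) + mean_b max_a s(a,b))`.
#' Annotation sets are used as given (no ancestor pre-extension).
#'
#' @inheritParams sim_term_resnik
#' @param A,B Character vectors of term ids (annotation sets).
#' @param term_sim `"resnik"` or `"lin"`.
#' @param normalize_resnik Passed to [sim_term_resnik()].
#' @return A number, or `NA` (undefined) when either set is empty.
#' @export
sim_group_bma <- function(graph, ic, A, B, term_sim = c("resnik", "lin"),
                          normalize_resnik = TRUE) {
  term_sim <- match.arg(term_sim)
  if (length(A) == 0 || length(B) == 0) return(NA_real_)
  s <- matrix(0, length(A), length(B))
  for (i in seq_along(A)) for (j in seq_along(B)) {
    s[i, j] <- if (term_sim == "resnik") {
      sim_term_resnik(graph, ic, A[[i]], B[[j]], normalize = normalize_resnik)
    } else {
      sim_term_lin(graph, ic, A[[i]], B[[j]])
    }
  }
  bma_from_matrix(s)
}

bma_from_matrix <- function(s) {
  (mean(apply(s, 1, max)) + mean(apply(s, 2, max))) / 2
}

#' Groupwise simUI similarity
#'
#' Jaccard index of the reflexive ancestor closures of the two annotation
#' sets: `|Anc(A) n Anc(B)| / |Anc(A) u Anc(B)|`.
#'
#' @inheritParams sim_group_bma
#' @return A number in `[0, 1]`, or `NA` when either set is empty.
#' @export
sim_group_simui <- function(graph, A, B) {
  if (length(A) == 0 || length(B) == 0) return(NA_real_)
  ca <- set_closure(graph, A)
  cb <- set_closure(graph, B)
  length(intersect(ca, cb)) / length(union(ca, cb))
}

#' Groupwise simGIC similarity
#'
#' IC-weighted Jaccard of the ancestor closures:
#' `sum IC over Anc(A) n Anc(B) / sum IC over Anc(A) u Anc(B)`.
#' When the denominator is 0 (all closure terms have IC 0) the score is 1 if
#' the closures are identical and 0 otherwise.
#'
#' @inheritParams sim_group_bma
#' @return A number in `[0, 1]`, or `NA` when either set is empty.
#' @export
sim_group_simgic <- function(graph, ic, A, B) {
  if (length(A) == 0 || length(B) == 0) return(NA_real_)
  ca <- set_closure(graph, A)
  cb <- set_closure(graph, B)
  denom <- sum(ic_of(ic, union(ca, cb)))
  if (denom == 0) {
    return(if (setequal(ca, cb)) 1 else 0)
  }
  sum(ic_of(ic, intersect(ca, cb))) / denom
}

set_closure <- function(graph, terms) {
  ids <- resolve_term(graph, terms)
  unique(unlist(graph$anc[ids], use.names = FALSE))
}

# Dispatch a groupwise measure on two raw term sets.
group_sim <- function(graph, ic, measure, A, B) {
  switch(measure$groupwise,
    resnik_bma = sim_group_bma(graph, ic, A, B, term_sim = "resnik",
                               normalize_resnik = measure$normalize_resnik),
    lin_bma = sim_group_bma(graph, ic, A, B, term_sim = "lin"),
    simui = sim_group_simui(graph, A, B),
    simgic = sim_group_simgic(graph, ic, A, B))
}

#' Multi-domain similarity between two resources
#'
#' Applies a groupwise measure under one of the four lifting settings. In
#' the aggregative settings, only domains where *both* resources have at
#' least one annotation contribute; with no shared domain the score is 0.
#' The weighted variant weights each shared domain by the two resources'
#' combined annotation count there. The integrative setting scores the full
#' annotation sets once against the merged ontology.
#'
#' @param corpus An [annotation_corpus].
#' @param r1,r2 Resource ids.
#' @param setting A [setting_spec].
#' @param measure A [measure_spec].
#' @param ontologies Named list of per-domain [ontology] objects.
#' @param ic_tables Named list of per-domain [ic_table]s (same names).
#' @param merged A `merged_ontology` (required for the integrative setting).
#' @param merged_ic [ic_table] for `merged` (ditto).
#' @return A number in `[0, 1]` (assuming normalized Resnik).
#' @export
sim_resources <- function(corpus, r1, r2, setting, measure,
                          ontologies, ic_tables,
                          merged = NULL, merged_ic = NULL) {
  ann <- corpus$annotations
  if (!all(c(r1, r2) %in% ann$resource)) {
    stop("unknown resource id(s): ",
         paste(setdiff(c(r1, r2), ann$resource), collapse = ", "),
         call. = FALSE)
  }
  a1 <- ann[ann$resource == r1, , drop = FALSE]
  a2 <- ann[ann$resource == r2, , drop = FALSE]

  if (setting$mode == "integrative") {
    if (is.null(merged) || is.null(merged_ic)) {
      stop("integrative setting needs `merged` and `merged_ic`", call. = FALSE)
    }
    v <- group_sim(merged, merged_ic, measure, a1$term, a2$term)
    return(if (is.na(v)) 0 else v)
  }

  if (setting$mode == "baseline") {
    d <- setting$baseline_domain
    v <- group_sim(ontologies[[d]], ic_tables[[d]], measure,
                   a1$term[a1$domain == d], a2$term[a2$domain == d])
    return(if (is.na(v)) 0 else v)
  }

  shared <- intersect(unique(a1$domain), unique(a2$domain))
  if (length(shared) == 0) return(0)
  scores <- vapply(shared, function(d) {
    group_sim(ontologies[[d]], ic_tables[[d]], measure,
              a1$term[a1$domain == d], a2$term[a2$domain == d])
  }, 1)
  if (setting$mode == "aggregative_raw") {
    mean(scores)
  } else {
    w <- vapply(shared, function(d) {
      sum(a1$domain == d) + sum(a2$domain == d)
    }, 1)
    sum(w * scores) / sum(w)
  }
}

# ---- fast engines used by similarity_matrix -------------------------------

# Pairwise term similarity matrix over `terms` for BMA-style measures.
term_sim_matrix <- function(graph, ic, terms, term_sim, normalize_resnik) {
  n <- length(terms)
  anc <- graph$anc[resolve_term(graph, terms)]
  icv <- ic$ic
  scale <- if (term_sim == "resnik" && normalize_resnik) {
    if (ic$ic_max == 0) Inf else ic$ic_max   # Inf -> all-zero scores
  } else 1
  self_ic <- vapply(anc, function(a) {
    v <- icv[a[[1]]]
    if (is.na(v)) 0 else v
  }, 1)
  m <- matrix(0, n, n, dimnames = list(terms, terms))
  for (i in seq_len(n)) {
    for (j in i:n) {
      common <- intersect(anc[[i]], anc[[j]])
      top <- if (length(common) == 0) 0 else {
        v <- icv[common]
        v[is.na(v)] <- 0
        max(v)
      }
      val <- if (term_sim == "resnik") {
        if (is.finite(scale)) top / scale else 0
      } else {
        denom <- self_ic[[i]] + self_ic[[j]]
        if (denom == 0) 0 else 2 * top / denom
      }
      m[i, j] <- val
      m[j, i] <- val
    }
  }
  m
}

# Groupwise similarity matrix over a named list of term sets.
group_sim_matrix <- function(graph, ic, measure, sets) {
  n <- length(sets)
  ids <- names(sets)
  out <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  nonempty <- vapply(sets, length, 1L) > 0

  if (measure$groupwise %in% c("resnik_bma", "lin_bma")) {
    used <- unique(unlist(sets, use.names = FALSE))
    ts <- if (length(used) > 0) {
      term_sim_matrix(graph, ic, used,
                      term_sim = sub("_bma$", "", measure$groupwise),
                      normalize_resnik = measure$normalize_resnik)
    } else NULL
    idx <- lapply(sets, function(s) match(s, used))
    for (i in seq_len(n)) {
      if (!nonempty[[i]]) next
      for (j in i:n) {
        if (!nonempty[[j]]) next
        v <- bma_from_matrix(ts[idx[[i]], idx[[j]], drop = FALSE])
        out[i, j] <- v
        out[j, i] <- v
      }
    }
  } else {
    closures <- lapply(sets, function(s) {
      if (length(s) == 0) character() else set_closure(graph, s)
    })
    gic <- measure$groupwise == "simgic"
    for (i in seq_len(n)) {
      if (!nonempty[[i]]) next
      for (j in i:n) {
        if (!nonempty[[j]]) next
        ca <- closures[[i]]; cb <- closures[[j]]
        v <- if (gic) {
          denom <- sum(ic_of(ic, union(ca, cb)))
          if (denom == 0) {
            if (setequal(ca, cb)) 1 else 0
          } else {
            sum(ic_of(ic, intersect(ca, cb))) / denom
          }
        } else {
          length(intersect(ca, cb)) / length(union(ca, cb))
        }
        out[i, j] <- v
        out[j, i] <- v
      }
    }
  }
  out
}

#' Resource-by-resource similarity matrix
#'
#' Computes every unordered resource pair (and the diagonal) once under a
#' given setting and measure. Internally the per-domain groupwise matrices
#' are computed from a precomputed term-pair similarity table, so the result
#' equals — but is much faster than — element-wise [sim_resources()] calls.
#'
#' @inheritParams sim_resources
#' @return An object of class `similarity_matrix`: list with `scores`
#'   (symmetric numeric matrix with resource-id dimnames), `setting` and
#'   `measure`.
#' @export
similarity_matrix <- function(corpus, setting, measure,
                              ontologies, ic_tables,
                              merged = NULL, merged_ic = NULL) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  if (corpus$m < 2) stop("need at least 2 resources", call. = FALSE)
  ann <- corpus$annotations
  resources <- corpus$resources %||% sort(unique(ann$resource))
  n <- length(resources)

  sets_by_domain <- function(d) {
    sub <- ann[ann$domain == d, , drop = FALSE]
    s <- split(sub$term, factor(sub$resource, levels = resources))
    lapply(s, as.character)
  }

  if (setting$mode == "integrative") {
    if (is.null(merged) || is.null(merged_ic)) {
      stop("integrative setting needs `merged` and `merged_ic`", call. = FALSE)
    }
    sets <- lapply(split(ann$term, factor(ann$resource, levels = resources)),
                   as.character)
    scores <- group_sim_matrix(merged, merged_ic, measure, sets)
    scores[is.na(scores)] <- 0
  } else if (setting$mode == "baseline") {
    d <- setting$baseline_domain
    if (!d %in% names(ontologies)) {
      stop("unknown baseline domain: ", d, call. = FALSE)
    }
    scores <- group_sim_matrix(ontologies[[d]], ic_tables[[d]], measure,
                               sets_by_domain(d))
    scores[is.na(scores)] <- 0
  } else {
    doms <- intersect(names(ontologies), unique(ann$domain))
    per_dom <- lapply(doms, function(d) {
      group_sim_matrix(ontologies[[d]], ic_tables[[d]], measure,
                       sets_by_domain(d))
    })
    names(per_dom) <- doms
    counts <- lapply(doms, function(d) {
      tab <- table(factor(ann$resource[ann$domain == d], levels = resources))
      as.numeric(tab)
    })
    names(counts) <- doms

    num <- matrix(0, n, n, dimnames = list(resources, resources))
    den <- matrix(0, n, n, dimnames = list(resources, resources))
    for (d in doms) {
      s <- per_dom[[d]]
      defined <- !is.na(s)
      w <- if (setting$mode == "aggregative_raw") {
        matrix(1, n, n)
      } else {
        outer(counts[[d]], counts[[d]], `+`)
      }
      num[defined] <- num[defined] + (w * s)[defined]
      den[defined] <- den[defined] + w[defined]
    }
    scores <- ifelse(den > 0, num / den, 0)
    dimnames(scores) <- list(resources, resources)
  }

  structure(list(scores = scores, setting = setting, measure = measure),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d x %d, setting = %s, measure = %s\n",
              nrow(x$scores), ncol(x$scores), setting_label(x$setting),
              x$measure$groupwise))
  invisible(x)
}

#' @rdname similarity_matrix
#' @param x A `similarity_matrix`.
#' @param ... Unused.
#' @export
tidy.similarity_matrix <- function(x, ...) {
  m <- x$scores
  tibble::tibble(
    r1 = rep(rownames(m), times = ncol(m)),
    r2 = rep(colnames(m), each = nrow(m)),
    score = as.vector(m)
  ) |>
    dplyr::filter(.data$r1 < .data$r2) |>
    dplyr::mutate(setting = setting_label(x$setting),
                  measure = x$measure$groupwise)
}

#' @rdname similarity_matrix
#' @export
glance.similarity_matrix <- function(x, ...) {
  off <- x$scores[lower.tri(x$scores)]
  tibble::tibble(n_resources = nrow(x$scores),
                 setting = setting_label(x$setting),
                 measure = x$measure$groupwise,
                 mean_score = mean(off),
                 max_score = max(off))
}

#' Write / read a similarity matrix as TSV
#'
#' `write_similarity_matrix()` writes the wide form (row/column headers are
#' resource ids); `long = TRUE` writes the long form (`r1`, `r2`, `score`).
#'
#' @param x A `similarity_matrix`.
#' @param path Output path.
#' @param long Write long format instead of wide.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(x, path, long = FALSE) {
  if (long) {
    readr::write_tsv(tidy(x), path)
  } else {
    wide <- tibble::as_tibble(x$scores, rownames = "resource")
    readr::write_tsv(wide, path)
  }
  invisible(path)
}
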