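#' Specification for a synthetic multi-domain dataset
#'
#' Describes a seeded toy dataset: one random rooted DAG ontology per domain
#' and an annotation corpus over `m` resources with controllable sparseness
#' (per-domain coverage), annotation volume, and a statistical dependency
#' between the source domains and a target domain. The dependency is driven
#' by latent resource classes: each class owns a disjoint "signature" pool
#' of terms in every source domain and one designated target-domain label.
#' With per-domain strength `dependency[d]`, a resource's annotations in
#' domain `d` are drawn from its class pool (else uniformly from the whole
#' domain); its target label is the class label with probability
#' `max(dependency)` (else uniform). At strength 1 the target label is thus
#' a deterministic function of the visible source-domain annotations; at 0
#' it is independent of them.
#'
#' The defaults describe the structure-recovery study conditions used
#' throughout the package's tests: 200 resources, two informative source
#' domains, one pure-noise source domain, and a fully dependent target
#' domain.
#'
#' @param seed Integer seed; fully determines all generated output.
#' @param source_domains Character vector of source-domain tags (>= 1).
#' @param target_domain Target-domain tag.
#' @param terms_per_domain Terms per ontology (>= 2), including the root.
#' @param max_depth Maximum DAG depth (root at depth 0).
#' @param m Number of resources.
#' @param coverage Per-source-domain probability that a resource is
#'   annotated in that domain (scalar recycled; named vector accepted).
#' @param target_coverage Probability that a resource carries a target
#'   label (default 1 so every resource is evaluable).
#' @param volume_mean Mean annotation count per covered domain (>= 1;
#'   scalar recycled over source domains).
#' @param dependency Named (or recycled) per-source-domain rule strength in
#'   `[0, 1]`.
#' @param n_classes Number of latent resource classes.
#' @param signature_size Terms per class signature pool per domain.
#' @param shared_ids Number of term ids duplicated verbatim across the
#'   first two source domains (exercises merge unification).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed,
                           source_domains = c("SRCA", "SRCB", "NOIS"),
                           target_domain = "TRGT",
                           terms_per_domain = 40,
                           max_depth = 5,
                           m = 200,
                           coverage = 0.7,
                           target_coverage = 1,
                           volume_mean = 2,
                           dependency = c(1, 1, 0),
                           n_classes = 8,
                           signature_size = 4,
                           shared_ids = 0) {
  stopifnot(terms_per_domain >= 2, max_depth >= 1, m >= 2,
            n_classes >= 1, signature_size >= 1, shared_ids >= 0,
            length(source_domains) >= 1)
  named_over <- function(x, what) {
    if (length(x) == 1) x <- rep(x, length(source_domains))
    if (is.null(names(x))) names(x) <- source_domains
    stopifnot(setequal(names(x), source_domains))
    x[source_domains]
  }
  coverage <- named_over(coverage)
  dependency <- named_over(dependency)
  volume_mean <- named_over(volume_mean)
  stopifnot(all(coverage >= 0 & coverage <= 1),
            all(dependency >= 0 & dependency <= 1),
            target_coverage >= 0, target_coverage <= 1,
            all(volume_mean >= 1))
  structure(list(seed = as.integer(seed), source_domains = source_domains,
                 target_domain = target_domain,
                 terms_per_domain = as.integer(terms_per_domain),
                 max_depth = as.integer(max_depth), m = as.integer(m),
                 coverage = coverage, target_coverage = target_coverage,
                 volume_mean = volume_mean, dependency = dependency,
                 n_classes = as.integer(n_classes),
                 signature_size = as.integer(signature_size),
                 shared_ids = as.integer(shared_ids)),
            class = "synthetic_spec")
}

#' A corpus spec loosely shaped like a sparse epidemiological repository
#'
#' Seven domains with sparse, uneven coverage and volume, 204 resources, a
#' disease-like target domain. A qualitative smoke fixture only — not a
#' numeric reproduction of any real dataset.
#'
#' @param seed Integer seed.
#' @return A [synthetic_spec].
#' @export
synthetic_spec_epimarket <- function(seed) {
  src <- c("CHEM", "ENVC", "PHEN", "SYMP", "TRNS", "VACC")
  synthetic_spec(
    seed, source_domains = src, target_domain = "DISE",
    terms_per_domain = 40, max_depth = 5, m = 204,
    coverage = c(CHEM = 0.01, ENVC = 0.24, PHEN = 0.01,
                 SYMP = 0.51, TRNS = 0.48, VACC = 0.23),
    target_coverage = 0.67,
    volume_mean = c(CHEM = 1, ENVC = 1, PHEN = 1,
                    SYMP = 3.55, TRNS = 1, VACC = 1.06),
    dependency = c(CHEM = 0, ENVC = 0, PHEN = 0,
                   SYMP = 0.9, TRNS = 0.6, VACC = 0),
    n_classes = 8, signature_size = 4)
}

# deterministic sub-seeds below 2^31
derive_seed <- function(seed, salt) {
  as.integer((abs(as.double(seed)) %% 1000003) * 2011 + salt)
}

# sample() that treats a length-1 x as a set, not 1:x
sample_set <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

all_domains <- function(spec) c(spec$source_domains, spec$target_domain)

#' Generate one seeded random domain ontology
#'
#' Builds a rooted random DAG with the requested size and maximum depth:
#' term `j` attaches to one or two earlier terms of depth below
#' `max_depth`, so every term is reachable from the single domain root.
#' Optionally injects `shared_ids` terms with identical ids into the first
#' two source domains (as root children) to exercise merge unification.
#'
#' @param spec A [synthetic_spec].
#' @param domain One of the spec's domain tags.
#' @return An [ontology].
#' @export
generate_ontology <- function(spec, domain) {
  doms <- all_domains(spec)
  idx <- match(domain, doms)
  if (is.na(idx)) stop("unknown domain: ", domain, call. = FALSE)
  n <- spec$terms_per_domain
  set.seed(derive_seed(spec$seed, 17 * idx))

  ids <- sprintf("%s:%07d", domain, seq_len(n) - 1L)
  # root, then one top-level category ("branch") per latent class, then the
  # remaining terms attached inside a branch — real domain ontologies have
  # top-level categories, and class signatures drawn from one branch share
  # informative ancestors
  n_branches <- max(1L, min(spec$n_classes, n - 1L))
  depth <- integer(n)
  branch <- integer(n)          # 0 = root
  child <- character(0)
  parent <- character(0)
  for (j in seq_len(n)[-1]) {
    if (j <= n_branches + 1L) { # top-level category under the root
      branch[[j]] <- j - 1L
      depth[[j]] <- 1L
      child <- c(child, ids[[j]])
      parent <- c(parent, ids[[1]])
      next
    }
    b <- sample.int(n_branches, 1L)
    branch[[j]] <- b
    eligible <- which(branch[seq_len(j - 1)] == b &
                        depth[seq_len(j - 1)] < spec$max_depth)
    if (length(eligible) == 0) eligible <- b + 1L  # saturated: the category
    np <- min(sample.int(2L, 1L), length(eligible))
    ps <- sample_set(eligible, np)
    depth[[j]] <- max(depth[ps]) + 1L
    child <- c(child, rep(ids[[j]], np))
    parent <- c(parent, ids[ps])
  }
  terms <- tibble::tibble(id = ids,
                          name = paste(domain, "term", seq_len(n) - 1L),
                          domain = domain, obsolete = FALSE)
  edges <- tibble::tibble(child = child, parent = parent, relation = "is_a")

  if (spec$shared_ids > 0 && idx <= 2 && length(spec$source_domains) >= 2) {
    sid <- sprintf("SHRD:%07d", seq_len(spec$shared_ids) - 1L)
    terms <- dplyr::bind_rows(
      terms,
      tibble::tibble(id = sid, name = paste("shared term", seq_along(sid) - 1L),
                     domain = domain, obsolete = FALSE))
    edges <- dplyr::bind_rows(
      edges, tibble::tibble(child = sid, parent = ids[[1]], relation = "is_a"))
  }
  ontology(terms, edges)
}

#' Generate all domain ontologies of a spec
#'
#' @param spec A [synthetic_spec].
#' @return Named list of [ontology] objects (sources then target).
#' @export
generate_ontologies <- function(spec) {
  doms <- all_domains(spec)
  out <- lapply(doms, function(d) generate_ontology(spec, d))
  names(out) <- doms
  out
}

# non-root, own-prefix term pool of a generated ontology
domain_pool <- function(graph, domain) {
  ids <- setdiff(names(graph$anc), graph$roots)
  sort(ids[startsWith(ids, paste0(domain, ":"))])
}

#' Generate a seeded annotation corpus
#'
#' Draws, for each resource and source domain, coverage by a Bernoulli
#' trial, an annotation count of `1 + Poisson(volume_mean - 1)`, and the
#' terms themselves either from the resource's class signature pool (with
#' probability `dependency[d]`) or uniformly from the whole domain. Target
#' labels follow the dependency rule described in [synthetic_spec()]. Every
#' resource ends up with at least one annotation.
#'
#' @param spec A [synthetic_spec].
#' @param ontologies Output of [generate_ontologies()] for the same spec.
#' @return An [annotation_corpus]; the latent class of each resource is
#'   attached as attribute `"classes"` for diagnostic use.
#' @export
generate_corpus <- function(spec, ontologies) {
  doms <- all_domains(spec)
  stopifnot(setequal(names(ontologies), doms))
  set.seed(derive_seed(spec$seed, 9973))

  pools <- lapply(doms, function(d) domain_pool(ontologies[[d]], d))
  names(pools) <- doms
  tgt_pool <- pools[[spec$target_domain]]
  if (length(tgt_pool) < spec$n_classes) {
    stop("target ontology too small for ", spec$n_classes, " classes",
         call. = FALSE)
  }

  # class signature pools: class c draws from the c-th top-level branch of
  # each source ontology, so same-class resources share informative
  # ancestors (disjoint across classes when every class has its own branch)
  n_branches <- max(1L, min(spec$n_classes, spec$terms_per_domain - 1L))
  signatures <- lapply(spec$source_domains, function(d) {
    g <- ontologies[[d]]
    lapply(seq_len(spec$n_classes), function(c) {
      b_id <- sprintf("%s:%07d", d, ((c - 1L) %% n_branches) + 1L)
      pool <- pools[[d]][vapply(pools[[d]],
                                function(t) b_id %in% g$anc[[t]], TRUE)]
      if (length(pool) == 0) pool <- pools[[d]]
      sample_set(pool, min(spec$signature_size, length(pool)))
    })
  })
  names(signatures) <- spec$source_domains
  class_labels <- sample_set(tgt_pool, spec$n_classes)

  classes <- sample.int(spec$n_classes, spec$m, replace = TRUE)
  res_ids <- sprintf("res%04d", seq_len(spec$m))
  target_strength <- if (length(spec$dependency)) max(spec$dependency) else 0

  # Coverage indicators. Informative domains (dependency > 0) are coupled so
  # that every resource is annotated in at least one of them — otherwise the
  # target label could not be a function of the visible source annotations
  # in the noiseless limit — while keeping the requested marginal coverages
  # exact. The coupling exists whenever the informative coverages sum to at
  # least 1; below that, draws fall back to independent Bernoulli trials.
  informative <- spec$source_domains[spec$dependency > 0]
  S <- sum(spec$coverage[informative])
  couple <- length(informative) > 0 && S >= 1
  draw_coverage <- function() {
    x <- stats::runif(length(spec$source_domains)) < spec$coverage
    names(x) <- spec$source_domains
    if (couple) {
      cj <- spec$coverage[informative]
      jstar <- informative[[sample.int(length(informative), 1,
                                       prob = cj / S)]]
      pj <- cj * (1 - 1 / S) / (1 - cj / S)
      pj[!is.finite(pj)] <- 0   # a domain with coverage S is always jstar
      x[informative] <- stats::runif(length(informative)) < pj
      x[[jstar]] <- TRUE
    }
    x
  }

  rows <- vector("list", spec$m)
  for (i in seq_len(spec$m)) {
    terms <- character(0)
    covered <- draw_coverage()
    for (d in spec$source_domains) {
      if (!covered[[d]]) next
      n_ann <- 1L + stats::rpois(1, spec$volume_mean[[d]] - 1)
      pool <- if (stats::runif(1) < spec$dependency[[d]]) {
        signatures[[d]][[classes[[i]]]]
      } else {
        pools[[d]]
      }
      terms <- c(terms, sample_set(pool, min(n_ann, length(pool))))
    }
    draw_label <- function() {
      if (stats::runif(1) < target_strength) {
        class_labels[[classes[[i]]]]
      } else {
        sample_set(tgt_pool, 1)
      }
    }
    if (stats::runif(1) < spec$target_coverage) {
      terms <- c(terms, draw_label())
    } else if (length(terms) == 0) {
      terms <- draw_label()   # every resource needs >= 1 annotation
    }
    rows[[i]] <- tibble::tibble(resource = res_ids[[i]], term = terms)
  }

  corp <- annotation_corpus(dplyr::bind_rows(rows), ontologies)
  attr(corp, "classes") <- stats::setNames(classes, res_ids)
  corp
}

#' Generate a complete synthetic dataset, optionally writing it to disk
#'
#' @param spec A [synthetic_spec].
#' @param dir If non-`NULL`, writes `<domain>.obo` per domain plus
#'   `annotations.tsv` there (byte-deterministic for a given spec).
#' @return List with `spec`, `ontologies`, `corpus`.
#' @export
generate_dataset <- function(spec, dir = NULL) {
  ontologies <- generate_ontologies(spec)
  corpus <- generate_corpus(spec, ontologies)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (d in names(ontologies)) {
      write_obo(ontologies[[d]], file.path(dir, paste0(d, ".obo")))
    }
    write_annotations(corpus, file.path(dir, "annotations.tsv"))
  }
  list(spec = spec, ontologies = ontologies, corpus = corpus)
}

#' Write a corpus to the two-column annotation TSV format
#'
#' @param corpus An [annotation_corpus].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(corpus, path) {
  ann <- dplyr::arrange(corpus$annotations, .data$resource, .data$term)
  readr::write_tsv(ann[, c("resource", "term")], path, col_names = FALSE)
  invisible(path)
}
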