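#' ML-KNN configuration
#'
#' @param k Neighbour count (>= 1, and < number of resources).
#' @param s Laplace-style smoothing constant (> 0, default 1).
#' @param target_domain Domain whose labels are predicted.
#' @param label_space `"observed"` (labels used at least once in the corpus,
#'   the default) or `"full_ontology"` (every non-obsolete non-root term of
#'   the target ontology; inflates the coverage and ranking-loss
#'   denominators).
#' @return An `mlknn_config` list.
#' @export
mlknn_config <- function(k, s = 1, target_domain,
                         label_space = c("observed", "full_ontology")) {
  stopifnot(k >= 1, is.finite(s), s > 0)
  structure(list(k = as.integer(k), s = s, target_domain = target_domain,
                 label_space = match.arg(label_space)),
            class = "mlknn_config")
}

#' k-nearest neighbourhoods from a similarity matrix
#'
#' For each resource, the `k` other resources with highest similarity (self
#' excluded), ties broken by ascending resource id.
#'
#' @param matrix A [similarity_matrix].
#' @param k Neighbourhood size; must be at most `m - 1`.
#' @return Named list of character vectors of length `k`, ordered from most
#'   to least similar.
#' @export
neighborhoods <- function(matrix, k) {
  s <- matrix$scores
  m <- nrow(s)
  if (k >= m) {
    stop("k must be smaller than the number of resources (", m, ")",
         call. = FALSE)
  }
  ids <- rownames(s)
  out <- vector("list", m)
  names(out) <- ids
  for (i in seq_len(m)) {
    others <- ids[-i]
    sims <- s[i, -i]
    ord <- order(-sims, others)
    out[[i]] <- others[ord][seq_len(k)]
  }
  out
}

#' Multi-label k-NN annotation prediction
#'
#' Predicts each resource's target-domain labels from its neighbours'
#' labels, leave-one-out over the corpus, via the ML-KNN Bayesian estimator.
#' The prior and count statistics are estimated once over the whole corpus;
#' each resource's own neighbourhood excludes itself ("compare each resource
#' to the other resources").
#' For a label with `n` positive resources among `m`, the prior is
#' `P(H) = (s + n) / (2s + m)`; the likelihood of observing `j` positive
#' neighbours given H is `P(E_j | H) = (s + c[j]) / (s (k + 1) + sum_j c[j])`
#' where `c[j]` counts resources carrying the label whose `k`-neighbourhood
#' contains exactly `j` positives (and analogously for not-H). The posterior
#' score combines both via Bayes' rule.
#'
#' @param corpus An [annotation_corpus] containing target-domain labels.
#' @param matrix A [similarity_matrix] over the same resources (typically
#'   built from annotations *excluding* the target domain).
#' @param config An [mlknn_config].
#' @param target_ontology Required when `label_space = "full_ontology"`.
#' @return An object of class `mlknn_prediction`: list with `scores`
#'   (resources x labels posterior matrix), `truth` (0/1 matrix), `labels`,
#'   `config`. Scores define a ranking (descending score, ties by ascending
#'   label id); the predicted set is every label with score > 0.5.
#' @export
mlknn_fit_predict <- function(corpus, matrix, config, target_ontology = NULL) {
  stopifnot(inherits(config, "mlknn_config"))
  ann <- corpus$annotations
  resources <- rownames(matrix$scores)
  tgt <- ann[ann$domain == config$target_domain, , drop = FALSE]
  if (nrow(tgt) == 0) {
    stop("no annotations in target domain ", config$target_domain,
         call. = FALSE)
  }

  labels <- if (config$label_space == "observed") {
    sort(unique(tgt$term))
  } else {
    if (is.null(target_ontology)) {
      stop('label_space = "full_ontology" needs `target_ontology`',
           call. = FALSE)
    }
    sort(setdiff(names(target_ontology$anc), target_ontology$roots))
  }
  if (length(labels) == 0) stop("empty label space", call. = FALSE)

  m <- length(resources)
  k <- config$k
  s <- config$s
  if (k >= m) stop("k must be smaller than the number of resources",
                   call. = FALSE)

  truth <- matrix(0L, m, length(labels), dimnames = list(resources, labels))
  hit <- tgt[tgt$resource %in% resources & tgt$term %in% labels, , drop = FALSE]
  truth[cbind(match(hit$resource, resources), match(hit$term, labels))] <- 1L

  nb <- neighborhoods(matrix, k)
  nb_idx <- do.call(rbind, lapply(nb, match, resources))  # m x k

  scores <- matrix(NA_real_, m, length(labels),
                   dimnames = list(resources, labels))
  for (l in seq_along(labels)) {
    y <- truth[, l]
    cn <- vapply(seq_len(m), function(i) sum(y[nb_idx[i, ]]), 0L)  # 0..k

    # corpus-wide j-histograms of neighbourhood positive counts
    k1 <- vapply(0:k, function(j) sum(y == 1L & cn == j), 0L)
    k0 <- vapply(0:k, function(j) sum(y == 0L & cn == j), 0L)
    p_h <- (s + sum(y)) / (2 * s + m)

    for (i in seq_len(m)) {
      j <- cn[[i]] + 1L
      pe_h <- (s + k1[[j]]) / (s * (k + 1) + sum(k1))
      pe_nh <- (s + k0[[j]]) / (s * (k + 1) + sum(k0))
      scores[i, l] <- p_h * pe_h / (p_h * pe_h + (1 - p_h) * pe_nh)
    }
  }

  structure(list(scores = scores, truth = truth, labels = labels,
                 config = config),
            class = "mlknn_prediction")
}

#' @export
print.mlknn_prediction <- function(x, ...) {
  cat(sprintf("<mlknn_prediction> %d resources x %d labels (k = %d, s = %g, target = %s)\n",
              nrow(x$scores), length(x$labels), x$config$k, x$config$s,
              x$config$target_domain))
  invisible(x)
}

# rank matrix: descending score, ties by ascending label id (column order
# is already ascending label id, so ties.method = "first" implements it).
label_ranks <- function(scores) {
  t(apply(scores, 1, function(v) rank(-v, ties.method = "first")))
}

#' @rdname mlknn_fit_predict
#' @param x An `mlknn_prediction`.
#' @param ... Unused.
#' @export
tidy.mlknn_prediction <- function(x, ...) {
  rk <- label_ranks(x$scores)
  tibble::tibble(
    resource = rep(rownames(x$scores), times = length(x$labels)),
    label = rep(x$labels, each = nrow(x$scores)),
    score = as.vector(x$scores),
    rank = as.vector(rk),
    predicted = as.vector(x$scores > 0.5),
    truth = as.vector(x$truth == 1L)
  ) |>
    dplyr::arrange(.data$resource, .data$rank)
}

#' @rdname mlknn_fit_predict
#' @export
glance.mlknn_prediction <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(m = nrow(x$scores), n_labels = length(x$labels),
                   k = x$config$k, s = x$config$s,
                   target_domain = x$config$target_domain),
    ml_metrics(x)
  )
}

#' Multi-label ranking metrics
#'
#' The five canonical ML-KNN evaluation metrics, computed from the posterior
#' scores, their deterministic ranking and the predicted sets:
#' * *hamming loss* — mean symmetric difference between predicted and true
#'   sets, normalized by label-space size (lower is better);
#' * *one-error* — fraction of resources whose top-ranked label is not a
#'   true label (lower);
#' * *coverage* — mean, over resources, of the worst rank of a true label
#'   minus 1 (lower);
#' * *ranking loss* — mean fraction of (true, false) label pairs ranked in
#'   the wrong order (lower);
#' * *average precision* — mean, over resources and their true labels, of
#'   the precision at each true label's rank (higher).
#'
#' Resources with no true label are excluded with a warning.
#'
#' @param prediction An `mlknn_prediction` (or a list with `scores` and
#'   `truth` matrices).
#' @return A one-row tibble with columns `hamming_loss`, `one_error`,
#'   `coverage`, `ranking_loss`, `average_precision`.
#' @export
ml_metrics <- function(prediction) {
  scores <- prediction$scores
  truth <- prediction$truth == 1L
  keep <- rowSums(truth) > 0
  if (!all(keep)) {
    warning(sum(!keep), " resource(s) with empty truth excluded from metrics",
            call. = FALSE)
    scores <- scores[keep, , drop = FALSE]
    truth <- truth[keep, , drop = FALSE]
  }
  m <- nrow(scores)
  L <- ncol(scores)
  rk <- label_ranks(scores)
  pred <- scores > 0.5

  hamming <- mean(vapply(seq_len(m), function(i) {
    sum(xor(pred[i, ], truth[i, ])) / L
  }, 1))
  one_error <- mean(vapply(seq_len(m), function(i) {
    !truth[i, which(rk[i, ] == 1L)]
  }, TRUE))
  coverage <- mean(vapply(seq_len(m), function(i) {
    max(rk[i, truth[i, ]]) - 1
  }, 1))
  ranking_loss <- mean(vapply(seq_len(m), function(i) {
    tr <- rk[i, truth[i, ]]
    fr <- rk[i, !truth[i, ]]
    if (length(fr) == 0) return(0)
    sum(outer(tr, fr, `>`)) / (length(tr) * length(fr))
  }, 1))
  avg_prec <- mean(vapply(seq_len(m), function(i) {
    tr <- sort(rk[i, truth[i, ]])
    mean(vapply(tr, function(r) sum(tr <= r) / r, 1))
  }, 1))

  tibble::tibble(hamming_loss = hamming, one_error = one_error,
                 coverage = coverage, ranking_loss = ranking_loss,
                 average_precision = avg_prec)
}

#' Run the full (setting x measure x k) evaluation sweep
#'
#' For each setting and measure, builds a similarity matrix from the corpus
#' with the target domain's annotations *excluded* (predicting labels from
#' the labels themselves would be circular), runs leave-one-out ML-KNN for
#' every `k`, and collects the five metrics. Deterministic given its inputs.
#'
#' @param corpus An [annotation_corpus].
#' @param ontologies Named list of per-domain [ontology] objects.
#' @param settings List of [setting_spec]s (a baseline on the target domain
#'   is rejected).
#' @param measures List of [measure_spec]s.
#' @param k_values Integer vector of neighbourhood sizes.
#' @param target_domain Domain whose labels are predicted.
#' @param s Smoothing constant.
#' @param label_space Passed to [mlknn_config()].
#' @param ic_source `"corpus"` (default) or `"intrinsic"` IC tables.
#' @return An `evaluation_report`: a tibble with columns `setting`,
#'   `measure`, `k`, the five metric columns, and attribute `target_domain`.
#' @export
run_experiment <- function(corpus, ontologies, settings, measures, k_values,
                           target_domain, s = 1,
                           label_space = "observed",
                           ic_source = c("corpus", "intrinsic")) {
  ic_source <- match.arg(ic_source)
  if (inherits(settings, "setting_spec")) settings <- list(settings)
  if (inherits(measures, "measure_spec")) measures <- list(measures)
  for (st in settings) {
    if (st$mode == "baseline" && identical(st$baseline_domain, target_domain)) {
      stop("baseline on the target domain would predict the labels from ",
           "themselves", call. = FALSE)
    }
  }
  ann <- corpus$annotations
  n_target <- dplyr::n_distinct(ann$resource[ann$domain == target_domain])
  if (n_target < max(k_values) + 1) {
    stop("target domain must be annotated in at least max(k) + 1 resources",
         call. = FALSE)
  }

  # similarity inputs: everything except the target domain
  feat <- ann[ann$domain != target_domain, , drop = FALSE]
  resources <- sort(unique(ann$resource))
  feat_corpus <- structure(
    list(annotations = feat, resources = resources, m = length(resources),
         domains = sort(unique(feat$domain))),
    class = "annotation_corpus")

  src_onts <- ontologies[setdiff(names(ontologies), target_domain)]
  ic_tables <- lapply(names(src_onts), function(d) {
    if (ic_source == "corpus") compute_ic_corpus(src_onts[[d]], feat_corpus)
    else compute_ic_intrinsic(src_onts[[d]])
  })
  names(ic_tables) <- names(src_onts)
  merged <- merge_ontologies(src_onts)
  merged_ic <- if (ic_source == "corpus") {
    compute_ic_corpus(merged, feat_corpus)
  } else {
    compute_ic_intrinsic(merged)
  }

  rows <- list()
  for (ms in measures) {
    for (st in settings) {
      mat <- similarity_matrix(feat_corpus, st, ms, src_onts, ic_tables,
                               merged = merged, merged_ic = merged_ic)
      # all resources participate, including ones with no feature
      # annotations (their similarity to everyone is 0)
      stopifnot(identical(rownames(mat$scores), resources))
      for (k in k_values) {
        cfg <- mlknn_config(k = k, s = s, target_domain = target_domain,
                            label_space = label_space)
        prd <- mlknn_fit_predict(corpus, mat, cfg,
                                 target_ontology = ontologies[[target_domain]])
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(setting = setting_label(st),
                         measure = ms$groupwise, k = as.integer(k)),
          suppressWarnings(ml_metrics(prd)))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "target_domain") <- target_domain
  class(out) <- c("evaluation_report", class(out))
  out
}

# metric orientation: TRUE if higher values are better
metric_directions <- c(hamming_loss = FALSE, one_error = FALSE,
                       coverage = FALSE, ranking_loss = FALSE,
                       average_precision = TRUE)

#' Multi-domain dominance summary H_p
#'
#' Counts, over all (metric, k) runs of an evaluation report, how many runs
#' have their `p` best-performing settings *all* drawn from the multi-domain
#' settings. With three multi-domain settings, `p` in 1..3 is meaningful; a
#' baseline tied with the `p`-th best value blocks the count (conservative).
#' When the report covers several measures or target domains, each is
#' summarized separately.
#'
#' @param report An `evaluation_report` (or any tibble with `setting`,
#'   `measure`, `k` and the five metric columns).
#' @param multi_domain_settings Character vector of setting labels counted
#'   as multi-domain.
#' @param p_values Integer vector of `p` values.
#' @return A tibble with one row per (target_domain, measure): columns
#'   `runs` and `H_1`, `H_2`, ... per requested `p`.
#' @export
compute_hp <- function(report,
                       multi_domain_settings = c("aggregative_raw",
                                                 "aggregative_weighted",
                                                 "integrative"),
                       p_values = 1:3) {
  metrics <- intersect(names(metric_directions), names(report))
  stopifnot(length(metrics) > 0)
  target <- attr(report, "target_domain") %||% NA_character_

  long <- tidyr::pivot_longer(tibble::as_tibble(report),
                              dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  groups <- dplyr::group_split(long, .data$measure)

  purrr::map_dfr(groups, function(g) {
    runs <- dplyr::group_split(g, .data$metric, .data$k)
    hp <- stats::setNames(integer(length(p_values)),
                          paste0("H_", p_values))
    for (run in runs) {
      higher <- metric_directions[[run$metric[[1]]]]
      v <- if (higher) -run$value else run$value   # smaller = better
      ord <- order(v, run$setting)
      for (pi in seq_along(p_values)) {
        p <- p_values[[pi]]
        if (p > nrow(run)) next
        top <- run$setting[ord[seq_len(p)]]
        boundary <- v[ord[[p]]]
        tied_baseline <- any(!run$setting %in% multi_domain_settings &
                               v == boundary)
        if (all(top %in% multi_domain_settings) && !tied_baseline) {
          hp[[pi]] <- hp[[pi]] + 1L
        }
      }
    }
    dplyr::bind_cols(
      tibble::tibble(target_domain = target, measure = g$measure[[1]],
                     runs = length(runs)),
      tibble::as_tibble_row(hp))
  })
}

#' Write an evaluation report (and optional H_p summary) to disk
#'
#' @param report An `evaluation_report`.
#' @param tsv,json Output paths for the report (`NULL` to skip).
#' @return `report`, invisibly.
#' @export
write_evaluation_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) readr::write_tsv(tibble::as_tibble(report), tsv)
  if (!is.null(json)) {
    jsonlite::write_json(tibble::as_tibble(report), json, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  }
  invisible(report)
}
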