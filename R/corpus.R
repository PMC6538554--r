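#' Annotation corpora
#'
#' An annotation corpus maps resources (datasets, documents, ...) to the
#' ontology terms they are annotated with, across one or more domains.
#'
#' @param annotations Data frame with columns `resource`, `term` and
#'   optionally `domain`; when `domain` is missing it is inferred from the
#'   term-id prefix (the OBO idbase convention) against `ontologies`.
#' @param ontologies Named list of [ontology] objects (names = domain tags)
#'   used to resolve term ids (including alternative ids) and infer domains.
#' @return An object of class `annotation_corpus`: list with `annotations`
#'   (tibble `resource`, `term`, `domain`), `m` (number of resources) and
#'   `domains` (character).
#' @export
annotation_corpus <- function(annotations, ontologies) {
  ann <- tibble::as_tibble(annotations)
  stopifnot(all(c("resource", "term") %in% names(ann)))
  if (is.null(names(ontologies))) {
    names(ontologies) <- vapply(ontologies, function(g) g$terms$domain[[1]], "")
  }

  lookup <- domain_lookup(ontologies)
  resolved <- character(nrow(ann))
  domain <- character(nrow(ann))
  for (d in names(ontologies)) {
    hit <- resolve_term(ontologies[[d]], ann$term, error = FALSE)
    ok <- !is.na(hit) & resolved == ""
    resolved[ok] <- hit[ok]
    domain[ok] <- d
  }
  bad <- resolved == ""
  if (any(bad)) {
    message(sum(bad), " annotation(s) with unresolvable term ids dropped: ",
            paste(utils::head(unique(ann$term[bad]), 5), collapse = ", "))
    ann <- ann[!bad, , drop = FALSE]
    resolved <- resolved[!bad]
    domain <- domain[!bad]
  }
  if (nrow(ann) == 0) stop("no resolvable annotations", call. = FALSE)
  ann$term <- resolved
  ann$domain <- domain
  ann <- dplyr::distinct(ann, .data$resource, .data$term, .data$domain)
  ann <- dplyr::arrange(ann, .data$resource, .data$domain, .data$term)

  structure(
    list(annotations = ann,
         resources = sort(unique(ann$resource)),
         m = dplyr::n_distinct(ann$resource),
         domains = sort(unique(ann$domain))),
    class = "annotation_corpus")
}

domain_lookup <- function(ontologies) {
  unlist(purrr::imap(ontologies, function(g, d) {
    stats::setNames(rep(d, nrow(g$terms)), g$terms$id)
  }))
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat(sprintf("<annotation_corpus> %d resources, %d annotations, %d domain%s (%s)\n",
              x$m, nrow(x$annotations), length(x$domains),
              if (length(x$domains) == 1) "" else "s",
              paste(x$domains, collapse = ", ")))
  invisible(x)
}

#' @export
as_tibble.annotation_corpus <- function(x, ...) x$annotations

#' Load a resource-annotation corpus from a TSV file
#'
#' Reads a two-column TSV (`resource_id`, `term_id`; header optional),
#' resolves term ids against the supplied ontologies (alternative ids are
#' mapped to primary ids), infers each annotation's domain from its term,
#' logs and drops unresolvable annotations, and deduplicates repeated
#' (resource, term) pairs. Resources left without any resolvable annotation
#' are dropped with a warning.
#'
#' @param path Path to the TSV file.
#' @param ontologies Named list of [ontology] objects.
#' @return An [annotation_corpus].
#' @export
load_annotations <- function(path, ontologies) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_names = c("resource", "term"),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) stop("empty annotation file: ", path, call. = FALSE)
  # optional header: first row whose term field carries no id separator
  if (!grepl(":", raw$term[[1]])) raw <- raw[-1, , drop = FALSE]
  if (nrow(raw) == 0) stop("no annotation rows in ", path, call. = FALSE)
  before <- unique(raw$resource)
  corp <- annotation_corpus(raw, ontologies)
  lost <- setdiff(before, unique(corp$annotations$resource))
  if (length(lost) > 0) {
    warning("dropped ", length(lost),
            " resource(s) with no resolvable annotations: ",
            paste(utils::head(lost, 5), collapse = ", "), call. = FALSE)
  }
  corp
}

#' Per-domain descriptive statistics of a corpus
#'
#' For each domain: *coverage*, the fraction of resources with at least one
#' annotation in the domain; *volume*, the mean annotation count in the
#' domain over the covered resources only; *diversity*, the number of
#' distinct terms of the domain in use; and *isolation*, the fraction of
#' resources annotated exclusively in that domain. Also tabulates the
#' histogram of how many distinct domains each resource is annotated in.
#'
#' @param corpus An [annotation_corpus].
#' @return An object of class `corpus_stats`: list with `domains` (tibble
#'   `domain`, `coverage`, `volume`, `diversity`, `isolation`), `histogram`
#'   (tibble `n_domains`, `n_resources`) and `m`.
#' @examples
#' \dontrun{
#' corpus_stats(load_annotations("annotations.tsv", ontologies))
#' }
#' @export
corpus_stats <- function(corpus) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  ann <- corpus$annotations
  m <- corpus$m

  per_rd <- ann |>
    dplyr::count(.data$resource, .data$domain, name = "n_ann")
  n_domains_of <- per_rd |>
    dplyr::count(.data$resource, name = "n_domains")

  only_in <- per_rd |>
    dplyr::inner_join(dplyr::filter(n_domains_of, .data$n_domains == 1),
                      by = "resource") |>
    dplyr::count(.data$domain, name = "n_isolated")

  domains <- per_rd |>
    dplyr::group_by(.data$domain) |>
    dplyr::summarise(coverage = dplyr::n() / m,
                     volume = mean(.data$n_ann), .groups = "drop") |>
    dplyr::left_join(
      ann |> dplyr::group_by(.data$domain) |>
        dplyr::summarise(diversity = dplyr::n_distinct(.data$term),
                         .groups = "drop"),
      by = "domain") |>
    dplyr::left_join(only_in, by = "domain") |>
    dplyr::mutate(isolation = dplyr::coalesce(.data$n_isolated, 0L) / m) |>
    dplyr::select("domain", "coverage", "volume", "diversity", "isolation") |>
    dplyr::arrange(.data$domain)

  histogram <- n_domains_of |>
    dplyr::count(.data$n_domains, name = "n_resources") |>
    dplyr::arrange(.data$n_domains)

  structure(list(domains = domains, histogram = histogram, m = m),
            class = "corpus_stats")
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat(sprintf("<corpus_stats> m = %d resources\n", x$m))
  print(x$domains)
  cat("domains-per-resource histogram:\n")
  print(x$histogram)
  invisible(x)
}

#' @rdname corpus_stats
#' @param x A `corpus_stats` object.
#' @param ... Unused.
#' @export
tidy.corpus_stats <- function(x, ...) x$domains

#' @rdname corpus_stats
#' @export
glance.corpus_stats <- function(x, ...) {
  tibble::tibble(m = x$m,
                 n_domains = nrow(x$domains),
                 max_domains_per_resource = max(x$histogram$n_domains),
                 multi_domain_fraction =
                   sum(x$histogram$n_resources[x$histogram$n_domains > 1]) / x$m)
}

#' Write corpus statistics to TSV and JSON
#'
#' @param stats A `corpus_stats` object.
#' @param tsv,json Output paths (either may be `NULL` to skip).
#' @return `stats`, invisibly.
#' @export
write_corpus_stats <- function(stats, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) readr::write_tsv(stats$domains, tsv)
  if (!is.null(json)) {
    jsonlite::write_json(
      list(m = stats$m,
           domains = stats$domains,
           histogram = stats$histogram),
      json, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(stats)
}
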