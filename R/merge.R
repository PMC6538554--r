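#' Merge several ontologies under a common root
#'
#' Implements the integrative construction: terms sharing an identical id
#' across input ontologies are unified into a single concept (so their
#' subclasses gain a common non-root ancestor even when they come from
#' different domains), and a fresh root subsuming every former root is
#' created — unless all inputs already share one single common root id, in
#' which case that root is reused.
#'
#' @param graphs List of [ontology] objects (named by source ontology, or
#'   names are taken from each graph's domain tags).
#' @param root_id Id for the created root (default `"MULTI:0000000"`).
#' @param root_name Label for the created root.
#' @return A `merged_ontology` (subclass of `ontology`) with extra fields
#'   `merged_root_id`, `provenance` (term id -> character vector of source
#'   names) and `collisions` (ids present in more than one source).
#' @examples
#' a <- ontology(tibble::tibble(id = c("A:r", "A:1"), name = id,
#'                              domain = "A", obsolete = FALSE),
#'               tibble::tibble(child = "A:1", parent = "A:r"))
#' b <- ontology(tibble::tibble(id = c("B:r", "B:1"), name = id,
#'                              domain = "B", obsolete = FALSE),
#'               tibble::tibble(child = "B:1", parent = "B:r"))
#' m <- merge_ontologies(list(a, b))
#' m$merged_root_id
#' @export
merge_ontologies <- function(graphs, root_id = "MULTI:0000000",
                             root_name = "multi-domain root") {
  stopifnot(length(graphs) >= 1)
  if (is.null(names(graphs)) || any(names(graphs) == "")) {
    names(graphs) <- vapply(graphs, function(g) g$terms$domain[[1]], "")
  }

  all_terms <- dplyr::bind_rows(purrr::imap(graphs, function(g, src) {
    dplyr::mutate(g$terms, source = src)
  }))
  prov <- split(all_terms$source, all_terms$id)
  prov <- lapply(prov, unique)
  collisions <- sort(names(prov)[vapply(prov, length, 1L) > 1])

  # unify by id: first-seen name and domain win; obsolete only if all agree
  first <- !duplicated(all_terms$id)
  name_conflict <- all_terms |>
    dplyr::distinct(.data$id, .data$name) |>
    dplyr::count(.data$id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(name_conflict) > 0) {
    warning("conflicting names for unified id(s): ",
            paste(name_conflict$id, collapse = ", "),
            "; keeping first-seen names", call. = FALSE)
  }
  terms <- all_terms[first, c("id", "name", "domain", "obsolete")]
  obs_all <- tapply(all_terms$obsolete, all_terms$id, all)
  terms$obsolete <- unname(obs_all[terms$id])

  edges <- dplyr::bind_rows(purrr::map(graphs, "edges")) |>
    dplyr::distinct()
  alt <- unlist(purrr::map(graphs, "alt"))
  if (is.null(alt)) alt <- character()
  alt <- alt[!duplicated(names(alt))]

  pre <- ontology(terms, edges, alt = alt)
  shared_root <- length(pre$roots) == 1 &&
    all(vapply(graphs, function(g) identical(g$roots, pre$roots), TRUE))

  if (shared_root) {
    merged_root_id <- pre$roots
    out <- pre
  } else {
    merged_root_id <- root_id
    if (root_id %in% terms$id) {
      stop("root id ", root_id, " already present in the inputs", call. = FALSE)
    }
    terms <- dplyr::bind_rows(
      tibble::tibble(id = root_id, name = root_name,
                     domain = "merged", obsolete = FALSE),
      terms)
    edges <- dplyr::bind_rows(
      edges,
      tibble::tibble(child = pre$roots, parent = root_id, relation = "is_a"))
    out <- ontology(terms, edges, alt = alt)
    prov[[root_id]] <- "merged"
  }

  out$merged_root_id <- merged_root_id
  out$provenance <- prov
  out$collisions <- collisions
  class(out) <- c("merged_ontology", class(out))
  out
}

#' @export
print.merged_ontology <- function(x, ...) {
  NextMethod()
  cat(sprintf("merged root: %s; %d id collision%s across sources\n",
              x$merged_root_id, length(x$collisions),
              if (length(x$collisions) == 1) "" else "s"))
  invisible(x)
}

#' Write the id-collision report of a merged ontology
#'
#' @param merged A `merged_ontology`.
#' @param path Output TSV path (`term_id`, `source_ontologies`).
#' @return `path`, invisibly.
#' @export
write_collision_report <- function(merged, path) {
  stopifnot(inherits(merged, "merged_ontology"))
  tbl <- tibble::tibble(
    term_id = merged$collisions,
    source_ontologies = vapply(
      merged$provenance[merged$collisions],
      function(s) paste(sort(s), collapse = ","), "")
  )
  readr::write_tsv(tbl, path)
  invisible(path)
}
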