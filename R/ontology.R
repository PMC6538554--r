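#' @title Subsumption ontologies
#' @description Tools to represent one domain ontology (or a merged
#'   multi-domain ontology) as a directed acyclic subsumption graph, with
#'   ancestor closure and most-informative-common-ancestor queries.
#' @name ontology
#' @keywords internal
NULL

#' Construct an ontology object
#'
#' Builds a validated subsumption DAG from a term table and an edge table.
#' Most users will obtain ontologies from [parse_obo()] or
#' [generate_ontology()] rather than calling this directly.
#'
#' @param terms A data frame with columns `id`, `name`, `domain`, `obsolete`
#'   (logical). `id` must be unique.
#' @param edges A data frame with columns `child`, `parent` and optionally
#'   `relation` (defaults to `"is_a"`). Both endpoints must exist in `terms`
#'   and neither may be obsolete.
#' @param alt Named character vector mapping alternative ids to primary ids.
#'
#' @return An object of class `ontology`: a list with elements `terms`
#'   (tibble), `edges` (tibble), `roots` (character), `alt` (named character)
#'   and `anc` (named list of reflexive ancestor-id vectors, one per
#'   non-obsolete term).
#' @export
ontology <- function(terms, edges, alt = character()) {
  terms <- tibble::as_tibble(terms)
  if (!all(c("id", "name", "domain", "obsolete") %in% names(terms))) {
    stop("`terms` needs columns id, name, domain, obsolete", call. = FALSE)
  }
  if (anyDuplicated(terms$id)) {
    dup <- unique(terms$id[duplicated(terms$id)])
    stop("duplicate term ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(child = character(), parent = character(),
                            relation = character())
  }
  if (!"relation" %in% names(edges)) edges$relation <- "is_a"
  edges <- dplyr::distinct(edges, .data$child, .data$parent, .data$relation)

  bad <- setdiff(c(edges$child, edges$parent), terms$id)
  if (length(bad) > 0) {
    stop("edge endpoints absent from term table: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  obs <- terms$id[terms$obsolete]
  touching <- edges$child %in% obs | edges$parent %in% obs
  if (any(touching)) edges <- edges[!touching, , drop = FALSE]

  live <- terms$id[!terms$obsolete]
  if (length(live) == 0) stop("ontology has no non-obsolete terms", call. = FALSE)

  parent_of <- split(edges$parent, factor(edges$child, levels = live))
  ord <- topo_order(live, parent_of)

  anc <- vector("list", length(live))
  names(anc) <- live
  for (id in ord) {   # ord visits parents before children
    ps <- parent_of[[id]]
    anc[[id]] <- if (length(ps) == 0) id else
      unique(c(id, unlist(anc[ps], use.names = FALSE)))
  }

  roots <- live[vapply(parent_of[live], length, 1L) == 0]
  structure(
    list(terms = terms, edges = edges, roots = roots,
         alt = alt, anc = anc),
    class = "ontology"
  )
}

# Kahn topological sort, parents first; errors with the offending cycle.
topo_order <- function(ids, parent_of) {
  n_parents <- vapply(parent_of[ids], length, 1L)
  children_of <- list()
  for (id in ids) for (p in parent_of[[id]]) {
    children_of[[p]] <- c(children_of[[p]], id)
  }
  queue <- ids[n_parents == 0]
  names(n_parents) <- ids
  out <- character(0)
  while (length(queue) > 0) {
    id <- queue[[1]]; queue <- queue[-1]
    out <- c(out, id)
    for (ch in children_of[[id]]) {
      n_parents[[ch]] <- n_parents[[ch]] - 1L
      if (n_parents[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < length(ids)) {
    cyc <- setdiff(ids, out)
    stop("cycle detected among terms: ", paste(cyc, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' @export
print.ontology <- function(x, ...) {
  live <- sum(!x$terms$obsolete)
  cat(sprintf("<ontology> %d terms (%d obsolete), %d is_a edges, %d root%s\n",
              nrow(x$terms), nrow(x$terms) - live, nrow(x$edges),
              length(x$roots), if (length(x$roots) == 1) "" else "s"))
  cat("domains:", paste(unique(x$terms$domain), collapse = ", "), "\n")
  invisible(x)
}

#' Parse an OBO flat file into an ontology
#'
#' Reads OBO 1.2/1.4 `[Term]` stanzas (keys: `id`, `name`, `is_a`, `alt_id`,
#' `is_obsolete`, `relationship: part_of`) into a subsumption DAG. By default
#' only `is_a` edges are used; `part_of` relationships can be included as
#' additional subsumption edges. Obsolete terms are retained as nodes for id
#' resolution but carry no edges and are excluded from closure queries.
#'
#' @param path Path to an OBO file.
#' @param domain Domain tag to attach to every term (e.g. `"DOID"`).
#' @param include_part_of Treat `relationship: part_of` lines as subsumption
#'   edges (default `FALSE`).
#'
#' @return An [ontology] object.
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("[Term]", "id: X:1", "name: root", "",
#'              "[Term]", "id: X:2", "name: leaf", "is_a: X:1"), obo)
#' parse_obo(obo, domain = "X")
#' @export
parse_obo <- function(path, domain, include_part_of = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)

  in_term <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function(cur) {
    if (is.null(cur)) return(invisible())
    if (is.null(cur$id)) {
      stop(sprintf("malformed [Term] stanza starting at line %d: missing id",
                   cur$line), call. = FALSE)
    }
    terms[[length(terms) + 1L]] <<- cur
    invisible()
  }
  for (i in seq_along(lines)) {
    ln <- sub("\\s+$", "", lines[[i]])
    if (grepl("^\\[", ln)) {
      flush(cur); cur <- NULL
      in_term <- identical(ln, "[Term]")
      if (in_term) cur <- list(line = i, parents = character(),
                               part_of = character(), alt = character(),
                               obsolete = FALSE)
      next
    }
    if (!in_term || ln == "") next
    if (!grepl("^[A-Za-z_]+:", ln)) {
      stop(sprintf("malformed line %d in [Term] stanza: %s", i, ln),
           call. = FALSE)
    }
    key <- sub(":.*$", "", ln)
    val <- sub("^[A-Za-z_]+:\\s*", "", ln)
    val <- sub("\\s*!.*$", "", val)  # trailing comment
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "is_a") cur$parents <- c(cur$parents, val)
    else if (key == "alt_id") cur$alt <- c(cur$alt, val)
    else if (key == "is_obsolete") cur$obsolete <- tolower(val) %in% c("true", "1")
    else if (key == "relationship") {
      parts <- strsplit(val, "\\s+")[[1]]
      if (length(parts) >= 2 && parts[[1]] == "part_of") {
        cur$part_of <- c(cur$part_of, parts[[2]])
      }
    }
  }
  flush(cur)
  if (length(terms) == 0) stop("no [Term] stanzas in ", path, call. = FALSE)

  ids <- vapply(terms, `[[`, "", "id")
  term_tbl <- tibble::tibble(
    id = ids,
    name = vapply(terms, function(t) t$name %||% t$id, ""),
    domain = domain,
    obsolete = vapply(terms, `[[`, TRUE, "obsolete")
  )
  if (all(term_tbl$obsolete)) {
    stop("ontology in ", path, " has no non-obsolete terms", call. = FALSE)
  }

  edge_rows <- purrr::map(terms, function(t) {
    ps <- t$parents
    rel <- rep("is_a", length(ps))
    if (include_part_of && length(t$part_of) > 0) {
      ps <- c(ps, t$part_of)
      rel <- c(rel, rep("part_of", length(t$part_of)))
    }
    if (length(ps) == 0) return(NULL)
    tibble::tibble(child = t$id, parent = ps, relation = rel)
  })
  edges <- dplyr::bind_rows(edge_rows)

  alt <- unlist(purrr::map(terms, function(t) {
    stats::setNames(rep(t$id, length(t$alt)), t$alt)
  }))
  if (is.null(alt)) alt <- character()

  # drop edges that point at ids not declared in this file
  if (nrow(edges) > 0) {
    known <- edges$parent %in% ids & edges$child %in% ids
    edges <- edges[known, , drop = FALSE]
  }
  ontology(term_tbl, edges, alt = alt)
}

#' Write an ontology back to an OBO flat file
#'
#' Emits `[Term]` stanzas sorted by term id, so output is byte-deterministic
#' for a given ontology.
#'
#' @param graph An [ontology] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  terms <- dplyr::arrange(graph$terms, .data$id)
  edges <- graph$edges
  alt_by_primary <- if (length(graph$alt) > 0) {
    split(names(graph$alt), graph$alt)
  } else {
    list()
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(terms))) {
    id <- terms$id[[i]]
    out <- c("[Term]", paste0("id: ", id), paste0("name: ", terms$name[[i]]))
    for (a in sort(alt_by_primary[[id]])) out <- c(out, paste0("alt_id: ", a))
    e <- edges[edges$child == id, , drop = FALSE]
    e <- e[order(e$parent), , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      out <- c(out, if (e$relation[[j]] == "is_a") {
        paste0("is_a: ", e$parent[[j]])
      } else {
        paste0("relationship: ", e$relation[[j]], " ", e$parent[[j]])
      })
    }
    if (terms$obsolete[[i]]) out <- c(out, "is_obsolete: true")
    writeLines(c(out, ""), con)
  }
  invisible(path)
}

#' Resolve a term id against an ontology
#'
#' Maps alternative ids to their primary id and validates existence.
#'
#' @param graph An [ontology].
#' @param id Character vector of term ids.
#' @param error Raise an error for unresolvable ids (default); otherwise
#'   return `NA` for them.
#' @return Character vector of primary ids.
#' @export
resolve_term <- function(graph, id, error = TRUE) {
  out <- ifelse(id %in% names(graph$alt), unname(graph$alt[id]), id)
  known <- out %in% graph$terms$id
  if (error && !all(known)) {
    stop("unknown term id(s): ", paste(unique(id[!known]), collapse = ", "),
         call. = FALSE)
  }
  out[!known] <- NA_character_
  out
}

#' Reflexive ancestor closure of a term
#'
#' Returns the term itself plus every term reachable by following
#' subsumption edges upwards, including all roots above it.
#'
#' @param graph An [ontology].
#' @param term A single term id (alternative ids are resolved).
#' @return Character vector of term ids.
#' @examples
#' g <- ontology(
#'   tibble::tibble(id = c("X:r", "X:a", "X:b"), name = id,
#'                  domain = "X", obsolete = FALSE),
#'   tibble::tibble(child = c("X:a", "X:b"), parent = c("X:r", "X:a")))
#' ancestors(g, "X:b")
#' @export
ancestors <- function(graph, term) {
  stopifnot(length(term) == 1)
  id <- resolve_term(graph, term)
  a <- graph$anc[[id]]
  if (is.null(a)) stop("term is obsolete: ", id, call. = FALSE)
  a
}

#' Proper descendant counts for every term
#'
#' @param graph An [ontology].
#' @return Named integer vector over non-obsolete terms; a leaf has count 0.
#' @export
descendant_counts <- function(graph) {
  live <- names(graph$anc)
  counts <- stats::setNames(integer(length(live)), live)
  for (id in live) {
    ups <- setdiff(graph$anc[[id]], id)
    counts[ups] <- counts[ups] + 1L
  }
  counts
}

#' Most informative common ancestor of two terms
#'
#' Finds the common ancestor with maximal information content. Ties are
#' broken by the lexicographically smallest term id, so results are
#' deterministic. If the terms share no ancestor (e.g. they live in disjoint
#' ontologies queried without merging) a sentinel with `term = NA` and
#' `ic = 0` is returned.
#'
#' @param graph An [ontology].
#' @param ic An [ic_table] for `graph`.
#' @param t1,t2 Term ids.
#' @return A list with elements `term` (id or `NA`) and `ic` (number).
#' @export
mica <- function(graph, ic, t1, t2) {
  a1 <- ancestors(graph, t1)
  a2 <- ancestors(graph, t2)
  common <- intersect(a1, a2)
  if (length(common) == 0) {
    return(list(term = NA_character_, ic = 0))
  }
  vals <- ic_of(ic, common)
  best <- max(vals)
  winners <- sort(common[vals == best])
  list(term = winners[[1]], ic = best)
}

#' @importFrom rlang %||% .data
NULL
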