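#' Information-content tables
#'
#' An `ic_table` assigns each non-obsolete term a non-negative information
#' content (IC) in natural-log units. Corpus-based IC follows the classical
#' negative-log relative annotation frequency, with annotation counts
#' propagated up the subsumption graph; the intrinsic variant scores terms by
#' structural rarity (descendant counts) and is the fallback for a domain
#' without annotation data.
#'
#' @param ic Named numeric vector of IC values.
#' @param source `"corpus"` or `"intrinsic"`.
#' @return An object of class `ic_table`: list with `ic` (named numeric),
#'   `ic_max` (max finite IC) and `source`.
#' @export
ic_table <- function(ic, source) {
  stopifnot(is.numeric(ic), !is.null(names(ic)),
            source %in% c("corpus", "intrinsic"))
  if (any(!is.finite(ic)) || any(ic < 0)) {
    stop("IC values must be finite and non-negative", call. = FALSE)
  }
  structure(list(ic = ic, ic_max = if (length(ic)) max(ic) else 0,
                 source = source),
            class = "ic_table")
}

#' @export
print.ic_table <- function(x, ...) {
  cat(sprintf("<ic_table> %d terms, source = %s, ic_max = %.4g\n",
              length(x$ic), x$source, x$ic_max))
  invisible(x)
}

# IC lookup; unknown terms get 0 (roots created at merge time, say).
ic_of <- function(ic, ids) {
  v <- ic$ic[ids]
  v[is.na(v)] <- 0
  unname(v)
}

#' Corpus-based information content
#'
#' Propagated annotation frequency: `freq(t)` is the number of
#' (resource, annotation) pairs whose term is `t` or a descendant of `t`;
#' `IC(t) = -ln(freq(t) / N)` with `N` the total number of resolvable
#' annotation pairs. Roots have IC 0. Terms never observed (frequency 0)
#' receive the maximum observed IC, which keeps every value finite while
#' preserving the rarity ordering.
#'
#' @param graph An [ontology].
#' @param corpus An [annotation_corpus]; annotations whose terms do not
#'   resolve in `graph` are ignored.
#' @return An [ic_table] with `source = "corpus"`.
#' @export
compute_ic_corpus <- function(graph, corpus) {
  ann <- corpus$annotations
  if (nrow(ann) == 0) stop("corpus is empty", call. = FALSE)
  ids <- resolve_term(graph, ann$term, error = FALSE)
  ids <- ids[!is.na(ids) & ids %in% names(graph$anc)]
  if (length(ids) == 0) {
    stop("no corpus annotation resolves in this ontology", call. = FALSE)
  }
  n_total <- length(ids)

  live <- names(graph$anc)
  freq <- stats::setNames(numeric(length(live)), live)
  tab <- table(ids)
  for (id in names(tab)) {
    up <- graph$anc[[id]]
    freq[up] <- freq[up] + as.numeric(tab[[id]])
  }

  icv <- ifelse(freq > 0, -log(freq / n_total), NA_real_)
  icv[graph$roots] <- 0
  max_obs <- max(icv, na.rm = TRUE)
  icv[is.na(icv)] <- max_obs
  ic_table(icv, source = "corpus")
}

#' Intrinsic (structure-only) information content
#'
#' `IC(t) = 1 - ln(1 + |descendants(t)|) / ln(n)` over the `n` non-obsolete
#' terms, clipped to `[0, 1]`: leaves score 1, a root subsuming everything
#' scores 0. A single-term ontology gets all-zero IC.
#'
#' @param graph An [ontology].
#' @return An [ic_table] with `source = "intrinsic"`.
#' @export
compute_ic_intrinsic <- function(graph) {
  live <- names(graph$anc)
  n <- length(live)
  if (n <= 1) {
    return(ic_table(stats::setNames(numeric(n), live), source = "intrinsic"))
  }
  d <- descendant_counts(graph)
  icv <- 1 - log(1 + d) / log(n)
  icv <- pmin(pmax(icv, 0), 1)
  icv[graph$roots] <- 0
  ic_table(icv, source = "intrinsic")
}

#' @rdname compute_ic_corpus
#' @param x An `ic_table`.
#' @param ... Unused.
#' @export
tidy.ic_table <- function(x, ...) {
  tibble::tibble(id = names(x$ic), ic = unname(x$ic), source = x$source)
}
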