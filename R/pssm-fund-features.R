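#' Extract the 20-dimensional PSSM descriptor
#'
#' Column means of the L x 20 log-odds profile: component j is
#' `sum(S[, j]) / L`, in the column order of the source file.
#'
#' @param m a [pssm_matrix()].
#' @return named numeric vector of length 20 (`pssm.mean.` prefix).
#' @export
extract_pssm_features <- function(m) {
  if (!inherits(m, "pssm_matrix")) stop_("'m' must be a pssm_matrix")
  setNames(colMeans(m$scores), paste0("pssm.mean.", m$column_order))
}

#' Ordered functional-domain universe
#'
#' The fixed, ordered set of domain identifiers that defines the bases of
#' the binary occupancy vector. Order is preserved and persisted so feature
#' columns are reproducible across runs.
#'
#' @param domain_ids character vector of unique, nonempty domain ids.
#' @return an object of class `domain_universe`.
#' @export
domain_universe <- function(domain_ids) {
  domain_ids <- as.character(domain_ids)
  if (!length(domain_ids)) stop_("domain universe must be nonempty")
  if (any(!nzchar(domain_ids))) stop_("empty domain id in universe")
  if (anyDuplicated(domain_ids)) stop_("duplicated domain ids in universe")
  structure(list(domain_ids = domain_ids, size = length(domain_ids)),
            class = "domain_universe")
}

#' @export
print.domain_universe <- function(x, ...) {
  cat(sprintf("<domain_universe> %d domains (%s, ...)\n", x$size,
              paste(head(x$domain_ids, 3), collapse = ", ")))
  invisible(x)
}

#' @rdname domain_universe
#' @param path one-id-per-line text file.
#' @export
read_domain_universe <- function(path) {
  ids <- readLines(path)
  domain_universe(ids[nzchar(ids)])
}

#' @rdname domain_universe
#' @param universe a `domain_universe`.
#' @export
write_domain_universe <- function(universe, path) {
  writeLines(universe$domain_ids, path)
  invisible(path)
}

#' Extract the binary functional-domain occupancy descriptor
#'
#' Component d is 1 if some hit to domain d has E-value at or below the
#' significance threshold (inclusive), otherwise 0. Hits to domains outside
#' the universe are ignored with a warning.
#'
#' @param hits data.frame of hits as returned by [parse_domain_hits()]
#'   (columns `domain_id`, `e_value`).
#' @param universe a [domain_universe()].
#' @param threshold E-value significance cutoff (default 0.001, inclusive).
#' @return named 0/1 numeric vector of length `universe$size`
#'   (`fund.` prefix).
#' @export
extract_fund_features <- function(hits, universe, threshold = 0.001) {
  if (!inherits(universe, "domain_universe")) {
    stop_("'universe' must be a domain_universe")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop_("'threshold' must be a single nonnegative number")
  }
  out <- setNames(numeric(universe$size),
                  paste0("fund.", universe$domain_ids))
  if (nrow(hits)) {
    sig <- hits[hits$e_value <= threshold, , drop = FALSE]
    unknown <- setdiff(unique(sig$domain_id), universe$domain_ids)
    if (length(unknown)) {
      warning("ignoring hits to ", length(unknown),
              " domain(s) outside the universe: ",
              paste(head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    idx <- match(sig$domain_id, universe$domain_ids)
    out[idx[!is.na(idx)]] <- 1
  }
  out
}
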