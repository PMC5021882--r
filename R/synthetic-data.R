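#' Generate a random protein sequence
#'
#' Uniform over the 20 standard amino acids; a pure function of
#' `(length, seed)`.
#'
#' @param length sequence length (>= 1).
#' @param seed integer seed.
#' @param id record id (default derived from the seed).
#' @return one-row data.frame with columns `id`, `sequence`, `label` (NA),
#'   matching [read_fasta()] output.
#' @export
gen_sequence <- function(length, seed = 1, id = sprintf("synth%04d", seed)) {
  if (!is_count(length, min = 1L)) stop_("'length' must be a positive integer")
  seq <- with_seed(seed,
    paste(sample(STANDARD_AA, length, replace = TRUE), collapse = ""))
  data.frame(id = id, sequence = seq, label = NA_character_,
             stringsAsFactors = FALSE)
}

# one residue record in the DSSP fixed-column dialect: chain id at char 12,
# amino acid at char 14, structure summary letter at char 17
format_dssp_line <- function(i, chain, aa, ss) {
  sprintf("%5d%5d %s %s  %s", i, i, chain, aa, if (ss == "L") " " else ss)
}

#' Generate a secondary-structure string plus a parsable DSSP file
#'
#' States follow a first-order Markov chain: with probability `persistence`
#' the previous state repeats, otherwise a uniformly random different state
#' is drawn — so runs of identical states occur as they do in real
#' structures. The emitted text is a syntactically valid DSSP file whose
#' [parse_dssp()] result is exactly the generated string.
#'
#' @param length number of residues (>= 1).
#' @param seed integer seed.
#' @param persistence probability of repeating the previous state
#'   (default 0.7).
#' @param chain chain id used in the file (default "A").
#' @return list with `dssp` (a [dssp_string()]) and `text` (character
#'   vector of file lines).
#' @export
gen_dssp_fixture <- function(length, seed = 1, persistence = 0.7, chain = "A") {
  if (!is_count(length, min = 1L)) stop_("'length' must be a positive integer")
  if (persistence < 0 || persistence > 1) stop_("'persistence' must be in [0, 1]")
  states <- with_seed(seed, {
    s <- character(length)
    s[[1L]] <- sample(DSSP_STATES, 1L)
    for (i in seq_len(length - 1L)) {
      s[[i + 1L]] <- if (runif(1) < persistence) s[[i]] else
        sample(setdiff(DSSP_STATES, s[[i]]), 1L)
    }
    s
  })
  aa <- with_seed(seed + 1L, sample(STANDARD_AA, length, replace = TRUE))
  text <- c(
    "==== Secondary Structure Definition, synthetic fixture ====",
    sprintf("  %d  1  0  0  0    TOTAL NUMBER OF RESIDUES", length),
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA",
    vapply(seq_len(length),
           function(i) format_dssp_line(i, chain, aa[[i]], states[[i]]),
           character(1))
  )
  list(dssp = dssp_string(paste(states, collapse = ""), chain_id = chain),
       text = text)
}

#' Generate a PSSM plus a parsable ASCII PSSM file
#'
#' Integer log-odds scores uniform on \[-10, 10\]; the emitted text mimics
#' the PSI-BLAST ASCII layout (header rows, position/residue columns, 20
#' log-odds columns, trailing weighted-percentage and information columns)
#' and round-trips through [parse_pssm()].
#'
#' @param L number of residue rows (>= 1).
#' @param seed integer seed.
#' @return list with `pssm` (a [pssm_matrix()]) and `text`.
#' @export
gen_pssm_fixture <- function(L, seed = 1) {
  if (!is_count(L, min = 1L)) stop_("'L' must be a positive integer")
  out <- with_seed(seed, {
    scores <- matrix(sample(-10:10, L * 20L, replace = TRUE), nrow = L)
    residues <- sample(STANDARD_AA, L, replace = TRUE)
    list(scores = scores, residues = residues)
  })
  m <- pssm_matrix(out$scores, paste(out$residues, collapse = ""))
  hdr <- paste(c("     ", sprintf("%3s", PSSM_COLUMN_ORDER),
                 sprintf("%4s", PSSM_COLUMN_ORDER)), collapse = "")
  rows <- vapply(seq_len(L), function(i) {
    paste(c(sprintf("%5d %s ", i, out$residues[[i]]),
            sprintf("%4d", out$scores[i, ]),
            sprintf("%4d", rep(0L, 20L)),
            sprintf("%6.2f", 0), sprintf("%9.2f", 0)), collapse = "")
  }, character(1))
  text <- c("",
            "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
            hdr, rows, "", "                      K         Lambda")
  list(pssm = m, text = text)
}

#' Generate a domain-hit table plus a parsable BLAST tabular file
#'
#' Hit domains are drawn from the universe; E-values are log-uniform on
#' \[1e-10, 10\]. The emitted 12-column tabular text round-trips through
#' [parse_domain_hits()] exactly (E-values written with full precision).
#'
#' @param universe a [domain_universe()].
#' @param n_hits number of hit lines (>= 0; 0 gives an empty file).
#' @param seed integer seed.
#' @param query query id used in column 1.
#' @return list with `hits` (data.frame `domain_id`, `e_value`) and `text`.
#' @export
gen_hits_fixture <- function(universe, n_hits, seed = 1, query = "query1") {
  if (!is_count(n_hits)) stop_("'n_hits' must be a nonnegative integer")
  if (n_hits == 0L) {
    return(list(hits = data.frame(domain_id = character(),
                                  e_value = numeric(),
                                  stringsAsFactors = FALSE),
                text = character()))
  }
  out <- with_seed(seed, {
    ids <- sample(universe$domain_ids, n_hits, replace = TRUE)
    ev <- 10^runif(n_hits, min = -10, max = 1)
    list(ids = ids, ev = ev)
  })
  text <- vapply(seq_len(n_hits), function(i) {
    paste(c(query, paste0("gnl|CDD|", out$ids[[i]]), "50.0", "100", "40", "2",
            "1", "100", "1", "100", sprintf("%.17g", out$ev[[i]]), "120"),
          collapse = "\t")
  }, character(1))
  list(hits = data.frame(domain_id = out$ids, e_value = out$ev,
                         stringsAsFactors = FALSE),
       text = text)
}

#' Specification for a synthetic labelled multi-view dataset
#'
#' @param n_classes number of fold classes (>= 2).
#' @param n_per_class samples per class (>= 2).
#' @param separation nonnegative scale of between-class centroid spread
#'   relative to unit within-class noise; 0 gives chance-level data.
#' @param group_dims named integer vector of per-group feature dimensions;
#'   the defaults mirror the real descriptor sizes (the FunD dimension is
#'   kept at 500 rather than a full domain database for tractability).
#' @param seed integer seed.
#' @return an object of class `synthetic_dataset_spec`.
#' @export
synthetic_dataset_spec <- function(n_classes = 5, n_per_class = 60,
                                   separation = 10,
                                   group_dims = c(DSSP = 40, AAsCPP = 188,
                                                  PSSM = 20, FunD = 500),
                                   seed = 1) {
  if (!is_count(n_classes, 2L)) stop_("'n_classes' must be >= 2")
  if (!is_count(n_per_class, 2L)) stop_("'n_per_class' must be >= 2")
  if (!is.numeric(separation) || separation < 0) {
    stop_("'separation' must be nonnegative")
  }
  if (is.null(names(group_dims)) || any(group_dims < 1)) {
    stop_("'group_dims' must be a named vector of positive dimensions")
  }
  structure(list(n_classes = n_classes, n_per_class = n_per_class,
                 separation = separation, group_dims = group_dims,
                 seed = seed),
            class = "synthetic_dataset_spec")
}

#' Generate a labelled four-view dataset with controllable separation
#'
#' Class structure lives in feature space: for every feature group each
#' class gets a Gaussian centroid with standard deviation `separation`, and
#' samples are the centroid plus unit-variance noise. All groups share the
#' same sample ids and labels. Deterministic per seed.
#'
#' @param spec a [synthetic_dataset_spec()].
#' @return list with `feature_groups` (named list of [feature_matrix()])
#'   and `labels` (named character vector).
#' @examples
#' d <- gen_labelled_dataset(synthetic_dataset_spec(
#'   n_classes = 2, n_per_class = 4, group_dims = c(A = 3, B = 2), seed = 7))
#' sapply(d$feature_groups, dim)
#' @export
gen_labelled_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_dataset_spec"))
  n <- spec$n_classes * spec$n_per_class
  class_names <- sprintf("fold%02d", seq_len(spec$n_classes))
  labels <- rep(class_names, each = spec$n_per_class)
  ids <- sprintf("s%04d", seq_len(n))
  feature_groups <- with_seed(spec$seed, {
    out <- list()
    for (g in names(spec$group_dims)) {
      d <- spec$group_dims[[g]]
      centroids <- matrix(rnorm(spec$n_classes * d, sd = spec$separation),
                          nrow = spec$n_classes)
      vals <- centroids[rep(seq_len(spec$n_classes),
                            each = spec$n_per_class), , drop = FALSE] +
        matrix(rnorm(n * d), nrow = n)
      dimnames(vals) <- list(ids, sprintf("%s.f%03d", tolower(g), seq_len(d)))
      out[[g]] <- feature_matrix(vals, group_name = g)
    }
    out
  })
  list(feature_groups = feature_groups, labels = setNames(labels, ids))
}
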