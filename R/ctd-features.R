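# The 20 standard amino acids, alphabetically (fixed descriptor order).
STANDARD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Classical three-group partitions of the 20 amino acids per
# physicochemical property (Dubchak-style groupings). Each row is an exact
# partition; property order is the canonical descriptor order.
AA_GROUPINGS <- list(
  hydrophobicity        = c("RKEDQN",   "GASTPHY",          "CVLIMFW"),
  vdw_volume            = c("GASCTPD",  "NVEQIL",           "MHKFRYW"),
  polarity              = c("LIFWCMVY", "PATGS",            "HQRKNED"),
  polarizability        = c("GASDT",    "CPNVEQIL",         "KMHFRYW"),
  charge                = c("KR",       "ANCQGHILMFPSTWYV", "DE"),
  surface_tension       = c("GQDNAHR",  "KTSEC",            "ILMFPWYV"),
  secondary_structure   = c("EALMQKRH", "VIYCWFT",          "GNPSD"),
  solvent_accessibility = c("ALFCGIVW", "RKQEND",           "MPSTHY")
)

#' Physicochemical grouping scheme
#'
#' Partition of the 20 standard amino acids into three groups under one
#' physicochemical property. Eight built-in schemes are available via
#' [grouping_scheme()]; see [grouping_scheme_names()].
#'
#' @param property one of the built-in property names, e.g.
#'   `"hydrophobicity"`.
#' @return an object of class `grouping_scheme`: a list with
#'   `property_name`, `groups` (three character vectors) and an internal
#'   residue-to-group lookup.
#' @examples
#' grouping_scheme("charge")
#' @export
grouping_scheme <- function(property) {
  if (!property %in% names(AA_GROUPINGS)) {
    stop_("unknown property '", property, "'; available: ",
          paste(names(AA_GROUPINGS), collapse = ", "))
  }
  groups <- lapply(AA_GROUPINGS[[property]], function(g) strsplit(g, "")[[1L]])
  all_res <- sort(unlist(groups))
  stopifnot(identical(all_res, STANDARD_AA))  # partitions are exact
  lookup <- integer(0)
  for (i in 1:3) lookup[groups[[i]]] <- i
  structure(list(property_name = property, groups = groups, lookup = lookup),
            class = "grouping_scheme")
}

#' @rdname grouping_scheme
#' @export
grouping_scheme_names <- function() names(AA_GROUPINGS)

#' @export
print.grouping_scheme <- function(x, ...) {
  cat(sprintf("<grouping_scheme> %s: %s | %s | %s\n", x$property_name,
              paste(x$groups[[1]], collapse = ""),
              paste(x$groups[[2]], collapse = ""),
              paste(x$groups[[3]], collapse = "")))
  invisible(x)
}

# split a sequence into standard residues only (nonstandard letters such as
# B, J, O, U, X, Z are dropped before any descriptor computation)
standard_residues <- function(seq) {
  if (!is_string(seq)) stop_("'seq' must be a single string")
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  ch <- ch[ch %in% STANDARD_AA]
  if (!length(ch)) stop_("sequence contains no standard amino acids")
  ch
}

#' Amino-acid composition
#'
#' Fraction of each of the 20 standard amino acids among the standard
#' residues of the sequence, in alphabetical order. Nonstandard letters are
#' excluded from both numerator and denominator.
#'
#' @param seq amino-acid sequence (string).
#' @return named numeric vector of length 20 summing to 1.
#' @examples
#' aa_composition("AAXA")  # A = 1, X ignored
#' @export
aa_composition <- function(seq) {
  ch <- standard_residues(seq)
  tab <- table(factor(ch, levels = STANDARD_AA))
  setNames(as.numeric(tab) / length(ch), STANDARD_AA)
}

#' CTD descriptors under one grouping scheme
#'
#' `ctd_composition`: fraction of residues in each of the scheme's three
#' groups. `ctd_transition`: for the unordered group pairs (1,2), (1,3),
#' (2,3), the frequency of adjacent residue pairs whose groups are the two
#' members (either orientation), divided by L' - 1 (L' = number of standard
#' residues); zeros when L' = 1. `ctd_distribution`: for each group, the
#' normalized sequence positions at which the first, 25%, 50%, 75% and 100%
#' of that group's residues have occurred (position of occurrence number
#' `ceiling(q * n_g)`, divided by L'); all five are 0 for an absent group.
#'
#' @inheritParams aa_composition
#' @param scheme a [grouping_scheme()].
#' @return numeric vector of length 3 (composition, transition) or 15
#'   (distribution, ordered g1 block then g2 then g3).
#' @examples
#' ctd_composition("KRKR", grouping_scheme("charge"))
#' @export
ctd_composition <- function(seq, scheme) {
  ch <- standard_residues(seq)
  g <- scheme$lookup[ch]
  tab <- table(factor(g, levels = 1:3))
  setNames(as.numeric(tab) / length(ch), paste0("g", 1:3))
}

#' @rdname ctd_composition
#' @export
ctd_transition <- function(seq, scheme) {
  ch <- standard_residues(seq)
  out <- setNames(numeric(3L), c("g1g2", "g1g3", "g2g3"))
  n <- length(ch)
  if (n < 2L) return(out)
  g <- scheme$lookup[ch]
  a <- g[-n]
  b <- g[-1L]
  out[["g1g2"]] <- sum((a == 1 & b == 2) | (a == 2 & b == 1)) / (n - 1L)
  out[["g1g3"]] <- sum((a == 1 & b == 3) | (a == 3 & b == 1)) / (n - 1L)
  out[["g2g3"]] <- sum((a == 2 & b == 3) | (a == 3 & b == 2)) / (n - 1L)
  out
}

#' @rdname ctd_composition
#' @export
ctd_distribution <- function(seq, scheme) {
  ch <- standard_residues(seq)
  g <- scheme$lookup[ch]
  n <- length(ch)
  qs <- c(0.25, 0.5, 0.75, 1)
  out <- numeric(0)
  for (gr in 1:3) {
    pos <- which(g == gr)
    block <- numeric(5L)
    if (length(pos)) {
      idx <- c(1L, ceiling(qs * length(pos)))
      block <- pos[idx] / n
    }
    names(block) <- paste0("g", gr, ".", c("first", "q25", "q50", "q75", "q100"))
    out <- c(out, block)
  }
  out
}

#' Extract the 188-dimensional composition + physicochemical descriptor
#'
#' Concatenates the 20D amino-acid composition with, for each of the eight
#' physicochemical grouping schemes, a 21D CTD block (3 composition + 3
#' transition + 15 distribution), giving 20 + 8 * 21 = 188 descriptors.
#'
#' @inheritParams aa_composition
#' @return named numeric vector of length 188 with `aascpp.`-prefixed names.
#' @examples
#' length(extract_aascpp_features("ACDEFGHIKLMNPQRSTVWY"))
#' @export
extract_aascpp_features <- function(seq) {
  out <- aa_composition(seq)
  names(out) <- paste0("aascpp.comp.", STANDARD_AA)
  for (prop in grouping_scheme_names()) {
    sch <- grouping_scheme(prop)
    block <- c(ctd_composition(seq, sch), ctd_transition(seq, sch),
               ctd_distribution(seq, sch))
    names(block) <- paste0("aascpp.", prop, ".",
                           c(paste0("C.", paste0("g", 1:3)),
                             paste0("T.", c("g1g2", "g1g3", "g2g3")),
                             paste0("D.", names(ctd_distribution("A", sch)))))
    out <- c(out, block)
  }
  out
}

#' @rdname extract_aascpp_features
#' @export
aascpp_feature_names <- function() names(extract_aascpp_features("A"))
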