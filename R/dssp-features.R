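# Mapping of the eight secondary-structure states to four coarse groups:
# helices (G, H, I), strands (E, B), turn/bend (T, S), irregular (L).
DSSP_GROUP_MAP <- c(G = 1L, H = 1L, I = 1L, E = 2L, B = 2L, T = 3L, S = 3L, L = 4L)

as_state_vector <- function(s) {
  if (inherits(s, "dssp_string")) s <- s$states
  if (!is_string(s) || !nzchar(s)) stop_("secondary-structure string must be nonempty")
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(ch), DSSP_STATES)
  if (length(bad)) stop_("invalid state(s): ", paste(bad, collapse = ", "))
  ch
}

# maximal runs of identical symbols; returns lengths and symbols
runs_of <- function(x) {
  r <- rle(x)
  list(values = r$values, lengths = r$lengths)
}

#' Secondary-structure state and group compositions
#'
#' `dssp_state_composition` gives the fraction of residues in each of the
#' eight states (order G, H, I, E, B, T, S, L); `dssp_group_composition`
#' gives the fraction in each of the four state groups (helix, strand,
#' turn/bend, irregular). Both sum to 1.
#'
#' @param s a [dssp_string()] or a plain string over the eight-state
#'   alphabet.
#' @return named numeric vector of length 8 (states) or 4 (groups).
#' @examples
#' dssp_state_composition("HHHHEEEETTSS")
#' dssp_group_composition("HHHHEEEETTSS")
#' @export
dssp_state_composition <- function(s) {
  ch <- as_state_vector(s)
  tab <- table(factor(ch, levels = DSSP_STATES))
  setNames(as.numeric(tab) / length(ch), DSSP_STATES)
}

#' @rdname dssp_state_composition
#' @export
dssp_group_composition <- function(s) {
  ch <- as_state_vector(s)
  g <- DSSP_GROUP_MAP[ch]
  tab <- table(factor(g, levels = 1:4))
  setNames(as.numeric(tab) / length(ch), paste0("g", 1:4))
}

#' Run statistics of a secondary-structure string
#'
#' A "run" is a maximal stretch of length >= 2 of one state (or, for the
#' group variants, of states in one group). `dssp_run_counts` /
#' `dssp_group_run_counts` return the raw number of such runs per state /
#' group; `dssp_run_compositions` / `dssp_group_run_compositions` return
#' the fraction of all residues lying inside such runs.
#'
#' @inheritParams dssp_state_composition
#' @return named numeric vector of length 8 (state variants) or 4 (group
#'   variants).
#' @examples
#' dssp_run_counts("HHEHH")        # two H-runs
#' dssp_run_compositions("HHEHH")  # 4 of 5 residues inside H-runs
#' @export
dssp_run_counts <- function(s) {
  ch <- as_state_vector(s)
  r <- runs_of(ch)
  out <- setNames(numeric(8L), DSSP_STATES)
  keep <- r$lengths >= 2L
  if (any(keep)) {
    tab <- table(factor(r$values[keep], levels = DSSP_STATES))
    out[] <- as.numeric(tab)
  }
  out
}

#' @rdname dssp_run_counts
#' @export
dssp_group_run_counts <- function(s) {
  ch <- as_state_vector(s)
  r <- runs_of(as.character(DSSP_GROUP_MAP[ch]))
  out <- setNames(numeric(4L), paste0("g", 1:4))
  keep <- r$lengths >= 2L
  if (any(keep)) {
    tab <- table(factor(r$values[keep], levels = as.character(1:4)))
    out[] <- as.numeric(tab)
  }
  out
}

#' @rdname dssp_run_counts
#' @export
dssp_run_compositions <- function(s) {
  ch <- as_state_vector(s)
  r <- runs_of(ch)
  out <- setNames(numeric(8L), DSSP_STATES)
  keep <- r$lengths >= 2L
  for (i in which(keep)) {
    out[r$values[[i]]] <- out[r$values[[i]]] + r$lengths[[i]]
  }
  out / length(ch)
}

#' @rdname dssp_run_counts
#' @export
dssp_group_run_compositions <- function(s) {
  ch <- as_state_vector(s)
  gl <- as.character(DSSP_GROUP_MAP[ch])
  r <- runs_of(gl)
  out <- setNames(numeric(4L), paste0("g", 1:4))
  keep <- r$lengths >= 2L
  for (i in which(keep)) {
    g <- as.integer(r$values[[i]])
    out[[g]] <- out[[g]] + r$lengths[[i]]
  }
  out / length(gl)
}

#' Group alternation frequency
#'
#' For each of the four state groups g: the number of adjacent residue
#' pairs whose groups differ and that have at least one member in g,
#' divided by L - 1. All zeros for a single-residue string.
#'
#' @inheritParams dssp_state_composition
#' @return named numeric vector of length 4, each entry in \[0, 1\].
#' @export
dssp_group_alternation <- function(s) {
  ch <- as_state_vector(s)
  out <- setNames(numeric(4L), paste0("g", 1:4))
  n <- length(ch)
  if (n < 2L) return(out)
  g <- unname(DSSP_GROUP_MAP[ch])
  a <- g[-n]
  b <- g[-1L]
  diff <- a != b
  for (gr in 1:4) {
    out[[gr]] <- sum(diff & (a == gr | b == gr)) / (n - 1L)
  }
  out
}

#' Extract the 40-dimensional secondary-structure descriptor
#'
#' Concatenates, in fixed order: state composition (8), group composition
#' (4), state run counts (8), group run counts (4), state run compositions
#' (8), group run compositions (4), and group alternation frequency (4).
#'
#' @inheritParams dssp_state_composition
#' @return named numeric vector of length 40 with `dssp.`-prefixed names.
#' @examples
#' length(extract_dssp_features("HHHHEEEETTSS"))
#' @export
extract_dssp_features <- function(s) {
  v <- c(dssp_state_composition(s), dssp_group_composition(s),
         dssp_run_counts(s), dssp_group_run_counts(s),
         dssp_run_compositions(s), dssp_group_run_compositions(s),
         dssp_group_alternation(s))
  names(v) <- dssp_feature_names()
  v
}

#' @rdname extract_dssp_features
#' @export
dssp_feature_names <- function() {
  c(paste0("dssp.comp.", DSSP_STATES),
    paste0("dssp.groupcomp.g", 1:4),
    paste0("dssp.runs.", DSSP_STATES),
    paste0("dssp.groupruns.g", 1:4),
    paste0("dssp.runcomp.", DSSP_STATES),
    paste0("dssp.grouprunc.g", 1:4),
    paste0("dssp.alt.g", 1:4))
}
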