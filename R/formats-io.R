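#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file. Sequences are uppercased; nonstandard residue
#'   letters (B, J, O, U, X, Z) are retained here and handled downstream by
#'   the descriptor functions.
#' @return a data.frame with columns `id`, `sequence` (and `label`, all NA,
#'   for convenience), one row per record in file order.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "ACDE", ">p2", "ghik"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_("no such file: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (!length(seqs)) stop_("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(ids))) stop_("FASTA record with empty id in ", path)
  seq_chr <- toupper(as.character(seqs))
  empty <- !nzchar(seq_chr)
  if (any(empty)) {
    stop_("FASTA record with empty sequence: ", paste(ids[empty], collapse = ", "))
  }
  data.frame(id = ids, sequence = unname(seq_chr), label = NA_character_,
             stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records data.frame with columns `id` and `sequence` (as returned
#'   by [read_fasta()]).
#' @param path output file.
#' @export
write_fasta <- function(records, path) {
  writeLines(as.vector(rbind(paste0(">", records$id), records$sequence)), path)
  invisible(path)
}

# The eight-state secondary-structure alphabet in fixed order. The DSSP
# blank state ("no structure assigned") is encoded as L.
DSSP_STATES <- c("G", "H", "I", "E", "B", "T", "S", "L")

#' Eight-state secondary-structure string
#'
#' @param states character scalar over the alphabet G,H,I,E,B,T,S,L
#'   (L = irregular / no structure assigned).
#' @param chain_id chain identifier the string came from.
#' @return an object of class `dssp_string`.
#' @export
dssp_string <- function(states, chain_id = "A") {
  if (!is_string(states) || !nzchar(states)) {
    stop_("'states' must be a nonempty string")
  }
  ch <- strsplit(states, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(ch), DSSP_STATES)
  if (length(bad)) {
    stop_("invalid secondary-structure state(s): ", paste(bad, collapse = ", "))
  }
  structure(list(chain_id = chain_id, states = states), class = "dssp_string")
}

#' @export
print.dssp_string <- function(x, ...) {
  cat(sprintf("<dssp_string> chain %s, %d residues\n%s\n",
              x$chain_id, nchar(x$states), x$states))
  invisible(x)
}

#' Parse the secondary-structure string of one chain from a DSSP file
#'
#' Residue records start after the header line beginning with
#' `"  #  RESIDUE"`. Within a residue record the chain id sits at character
#' 12 and the structure-summary letter at character 17 (1-based); a blank
#' summary field maps to `L` and chain-break rows (`!` in the amino-acid
#' column) contribute nothing.
#'
#' @param path DSSP file.
#' @param chain chain id to extract; `NULL` (default) takes the first chain
#'   in the file.
#' @return a [dssp_string()].
#' @export
parse_dssp <- function(path, chain = NULL) {
  if (!file.exists(path)) stop_("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr)) stop_("not a DSSP file (no residue header): ", path)
  body <- lines[seq.int(hdr[[1L]] + 1L, length.out = length(lines) - hdr[[1L]])]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop_("DSSP file has no residue lines: ", path)
  aa    <- substr(body, 14L, 14L)
  keep  <- aa != "!"
  chains <- substr(body, 12L, 12L)[keep]
  ss     <- substr(body, 17L, 17L)[keep]
  if (!length(ss)) stop_("DSSP file has no residue lines: ", path)
  if (is.null(chain)) chain <- chains[[1L]]
  sel <- chains == chain
  if (!any(sel)) {
    stop_("chain '", chain, "' not present in ", path,
          " (available: ", paste(unique(chains), collapse = ", "), ")")
  }
  ss <- ss[sel]
  ss[ss == " " | ss == ""] <- "L"
  dssp_string(paste(ss, collapse = ""), chain_id = chain)
}

# standard PSI-BLAST column ordering of the 20 amino acids
PSSM_COLUMN_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                       "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Position-specific scoring matrix
#'
#' @param scores L x 20 numeric matrix of log-odds scores, entry `[i, j]`
#'   scoring amino acid `j` at sequence position `i`.
#' @param row_residues length-L string of the query residues.
#' @param column_order the 20-amino-acid column ordering of the source file.
#' @return an object of class `pssm_matrix`.
#' @export
pssm_matrix <- function(scores, row_residues,
                        column_order = PSSM_COLUMN_ORDER) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (ncol(scores) != 20L) stop_("PSSM must have exactly 20 columns")
  if (nrow(scores) < 1L) stop_("PSSM must have at least one row")
  if (nchar(row_residues) != nrow(scores)) {
    stop_("'row_residues' length must equal the number of rows")
  }
  if (length(column_order) != 20L) stop_("'column_order' must have 20 entries")
  colnames(scores) <- column_order
  structure(list(scores = scores, row_residues = row_residues,
                 column_order = column_order), class = "pssm_matrix")
}

#' @export
print.pssm_matrix <- function(x, ...) {
  cat(sprintf("<pssm_matrix> L=%d x 20 (%s...)\n", nrow(x$scores),
              substr(x$row_residues, 1, 20)))
  invisible(x)
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Takes the first 20 numeric columns of each residue row (the log-odds
#' block); trailing weighted-percentage and information-content columns are
#' ignored. Header and comment lines are skipped; the column ordering is
#' read from the amino-acid header row.
#'
#' @param path ASCII PSSM file as produced by `psiblast -out_ascii_pssm`.
#' @return a [pssm_matrix()].
#' @export
parse_pssm <- function(path) {
  if (!file.exists(path)) stop_("no such file: ", path)
  lines <- readLines(path)
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1L]])
  column_order <- PSSM_COLUMN_ORDER
  for (tk in toks) {
    if (length(tk) >= 20L && all(grepl("^[A-Z]$", tk))) {
      column_order <- tk[seq_len(20L)]
      break
    }
  }
  rows <- list()
  residues <- character()
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (length(tk) < 2L || !grepl("^[0-9]+$", tk[[1L]]) ||
        !grepl("^[A-Za-z]$", tk[[2L]])) {
      next
    }
    if (length(tk) < 22L) {
      stop_("line ", i, " of ", path, ": fewer than 20 score columns")
    }
    v <- suppressWarnings(as.numeric(tk[3:22]))
    if (anyNA(v)) stop_("line ", i, " of ", path, ": malformed numeric field")
    rows[[length(rows) + 1L]] <- v
    residues <- c(residues, toupper(tk[[2L]]))
  }
  if (!length(rows)) stop_("no PSSM residue rows found in ", path)
  pssm_matrix(do.call(rbind, rows), paste(residues, collapse = ""),
              column_order = column_order)
}

#' Parse an RPS-BLAST tabular hit file
#'
#' Standard 12-column BLAST tabular output (`-outfmt 6`): the subject field
#' is column 2 (a leading `gnl|CDD|` prefix is stripped) and the E-value is
#' column 11.
#'
#' @param path hit table file; an empty file yields an empty table.
#' @return a data.frame with columns `domain_id` and `e_value`.
#' @export
parse_domain_hits <- function(path) {
  if (!file.exists(path)) stop_("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(data.frame(domain_id = character(), e_value = numeric(),
                      stringsAsFactors = FALSE))
  }
  ids <- character(length(lines))
  ev <- numeric(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 11L) stop_("line ", i, " of ", path, ": expected >= 11 tab-separated fields")
    ids[[i]] <- sub("^gnl\\|CDD\\|", "", f[[2L]])
    e <- suppressWarnings(as.numeric(f[[11L]]))
    if (is.na(e)) stop_("line ", i, " of ", path, ": non-numeric E-value '", f[[11L]], "'")
    ev[[i]] <- e
  }
  data.frame(domain_id = ids, e_value = ev, stringsAsFactors = FALSE)
}
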