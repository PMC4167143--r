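#' @title Alignment input/output and residue classification
#' @name msa_io
#' @description Read and write aligned FASTA, detect the alphabet, and
#'   classify residues into canonical states versus neutral symbols under
#'   the two gap-handling modes.
NULL

NT_STATES <- c("A", "C", "G", "T")
NT_AMBIG  <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
AA_STATES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_AMBIG  <- c("X", "B", "Z", "J")
GAP_CHARS <- c("-", "?")
GAP_STATE <- "GAP"

#' Alphabet specification
#'
#' Canonical states, ambiguity codes, and gap symbols for an alphabet.
#' The three sets are disjoint. `'?'` is treated as missing data and
#' classified with `'-'`.
#'
#' @param alphabet `"nucleotide"` or `"amino_acid"`.
#' @return A list with `canonical`, `ambiguity` and `gap` character vectors.
#' @export
alphabet_spec <- function(alphabet = c("nucleotide", "amino_acid")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "nucleotide") {
    list(alphabet = alphabet, canonical = NT_STATES, ambiguity = NT_AMBIG,
         gap = GAP_CHARS)
  } else {
    list(alphabet = alphabet, canonical = AA_STATES, ambiguity = AA_AMBIG,
         gap = GAP_CHARS)
  }
}

new_alignment <- function(taxa, residues, alphabet) {
  structure(list(taxa = taxa, residues = residues, alphabet = alphabet),
            class = "alignment")
}

#' Construct an alignment from character data
#'
#' @param seqs Named character vector of equal-length (aligned) sequences,
#'   or a character matrix with one row per taxon.
#' @param alphabet `"nucleotide"`, `"amino_acid"`, or `NULL` to
#'   auto-detect with [detect_alphabet()].
#' @return An `alignment` object: `taxa` (labels), `residues` (character
#'   matrix, rows = taxa, columns = sites), `alphabet`.
#' @export
as_alignment <- function(seqs, alphabet = NULL) {
  if (is.matrix(seqs)) {
    res <- toupper(seqs)
    taxa <- rownames(seqs)
  } else {
    taxa <- names(seqs)
    lens <- nchar(seqs)
    if (length(seqs) < 2L) abort_input("an alignment needs at least 2 sequences")
    if (length(unique(lens)) != 1L)
      abort_input("aligned sequences must have equal length (got %s)",
                  paste(unique(lens), collapse = ", "))
    if (lens[1] < 1L) abort_input("alignment has zero columns")
    res <- matrix(toupper(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)),
                  nrow = length(seqs), byrow = TRUE)
  }
  if (is.null(taxa) || any(!nzchar(taxa)))
    abort_input("all sequences must carry a non-empty label")
  if (anyDuplicated(taxa))
    abort_input("duplicate taxon labels: %s",
                paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  if (nrow(res) < 2L) abort_input("an alignment needs at least 2 sequences")
  rownames(res) <- NULL
  aln <- new_alignment(taxa, res, alphabet %||% "nucleotide")
  if (is.null(alphabet)) {
    aln$alphabet <- detect_alphabet(aln)
    if (aln$alphabet == "nucleotide") aln$residues[aln$residues == "U"] <- "T"
  } else {
    alphabet <- match.arg(alphabet, c("nucleotide", "amino_acid"))
    if (alphabet == "nucleotide") aln$residues[aln$residues == "U"] <- "T"
    aln$alphabet <- alphabet
    validate_residues(aln)
  }
  aln
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_residues <- function(aln) {
  spec <- alphabet_spec(aln$alphabet)
  ok <- c(spec$canonical, spec$ambiguity, spec$gap)
  bad <- setdiff(unique(as.vector(aln$residues)), ok)
  if (length(bad))
    abort_input("residues not valid for the %s alphabet: %s", aln$alphabet,
                paste(bad, collapse = ", "))
  invisible(aln)
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("Multiple sequence alignment: %d taxa x %d sites (%s)\n",
              length(x$taxa), ncol(x$residues), x$alphabet))
  shown <- head(seq_along(x$taxa), 6L)
  for (i in shown) {
    s <- paste(x$residues[i, seq_len(min(50L, ncol(x$residues)))], collapse = "")
    cat(sprintf("  %-15s %s%s\n", x$taxa[i], s,
                if (ncol(x$residues) > 50L) "..." else ""))
  }
  if (length(x$taxa) > 6L) cat(sprintf("  ... and %d more\n", length(x$taxa) - 6L))
  invisible(x)
}

#' Dimensions of an alignment
#' @param x An `alignment`.
#' @return `c(n_taxa, n_sites)`.
#' @export
dim.alignment <- function(x) c(length(x$taxa), ncol(x$residues))

#' Read an aligned FASTA file
#'
#' Labels are taken up to the first whitespace; residues are upper-cased;
#' record order is preserved. All records must have identical length.
#'
#' @param path Path to a FASTA file of aligned sequences.
#' @param alphabet `"nucleotide"`, `"amino_acid"`, or `NULL` (auto-detect).
#' @return An `alignment`.
#' @export
read_fasta <- function(path, alphabet = NULL) {
  if (!file.exists(path)) abort_input("file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) abort_input("cannot parse FASTA %s: %s",
                                                  path, conditionMessage(e)))
  if (length(set) == 0L) abort_input("no FASTA records in %s", path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  as_alignment(seqs, alphabet)
}

#' Write an alignment to FASTA
#'
#' @param aln An `alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  seqs <- apply(aln$residues, 1L, paste, collapse = "")
  set <- Biostrings::BStringSet(setNames(seqs, aln$taxa))
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

#' Detect the alignment alphabet
#'
#' Classified as nucleotide when at least 95% of the non-gap residues are
#' nucleotide symbols (canonical A, C, G, T/U or IUPAC ambiguity codes);
#' otherwise amino acid. `U` is mapped to `T` on the nucleotide side.
#'
#' @param aln An `alignment` (the `alphabet` field is ignored).
#' @return `"nucleotide"` or `"amino_acid"`.
#' @export
detect_alphabet <- function(aln) {
  res <- as.vector(aln$residues)
  res <- res[!res %in% GAP_CHARS]
  if (length(res) == 0L) abort_input("alignment contains only gap characters")
  nt_ok <- res %in% c(NT_STATES, "U", NT_AMBIG)
  alphabet <- if (mean(nt_ok) >= 0.95) "nucleotide" else "amino_acid"
  spec <- alphabet_spec(alphabet)
  valid <- c(spec$canonical, spec$ambiguity, if (alphabet == "nucleotide") "U")
  bad <- setdiff(unique(res), valid)
  if (length(bad))
    abort_input("residues not valid for either alphabet: %s",
                paste(bad, collapse = ", "))
  alphabet
}

#' Classify a residue as canonical state or neutral symbol
#'
#' Ambiguity codes are neutral in both gap modes. Under `"fifth_state"`
#' the gap is a canonical, matchable state (`"GAP"`); under `"ambiguous"`
#' (the `-N` behaviour) it is neutral and contributes zero to any score.
#'
#' @param residue Single residue character.
#' @param alphabet `"nucleotide"` or `"amino_acid"`.
#' @param gap_mode `"fifth_state"` (default) or `"ambiguous"`.
#' @return The canonical state character (`"A"`, ..., `"GAP"`) or
#'   `"neutral"`.
#' @export
residue_class <- function(residue, alphabet = c("nucleotide", "amino_acid"),
                          gap_mode = c("fifth_state", "ambiguous")) {
  alphabet <- match.arg(alphabet)
  gap_mode <- match.arg(gap_mode)
  spec <- alphabet_spec(alphabet)
  residue <- toupper(residue)
  if (alphabet == "nucleotide" && residue == "U") residue <- "T"
  if (residue %in% spec$canonical) return(residue)
  if (residue %in% spec$ambiguity) return("neutral")
  if (residue %in% spec$gap)
    return(if (gap_mode == "fifth_state") GAP_STATE else "neutral")
  abort_input("residue '%s' not valid for the %s alphabet", residue, alphabet)
}

# Integer class codes for the compiled engine: 1..k index the canonical
# states (k includes GAP under fifth_state), NA = neutral.
encode_classes <- function(aln, gap_mode = c("fifth_state", "ambiguous")) {
  gap_mode <- match.arg(gap_mode)
  spec <- alphabet_spec(aln$alphabet)
  states <- spec$canonical
  if (gap_mode == "fifth_state") states <- c(states, GAP_STATE)
  lookup <- setNames(seq_along(spec$canonical), spec$canonical)
  if (gap_mode == "fifth_state") {
    lookup[spec$gap] <- length(spec$canonical) + 1L
  }
  codes <- matrix(lookup[aln$residues], nrow = nrow(aln$residues))
  list(codes = codes, states = states)
}

#' Concatenate alignments into a supermatrix
#'
#' All alignments must share the same taxa (any order; rows are matched by
#' label) and alphabet. Columns are concatenated partition by partition.
#'
#' @param alignments List of `alignment` objects.
#' @return An `alignment` with `M = sum of partition lengths`.
#' @export
cat_alignments <- function(alignments) {
  if (!length(alignments)) abort_input("no alignments to concatenate")
  taxa <- alignments[[1]]$taxa
  alphabet <- alignments[[1]]$alphabet
  blocks <- lapply(alignments, function(a) {
    if (!setequal(a$taxa, taxa))
      abort_input("all partitions must contain the same taxa")
    if (a$alphabet != alphabet)
      abort_input("all partitions must share one alphabet")
    a$residues[match(taxa, a$taxa), , drop = FALSE]
  })
  new_alignment(taxa, do.call(cbind, blocks), alphabet)
}
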