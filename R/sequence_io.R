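# Reading proteins and site annotations, extracting centered fragments,
# redundancy reduction and balanced train/test splits.

FRAGMENT_LENGTH <- 41L
FRAGMENT_FLANK  <- 20L
CENTER_RESIDUES <- c("S", "T", "Y")

#' Read a protein FASTA file
#'
#' Parses a FASTA file into a named character vector of amino-acid sequences.
#' Non-standard residue letters (B, J, O, U, Z, `*`, gaps) are replaced by the
#' unknown placeholder `X`; the number of replacements is reported with a
#' message.
#'
#' @param path path to a FASTA file.
#' @return named character vector (names = record ids, first whitespace token
#'   of each header).
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  clean <- clean_sequences(seqs)
  if (attr(clean, "n_replaced") > 0L) {
    message(attr(clean, "n_replaced"), " non-standard residue(s) replaced by X")
  }
  attr(clean, "n_replaced") <- NULL
  clean
}

# Replace any letter outside the 20-AA alphabet (and X) by X.
clean_sequences <- function(seqs) {
  pat <- sprintf("[^%sX]", paste(AA_ALPHABET, collapse = ""))
  n_bad <- sum(vapply(gregexpr(pat, seqs), function(g) sum(g > 0L), integer(1)))
  out <- gsub(pat, "X", seqs)
  if (any(nchar(out) < 1L)) stop("zero-length sequence in input")
  attr(out, "n_replaced") <- n_bad
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a site annotation table
#'
#' TSV with header `protein_id  position  residue  label`; labels must be
#' `positive` / `negative`. Each annotation is validated against the protein
#' sequences: the residue at `position` must equal `residue` and be one of
#' S/T/Y.
#'
#' @param path TSV path.
#' @param proteins optional named character vector of sequences to validate
#'   against.
#' @return data.frame with columns protein_id, position, residue, label.
#' @export
read_sites <- function(path, proteins = NULL) {
  sites <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "residue", "label")
  if (!all(need %in% names(sites))) {
    stop("site table must have columns: ", paste(need, collapse = ", "))
  }
  sites$position <- as.integer(sites$position)
  if (!all(sites$residue %in% CENTER_RESIDUES)) stop("residue column must be S, T or Y")
  if (!all(sites$label %in% c("positive", "negative"))) {
    stop("label column must be 'positive' or 'negative'")
  }
  if (!is.null(proteins)) validate_sites(sites, proteins)
  sites
}

validate_sites <- function(sites, proteins) {
  missing <- setdiff(sites$protein_id, names(proteins))
  if (length(missing)) stop("site refers to unknown protein id: ", missing[1])
  at <- substr(proteins[sites$protein_id], sites$position, sites$position)
  bad <- which(at != sites$residue)
  if (length(bad)) {
    stop("annotation mismatch at ", sites$protein_id[bad[1]], ":",
         sites$position[bad[1]], " (sequence has '", at[bad[1]], "', annotation says '",
         sites$residue[bad[1]], "')")
  }
  invisible(TRUE)
}

#' Extract the 41-residue fragment centered on a candidate site
#'
#' Returns the window `[position - 20, position + 20]` of the protein, padded
#' with `X` where the window runs past either terminus, so the candidate
#' residue always sits at fragment position 21.
#'
#' @param sequence protein sequence (single string).
#' @param position 1-based residue index of the candidate site.
#' @param flank residues kept on each side (default 20, fragment length 41).
#' @return character fragment of length `2 * flank + 1`.
#' @export
#' @examples
#' extract_fragment(paste(rep("A", 50), collapse = ""), 5)  # starts with 16 X
extract_fragment <- function(sequence, position, flank = FRAGMENT_FLANK) {
  n <- nchar(sequence)
  stopifnot(position >= 1L, position <= n)
  center <- substr(sequence, position, position)
  if (!center %in% CENTER_RESIDUES) {
    stop("center residue at position ", position, " is '", center, "', not S/T/Y")
  }
  lo <- position - flank
  hi <- position + flank
  core <- substr(sequence, max(1L, lo), min(n, hi))
  pad_l <- max(0L, 1L - lo)
  pad_r <- max(0L, hi - n)
  paste0(strrep("X", pad_l), core, strrep("X", pad_r))
}

#' Extract fragments for a whole site table
#'
#' @param proteins named character vector of sequences.
#' @param sites data.frame as returned by [read_sites()].
#' @param flank residues on each side of the site.
#' @return data.frame with columns protein_id, position, residue, label,
#'   sequence (the fragment).
#' @export
extract_fragments <- function(proteins, sites, flank = FRAGMENT_FLANK) {
  validate_sites(sites, proteins)
  frag <- mapply(function(id, pos) extract_fragment(proteins[[id]], pos, flank),
                 sites$protein_id, sites$position, USE.NAMES = FALSE)
  data.frame(protein_id = sites$protein_id, position = sites$position,
             residue = sites$residue, label = sites$label,
             sequence = frag, stringsAsFactors = FALSE)
}

.blosum62_env <- new.env(parent = emptyenv())
.blosum62 <- function() {
  if (is.null(.blosum62_env$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum62_env$m <- e$BLOSUM62
  }
  .blosum62_env$m
}

#' Global-alignment percent identity between sequences
#'
#' Needleman-Wunsch global alignment with affine gaps (BLOSUM62, gap opening
#' 10, extension 0.5); identity is matches / alignment length (gaps included
#' in the denominator). Vectorized over `patterns`.
#'
#' @param patterns character vector of sequences.
#' @param subject single sequence to align against.
#' @return numeric vector of identities in `[0, 1]`.
#' @export
percent_identity <- function(patterns, subject) {
  .nw_identity_cpp(patterns, subject, .blosum62(), 10, 0.5)
}

#' Greedy redundancy reduction by pairwise identity
#'
#' Iterates sequences in input order; a sequence is retained iff its global
#' percent identity to every previously retained sequence is strictly below
#' `threshold`. Deterministic for a fixed input order.
#'
#' @param items character vector of sequences.
#' @param threshold identity threshold in `(0, 1]` (e.g. 0.3 for proteins,
#'   0.4 for fragments).
#' @return integer vector of retained indices into `items`.
#' @export
reduce_redundancy <- function(items, threshold) {
  stopifnot(length(items) > 0L)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]")
  }
  keep <- integer(0)
  for (i in seq_along(items)) {
    if (length(keep) == 0L) { keep <- i; next }
    # exact duplicates short-circuit the alignment
    if (any(items[keep] == items[i])) next
    pid <- percent_identity(items[keep], items[i])
    if (all(pid < threshold)) keep <- c(keep, i)
  }
  keep
}

#' Balance a dataset by down-sampling negatives
#'
#' Keeps all positive fragments and samples `n_positive` negatives uniformly
#' without replacement.
#'
#' @param positives,negatives fragment data.frames (see [extract_fragments()]).
#' @param seed integer seed for the negative sampling.
#' @return combined fragment data.frame (positives first).
#' @export
build_balanced_dataset <- function(positives, negatives, seed) {
  np <- nrow(positives); nn <- nrow(negatives)
  if (nn < np) stop("fewer negatives (", nn, ") than positives (", np, ")")
  idx <- withr::with_seed(seed, sample.int(nn, np))
  out <- rbind(positives, negatives[idx, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Stratified train/test split
#'
#' Splits fragments into train and test parts, stratified by label, with
#' `fraction` of each class (rounded) in the training part.
#'
#' @param dataset fragment data.frame with a `label` column.
#' @param fraction training fraction (default 0.8).
#' @param seed integer seed.
#' @return list with elements `train`, `test` (data.frames) and `seed`.
#' @export
split_train_test <- function(dataset, fraction = 0.8, seed) {
  labs <- unique(dataset$label)
  if (!all(c("positive", "negative") %in% labs)) stop("both classes must be present")
  counts <- table(dataset$label)
  if (any(counts < 5L)) stop("need at least 5 fragments per class")
  train_idx <- withr::with_seed(seed, {
    unlist(lapply(labs, function(l) {
      idx <- which(dataset$label == l)
      sample(idx, round(fraction * length(idx)))
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  list(train = dataset[train_idx, , drop = FALSE],
       test  = dataset[-train_idx, , drop = FALSE],
       seed  = seed)
}

#' Write fragments as FASTA
#'
#' Record ids follow `proteinid_pos_label`.
#'
#' @param fragments fragment data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragments_fasta <- function(fragments, path) {
  seqs <- fragments$sequence
  names(seqs) <- paste(fragments$protein_id, fragments$position, fragments$label,
                       sep = "_")
  write_fasta(seqs, path)
}
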