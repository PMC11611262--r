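# Physicochemical descriptor blocks: AAC, EAAC, CTDC, PAAC, QSOrder, BINARY.
# All composition-type encoders count over non-X residues only (numerator AND
# denominator), so vectors stay on the probability simplex for real residues;
# an all-X stretch yields zeros.

#' Feature block container
#'
#' A named, ordered list of feature identifiers plus a sample x feature value
#' matrix — the unit passed between encoders, selectors and the classifier.
#'
#' @param block_name block label (e.g. "AAC", "EMBED", "COMBINED").
#' @param feature_names character vector, one per column.
#' @param values numeric matrix, samples in rows.
#' @return object of class `feature_block`.
#' @export
feature_block <- function(block_name, feature_names, values) {
  values <- as.matrix(values)
  if (length(feature_names) != ncol(values)) {
    stop("feature_names length (", length(feature_names),
         ") != number of columns (", ncol(values), ")")
  }
  if (anyDuplicated(feature_names)) {
    stop("duplicate feature name: ", feature_names[duplicated(feature_names)][1])
  }
  colnames(values) <- feature_names
  structure(list(block_name = block_name, feature_names = feature_names,
                 values = values),
            class = "feature_block")
}

#' @export
print.feature_block <- function(x, ...) {
  cat("<feature_block ", x$block_name, ": ", nrow(x$values), " samples x ",
      ncol(x$values), " features>\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_block <- function(x) dim(x$values)

# fragments (character vector) -> n x 41 matrix of single characters
.frag_chars <- function(fragments) {
  len <- unique(nchar(fragments))
  if (length(len) != 1L) stop("fragments must all have the same length")
  matrix(unlist(strsplit(fragments, "")), nrow = length(fragments), byrow = TRUE)
}

# residue counts over the alphabet for each row of a character matrix
.count_aa <- function(chars) {
  t(apply(chars, 1L, function(r) tabulate(match(r, AA_ALPHABET), nbins = 20L)))
}

#' Encoder configuration
#'
#' Bundles the tunable constants of the physicochemical encoders.
#'
#' @param eaac_window sliding-window width for EAAC (default 5).
#' @param paac_lambda number of PAAC sequence-order correlation factors.
#' @param paac_weight PAAC weighting factor.
#' @param qsorder_nlag maximum lag of the quasi-sequence-order terms.
#' @param qsorder_weight QSOrder weighting factor.
#' @param use_binary include the positional one-hot block (recommended for
#'   larger datasets).
#' @return list of class `encoder_config`.
#' @export
encoder_config <- function(eaac_window = 5L, paac_lambda = 2L, paac_weight = 0.05,
                           qsorder_nlag = 2L, qsorder_weight = 0.1,
                           use_binary = TRUE) {
  stopifnot(eaac_window <= FRAGMENT_LENGTH, paac_lambda < FRAGMENT_LENGTH,
            qsorder_nlag < FRAGMENT_LENGTH)
  structure(list(eaac_window = as.integer(eaac_window),
                 paac_lambda = as.integer(paac_lambda),
                 paac_weight = paac_weight,
                 qsorder_nlag = as.integer(qsorder_nlag),
                 qsorder_weight = qsorder_weight,
                 use_binary = isTRUE(use_binary)),
            class = "encoder_config")
}

#' Amino-acid composition (AAC)
#'
#' Frequency of each of the 20 amino acids over the non-X positions of each
#' fragment, in alphabet order; rows sum to 1.
#'
#' @param fragments character vector of equal-length fragments.
#' @return `feature_block` with 20 features `AAC.<residue>`.
#' @export
encode_aac <- function(fragments) {
  counts <- .count_aa(.frag_chars(fragments))
  tot <- rowSums(counts)
  if (any(tot == 0)) stop("fragment with no standard residues (all X)")
  feature_block("AAC", paste0("AAC.", AA_ALPHABET), counts / tot)
}

#' Enhanced amino-acid composition (EAAC)
#'
#' AAC computed inside each sliding window along the fragment. Window `i`
#' covers fragment positions `i .. i+window-1`; features are named
#' `SW.<i>.<residue>` (e.g. `SW.17.S` is the serine composition of positions
#' 17-21 for the default window of 5). An all-X window yields zeros.
#'
#' @param fragments character vector of fragments.
#' @param window sliding-window width.
#' @return `feature_block` with `(L - window + 1) * 20` features.
#' @export
encode_eaac <- function(fragments, window = 5L) {
  chars <- .frag_chars(fragments)
  L <- ncol(chars)
  stopifnot(window >= 1L, window <= L)
  nwin <- L - window + 1L
  out <- matrix(0, nrow(chars), nwin * 20L)
  for (i in seq_len(nwin)) {
    counts <- .count_aa(chars[, i:(i + window - 1L), drop = FALSE])
    tot <- rowSums(counts)
    frac <- counts / ifelse(tot == 0, 1, tot)
    out[, ((i - 1L) * 20L + 1L):(i * 20L)] <- frac
  }
  nms <- as.vector(t(outer(seq_len(nwin), AA_ALPHABET,
                           function(i, a) paste0("SW.", i, ".", a))))
  feature_block("EAAC", nms, out)
}

#' Composition term of C/T/D (CTDC)
#'
#' For each of 13 physicochemical properties, each partitioning the 20 amino
#' acids into three groups, the fraction of non-X residues falling in each
#' group. Features named `<property>.G1` / `.G2` / `.G3`; groups of one
#' property sum to 1 on X-free fragments.
#'
#' @param fragments character vector of fragments.
#' @return `feature_block` with 39 features.
#' @export
encode_ctdc <- function(fragments) {
  chars <- .frag_chars(fragments)
  nonx <- rowSums(matrix(chars %in% AA_ALPHABET, nrow(chars)))
  if (any(nonx == 0)) stop("fragment with no standard residues (all X)")
  out <- matrix(0, nrow(chars), 13L * 3L)
  nms <- character(13L * 3L)
  j <- 0L
  for (prop in names(CTDC_GROUPS)) {
    for (g in 1:3) {
      j <- j + 1L
      grp <- strsplit(CTDC_GROUPS[[prop]][g], "")[[1]]
      out[, j] <- rowSums(matrix(chars %in% grp, nrow(chars))) / nonx
      nms[j] <- paste0(prop, ".G", g)
    }
  }
  feature_block("CTDC", nms, out)
}

#' Pseudo-amino-acid composition (PAAC)
#'
#' Chou's PAAC: 20 composition components plus `lambda` sequence-order
#' correlation factors. The correlation at lag `j` is the mean, over residue
#' pairs `(i, i+j)` with both residues standard, of the mean squared
#' difference of normalized hydrophobicity, hydrophilicity and side-chain
#' mass. All components are divided by `1 + weight * sum(theta)`, so the full
#' vector sums to 1.
#'
#' @param fragments character vector of fragments.
#' @param lambda number of correlation factors (must be < number of non-X
#'   residues in every fragment).
#' @param weight weighting factor for the correlation tail.
#' @return `feature_block` with `20 + lambda` features.
#' @export
encode_paac <- function(fragments, lambda = 2L, weight = 0.05) {
  chars <- .frag_chars(fragments)
  h1 <- .paac_normalize(PAAC_HYDROPHOBICITY)
  h2 <- .paac_normalize(PAAC_HYDROPHILICITY)
  ms <- .paac_normalize(PAAC_SIDECHAIN_MASS)
  n <- nrow(chars)
  out <- matrix(0, n, 20L + lambda)
  for (s in seq_len(n)) {
    ranks <- match(chars[s, ], AA_ALPHABET)   # NA for X
    valid <- which(!is.na(ranks))
    if (length(valid) <= lambda) {
      stop("lambda (", lambda, ") must be < number of standard residues (",
           length(valid), ") in fragment ", s)
    }
    freq <- tabulate(ranks[!is.na(ranks)], nbins = 20L) / length(valid)
    theta <- vapply(seq_len(lambda), function(j) {
      i <- seq_len(length(ranks) - j)
      a <- ranks[i]; b <- ranks[i + j]
      ok <- !is.na(a) & !is.na(b)
      if (!any(ok)) return(0)
      mean(((h1[a[ok]] - h1[b[ok]])^2 +
            (h2[a[ok]] - h2[b[ok]])^2 +
            (ms[a[ok]] - ms[b[ok]])^2) / 3)
    }, numeric(1))
    denom <- 1 + weight * sum(theta)
    out[s, ] <- c(freq, weight * theta) / denom
  }
  feature_block("PAAC", c(paste0("PAAC.", AA_ALPHABET),
                          paste0("PAAC.lam", seq_len(lambda))), out)
}

#' Quasi-sequence-order descriptor (QSOrder)
#'
#' Sequence-order coupling built on two residue-pair distance matrices: the
#' Grantham chemical distance ([grantham_matrix()]) and the
#' hydrophobicity/hydrophilicity/mass distance ([hphys_matrix()]). For each
#' matrix, `tau_d = sum_i d(r_i, r_(i+d))^2` for `d = 1..nlag` (pairs with an
#' X are skipped), and the 20 composition terms are
#' `count_r / (total + weight * sum(tau))`.
#'
#' @param fragments character vector of fragments.
#' @param nlag maximum lag.
#' @param weight weighting factor.
#' @return `feature_block` with `40 + 2 * nlag` features: `QSO.HPhys.<AA>`,
#'   `QSO.Grantham.<AA>`, `QSO.HPhys.d<j>`, `QSO.Grantham.d<j>`.
#' @export
encode_qsorder <- function(fragments, nlag = 2L, weight = 0.1) {
  chars <- .frag_chars(fragments)
  mats <- list(HPhys = hphys_matrix(), Grantham = grantham_matrix())
  n <- nrow(chars)
  out <- matrix(0, n, 40L + 2L * nlag)
  for (s in seq_len(n)) {
    ranks <- match(chars[s, ], AA_ALPHABET)
    valid <- sum(!is.na(ranks))
    if (valid <= nlag) {
      stop("nlag (", nlag, ") must be < number of standard residues (",
           valid, ") in fragment ", s)
    }
    counts <- tabulate(ranks[!is.na(ranks)], nbins = 20L)
    taus <- lapply(mats, function(m) {
      vapply(seq_len(nlag), function(d) {
        i <- seq_len(length(ranks) - d)
        a <- ranks[i]; b <- ranks[i + d]
        ok <- !is.na(a) & !is.na(b)
        if (!any(ok)) return(0)
        sum(m[cbind(a[ok], b[ok])]^2)
      }, numeric(1))
    })
    comp <- lapply(taus, function(tau) counts / (sum(counts) + weight * sum(tau)))
    tail <- lapply(taus, function(tau) weight * tau / (sum(counts) + weight * sum(tau)))
    out[s, ] <- c(comp$HPhys, comp$Grantham, tail$HPhys, tail$Grantham)
  }
  nms <- c(paste0("QSO.HPhys.", AA_ALPHABET), paste0("QSO.Grantham.", AA_ALPHABET),
           paste0("QSO.HPhys.d", seq_len(nlag)), paste0("QSO.Grantham.d", seq_len(nlag)))
  feature_block("QSOrder", nms, out)
}

#' Positional one-hot encoding (BINARY)
#'
#' One 20-slot indicator per fragment position, alphabet order
#' `ARNDCQEGHILKMFPSTWYV`; feature `BINARY.F<n>` with
#' `n = (position - 1) * 20 + rank(residue)` (so arginine at position 18 is
#' F342 and proline at position 22 is F435). X positions emit all zeros.
#'
#' @param fragments character vector of fragments.
#' @return `feature_block` with `41 * 20 = 820` features.
#' @export
encode_binary <- function(fragments) {
  chars <- .frag_chars(fragments)
  L <- ncol(chars)
  n <- nrow(chars)
  out <- matrix(0, n, L * 20L)
  ranks <- matrix(match(chars, AA_ALPHABET), n, L)
  for (p in seq_len(L)) {
    hit <- which(!is.na(ranks[, p]))
    out[cbind(hit, (p - 1L) * 20L + ranks[hit, p])] <- 1
  }
  feature_block("BINARY", paste0("BINARY.F", seq_len(L * 20L)), out)
}

#' Map a (position, residue) pair to its BINARY feature index
#'
#' @param position 1-based fragment position.
#' @param residue single amino-acid letter.
#' @return integer feature index `n = (position - 1) * 20 + rank(residue)`.
#' @export
#' @examples
#' binary_feature_index(18, "R")  # 342
#' binary_feature_index(22, "P")  # 435
binary_feature_index <- function(position, residue) {
  r <- aa_rank(residue)
  stopifnot(!is.na(r), position >= 1L)
  as.integer((position - 1L) * 20L + r)
}

#' Decode a BINARY feature index into (position, residue)
#'
#' @param n feature index (as in `BINARY.F<n>`).
#' @return list with elements `position` and `residue`.
#' @export
binary_feature_info <- function(n) {
  stopifnot(n >= 1L)
  p <- (as.integer(n) - 1L) %/% 20L + 1L
  r <- (as.integer(n) - 1L) %% 20L + 1L
  list(position = p, residue = AA_ALPHABET[r])
}

#' Concatenate feature blocks column-wise
#'
#' Blocks must have identical sample counts; feature names must be unique
#' across blocks. Block order is preserved.
#'
#' @param blocks list of `feature_block` objects.
#' @param name name of the combined block.
#' @return a single `feature_block`.
#' @export
combine_blocks <- function(blocks, name = "COMBINED") {
  stopifnot(length(blocks) >= 1L)
  ns <- vapply(blocks, function(b) nrow(b$values), integer(1))
  if (length(unique(ns)) != 1L) {
    stop("sample-count mismatch across blocks: ", paste(ns, collapse = ", "))
  }
  vals <- do.call(cbind, lapply(blocks, function(b) b$values))
  nms <- unlist(lapply(blocks, function(b) b$feature_names), use.names = FALSE)
  feature_block(name, nms, vals)
}

#' Encode all physicochemical blocks of a fragment set
#'
#' Runs AAC, CTDC, EAAC, PAAC, QSOrder and (optionally) BINARY with the given
#' configuration and returns the blocks as a named list, in the canonical
#' combination order.
#'
#' @param fragments character vector of fragments.
#' @param config an [encoder_config()].
#' @return named list of `feature_block`s.
#' @export
encode_physchem <- function(fragments, config = encoder_config()) {
  blocks <- list(
    AAC     = encode_aac(fragments),
    CTDC    = encode_ctdc(fragments),
    EAAC    = encode_eaac(fragments, config$eaac_window),
    PAAC    = encode_paac(fragments, config$paac_lambda, config$paac_weight),
    QSOrder = encode_qsorder(fragments, config$qsorder_nlag, config$qsorder_weight)
  )
  if (config$use_binary) blocks$BINARY <- encode_binary(fragments)
  blocks
}

#' Write a feature block as TSV (+ JSON manifest)
#'
#' Writes the sample x feature matrix with a header of feature names and a
#' trailing `label` column; a sidecar `<path>.json` records the encoder
#' configuration when given.
#'
#' @param block a `feature_block`.
#' @param labels character/numeric label vector, one per row.
#' @param path output TSV path.
#' @param config optional configuration list stored in the manifest.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(block, labels, path, config = NULL) {
  df <- as.data.frame(block$values)
  df$label <- labels
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(config)) {
    jsonlite::write_json(config, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
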