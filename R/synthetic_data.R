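# Synthetic fixtures: proteins with planted positional phospho-motifs and
# abstract feature matrices with planted informative columns. These make
# every pipeline stage testable without any external database.

#' Motif specification
#'
#' One positional enrichment rule applied to positive fragments: at fragment
#' `position` (1-based, 1..41), `residue` appears with probability
#' `enrichment` (background is uniform 1/20).
#'
#' @param position fragment position in 1..41.
#' @param residue single amino-acid letter.
#' @param enrichment probability in `[0, 1]`.
#' @return list of class `motif_spec`.
#' @export
motif_spec <- function(position, residue, enrichment) {
  stopifnot(position >= 1L, position <= FRAGMENT_LENGTH,
            residue %in% AA_ALPHABET, enrichment >= 0, enrichment <= 1)
  structure(list(position = as.integer(position), residue = residue,
                 enrichment = enrichment), class = "motif_spec")
}

#' The default planted motif set
#'
#' Mirrors the positional biases around fungal serine phosphosites: arginine
#' enrichment just left of the site (fragment position 18), proline just
#' right of it (position 22) and a serine-rich stretch at positions 17-20
#' (position 21 is the site itself).
#'
#' @return list of [motif_spec()]s.
#' @export
paperlike_motifs <- function() {
  list(motif_spec(18, "R", 0.40),
       motif_spec(22, "P", 0.40),
       motif_spec(17, "S", 0.30),
       motif_spec(19, "S", 0.30),
       motif_spec(20, "S", 0.30))
}

.sample_residues <- function(n, background = NULL) {
  if (is.null(background)) background <- rep(1 / 20, 20)
  AA_ALPHABET[sample.int(20L, n, replace = TRUE, prob = background)]
}

#' Generate synthetic proteins with planted phosphosites
#'
#' Proteins are i.i.d. background residues. `n_sites["positive"]` sites get
#' the motif residues planted (with their stated enrichments) in the
#' 41-window frame around them; negative sites draw background everywhere.
#' Every site's center residue is set to `residue` so annotations validate.
#'
#' @param n number of proteins.
#' @param length_range integer range of protein lengths.
#' @param motifs list of [motif_spec()]s applied to positives.
#' @param n_sites named integer vector `c(positive = ..., negative = ...)`.
#' @param seed integer seed.
#' @param residue center residue of the planted sites ("S", "T" or "Y").
#' @param background optional length-20 residue probability vector
#'   (default uniform).
#' @return list with `proteins` (named character vector) and `sites`
#'   (annotation data.frame: protein_id, position, residue, label).
#' @export
generate_proteins <- function(n, length_range = c(120L, 240L),
                              motifs = paperlike_motifs(),
                              n_sites = c(positive = 400L, negative = 4000L),
                              seed = 1L, residue = "S", background = NULL) {
  stopifnot(n >= 1L, residue %in% CENTER_RESIDUES)
  pos_by_site <- vapply(motifs, `[[`, integer(1), "position")
  if (anyDuplicated(pos_by_site)) stop("motif positions must be unique")
  if (any(pos_by_site == 21L)) stop("position 21 is the site itself")
  withr::with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
    prot <- vapply(lens, function(L) {
      paste(.sample_residues(L, background), collapse = "")
    }, character(1))
    names(prot) <- sprintf("synth%04d", seq_len(n))

    total <- sum(n_sites)
    # candidate slots: (protein, position) pairs far enough from both termini
    # that planted motifs land inside the protein, spaced >= 43 apart so the
    # windows of two sites never overlap
    slots <- do.call(rbind, lapply(seq_len(n), function(i) {
      p <- seq(22L, lens[i] - 21L, by = 43L)
      if (length(p) == 0L) return(NULL)
      data.frame(prot = i, pos = p)
    }))
    if (is.null(slots) || nrow(slots) < total) {
      stop("not enough site slots: increase n or protein length")
    }
    slots <- slots[sample.int(nrow(slots), total), ]
    label <- rep(c("positive", "negative"), times = n_sites[c("positive", "negative")])

    chars <- strsplit(prot, "")
    for (s in seq_len(total)) {
      i <- slots$prot[s]; p <- slots$pos[s]
      chars[[i]][p] <- residue
      if (label[s] == "positive") {
        for (m in motifs) {
          at <- p - 21L + m$position
          if (at >= 1L && at <= lens[i] && stats::runif(1) < m$enrichment) {
            chars[[i]][at] <- m$residue
          }
        }
      }
    }
    proteins <- vapply(chars, paste, character(1), collapse = "")
    names(proteins) <- names(prot)
    sites <- data.frame(protein_id = names(prot)[slots$prot],
                        position = slots$pos, residue = residue,
                        label = label, stringsAsFactors = FALSE)
    list(proteins = proteins, sites = sites)
  })
}

#' Planted-feature matrix specification
#'
#' @param n_samples total samples (balanced classes).
#' @param n_features total feature columns.
#' @param n_informative columns carrying a class signal.
#' @param effect_size standardized mean shift of informative columns.
#' @param seed integer seed.
#' @return list of class `planted_matrix_spec`.
#' @export
planted_matrix_spec <- function(n_samples = 400L, n_features = 499L,
                                n_informative = 20L, effect_size = 1.0,
                                seed = 1L) {
  stopifnot(n_informative <= n_features, n_samples >= 2L)
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, seed = as.integer(seed)),
            class = "planted_matrix_spec")
}

#' Generate a feature matrix with planted informative columns
#'
#' Noise columns are standard normal in both classes; informative columns
#' are shifted by `effect_size` in the positive class. Informative column
#' positions are drawn uniformly.
#'
#' @param spec a [planted_matrix_spec()].
#' @return list with `X` (matrix), `y` (0/1 vector, balanced) and
#'   `informative` (column indices).
#' @export
generate_feature_matrix <- function(spec = planted_matrix_spec()) {
  withr::with_seed(spec$seed, {
    n <- spec$n_samples
    y <- rep(c(0L, 1L), length.out = n)
    X <- matrix(stats::rnorm(n * spec$n_features), n, spec$n_features)
    informative <- sort(sample.int(spec$n_features, spec$n_informative))
    X[y == 1L, informative] <- X[y == 1L, informative] + spec$effect_size
    colnames(X) <- paste0("V", seq_len(spec$n_features))
    list(X = X, y = y, informative = informative)
  })
}
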