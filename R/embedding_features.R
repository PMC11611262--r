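# Distributed k-mer representations: overlapping tokenization, subword-aware
# skip-gram embedding, per-fragment concatenation and the K/W grid search.

#' Embedding configuration
#'
#' @param k k-mer length (2..10 in the grid search; must be < fragment length).
#' @param w skip-gram context window size.
#' @param dim per-word vector size (20).
#' @param epochs training epochs over the corpus.
#' @param negative negatives sampled per positive pair.
#' @param minn,maxn character n-gram (subword) range.
#' @param buckets hash buckets shared by the subword n-grams.
#' @param lr,lr_min linear learning-rate schedule endpoints.
#' @param seed integer seed for the deterministic trainer.
#' @return list of class `embedding_config`.
#' @export
embedding_config <- function(k = 7L, w = 1L, dim = 20L, epochs = 100L,
                             negative = 5L, minn = 3L, maxn = 6L,
                             buckets = 65536L, lr = 0.05, lr_min = 1e-4,
                             seed = 1L) {
  stopifnot(k >= 2L, k < FRAGMENT_LENGTH, w >= 1L, dim >= 1L, buckets >= 1L)
  structure(list(k = as.integer(k), w = as.integer(w), dim = as.integer(dim),
                 epochs = as.integer(epochs), negative = as.integer(negative),
                 minn = as.integer(minn), maxn = as.integer(maxn),
                 buckets = as.integer(buckets),
                 lr = lr, lr_min = lr_min, seed = as.integer(seed)),
            class = "embedding_config")
}

#' Tokenize a fragment into overlapping k-mers
#'
#' Sliding window of length `k`, stride 1: `N - k + 1` tokens in sequence
#' order. Tokens containing X are legal (subword composition covers them).
#'
#' @param fragment a single sequence string.
#' @param k k-mer length.
#' @return character vector of tokens.
#' @export
#' @examples
#' tokenize("ABCDE", 2)  # "AB" "BC" "CD" "DE"
tokenize <- function(fragment, k) {
  n <- nchar(fragment)
  if (k > n) stop("k (", k, ") exceeds sequence length (", n, ")")
  if (k < 1L) stop("k must be >= 1")
  starts <- seq_len(n - k + 1L)
  substring(fragment, starts, starts + k - 1L)
}

#' Build a k-mer corpus from fragments
#'
#' @param fragments character vector of fragments.
#' @param k k-mer length.
#' @return list of token vectors (one bio-sentence per fragment).
#' @export
kmer_corpus <- function(fragments, k) {
  lapply(fragments, tokenize, k = k)
}

# 0-based hash-bucket ids of a word's character n-grams (boundary-marked,
# fastText-style shared bucket table)
.word_buckets <- function(words, config) {
  .ngram_buckets_cpp(words, config$minn, config$maxn, config$buckets)
}

#' Train a subword skip-gram embedding on a k-mer corpus
#'
#' Skip-gram with negative sampling in which each word (k-mer) is represented
#' as the mean of its own vector and its character n-gram vectors, so unseen
#' k-mers still receive a vector through their n-grams. Training is
#' single-threaded with an internal seeded RNG and is therefore deterministic
#' for a fixed seed.
#'
#' @param corpus list of token vectors (see [kmer_corpus()]).
#' @param config an [embedding_config()]; `config$k` must match the corpus.
#' @return object of class `kmer_embedding` with the word-vector table and
#'   enough state to compose vectors for unseen k-mers.
#' @export
train_embedding <- function(corpus, config = embedding_config()) {
  if (length(corpus) == 0L || sum(lengths(corpus)) == 0L) stop("empty corpus")
  klen <- unique(nchar(unlist(corpus, use.names = FALSE)))
  if (length(klen) != 1L || klen != config$k) {
    stop("corpus token length (", paste(klen, collapse = ","),
         ") does not match config k = ", config$k)
  }
  tokens <- unlist(corpus, use.names = FALSE)
  vocab <- unique(tokens)                      # first-appearance order: deterministic
  counts <- as.integer(table(factor(tokens, levels = vocab)))
  wid <- match(tokens, vocab)
  sentences <- split(wid - 1L, rep(seq_along(corpus), lengths(corpus)))

  nv <- length(vocab)
  buckets_per_word <- .word_buckets(vocab, config)
  subwords <- lapply(seq_len(nv), function(i) c(i - 1L, nv + buckets_per_word[[i]]))
  n_rows <- nv + config$buckets

  input <- .skipgram_train_cpp(sentences, subwords, n_rows, nv, counts,
                               config$dim, config$w, config$epochs,
                               config$negative, config$lr, config$lr_min,
                               config$seed)
  vectors <- t(vapply(seq_len(nv), function(i) {
    colMeans(input[subwords[[i]] + 1L, , drop = FALSE])
  }, numeric(config$dim)))
  rownames(vectors) <- vocab
  structure(list(vectors = vectors, vocab = vocab,
                 input = input, n_words = nv, config = config),
            class = "kmer_embedding")
}

#' @export
print.kmer_embedding <- function(x, ...) {
  cat("<kmer_embedding: ", x$n_words, " k-mers (k=", x$config$k, "), ",
      x$config$buckets, " subword buckets, dim ", x$config$dim, ">\n", sep = "")
  invisible(x)
}

#' Vector of a single k-mer under a trained embedding
#'
#' Known k-mers return their trained vector; unseen k-mers are composed from
#' the mean of their known character n-gram vectors (zero vector if none).
#'
#' @param model a `kmer_embedding`.
#' @param token a k-mer string of length `model$config$k`.
#' @return numeric vector of length `model$config$dim`.
#' @export
embedding_vector <- function(model, token) {
  i <- match(token, model$vocab)
  if (!is.na(i)) return(model$vectors[i, ])
  rows <- model$n_words + .word_buckets(token, model$config)[[1]] + 1L
  if (length(rows) == 0L) return(numeric(model$config$dim))
  colMeans(model$input[rows, , drop = FALSE])
}

#' Encode fragments by concatenated k-mer embeddings
#'
#' Each fragment's `N - k + 1` token vectors are concatenated in sequence
#' order into a `(N - k + 1) * dim` vector; features are named `EmbedFea<n>`
#' with `n = (token_index - 1) * dim + component` (so for k = 7 components
#' 281-300 belong to the 15th k-mer, covering fragment positions 15-21).
#'
#' @param fragments character vector of fragments.
#' @param model a trained `kmer_embedding`.
#' @return `feature_block` named `EMBED`.
#' @export
encode_fragment_embedding <- function(fragments, model) {
  k <- model$config$k
  dim <- model$config$dim
  L <- unique(nchar(fragments))
  if (length(L) != 1L) stop("fragments must all have the same length")
  ntok <- L - k + 1L
  # all tokens, fragment-major order
  toks <- unlist(lapply(fragments, tokenize, k = k), use.names = FALSE)
  uniq <- unique(toks)
  tv <- t(vapply(uniq, embedding_vector, numeric(dim), model = model))
  T <- tv[match(toks, uniq), , drop = FALSE]       # (nfrag * ntok) x dim
  vals <- matrix(as.vector(t(T)), nrow = length(fragments), byrow = TRUE)
  feature_block("EMBED", paste0("EmbedFea", seq_len(ntok * dim)), vals)
}

#' Map (token index, component) to an embedding feature index
#'
#' @param token_index 1-based k-mer position along the fragment.
#' @param component 1-based vector component (1..dim).
#' @param dim per-word vector size.
#' @return integer `n` as in `EmbedFea<n>`.
#' @export
embed_feature_index <- function(token_index, component, dim = 20L) {
  stopifnot(token_index >= 1L, component >= 1L, component <= dim)
  as.integer((token_index - 1L) * dim + component)
}

#' Decode an embedding feature index
#'
#' @param n feature index (as in `EmbedFea<n>`).
#' @param k k-mer length (gives the fragment positions the token covers).
#' @param dim per-word vector size.
#' @return list with `token_index`, `component`, and the covered fragment
#'   positions `span` (first, last).
#' @export
#' @examples
#' embed_feature_info(282, k = 7)  # token 15, spanning positions 15..21
embed_feature_info <- function(n, k = 7L, dim = 20L) {
  stopifnot(n >= 1L)
  dim <- as.integer(dim)
  tok <- (as.integer(n) - 1L) %/% dim + 1L
  comp <- (as.integer(n) - 1L) %% dim + 1L
  list(token_index = tok, component = comp,
       span = c(tok, tok + as.integer(k) - 1L))
}

#' Export a trained embedding as TSV
#'
#' One row per known k-mer: `token<TAB>v1..v<dim>`.
#'
#' @param model a `kmer_embedding`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_embedding_tsv <- function(model, path) {
  df <- data.frame(token = model$vocab, model$vectors, check.names = FALSE)
  colnames(df) <- c("token", paste0("v", seq_len(model$config$dim)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Grid search over k-mer length and context window
#'
#' Trains an embedding and evaluates a downstream classifier for every (k, w)
#' cell; returns the accuracy grid and the best cell, with ties broken toward
#' smaller k, then smaller w (simpler models preferred when accuracies tie).
#' A failing cell is marked `NA` and the search continues with a warning.
#'
#' @param fragments training fragments.
#' @param labels 0/1 labels (1 = phosphorylated).
#' @param k_range,w_range integer vectors of candidate values.
#' @param evaluator `function(X, y, seed) -> accuracy`; default: stratified
#'   5-fold CV accuracy of the RBF-SVM ([svm_cv_metrics()]).
#' @param config base [embedding_config()] (k and w are overridden per cell).
#' @param seed integer seed for embedding training and CV folds.
#' @return list with `best_k`, `best_w`, `grid` (data.frame k, w, acc).
#' @export
grid_search_kw <- function(fragments, labels, k_range = 2:10, w_range = 1:10,
                           evaluator = NULL, config = embedding_config(),
                           seed = 1L) {
  stopifnot(length(unique(labels)) == 2L)
  if (is.null(evaluator)) {
    evaluator <- function(X, y, seed) {
      svm_cv_metrics(X, y, folds = make_cv_folds(y, 5L, seed))["acc"]
    }
  }
  grid <- expand.grid(k = as.integer(k_range), w = as.integer(w_range))
  grid$acc <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    cfg$k <- grid$k[i]; cfg$w <- grid$w[i]; cfg$seed <- as.integer(seed)
    acc <- tryCatch({
      model <- train_embedding(kmer_corpus(fragments, cfg$k), cfg)
      emb <- encode_fragment_embedding(fragments, model)
      as.numeric(evaluator(emb$values, labels, seed))
    }, error = function(e) {
      warning("grid cell k=", cfg$k, " w=", cfg$w, " failed: ",
              conditionMessage(e))
      NA_real_
    })
    grid$acc[i] <- acc
  }
  if (all(is.na(grid$acc))) stop("every grid cell failed")
  # highest accuracy; ties -> smaller k, then smaller w
  ord <- order(-grid$acc, grid$k, grid$w, na.last = TRUE)
  best <- grid[ord[1], ]
  list(best_k = best$k, best_w = best$w, grid = grid)
}
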