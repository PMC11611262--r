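# Shared fixtures and independent brute-force oracles, all built in code.

AAS <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

random_fragment <- function(n = 1L, len = 41L, seed = NULL, alphabet = AAS) {
  gen <- function() paste(sample(alphabet, len, replace = TRUE), collapse = "")
  if (!is.null(seed)) {
    withr::with_seed(seed, vapply(seq_len(n), function(i) gen(), character(1)))
  } else {
    vapply(seq_len(n), function(i) gen(), character(1))
  }
}

# scaled-down paperlike dataset: proteins with the default planted motifs
paperlike_fixture <- function(n_pos = 60L, n_neg = 600L, n_prot = 180L,
                              seed = 1L) {
  generate_proteins(n_prot, length_range = c(150L, 250L),
                    n_sites = c(positive = n_pos, negative = n_neg),
                    seed = seed)
}

# --- independent counting/looping oracles (deliberately naive) --------------

oracle_aac <- function(frag) {
  ch <- strsplit(frag, "")[[1]]
  ch <- ch[ch != "X"]
  unname(vapply(AAS, function(a) sum(ch == a) / length(ch), numeric(1)))
}

oracle_eaac <- function(frag, window = 5L) {
  ch <- strsplit(frag, "")[[1]]
  out <- numeric(0)
  for (i in seq_len(length(ch) - window + 1L)) {
    win <- ch[i:(i + window - 1L)]
    win <- win[win != "X"]
    v <- if (length(win) == 0L) rep(0, 20) else
      unname(vapply(AAS, function(a) sum(win == a) / length(win), numeric(1)))
    out <- c(out, v)
  }
  out
}

oracle_paac_theta <- function(frag, lambda) {
  ch <- strsplit(frag, "")[[1]]
  norm <- function(p) { p <- p[AAS]; (p - mean(p)) / sqrt(sum((p - mean(p))^2) / 20) }
  h1 <- norm(phosphoseed:::PAAC_HYDROPHOBICITY)
  h2 <- norm(phosphoseed:::PAAC_HYDROPHILICITY)
  ms <- norm(phosphoseed:::PAAC_SIDECHAIN_MASS)
  vapply(seq_len(lambda), function(j) {
    vals <- c()
    for (i in seq_len(length(ch) - j)) {
      a <- ch[i]; b <- ch[i + j]
      if (a != "X" && b != "X") {
        vals <- c(vals, ((h1[a] - h1[b])^2 + (h2[a] - h2[b])^2 +
                           (ms[a] - ms[b])^2) / 3)
      }
    }
    if (length(vals) == 0L) 0 else mean(vals)
  }, numeric(1))
}

oracle_qsorder_tau <- function(frag, nlag, mat) {
  ch <- strsplit(frag, "")[[1]]
  vapply(seq_len(nlag), function(d) {
    tot <- 0
    for (i in seq_len(length(ch) - d)) {
      a <- ch[i]; b <- ch[i + d]
      if (a != "X" && b != "X") tot <- tot + mat[a, b]^2
    }
    tot
  }, numeric(1))
}

# greedy redundancy filter computed pair-by-pair (scalar identity calls)
oracle_redundancy <- function(items, threshold) {
  keep <- integer(0)
  for (i in seq_along(items)) {
    ok <- TRUE
    for (j in keep) {
      if (percent_identity(items[j], items[i]) >= threshold) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, i)
  }
  keep
}

# AUC via the rank-sum (Mann-Whitney) statistic with midranks for ties
oracle_auc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
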