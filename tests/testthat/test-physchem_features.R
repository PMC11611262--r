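test_that("AAC counts residue frequencies over non-X positions", {
  expect_equal(unname(encode_aac(strrep("A", 41))$values[1, ]),
               c(1, rep(0, 19)))
  # each of 20 AAs twice plus one extra A
  frag <- paste(c(rep(AAS, 2), "A"), collapse = "")
  v <- encode_aac(frag)$values[1, ]
  expect_equal(unname(v["AAC.A"]), 3 / 41)
  expect_equal(unname(v["AAC.V"]), 2 / 41)
  expect_equal(sum(v), 1, tolerance = 1e-12)
  # X ignored in numerator and denominator
  vx <- encode_aac(paste0(strrep("X", 20), strrep("A", 21)))$values[1, ]
  expect_equal(unname(vx["AAC.A"]), 1)
  expect_error(encode_aac(strrep("X", 41)), "all X")
})

test_that("EAAC windows slide with the documented naming and normalization", {
  b <- encode_eaac(random_fragment(seed = 1), window = 5)
  expect_identical(dim(b$values), c(1L, 740L))          # 37 windows x 20
  expect_identical(b$feature_names[1], "SW.1.A")
  # SSSSS at positions 17-21 gives SW.17.S = 1
  frag <- paste0(strrep("A", 16), "SSSSS", strrep("G", 20))
  v <- encode_eaac(frag)$values[1, ]
  expect_equal(unname(v["SW.17.S"]), 1)
  # every fully non-X window sums to 1
  sums <- vapply(seq_len(37), function(i) {
    sum(v[((i - 1) * 20 + 1):(i * 20)])
  }, numeric(1))
  expect_equal(sums, rep(1, 37), tolerance = 1e-12)
  # all-X window is zero
  vX <- encode_eaac(paste0(strrep("X", 10), strrep("A", 31)))$values[1, ]
  expect_equal(sum(vX[1:20]), 0)
})

test_that("EAAC matches a brute-force window count on random fragments", {
  for (f in random_fragment(20, seed = 2)) {
    expect_equal(unname(encode_eaac(f)$values[1, ]), oracle_eaac(f),
                 tolerance = 1e-12)
  }
  # fragments containing X
  fx <- random_fragment(5, seed = 3, alphabet = c(AAS, "X", "X"))
  for (f in fx) {
    expect_equal(unname(encode_eaac(f)$values[1, ]), oracle_eaac(f),
                 tolerance = 1e-12)
  }
})

test_that("CTDC groups partition residues per property", {
  b <- encode_ctdc(random_fragment(seed = 4))
  expect_identical(ncol(b$values), 39L)
  # all K/R fragment: charge group 1 is 1
  v <- encode_ctdc(paste(rep(c("K", "R"), len = 41), collapse = ""))$values[1, ]
  expect_equal(unname(v["charge.G1"]), 1)
  # fragment drawn only from the CASG920101 polar group
  polar <- strsplit("KDEQPSRNTG", "")[[1]]
  vp <- encode_ctdc(paste(rep(polar, len = 41), collapse = ""))$values[1, ]
  expect_equal(unname(vp["hydrophobicity_CASG920101.G1"]), 1)
  # G1+G2+G3 = 1 for every property on X-free fragments
  for (f in random_fragment(10, seed = 5)) {
    vv <- encode_ctdc(f)$values[1, ]
    g <- matrix(vv, nrow = 3)
    expect_equal(colSums(g), rep(1, 13), tolerance = 1e-12)
  }
})

test_that("PAAC reduces to AAC on a homopolymer and matches the brute-force theta", {
  v <- encode_paac(strrep("A", 41), lambda = 3)$values[1, ]
  expect_equal(unname(v[1:20]), c(1, rep(0, 19)))       # all theta = 0
  expect_equal(unname(v[21:23]), rep(0, 3))
  for (f in random_fragment(10, seed = 6)) {
    lam <- 4; w <- 0.05
    theta <- oracle_paac_theta(f, lam)
    freq <- oracle_aac(f)
    expected <- c(freq, w * theta) / (1 + w * sum(theta))
    got <- encode_paac(f, lambda = lam, weight = w)$values[1, ]
    expect_equal(unname(got), unname(expected), tolerance = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-12)
  }
  expect_error(encode_paac(strrep("A", 41), lambda = 41), "lambda")
})

test_that("QSOrder has dimension 40 + 2*nlag and matches brute-force tau sums", {
  hom <- encode_qsorder(strrep("A", 41), nlag = 5)$values[1, ]
  expect_identical(length(hom), 50L)
  expect_equal(unname(hom[41:50]), rep(0, 10))          # self-distance 0
  expect_equal(unname(hom[1:20]), c(1, rep(0, 19)))     # reduces to AAC
  gm <- grantham_matrix(); hm <- hphys_matrix()
  for (f in random_fragment(8, seed = 7)) {
    nl <- 3; w <- 0.1
    tau_h <- oracle_qsorder_tau(f, nl, hm)
    tau_g <- oracle_qsorder_tau(f, nl, gm)
    counts <- oracle_aac(f) * sum(strsplit(f, "")[[1]] != "X")
    got <- encode_qsorder(f, nlag = nl, weight = w)$values[1, ]
    expect_equal(unname(got[1:20]),
                 unname(counts / (sum(counts) + w * sum(tau_h))), tolerance = 1e-12)
    expect_equal(unname(got[21:40]),
                 unname(counts / (sum(counts) + w * sum(tau_g))), tolerance = 1e-12)
    expect_equal(unname(got[41:43]),
                 w * tau_h / (sum(counts) + w * sum(tau_h)), tolerance = 1e-12)
    expect_equal(unname(got[44:46]),
                 w * tau_g / (sum(counts) + w * sum(tau_g)), tolerance = 1e-12)
  }
})

test_that("Grantham distances reproduce published values", {
  # recomputed from the published formula; printed table values are rounded,
  # so agreement is to +/- 1.5
  g <- grantham_matrix()
  expect_lt(abs(g["L", "I"] - 5), 1.5)
  expect_lt(abs(g["W", "C"] - 215), 1.5)
  expect_lt(abs(g["S", "F"] - 155), 1.5)
  expect_lt(abs(g["R", "L"] - 102), 1.5)
  expect_true(isSymmetric(g))
  expect_equal(unname(diag(g)), rep(0, 20))
})

test_that("BINARY one-hot uses the documented index arithmetic", {
  frag <- random_fragment(seed = 8)
  b <- encode_binary(frag)
  expect_identical(ncol(b$values), 820L)
  ch <- strsplit(frag, "")[[1]]
  for (p in c(1, 18, 22, 41)) {
    idx <- binary_feature_index(p, ch[p])
    expect_equal(unname(b$values[1, idx]), 1)
    slice <- b$values[1, ((p - 1) * 20 + 1):(p * 20)]
    expect_equal(sum(slice), 1)
  }
  expect_identical(binary_feature_index(18, "R"), 342L)
  expect_identical(binary_feature_index(22, "P"), 435L)
  expect_identical(binary_feature_index(1, "A"), 1L)
  # X position emits all zeros
  bx <- encode_binary(paste0("X", strrep("A", 40)))
  expect_equal(sum(bx$values[1, 1:20]), 0)
  # name -> index -> (position, residue) round trip
  info <- binary_feature_info(342)
  expect_identical(info$position, 18L)
  expect_identical(info$residue, "R")
  for (n in c(1L, 57L, 342L, 435L, 820L)) {
    i <- binary_feature_info(n)
    expect_identical(binary_feature_index(i$position, i$residue), n)
  }
})

test_that("encoders are pure functions and blocks combine with unique names", {
  frags <- random_fragment(5, seed = 9)
  expect_identical(encode_aac(frags), encode_aac(frags))
  expect_identical(encode_paac(frags), encode_paac(frags))
  blocks <- encode_physchem(frags, encoder_config())
  comb <- combine_blocks(blocks)
  widths <- vapply(blocks, function(b) ncol(b$values), integer(1))
  expect_identical(ncol(comb$values), sum(widths))
  expect_false(anyDuplicated(comb$feature_names) > 0)
  # name lookup returns the original column
  expect_identical(comb$values[, "SW.17.S"], blocks$EAAC$values[, "SW.17.S"])
  # without BINARY the width drops by exactly 820
  no_bin <- combine_blocks(encode_physchem(frags, encoder_config(use_binary = FALSE)))
  expect_identical(ncol(comb$values) - ncol(no_bin$values), 820L)
  # sample-count mismatch errors
  expect_error(combine_blocks(list(encode_aac(frags), encode_aac(frags[1:2]))),
               "mismatch")
})
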