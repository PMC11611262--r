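test_that("read_fasta parses records, maps non-standard residues and round-trips", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "MSTY", ">p2 description", "ACDEU", ">p3", "GGGG"), path)
  seqs <- suppressMessages(read_fasta(path))
  expect_named(seqs, c("p1", "p2", "p3"))
  expect_identical(unname(seqs[["p1"]]), "MSTY")
  expect_identical(unname(seqs[["p2"]]), "ACDEX")  # U -> X

  out <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, out)
  expect_identical(suppressMessages(read_fasta(out)), seqs)

  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_fasta(empty))
  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MM", ">a", "KK"), dup)
  expect_error(read_fasta(dup), "duplicate.*a")
})

test_that("extract_fragment returns the centered 41-window with X padding", {
  prot41 <- paste0(strrep("A", 20), "S", strrep("G", 20))
  expect_identical(extract_fragment(prot41, 21), prot41)

  p <- paste0("S", strrep("A", 60))
  f <- extract_fragment(p, 1)
  expect_identical(substr(f, 1, 20), strrep("X", 20))
  expect_identical(substr(f, 21, 21), "S")

  # S at position 5 of a length-50 protein: 16 X then residues 1..25
  p50 <- paste0("AAAA", "S", paste(rep("L", 45), collapse = ""))
  f5 <- extract_fragment(p50, 5)
  expect_identical(f5, paste0(strrep("X", 16), substr(p50, 1, 25)))
  expect_identical(nchar(f5), 41L)

  expect_error(extract_fragment("AAAA", 2), "not S/T/Y")
})

test_that("extracted fragments always re-locate their center residue", {
  gen <- paperlike_fixture(n_pos = 10L, n_neg = 10L, n_prot = 30L, seed = 5)
  frags <- extract_fragments(gen$proteins, gen$sites)
  expect_true(all(nchar(frags$sequence) == 41L))
  expect_true(all(substr(frags$sequence, 21, 21) %in% c("S", "T", "Y")))
  # position-reversibility: the source protein has the center residue there
  at <- substr(gen$proteins[frags$protein_id], frags$position, frags$position)
  expect_identical(unname(at), frags$residue)
})

test_that("percent_identity matches Biostrings global alignment on similar pairs", {
  base <- random_fragment(seed = 11)
  withr::with_seed(12, {
    for (trial in 1:10) {
      ch <- strsplit(base, "")[[1]]
      k <- sample(3:15, 1)
      ch[sample(41, k)] <- sample(AAS, k, TRUE)
      if (trial %% 2 == 0) ch <- ch[-sample(41, 2)]
      s <- paste(ch, collapse = "")
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(s), Biostrings::AAString(base), type = "global",
        substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
      ref <- Biostrings::nmatch(aln) /
        nchar(as.character(Biostrings::alignedPattern(aln)))
      expect_equal(percent_identity(s, base), ref, tolerance = 1e-12)
    }
  })
  expect_identical(percent_identity("MSTYA", "MSTYA"), 1)
})

test_that("reduce_redundancy is greedy, deterministic and matches the all-pairs oracle", {
  expect_identical(reduce_redundancy(c("AAASAAA", "AAASAAA"), 0.4), 1L)
  expect_error(reduce_redundancy(c("AA", "BB"), 1.5), "threshold")

  # 20 fragments, some mutated copies of each other
  withr::with_seed(21, {
    base <- random_fragment(5)
    items <- c(base, vapply(rep(base, 3), function(b) {
      ch <- strsplit(b, "")[[1]]
      k <- sample(2:25, 1)
      ch[sample(41, k)] <- sample(AAS, k, TRUE)
      paste(ch, collapse = "")
    }, character(1)))
  })
  got <- reduce_redundancy(items, 0.4)
  expect_identical(got, oracle_redundancy(items, 0.4))
  expect_identical(got, reduce_redundancy(items, 0.4))  # deterministic
})

test_that("build_balanced_dataset keeps positives and samples negatives uniformly", {
  pos <- data.frame(protein_id = "p", position = 1:10, residue = "S",
                    label = "positive", sequence = random_fragment(10, seed = 1))
  neg <- data.frame(protein_id = "p", position = 11:110, residue = "S",
                    label = "negative", sequence = random_fragment(100, seed = 2))
  d <- build_balanced_dataset(pos, neg, seed = 3)
  expect_identical(nrow(d), 20L)
  expect_identical(as.integer(table(d$label)["positive"]), 10L)
  expect_identical(d, build_balanced_dataset(pos, neg, seed = 3))
  expect_error(build_balanced_dataset(neg, pos, seed = 1), "fewer negatives")

  # sampling-uniformity: each negative picked with frequency ~ 10/100
  counts <- integer(100)
  for (s in 1:100) {
    d <- build_balanced_dataset(pos, neg, seed = s)
    picked <- d$position[d$label == "negative"] - 10L
    counts[picked] <- counts[picked] + 1L
  }
  expect_equal(mean(counts) / 100, 0.1, tolerance = 1e-9)
  expect_true(all(counts / 100 > 0.01 & counts / 100 < 0.30))
})

test_that("split_train_test stratifies by label and partitions the data", {
  d <- data.frame(protein_id = "p", position = 1:100, residue = "S",
                  label = rep(c("positive", "negative"), 50),
                  sequence = random_fragment(100, seed = 4))
  sp <- split_train_test(d, 0.8, seed = 9)
  expect_identical(nrow(sp$train), 80L)
  expect_identical(nrow(sp$test), 20L)
  expect_identical(as.integer(table(sp$train$label)), c(40L, 40L))
  expect_identical(as.integer(table(sp$test$label)), c(10L, 10L))
  expect_identical(sort(c(sp$train$position, sp$test$position)), 1:100)
  expect_error(split_train_test(d[d$label == "positive", ], 0.8, seed = 1))
})
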