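random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(AA_ALPHABET20, n, replace = TRUE), collapse = "")
}

test_that("AAC matches letter frequencies", {
  v <- encode_aac("AAAAA")
  expect_equal(unname(v["A"]), 1)
  expect_equal(sum(v), 1)
  v2 <- encode_aac("ACDE")
  expect_equal(unname(v2[c("A", "C", "D", "E")]), rep(0.25, 4))

  s <- random_seq(30, seed = 1)
  ch <- strsplit(s, "")[[1]]
  brute <- vapply(AA_ALPHABET20, function(a) sum(ch == a) / 30, numeric(1))
  expect_equal(unname(encode_aac(s)), unname(brute))
  expect_error(encode_aac(""), "empty")
})

test_that("DC matches sliding-window dipeptide counts", {
  v <- encode_dc("AAA")
  expect_equal(unname(v["AA"]), 1)
  expect_equal(sum(v), 1)

  s <- random_seq(25, seed = 2)
  ch <- strsplit(s, "")[[1]]
  v <- encode_dc(s)
  for (pair in c("AC", "KL", "YY", paste0(ch[1], ch[2]))) {
    hits <- sum(ch[-25] == substr(pair, 1, 1) & ch[-1] == substr(pair, 2, 2))
    expect_equal(unname(v[pair]), hits / 24)
  }
  expect_equal(sum(encode_dc(random_seq(40, 3))), 1)
  expect_error(encode_dc("A"), "length")
})

test_that("PAAC has dimension 20 + lam and sums to 1", {
  for (lam in 1:4) {
    v <- encode_paac(random_seq(12, lam), lam = lam)
    expect_length(v, 20 + lam)
    expect_equal(sum(v), 1)
    expect_true(all(v >= 0))
  }
  expect_error(encode_paac("ACDEF", lam = 5), "lam")
})

test_that("PAAC correlation factors vanish on a homopolymer", {
  v <- encode_paac("LLLLL", lam = 1)
  expect_equal(unname(v["lambda1"]), 0)
  expect_equal(unname(v["L"]), 1)
})

test_that("PAAC matches an independent Chou-style reimplementation", {
  for (seed in 1:3) {
    s <- random_seq(15, seed)
    expect_equal(unname(encode_paac(s, lam = 2, w = 0.05)),
                 oracle_paac(s, lam = 2, w = 0.05), tolerance = 1e-12)
  }
})

test_that("CTD blocks have the documented shape and normalization", {
  ctd <- encode_ctd(random_seq(40, 4))
  expect_length(ctd$composition, 21)
  expect_length(ctd$transition, 21)
  expect_length(ctd$distribution, 105)
  # composition sums to 1 per property
  for (p in seq_len(7)) {
    expect_equal(sum(ctd$composition[(3 * p - 2):(3 * p)]), 1)
  }
})

test_that("CTD single-class sequences give pure composition, no transitions", {
  # K and R are the positive-charge class of the charge property
  ctd <- encode_ctd("KRKRK")
  expect_equal(unname(ctd$composition[c("charge.C1", "charge.C2", "charge.C3")]),
               c(1, 0, 0))
  expect_equal(unname(ctd$transition[grepl("^charge", names(ctd$transition))]),
               c(0, 0, 0))
})

test_that("CTD distribution matches a brute-force positional scan", {
  s <- random_seq(40, 9)
  ch <- strsplit(s, "")[[1]]
  ctd <- encode_ctd(s)
  groups <- ctd_default_groups()
  for (p in names(groups)) {
    for (k in 1:3) {
      pos <- which(ch %in% groups[[p]][[k]])
      expected <- if (length(pos) == 0) rep(0, 5) else {
        idx <- pmax(1, ceiling(c(0, 0.25, 0.5, 0.75, 1) * length(pos)))
        idx[1] <- 1
        pos[idx] / 40
      }
      got <- ctd$distribution[paste0(p, ".D", k, ".",
                                     c("first", "25", "50", "75", "100"))]
      expect_equal(unname(got), expected)
    }
  }
})

test_that("AAC is shuffle-invariant, DC and CTD are not", {
  s <- "KKKKKLLLLLAAAAA"
  shuffled <- "KLAKLAKLAKLAKLA"
  expect_equal(encode_aac(s), encode_aac(shuffled))
  expect_false(isTRUE(all.equal(encode_dc(s), encode_dc(shuffled))))
  expect_false(isTRUE(all.equal(encode_ctd(s)$transition,
                                encode_ctd(shuffled)$transition)))
})

test_that("encode_peptides stacks rows and round-trips through text", {
  rec <- make_sequences(sequence_spec(n_pos = 10L, n_neg = 10L, seed = 5L))
  X <- encode_peptides(rec, "aac")
  expect_equal(dim(X), c(20L, 20L))
  expect_equal(rownames(X), rec$id)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(X, f)
  back <- read_feature_matrix(f)
  expect_equal(unname(back), unname(as.matrix(X)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(back, "labels"), rec$label)
})
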