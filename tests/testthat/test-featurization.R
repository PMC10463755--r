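test_that("rendered molecule images are deterministic, bounded grids", {
  img <- render_image("C", 64)
  expect_equal(dim(img), c(64L, 64L, 3L))
  expect_true(all(img >= 0 & img <= 1))
  expect_lt(min(img), 1)  # not all-white

  a <- render_image("CC(=O)Oc1ccccc1C(=O)O", 32)
  b <- render_image("CC(=O)Oc1ccccc1C(=O)O", 32)
  expect_identical(a, b)

  expect_error(render_image("X#", 32), "SMILES")
})

# Expected families below were frozen from a reference pharmacophore
# feature factory run on the same molecules.
test_that("pharmacophore chemical text contains the expected families", {
  benzene <- chemical_text("c1ccccc1")
  expect_true("Aromatic" %in% benzene)

  aspirin <- chemical_text("CC(=O)Oc1ccccc1C(=O)O")
  expect_true(all(c("Donor", "Acceptor", "Aromatic", "NegIonizable")
                  %in% aspirin))

  ethanol <- chemical_text("CCO")
  expect_true(all(c("Donor", "Acceptor") %in% ethanol))
  expect_false("Aromatic" %in% ethanol)

  expect_identical(chemical_text("CCO"), chemical_text("CCO"))
  expect_error(chemical_text("X#"), "SMILES")
})

test_that("features serialise as (family, type, atom-tuple) word triples", {
  words <- chemical_text("c1ccccc1")
  expect_equal(length(words) %% 3L, 0L)
  expect_equal(words[1:3], c("Aromatic", "Arom6", "(1,2,3,4,5,6)"))
})

test_that("k-gram segmentation is a stride-1 sliding window", {
  expect_equal(segment_kgrams(c("M", "K", "V", "L"), 2),
               c("MK", "KV", "VL"))
  x <- c("a", "b", "c")
  expect_equal(segment_kgrams(x, 1), x)
  expect_equal(segment_kgrams(c("M", "K"), 3), character())
  expect_error(segment_kgrams(x, 0), "k must be")
  for (k in 1:4) {
    tok <- letters[1:9]
    expect_length(segment_kgrams(tok, k), max(0L, 9L - k + 1L))
  }
})

test_that("vocabulary indices follow first appearance, from 2 upward", {
  v <- build_vocab(list(c("A", "B", "A", "C")))
  expect_equal(unname(v$map[c("A", "B", "C")]), c(2L, 3L, 4L))
  expect_equal(vocab_size(build_vocab(list())), 2L)  # PAD + UNK only
  v2 <- build_vocab(list(c("X", "Y"), c("Y", "Z")))
  expect_equal(unname(v2$map[c("X", "Y", "Z")]), c(2L, 3L, 4L))
})

test_that("encoding maps, truncates, pads, and flags padding", {
  v <- build_vocab(list(c("A", "B", "C")))
  ts <- encode_tokens(c("C", "A"), v, 4)
  expect_equal(ts$indices, c(4L, 2L, 0L, 0L))
  expect_equal(ts$valid_length, 2L)
  expect_equal(ts$pad_mask, c(FALSE, FALSE, TRUE, TRUE))

  expect_equal(encode_tokens("D", v, 2)$indices, c(1L, 0L))  # UNK

  long <- encode_tokens(rep("A", 10), v, 4)
  expect_equal(long$indices, rep(2L, 4))
  expect_equal(sum(long$indices == 0L), 4L - long$valid_length)
})

test_that("vocabularies built on a corpus never emit UNK on that corpus", {
  set.seed(3)
  docs <- replicate(20, sample(letters[1:6], sample(3:9, 1), TRUE),
                    simplify = FALSE)
  segs <- lapply(docs, segment_kgrams, k = 2)
  v <- build_vocab(segs, k = 2)
  for (s in segs) {
    enc <- encode_tokens(s, v, 16)
    expect_false(any(enc$indices == v$unk))
  }
})

test_that("protein featurisation uppercases and k-gram-encodes", {
  v <- build_vocab(list(c("M", "K", "V")))
  ts <- featurize_protein("MKV", v, k = 1, L = 5)
  expect_equal(ts$indices, c(2L, 3L, 4L, 0L, 0L))
  expect_identical(featurize_protein("mkv", v, k = 1, L = 5)$indices,
                   ts$indices)
  v3 <- build_vocab(list("MKV"), k = 3)
  expect_equal(featurize_protein("MKV", v3, k = 3, L = 2)$valid_length, 1L)
  expect_error(featurize_protein("", v, k = 1, L = 5), "empty")
})

test_that("vocabularies survive a JSON round trip", {
  v <- build_vocab(list(c("HKH", "KHA", "AAB")), k = 3)
  path <- withr::local_tempfile()
  save_vocab(v, path)
  v2 <- load_vocab(path)
  expect_identical(v$map, v2$map)
  expect_identical(v$k, v2$k)
})

test_that("featurisation is byte-reproducible across repeated runs", {
  smi <- smiles_library()[1:5]
  w1 <- lapply(smi, chemical_text)
  w2 <- lapply(smi, chemical_text)
  expect_identical(w1, w2)
  i1 <- lapply(smi, render_image, h = 32)
  i2 <- lapply(smi, render_image, h = 32)
  expect_identical(i1, i2)
})
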