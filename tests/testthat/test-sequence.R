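test_that("template alignment is a gap-stripping round trip at 145/127", {
  pairs <- make_synthetic_sequences(6, seed = 2)
  for (i in seq_len(nrow(pairs))) {
    p <- fv_pair(pairs$name[i], pairs$heavy[i], pairs$light[i])
    al <- number_and_align(p)
    expect_true(al$ok)
    expect_equal(nchar(al$heavy), 145)
    expect_equal(nchar(al$light), 127)
    expect_equal(gsub("-", "", al$heavy), p$heavy)
    expect_equal(gsub("-", "", al$light), p$light)
    # residues land on their scheme slots: anchors at 23 and 104
    expect_equal(unname(al$positions$heavy[c("23", "104")]), c("C", "C"))
    expect_equal(unname(al$positions$light[c("23", "104")]), c("C", "C"))
  }
  # empty and non-alphabet sequences fail numbering
  expect_false(number_and_align(list(heavy = "", light = "ACD"))$ok)
  expect_true("NUMBERING_FAIL" %in%
                number_and_align(list(heavy = "", light = ""))$reasons)
})

test_that("explicit loop lengths place insertions and flag non-canonical ones", {
  pairs <- make_synthetic_sequences(1, seed = 3)
  al <- align_chain(pairs$heavy[1], "heavy")
  expect_true(al$ok)
  h3 <- al$cdr_lengths[["CDRH3"]]
  # same sequence with declared longer CDRH1 shifts length out of CDRH3
  al2 <- align_chain(pairs$heavy[1], "heavy",
                     cdr_lengths = c(CDRH1 = 9, CDRH2 = 5, CDRH3 = h3 - 2))
  expect_true(al2$ok)
  expect_true("INSERTION" %in% al2$reasons)
  expect_equal(gsub("-", "", al2$aligned), pairs$heavy[1])
})

test_that("filters accumulate reason codes without short-circuiting", {
  pairs <- make_synthetic_sequences(4, seed = 5)
  p <- fv_pair(pairs$name[1], pairs$heavy[1], pairs$light[1])
  al <- number_and_align(p)
  expect_true(apply_filters(p, al)$pass)

  # boundary acceptance: a CDRH3 of exactly 30 residues still aligns
  base <- make_synthetic_sequences(1, seed = 6)
  l <- align_chain(base$heavy[1], "heavy")$cdr_lengths[["CDRH3"]]
  h30 <- paste0(substr(base$heavy[1], 1, 94), strrep("G", 30 - l),
                substr(base$heavy[1], 95, nchar(base$heavy[1])))
  al30 <- align_chain(h30, "heavy")
  expect_true(al30$ok)
  expect_equal(al30$cdr_lengths[["CDRH3"]], 30)

  v <- make_synthetic_sequences(2, seed = 7, violation = "cdrh3_31")
  pv <- fv_pair("v", v$heavy[1], v$light[1])
  alv <- number_and_align(pv)
  repv <- apply_filters(pv, alv)
  expect_false(repv$pass)
  expect_true("CDRH3_TOO_LONG" %in% repv$reasons)

  # missing cysteine
  vc <- make_synthetic_sequences(2, seed = 8, violation = "cys_missing")
  pc <- fv_pair("c", vc$heavy[1], vc$light[1])
  repc <- apply_filters(pc, number_and_align(pc))
  expect_true("CYS_MISSING" %in% repc$reasons)

  # duplicate + unpaired accumulate together
  pu <- list(name = "u", heavy = pairs$heavy[2], light = "")
  alu <- number_and_align(pu)
  repu <- apply_filters(pu, alu,
                        seen = paste(pu$heavy, pu$light, sep = "|"))
  expect_setequal(repu$reasons,
                  c("UNPAIRED", "DUPLICATE", "NUMBERING_FAIL"))

  # duplicate depends only on the declared seen set, not call order
  p2 <- fv_pair(pairs$name[2], pairs$heavy[2], pairs$light[2])
  al2 <- number_and_align(p2)
  expect_true(apply_filters(p2, al2, seen = character(0))$pass)
  expect_false(apply_filters(p2, al2,
                             seen = paste(p2$heavy, p2$light,
                                          sep = "|"))$pass)
})

test_that("one-hot encoding is exact, ordered and invertible", {
  pairs <- make_synthetic_sequences(3, seed = 9)
  p <- fv_pair(pairs$name[1], pairs$heavy[1], pairs$light[1])
  al <- number_and_align(p)
  m <- one_hot_encode(al)
  expect_equal(dim(m), c(272, 21))
  expect_true(all(rowSums(m) == 1))
  expect_equal(colnames(m), c("A", "C", "D", "E", "F", "G", "H", "I", "K",
                              "L", "M", "N", "P", "Q", "R", "S", "T", "V",
                              "W", "Y", "-"))
  dec <- decode_one_hot(m)
  expect_equal(dec$heavy, al$heavy)
  expect_equal(dec$light, al$light)
  expect_equal(one_hot_encode(dec), m)   # encode(decode(encode)) fixpoint

  # all-gap input activates the gap channel everywhere
  allgap <- list(heavy = strrep("-", 145), light = strrep("-", 127))
  mg <- one_hot_encode(allgap)
  expect_equal(sum(mg[, "-"]), 272)
  # characters outside the alphabet are rejected
  bad <- list(heavy = paste0("X", strrep("-", 144)), light = strrep("-", 127))
  expect_error(one_hot_encode(bad), "alphabet")
})

test_that("encode_pairs reports failures and stacks passing encodings", {
  good <- make_synthetic_sequences(3, seed = 10)
  bad <- make_synthetic_sequences(1, seed = 11, violation = "cdrh3_31")
  bad$name <- "bad_1"
  dup <- good[1, ]
  dup$name <- "dup_of_1"
  pairs <- rbind(good, bad, dup)
  enc <- encode_pairs(pairs)
  expect_equal(nrow(enc$report), 5)
  expect_equal(sum(enc$report$pass), 3)
  expect_equal(dim(enc$x), c(3, 272, 21))
  expect_match(enc$report$reasons[4], "CDRH3_TOO_LONG")
  expect_match(enc$report$reasons[5], "DUPLICATE")
})
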