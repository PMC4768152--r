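test_that("anchor-class membership follows the two grammars", {
  expect_true(classifyResidue("K", "basic", "CARC"))
  expect_true(classifyResidue("R", "basic", "CRAC"))
  # Trp is an admissible CARC aromatic but not a CRAC one
  expect_true(classifyResidue("W", "aromatic", "CARC"))
  expect_false(classifyResidue("W", "aromatic", "CRAC"))
  expect_false(classifyResidue("G", "basic", "CARC"))
  expect_true(classifyResidue("v", "aliphatic", "CARC"))  # case-insensitive
  # Ile only with the relaxed aliphatic class
  expect_false(classifyResidue("I", "aliphatic", "CRAC"))
  expect_true(classifyResidue("I", "aliphatic", "CRAC", scanConfig(allowIle = TRUE)))
  # ambiguity codes are never anchors
  expect_false(classifyResidue("X", "aromatic", "CARC"))
  expect_error(classifyResidue("K", "charged", "CARC"), "unknown anchor role")
})

test_that("strict-CRAC mode restricts the aromatic class to Tyr", {
  m <- enumerateMotifs("VGSLFLTAIDR", "CRAC", offset = 204)
  expect_identical(nrow(m), 1L)  # needs the relaxed Y/F class: aromatic is F208
  strict <- enumerateMotifs("VGSLFLTAIDR", "CRAC", offset = 204,
                            config = scanConfig(strictCrac = TRUE))
  expect_identical(nrow(strict), 0L)
})

test_that("printed peptide motifs are enumerated at their published anchors", {
  # human AChR gamma-TM4 prototype CARC
  m <- enumerateMotifs("RVCFLAML", "CARC", offset = 455)
  expect_identical(nrow(m), 1L)
  expect_identical(m$pos_basic, 455L)
  expect_identical(m$pos_aromatic, 458L)
  expect_identical(m$pos_aliphatic, 462L)
  expect_identical(m$span, 8L)
  # Torpedo variant, Lys-449 / Phe-452 / Leu-456
  m2 <- enumerateMotifs("KACFWIAL", "CARC", offset = 449)
  expect_true(any(m2$pos_basic == 449 & m2$pos_aromatic == 452 &
                    m2$pos_aliphatic == 456))
  # destroying the aromatic anchor kills the motif
  expect_identical(nrow(enumerateMotifs("RVCALAML", "CARC", offset = 455)), 0L)
  # CB1 TM3 CRAC: V204 - F208 - R214 (frozen from the all-triples oracle)
  m3 <- enumerateMotifs("VGSLFLTAIDR", "CRAC", offset = 204)
  expect_identical(m3$pos_aliphatic, 204L)
  expect_identical(m3$pos_aromatic, 208L)
  expect_identical(m3$pos_basic, 214L)
  expect_identical(m3, bruteForceMotifs("VGSLFLTAIDR", "CRAC", offset = 204))
})

test_that("enumeration is exhaustive, ordered and offset-correct", {
  m <- enumerateMotifs("RNVFLFKLGGV", "CARC", offset = 186)
  # two Phe and both Leu/Val give several overlapping triads
  expect_gt(nrow(m), 1L)
  expect_false(is.unsorted(m$start))
  expect_identical(m, bruteForceMotifs("RNVFLFKLGGV", "CARC", offset = 186))
  # shifting the offset translates every coordinate rigidly
  m1 <- enumerateMotifs("RNVFLFKLGGV", "CARC", offset = 1)
  for (cc in c("start", "end", "pos_basic", "pos_aromatic", "pos_aliphatic"))
    expect_identical(m[[cc]], m1[[cc]] + 185L)
  expect_identical(nrow(enumerateMotifs("", "CARC")), 0L)
  expect_error(enumerateMotifs("RVCFLAML", "CARC", offset = 0), "offset")
})

test_that("spacer positions are unconstrained, only anchors are class-checked", {
  # anchor-class letters (F, K) inside spacers must not block a match
  m <- enumerateMotifs("RNVFLFKLGGV", "CARC", offset = 186)
  expect_true(any(m$start == 186 & m$end == 196))  # spacers contain F and K
  # ambiguity codes may serve as spacers but never as anchors
  m2 <- enumerateMotifs("KXXFXXL", "CARC")
  expect_identical(nrow(m2), 1L)
  expect_identical(m2$pos_aromatic, 4L)
})

test_that("maximal-span selection keeps the largest triad of each cluster", {
  # overlapping CARCs in the CB1 TM3 N-terminal region: one representative
  m <- enumerateMotifs("RNVFLFKLGGV", "CARC", offset = 186)
  sel <- selectMaximal(m)
  expect_identical(nrow(sel), 1L)
  expect_identical(sel$start, 186L)
  expect_identical(sel$end, 196L)
  # brute-force check of the documented small case
  m2 <- enumerateMotifs("RAFALAV", "CARC")
  expect_identical(sort(m2$end), c(5L, 7L))
  sel2 <- selectMaximal(m2)
  expect_identical(sel2$start, 1L)
  expect_identical(sel2$end, 7L)
  # a singleton passes through unchanged
  single <- enumerateMotifs("RVCFLAML", "CARC", offset = 455)
  expect_identical(selectMaximal(single), single)
  # mixed kinds are a usage error
  mixed <- rbind(enumerateMotifs("KAAFAAL", "CARC"),
                 enumerateMotifs("LAAYAAK", "CRAC"))
  expect_error(selectMaximal(mixed), "mixed")
})

test_that("enumeration equals the all-triples brute force on random sequences", {
  set.seed(4202)
  for (rep in seq_len(400)) {
    s <- randomOracleSequence()
    for (kind in c("CARC", "CRAC")) {
      got <- enumerateMotifs(s, kind)
      want <- bruteForceMotifs(s, kind)
      expect_identical(got, want)
    }
  }
})

test_that("every returned match re-validates character by character", {
  cfg <- scanConfig()
  set.seed(907)
  for (rep in seq_len(150)) {
    s <- randomOracleSequence()
    for (kind in c("CARC", "CRAC")) {
      m <- enumerateMotifs(s, kind, offset = 101L, config = cfg)
      expect_true(mirrorCode:::.revalidateMatches(m, s, 101L, cfg))
    }
  }
})

test_that("maximal representatives dominate their clusters and do not overlap", {
  set.seed(3117)
  for (rep in seq_len(120)) {
    s <- randomOracleSequence()
    m <- enumerateMotifs(s, "CARC")
    if (nrow(m) == 0L) next
    sel <- selectMaximal(m)
    # each representative's span is >= the span of every match it overlaps
    for (i in seq_len(nrow(sel))) {
      members <- m[m$start <= sel$end[i] & m$end >= sel$start[i], ]
      expect_true(all(sel$span[i] >= members$span))
    }
    if (nrow(sel) > 1L)
      expect_true(all(sel$start[-1L] > sel$end[-nrow(sel)]))
  }
})

test_that("reversing a sequence maps CARC onto CRAC (mirror duality)", {
  cfg <- scanConfig(aromaticCarc = c("F", "Y", "W"),
                    aromaticCrac = c("F", "Y", "W"))  # equalized aromatic sets
  set.seed(5150)
  for (rep in seq_len(150)) {
    s <- randomOracleSequence()
    n <- nchar(s)
    rs <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    carc <- enumerateMotifs(s, "CARC", config = cfg)
    crac <- enumerateMotifs(rs, "CRAC", config = cfg)
    # mirrored anchor positions, same classes
    expect_identical(nrow(carc), nrow(crac))
    if (nrow(carc) > 0L) {
      got <- crac[order(crac$pos_basic, crac$pos_aromatic), ]
      want_basic <- sort(n + 1L - carc$pos_basic)
      expect_identical(sort(got$pos_basic), want_basic)
      expect_identical(sort(n + 1L - carc$pos_aromatic), sort(got$pos_aromatic))
      expect_identical(sort(n + 1L - carc$pos_aliphatic), sort(got$pos_aliphatic))
    }
  }
})
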