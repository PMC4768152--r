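test_that("TM orientation alternates with index parity from the N-terminus", {
  segs <- data.frame(index = 1:7, start = seq(10, 310, 50), end = seq(30, 330, 50))
  o <- orientTMs("extracellular", segs)
  expect_identical(o$n_end_faces[c(1, 3, 5, 7)], rep("outer", 4))
  expect_identical(o$n_end_faces[c(2, 4, 6)], rep("inner", 3))
  # cytoplasmic N-terminus reverses the parity
  o1 <- orientTMs("cytoplasmic", data.frame(index = 1, start = 10, end = 30))
  expect_identical(o1$n_end_faces, "inner")
  # annotation of a single non-initial TM keeps its native parity
  o5 <- orientTMs("extracellular", data.frame(index = 5, start = 10, end = 30))
  expect_identical(o5$n_end_faces, "outer")
  empty <- orientTMs("extracellular", segs[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("TM extension finds interfacial basic residues within the window", {
  s <- paste(rep("A", 250), collapse = "")
  substr(s, 186, 186) <- "R"
  substr(s, 214, 214) <- "R"
  # the CB1 TM3 case: 188-212 extended to 186-214
  expect_identical(unname(extendTM(s, 188, 212, window = 2)), c(186L, 214L))
  # nothing to extend
  expect_identical(unname(extendTM(s, 100, 120, window = 5)), c(100L, 120L))
  # window rule is strict: K at 34 is 4 residues out, window 3 misses it
  s2 <- paste(rep("A", 60), collapse = "")
  substr(s2, 7, 7) <- "K"
  substr(s2, 34, 34) <- "K"
  expect_identical(unname(extendTM(s2, 10, 30, window = 3)), c(7L, 30L))
  # window 0 reproduces the annotation
  expect_identical(unname(extendTM(s, 188, 212, window = 0)), c(188L, 212L))
  # a wider window reaches both flanking basics
  expect_identical(unname(extendTM(s2, 10, 30, window = 5)), c(7L, 34L))
  # extension is clipped at a neighbouring TM boundary
  expect_identical(unname(extendTM(s2, 10, 30, window = 5,
                                   prevEnd = 7, nextStart = 33)),
                   c(10L, 30L))
  expect_error(extendTM(s2, 55, 70, window = 1), "outside")
})

test_that("extension grows monotonically with the window", {
  set.seed(88)
  for (rep in seq_len(50)) {
    chars <- sample(c("A", "G", "L", "K", "R", "S"), 80, replace = TRUE)
    s <- paste(chars, collapse = "")
    prev <- NULL
    for (w in 0:6) {
      e <- extendTM(s, 30, 55, window = w)
      expect_lte(e[["extended_start"]], 30L)
      expect_gte(e[["extended_end"]], 55L)
      if (!is.null(prev)) {
        expect_lte(e[["extended_start"]], prev[["extended_start"]])
        expect_gte(e[["extended_end"]], prev[["extended_end"]])
      }
      prev <- e
    }
  }
})

test_that("leaflet assignment follows the basic anchor's half and the helix orientation", {
  carc <- enumerateMotifs("KAAFAAL", "CARC", offset = 10)  # basic anchor at 10
  crac <- enumerateMotifs("LAAYAAK", "CRAC", offset = 24)  # basic anchor at 30
  # N-end faces outer: N-half CARC -> outer, C-half CRAC -> inner
  expect_identical(assignLeaflet(carc[1, ], 10, 30, "outer"), "outer")
  expect_identical(assignLeaflet(crac[1, ], 10, 30, "outer"), "inner")
  # same motifs on an inverted helix swap leaflets
  expect_identical(assignLeaflet(carc[1, ], 10, 30, "inner"), "inner")
  expect_identical(assignLeaflet(crac[1, ], 10, 30, "inner"), "outer")
  # integer midpoint rule: anchor at floor((start+end)/2) is N-half
  m <- enumerateMotifs("KAAFAAL", "CARC", offset = 15)  # basic at 15
  expect_identical(assignLeaflet(m[1, ], 10, 21, "outer"), "outer")  # mid = 15
  expect_identical(assignLeaflet(m[1, ], 8, 21, "outer"), "inner")   # mid = 14
  expect_error(assignLeaflet(carc[1, ], 12, 30, "outer"), "outside")
})

test_that("TM classification distinguishes mirror duets from single and distant pairs", {
  expect_identical(classifyTM("outer", "inner"),
                   list(status = "dual_mirror", distant_pair = FALSE))
  expect_identical(classifyTM("outer", character(0))$status, "carc_only")
  expect_identical(classifyTM(character(0), "inner")$status, "crac_only")
  expect_identical(classifyTM(character(0), character(0))$status, "none")
  # both kinds in the same leaflet is not a mirror arrangement
  same <- classifyTM("outer", "outer")
  expect_identical(same$status, "none")
  expect_true(same$distant_pair)
  # one opposite pair suffices even with extra same-leaflet motifs
  expect_identical(classifyTM(c("outer", "inner"), "inner")$status, "dual_mirror")
})

test_that("flipping the topology flips every leaflet and preserves duality", {
  for (seed in 1:12) {
    set.seed(seed)
    plants <- randomPlantSpecs(sample.int(4L, 1L), nTM = 5L)
    for (topo in c("extracellular", "cytoplasmic")) {
      sp <- syntheticProtein(5L, plants, seed = seed, topology = topo)
      flipped <- membraneProtein(proteinId(sp$protein), proteinSeq(sp$protein),
                                 setdiff(c("extracellular", "cytoplasmic"), topo),
                                 tmStart = tmSegments(sp$protein)$start,
                                 tmEnd = tmSegments(sp$protein)$end)
      r1 <- scanProtein(sp$protein)
      r2 <- scanProtein(flipped)
      m1 <- motifs(r1); m2 <- motifs(r2)
      expect_identical(m1[, setdiff(names(m1), "leaflet")],
                       m2[, setdiff(names(m2), "leaflet")])
      expect_true(all(m1$leaflet != m2$leaflet))
      expect_identical(tmClassification(r1)$status, tmClassification(r2)$status)
    }
  }
})

test_that("a dual-mirror TM has basic anchors of the two kinds in opposite halves", {
  set.seed(2024)
  for (rep in seq_len(20)) {
    plants <- rbind(plantSpec(2, "CARC", "outer", s1 = sample.int(5, 1)),
                    plantSpec(2, "CRAC", "inner", s2 = sample.int(5, 1)))
    sp <- syntheticProtein(3L, plants, seed = rep)
    r <- scanProtein(sp$protein)
    tc <- tmClassification(r)
    i <- which(tc$tm_index == 2)
    expect_identical(tc$status[i], "dual_mirror")
    mid <- (tc$extended_start[i] + tc$extended_end[i]) %/% 2L
    m <- motifs(r)
    m <- m[m$tm_index == 2, ]
    sides <- split(m$pos_basic <= mid, m$kind)
    expect_true(any(outer(sides$CARC, sides$CRAC, FUN = "!=")))
  }
})
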