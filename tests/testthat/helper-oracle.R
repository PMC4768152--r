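# Independent brute-force oracle for motif enumeration: tests every
# position triple i < j < k of the sequence against the anchor classes
# and spacer bounds, with no candidate pre-filtering.  Kept deliberately
# separate from the package's enumeration path.

bruteForceMotifs <- function(sequence, kind, offset = 1L, config = scanConfig()) {
  chars <- strsplit(toupper(as.character(sequence)), "", fixed = TRUE)[[1]]
  n <- length(chars)
  arom <- if (kind == "CARC") config@aromaticCarc else config@aromaticCrac
  sets <- if (kind == "CARC")
    list(config@basic, arom, config@aliphatic)
  else
    list(config@aliphatic, arom, config@basic)
  empty <- data.frame(kind = character(0), start = integer(0), end = integer(0),
                      pos_basic = integer(0), pos_aromatic = integer(0),
                      pos_aliphatic = integer(0), span = integer(0),
                      stringsAsFactors = FALSE)
  if (n < 3L) return(empty)
  tri <- utils::combn(n, 3L)
  ok <- logical(ncol(tri))
  for (c_ in seq_len(ncol(tri))) {
    i <- tri[1L, c_]; j <- tri[2L, c_]; k <- tri[3L, c_]
    s1 <- j - i - 1L; s2 <- k - j - 1L
    ok[c_] <- s1 >= config@spacerMin && s1 <= config@spacerMax &&
      s2 >= config@spacerMin && s2 <= config@spacerMax &&
      chars[i] %in% sets[[1L]] && chars[j] %in% sets[[2L]] &&
      chars[k] %in% sets[[3L]]
  }
  if (!any(ok)) return(empty)
  tri <- tri[, ok, drop = FALSE]
  first <- as.integer(tri[1L, ]) + as.integer(offset) - 1L
  mid <- as.integer(tri[2L, ]) + as.integer(offset) - 1L
  last <- as.integer(tri[3L, ]) + as.integer(offset) - 1L
  out <- data.frame(kind = rep(kind, ncol(tri)), start = first, end = last,
                    pos_basic = if (kind == "CARC") first else last,
                    pos_aromatic = mid,
                    pos_aliphatic = if (kind == "CARC") last else first,
                    span = last - first + 1L, stringsAsFactors = FALSE)
  out <- out[order(out$start, out$pos_aromatic, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# reduced alphabet used by the sampled equivalence sweeps
ORACLE_ALPHABET <- c("K", "R", "F", "Y", "W", "L", "V", "I", "A", "G")

randomOracleSequence <- function(max_len = 15L) {
  paste(sample(ORACLE_ALPHABET, sample.int(max_len, 1L), replace = TRUE),
        collapse = "")
}

cb1Protein <- function() {
  ext <- system.file("extdata", package = "mirrorCode")
  readProteins(file.path(ext, "CB1_P21554_synthetic.fasta"),
               file.path(ext, "CB1_P21554_tm.tsv"))[[1L]]
}

tspoProtein <- function() {
  ext <- system.file("extdata", package = "mirrorCode")
  readProteins(file.path(ext, "TSPO_TM5_synthetic.fasta"),
               file.path(ext, "TSPO_TM5_tm.tsv"))[[1L]]
}
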