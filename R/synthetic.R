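# Synthetic membrane proteins with planted motifs.  The default
# background alphabet contains no basic or aromatic residues, so no motif
# can arise by chance and plant-and-recover tests are exact; a "realistic"
# mode draws from a hydrophobic residue-frequency table instead.

.BACKGROUND_ANCHOR_FREE <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                   c("K", "R", "F", "Y", "W"))

.TM_FREQ <- c(L = 0.16, I = 0.11, V = 0.11, A = 0.10, F = 0.09, G = 0.07,
              S = 0.06, T = 0.06, M = 0.04, Y = 0.04, W = 0.03, C = 0.02,
              P = 0.02, N = 0.02, Q = 0.02, H = 0.01, K = 0.01, R = 0.01,
              D = 0.01, E = 0.01)

# run expr with a locally seeded RNG, restoring the caller's stream
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Specify a motif to plant in a synthetic protein
#'
#' @param tm_index which TM helix receives the motif.
#' @param kind `"CARC"` or `"CRAC"`.
#' @param leaflet `"outer"` or `"inner"`: the leaflet the planted motif
#'   must be assigned to when the protein is scanned.
#' @param s1,s2 spacer lengths between the first/second and second/third
#'   anchors, each in `[1, 5]`.
#' @param basic,aromatic,aliphatic anchor residues; defaults K, F (CARC) /
#'   Y (CRAC), L.
#' @return One-row `data.frame`; rows from several calls can be `rbind`ed
#'   into a plant list for [syntheticProtein()].
#' @export
plantSpec <- function(tm_index, kind = c("CARC", "CRAC"),
                      leaflet = c("outer", "inner"), s1 = 2L, s2 = 3L,
                      basic = "K",
                      aromatic = if (kind == "CARC") "F" else "Y",
                      aliphatic = "L") {
  kind <- match.arg(kind)
  leaflet <- match.arg(leaflet)
  stopifnot(s1 >= 1L, s1 <= 5L, s2 >= 1L, s2 <= 5L)
  data.frame(tm_index = as.integer(tm_index), kind = kind, leaflet = leaflet,
             s1 = as.integer(s1), s2 = as.integer(s2),
             basic = toupper(basic), aromatic = toupper(aromatic),
             aliphatic = toupper(aliphatic), stringsAsFactors = FALSE)
}

#' Draw random plant specifications
#'
#' Draws `n` plants with random TM index, kind, leaflet, spacer lengths
#' and anchor residues (from the configured classes), never assigning the
#' same kind twice to one TM.  Uses the current RNG stream; seed the
#' caller for reproducibility.
#'
#' @param n number of plants (at most `2 * nTM`).
#' @param nTM number of TM helices of the target protein.
#' @param config a [ScanConfig-class] supplying the anchor classes.
#' @return `data.frame` of plant rows as from [plantSpec()].
#' @export
randomPlantSpecs <- function(n, nTM = 7L, config = scanConfig()) {
  stopifnot(n >= 1L, n <= 2L * nTM)
  slots <- expand.grid(tm_index = seq_len(nTM), kind = .MOTIF_KINDS,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pick <- slots[sample.int(nrow(slots), n), , drop = FALSE]
  # when both kinds land on one TM they must occupy different halves, so
  # give them opposite leaflets; a lone plant gets a random leaflet
  leaf <- sample(.LEAFLETS, n, replace = TRUE)
  for (tm in unique(pick$tm_index[duplicated(pick$tm_index)])) {
    ix <- which(pick$tm_index == tm)
    leaf[ix] <- sample(.LEAFLETS)
  }
  do.call(rbind, lapply(seq_len(n), function(i) {
    kind <- pick$kind[i]
    plantSpec(pick$tm_index[i], kind,
              leaflet = leaf[i],
              s1 = sample.int(5L, 1L), s2 = sample.int(5L, 1L),
              basic = sample(config@basic, 1L),
              aromatic = sample(if (kind == "CARC") config@aromaticCarc
                                else config@aromaticCrac, 1L),
              aliphatic = sample(config@aliphatic, 1L))
  }))
}

#' Generate a synthetic membrane protein with planted motifs
#'
#' Builds `nTM` hydrophobic TM segments (20-26 residues; 26 when a TM
#' carries a plant, so any spacer combination fits its half) joined by
#' loops of 8-15 residues, then writes each requested motif into the TM
#' half corresponding to its leaflet: the basic anchor lands in the
#' half whose end faces the requested leaflet, flush against the segment
#' boundary, exactly as an interfacial (snorkeling) Lys/Arg would sit.
#'
#' @param nTM number of TM helices.
#' @param plants `data.frame` of [plantSpec()] rows (or `NULL`).
#' @param seed integer seed; the generator is deterministic given the
#'   seed and restores the caller's RNG stream.
#' @param topology N-terminus location.
#' @param id protein identifier.
#' @param background `"anchor_free"` (default: no K/R/F/Y/W anywhere, so
#'   any motif found must have been planted) or `"realistic"` (residues
#'   drawn from a hydrophobic TM frequency table).
#' @return `list(protein = MembraneProtein, plants = data.frame)` where
#'   `plants` echoes the input plus the absolute planted anchor positions
#'   (`pos_basic`, `pos_aromatic`, `pos_aliphatic`).
#' @examples
#' sp <- syntheticProtein(7, rbind(plantSpec(3, "CARC", "outer"),
#'                                 plantSpec(3, "CRAC", "inner")), seed = 1)
#' tmClassification(scanProtein(sp$protein))$status[3]  # "dual_mirror"
#' @export
syntheticProtein <- function(nTM, plants = NULL, seed = NULL,
                             topology = c("extracellular", "cytoplasmic"),
                             id = "synthetic",
                             background = c("anchor_free", "realistic")) {
  topology <- match.arg(topology)
  background <- match.arg(background)
  stopifnot(nTM >= 1L)
  if (!is.null(plants) && nrow(plants) > 0L) {
    if (any(plants$tm_index < 1L | plants$tm_index > nTM))
      stop("plant references a TM index outside 1..", nTM)
    if (anyDuplicated(plants[, c("tm_index", "kind")]))
      stop("at most one plant per kind per TM")
    if (anyDuplicated(plants[, c("tm_index", "leaflet")]))
      stop("two plants cannot fit in the same half of one TM: ",
           "same-TM plants must target opposite leaflets")
  }
  .withSeed(seed, {
    draw <- function(n) {
      if (background == "anchor_free")
        sample(.BACKGROUND_ANCHOR_FREE, n, replace = TRUE)
      else
        sample(names(.TM_FREQ), n, replace = TRUE, prob = .TM_FREQ)
    }
    planted_tm <- if (is.null(plants)) integer(0) else unique(plants$tm_index)
    tm_len <- ifelse(seq_len(nTM) %in% planted_tm, 26L,
                     sample(20:26, nTM, replace = TRUE))
    loop_len <- sample(8:15, nTM + 1L, replace = TRUE)
    pieces <- character(0)
    tm_start <- integer(nTM)
    pos <- 0L
    for (i in seq_len(nTM)) {
      pieces <- c(pieces, paste(draw(loop_len[i]), collapse = ""))
      pos <- pos + loop_len[i]
      tm_start[i] <- pos + 1L
      pieces <- c(pieces, paste(draw(tm_len[i]), collapse = ""))
      pos <- pos + tm_len[i]
    }
    pieces <- c(pieces, paste(draw(loop_len[nTM + 1L]), collapse = ""))
    chars <- strsplit(paste(pieces, collapse = ""), "", fixed = TRUE)[[1]]
    tm_end <- tm_start + tm_len - 1L
    oriented <- orientTMs(topology, data.frame(index = seq_len(nTM),
                                               start = tm_start, end = tm_end))
    truth <- NULL
    if (!is.null(plants) && nrow(plants) > 0L) {
      truth <- plants
      truth$pos_basic <- truth$pos_aromatic <- truth$pos_aliphatic <- NA_integer_
      for (i in seq_len(nrow(plants))) {
        p <- plants[i, ]
        tm <- oriented[oriented$index == p$tm_index, ]
        len <- 3L + p$s1 + p$s2
        half_len <- ((tm$start + tm$end) %/% 2L) - tm$start + 1L
        if (len > half_len)
          stop(sprintf("plant of length %d cannot fit in one half (%d) of TM%d",
                       len, half_len, p$tm_index))
        n_half <- tm$n_end_faces == p$leaflet
        motif_start <- if (n_half) tm$start else tm$end - len + 1L
        a1 <- motif_start
        a2 <- motif_start + p$s1 + 1L
        a3 <- motif_start + p$s1 + p$s2 + 2L
        if (p$kind == "CARC") {
          res <- c(p$basic, p$aromatic, p$aliphatic)
          truth$pos_basic[i] <- a1; truth$pos_aromatic[i] <- a2
          truth$pos_aliphatic[i] <- a3
        } else {
          res <- c(p$aliphatic, p$aromatic, p$basic)
          truth$pos_aliphatic[i] <- a1; truth$pos_aromatic[i] <- a2
          truth$pos_basic[i] <- a3
        }
        chars[c(a1, a2, a3)] <- res
      }
    }
    prot <- membraneProtein(id, paste(chars, collapse = ""), topology,
                            tmStart = tm_start, tmEnd = tm_end)
    list(protein = prot, plants = truth)
  })
}

#' Empirical motif frequency under composition-preserving shuffling
#'
#' Shuffles the sequence `nShuffles` times (each shuffle a uniform random
#' permutation, preserving the residue multiset) and returns the fraction
#' of shuffles containing at least one motif of the requested kind.
#'
#' @param sequence residue string.
#' @param kind `"CARC"` or `"CRAC"`.
#' @param nShuffles number of shuffles (>= 1).
#' @param seed integer seed (local to this call).
#' @param config a [ScanConfig-class].
#' @return Fraction in `[0, 1]`.
#' @export
shuffleNull <- function(sequence, kind = c("CARC", "CRAC"), nShuffles = 100L,
                        seed = NULL, config = scanConfig()) {
  kind <- match.arg(kind)
  stopifnot(nShuffles >= 1L)
  chars <- strsplit(.normalizeSeq(sequence), "", fixed = TRUE)[[1]]
  .withSeed(seed, {
    hits <- vapply(seq_len(nShuffles), function(i) {
      s <- paste(sample(chars), collapse = "")
      nrow(enumerateMotifs(s, kind, config = config)) > 0L
    }, logical(1L))
    mean(hits)
  })
}

#' Write a set of synthetic proteins as FASTA + TM annotation table
#'
#' @param proteins list of [MembraneProtein-class] objects.
#' @param fasta,tmFile output paths.
#' @return Invisibly, a list with the two paths.
#' @export
writeSyntheticSet <- function(proteins, fasta, tmFile) {
  stopifnot(length(proteins) > 0L)
  seqs <- Biostrings::AAStringSet(vapply(proteins, proteinSeq, character(1L)))
  names(seqs) <- vapply(proteins, proteinId, character(1L))
  Biostrings::writeXStringSet(seqs, fasta)
  tab <- do.call(rbind, lapply(proteins, function(p) {
    segs <- tmSegments(p)
    if (nrow(segs) == 0L) return(NULL)
    data.frame(protein_id = proteinId(p), tm_index = segs$index,
               start = segs$start, end = segs$end,
               topology = nTermSide(p), stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, tmFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fasta, tmFile = tmFile))
}
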