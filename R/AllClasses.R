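#' @import methods
#' @importFrom Biostrings AAString AAStringSet readAAStringSet writeXStringSet
#' @importFrom IRanges IRanges
NULL

.LEAFLETS <- c("outer", "inner")
.TOPOLOGIES <- c("extracellular", "cytoplasmic")
.MOTIF_KINDS <- c("CARC", "CRAC")
.TM_STATUS <- c("dual_mirror", "carc_only", "crac_only", "none")

#' Scan configuration for CARC/CRAC motif detection
#'
#' Holds the residue-class grammar shared by both motif kinds and the
#' pipeline knobs.  CARC reads basic -> aromatic -> aliphatic in the N- to
#' C-terminal direction; CRAC reads aliphatic -> aromatic -> basic.  The
#' aromatic class differs between the two kinds: CARC tolerates Phe, Tyr
#' and Trp while CRAC tolerates Tyr and Phe (Tyr only in strict mode).
#' Spacer residues between anchors are completely unconstrained; only
#' anchor positions are class-checked.
#'
#' @slot basic basic anchor residues (default K, R).
#' @slot aromaticCarc aromatic anchors accepted by CARC (default F, Y, W).
#' @slot aromaticCrac aromatic anchors accepted by CRAC (default Y, F; Y
#'   only when `strictCrac = TRUE`).
#' @slot aliphatic aliphatic anchors (default L, V; plus I when
#'   `allowIle = TRUE`).
#' @slot spacerMin,spacerMax bounds on the number of unconstrained spacer
#'   residues between consecutive anchors (defaults 1 and 5).
#' @slot window how many residues beyond an annotated transmembrane
#'   boundary to search for an interfacial Lys/Arg when extending the
#'   segment (default 2 per side).
#' @slot maximalOnly if `TRUE` (default) scan reports keep only the maximal
#'   representative of each overlap cluster; if `FALSE` every enumerated
#'   match is kept, with the representative flagged.
#'
#' @seealso [scanConfig()]
#' @export
setClass("ScanConfig", representation(
  basic = "character",
  aromaticCarc = "character",
  aromaticCrac = "character",
  aliphatic = "character",
  spacerMin = "integer",
  spacerMax = "integer",
  window = "integer",
  maximalOnly = "logical"
))

setValidity("ScanConfig", function(object) {
  msg <- character(0)
  all_sets <- list(basic = object@basic, aliphatic = object@aliphatic,
                   aromaticCarc = object@aromaticCarc,
                   aromaticCrac = object@aromaticCrac)
  for (nm in names(all_sets)) {
    s <- all_sets[[nm]]
    if (length(s) == 0L || !all(s %in% LETTERS))
      msg <- c(msg, sprintf("%s must be a non-empty set of one-letter codes", nm))
  }
  # within one pattern evaluation the three anchor classes must not overlap
  for (arom in c("aromaticCarc", "aromaticCrac")) {
    cls <- c(object@basic, all_sets[[arom]], object@aliphatic)
    if (anyDuplicated(cls))
      msg <- c(msg, sprintf("basic, %s and aliphatic sets must be pairwise disjoint", arom))
  }
  if (length(object@spacerMin) != 1L || length(object@spacerMax) != 1L ||
      is.na(object@spacerMin) || is.na(object@spacerMax) ||
      object@spacerMin < 1L || object@spacerMin > object@spacerMax)
    msg <- c(msg, "spacer bounds must satisfy 1 <= spacerMin <= spacerMax")
  if (length(object@window) != 1L || is.na(object@window) || object@window < 0L)
    msg <- c(msg, "window must be a single non-negative integer")
  if (length(object@maximalOnly) != 1L || is.na(object@maximalOnly))
    msg <- c(msg, "maximalOnly must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Create a scan configuration
#'
#' @param allowIle logical; admit Ile as an aliphatic anchor in addition to
#'   Leu/Val.  Off by default: the consensus as usually written is (L/V),
#'   although branched Ile side chains accommodate the methyl groups of
#'   cholesterol equally well and at least one published motif is anchored
#'   on an Ile.
#' @param strictCrac logical; restrict the CRAC aromatic class to Tyr (the
#'   original literal consensus).  The default relaxed class Y/F is
#'   required to reproduce the CB1 TM3 worked example, whose CRAC motif
#'   contains no Tyr.
#' @param window integer, residues searched beyond each annotated TM
#'   boundary for an interfacial Lys/Arg (see [extendTM()]).  Default 2,
#'   the distance used in the CB1 TM3 worked example (188-212 extended to
#'   186-214).
#' @param spacerMin,spacerMax integer bounds for the X(1-5) spacers.
#' @param maximalOnly logical; keep only maximal overlap-cluster
#'   representatives in scan reports.
#' @param basic,aromaticCarc,aromaticCrac,aliphatic explicit residue-class
#'   overrides (one-letter codes); normally left at their defaults.
#' @return A validated [ScanConfig-class] object.
#' @examples
#' scanConfig()
#' scanConfig(allowIle = TRUE, window = 5)
#' @export
scanConfig <- function(allowIle = FALSE, strictCrac = FALSE, window = 2L,
                       spacerMin = 1L, spacerMax = 5L, maximalOnly = TRUE,
                       basic = c("K", "R"),
                       aromaticCarc = c("F", "Y", "W"),
                       aromaticCrac = if (strictCrac) "Y" else c("Y", "F"),
                       aliphatic = if (allowIle) c("L", "V", "I") else c("L", "V")) {
  new("ScanConfig",
      basic = toupper(basic),
      aromaticCarc = toupper(aromaticCarc),
      aromaticCrac = toupper(aromaticCrac),
      aliphatic = toupper(aliphatic),
      spacerMin = as.integer(spacerMin), spacerMax = as.integer(spacerMax),
      window = as.integer(window), maximalOnly = maximalOnly)
}

setMethod("show", "ScanConfig", function(object) {
  cat("ScanConfig\n",
      "  basic:          ", paste(object@basic, collapse = ","), "\n",
      "  aromatic (CARC):", paste(object@aromaticCarc, collapse = ","), "\n",
      "  aromatic (CRAC):", paste(object@aromaticCrac, collapse = ","), "\n",
      "  aliphatic:      ", paste(object@aliphatic, collapse = ","), "\n",
      "  spacers:        ", object@spacerMin, "-", object@spacerMax, "\n",
      "  extension window:", object@window, "residue(s) per side\n",
      "  maximal only:   ", object@maximalOnly, "\n", sep = " ")
  invisible(object)
})

#' Membrane protein with transmembrane annotation
#'
#' Couples a protein sequence with its annotated transmembrane (TM)
#' segments and the side of the membrane faced by the N-terminus, which
#' together determine the orientation of every TM helix and hence the
#' leaflet assignment of any motif found in it.
#'
#' @slot id accession or free-text identifier.
#' @slot seq an [Biostrings::AAString] (uppercased on construction).
#' @slot topology `"extracellular"` or `"cytoplasmic"`: location of the
#'   N-terminus.
#' @slot tm an [IRanges::IRanges] of TM segments, sorted and
#'   non-overlapping, with names giving the TM index along the sequence.
#' @seealso [membraneProtein()], [scanProtein()]
#' @export
setClass("MembraneProtein", representation(
  id = "character",
  seq = "AAString",
  topology = "character",
  tm = "IRanges"
))

setValidity("MembraneProtein", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "id must be a single non-empty string")
  if (length(object@topology) != 1L || !object@topology %in% .TOPOLOGIES)
    msg <- c(msg, sprintf("topology must be one of: %s",
                          paste(.TOPOLOGIES, collapse = ", ")))
  tm <- object@tm
  n <- length(tm)
  if (n > 0L) {
    st <- IRanges::start(tm); en <- IRanges::end(tm)
    if (any(st >= en))
      msg <- c(msg, "each TM segment must satisfy start < end")
    if (any(st < 1L) || any(en > length(object@seq)))
      msg <- c(msg, "TM segments must lie within the sequence")
    if (is.unsorted(st, strictly = TRUE))
      msg <- c(msg, "TM segments must be sorted by start")
    if (n > 1L && any(st[-1L] <= en[-n]))
      msg <- c(msg, "TM segments must not overlap")
    idx <- suppressWarnings(as.integer(names(tm)))
    if (is.null(names(tm)) || anyNA(idx) || any(idx < 1L) ||
        anyDuplicated(idx) || is.unsorted(idx, strictly = TRUE))
      msg <- c(msg, "TM indices must be unique increasing positive integers")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MembraneProtein
#'
#' @param id protein identifier (accession or free text).
#' @param seq amino-acid sequence: a string or an
#'   [Biostrings::AAString].  Whitespace and gap characters are stripped
#'   and the sequence is uppercased.
#' @param topology `"extracellular"` or `"cytoplasmic"` location of the
#'   N-terminus (type I vs type II single-pass convention; for a GPCR the
#'   N-terminus is extracellular).
#' @param tmStart,tmEnd integer vectors of 1-based inclusive TM segment
#'   boundaries.
#' @param tmIndex TM indices (defaults to 1, 2, ... in order along the
#'   sequence).  Indices determine orientation parity, so a protein
#'   annotated only at, say, TM5 may be given `tmIndex = 5`.
#' @return A validated [MembraneProtein-class].
#' @examples
#' p <- membraneProtein("toy", "GGGKACFWIALGGG", "extracellular",
#'                      tmStart = 4, tmEnd = 11)
#' p
#' @export
membraneProtein <- function(id, seq, topology = c("extracellular", "cytoplasmic"),
                            tmStart = integer(0), tmEnd = integer(0),
                            tmIndex = seq_along(tmStart)) {
  topology <- match.arg(topology)
  if (length(tmStart) != length(tmEnd))
    stop("tmStart and tmEnd must have the same length")
  seq <- .normalizeSeq(seq)
  ord <- order(as.integer(tmStart))
  tm <- IRanges::IRanges(start = as.integer(tmStart)[ord],
                         end = as.integer(tmEnd)[ord],
                         names = as.character(as.integer(tmIndex)[ord]))
  new("MembraneProtein", id = as.character(id), seq = Biostrings::AAString(seq),
      topology = topology, tm = tm)
}

# strip whitespace/gaps, uppercase; accepts character or AAString
.normalizeSeq <- function(seq) {
  s <- toupper(gsub("[-.* \t\r\n]", "", as.character(seq)))
  if (!nzchar(s)) stop("sequence is empty after normalization")
  s
}

setMethod("show", "MembraneProtein", function(object) {
  cat("MembraneProtein:", object@id, "\n")
  cat("  length:  ", length(object@seq), "aa\n")
  cat("  N-terminus:", object@topology, "\n")
  cat("  TM segments:", length(object@tm), "\n")
  if (length(object@tm) > 0L) {
    df <- tmSegments(object)
    for (i in seq_len(nrow(df)))
      cat(sprintf("    TM%-2d %d-%d\n", df$index[i], df$start[i], df$end[i]))
  }
  invisible(object)
})

#' Per-protein motif scan report
#'
#' Result container of [scanProtein()]: the flat motif table, the per-TM
#' classification and the summary counts.
#'
#' @slot proteinId scanned protein identifier.
#' @slot motifs `data.frame` with one motif per row: `tm_index`, `kind`,
#'   `start`, `end`, `pos_basic`, `pos_aromatic`, `pos_aliphatic`, `span`,
#'   `leaflet`, `maximal` (all coordinates 1-based inclusive).
#' @slot tmClass `data.frame` with one TM per row: `tm_index`, `start`,
#'   `end`, `extended_start`, `extended_end`, `n_end_faces`, `status`
#'   (`dual_mirror`, `carc_only`, `crac_only` or `none`) and
#'   `distant_pair` (both motif kinds present but their basic anchors in
#'   the same half, a configuration reported separately from the true
#'   mirror arrangement).
#' @slot counts named integer vector `n_dual`, `n_carc_only`,
#'   `n_crac_only`, `n_none`; sums to the number of TMs.
#' @seealso [scanProtein()], [writeReport()]
#' @export
setClass("ScanReport", representation(
  proteinId = "character",
  motifs = "data.frame",
  tmClass = "data.frame",
  counts = "integer"
))

setValidity("ScanReport", function(object) {
  msg <- character(0)
  need <- c("tm_index", "kind", "start", "end", "pos_basic", "pos_aromatic",
            "pos_aliphatic", "span", "leaflet", "maximal")
  if (!all(need %in% names(object@motifs)))
    msg <- c(msg, "motifs table lacks required columns")
  needc <- c("tm_index", "start", "end", "extended_start", "extended_end",
             "n_end_faces", "status", "distant_pair")
  if (!all(needc %in% names(object@tmClass)))
    msg <- c(msg, "tmClass table lacks required columns")
  if (!identical(names(object@counts),
                 c("n_dual", "n_carc_only", "n_crac_only", "n_none")))
    msg <- c(msg, "counts must be named n_dual, n_carc_only, n_crac_only, n_none")
  else if (sum(object@counts) != nrow(object@tmClass))
    msg <- c(msg, "summary counts must sum to the number of TMs")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ScanReport", function(object) {
  cat("ScanReport:", object@proteinId, "\n")
  cat(sprintf("  %d TM domain(s): %d dual-mirror, %d CARC-only, %d CRAC-only, %d without motif\n",
              nrow(object@tmClass), object@counts[["n_dual"]],
              object@counts[["n_carc_only"]], object@counts[["n_crac_only"]],
              object@counts[["n_none"]]))
  if (nrow(object@motifs) > 0L) {
    cat("  motifs:\n")
    m <- object@motifs
    for (i in seq_len(nrow(m)))
      cat(sprintf("    TM%-2d %s %d-%d (%s/%s/%s at %d/%d/%d) leaflet=%s%s\n",
                  m$tm_index[i], m$kind[i], m$start[i], m$end[i],
                  "basic", "aromatic", "aliphatic",
                  m$pos_basic[i], m$pos_aromatic[i], m$pos_aliphatic[i],
                  m$leaflet[i], if (m$maximal[i]) "" else " (non-maximal)"))
  }
  invisible(object)
})

#' @describeIn MembraneProtein-class protein identifier
#' @param object a `MembraneProtein` or `ScanReport`
#' @export
setGeneric("proteinId", function(object) standardGeneric("proteinId"))

#' @export
setMethod("proteinId", "MembraneProtein", function(object) object@id)

#' @export
setMethod("proteinId", "ScanReport", function(object) object@proteinId)

#' TM segment table of a MembraneProtein
#'
#' @param object a [MembraneProtein-class]
#' @return `data.frame` with columns `index`, `start`, `end`.
#' @export
setGeneric("tmSegments", function(object) standardGeneric("tmSegments"))

#' @export
setMethod("tmSegments", "MembraneProtein", function(object) {
  data.frame(index = as.integer(names(object@tm)),
             start = IRanges::start(object@tm),
             end = IRanges::end(object@tm))
})

#' Protein sequence as a character string
#' @param object a [MembraneProtein-class]
#' @export
setGeneric("proteinSeq", function(object) standardGeneric("proteinSeq"))

#' @export
setMethod("proteinSeq", "MembraneProtein", function(object) as.character(object@seq))

#' N-terminus location of a MembraneProtein
#' @param object a [MembraneProtein-class]
#' @export
setGeneric("nTermSide", function(object) standardGeneric("nTermSide"))

#' @export
setMethod("nTermSide", "MembraneProtein", function(object) object@topology)

#' Motif table of a ScanReport
#' @param object a [ScanReport-class]
#' @export
setGeneric("motifs", function(object) standardGeneric("motifs"))

#' @export
setMethod("motifs", "ScanReport", function(object) object@motifs)

#' Per-TM classification table of a ScanReport
#' @param object a [ScanReport-class]
#' @export
setGeneric("tmClassification", function(object) standardGeneric("tmClassification"))

#' @export
setMethod("tmClassification", "ScanReport", function(object) object@tmClass)

#' Summary counts of a ScanReport
#' @param object a [ScanReport-class]
#' @export
setGeneric("summaryCounts", function(object) standardGeneric("summaryCounts"))

#' @export
setMethod("summaryCounts", "ScanReport", function(object) object@counts)
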