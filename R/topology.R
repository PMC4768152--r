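# Membrane topology: which end of each TM helix faces the extracellular
# milieu.  For an extracellular N-terminus, odd-numbered TM helices run
# outside -> inside (N-end faces the outer leaflet) and even-numbered ones
# inside -> outside; a cytoplasmic N-terminus reverses the parity.  The
# vectorial CARC/CRAC grammars then place the basic anchor of each motif
# at the aqueous interface of its leaflet (Lys/Arg snorkeling).

#' Orient TM segments with respect to the membrane
#'
#' @param topology `"extracellular"` or `"cytoplasmic"`: location of the
#'   protein N-terminus.
#' @param segments `data.frame` with columns `index`, `start`, `end`
#'   (sorted, non-overlapping), as returned by [tmSegments()].
#' @return The same table with a column `n_end_faces` (`"outer"` or
#'   `"inner"`): the leaflet faced by the N-terminal end of each helix.
#'   Empty input yields an empty result.
#' @examples
#' segs <- data.frame(index = 1:7, start = seq(10, 250, 40),
#'                    end = seq(30, 270, 40))
#' orientTMs("extracellular", segs)  # TM1,3,5,7 outer; TM2,4,6 inner
#' @export
orientTMs <- function(topology = c("extracellular", "cytoplasmic"), segments) {
  topology <- match.arg(topology)
  stopifnot(is.data.frame(segments),
            all(c("index", "start", "end") %in% names(segments)))
  out <- segments
  if (nrow(out) == 0L) {
    out$n_end_faces <- character(0)
    return(out)
  }
  odd_out <- topology == "extracellular"
  odd <- out$index %% 2L == 1L
  out$n_end_faces <- ifelse(odd == odd_out, "outer", "inner")
  out
}

#' Extend a TM segment to interfacial basic residues
#'
#' Charged residues lining a TM helix are often left out of database TM
#' annotations even though they sit at the apolar-polar interface.  This
#' looks up to `window` residues beyond each annotated boundary for a
#' Lys/Arg and, if found, moves the boundary to the outermost one.  The
#' extension never crosses into a neighbouring annotated TM segment
#' (clipped at neighbour boundary - 1) nor beyond the sequence.
#'
#' @param sequence full protein sequence (string).
#' @param start,end annotated TM boundaries (1-based inclusive).
#' @param window non-negative integer search distance per side; `window =
#'   0` reproduces the annotated boundaries.
#' @param prevEnd end of the preceding TM segment (or `0L` if none).
#' @param nextStart start of the following TM segment (or `NA` if none).
#' @param basic residue codes treated as basic (default K, R).
#' @return Integer vector `c(extended_start, extended_end)`.
#' @examples
#' s <- paste(rep("A", 220), collapse = "")
#' substr(s, 186, 186) <- "R"; substr(s, 214, 214) <- "R"
#' extendTM(s, 188, 212, window = 2)  # c(186, 214)
#' @export
extendTM <- function(sequence, start, end, window = 2L,
                     prevEnd = 0L, nextStart = NA_integer_,
                     basic = c("K", "R")) {
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  start <- as.integer(start); end <- as.integer(end); window <- as.integer(window)
  if (window < 0L) stop("window must be >= 0")
  if (start < 1L || end > n || start >= end)
    stop(sprintf("TM segment %d-%d outside sequence of length %d", start, end, n))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  lo <- max(1L, start - window, as.integer(prevEnd) + 1L)
  ext_start <- start
  if (lo < start) {
    hit <- which(chars[lo:(start - 1L)] %in% basic)
    if (length(hit)) ext_start <- lo + hit[1L] - 1L  # outermost = farthest upstream
  }
  hi <- min(n, end + window, if (is.na(nextStart)) n else as.integer(nextStart) - 1L)
  ext_end <- end
  if (hi > end) {
    hit <- which(chars[(end + 1L):hi] %in% basic)
    if (length(hit)) ext_end <- end + hit[length(hit)]  # outermost = farthest downstream
  }
  c(extended_start = ext_start, extended_end = ext_end)
}

#' Assign a motif to a membrane leaflet
#'
#' The basic anchor of a motif faces the aqueous phase, so the motif
#' belongs to the leaflet of the TM half that contains its basic residue.
#' The extended segment is split at the integer midpoint
#' `floor((extended_start + extended_end) / 2)`; an anchor at or before
#' the midpoint is in the N-terminal half.  The half is then resolved to
#' `"outer"`/`"inner"` through the helix orientation.
#'
#' @param match one motif row (as from [enumerateMotifs()]); the match
#'   must lie within the extended segment.
#' @param extendedStart,extendedEnd extended TM boundaries.
#' @param nEndFaces leaflet faced by the helix N-end (`"outer"` or
#'   `"inner"`, from [orientTMs()]).
#' @return `"outer"` or `"inner"`.
#' @export
assignLeaflet <- function(match, extendedStart, extendedEnd, nEndFaces) {
  stopifnot(nEndFaces %in% .LEAFLETS)
  if (match$start < extendedStart || match$end > extendedEnd)
    stop(sprintf("motif %d-%d lies outside the extended TM %d-%d",
                 match$start, match$end, extendedStart, extendedEnd))
  mid <- (as.integer(extendedStart) + as.integer(extendedEnd)) %/% 2L
  n_half <- match$pos_basic <= mid
  if (n_half) nEndFaces else setdiff(.LEAFLETS, nEndFaces)
}

#' Classify a TM domain from its leaflet-assigned motifs
#'
#' A TM carrying at least one CARC and one CRAC in opposite leaflets is a
#' `dual_mirror` domain: it can accommodate two tail-to-tail cholesterol
#' molecules, one per leaflet.  A single kind gives `carc_only` /
#' `crac_only`; no motif gives `none`.  Both kinds in the same leaflet is
#' not a mirror arrangement; such domains are classified `none` but
#' flagged `distant_pair` so they are not silently dropped.
#'
#' @param carcLeaflets,cracLeaflets character vectors of leaflet labels of
#'   the (maximal) CARC and CRAC motifs of the TM.
#' @return `list(status = ..., distant_pair = logical)`.
#' @export
classifyTM <- function(carcLeaflets, cracLeaflets) {
  stopifnot(all(carcLeaflets %in% .LEAFLETS), all(cracLeaflets %in% .LEAFLETS))
  has_carc <- length(carcLeaflets) > 0L
  has_crac <- length(cracLeaflets) > 0L
  if (has_carc && has_crac) {
    opposite <- any(outer(carcLeaflets, cracLeaflets, FUN = "!="))
    if (opposite) return(list(status = "dual_mirror", distant_pair = FALSE))
    return(list(status = "none", distant_pair = TRUE))
  }
  if (has_carc) return(list(status = "carc_only", distant_pair = FALSE))
  if (has_crac) return(list(status = "crac_only", distant_pair = FALSE))
  list(status = "none", distant_pair = FALSE)
}
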