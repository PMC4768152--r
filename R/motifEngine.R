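# Core grammar: a motif is an anchor triad read N->C.
#   CARC: basic (K/R)  -> aromatic (F/Y/W) -> aliphatic (L/V)
#   CRAC: aliphatic (L/V) -> aromatic (Y/F) -> basic (K/R)
# with spacerMin..spacerMax unconstrained residues between consecutive
# anchors.  Both algorithms are vectorial: reversing a sequence maps one
# kind onto the other.

# role sets in N->C order for a kind
.roleOrder <- function(kind) {
  if (kind == "CARC") c("basic", "aromatic", "aliphatic")
  else c("aliphatic", "aromatic", "basic")
}

.roleSet <- function(role, kind, config) {
  switch(role,
         basic = config@basic,
         aliphatic = config@aliphatic,
         aromatic = if (kind == "CARC") config@aromaticCarc else config@aromaticCrac,
         stop("unknown anchor role: ", role))
}

#' Test residue membership in an anchor class
#'
#' @param code one-letter residue code (case-insensitive).
#' @param role `"basic"`, `"aromatic"` or `"aliphatic"`.
#' @param kind `"CARC"` or `"CRAC"`; the aromatic class differs between
#'   the two (Trp is admitted by CARC only).
#' @param config a [ScanConfig-class].
#' @return `TRUE` iff `code` belongs to the role's residue class for that
#'   motif kind.  Characters outside the 20 standard residues (including
#'   ambiguity codes X/B/Z/U) are never anchors.
#' @examples
#' classifyResidue("K", "basic", "CARC")              # TRUE
#' classifyResidue("W", "aromatic", "CARC")           # TRUE
#' classifyResidue("W", "aromatic", "CRAC")           # FALSE
#' @export
classifyResidue <- function(code, role, kind = c("CARC", "CRAC"),
                            config = scanConfig()) {
  kind <- match.arg(kind)
  if (length(role) != 1L || !role %in% c("basic", "aromatic", "aliphatic"))
    stop("unknown anchor role: ", paste(role, collapse = ","))
  toupper(as.character(code)) %in% .roleSet(role, kind, config)
}

.emptyMatches <- function(kind = character(0)) {
  data.frame(kind = as.character(kind)[0], start = integer(0), end = integer(0),
             pos_basic = integer(0), pos_aromatic = integer(0),
             pos_aliphatic = integer(0), span = integer(0),
             stringsAsFactors = FALSE)
}

#' Enumerate all CARC or CRAC matches in a sequence
#'
#' Exhaustive: every anchor triad satisfying the grammar is returned, and
#' overlapping triads are all reported.  Use [selectMaximal()] to reduce
#' each overlap cluster to its largest representative.
#'
#' @param sequence residue string (whitespace/gaps stripped, uppercased).
#' @param kind `"CARC"` or `"CRAC"`.
#' @param offset coordinate of the first residue of `sequence` (1-based);
#'   all reported coordinates are offset-based 1-based inclusive, so a
#'   peptide excised from a larger protein keeps its native numbering.
#' @param config a [ScanConfig-class].
#' @return `data.frame` with one triad per row, ordered by `start`, then
#'   `pos_aromatic`, then `end`; columns `kind`, `start`, `end`,
#'   `pos_basic`, `pos_aromatic`, `pos_aliphatic`, `span`.  An empty
#'   sequence yields zero rows.
#' @examples
#' ## the prototype AChR gamma-TM4 CARC motif
#' enumerateMotifs("RVCFLAML", "CARC", offset = 455)
#' @export
enumerateMotifs <- function(sequence, kind = c("CARC", "CRAC"), offset = 1L,
                            config = scanConfig()) {
  kind <- match.arg(kind)
  offset <- as.integer(offset)
  if (length(offset) != 1L || is.na(offset) || offset < 1L)
    stop("offset must be a single integer >= 1")
  s <- toupper(gsub("[-.* \t\r\n]", "", as.character(sequence)))
  if (!nzchar(s)) return(.emptyMatches())
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  roles <- .roleOrder(kind)
  p1 <- which(chars %in% .roleSet(roles[1L], kind, config))
  p2 <- which(chars %in% .roleSet(roles[2L], kind, config))
  p3 <- which(chars %in% .roleSet(roles[3L], kind, config))
  if (!length(p1) || !length(p2) || !length(p3)) return(.emptyMatches())
  smin <- config@spacerMin; smax <- config@spacerMax
  # valid (first, mid) pairs: spacer = mid - first - 1 in [smin, smax]
  g12 <- expand.grid(a = p1, b = p2, KEEP.OUT.ATTRS = FALSE)
  g12 <- g12[g12$b - g12$a - 1L >= smin & g12$b - g12$a - 1L <= smax, , drop = FALSE]
  g23 <- expand.grid(b = p2, c = p3, KEEP.OUT.ATTRS = FALSE)
  g23 <- g23[g23$c - g23$b - 1L >= smin & g23$c - g23$b - 1L <= smax, , drop = FALSE]
  if (!nrow(g12) || !nrow(g23)) return(.emptyMatches())
  tri <- merge(g12, g23, by = "b")
  if (!nrow(tri)) return(.emptyMatches())
  first <- tri$a + offset - 1L
  mid <- tri$b + offset - 1L
  last <- tri$c + offset - 1L
  out <- data.frame(
    kind = rep(kind, nrow(tri)),
    start = first, end = last,
    pos_basic = if (kind == "CARC") first else last,
    pos_aromatic = mid,
    pos_aliphatic = if (kind == "CARC") last else first,
    stringsAsFactors = FALSE)
  out$span <- out$end - out$start + 1L
  out <- out[order(out$start, out$pos_aromatic, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# cluster ids for matches sharing >= 1 residue (input sorted by start)
.overlapClusters <- function(start, end) {
  if (length(start) == 0L) return(integer(0))
  run_end <- cummax(end)
  breaks <- c(FALSE, start[-1L] > run_end[-length(run_end)])
  cumsum(breaks) + 1L
}

#' Reduce overlapping matches to maximal representatives
#'
#' Partitions matches of one kind into overlap clusters (triads sharing at
#' least one residue, transitively) and keeps from each cluster the single
#' triad with the greatest span.  Ties are broken by smallest start, then
#' smallest aromatic position, making the selection deterministic.  When
#' several overlapping motifs are present "the largest possible sequence"
#' is thereby selected.
#'
#' @param matches a `data.frame` as returned by [enumerateMotifs()]; all
#'   rows must share one kind and one coordinate frame.
#' @return The representative rows, ordered by start, with row names
#'   dropped.
#' @examples
#' m <- enumerateMotifs("RNVFLFKLGGV", "CARC", offset = 186)
#' selectMaximal(m)  # single representative spanning 186-196
#' @export
selectMaximal <- function(matches) {
  if (!is.data.frame(matches))
    stop("matches must be a data.frame from enumerateMotifs()")
  if (nrow(matches) == 0L) return(matches)
  if (length(unique(matches$kind)) > 1L)
    stop("mixed motif kinds: selectMaximal() operates within one kind")
  m <- matches[order(matches$start, matches$pos_aromatic, matches$end), , drop = FALSE]
  cl <- .overlapClusters(m$start, m$end)
  keep <- unlist(lapply(split(seq_len(nrow(m)), cl), function(ix) {
    sub <- m[ix, , drop = FALSE]
    o <- order(-sub$span, sub$start, sub$pos_aromatic)
    ix[o[1L]]
  }), use.names = FALSE)
  out <- m[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# recheck a match table character-by-character against the grammar
.revalidateMatches <- function(matches, sequence, offset, config) {
  if (nrow(matches) == 0L) return(TRUE)
  chars <- strsplit(toupper(as.character(sequence)), "", fixed = TRUE)[[1]]
  at <- function(pos) chars[pos - offset + 1L]
  ok <- vapply(seq_len(nrow(matches)), function(i) {
    m <- matches[i, ]
    anchors <- sort(c(m$pos_basic, m$pos_aromatic, m$pos_aliphatic))
    sp <- diff(anchors) - 1L
    all(sp >= config@spacerMin & sp <= config@spacerMax) &&
      m$start == anchors[1L] && m$end == anchors[3L] &&
      m$span == m$end - m$start + 1L &&
      classifyResidue(at(m$pos_basic), "basic", m$kind, config) &&
      classifyResidue(at(m$pos_aromatic), "aromatic", m$kind, config) &&
      classifyResidue(at(m$pos_aliphatic), "aliphatic", m$kind, config) &&
      (if (m$kind == "CARC") m$pos_basic < m$pos_aromatic && m$pos_aromatic < m$pos_aliphatic
       else m$pos_aliphatic < m$pos_aromatic && m$pos_aromatic < m$pos_basic)
  }, logical(1L))
  all(ok)
}
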