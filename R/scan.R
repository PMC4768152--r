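#' Scan a membrane protein for CARC/CRAC motifs
#'
#' Runs the full per-TM pipeline: orient each annotated TM helix from the
#' protein topology, extend its boundaries to interfacial Lys/Arg
#' residues, enumerate all CARC and CRAC triads within the extended
#' segment, reduce each overlap cluster to its maximal representative,
#' assign every motif to a membrane leaflet via its basic anchor, and
#' classify the TM as dual-mirror, CARC-only, CRAC-only or motif-free.
#'
#' @param protein a [MembraneProtein-class].
#' @param config a [ScanConfig-class]; with `maximalOnly = FALSE` the
#'   motif table retains every enumerated triad (maximal representatives
#'   flagged), which is useful for auditing overlap clusters.
#' @return A [ScanReport-class].
#' @examples
#' p <- membraneProtein("toy", "GGRNVFLFKLGGVTASFTASVGSLFLTAIDRGG",
#'                      "extracellular", tmStart = 5, tmEnd = 29)
#' scanProtein(p)
#' @export
scanProtein <- function(protein, config = scanConfig()) {
  stopifnot(is(protein, "MembraneProtein"), is(config, "ScanConfig"))
  seq <- proteinSeq(protein)
  segs <- tmSegments(protein)
  oriented <- orientTMs(nTermSide(protein), segs)
  motif_rows <- list()
  tm_rows <- list()
  for (i in seq_len(nrow(oriented))) {
    tm <- oriented[i, ]
    ext <- extendTM(seq, tm$start, tm$end, window = config@window,
                    prevEnd = if (i > 1L) oriented$end[i - 1L] else 0L,
                    nextStart = if (i < nrow(oriented)) oriented$start[i + 1L] else NA_integer_,
                    basic = config@basic)
    es <- ext[["extended_start"]]; ee <- ext[["extended_end"]]
    sub <- substr(seq, es, ee)
    per_kind <- lapply(.MOTIF_KINDS, function(kind) {
      m <- enumerateMotifs(sub, kind, offset = es, config = config)
      if (nrow(m) == 0L) {
        m$maximal <- logical(0)
        return(m)
      }
      reps <- selectMaximal(m)
      key <- function(x) paste(x$pos_basic, x$pos_aromatic, x$pos_aliphatic)
      m$maximal <- key(m) %in% key(reps)
      m
    })
    both <- do.call(rbind, per_kind)
    if (nrow(both) > 0L) {
      both$leaflet <- vapply(seq_len(nrow(both)), function(j)
        assignLeaflet(both[j, ], es, ee, tm$n_end_faces), character(1L))
      both$tm_index <- tm$index
    } else {
      both$leaflet <- character(0)
      both$tm_index <- integer(0)
    }
    # classification uses the maximal representatives of each kind
    reps <- both[both$maximal, , drop = FALSE]
    cls <- classifyTM(reps$leaflet[reps$kind == "CARC"],
                      reps$leaflet[reps$kind == "CRAC"])
    if (config@maximalOnly) both <- reps
    motif_rows[[length(motif_rows) + 1L]] <- both
    tm_rows[[length(tm_rows) + 1L]] <- data.frame(
      tm_index = tm$index, start = tm$start, end = tm$end,
      extended_start = unname(es), extended_end = unname(ee),
      n_end_faces = tm$n_end_faces, status = cls$status,
      distant_pair = cls$distant_pair, stringsAsFactors = FALSE)
  }
  motif_tab <- if (length(motif_rows)) do.call(rbind, motif_rows) else .emptyMatches()
  if (is.null(motif_tab$maximal)) motif_tab$maximal <- logical(0)
  if (is.null(motif_tab$leaflet)) motif_tab$leaflet <- character(0)
  if (is.null(motif_tab$tm_index)) motif_tab$tm_index <- integer(0)
  motif_tab <- motif_tab[, c("tm_index", "kind", "start", "end", "pos_basic",
                             "pos_aromatic", "pos_aliphatic", "span",
                             "leaflet", "maximal"), drop = FALSE]
  rownames(motif_tab) <- NULL
  tm_tab <- if (length(tm_rows)) do.call(rbind, tm_rows) else
    data.frame(tm_index = integer(0), start = integer(0), end = integer(0),
               extended_start = integer(0), extended_end = integer(0),
               n_end_faces = character(0), status = character(0),
               distant_pair = logical(0), stringsAsFactors = FALSE)
  rownames(tm_tab) <- NULL
  counts <- c(n_dual = sum(tm_tab$status == "dual_mirror"),
              n_carc_only = sum(tm_tab$status == "carc_only"),
              n_crac_only = sum(tm_tab$status == "crac_only"),
              n_none = sum(tm_tab$status == "none"))
  new("ScanReport", proteinId = proteinId(protein), motifs = motif_tab,
      tmClass = tm_tab,
      counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Scan a single peptide for motifs
#'
#' Convenience wrapper for peptide-level queries: enumerates CARC and/or
#' CRAC triads in a raw peptide string with a numbering offset (no
#' topology, hence no leaflet labels).
#'
#' @param sequence peptide string.
#' @param offset native coordinate of the first residue (1-based).
#' @param kind `"both"` (default), `"CARC"` or `"CRAC"`.
#' @param config a [ScanConfig-class]; `maximalOnly` controls whether
#'   only cluster representatives are returned.
#' @return Motif `data.frame` with a `maximal` flag.
#' @examples
#' scanPeptide("KAVVAFCL", offset = 232, kind = "CARC")
#' @export
scanPeptide <- function(sequence, offset = 1L, kind = c("both", "CARC", "CRAC"),
                        config = scanConfig()) {
  kind <- match.arg(kind)
  kinds <- if (kind == "both") .MOTIF_KINDS else kind
  out <- lapply(kinds, function(k) {
    m <- enumerateMotifs(sequence, k, offset = offset, config = config)
    if (nrow(m) == 0L) {
      m$maximal <- logical(0)
      return(m)
    }
    reps <- selectMaximal(m)
    key <- function(x) paste(x$pos_basic, x$pos_aromatic, x$pos_aliphatic)
    m$maximal <- key(m) %in% key(reps)
    if (config@maximalOnly) m <- m[m$maximal, , drop = FALSE]
    m
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
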