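#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()]: multi-record FASTA
#' supported, sequences uppercased and gap/whitespace characters
#' stripped.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (names from the FASTA
#'   headers, first whitespace-delimited token).
#' @export
readFastaSequences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L)
    stop("empty FASTA file: ", path)
  seqs <- vapply(as.character(set), .normalizeSeq, character(1L))
  names(seqs) <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1L), 1L)
  seqs
}

#' Read TM annotations and assemble MembraneProtein objects
#'
#' The annotation file is tab-separated with one row per TM segment and
#' columns `protein_id`, `tm_index`, `start`, `end`, `topology`
#' (coordinates 1-based inclusive; `topology` is the N-terminus location,
#' constant within a protein).  Rows may come in any order.
#'
#' @param path TSV annotation file.
#' @return Named list, per protein: `list(topology = ..., segments =
#'   data.frame(index, start, end))`, segments sorted by start.
#' @export
readTMAnnotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "tm_index", "start", "end", "topology")
  if (!all(need %in% names(tab)))
    stop("TM annotation file must have columns: ", paste(need, collapse = ", "))
  tab$.row <- seq_len(nrow(tab)) + 1L  # file line (1 header line)
  bad <- which(!(tab$topology %in% .TOPOLOGIES))
  if (length(bad))
    stop("unknown topology value '", tab$topology[bad[1L]], "' at line ",
         tab$.row[bad[1L]])
  bad <- which(!(tab$start < tab$end))
  if (length(bad))
    stop("TM start >= end at line ", tab$.row[bad[1L]])
  out <- lapply(split(tab, tab$protein_id), function(sub) {
    sub <- sub[order(sub$start), , drop = FALSE]
    if (length(unique(sub$topology)) != 1L)
      stop("conflicting topology values for protein ", sub$protein_id[1L])
    if (nrow(sub) > 1L && any(sub$start[-1L] <= sub$end[-nrow(sub)]))
      stop("overlapping TM segments for protein ", sub$protein_id[1L],
           " at line ", sub$.row[which(sub$start[-1L] <= sub$end[-nrow(sub)])[1L] + 1L])
    list(topology = sub$topology[1L],
         segments = data.frame(index = as.integer(sub$tm_index),
                               start = as.integer(sub$start),
                               end = as.integer(sub$end)))
  })
  out
}

#' Assemble MembraneProtein objects from FASTA + TM annotation files
#'
#' @param fasta FASTA file of sequences.
#' @param tmFile TSV file as for [readTMAnnotations()].
#' @return Named list of [MembraneProtein-class] objects (only proteins
#'   present in both files; an error is raised if a TM annotation refers
#'   to a missing sequence).
#' @export
readProteins <- function(fasta, tmFile) {
  seqs <- readFastaSequences(fasta)
  ann <- readTMAnnotations(tmFile)
  missing <- setdiff(names(ann), names(seqs))
  if (length(missing))
    stop("TM annotations without sequence: ", paste(missing, collapse = ", "))
  out <- lapply(names(ann), function(id) {
    a <- ann[[id]]
    membraneProtein(id, seqs[[id]], a$topology,
                    tmStart = a$segments$start, tmEnd = a$segments$end,
                    tmIndex = a$segments$index)
  })
  stats::setNames(out, names(ann))
}

.formatMotifTSV <- function(report) {
  m <- motifs(report)
  df <- cbind(protein_id = rep(proteinId(report), nrow(m)), m)
  df
}

#' Write a scan report
#'
#' Three formats are supported.  `tsv`: one motif per row, 1-based
#' inclusive coordinates.  `bed`: 0-based half-open intervals, reference
#' name = protein id, name field `KIND:leaflet`, score 0, strand `+`.
#' `json`: the full nested report (id, motif table, per-TM classification,
#' summary counts).  Output is byte-stable given identical input.
#'
#' @param report a [ScanReport-class].
#' @param path output file.
#' @param format `"tsv"`, `"bed"` or `"json"`.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, format = c("tsv", "bed", "json")) {
  stopifnot(is(report, "ScanReport"))
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unsupported report format", call. = FALSE))
  m <- motifs(report)
  if (format == "tsv") {
    utils::write.table(.formatMotifTSV(report), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else if (format == "bed") {
    lines <- sprintf("%s\t%d\t%d\t%s:%s\t0\t+",
                     proteinId(report), m$start - 1L, m$end,
                     m$kind, m$leaflet)
    writeLines(lines, path)
  } else {
    obj <- list(protein_id = proteinId(report),
                motifs = motifs(report),
                tm_classification = tmClassification(report),
                summary = as.list(summaryCounts(report)))
    json <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                             pretty = TRUE, digits = NA)
    writeLines(json, path)
  }
  invisible(path)
}

#' Rebuild a ScanReport from its JSON serialization
#'
#' Inverse of `writeReport(..., format = "json")`; the round trip is
#' lossless.
#'
#' @param path JSON file written by [writeReport()].
#' @return A [ScanReport-class].
#' @export
readReportJSON <- function(path) {
  obj <- jsonlite::fromJSON(path)
  m <- as.data.frame(obj$motifs, stringsAsFactors = FALSE)
  tc <- as.data.frame(obj$tm_classification, stringsAsFactors = FALSE)
  if (nrow(m) == 0L) {
    m <- .emptyMatches()
    m$leaflet <- character(0); m$maximal <- logical(0); m$tm_index <- integer(0)
  }
  int_cols <- c("tm_index", "start", "end", "pos_basic", "pos_aromatic",
                "pos_aliphatic", "span")
  for (cc in intersect(int_cols, names(m))) m[[cc]] <- as.integer(m[[cc]])
  m <- m[, c("tm_index", "kind", "start", "end", "pos_basic", "pos_aromatic",
             "pos_aliphatic", "span", "leaflet", "maximal"), drop = FALSE]
  if (nrow(tc) == 0L)
    tc <- data.frame(tm_index = integer(0), start = integer(0), end = integer(0),
                     extended_start = integer(0), extended_end = integer(0),
                     n_end_faces = character(0), status = character(0),
                     distant_pair = logical(0), stringsAsFactors = FALSE)
  for (cc in intersect(c("tm_index", "start", "end", "extended_start",
                         "extended_end"), names(tc)))
    tc[[cc]] <- as.integer(tc[[cc]])
  rownames(m) <- NULL
  rownames(tc) <- NULL
  counts <- stats::setNames(as.integer(unlist(obj$summary)), names(obj$summary))
  new("ScanReport", proteinId = obj$protein_id, motifs = m, tmClass = tc,
      counts = counts)
}

#' Convert motif coordinates between 1-based inclusive and BED conventions
#'
#' Internal coordinates are 1-based inclusive (UniProt convention); BED
#' intervals are 0-based half-open.  The two helpers are exact inverses.
#'
#' @param start,end coordinates in the source convention.
#' @return two-column matrix of converted coordinates.
#' @export
toBedCoords <- function(start, end) {
  cbind(start = as.integer(start) - 1L, end = as.integer(end))
}

#' @rdname toBedCoords
#' @export
fromBedCoords <- function(start, end) {
  cbind(start = as.integer(start) + 1L, end = as.integer(end))
}
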