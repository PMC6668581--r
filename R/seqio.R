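#' @include AllClasses.R
NULL

#' Read protein sequences from a FASTA file
#'
#' Reads a (possibly multi-line) protein FASTA file into an
#' \code{AAStringSet}. The first whitespace-delimited token of each header
#' becomes the record id (stored in \code{names}); the remainder is kept as
#' the \code{description} metadata column. Residues are uppercased and any
#' character outside the 20 standard amino-acid letters plus X is replaced
#' by X with a warning. Metadata columns \code{chimeric} (FALSE) and
#' \code{source} record provenance for downstream N-terminus curation.
#'
#' @param path path to a FASTA file.
#' @param source free-text provenance tag stored with every record.
#' @return an \code{AAStringSet} with metadata columns \code{description},
#'   \code{chimeric} and \code{source}.
#' @examples
#' fa <- tempfile(fileext = ".faa")
#' writeLines(c(">p1 demo protein", "MKLFAVST"), fa)
#' readFastaProteins(fa)
#' @export
readFastaProteins <- function(path, source = basename(path)) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L)
    stop("FASTA file contains no records: ", path)
  headers <- names(aa)
  if (any(!nzchar(gsub("\\s", "", headers))))
    stop("FASTA record with empty header in ", path)
  empty <- Biostrings::width(aa) == 0L
  if (any(empty))
    stop("FASTA record with empty sequence: ",
         paste(headers[empty], collapse = ", "))
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(aa))
  bad <- gsub(paste0("[", paste(AA21, collapse = ""), "]"), "", seqs)
  nBad <- sum(nchar(bad))
  if (nBad > 0) {
    offending <- sort(unique(strsplit(paste(bad, collapse = ""), "")[[1]]))
    warning(sprintf("replaced %d non-standard residue character(s) (%s) by X",
                    nBad, paste(offending, collapse = "")))
    seqs <- vapply(seqs, function(s)
      gsub(paste0("[^", paste(AA21, collapse = ""), "]"), "X", s),
      character(1), USE.NAMES = FALSE)
  }
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    description = unname(desc),
    chimeric = rep(FALSE, length(out)),
    source = rep(source, length(out)))
  out
}

#' Write protein sequences to FASTA
#'
#' Writes an \code{AAStringSet} (as produced by
#' \code{\link{readFastaProteins}}) to a FASTA file, 80 residues per line.
#' Descriptions in the \code{description} metadata column are appended to
#' the id on the header line, so a read/write round trip is the identity on
#' (id, description, residues). An empty set writes an empty file.
#'
#' @param records an \code{AAStringSet}; names are the record ids.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeFastaProteins <- function(records, path) {
  stopifnot(is(records, "AAStringSet"))
  if (length(records) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  out <- records
  mc <- S4Vectors::mcols(records)
  if (!is.null(mc) && "description" %in% colnames(mc)) {
    desc <- mc$description
    hdr <- ifelse(nzchar(desc), paste(names(records), desc), names(records))
    names(out) <- hdr
  }
  Biostrings::writeXStringSet(out, filepath = path, width = 80L)
  invisible(path)
}

.recordResidues <- function(records, id) {
  as.character(records[[id]])
}

#' Extend a truncated N-terminus from an overlapping transcript
#'
#' Fragmented genome assemblies often yield proteins truncated at the
#' 5' end, which defeats N-terminal targeting prediction. Given near-
#' identical transcripts from another source, this joins them: if the first
#' \code{minOverlap} residues of \code{target} occur as an exact substring
#' of a candidate at a position preceded by at least one residue, the
#' candidate's upstream residues are prepended and the record is flagged
#' \code{chimeric} (it fuses orthologs from different strains). Among
#' qualifying candidates the longest extension wins; ties break by
#' candidate id in lexicographic order. With no qualifying candidate the
#' target is returned unchanged with \code{chimeric = FALSE}.
#'
#' @param target a single-record \code{AAStringSet} (or the name of a
#'   record in \code{candidates}' format): the protein to extend.
#' @param candidates an \code{AAStringSet} of candidate transcripts.
#' @param minOverlap required exact-match prefix length (default 30).
#' @return a single-record \code{AAStringSet} with updated residues and a
#'   \code{chimeric} metadata flag; the original residues are always an
#'   exact suffix of the result.
#' @export
extendNTerminus <- function(target, candidates, minOverlap = 30L) {
  stopifnot(is(target, "AAStringSet"), length(target) == 1L,
            is(candidates, "AAStringSet"))
  minOverlap <- as.integer(minOverlap)
  if (minOverlap < 1L)
    stop("minOverlap must be >= 1")
  tseq <- as.character(target[[1]])
  if (nchar(tseq) < minOverlap)
    stop("target '", names(target), "' is shorter than minOverlap (",
         minOverlap, ")")
  prefix <- substr(tseq, 1L, minOverlap)
  bestExt <- ""
  bestId <- NA_character_
  candIds <- names(candidates)
  ord <- order(candIds, method = "radix")
  for (i in ord) {
    cseq <- as.character(candidates[[i]])
    hits <- gregexpr(prefix, cseq, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    start <- max(hits)            # latest occurrence = longest extension
    if (start <= 1L) next         # needs >= 1 upstream residue
    ext <- substr(cseq, 1L, start - 1L)
    if (nchar(ext) > nchar(bestExt)) {   # strict: ties keep earlier id
      bestExt <- ext
      bestId <- candIds[i]
    }
  }
  out <- target
  mc <- S4Vectors::mcols(out)
  if (is.null(mc) || !"chimeric" %in% colnames(mc)) {
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      description = "", chimeric = FALSE, source = "")
    mc <- S4Vectors::mcols(out)
  }
  if (nchar(bestExt) > 0) {
    ext <- Biostrings::AAStringSet(paste0(bestExt, tseq))
    names(ext) <- names(target)
    S4Vectors::mcols(ext) <- mc
    S4Vectors::mcols(ext)$chimeric <- TRUE
    S4Vectors::mcols(ext)$source <-
      paste0(mc$source, "+", bestId)
    return(ext)
  }
  S4Vectors::mcols(out)$chimeric <- FALSE
  out
}

#' Read a labelled reference table
#'
#' Reads a TSV of curated reference proteins (header columns \code{id},
#' \code{label}, optionally \code{known_cleavage}, \code{excluded},
#' \code{reason}) and resolves every id against a loaded sequence
#' collection. Labels must come from the closed set plastid /
#' mitochondrion / cytosol / secretory. Excluded entries (e.g. organellar
#' genome-encoded proteins) are retained but flagged, so they can be
#' dropped from training while staying visible in reports.
#'
#' @param path path to the TSV file.
#' @param sequences an \code{AAStringSet} containing (at least) every id in
#'   the table.
#' @return a \linkS4class{ReferenceSet}.
#' @export
readReferenceTable <- function(path, sequences) {
  stopifnot(is(sequences, "AAStringSet"))
  if (!file.exists(path))
    stop("reference table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  if (!all(c("id", "label") %in% colnames(tab)))
    stop("reference table must have header columns 'id' and 'label'")
  if (!"known_cleavage" %in% colnames(tab)) tab$known_cleavage <- NA
  if (!"excluded" %in% colnames(tab)) tab$excluded <- FALSE
  if (!"reason" %in% colnames(tab)) tab$reason <- ""
  missing <- setdiff(tab$id, names(sequences))
  if (length(missing))
    stop("reference ids not found in the sequence collection: ",
         paste(missing, collapse = ", "))
  badLabel <- !tab$label %in% COMPARTMENTS
  if (any(badLabel))
    stop("unknown label(s) in reference table row(s) ",
         paste(which(badLabel), collapse = ", "), ": ",
         paste(unique(tab$label[badLabel]), collapse = ", "))
  kc <- suppressWarnings(as.integer(tab$known_cleavage))
  rawKc <- trimws(as.character(tab$known_cleavage))
  malformed <- !is.na(tab$known_cleavage) & nzchar(rawKc) &
    rawKc != "NA" & is.na(kc)
  if (any(malformed))
    stop("malformed known_cleavage in row(s) ",
         paste(which(malformed), collapse = ", "))
  excl <- tab$excluded
  if (is.character(excl))
    excl <- tolower(trimws(excl)) %in% c("true", "t", "1", "yes")
  excl[is.na(excl)] <- FALSE
  referenceSet(sequences[tab$id], id = tab$id, label = tab$label,
               knownCleavage = kc, excluded = as.logical(excl),
               reason = as.character(tab$reason))
}

#' Construct a ReferenceSet
#'
#' @param sequences \code{AAStringSet} of the referenced proteins.
#' @param id,label character vectors, one entry per reference protein.
#' @param knownCleavage integer positions of the last signal-peptide
#'   residue, NA where unknown.
#' @param excluded logical exclusion flags.
#' @param reason free-text exclusion reasons.
#' @return a validated \linkS4class{ReferenceSet}.
#' @export
referenceSet <- function(sequences, id, label,
                         knownCleavage = NA_integer_,
                         excluded = FALSE, reason = "") {
  n <- length(id)
  info <- S4Vectors::DataFrame(
    id = as.character(id),
    label = as.character(label),
    knownCleavage = rep_len(as.integer(knownCleavage), n),
    excluded = rep_len(as.logical(excluded), n),
    reason = rep_len(as.character(reason), n))
  new("ReferenceSet", sequences = sequences, info = info)
}

#' Subset a ReferenceSet to usable training entries
#'
#' Keeps non-excluded entries, optionally restricted to one compartment
#' label and/or to entries with a known cleavage position.
#'
#' @param x a \linkS4class{ReferenceSet}.
#' @param label optional compartment label to keep.
#' @param withCleavage keep only entries with a known cleavage position.
#' @return a \linkS4class{ReferenceSet}.
#' @export
filterReferenceSet <- function(x, label = NULL, withCleavage = FALSE) {
  stopifnot(is(x, "ReferenceSet"))
  keep <- !x@info$excluded
  if (!is.null(label)) keep <- keep & x@info$label %in% label
  if (withCleavage) keep <- keep & !is.na(x@info$knownCleavage)
  new("ReferenceSet", sequences = x@sequences[x@info$id[keep]],
      info = x@info[keep, , drop = FALSE])
}
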