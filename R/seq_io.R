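#' Read a multiple-FASTA file of RNA (or DNA) sequences
#'
#' Wrapped and unwrapped FASTA are both accepted (parsing is delegated to
#' Biostrings).  Sequences are uppercased and T is normalized to U; ids
#' are the first whitespace-delimited header token and must be unique.
#'
#' @param path FASTA file.
#' @return named character vector of RNA sequences (5'->3').
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- vapply(as.character(set), as_rna, character(1), USE.NAMES = FALSE)
  setNames(seqs, ids)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping (default 70).
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a per-transcript multi-species UTR alignment
#'
#' An aligned multi-FASTA with one row per species; rows must have equal
#' length over the alphabet `{A, C, G, U, -}` (T accepted and mapped to
#' U).  The reference row, identified by `reference`, degaps to the UTR
#' sequence used by the predictor.
#'
#' @param path aligned FASTA file.
#' @param reference species id of the reference row.
#' @return object of class `aligned_utr_set`: list with `rows` (named
#'   character vector), `reference`, and `ref_map` (UTR position ->
#'   alignment column).
#' @export
read_aligned_fasta <- function(path, reference) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 2L) stop("alignment needs at least 2 species rows")
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  rows <- toupper(chartr("tT", "uU", as.character(set)))
  names(rows) <- ids
  if (length(unique(nchar(rows))) != 1L) stop("ragged alignment: rows differ in length")
  bad <- grepl("[^ACGU-]", rows)
  if (any(bad)) stop("invalid characters in alignment row(s): ",
                     paste(ids[bad], collapse = ", "))
  if (!reference %in% ids) stop("reference species '", reference, "' not in alignment")
  aligned_utr_set(rows, reference)
}

#' Construct an aligned UTR set from in-memory rows
#'
#' @param rows named character vector of equal-length aligned rows.
#' @param reference name of the reference row.
#' @return an `aligned_utr_set` (see [read_aligned_fasta()]).
#' @export
aligned_utr_set <- function(rows, reference) {
  stopifnot(length(rows) >= 2L, reference %in% names(rows),
            length(unique(nchar(rows))) == 1L)
  ref_chars <- strsplit(rows[[reference]], "")[[1]]
  structure(list(rows = rows, reference = reference,
                 ref_map = which(ref_chars != "-")),
            class = "aligned_utr_set")
}

# degapped reference sequence of an alignment
reference_utr <- function(aln) {
  gsub("-", "", aln$rows[[aln$reference]], fixed = TRUE)
}

#' Write prediction records to TSV, BED or GFF3
#'
#' Internally intervals are 1-based inclusive on the transcript; BED is
#' emitted 0-based half-open and GFF3 1-based inclusive (both via
#' rtracklayer, with the UTR id as the sequence name).
#'
#' @param records prediction data frame from [predict_targets()].
#' @param path output path.
#' @param format `"tsv"`, `"bed"` or `"gff3"`.
#' @export
write_predictions <- function(records, path, format = c("tsv", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv") {
    cols <- c("utr_id", "mirna_id", "start", "end", "score",
              "seed_flag", "conserved_flag", "stringency")
    write.table(records[, cols, drop = FALSE], path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  if (nrow(records) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  gr <- GenomicRanges::GRanges(
    seqnames = records$utr_id,
    ranges = IRanges::IRanges(start = records$start, end = records$end),
    strand = "+",
    name = records$mirna_id,
    score = records$score)
  rtracklayer::export(gr, path, format = if (format == "bed") "bed" else "gff3")
  invisible(path)
}

#' Read a BED file of validated binding-site intervals
#'
#' @param path BED file (0-based half-open; transcript ids as sequence
#'   names).
#' @return data frame with `transcript_id`, `start`, `end` (1-based
#'   inclusive) and `name`.
#' @export
read_sites_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(transcript_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else NA_character_,
             stringsAsFactors = FALSE)
}
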