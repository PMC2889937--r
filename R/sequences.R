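#' Normalize an RNA sequence
#'
#' Accepts a character string (or a [Biostrings::RNAString]/`DNAString`)
#' and returns the uppercase RNA residues with `T` mapped to `U`.  Any
#' character outside `{A, C, G, U}` is an error.
#'
#' @param x character scalar or Biostrings string object.
#' @return character scalar over the RNA alphabet, 5'->3'.
#' @export
as_rna <- function(x) {
  if (methods::is(x, "XString") || methods::is(x, "XStringSet")) {
    x <- as.character(x)
  }
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("expected a single character string")
  }
  s <- chartr("tT", "uU", x)
  s <- toupper(s)
  if (nchar(s) == 0L) stop("empty sequence")
  if (grepl("[^ACGU]", s)) {
    bad <- unique(strsplit(gsub("[ACGU]", "", s), "")[[1]])
    stop("invalid residue(s) in RNA sequence: ", paste(bad, collapse = ", "))
  }
  s
}

# integer codes A=0, C=1, G=2, U=3 used by the C++ kernels
rna_codes <- function(x) {
  s <- as_rna(x)
  m <- match(strsplit(s, "")[[1]], c("A", "C", "G", "U")) - 1L
  m
}

codes_to_rna <- function(codes) {
  paste(c("A", "C", "G", "U")[codes + 1L], collapse = "")
}

#' Watson-Crick reverse complement of an RNA sequence
#'
#' @param x RNA sequence (character or Biostrings object).
#' @return character scalar, the reverse complement (5'->3').
#' @export
reverse_complement <- function(x) {
  s <- as_rna(x)
  comp <- chartr("ACGU", "UGCA", s)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# complement without reversal
wc_complement_base <- function(b) chartr("ACGU", "UGCA", b)

# TRUE if (a, b) can pair (Watson-Crick or G:U wobble)
can_pair <- function(a, b) {
  p <- paste0(a, b)
  p %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

is_gu_pair <- function(a, b) paste0(a, b) %in% c("GU", "UG")
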