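## IUPAC sequence model: canonicalization, reverse complement, palindrome
## test, degenerate matching. All coordinates are 0-based half-open
## internally; user-facing tables are 1-based inclusive.

.IUPAC <- Biostrings::IUPAC_CODE_MAP  # code -> string of allowed bases

#' Canonicalize a nucleotide sequence
#'
#' Uppercases, maps U to T, and validates every residue against the 15-letter
#' IUPAC alphabet. All other package functions accept raw character input and
#' canonicalize through this function.
#'
#' @param x a single character string of IUPAC nucleotide codes
#' @return the canonicalized sequence as a character scalar
#' @examples
#' ntSeq("acgu")  # "ACGT"
#' @export
ntSeq <- function(x) {
    if (is(x, "DNAString") || is(x, "RNAString"))
        x <- as.character(x)
    stopifnot(is.character(x), length(x) == 1L, !is.na(x))
    x <- chartr("uU", "tT", x)
    x <- toupper(x)
    bad <- !strsplit(x, "")[[1]] %in% names(.IUPAC)
    if (any(bad))
        stop(sprintf("invalid IUPAC residue '%s' at position %d",
                     substr(x, which(bad)[1], which(bad)[1]), which(bad)[1]))
    x
}

#' IUPAC-aware reverse complement
#'
#' Degenerate codes complement by their allowed-set complements (R to Y,
#' S to S, B to V, N to N, ...). Applying the function twice returns the
#' input.
#'
#' @param x sequence (character or DNAString)
#' @return reverse complement as a character scalar
#' @examples
#' revComp("GAATTC")  # "GAATTC" (EcoRI site is its own reverse complement)
#' revComp("RY")      # "RY"
#' @export
revComp <- function(x) {
    x <- ntSeq(x)
    if (nchar(x) == 0L) return(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Test whether a sequence is a DNA palindrome
#'
#' A DNA palindrome equals its own reverse complement and is therefore
#' identical on both strands; PST sites (restriction-enzyme recognition
#' sequences) are palindromes of this kind. Only unambiguous sequences are
#' accepted: palindromy is defined here on concrete motifs, not on
#' degenerate patterns.
#'
#' @param x sequence (character or DNAString); must be unambiguous A/C/G/T
#' @return TRUE iff \code{x} equals its reverse complement (odd-length
#'   sequences are never palindromic)
#' @examples
#' isPalindrome("GACGTC")  # TRUE  (AatII)
#' isPalindrome("GGATCA")  # FALSE
#' @export
isPalindrome <- function(x) {
    x <- ntSeq(x)
    ch <- strsplit(x, "")[[1]]
    if (!all(ch %in% c("A", "C", "G", "T")))
        stop("palindromy is defined only on unambiguous A/C/G/T sequences")
    if (nchar(x) %% 2L != 0L) return(FALSE)
    identical(x, revComp(x))
}

#' Match a degenerate pattern against an unambiguous target
#'
#' Position-wise IUPAC containment: TRUE iff at every position the target
#' base belongs to the pattern code's allowed set (N matches any base, S
#' matches G/C, and so on). This is the annealing model for degenerate
#' primer positions.
#'
#' @param pattern sequence possibly containing degenerate codes
#' @param target unambiguous sequence of the same length
#' @return TRUE or FALSE
#' @examples
#' iupacMatches("NNGACGTC", "TTGACGTC")  # TRUE
#' iupacMatches("S", "A")                # FALSE
#' @export
iupacMatches <- function(pattern, target) {
    pattern <- ntSeq(pattern)
    target <- ntSeq(target)
    if (nchar(pattern) != nchar(target))
        stop("pattern and target must have equal lengths")
    tc <- strsplit(target, "")[[1]]
    if (!all(tc %in% c("A", "C", "G", "T")))
        stop("target must be unambiguous (A/C/G/T)")
    pc <- strsplit(pattern, "")[[1]]
    all(mapply(function(p, t) grepl(t, .IUPAC[[p]], fixed = TRUE), pc, tc))
}

## per-position logical match vector; degenerate target bases (incl. N)
## never match.
.matchVec <- function(pattern_chars, target_chars) {
    allowed <- .IUPAC[pattern_chars]
    mapply(function(a, t) {
        t %in% c("A", "C", "G", "T") && grepl(t, a, fixed = TRUE)
    }, allowed, target_chars, USE.NAMES = FALSE)
}

#' Read a multi-record FASTA of templates
#'
#' Wrapped or single-line records and CRLF line endings are tolerated.
#' Record identifiers are the first whitespace-delimited token of each
#' header; residues are canonicalized (uppercased, U mapped to T).
#'
#' @param path path to a FASTA file
#' @return a named [Biostrings::DNAStringSet]
#' @export
readTemplates <- function(path) {
    if (!file.exists(path))
        stop(sprintf("FASTA file not found: %s", path))
    x <- Biostrings::readBStringSet(path)
    if (length(x) == 0L)
        stop(sprintf("no FASTA records in %s", path))
    ids <- vapply(strsplit(names(x), "\\s+"), `[`, "", 1L)
    ## canonicalize case and U (soft-masking is not tracked); the
    ## DNAStringSet constructor validates the IUPAC alphabet
    seqs <- chartr("uU", "tT", toupper(as.character(x)))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- ids
    out
}
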