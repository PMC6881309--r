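## Palindromic-site scanning, spacing statistics, the i.i.d. analytic
## spacing model, and multi-record genome reports.

#' Scan a template for occurrences of a palindromic motif
#'
#' Exact matching on the plus strand only, which is exhaustive because a
#' palindrome occurs identically on both strands. Overlapping occurrences
#' are counted; matches never overlap an N (assembly gaps cannot create
#' phantom sites).
#'
#' @param template template sequence (character, DNAString, or a
#'   single-record DNAStringSet)
#' @param motif unambiguous palindromic motif (6 or 8 nt typical)
#' @param seq_id identifier recorded in the result
#' @return a [PalindromeSiteSet-class] with 0-based start positions
#' @examples
#' scanPstSites("AAGGATCCAA", "GGATCC")
#' @export
scanPstSites <- function(template, motif, seq_id = "template") {
    motif <- ntSeq(motif)
    if (!isPalindrome(motif))
        stop(sprintf("'%s' is not a palindrome", motif))
    if (is(template, "DNAStringSet")) {
        stopifnot(length(template) == 1L)
        if (!is.null(names(template))) seq_id <- names(template)[1L]
        template <- template[[1L]]
    }
    if (!is(template, "DNAString"))
        template <- Biostrings::DNAString(ntSeq(template))
    hits <- Biostrings::matchPattern(motif, template, fixed = TRUE)
    pos <- Biostrings::start(hits) - 1L  # 0-based
    new("PalindromeSiteSet", motif = motif, seqId = as.character(seq_id),
        positions = as.integer(pos), seqLength = length(template))
}

setMethod("show", "PalindromeSiteSet", function(object) {
    cat(sprintf("PalindromeSiteSet: %s in %s (%d bp): %d site(s)\n",
                object@motif, object@seqId, object@seqLength,
                length(object@positions)))
})

#' @rdname accessors
#' @export
setGeneric("sitePositions", function(x) standardGeneric("sitePositions"))
#' @rdname accessors
setMethod("sitePositions", "PalindromeSiteSet", function(x) x@positions)

#' Convert a site set to GRanges
#'
#' Palindromic sites are strand-symmetric, so strand is "*". Coordinates
#' follow the GRanges convention (1-based inclusive); BED export through
#' \code{rtracklayer} shifts back to 0-based.
#'
#' @param sites a [PalindromeSiteSet-class]
#' @return a [GenomicRanges::GRanges] with metadata columns name (the
#'   motif) and score (0)
#' @export
sitesAsGRanges <- function(sites) {
    stopifnot(is(sites, "PalindromeSiteSet"))
    w <- nchar(sites@motif)
    GenomicRanges::GRanges(
        seqnames = sites@seqId,
        ranges = IRanges::IRanges(start = sites@positions + 1L, width = w),
        strand = "*",
        name = rep(sites@motif, length(sites@positions)),
        score = rep(0L, length(sites@positions)))
}

#' Spacing statistics for a site set
#'
#' Mean start-to-start distance between successive sites, site density per
#' kilobase, and the expected PST-PCR product length, which is half the
#' mean inter-site distance (an SSP lands uniformly between two sites, so
#' the expected distance to the next site is half the gap).
#'
#' @param sites a [PalindromeSiteSet-class]
#' @return a one-row data.frame: motif, sequence_id, n_sites,
#'   sequence_length, mean_distance_bp (NA when fewer than two sites),
#'   density_per_kb, expected_product_bp
#' @examples
#' spacingStats(scanPstSites("CACGTGCACGTG", "CACGTG"))
#' @export
spacingStats <- function(sites) {
    stopifnot(is(sites, "PalindromeSiteSet"))
    p <- sites@positions
    md <- if (length(p) >= 2L) mean(diff(p)) else NA_real_
    data.frame(
        motif = sites@motif, sequence_id = sites@seqId,
        n_sites = length(p), sequence_length = sites@seqLength,
        mean_distance_bp = md,
        density_per_kb = 1000 * length(p) / sites@seqLength,
        expected_product_bp = md / 2,
        stringsAsFactors = FALSE)
}

#' Analytic spacing under an i.i.d. base model
#'
#' With P(G) = P(C) = gc/2 and P(A) = P(T) = (1 - gc)/2 at every position
#' independently, the per-position probability of a motif hit is the
#' product of its base probabilities; the mean inter-site distance is 1/p
#' and the expected product length 1/(2p). At gc = 0.5 any 6-mer gives
#' 4096 bp and any 8-mer 65536 bp.
#'
#' @param gc_content genomic GC content as a fraction in (0, 1); the
#'   boundary values are accepted but yield NA when the motif requires the
#'   absent base class
#' @param motif unambiguous palindromic motif
#' @return a one-row data.frame shaped like [spacingStats()] output, with
#'   n_sites and sequence_length NA
#' @examples
#' analyticSpacing(0.6, "GGATCC")  # mean distance ~3086.4 bp
#' @export
analyticSpacing <- function(gc_content, motif) {
    motif <- ntSeq(motif)
    if (!isPalindrome(motif))
        stop(sprintf("'%s' is not a palindrome", motif))
    stopifnot(is.numeric(gc_content), length(gc_content) == 1L,
              gc_content >= 0, gc_content <= 1)
    ch <- strsplit(motif, "")[[1]]
    pr <- ifelse(ch %in% c("G", "C"), gc_content / 2, (1 - gc_content) / 2)
    p <- prod(pr)
    md <- if (p > 0) 1 / p else NA_real_
    data.frame(
        motif = motif, sequence_id = NA_character_,
        n_sites = NA_integer_, sequence_length = NA_integer_,
        mean_distance_bp = md, density_per_kb = 1000 * p,
        expected_product_bp = md / 2, stringsAsFactors = FALSE)
}

#' Per-record and pooled spacing report over a genome
#'
#' Scans every record of a FASTA (or DNAStringSet) for every motif. Pooled
#' rows (sequence_id \code{"(all)"}) aggregate counts over records; the
#' pooled mean distance averages within-record gaps only - gaps never span
#' record boundaries, since distances across scaffolds are meaningless.
#'
#' @param fasta path to a FASTA file, or a named
#'   [Biostrings::DNAStringSet]
#' @param motifs character vector of palindromic motifs
#' @return a data.frame of spacing statistics, one row per (record, motif)
#'   plus one pooled row per motif
#' @export
genomeReport <- function(fasta, motifs) {
    templates <- if (is(fasta, "DNAStringSet")) fasta else readTemplates(fasta)
    if (is.null(names(templates)))
        names(templates) <- paste0("seq", seq_along(templates))
    motifs <- vapply(motifs, ntSeq, "")
    rows <- list()
    for (m in motifs) {
        gaps <- integer()
        n_tot <- 0L
        len_tot <- 0L
        for (i in seq_along(templates)) {
            sites <- scanPstSites(templates[i], m)
            rows[[length(rows) + 1L]] <- spacingStats(sites)
            if (length(sites@positions) >= 2L)
                gaps <- c(gaps, diff(sites@positions))
            n_tot <- n_tot + length(sites@positions)
            len_tot <- len_tot + sites@seqLength
        }
        md <- if (length(gaps)) mean(gaps) else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
            motif = m, sequence_id = "(all)", n_sites = n_tot,
            sequence_length = len_tot, mean_distance_bp = md,
            density_per_kb = 1000 * n_tot / len_tot,
            expected_product_bp = md / 2, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
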