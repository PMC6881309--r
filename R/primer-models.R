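## PST primer / SSP construction, rule-based validation, and the bundled
## primer catalog (25 PST primers, the universal tail primer, 12 SSPs).

#' Assemble a PST primer
#'
#' Full sequence, 5' to 3': adapter, then \code{degenerate_len} fully
#' degenerate N positions, then the unambiguous 3'-terminal palindrome.
#' The degenerate block length must lie in the design range 8-12 (the
#' bundled catalog uses 10 throughout).
#'
#' @param adapter unambiguous adapter sequence
#' @param palindrome unambiguous even-length palindrome, >= 6 nt
#' @param degenerate_len number of N positions between adapter and
#'   palindrome (8-12, default 10)
#' @param id primer identifier
#' @param enzyme optional restriction-enzyme name for the palindrome
#' @return a [PSTPrimer-class] object
#' @examples
#' p <- buildPstPrimer("GTTGCGGCAGGTCCTCACC", "GACGTC", id = "5601",
#'                     enzyme = "AatII")
#' primerSequence(p)
#' @export
buildPstPrimer <- function(adapter, palindrome, degenerate_len = 10L,
                           id, enzyme = "") {
    adapter <- ntSeq(adapter)
    palindrome <- ntSeq(palindrome)
    if (!all(strsplit(palindrome, "")[[1]] %in% c("A", "C", "G", "T")) ||
        nchar(palindrome) %% 2L != 0L || !isPalindrome(palindrome))
        stop(sprintf("'%s' is not a palindrome", palindrome))
    degenerate_len <- as.integer(degenerate_len)
    if (degenerate_len < 8L || degenerate_len > 12L)
        stop("degenerate block length must be within the design range 8-12")
    new("PSTPrimer", id = as.character(id), adapter = adapter,
        degenerateLen = degenerate_len, palindrome = palindrome,
        enzyme = as.character(enzyme))
}

#' Construct a sequence-specific primer
#'
#' @param id primer identifier
#' @param sequence primer sequence 5' to 3' (limited degeneracy allowed)
#' @param orientation "F" (extends rightward on the plus strand) or "R"
#' @param target_note free-text target description
#' @param nested_parent id of the outer SSP this primer nests within, or NA
#' @return an [SSP-class] object
#' @examples
#' ssp("5315", "CTSAAGCGGATCGAGAACAAGATCAACC", "F", "exon1")
#' @export
ssp <- function(id, sequence, orientation = c("F", "R"), target_note = "",
                nested_parent = NA_character_) {
    orientation <- match.arg(orientation)
    new("SSP", id = as.character(id), sequence = ntSeq(sequence),
        orientation = orientation, targetNote = as.character(target_note),
        nestedParent = as.character(nested_parent))
}

## ---- accessors -----------------------------------------------------------

#' @rdname accessors
#' @param x a [PSTPrimer-class] or [SSP-class] object
#' @export
setGeneric("primerId", function(x) standardGeneric("primerId"))

#' @rdname accessors
#' @export
setGeneric("primerSequence", function(x) standardGeneric("primerSequence"))

#' @rdname accessors
#' @export
setGeneric("coreSequence", function(x) standardGeneric("coreSequence"))

#' @rdname accessors
#' @export
setGeneric("adapterSequence", function(x) standardGeneric("adapterSequence"))

#' @rdname accessors
#' @export
setGeneric("palindromeSequence",
           function(x) standardGeneric("palindromeSequence"))

#' @rdname accessors
#' @export
setGeneric("degenerateLength", function(x) standardGeneric("degenerateLength"))

#' @rdname accessors
#' @export
setGeneric("enzymeName", function(x) standardGeneric("enzymeName"))

#' @rdname accessors
#' @export
setGeneric("orientation", function(x) standardGeneric("orientation"))

#' Accessors for primer objects
#'
#' \code{primerSequence} returns the full 5'-to-3' sequence (degenerate
#' block rendered as N); \code{coreSequence} returns the template-pairing
#' part of a PST primer (N block + palindrome).
#'
#' @name accessors
#' @return character scalars (or integer for \code{degenerateLength})
#' @examples
#' cat <- loadCatalog()
#' coreSequence(cat$pst[["5605"]])
NULL

#' @rdname accessors
setMethod("primerId", "PSTPrimer", function(x) x@id)
#' @rdname accessors
setMethod("primerId", "SSP", function(x) x@id)
#' @rdname accessors
setMethod("adapterSequence", "PSTPrimer", function(x) x@adapter)
#' @rdname accessors
setMethod("palindromeSequence", "PSTPrimer", function(x) x@palindrome)
#' @rdname accessors
setMethod("degenerateLength", "PSTPrimer", function(x) x@degenerateLen)
#' @rdname accessors
setMethod("enzymeName", "PSTPrimer", function(x) x@enzyme)
#' @rdname accessors
setMethod("coreSequence", "PSTPrimer", function(x)
    paste0(strrep("N", x@degenerateLen), x@palindrome))
#' @rdname accessors
setMethod("primerSequence", "PSTPrimer", function(x)
    paste0(x@adapter, strrep("N", x@degenerateLen), x@palindrome))
#' @rdname accessors
setMethod("primerSequence", "SSP", function(x) x@sequence)
#' @rdname accessors
setMethod("orientation", "SSP", function(x) x@orientation)

#' @rdname accessors
#' @export
setGeneric("nestedParent", function(x) standardGeneric("nestedParent"))
#' @rdname accessors
setMethod("nestedParent", "SSP", function(x) x@nestedParent)

setMethod("show", "PSTPrimer", function(object) {
    cat(sprintf("PSTPrimer %s (%s): %s\n", object@id,
                if (nzchar(object@enzyme)) object@enzyme else "?",
                primerSequence(object)))
    cat(sprintf("  adapter %d nt | dN%d | palindrome %s\n",
                nchar(object@adapter), object@degenerateLen,
                object@palindrome))
})

setMethod("show", "SSP", function(object) {
    cat(sprintf("SSP %s [%s, %s]: %s (%d nt)\n", object@id,
                object@orientation,
                if (nzchar(object@targetNote)) object@targetNote else "?",
                object@sequence, nchar(object@sequence)))
    if (!is.na(object@nestedParent))
        cat(sprintf("  nested within SSP %s\n", object@nestedParent))
})

## ---- validation ----------------------------------------------------------

.verdict <- function(rule_id, passed, observed, allowed, advisory = FALSE) {
    data.frame(rule_id = rule_id, passed = passed,
               observed = as.character(observed), allowed = allowed,
               advisory = advisory, stringsAsFactors = FALSE)
}

.round1 <- function(x) floor(x * 10 + 0.5) / 10  # half-up, as printed tables

#' Validate a PST primer against the design rules
#'
#' One verdict row per rule: palindrome GC within the empirically favorable
#' band 33.3-66.7% (2-4 G/C in a 6-mer; advisory), palindrome linguistic
#' complexity (reported, never failing), absence of a 3'-terminal
#' complementary run between adapter and core (a primer whose adapter can
#' fold back on its own core would self-prime), and the expected 19-nt
#' adapter length (advisory).
#'
#' @param p a [PSTPrimer-class] object
#' @param min_run run length threshold for the adapter/core dimer screen
#' @return a data.frame of verdicts (columns rule_id, passed, observed,
#'   allowed, advisory)
#' @examples
#' validatePstPrimer(buildPstPrimer("GTTGCGGCAGGTCCTCACC", "GGATCC",
#'                                  id = "x"))
#' @export
validatePstPrimer <- function(p, min_run = 4L) {
    stopifnot(is(p, "PSTPrimer"))
    gc <- gcPercent(p@palindrome)
    lc <- linguisticComplexity(p@palindrome)
    dim3 <- dimerScreen(p@adapter, coreSequence(p), min_run = min_run)
    core_len <- p@degenerateLen + nchar(p@palindrome)
    bad_dim <- nrow(dim3) > 0 && any(dim3$b_end == core_len)
    rbind(
        .verdict("palindrome_gc", gc >= 100 / 3 - 0.05 && gc <= 200 / 3 + 0.05,
                 .round1(gc), "33.3-66.7%", advisory = TRUE),
        .verdict("palindrome_lc", TRUE, floor(lc + 0.5), "reported",
                 advisory = TRUE),
        .verdict("adapter_core_dimer", !bad_dim,
                 if (bad_dim) "3'-terminal run" else "none",
                 sprintf("no adapter/core run >= %d at core 3' end", min_run)),
        .verdict("adapter_length", nchar(p@adapter) == 19L, nchar(p@adapter),
                 "19 nt", advisory = TRUE))
}

#' Validate an SSP against the selection rules
#'
#' Rules: length 25-35 nt; GC content 40-60% (degenerate-weighted); Tm of at
#' least 65 C under \code{cond} (advisory: the bundled catalog itself lists
#' primers below this bound under the catalog's stated conditions); no
#' self-dimer run of >= min_run involving the 3' terminus; and, when a
#' nested parent is declared, no sequence overlap with the parent
#' (advisory).
#'
#' @param s an [SSP-class] object
#' @param cond [IonicConditions-class] for the Tm rule
#' @param min_run self-dimer run threshold
#' @param parent optional [SSP-class], the declared nested parent
#' @return a data.frame of verdicts
#' @examples
#' validateSsp(ssp("x", "GCACGGAGATCTCGTGCGCCTTCTTGAG", "R"))
#' @export
validateSsp <- function(s, cond = SSP_CONDITIONS, min_run = 4L,
                        parent = NULL) {
    stopifnot(is(s, "SSP"))
    len <- nchar(s@sequence)
    gc <- gcPercent(s@sequence)
    tm <- meltingTemperature(s@sequence, cond)
    sd <- dimerScreen(s@sequence, s@sequence, min_run = min_run)
    bad_sd <- nrow(sd) > 0 && any(sd$involves_3prime)
    out <- rbind(
        .verdict("length_25_35", len >= 25L && len <= 35L, len, "25-35 nt"),
        .verdict("gc_40_60", gc >= 40 && gc <= 60, .round1(gc), "40-60%"),
        .verdict("tm_ge_65", tm >= 65, .round1(tm), ">= 65 C",
                 advisory = TRUE),
        .verdict("no_3prime_self_dimer", !bad_sd,
                 if (bad_sd) "3'-involving run" else "none",
                 sprintf("no self-dimer run >= %d at 3' end", min_run)))
    if (!is.null(parent)) {
        stopifnot(is(parent, "SSP"))
        overlap <- .longestSharedSubstring(s@sequence, parent@sequence)
        out <- rbind(out, .verdict(
            "no_parent_overlap", overlap < min_run, overlap,
            "outer and nested primers preferably should not overlap",
            advisory = TRUE))
    }
    out
}

.longestSharedSubstring <- function(a, b) {
    best <- 0L
    for (L in seq(nchar(a), 1L)) {
        starts <- seq_len(nchar(a) - L + 1L)
        subs <- substring(a, starts, starts + L - 1L)
        if (any(vapply(subs, grepl, NA, x = b, fixed = TRUE))) {
            best <- L
            break
        }
    }
    best
}

## ---- catalog -------------------------------------------------------------

#' Load the bundled primer catalog
#'
#' Returns the 25 PST primers (a common 19-nt adapter, a dN10 block and one
#' 6-nt restriction-site palindrome each), the universal tail primer (5600,
#' identical to the adapter), and the 12 SSPs targeting the VRN1 gene with
#' their orientations. Catalog files are plain TSV under
#' \code{inst/extdata}; an integrity check rebuilds every PST primer through
#' [buildPstPrimer()] at load time.
#'
#' The printed reference metrics carried alongside the catalog (columns
#' \code{printed_*}) are the values reported with the original primer set
#' and are retained for regression auditing.
#'
#' @return a list with elements \code{pst} (named list of
#'   [PSTPrimer-class]), \code{tail} (character), \code{ssp} (named list of
#'   [SSP-class]), and \code{tables} (the raw catalog data.frames)
#' @examples
#' cat <- loadCatalog()
#' length(cat$pst)  # 25
#' cat$tail         # "GTTGCGGCAGGTCCTCACC"
#' @export
loadCatalog <- function() {
    dir <- system.file("extdata", package = "pstwalk", mustWork = TRUE)
    pst_tab <- read.delim(file.path(dir, "pst_primers.tsv"),
                          colClasses = c(id = "character"))
    tail_tab <- read.delim(file.path(dir, "tail_primer.tsv"),
                           colClasses = c(id = "character"))
    ssp_tab <- read.delim(file.path(dir, "ssp_primers.tsv"),
                          colClasses = c(id = "character",
                                         nested_parent = "character"))
    if (nrow(pst_tab) != 25L || nrow(tail_tab) != 1L)
        stop("corrupt bundled catalog: unexpected row counts")
    pst <- lapply(seq_len(nrow(pst_tab)), function(i)
        buildPstPrimer(pst_tab$adapter[i], pst_tab$palindrome[i],
                       pst_tab$n_len[i], id = pst_tab$id[i],
                       enzyme = pst_tab$enzyme[i]))
    names(pst) <- pst_tab$id
    tail_seq <- ntSeq(tail_tab$sequence[1L])
    if (nchar(tail_seq) != 19L ||
        !all(vapply(pst, function(p) identical(p@adapter, tail_seq), NA)))
        stop("corrupt bundled catalog: tail primer must equal every adapter")
    ssps <- lapply(seq_len(nrow(ssp_tab)), function(i)
        ssp(ssp_tab$id[i], ssp_tab$sequence[i], ssp_tab$orientation[i],
            ssp_tab$target_note[i], ssp_tab$nested_parent[i]))
    names(ssps) <- ssp_tab$id
    list(pst = pst, tail = tail_seq, ssp = ssps,
         tables = list(pst = pst_tab, tail = tail_tab, ssp = ssp_tab))
}

#' Catalog-style metrics table
#'
#' Computes, for each primer, the columns of a primer-design report:
#' palindrome (for PST primers), nearest-neighbor Tm of the
#' template-pairing sequence (the core for PST primers, the whole sequence
#' otherwise), degenerate-weighted GC% of that sequence, and linguistic
#' complexity of the palindrome. Rounding matches report convention: one
#' decimal for Tm and GC, integer for LC.
#'
#' @param catalog a catalog list from [loadCatalog()]; default loads the
#'   bundled one
#' @return a data.frame with one row per primer (tail primer first)
#' @examples
#' head(primerMetricsTable())
#' @export
primerMetricsTable <- function(catalog = loadCatalog()) {
    rows <- list()
    tail_seq <- catalog$tail
    rows[[1L]] <- data.frame(
        id = catalog$tables$tail$id[1L], sequence = tail_seq,
        palindrome = NA_character_, enzyme = NA_character_,
        Tm_C = .round1(meltingTemperature(tail_seq, SSP_CONDITIONS)),
        GC_pct = .round1(gcPercent(tail_seq)),
        LC_pct = floor(linguisticComplexity(tail_seq) + 0.5),
        stringsAsFactors = FALSE)
    for (p in catalog$pst) {
        core <- coreSequence(p)
        rows[[length(rows) + 1L]] <- data.frame(
            id = p@id, sequence = primerSequence(p),
            palindrome = p@palindrome, enzyme = p@enzyme,
            Tm_C = .round1(meltingTemperature(core, PST_CONDITIONS)),
            GC_pct = .round1(gcPercent(core)),
            LC_pct = floor(linguisticComplexity(p@palindrome) + 0.5),
            stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
}
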