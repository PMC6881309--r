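## Two-round virtual PST-PCR. Round 1 pairs one SSP with one PST primer
## whose core (dN block + 3' palindrome) anchors at a palindromic site and
## whose degenerate block pairs the flank on the side facing the SSP.
## Round 2 replaces the PST primer's adapter with the identical-length tail
## primer (and optionally the outer SSP with a nested one), so round-1 and
## round-2 lengths coincide unless a nested SSP shortens the product.

.asTemplateString <- function(template) {
    if (is(template, "DNAStringSet")) {
        stopifnot(length(template) == 1L)
        template <- template[[1L]]
    }
    if (is(template, "DNAString")) as.character(template) else ntSeq(template)
}

.isUnambiguous <- function(s) !grepl("[^ACGT]", s)

#' Locate SSP annealing sites on a template
#'
#' Finds all plus- and minus-strand footprints where the SSP matches with
#' at most \code{cfg@sspMaxMismatches} mismatches, degenerate SSP codes
#' matching by IUPAC containment, under the constraint that the
#' 3'-terminal \code{cfg@sspSeedLen} bases match perfectly (a mismatched
#' 3' terminus is not extensible). Footprints overlapping N never anneal.
#'
#' @param template template sequence (character/DNAString/one-record set)
#' @param s an [SSP-class] object
#' @param cfg a [PCRConfig-class]; defaults used when omitted
#' @return a data.frame with columns primer_id, start, end (0-based
#'   half-open), strand ("+" extends rightward, "-" leftward), mismatches,
#'   three_prime_pos (coordinate of the primer's 3'-terminal paired base)
#' @examples
#' tpl <- paste0(strrep("A", 20), "CTGAAGCGGATCGAGAACAAGATCAACC",
#'               strrep("T", 20))
#' cat <- loadCatalog()
#' findSspSites(tpl, cat$ssp[["5315"]])
#' @export
findSspSites <- function(template, s, cfg = pcrConfig()) {
    stopifnot(is(s, "SSP"), is(cfg, "PCRConfig"))
    tpl <- .asTemplateString(template)
    pat <- s@sequence
    n <- nchar(pat)
    seed <- min(cfg@sspSeedLen, n)
    subj <- Biostrings::DNAString(tpl)
    scanStrand <- function(pattern, strand) {
        hits <- Biostrings::matchPattern(
            pattern, subj, max.mismatch = cfg@sspMaxMismatches,
            fixed = "subject")
        starts <- Biostrings::start(hits) - 1L
        rows <- lapply(starts, function(st) {
            tgt <- substr(tpl, st + 1L, st + n)
            if (!.isUnambiguous(tgt)) return(NULL)
            mv <- .matchVec(strsplit(pattern, "")[[1]],
                            strsplit(tgt, "")[[1]])
            mm <- sum(!mv)
            if (mm > cfg@sspMaxMismatches) return(NULL)
            ## seed = the primer's 3'-terminal bases: pattern end on "+",
            ## pattern start on "-" (the pattern is already revcomp'ed)
            seed_ok <- if (strand == "+") all(mv[(n - seed + 1L):n])
                       else all(mv[seq_len(seed)])
            if (!seed_ok) return(NULL)
            data.frame(primer_id = s@id, start = st, end = st + n,
                       strand = strand, mismatches = mm,
                       three_prime_pos = if (strand == "+") st + n - 1L
                                         else st,
                       stringsAsFactors = FALSE)
        })
        do.call(rbind, rows)
    }
    fwd <- scanStrand(pat, "+")
    rev <- scanStrand(revComp(pat), "-")
    out <- rbind(fwd, rev)
    if (is.null(out)) return(data.frame(
        primer_id = character(), start = integer(), end = integer(),
        strand = character(), mismatches = integer(),
        three_prime_pos = integer(), stringsAsFactors = FALSE))
    out[order(out$start, out$strand), , drop = FALSE]
}

#' Feasible PST-primer annealing orientations at palindromic sites
#'
#' At every palindromic site two annealing orientations are conceivable:
#' the fully degenerate block can pair with either flank of the palindrome.
#' An orientation is feasible when the flank covered by the degenerate
#' block lies fully inside the template and contains no N. Orientation "+"
#' (block pairs the left flank) extends rightward; "-" (block pairs the
#' right flank) extends leftward.
#'
#' @param template template sequence
#' @param pst a [PSTPrimer-class]
#' @param window optional integer c(start, end), 0-based half-open, to
#'   restrict the scanned region
#' @param extend_toward "both", "left" or "right": keep only orientations
#'   whose extension direction points that way (toward the SSP)
#' @return a data.frame with columns primer_id, site_pos, start, end
#'   (core footprint, 0-based half-open), strand, extends
#' @export
findPstAnneal <- function(template, pst, window = NULL,
                          extend_toward = c("both", "left", "right")) {
    stopifnot(is(pst, "PSTPrimer"))
    extend_toward <- match.arg(extend_toward)
    tpl <- .asTemplateString(template)
    L <- nchar(tpl)
    pal <- nchar(pst@palindrome)
    nlen <- pst@degenerateLen
    sites <- scanPstSites(tpl, pst@palindrome)@positions
    if (!is.null(window)) {
        stopifnot(length(window) == 2L, window[1] >= 0, window[2] <= L)
        sites <- sites[sites >= window[1L] & sites + pal <= window[2L]]
    }
    rows <- list()
    for (p in sites) {
        ## "-": primer on the minus strand; block pairs the right flank
        if (extend_toward %in% c("both", "left")) {
            flank <- substr(tpl, p + pal + 1L, p + pal + nlen)
            if (p + pal + nlen <= L && .isUnambiguous(flank))
                rows[[length(rows) + 1L]] <- data.frame(
                    primer_id = pst@id, site_pos = p, start = p,
                    end = p + pal + nlen, strand = "-", extends = "left",
                    stringsAsFactors = FALSE)
        }
        ## "+": primer on the plus strand; block pairs the left flank
        if (extend_toward %in% c("both", "right")) {
            flank <- if (p >= nlen) substr(tpl, p - nlen + 1L, p) else ""
            if (p - nlen >= 0L && .isUnambiguous(flank))
                rows[[length(rows) + 1L]] <- data.frame(
                    primer_id = pst@id, site_pos = p, start = p - nlen,
                    end = p + pal, strand = "+", extends = "right",
                    stringsAsFactors = FALSE)
        }
    }
    if (!length(rows)) return(data.frame(
        primer_id = character(), site_pos = integer(), start = integer(),
        end = integer(), strand = character(), extends = character(),
        stringsAsFactors = FALSE))
    do.call(rbind, rows)
}

.emptyAmpliconTable <- function() {
    data.frame(ssp_id = character(), pst_id = character(),
               record = character(), start = integer(), end = integer(),
               strand = character(), orientation = character(),
               site_pos = integer(), round1_len_bp = integer(),
               round2_len_bp = integer(), side_product = logical(),
               stringsAsFactors = FALSE)
}

#' Predict two-round PST-PCR amplicons
#'
#' For every (SSP annealing site, compatible PST orientation) pair with the
#' PST core downstream of the SSP 3' end in its extension direction, emits
#' one predicted product. The round-2 length is the distance from the SSP
#' 5' coordinate to the far edge of the PST core footprint plus the tail
#' length (the tail replaces the identical-length adapter). When
#' \code{cfg@secondRoundSsp} names a nested SSP, the round-2 length is
#' recomputed from the nested SSP's 5' coordinate (site nearest the outer
#' SSP); outer sites whose product contains no nested annealing site yield
#' no round-2 product and are dropped. Products are filtered to
#' [minProductBp, maxProductBp] on the round-2 length (round 1 must also
#' not exceed the polymerase limit).
#'
#' @param template template sequence
#' @param s outer [SSP-class]
#' @param pst [PSTPrimer-class]
#' @param tail tail primer sequence; must equal the PST primer's adapter
#'   (it anneals to the adapter sequence). Defaults to the adapter.
#' @param cfg a [PCRConfig-class]
#' @param nested the nested [SSP-class] when \code{cfg@secondRoundSsp} is
#'   not "same"
#' @param seq_id record name for the output
#' @return an amplicon table (data.frame); zero rows when nothing amplifies
#' @examples
#' cat <- loadCatalog()
#' tpl <- paste0(strrep("A", 100), "CTGAAGCGGATCGAGAACAAGATCAACC",
#'               strrep("AC", 200), "GGATCC", strrep("T", 50))
#' predictAmplicons(tpl, cat$ssp[["5315"]], cat$pst[["5605"]])
#' @export
predictAmplicons <- function(template, s, pst, tail = adapterSequence(pst),
                             cfg = pcrConfig(), nested = NULL,
                             seq_id = "template") {
    stopifnot(is(s, "SSP"), is(pst, "PSTPrimer"), is(cfg, "PCRConfig"))
    tail <- ntSeq(tail)
    if (!identical(tail, pst@adapter))
        stop("tail primer must equal the PST primer's adapter ",
             "(it anneals to the adapter sequence)")
    use_nested <- !identical(cfg@secondRoundSsp, "same")
    if (use_nested) {
        if (is.null(nested) || !is(nested, "SSP") ||
            !identical(nested@id, cfg@secondRoundSsp))
            stop(sprintf("config requests nested SSP '%s'; pass it as 'nested'",
                         cfg@secondRoundSsp))
    }
    tpl <- .asTemplateString(template)
    pal <- nchar(pst@palindrome)
    nlen <- pst@degenerateLen
    tl <- nchar(tail)
    ssp_sites <- findSspSites(tpl, s, cfg)
    pst_sites <- findPstAnneal(tpl, pst)
    nested_sites <- if (use_nested) findSspSites(tpl, nested, cfg) else NULL
    rows <- list()
    for (i in seq_len(nrow(ssp_sites))) {
        fs <- ssp_sites$start[i]
        fe <- ssp_sites$end[i]
        if (ssp_sites$strand[i] == "+") {
            cand <- pst_sites[pst_sites$strand == "-" &
                              pst_sites$site_pos >= fe, , drop = FALSE]
            for (k in seq_len(nrow(cand))) {
                far <- cand$end[k]          # p + pal + nlen
                r1 <- (far - fs) + nchar(pst@adapter)
                r2 <- (far - fs) + tl
                s2 <- fs
                if (use_nested) {
                    nn <- nested_sites[nested_sites$strand == "+" &
                                       nested_sites$start >= fs &
                                       nested_sites$end <= cand$site_pos[k], ,
                                       drop = FALSE]
                    if (!nrow(nn)) next
                    s2 <- min(nn$start)     # nested site nearest the outer SSP
                    r2 <- (far - s2) + tl
                }
                if (r1 > cfg@maxProductBp) next
                if (r2 < cfg@minProductBp || r2 > cfg@maxProductBp) next
                rows[[length(rows) + 1L]] <- data.frame(
                    ssp_id = s@id, pst_id = pst@id, record = seq_id,
                    start = fs, end = far, strand = "+",
                    orientation = "SSP-forward",
                    site_pos = cand$site_pos[k],
                    round1_len_bp = r1, round2_len_bp = r2,
                    side_product = FALSE, stringsAsFactors = FALSE)
            }
        } else {
            cand <- pst_sites[pst_sites$strand == "+" &
                              pst_sites$site_pos + pal <= fs, , drop = FALSE]
            for (k in seq_len(nrow(cand))) {
                far <- cand$start[k]        # p - nlen
                r1 <- (fe - far) + nchar(pst@adapter)
                r2 <- (fe - far) + tl
                e2 <- fe
                if (use_nested) {
                    nn <- nested_sites[nested_sites$strand == "-" &
                                       nested_sites$end <= fe &
                                       nested_sites$start >=
                                           cand$site_pos[k] + pal, ,
                                       drop = FALSE]
                    if (!nrow(nn)) next
                    e2 <- max(nn$end)
                    r2 <- (e2 - far) + tl
                }
                if (r1 > cfg@maxProductBp) next
                if (r2 < cfg@minProductBp || r2 > cfg@maxProductBp) next
                rows[[length(rows) + 1L]] <- data.frame(
                    ssp_id = s@id, pst_id = pst@id, record = seq_id,
                    start = far, end = fe, strand = "-",
                    orientation = "SSP-reverse",
                    site_pos = cand$site_pos[k],
                    round1_len_bp = r1, round2_len_bp = r2,
                    side_product = FALSE, stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(rows)) return(.emptyAmpliconTable())
    out <- do.call(rbind, rows)
    out[order(out$round2_len_bp, out$start), , drop = FALSE]
}

#' Enumerate PST-PST side products
#'
#' Products flanked by the walking primer at both ends (RAPD-like side
#' products): pairs of palindromic sites whose feasible orientations face
#' each other within the product-length bounds. Such products are flagged,
#' never scored - in practice specific SSP-anchored products outcompete
#' them.
#'
#' @param template template sequence
#' @param pst a [PSTPrimer-class]
#' @param cfg a [PCRConfig-class] with \code{reportSideProducts = TRUE}
#' @param seq_id record name for the output
#' @return an amplicon table with \code{side_product = TRUE}
#' @export
enumerateSideProducts <- function(template, pst, cfg = pcrConfig(),
                                  seq_id = "template") {
    stopifnot(is(pst, "PSTPrimer"), is(cfg, "PCRConfig"))
    if (!cfg@reportSideProducts)
        stop("side-product reporting is disabled in this configuration")
    tpl <- .asTemplateString(template)
    pal <- nchar(pst@palindrome)
    al <- nchar(pst@adapter)
    anneal <- findPstAnneal(tpl, pst)
    right_ext <- anneal[anneal$strand == "+", , drop = FALSE]
    left_ext <- anneal[anneal$strand == "-", , drop = FALSE]
    rows <- list()
    for (i in seq_len(nrow(right_ext))) {
        p1 <- right_ext$site_pos[i]
        cand <- left_ext[left_ext$site_pos >= p1 + pal, , drop = FALSE]
        for (k in seq_len(nrow(cand))) {
            span <- cand$end[k] - right_ext$start[i]
            len <- span + 2L * al
            if (len < cfg@minProductBp || len > cfg@maxProductBp) next
            rows[[length(rows) + 1L]] <- data.frame(
                ssp_id = NA_character_, pst_id = pst@id, record = seq_id,
                start = right_ext$start[i], end = cand$end[k],
                strand = "*", orientation = "PST-PST",
                site_pos = p1, round1_len_bp = len, round2_len_bp = len,
                side_product = TRUE, stringsAsFactors = FALSE)
        }
    }
    if (!length(rows)) return(.emptyAmpliconTable())
    out <- do.call(rbind, rows)
    out[order(out$round2_len_bp, out$start), , drop = FALSE]
}

#' Predicted product sequence for one amplicon row
#'
#' The second-round product written 5' to 3' from the tail primer: tail,
#' the degenerate block rendered as N (each product molecule carries the
#' random realization synthesized into its primer, not template sequence),
#' the palindrome, then the template-derived span ending in the SSP.
#'
#' @param template template sequence
#' @param row one row of an amplicon table
#' @param pst the [PSTPrimer-class] that produced the row
#' @param tail tail primer sequence
#' @return a character scalar whose nchar equals \code{row$round2_len_bp}
#'   (for SSP-anchored products)
#' @export
productSequence <- function(template, row, pst, tail = adapterSequence(pst)) {
    tpl <- .asTemplateString(template)
    nlen <- pst@degenerateLen
    pal <- nchar(pst@palindrome)
    if (isTRUE(row$side_product)) {
        inner <- substr(tpl, row$start + nlen + 1L, row$end - nlen)
        return(paste0(tail, strrep("N", nlen), inner,
                      strrep("N", nlen), revComp(tail)))
    }
    if (row$strand == "+") {
        span <- substr(tpl, row$start + 1L, row$site_pos + pal)
        paste0(tail, strrep("N", nlen), revComp(span))
    } else {
        span <- substr(tpl, row$site_pos + 1L, row$end)
        paste0(tail, strrep("N", nlen), span)
    }
}

#' Cartesian virtual PST-PCR screen
#'
#' Runs [predictAmplicons()] for every combination of template record,
#' selected SSP and selected PST primer - the screen recommended before
#' committing a walking experiment - and, when enabled, appends PST-PST
#' side products per (record, PST primer). Rows are ordered by
#' (ssp_id, pst_id, record, round-2 length), shortest products first.
#'
#' @param templates FASTA path or named [Biostrings::DNAStringSet]
#' @param ssp_ids SSP ids to screen (default: all catalog SSPs)
#' @param catalog catalog list from [loadCatalog()]
#' @param cfg a [PCRConfig-class]
#' @param pst_ids "all" or a character vector of PST primer ids
#' @return an amplicon table over all combinations
#' @export
runWalk <- function(templates, ssp_ids = NULL, catalog = loadCatalog(),
                    cfg = pcrConfig(), pst_ids = "all") {
    tset <- if (is(templates, "DNAStringSet")) templates
            else readTemplates(templates)
    if (is.null(names(tset)))
        names(tset) <- paste0("seq", seq_along(tset))
    if (is.null(ssp_ids)) ssp_ids <- names(catalog$ssp)
    ssp_ids <- as.character(ssp_ids)
    unknown <- setdiff(ssp_ids, names(catalog$ssp))
    if (length(unknown))
        stop(sprintf("unknown SSP id(s) %s; available: %s",
                     paste(unknown, collapse = ", "),
                     paste(names(catalog$ssp), collapse = ", ")))
    if (identical(pst_ids, "all")) pst_ids <- names(catalog$pst)
    pst_ids <- as.character(pst_ids)
    unknown <- setdiff(pst_ids, names(catalog$pst))
    if (length(unknown))
        stop(sprintf("unknown PST primer id(s) %s; available: %s",
                     paste(unknown, collapse = ", "),
                     paste(names(catalog$pst), collapse = ", ")))
    nested <- NULL
    if (!identical(cfg@secondRoundSsp, "same")) {
        if (!cfg@secondRoundSsp %in% names(catalog$ssp))
            stop(sprintf("unknown nested SSP id '%s'", cfg@secondRoundSsp))
        nested <- catalog$ssp[[cfg@secondRoundSsp]]
    }
    tabs <- list()
    any_ssp_site <- FALSE
    for (rec in names(tset)) {
        tpl <- as.character(tset[[rec]])
        for (sid in ssp_ids) {
            sobj <- catalog$ssp[[sid]]
            if (nrow(findSspSites(tpl, sobj, cfg)) > 0) any_ssp_site <- TRUE
            for (pid in pst_ids) {
                tabs[[length(tabs) + 1L]] <- predictAmplicons(
                    tpl, sobj, catalog$pst[[pid]], catalog$tail, cfg,
                    nested = nested, seq_id = rec)
            }
        }
        if (cfg@reportSideProducts)
            for (pid in pst_ids)
                tabs[[length(tabs) + 1L]] <- enumerateSideProducts(
                    tpl, catalog$pst[[pid]], cfg, seq_id = rec)
    }
    out <- do.call(rbind, tabs)
    if (is.null(out) || !nrow(out)) out <- .emptyAmpliconTable()
    if (!any_ssp_site)
        warning("no SSP annealing site found on any template; check SSP ",
                "design and template quality (troubleshooting item 1)")
    out <- out[order(out$ssp_id, out$pst_id, out$record,
                     out$round2_len_bp, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
}
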