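## Sequence metrics used in primer design and auditing: degenerate-weighted
## GC content, nearest-neighbor melting temperature, linguistic complexity,
## and combinatorial hairpin / primer-dimer screens.

## expected G+C content of one IUPAC code at equimolar degeneracy
.GC_WEIGHT <- c(A = 0, C = 1, G = 1, T = 0,
                S = 1, W = 0,
                R = 0.5, Y = 0.5, K = 0.5, M = 0.5, N = 0.5,
                B = 2 / 3, V = 2 / 3, D = 1 / 3, H = 1 / 3)

#' GC percentage with degenerate-base weighting
#'
#' Each residue contributes its expected G+C fraction under equimolar
#' degeneracy: 1 for G/C/S, 0 for A/T/W, 0.5 for R/Y/K/M/N, 2/3 for B/V and
#' 1/3 for D/H. For a PST primer the GC column of a design report is
#' computed on the core (degenerate block + palindrome), where the ten N
#' positions each contribute 0.5.
#'
#' @param x sequence (character or DNAString); IUPAC codes allowed
#' @return unrounded percentage (report writers round to one decimal)
#' @examples
#' gcPercent("NNNNNNNNNNGACGTC")  # 56.25 -> printed 56.3
#' gcPercent("NNNN")              # 50
#' @export
gcPercent <- function(x) {
    x <- ntSeq(x)
    if (nchar(x) == 0L) stop("gcPercent is undefined for the empty sequence")
    w <- .GC_WEIGHT[strsplit(x, "")[[1]]]
    100 * sum(w) / nchar(x)
}

## Unified nearest-neighbor duplex parameters (dH kcal/mol, dS cal/mol/K),
## 1 M NaCl reference, plus initiation terms per terminal base pair.
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
.INIT_GC <- c(dH = 0.1, dS = -2.8)
.INIT_AT <- c(dH = 2.3, dS = 4.1)

.expand <- function(code) strsplit(.IUPAC[[code]], "")[[1]]

## mean dH/dS of one stack over the realizations of two IUPAC codes
.stackParams <- function(c1, c2) {
    keys <- as.vector(outer(.expand(c1), .expand(c2), paste0))
    c(dH = mean(.NN_DH[keys]), dS = mean(.NN_DS[keys]))
}

## mean initiation term over the realizations of a terminal code
.initParams <- function(code) {
    f_gc <- mean(.expand(code) %in% c("G", "C"))
    f_gc * .INIT_GC + (1 - f_gc) * .INIT_AT
}

#' Nearest-neighbor melting temperature
#'
#' Duplex Tm from nearest-neighbor dH/dS accumulation with initiation terms
#' (unified parameter set, 1 M Na+ reference), an entropic salt correction
#' of 0.368 cal/(mol K) per stack times ln of the effective monovalent
#' concentration, and the bimolecular term R ln(CT/4) with CT the primer
#' concentration. Mg2+ is folded into the effective monovalent concentration
#' by the square-root equivalence (120 sqrt(mM Mg) mM). Degenerate positions
#' contribute the arithmetic mean of the stack parameters over their allowed
#' realizations, modeling an equimolar synthesis pool.
#'
#' @param x sequence of length >= 8 (degenerate codes allowed)
#' @param cond an [IonicConditions-class] object; default [PST_CONDITIONS]
#' @return melting temperature in degrees Celsius
#' @examples
#' meltingTemperature("GTTGCGGCAGGTCCTCACC", SSP_CONDITIONS)
#' @export
meltingTemperature <- function(x, cond = PST_CONDITIONS) {
    x <- ntSeq(x)
    n <- nchar(x)
    if (n < 8L)
        stop("melting temperature requires length >= 8 (no stack statistics)")
    stopifnot(is(cond, "IonicConditions"))
    ch <- strsplit(x, "")[[1]]
    dH <- 0
    dS <- 0
    for (i in seq_len(n - 1L)) {
        p <- .stackParams(ch[i], ch[i + 1L])
        dH <- dH + p[["dH"]]
        dS <- dS + p[["dS"]]
    }
    ini <- .initParams(ch[1L]) + .initParams(ch[n])
    dH <- dH + ini[["dH"]]
    dS <- dS + ini[["dS"]]
    na_eq <- (cond@monovalent_mM + 120 * sqrt(cond@divalent_mM)) / 1000  # M
    if (na_eq <= 0) stop("effective monovalent concentration must be > 0")
    dS_salt <- dS + 0.368 * (n - 1L) * log(na_eq)
    ct <- cond@primer_uM * 1e-6
    tm_k <- dH * 1000 / (dS_salt + 1.987 * log(ct / 4))
    tm_k - 273.15
}

#' Linguistic complexity
#'
#' Vocabulary-usage measure: the number of distinct k-mers observed, summed
#' over word lengths 1..max_word, divided by the maximum attainable
#' (min(4^k, L - k + 1) per word length), times 100. With the default
#' max_word = 2 this reproduces the 6-nt restriction-site LC column of the
#' bundled primer catalog (e.g. ATCGAT: 4 distinct 1-mers + 4 distinct
#' 2-mers out of 4 + 5 = 88.9, printed 89).
#'
#' @param x unambiguous sequence
#' @param max_word longest word length considered (default 2)
#' @return unrounded percentage (report writers round to integer)
#' @examples
#' linguisticComplexity("GGATCC")  # 100
#' @export
linguisticComplexity <- function(x, max_word = 2L) {
    x <- ntSeq(x)
    ch <- strsplit(x, "")[[1]]
    if (!all(ch %in% c("A", "C", "G", "T")))
        stop("linguistic complexity is defined only on unambiguous sequences")
    max_word <- as.integer(max_word)
    if (nchar(x) < max_word)
        stop("sequence shorter than max_word")
    obs <- 0L
    denom <- 0L
    for (k in seq_len(max_word)) {
        words <- substring(x, seq_len(nchar(x) - k + 1L),
                           seq_len(nchar(x) - k + 1L) + k - 1L)
        obs <- obs + length(unique(words))
        denom <- denom + min(4^k, nchar(x) - k + 1L)
    }
    100 * obs / denom
}

.PAIR <- c(A = "T", T = "A", G = "C", C = "G")

## weight of one base pair in the stability score (degenerate = no pair)
.pairWeight <- function(a, b) {
    if (!a %in% names(.PAIR) || !b %in% names(.PAIR)) return(0)
    if (.PAIR[[a]] == b) (if (a %in% c("G", "C")) 3 else 2) else 0
}

.emptyDuplexReport <- function() {
    data.frame(partner_kind = character(), a_start = integer(),
               a_end = integer(), b_start = integer(), b_end = integer(),
               stem_len = integer(), loop_len = integer(),
               involves_3prime = logical(), stability_score = numeric(),
               stringsAsFactors = FALSE)
}

#' Screen a primer for self-hairpins
#'
#' Enumerates all maximal intramolecular stems: runs of base pairs between
#' disjoint spans of the primer, read antiparallel, of length >= min_stem
#' and enclosing a loop of >= min_loop unpaired bases. Degenerate positions
#' never pair. The stability score sums per-pair weights (G:C = 3, A:T = 2).
#' A 3'-terminal hairpin (one whose paired span includes the primer's final
#' base) blocks extension and is the unfavorable configuration screened for
#' in PST-primer design.
#'
#' Reported spans are 1-based inclusive.
#'
#' @param primer primer sequence
#' @param min_stem minimum stem length in base pairs (default 4)
#' @param min_loop minimum loop length in bases (default 3)
#' @return a data.frame of duplex reports (zero rows when no stem exists)
#' @examples
#' hairpinScreen("GGGGAAATTTCCCC")
#' @export
hairpinScreen <- function(primer, min_stem = 4L, min_loop = 3L) {
    primer <- ntSeq(primer)
    ch <- strsplit(primer, "")[[1]]
    n <- length(ch)
    out <- .emptyDuplexReport()
    if (n < 2L * min_stem + min_loop) return(out)
    ## pairs (i, j), i < j, live on anti-diagonals d = i + j
    for (d in seq(0L, 2L * n - 3L)) {
        i <- max(0L, d - n + 1L)
        runs <- list()
        run_start <- NA_integer_
        while (2L * i < d) {  # strictly i < j
            j <- d - i
            paired <- j < n && .pairWeight(ch[i + 1L], ch[j + 1L]) > 0
            if (paired && is.na(run_start)) run_start <- i
            if ((!paired || 2L * (i + 1L) >= d) && !is.na(run_start)) {
                run_end <- if (paired) i else i - 1L
                runs[[length(runs) + 1L]] <- c(run_start, run_end)
                run_start <- NA_integer_
            }
            i <- i + 1L
        }
        for (r in runs) {
            i0 <- r[1L]
            raw <- r[2L] - r[1L] + 1L
            j0 <- d - i0
            ## trim the stem so the enclosed loop stays >= min_loop
            L <- min(raw, (j0 - i0 + 1L - min_loop) %/% 2L)
            if (L < min_stem) next
            ia <- i0; ja <- j0  # outermost pair of trimmed stem
            score <- sum(vapply(seq_len(L) - 1L, function(k)
                .pairWeight(ch[ia + k + 1L], ch[ja - k + 1L]), 0))
            out <- rbind(out, data.frame(
                partner_kind = "self-hairpin",
                a_start = ia + 1L, a_end = ia + L,
                b_start = ja - L + 2L, b_end = ja + 1L,
                stem_len = L, loop_len = (ja - L + 1L) - (ia + L - 1L) - 1L,
                involves_3prime = (ja + 1L) == n,
                stability_score = score, stringsAsFactors = FALSE))
        }
    }
    out[order(out$a_start, out$b_start), , drop = FALSE]
}

#' Screen two primers for antiparallel dimers
#'
#' Enumerates all maximal ungapped antiparallel complementary runs of
#' length >= min_run between primers a and b (b may equal a, giving the
#' self-dimer screen). Runs that involve either primer's 3' terminus are
#' extensible by the polymerase and are the problematic class: the
#' 3'-terminal palindromes of two PST primers always pair this way, which
#' is why a hot start is part of the PST-PCR protocol.
#'
#' Reported spans are 1-based inclusive; the b span is given in b's own
#' 5'-to-3' coordinates.
#'
#' @param a,b primer sequences
#' @param min_run minimum complementary run length (default 4)
#' @return a data.frame of duplex reports
#' @examples
#' dimerScreen("GTTGCGGCAGGTCCTCACCNNNNNNNNNNGGATCC",
#'             "GTTGCGGCAGGTCCTCACCNNNNNNNNNNGGATCC")
#' @export
dimerScreen <- function(a, b, min_run = 4L) {
    a <- ntSeq(a)
    b <- ntSeq(b)
    if (nchar(a) == 0L || nchar(b) == 0L) stop("both primers must be non-empty")
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    la <- length(ca)
    lb <- length(cb)
    kind <- if (identical(a, b)) "self-dimer" else "cross-dimer"
    out <- .emptyDuplexReport()
    ## antiparallel alignment: a[i] pairs b[j] with i + j = d constant
    for (d in seq(0L, la + lb - 2L)) {
        i_lo <- max(0L, d - lb + 1L)
        i_hi <- min(la - 1L, d)
        run_start <- NA_integer_
        for (i in seq(i_lo, i_hi)) {
            paired <- .pairWeight(ca[i + 1L], cb[d - i + 1L]) > 0
            if (paired && is.na(run_start)) run_start <- i
            if ((!paired || i == i_hi) && !is.na(run_start)) {
                i_end <- if (paired) i else i - 1L
                L <- i_end - run_start + 1L
                if (L >= min_run) {
                    j_hi <- d - run_start
                    score <- sum(vapply(seq_len(L) - 1L, function(k)
                        .pairWeight(ca[run_start + k + 1L],
                                    cb[j_hi - k + 1L]), 0))
                    out <- rbind(out, data.frame(
                        partner_kind = kind,
                        a_start = run_start + 1L, a_end = i_end + 1L,
                        b_start = j_hi - L + 2L, b_end = j_hi + 1L,
                        stem_len = L, loop_len = NA_integer_,
                        involves_3prime = (i_end + 1L == la) ||
                            (j_hi + 1L == lb),
                        stability_score = score, stringsAsFactors = FALSE))
                }
                run_start <- NA_integer_
            }
        }
    }
    out[order(out$a_start, out$b_start), , drop = FALSE]
}
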