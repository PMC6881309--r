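## Brute-force oracles, coded independently of the package internals.
## These define ground truth for the combinatorial operations: character
## tables and exhaustive enumeration only, no Biostrings.

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A",
                 R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                 B = "V", V = "B", D = "H", H = "D", N = "N")

ORACLE_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                    W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                    B = c("C", "G", "T"), D = c("A", "G", "T"),
                    H = c("A", "C", "T"), V = c("A", "C", "G"),
                    N = c("A", "C", "G", "T"))

oracleRevComp <- function(x) {
    ch <- strsplit(x, "")[[1]]
    paste(rev(unname(ORACLE_COMP[ch])), collapse = "")
}

## palindrome by explicit character-pair comparison
oraclePalindrome <- function(x) {
    ch <- strsplit(x, "")[[1]]
    n <- length(ch)
    if (n %% 2 != 0) return(FALSE)
    all(vapply(seq_len(n), function(i)
        ORACLE_COMP[[ch[i]]] == ch[n - i + 1], NA))
}

## full realization set of a degenerate pattern
oracleExpand <- function(pattern) {
    ch <- strsplit(pattern, "")[[1]]
    out <- ""
    for (c in ch) out <- as.vector(outer(out, ORACLE_SETS[[c]], paste0))
    out
}

oracleMatches <- function(pattern, target) target %in% oracleExpand(pattern)

## sliding-window exact scan, 0-based starts
oracleScan <- function(template, motif) {
    n <- nchar(template)
    w <- nchar(motif)
    if (n < w) return(integer())
    starts <- seq_len(n - w + 1)
    which(substring(template, starts, starts + w - 1) == motif) - 1L
}

oraclePairWeight <- function(a, b) {
    if (!a %in% c("A", "C", "G", "T") || !b %in% c("A", "C", "G", "T"))
        return(0)
    if (ORACLE_COMP[[a]] == b) (if (a %in% c("G", "C")) 3 else 2) else 0
}

## all maximal hairpin stems by exhaustive span enumeration: spans
## [i, i+L) and [j, j+L) (0-based), j >= i + L + min_loop, antiparallel
## pairing a[i+k] ~ a[j+L-1-k]; maximality = no containing valid stem.
oracleHairpins <- function(x, min_stem = 4, min_loop = 3) {
    ch <- strsplit(x, "")[[1]]
    n <- length(ch)
    stems <- list()
    for (i in seq_len(n) - 1L) for (L in min_stem:max(min_stem, n)) {
        for (j in seq_len(n) - 1L) {
            if (j < i + L + min_loop) next
            if (j + L > n) next
            ok <- all(vapply(seq_len(L) - 1L, function(k)
                oraclePairWeight(ch[i + k + 1], ch[j + L - k]) > 0, NA))
            if (ok) stems[[length(stems) + 1L]] <- c(i = i, j = j, L = L)
        }
    }
    if (!length(stems)) return(data.frame(i = integer(), j = integer(),
                                          L = integer()))
    df <- unique(as.data.frame(do.call(rbind, stems)))
    ## drop stems contained in a longer valid stem on the same diagonal
    keep <- vapply(seq_len(nrow(df)), function(r) {
        a <- df[r, ]
        !any(vapply(seq_len(nrow(df)), function(s) {
            b <- df[s, ]
            s != r && (b$i + b$j + b$L) == (a$i + a$j + a$L) &&
                b$L > a$L && b$i <= a$i && (b$i + b$L) >= (a$i + a$L)
        }, NA))
    }, NA)
    df <- df[keep, , drop = FALSE]
    df[order(df$i, df$j), , drop = FALSE]
}

## all maximal antiparallel dimer runs between a and b: run of length L,
## a[i+k] pairs b[j-k] for k in 0..L-1; maximality = not extensible.
oracleDimers <- function(a, b, min_run = 4) {
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    la <- length(ca)
    lb <- length(cb)
    pair <- function(i, j)  # 0-based, out-of-range = no pair
        i >= 0 && i < la && j >= 0 && j < lb &&
            oraclePairWeight(ca[i + 1], cb[j + 1]) > 0
    runs <- list()
    for (i in seq_len(la) - 1L) for (j in seq_len(lb) - 1L) {
        if (!pair(i, j) || pair(i - 1, j + 1)) next  # not a run start
        L <- 1L
        while (pair(i + L, j - L)) L <- L + 1L
        if (L >= min_run)
            runs[[length(runs) + 1L]] <-
                c(a_start = i + 1L, a_end = i + L,
                  b_start = j - L + 2L, b_end = j + 1L)
    }
    if (!length(runs)) return(data.frame(a_start = integer(),
        a_end = integer(), b_start = integer(), b_end = integer()))
    df <- as.data.frame(do.call(rbind, runs))
    df[order(df$a_start, df$b_start), , drop = FALSE]
}

## String-level two-round PST-PCR simulator: literal annealing and
## extension on character strings. Returns the multiset of second-round
## product lengths for one SSP (given as its realization set) and one PST
## primer, on the plus strand reading of `tpl`; call again on the reverse
## complement for "R" primers.
oracleExtensionLengths <- function(tpl, ssp_realizations, palindrome,
                                   nlen, tail_len, min_bp, max_bp) {
    lens <- integer()
    n <- nchar(tpl)
    for (real in ssp_realizations) {
        w <- nchar(real)
        if (n < w) next
        starts <- which(substring(tpl, seq_len(n - w + 1),
                                  seq_len(n - w + 1) + w - 1) == real)
        for (fs in starts - 1L) {
            ## linear phase: polymerase copies from the SSP to template end
            P1 <- substr(tpl, fs + 1, n)
            ## PST primer anneals where P1 shows the palindrome with a
            ## defined flank long enough for the degenerate block
            for (q in oracleScan(P1, palindrome)) {
                if (q < w) next                     # must sit past the SSP
                flank <- substr(P1, q + nchar(palindrome) + 1,
                                q + nchar(palindrome) + nlen)
                if (nchar(flank) < nlen || grepl("[^ACGT]", flank)) next
                ## extension from the primer 3' end back to P1's 5' end,
                ## then round 2 trims to tail + core + copied span
                P2 <- paste0(strrep("N", tail_len), strrep("N", nlen),
                             palindrome, oracleRevComp(substr(P1, 1, q)))
                if (nchar(P2) >= min_bp && nchar(P2) <= max_bp)
                    lens <- c(lens, nchar(P2))
            }
        }
    }
    lens
}

## realizations of an SSP sequence (degenerate codes expanded); capped
## expansion guard for test safety
sspRealizations <- function(seq) {
    stopifnot(prod(vapply(strsplit(seq, "")[[1]],
                          function(c) length(ORACLE_SETS[[c]]), 0)) <= 64)
    oracleExpand(seq)
}

## independent textbook NN evaluation for an unambiguous sequence:
## hand-indexed parameter sums, written without the package's tables
oracleTmUnambiguous <- function(seq, mono_mM, mg_mM, primer_uM) {
    dh <- c(AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
            CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
            GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
            TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9)
    ds <- c(AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
            CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
            GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
            TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2)
    ch <- strsplit(seq, "")[[1]]
    n <- length(ch)
    stacks <- paste0(ch[-n], ch[-1])
    H <- sum(dh[stacks])
    S <- sum(ds[stacks])
    for (term in ch[c(1, n)]) {
        if (term %in% c("G", "C")) { H <- H + 0.1; S <- S - 2.8 }
        else { H <- H + 2.3; S <- S + 4.1 }
    }
    na <- (mono_mM + 120 * sqrt(mg_mM)) / 1000
    S <- S + 0.368 * (n - 1) * log(na)
    H * 1000 / (S + 1.987 * log(primer_uM * 1e-6 / 4)) - 273.15
}

## random unambiguous / IUPAC strings
randSeq <- function(n, alphabet = c("A", "C", "G", "T"))
    paste(sample(alphabet, n, replace = TRUE), collapse = "")

CATALOG_PALINDROMES <- c(
    "GACGTC", "AACGTT", "TTCGAA", "TGGCCA", "GGATCC", "TGATCA", "AGATCT",
    "ATCGAT", "GAATTC", "GATATC", "AAGCTT", "GTTAAC", "GGTACC", "CCATGG",
    "GCTAGC", "CACGTG", "CTGCAG", "CAGCTG", "GAGCTC", "GTCGAC", "AGTACT",
    "GCATGC", "AGGCCT", "TCTAGA", "CTCGAG")
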