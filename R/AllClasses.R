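#' @import methods
#' @importFrom stats runif setNames
#' @importFrom utils read.delim write.table
NULL

#' Ionic conditions for melting-temperature calculations
#'
#' Holds the reaction conditions that enter the nearest-neighbor melting
#' temperature: monovalent cation concentration (K+/NH4+), free Mg2+, and the
#' primer concentration used in the duplex-initiation term.
#'
#' Two presets are exported: [PST_CONDITIONS] (50 mM monovalent, 2 mM Mg2+,
#' 0.5 uM primer, the first-round PST-primer conditions) and
#' [SSP_CONDITIONS] (50 mM monovalent, no Mg2+, 0.25 uM primer, the
#' conditions used for SSP and tail-primer Tm).
#'
#' @slot monovalent_mM monovalent cation concentration in mM
#' @slot divalent_mM Mg2+ concentration in mM
#' @slot primer_uM primer concentration in micromolar
#' @export
setClass("IonicConditions", representation(
    monovalent_mM = "numeric",
    divalent_mM = "numeric",
    primer_uM = "numeric"
))

setValidity("IonicConditions", function(object) {
    v <- c(object@monovalent_mM, object@divalent_mM, object@primer_uM)
    if (length(v) != 3L || any(!is.finite(v)) || any(v < 0))
        return("all concentrations must be finite and >= 0")
    if (object@primer_uM == 0)
        return("primer concentration must be > 0")
    TRUE
})

#' Construct ionic conditions
#'
#' @param monovalent_mM monovalent cation (K+/NH4+) concentration, mM
#' @param divalent_mM Mg2+ concentration, mM
#' @param primer_uM primer concentration, uM
#' @return an [IonicConditions-class] object
#' @examples
#' ionicConditions(50, 2, 0.5)
#' @export
ionicConditions <- function(monovalent_mM, divalent_mM, primer_uM) {
    new("IonicConditions", monovalent_mM = as.numeric(monovalent_mM),
        divalent_mM = as.numeric(divalent_mM), primer_uM = as.numeric(primer_uM))
}

setMethod("show", "IonicConditions", function(object) {
    cat(sprintf("IonicConditions: %g mM monovalent, %g mM Mg2+, %g uM primer\n",
                object@monovalent_mM, object@divalent_mM, object@primer_uM))
})

#' PST (palindromic sequence-targeted) walking primer
#'
#' A PST primer is, 5' to 3': an invariant adapter (19 nt in the bundled
#' catalog), a fully degenerate block of 8-12 N positions, and an unambiguous
#' even-length palindrome (a restriction-enzyme recognition site) at the 3'
#' terminus. The degenerate block plus the palindrome is the "core", the part
#' of the primer that base-pairs with template DNA.
#'
#' @slot id primer identifier
#' @slot adapter unambiguous adapter sequence (5' terminus)
#' @slot degenerateLen number of fully degenerate (N) positions
#' @slot palindrome unambiguous palindromic 3'-terminal block
#' @slot enzyme name of the restriction enzyme recognizing the palindrome
#' @seealso [buildPstPrimer()], [loadCatalog()]
#' @export
setClass("PSTPrimer", representation(
    id = "character",
    adapter = "character",
    degenerateLen = "integer",
    palindrome = "character",
    enzyme = "character"
))

setValidity("PSTPrimer", function(object) {
    if (length(object@id) != 1L || !nzchar(object@id))
        return("id must be a single non-empty string")
    if (!all(strsplit(object@adapter, "")[[1]] %in% c("A", "C", "G", "T")))
        return("adapter must be unambiguous (A/C/G/T)")
    pal <- object@palindrome
    if (nchar(pal) < 6L || nchar(pal) %% 2L != 0L)
        return("palindrome must have even length >= 6")
    if (!isPalindrome(pal))
        return(sprintf("'%s' is not a palindrome", pal))
    if (object@degenerateLen < 8L || object@degenerateLen > 12L)
        return("degenerate block length must be in [8, 12]")
    TRUE
})

#' Sequence-specific primer (SSP)
#'
#' An SSP anneals within the known part of the template and is paired with a
#' PST primer in the first PCR round. Orientation "F" primers anneal to the
#' minus strand and extend rightward along the plus strand; "R" primers the
#' converse. Limited degeneracy (e.g. S, R, Y) is permitted.
#'
#' @slot id primer identifier
#' @slot sequence primer sequence, 5' to 3' (IUPAC codes allowed)
#' @slot orientation "F" or "R"
#' @slot targetNote free-text description of the target region
#' @slot nestedParent id of the outer SSP this primer nests within, or NA
#' @seealso [validateSsp()], [loadCatalog()]
#' @export
setClass("SSP", representation(
    id = "character",
    sequence = "character",
    orientation = "character",
    targetNote = "character",
    nestedParent = "character"
))

setValidity("SSP", function(object) {
    if (length(object@id) != 1L || !nzchar(object@id))
        return("id must be a single non-empty string")
    if (!object@orientation %in% c("F", "R"))
        return("orientation must be 'F' or 'R'")
    ok <- strsplit(object@sequence, "")[[1]] %in% names(Biostrings::IUPAC_CODE_MAP)
    if (!all(ok))
        return(sprintf("invalid residue at position %d", which(!ok)[1]))
    TRUE
})

#' Set of palindromic-site positions in one template
#'
#' Start coordinates (0-based) of every occurrence of a palindromic motif in
#' a template sequence. Because the motif equals its own reverse complement, a
#' single plus-strand scan is exhaustive; sites are strand-symmetric.
#'
#' @slot motif the palindromic motif scanned for
#' @slot seqId identifier of the scanned sequence
#' @slot positions sorted 0-based start coordinates of motif occurrences
#' @slot seqLength length of the scanned sequence in bp
#' @seealso [scanPstSites()], [spacingStats()]
#' @export
setClass("PalindromeSiteSet", representation(
    motif = "character",
    seqId = "character",
    positions = "integer",
    seqLength = "integer"
))

setValidity("PalindromeSiteSet", function(object) {
    p <- object@positions
    if (length(p) && (any(p < 0L) || is.unsorted(p, strictly = TRUE)))
        return("positions must be strictly increasing and >= 0")
    if (length(p) && max(p) + nchar(object@motif) > object@seqLength)
        return("site extends past the end of the sequence")
    TRUE
})

#' Virtual PST-PCR configuration
#'
#' Product-size bounds default to the practical amplifiable range for
#' thermophilic polymerases (100 bp to 3 kb). SSP annealing is exact-match by
#' default, with a mandatory perfectly matched 3'-terminal seed.
#'
#' @slot maxProductBp upper product-length bound, bp (default 3000)
#' @slot minProductBp lower product-length bound, bp (default 100)
#' @slot sspMaxMismatches mismatches tolerated outside the SSP seed (default 0)
#' @slot sspSeedLen 3'-terminal bases of the SSP that must match exactly
#' @slot reportSideProducts whether PST-PST side products are enumerated
#' @slot secondRoundSsp "same" or the id of a nested SSP used in round two
#' @seealso [predictAmplicons()], [runWalk()]
#' @export
setClass("PCRConfig", representation(
    maxProductBp = "integer",
    minProductBp = "integer",
    sspMaxMismatches = "integer",
    sspSeedLen = "integer",
    reportSideProducts = "logical",
    secondRoundSsp = "character"
))

setValidity("PCRConfig", function(object) {
    if (object@minProductBp <= 0L || object@minProductBp >= object@maxProductBp)
        return("need 0 < minProductBp < maxProductBp")
    if (object@sspMaxMismatches < 0L || object@sspSeedLen < 1L)
        return("sspMaxMismatches must be >= 0 and sspSeedLen >= 1")
    TRUE
})

#' Construct a virtual-PCR configuration
#'
#' @param max_product_bp,min_product_bp product length bounds in bp
#' @param ssp_max_mismatches mismatches tolerated outside the 3' seed
#' @param ssp_seed_len length of the mandatory exact 3'-terminal seed
#' @param report_side_products enumerate PST-PST side products as well
#' @param second_round_ssp "same", or the id of the nested SSP driving round 2
#' @return a [PCRConfig-class] object
#' @examples
#' pcrConfig(max_product_bp = 2000)
#' @export
pcrConfig <- function(max_product_bp = 3000, min_product_bp = 100,
                      ssp_max_mismatches = 0, ssp_seed_len = 3,
                      report_side_products = FALSE, second_round_ssp = "same") {
    new("PCRConfig",
        maxProductBp = as.integer(max_product_bp),
        minProductBp = as.integer(min_product_bp),
        sspMaxMismatches = as.integer(ssp_max_mismatches),
        sspSeedLen = as.integer(ssp_seed_len),
        reportSideProducts = isTRUE(report_side_products),
        secondRoundSsp = as.character(second_round_ssp))
}

setMethod("show", "PCRConfig", function(object) {
    cat(sprintf(paste0("PCRConfig: products %d-%d bp, ssp mismatches <= %d ",
                       "(seed %d), side products %s, round-2 SSP '%s'\n"),
                object@minProductBp, object@maxProductBp,
                object@sspMaxMismatches, object@sspSeedLen,
                if (object@reportSideProducts) "on" else "off",
                object@secondRoundSsp))
})

#' First-round conditions for PST-primer Tm (50 mM monovalent, 2 mM Mg2+,
#' 0.5 uM primer).
#' @format an [IonicConditions-class] object
#' @export
PST_CONDITIONS <- new("IonicConditions", monovalent_mM = 50,
                      divalent_mM = 2, primer_uM = 0.5)

#' SSP/tail-primer conditions for Tm (50 mM monovalent, no Mg2+, 0.25 uM
#' primer).
#' @format an [IonicConditions-class] object
#' @export
SSP_CONDITIONS <- new("IonicConditions", monovalent_mM = 50,
                      divalent_mM = 0, primer_uM = 0.25)
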