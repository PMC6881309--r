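## Seeded synthetic-template generator with exhaustive ground truth. Every
## accidental background occurrence of an implanted motif is destroyed by
## resampling, so scanners and the virtual PCR can be checked with exact
## equality rather than tolerances.

#' Specify a synthetic template
#'
#' @param length_bp template length
#' @param gc_content GC fraction of the i.i.d. background
#' @param seed RNG seed; identical specs generate identical sequences
#' @param implants data.frame with columns feature (label), sequence (the
#'   implanted motif or primer-site realization), position (0-based start)
#'   and strand ("+" or "-"; "-" implants the reverse complement); may have
#'   zero rows
#' @param forbidden character vector of additional motifs purged from the
#'   background without being implanted (useful when a whole primer
#'   catalog is screened against the fixture)
#' @return a validated fixture specification (list)
#' @examples
#' fixtureSpec(1000, 0.5, 1,
#'             data.frame(feature = "site", sequence = "GGATCC",
#'                        position = 600, strand = "+"))
#' @export
fixtureSpec <- function(length_bp, gc_content, seed, implants = NULL,
                        forbidden = character()) {
    stopifnot(length_bp >= 1, gc_content >= 0, gc_content <= 1)
    if (is.null(implants))
        implants <- data.frame(feature = character(), sequence = character(),
                               position = integer(), strand = character(),
                               stringsAsFactors = FALSE)
    stopifnot(all(c("feature", "sequence", "position", "strand") %in%
                  names(implants)))
    implants$sequence <- vapply(implants$sequence, ntSeq, "")
    implants$position <- as.integer(implants$position)
    if (nrow(implants)) {
        ends <- implants$position + nchar(implants$sequence)
        if (any(implants$position < 0L) || any(ends > length_bp))
            stop("implant does not fit within the template")
        o <- order(implants$position)
        if (any(ends[o][-length(o)] > implants$position[o][-1L]))
            stop("implants overlap one another")
        if (gc_content == 0 && any(grepl("[GC]", implants$sequence)) ||
            gc_content == 1 && any(grepl("[AT]", implants$sequence)))
            stop("implant composition impossible at the requested GC content")
    }
    list(length_bp = as.integer(length_bp), gc_content = gc_content,
         seed = as.integer(seed), implants = implants,
         forbidden = vapply(forbidden, ntSeq, "", USE.NAMES = FALSE))
}

.sampleBases <- function(n, gc) {
    sample(c("A", "C", "G", "T"), n, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Generate a synthetic template with exhaustive ground truth
#'
#' Draws i.i.d. bases at the requested GC content from a seeded generator,
#' writes each implant at its stated position (reverse-complemented for
#' strand "-"), then destroys any background occurrence of an implanted
#' motif outside the implant positions by resampling a base of the
#' offending window that lies outside every implant footprint. The returned
#' ground truth is therefore exhaustive: a scanner must find the implants
#' and nothing else.
#'
#' @param spec a [fixtureSpec()]
#' @return a list with elements \code{sequence} (character),
#'   \code{ground_truth} (data.frame feature, record, start, end, strand)
#'   and \code{spec}
#' @examples
#' g <- generateGenome(fixtureSpec(5000, 0.5, 42,
#'         data.frame(feature = "site", sequence = "GGATCC",
#'                    position = 600, strand = "+")))
#' sitePositions(scanPstSites(g$sequence, "GGATCC"))  # 600
#' @export
generateGenome <- function(spec) {
    stopifnot(is.list(spec), !is.null(spec$seed))
    set.seed(spec$seed)
    ch <- .sampleBases(spec$length_bp, spec$gc_content)
    imp <- spec$implants
    in_implant <- rep(FALSE, spec$length_bp)
    for (i in seq_len(nrow(imp))) {
        s <- if (imp$strand[i] == "-") revComp(imp$sequence[i])
             else imp$sequence[i]
        idx <- imp$position[i] + seq_len(nchar(s))
        ch[idx] <- strsplit(s, "")[[1]]
        in_implant[idx] <- TRUE
    }
    ## destroy accidental occurrences of every implanted motif (either
    ## strand orientation) outside the declared positions
    motifs <- unique(c(
        unlist(lapply(seq_len(nrow(imp)), function(i)
            c(imp$sequence[i], revComp(imp$sequence[i])))),
        spec$forbidden, vapply(spec$forbidden, revComp, "",
                               USE.NAMES = FALSE)))
    if (length(motifs)) {
        for (iter in seq_len(1000L)) {
            seq_str <- paste(ch, collapse = "")
            dirty <- FALSE
            for (m in motifs) {
                hits <- Biostrings::start(Biostrings::matchPattern(
                    m, Biostrings::DNAString(seq_str), fixed = TRUE)) - 1L
                for (h in hits) {
                    idx <- h + seq_len(nchar(m))
                    if (all(in_implant[idx])) next  # the implant itself
                    free <- idx[!in_implant[idx]]
                    if (!length(free))
                        stop("accidental motif hit irresolvably inside implants")
                    pos <- free[sample.int(length(free), 1L)]
                    repeat {
                        nb <- .sampleBases(1L, spec$gc_content)
                        if (nb != ch[pos]) break
                    }
                    ch[pos] <- nb
                    dirty <- TRUE
                }
            }
            if (!dirty) break
            if (iter == 1000L) stop("could not purge background motif hits")
        }
    }
    gt <- data.frame(
        feature = imp$feature,
        record = rep("fixture", nrow(imp)),
        start = imp$position, end = imp$position + nchar(imp$sequence),
        strand = imp$strand, sequence = imp$sequence,
        stringsAsFactors = FALSE)
    list(sequence = paste(ch, collapse = ""), ground_truth = gt, spec = spec)
}

#' Generate a population of length-polymorphic variants
#'
#' Emulates fingerprinting across accessions: n variants of a base
#' template, each with one insertion or deletion of a random size in
#' [-indel_range, indel_range] applied in the region between the two
#' implants named by \code{between} (an SSP annealing site and a PST site
#' in the intended use), so that predicted product lengths differ across
#' records by exactly the implanted indel sizes. Records listed in
#' \code{drop_site} instead have the second implant deleted entirely, and
#' yield no product.
#'
#' @param n number of variant records
#' @param base_spec a [fixtureSpec()] with at least the two named implants
#' @param indel_range maximum absolute indel size in bp (0 = no change)
#' @param between character vector of two implant feature names; the indel
#'   is placed midway between them
#' @param drop_site integer indices of records whose downstream implant is
#'   deleted
#' @return a list with \code{templates} (named DNAStringSet),
#'   \code{ground_truth} (data.frame with per-record indel sizes and
#'   updated implant coordinates) and \code{base}
#' @export
generatePopulation <- function(n, base_spec, indel_range,
                               between = c("ssp_site", "pst_site"),
                               drop_site = integer()) {
    stopifnot(n >= 1)
    base <- generateGenome(base_spec)
    gt <- base$ground_truth
    stopifnot(all(between %in% gt$feature))
    a <- gt[gt$feature == between[1L], , drop = FALSE][1L, ]
    b <- gt[gt$feature == between[2L], , drop = FALSE][1L, ]
    if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
    gap <- c(a$end, b$start)  # open region between the two implants
    set.seed(base_spec$seed + 1L)
    sizes <- if (indel_range > 0)
        sample(seq(-indel_range, indel_range), n, replace = TRUE)
    else rep(0L, n)
    mid <- floor(mean(gap))
    ## motifs that must not appear anywhere new (indel junctions, inserted
    ## bases): every implanted or forbidden sequence, both orientations
    watch <- unique(c(gt$sequence, vapply(gt$sequence, revComp, ""),
                      base_spec$forbidden,
                      vapply(base_spec$forbidden, revComp, "",
                             USE.NAMES = FALSE)))
    countHits <- function(s) sum(vapply(watch, function(m)
        length(Biostrings::start(Biostrings::matchPattern(
            m, Biostrings::DNAString(s), fixed = TRUE))), 0L))
    hits0 <- countHits(base$sequence)
    seqs <- character(n)
    rows <- list()
    for (i in seq_len(n)) {
        d <- sizes[i]
        for (attempt in seq_len(100L)) {
            s <- base$sequence
            if (i %in% drop_site) {
                ## delete the downstream implant entirely
                s <- paste0(substr(s, 1L, b$start),
                            substr(s, b$end + 1L, nchar(s)))
                d <- -(b$end - b$start)
                shift <- NA_integer_
                want <- hits0 - 1L  # minus the deleted site (palindromic)
            } else if (d > 0) {
                ins <- paste(.sampleBases(d, base_spec$gc_content),
                             collapse = "")
                s <- paste0(substr(s, 1L, mid), ins,
                            substr(s, mid + 1L, nchar(s)))
                shift <- d
                want <- hits0
            } else if (d < 0) {
                if (mid - d > gap[2L]) d <- -(gap[2L] - mid)  # stay in gap
                s <- paste0(substr(s, 1L, mid),
                            substr(s, mid - d + 1L, nchar(s)))
                shift <- d
                want <- hits0
            } else { shift <- 0L; want <- hits0 }
            if (countHits(s) == want) break
            if (attempt == 100L)
                stop("could not place an indel without creating motif hits")
        }
        seqs[i] <- s
        rows[[i]] <- data.frame(
            record = sprintf("variant%02d", i), indel_bp = d,
            upstream_start = a$start,
            downstream_start = if (i %in% drop_site) NA_integer_
                               else b$start + (if (is.na(shift)) 0L else shift),
            site_present = !(i %in% drop_site),
            stringsAsFactors = FALSE)
        sizes[i] <- d
    }
    templates <- Biostrings::DNAStringSet(seqs)
    names(templates) <- sprintf("variant%02d", seq_len(n))
    list(templates = templates, ground_truth = do.call(rbind, rows),
         base = base)
}

#' Write a fixture to FASTA plus ground-truth TSV
#'
#' The FASTA header records the generator seed for reproducibility.
#'
#' @param genome result of [generateGenome()]
#' @param fasta_path,tsv_path output paths
#' @return invisibly, the FASTA path
#' @export
writeFixture <- function(genome, fasta_path, tsv_path = NULL) {
    x <- Biostrings::DNAStringSet(genome$sequence)
    names(x) <- sprintf("fixture seed=%d gc=%g", genome$spec$seed,
                        genome$spec$gc_content)
    Biostrings::writeXStringSet(x, fasta_path)
    if (!is.null(tsv_path))
        write.table(genome$ground_truth, tsv_path, sep = "\t",
                    quote = FALSE, row.names = FALSE)
    invisible(fasta_path)
}
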