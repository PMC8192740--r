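# Spliced alignment of RNA reads to the locus and detection of
# intron-spanning (exon-exon junction) reads confirming the two-exon
# structure of SEDC genes.

#' Spliced-alignment parameters
#'
#' Defaults: minimal block anchor 8 nt, up to 2 mismatches, at least 1
#' junction read to confirm a structure; intron length bounds shared with
#' [geneModelParams()].
#'
#' @param minAnchor minimal length of each aligned block.
#' @param maxMismatch maximal total mismatches.
#' @param intronMin,intronMax intron length bounds.
#' @param minJunctionReads junction reads required to confirm a model.
#' @param revcomp reverse-complement input reads before aligning (reads are
#'   otherwise searched on the locus's forward orientation only).
#' @return A named parameter list.
#' @export
spliceParams <- function(minAnchor = 8L, maxMismatch = 2L, intronMin = 50L,
                         intronMax = 20000L, minJunctionReads = 1L,
                         revcomp = FALSE) {
    list(minAnchor = as.integer(minAnchor),
         maxMismatch = as.integer(maxMismatch),
         intronMin = as.integer(intronMin),
         intronMax = as.integer(intronMax),
         minJunctionReads = as.integer(minJunctionReads),
         revcomp = isTRUE(revcomp))
}

#' Spliced alignment of one read to the locus
#'
#' Exhaustively evaluates contiguous ungapped placements and all two-block
#' placements (split at every internal read position, each block at least
#' `minAnchor` nt, intervening gap within the intron bounds) and returns the
#' placement minimizing mismatches, requiring at most `maxMismatch`. On
#' mismatch ties a contiguous placement is preferred over a spliced one, and
#' canonical GT..AG gaps over non-canonical ones.
#'
#' @param read read sequence (character or [Biostrings::DNAString]).
#' @param locus a [Locus-class] or nucleotide sequence.
#' @param params [spliceParams()].
#' @param readId identifier recorded in the result.
#' @return One-row data.frame (`read_id`, `n_blocks`, `start1`, `size1`,
#'   `start2`, `size2`, `intron_start`, `intron_end`, `mismatches`,
#'   `canonical`; 0-based half-open) or `NULL` when no placement passes.
#' @export
splicedAlign <- function(read, locus, params = spliceParams(),
                         readId = "read") {
    seqchar <- if (is(locus, "Locus")) as.character(locusSequence(locus))
               else as.character(locus)
    read <- toupper(as.character(read))
    if (params$revcomp) read <- .revcomp(read)
    if (nchar(read) < 2L * params$minAnchor)
        stop("read shorter than twice the minimal anchor")
    al <- spliced_align_cpp(.encodeDNA(read), .encodeDNA(seqchar),
                            params$minAnchor, params$maxMismatch,
                            params$intronMin, params$intronMax)
    if (!isTRUE(al$found)) return(NULL)
    if (al$n_blocks == 1L) {
        data.frame(read_id = readId, n_blocks = 1L,
                   start1 = al$starts[1L], size1 = al$sizes[1L],
                   start2 = NA_integer_, size2 = NA_integer_,
                   intron_start = NA_integer_, intron_end = NA_integer_,
                   mismatches = al$mismatches, canonical = NA,
                   stringsAsFactors = FALSE)
    } else {
        data.frame(read_id = readId, n_blocks = 2L,
                   start1 = al$starts[1L], size1 = al$sizes[1L],
                   start2 = al$starts[2L], size2 = al$sizes[2L],
                   intron_start = al$starts[1L] + al$sizes[1L],
                   intron_end = al$starts[2L],
                   mismatches = al$mismatches,
                   canonical = isTRUE(al$canonical),
                   stringsAsFactors = FALSE)
    }
}

#' Align a set of reads to the locus
#'
#' @param reads named character vector or [Biostrings::DNAStringSet].
#' @param locus a [Locus-class] or nucleotide sequence.
#' @param params [spliceParams()].
#' @return data.frame of placed reads (unplaced reads are dropped), in the
#'   simplified SAM-like layout of [splicedAlign()].
#' @export
alignReads <- function(reads, locus, params = spliceParams()) {
    reads <- setNames(as.character(reads), names(reads))
    if (is.null(names(reads)))
        names(reads) <- sprintf("read%05d", seq_along(reads))
    out <- lapply(names(reads), function(id)
        splicedAlign(reads[[id]], locus, params, id))
    out <- out[!vapply(out, is.null, logical(1L))]
    if (!length(out))
        return(data.frame(read_id = character(0L), n_blocks = integer(0L),
                          start1 = integer(0L), size1 = integer(0L),
                          start2 = integer(0L), size2 = integer(0L),
                          intron_start = integer(0L),
                          intron_end = integer(0L),
                          mismatches = integer(0L), canonical = logical(0L),
                          stringsAsFactors = FALSE))
    do.call(rbind, out)
}

#' Expression support for a gene model from aligned reads
#'
#' Counts reads overlapping the model and intron-spanning reads whose intron
#' interval is identical to the model's intron. The two-exon structure is
#' confirmed when at least `minJunctionReads` junction reads match the model
#' intron exactly; a gene with aligned reads but no matching junction read is
#' reported as expression evidence with unconfirmed structure.
#'
#' @param model a [SedcGeneModel-class].
#' @param alignments data.frame from [alignReads()].
#' @param params [spliceParams()].
#' @return list with `n_reads`, `n_intron_spanning`, `structure_confirmed`
#'   and `note`.
#' @export
expressionSupport <- function(model, alignments, params = spliceParams()) {
    span <- range(c(model@exon2, model@exon1))
    if (nrow(alignments) == 0L)
        return(list(n_reads = 0L, n_intron_spanning = 0L,
                    structure_confirmed = FALSE, note = "no reads"))
    ov <- alignments$start1 < span[2L] &
        (ifelse(is.na(alignments$start2),
                alignments$start1 + alignments$size1,
                alignments$start2 + alignments$size2)) > span[1L]
    aln <- alignments[ov, , drop = FALSE]
    nj <- 0L
    if (!model@singleExon && !is.null(model@intron)) {
        nj <- sum(!is.na(aln$intron_start) &
                  aln$intron_start == model@intron[1L] &
                  aln$intron_end == model@intron[2L])
    }
    confirmed <- nj >= params$minJunctionReads && !model@singleExon
    note <- if (confirmed) "structure confirmed"
            else if (nrow(aln) > 0L) "expression evidence, structure unconfirmed"
            else "no reads"
    list(n_reads = nrow(aln), n_intron_spanning = nj,
         structure_confirmed = confirmed, note = note)
}

#' Write spliced alignments as TSV and junction BED
#'
#' @param alignments data.frame from [alignReads()].
#' @param tsvPath,bedPath output paths (`NULL` to skip).
#' @param seqid sequence name for the BED.
#' @return Named list of written paths, invisibly.
#' @export
writeAlignments <- function(alignments, tsvPath = NULL, bedPath = NULL,
                            seqid = "locus") {
    if (!is.null(tsvPath))
        write.table(alignments, tsvPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    if (!is.null(bedPath)) {
        j <- alignments[!is.na(alignments$intron_start), , drop = FALSE]
        lines <- if (nrow(j)) sprintf("%s\t%d\t%d\t%s\t%d\t+", seqid,
                                      j$intron_start, j$intron_end,
                                      j$read_id, j$mismatches)
                 else character(0L)
        writeLines(lines, bedPath)
    }
    invisible(list(tsv = tsvPath, bed = bedPath))
}
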