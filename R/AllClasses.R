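# Core S4 classes. Coordinates are 0-based half-open in the locus frame
# throughout; conversion to 1-based GFF3 happens only at I/O boundaries.

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' Locus: an oriented genomic interval between two anchor genes
#'
#' The EDC locus extracted between the left and right anchor genes
#' (canonically \emph{S100A9} and \emph{S100A11}), anchors included. When the
#' anchor requested as the left one lies genomically to the right of the
#' other, the sequence is reverse-complemented so that the left anchor always
#' precedes the right anchor in locus coordinates (`orientation` is then
#' `"-"`).
#'
#' @slot seqId source sequence identifier in the assembly.
#' @slot start,end genomic interval on the source sequence, 0-based half-open.
#' @slot orientation `"+"` or `"-"` (locus frame relative to the assembly).
#' @slot sequence the oriented locus sequence ([Biostrings::DNAString]).
#' @slot anchorLeft,anchorRight anchor gene symbols.
#' @slot anchorLeftRange,anchorRightRange anchor intervals in locus
#'   coordinates (0-based half-open `integer(2)`).
#' @slot gaps two-column integer matrix of N-run intervals (the gap track),
#'   0-based half-open, disjoint and sorted.
#' @export
setClass("Locus",
    representation(
        seqId = "character",
        start = "integer",
        end = "integer",
        orientation = "character",
        sequence = "ANY",
        anchorLeft = "character",
        anchorRight = "character",
        anchorLeftRange = "integer",
        anchorRightRange = "integer",
        gaps = "matrix"
    )
)

setValidity("Locus", function(object) {
    msg <- character()
    if (length(object@sequence) != object@end - object@start)
        msg <- c(msg, "sequence length must equal end - start")
    if (!object@orientation %in% c("+", "-"))
        msg <- c(msg, "orientation must be '+' or '-'")
    if (object@anchorLeftRange[1L] > object@anchorRightRange[1L])
        msg <- c(msg, "left anchor must precede right anchor in locus frame")
    g <- object@gaps
    if (nrow(g)) {
        if (any(g[, 1L] < 0L) || any(g[, 2L] > length(object@sequence)))
            msg <- c(msg, "gap intervals must lie within the locus")
        if (is.unsorted(g[, 1L], strictly = TRUE) ||
            any(g[-1L, 1L] < g[-nrow(g), 2L]))
            msg <- c(msg, "gap intervals must be sorted and disjoint")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn Locus length of the oriented locus sequence
#' @param x a `Locus`
#' @export
setMethod("length", "Locus", function(x) length(x@sequence))

#' Accessors for Locus objects
#'
#' @param x a [Locus-class] object.
#' @return `locusSequence` the oriented [Biostrings::DNAString];
#'   `locusGaps` the gap track as a two-column 0-based half-open matrix;
#'   `locusAnchors` a named list with the anchor symbols and their locus
#'   intervals.
#' @export
locusSequence <- function(x) x@sequence

#' @rdname locusSequence
#' @export
locusGaps <- function(x) x@gaps

#' @rdname locusSequence
#' @export
locusAnchors <- function(x) {
    list(left = list(symbol = x@anchorLeft, range = x@anchorLeftRange),
         right = list(symbol = x@anchorRight, range = x@anchorRightRange))
}

setMethod("show", "Locus", function(object) {
    cat(sprintf("Locus %s:%d-%d (%s), %d bp, anchors %s..%s, %d gap(s)\n",
                object@seqId, object@start, object@end, object@orientation,
                length(object@sequence), object@anchorLeft,
                object@anchorRight, nrow(object@gaps)))
})

#' SedcGeneModel: a two-exon single-coding-exon gene call
#'
#' The canonical SEDC anatomy: a noncoding exon 1 preceded by a TATA box, a
#' GT/AG intron, and an exon 2 that carries the complete CDS. All intervals
#' are 0-based half-open in locus coordinates; for minus-strand calls the
#' intervals still refer to the forward locus frame and `strand` records the
#' coding strand. A model may be single-exon (`singleExon = TRUE`) when no
#' consistent upstream structure was found; `intron`, `exon1` are then empty.
#'
#' @slot geneId gene identifier.
#' @slot exon1,intron,exon2,cds `integer(2)` intervals (0-based half-open) or
#'   `NULL` when absent.
#' @slot tata TATA-box start position or `NULL`.
#' @slot donor,acceptor splice dinucleotides (`"GT"` / `"AG"`) or `NA`.
#' @slot strand coding strand in locus frame.
#' @slot protein translated CDS (without the terminal stop).
#' @slot singleExon logical flag.
#' @export
setClass("SedcGeneModel",
    representation(
        geneId = "character",
        exon1 = "integerOrNULL",
        intron = "integerOrNULL",
        exon2 = "integerOrNULL",
        cds = "integerOrNULL",
        tata = "integerOrNULL",
        donor = "character",
        acceptor = "character",
        strand = "character",
        protein = "character",
        singleExon = "logical"
    )
)

setValidity("SedcGeneModel", function(object) {
    msg <- character()
    if (!object@singleExon) {
        if (is.null(object@exon1) || is.null(object@intron))
            msg <- c(msg, "two-exon models need exon1 and intron")
        else {
            if (object@strand == "+" &&
                (object@exon1[2L] != object@intron[1L] ||
                 object@intron[2L] != object@exon2[1L]))
                msg <- c(msg, "exon1/intron/exon2 must be contiguous")
            if (!is.na(object@donor) && object@donor != "GT")
                msg <- c(msg, "donor must be GT")
            if (!is.na(object@acceptor) && object@acceptor != "AG")
                msg <- c(msg, "acceptor must be AG")
        }
    }
    if (!is.null(object@cds)) {
        if ((object@cds[2L] - object@cds[1L]) %% 3L != 0L)
            msg <- c(msg, "CDS length must be divisible by 3")
        if (!is.null(object@exon2) &&
            (object@cds[1L] < object@exon2[1L] ||
             object@cds[2L] > object@exon2[2L]))
            msg <- c(msg, "CDS must lie within exon2")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "SedcGeneModel", function(object) {
    if (object@singleExon) {
        cat(sprintf("SedcGeneModel %s (%s, single-exon) CDS [%d,%d) TATA %s\n",
                    object@geneId, object@strand,
                    object@cds[1L], object@cds[2L],
                    if (is.null(object@tata)) "none" else object@tata))
    } else {
        cat(sprintf(
            "SedcGeneModel %s (%s) exon1 [%d,%d) intron [%d,%d) exon2 [%d,%d) CDS [%d,%d) TATA %s\n",
            object@geneId, object@strand,
            object@exon1[1L], object@exon1[2L],
            object@intron[1L], object@intron[2L],
            object@exon2[1L], object@exon2[2L],
            object@cds[1L], object@cds[2L],
            if (is.null(object@tata)) "none" else object@tata))
    }
})

#' GeneStatus: coding-integrity classification of a candidate gene
#'
#' One of `intact`, `disrupted_stop`, `disrupted_frameshift`, `truncated`,
#' `absent`, `unknown`. Disrupted states carry at least one lesion (premature
#' in-frame stop codon or single-nucleotide frameshift); `unknown` is used
#' only when the expected interval overlaps an assembly gap.
#'
#' @slot state the classification.
#' @slot lesions data.frame with columns `kind` (`stop`/`frameshift`),
#'   `ref_codon` (1-based codon index in the reference protein) and `nt_pos`
#'   (0-based nucleotide position in the candidate region).
#' @slot score frameshift-aware alignment score against the reference.
#' @slot coverage fraction of the reference protein aligned.
#' @export
setClass("GeneStatus",
    representation(state = "character", lesions = "data.frame",
                   score = "numeric", coverage = "numeric")
)

setValidity("GeneStatus", function(object) {
    ok <- c("intact", "disrupted_stop", "disrupted_frameshift", "truncated",
            "absent", "unknown")
    msg <- character()
    if (!object@state %in% ok)
        msg <- c(msg, paste("state must be one of", paste(ok, collapse = ", ")))
    if (grepl("^disrupted", object@state) && nrow(object@lesions) < 1L)
        msg <- c(msg, "disrupted states must carry at least one lesion")
    if (length(msg)) msg else TRUE
})

setMethod("show", "GeneStatus", function(object) {
    cat(sprintf("GeneStatus: %s (score %.0f, coverage %.2f, %d lesion(s))\n",
                object@state, object@score, object@coverage,
                nrow(object@lesions)))
})

#' EventMap: gain and loss events on the species tree
#'
#' Per character (gene family), the branch carrying the single gain
#' (duplication/origin) under Dollo parsimony and the minimal set of loss
#' branches. Branches are identified by their child node, labelled by the
#' sorted tip set of the clade below.
#'
#' @slot tree the species tree (`ape::phylo`).
#' @slot events data.frame with columns `character`, `type` (`gain`/`loss`),
#'   `node` (ape node id of the branch's child) and `branch` (label).
#' @slot flags data.frame of per-character flags (e.g. `never_observed`).
#' @export
setClass("EventMap",
    representation(tree = "ANY", events = "data.frame", flags = "data.frame")
)

setMethod("show", "EventMap", function(object) {
    ev <- object@events
    cat(sprintf("EventMap: %d character(s), %d gain(s), %d loss(es)\n",
                length(unique(ev$character)),
                sum(ev$type == "gain"), sum(ev$type == "loss")))
})

#' Accessors for EventMap objects
#'
#' @param x an [EventMap-class].
#' @return `eventTable` the event data.frame; `lossCount` a named vector of
#'   per-character loss counts; `gainBranch` a named vector of per-character
#'   gain branch labels.
#' @export
eventTable <- function(x) x@events

#' @rdname eventTable
#' @export
lossCount <- function(x) {
    ev <- x@events
    chars <- unique(ev$character)
    n <- vapply(chars, function(ch)
        sum(ev$type == "loss" & ev$character == ch), integer(1L))
    setNames(n, chars)
}

#' @rdname eventTable
#' @export
gainBranch <- function(x) {
    ev <- x@events[x@events$type == "gain", , drop = FALSE]
    setNames(ev$branch, ev$character)
}

#' RunReport: the end-to-end pipeline result
#'
#' @slot geneTable per-species gene inventory (family, subtype, status,
#'   coordinates, expression support).
#' @slot presenceAbsence characters x taxa matrix with `P`/`A`/`?` states.
#' @slot events the [EventMap-class].
#' @slot speciesStatus named character vector, `"ok"` or a failure message.
#' @slot params the resolved configuration used for the run.
#' @export
setClass("RunReport",
    representation(geneTable = "data.frame", presenceAbsence = "matrix",
                   events = "ANY", speciesStatus = "character",
                   params = "list")
)

setMethod("show", "RunReport", function(object) {
    cat(sprintf(
        "RunReport: %d gene call(s) across %d species; %d character(s)\n",
        nrow(object@geneTable), length(object@speciesStatus),
        nrow(object@presenceAbsence)))
    st <- object@speciesStatus
    for (s in names(st))
        cat(sprintf("  %s: %s\n", s, st[[s]]))
})
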