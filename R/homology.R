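# tBLASTn-style discovery: protein queries against the six-frame translation
# of the locus. Two-hit word seeding selects candidate windows; each window is
# scored by full affine-gap Smith-Waterman so that every reported hit score
# equals the optimal local-alignment score of the hit region.

#' Search parameters for translated homology search
#'
#' Defaults mirror NCBI tBLASTn conventions: BLOSUM62, gap open 11 / extend 1,
#' word length 4 with two-hit seeding within a 40-residue window on the same
#' diagonal, and a raw score threshold of 40 (no E-value statistics at locus
#' scale). Stop codons in a frame score -4 against any residue (see
#' [edcSubstitutionMatrix()]).
#'
#' @param gapOpen,gapExt affine gap penalties (a gap of length L costs
#'   `gapOpen + L * gapExt`).
#' @param word seed word length (>= 3).
#' @param window two-hit window in residues.
#' @param xDrop retained for interface compatibility; window alignment is
#'   exhaustive so no x-drop pruning is applied.
#' @param scoreThreshold minimal reported hit score.
#' @return A named list of validated parameters.
#' @export
searchParams <- function(gapOpen = 11, gapExt = 1, word = 4L, window = 40L,
                         xDrop = 20, scoreThreshold = 40) {
    stopifnot(gapOpen > 0, gapExt > 0, word >= 3L, window >= word,
              scoreThreshold > 0)
    list(gapOpen = gapOpen, gapExt = gapExt, word = as.integer(word),
         window = as.integer(window), xDrop = xDrop,
         scoreThreshold = scoreThreshold)
}

#' Six-frame translation of a locus
#'
#' Translates the oriented locus sequence in all six reading frames under the
#' standard genetic code. Codons containing N translate to X; trailing 1-2 nt
#' are dropped per frame. Frame ids are `+1,+2,+3` (forward) and `-1,-2,-3`
#' (reverse complement).
#'
#' @param x a [Locus-class], [Biostrings::DNAString] or character string.
#' @return A list with one element per frame: `frame` (id), `protein`
#'   (character), `offset` (0-based offset on the frame's strand) and `codes`
#'   (integer residue codes for the alignment kernels). The locus length is
#'   attached as attribute `locusLength`.
#' @examples
#' f <- sixFrameTranslate("ATGGCC")
#' f[["+1"]]$protein  # "MA"
#' @export
sixFrameTranslate <- function(x) {
    seqchar <- if (is(x, "Locus")) as.character(locusSequence(x))
               else as.character(x)
    if (nchar(seqchar) == 0L) stop("empty sequence")
    rc <- .revcomp(seqchar)
    frames <- list()
    for (f in 1:3) {
        p <- .translateStr(substr(seqchar, f, nchar(seqchar)))
        frames[[paste0("+", f)]] <- list(frame = f, protein = p,
                                         offset = f - 1L, codes = .encodeAA(p))
        p <- .translateStr(substr(rc, f, nchar(rc)))
        frames[[paste0("-", f)]] <- list(frame = -f, protein = p,
                                         offset = f - 1L, codes = .encodeAA(p))
    }
    attr(frames, "locusLength") <- nchar(seqchar)
    frames
}

# Map frame-protein positions (1-based inclusive) to a locus nucleotide
# interval (0-based half-open, forward locus frame).
.frameToLocus <- function(frame, aaStart, aaEnd, locusLen) {
    off <- abs(frame) - 1L
    nt <- c(off + 3L * (aaStart - 1L), off + 3L * aaEnd)
    if (frame > 0L) nt else c(locusLen - nt[2L], locusLen - nt[1L])
}

# Inverse: locus nt interval of a full frame-codon range back to aa indices.
.locusToFrame <- function(frame, ntStart, ntEnd, locusLen) {
    if (frame < 0L) {
        tmp <- c(locusLen - ntEnd, locusLen - ntStart)
        ntStart <- tmp[1L]; ntEnd <- tmp[2L]
    }
    off <- abs(frame) - 1L
    c((ntStart - off) / 3L + 1L, (ntEnd - off) / 3L)
}

.emptyHits <- function() {
    data.frame(query_id = character(0L), frame = integer(0L),
               q_start = integer(0L), q_end = integer(0L),
               aa_start = integer(0L), aa_end = integer(0L),
               s_start = integer(0L), s_end = integer(0L),
               score = numeric(0L), stringsAsFactors = FALSE)
}

#' Translated homology search of one protein query against six frames
#'
#' Two-hit exact-word seeds (same diagonal, within `params$window` residues)
#' nominate candidate regions per frame; each candidate window (expanded by
#' the query length) is then aligned by full affine-gap Smith-Waterman.
#' Overlapping hits in the same frame are merged to the higher-scoring one,
#' and hits are returned sorted by score (descending).
#'
#' @param query protein sequence (character or [Biostrings::AAString]).
#' @param queryId identifier recorded in the hit table.
#' @param frames result of [sixFrameTranslate()].
#' @param params [searchParams()].
#' @return data.frame of hits: `query_id`, `frame`, `q_start`/`q_end`
#'   (1-based query residues), `aa_start`/`aa_end` (1-based frame residues),
#'   `s_start`/`s_end` (0-based half-open locus nucleotides), `score`.
#' @export
translatedSearch <- function(query, queryId = "query", frames,
                             params = searchParams()) {
    query <- as.character(query)
    if (nchar(query) < params$word) {
        warning("query '", queryId, "' shorter than seed word length; ",
                "no search performed")
        return(.emptyHits())
    }
    qcode <- .encodeAA(query)
    L <- attr(frames, "locusLength")
    mat <- edcSubstitutionMatrix()
    hits <- list()
    for (fr in frames) {
        scode <- fr$codes
        if (length(scode) < params$word) next
        ev <- seed_windows_cpp(qcode, scode, params$word, params$window)
        if (nrow(ev) == 0L) next
        margin <- nchar(query) + 30L
        win <- IRanges::reduce(IRanges::IRanges(
            start = pmax(1L, ev[, 1L] + 1L - margin),
            end = pmin(length(scode), ev[, 2L] + margin)))
        for (k in seq_along(win)) {
            ws <- IRanges::start(win)[k]; we <- IRanges::end(win)[k]
            al <- sw_align_cpp(qcode, scode[ws:we], mat,
                               params$gapOpen, params$gapExt, TRUE)
            if (al$score < params$scoreThreshold) next
            aaS <- ws + al$s_start - 1L
            aaE <- ws + al$s_end - 1L
            nt <- .frameToLocus(fr$frame, aaS, aaE, L)
            hits[[length(hits) + 1L]] <- data.frame(
                query_id = queryId, frame = fr$frame,
                q_start = al$q_start, q_end = al$q_end,
                aa_start = aaS, aa_end = aaE,
                s_start = nt[1L], s_end = nt[2L],
                score = al$score, stringsAsFactors = FALSE)
        }
    }
    if (!length(hits)) return(.emptyHits())
    h <- do.call(rbind, hits)
    h <- h[order(-h$score, h$frame, h$s_start), , drop = FALSE]
    # merge overlapping hits in the same frame: keep the higher-scoring one
    keep <- rep(TRUE, nrow(h))
    for (i in seq_len(nrow(h))) {
        if (!keep[i]) next
        if (i < nrow(h)) {
            for (j in seq(i + 1L, nrow(h))) {
                if (!keep[j]) next
                if (h$frame[j] == h$frame[i] &&
                    h$s_start[j] < h$s_end[i] && h$s_end[j] > h$s_start[i])
                    keep[j] <- FALSE
            }
        }
    }
    h <- h[keep, , drop = FALSE]
    rownames(h) <- NULL
    h
}

#' Iterative translated-search closure
#'
#' Emulates iterative tBLASTn: proteins derived from newly called genes are
#' added as queries and the search repeats until no new non-overlapping hit
#' appears (or `maxRounds` is reached). The result uses set semantics and is
#' independent of the initial query order.
#'
#' @param queries named character vector (or [Biostrings::AAStringSet]) of
#'   initial protein queries.
#' @param locus a [Locus-class].
#' @param params [searchParams()].
#' @param maxRounds maximal number of search rounds (>= 1).
#' @param orfParams parameters passed to [callOrf()] for deriving proteins
#'   from new hits.
#' @return list with `hits` (combined hit table, deduplicated), `proteins`
#'   (named vector: initial queries plus newly derived proteins) and `rounds`
#'   (number of rounds run).
#' @export
iterativeClosure <- function(queries, locus, params = searchParams(),
                             maxRounds = 10L, orfParams = geneModelParams()) {
    stopifnot(maxRounds >= 1L)
    queries <- setNames(as.character(queries), names(queries))
    if (is.null(names(queries)))
        names(queries) <- sprintf("query%03d", seq_along(queries))
    queries <- queries[order(names(queries))]
    frames <- sixFrameTranslate(locus)
    allHits <- .emptyHits()
    known <- unname(queries)
    pending <- queries
    round <- 0L
    while (length(pending) && round < maxRounds) {
        round <- round + 1L
        newHits <- list()
        for (qi in seq_along(pending)) {
            h <- translatedSearch(pending[[qi]], names(pending)[qi], frames,
                                  params)
            if (nrow(h)) newHits[[length(newHits) + 1L]] <- h
        }
        pending <- character(0L)
        if (!length(newHits)) break
        nh <- do.call(rbind, newHits)
        # keep hits not overlapping an already-accepted hit (locus frame)
        fresh <- rep(TRUE, nrow(nh))
        if (nrow(allHits)) {
            for (i in seq_len(nrow(nh)))
                fresh[i] <- !any(nh$s_start[i] < allHits$s_end &
                                 nh$s_end[i] > allHits$s_start)
        }
        nh <- nh[fresh, , drop = FALSE]
        if (!nrow(nh)) break
        allHits <- rbind(allHits, nh)
        # derive proteins from the new hits and queue unseen ones
        newProt <- character(0L)
        for (i in seq_len(nrow(nh))) {
            orf <- callOrf(locus, nh[i, ], queries[[nh$query_id[i]]] %||%
                           known[1L], orfParams)
            if (!is.null(orf$protein) && !(orf$protein %in% known)) {
                known <- c(known, orf$protein)
                newProt <- c(newProt, orf$protein)
            }
        }
        if (length(newProt)) {
            names(newProt) <- sprintf("iter%d_%03d", round,
                                      seq_along(newProt))
            queries <- c(queries, newProt)
            pending <- newProt
        }
    }
    allHits <- allHits[order(allHits$s_start, allHits$frame,
                             -allHits$score), , drop = FALSE]
    rownames(allHits) <- NULL
    list(hits = allHits, proteins = queries, rounds = round)
}

#' Write a hit table as TSV and BED
#'
#' @param hits hit table from [translatedSearch()].
#' @param tsvPath,bedPath output paths (`NULL` to skip).
#' @param seqid sequence name used in the BED.
#' @return Named list of written paths, invisibly.
#' @export
writeHits <- function(hits, tsvPath = NULL, bedPath = NULL, seqid = "locus") {
    if (!is.null(tsvPath))
        write.table(hits, tsvPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    if (!is.null(bedPath)) {
        lines <- if (nrow(hits)) sprintf(
            "%s\t%d\t%d\t%s\t%d\t%s", seqid, hits$s_start, hits$s_end,
            hits$query_id, round(hits$score),
            ifelse(hits$frame > 0, "+", "-")) else character(0L)
        writeLines(lines, bedPath)
    }
    invisible(list(tsv = tsvPath, bed = bedPath))
}
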