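# Reading genomes/annotations, extracting the oriented EDC locus between the
# anchor genes, and writing gene maps in standard formats.

#' Read a genome assembly from FASTA
#'
#' Sequences are uppercased and any character outside `{A,C,G,T,N}` is
#' replaced by `N` with a warning. Duplicate sequence identifiers and empty
#' files are hard errors.
#'
#' @param path path to a FASTA file.
#' @param sourceLabel free-text provenance label (e.g. an assembly accession)
#'   stored in the metadata of the returned object.
#' @return A [Biostrings::DNAStringSet] with per-sequence names;
#'   `metadata(x)$sourceLabel` carries the provenance label.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgt"), tf)
#' readGenome(tf)
#' @export
readGenome <- function(path, sourceLabel = basename(path)) {
    if (!file.exists(path)) stop("file not found: ", path)
    seqs <- tryCatch(
        Biostrings::readDNAStringSet(path, use.names = TRUE),
        error = function(e) {
            # fall back to a permissive read so non-IUPAC letters can be
            # mapped to N rather than rejected outright
            Biostrings::readBStringSet(path, use.names = TRUE)
        })
    if (length(seqs) == 0L) stop("empty FASTA file: ", path)
    ids <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(ids))
        stop("duplicate sequence id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    chars <- toupper(as.character(seqs))
    cleaned <- gsub("[^ACGTN]", "N", chars)
    nbad <- sum(nchar(gsub("[ACGTN]", "", chars)))
    if (nbad > 0L)
        warning(nbad, " non-ACGTN character(s) replaced by N")
    out <- Biostrings::DNAStringSet(cleaned)
    names(out) <- ids
    S4Vectors::metadata(out)$sourceLabel <- sourceLabel
    out
}

#' Write a genome assembly to FASTA
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenome <- function(genome, path) {
    Biostrings::writeXStringSet(genome, path)
    invisible(path)
}

#' Read gene annotations from GFF3
#'
#' Imports a GFF3 file (via \pkg{rtracklayer}) and returns the gene records
#' as a data.frame in the package's internal convention (0-based half-open
#' coordinates). The gene symbol is taken from the `Name`, `gene_name` or
#' `symbol` attribute, falling back to `ID`.
#'
#' @param path path to a GFF3 file.
#' @param types feature types retained (default `"gene"`; use `NULL` for all).
#' @return data.frame with columns `gene_id`, `seq_id`, `start`, `end`
#'   (0-based half-open), `strand`, `symbol`.
#' @export
readAnnotation <- function(path, types = "gene") {
    gr <- rtracklayer::import(path)
    df <- as.data.frame(gr)
    if (!is.null(types) && "type" %in% names(df))
        df <- df[df$type %in% types, , drop = FALSE]
    sym <- rep(NA_character_, nrow(df))
    for (col in c("Name", "gene_name", "symbol", "ID")) {
        if (col %in% names(df)) {
            take <- is.na(sym) & !is.na(df[[col]])
            sym[take] <- as.character(df[[col]][take])
        }
    }
    id <- if ("ID" %in% names(df)) as.character(df$ID) else sym
    id[is.na(id)] <- sprintf("gene%04d", which(is.na(id)))
    data.frame(
        gene_id = id,
        seq_id = as.character(df$seqnames),
        start = as.integer(df$start - 1L),
        end = as.integer(df$end),
        strand = as.character(df$strand),
        symbol = sym,
        stringsAsFactors = FALSE)
}

# N-run gap track >= gapMinLength; 0-based half-open matrix.
.gapTrack <- function(seqchar, gapMinLength) {
    m <- gregexpr(sprintf("N{%d,}", gapMinLength), seqchar)[[1L]]
    if (m[1L] == -1L)
        return(matrix(integer(0L), ncol = 2L,
                      dimnames = list(NULL, c("start", "end"))))
    st <- as.integer(m) - 1L
    en <- st + attr(m, "match.length")
    cbind(start = st, end = en)
}

#' Extract the oriented EDC locus between two anchor genes
#'
#' The locus spans from the leftmost coordinate of the genomically left
#' anchor to the rightmost coordinate of the genomically right anchor,
#' anchors included. Multiple annotation records per anchor symbol (isoforms)
#' are merged to the union of their spans. When the anchor requested as
#' `anchorLeftSymbol` lies genomically to the right of the other anchor, the
#' locus is reverse-complemented and coordinates remapped so that the left
#' anchor precedes the right anchor in locus frame. A gap track of N-runs is
#' computed on the oriented sequence.
#'
#' @param genome a [Biostrings::DNAStringSet] from [readGenome()].
#' @param genes annotation data.frame from [readAnnotation()] (columns
#'   `seq_id`, `start`, `end`, `symbol`).
#' @param anchorLeftSymbol,anchorRightSymbol anchor gene symbols
#'   (canonically `"S100A9"` and `"S100A11"`).
#' @param gapMinLength minimal N-run length flagged as an assembly gap
#'   (default 10, so isolated ambiguous bases are not flagged).
#' @return A [Locus-class] object.
#' @export
extractLocus <- function(genome, genes, anchorLeftSymbol, anchorRightSymbol,
                         gapMinLength = 10L) {
    pick <- function(sym) {
        rows <- genes[!is.na(genes$symbol) & genes$symbol == sym, ,
                      drop = FALSE]
        if (nrow(rows) == 0L) stop("anchor not found: ", sym)
        if (length(unique(rows$seq_id)) > 1L)
            stop("anchor ", sym, " annotated on multiple sequences")
        list(seq_id = rows$seq_id[1L],
             start = min(rows$start), end = max(rows$end))
    }
    al <- pick(anchorLeftSymbol)
    ar <- pick(anchorRightSymbol)
    if (al$seq_id != ar$seq_id)
        stop("discontiguous locus: anchors on different sequences (",
             al$seq_id, ", ", ar$seq_id, ")")
    if (!al$seq_id %in% names(genome))
        stop("annotation references unknown sequence: ", al$seq_id)

    gstart <- min(al$start, ar$start)
    gend <- max(al$end, ar$end)
    slice <- as.character(Biostrings::subseq(genome[[al$seq_id]],
                                             gstart + 1L, gend))
    flipped <- al$start > ar$start
    len <- gend - gstart
    remap <- function(iv) {
        iv <- c(iv$start - gstart, iv$end - gstart)
        if (flipped) c(len - iv[2L], len - iv[1L]) else iv
    }
    seqchar <- if (flipped) .revcomp(slice) else slice
    new("Locus",
        seqId = al$seq_id,
        start = as.integer(gstart), end = as.integer(gend),
        orientation = if (flipped) "-" else "+",
        sequence = Biostrings::DNAString(seqchar),
        anchorLeft = anchorLeftSymbol, anchorRight = anchorRightSymbol,
        anchorLeftRange = as.integer(remap(al)),
        anchorRightRange = as.integer(remap(ar)),
        gaps = .gapTrack(seqchar, gapMinLength))
}

#' Write a gene map as GFF3 and BED
#'
#' Renders gene calls on the locus in standard annotation formats: GFF3 with
#' 1-based inclusive coordinates and BED with 0-based half-open coordinates.
#' Disrupted genes carry the attribute `status=disrupted` in the GFF3 (and in
#' the BED name), mirroring the convention of marking genes whose coding
#' sequence is broken.
#'
#' @param locus a [Locus-class].
#' @param calls data.frame with columns `gene_id`, `start`, `end` (0-based
#'   half-open, locus frame), `strand`, and optionally `status`, `family`,
#'   `subtype`.
#' @param gff3Path,bedPath output paths (`NULL` to skip one of them).
#' @return Named list of the written paths, invisibly.
#' @export
writeGeneMap <- function(locus, calls, gff3Path = NULL, bedPath = NULL) {
    if (nrow(calls)) {
        if (any(calls$start < 0L) || any(calls$end > length(locus)) ||
            any(calls$start >= calls$end))
            stop("gene call out of locus bounds")
    }
    seqid <- paste0(locus@seqId, "_locus")
    if (!is.null(gff3Path)) {
        lines <- c("##gff-version 3",
                   sprintf("##sequence-region %s 1 %d", seqid,
                           length(locus)))
        if (nrow(calls)) {
            attrs <- sprintf("ID=%s", calls$gene_id)
            for (col in c("status", "family", "subtype")) {
                if (col %in% names(calls)) {
                    has <- !is.na(calls[[col]])
                    attrs[has] <- paste0(attrs[has], ";", col, "=",
                                         calls[[col]][has])
                }
            }
            lines <- c(lines, sprintf(
                "%s\tedcscan\tgene\t%d\t%d\t.\t%s\t.\t%s",
                seqid, calls$start + 1L, calls$end,
                ifelse(is.na(calls$strand), ".", calls$strand), attrs))
        }
        writeLines(lines, gff3Path)
    }
    if (!is.null(bedPath)) {
        lines <- character(0L)
        if (nrow(calls)) {
            nm <- calls$gene_id
            if ("status" %in% names(calls)) {
                dis <- !is.na(calls$status) &
                    grepl("^disrupted", calls$status)
                nm[dis] <- paste0(nm[dis], "|disrupted")
            }
            lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                             seqid, calls$start, calls$end, nm,
                             ifelse(is.na(calls$strand), ".", calls$strand))
        }
        writeLines(lines, bedPath)
    }
    invisible(list(gff3 = gff3Path, bed = bedPath))
}

#' Flag an expected gene interval as unknown when it overlaps an assembly gap
#'
#' A gene whose expected syntenic interval overlaps a run of Ns cannot be
#' scored as absent: real discontinuity cannot be excluded.
#'
#' @param interval `integer(2)` 0-based half-open interval in locus frame.
#' @param gaps gap track matrix from [locusGaps()].
#' @return `"unknown"` if the interval overlaps any gap, else `"ok"`.
#' @export
markUnknown <- function(interval, gaps) {
    if (nrow(gaps) == 0L) return("ok")
    hit <- any(interval[1L] < gaps[, 2L] & interval[2L] > gaps[, 1L])
    if (hit) "unknown" else "ok"
}
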