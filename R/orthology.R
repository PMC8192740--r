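# Orthology by reciprocal best hit plus synteny; paralog clustering into gene
# families; subtype labelling against reference proteins.

#' Orthology parameters
#'
#' The orthology criteria (reciprocal best BLAST-style hits of the encoded
#' proteins, corroborated by gene locus synteny) take these thresholds:
#' synteny window of 2 genes per side, minimal synteny support 0.5, family
#' clustering at 50 percent alignment identity over the shorter sequence.
#'
#' @param minScore minimal local-alignment score for a match to count.
#' @param syntenyWindow flanking genes considered per side.
#' @param syntenyMin minimal synteny support for an `ortholog` verdict.
#' @param familyIdentity single-linkage identity threshold for families.
#' @param gapOpen,gapExt alignment gap penalties.
#' @return A named parameter list.
#' @export
orthologyParams <- function(minScore = 40, syntenyWindow = 2L,
                            syntenyMin = 0.5, familyIdentity = 0.5,
                            gapOpen = 11, gapExt = 1) {
    list(minScore = minScore, syntenyWindow = as.integer(syntenyWindow),
         syntenyMin = syntenyMin, familyIdentity = familyIdentity,
         gapOpen = gapOpen, gapExt = gapExt)
}

.asProtVec <- function(x, prefix) {
    v <- setNames(as.character(x), names(x))
    if (is.null(names(v)) || any(!nzchar(names(v))))
        names(v) <- sprintf("%s%03d", prefix, seq_along(v))
    v
}

# all-vs-all local alignment scores (rows = a, cols = b)
.scoreMatrix <- function(a, b, params) {
    mat <- edcSubstitutionMatrix()
    ac <- lapply(a, .encodeAA)
    bc <- lapply(b, .encodeAA)
    out <- matrix(0, nrow = length(a), ncol = length(b),
                  dimnames = list(names(a), names(b)))
    for (i in seq_along(a)) for (j in seq_along(b))
        out[i, j] <- sw_align_cpp(ac[[i]], bc[[j]], mat, params$gapOpen,
                                  params$gapExt, FALSE)$score
    out
}

#' Reciprocal best hits between two proteomes
#'
#' A pair (a, b) is reported as RBH iff b is a's unique top-scoring match and
#' a is b's unique top-scoring match under gapped local alignment. Ties for
#' the top score yield no pair and an `ambiguous` record.
#'
#' @param proteomeA,proteomeB named character vectors (or
#'   [Biostrings::AAStringSet]) of proteins.
#' @param params [orthologyParams()].
#' @return data.frame with columns `gene_a`, `gene_b`, `score`, `rbh`
#'   (logical) and `note` (`"ok"`, `"ambiguous"` or `"no_hit"`); one row per
#'   protein of proteome A.
#' @export
reciprocalBestHit <- function(proteomeA, proteomeB,
                              params = orthologyParams()) {
    a <- .asProtVec(proteomeA, "a")
    b <- .asProtVec(proteomeB, "b")
    stopifnot(length(a) > 0L, length(b) > 0L)
    S <- .scoreMatrix(a, b, params)
    res <- data.frame(gene_a = names(a), gene_b = NA_character_,
                      score = NA_real_, rbh = FALSE, note = "no_hit",
                      stringsAsFactors = FALSE)
    topB <- apply(S, 1L, max)       # per a
    topA <- apply(S, 2L, max)       # per b
    for (i in seq_along(a)) {
        sc <- topB[i]
        if (sc < params$minScore) next
        cand <- which(S[i, ] == sc)
        if (length(cand) > 1L) {
            res$note[i] <- "ambiguous"; res$score[i] <- sc
            next
        }
        j <- cand
        back <- which(S[, j] == topA[j])
        if (length(back) == 1L && back == i && topA[j] == sc) {
            res$gene_b[i] <- names(b)[j]
            res$score[i] <- sc
            res$rbh[i] <- TRUE
            res$note[i] <- "ok"
        } else if (length(back) > 1L && i %in% back) {
            res$note[i] <- "ambiguous"; res$score[i] <- sc
        } else {
            res$score[i] <- sc
        }
    }
    res
}

#' Synteny support for a putative ortholog pair
#'
#' Fraction of the up-to-`window` nearest flanking genes on each side of
#' `gene` whose own orthologs also flank the partner gene on the
#' corresponding side (gene orders are given in oriented locus frame).
#'
#' @param gene gene id in `orderA`.
#' @param orderA,orderB ordered gene ids along the two loci.
#' @param orthoMap named character vector mapping A-genes to B-genes
#'   (including the pair under scrutiny).
#' @param window flanking genes per side.
#' @return Support score in `[0, 1]`; `NaN` when no flanking gene has a
#'   mapped ortholog.
#' @export
syntenySupport <- function(gene, orderA, orderB, orthoMap, window = 2L) {
    ia <- match(gene, orderA)
    if (is.na(ia)) stop("gene not in locus order: ", gene)
    partner <- orthoMap[[gene]]
    ib <- match(partner, orderB)
    if (is.na(ib)) stop("partner not in locus order: ", partner)
    considered <- 0L; conserved <- 0L
    for (side in c(-1L, 1L)) {
        flanksA <- ia + side * seq_len(window)
        flanksA <- flanksA[flanksA >= 1L & flanksA <= length(orderA)]
        flanksB <- ib + side * seq_len(window)
        flanksB <- flanksB[flanksB >= 1L & flanksB <= length(orderB)]
        for (fa in flanksA) {
            fo <- orthoMap[[orderA[fa]]] %||% NA_character_
            if (is.na(fo)) next
            considered <- considered + 1L
            if (fo %in% orderB[flanksB]) conserved <- conserved + 1L
        }
    }
    if (considered == 0L) return(NaN)
    conserved / considered
}

#' Assign orthology verdicts combining RBH and synteny
#'
#' @param proteomeA,proteomeB named protein vectors.
#' @param orderA,orderB gene orders along the two oriented loci.
#' @param params [orthologyParams()].
#' @return data.frame with `gene_a`, `gene_b`, `score`, `rbh`, `synteny` and
#'   `verdict` (`ortholog` requires RBH and synteny support >=
#'   `params$syntenyMin`; RBH with weak or unassessable synteny, or score
#'   ties, give `ambiguous`; otherwise `none`).
#' @export
assignOrthologs <- function(proteomeA, proteomeB, orderA, orderB,
                            params = orthologyParams()) {
    rb <- reciprocalBestHit(proteomeA, proteomeB, params)
    rb$synteny <- NA_real_
    rb$verdict <- "none"
    pairs <- rb$gene_a[rb$rbh]
    orthoMap <- setNames(rb$gene_b, rb$gene_a)
    for (g in pairs) {
        i <- match(g, rb$gene_a)
        sup <- tryCatch(
            syntenySupport(g, orderA, orderB, orthoMap,
                           params$syntenyWindow),
            error = function(e) NaN)
        rb$synteny[i] <- sup
        rb$verdict[i] <- if (!is.nan(sup) && sup >= params$syntenyMin)
            "ortholog" else "ambiguous"
    }
    rb$verdict[!rb$rbh & rb$note == "ambiguous"] <- "ambiguous"
    rb
}

# pairwise alignment identity over the shorter sequence
.pairIdentity <- function(ca, cb, mat, params) {
    al <- sw_align_cpp(ca, cb, mat, params$gapOpen, params$gapExt, TRUE)
    qa <- al$q_aligned; sa <- al$s_aligned
    if (!length(qa)) return(0)
    ok <- qa > 0L & sa > 0L
    nid <- sum(ca[qa[ok]] == cb[sa[ok]])
    nid / min(length(ca), length(cb))
}

#' Cluster proteins into gene families by single-linkage identity
#'
#' Single-linkage clustering on pairwise alignment identity computed over the
#' shorter sequence. Family ids are deterministic, derived from the sorted
#' member ids, so the result is invariant under input order.
#'
#' @param proteins named character vector (or [Biostrings::AAStringSet]).
#' @param params [orthologyParams()]; `familyIdentity` is the threshold.
#' @return data.frame with `gene_id` and `family_id`; families are numbered
#'   `FAM001, ...` in order of their lexicographically smallest member.
#' @export
clusterFamilies <- function(proteins, params = orthologyParams()) {
    p <- .asProtVec(proteins, "p")
    stopifnot(length(p) >= 1L)
    p <- p[order(names(p))]
    n <- length(p)
    mat <- edcSubstitutionMatrix()
    codes <- lapply(p, .encodeAA)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (n > 1L) {
        for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
            if (.pairIdentity(codes[[i]], codes[[j]], mat, params) >=
                params$familyIdentity) {
                ri <- find(i); rj <- find(j)
                if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
            }
        }
    }
    root <- vapply(seq_len(n), find, integer(1L))
    fams <- split(names(p), root)
    fams <- fams[order(vapply(fams, min, character(1L)))]
    out <- data.frame(gene_id = names(p), family_id = NA_character_,
                      stringsAsFactors = FALSE)
    for (k in seq_along(fams))
        out$family_id[out$gene_id %in% fams[[k]]] <- sprintf("FAM%03d", k)
    out[order(out$gene_id), , drop = FALSE]
}

#' Label proteins by nearest labelled reference
#'
#' Assigns each protein the subtype label of its highest-scoring reference
#' protein (e.g. SPRR2, SPRR5, SPRRc, LCE7A). On score ties, SPRR-specific
#' sequence evidence (SPRRc motif count, cysteine duplets; see
#' [sprrSubtypeEvidence()]) breaks the tie, then the lexicographically first
#' label. Proteins scoring below `minScore` against every reference are
#' labelled `"unplaced"`.
#'
#' @param proteins named protein vector.
#' @param references named protein vector; names are the subtype labels.
#' @param params [orthologyParams()].
#' @return data.frame with `gene_id`, `subtype`, `ref_score`.
#' @export
assignSubtypes <- function(proteins, references,
                           params = orthologyParams()) {
    p <- .asProtVec(proteins, "p")
    r <- .asProtVec(references, "ref")
    S <- .scoreMatrix(p, r, params)
    out <- data.frame(gene_id = names(p), subtype = "unplaced",
                      ref_score = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_along(p)) {
        sc <- max(S[i, ])
        if (sc < params$minScore) next
        cand <- sort(colnames(S)[S[i, ] == sc])
        if (length(cand) > 1L) {
            ev <- sprrSubtypeEvidence(p[[i]])
            if (ev$sprrc && any(grepl("SPRRc", cand, ignore.case = TRUE)))
                cand <- cand[grepl("SPRRc", cand, ignore.case = TRUE)]
            else if (ev$sprr5 && any(grepl("SPRR5", cand)))
                cand <- cand[grepl("SPRR5", cand)]
        }
        out$subtype[i] <- cand[1L]
        out$ref_score[i] <- sc
    }
    out
}
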