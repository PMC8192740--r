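# End-to-end orchestration: extract locus -> iterative translated search ->
# gene models -> integrity -> families/subtypes -> features -> optional
# transcript evidence -> presence/absence matrix -> Dollo parsimony -> report.

#' Pipeline configuration
#'
#' All stage parameters are config keys with the package defaults; unknown
#' keys are rejected before any computation.
#'
#' @param species list of per-species entries, each a list with `name`,
#'   `genome` (path or [Biostrings::DNAStringSet]), `annotation` (path or
#'   data.frame) and optional `reads` (path or [Biostrings::DNAStringSet]).
#' @param queries named character vector / [Biostrings::AAStringSet] of
#'   reference query proteins (names double as family labels), or a FASTA
#'   path.
#' @param tree `ape::phylo` or newick path; divergence times, when present,
#'   are branch lengths supplied by the user (never computed here).
#' @param anchorLeft,anchorRight anchor gene symbols.
#' @param search,geneModel,orthology,splice stage parameter blocks.
#' @param disruptedAs state mapping for disrupted genes in the
#'   presence/absence matrix (see [buildPresenceAbsence()]).
#' @param mergeGap hits closer than this many nt are grouped into one
#'   candidate gene region.
#' @param maxRounds maximal iterative-search rounds.
#' @param gapMinLength minimal N-run length flagged as an assembly gap.
#' @param outDir output directory (`NULL` for no file output).
#' @param seed integer seed for any stochastic step.
#' @return A validated configuration list.
#' @export
pipelineConfig <- function(species = list(), queries = character(0L),
                           tree = NULL, anchorLeft = "S100A9",
                           anchorRight = "S100A11",
                           search = searchParams(),
                           geneModel = geneModelParams(),
                           orthology = orthologyParams(),
                           splice = spliceParams(),
                           disruptedAs = "present", mergeGap = 200L,
                           maxRounds = 4L, gapMinLength = 10L,
                           outDir = NULL, seed = 1L) {
    cfg <- list(species = species, queries = queries, tree = tree,
                anchorLeft = anchorLeft, anchorRight = anchorRight,
                search = search, geneModel = geneModel,
                orthology = orthology, splice = splice,
                disruptedAs = disruptedAs, mergeGap = as.integer(mergeGap),
                maxRounds = as.integer(maxRounds),
                gapMinLength = as.integer(gapMinLength),
                outDir = outDir, seed = as.integer(seed))
    validatePipelineConfig(cfg)
    cfg
}

#' Validate a pipeline configuration
#'
#' Checks the configuration against the schema (the argument set of
#' [pipelineConfig()] and of the stage parameter constructors); an unknown
#' key aborts with an error naming the key, before any computation.
#'
#' @param config a configuration list.
#' @return `TRUE`, invisibly; errors otherwise.
#' @export
validatePipelineConfig <- function(config) {
    known <- names(formals(pipelineConfig))
    extra <- setdiff(names(config), known)
    if (length(extra))
        stop("unknown configuration key(s): ", paste(extra, collapse = ", "))
    blocks <- list(search = searchParams, geneModel = geneModelParams,
                   orthology = orthologyParams, splice = spliceParams)
    for (b in names(blocks)) {
        if (is.null(config[[b]])) next
        extra <- setdiff(names(config[[b]]), names(formals(blocks[[b]])))
        if (length(extra))
            stop("unknown configuration key(s) in '", b, "': ",
                 paste(extra, collapse = ", "))
    }
    for (sp in config$species) {
        extra <- setdiff(names(sp), c("name", "genome", "annotation",
                                      "reads"))
        if (length(extra))
            stop("unknown configuration key(s) in species entry: ",
                 paste(extra, collapse = ", "))
    }
    invisible(TRUE)
}

.resolveGenome <- function(x) {
    if (is.character(x) && length(x) == 1L) readGenome(x) else x
}
.resolveAnnotation <- function(x) {
    if (is.character(x) && length(x) == 1L) readAnnotation(x) else x
}
.resolveQueries <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x))
        x <- Biostrings::readAAStringSet(x)
    setNames(as.character(x), names(x))
}
.resolveTree <- function(x) {
    if (is.character(x)) ape::read.tree(x) else x
}

# Group hits into candidate gene regions (overlap or gap <= mergeGap).
.groupHits <- function(hits, mergeGap) {
    if (!nrow(hits)) return(list())
    hits <- hits[order(hits$s_start), , drop = FALSE]
    groups <- list(); cur <- hits[1L, , drop = FALSE]
    curEnd <- hits$s_end[1L]
    for (i in seq_len(nrow(hits))[-1L]) {
        if (hits$s_start[i] <= curEnd + mergeGap) {
            cur <- rbind(cur, hits[i, ])
            curEnd <- max(curEnd, hits$s_end[i])
        } else {
            groups[[length(groups) + 1L]] <- cur
            cur <- hits[i, , drop = FALSE]
            curEnd <- hits$s_end[i]
        }
    }
    groups[[length(groups) + 1L]] <- cur
    groups
}

#' Discover and classify SEDC genes on one locus
#'
#' Runs the iterative translated-search closure, groups hits into candidate
#' gene regions, calls ORFs and two-exon models, classifies coding integrity
#' against the best-matching reference protein, and flags regions
#' overlapping assembly gaps as unknown. Regions overlapping the anchor
#' genes are skipped.
#'
#' @param locus a [Locus-class].
#' @param queries named reference protein vector.
#' @param config a [pipelineConfig()] (stage parameter blocks are used).
#' @param species species label used in gene ids.
#' @return list with `genes` (data.frame), `models` (list of
#'   [SedcGeneModel-class] per gene id), `hits` and `proteins`.
#' @export
discoverGenes <- function(locus, queries, config = pipelineConfig(),
                          species = "sp") {
    cl <- iterativeClosure(queries, locus, config$search, config$maxRounds,
                           config$geneModel)
    seqchar <- as.character(locusSequence(locus))
    L <- nchar(seqchar)
    anch <- locusAnchors(locus)
    regions <- .groupHits(cl$hits, config$mergeGap)
    rows <- list(); models <- list()
    k <- 0L
    for (reg in regions) {
        rs <- min(reg$s_start); re <- max(reg$s_end)
        if ((rs < anch$left$range[2L] && re > anch$left$range[1L]) ||
            (rs < anch$right$range[2L] && re > anch$right$range[1L]))
            next
        k <- k + 1L
        gid <- sprintf("%s_g%02d", species, k)
        best <- reg[which.max(reg$score), , drop = FALSE]
        # reference = original labelled query when available
        refId <- best$query_id
        ref <- cl$proteins[[refId]] %||% queries[[1L]]
        family <- if (refId %in% names(queries)) refId else {
            # iterative query: map back by best score against the references
            sc <- vapply(queries, function(q)
                sw_align_cpp(.encodeAA(ref), .encodeAA(q),
                             edcSubstitutionMatrix(), 11, 1, FALSE)$score,
                numeric(1L))
            names(queries)[which.max(sc)]
        }
        orf <- callOrf(locus, best[1L, ], ref, config$geneModel)
        ext <- 30L
        crs <- max(0L, rs - ext); cre <- min(L, re + ext)
        cand <- substr(seqchar, crs + 1L, cre)
        strand <- if (best$frame[1L] > 0L) "+" else "-"
        if (strand == "-") cand <- .revcomp(cand)
        status <- classifyIntegrity(cand, ref, config$geneModel)
        state <- status@state
        if (markUnknown(c(rs, re), locusGaps(locus)) == "unknown")
            state <- "unknown"
        model <- NULL
        if (!is.null(orf$cds) && state %in% c("intact", "truncated")) {
            model <- findUpstreamExon(locus, orf$cds, orf$strand, gid,
                                      orf$protein, config$geneModel)
            models[[gid]] <- model
        }
        les <- status@lesions
        if (state == "disrupted_frameshift")
            les <- les[les$kind == "frameshift", , drop = FALSE]
        else if (state == "disrupted_stop")
            les <- les[les$kind == "stop", , drop = FALSE]
        lesion <- if (nrow(les)) les$ref_codon[1L] else NA_integer_
        lesionHi <- if (nrow(les)) les$ref_codon_hi[1L] else NA_integer_
        rows[[gid]] <- data.frame(
            species = species, gene_id = gid, family = family,
            status = state,
            region_start = rs, region_end = re,
            cds_start = if (!is.null(orf$cds)) orf$cds[1L] else NA_integer_,
            cds_end = if (!is.null(orf$cds)) orf$cds[2L] else NA_integer_,
            strand = strand, score = status@score,
            coverage = status@coverage, lesion_codon = lesion,
            lesion_codon_hi = lesionHi,
            protein = orf$protein %||% NA_character_,
            two_exon = !is.null(model) && !model@singleExon,
            stringsAsFactors = FALSE)
    }
    genes <- if (length(rows)) do.call(rbind, rows)
             else data.frame(species = character(0L), gene_id = character(0L),
                             family = character(0L), status = character(0L),
                             stringsAsFactors = FALSE)
    rownames(genes) <- NULL
    list(genes = genes, models = models, hits = cl$hits,
         proteins = cl$proteins)
}

#' Run the full pipeline
#'
#' Stages run in order per species (extract, search closure, gene models,
#' integrity, subtype features, optional transcript evidence), then across
#' species (presence/absence matrix, Dollo parsimony, report). A failure in
#' one species does not abort the others; the species is marked failed in
#' the report. With `outDir` set, all intermediate tables, gene maps
#' (GFF3/BED), the matrix, the annotated cladogram and the resolved
#' configuration are written alongside the report.
#'
#' @param config a [pipelineConfig()].
#' @return A [RunReport-class].
#' @export
runPipeline <- function(config) {
    validatePipelineConfig(config)
    set.seed(config$seed)
    queries <- .resolveQueries(config$queries)
    tree <- .resolveTree(config$tree)
    outDir <- config$outDir
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)

    status <- character(0L)
    geneTables <- list()
    allModels <- list()
    for (sp in config$species) {
        nm <- sp$name
        res <- tryCatch({
            genome <- .resolveGenome(sp$genome)
            ann <- .resolveAnnotation(sp$annotation)
            locus <- extractLocus(genome, ann, config$anchorLeft,
                                  config$anchorRight, config$gapMinLength)
            disc <- discoverGenes(locus, queries, config, nm)
            genes <- disc$genes
            # subtype evidence
            if (nrow(genes)) {
                genes$subtype <- NA_character_
                hasProt <- !is.na(genes$protein)
                if (any(hasProt)) {
                    st <- assignSubtypes(
                        setNames(genes$protein[hasProt],
                                 genes$gene_id[hasProt]),
                        queries, config$orthology)
                    genes$subtype[hasProt] <-
                        st$subtype[match(genes$gene_id[hasProt], st$gene_id)]
                }
            }
            # transcript evidence
            genes$n_reads <- NA_integer_
            genes$n_junction <- NA_integer_
            genes$expression <- "not assessed"
            if (!is.null(sp$reads)) {
                reads <- if (is.character(sp$reads))
                    Biostrings::readDNAStringSet(sp$reads) else sp$reads
                aln <- alignReads(reads, locus, config$splice)
                for (gid in names(disc$models)) {
                    supp <- expressionSupport(disc$models[[gid]], aln,
                                              config$splice)
                    i <- match(gid, genes$gene_id)
                    genes$n_reads[i] <- supp$n_reads
                    genes$n_junction[i] <- supp$n_intron_spanning
                    genes$expression[i] <- supp$note
                }
            }
            if (!is.null(outDir) && nrow(genes)) {
                calls <- data.frame(gene_id = genes$gene_id,
                                    start = genes$region_start,
                                    end = genes$region_end,
                                    strand = genes$strand,
                                    status = genes$status,
                                    family = genes$family,
                                    stringsAsFactors = FALSE)
                writeGeneMap(locus, calls,
                             file.path(outDir, paste0(nm, "_genes.gff3")),
                             file.path(outDir, paste0(nm, "_genes.bed")))
                writeHits(disc$hits,
                          file.path(outDir, paste0(nm, "_hits.tsv")))
            }
            allModels[[nm]] <- disc$models
            genes
        }, error = function(e) e)
        if (inherits(res, "error")) {
            status[nm] <- paste("failed:", conditionMessage(res))
        } else {
            status[nm] <- "ok"
            geneTables[[nm]] <- res
        }
    }
    geneTable <- if (length(geneTables)) do.call(rbind, geneTables)
                 else data.frame(species = character(0L),
                                 family = character(0L),
                                 status = character(0L))
    rownames(geneTable) <- NULL

    pa <- matrix(character(0L), nrow = 0L, ncol = 0L)
    em <- NULL
    if (nrow(geneTable)) {
        okSpecies <- names(status)[status == "ok"]
        pa <- buildPresenceAbsence(geneTable, species = okSpecies,
                                   families = sort(names(queries)),
                                   disruptedAs = config$disruptedAs)
        pa <- pa[rowSums(pa != "?") > 0L, , drop = FALSE]
        if (!is.null(tree) && nrow(pa))
            em <- dolloReconstruct(tree, pa)
    }

    if (!is.null(outDir)) {
        if (nrow(pa))
            write.table(pa, file.path(outDir, "presence_absence.tsv"),
                        sep = "\t", quote = FALSE, col.names = NA)
        if (nrow(geneTable))
            write.table(geneTable, file.path(outDir, "gene_table.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(em)) {
            rend <- renderEventCladogram(tree, em)
            writeLines(rend$newick, file.path(outDir, "events.nwk"))
            writeLines(as.character(rend$json),
                       file.path(outDir, "events.json"))
        }
        echo <- config
        echo$species <- lapply(config$species, function(s)
            list(name = s$name,
                 genome = if (is.character(s$genome)) s$genome else "<object>",
                 annotation = if (is.character(s$annotation)) s$annotation
                              else "<object>",
                 reads = if (is.null(s$reads)) NULL
                         else if (is.character(s$reads)) s$reads
                         else "<object>"))
        echo$queries <- names(queries)
        echo$tree <- if (is.character(config$tree)) config$tree
                     else if (is.null(tree)) NULL else ape::write.tree(tree)
        jsonlite::write_json(echo, file.path(outDir, "config.json"),
                             auto_unbox = TRUE, null = "null", digits = NA)
    }

    new("RunReport", geneTable = geneTable, presenceAbsence = pa,
        events = em, speciesStatus = status,
        params = config[c("anchorLeft", "anchorRight", "search", "geneModel",
                          "orthology", "splice", "disruptedAs", "mergeGap",
                          "maxRounds", "gapMinLength", "seed")])
}
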