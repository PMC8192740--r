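# Gain (origin/duplication) and loss events of gene families reconstructed
# on a rooted species tree by maximum parsimony. Dollo (single gain, any
# number of losses) is the default model; Fitch is the comparator.

# --- tree helpers (ape phylo) ------------------------------------------------

.childrenList <- function(tree) {
    n <- Ntip(tree) + Nnode(tree)
    ch <- vector("list", n)
    for (k in seq_len(nrow(tree$edge)))
        ch[[tree$edge[k, 1L]]] <- c(ch[[tree$edge[k, 1L]]], tree$edge[k, 2L])
    ch
}

.tipSets <- function(tree) {
    nt <- Ntip(tree)
    n <- nt + Nnode(tree)
    ch <- .childrenList(tree)
    sets <- vector("list", n)
    rec <- function(v) {
        if (v <= nt) { sets[[v]] <<- v; return(v) }
        out <- integer(0L)
        for (c in ch[[v]]) out <- c(out, rec(c))
        sets[[v]] <<- out
        out
    }
    rec(nt + 1L)
    sets
}

#' Branch label for a tree node
#'
#' Branches are identified by their child node and labelled by the sorted
#' tip set of the clade below (a tip branch is labelled by the tip itself).
#'
#' @param tree an `ape::phylo` rooted tree.
#' @param node ape node id.
#' @return Character label.
#' @export
branchLabel <- function(tree, node) {
    sets <- .tipSets(tree)
    vapply(node, function(v)
        paste(sort(tree$tip.label[sets[[v]]]), collapse = ","),
        character(1L))
}

.checkMatrix <- function(tree, pa) {
    stopifnot(is.matrix(pa), !is.null(colnames(pa)), !is.null(rownames(pa)))
    if (!all(colnames(pa) %in% tree$tip.label))
        stop("matrix taxa not in tree: ",
             paste(setdiff(colnames(pa), tree$tip.label), collapse = ", "))
    bad <- rowSums(pa != "?" & pa != "U") == 0L
    if (any(bad))
        stop("character(s) with no observed state: ",
             paste(rownames(pa)[bad], collapse = ", "))
    invisible(TRUE)
}

# --- Dollo -------------------------------------------------------------------

.dolloOne <- function(tree, states, sets, children) {
    # states: named P/A/D/? per tip (D = disrupted, counts as present)
    nt <- Ntip(tree)
    tipState <- states[tree$tip.label]
    present <- which(tipState %in% c("P", "D"))
    absent <- which(tipState == "A")
    if (!length(present))
        return(list(gain = NA_integer_, losses = integer(0L),
                    never = TRUE))
    gain <- if (length(present) == 1L) present
            else getMRCA(tree, present)
    hasP <- vapply(sets, function(s) any(s %in% present), logical(1L))
    hasA <- vapply(sets, function(s) any(s %in% absent), logical(1L))
    losses <- integer(0L)
    rec <- function(v) {
        for (c in children[[v]] %||% integer(0L)) {
            if (hasP[c]) rec(c)
            else if (hasA[c]) losses <<- c(losses, c)
            # all-unknown subtree: assigned present, no event
        }
    }
    rec(gain)
    list(gain = gain, losses = sort(losses), never = FALSE)
}

#' Dollo parsimony reconstruction of gain and loss events
#'
#' For each character, places a single gain at the most recent common
#' ancestor of all tips carrying the gene and the minimal set of loss
#' branches such that every absent tip descends from exactly one loss.
#' Unknown tips (assembly gaps, `?`) are free and never force events. The
#' loss count is provably minimal; equally parsimonious placements are
#' resolved by preferring internal (stem) placements over terminal branches
#' (all co-optimal maps are available via `enumerate = TRUE`). Tips whose
#' state is `D` (disrupted gene) count as present for origin dating, and the
#' disruption is additionally reported as a `loss_in_progress` event on the
#' terminal branch.
#'
#' @param tree rooted `ape::phylo`; tip labels are species ids.
#' @param pa characters x taxa matrix with states `P` (present), `A`
#'   (absent), `D` (present but disrupted) and `?`/`U` (unknown).
#' @param enumerate also return every co-optimal (gain, loss-set) map per
#'   character (exhaustive over unknown-tip assignments; intended for small
#'   trees).
#' @return An [EventMap-class]; with `enumerate = TRUE` the co-optimal maps
#'   are attached as `metadata` in the `flags` attribute column `n_cooptimal`
#'   and in `attr(, "cooptimal")` of the events slot.
#' @export
dolloReconstruct <- function(tree, pa, enumerate = FALSE) {
    .checkMatrix(tree, pa)
    sets <- .tipSets(tree)
    children <- .childrenList(tree)
    nt <- Ntip(tree)
    ev <- list(); fl <- list()
    coopt <- list()
    for (ch in rownames(pa)) {
        states <- setNames(rep("?", nt), tree$tip.label)
        states[colnames(pa)] <- pa[ch, ]
        states[states == "U"] <- "?"
        r <- .dolloOne(tree, states, sets, children)
        fl[[ch]] <- data.frame(character = ch, never_observed = r$never,
                               stringsAsFactors = FALSE)
        if (r$never) next
        rows <- data.frame(character = ch, type = "gain", node = r$gain,
                           branch = branchLabel(tree, r$gain),
                           stringsAsFactors = FALSE)
        if (length(r$losses))
            rows <- rbind(rows, data.frame(
                character = ch, type = "loss", node = r$losses,
                branch = branchLabel(tree, r$losses),
                stringsAsFactors = FALSE))
        disTips <- which(states[tree$tip.label] == "D")
        if (length(disTips))
            rows <- rbind(rows, data.frame(
                character = ch, type = "loss_in_progress", node = disTips,
                branch = tree$tip.label[disTips], stringsAsFactors = FALSE))
        ev[[ch]] <- rows
        if (enumerate) {
            unk <- which(states[tree$tip.label] == "?")
            maps <- list()
            combos <- if (length(unk))
                expand.grid(rep(list(c("P", "A")), length(unk)),
                            stringsAsFactors = FALSE)
            else data.frame(row.names = 1L)
            for (i in seq_len(nrow(combos))) {
                st2 <- states
                if (length(unk)) st2[unk] <- unlist(combos[i, ])
                r2 <- .dolloOne(tree, st2, sets, children)
                maps[[length(maps) + 1L]] <- r2
            }
            nl <- vapply(maps, function(m) length(m$losses), integer(1L))
            best <- min(nl)
            keys <- vapply(maps, function(m)
                paste(m$gain, paste(m$losses, collapse = "+")),
                character(1L))
            keep <- !duplicated(keys) & nl == best
            coopt[[ch]] <- maps[keep]
        }
    }
    events <- if (length(ev)) do.call(rbind, ev)
              else data.frame(character = character(0L), type = character(0L),
                              node = integer(0L), branch = character(0L),
                              stringsAsFactors = FALSE)
    rownames(events) <- NULL
    if (enumerate) attr(events, "cooptimal") <- coopt
    new("EventMap", tree = tree, events = events,
        flags = if (length(fl)) do.call(rbind, fl)
                else data.frame(character = character(0L),
                                never_observed = logical(0L)))
}

# --- Fitch -------------------------------------------------------------------

#' Fitch parsimony: minimum change count and one optimal labelling
#'
#' Unordered two-state (present/absent) Fitch passes; unknown tips carry the
#' full state set. Ties in the top-down pass are resolved deterministically:
#' the root prefers `present`, and every other node copies its parent's state
#' when allowed.
#'
#' @param tree rooted `ape::phylo`.
#' @param pa characters x taxa matrix (`P`/`A`/`D`/`?`; `D` counts as
#'   present).
#' @return list with `changes` (named integer vector per character) and
#'   `labelling` (nodes x characters matrix of `P`/`A`, rows ordered by ape
#'   node id, tips first).
#' @export
fitchReconstruct <- function(tree, pa) {
    .checkMatrix(tree, pa)
    nt <- Ntip(tree)
    nn <- nt + Nnode(tree)
    children <- .childrenList(tree)
    root <- nt + 1L
    changes <- setNames(integer(nrow(pa)), rownames(pa))
    lab <- matrix(NA_character_, nrow = nn, ncol = nrow(pa),
                  dimnames = list(NULL, rownames(pa)))
    PRES <- 2L; ABS <- 1L; BOTH <- 3L
    for (ch in rownames(pa)) {
        states <- setNames(rep("?", nt), tree$tip.label)
        states[colnames(pa)] <- pa[ch, ]
        sets <- integer(nn)
        nch <- 0L
        up <- function(v) {
            if (v <= nt) {
                s <- states[tree$tip.label[v]]
                sets[v] <<- if (s %in% c("P", "D")) PRES
                            else if (s == "A") ABS else BOTH
                return(invisible(NULL))
            }
            acc <- 0L
            for (c in children[[v]]) {
                up(c)
                if (acc == 0L) acc <- sets[c]
                else {
                    inter <- bitwAnd(acc, sets[c])
                    if (inter == 0L) {
                        acc <- bitwOr(acc, sets[c])
                        nch <<- nch + 1L
                    } else acc <- inter
                }
            }
            sets[v] <<- acc
            invisible(NULL)
        }
        up(root)
        changes[ch] <- nch
        down <- function(v, parentState) {
            s <- sets[v]
            pick <- if (!is.na(parentState) &&
                        bitwAnd(s, parentState) != 0L) {
                bitwAnd(s, parentState)
            } else s
            st <- if (bitwAnd(pick, PRES) != 0L) PRES else ABS
            lab[v, ch] <<- if (st == PRES) "P" else "A"
            for (c in children[[v]] %||% integer(0L)) down(c, st)
        }
        down(root, NA_integer_)
    }
    list(changes = changes, labelling = lab)
}

# --- presence/absence matrix -------------------------------------------------

#' Build a presence/absence matrix from per-species gene statuses
#'
#' Characters are gene families; per species the state is `P` when any
#' member gene is intact or truncated, `A` when no member was found,
#' `?` when the family's expected interval overlaps an assembly gap, and for
#' disrupted genes whatever `disruptedAs` selects (`"present"` maps to `P`
#' but keeps the disruption visible to [dolloReconstruct()] via state `D`;
#' pseudogenes are evidence of prior presence).
#'
#' @param geneTable data.frame with columns `species`, `family`, `status`
#'   (a [GeneStatus-class] state string).
#' @param species character vector of all species (columns); defaults to the
#'   species present in `geneTable`.
#' @param families character vector of all characters (rows); defaults to
#'   the families present in `geneTable`.
#' @param disruptedAs one of `"present"`, `"absent"`, `"own_state"`. Both
#'   `"present"` and `"own_state"` emit `D` (present-but-disrupted);
#'   `"absent"` emits `A`.
#' @return Character matrix families x species over `{P, A, D, ?}`.
#' @export
buildPresenceAbsence <- function(geneTable, species = NULL, families = NULL,
                                 disruptedAs = c("present", "own_state",
                                                 "absent")) {
    disruptedAs <- match.arg(disruptedAs)
    species <- species %||% sort(unique(geneTable$species))
    families <- families %||% sort(unique(geneTable$family))
    pa <- matrix("A", nrow = length(families), ncol = length(species),
                 dimnames = list(families, species))
    for (i in seq_len(nrow(geneTable))) {
        sp <- geneTable$species[i]; fam <- geneTable$family[i]
        if (!sp %in% species || !fam %in% families) next
        st <- geneTable$status[i]
        cur <- pa[fam, sp]
        val <- if (st %in% c("intact", "truncated")) "P"
               else if (grepl("^disrupted", st)) {
                   if (disruptedAs == "absent") "A" else "D"
               }
               else if (st == "unknown") "?"
               else "A"
        # precedence: P > D > ? > A
        rank <- c(P = 4L, D = 3L, "?" = 2L, A = 1L)
        if (rank[[val]] > rank[[cur]]) pa[fam, sp] <- val
    }
    pa
}

# --- rendering ---------------------------------------------------------------

#' Render an event map on the dated cladogram
#'
#' Produces an annotated newick string (gain and loss tags appended to tip
#' labels and placed as internal node labels) plus a JSON-ready event list
#' with branch endpoints and, when branch lengths carry divergence times,
#' the bounding times of each event branch (million years ago, tips at 0).
#'
#' @param tree rooted `ape::phylo`; branch lengths, when present, are
#'   interpreted as time.
#' @param eventMap an [EventMap-class].
#' @return list with `newick` (annotated tree), `events` (data.frame with
#'   `character`, `type`, `branch`, `t_parent`, `t_child`) and `json`.
#' @export
renderEventCladogram <- function(tree, eventMap) {
    ev <- eventTable(eventMap)
    nn <- Ntip(tree) + Nnode(tree)
    if (nrow(ev) && any(ev$node < 1L | ev$node > nn))
        stop("event references a branch not in the tree")
    atree <- tree
    if (nrow(ev)) {
        tags <- vapply(seq_len(nn), function(v) {
            e <- ev[ev$node == v, , drop = FALSE]
            if (!nrow(e)) return("")
            paste(paste0(e$type, ".", e$character), collapse = "+")
        }, character(1L))
        nt <- Ntip(tree)
        tipTags <- tags[seq_len(nt)]
        atree$tip.label <- ifelse(nzchar(tipTags),
                                  paste0(tree$tip.label, "__", tipTags),
                                  tree$tip.label)
        atree$node.label <- tags[(nt + 1L):nn]
    }
    times <- NULL
    if (!is.null(tree$edge.length)) {
        depth <- node.depth.edgelength(tree)
        times <- max(depth) - depth
    }
    evOut <- ev
    if (nrow(evOut)) {
        parentOf <- integer(nn)
        parentOf[tree$edge[, 2L]] <- tree$edge[, 1L]
        evOut$t_child <- if (is.null(times)) NA_real_ else times[evOut$node]
        evOut$t_parent <- if (is.null(times)) NA_real_ else
            ifelse(parentOf[evOut$node] == 0L, NA_real_,
                   times[parentOf[evOut$node]])
    } else {
        evOut$t_child <- numeric(0L); evOut$t_parent <- numeric(0L)
    }
    list(newick = ape::write.tree(atree),
         events = evOut,
         json = jsonlite::toJSON(evOut, auto_unbox = TRUE, digits = NA))
}
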