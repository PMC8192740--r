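cet_tree <- function() {
    ape::read.tree(text = "((dolphin,vaquita),(right_whale,(minke,blue)));")
}

pa_row <- function(tree, states, char = "X") {
    matrix(states, nrow = 1L,
           dimnames = list(char, tree$tip.label))
}

test_that("a gene observed in a single tip gains on its terminal branch", {
    tr <- ape::read.tree(text = "((A,B),C);")
    em <- dolloReconstruct(tr, pa_row(tr, c("P", "A", "A")))
    ev <- eventTable(em)
    expect_equal(ev$branch[ev$type == "gain"], "A")
    expect_equal(sum(ev$type == "loss"), 0L)
})

test_that("discordant presence forces a root gain and one loss", {
    tr <- ape::read.tree(text = "((A,B),C);")
    em <- dolloReconstruct(tr, pa_row(tr, c("P", "A", "P")))
    ev <- eventTable(em)
    expect_equal(ev$branch[ev$type == "gain"], "A,B,C")
    expect_equal(ev$branch[ev$type == "loss"], "B")
    expect_equal(unname(lossCount(em)), 1L)
    expect_equal(unname(lossCount(em)),
                 oracle_dollo(tr, c(A = "P", B = "A", C = "P")))
})

test_that("the PRR9 presence pattern maps to two specific losses", {
    tr <- cet_tree()
    pa <- pa_row(tr, c("P", "A", "P", "A", "A"), "PRR9")
    em <- dolloReconstruct(tr, pa)
    ev <- eventTable(em)
    expect_equal(ev$branch[ev$type == "gain"],
                 "blue,dolphin,minke,right_whale,vaquita")
    expect_setequal(ev$branch[ev$type == "loss"], c("vaquita", "blue,minke"))
    expect_equal(unname(lossCount(em)), 2L)
})

test_that("Dollo equals exhaustive minimization on one 5-tip shape", {
    tr <- five_tip_shapes()[[2L]]
    pats <- all_patterns(tr$tip.label)
    for (i in seq_len(nrow(pats))) {
        states <- unlist(pats[i, ])
        if (!any(states == "P")) next
        em <- dolloReconstruct(tr, pa_row(tr, states))
        expect_equal(unname(lossCount(em)), oracle_dollo(tr, states),
                     info = paste(states, collapse = ""))
    }
})

test_that("unknown tips never force events", {
    tr <- ape::read.tree(text = "((A,B),C);")
    # unknown inside the present clade: resolved as present, no loss
    em <- dolloReconstruct(tr, pa_row(tr, c("P", "?", "P")))
    expect_equal(unname(lossCount(em)), 0L)
    # character observed in one tip, unknown elsewhere
    em2 <- dolloReconstruct(tr, pa_row(tr, c("P", "?", "?")))
    ev2 <- eventTable(em2)
    expect_equal(ev2$branch[ev2$type == "gain"], "A")
    expect_equal(sum(ev2$type == "loss"), 0L)
})

test_that("a never-observed character is flagged, not reconstructed", {
    tr <- ape::read.tree(text = "((A,B),C);")
    em <- dolloReconstruct(tr, pa_row(tr, c("A", "A", "?")))
    expect_true(em@flags$never_observed[1L])
    expect_equal(nrow(eventTable(em)), 0L)
})

test_that("disrupted genes date the origin but flag loss in progress", {
    tr <- cet_tree()
    pa <- pa_row(tr, c("P", "D", "A", "A", "A"), "LELP1")
    em <- dolloReconstruct(tr, pa)
    ev <- eventTable(em)
    expect_equal(ev$branch[ev$type == "gain"], "dolphin,vaquita")
    expect_equal(ev$branch[ev$type == "loss_in_progress"], "vaquita")
    expect_equal(sum(ev$type == "loss"), 0L)
})

test_that("co-optimal loss placements are enumerable", {
    tr <- ape::read.tree(text = "(((A,B),C),D);")
    # B unknown: loss on the (A,B) stem (with B absent) or on A alone
    em <- dolloReconstruct(tr, pa_row(tr, c("A", "?", "P", "P")),
                           enumerate = TRUE)
    co <- attr(eventTable(em), "cooptimal")[["X"]]
    expect_equal(length(co), 2L)
    nl <- vapply(co, function(m) length(m$losses), integer(1L))
    expect_true(all(nl == 1L))
    # the canonical map prefers the internal stem placement
    ev <- eventTable(em)
    expect_equal(ev$branch[ev$type == "loss"], "A,B")
})

test_that("Fitch counts match exhaustive minimization", {
    tr <- ape::read.tree(text = "((A,B),C);")
    f <- fitchReconstruct(tr, pa_row(tr, c("P", "P", "P")))
    expect_equal(unname(f$changes), 0L)
    f2 <- fitchReconstruct(tr, pa_row(tr, c("P", "A", "P")))
    expect_equal(unname(f2$changes), 1L)
    cat4 <- ape::read.tree(text = "(((A,B),C),D);")
    f3 <- fitchReconstruct(cat4, pa_row(cat4, c("P", "A", "P", "A")))
    expect_equal(unname(f3$changes), 2L)
    expect_equal(unname(f3$changes),
                 oracle_fitch(cat4, c(A = "P", B = "A", C = "P", D = "A")))

    set.seed(601)
    tr5 <- five_tip_shapes()[[1L]]
    pats <- all_patterns(tr5$tip.label, c("P", "A"))
    for (i in sample(nrow(pats), 12L)) {
        states <- unlist(pats[i, ])
        if (!any(states == "P")) next
        f <- fitchReconstruct(tr5, pa_row(tr5, states))
        expect_equal(unname(f$changes), oracle_fitch(tr5, states))
    }
})

test_that("Dollo and Fitch agree on single contiguous present clades", {
    tr <- cet_tree()
    # present exactly in the toothed whales (dolphin, vaquita)
    pa <- pa_row(tr, c("P", "P", "A", "A", "A"))
    em <- dolloReconstruct(tr, pa)
    f <- fitchReconstruct(tr, pa)
    expect_equal(unname(lossCount(em)), 0L)
    expect_equal(eventTable(em)$branch[1L], "dolphin,vaquita")
    expect_equal(unname(f$changes), 1L)  # the single gain transition
})

test_that("event cladograms annotate exactly the event branches", {
    tr <- cet_tree()
    tr$edge.length <- rep(5, nrow(tr$edge))
    pa <- pa_row(tr, c("P", "A", "P", "A", "A"), "PRR9")
    em <- dolloReconstruct(tr, pa)
    r <- renderEventCladogram(tr, em)
    expect_match(r$newick, "vaquita__loss.PRR9", fixed = TRUE)
    expect_match(r$newick, "gain.PRR9")
    expect_false(grepl("dolphin__", r$newick))
    expect_true(all(c("t_parent", "t_child") %in% names(r$events)))
    expect_true(all(r$events$t_parent > r$events$t_child, na.rm = TRUE))

    # empty event map leaves the newick unchanged
    empty <- new("EventMap", tree = tr,
                 events = eventTable(em)[0L, ],
                 flags = em@flags[0L, ])
    expect_equal(renderEventCladogram(tr, empty)$newick,
                 ape::write.tree(tr))

    bad <- em
    bad@events$node[1L] <- 99L
    expect_error(renderEventCladogram(tr, bad), "not in the tree")
})

test_that("presence/absence matrices map statuses with precedence", {
    gt <- data.frame(
        species = c("a", "a", "b", "c", "c"),
        family = c("F1", "F1", "F1", "F1", "F2"),
        status = c("intact", "disrupted_stop", "disrupted_frameshift",
                   "unknown", "truncated"),
        stringsAsFactors = FALSE)
    pa <- buildPresenceAbsence(gt, species = c("a", "b", "c"))
    expect_equal(pa["F1", ], c(a = "P", b = "D", c = "?"))
    expect_equal(pa["F2", ], c(a = "A", b = "A", c = "P"))
    pa2 <- buildPresenceAbsence(gt, species = c("a", "b", "c"),
                                disruptedAs = "absent")
    expect_equal(pa2["F1", "b"], "A")
})
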