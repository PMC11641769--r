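test_that("identity-to-distance conversions match their closed forms", {
    expect_equal(identityToDistance(1.0, "p"), 0)
    expect_equal(identityToDistance(1.0, "kimura"), 0)
    expect_equal(identityToDistance(0.75, "p"), 0.25)
    expect_equal(identityToDistance(0.75, "kimura"),
                 -log(1 - 0.25 - 0.2 * 0.25^2))
    expect_error(identityToDistance(0.05, "kimura"), "correction undefined")
    expect_error(identityToDistance(1.2), "\\[0, 1\\]")
})

test_that("2- and 3-leaf trees take their closed forms", {
    d2 <- matrix(c(0, 0.8, 0.8, 0), 2, dimnames = list(c("A", "B"),
                                                       c("A", "B")))
    t2 <- neighborJoining(d2)
    expect_equal(sum(t2@lengths), 0.8)
    expect_identical(toNewick(t2), "(A:0.4,B:0.4);")

    d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
                 dimnames = list(LETTERS[1:3], LETTERS[1:3]))
    expect_identical(toNewick(neighborJoining(d3)), "(A:1,B:1,C:3);")
})

test_that("NJ rejects invalid distance matrices", {
    d <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
    expect_error(neighborJoining(d), "symmetric")
    d <- matrix(c(0, -1, -1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
    expect_error(neighborJoining(d), "non-negative")
})

test_that("the four-taxon additive example is recovered exactly", {
    dm <- matrix(c(0, 3, 3, 5, 3, 0, 4, 6, 3, 4, 0, 4, 5, 6, 4, 0), 4,
                 dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    tr <- neighborJoining(dm)
    expect_identical(toNewick(tr), "((A:1,B:2):1,C:1,D:3);")
    expect_equal(treeDistances(tr)[LETTERS[1:4], LETTERS[1:4]], dm)
})

test_that("NJ recovers topology and branch lengths on additive matrices (n <= 6), vs topology enumeration", {
    set.seed(77)
    for (n in 4:6) {
        for (rep in 1:6) {
            gen <- random_additive_matrix(n)
            tr <- neighborJoining(gen$d)
            # exact path-length recovery
            expect_equal(treeDistances(tr)[rownames(gen$d), colnames(gen$d)],
                         gen$d, tolerance = 1e-9)
            # topology equals the generating one
            got <- tree_splits(tr)
            expect_true(same_split_set(got, gen$splits))
            # brute force: the generating topology is the unique additive fit
            topos <- enumerate_topologies(n)
            fits <- vapply(topos, function(tp)
                topology_fits_additive(tp$edges, gen$d)$ok, logical(1))
            expect_identical(sum(fits), 1L)
            fit_splits <- edge_splits(topos[[which(fits)]]$edges, n)
            expect_true(same_split_set(got, fit_splits))
        }
    }
})

test_that("NJ agrees with the ape reference implementation on additive input", {
    set.seed(78)
    for (rep in 1:5) {
        n <- sample(4:8, 1)
        gen <- random_additive_matrix(n)
        mine <- asPhylo(neighborJoining(gen$d))
        ref <- ape::nj(as.dist(gen$d))
        expect_equal(phangorn::RF.dist(mine, ref), 0)
    }
})

test_that("relabeling/permutation leaves topology and lengths unchanged", {
    set.seed(79)
    gen <- random_additive_matrix(6)
    perm <- sample(6)
    dp <- gen$d[perm, perm]
    t1 <- neighborJoining(gen$d)
    t2 <- neighborJoining(dp)
    labs <- rownames(gen$d)
    expect_equal(treeDistances(t1)[labs, labs],
                 treeDistances(t2)[labs, labs], tolerance = 1e-9)
    expect_identical(toNewick(t1), toNewick(t2))
})

test_that("Newick serialization is deterministic and round-trips through ape", {
    set.seed(80)
    gen <- random_additive_matrix(5)
    tr <- neighborJoining(gen$d)
    nwk <- toNewick(tr)
    expect_match(nwk, ";$")
    parsed <- ape::read.tree(text = nwk)
    expect_setequal(parsed$tip.label, leafLabels(tr))
    back <- ape::cophenetic.phylo(parsed)
    labs <- leafLabels(tr)
    expect_equal(back[labs, labs], treeDistances(tr)[labs, labs],
                 tolerance = 1e-4)
})

test_that("negative NJ branch lengths are clamped with the deficit moved to the sister", {
    # A matrix known to produce a negative branch estimate.
    d <- matrix(c(0, 5, 9, 9, 8,
                  5, 0, 10, 10, 9,
                  9, 10, 0, 8, 7,
                  9, 10, 8, 0, 3,
                  8, 9, 7, 3, 0), 5,
                dimnames = list(letters[1:5], letters[1:5]))
    tr <- neighborJoining(d)
    expect_true(all(tr@lengths >= 0))
    # joined-pair path lengths are preserved by the deficit transfer
    expect_true(all(is.finite(treeDistances(tr))))
})

test_that("clade membership queries work on unrooted trees", {
    dm <- matrix(c(0, 3, 3, 5, 3, 0, 4, 6, 3, 4, 0, 4, 5, 6, 4, 0), 4,
                 dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    tr <- neighborJoining(dm)
    expect_true(hasClade(tr, c("A", "B")))
    expect_true(hasClade(tr, c("C", "D")))
    expect_false(hasClade(tr, c("A", "C")))
    expect_error(hasClade(tr, "Z"), "unknown leaf")
})

test_that("distance matrix TSV round trip", {
    set.seed(81)
    gen <- random_additive_matrix(4)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeDistanceMatrix(gen$d, path)
    expect_equal(readDistanceMatrix(path), gen$d)
})
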