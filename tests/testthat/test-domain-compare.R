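make_toy_set <- function() {
    # two proteins with 3 domains each plus one with 2 domains
    doms <- list(P1 = c("ACDEFGHIKL", "MNPQRSTVWY", "ACDEFGHIKW"),
                 P2 = c("ACDEFGHIKL", "MNPQRSTVWF", "ACDEFGHIKW"),
                 P3 = c("ACDEFGHIKL", "MNPQRSTVWY"))
    seqs <- vapply(doms, function(d) paste(d, collapse = "GSGSG"),
                   character(1))
    ann <- do.call(rbind, lapply(names(doms), function(p) {
        k <- length(doms[[p]])
        starts <- cumsum(c(1, rep(15, k - 1)))
        data.frame(protein_id = p, domain_index = seq_len(k),
                   start = starts, end = starts + 9L, score = 2)
    }))
    tax <- data.frame(id = names(doms), domain_of_life = "Bacteria",
                      phylum = c("PhyA", "PhyA", "PhyA"), class_ = "")
    list(records = Biostrings::AAStringSet(seqs), ann = ann, tax = tax)
}

test_that("extractDomains slices by position and enforces a hard k", {
    toy <- make_toy_set()
    expect_warning(
        g <- extractDomains(toy$records, toy$ann, toy$tax, k = 3,
                            name = "PhyA", phylum = "PhyA"),
        "excluded 1 protein.*P3")
    expect_identical(length(g), 3L)
    expect_identical(names(groupMembers(g, 1)), c("P1", "P2"))
    expect_identical(unname(groupMembers(g, 2)[["P1"]]), "MNPQRSTVWY")
    expect_error(
        suppressWarnings(extractDomains(toy$records, toy$ann, toy$tax,
                                        k = 5, name = "PhyA",
                                        phylum = "PhyA")),
        "exactly 5 domains")
    expect_error(extractDomains(toy$records, toy$ann, toy$tax, k = 3,
                                name = "nope", phylum = "PhyX"),
                 "empty selection")
})

test_that("identity matrix cells are cross/within means; transpose symmetry", {
    toy <- make_toy_set()
    g <- suppressWarnings(extractDomains(toy$records, toy$ann, toy$tax,
                                         k = 3, name = "PhyA",
                                         phylum = "PhyA"))
    m <- identityMatrix(g)
    v <- identityValues(m)
    expect_identical(dim(v), c(3L, 3L))
    expect_true(all(v >= 0 & v <= 1))
    # diagonal: within-position mean identity
    expect_equal(v[1, 1], 1.0)                     # identical first domains
    expect_equal(v[2, 2], 0.9)                     # one mismatch in 10
    # off-diagonal (1,3): all 4 cross pairs are 9/10 identical
    expect_equal(v[1, 3], 0.9)
    expect_identical(identityCounts(m)[1, 3], 4L)

    # transpose symmetry against a second group
    g2 <- suppressWarnings(extractDomains(toy$records, toy$ann, toy$tax,
                                          k = 3, name = "B",
                                          phylum = "PhyA"))
    m12 <- identityMatrix(g, g2)
    m21 <- identityMatrix(g2, g)
    expect_equal(identityValues(m12), t(identityValues(m21)))
})

test_that("single protein with two identical domains gives an all-1 matrix", {
    seqs <- Biostrings::AAStringSet(c(P1 = "ACDEFGHIKLWWACDEFGHIKL"))
    ann <- data.frame(protein_id = "P1", domain_index = 1:2,
                      start = c(1L, 13L), end = c(10L, 22L), score = 2)
    g <- extractDomains(seqs, ann, k = 2, name = "solo")
    v <- identityValues(identityMatrix(g))
    expect_equal(unname(v), matrix(1, 2, 2))
})

test_that("best correspondence takes row argmax with smallest-column ties", {
    m <- new("IdentityMatrix", groupA = "A", groupB = "B",
             values = matrix(c(0.2, 0.5, 0.5, 0.2), 2, byrow = TRUE),
             counts = matrix(1L, 2, 2))
    bc <- bestCorrespondence(m)
    expect_identical(bc$position_b, c(2L, 1L))
    expect_equal(bc$identity, c(0.5, 0.5))
    expect_identical(bc$tied, c("", ""))

    m2 <- new("IdentityMatrix", groupA = "A", groupB = "B",
              values = matrix(c(0.4, 0.4, 0.1), 1), counts = matrix(1L, 1, 3))
    bc2 <- bestCorrespondence(m2)
    expect_identical(bc2$position_b, 1L)
    expect_identical(bc2$tied, "1,2")
})

test_that("adding a duplicate member moves a cell at most by the pair bound", {
    set.seed(15)
    a <- vapply(1:3, function(i) rand_seq(30), character(1))
    b <- vapply(1:4, function(i) rand_seq(30), character(1))
    base <- crossGroupIdentity(a, b)
    withdup <- crossGroupIdentity(a, c(b, b[1]))
    # mean over 15 pairs vs 12: the 3 duplicated pairs shift the mean by
    # at most (max pair - min pair) * 3/15 <= 1 * 3/15
    expect_lte(abs(withdup - base), 3 / 15 + 1e-12)
})

test_that("length/repeat correlation: perfect monotone, degenerate, synthetic", {
    recs <- Biostrings::AAStringSet(c(A = rand_seq(100), B = rand_seq(200),
                                      C = rand_seq(300)))
    ann <- data.frame(protein_id = c("A", "B", "B", "C", "C", "C"),
                      domain_index = c(1L, 1L, 2L, 1L, 2L, 3L),
                      start = c(1, 1, 60, 1, 60, 120),
                      end = c(50, 50, 110, 50, 110, 170), score = 2)
    expect_equal(lengthRepeatCorrelation(recs, ann), 1.0)

    ann1 <- ann[ann$domain_index == 1L, ]
    expect_warning(r0 <- lengthRepeatCorrelation(recs, ann1), "constant")
    expect_equal(r0, 0)

    # generator couples protein size with domain count
    rows <- data.frame(domain_of_life = "Bacteria", n_domains = 1:3,
                       n_proteins = 4,
                       min_len = c(100L, 220L, 340L),
                       max_len = c(200L, 320L, 440L))
    truth <- generateCensusFixture(rows, seed = 7)
    expect_gt(lengthRepeatCorrelation(truthRecords(truth),
                                      truthAnnotations(truth)), 0)
})

test_that("identity matrix TSV export has percent cells at one decimal", {
    toy <- make_toy_set()
    g <- suppressWarnings(extractDomains(toy$records, toy$ann, toy$tax,
                                         k = 3, name = "PhyA",
                                         phylum = "PhyA"))
    m <- identityMatrix(g)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeIdentityMatrix(m, path)
    tab <- utils::read.delim(path)
    expect_identical(tab$position, c("pos1", "pos2", "pos3"))
    expect_equal(tab$pos2[1], round(100 * identityValues(m)[1, 2], 1))
})
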