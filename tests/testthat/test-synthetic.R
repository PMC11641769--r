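test_that("spec validation catches inconsistent requests before generation", {
    g <- list(list(name = "G", n_proteins = 2, k = 2, divergence = 0.2))
    expect_error(syntheticSpec(groups = g), "seed is mandatory")
    expect_error(syntheticSpec(groups = list(list(name = "G")), seed = 1),
                 "needs name")
    expect_error(syntheticSpec(groups = g, seed = 1,
                               transfer = list(source_group = "G",
                                               source_position = 5,
                                               target_group_name = "G")),
                 "source_position")
    expect_error(syntheticSpec(groups = g, seed = 1,
                               transfer = list(source_group = "X",
                                               source_position = 1,
                                               target_group_name = "G")),
                 "unknown transfer source")
})

test_that("mutateSequence: zero divergence and full conservation are identities", {
    set.seed(2)
    s <- rand_seq(120)
    expect_identical(mutateSequence(s, 0), s)
    expect_identical(mutateSequence(s, 5, conservation = 1), s)
    expect_identical(nchar(mutateSequence(s, 0.5)), 120L)
})

test_that("mutateSequence substitution fraction matches the binomial oracle", {
    set.seed(1)
    s <- rand_seq(1000)
    m <- mutateSequence(s, 0.3)
    p <- 1 - exp(-0.3)
    obs <- mean(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
    se <- sqrt(p * (1 - p) / 1000)
    expect_lt(abs(obs - p), 3 * se)
})

test_that("one zero-divergence group yields identical proteins' domains", {
    sp <- syntheticSpec(groups = list(list(name = "G", n_proteins = 3, k = 1,
                                           divergence = 0)), seed = 4)
    truth <- generateFamily(sp)
    ann <- truthAnnotations(truth)
    seqs <- as.character(truthRecords(truth))
    doms <- substr(seqs[ann$protein_id], ann$start, ann$end)
    expect_identical(length(unique(doms)), 1L)
    expect_equal(groupIdentity(doms), 1.0)
})

test_that("generation is fully deterministic under a fixed seed", {
    sp1 <- endosymbiosisSpec(seed = 42)
    sp2 <- endosymbiosisSpec(seed = 42)
    t1 <- generateFamily(sp1)
    t2 <- generateFamily(sp2)
    expect_identical(as.character(truthRecords(t1)),
                     as.character(truthRecords(t2)))
    expect_identical(truthAnnotations(t1), truthAnnotations(t2))
    f1 <- withr::local_tempfile(fileext = ".fasta")
    f2 <- withr::local_tempfile(fileext = ".fasta")
    writeProteins(truthRecords(t1), f1)
    writeProteins(truthRecords(t2), f2)
    expect_identical(readLines(f1), readLines(f2))
    t3 <- generateFamily(endosymbiosisSpec(seed = 43))
    expect_false(identical(as.character(truthRecords(t1)),
                           as.character(truthRecords(t3))))
})

test_that("truth annotations are consistent with the emitted records", {
    truth <- generateFamily(endosymbiosisSpec(seed = 6))
    ann <- truthAnnotations(truth)
    w <- setNames(Biostrings::width(truthRecords(truth)),
                  names(truthRecords(truth)))
    expect_true(all(ann$end <= w[ann$protein_id]))
    expect_true(all(ann$start >= 1))
    # every domain slice has the spec'd length (no indels in domains)
    expect_true(all(ann$end - ann$start + 1 == 80L))
    # source map present iff transfer requested
    expect_identical(names(truthSourceMap(truth)), "Organelle")
    no_tr <- generateFamily(syntheticSpec(
        groups = list(list(name = "G", n_proteins = 2, k = 2,
                           divergence = 0.2)), seed = 1))
    expect_identical(truthSourceMap(no_tr), list())
})

test_that("independently rooted groups are less alike than group members", {
    sp <- syntheticSpec(groups = list(
        list(name = "G1", n_proteins = 3, k = 1, divergence = 0.2),
        list(name = "G2", n_proteins = 3, k = 1, divergence = 0.2)),
        seed = 11, root_divergence = 1.5)
    truth <- generateFamily(sp)
    ann <- truthAnnotations(truth)
    seqs <- as.character(truthRecords(truth))
    doms <- substr(seqs[ann$protein_id], ann$start, ann$end)
    names(doms) <- ann$protein_id
    g1 <- doms[grepl("^G1", names(doms))]
    g2 <- doms[grepl("^G2", names(doms))]
    expect_gt(groupIdentity(g1), crossGroupIdentity(g1, g2))
    expect_gt(groupIdentity(g2), crossGroupIdentity(g1, g2))
})

test_that("pairwise identity after divergence matches the analytic expectation", {
    # Two sequences independently diverged by d from one ancestor. Per free
    # site: P(same) = e^{-2d} + (1 - e^{-2d}) * ~1/19 background collision.
    d <- 0.25
    cons <- 0.3
    set.seed(21)
    idents <- replicate(40, {
        L <- 200
        w <- numeric(L)
        w[sample(L, round(cons * L))] <- 1
        anc <- rand_seq(L)
        a <- mutateSequence(anc, d, w)
        b <- mutateSequence(anc, d, w)
        mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
    })
    coll <- 1 / 19   # approximate: uniform background excluding current
    expected <- cons + (1 - cons) * (exp(-2 * d) + (1 - exp(-2 * d)) * coll)
    expect_lt(abs(mean(idents) - expected), 0.05)
})

test_that("census fixture pins row counts, extremes and archaeal k = 1", {
    rows <- data.frame(domain_of_life = c("Archaea", "Bacteria", "Eukaryota"),
                       n_domains = c(1L, 6L, 3L), n_proteins = c(5L, 3L, 4L),
                       min_len = c(79L, 500L, 300L),
                       max_len = c(896L, 932L, 420L))
    truth <- generateCensusFixture(rows, seed = 7)
    cen <- buildCensus(truthRecords(truth), truthAnnotations(truth),
                       truthTaxonomy(truth))
    expect_identical(cen$count, rows$n_proteins)
    expect_identical(cen$min_len, rows$min_len)
    expect_identical(cen$max_len, rows$max_len)
    arch <- cen[cen$domain_of_life == "Archaea", ]
    expect_identical(arch$n_domains, 1L)

    # byte-identical FASTA under the same seed
    t2 <- generateCensusFixture(rows, seed = 7)
    f1 <- withr::local_tempfile(fileext = ".fasta")
    f2 <- withr::local_tempfile(fileext = ".fasta")
    writeProteins(truthRecords(truth), f1)
    writeProteins(truthRecords(t2), f2)
    expect_identical(readLines(f1), readLines(f2))
})
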