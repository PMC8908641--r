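test_that("group selection keeps markers with at least GMode contigs", {
    ms <- new("MarkerSet", groups = list(
        m1 = c("a", "b", "c"), m2 = c("b", "c", "d"), m3 = c("a", "d")))
    sel <- selectGroups(ms, 3L)
    expect_named(sel, c("m1", "m2"))
    expect_length(selectGroups(ms, 2L), 3)
    expect_error(selectGroups(ms, 4L), "no marker group")
    ones <- new("MarkerSet", groups = list(m1 = "a", m2 = "b"))
    expect_length(selectGroups(ones, 1L), 2)
})

test_that("adjacency bonuses: full, split and absent cases", {
    ids <- c("c1", "c2", "c3", "c4")
    A <- matrix(0, 4, 4, dimnames = list(ids, ids))
    # classifier trained on group {c1, c2}; predicted labels of the others
    # place the full bonus of 1 when a label claims one contig of a group
    pred <- c(c1 = "c1", c2 = "c2", c3 = "c1", c4 = "c2")
    A1 <- accumulateBonuses(A, list(c("c3"), c("c4")), pred)
    expect_equal(A1["c1", "c3"], 1)
    expect_equal(A1["c2", "c4"], 1)
    expect_equal(sum(A1), 2)
    # two contigs of one predicted group claimed by the same label: 0.5 each
    pred2 <- c(c1 = "c1", c2 = "c2", c3 = "c1", c4 = "c1")
    A2 <- accumulateBonuses(A, list(c("c3", "c4")), pred2)
    expect_equal(A2["c1", "c3"], 0.5)
    expect_equal(A2["c1", "c4"], 0.5)
    expect_equal(sum(A2["c2", ]), 0)  # unclaimed label adds nothing
})

test_that("symmetrized adjacency is exactly symmetric", {
    set.seed(1)
    A <- matrix(runif(25), 5, 5)
    M <- A + t(A)
    expect_identical(M, t(M))
})

test_that("spectral clustering recovers disconnected blocks exactly", {
    ids <- letters[1:6]
    A <- matrix(0, 6, 6, dimnames = list(ids, ids))
    A[1:3, 1:3] <- 1
    A[4:6, 4:6] <- 1
    part <- spectralSeedClusters(A, 2L, seed = 1)
    expect_length(unique(part[1:3]), 1)
    expect_length(unique(part[4:6]), 1)
    expect_true(part[["a"]] != part[["d"]])
    expect_equal(unname(spectralSeedClusters(A, 1L, seed = 1)),
        rep(1L, 6))
})

test_that("spectral bipartition matches the brute-force normalized cut", {
    ids <- paste0("n", 1:6)
    M <- matrix(0, 6, 6, dimnames = list(ids, ids))
    M[1:3, 1:3] <- 2
    M[4:6, 4:6] <- 2
    diag(M) <- 0
    M["n3", "n4"] <- M["n4", "n3"] <- 0.2   # weak bridge
    M["n1", "n5"] <- M["n5", "n1"] <- 0.1
    part <- spectralSeedClusters(M / 2, 2L, seed = 1)  # A: half of M
    want <- bruteNormalizedCut(M)$side
    agree <- mean((part == part[1]) == (want == want[1]))
    expect_true(agree %in% c(0, 1))  # identical up to label swap
})

test_that("seeds concatenate members in input contig order", {
    contigs <- Biostrings::DNAStringSet(c(
        c1 = "AAAA", c2 = "CCCCCC", c3 = "GGG"))
    part <- c(c1 = 1L, c2 = 1L, c3 = 2L)
    seeds <- buildSeeds(part, contigs)
    expect_length(seeds, 2)
    expect_equal(as.character(seeds[[1]]), "AAAACCCCCC")
    expect_equal(Biostrings::width(seeds), c(10L, 3L))
    expect_equal(S4Vectors::mcols(seeds)$members[[1]], c("c1", "c2"))
    # singletons reproduce their contig
    single <- buildSeeds(c(c1 = 1L, c2 = 2L, c3 = 3L), contigs)
    expect_equal(unname(as.character(single)),
        unname(as.character(contigs)))
})

test_that("marker-guided seeding recovers genomes on a small community", {
    com <- smallCommunity(seed = 31, G = 3L, genomeBp = 8e5)
    ms <- filterMarkerHits(com$markerHits)
    est <- estimateGenomeNumber(ms)
    expect_equal(est$G, 3L)
    sel <- selectGroups(ms, est$GMode)
    logCov <- log(com$coverage + 1)
    A <- buildAdjacency(sel, com$contigs, logCov, seed = 5)
    part <- spectralSeedClusters(A, est$G, seed = 5)
    truthOf <- com$truth$genome_id[match(names(part),
        com$truth$contig_id)]
    # each spectral cluster should be dominated by one genome
    purity <- vapply(split(truthOf, part), function(v)
        max(table(v)) / length(v), numeric(1))
    expect_true(all(purity >= 0.9))
    seeds <- buildSeeds(part, com$contigs)
    expect_length(seeds, 3)
    memberLens <- vapply(S4Vectors::mcols(seeds)$members, function(m)
        sum(Biostrings::width(com$contigs[m])), numeric(1))
    expect_equal(unname(Biostrings::width(seeds)), unname(memberLens))
})
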