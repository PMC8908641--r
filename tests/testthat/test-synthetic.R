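test_that("community generation is a deterministic function of the spec", {
    spec <- communitySpec(G = 2L, genomeBp = 3e5,
        contigLenRange = c(5000L, 15000L), markerCount = 10L, seed = 5L)
    a <- generateCommunity(spec)
    b <- generateCommunity(spec)
    expect_identical(as.character(a$contigs), as.character(b$contigs))
    expect_identical(a$coverage, b$coverage)
    expect_identical(a$markerHits, b$markerHits)
    expect_identical(a$truth, b$truth)
})

test_that("without dropout or duplication every marker maps to G contigs", {
    spec <- communitySpec(G = 3L, genomeBp = 3e5,
        contigLenRange = c(5000L, 15000L), markerCount = 12L,
        dropout = 0, duplication = 0, seed = 9L)
    com <- generateCommunity(spec)
    ms <- filterMarkerHits(com$markerHits)
    expect_true(all(markerCounts(ms) == 3L))
    expect_equal(estimateGenomeNumber(ms)$G, 3L)
})

test_that("genomes are compositionally separable and truth bp consistent", {
    com <- generateCommunity(communitySpec(G = 2L, genomeBp = 4e5,
        contigLenRange = c(8000L, 16000L), seed = 21L))
    expect_equal(as.numeric(Biostrings::width(com$contigs)),
        com$truth$length)
    km <- kmerFrequencies(com$contigs)
    g <- com$truth$genome_id
    intra <- mean(c(averagePairwiseDistance(km[g == g[1], ]),
        averagePairwiseDistance(km[g != g[1], ])))
    inter <- sqrt(sum((colMeans(km[g == g[1], ]) -
        colMeans(km[g != g[1], ]))^2))
    expect_gt(inter, intra)
    # coverage table covers all contigs, all samples positive
    expect_identical(rownames(com$coverage), names(com$contigs))
    expect_true(all(com$coverage > 0))
})

test_that("generated files round-trip through the pipeline readers", {
    dir <- withr::local_tempdir()
    com <- generateCommunity(communitySpec(G = 2L, genomeBp = 2.5e5,
        contigLenRange = c(5000L, 12000L), markerCount = 6L, seed = 3L),
        dir = dir)
    back <- readContigs(file.path(dir, "contigs.fasta"))
    expect_identical(as.character(back), as.character(com$contigs))
    cov <- readCoverageTable(file.path(dir, "coverage.tsv"))
    expect_equal(cov, com$coverage)
    hits <- readMarkerHits(file.path(dir, "markers.tsv"))
    expect_equal(hits$contig_id, com$markerHits$contig_id)
})

test_that("evaluator metrics match hand arithmetic on a toy clustering", {
    truth <- data.frame(contig_id = c("c1", "c2", "c3"),
        genome_id = c("gA", "gB", "gB"),
        length = c(100, 100, 200), stringsAsFactors = FALSE)
    pred <- data.frame(contig_id = c("c1", "c2", "c3"),
        cluster_id = c("k1", "k1", "k2"),
        status = "output", stringsAsFactors = FALSE)
    ev <- evaluateClusters(pred, truth)
    per <- ev$perCluster[order(ev$perCluster$cluster_id), ]
    # k1: 100 bp gA + 100 bp gB, tie broken by first max -> precision 0.5
    expect_equal(per$precision[per$cluster_id == "k1"], 0.5)
    # k2: pure gB, holds 200 of gB's 300 bp
    expect_equal(per$precision[per$cluster_id == "k2"], 1)
    expect_equal(per$recall[per$cluster_id == "k2"], 2 / 3)
    expect_equal(per$f1[per$cluster_id == "k2"], 2 * 1 * (2/3) / (1 + 2/3))
    # greedy matching credits each genome at most once
    expect_lte(sum(ev$perCluster$matched[ev$perCluster$genome_id == "gB"]),
        1)
    # perfect clustering scores 1 everywhere
    perf <- data.frame(contig_id = c("c1", "c2", "c3"),
        cluster_id = c("k1", "k2", "k2"), status = "output",
        stringsAsFactors = FALSE)
    evp <- evaluateClusters(perf, truth)
    expect_true(all(evp$perCluster$precision == 1))
    expect_true(all(evp$perCluster$recall == 1))
    expect_equal(evp$summary$highQuality, 2L)
    expect_error(evaluateClusters(
        data.frame(contig_id = "zz", cluster_id = "k", status = "output"),
        truth), "absent")
})

test_that("evaluation is invariant under relabeling and bp-bounded", {
    com <- smallCommunity(seed = 13)
    mem <- data.frame(contig_id = com$truth$contig_id,
        cluster_id = com$truth$genome_id, status = "output",
        stringsAsFactors = FALSE)
    ev1 <- evaluateClusters(mem, com$truth)
    mem2 <- mem
    mem2$cluster_id <- paste0("relabel_", as.integer(factor(mem$cluster_id,
        levels = rev(sort(unique(mem$cluster_id))))))
    ev2 <- evaluateClusters(mem2, com$truth)
    expect_equal(sort(ev1$perCluster$f1), sort(ev2$perCluster$f1))
    expect_equal(ev1$summary, ev2$summary)
    bpBound <- sum(ev1$perCluster$precision * ev1$perCluster$cluster_bp)
    expect_lte(bpBound, sum(com$truth$length) + 1e-9)
})
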