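test_that("fragment ANI recovers identity and substitution divergence", {
    g <- randomGenome(60000, gc = 0.5, seed = 101)
    A <- genomeRecord("A", g)
    expect_equal(ani(A, A)$ani, 100)
    B <- genomeRecord("B", mutateGenome(g, 0.05, seed = 102))
    r <- ani(A, B)
    expect_equal(r$ani, 95, tolerance = 0.5 / 95)
    expect_gt(min(r$fragments_used), 0)
    ## symmetrised: both orders agree
    expect_equal(ani(B, A)$ani, r$ani, tolerance = 1e-9)
    ## unrelated genomes: undefined with a reason
    U <- genomeRecord("U", randomGenome(60000, seed = 103))
    ru <- ani(A, U)
    expect_true(is.na(ru$ani))
    expect_match(ru$reason, "no fragment")
})

test_that("RBH AAI is exact on identity, symmetric, and tracks divergence", {
    P <- randomProteome(60, c(200, 350), seed = 104)
    r <- aai(P, P)
    expect_equal(r$aai, 100)
    expect_equal(r$rbh_count, 60L)
    Q <- mutateProteome(P, 0.10, seed = 105)
    r2 <- aai(P, Q)
    expect_equal(r2$aai, 90, tolerance = 1.5 / 90)
    expect_identical(r2$aai, aai(Q, P)$aai)
})

test_that("tetranucleotide signatures behave as genome fingerprints", {
    g <- randomGenome(50000, gc = 0.55, seed = 106)
    s <- tetraSignature(g)
    expect_length(s, 256)
    expect_equal(tetraCorrelation(s, s), 1.0)
    ## both-strand counting makes the signature strand-invariant
    expect_equal(tetraSignature(Biostrings::reverseComplement(g)), s)
    ## invariant to contig order
    two <- c(randomGenome(30000, seed = 107, id = "c1"),
             randomGenome(20000, seed = 108, id = "c2"))
    expect_equal(tetraSignature(two), tetraSignature(rev(two)))
    ## unrelated random genomes decorrelate
    for (sd in 1:5) {
        r <- tetraCorrelation(randomGenome(100000, seed = 200 + sd),
                              randomGenome(100000, seed = 300 + sd))
        expect_lt(abs(r), 0.3)
    }
    expect_warning(tetraSignature(randomGenome(5000, seed = 1)), "10 kb")
})

test_that("species calls apply the 95% ANI / 70% AAI cut-offs", {
    expect_true(sameSpecies(ani_pct = 99.99)$same_species)
    expect_false(sameSpecies(ani_pct = 82.6)$same_species)
    expect_true(sameSpecies(ani_pct = 95.0)$same_species)   # inclusive
    ## AAI rule decides when ANI is undefined
    expect_true(sameSpecies(aai_pct = 99.3)$same_species)
    expect_false(sameSpecies(aai_pct = 69.7)$same_species)
    u <- sameSpecies()
    expect_false(u$callable)
    expect_true(is.na(u$same_species))
})

test_that("quality filtering applies strict completeness/contamination rules", {
    tab <- data.frame(
        id = c("m1", "m2", "m3", "m4", "m5"),
        completeness = c(86.9, 70.7, 70.0, 99.8, NA),
        contamination = c(4.8, 0.0, 1.0, 4.1, 1.0))
    kept <- qualityFilter(tab)
    expect_setequal(kept$id, c("m1", "m2", "m4"))
    excl <- attr(kept, "excluded")
    expect_equal(excl$reason[excl$id == "m5"], "missing quality metadata")
    expect_equal(excl$reason[excl$id == "m3"], "below quality thresholds")
    ## GenomeRecord input path
    recs <- list(genomeRecord("a", completeness = 90, contamination = 1),
                 genomeRecord("b", completeness = 60, contamination = 1))
    expect_length(qualityFilter(recs), 1)
})

test_that("dereplication keeps the best-scoring genome per ANI cluster", {
    g <- randomGenome(30000, seed = 109)
    hi <- genomeRecord("hi", g, completeness = 90, contamination = 0)
    lo <- genomeRecord("lo", g, completeness = 80, contamination = 0)
    d <- dereplicate(list(hi, lo))
    expect_length(d$representatives, 1)
    expect_equal(d$representatives[[1]]@id, "hi")
    ## undefined pairwise ANI: all retained as singletons
    recs <- lapply(1:3, function(i)
        genomeRecord(paste0("g", i), completeness = 80, contamination = 0))
    m <- matrix(NA_real_, 3, 3)
    expect_length(dereplicate(recs, ani_matrix = m)$representatives, 3)
})

test_that("dereplication clusters equal brute-force transitive closure", {
    set.seed(110)
    n <- 10
    recs <- lapply(1:n, function(i)
        genomeRecord(sprintf("g%02d", i),
                     completeness = runif(1, 70, 100),
                     contamination = runif(1, 0, 5)))
    m <- matrix(runif(n * n, 80, 100), n, n)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 100
    d <- dereplicate(recs, ani_threshold = 95, ani_matrix = m)
    ## oracle: reachability over the >= 95 adjacency graph
    adj <- m >= 95
    reach <- adj | diag(n) > 0
    for (k in 1:n)
        reach <- reach | (reach %*% (reach * 1) > 0)
    oracle_same <- function(i, j) reach[i, j]
    cl <- d$clusters
    for (i in 1:n) for (j in 1:n)
        expect_equal(unname(cl[i] == cl[j]), unname(oracle_same(i, j)),
                     info = paste(i, j))
    ## representatives: one per cluster, subset of input, argmax score
    reps <- vapply(d$representatives, function(r) r@id, character(1))
    expect_equal(length(reps), length(unique(cl)))
    for (c_ in unique(cl)) {
        members <- names(cl)[cl == c_]
        sc <- d$scores[members]
        best <- members[order(-sc, members)][1]
        expect_true(best %in% reps)
    }
})
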