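panel <- syntheticMarkerPanel(seed = 7)

test_that("every panel reference self-assigns to its own group at 100%", {
    hits <- assignGroup(findMarkers(panel@sequences, panel))
    expect_equal(nrow(hits), nrow(panel@manifest))
    expect_true(all(hits$identity == 100))
    m <- match(hits$query_id, panel@manifest$id)
    expect_equal(hits$assigned_group, panel@manifest$group[m])
})

test_that("random and shuffled proteins produce no passing marker hits", {
    set.seed(12)
    shuffles <- Biostrings::AAStringSet(vapply(1:20, function(i) {
        s <- strsplit(as.character(panel@sequences[[1]]), "")[[1]]
        paste(sample(s), collapse = "")
    }, character(1)))
    names(shuffles) <- paste0("shuf", 1:20)
    hits <- findMarkers(shuffles, panel)
    expect_equal(nrow(hits), 0)
    expect_equal(nrow(findMarkers(Biostrings::AAStringSet(), panel)), 0)
})

test_that("a diverged marker copy finds its parent reference as best hit", {
    mut <- mutateProteome(panel@sequences["bmoX_III"], 0.4, seed = 13)
    names(mut) <- "query60"
    hits <- findMarkers(mut, panel)
    expect_equal(nrow(hits), 1)
    expect_equal(hits$best_reference, "bmoX_III")
    expect_equal(hits$group, "III")
    expect_equal(hits$identity, 60, tolerance = 0.1)
})

test_that("group assignment follows the family mapping and the identity floor", {
    cand <- data.frame(query_id = c("q1", "q2", "q3", "q4"),
                       best_reference = c("bmoX_III", "prmA_V", "prmA_VI",
                                          "tmoA_I"),
                       family = c("bmoX", "prmA", "prmA", "tmoA"),
                       group = c("III", "V", "VI", "I"),
                       identity = c(85, 70, 55, 25),
                       evalue = rep(1e-30, 4), coverage = rep(95, 4))
    out <- assignGroup(cand)
    expect_equal(out$assigned_group, c("III", "V", "VI", "undefined"))
})

test_that("fragment recruitment is exact on constructed mixtures", {
    mag_seq <- randomGenome(40000, seed = 14)
    mag <- genomeRecord("mag1", mag_seq)
    self_reads <- sampleReads(mag_seq, 40, 500, seed = 15)
    expect_equal(recruitAbundance(self_reads, mag)$abundance_pct, 100)
    other <- sampleReads(randomGenome(40000, seed = 16), 60, 500, seed = 17)
    expect_equal(recruitAbundance(other, mag)$abundance_pct, 0)
    names(other) <- paste0("bg", seq_along(other))
    mix <- c(self_reads, other)
    r <- recruitAbundance(mix, mag)
    expect_equal(r$abundance_pct, 40)
    expect_equal(r$total_queries, 100L)
    ## strand invariance
    r_rc <- recruitAbundance(Biostrings::reverseComplement(mix), mag)
    expect_equal(r_rc$abundance_pct, r$abundance_pct)
    ## raising the identity threshold never recruits more
    mut_reads <- mutateGenome(self_reads, 0.03, seed = 18)
    names(mut_reads) <- names(self_reads)
    loose <- recruitAbundance(c(mut_reads, other), mag, min_identity = 90)
    strict <- recruitAbundance(c(mut_reads, other), mag, min_identity = 98)
    expect_lte(strict$recruited, loose$recruited)
    ## short queries are skipped and counted
    shorty <- Biostrings::DNAStringSet(c(s1 = randomSeq(50)))
    rs <- recruitAbundance(c(self_reads, shorty), mag)
    expect_equal(rs$skipped_short, 1L)
    expect_equal(rs$total_queries, 40L)
})

test_that("the screen report marks exactly the planted marker groups present", {
    for (s in 1:3) {
        planted_ids <- sample(panel@manifest$id, 2)
        prot <- plantMarkers(randomProteome(25, c(200, 350), seed = 20 + s),
                             panel, planted_ids, sub_rate = 0.2,
                             seed = 30 + s)
        mag <- genomeRecord(paste0("mag", s),
                            randomGenome(20000, seed = 40 + s), prot)
        row <- screenReport(list(mag), panel)
        want <- panel@manifest$group[match(planted_ids, panel@manifest$id)]
        pres <- startsWith(names(row), "present_")
        got <- sub("present_", "", names(row)[pres][unlist(row[pres])])
        expect_setequal(got, unique(want))
    }
})

test_that("screen report abundance columns compose recruitAbundance", {
    mag_seq <- randomGenome(30000, seed = 50)
    mag <- genomeRecord("magA", mag_seq, randomProteome(10, 250, seed = 51))
    reads <- c(sampleReads(mag_seq, 20, 500, seed = 52),
               local({
                   r <- sampleReads(randomGenome(30000, seed = 53), 30, 500,
                                    seed = 54)
                   names(r) <- paste0("x", seq_along(r)); r
               }))
    row <- screenReport(list(mag), panel, metagenomes = list(mg1 = reads))
    expect_equal(row$abundance_mg1,
                 recruitAbundance(reads, mag)$abundance_pct)
    expect_equal(row$abundance_mg1, 40)
})
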