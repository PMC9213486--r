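test_that("relative abundance normalises to 100% and rejects empty pools", {
    expect_equal(unname(relativeAbundance(c(A = 50, B = 50))), c(50, 50))
    expect_equal(unname(relativeAbundance(c(A = 27, B = 73))), c(27, 73))
    expect_equal(unname(relativeAbundance(c(A = 7))), 100)
    set.seed(1)
    x <- rpois(20, 30) + 1
    expect_equal(sum(relativeAbundance(x)), 100, tolerance = 1e-9)
    expect_error(relativeAbundance(c(A = 0, B = 0)), "undefined pool")
    expect_error(relativeAbundance(c(A = -1, B = 2)), "non-negative")
})

quad <- function(h13, l13, h12, l12, taxon = "t")
    data.frame(taxon = taxon, heavy_13C = h13, light_13C = l13,
               heavy_12C = h12, light_12C = l12)

test_that("the three labelling criteria evaluate as printed", {
    r <- classifyLabelled(quad(2.0, 0.5, 0.8, 0.9))
    expect_true(r$c1 && r$c2 && r$c3 && r$labelled)
    r <- classifyLabelled(quad(0.9, 0.1, 0.1, 0.1))
    expect_false(r$c1)
    expect_false(r$labelled)
    ## criterion 1 is strict: exactly 1.0% fails
    r <- classifyLabelled(quad(1.0, 0.5, 0.0, 0.0))
    expect_false(r$c1)
    expect_false(r$labelled)
    ## criterion 2 failure
    r <- classifyLabelled(quad(5.0, 6.0, 0.0, 0.0))
    expect_true(r$c1)
    expect_false(r$c2)
    expect_false(r$labelled)
    ## criterion 3 is strict on the difference of differences
    r <- classifyLabelled(quad(5.0, 2.0, 4.0, 1.0))   # 3 > 3 is false
    expect_false(r$c3)
})

test_that("missing abundances make a taxon uncallable, never labelled", {
    r <- classifyLabelled(quad(5.0, NA, 0.1, 0.1))
    expect_false(r$callable)
    expect_false(r$labelled)
})

test_that("raising the heavy-abundance threshold never adds labelled taxa", {
    set.seed(42)
    qs <- data.frame(taxon = paste0("t", 1:200),
                     heavy_13C = runif(200, 0, 8),
                     light_13C = runif(200, 0, 8),
                     heavy_12C = runif(200, 0, 8),
                     light_12C = runif(200, 0, 8))
    prev <- NULL
    for (thr in c(0.5, 1, 2, 4)) {
        lab <- qs$taxon[classifyLabelled(qs, thr)$labelled]
        if (!is.null(prev))
            expect_true(all(lab %in% prev))
        prev <- lab
    }
})

test_that("an exact 12C copy of the 13C profile fails criterion 3 everywhere", {
    set.seed(9)
    h <- runif(50, 0, 10); l <- runif(50, 0, 10)
    qs <- data.frame(taxon = paste0("t", 1:50), heavy_13C = h,
                     light_13C = l, heavy_12C = h, light_12C = l)
    r <- classifyLabelled(qs)
    expect_false(any(r$c3))
    expect_false(any(r$labelled))
})

test_that("recovery metrics match an exhaustive confusion-matrix oracle", {
    expect_equal(evaluateRecovery(
        data.frame(taxon = c("a", "b"), labelled = c(TRUE, FALSE)),
        truth = "a")[c("sensitivity", "specificity")],
        list(sensitivity = 1, specificity = 1))
    ## no taxa called
    r <- evaluateRecovery(
        data.frame(taxon = c("a", "b"), labelled = FALSE), truth = "a")
    expect_equal(r$sensitivity, 0)
    expect_equal(r$specificity, 1)
    set.seed(5)
    for (k in 1:10) {
        taxa <- paste0("t", 1:12)
        called <- sample(taxa, sample(0:12, 1))
        truth <- sample(taxa, sample(1:12, 1))
        r <- evaluateRecovery(
            data.frame(taxon = taxa, labelled = taxa %in% called), truth)
        o <- bruteConfusion(taxa, called, truth)
        expect_equal(c(tp = r$tp, fp = r$fp, tn = r$tn, fn = r$fn), o)
    }
    expect_error(evaluateRecovery(
        data.frame(taxon = "a", labelled = TRUE), truth = "zz"), "disjoint")
})

test_that("consumers at zero atom excess are labelled only at the null rate", {
    ## nobody incorporates label: the designated "consumers" must be
    ## indistinguishable from the stochastic null of the other taxa
    cons_lab <- cons_n <- null_lab <- null_n <- 0
    for (s in 1:8) {
        cm <- simulateCommunity(seed = s, atom_excess = 0)
        ds <- simulateExperiment(cm, sipDesign(depth = 2e4, seed = s))
        calls <- callLabelledTaxa(ds, "ethane")
        consumers <- cm$id[nzchar(cm$consumes)]
        is_cons <- calls$taxon %in% consumers
        cons_lab <- cons_lab + sum(calls$labelled[is_cons])
        cons_n <- cons_n + sum(is_cons)
        null_lab <- null_lab + sum(calls$labelled[!is_cons])
        null_n <- null_n + sum(!is_cons)
    }
    expect_lte(cons_lab / cons_n, null_lab / null_n + 0.25)
})

test_that("replicate handling supports averaging and per-replicate AND", {
    cm <- simulateCommunity(seed = 2)
    ds <- simulateExperiment(cm, sipDesign(depth = 2e4, seed = 2))
    avg <- callLabelledTaxa(ds, "propane", replicate_rule = "average")
    all_ <- callLabelledTaxa(ds, "propane", replicate_rule = "all")
    ## the AND rule can only be more conservative
    expect_true(all(all_$taxon[all_$labelled] %in% avg$taxon[avg$labelled]))
})
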