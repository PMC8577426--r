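# Thresholding, gene scores, RALs, significance and task scores.

# two-reaction model whose reactions share one gene, for hand-computed
# significance examples
sharedGeneModel <- function() {
    makeMetabolicModel(
        data.frame(id = c("A_c", "B_c", "C_c"), compartment = "c"),
        list(list(id = "R1", metabolites = list(A_c = -1, B_c = 1),
                  lower_bound = 0, upper_bound = 10,
                  gene_reaction_rule = "g"),
             list(id = "R2", metabolites = list(B_c = -1, C_c = 1),
                  lower_bound = 0, upper_bound = 10,
                  gene_reaction_rule = "g")))
}

setsFor <- function(taskId, rxns, genes)
    TaskEssentialSets(list(new("TaskEssentialSet", taskId = taskId,
                               feasible = TRUE, reactions = rxns,
                               genes = genes,
                               fluxes = stats::setNames(rep(1, length(rxns)),
                                                        rxns))))

test_that("local thresholds clamp gene means into the percentile bounds", {
    # 8 genes, means spanning 1..5000; constant across 2 samples
    means <- c(1, 2, 5, 10, 50, 100, 1000, 5000)
    expr <- cbind(means, means)
    rownames(expr) <- paste0("g", seq_along(means))
    th <- computeThresholds(expr, mode = "local", lowerPct = 25,
                            upperPct = 75)
    lo <- stats::quantile(means, 0.25, names = FALSE)
    hi <- stats::quantile(means, 0.75, names = FALSE)
    expect_equal(unname(th), pmin(pmax(means, lo), hi))
    # interior gene keeps its own mean; extremes are clamped (boundary
    # inclusive)
    expect_equal(th[["g4"]], 10)
    expect_equal(th[["g1"]], lo)
    expect_equal(th[["g8"]], hi)
    # defaults are the 25th and 75th percentiles
    expect_equal(formals(computeThresholds)$lowerPct, 25)
    expect_equal(formals(computeThresholds)$upperPct, 75)
})

test_that("global mode gives one threshold; degenerate inputs are handled", {
    expr <- cbind(c(1, 10, 100), c(3, 10, 100))
    rownames(expr) <- c("a", "b", "c")
    th <- computeThresholds(expr, mode = "global", globalPct = 50)
    expect_length(unique(th), 1L)
    expect_equal(unname(th[1]), 10)
    # single sample: local falls back to global with a warning
    expect_warning(th1 <- computeThresholds(expr[, 1, drop = FALSE],
                                            mode = "local"), "falling back")
    expect_length(unique(th1), 1L)
    expect_error(computeThresholds(matrix(numeric(), 0, 0)), "empty")
    expect_error(computeThresholds(expr, lowerPct = 80, upperPct = 20),
                 "lowerPct")
    # all-zero gene row: threshold still positive, score will be zero
    expr0 <- rbind(expr, z = c(0, 0))
    th0 <- computeThresholds(expr0)
    expect_true(all(th0 > 0))
})

test_that("gene score is 5*log(1 + expression/threshold)", {
    th <- c(g = 7)
    expect_equal(geneActivityScores(matrix(7, 1, 1, dimnames = list("g", "s")),
                                    th)[1, 1], 5 * log(2))
    expect_equal(geneActivityScores(matrix(0, 1, 1, dimnames = list("g", "s")),
                                    th)[1, 1], 0)
    expect_equal(geneActivityScores(matrix(21, 1, 1, dimnames = list("g", "s")),
                                    th)[1, 1], 5 * log(4))
    expect_error(geneActivityScores(matrix(-1, 1, 1,
                                           dimnames = list("g", "s")), th),
                 "non-negative")
})

test_that("reaction activity propagates isozyme max and flags undefined GPRs", {
    m <- chainModel(gprA = "A or B", gprB = "G2")
    sets <- setsFor("t", c("RAB", "RBC"), c("A", "B", "G2"))
    scores <- matrix(c(2, 5, 1), 3, 1, dimnames = list(c("A", "B", "G2"), "s1"))
    act <- reactionActivity(scores, sets, m)
    expect_equal(act@ral["RAB", "s1"], 5)
    expect_equal(act@determinant["RAB", "s1"], "B")
    # all genes unmeasured -> undefined, not zero
    scores2 <- matrix(1, 1, 1, dimnames = list("ZZZ", "s1"))
    act2 <- reactionActivity(scores2, sets, m)
    expect_false(act2@defined["RAB", "s1"])
    expect_true(is.na(act2@ral["RAB", "s1"]))
})

test_that("reactions shared by tasks are evaluated once (deduplicated)", {
    m <- chainModel(gprA = "A", gprB = "B")
    sets <- TaskEssentialSets(list(
        new("TaskEssentialSet", taskId = "t1", feasible = TRUE,
            reactions = c("RAB", "RBC"), genes = c("A", "B"),
            fluxes = c(RAB = 1, RBC = 1)),
        new("TaskEssentialSet", taskId = "t2", feasible = TRUE,
            reactions = "RAB", genes = "A", fluxes = c(RAB = 1))))
    scores <- matrix(c(3, 4), 2, 1, dimnames = list(c("A", "B"), "s1"))
    act <- reactionActivity(scores, sets, m)
    expect_equal(nrow(act@ral), 2L)  # RAB appears once
    expect_setequal(rownames(act@ral), c("RAB", "RBC"))
})

test_that("gene significance is the reciprocal determinant count, per sample", {
    m <- sharedGeneModel()
    sets <- setsFor("t", c("R1", "R2"), "g")
    scores <- matrix(2, 1, 1, dimnames = list("g", "s1"))
    act <- reactionActivity(scores, sets, m)
    S <- geneSignificance(act, "s1")
    expect_equal(S[["g"]], 0.5)  # determinant of both reactions

    # a gene determinant for exactly one reaction has S = 1; 4 reactions -> 1/4
    m4 <- makeMetabolicModel(
        data.frame(id = c("A_c", "B_c"), compartment = "c"),
        lapply(1:4, function(i)
            list(id = paste0("R", i), metabolites = list(A_c = -1, B_c = 1),
                 lower_bound = 0, upper_bound = 10,
                 gene_reaction_rule = "h")))
    sets4 <- setsFor("t", paste0("R", 1:4), "h")
    act4 <- reactionActivity(matrix(1, 1, 1, dimnames = list("h", "s1")),
                             sets4, m4)
    expect_equal(geneSignificance(act4, "s1")[["h"]], 0.25)

    # determinants can differ between samples, so S is per-sample
    mAB <- chainModel(gprA = "A or B", gprB = "A or B")
    setsAB <- setsFor("t", c("RAB", "RBC"), c("A", "B"))
    sc <- matrix(c(5, 1, 1, 5), 2, 2,
                 dimnames = list(c("A", "B"), c("s1", "s2")))
    actAB <- reactionActivity(sc, setsAB, mAB)
    expect_equal(geneSignificance(actAB, "s1"),
                 c(A = 0.5))
    expect_equal(geneSignificance(actAB, "s2"),
                 c(B = 0.5))
})

test_that("task scores reproduce the hand-computed formula values", {
    # 1-reaction task, RAL 4, unique determinant (S = 1) -> score 4, active
    m1 <- chainModel(gprA = "u", gprB = "v")
    sets1 <- setsFor("t", "RAB", "u")
    act1 <- reactionActivity(matrix(4, 1, 1, dimnames = list("u", "s1")),
                             sets1, m1)
    res1 <- metabolicTaskScores(act1, sets1)
    expect_equal(mtScores(res1)["t", "s1"], 4)
    expect_true(binaryActivity(res1)["t", "s1"])  # 4 > 5*log(2)
    expect_equal(combinedScores(res1)["t", "s1"], 4)

    # 2-reaction task, both determined by the same gene (S = 1/2),
    # RALs (4, 4) -> score (4*0.5 + 4*0.5)/2 = 2; mean RAL 4 -> active
    m2 <- sharedGeneModel()
    sets2 <- setsFor("t", c("R1", "R2"), "g")
    # gene score 4 <=> expression = threshold * (e^{4/5} - 1)
    act2 <- reactionActivity(matrix(4, 1, 1, dimnames = list("g", "s1")),
                             sets2, m2)
    res2 <- metabolicTaskScores(act2, sets2)
    expect_equal(mtScores(res2)["t", "s1"], 2)
    expect_true(binaryActivity(res2)["t", "s1"])
    expect_equal(taskCoverage(res2)["t", "s1"], 1)
})

test_that("a sample with every determinant exactly at threshold is inactive", {
    m <- sharedGeneModel()
    sets <- setsFor("t", c("R1", "R2"), "g")
    atThreshold <- 5 * log(2)  # score of a gene expressed at its threshold
    act <- reactionActivity(matrix(atThreshold, 1, 1,
                                   dimnames = list("g", "s1")), sets, m)
    res <- metabolicTaskScores(act, sets)
    expect_false(binaryActivity(res)["t", "s1"])  # strict inequality
    expect_equal(combinedScores(res)["t", "s1"], 0)
})

test_that("undefined reactions are excluded with coverage reporting", {
    # RBC has no GPR -> undefined RAL everywhere
    m <- chainModel(gprA = "A", gprB = "")
    sets <- setsFor("t", c("RAB", "RBC"), "A")
    scores <- matrix(4, 1, 1, dimnames = list("A", "s1"))
    suppressMessages(act <- reactionActivity(scores, sets, m))
    res <- metabolicTaskScores(act, sets)
    expect_equal(taskCoverage(res)["t", "s1"], 0.5)
    expect_equal(mtScores(res)["t", "s1"], 4)  # defined-only denominator
    # literal denominator divides by all task reactions
    resAll <- metabolicTaskScores(act, sets, denominator = "all")
    expect_equal(mtScores(resAll)["t", "s1"], 2)
    # minimum-coverage gating yields undefined markers
    resCov <- metabolicTaskScores(act, sets, minCoverage = 0.9)
    expect_true(is.na(mtScores(resCov)["t", "s1"]))
})

test_that("the whole pipeline is invariant to rescaling the expression matrix", {
    fx <- makeToyModel(nPathways = 3, pathwayLength = 2,
                       gprComplexity = "isozyme")
    gm <- buildTaskGeneMap(fx$model, fx$tasks)
    ex <- makeExpression(fx$model, fx$tasks, gm$sets, nSamples = 10, seed = 5)
    ref <- scoreTasks(ex$expr, gm$sets, fx$model)
    for (c in c(0.1, 7, 1000)) {
        res <- scoreTasks(ex$expr * c, gm$sets, fx$model)
        expect_equal(mtScores(res), mtScores(ref), tolerance = 1e-12)
        expect_identical(binaryActivity(res), binaryActivity(ref))
    }
})

test_that("scores are bounded by 5*log(1+k) when expression is capped at k*threshold", {
    set.seed(3)
    k <- 6
    m <- chainModel(gprA = "A or B", gprB = "(A and C) or B")
    sets <- setsFor("t", c("RAB", "RBC"), c("A", "B", "C"))
    expr <- matrix(stats::runif(3 * 20, 0, 50), 3, 20,
                   dimnames = list(c("A", "B", "C"), paste0("s", 1:20)))
    th <- computeThresholds(expr)
    expr <- pmin(expr, k * matrix(th, 3, 20))
    gs <- geneActivityScores(expr, th)
    act <- reactionActivity(gs, sets, m)
    res <- metabolicTaskScores(act, sets)
    expect_true(all(mtScores(res) <= 5 * log(1 + k) + 1e-12))
})

test_that("increasing one gene's expression never decreases any RAL", {
    set.seed(9)
    fx <- makeToyModel(nPathways = 2, pathwayLength = 2,
                       gprComplexity = "nested")
    gm <- buildTaskGeneMap(fx$model, fx$tasks)
    ex <- makeExpression(fx$model, fx$tasks, gm$sets, nSamples = 4, seed = 2)
    th <- computeThresholds(ex$expr)
    gs <- geneActivityScores(ex$expr, th)
    act0 <- reactionActivity(gs, gm$sets, fx$model)
    for (i in 1:10) {
        g <- sample(rownames(ex$expr), 1)
        gs2 <- gs
        gs2[g, ] <- gs2[g, ] + stats::runif(1, 0, 3)
        act1 <- reactionActivity(gs2, gm$sets, fx$model)
        expect_true(all(act1@ral >= act0@ral - 1e-12, na.rm = TRUE))
    }
})

test_that("expression matrices round-trip through the TSV reader", {
    p <- withr::local_tempfile(fileext = ".tsv")
    m <- matrix(c(1.5, 0, 3, 4), 2, 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
    utils::write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
                       p, sep = "\t", row.names = FALSE, quote = FALSE)
    expect_equal(readExpression(p), m)
})
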