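# Permutation similarity test, binary-combination clustering, trait
# enrichment and patient aggregation.

test_that("a pool of identical profiles gives empirical p = 0 under strict counting", {
    m <- matrix(1, 5, 6, dimnames = list(paste0("t", 1:5), paste0("e", 1:6)))
    groups <- stats::setNames(rep(c("g1", "g2"), each = 3), colnames(m))
    res <- groupSimilarityTest(m, groups, nRandom = 50, seed = 1)
    expect_equal(res$observed, c(0, 0))
    # all random distances are 0 too; none is strictly lower
    expect_equal(res$empirical_p, c(0, 0))
})

test_that("a planted tight group is significantly more similar than random groups", {
    m <- plantedScoreMatrix()
    groups <- stats::setNames(c(rep("tight", 3), rep("noise", 12)),
                              colnames(m))
    res <- groupSimilarityTest(m, groups, nRandom = 2000, seed = 7)
    p <- res$empirical_p[res$group == "tight"]
    expect_lt(p, 0.01)
    # empirical p is exactly the strictly-lower proportion of the null
    nd <- attr(res, "null")[["tight"]]
    obs <- res$observed[res$group == "tight"]
    expect_equal(p, sum(nd < obs) / length(nd))
    # noise group should not look coherent
    expect_gt(res$empirical_p[res$group == "noise"], 0.05)
})

test_that("the test only considers groups with more than two members", {
    m <- plantedScoreMatrix()
    groups <- stats::setNames(c("a", "a", "b", rep("c", 12)), colnames(m))
    res <- groupSimilarityTest(m, groups, nRandom = 10, seed = 1)
    expect_setequal(res$group, "c")  # a (n=2) and b (n=1) skipped
    expect_error(groupSimilarityTest(m,
        stats::setNames(rep("x", 2), colnames(m)[1:2]), nRandom = 5),
        "no group")
})

test_that("empirical p is invariant to relabeling non-group entities", {
    m <- plantedScoreMatrix()
    g1 <- stats::setNames(c(rep("tight", 3), rep("noise", 12)), colnames(m))
    g2 <- stats::setNames(c(rep("tight", 3), rep(c("nA", "nB"), 6)),
                          colnames(m))
    p1 <- groupSimilarityTest(m, g1, nRandom = 500, seed = 3)
    p2 <- groupSimilarityTest(m, g2, nRandom = 500, seed = 3)
    expect_equal(p1$empirical_p[p1$group == "tight"],
                 p2$empirical_p[p2$group == "tight"])
})

test_that("doubling the permutation count converges (Monte-Carlo stability)", {
    m <- plantedScoreMatrix(nTight = 4, nNoise = 11, seed = 17)
    groups <- stats::setNames(c(rep("g", 4), rep("h", 11)), colnames(m))
    pA <- groupSimilarityTest(m, groups, nRandom = 1000,
                              seed = 1)$empirical_p[1]
    pB <- groupSimilarityTest(m, groups, nRandom = 2000,
                              seed = 2)$empirical_p[1]
    expect_lt(abs(pA - pB), 0.05)
})

test_that("majority-active selection uses a strict fraction cutoff", {
    b <- rbind(t51 = c(rep(1, 51), rep(0, 49)),
               t50 = c(rep(1, 50), rep(0, 50)),
               t00 = rep(0, 100))
    expect_equal(selectMajorityActiveTasks(b), "t51")
    expect_length(selectMajorityActiveTasks(b * 0), 0L)
})

test_that("binary-combination clustering partitions samples by signature", {
    # 3 tasks, samples covering all 8 signatures -> 8 clusters
    sig <- t(expand.grid(0:1, 0:1, 0:1))
    b <- sig[, rep(1:8, each = 2)]
    rownames(b) <- paste0("task", 1:3)
    colnames(b) <- paste0("s", 1:16)
    cl <- binaryCombinationClusters(b)
    expect_equal(nrow(clusterSignatures(cl)), 8L)
    expect_equal(cl@universeSize, 8)
    # partition: disjoint members covering all samples
    members <- lapply(rownames(clusterSignatures(cl)),
                      function(l) clusterMembers(cl, l))
    expect_equal(sort(unlist(members)), sort(colnames(b)))
    expect_equal(sum(lengths(members)), ncol(b))
    # one task -> at most 2 clusters; identical signatures -> 1 cluster
    cl1 <- binaryCombinationClusters(b[1, , drop = FALSE])
    expect_lte(nrow(clusterSignatures(cl1)), 2L)
    clSame <- binaryCombinationClusters(matrix(1, 2, 5))
    expect_equal(nrow(clusterSignatures(clSame)), 1L)
    expect_length(clusterMembers(clSame, "M1"), 5L)
})

test_that("cluster labels follow canonical signature order deterministically", {
    b <- rbind(a = c(1, 0, 1), b = c(1, 0, 0))
    colnames(b) <- paste0("s", 1:3)
    cl <- binaryCombinationClusters(b)
    # signatures "11", "10", "00" in canonical (descending) order
    expect_equal(unname(clusterAssignments(cl)),
                 c("M1", "M3", "M2"))
})

test_that("random binary matrices always yield a valid partition", {
    set.seed(23)
    for (i in 1:20) {
        k <- sample(1:4, 1); n <- sample(3:30, 1)
        b <- matrix(stats::rbinom(k * n, 1, 0.5), k, n,
                    dimnames = list(paste0("t", 1:k), paste0("s", 1:n)))
        cl <- binaryCombinationClusters(b)
        expect_lte(nrow(clusterSignatures(cl)), 2^k)
        asg <- clusterAssignments(cl)
        expect_setequal(names(asg), colnames(b))
        # samples in one cluster share the exact signature
        for (l in unique(asg)) {
            cols <- b[, names(asg)[asg == l], drop = FALSE]
            expect_equal(max(apply(cols, 1, function(x) length(unique(x)))), 1L)
        }
    }
})

test_that("one-tailed Fisher p matches the hypergeometric-sum oracle exhaustively", {
    # every 2x2 table with all margins <= 30
    g <- expand.grid(a = 0:30, b = 0:30, c = 0:30, d = 0:30)
    g <- g[g$a + g$b <= 30 & g$c + g$d <= 30 &
           g$a + g$c <= 30 & g$b + g$d <= 30 &
           g$a + g$b + g$c + g$d > 0, ]
    ours <- stats::phyper(g$a - 1, g$a + g$c, g$b + g$d, g$a + g$b,
                          lower.tail = FALSE)
    # vectorised direct summation of the hypergeometric pmf
    oracle <- numeric(nrow(g))
    N <- g$a + g$b + g$c + g$d; K <- g$a + g$c; n <- g$a + g$b
    for (k in 0:30) {
        term <- exp(lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n))
        term[k < g$a | k > pmin(K, n)] <- 0
        term[is.na(term)] <- 0
        oracle <- oracle + term
    }
    expect_lt(max(abs(ours - oracle)), 1e-10)
})

test_that("cluster trait enrichment builds the right tables and tails", {
    # 4 in-cluster of which 1 with trait; 12 outside of which 11 with trait
    asg <- stats::setNames(c(rep("M1", 10), rep("M2", 14)),
                           paste0("s", 1:24))
    sigs <- matrix(c(TRUE, FALSE), 2, 1,
                   dimnames = list(c("M1", "M2"), "task"))
    cl <- new("MetabolicClusters", signatures = sigs, assignment = asg,
              universeSize = 2)
    trait <- stats::setNames(c(rep("yes", 1), rep("no", 9),
                               rep("yes", 11), rep("no", 3)),
                             names(asg))
    resOver <- clusterTraitEnrichment(cl, trait)
    row <- resOver[resOver$cluster == "M1" & resOver$level == "yes", ]
    expect_equal(unlist(row[c("a", "b", "c", "d")]),
                 c(a = 1, b = 9, c = 11, d = 3))
    # depletion of the trait in M1: the under tail reproduces the direct
    # hypergeometric value 0.00138
    resUnder <- clusterTraitEnrichment(cl, trait, alternative = "under")
    rowU <- resUnder[resUnder$cluster == "M1" & resUnder$level == "yes", ]
    expect_equal(rowU$p_value, 0.001379728, tolerance = 1e-6)
    # both tails agree with fisher.test on this table
    expect_equal(row$p_value,
                 stats::fisher.test(matrix(c(1, 9, 11, 3), 2, byrow = TRUE),
                                    alternative = "greater")$p.value,
                 tolerance = 1e-12)
    expect_equal(rowU$p_value,
                 stats::fisher.test(matrix(c(1, 9, 11, 3), 2, byrow = TRUE),
                                    alternative = "less")$p.value,
                 tolerance = 1e-12)
})

test_that("degenerate enrichment inputs: all-sample cluster and single-level trait", {
    asg <- stats::setNames(rep("M1", 8), paste0("s", 1:8))
    sigs <- matrix(TRUE, 1, 1, dimnames = list("M1", "task"))
    cl <- new("MetabolicClusters", signatures = sigs, assignment = asg,
              universeSize = 2)
    trait <- stats::setNames(rep(c("x", "y"), 4), names(asg))
    res <- clusterTraitEnrichment(cl, trait)
    expect_true(all(res$p_value == 1))  # no contrast possible
    expect_warning(res1 <- clusterTraitEnrichment(cl,
        stats::setNames(rep("x", 8), names(asg))), "single level")
    expect_equal(nrow(res1), 0L)
})

test_that("patient ranking by target-cluster proportion and prevalence accuracy", {
    asg <- stats::setNames(c(rep("M3", 4), rep("M1", 4),   # p1: 4/8 in target
                             rep("M3", 9), "M1",           # p2: 0.9
                             "M3", rep("M1", 9)),          # p3: 0.1
                           paste0("s", 1:28))
    sigs <- matrix(c(TRUE, FALSE), 2, 1,
                   dimnames = list(c("M3", "M1"), "task"))
    cl <- new("MetabolicClusters", signatures = sigs, assignment = asg,
              universeSize = 2)
    s2p <- stats::setNames(c(rep("p1", 8), rep("p2", 10), rep("p3", 10)),
                           names(asg))
    res <- patientClusterProportions(cl, s2p, "M3")
    expect_equal(res$proportion[res$patient == "p1"], 0.5)
    expect_equal(res$patient[1], "p2")  # highest proportion ranks first

    res2 <- patientClusterProportions(cl, s2p, "M3",
        labels = c(p1 = TRUE, p2 = TRUE, p3 = FALSE))
    expect_equal(attr(res2, "accuracy"), 1.0)
})

test_that("a planted cluster-label association yields above-chance accuracy", {
    set.seed(31)
    nPat <- 20; perPat <- 6
    lab <- rep(c(TRUE, FALSE), each = nPat / 2)
    names(lab) <- paste0("p", seq_len(nPat))
    samples <- paste0("smp", seq_len(nPat * perPat))
    s2p <- stats::setNames(rep(names(lab), each = perPat), samples)
    pTarget <- ifelse(lab[s2p], 0.7, 0.3)
    asg <- stats::setNames(ifelse(stats::runif(length(samples)) < pTarget,
                                  "M3", "M1"), samples)
    sigs <- matrix(c(TRUE, FALSE), 2, 1,
                   dimnames = list(c("M3", "M1"), "task"))
    cl <- new("MetabolicClusters", signatures = sigs, assignment = asg,
              universeSize = 2)
    res <- patientClusterProportions(cl, s2p, "M3", labels = lab)
    expect_gt(attr(res, "accuracy"), 0.5)
})

test_that("cluster medians of combined scores follow the member samples", {
    asg <- stats::setNames(c("M1", "M1", "M1", "M2", "M2", "M2"),
                           paste0("s", 1:6))
    sigs <- matrix(c(TRUE, FALSE), 2, 1,
                   dimnames = list(c("M1", "M2"), "task"))
    cl <- new("MetabolicClusters", signatures = sigs, assignment = asg,
              universeSize = 2)
    combined <- rbind(tA = c(0, 0, 5, 2, 4, 6),
                      tB = rep(0, 6))
    colnames(combined) <- names(asg)
    med <- clusterMedianScores(cl, combined)
    expect_equal(med["tA", "M1"], 0)   # (0, 0, 5) -> 0
    expect_equal(med["tA", "M2"], 4)   # (2, 4, 6) -> 4
    expect_equal(attr(med, "nonzero"), "tA")  # all-zero task excluded
})
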