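# Independent oracles and small builders shared by unit and acceptance
# tests.  Everything here is deliberately naive (brute force, exhaustive
# enumeration, direct summation) and independent of the package's code
# paths.

# ---- GPR ---------------------------------------------------------------

# brute-force min/max evaluation of a rule tree: no determinant logic, no
# shortcuts; unmeasured genes dropped, all-missing nodes dropped
bruteGPRValue <- function(node, scores) {
    if (node$op == "leaf") {
        if (!(node$gene %in% names(scores)) || is.na(scores[[node$gene]]))
            return(NA_real_)
        return(unname(scores[[node$gene]]))
    }
    vals <- vapply(node$children, bruteGPRValue, numeric(1), scores = scores)
    vals <- vals[!is.na(vals)]
    if (!length(vals)) return(NA_real_)
    if (node$op == "and") min(vals) else max(vals)
}

# random rule tree with <= maxLeaves leaves over the given gene alphabet
randomGPRTree <- function(maxLeaves = 8, genes = LETTERS[1:10]) {
    nLeaves <- sample(seq_len(maxLeaves), 1)
    build <- function(n) {
        if (n == 1) return(list(op = "leaf", gene = sample(genes, 1)))
        k <- sample(seq_len(n - 1), 1)
        op <- sample(c("and", "or"), 1)
        left <- build(k); right <- build(n - k)
        # flatten like the parser does, so format/parse round-trips
        kids <- list()
        for (ch in list(left, right))
            if (ch$op == op) kids <- c(kids, ch$children)
            else kids <- c(kids, list(ch))
        list(op = op, children = kids)
    }
    new("GPRRule", tree = build(nLeaves))
}

# ---- Fisher / hypergeometric ------------------------------------------

# over-representation tail by direct summation of the hypergeometric pmf
hyperTailOracle <- function(a, b, c, d) {
    N <- a + b + c + d; K <- a + c; n <- a + b
    kmax <- min(K, n)
    if (a > kmax) return(0)
    ks <- a:kmax
    sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# ---- pFBA subset minimality -------------------------------------------

# copy of a model with every internal reaction outside `keep` closed
restrictModel <- function(model, keep) {
    r <- reactions(model)
    exch <- Matrix::colSums(stoichiometry(model) != 0) == 1
    closed <- !exch & !(r$id %in% keep)
    r$lower_bound[closed] <- 0
    r$upper_bound[closed] <- 0
    m <- model
    m@reactions <- r
    m
}

internalReactionIds <- function(model) {
    exch <- Matrix::colSums(stoichiometry(model) != 0) == 1
    reactions(model)$id[!exch]
}

feasibleWithSubset <- function(model, task, keep)
    checkTaskFeasibility(restrictModel(model, keep), task)$feasible

# exhaustive search: is any feasible internal-reaction subset strictly
# smaller than `size`?  (feasibility is monotone in the reaction set)
smallestFeasibleSubsetAtMost <- function(model, task, size) {
    rxns <- internalReactionIds(model)
    for (k in seq_len(size)) {
        combs <- utils::combn(rxns, k, simplify = FALSE)
        for (s in combs)
            if (feasibleWithSubset(model, task, s)) return(k)
    }
    Inf
}

# support is subset-minimal iff it is feasible and removing any one
# reaction breaks the task (monotonicity makes this equivalent to full
# subset enumeration over subsets of the support)
expectSubsetMinimal <- function(model, task, support) {
    expect_true(feasibleWithSubset(model, task, support))
    for (r in support)
        expect_false(feasibleWithSubset(model, task, setdiff(support, r)))
}

# ---- misc --------------------------------------------------------------

# score matrix with a tight planted group among noisy entities
plantedScoreMatrix <- function(nTight = 3, nNoise = 12, nTasks = 20,
                               seed = 101) {
    set.seed(seed)
    base <- stats::rnorm(nTasks, 5, 1)
    tight <- vapply(seq_len(nTight), function(i)
        base + stats::rnorm(nTasks, 0, 0.05), numeric(nTasks))
    noise <- matrix(stats::rnorm(nTasks * nNoise, 5, 2), nTasks, nNoise)
    m <- cbind(tight, noise)
    dimnames(m) <- list(paste0("task", seq_len(nTasks)),
                        c(paste0("t", seq_len(nTight)),
                          paste0("n", seq_len(nNoise))))
    m
}

# tiny hand-built model: linear chain A -> B -> C with endpoint exchanges
chainModel <- function(gprA = "G1", gprB = "G2") {
    makeMetabolicModel(
        data.frame(id = c("A_c", "B_c", "C_c"), compartment = "c"),
        list(list(id = "RAB", metabolites = list(A_c = -1, B_c = 1),
                  lower_bound = 0, upper_bound = 1000,
                  gene_reaction_rule = gprA),
             list(id = "RBC", metabolites = list(B_c = -1, C_c = 1),
                  lower_bound = 0, upper_bound = 1000,
                  gene_reaction_rule = gprB),
             list(id = "EX_A", metabolites = list(A_c = -1),
                  lower_bound = -1000, upper_bound = 1000),
             list(id = "EX_C", metabolites = list(C_c = -1),
                  lower_bound = -1000, upper_bound = 1000)))
}

chainTask <- function(id = "chain", outMet = "C", outLb = 1) {
    makeTaskDefinition(id,
        inputs = data.frame(metabolite = "A", compartment = "c",
                            lb = 0, ub = 10),
        outputs = data.frame(metabolite = outMet, compartment = "c",
                             lb = outLb, ub = 1000))
}
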