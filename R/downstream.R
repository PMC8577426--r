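# Downstream statistics over task-score matrices: permutation similarity
# test, binary-combination clustering, trait enrichment, patient-level
# aggregation.

meanPairwiseDistance <- function(m, cols, measure = "pairwise") {
    x <- t(m[, cols, drop = FALSE])
    if (measure == "centroid") {
        ctr <- colMeans(x)
        return(mean(sqrt(rowSums(sweep(x, 2, ctr)^2))))
    }
    mean(stats::dist(x))
}

#' Permutation test for within-group similarity of task-score profiles
#'
#' For each group with at least \code{minGroupSize} members, the observed
#' statistic is the mean Euclidean distance between the task-score profiles
#' of its members (mean over all unordered pairs).  The null distribution is
#' the same statistic for \code{nRandom} uniformly random same-size subsets
#' of the pool of all entities belonging to a considered group.  The
#' empirical p value is the proportion of random distances strictly lower
#' than the observed distance (no +1 correction; a conservative
#' \code{(r + 1) / (n + 1)} variant is available).
#'
#' @param scores task-by-entity numeric matrix (e.g. [mtScores()] output;
#'   binary calls may be passed for the binary variant).
#' @param groups named character vector or factor mapping entity (column)
#'   ids to group labels.
#' @param nRandom number of random groups (default 10000).
#' @param seed RNG seed for reproducibility.
#' @param minGroupSize smallest group tested (default 3, i.e. groups with
#'   more than two members).
#' @param measure \code{"pairwise"} (default) mean over unordered pairs, or
#'   \code{"centroid"} mean distance to the group centroid.
#' @param conservative add-one correction to the empirical p (default
#'   \code{FALSE}, exact proportion).
#' @return data.frame with one row per tested group (\code{group}, \code{n},
#'   \code{observed}, \code{empirical_p}); the per-group null distance
#'   vectors are in \code{attr(, "null")}.
#' @export
groupSimilarityTest <- function(scores, groups, nRandom = 10000, seed = NULL,
                                minGroupSize = 3,
                                measure = c("pairwise", "centroid"),
                                conservative = FALSE) {
    measure <- match.arg(measure)
    scores <- as.matrix(scores)
    groups <- stats::setNames(as.character(groups), names(groups))
    unknown <- setdiff(names(groups), colnames(scores))
    if (length(unknown))
        stop(sprintf("entities absent from score matrix: %s",
                     paste(utils::head(unknown, 3), collapse = ", ")),
             call. = FALSE)
    sizes <- table(groups)
    tested <- names(sizes)[sizes >= minGroupSize]
    if (length(tested) == 0)
        stop(sprintf("no group has >= %d members", minGroupSize),
             call. = FALSE)
    pool <- names(groups)[groups %in% tested]
    if (!is.null(seed)) set.seed(seed)
    nulls <- list()
    rows <- lapply(tested, function(g) {
        members <- names(groups)[groups == g]
        if (length(members) > length(pool))
            stop("group larger than entity pool", call. = FALSE)
        obs <- meanPairwiseDistance(scores, members, measure)
        nd <- vapply(seq_len(nRandom), function(i)
            meanPairwiseDistance(scores, sample(pool, length(members)),
                                 measure), numeric(1))
        nulls[[g]] <<- nd
        p <- if (conservative) (sum(nd < obs) + 1) / (nRandom + 1)
        else sum(nd < obs) / nRandom
        data.frame(group = g, n = length(members), observed = obs,
                   empirical_p = p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "null") <- nulls
    out
}

#' Tasks active in a majority of samples
#'
#' @param binary logical or 0/1 task-by-sample matrix.
#' @param fraction strict activity-proportion cutoff in (0, 1); a task is
#'   selected when its active proportion strictly exceeds it (default 0.5).
#' @return character vector of selected task ids.
#' @export
selectMajorityActiveTasks <- function(binary, fraction = 0.5) {
    stopifnot(fraction > 0, fraction < 1)
    binary <- as.matrix(binary) * 1
    prop <- rowMeans(binary, na.rm = TRUE)
    rownames(binary)[!is.na(prop) & prop > fraction]
}

#' Cluster samples by their binary task-activity combination
#'
#' Samples sharing the exact same on/off signature over the selected tasks
#' form one cluster; with \code{k} tasks there are at most \code{2^k}
#' clusters.  Labels \code{M1, M2, ...} are assigned in canonical signature
#' order (signatures read as binary strings, most-active first); unobserved
#' signatures are omitted from the output but counted in the cluster
#' universe.
#'
#' @param binary logical or 0/1 selected-task-by-sample matrix (no
#'   \code{NA}).
#' @return a [MetabolicClusters-class].
#' @export
binaryCombinationClusters <- function(binary) {
    binary <- as.matrix(binary) * 1
    if (nrow(binary) == 0) stop("no selected tasks", call. = FALSE)
    if (anyNA(binary)) stop("binary matrix contains NA", call. = FALSE)
    if (is.null(colnames(binary)))
        colnames(binary) <- paste0("S", seq_len(ncol(binary)))
    if (is.null(rownames(binary)))
        rownames(binary) <- paste0("T", seq_len(nrow(binary)))
    sigs <- apply(binary, 2, paste, collapse = "")
    uniq <- sort(unique(sigs), decreasing = TRUE)
    labels <- stats::setNames(paste0("M", seq_along(uniq)), uniq)
    sigMat <- matrix(FALSE, length(uniq), nrow(binary),
                     dimnames = list(unname(labels), rownames(binary)))
    for (i in seq_along(uniq))
        sigMat[i, ] <- strsplit(uniq[i], "")[[1]] == "1"
    new("MetabolicClusters", signatures = sigMat,
        assignment = stats::setNames(unname(labels[sigs]), colnames(binary)),
        universeSize = 2^nrow(binary))
}

#' One-tailed Fisher trait enrichment within metabolic clusters
#'
#' For every cluster and every level of every categorical trait, builds the
#' 2x2 table (in-cluster with trait, in-cluster without, out-of-cluster
#' with, out-of-cluster without) over samples with a non-missing trait value
#' and computes the one-tailed Fisher exact p (hypergeometric tail;
#' over-representation of the trait level in the cluster by default).
#'
#' @param clusters a [MetabolicClusters-class].
#' @param traits data.frame of categorical traits with sample rownames, or a
#'   named vector for a single trait.  Samples with missing values are
#'   excluded per trait, with a message.
#' @param alternative \code{"over"} (default) or \code{"under"}.
#' @return data.frame with columns \code{cluster}, \code{trait},
#'   \code{level}, the four table counts \code{a,b,c,d} and \code{p_value}.
#' @export
clusterTraitEnrichment <- function(clusters, traits,
                                   alternative = c("over", "under")) {
    alternative <- match.arg(alternative)
    assign <- clusterAssignments(clusters)
    if (!is.data.frame(traits))
        traits <- data.frame(trait = traits, check.names = FALSE,
                             row.names = names(traits))
    rows <- list()
    for (tr in names(traits)) {
        v <- stats::setNames(as.character(traits[[tr]]), rownames(traits))
        v <- v[names(assign)]
        ok <- !is.na(v)
        if (sum(!ok))
            message(sprintf("trait %s: excluding %d sample(s) with missing values",
                            tr, sum(!ok)))
        lv <- unique(v[ok])
        if (length(lv) < 2) {
            warning(sprintf("trait %s has a single level; skipped", tr),
                    call. = FALSE)
            next
        }
        for (cl in rownames(clusterSignatures(clusters))) {
            inCl <- assign[ok] == cl
            if (!any(inCl)) next
            for (level in sort(lv)) {
                hasTr <- v[ok] == level
                a <- sum(inCl & hasTr); b <- sum(inCl & !hasTr)
                cc <- sum(!inCl & hasTr); d <- sum(!inCl & !hasTr)
                # hypergeometric tail == one-tailed Fisher exact test
                p <- if (alternative == "over")
                    stats::phyper(a - 1, a + cc, b + d, a + b,
                                  lower.tail = FALSE)
                else stats::phyper(a, a + cc, b + d, a + b)
                rows[[length(rows) + 1L]] <- data.frame(
                    cluster = cl, trait = tr, level = level,
                    a = a, b = b, c = cc, d = d, p_value = p,
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(rows))
        return(data.frame(cluster = character(), trait = character(),
                          level = character(), a = integer(), b = integer(),
                          c = integer(), d = integer(), p_value = numeric()))
    do.call(rbind, rows)
}

#' Rank patients by their proportion of samples in target clusters
#'
#' Aggregates sample-level cluster membership to patients: each patient's
#' statistic is the fraction of their samples falling in the target
#' clusters, and patients are ranked in decreasing order.  Given binary
#' labels, the ranking is thresholded at the label prevalence (the top
#' \code{k} patients are called positive, \code{k} = number of positives)
#' and the resulting classification accuracy is reported.
#'
#' @param clusters a [MetabolicClusters-class].
#' @param sampleToPatient named character vector mapping every sample to a
#'   patient id.
#' @param targetClusters cluster labels counted as positive membership.
#' @param labels optional named logical (or two-level) vector per patient;
#'   the \code{TRUE}/second level is the positive class.
#' @return data.frame with columns \code{patient}, \code{n_samples},
#'   \code{proportion}, \code{rank} and, when labels are given,
#'   \code{label}, \code{predicted}; classification accuracy in
#'   \code{attr(, "accuracy")}.
#' @export
patientClusterProportions <- function(clusters, sampleToPatient,
                                      targetClusters, labels = NULL) {
    assign <- clusterAssignments(clusters)
    miss <- setdiff(names(assign), names(sampleToPatient))
    if (length(miss))
        stop(sprintf("sample(s) without patient mapping: %s",
                     paste(utils::head(miss, 3), collapse = ", ")),
             call. = FALSE)
    pat <- sampleToPatient[names(assign)]
    hits <- assign %in% targetClusters
    nSamples <- table(pat)
    prop <- tapply(hits, pat, mean)
    # deterministic ranking: ties broken by patient id
    ord <- order(-prop, names(prop))
    out <- data.frame(patient = names(prop)[ord],
                      n_samples = as.integer(nSamples[names(prop)[ord]]),
                      proportion = as.numeric(prop[ord]),
                      rank = seq_along(ord), stringsAsFactors = FALSE)
    if (!is.null(labels)) {
        lab <- labels[out$patient]
        if (anyNA(lab))
            stop("labels missing for some patients", call. = FALSE)
        if (!is.logical(lab)) {
            lev <- sort(unique(as.character(lab)))
            if (length(lev) != 2)
                stop("labels must be binary", call. = FALSE)
            lab <- as.character(lab) == lev[2]
        }
        k <- sum(lab)
        out$label <- lab
        out$predicted <- seq_len(nrow(out)) <= k
        attr(out, "accuracy") <- mean(out$predicted == out$label)
    }
    out
}

#' Per-cluster median combined scores
#'
#' The median, within each cluster, of the combined task score (binary call
#' multiplied by the continuous score) of its member samples.
#'
#' @param clusters a [MetabolicClusters-class].
#' @param combined task-by-sample matrix of combined scores
#'   ([combinedScores()]).
#' @return task-by-cluster matrix of medians; tasks with a nonzero median in
#'   any cluster are listed in \code{attr(, "nonzero")}.
#' @export
clusterMedianScores <- function(clusters, combined) {
    combined <- as.matrix(combined)
    labels <- rownames(clusterSignatures(clusters))
    med <- vapply(labels, function(cl) {
        members <- clusterMembers(clusters, cl)
        apply(combined[, members, drop = FALSE], 1, stats::median,
              na.rm = TRUE)
    }, numeric(nrow(combined)))
    med <- matrix(med, nrow = nrow(combined),
                  dimnames = list(rownames(combined), labels))
    attr(med, "nonzero") <-
        rownames(med)[apply(med, 1, function(x) any(!is.na(x) & x != 0))]
    med
}
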