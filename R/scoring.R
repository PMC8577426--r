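# Expression thresholding, gene activity scores, reaction activity levels,
# gene significance and task scores.

#' Per-gene expression thresholds
#'
#' Local mode: the lower and upper percentiles of the overall expression
#' distribution bound each gene's threshold, which is that gene's mean
#' expression across samples clamped into \code{[lower, upper]} (boundary
#' inclusive).  Global mode: a single percentile of the overall distribution
#' is used for every gene.  The overall distribution is, by default, the set
#' of per-gene mean expression values; set \code{distribution = "all_values"}
#' to use every gene-by-sample entry instead.
#'
#' @param expr non-negative gene-by-sample numeric matrix with gene
#'   rownames.
#' @param mode \code{"local"} (default) or \code{"global"}.
#' @param lowerPct,upperPct local-mode percentile bounds, defaults 25 and 75.
#' @param globalPct percentile used in global mode (default 50).
#' @param distribution \code{"gene_means"} (default) or \code{"all_values"}.
#' @return named numeric vector of positive per-gene thresholds.
#' @export
computeThresholds <- function(expr, mode = c("local", "global"),
                              lowerPct = 25, upperPct = 75, globalPct = 50,
                              distribution = c("gene_means", "all_values")) {
    mode <- match.arg(mode)
    distribution <- match.arg(distribution)
    expr <- as.matrix(expr)
    if (length(expr) == 0) stop("empty expression matrix", call. = FALSE)
    if (any(expr < 0)) stop("expression values must be non-negative",
                            call. = FALSE)
    if (is.null(rownames(expr)))
        stop("expression matrix must have gene rownames", call. = FALSE)
    if (!(lowerPct >= 0 && lowerPct < upperPct && upperPct <= 100))
        stop("require 0 <= lowerPct < upperPct <= 100", call. = FALSE)
    if (mode == "local" && ncol(expr) < 2) {
        warning("local thresholding needs >= 2 samples; falling back to global",
                call. = FALSE)
        mode <- "global"
    }
    pool <- if (distribution == "gene_means") rowMeans(expr) else as.numeric(expr)
    th <- if (mode == "local") {
        bounds <- stats::quantile(pool, c(lowerPct, upperPct) / 100,
                                  names = FALSE)
        pmin(pmax(rowMeans(expr), bounds[1]), bounds[2])
    } else {
        rep(stats::quantile(pool, globalPct / 100, names = FALSE), nrow(expr))
    }
    # a zero threshold (all-zero pool tail) would make the score ratio
    # undefined; floor at the smallest representable positive value
    stats::setNames(pmax(th, .Machine$double.xmin), rownames(expr))
}

#' Gene activity scores
#'
#' \code{score = 5 * log(1 + expression / threshold)} (natural log), so a
#' gene expressed exactly at its threshold scores \code{5 * log(2)} — the
#' same constant used as the binary activity cutoff — and an unexpressed
#' gene scores 0.
#'
#' @param expr non-negative gene-by-sample matrix with gene rownames.
#' @param thresholds named positive vector from [computeThresholds()].
#' @return gene-by-sample matrix of non-negative scores.
#' @export
geneActivityScores <- function(expr, thresholds) {
    expr <- as.matrix(expr)
    if (any(expr < 0)) stop("expression values must be non-negative",
                            call. = FALSE)
    th <- thresholds[rownames(expr)]
    if (anyNA(th))
        stop(sprintf("missing threshold for gene(s): %s",
                     paste(utils::head(rownames(expr)[is.na(th)], 3),
                           collapse = ", ")), call. = FALSE)
    if (any(th <= 0)) stop("thresholds must be positive", call. = FALSE)
    5 * log1p(expr / th)
}

#' Reaction activity levels
#'
#' For every unique reaction appearing in any task-essential set, evaluates
#' its GPR rule over the per-sample gene scores ([evaluateGPR()]): the
#' reaction activity level (RAL) is the propagated score of the determinant
#' gene.  Reactions are deduplicated across tasks and evaluated once per
#' sample.  A reaction with no GPR, or whose genes are all unmeasured in a
#' sample, has an undefined RAL (\code{defined = FALSE}), never zero.
#'
#' @param scores gene-by-sample matrix from [geneActivityScores()].
#' @param essentialSets a [TaskEssentialSets-class].
#' @param model the [MetabolicModel-class] providing the GPR rules.
#' @return a [ReactionActivity-class].
#' @export
reactionActivity <- function(scores, essentialSets, model) {
    rxns <- sort(unique(unlist(lapply(as.list(essentialSets), function(s)
        s@reactions))))
    if (length(rxns) == 0) stop("no reactions in essential sets", call. = FALSE)
    unknown <- setdiff(rxns, model@reactions$id)
    if (length(unknown))
        stop(sprintf("essential sets reference reactions absent from model: %s",
                     paste(utils::head(unknown, 3), collapse = ", ")),
             call. = FALSE)
    samples <- colnames(scores)
    ral <- matrix(NA_real_, length(rxns), ncol(scores),
                  dimnames = list(rxns, samples))
    det <- matrix(NA_character_, length(rxns), ncol(scores),
                  dimnames = list(rxns, samples))
    noGPR <- character()
    for (j in seq_len(ncol(scores))) {
        sv <- stats::setNames(scores[, j], rownames(scores))
        for (r in rxns) {
            rule <- model@gprRules[[r]]
            if (is.null(rule)) { if (j == 1L) noGPR <- c(noGPR, r); next }
            ev <- evaluateGPR(rule, sv)
            ral[r, j] <- ev$value
            det[r, j] <- ev$determinant
        }
    }
    if (length(noGPR))
        message(sprintf("%d reaction(s) without GPR have undefined activity: %s",
                        length(noGPR),
                        paste(utils::head(noGPR, 5), collapse = ", ")))
    new("ReactionActivity", ral = ral, determinant = det,
        defined = !is.na(ral))
}

#' Gene significance in one sample
#'
#' The significance \code{S} of a gene is the reciprocal of the number of
#' unique reactions (across the union of all task-essential sets) for which
#' it is the determinant in that sample; it down-weights promiscuous
#' enzymes.  Determinants can differ between samples, so \code{S} is a
#' per-sample quantity.  Genes that are never a determinant are absent from
#' the map.
#'
#' @param activity a [ReactionActivity-class].
#' @param sample sample id or column index.
#' @return named numeric vector of values in \code{(0, 1]}.
#' @export
geneSignificance <- function(activity, sample) {
    d <- activity@determinant[, sample]
    d <- d[!is.na(d)]
    if (length(d) == 0) return(stats::setNames(numeric(), character()))
    tab <- table(d)
    stats::setNames(1 / as.numeric(tab), names(tab))
}

#' Metabolic task scores
#'
#' The continuous task score in a sample is the mean, over the task's
#' essential reactions, of each reaction's activity level multiplied by the
#' significance of its determinant gene.  The binary call declares a task
#' active when the mean RAL over its reactions is \emph{strictly} greater
#' than \code{binaryThreshold} (default \code{5 * log(2)}, the score of a
#' gene exactly at its threshold).  The combined score is the continuous
#' score where active and 0 otherwise.  Reactions with undefined RAL are
#' excluded from both numerator and denominator by default (the reported
#' coverage tracks how many were measured); set
#' \code{denominator = "all"} for the literal all-reactions denominator.
#'
#' @param activity a [ReactionActivity-class].
#' @param essentialSets a [TaskEssentialSets-class]; infeasible tasks are
#'   skipped.
#' @param binaryThreshold strict activity cutoff on the mean RAL.
#' @param minCoverage minimum fraction of task reactions with a defined RAL;
#'   below it the task's scores are \code{NA} in that sample (default 0).
#' @param denominator \code{"defined"} (default) or \code{"all"}.
#' @return a [TaskScoreResult-class] with assays \code{score},
#'   \code{active}, \code{combined} and \code{coverage}.  Scores are
#'   comparable across samples, never across tasks.
#' @export
metabolicTaskScores <- function(activity, essentialSets,
                                binaryThreshold = 5 * log(2),
                                minCoverage = 0,
                                denominator = c("defined", "all")) {
    denominator <- match.arg(denominator)
    sets <- Filter(function(s) s@feasible, as.list(essentialSets))
    if (length(sets) == 0) stop("no feasible tasks to score", call. = FALSE)
    taskIds <- vapply(sets, function(s) s@taskId, character(1))
    samples <- colnames(activity@ral)
    nT <- length(sets); nS <- length(samples)
    score <- matrix(NA_real_, nT, nS, dimnames = list(taskIds, samples))
    active <- matrix(NA, nT, nS, dimnames = list(taskIds, samples))
    coverage <- matrix(NA_real_, nT, nS, dimnames = list(taskIds, samples))

    sig <- lapply(samples, function(s) geneSignificance(activity, s))
    names(sig) <- samples
    for (j in seq_len(nS)) {
        Smap <- sig[[j]]
        for (i in seq_len(nT)) {
            rxns <- sets[[i]]@reactions
            ral <- activity@ral[rxns, j]
            det <- activity@determinant[rxns, j]
            ok <- !is.na(ral)
            coverage[i, j] <- mean(ok)
            if (!any(ok) || coverage[i, j] < minCoverage) next
            n <- if (denominator == "defined") sum(ok) else length(rxns)
            score[i, j] <- sum(ral[ok] * Smap[det[ok]]) / n
            active[i, j] <- mean(ral[ok]) > binaryThreshold
        }
    }
    combined <- ifelse(!is.na(active) & active, score, 0)
    combined[is.na(active)] <- NA_real_
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(score = score, active = active, combined = combined,
                      coverage = coverage),
        rowData = S4Vectors::DataFrame(
            taskId = taskIds,
            nReactions = vapply(sets, function(s) length(s@reactions),
                                integer(1))))
    S4Vectors::metadata(se) <- list(binaryThreshold = binaryThreshold,
                                    minCoverage = minCoverage,
                                    denominator = denominator)
    new("TaskScoreResult", se)
}

#' Score metabolic tasks from an expression matrix
#'
#' Convenience pipeline: thresholds ([computeThresholds()]), gene scores
#' ([geneActivityScores()]), reaction activity ([reactionActivity()]) and
#' task scores ([metabolicTaskScores()]).
#'
#' @param expr non-negative gene-by-sample matrix with gene rownames.
#' @param essentialSets a [TaskEssentialSets-class].
#' @param model the [MetabolicModel-class] providing GPR rules.
#' @param mode,lowerPct,upperPct,globalPct,distribution see
#'   [computeThresholds()].
#' @param binaryThreshold,minCoverage,denominator see
#'   [metabolicTaskScores()].
#' @return a [TaskScoreResult-class]; the thresholds and configuration are
#'   stored in its metadata.
#' @examples
#' fx <- makeToyModel(nPathways = 2, pathwayLength = 2, seed = 1)
#' sets <- buildTaskGeneMap(fx$model, fx$tasks)$sets
#' ex <- makeExpression(fx$model, fx$tasks, sets, nSamples = 4, seed = 1)
#' res <- scoreTasks(ex$expr, sets, fx$model)
#' mtScores(res)
#' @export
scoreTasks <- function(expr, essentialSets, model,
                       mode = c("local", "global"), lowerPct = 25,
                       upperPct = 75, globalPct = 50,
                       distribution = c("gene_means", "all_values"),
                       binaryThreshold = 5 * log(2), minCoverage = 0,
                       denominator = c("defined", "all")) {
    th <- computeThresholds(expr, mode, lowerPct, upperPct, globalPct,
                            distribution)
    gs <- geneActivityScores(expr, th)
    act <- reactionActivity(gs, essentialSets, model)
    res <- metabolicTaskScores(act, essentialSets, binaryThreshold,
                               minCoverage, denominator)
    md <- S4Vectors::metadata(res)
    md$thresholds <- th
    md$thresholdMode <- match.arg(mode)
    S4Vectors::metadata(res) <- md
    res
}

#' Read a gene-by-sample expression matrix
#'
#' TSV/CSV with gene ids in the first column and one column per sample.
#'
#' @param path file path (delimiter guessed from the extension).
#' @return numeric matrix with gene rownames.
#' @export
readExpression <- function(path) {
    if (!file.exists(path))
        stop(sprintf("expression file not found: %s", path), call. = FALSE)
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(df[[1]])
    if (anyDuplicated(genes))
        stop(sprintf("duplicate gene id in expression file: %s",
                     genes[duplicated(genes)][1]), call. = FALSE)
    m <- as.matrix(df[-1])
    if (!is.numeric(m)) stop("non-numeric expression values", call. = FALSE)
    rownames(m) <- genes
    m
}
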