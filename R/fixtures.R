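# Synthetic fixture generators: toy models with GPRs, feasible task
# definitions and expression matrices with planted task activity.  Identical
# arguments and seed give byte-identical outputs.

gprForStep <- function(prefix, complexity) {
    switch(complexity,
           single = prefix,
           isozyme = sprintf("%sa or %sb", prefix, prefix),
           complex = sprintf("%sa and %sb", prefix, prefix),
           nested = sprintf("(%sa and %sb) or %sc", prefix, prefix, prefix))
}

#' Generate a toy metabolic model with tasks and known essential sets
#'
#' Builds disjoint linear pathways (one per task): metabolites
#' \code{p<i>m<j>_c}, unidirectional conversion reactions \code{R<i>_<j>}
#' with GPRs of the requested complexity, and endpoint exchange reactions
#' (which the task environment closes).  Each pathway yields a feasible task
#' "convert the pathway substrate into its product"; the known minimal route
#' is returned as the ground-truth essential set.  Pathways listed in
#' \code{shortcut} additionally get a one-step bypass reaction, making the
#' bypass (not the chain) the parsimonious route.
#'
#' @param nPathways number of disjoint pathways/tasks (default 3).
#' @param pathwayLength reactions per pathway chain (default 3).
#' @param gprComplexity \code{"single"}, \code{"isozyme"}, \code{"complex"}
#'   or \code{"nested"}.
#' @param shortcut integer vector of pathway indices receiving a one-step
#'   bypass (default none).
#' @param seed unused by the deterministic construction but accepted for
#'   interface uniformity.
#' @return list with \code{model} ([MetabolicModel-class]), \code{tasks}
#'   ([TaskSet-class]) and \code{truth} ([TaskEssentialSets-class], the
#'   known minimal reaction/gene sets).
#' @export
makeToyModel <- function(nPathways = 3, pathwayLength = 3,
                         gprComplexity = c("single", "isozyme", "complex",
                                           "nested"),
                         shortcut = integer(), seed = NULL) {
    gprComplexity <- match.arg(gprComplexity)
    stopifnot(nPathways >= 1, pathwayLength >= 1)
    mets <- list(); rxns <- list(); tasks <- list(); truth <- list()
    for (p in seq_len(nPathways)) {
        mid <- sprintf("p%dm%d_c", p, 0:pathwayLength)
        mets[[p]] <- data.frame(id = mid, compartment = "c",
                                name = sprintf("pathway %d metabolite %d",
                                               p, 0:pathwayLength))
        chain <- character(pathwayLength)
        for (s in seq_len(pathwayLength)) {
            rid <- sprintf("R%d_%d", p, s)
            chain[s] <- rid
            st <- stats::setNames(c(-1, 1), c(mid[s], mid[s + 1]))
            rxns[[length(rxns) + 1L]] <- list(
                id = rid, metabolites = as.list(st), lower_bound = 0,
                upper_bound = 1000,
                gene_reaction_rule = gprForStep(sprintf("G%d_%d", p, s),
                                                gprComplexity))
        }
        essential <- chain
        if (p %in% shortcut && pathwayLength > 1) {
            rid <- sprintf("R%d_direct", p)
            st <- stats::setNames(c(-1, 1),
                                  c(mid[1], mid[pathwayLength + 1]))
            rxns[[length(rxns) + 1L]] <- list(
                id = rid, metabolites = as.list(st), lower_bound = 0,
                upper_bound = 1000,
                gene_reaction_rule = gprForStep(sprintf("G%d_direct", p),
                                                gprComplexity))
            essential <- rid
        }
        # endpoint exchanges; the task environment closes these
        for (mm in c(mid[1], mid[pathwayLength + 1]))
            rxns[[length(rxns) + 1L]] <- list(
                id = paste0("EX_", mm),
                metabolites = stats::setNames(list(-1), mm),
                lower_bound = -1000, upper_bound = 1000,
                gene_reaction_rule = "")
        tasks[[p]] <- makeTaskDefinition(
            id = sprintf("T%d", p),
            description = sprintf("convert p%dm0 to p%dm%d", p, p,
                                  pathwayLength),
            system = c("energy", "nucleotide", "carbohydrates", "amino acid",
                       "lipid", "vitamin & cofactor",
                       "glycan")[(p - 1L) %% 7L + 1L],
            inputs = data.frame(metabolite = sprintf("p%dm0", p),
                                compartment = "c", lb = 0, ub = 10),
            outputs = data.frame(metabolite = sprintf("p%dm%d", p,
                                                      pathwayLength),
                                 compartment = "c", lb = 1, ub = 1000))
        genes <- sort(unique(unlist(lapply(essential, function(r) {
            k <- which(vapply(rxns, `[[`, character(1), "id") == r)
            gprGenes(parseGPR(rxns[[k]]$gene_reaction_rule))
        }))))
        truth[[p]] <- new("TaskEssentialSet", taskId = sprintf("T%d", p),
                          feasible = TRUE, reactions = essential,
                          genes = genes,
                          fluxes = stats::setNames(rep(1, length(essential)),
                                                   essential))
    }
    model <- makeMetabolicModel(do.call(rbind, mets), rxns)
    list(model = model, tasks = TaskSet(tasks),
         truth = TaskEssentialSets(truth))
}

#' Generate an expression matrix with planted task activity
#'
#' Baseline expression is drawn log-normally around a common scale.  Each
#' task is planted active or inactive independently per sample; in active
#' samples every gene of the task's essential set is scaled
#' \code{effect}-fold above baseline (default 4), in inactive samples
#' \code{inactiveEffect}-fold (default 0.25), so min-based AND rules respond
#' unambiguously.  The generator assumes the task gene sets are disjoint
#' (true for [makeToyModel()] pathways).
#'
#' @param model,tasks from [makeToyModel()].
#' @param essentialSets a [TaskEssentialSets-class] (ground truth or
#'   extracted) providing the gene sets to manipulate.
#' @param nSamples number of samples (default 50).
#' @param activeProb probability a task is planted active in a sample
#'   (default 0.5); alternatively pass a logical task-by-sample matrix as
#'   \code{truth}.
#' @param truth optional logical task-by-sample matrix overriding the random
#'   planting.
#' @param effect,inactiveEffect fold change of essential-set genes in
#'   active/inactive samples.
#' @param noiseSd log-scale noise standard deviation (default 0.1).
#' @param baseline common expression scale (default 10, arbitrary platform
#'   units).
#' @param seed RNG seed (default 1).
#' @return list with \code{expr} (gene-by-sample matrix over all model
#'   genes) and \code{truth} (logical task-by-sample planted activity).
#' @export
makeExpression <- function(model, tasks, essentialSets, nSamples = 50,
                           activeProb = 0.5, truth = NULL, effect = 4,
                           inactiveEffect = 0.25, noiseSd = 0.1,
                           baseline = 10, seed = 1) {
    set.seed(seed)
    tasks <- as.list(tasks)
    sets <- as.list(essentialSets)
    taskIds <- vapply(sets, function(s) s@taskId, character(1))
    samples <- sprintf("S%03d", seq_len(nSamples))
    if (is.null(truth)) {
        truth <- matrix(stats::runif(length(taskIds) * nSamples) < activeProb,
                        length(taskIds), nSamples,
                        dimnames = list(taskIds, samples))
    } else {
        truth <- as.matrix(truth)
        dimnames(truth) <- list(taskIds, samples)
    }
    genes <- geneIds(model)
    mult <- matrix(1, length(genes), nSamples,
                   dimnames = list(genes, samples))
    for (i in seq_along(sets)) {
        g <- sets[[i]]@genes
        if (!length(g)) next
        mult[g, ] <- ifelse(rep(truth[i, ], each = length(g)), effect,
                            inactiveEffect)
    }
    noise <- matrix(exp(stats::rnorm(length(genes) * nSamples, 0, noiseSd)),
                    length(genes), nSamples)
    expr <- baseline * mult * noise
    dimnames(expr) <- list(genes, samples)
    list(expr = expr, truth = truth)
}

#' Write a complete fixture to disk
#'
#' Emits the same formats the pipeline reads (model JSON, task CSV,
#' expression TSV, planted-truth CSV), so fixtures double as format
#' conformance tests.
#'
#' @param dir output directory (created if needed).
#' @param ... passed to [makeToyModel()].
#' @param nSamples,seed passed to [makeExpression()].
#' @return named character vector of the written paths, invisibly.
#' @export
writeFixture <- function(dir, ..., nSamples = 20, seed = 1) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fx <- makeToyModel(...)
    ex <- makeExpression(fx$model, fx$tasks, fx$truth, nSamples = nSamples,
                         seed = seed)
    paths <- c(model = file.path(dir, "model.json"),
               tasks = file.path(dir, "tasks.csv"),
               expr = file.path(dir, "expression.tsv"),
               truth = file.path(dir, "truth.csv"))
    writeMetabolicModel(fx$model, paths["model"])
    writeTaskList(fx$tasks, paths["tasks"])
    utils::write.table(data.frame(gene = rownames(ex$expr), ex$expr,
                                  check.names = FALSE),
                       paths["expr"], sep = "\t", row.names = FALSE,
                       quote = FALSE)
    utils::write.csv(data.frame(task = rownames(ex$truth), ex$truth * 1,
                                check.names = FALSE),
                     paths["truth"], row.names = FALSE, quote = FALSE)
    invisible(paths)
}
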