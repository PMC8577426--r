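# Task feasibility and parsimonious (L1-minimal) essential-set extraction.
#
# A task is imposed on a model by closing every exchange reaction (columns
# touching a single metabolite), adding an uptake flux per task input
# (0 <= lb <= flux <= ub, producing the metabolite) and a demand flux per
# task output (required production enforced as the demand lower bound).
# Reversible reactions are split into irreversible pairs so that total
# absolute flux is a linear objective.

stripCompartmentSuffix <- function(id)
    sub("(_[a-zA-Z0-9]+|\\[[a-zA-Z0-9]+\\])$", "", id)

#' Resolve a task metabolite in a model namespace
#'
#' Matching order: an optional user mapping table, exact id, id with
#' \code{_compartment} or \code{[compartment]} suffix, then model ids whose
#' compartment suffix strips to the queried id in the right compartment.
#'
#' @param model a [MetabolicModel-class].
#' @param metabolite,compartment task-side identifiers.
#' @param mapping optional named character vector (task id -> model id).
#' @return the model metabolite id, or \code{NA_character_} if unresolved.
#' @export
resolveTaskMetabolite <- function(model, metabolite, compartment = "",
                                  mapping = NULL) {
    ids <- model@metabolites$id
    if (!is.null(mapping) && metabolite %in% names(mapping)) {
        cand <- unname(mapping[[metabolite]])
        if (cand %in% ids) return(cand)
    }
    if (metabolite %in% ids) return(metabolite)
    for (cand in c(paste0(metabolite, "_", compartment),
                   paste0(metabolite, "[", compartment, "]")))
        if (cand %in% ids) return(cand)
    hit <- ids[stripCompartmentSuffix(ids) == metabolite &
               model@metabolites$compartment == compartment]
    if (length(hit) >= 1L) return(hit[1L])
    NA_character_
}

isExchangeReaction <- function(model)
    Matrix::colSums(model@stoichiometry != 0) == 1L

# Build the split-variable LP for a task environment.  Returns the variable
# table, constraint matrices and the signed stoichiometry over variables.
buildTaskLP <- function(model, task, mapping = NULL, bigM = 1000) {
    ids <- model@metabolites$id
    resolve <- function(df) {
        if (nrow(df) == 0) return(character())
        vapply(seq_len(nrow(df)), function(k)
            resolveTaskMetabolite(model, df$metabolite[k], df$compartment[k],
                                  mapping), character(1))
    }
    inMet <- resolve(task@inputs)
    outMet <- resolve(task@outputs)
    missing <- c(task@inputs$metabolite[is.na(inMet)],
                 task@outputs$metabolite[is.na(outMet)])
    if (length(missing))
        stop(sprintf("task %s: cannot resolve metabolite(s) in model: %s",
                     task@id, paste(unique(missing), collapse = ", ")),
             call. = FALSE)

    exch <- isExchangeReaction(model)
    S <- model@stoichiometry
    vars <- list()
    addVar <- function(name, kind, rxn, col, lb, ub)
        vars[[length(vars) + 1L]] <<- list(name = name, kind = kind,
                                           rxn = rxn, col = col,
                                           lb = lb, ub = min(ub, bigM))
    for (k in seq_len(nrow(model@reactions))) {
        if (exch[k]) next  # non-task exchanges are closed
        r <- model@reactions[k, ]
        if (r$upper_bound > 0)
            addVar(paste0(r$id, ":f"), "fwd", r$id, S[, k],
                   max(r$lower_bound, 0), r$upper_bound)
        if (r$lower_bound < 0)
            addVar(paste0(r$id, ":b"), "bwd", r$id, -S[, k],
                   0, -r$lower_bound)
    }
    if (nrow(task@inputs))
        for (k in seq_len(nrow(task@inputs))) {
            col <- numeric(length(ids)); col[match(inMet[k], ids)] <- 1
            addVar(paste0("UPTAKE[", inMet[k], "]"), "uptake", NA_character_,
                   col, task@inputs$lb[k], task@inputs$ub[k])
        }
    for (k in seq_len(nrow(task@outputs))) {
        col <- numeric(length(ids)); col[match(outMet[k], ids)] <- -1
        addVar(paste0("DEMAND[", outMet[k], "]"), "demand", NA_character_,
               col, task@outputs$lb[k], task@outputs$ub[k])
    }
    A <- do.call(cbind, lapply(vars, function(v) as.numeric(v$col)))
    rownames(A) <- ids
    keep <- rowSums(A != 0) > 0
    vtab <- data.frame(
        name = vapply(vars, `[[`, character(1), "name"),
        kind = vapply(vars, `[[`, character(1), "kind"),
        rxn = vapply(vars, `[[`, character(1), "rxn"),
        lb = vapply(vars, `[[`, numeric(1), "lb"),
        ub = vapply(vars, `[[`, numeric(1), "ub"),
        stringsAsFactors = FALSE)
    lbpos <- vtab$lb > 0
    list(vars = vtab,
         A1 = diag(nrow(vtab)), b1 = vtab$ub,
         A2 = if (any(lbpos)) diag(nrow(vtab))[lbpos, , drop = FALSE] else NULL,
         b2 = if (any(lbpos)) vtab$lb[lbpos] else NULL,
         A3 = A[keep, , drop = FALSE], b3 = rep(0, sum(keep)))
}

lpNetFluxes <- function(model, lp, solution) {
    net <- stats::setNames(rep(0, nrow(model@reactions)), model@reactions$id)
    for (k in seq_len(nrow(lp$vars))) {
        v <- lp$vars[k, ]
        if (v$kind == "fwd") net[v$rxn] <- net[v$rxn] + solution[k]
        else if (v$kind == "bwd") net[v$rxn] <- net[v$rxn] - solution[k]
    }
    bnd <- lp$vars$kind %in% c("uptake", "demand")
    c(net, stats::setNames(solution[bnd], lp$vars$name[bnd]))
}

# Max-abs steady-state residual of a stored flux vector under the task
# environment; used to audit solutions.
taskFluxResidual <- function(model, task, fluxes, mapping = NULL) {
    lp <- buildTaskLP(model, task, mapping)
    sol <- numeric(nrow(lp$vars))
    for (k in seq_len(nrow(lp$vars))) {
        v <- lp$vars[k, ]
        sol[k] <- if (v$kind == "fwd") max(fluxes[v$rxn], 0)
        else if (v$kind == "bwd") max(-fluxes[v$rxn], 0)
        else unname(fluxes[v$name])
    }
    max(abs(lp$A3 %*% sol))
}

#' Check whether a model can accomplish a task
#'
#' Decides if a steady-state flux vector exists satisfying the model's
#' stoichiometry and bounds with all non-task exchanges closed, uptake
#' limited to the task inputs and every task output produced at its required
#' minimum rate.
#'
#' @param model a [MetabolicModel-class].
#' @param task a [TaskDefinition-class].
#' @param mapping optional task-to-model metabolite id mapping.
#' @return list with \code{feasible} (logical), \code{status} (solver
#'   status string) and \code{fluxes} (named net flux vector over model
#'   reactions plus \code{UPTAKE[...]}/\code{DEMAND[...]} boundary fluxes;
#'   \code{NULL} when infeasible).  An unresolvable task metabolite is an
#'   error naming the missing ids; a solver failure is an error distinct
#'   from infeasibility.
#' @export
checkTaskFeasibility <- function(model, task, mapping = NULL) {
    lp <- buildTaskLP(model, task, mapping)
    res <- solveLP(rep(0, nrow(lp$vars)), A1 = lp$A1, b1 = lp$b1,
                   A2 = lp$A2, b2 = lp$b2, A3 = lp$A3, b3 = lp$b3)
    if (res$status == "infeasible")
        return(list(feasible = FALSE, status = "infeasible", fluxes = NULL))
    if (res$status != "optimal")
        stop(sprintf("LP solver failure for task %s: %s", task@id,
                     res$status), call. = FALSE)
    list(feasible = TRUE, status = "optimal",
         fluxes = lpNetFluxes(model, lp, res$solution))
}

#' Extract the parsimonious task-essential reaction and gene set
#'
#' Minimises total absolute flux (parsimonious FBA, reversible reactions
#' split into irreversible pairs) subject to the task environment; the
#' reactions carrying flux above \code{fluxTolerance} in the optimum form the
#' essential set, and the gene set is the union of all genes appearing in
#' those reactions' GPR rules.  Because L1 optima need not be unique, an
#' optional canonicalisation pass fixes the optimal total flux and then
#' lexicographically minimises each reaction's flux in id order, yielding a
#' deterministic support.
#'
#' @param model a [MetabolicModel-class].
#' @param task a [TaskDefinition-class].
#' @param fluxTolerance smallest absolute flux regarded as carrying the task
#'   (default \code{1e-6}, flux units of the model).
#' @param canonical run the lexicographic tie-breaking pass (default
#'   \code{TRUE}).
#' @param mapping optional task-to-model metabolite id mapping.
#' @return a [TaskEssentialSet-class]; an infeasible task yields
#'   \code{feasible = FALSE} with empty sets, not an error.
#' @export
extractEssentialSet <- function(model, task, fluxTolerance = 1e-6,
                                canonical = TRUE, mapping = NULL) {
    lp <- buildTaskLP(model, task, mapping)
    nv <- nrow(lp$vars)
    internal <- lp$vars$kind %in% c("fwd", "bwd")
    obj <- as.numeric(internal)
    res <- solveLP(obj, A1 = lp$A1, b1 = lp$b1, A2 = lp$A2, b2 = lp$b2,
                   A3 = lp$A3, b3 = lp$b3, maximize = FALSE)
    if (res$status == "infeasible")
        return(new("TaskEssentialSet", taskId = task@id, feasible = FALSE,
                   reactions = character(), genes = character(),
                   fluxes = stats::setNames(numeric(), character())))
    if (res$status != "optimal")
        stop(sprintf("LP solver failure for task %s: %s", task@id,
                     res$status), call. = FALSE)
    total <- sum(res$solution[internal])
    sol <- res$solution

    if (canonical) {
        slack <- 1e-7 * (1 + abs(total))
        A1 <- rbind(lp$A1, obj)
        b1 <- c(lp$b1, total + slack)
        rxns <- sort(unique(lp$vars$rxn[internal]))
        for (r in rxns) {
            sel <- as.numeric(internal & lp$vars$rxn == r)
            res2 <- solveLP(sel, A1 = A1, b1 = b1, A2 = lp$A2, b2 = lp$b2,
                            A3 = lp$A3, b3 = lp$b3, maximize = FALSE)
            if (res2$status != "optimal") next  # keep previous solution
            sol <- res2$solution
            A1 <- rbind(A1, sel)
            b1 <- c(b1, sum(sel * sol) + 1e-9)
        }
    }

    fluxes <- lpNetFluxes(model, lp, sol)
    rxnFlux <- fluxes[model@reactions$id]
    ess <- names(rxnFlux)[abs(rxnFlux) > fluxTolerance]
    genes <- sort(unique(unlist(lapply(ess, function(r)
        gprGenes(model@gprRules[[r]])))))
    if (is.null(genes)) genes <- character()
    new("TaskEssentialSet", taskId = task@id, feasible = TRUE,
        reactions = ess, genes = genes, fluxes = fluxes)
}

#' Extract essential sets for a task collection
#'
#' Runs [extractEssentialSet()] per task, collecting per-task failures
#' without aborting the batch, and summarises how much of the model's gene
#' complement the task collection covers.
#'
#' @param model a [MetabolicModel-class].
#' @param tasks a [TaskSet-class] (or list of [TaskDefinition-class]).
#' @param fluxTolerance,canonical,mapping passed to [extractEssentialSet()].
#' @return list with \code{sets} (a [TaskEssentialSets-class] over tasks that
#'   did not error), \code{coveragePct} (percentage of model genes in the
#'   union of task gene sets) and \code{summary} (per-task data.frame:
#'   feasibility, reaction/gene counts, error messages).
#' @export
buildTaskGeneMap <- function(model, tasks, fluxTolerance = 1e-6,
                             canonical = TRUE, mapping = NULL) {
    tasks <- as.list(tasks)
    sets <- list()
    rows <- list()
    for (t in tasks) {
        s <- tryCatch(extractEssentialSet(model, t, fluxTolerance, canonical,
                                          mapping),
                      error = function(e) e)
        if (inherits(s, "error")) {
            rows[[length(rows) + 1L]] <- data.frame(
                task_id = t@id, feasible = NA, n_reactions = NA_integer_,
                n_genes = NA_integer_, error = conditionMessage(s),
                stringsAsFactors = FALSE)
        } else {
            sets[[length(sets) + 1L]] <- s
            rows[[length(rows) + 1L]] <- data.frame(
                task_id = t@id, feasible = s@feasible,
                n_reactions = length(s@reactions),
                n_genes = length(s@genes), error = "",
                stringsAsFactors = FALSE)
        }
    }
    covered <- unique(unlist(lapply(sets, function(s) s@genes)))
    pct <- if (length(model@genes) == 0) 0 else
        100 * length(intersect(covered, model@genes)) / length(model@genes)
    list(sets = TaskEssentialSets(sets), coveragePct = pct,
         summary = if (length(rows)) do.call(rbind, rows) else
             data.frame(task_id = character(), feasible = logical(),
                        n_reactions = integer(), n_genes = integer(),
                        error = character()))
}
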