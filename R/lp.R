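# Dense two-phase simplex with Bland's anti-cycling rule.
#
# Flux LPs over task environments are small but highly degenerate (closing
# exchanges forces many fluxes to zero through equality rows), which is
# exactly the regime where naive pivoting produces zero pivots; Bland's rule
# guarantees termination.  Problems: min/max obj'x subject to A1 x <= b1,
# A2 x >= b2, A3 x = b3, x >= 0.

simplexPivot <- function(Tb, basis, cost, tol = 1e-9, maxIter = 100000L) {
    m <- nrow(Tb)
    nc <- ncol(Tb) - 1L
    iter <- 0L
    repeat {
        iter <- iter + 1L
        if (iter > maxIter) return(list(status = "iteration_limit"))
        red <- cost - as.numeric(cost[basis] %*% Tb[, seq_len(nc), drop = FALSE])
        ent <- which(red < -tol)
        if (!length(ent))
            return(list(status = "optimal", Tb = Tb, basis = basis))
        e <- ent[1L]  # Bland: smallest entering index
        col <- Tb[, e]
        pos <- which(col > tol)
        if (!length(pos)) return(list(status = "unbounded"))
        ratios <- Tb[pos, nc + 1L] / col[pos]
        rmin <- min(ratios)
        cand <- pos[ratios <= rmin + tol]
        l <- cand[which.min(basis[cand])]  # Bland: smallest leaving basis var
        Tb[l, ] <- Tb[l, ] / Tb[l, e]
        upd <- setdiff(which(abs(Tb[, e]) > 0), l)
        if (length(upd))
            Tb[upd, ] <- Tb[upd, ] - outer(Tb[upd, e], Tb[l, ])
        basis[l] <- e
    }
}

solveLP <- function(obj, A1 = NULL, b1 = NULL, A2 = NULL, b2 = NULL,
                    A3 = NULL, b3 = NULL, maximize = FALSE, tol = 1e-9) {
    n <- length(obj)
    rows <- list(); rhs <- numeric()
    slackSign <- integer()
    if (!is.null(A1) && nrow(A1)) { rows <- c(rows, list(A1)); rhs <- c(rhs, b1)
        slackSign <- c(slackSign, rep(1L, nrow(A1))) }
    if (!is.null(A2) && nrow(A2)) { rows <- c(rows, list(A2)); rhs <- c(rhs, b2)
        slackSign <- c(slackSign, rep(-1L, nrow(A2))) }
    if (!is.null(A3) && nrow(A3)) { rows <- c(rows, list(A3)); rhs <- c(rhs, b3)
        slackSign <- c(slackSign, rep(0L, nrow(A3))) }
    A <- do.call(rbind, rows)
    m <- nrow(A)
    nSlack <- sum(slackSign != 0L)
    Afull <- cbind(A, matrix(0, m, nSlack))
    j <- n
    for (i in seq_len(m)) if (slackSign[i] != 0L) {
        j <- j + 1L
        Afull[i, j] <- slackSign[i]
    }
    # phase 1: artificial basis, b made non-negative first
    neg <- rhs < 0
    Afull[neg, ] <- -Afull[neg, , drop = FALSE]
    rhs[neg] <- -rhs[neg]
    nv <- n + nSlack
    Tb <- cbind(Afull, diag(m), rhs)
    basis <- nv + seq_len(m)
    cost1 <- c(rep(0, nv), rep(1, m))
    r1 <- simplexPivot(Tb, basis, cost1, tol)
    if (r1$status != "optimal")
        return(list(status = r1$status, solution = NULL, value = NA_real_))
    Tb <- r1$Tb; basis <- r1$basis
    if (sum(Tb[basis > nv, ncol(Tb)]) > 1e-7)
        return(list(status = "infeasible", solution = NULL, value = NA_real_))
    # drive remaining artificial variables out of the basis (degenerate rows)
    keep <- rep(TRUE, m)
    for (i in which(basis > nv)) {
        piv <- which(abs(Tb[i, seq_len(nv)]) > tol)
        if (!length(piv)) { keep[i] <- FALSE; next }  # redundant row
        e <- piv[1L]
        Tb[i, ] <- Tb[i, ] / Tb[i, e]
        upd <- setdiff(which(abs(Tb[, e]) > 0), i)
        if (length(upd))
            Tb[upd, ] <- Tb[upd, ] - outer(Tb[upd, e], Tb[i, ])
        basis[i] <- e
    }
    Tb <- Tb[keep, c(seq_len(nv), ncol(Tb)), drop = FALSE]
    basis <- basis[keep]
    cost2 <- c(if (maximize) -obj else obj, rep(0, nSlack))
    r2 <- simplexPivot(Tb, basis, cost2, tol)
    if (r2$status != "optimal")
        return(list(status = r2$status, solution = NULL, value = NA_real_))
    x <- numeric(nv)
    x[r2$basis] <- r2$Tb[, ncol(r2$Tb)]
    sol <- x[seq_len(n)]
    list(status = "optimal", solution = sol, value = sum(obj * sol))
}
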