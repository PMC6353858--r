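# Minimal least-squares flux estimation from (corrected) compact tandem MS
# matrices. The network's free degrees of freedom are fitted with a bounded
# Levenberg-Marquardt solver while the remaining fluxes follow from the
# stoichiometric steady-state constraints.

## simulate the stacked measurement vector for one flux map
simulateMeasurementVector <- function(systems, fluxes, tracers, table,
                                      marginalOnly = FALSE) {
    unlist(lapply(systems, function(sys) {
        sol <- solveCascade(sys, fluxes, inputMatrices(sys, tracers, table))
        m <- targetMatrix(sys, sol)
        if (marginalOnly) parentMarginal(m) else flattenCompact(tandemValues(m))
    }), use.names = FALSE)
}

#' Fit free fluxes to tandem MS measurements
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt,
#' \code{minpack.lm::nls.lm}) over the free fluxes named in \code{init}; all
#' other fluxes follow from \code{fix} and the steady-state balances via
#' \code{\link{balancedFluxes}}. Each measurement is simulated with
#' \code{\link{solveCascade}} and compared entrywise (identity weights).
#' Flux maps in which any derived flux goes negative are rejected with a
#' large penalty residual rather than an error, so the solver can retreat.
#'
#' @param model a \linkS4class{NetworkModel}
#' @param measurements list of \code{list(target = TandemEMU, matrix =
#'   CompactTandemMatrix)} entries
#' @param init named numeric vector of starting values for the free fluxes
#' @param tracers named list, input metabolite -> \linkS4class{TracerSpec}
#' @param fix named numeric vector of fixed fluxes (default: flux "1" at
#'   100, the conventional input-flux normalization)
#' @param lower,upper bounds on the free fluxes
#' @param table an \linkS4class{ElementIsotopeTable}
#' @param maxIter solver iteration cap
#' @return a \linkS4class{FitResult}
#' @export
fitFluxes <- function(model, measurements, init, tracers,
                      fix = c("1" = 100), lower = rep(0, length(init)),
                      upper = rep(Inf, length(init)),
                      table = defaultIsotopeTable(), maxIter = 100L) {
    stopifnot(length(init) > 0, !is.null(names(init)))
    systems <- lapply(measurements, function(ms) decomposeTandem(model, ms$target))
    observed <- unlist(lapply(measurements, function(ms)
        flattenCompact(tandemValues(ms$matrix))), use.names = FALSE)
    resFn <- function(par) {
        names(par) <- names(init)
        fl <- tryCatch(balancedFluxes(model, fix = c(fix, par)),
                       error = function(e) NULL)
        if (is.null(fl)) return(rep(1e3, length(observed)))
        simulateMeasurementVector(systems, fl, tracers, table) - observed
    }
    fit <- minpack.lm::nls.lm(par = unname(init), lower = lower, upper = upper,
                              fn = resFn,
                              control = minpack.lm::nls.lm.control(
                                  maxiter = maxIter, ftol = 1e-15,
                                  ptol = 1e-15, gtol = 1e-15))
    est <- stats::setNames(fit$par, names(init))
    fluxes <- tryCatch(balancedFluxes(model, fix = c(fix, est)),
                       error = function(e) stats::setNames(numeric(0), character(0)))
    new("FitResult", estimates = est, fluxes = fluxes,
        rss = sum(fit$fvec^2),
        converged = fit$info %in% 1:4, iterations = as.integer(fit$niter),
        message = fit$message)
}

#' Linearized flux standard errors from labeling measurements
#'
#' Local sensitivity analysis at a given point in free-flux space: the
#' Jacobian J of the stacked (noise-free) measurement vector with respect to
#' the free fluxes is computed by central differences, and unit-weight
#' standard errors are returned as sqrt(diag((J'J)^-1)). With
#' \code{marginalOnly = TRUE} only the parent-fragment MID of each target is
#' used, which quantifies how much flux information the tandem (joint
#' daughter/parent) measurement adds over conventional MS.
#'
#' @param model a \linkS4class{NetworkModel}
#' @param targets list of \linkS4class{TandemEMU} measurement targets
#' @param free named numeric vector of free flux values (evaluation point)
#' @param tracers named list, input metabolite -> \linkS4class{TracerSpec}
#' @param fix named numeric vector of fixed fluxes
#' @param marginalOnly use only the parent MID of each target
#' @param h relative step for central differences
#' @param table an \linkS4class{ElementIsotopeTable}
#' @return named numeric vector of standard errors, one per free flux
#' @export
fluxStandardErrors <- function(model, targets, free, tracers,
                               fix = c("1" = 100), marginalOnly = FALSE,
                               h = 1e-5, table = defaultIsotopeTable()) {
    systems <- lapply(targets, function(tg) decomposeTandem(model, tg))
    f <- function(par) {
        names(par) <- names(free)
        fl <- balancedFluxes(model, fix = c(fix, par), nonneg = FALSE)
        simulateMeasurementVector(systems, fl, tracers, table, marginalOnly)
    }
    J <- vapply(seq_along(free), function(i) {
        step <- h * max(1, abs(free[i]))
        up <- free; up[i] <- up[i] + step
        dn <- free; dn[i] <- dn[i] - step
        (f(up) - f(dn)) / (2 * step)
    }, f(free))
    info <- crossprod(J)
    if (rcond(info) < 1e-14)
        stop("measurement set does not locally identify the free fluxes")
    stats::setNames(sqrt(diag(solve(info))), names(free))
}

setMethod("show", "FitResult", function(object) {
    cat(sprintf("FitResult: %s after %d iterations (RSS %.6g)\n",
                if (object@converged) "converged" else "NOT converged",
                object@iterations, object@rss))
    print(round(object@estimates, 6))
})
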