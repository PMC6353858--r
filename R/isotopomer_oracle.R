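# Brute-force full-isotopomer steady-state simulator. Deliberately naive:
# used as the independent correctness oracle for the EMU cascade and the
# labeling simulator, not for performance.

.ORACLE_MAX_CARBONS <- 12L

#' Isotopomer distribution of a tracer-defined input metabolite
#'
#' Entry b (0-based bit pattern, bit i set = atom i labeled) is the product
#' of the per-atom heavy-isotope probabilities.
#'
#' @param tracer a \linkS4class{TracerSpec}
#' @param table an \linkS4class{ElementIsotopeTable}
#' @return numeric vector of length 2^nAtoms, summing to 1
#' @export
tracerIsotopomers <- function(tracer, table = defaultIsotopeTable()) {
    mids <- atomMIDs(tracer, table)
    heavy <- vapply(mids, function(m) sum(m[-1L]), 0)
    n <- tracer@nAtoms
    out <- numeric(2^n)
    for (b in 0:(2^n - 1L)) {
        bits <- bitwAnd(bitwShiftR(b, 0:(n - 1L)), 1L) == 1L
        out[b + 1L] <- prod(ifelse(bits, heavy, 1 - heavy))
    }
    out
}

## marginal of an isotopomer distribution over a subset of atom positions
isotopomerMarginal <- function(dist, positions, nAtoms) {
    ns <- length(positions)
    out <- numeric(2^ns)
    for (b in 0:(2^nAtoms - 1L)) {
        bits <- bitwAnd(bitwShiftR(b, 0:(nAtoms - 1L)), 1L)
        sub <- sum(bits[positions] * 2^(seq_len(ns) - 1L))
        out[sub + 1L] <- out[sub + 1L] + dist[b + 1L]
    }
    out
}

#' Brute-force steady-state isotopomer simulation
#'
#' Solves the full isotopomer balance of every non-input metabolite by
#' fixed-point iteration of the (bilinear, because of condensation
#' reactions) flux-weighted mixing map, starting from the unlabeled
#' distribution.
#'
#' @param model a \linkS4class{NetworkModel}
#' @param fluxes named unidirectional flux map, balanced at steady state
#' @param inputDists named list, input metabolite -> isotopomer distribution
#'   of length 2^carbons (see \code{\link{tracerIsotopomers}})
#' @param tol fixed-point tolerance on the max absolute change (default 1e-12)
#' @param maxIter iteration cap (default 10000)
#' @return named list, metabolite -> isotopomer distribution
#' @export
simulateIsotopomers <- function(model, fluxes, inputDists,
                                tol = 1e-12, maxIter = 10000L) {
    carbons <- model@carbons
    if (any(carbons > .ORACLE_MAX_CARBONS))
        stop(sprintf("oracle limited to metabolites with <= %d carbons",
                     .ORACLE_MAX_CARBONS))
    for (met in model@inputs) {
        d <- inputDists[[met]]
        if (is.null(d)) stop(sprintf("missing input distribution for %s", met))
        if (length(d) != 2^carbons[[met]] || abs(sum(d) - 1) > .TOL_NORM)
            stop(sprintf("input distribution for %s has wrong length or sum", met))
    }
    urx <- unidirectionalReactions(model)
    free <- setdiff(names(carbons), model@inputs)
    x <- inputDists[model@inputs]
    for (met in free) {
        x[[met]] <- numeric(2^carbons[[met]])
        x[[met]][1L] <- 1
    }
    for (iter in seq_len(maxIter)) {
        delta <- 0
        xNew <- x
        for (met in free) {
            n <- carbons[[met]]
            num <- numeric(2^n)
            vtot <- 0
            for (r in urx) {
                v <- fluxes[[r$flux]]
                if (is.null(v)) stop(sprintf("missing flux value for %s", r$flux))
                if (v == 0) next
                for (slot in which(vapply(r$products, `[[`, "", "met") == met)) {
                    labels <- r$products[[slot]]$labels
                    # which educt and which educt atom feeds each product atom
                    src <- lapply(labels, function(lb) {
                        for (ei in seq_along(r$educts)) {
                            p <- match(lb, r$educts[[ei]]$labels)
                            if (!is.na(p)) return(c(ei, p))
                        }
                        stop("unmapped atom label")  # unreachable: validated reaction
                    })
                    eIdx <- vapply(src, `[[`, 0, 1L)
                    # per educt: marginal over the positions feeding this product
                    margs <- list()
                    posIn <- list()
                    for (ei in unique(eIdx)) {
                        pos <- vapply(src[eIdx == ei], `[[`, 0, 2L)
                        em <- r$educts[[ei]]$met
                        margs[[as.character(ei)]] <-
                            isotopomerMarginal(x[[em]], pos, carbons[[em]])
                        posIn[[as.character(ei)]] <- which(eIdx == ei)
                    }
                    for (b in 0:(2^n - 1L)) {
                        bits <- bitwAnd(bitwShiftR(b, 0:(n - 1L)), 1L)
                        p <- 1
                        for (ei in names(margs)) {
                            sub <- sum(bits[posIn[[ei]]] *
                                       2^(seq_along(posIn[[ei]]) - 1L))
                            p <- p * margs[[ei]][sub + 1L]
                        }
                        num[b + 1L] <- num[b + 1L] + v * p
                    }
                    vtot <- vtot + v
                }
            }
            if (vtot > 0) xNew[[met]] <- num / vtot
            delta <- max(delta, max(abs(xNew[[met]] - x[[met]])))
        }
        x <- xNew
        if (delta < tol) return(x)
    }
    stop(sprintf("isotopomer fixed point did not converge in %d iterations (residual %.3g)",
                 maxIter, delta))
}

#' Aggregate an isotopomer distribution to a compact tandem MS matrix
#'
#' Entry (m, k) sums the fractions of all isotopomers with exactly m labeled
#' atoms among the daughter atoms and k among the complement atoms (parent
#' atoms not in the daughter set); atoms outside the parent set are
#' marginalized over.
#'
#' @param dist isotopomer distribution (length 2^nAtoms)
#' @param parentAtoms integer parent atom indices
#' @param daughterAtoms subset of \code{parentAtoms} in the daughter fragment
#' @return a normalized \linkS4class{CompactTandemMatrix}
#' @export
aggregateToCompact <- function(dist, parentAtoms, daughterAtoms = integer()) {
    nAtoms <- as.integer(round(log2(length(dist))))
    stopifnot(2^nAtoms == length(dist), all(daughterAtoms %in% parentAtoms),
              all(parentAtoms >= 1L), all(parentAtoms <= nAtoms))
    compl <- setdiff(parentAtoms, daughterAtoms)
    out <- matrix(0, length(daughterAtoms) + 1L, length(compl) + 1L)
    for (b in 0:(2^nAtoms - 1L)) {
        bits <- bitwAnd(bitwShiftR(b, 0:(nAtoms - 1L)), 1L)
        m <- sum(bits[daughterAtoms])
        k <- sum(bits[compl])
        out[m + 1L, k + 1L] <- out[m + 1L, k + 1L] + dist[b + 1L]
    }
    compactTandemMatrix(out, normalized = abs(sum(out) - 1) <= .TOL_NORM)
}

#' Maximum discrepancy between the EMU cascade and the isotopomer oracle
#'
#' Runs both the EMU cascade and the brute-force isotopomer simulation for
#' every (parent, daughter) atom-subset pair of every metabolite up to
#' \code{maxSize} atoms, and reports the largest absolute difference between
#' the two compact tandem MS matrices.
#'
#' @param model a \linkS4class{NetworkModel}
#' @param fluxes named unidirectional flux map
#' @param tracers named list, input metabolite -> \linkS4class{TracerSpec}
#' @param maxSize largest parent atom-set size to check (default 3)
#' @param table an \linkS4class{ElementIsotopeTable}
#' @return maximum absolute discrepancy over all checked pairs
#' @export
verifyAgainstOracle <- function(model, fluxes, tracers, maxSize = 3L,
                                table = defaultIsotopeTable()) {
    inputDists <- lapply(tracers, tracerIsotopomers, table = table)
    oracle <- simulateIsotopomers(model, fluxes, inputDists[model@inputs])
    worst <- 0
    for (met in names(model@carbons)) {
        n <- model@carbons[[met]]
        subsets <- unlist(lapply(seq_len(min(n, maxSize)), function(s)
            utils::combn(n, s, simplify = FALSE)), recursive = FALSE)
        for (atoms in subsets) {
            dsubs <- unlist(lapply(0:length(atoms), function(s)
                utils::combn(length(atoms), s, simplify = FALSE)), recursive = FALSE)
            for (di in dsubs) {
                emu <- tandemEMU(met, atoms, atoms[di])
                emuMat <- simulateTandemEMU(model, emu, fluxes, tracers, table)
                oraMat <- aggregateToCompact(oracle[[met]], atoms, atoms[di])
                worst <- max(worst, max(abs(tandemValues(emuMat) - tandemValues(oraMat))))
            }
        }
    }
    worst
}
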