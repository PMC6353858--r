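# Correction of measured tandem MS data for natural isotope abundances by
# 2D-deconvolution: a structured least-squares inverse of the Q/S
# convolution applied in simulateMeasured().

#' Truncated convolution operators for natural-abundance correction
#'
#' Builds the lower-triangular Toeplitz operators C_Q (daughter axis) and
#' C_S (complement axis) from the natural-abundance MIDs of the fragment's
#' other-atom formulas, truncated to the measured window. Column j of each
#' operator is the corresponding MID shifted down by j.
#'
#' @param frag a \linkS4class{FragmentSpec}
#' @param measuredDim integer c(rows, cols) of the measured compact matrix
#' @param table an \linkS4class{ElementIsotopeTable}
#' @return list with matrices \code{CQ}, \code{CS} and the natural-abundance
#'   weights \code{lostQ}, \code{lostS} falling outside the measured window
#' @export
correctionOperators <- function(frag, measuredDim, table = defaultIsotopeTable()) {
    qs <- otherAtomFormulas(frag)
    nD <- length(frag@daughterCore)
    nK <- length(frag@coreAtoms) - nD
    qmid <- naturalMID(qs$Q, table)
    smid <- naturalMID(qs$S, table)
    CQ <- convOperator(qmid, measuredDim[1L], nD + 1L)
    CS <- convOperator(smid, measuredDim[2L], nK + 1L)
    list(CQ = CQ, CS = CS,
         lostQ = 1 - min(colSums(CQ)), lostS = 1 - min(colSums(CS)))
}

#' Correct a measured tandem MS matrix for natural isotope abundances
#'
#' Inverts the natural-abundance 2D-convolution of the fragment's non-core
#' atoms: finds the core-atom compact matrix X minimizing
#' ||C_Q X C_S' - M|| in least squares, where M is the measured compact
#' matrix and C_Q, C_S are the truncated convolution operators of the
#' daughter/complement other-atom formulas. When the measured window covers
#' the full convolution support this solve inverts
#' \code{\link{simulateMeasured}} exactly. Masses beyond the measured window
#' are treated as unobserved; a warning reports the natural-abundance weight
#' lost to truncation. Non-negativity is deliberately not enforced in the
#' solve — apply \code{\link{clipAndRenormalize}} to noisy results.
#'
#' @param measured measured \linkS4class{CompactTandemMatrix}; its window
#'   must be at least as large as the core window
#' @param frag a \linkS4class{FragmentSpec}
#' @param table an \linkS4class{ElementIsotopeTable}
#' @param renormalize rescale the result to sum 1 (default TRUE)
#' @return a \linkS4class{CompactTandemMatrix} of shape (core daughter
#'   atoms + 1) x (core complement atoms + 1); \code{metadata} carries the
#'   least-squares \code{residual} and truncation weights
#' @export
correctTandem <- function(measured, frag, table = defaultIsotopeTable(),
                          renormalize = TRUE) {
    stopifnot(is(measured, "CompactTandemMatrix"), is(frag, "FragmentSpec"))
    nD <- length(frag@daughterCore)
    nK <- length(frag@coreAtoms) - nD
    M <- measured@values
    if (nrow(M) < nD + 1L || ncol(M) < nK + 1L)
        stop(sprintf("measured window (%d x %d) smaller than core window (%d x %d)",
                     nrow(M), ncol(M), nD + 1L, nK + 1L))
    ops <- correctionOperators(frag, dim(M), table)
    if (max(ops$lostQ, ops$lostS) > 1e-9)
        warning(sprintf(
            "measured window truncates natural-abundance weight (Q: %.3g, S: %.3g); treated as unobserved",
            ops$lostQ, ops$lostS))
    K <- kronecker(ops$CS, ops$CQ)  # vec(CQ %*% X %*% t(CS)) = K %*% vec(X)
    qrK <- qr(K)
    if (qrK$rank < ncol(K))
        stop("correction operator is rank deficient; check fragment formulas")
    x <- qr.coef(qrK, as.vector(M))
    residual <- sqrt(sum((K %*% x - as.vector(M))^2))
    X <- matrix(x, nrow = nD + 1L)
    if (renormalize) X <- X / sum(X)
    # negatives can legitimately appear on noisy data; bypass the
    # non-negativity clamp of the public constructor
    new("CompactTandemMatrix", values = labelCompact(X),
        normalized = renormalize,
        metadata = list(residual = residual,
                        lostQ = ops$lostQ, lostS = ops$lostS))
}

#' Zero small negative entries and renormalize
#'
#' Noisy measured data can yield small negative entries after
#' deconvolution. Entries between \code{floor} and 0 are zeroed and the
#' matrix renormalized; anything below \code{floor} signals an inconsistent
#' measurement or fragment specification and raises an error.
#'
#' @param x a \linkS4class{CompactTandemMatrix}
#' @param floor most negative tolerated entry (default -1e-3)
#' @return a non-negative, normalized \linkS4class{CompactTandemMatrix}
#' @export
clipAndRenormalize <- function(x, floor = -1e-3) {
    stopifnot(is(x, "CompactTandemMatrix"), floor <= 0)
    v <- x@values
    if (min(v) < floor)
        stop(sprintf(
            "entry %.4g below floor %.4g: measurement inconsistent with fragment specification",
            min(v), floor))
    clipped <- v < 0
    if (any(clipped)) {
        warning(sprintf("clipped %d negative entries (max magnitude %.3g)",
                        sum(clipped), max(-v[clipped])))
        v[clipped] <- 0
    }
    v <- v / sum(v)
    new("CompactTandemMatrix", values = labelCompact(v), normalized = TRUE,
        metadata = x@metadata)
}
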