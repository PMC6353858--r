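# The compact tandem MS matrix type, full <-> compact conversion, marginals,
# and the elementary 2D-convolution step used to build a fragment atom by atom.

## full 2D discrete convolution
conv2Mat <- function(A, B) {
    out <- matrix(0, nrow(A) + nrow(B) - 1L, ncol(A) + ncol(B) - 1L)
    for (i in seq_len(nrow(B))) {
        for (j in seq_len(ncol(B))) {
            b <- B[i, j]
            if (b == 0) next
            ri <- (i - 1L) + seq_len(nrow(A))
            ci <- (j - 1L) + seq_len(ncol(A))
            out[ri, ci] <- out[ri, ci] + A * b
        }
    }
    out
}

labelCompact <- function(v) {
    dimnames(v) <- list(paste0("m", seq_len(nrow(v)) - 1L),
                        paste0("k", seq_len(ncol(v)) - 1L))
    v
}

labelFull <- function(v) {
    dimnames(v) <- list(paste0("m", seq_len(nrow(v)) - 1L),
                        paste0("M", seq_len(ncol(v)) - 1L))
    v
}

#' Construct a compact tandem MS matrix
#'
#' Rows index the daughter mass shift m = 0..d and columns the complement
#' mass shift k = 0..c (parent shift M = m + k). Entries below -1e-9 are
#' rejected; tiny negative round-off is clamped to zero.
#'
#' @param values numeric matrix (a plain vector is taken as a single row)
#' @param normalized logical or NA; NA flags the matrix as normalized when
#'   its entries sum to 1 within 1e-9
#' @param metadata optional list of provenance values
#' @return a \linkS4class{CompactTandemMatrix}
#' @export
compactTandemMatrix <- function(values, normalized = NA, metadata = list()) {
    if (!is.matrix(values)) values <- matrix(values, nrow = 1L)
    if (any(values < -.TOL_NORM))
        stop("negative entries in compact tandem MS matrix")
    values[values < 0] <- 0
    if (is.na(normalized)) normalized <- abs(sum(values) - 1) <= .TOL_NORM
    new("CompactTandemMatrix", values = labelCompact(values),
        normalized = normalized, metadata = metadata)
}

#' Construct a full tandem MS matrix
#'
#' Rows index the daughter mass shift m = 0..d, columns the parent mass shift
#' M = 0..p. Cells with M < m or M > m + (p - d) are infeasible by
#' definition; values there above 1e-9 raise a structural error, smaller
#' ones are silently zeroed.
#'
#' @inheritParams compactTandemMatrix
#' @return a \linkS4class{TandemMSMatrix}
#' @export
tandemMSMatrix <- function(values, normalized = NA) {
    if (!is.matrix(values)) values <- matrix(values, nrow = 1L)
    d <- nrow(values) - 1L; p <- ncol(values) - 1L
    if (p < d) stop("parent size must be >= daughter size")
    for (m in 0:d) {
        feas <- (0:p) >= m & (0:p) <= m + (p - d)
        bad <- abs(values[m + 1L, ]) > .TOL_NORM & !feas
        if (any(bad))
            stop(sprintf("nonzero entry in infeasible cell (m=%d, M=%d)",
                         m, which(bad)[1L] - 1L))
        values[m + 1L, !feas] <- 0
    }
    if (any(values < -.TOL_NORM)) stop("negative entries in tandem MS matrix")
    values[values < 0] <- 0
    if (is.na(normalized)) normalized <- abs(sum(values) - 1) <= .TOL_NORM
    new("TandemMSMatrix", values = labelFull(values), normalized = normalized)
}

#' @rdname tandemValues
#' @param x a tandem MS matrix object
#' @export
setMethod("tandemValues", "CompactTandemMatrix", function(x) x@values)

#' @rdname tandemValues
#' @export
setMethod("tandemValues", "TandemMSMatrix", function(x) x@values)

#' @rdname tandemValues
#' @export
setMethod("isNormalized", "CompactTandemMatrix", function(x) x@normalized)

#' @rdname tandemValues
#' @export
setMethod("isNormalized", "TandemMSMatrix", function(x) x@normalized)

#' Mass-shift capacities of tandem MS matrices
#'
#' \code{daughterSize}, \code{complementSize} and \code{parentSize} return
#' the maximum representable daughter, complement and parent mass shifts.
#'
#' @param x a tandem MS matrix object
#' @return integer mass-shift capacity
#' @name tandemDims
NULL

#' @rdname tandemDims
#' @export
setMethod("daughterSize", "CompactTandemMatrix", function(x) nrow(x@values) - 1L)

#' @rdname tandemDims
#' @export
setMethod("complementSize", "CompactTandemMatrix", function(x) ncol(x@values) - 1L)

#' @rdname tandemDims
#' @export
setMethod("parentSize", "CompactTandemMatrix",
    function(x) nrow(x@values) + ncol(x@values) - 2L)

#' @rdname tandemDims
#' @export
setMethod("daughterSize", "TandemMSMatrix", function(x) nrow(x@values) - 1L)

#' @rdname tandemDims
#' @export
setMethod("parentSize", "TandemMSMatrix", function(x) ncol(x@values) - 1L)

#' @rdname tandemDims
#' @export
setMethod("complementSize", "TandemMSMatrix",
    function(x) ncol(x@values) - nrow(x@values))

#' Convert between full and compact tandem MS matrices
#'
#' \code{toCompact} shifts the rows of a full tandem MS matrix left so that
#' column k holds the complement mass shift: \code{compact[m, k] =
#' full[m, m + k]}. \code{toFull} is the exact inverse.
#'
#' @param x the matrix to convert
#' @param ... unused
#' @return the converted matrix object
#' @name compaction
NULL

#' @rdname compaction
#' @export
setMethod("toCompact", "TandemMSMatrix", function(x, ...) {
    v <- x@values
    d <- nrow(v) - 1L; p <- ncol(v) - 1L
    out <- matrix(0, d + 1L, p - d + 1L)
    for (m in 0:d) out[m + 1L, ] <- v[m + 1L, m + seq_len(p - d + 1L)]
    compactTandemMatrix(out, normalized = x@normalized)
})

#' @rdname compaction
#' @param parentSize total parent mass-shift capacity; must equal
#'   daughter size + complement size
#' @export
setMethod("toFull", "CompactTandemMatrix", function(x, parentSize = NULL, ...) {
    v <- x@values
    d <- nrow(v) - 1L; k <- ncol(v) - 1L
    if (is.null(parentSize)) parentSize <- d + k
    if (parentSize != d + k)
        stop(sprintf("parentSize must equal daughter size + complement size (%d)", d + k))
    out <- matrix(0, d + 1L, parentSize + 1L)
    for (m in 0:d) out[m + 1L, m + seq_len(k + 1L)] <- v[m + 1L, ]
    tandemMSMatrix(out, normalized = x@normalized)
})

#' Marginal distributions of a tandem MS matrix
#'
#' \code{parentMarginal} sums the compact matrix along its anti-diagonals
#' (parent shift M = m + k), \code{daughterMarginal} over rows, and
#' \code{complementMarginal} over columns.
#'
#' @param x a tandem MS matrix object
#' @return numeric MID vector
#' @name marginals
NULL

#' @rdname marginals
#' @export
setMethod("parentMarginal", "CompactTandemMatrix", function(x) {
    v <- x@values
    d <- nrow(v) - 1L; k <- ncol(v) - 1L
    out <- numeric(d + k + 1L)
    for (m in 0:d)
        for (j in 0:k) out[m + j + 1L] <- out[m + j + 1L] + v[m + 1L, j + 1L]
    out
})

#' @rdname marginals
#' @export
setMethod("parentMarginal", "TandemMSMatrix", function(x) unname(colSums(x@values)))

#' @rdname marginals
#' @export
setMethod("daughterMarginal", "CompactTandemMatrix", function(x) unname(rowSums(x@values)))

#' @rdname marginals
#' @export
setMethod("daughterMarginal", "TandemMSMatrix", function(x) unname(rowSums(x@values)))

#' @rdname marginals
#' @export
setMethod("complementMarginal", "CompactTandemMatrix", function(x) unname(colSums(x@values)))

#' 2D-convolve a compact tandem MS matrix with one atom's MID
#'
#' The elementary step of tandem MS simulation: the atom's MID is applied
#' along the daughter (row) axis when the atom belongs to the daughter
#' fragment — i.e. convolution with the transposed MID vector — and along the
#' complement (column) axis otherwise.
#'
#' @param x a normalized \linkS4class{CompactTandemMatrix}
#' @param atomMID normalized MID vector of the atom
#' @param inDaughter logical; is the atom part of the daughter fragment?
#' @return the grown \linkS4class{CompactTandemMatrix}
#' @export
conv2Atom <- function(x, atomMID, inDaughter) {
    stopifnot(is(x, "CompactTandemMatrix"), is.numeric(atomMID),
              is.logical(inDaughter), length(inDaughter) == 1L)
    kern <- if (inDaughter) matrix(atomMID, ncol = 1L) else matrix(atomMID, nrow = 1L)
    out <- conv2Mat(x@values, kern)
    s <- sum(out)
    if (x@normalized && abs(s - 1) <= 1e-6 && s > 0) out <- out / s
    compactTandemMatrix(out, normalized = x@normalized && abs(sum(out) - 1) <= .TOL_NORM)
}

#' 2D-convolve two compact tandem MS matrices
#'
#' Joint distribution of the condensation of two fragments: daughter shifts
#' and complement shifts add independently, so the compact matrices combine
#' by full 2D discrete convolution.
#'
#' @param a,b \linkS4class{CompactTandemMatrix} objects
#' @return their 2D convolution
#' @export
convolveCompact <- function(a, b) {
    stopifnot(is(a, "CompactTandemMatrix"), is(b, "CompactTandemMatrix"))
    out <- conv2Mat(a@values, b@values)
    s <- sum(out)
    norm <- a@normalized && b@normalized
    if (norm && abs(s - 1) <= 1e-6 && s > 0) out <- out / s
    compactTandemMatrix(out, normalized = norm && abs(sum(out) - 1) <= .TOL_NORM)
}

#' Transpose a compact tandem MS matrix
#'
#' Swaps the daughter and complement orientation; used when an EMU stored in
#' complement orientation is consumed as a daughter-side educt.
#'
#' @param x a \linkS4class{CompactTandemMatrix}
#' @export
setMethod("t", "CompactTandemMatrix", function(x) {
    new("CompactTandemMatrix", values = labelCompact(t(x@values)),
        normalized = x@normalized, metadata = x@metadata)
})

fmtNum <- function(x) formatC(x, digits = 12, format = "g")

#' Write a tandem MS matrix to CSV
#'
#' Compact matrices use column headers \code{k0,k1,...}, full matrices
#' \code{M0,M1,...}; the first column holds the daughter shifts
#' \code{m0,m1,...}. Values are decimal fractions with 12 significant digits.
#'
#' @param x a tandem MS matrix object
#' @param path output file path
#' @export
writeTandemCSV <- function(x, path) {
    v <- tandemValues(x)
    out <- matrix(fmtNum(v), nrow(v), dimnames = dimnames(v))
    df <- data.frame(out, check.names = FALSE)
    utils::write.table(df, path, sep = ",", quote = FALSE,
                       col.names = NA, row.names = TRUE)
    invisible(path)
}

#' Read a tandem MS matrix from CSV
#'
#' The compact/full form is detected from the column-header prefix
#' (\code{k} or \code{M}).
#'
#' @param path CSV file path
#' @param normalized passed to the constructor (NA = auto-detect)
#' @return a \linkS4class{CompactTandemMatrix} or \linkS4class{TandemMSMatrix}
#' @export
readTandemCSV <- function(path, normalized = NA) {
    df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
    v <- as.matrix(df)
    if (all(grepl("^k", colnames(v)))) compactTandemMatrix(unname(v), normalized)
    else if (all(grepl("^M", colnames(v)))) tandemMSMatrix(unname(v), normalized)
    else stop("unrecognized tandem matrix CSV header (expected k0.. or M0..)")
}

setMethod("show", "CompactTandemMatrix", function(object) {
    cat(sprintf("CompactTandemMatrix (daughter size %d, complement size %d%s)\n",
                daughterSize(object), complementSize(object),
                if (object@normalized) ", normalized" else ""))
    print(round(object@values, 6))
})

setMethod("show", "TandemMSMatrix", function(object) {
    cat(sprintf("TandemMSMatrix (daughter size %d, parent size %d%s)\n",
                daughterSize(object), parentSize(object),
                if (object@normalized) ", normalized" else ""))
    print(round(object@values, 6))
})
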