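# 1D machinery: chemical formulas, element isotope tables, and mass
# isotopomer distributions (MIDs) built atom-by-atom by convolution.

`%||%` <- function(a, b) if (is.null(a)) b else a

## discrete linear convolution, length |a| + |b| - 1
convSeq <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1L)
    for (i in seq_along(a)) {
        if (a[i] == 0) next
        idx <- (i - 1L) + seq_along(b)
        out[idx] <- out[idx] + a[i] * b
    }
    out
}

#' Parse a chemical formula string
#'
#' Parses flat element-count formulas as printed for MS fragments (e.g.
#' \code{"C18H40O4NSi3"}). Element symbols are a capital letter plus optional
#' lowercase letters; an omitted count means 1. No parentheses or charges.
#'
#' @param text a single formula string; \code{""} gives the empty formula
#' @return named numeric vector, element -> count
#' @examples
#' parseFormula("C18H40O4NSi3")
#' @export
parseFormula <- function(text) {
    if (!is.character(text) || length(text) != 1L || is.na(text))
        stop("formula must be a single character string")
    counts <- numeric(0)
    pos <- 1L
    n <- nchar(text)
    while (pos <= n) {
        rest <- substring(text, pos)
        m <- regmatches(rest, regexec("^([A-Z][a-z]*)([0-9]*)", rest))[[1L]]
        if (length(m) == 0L || m[1L] == "")
            stop(sprintf("malformed formula '%s' at position %d", text, pos))
        elem <- m[2L]
        cnt <- if (m[3L] == "") 1 else as.numeric(m[3L])
        counts[elem] <- (if (elem %in% names(counts)) counts[[elem]] else 0) + cnt
        pos <- pos + nchar(m[1L])
    }
    counts
}

asFormula <- function(f) {
    if (is.character(f)) return(parseFormula(f))
    if (is.null(f)) return(numeric(0))
    stopifnot(is.numeric(f))
    if (length(f) && (is.null(names(f)) || any(!nzchar(names(f)))))
        stop("formula vector must be named by element symbol")
    if (any(f < 0) || any(f != round(f))) stop("element counts must be non-negative integers")
    f[f > 0]
}

#' Format a formula as a string
#'
#' @param f named element-count vector (or formula string)
#' @return a single string, elements in Hill-like order (C, H, then others
#'   alphabetically)
#' @export
formulaToString <- function(f) {
    f <- asFormula(f)
    if (!length(f)) return("")
    els <- names(f)
    ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
    paste0(vapply(ord, function(el) {
        paste0(el, if (f[[el]] == 1) "" else format(f[[el]]))
    }, ""), collapse = "")
}

## elementwise formula arithmetic; subtraction errors on negative counts
formulaAdd <- function(a, b) {
    a <- asFormula(a); b <- asFormula(b)
    els <- union(names(a), names(b))
    out <- vapply(els, function(el) {
        (if (el %in% names(a)) a[[el]] else 0) + (if (el %in% names(b)) b[[el]] else 0)
    }, 0)
    out[out > 0]
}

formulaSubtract <- function(a, b, context = "formula difference") {
    a <- asFormula(a); b <- asFormula(b)
    els <- union(names(a), names(b))
    out <- vapply(els, function(el) {
        (if (el %in% names(a)) a[[el]] else 0) - (if (el %in% names(b)) b[[el]] else 0)
    }, 0)
    if (any(out < 0))
        stop(sprintf("%s has negative count for element(s): %s", context,
                     paste(els[out < 0], collapse = ", ")))
    out[out > 0]
}

#' Construct an element isotope table
#'
#' @param abundances named list of numeric abundance vectors indexed by mass
#'   shift (M+0, M+1, ...); each must sum to 1
#' @param baseMass named numeric vector of base nominal masses (amu)
#' @return an \linkS4class{ElementIsotopeTable}
#' @export
isotopeTable <- function(abundances, baseMass) {
    new("ElementIsotopeTable", abundances = abundances,
        baseMass = baseMass[names(abundances)])
}

#' Read an isotope table from CSV
#'
#' The CSV has columns \code{element}, \code{base_mass}, and abundance
#' columns \code{a0}, \code{a1}, ... (trailing empty cells allowed).
#'
#' @param path CSV file path
#' @return an \linkS4class{ElementIsotopeTable}
#' @export
readIsotopeTable <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    acols <- grep("^a[0-9]+$", names(df), value = TRUE)
    acols <- acols[order(as.integer(sub("^a", "", acols)))]
    ab <- lapply(seq_len(nrow(df)), function(i) {
        v <- as.numeric(df[i, acols])
        n <- max(which(!is.na(v)))
        v <- v[seq_len(n)]
        v[is.na(v)] <- 0
        v
    })
    names(ab) <- df$element
    isotopeTable(ab, stats::setNames(as.numeric(df$base_mass), df$element))
}

#' Default natural isotope abundance table
#'
#' Standard natural abundances for C, H, N, O, Si and S, shipped with the
#' package as \code{extdata/isotopes.csv}. The S and O M+2 abundances print
#' as 4.2\% and 0.2\% when rounded to one decimal.
#'
#' @return an \linkS4class{ElementIsotopeTable}
#' @export
defaultIsotopeTable <- function() {
    if (is.null(.pkgCache$isotopes))
        .pkgCache$isotopes <- readIsotopeTable(
            system.file("extdata", "isotopes.csv", package = "tandemEMU",
                        mustWork = TRUE))
    .pkgCache$isotopes
}

.pkgCache <- new.env(parent = emptyenv())

elementAbundance <- function(table, el) {
    if (!el %in% names(table@abundances))
        stop(sprintf("unknown element symbol '%s' (not in isotope table)", el))
    table@abundances[[el]]
}

#' Nominal (monoisotopic integer) mass of a formula
#'
#' @param f formula string or named element-count vector
#' @param table an \linkS4class{ElementIsotopeTable}
#' @return integer nominal mass in amu
#' @examples
#' nominalMass("C18H40O4NSi3")  # 418
#' @export
nominalMass <- function(f, table = defaultIsotopeTable()) {
    f <- asFormula(f)
    if (!length(f)) return(0)
    for (el in names(f)) elementAbundance(table, el)  # element check
    sum(f * table@baseMass[names(f)])
}

#' Natural-abundance mass isotopomer distribution of a formula
#'
#' Builds the MID of a molecule atom-by-atom by a series of discrete
#' convolutions of single-atom isotope abundance vectors. When
#' \code{maxShift} is given the vector is truncated WITHOUT renormalization,
#' so entries remain absolute probabilities of each mass shift.
#'
#' @param f formula string or named element-count vector
#' @param table an \linkS4class{ElementIsotopeTable}
#' @param maxShift optional maximum mass shift to retain
#' @return numeric MID vector indexed by mass shift 0..n
#' @examples
#' round(100 * naturalMID("S")[3], 1)  # 4.2 (% M+2 of sulfur)
#' @export
naturalMID <- function(f, table = defaultIsotopeTable(), maxShift = NULL) {
    f <- asFormula(f)
    mid <- 1
    for (el in names(f)) {
        a <- elementAbundance(table, el)
        for (i in seq_len(f[[el]])) mid <- convSeq(mid, a)
    }
    if (!is.null(maxShift)) {
        stopifnot(maxShift >= 0)
        n <- maxShift + 1L
        mid <- if (length(mid) >= n) mid[seq_len(n)] else c(mid, numeric(n - length(mid)))
    }
    mid
}

#' Convolve two normalized MID vectors
#'
#' Full discrete linear convolution of length |a| + |b| - 1; the result is
#' renormalized to remove floating-point drift.
#'
#' @param a,b normalized MID vectors
#' @return normalized MID vector
#' @export
convolveMID <- function(a, b) {
    for (v in list(a, b))
        if (abs(sum(v) - 1) > 1e-6 || any(v < -.TOL_NORM))
            stop("convolveMID expects normalized MID vectors")
    out <- convSeq(a, b)
    out / sum(out)
}

#' Least-squares deconvolution of a MID
#'
#' Inverts \code{convolveMID} for a known kernel: finds the length-
#' \code{outLength} vector x minimizing ||C x - measured|| where C is the
#' truncated lower-triangular (Toeplitz) convolution operator of \code{mid}.
#'
#' @param measured measured MID vector (possibly truncated)
#' @param mid the natural-abundance kernel to remove
#' @param outLength length of the corrected vector
#' @param renormalize rescale the result to sum 1 (default TRUE)
#' @return corrected MID vector with attribute \code{"residual"}
#' @export
deconvolveMID <- function(measured, mid, outLength, renormalize = TRUE) {
    C <- convOperator(mid, length(measured), outLength)
    qr_ <- qr(C)
    if (qr_$rank < outLength) stop("deconvolution operator is rank deficient")
    x <- qr.coef(qr_, measured)
    res <- sqrt(sum((C %*% x - measured)^2))
    if (renormalize) x <- x / sum(x)
    attr(x, "residual") <- res
    x
}

## truncated convolution operator: column j is `mid` shifted down by j-1
convOperator <- function(mid, nOut, nIn) {
    C <- matrix(0, nOut, nIn)
    for (j in seq_len(nIn)) {
        i <- (j - 1L) + seq_along(mid)
        keep <- i <= nOut
        C[i[keep], j] <- mid[keep]
    }
    C
}

setMethod("show", "ElementIsotopeTable", function(object) {
    cat(sprintf("ElementIsotopeTable with %d elements: %s\n",
                length(object@abundances),
                paste(names(object@abundances), collapse = ", ")))
})
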