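#' tandemEMU: tandem MS simulation and correction for 13C-MFA
#'
#' Simulation of compact tandem MS matrices by 2D-convolution, correction of
#' measured tandem MS data for natural isotope abundances by 2D-deconvolution,
#' EMU decomposition of atom-transition networks with daughter-fragment atom
#' tracking, cascade solving of EMU balance equations, a brute-force
#' isotopomer oracle, and least-squares flux estimation.
#'
#' @import methods
#' @importFrom stats setNames
#' @importFrom utils read.csv write.table
#' @name tandemEMU-package
#' @aliases tandemEMU
#' @keywords internal
NULL

.TOL_NORM <- 1e-9

#' Element isotope abundance table
#'
#' Holds, per element symbol, the vector of natural fractional isotope
#' abundances indexed by integer mass shift (M+0, M+1, ...) together with the
#' base nominal mass of the lightest isotope.
#'
#' @slot abundances named list of numeric vectors; each sums to 1
#' @slot baseMass named numeric vector of integer nominal masses (amu)
#' @exportClass ElementIsotopeTable
setClass("ElementIsotopeTable",
    representation(abundances = "list", baseMass = "numeric"))

setValidity("ElementIsotopeTable", function(object) {
    msgs <- character()
    if (!identical(sort(names(object@abundances)), sort(names(object@baseMass))))
        msgs <- c(msgs, "abundances and baseMass must cover the same elements")
    for (el in names(object@abundances)) {
        v <- object@abundances[[el]]
        if (any(v < 0) || any(v > 1))
            msgs <- c(msgs, sprintf("abundances of '%s' outside [0, 1]", el))
        if (abs(sum(v) - 1) > .TOL_NORM)
            msgs <- c(msgs, sprintf("abundances of '%s' do not sum to 1", el))
    }
    if (any(object@baseMass < 0) || any(object@baseMass != round(object@baseMass)))
        msgs <- c(msgs, "base masses must be non-negative integers")
    if (length(msgs)) msgs else TRUE
})

#' Full tandem MS matrix
#'
#' Joint mass-shift distribution of a parent/daughter fragment pair: rows are
#' daughter mass shifts m = 0..d, columns are parent mass shifts M = 0..p.
#' Cells with M < m or M > m + (p - d) are infeasible by definition and hold
#' exact zeros.
#'
#' @slot values numeric matrix, (d+1) x (p+1)
#' @slot normalized logical; TRUE when the entries sum to 1
#' @exportClass TandemMSMatrix
setClass("TandemMSMatrix",
    representation(values = "matrix", normalized = "logical"))

setValidity("TandemMSMatrix", function(object) {
    v <- object@values
    msgs <- character()
    if (!is.numeric(v) || anyNA(v)) msgs <- c(msgs, "values must be numeric without NA")
    if (nrow(v) < 1L || ncol(v) < 1L) msgs <- c(msgs, "matrix must be at least 1 x 1")
    if (ncol(v) < nrow(v)) msgs <- c(msgs, "parent size must be >= daughter size")
    if (is.numeric(v) && any(v < 0)) msgs <- c(msgs, "entries must be non-negative")
    d <- nrow(v) - 1L; p <- ncol(v) - 1L
    for (m in 0:d) {
        feas <- (0:p) >= m & (0:p) <= m + (p - d)
        if (any(v[m + 1L, !feas] != 0))
            msgs <- c(msgs, "nonzero entry in an infeasible cell")
    }
    if (isTRUE(object@normalized) && abs(sum(v) - 1) > .TOL_NORM)
        msgs <- c(msgs, "flagged normalized but entries do not sum to 1")
    if (length(msgs)) msgs else TRUE
})

#' Compact tandem MS matrix
#'
#' Row-shifted form of the full tandem MS matrix with the infeasible cells
#' removed: rows are daughter mass shifts m = 0..d, columns are complement
#' mass shifts k = 0..c, so the parent mass shift is M = m + k. This is the
#' state variable used throughout simulation, correction, and EMU balancing.
#'
#' @slot values numeric matrix, (d+1) x (c+1)
#' @slot normalized logical; TRUE when the entries sum to 1
#' @slot metadata list; computational provenance (e.g. deconvolution residual)
#' @exportClass CompactTandemMatrix
setClass("CompactTandemMatrix",
    representation(values = "matrix", normalized = "logical",
                   metadata = "list"),
    prototype(metadata = list()))

setValidity("CompactTandemMatrix", function(object) {
    v <- object@values
    msgs <- character()
    if (!is.numeric(v) || anyNA(v)) msgs <- c(msgs, "values must be numeric without NA")
    if (nrow(v) < 1L || ncol(v) < 1L) msgs <- c(msgs, "matrix must be at least 1 x 1")
    if (isTRUE(object@normalized) && abs(sum(v) - 1) > .TOL_NORM)
        msgs <- c(msgs, "flagged normalized but entries do not sum to 1")
    if (length(msgs)) msgs else TRUE
})

#' Fragment specification for a parent/daughter pair
#'
#' Describes a (possibly derivatized) parent fragment, its daughter fragment,
#' and which core carbon atoms of the measured metabolite each contains. The
#' non-core ("other") atoms of the daughter and of the complement fragment
#' are derived from the formulas and drive natural-abundance convolution and
#' correction.
#'
#' @slot metabolite metabolite identifier
#' @slot parentFormula named integer vector, element -> count
#' @slot daughterFormula named integer vector, element -> count
#' @slot coreAtoms integer indices of the metabolite's core carbon atoms
#'   contained in the parent fragment
#' @slot daughterCore subset of \code{coreAtoms} contained in the daughter
#' @exportClass FragmentSpec
setClass("FragmentSpec",
    representation(metabolite = "character", parentFormula = "numeric",
                   daughterFormula = "numeric", coreAtoms = "integer",
                   daughterCore = "integer"))

setValidity("FragmentSpec", function(object) {
    msgs <- character()
    if (length(object@metabolite) != 1L) msgs <- c(msgs, "metabolite must be a single id")
    if (anyDuplicated(object@coreAtoms)) msgs <- c(msgs, "core atom indices must be unique")
    if (!all(object@daughterCore %in% object@coreAtoms))
        msgs <- c(msgs, "daughter core atoms must be a subset of the core atoms")
    for (el in names(object@daughterFormula)) {
        pc <- if (el %in% names(object@parentFormula)) object@parentFormula[[el]] else 0
        if (object@daughterFormula[[el]] > pc)
            msgs <- c(msgs, sprintf("daughter formula exceeds parent formula for '%s'", el))
    }
    qs <- tryCatch(otherAtomFormulas(object), error = function(e) e)
    if (inherits(qs, "error")) msgs <- c(msgs, conditionMessage(qs))
    if (length(msgs)) msgs else TRUE
})

#' Positional tracer specification
#'
#' Per core carbon atom: whether the position is 13C-labeled and at what
#' isotopic purity. Unlabeled positions carry either the natural carbon
#' isotope distribution (background "natural") or pure 12C (background
#' "pure").
#'
#' @slot nAtoms number of core carbon atoms
#' @slot labeled logical vector, length nAtoms
#' @slot purity numeric vector in [0,1], length nAtoms (used where labeled)
#' @slot background "natural" or "pure"
#' @exportClass TracerSpec
setClass("TracerSpec",
    representation(nAtoms = "integer", labeled = "logical",
                   purity = "numeric", background = "character"))

setValidity("TracerSpec", function(object) {
    msgs <- character()
    if (length(object@labeled) != object@nAtoms || length(object@purity) != object@nAtoms)
        msgs <- c(msgs, "labeled and purity must have length nAtoms")
    if (any(object@purity < 0) || any(object@purity > 1))
        msgs <- c(msgs, "purities must lie in [0, 1]")
    if (!object@background %in% c("natural", "pure"))
        msgs <- c(msgs, "background must be 'natural' or 'pure'")
    if (length(msgs)) msgs else TRUE
})

#' A reaction with atom transitions
#'
#' @slot id reaction identifier
#' @slot educts list of list(met=, labels=) with per-atom label letters
#' @slot products list of list(met=, labels=)
#' @slot reversible logical
#' @exportClass Reaction
setClass("Reaction",
    representation(id = "character", educts = "list", products = "list",
                   reversible = "logical"))

setValidity("Reaction", function(object) {
    lab <- function(side) unlist(lapply(side, `[[`, "labels"))
    el <- lab(object@educts); pl <- lab(object@products)
    msgs <- character()
    if (anyDuplicated(el) || anyDuplicated(pl))
        msgs <- c(msgs, sprintf("reaction %s: atom labels not unique within a side", object@id))
    if (!identical(sort(el), sort(pl)))
        msgs <- c(msgs, sprintf("reaction %s: atom labels not conserved", object@id))
    if (length(msgs)) msgs else TRUE
})

#' Atom-transition network model
#'
#' @slot reactions list of \linkS4class{Reaction}
#' @slot carbons named numeric vector, metabolite -> carbon count
#' @slot inputs substrate (network input) metabolite ids
#' @slot outputs product (network output) metabolite ids
#' @exportClass NetworkModel
setClass("NetworkModel",
    representation(reactions = "list", carbons = "numeric",
                   inputs = "character", outputs = "character"))

setValidity("NetworkModel", function(object) {
    msgs <- character()
    for (rx in object@reactions) {
        for (term in c(rx@educts, rx@products)) {
            if (object@carbons[[term$met]] != length(term$labels))
                msgs <- c(msgs, sprintf(
                    "metabolite %s: inconsistent carbon count in reaction %s",
                    term$met, rx@id))
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' Tandem EMU: an atom set with daughter-atom marks
#'
#' Identifies one EMU state variable for tandem MS simulation: a metabolite,
#' the parent atom index set, and the subset of those atoms contained in the
#' daughter fragment.
#'
#' @slot metabolite metabolite id
#' @slot atoms sorted integer vector of parent atom indices (size >= 1)
#' @slot daughter subset of \code{atoms} marked as daughter atoms
#' @exportClass TandemEMU
setClass("TandemEMU",
    representation(metabolite = "character", atoms = "integer",
                   daughter = "integer"))

setValidity("TandemEMU", function(object) {
    msgs <- character()
    if (length(object@atoms) < 1L) msgs <- c(msgs, "EMU must contain at least one atom")
    if (is.unsorted(object@atoms, strictly = TRUE)) msgs <- c(msgs, "atoms must be strictly increasing")
    if (!all(object@daughter %in% object@atoms)) msgs <- c(msgs, "daughter atoms must be a subset of the EMU atoms")
    if (length(msgs)) msgs else TRUE
})

#' EMU reaction (after pairwise reduction)
#'
#' @slot flux unidirectional flux id carrying the reaction
#' @slot educts list of \linkS4class{TandemEMU} (canonical form)
#' @slot eductTransposed logical; whether each educt's stored compact matrix
#'   must be transposed at the point of use
#' @slot product \linkS4class{TandemEMU}
#' @exportClass EMUReaction
setClass("EMUReaction",
    representation(flux = "character", educts = "list",
                   eductTransposed = "logical", product = "TandemEMU"))

#' EMU system produced by network decomposition
#'
#' @slot target the requested target EMU (as given)
#' @slot targetId canonical id of the target
#' @slot targetTransposed whether the canonical target matrix must be
#'   transposed to obtain the requested orientation
#' @slot emus named list of all canonical EMUs, keyed by \code{emuId}
#' @slot reactions list of \linkS4class{EMUReaction}
#' @slot knownIds ids of input-metabolite EMUs (the known boundary)
#' @exportClass EMUSystem
setClass("EMUSystem",
    representation(target = "TandemEMU", targetId = "character",
                   targetTransposed = "logical", emus = "list",
                   reactions = "list", knownIds = "character"))

#' Result of a least-squares flux fit
#'
#' @slot estimates named numeric vector of fitted free fluxes
#' @slot fluxes full unidirectional flux map at the optimum
#' @slot rss residual sum of squares
#' @slot converged logical
#' @slot iterations number of solver iterations
#' @slot message solver termination message
#' @exportClass FitResult
setClass("FitResult",
    representation(estimates = "numeric", fluxes = "numeric", rss = "numeric",
                   converged = "logical", iterations = "integer",
                   message = "character"))
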