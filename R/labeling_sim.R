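# Forward simulation of compact tandem MS matrices for positionally labeled
# tracers and derivatized fragments.

#' Construct a fragment specification
#'
#' @param metabolite metabolite identifier
#' @param parentFormula parent fragment formula (string or named vector)
#' @param daughterFormula daughter fragment formula
#' @param coreAtoms ordered indices of the metabolite's core carbon atoms
#'   contained in the parent fragment
#' @param daughterCore subset of \code{coreAtoms} contained in the daughter
#' @return a \linkS4class{FragmentSpec}
#' @examples
#' ## TBDMS-derivatized aspartate, parent m/z 418 > daughter m/z 244
#' fragmentSpec("ASP", "C18H40O4NSi3", "C10H22O2NSi2", 1:4, 1:2)
#' @export
fragmentSpec <- function(metabolite, parentFormula, daughterFormula,
                         coreAtoms, daughterCore) {
    new("FragmentSpec", metabolite = metabolite,
        parentFormula = asFormula(parentFormula),
        daughterFormula = asFormula(daughterFormula),
        coreAtoms = as.integer(coreAtoms),
        daughterCore = as.integer(daughterCore))
}

#' Other-atom formulas of the daughter and complement fragments
#'
#' The daughter fragment consists of its core carbon atoms plus "other"
#' atoms (formula Q); the complement fragment — the part of the parent not in
#' the daughter — likewise has other atoms (formula S). Q and S drive the
#' natural-abundance convolution and its inverse, the correction.
#'
#' @param frag a \linkS4class{FragmentSpec}
#' @return list with named element-count vectors \code{Q} and \code{S}
#' @export
otherAtomFormulas <- function(frag) {
    nD <- length(frag@daughterCore)
    nK <- length(frag@coreAtoms) - nD
    Q <- formulaSubtract(frag@daughterFormula, c(C = nD),
                         context = "daughter other-atom formula (Q)")
    compl <- formulaSubtract(frag@parentFormula, frag@daughterFormula,
                             context = "complement fragment formula")
    S <- formulaSubtract(compl, c(C = nK),
                         context = "complement other-atom formula (S)")
    list(Q = Q, S = S)
}

#' Construct a positional tracer specification
#'
#' @param nAtoms number of core carbon atoms of the metabolite
#' @param positions integer positions that are 13C-labeled
#' @param purity isotopic purity of the labeled positions (scalar or one per
#'   position)
#' @param background isotope content of unlabeled positions: \code{"natural"}
#'   (natural carbon MID, the default) or \code{"pure"} (pure 12C)
#' @return a \linkS4class{TracerSpec}
#' @examples
#' tracerSpec(4, c(1, 4), purity = 0.99)  # [1,4-13C] tracer
#' @export
tracerSpec <- function(nAtoms, positions = integer(),
                       purity = 1, background = c("natural", "pure")) {
    background <- match.arg(background)
    nAtoms <- as.integer(nAtoms)
    labeled <- rep(FALSE, nAtoms)
    labeled[as.integer(positions)] <- TRUE
    pur <- rep(0, nAtoms)
    pur[as.integer(positions)] <- purity
    new("TracerSpec", nAtoms = nAtoms, labeled = labeled, purity = pur,
        background = background)
}

## per-atom 2-entry MID vectors [P(12C), P(13C)] for the core carbon atoms
atomMIDs <- function(tracer, table = defaultIsotopeTable()) {
    natural <- elementAbundance(table, "C")
    lapply(seq_len(tracer@nAtoms), function(i) {
        if (tracer@labeled[i]) c(1 - tracer@purity[i], tracer@purity[i])
        else if (tracer@background == "natural") natural
        else c(1, 0)
    })
}

#' Simulate the compact tandem MS matrix of the core carbon atoms
#'
#' Reconstructs the metabolite atom-by-atom by a series of 2D-convolutions:
#' each core atom's MID is applied along the daughter axis when the atom is
#' in the daughter fragment, along the complement axis otherwise.
#'
#' @param tracer a \linkS4class{TracerSpec}
#' @param daughterMask logical vector (length = number of core atoms); TRUE
#'   marks atoms contained in the daughter fragment
#' @param table an \linkS4class{ElementIsotopeTable}
#' @return a normalized \linkS4class{CompactTandemMatrix}
#' @export
simulateCore <- function(tracer, daughterMask, table = defaultIsotopeTable()) {
    stopifnot(is(tracer, "TracerSpec"), is.logical(daughterMask),
              length(daughterMask) == tracer@nAtoms)
    mids <- atomMIDs(tracer, table)
    out <- compactTandemMatrix(matrix(1), normalized = TRUE)
    for (i in seq_len(tracer@nAtoms))
        out <- conv2Atom(out, mids[[i]], daughterMask[i])
    out
}

#' Predict the measured compact tandem MS matrix of a derivatized fragment
#'
#' 2D-convolves the core-atom matrix with the natural-abundance MID of the
#' daughter's other atoms (Q) along the daughter axis and with that of the
#' complement's other atoms (S) along the complement axis — the forward model
#' whose inverse is \code{\link{correctTandem}}.
#'
#' @param core compact tandem MS matrix of the core carbon atoms; its
#'   daughter/complement sizes must equal the fragment's core atom counts
#' @param frag a \linkS4class{FragmentSpec}
#' @param table an \linkS4class{ElementIsotopeTable}
#' @return a normalized \linkS4class{CompactTandemMatrix}
#' @export
simulateMeasured <- function(core, frag, table = defaultIsotopeTable()) {
    stopifnot(is(core, "CompactTandemMatrix"), is(frag, "FragmentSpec"))
    nD <- length(frag@daughterCore)
    nK <- length(frag@coreAtoms) - nD
    if (daughterSize(core) != nD || complementSize(core) != nK)
        stop(sprintf("core matrix is %d x %d but fragment has %d daughter and %d complement core atoms",
                     daughterSize(core) + 1L, complementSize(core) + 1L, nD, nK))
    qs <- otherAtomFormulas(frag)
    out <- core
    if (length(qs$Q)) out <- conv2Atom(out, naturalMID(qs$Q, table), inDaughter = TRUE)
    if (length(qs$S)) out <- conv2Atom(out, naturalMID(qs$S, table), inDaughter = FALSE)
    out
}

#' Simulate the full measured matrix of a fragment for a tracer
#'
#' Convenience composition of \code{\link{simulateCore}} and
#' \code{\link{simulateMeasured}} with the daughter mask taken from the
#' fragment specification.
#'
#' @inheritParams simulateMeasured
#' @param tracer a \linkS4class{TracerSpec} for the core carbon atoms
#' @return a normalized \linkS4class{CompactTandemMatrix}
#' @export
simulateFragment <- function(frag, tracer, table = defaultIsotopeTable()) {
    mask <- frag@coreAtoms %in% frag@daughterCore
    simulateMeasured(simulateCore(tracer, mask, table), frag, table)
}

#' Read a fragment specification from YAML
#'
#' Expected keys: \code{metabolite}, \code{parent_formula},
#' \code{daughter_formula}, \code{core_atoms}, \code{daughter_core}.
#'
#' @param path YAML file path
#' @return a \linkS4class{FragmentSpec}
#' @export
readFragmentSpec <- function(path) {
    y <- yaml::read_yaml(path)
    fragmentSpec(y$metabolite, y$parent_formula, y$daughter_formula,
                 unlist(y$core_atoms), unlist(y$daughter_core))
}

#' Read a tracer specification from YAML
#'
#' Expected keys: \code{n_atoms}, \code{positions} (list of
#' \code{position}/\code{purity} pairs), optional \code{background}.
#'
#' @param path YAML file path
#' @return a \linkS4class{TracerSpec}
#' @export
readTracerSpec <- function(path) {
    y <- yaml::read_yaml(path)
    pos <- vapply(y$positions, function(p) as.integer(p$position), 1L)
    pur <- vapply(y$positions, function(p) as.numeric(p$purity %||% 1), 1)
    tracerSpec(y$n_atoms, pos, pur, y$background %||% "natural")
}

setMethod("show", "FragmentSpec", function(object) {
    cat(sprintf("FragmentSpec %s: parent %s > daughter %s; core atoms %s (daughter: %s)\n",
                object@metabolite, formulaToString(object@parentFormula),
                formulaToString(object@daughterFormula),
                paste(object@coreAtoms, collapse = ","),
                paste(object@daughterCore, collapse = ",")))
})

setMethod("show", "TracerSpec", function(object) {
    lab <- which(object@labeled)
    cat(sprintf("TracerSpec: %d atoms, 13C at %s (purity %s), %s background\n",
                object@nAtoms,
                if (length(lab)) paste(lab, collapse = ",") else "none",
                if (length(lab)) paste(object@purity[lab], collapse = ",") else "-",
                object@background))
})
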