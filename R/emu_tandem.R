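# EMU decomposition with daughter-atom tracking and cascade solving of EMU
# balance equations with compact tandem MS matrices as state variables.

#' Construct a tandem EMU
#'
#' @param metabolite metabolite id
#' @param atoms parent atom indices (1-based within the metabolite)
#' @param daughter subset of \code{atoms} contained in the daughter fragment
#' @return a \linkS4class{TandemEMU}
#' @examples
#' tandemEMU("F", 1:3, 2:3)  # parent F[1,2,3], daughter F[2,3]
#' @export
tandemEMU <- function(metabolite, atoms, daughter = integer()) {
    new("TandemEMU", metabolite = metabolite,
        atoms = sort(unique(as.integer(atoms))),
        daughter = sort(unique(as.integer(daughter))))
}

#' Canonical identifier of a tandem EMU
#'
#' Format \code{"MET[atoms|daughter]"}, e.g. \code{"B[2,3|3]"}.
#'
#' @param emu a \linkS4class{TandemEMU}
#' @return character id
#' @export
emuId <- function(emu)
    sprintf("%s[%s|%s]", emu@metabolite,
            paste(emu@atoms, collapse = ","),
            paste(emu@daughter, collapse = ","))

#' Parse a tandem EMU identifier
#'
#' Accepts the canonical \code{"MET[atoms|daughter]"} form (e.g.
#' \code{"F[1,2,3|2,3]"}; the \code{|daughter} part may be omitted) and the
#' parent>daughter form \code{"F[1,2,3]>F[2,3]"}.
#'
#' @param text a single EMU id string
#' @return a \linkS4class{TandemEMU}
#' @export
parseEMU <- function(text) {
    text <- gsub("\\s", "", text)
    nums <- function(s) if (nzchar(s)) as.integer(strsplit(s, ",")[[1L]]) else integer(0)
    m <- regmatches(text, regexec(
        "^([A-Za-z0-9_]+)\\[([0-9,]+)\\]>([A-Za-z0-9_]+)\\[([0-9,]*)\\]$", text))[[1L]]
    if (length(m) && m[1L] != "") {
        if (m[2L] != m[4L]) stop("parent and daughter must name the same metabolite")
        return(tandemEMU(m[2L], nums(m[3L]), nums(m[5L])))
    }
    m <- regmatches(text, regexec(
        "^([A-Za-z0-9_]+)\\[([0-9,]+)(\\|([0-9,]*))?\\]$", text))[[1L]]
    if (length(m) && m[1L] != "")
        return(tandemEMU(m[2L], nums(m[3L]), nums(m[5L])))
    stop(sprintf("cannot parse EMU id '%s'", text))
}

## An EMU whose daughter set is the full atom set carries the same
## information as the empty-daughter EMU transposed; store one state
## variable in complement orientation and transpose at the point of use.
canonicalEMU <- function(emu) {
    if (length(emu@daughter) == length(emu@atoms) && length(emu@atoms) > 0L)
        list(emu = tandemEMU(emu@metabolite, emu@atoms), transposed = TRUE)
    else list(emu = emu, transposed = FALSE)
}

#' EMU size
#'
#' @param emu a \linkS4class{TandemEMU}
#' @return number of atoms in the EMU
#' @export
emuSize <- function(emu) length(emu@atoms)

#' Decompose a network model for a tandem MS target
#'
#' Breadth-first trace from the target EMU through all reactions producing
#' its metabolite: unimolecular and cleavage reactions pull the atom set
#' (and its daughter marks) back to the educt; condensation reactions split
#' the EMU by educt membership with daughter marks inherited per atom. EMUs
#' are deduplicated by (metabolite, atom set, daughter set); EMUs whose
#' daughter set equals their atom set are stored once in complement
#' orientation and transposed at the point of use. A target with an empty
#' daughter set reproduces the classic MID-only EMU decomposition.
#'
#' @param model a \linkS4class{NetworkModel}
#' @param target a \linkS4class{TandemEMU}; its metabolite and atoms must
#'   exist in the model
#' @return an \linkS4class{EMUSystem}
#' @export
decomposeTandem <- function(model, target) {
    stopifnot(is(model, "NetworkModel"), is(target, "TandemEMU"))
    if (!target@metabolite %in% names(model@carbons))
        stop(sprintf("unknown metabolite '%s'", target@metabolite))
    if (max(target@atoms) > model@carbons[[target@metabolite]])
        stop(sprintf("atom index exceeds carbon count of %s", target@metabolite))
    urx <- unidirectionalReactions(model)
    prodMets <- lapply(urx, function(r) vapply(r$products, `[[`, "", "met"))

    canon <- canonicalEMU(target)
    queue <- list(canon$emu)
    emus <- list()
    knownIds <- character(0)
    reactions <- list()
    while (length(queue)) {
        emu <- queue[[1L]]; queue <- queue[-1L]
        id <- emuId(emu)
        if (!is.null(emus[[id]])) next
        emus[[id]] <- emu
        if (emu@metabolite %in% model@inputs) {
            knownIds <- c(knownIds, id)
            next
        }
        produced <- FALSE
        for (ri in seq_along(urx)) {
            for (slot in which(prodMets[[ri]] == emu@metabolite)) {
                produced <- TRUE
                labels <- urx[[ri]]$products[[slot]]$labels
                need <- labels[emu@atoms]
                needD <- labels[emu@daughter]
                educts <- list(); transposed <- logical(0)
                for (e in urx[[ri]]$educts) {
                    pos <- which(e$labels %in% need)
                    if (!length(pos)) next
                    dpos <- which(e$labels %in% needD)
                    ce <- canonicalEMU(tandemEMU(e$met, pos, dpos))
                    educts <- c(educts, ce$emu)
                    transposed <- c(transposed, ce$transposed)
                }
                sizes <- vapply(educts, emuSize, 0L)
                stopifnot(sum(sizes) == emuSize(emu))  # atom conservation
                ord <- order(vapply(educts, function(x) x@metabolite, ""),
                             vapply(educts, function(x)
                                 paste(sprintf("%03d", x@atoms), collapse = ","), ""))
                reactions[[length(reactions) + 1L]] <-
                    new("EMUReaction", flux = urx[[ri]]$flux,
                        educts = educts[ord], eductTransposed = transposed[ord],
                        product = emu)
                for (e in educts) queue[[length(queue) + 1L]] <- e
            }
        }
        if (!produced)
            stop(sprintf("EMU %s is unreachable: %s is neither produced nor a network input",
                         id, emu@metabolite))
    }
    new("EMUSystem", target = target, targetId = emuId(canon$emu),
        targetTransposed = canon$transposed, emus = emus,
        reactions = reactions, knownIds = knownIds)
}

## compact matrix of an input-metabolite EMU under a tracer
#' Compact tandem MS matrix of a tracer-defined EMU
#'
#' Builds the compact matrix of an atom subset of an input metabolite by
#' 2D-convolution of the per-atom tracer MIDs, oriented by daughter
#' membership.
#'
#' @param tracer a \linkS4class{TracerSpec} for the input metabolite
#' @param emu a \linkS4class{TandemEMU} on that metabolite
#' @param table an \linkS4class{ElementIsotopeTable}
#' @return a normalized \linkS4class{CompactTandemMatrix}
#' @export
tracerCompact <- function(tracer, emu, table = defaultIsotopeTable()) {
    mids <- atomMIDs(tracer, table)
    out <- compactTandemMatrix(matrix(1), normalized = TRUE)
    for (a in emu@atoms)
        out <- conv2Atom(out, mids[[a]], a %in% emu@daughter)
    out
}

#' Input matrices for an EMU system from tracer specifications
#'
#' @param system an \linkS4class{EMUSystem}
#' @param tracers named list, input metabolite id -> \linkS4class{TracerSpec}
#' @param table an \linkS4class{ElementIsotopeTable}
#' @return named list, EMU id -> \linkS4class{CompactTandemMatrix}, covering
#'   all known (input) EMUs of the system
#' @export
inputMatrices <- function(system, tracers, table = defaultIsotopeTable()) {
    out <- list()
    for (id in system@knownIds) {
        emu <- system@emus[[id]]
        tr <- tracers[[emu@metabolite]]
        if (is.null(tr))
            stop(sprintf("no tracer specification for input metabolite %s", emu@metabolite))
        out[[id]] <- tracerCompact(tr, emu, table)
    }
    out
}

## row-major flattening (daughter index outer, complement index inner)
flattenCompact <- function(v) as.vector(t(v))
unflattenCompact <- function(x, d) matrix(x, nrow = d + 1L, byrow = TRUE)

#' Solve an EMU system by cascade through increasing EMU size
#'
#' Groups the unknown EMUs by (size, number of daughter atoms) and solves
#' the flux-dependent linear system A X = B Y per group in increasing size.
#' Rows of X and Y are compact tandem MS matrices flattened row-major;
#' condensation entries of Y are computed by 2D-convolution of the educt
#' matrices (transposed at the point of use where the stored orientation
#' differs). Each solved matrix must come out normalized within 1e-9 and is
#' renormalized exactly.
#'
#' @param system an \linkS4class{EMUSystem}
#' @param fluxes named flux map over the model's unidirectional flux ids
#' @param inputs named list, EMU id -> \linkS4class{CompactTandemMatrix},
#'   for every known (input) EMU of the system (see
#'   \code{\link{inputMatrices}})
#' @return named list, EMU id -> normalized
#'   \linkS4class{CompactTandemMatrix}, for every EMU of the system
#' @export
solveCascade <- function(system, fluxes, inputs) {
    solved <- list()
    for (id in system@knownIds) {
        m <- inputs[[id]]
        if (is.null(m)) stop(sprintf("missing input matrix for EMU %s", id))
        if (abs(sum(tandemValues(m)) - 1) > .TOL_NORM)
            stop(sprintf("input matrix for EMU %s is not normalized", id))
        solved[[id]] <- tandemValues(m)
    }
    unknowns <- setdiff(names(system@emus), system@knownIds)
    if (length(unknowns)) {
        sizes <- vapply(unknowns, function(id) emuSize(system@emus[[id]]), 0L)
        ndaug <- vapply(unknowns, function(id) length(system@emus[[id]]@daughter), 0L)
        groups <- split(unknowns, list(sizes, ndaug), drop = TRUE)
        groups <- groups[order(vapply(groups, function(g) emuSize(system@emus[[g[1L]]]), 0L))]
        prodIds <- vapply(system@reactions, function(rx) emuId(rx@product), "")

        fetch <- function(id, transposed) {
            m <- solved[[id]]
            if (is.null(m)) stop(sprintf("internal: EMU %s not yet solved", id))
            if (transposed) t(m) else m
        }
        for (g in groups) {
            n <- length(g)
            sz <- emuSize(system@emus[[g[1L]]])
            d <- length(system@emus[[g[1L]]]@daughter)
            k <- sz - d
            w <- (d + 1L) * (k + 1L)
            A <- matrix(0, n, n, dimnames = list(g, g))
            R <- matrix(0, n, w)
            for (rxi in which(prodIds %in% g)) {
                rx <- system@reactions[[rxi]]
                v <- fluxes[[rx@flux]]
                if (is.null(v)) stop(sprintf("missing flux value for %s", rx@flux))
                u <- emuId(rx@product)
                A[u, u] <- A[u, u] - v
                if (length(rx@educts) == 1L) {
                    eid <- emuId(rx@educts[[1L]])
                    if (eid %in% g) {
                        A[u, eid] <- A[u, eid] + v
                    } else {
                        R[match(u, g), ] <- R[match(u, g), ] -
                            v * flattenCompact(fetch(eid, rx@eductTransposed[1L]))
                    }
                } else {
                    mats <- lapply(seq_along(rx@educts), function(i)
                        fetch(emuId(rx@educts[[i]]), rx@eductTransposed[i]))
                    y <- Reduce(conv2Mat, mats)
                    R[match(u, g), ] <- R[match(u, g), ] - v * flattenCompact(y)
                }
            }
            if (rcond(A) < 1e-12)
                stop(sprintf("singular EMU balance at size %d (daughter count %d)", sz, d))
            X <- solve(A, R)
            for (i in seq_len(n)) {
                m <- unflattenCompact(X[i, ], d)
                if (abs(sum(m) - 1) > .TOL_NORM)
                    stop(sprintf("solved EMU %s is not normalized (sum %.12g)", g[i], sum(m)))
                m[m < 0 & m > -.TOL_NORM] <- 0
                solved[[g[i]]] <- m / sum(m)
            }
        }
    }
    lapply(solved, compactTandemMatrix, normalized = TRUE)
}

#' Look up one EMU in a cascade solution
#'
#' Canonicalizes the requested EMU and transposes the stored matrix where
#' the requested orientation differs from the stored one.
#'
#' @param solution named list returned by \code{\link{solveCascade}}
#' @param emu the requested \linkS4class{TandemEMU}
#' @return a \linkS4class{CompactTandemMatrix}
#' @export
lookupEMU <- function(solution, emu) {
    ce <- canonicalEMU(emu)
    m <- solution[[emuId(ce$emu)]]
    if (is.null(m)) stop(sprintf("EMU %s not present in solution", emuId(ce$emu)))
    if (ce$transposed) t(m) else m
}

#' Target matrix of a solved EMU system
#'
#' @param system an \linkS4class{EMUSystem}
#' @param solution named list returned by \code{\link{solveCascade}}
#' @return the target's \linkS4class{CompactTandemMatrix} in the requested
#'   orientation
#' @export
targetMatrix <- function(system, solution) lookupEMU(solution, system@target)

#' Simulate the tandem MS matrix of a target EMU
#'
#' Convenience wrapper: decompose, build input matrices from tracers, solve
#' the cascade, and return the target matrix.
#'
#' @param model a \linkS4class{NetworkModel}
#' @param target a \linkS4class{TandemEMU}
#' @param fluxes named unidirectional flux map
#' @param tracers named list, input metabolite -> \linkS4class{TracerSpec}
#' @param table an \linkS4class{ElementIsotopeTable}
#' @return the target's \linkS4class{CompactTandemMatrix}
#' @export
simulateTandemEMU <- function(model, target, fluxes, tracers,
                              table = defaultIsotopeTable()) {
    system <- decomposeTandem(model, target)
    solution <- solveCascade(system, fluxes, inputMatrices(system, tracers, table))
    targetMatrix(system, solution)
}

setMethod("show", "TandemEMU", function(object) cat(emuId(object), "\n"))

setMethod("show", "EMUReaction", function(object) {
    cat(sprintf("%s: %s -> %s\n", object@flux,
                paste(vapply(object@educts, emuId, ""), collapse = " + "),
                emuId(object@product)))
})

setMethod("show", "EMUSystem", function(object) {
    cat(sprintf("EMUSystem for target %s: %d EMUs (%d known inputs), %d EMU reactions\n",
                emuId(object@target), length(object@emus),
                length(object@knownIds), length(object@reactions)))
    sizes <- vapply(object@reactions, function(rx) emuSize(rx@product), 0L)
    for (s in sort(unique(sizes))) {
        cat(sprintf("  size %d:\n", s))
        for (rx in object@reactions[sizes == s])
            cat(sprintf("    %s: %s -> %s\n", rx@flux,
                        paste(vapply(rx@educts, emuId, ""), collapse = " + "),
                        emuId(rx@product)))
    }
})
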