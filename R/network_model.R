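# Parsing and validation of atom-transition network models and flux maps,
# and steady-state balance checking.

parseTerm <- function(txt, rxnId) {
    m <- regmatches(txt, regexec("^\\s*([A-Za-z0-9_]+)\\s*\\(([a-z]*)\\)\\s*$", txt))[[1L]]
    if (length(m) == 0L || m[1L] == "")
        stop(sprintf("reaction %s: cannot parse term '%s' (expected 'Met (abc)')",
                     rxnId, trimws(txt)))
    list(met = m[2L], labels = strsplit(m[3L], "")[[1L]])
}

parseSide <- function(txt, rxnId) {
    lapply(strsplit(txt, "+", fixed = TRUE)[[1L]], parseTerm, rxnId = rxnId)
}

#' Parse an atom-transition network model
#'
#' One reaction per line, in the grammar
#' \preformatted{id: A (abc) + C (de) -> D (bcd) + E (a) + E (e)}
#' with \code{<->} marking a reversible reaction. Atom labels are single
#' lowercase letters scoped per reaction line; the multiset of labels must
#' balance across the arrow. Blank lines and \code{#} comments are ignored.
#' Input metabolites (never produced) and output metabolites (never
#' consumed) are inferred unless given explicitly.
#'
#' @param text model text (single string or character vector of lines)
#' @param inputs,outputs optional explicit metabolite designations
#' @return a \linkS4class{NetworkModel}
#' @export
parseModel <- function(text, inputs = NULL, outputs = NULL) {
    lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    reactions <- lapply(lines, function(ln) {
        hdr <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln))[[1L]]
        if (length(hdr) == 0L) stop(sprintf("cannot parse reaction line '%s'", ln))
        id <- hdr[2L]; body <- hdr[3L]
        rev <- grepl("<->", body, fixed = TRUE)
        sides <- strsplit(body, if (rev) "<->" else "->", fixed = TRUE)[[1L]]
        if (length(sides) != 2L) stop(sprintf("reaction %s: expected one arrow", id))
        new("Reaction", id = id, educts = parseSide(sides[1L], id),
            products = parseSide(sides[2L], id), reversible = rev)
    })
    carbons <- numeric(0)
    for (rx in reactions) {
        for (term in c(rx@educts, rx@products)) {
            n <- length(term$labels)
            if (term$met %in% names(carbons) && carbons[[term$met]] != n)
                stop(sprintf("metabolite %s: inconsistent carbon count (%d vs %d)",
                             term$met, carbons[[term$met]], n))
            carbons[term$met] <- n
        }
    }
    mets <- names(carbons)
    produced <- consumed <- character(0)
    for (rx in reactions) {
        e <- vapply(rx@educts, `[[`, "", "met")
        p <- vapply(rx@products, `[[`, "", "met")
        consumed <- c(consumed, e, if (rx@reversible) p)
        produced <- c(produced, p, if (rx@reversible) e)
    }
    new("NetworkModel", reactions = reactions, carbons = carbons,
        inputs = inputs %||% setdiff(mets, produced),
        outputs = outputs %||% setdiff(mets, consumed))
}

#' Read a network model from a text file
#'
#' @param path path to a model file in the \code{\link{parseModel}} grammar
#' @return a \linkS4class{NetworkModel}
#' @export
readModel <- function(path) parseModel(readLines(path))

#' Serialize a network model to its text grammar
#'
#' \code{parseModel(serializeModel(m))} reproduces \code{m}.
#'
#' @param model a \linkS4class{NetworkModel}
#' @return character vector of reaction lines
#' @export
serializeModel <- function(model) {
    vapply(model@reactions, function(rx) {
        side <- function(s) paste(vapply(s, function(t)
            sprintf("%s (%s)", t$met, paste(t$labels, collapse = "")), ""),
            collapse = " + ")
        sprintf("%s: %s %s %s", rx@id, side(rx@educts),
                if (rx@reversible) "<->" else "->", side(rx@products))
    }, "")
}

## expand reversible reactions into unidirectional fluxes <id>_f / <id>_b
unidirectionalReactions <- function(model) {
    out <- list()
    for (rx in model@reactions) {
        if (rx@reversible) {
            out[[length(out) + 1L]] <- list(flux = paste0(rx@id, "_f"),
                                            educts = rx@educts, products = rx@products)
            out[[length(out) + 1L]] <- list(flux = paste0(rx@id, "_b"),
                                            educts = rx@products, products = rx@educts)
        } else {
            out[[length(out) + 1L]] <- list(flux = rx@id,
                                            educts = rx@educts, products = rx@products)
        }
    }
    out
}

#' Unidirectional flux identifiers of a model
#'
#' Reversible reactions contribute \code{<id>_f} and \code{<id>_b}.
#'
#' @param model a \linkS4class{NetworkModel}
#' @return character vector of flux ids
#' @export
fluxIds <- function(model)
    vapply(unidirectionalReactions(model), `[[`, "", "flux")

#' Metabolites subject to a steady-state balance
#'
#' All metabolites except the designated network inputs and outputs.
#'
#' @param model a \linkS4class{NetworkModel}
#' @return character vector of metabolite ids
#' @export
balancedMetabolites <- function(model)
    setdiff(names(model@carbons), c(model@inputs, model@outputs))

#' Stoichiometric matrix over unidirectional fluxes
#'
#' @param model a \linkS4class{NetworkModel}
#' @param metabolites which metabolites to include (default: balanced ones)
#' @return numeric matrix, metabolites x fluxes, with net stoichiometric
#'   coefficients
#' @export
stoichMatrix <- function(model, metabolites = balancedMetabolites(model)) {
    urx <- unidirectionalReactions(model)
    S <- matrix(0, length(metabolites), length(urx),
                dimnames = list(metabolites, vapply(urx, `[[`, "", "flux")))
    for (j in seq_along(urx)) {
        for (term in urx[[j]]$educts)
            if (term$met %in% metabolites) S[term$met, j] <- S[term$met, j] - 1
        for (term in urx[[j]]$products)
            if (term$met %in% metabolites) S[term$met, j] <- S[term$met, j] + 1
    }
    S
}

#' Check steady-state flux balances
#'
#' @param model a \linkS4class{NetworkModel}
#' @param fluxes named numeric vector over the model's unidirectional flux
#'   ids (a flux map)
#' @return named residual vector (production - consumption) per balanced
#'   metabolite; all zero within 1e-9 for a valid steady-state flux map
#' @export
checkBalance <- function(model, fluxes) {
    ids <- fluxIds(model)
    missing <- setdiff(ids, names(fluxes))
    if (length(missing))
        stop(sprintf("flux map is missing flux id(s): %s", paste(missing, collapse = ", ")))
    S <- stoichMatrix(model)
    drop(S %*% fluxes[colnames(S)])
}

#' Construct a balanced flux map from fixed fluxes
#'
#' Solves the stoichiometric steady-state system S v = 0 for the free
#' fluxes given a set of fixed flux values (e.g. the network input flux and
#' the free degrees of freedom), by least squares on the remaining columns.
#'
#' @param model a \linkS4class{NetworkModel}
#' @param fix named numeric vector of fixed flux values
#' @param nonneg error when any resulting flux is negative (default TRUE)
#' @return complete named flux map satisfying \code{\link{checkBalance}}
#' @export
balancedFluxes <- function(model, fix, nonneg = TRUE) {
    S <- stoichMatrix(model)
    ids <- colnames(S)
    if (!all(names(fix) %in% ids))
        stop(sprintf("unknown flux id(s): %s",
                     paste(setdiff(names(fix), ids), collapse = ", ")))
    free <- setdiff(ids, names(fix))
    rhs <- -S[, names(fix), drop = FALSE] %*% fix
    sol <- qr.coef(qr(S[, free, drop = FALSE]), rhs)
    v <- stats::setNames(numeric(length(ids)), ids)
    v[names(fix)] <- fix
    v[free] <- sol
    if (anyNA(v)) stop("flux system is underdetermined; fix more fluxes")
    resid <- checkBalance(model, v)
    if (max(abs(resid)) > 1e-9)
        stop(sprintf("fixed fluxes are inconsistent with steady state (max residual %.3g)",
                     max(abs(resid))))
    if (nonneg && any(v < -1e-12))
        stop(sprintf("negative flux in balanced solution: %s",
                     paste(ids[v < -1e-12], collapse = ", ")))
    v[v < 0] <- 0
    v
}

#' Read / write a flux map as CSV
#'
#' Two columns: \code{flux_id}, \code{value}.
#'
#' @param path CSV file path
#' @return named numeric flux map
#' @export
readFluxMap <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    stats::setNames(as.numeric(df$value), as.character(df$flux_id))
}

#' @rdname readFluxMap
#' @param fluxes named numeric flux map
#' @export
writeFluxMap <- function(fluxes, path) {
    df <- data.frame(flux_id = names(fluxes), value = fmtNum(unname(fluxes)))
    utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
    invisible(path)
}

setMethod("show", "NetworkModel", function(object) {
    cat(sprintf("NetworkModel: %d reactions, %d metabolites (inputs: %s; outputs: %s)\n",
                length(object@reactions), length(object@carbons),
                paste(object@inputs, collapse = ","),
                paste(object@outputs, collapse = ",")))
    cat(paste0("  ", serializeModel(object), collapse = "\n"), "\n")
})

setMethod("show", "Reaction", function(object) {
    side <- function(s) paste(vapply(s, function(t)
        sprintf("%s (%s)", t$met, paste(t$labels, collapse = "")), ""),
        collapse = " + ")
    cat(sprintf("%s: %s %s %s\n", object@id, side(object@educts),
                if (object@reversible) "<->" else "->", side(object@products)))
})
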