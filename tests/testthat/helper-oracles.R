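# Independent brute-force oracles used to validate the convolution-based
# implementation. These enumerate every isotope assignment explicitly and
# share no code with the package's convolution machinery.

# expand a formula into one abundance vector per atom
atomVectors <- function(formula, table = defaultIsotopeTable()) {
    f <- parseFormula(formula)
    out <- list()
    for (el in names(f))
        for (i in seq_len(f[[el]]))
            out[[length(out) + 1L]] <- table@abundances[[el]]
    out
}

# exhaustive MID: enumerate all per-atom isotope assignments (<= ~6 atoms)
enumMID <- function(atoms) {
    if (!length(atoms)) return(1)
    grid <- expand.grid(lapply(atoms, seq_along))
    maxShift <- sum(vapply(atoms, length, 0L)) - length(atoms)
    out <- numeric(maxShift + 1L)
    for (r in seq_len(nrow(grid))) {
        idx <- as.integer(grid[r, ])
        p <- prod(vapply(seq_along(atoms), function(i) atoms[[i]][idx[i]], 0))
        shift <- sum(idx - 1L)
        out[shift + 1L] <- out[shift + 1L] + p
    }
    out
}

# exhaustive joint (daughter shift, complement shift) matrix: enumerate all
# per-atom isotope assignments of a fragment whose atoms are partitioned by
# daughter membership
enumTandem <- function(atoms, inDaughter) {
    stopifnot(length(atoms) == length(inDaughter))
    dMax <- sum(vapply(atoms[inDaughter], length, 0L)) - sum(inDaughter)
    kMax <- sum(vapply(atoms[!inDaughter], length, 0L)) - sum(!inDaughter)
    out <- matrix(0, dMax + 1L, kMax + 1L)
    grid <- expand.grid(lapply(atoms, seq_along))
    for (r in seq_len(nrow(grid))) {
        idx <- as.integer(grid[r, ])
        p <- prod(vapply(seq_along(atoms), function(i) atoms[[i]][idx[i]], 0))
        m <- sum(idx[inDaughter] - 1L)
        k <- sum(idx[!inDaughter] - 1L)
        out[m + 1L, k + 1L] <- out[m + 1L, k + 1L] + p
    }
    out
}

# independent classic (MID-only) EMU decomposer: breadth-first trace of atom
# sets without daughter marks; returns sorted "MET{a,b}" ids
classicEMUSet <- function(model, metabolite, atoms) {
    urx <- tandemEMU:::unidirectionalReactions(model)
    key <- function(met, a) paste0(met, "{", paste(sort(a), collapse = ","), "}")
    seen <- character(0)
    queue <- list(list(met = metabolite, atoms = sort(atoms)))
    while (length(queue)) {
        cur <- queue[[1L]]; queue <- queue[-1L]
        k <- key(cur$met, cur$atoms)
        if (k %in% seen) next
        seen <- c(seen, k)
        if (cur$met %in% model@inputs) next
        for (r in urx) {
            for (slot in which(vapply(r$products, `[[`, "", "met") == cur$met)) {
                need <- r$products[[slot]]$labels[cur$atoms]
                for (e in r$educts) {
                    pos <- which(e$labels %in% need)
                    if (length(pos))
                        queue[[length(queue) + 1L]] <- list(met = e$met, atoms = pos)
                }
            }
        }
    }
    sort(seen)
}

randomCompact <- function(d, k) {
    v <- matrix(stats::runif((d + 1L) * (k + 1L)), d + 1L)
    compactTandemMatrix(v / sum(v), normalized = TRUE)
}
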