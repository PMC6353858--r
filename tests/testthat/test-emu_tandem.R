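emuRxnString <- function(rx)
    sprintf("%s: %s -> %s", rx@flux,
            paste(vapply(rx@educts, emuId, ""), collapse = " + "),
            emuId(rx@product))

test_that("EMU identifiers parse in both accepted forms", {
    e <- parseEMU("F[1,2,3|2,3]")
    expect_equal(e@metabolite, "F")
    expect_equal(e@atoms, 1:3)
    expect_equal(e@daughter, 2:3)
    expect_equal(emuId(parseEMU("F[1,2,3]>F[2,3]")), "F[1,2,3|2,3]")
    expect_equal(parseEMU("B[2]")@daughter, integer(0))
    expect_error(parseEMU("F[1]>G[1]"), "same metabolite")
    expect_error(parseEMU("junk"), "cannot parse")
    expect_error(tandemEMU("B", 1:2, 3), "subset")
})

test_that("decomposition of the example network reproduces the size-1 EMU reactions", {
    sys <- decomposeTandem(exampleModel(), tandemEMU("F", 1:3, 2:3))
    size1 <- Filter(function(rx) emuSize(rx@product) == 1L, sys@reactions)
    expect_setequal(vapply(size1, emuRxnString, ""),
                    c("3: B[2|] -> C[1|]",
                      "1: A[2|] -> B[2|]",
                      "2_b: D[2|] -> B[2|]",
                      "2_f: B[2|] -> D[2|]",
                      "4: B[3|] -> D[2|]",
                      "1: A[3|] -> B[3|]",
                      "2_b: D[3|] -> B[3|]",
                      "2_f: B[3|] -> D[3|]",
                      "4: C[1|] -> D[3|]"))
    # the daughter-marked size-2 condensation educts inherit per-atom marks
    cond2 <- Filter(function(rx) emuSize(rx@product) == 2L &&
                        length(rx@educts) == 2L, sys@reactions)
    expect_length(cond2, 1L)
    expect_equal(emuRxnString(cond2[[1L]]), "4: B[3|] + C[1|] -> D[2,3|3]")
    expect_true(cond2[[1L]]@eductTransposed[2L])  # C[1] used in daughter orientation
})

test_that("a target on an input metabolite is known with no reactions", {
    sys <- decomposeTandem(exampleModel(), tandemEMU("A", 1:2, 2))
    expect_length(sys@reactions, 0L)
    expect_equal(sys@knownIds, "A[1,2|2]")
    tr <- list(A = exampleTracers()$A2)
    sol <- solveCascade(sys, exampleFluxes(), inputMatrices(sys, tr))
    expect_equal(tandemValues(targetMatrix(sys, sol)),
                 tandemValues(tracerCompact(tr$A, tandemEMU("A", 1:2, 2))))
})

test_that("unreachable targets and unknown atoms are rejected", {
    m <- parseModel(c("1: A (ab) -> B (ab)", "2: Z (c) -> W (c)"),
                    inputs = "A", outputs = c("B", "W", "Z"))
    # Z is declared an output but never produced; tracing it must fail
    expect_error(decomposeTandem(m, tandemEMU("Z", 1)), "unreachable")
    expect_error(decomposeTandem(exampleModel(), tandemEMU("Q", 1)), "unknown metabolite")
    expect_error(decomposeTandem(exampleModel(), tandemEMU("C", 1:3)), "exceeds")
})

test_that("empty-daughter decomposition collapses to the classic EMU decomposition", {
    m <- exampleModel()
    sys <- decomposeTandem(m, tandemEMU("F", 1:3))
    got <- sort(vapply(names(sys@emus), function(id) {
        e <- sys@emus[[id]]
        paste0(e@metabolite, "{", paste(e@atoms, collapse = ","), "}")
    }, "", USE.NAMES = FALSE))
    expect_equal(got, classicEMUSet(m, "F", 1:3))
    expect_true(all(vapply(sys@emus, function(e) length(e@daughter) == 0L, TRUE)))
})

test_that("the cascade solution matches the brute-force isotopomer oracle", {
    m <- exampleModel()
    fl <- exampleFluxes()
    tracers <- list(A = exampleTracers()$A2)  # 100% 13C at carbon 2
    target <- tandemEMU("F", 1:3, 2:3)
    emuMat <- simulateTandemEMU(m, target, fl, tracers)
    oracle <- simulateIsotopomers(m, fl, list(A = tracerIsotopomers(tracers$A)))
    oraMat <- aggregateToCompact(oracle$F, 1:3, 2:3)
    expect_lt(max(abs(tandemValues(emuMat) - tandemValues(oraMat))), 1e-9)
})

test_that("unlabeled pure inputs give a delta matrix at the origin", {
    tracers <- list(A = tracerSpec(3, background = "pure"))
    mat <- simulateTandemEMU(exampleModel(), tandemEMU("F", 1:3, 2:3),
                             exampleFluxes(), tracers)
    expected <- matrix(0, 3, 2); expected[1, 1] <- 1
    expect_lt(max(abs(tandemValues(mat) - expected)), 1e-12)
})

test_that("solved matrices are invariant to the overall flux scale", {
    m <- exampleModel()
    tracers <- list(A = exampleTracers()$A2)
    target <- tandemEMU("F", 1:3, 2:3)
    a <- simulateTandemEMU(m, target, exampleFluxes(), tracers)
    b <- simulateTandemEMU(m, target, 3.7 * exampleFluxes(), tracers)
    expect_lt(max(abs(tandemValues(a) - tandemValues(b))), 1e-12)
})

test_that("marginals of the tandem solution equal classic MID-only EMU solutions", {
    m <- exampleModel()
    fl <- exampleFluxes()
    tracers <- list(A = exampleTracers()$A2)
    tmat <- simulateTandemEMU(m, tandemEMU("F", 1:3, 2:3), fl, tracers)
    parentMID <- drop(tandemValues(simulateTandemEMU(m, tandemEMU("F", 1:3), fl, tracers)))
    daughterMID <- drop(tandemValues(simulateTandemEMU(m, tandemEMU("F", 2:3), fl, tracers)))
    expect_lt(max(abs(parentMarginal(tmat) - parentMID)), 1e-9)
    expect_lt(max(abs(daughterMarginal(tmat) - daughterMID)), 1e-9)
})

test_that("every solved matrix is a normalized distribution", {
    sys <- decomposeTandem(exampleModel(), tandemEMU("F", 1:3, 2:3))
    sol <- solveCascade(sys, exampleFluxes(),
                        inputMatrices(sys, list(A = exampleTracers()$A2)))
    for (m in sol) {
        v <- tandemValues(m)
        expect_gte(min(v), 0)
        expect_lte(max(v), 1)
        expect_equal(sum(v), 1, tolerance = 1e-9)
    }
})

test_that("an all-zero flux map makes the EMU balance singular", {
    sys <- decomposeTandem(exampleModel(), tandemEMU("F", 1:3, 2:3))
    zero <- stats::setNames(rep(0, 6), fluxIds(exampleModel()))
    expect_error(
        solveCascade(sys, zero, inputMatrices(sys, list(A = exampleTracers()$A2))),
        "singular")
})

test_that("missing or unnormalized inputs are rejected", {
    sys <- decomposeTandem(exampleModel(), tandemEMU("F", 1:3, 2:3))
    inputs <- inputMatrices(sys, list(A = exampleTracers()$A2))
    expect_error(solveCascade(sys, exampleFluxes(), inputs[-1]), "missing input")
    bad <- inputs
    bad[[1]] <- compactTandemMatrix(tandemValues(bad[[1]]) * 0.5, normalized = FALSE)
    expect_error(solveCascade(sys, exampleFluxes(), bad), "not normalized")
})
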