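test_that("a pure positional tracer forces a delta core matrix", {
    # [2,3-13C] of a 4-carbon metabolite, daughter C3-C4, pure background:
    # one label in the daughter (C3), one in the complement (C2)
    tr <- tracerSpec(4, c(2, 3), purity = 1, background = "pure")
    core <- simulateCore(tr, c(FALSE, FALSE, TRUE, TRUE))
    v <- tandemValues(core)
    expect_equal(dim(v), c(3L, 3L))
    expect_equal(unname(v[2, 2]), 1)
    expect_equal(sum(v), 1)
})

test_that("[1,4-13C]aspartate at 99% purity matches direct product enumeration", {
    tr <- tracerSpec(4, c(1, 4), purity = 0.99, background = "pure")
    mask <- c(TRUE, TRUE, FALSE, FALSE)  # daughter C1-C2
    core <- simulateCore(tr, mask)
    expect_equal(unname(tandemValues(core)[2, 2]), 0.99 * 0.99)
    # full matrix against the exhaustive 4-atom enumeration oracle
    mids <- list(c(0.01, 0.99), c(1, 0), c(1, 0), c(0.01, 0.99))
    expect_lt(max(abs(tandemValues(core) - enumTandem(mids, mask))), 1e-15)
})

test_that("natural-background core reproduces the natural carbon MID", {
    tr <- tracerSpec(4, background = "natural")
    core <- simulateCore(tr, c(TRUE, TRUE, FALSE, FALSE))
    expect_lt(max(abs(parentMarginal(core) - naturalMID("C4"))), 1e-12)
    expect_lt(max(abs(daughterMarginal(core) - naturalMID("C2"))), 1e-12)
})

test_that("fragments with no other atoms pass through simulateMeasured unchanged", {
    frag <- fragmentSpec("X", "C3", "C2", coreAtoms = 1:3, daughterCore = 1:2)
    tr <- tracerSpec(3, 2, background = "natural")
    core <- simulateCore(tr, c(TRUE, TRUE, FALSE))
    expect_equal(tandemValues(simulateMeasured(core, frag)), tandemValues(core))
})

test_that("simulateMeasured matches exhaustive enumeration over all fragment atoms", {
    # small derivatized fragment: parent C2H2O, daughter CH (one core carbon
    # in the daughter, one in the complement); Q = H, S = HO
    frag <- fragmentSpec("X", "C2H2O", "CH", coreAtoms = 1:2, daughterCore = 1L)
    qs <- otherAtomFormulas(frag)
    expect_equal(qs$Q, c(H = 1))
    expect_equal(sort(names(qs$S)), c("H", "O"))
    tr <- tracerSpec(2, 1, purity = 0.97, background = "natural")
    meas <- simulateFragment(frag, tr)
    tbl <- defaultIsotopeTable()
    atoms <- c(list(c(0.03, 0.97)), list(tbl@abundances$H),          # daughter: core C1 + H
               list(tbl@abundances$C),                               # complement core C2
               list(tbl@abundances$H), list(tbl@abundances$O))       # complement others
    oracle <- enumTandem(atoms, c(TRUE, TRUE, FALSE, FALSE, FALSE))
    expect_lt(max(abs(tandemValues(meas) - oracle)), 1e-12)
})

test_that("simulateMeasured commutes with parent marginalization", {
    frag <- aspartateFragment()
    tr <- tracerSpec(4, c(1, 4), purity = 0.99, background = "natural")
    core <- simulateCore(tr, frag@coreAtoms %in% frag@daughterCore)
    meas <- simulateMeasured(core, frag)
    expect_equal(sum(tandemValues(meas)), 1, tolerance = 1e-12)
    expect_gte(min(tandemValues(meas)), 0)
    qs <- otherAtomFormulas(frag)
    expected <- convolveMID(parentMarginal(core),
                            naturalMID(tandemEMU:::formulaAdd(qs$Q, qs$S)))
    expect_lt(max(abs(parentMarginal(meas) - expected)), 1e-12)
})

test_that("an unlabeled natural tracer equals natural simulation of the whole parent", {
    frag <- aspartateFragment()
    tr <- tracerSpec(4, background = "natural")
    meas <- simulateFragment(frag, tr)
    direct <- compactTandemMatrix(matrix(1), normalized = TRUE)
    tbl <- defaultIsotopeTable()
    direct <- conv2Atom(direct, naturalMID(frag@daughterFormula, tbl), TRUE)
    direct <- conv2Atom(direct,
                        naturalMID(tandemEMU:::formulaSubtract(
                            frag@parentFormula, frag@daughterFormula), tbl),
                        FALSE)
    expect_lt(max(abs(tandemValues(meas) - tandemValues(direct))), 1e-12)
})

test_that("inconsistent fragment formulas are rejected", {
    # daughter has fewer carbons than its core atom count -> negative Q
    expect_error(fragmentSpec("X", "C4H2", "CH2", coreAtoms = 1:4, daughterCore = 1:2),
                 "negative count")
    # daughter larger than parent
    expect_error(fragmentSpec("X", "C2H2", "C2H4", coreAtoms = 1:2, daughterCore = 1L),
                 "exceeds parent")
    # core/daughter size mismatch with the core matrix
    frag <- fragmentSpec("X", "C3H2", "C2H", coreAtoms = 1:3, daughterCore = 1:2)
    tr <- tracerSpec(3, background = "pure")
    wrong <- simulateCore(tr, c(TRUE, FALSE, FALSE))  # 1 daughter atom, not 2
    expect_error(simulateMeasured(wrong, frag), "core matrix")
})

test_that("fragment and tracer specifications round-trip through YAML", {
    frag <- aspartateFragment()
    f <- withr::local_tempfile(fileext = ".yaml")
    tandemEMU:::writeFragmentYAML(frag, f)
    back <- readFragmentSpec(f)
    expect_equal(back@parentFormula[sort(names(back@parentFormula))],
                 frag@parentFormula[sort(names(frag@parentFormula))])
    expect_equal(back@daughterCore, frag@daughterCore)
    tr <- tracerSpec(4, c(1, 4), purity = 0.99, background = "pure")
    g <- withr::local_tempfile(fileext = ".yaml")
    tandemEMU:::writeTracerYAML(tr, g)
    back2 <- readTracerSpec(g)
    expect_equal(back2@labeled, tr@labeled)
    expect_equal(back2@purity, tr@purity)
    expect_equal(back2@background, "pure")
})
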