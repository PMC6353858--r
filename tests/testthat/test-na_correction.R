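test_that("correction operators are shifted-MID columns with full rank", {
    frag <- aspartateFragment()
    ops <- correctionOperators(frag, c(10L, 10L))
    qmid <- naturalMID(otherAtomFormulas(frag)$Q)
    expect_equal(dim(ops$CQ), c(10L, 3L))
    expect_equal(ops$CQ[1:10, 1], qmid[1:10])
    expect_equal(ops$CQ[2:10, 2], qmid[1:9])     # column j shifted down by j
    expect_equal(ops$CQ[1, 2], 0)
    expect_equal(qr(ops$CQ)$rank, 3L)
})

test_that("deconvolution inverts the natural-abundance convolution exactly", {
    frag <- aspartateFragment()
    set.seed(33)
    for (i in 1:20) {
        core <- randomCompact(2, 2)
        corr <- correctTandem(simulateMeasured(core, frag), frag)
        expect_lt(max(abs(tandemValues(corr) - tandemValues(core))), 1e-10)
        expect_lt(corr@metadata$residual, 1e-10)
    }
})

test_that("simulated [1,4-13C]aspartate corrects back to the 0.9801 core entry", {
    frag <- aspartateFragment()
    tr <- tracerSpec(4, c(1, 4), purity = 0.99, background = "pure")
    core <- simulateCore(tr, frag@coreAtoms %in% frag@daughterCore)
    corr <- correctTandem(simulateMeasured(core, frag), frag)
    expect_equal(dim(tandemValues(corr)), c(3L, 3L))
    expect_equal(unname(tandemValues(corr)[2, 2]), 0.9801, tolerance = 1e-10)
    expect_lt(max(abs(tandemValues(corr) - tandemValues(core))), 1e-10)
})

test_that("a fragment with no other atoms corrects to the window-cropped input", {
    frag <- fragmentSpec("X", "C3", "C2", coreAtoms = 1:3, daughterCore = 1:2)
    meas <- randomCompact(2, 1)
    corr <- correctTandem(meas, frag)
    expect_equal(tandemValues(corr), tandemValues(meas), tolerance = 1e-12)
    # measured window smaller than the core window is an error
    small <- compactTandemMatrix(matrix(c(0.5, 0.5), 2, 1), normalized = TRUE)
    expect_error(correctTandem(small, frag), "smaller than")
})

test_that("truncated measured windows are solved with a lost-weight warning", {
    frag <- aspartateFragment()
    tr <- tracerSpec(4, c(1, 4), purity = 0.99, background = "pure")
    core <- simulateCore(tr, frag@coreAtoms %in% frag@daughterCore)
    meas <- simulateMeasured(core, frag)
    win <- compactTandemMatrix(tandemValues(meas)[1:5, 1:5] /
                               sum(tandemValues(meas)[1:5, 1:5]),
                               normalized = TRUE)
    expect_warning(corr <- correctTandem(win, frag), "truncates")
    # truncation plus renormalization costs accuracy but not correctness
    expect_lt(max(abs(tandemValues(corr) - tandemValues(core))), 5e-3)
})

test_that("corrected parent marginal agrees with classical 1D MID correction", {
    frag <- aspartateFragment()
    tr <- tracerSpec(4, c(1, 4), purity = 0.99, background = "natural")
    core <- simulateCore(tr, frag@coreAtoms %in% frag@daughterCore)
    meas <- simulateMeasured(core, frag)
    corr <- correctTandem(meas, frag)
    qs <- otherAtomFormulas(frag)
    mid1d <- deconvolveMID(parentMarginal(meas),
                           naturalMID(tandemEMU:::formulaAdd(qs$Q, qs$S)), 5)
    expect_lt(max(abs(parentMarginal(corr) - mid1d)), 1e-8)
})

test_that("a 100%-pure tracer corrects to a delta matrix", {
    frag <- aspartateFragment()
    tr <- tracerSpec(4, c(1, 4), purity = 1, background = "pure")
    corr <- correctTandem(simulateFragment(frag, tr), frag)
    expected <- matrix(0, 3, 3); expected[2, 2] <- 1
    expect_lt(max(abs(tandemValues(corr) - expected)), 1e-8)
})

test_that("clipAndRenormalize zeroes tolerable negatives and rejects gross ones", {
    ok <- randomCompact(1, 1)
    expect_equal(tandemValues(clipAndRenormalize(ok)), tandemValues(ok))
    v <- matrix(c(0.6, 0.4 + 1e-6, -1e-6, 0), 2)
    x <- new("CompactTandemMatrix", values = v, normalized = TRUE,
             metadata = list())
    expect_warning(clipped <- clipAndRenormalize(x), "clipped")
    expect_equal(min(tandemValues(clipped)), 0)
    expect_equal(sum(tandemValues(clipped)), 1)
    v2 <- matrix(c(0.61, 0.4, -0.01, 0), 2)
    x2 <- new("CompactTandemMatrix", values = v2, normalized = TRUE,
              metadata = list())
    expect_error(clipAndRenormalize(x2), "inconsistent")
})
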