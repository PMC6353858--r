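natC <- function() naturalMID("C")

# compact matrix of an n-carbon natural fragment with the first nd atoms in
# the daughter
naturalCompact <- function(n, nd) {
    out <- compactTandemMatrix(matrix(1), normalized = TRUE)
    for (i in seq_len(n)) out <- conv2Atom(out, natC(), i <= nd)
    out
}

test_that("a 4-carbon parent with 2-carbon daughter gives 3x5 full and 3x3 compact", {
    cmp <- naturalCompact(4, 2)
    expect_equal(dim(tandemValues(cmp)), c(3L, 3L))
    full <- toFull(cmp)
    expect_equal(dim(tandemValues(full)), c(3L, 5L))
    expect_equal(daughterSize(full), 2L)
    expect_equal(parentSize(full), 4L)
    expect_equal(complementSize(cmp), 2L)
})

test_that("compaction is the exact row-shift and preserves mass", {
    cmp <- naturalCompact(4, 2)
    full <- toFull(cmp)
    v <- tandemValues(full)
    for (m in 0:2) for (k in 0:2)
        expect_identical(tandemValues(cmp)[m + 1, k + 1], v[m + 1, m + k + 1])
    expect_identical(sum(tandemValues(cmp)), sum(v))
    rec <- toCompact(full)
    expect_identical(tandemValues(rec), tandemValues(cmp))
})

test_that("full-form constructor rejects infeasible mass and negative entries", {
    bad <- matrix(0, 2, 3); bad[2, 1] <- 0.5  # daughter heavier than parent
    expect_error(tandemMSMatrix(bad), "infeasible")
    ok <- matrix(0, 2, 3); ok[2, 1] <- 1e-12  # below tolerance: silently zeroed
    expect_identical(tandemValues(tandemMSMatrix(ok))[2, 1], 0)
    expect_error(compactTandemMatrix(matrix(c(0.5, -0.2), 1)), "negative")
    expect_error(toFull(naturalCompact(3, 1), parentSize = 5), "parentSize")
})

test_that("daughter covering the whole parent yields a single-column compact matrix", {
    cmp <- naturalCompact(3, 3)
    expect_equal(dim(tandemValues(cmp)), c(4L, 1L))
    expect_lt(max(abs(drop(tandemValues(cmp)) - naturalMID("C3"))), 1e-12)
    full <- toFull(cmp)
    expect_lt(max(abs(diag(tandemValues(full)) - naturalMID("C3"))), 1e-12)
})

test_that("toFull and toCompact are mutually inverse on random matrices", {
    set.seed(21)
    for (i in 1:10) {
        d <- sample(0:3, 1); k <- sample(0:3, 1)
        cmp <- randomCompact(d, k)
        expect_equal(tandemValues(toCompact(toFull(cmp))), tandemValues(cmp))
    }
})

test_that("conv2Atom base cases orient the atom MID by daughter membership", {
    unit <- compactTandemMatrix(matrix(1), normalized = TRUE)
    row <- conv2Atom(unit, natC(), inDaughter = FALSE)
    expect_equal(dim(tandemValues(row)), c(1L, 2L))
    expect_equal(unname(tandemValues(row)[1, ]), natC())
    col <- conv2Atom(unit, natC(), inDaughter = TRUE)
    expect_equal(dim(tandemValues(col)), c(2L, 1L))
    expect_equal(unname(tandemValues(col)[, 1]), natC())
    # MID [1] is the identity
    cmp <- naturalCompact(3, 1)
    expect_equal(tandemValues(conv2Atom(cmp, 1, TRUE)), tandemValues(cmp))
})

test_that("atom application order does not change the matrix", {
    set.seed(7)
    for (rep in 1:5) {
        n <- 5
        mids <- lapply(1:n, function(i) { v <- stats::runif(sample(2:3, 1)); v / sum(v) })
        mask <- sample(c(TRUE, FALSE), n, replace = TRUE)
        build <- function(ord) {
            out <- compactTandemMatrix(matrix(1), normalized = TRUE)
            for (i in ord) out <- conv2Atom(out, mids[[i]], mask[i])
            tandemValues(out)
        }
        expect_lt(max(abs(build(1:n) - build(sample(n)))), 1e-12)
    }
})

test_that("marginals collapse the 2D machinery onto 1D convolutions", {
    delta <- compactTandemMatrix({ m <- matrix(0, 2, 2); m[2, 2] <- 1; m },
                                 normalized = TRUE)
    expect_equal(parentMarginal(delta), c(0, 0, 1))
    cmp <- naturalCompact(4, 2)
    expect_lt(max(abs(parentMarginal(cmp) - naturalMID("C4"))), 1e-12)
    expect_lt(max(abs(daughterMarginal(cmp) - naturalMID("C2"))), 1e-12)
    expect_lt(max(abs(complementMarginal(cmp) - naturalMID("C2"))), 1e-12)
    expect_lt(max(abs(parentMarginal(toFull(cmp)) - naturalMID("C4"))), 1e-12)
    # sequential conv2Atom equals sequential 1D convolution on the parent MID
    mid1 <- Reduce(convolveMID, rep(list(natC()), 4))
    expect_lt(max(abs(parentMarginal(cmp) - mid1)), 1e-12)
})

test_that("tandem matrices survive a CSV round trip in both forms", {
    cmp <- naturalCompact(3, 1)
    f1 <- withr::local_tempfile(fileext = ".csv")
    writeTandemCSV(cmp, f1)
    back <- readTandemCSV(f1)
    expect_s4_class(back, "CompactTandemMatrix")
    expect_equal(tandemValues(back), tandemValues(cmp), tolerance = 1e-11)
    f2 <- withr::local_tempfile(fileext = ".csv")
    writeTandemCSV(toFull(cmp), f2)
    back2 <- readTandemCSV(f2)
    expect_s4_class(back2, "TandemMSMatrix")
    expect_equal(tandemValues(back2), tandemValues(toFull(cmp)), tolerance = 1e-11)
})
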