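# Volume / coordinate I/O, interpolation, superposition, filtering.

test_that("MRC round trip preserves data, voxel size, origin and stats", {
    set.seed(1)
    m <- GridMap(array(rnorm(16 * 20 * 12), dim = c(16, 20, 12)),
                 voxelSize = 1.06, origin = c(-3.5, 2.0, 7.25))
    p <- withr::local_tempfile(fileext = ".mrc")
    writeMap(m, p)
    m2 <- readMap(p)
    expect_equal(dim(gridData(m2)), c(16L, 20L, 12L))
    # float32 storage limits the round-trip precision
    expect_lt(max(abs(gridData(m2) - gridData(m))), 1e-5)
    expect_lt(max(abs(voxelSize(m2) - 1.06)), 1e-6)
    expect_equal(mapOrigin(m2), c(-3.5, 2.0, 7.25), tolerance = 1e-6)
    # header stats
    con <- file(p, "rb"); on.exit(close(con))
    hdr <- readBin(con, raw(), 1024L)
    dstats <- readBin(hdr[77:88], numeric(), 3, size = 4, endian = "little")
    expect_equal(dstats, c(min(gridData(m)), max(gridData(m)),
                           mean(gridData(m))), tolerance = 1e-6)
    # second round trip is bit-stable
    p2 <- withr::local_tempfile(fileext = ".mrc")
    writeMap(m2, p2)
    expect_identical(gridData(readMap(p2)), gridData(m2))
})

test_that("header axis permutations are canonicalised on read", {
    set.seed(2)
    arr <- array(rnorm(4 * 5 * 6), dim = c(4, 5, 6))
    m <- GridMap(arr, voxelSize = 1.2)
    pXYZ <- withr::local_tempfile(fileext = ".mrc")
    writeMap(m, pXYZ)
    # hand-write the same volume with file axis order z,y,x
    pZYX <- withr::local_tempfile(fileext = ".mrc")
    con <- file(pZYX, "wb")
    wInt <- function(x) writeBin(as.integer(x), con, size = 4L,
                                 endian = "little")
    wFlt <- function(x) writeBin(as.numeric(x), con, size = 4L,
                                 endian = "little")
    wInt(c(6L, 5L, 4L)); wInt(2L); wInt(c(0L, 0L, 0L))
    wInt(c(4L, 5L, 6L))                      # MX MY MZ (x,y,z sampling)
    wFlt(c(4, 5, 6) * 1.2); wFlt(c(90, 90, 90))
    wInt(c(3L, 2L, 1L))                      # columns=z, rows=y, sections=x
    wFlt(c(min(arr), max(arr), mean(arr)))
    wInt(c(1L, 0L)); wInt(rep(0L, 25L))
    wFlt(c(0, 0, 0))
    writeChar("MAP ", con, nchars = 4L, eos = NULL)
    writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
    wFlt(sd(arr)); wInt(0L)
    writeChar(paste(rep(" ", 800), collapse = ""), con, nchars = 800L,
              eos = NULL)
    writeBin(as.numeric(aperm(arr, c(3, 2, 1))), con, size = 4L,
             endian = "little")
    close(con)
    mz <- readMap(pZYX)
    mx <- readMap(pXYZ)
    expect_equal(gridData(mz), gridData(mx), tolerance = 1e-6)
    expect_equal(voxelSize(mz), voxelSize(mx))
})

test_that("fixture map carries its header voxel size and dimensions", {
    m <- GridMap(array(0.5, dim = c(64, 64, 64)), voxelSize = 1.06)
    p <- withr::local_tempfile(fileext = ".mrc")
    writeMap(m, p)
    m2 <- readMap(p)
    expect_equal(voxelSize(m2), rep(1.06, 3), tolerance = 1e-6)
    expect_equal(dim(gridData(m2)), c(64L, 64L, 64L))
    # a rescaled header survives the round trip
    writeMap(perturbVoxelSize(m, 1.03), p)
    expect_equal(voxelSize(readMap(p)), rep(1.06 * 1.03, 3),
                 tolerance = 1e-6)
})

test_that("malformed headers are rejected with the offending field named", {
    p <- withr::local_tempfile(fileext = ".mrc")
    writeBin(as.raw(rep(0L, 2048L)), p)
    expect_error(readMap(p), "MODE|NX")
    writeBin(as.raw(1:100), p)
    expect_error(readMap(p), "header")
})

test_that("interpolation is exact on grid nodes and constant on constants", {
    set.seed(3)
    a <- array(rnorm(10 * 11 * 12), dim = c(10, 11, 12))
    m <- GridMap(a, voxelSize = 1.5, origin = c(5, -2, 0))
    idx <- cbind(sample(10, 40, TRUE), sample(11, 40, TRUE),
                 sample(12, 40, TRUE))
    pts <- sweep((idx - 1) * 1.5, 2, c(5, -2, 0), "+")
    for (ord in c("cubic", "linear"))
        expect_equal(interpolateMap(m, pts, ord), a[idx], tolerance = 1e-9)
    mc <- GridMap(array(7.25, dim = c(6, 6, 6)))
    rnd <- matrix(runif(30, 0.5, 4.5), 10, 3)
    expect_equal(interpolateMap(mc, rnd), rep(7.25, 10), tolerance = 1e-9)
    expect_identical(interpolateMap(m, matrix(numeric(0), 0, 3)), numeric(0))
    expect_true(is.na(interpolateMap(m, matrix(c(-100, 0, 0), 1, 3))))
})

test_that("cubic interpolation matches an independent spline oracle", {
    # smooth Gaussian blob fixture
    n <- 14
    ax <- seq_len(n) - (n + 1) / 2
    a <- exp(-outer(outer(ax^2, ax^2, "+"), ax^2, "+") / (2 * 2.5^2))
    m <- GridMap(a, voxelSize = 1)
    set.seed(4)
    pts <- matrix(runif(60, 3, n - 4), 20, 3)  # interior points

    # oracle: separable cubic-spline interpolation, coefficients from the
    # 1D interpolation system solved directly (mirror boundary)
    splineMat <- function(n) {
        B <- matrix(0, n, n)
        for (i in seq_len(n)) {
            for (k in -1:1) {
                j <- i + k
                if (j < 1) j <- 2 - j
                if (j > n) j <- 2 * n - j
                B[i, j] <- B[i, j] + c(1, 4, 1)[k + 2] / 6
            }
        }
        B
    }
    solve1d <- function(v) as.vector(solve(splineMat(length(v)), v))
    coef <- a
    for (d in 1:3) {
        coef <- aperm(coef, c(d, setdiff(1:3, d)))
        dd <- dim(coef)
        coef <- array(apply(matrix(coef, dd[1]), 2, solve1d), dd)
        coef <- aperm(coef, order(c(d, setdiff(1:3, d))))
    }
    bs <- function(t) {
        w <- numeric(4)
        u <- 1 - t
        w[1] <- u^3 / 6; w[2] <- (4 - 6 * t^2 + 3 * t^3) / 6
        w[3] <- (1 + 3 * t + 3 * t^2 - 3 * t^3) / 6; w[4] <- t^3 / 6
        w
    }
    oracle <- vapply(seq_len(nrow(pts)), function(p) {
        g <- pts[p, ]  # 0-based voxel coords (voxel 1, origin 0)
        i0 <- floor(g); t <- g - i0
        acc <- 0
        wx <- bs(t[1]); wy <- bs(t[2]); wz <- bs(t[3])
        for (kz in 0:3) for (ky in 0:3) for (kx in 0:3)
            acc <- acc + wx[kx + 1] * wy[ky + 1] * wz[kz + 1] *
                coef[i0[1] + kx, i0[2] + ky, i0[3] + kz]
        acc
    }, numeric(1))
    got <- interpolateMap(m, pts, "cubic")
    expect_lt(max(abs(got - oracle)), 1e-3)
})

test_that("superposition recovers known transforms and matches a quaternion oracle", {
    set.seed(5)
    x <- matrix(rnorm(18), 6, 3)
    sp <- superpose(x, x)
    expect_lt(sp$rmsd, 1e-12)
    expect_equal(sp$rotation, diag(3), tolerance = 1e-9)

    R0 <- randomRotation()
    y <- x %*% t(R0) + matrix(c(1, -2, 3), 6, 3, byrow = TRUE)
    sp <- superpose(x, y)
    expect_equal(sp$rotation, R0, tolerance = 1e-9)
    expect_lt(sp$rmsd, 1e-10)

    # Horn's quaternion method as an independent rmsd oracle
    quatRMSD <- function(P, Q) {
        Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
        M <- crossprod(Pc, Qc)
        Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
        Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
        Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
        K <- matrix(c(
            Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
            Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
            Szx-Sxz,     Sxy+Syx,    -Sxx+Syy-Szz, Syz+Szy,
            Sxy-Syx,     Szx+Sxz,     Syz+Szy,    -Sxx-Syy+Szz), 4, 4)
        lmax <- max(eigen(K, symmetric = TRUE)$values)
        sqrt(max(0, (sum(Pc^2) + sum(Qc^2) - 2 * lmax)) / nrow(P))
    }
    for (k in 1:5) {
        P <- matrix(rnorm(18), 6, 3)
        Q <- matrix(rnorm(18), 6, 3)
        expect_equal(superpose(P, Q)$rmsd, quatRMSD(P, Q),
                     tolerance = 1e-6)
    }

    # forward and reverse fits are inverse transforms with equal rmsd
    P <- matrix(rnorm(21), 7, 3); Q <- matrix(rnorm(21), 7, 3)
    f <- superpose(P, Q); r <- superpose(Q, P)
    expect_equal(f$rotation, t(r$rotation), tolerance = 1e-9)
    expect_equal(f$rmsd, r$rmsd, tolerance = 1e-9)
    expect_equal(as.vector(f$rotation %*% r$translation + f$translation),
                 c(0, 0, 0), tolerance = 1e-9)

    expect_error(superpose(P[1:2, ], Q[1:2, ]), "3 points")
    line <- cbind(1:6, 2 * (1:6), -1 * (1:6))
    expect_warning(superpose(line, line + 1), "collinear")
})

test_that("low-pass filter preserves the mean and kills power beyond the edge", {
    set.seed(6)
    m <- GridMap(array(rnorm(24^3), dim = c(24, 24, 24)), voxelSize = 1)
    f <- lowpassFilter(m, 4)
    expect_equal(mean(gridData(f)), mean(gridData(m)), tolerance = 1e-10)
    # spectrum beyond cutoff + edge
    F2 <- Mod(fft(gridData(f)))^2
    fr <- cryobuild:::.freqGrid(dim(gridData(f)), voxelSize(f))
    beyond <- fr > 1 / 4 + 2 / 24 + 1e-9
    expect_lt(sum(F2[beyond]) / sum(F2), 1e-6)
    # a band-limited map is unchanged by a filter passing all its content
    # (content ends at 1/4 + edge = 1/3 cycles/A; 2.9 A passes up to 0.345)
    f2 <- lowpassFilter(f, 2.9)
    expect_equal(gridData(f2), gridData(f), tolerance = 1e-6)
    expect_error(lowpassFilter(m, 1.9), "Nyquist")
})

test_that("PDB round trip preserves atoms and secondary structure", {
    h <- makeIdealHelix(6)
    expect_equal(sum(atoms(h)$atom == "CA"), 6L)
    p <- withr::local_tempfile(fileext = ".pdb")
    writeModel(h, p)
    h2 <- readModel(p)
    expect_equal(nrow(atoms(h2)), nrow(atoms(h)))
    expect_equal(atoms(h2)$atom, atoms(h)$atom)
    expect_lt(max(abs(as.matrix(atoms(h2)[, c("x", "y", "z")]) -
                      as.matrix(atoms(h)[, c("x", "y", "z")]))), 5.1e-4)
    expect_true(all(atoms(h2)$ss[atoms(h2)$atom == "CA"] == "H"))

    tp <- makeToyProtein()
    writeModel(tp, p)
    tp2 <- suppressWarnings(readModel(p))
    caSS <- function(m) atoms(m)$ss[atoms(m)$atom == "CA"]
    expect_equal(caSS(tp2), caSS(tp))
})

test_that("HELIX records spanning residues 133-138 label those residues", {
    lines <- c(sprintf(
        "HELIX    1   1 ALA A  133  ALA A  138  1%30s     6", ""))
    for (i in 133:140) {
        lines <- c(lines, sprintf(
            "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00 20.00           C",
            i - 132, i, i * 3.8, 0, 0))
    }
    lines <- c(lines, "END")
    p <- withr::local_tempfile(fileext = ".pdb")
    writeLines(lines, p)
    m <- readModel(p)
    a <- atoms(m)
    expect_true(all(a$ss[a$resno %in% 133:138] == "H"))
    expect_true(all(a$ss[a$resno %in% 139:140] == "-"))
})

test_that("readFasta parses multi-line records", {
    p <- withr::local_tempfile(fileext = ".fasta")
    writeLines(c(">chainA desc", "AAWL", "ASAF", ">chainB", "GVLF"), p)
    s <- readFasta(p)
    expect_equal(unname(s), c("AAWLASAF", "GVLF"))
    expect_equal(names(s), c("chainA desc", "chainB"))
})
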