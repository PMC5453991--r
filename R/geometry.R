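#' Rodrigues rotation: rotation vector to matrix
#'
#' @param v numeric(3) rotation vector (axis * angle in radians).
#' @return 3x3 proper rotation matrix.
#' @keywords internal
rotvecToMatrix <- function(v) {
    theta <- sqrt(sum(v^2))
    if (theta < 1e-12) return(diag(3))
    k <- v / theta
    K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
    diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Rotation taking the z axis onto unit vector d.
.rotationFromZ <- function(d) {
    d <- d / sqrt(sum(d^2))
    z <- c(0, 0, 1)
    v <- c(z[2] * d[3] - z[3] * d[2],
           z[3] * d[1] - z[1] * d[3],
           z[1] * d[2] - z[2] * d[1])
    s <- sqrt(sum(v^2))
    c_ <- sum(z * d)
    if (s < 1e-12) {
        if (c_ > 0) return(diag(3))
        return(diag(c(1, -1, -1)))  # 180 deg about x
    }
    rotvecToMatrix(v / s * atan2(s, c_))
}

# Approximately uniform directions on the unit sphere (Fibonacci lattice).
.fibonacciSphere <- function(n) {
    i <- seq_len(n) - 0.5
    phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
    z <- 1 - 2 * i / n
    r <- sqrt(pmax(0, 1 - z^2))
    cbind(r * cos(phi), r * sin(phi), z)
}

# Quasi-uniform SO(3) grid: nDir axis directions x nRoll rolls about the axis.
.orientationGrid <- function(nDir = 72, nRoll = 8) {
    dirs <- .fibonacciSphere(nDir)
    rolls <- seq(0, 2 * pi, length.out = nRoll + 1)[seq_len(nRoll)]
    out <- vector("list", nDir * nRoll)
    k <- 1L
    for (i in seq_len(nDir)) {
        Rd <- .rotationFromZ(dirs[i, ])
        for (a in rolls) {
            ca <- cos(a); sa <- sin(a)
            Rz <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
            out[[k]] <- Rd %*% Rz
            k <- k + 1L
        }
    }
    out
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimising
#' \code{sum(|R m_i + t - f_i|^2)} over paired coordinate sets.
#'
#' @param mobile n x 3 matrix of coordinates to move.
#' @param fixed n x 3 matrix of target coordinates (paired with mobile).
#' @return list with \code{rotation} (3x3, proper), \code{translation}
#'   (length 3), \code{rmsd} (post-fit, Angstrom) and \code{degenerate}
#'   (TRUE when the point sets are near-collinear, making the rotation
#'   about the common axis ill-determined).
#' @export
superpose <- function(mobile, fixed) {
    mobile <- as.matrix(mobile); fixed <- as.matrix(fixed)
    if (nrow(mobile) != nrow(fixed))
        stop("mobile and fixed must have the same number of points")
    n <- nrow(mobile)
    if (n < 3) stop("superposition requires at least 3 points")
    cm <- colMeans(mobile); cf <- colMeans(fixed)
    P <- sweep(mobile, 2, cm); Q <- sweep(fixed, 2, cf)
    H <- crossprod(P, Q)  # 3x3
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    degenerate <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-300)
    if (degenerate)
        warning("near-collinear point sets: rotation is ill-determined")
    t <- cf - as.vector(R %*% cm)
    moved <- P %*% t(R)
    rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
    list(rotation = R, translation = t, rmsd = rmsd, degenerate = degenerate)
}

# --- internal-coordinate chain building (NeRF) ------------------------------

# Place atom D given positions A, B, C, bond |CD|, angle B-C-D (deg) and
# dihedral A-B-C-D (deg).
.placeAtom <- function(a, b, c_, bond, angle, torsion) {
    angle <- angle * pi / 180
    torsion <- torsion * pi / 180
    bc <- c_ - b; bc <- bc / sqrt(sum(bc^2))
    ab <- b - a
    nrm <- c(ab[2] * bc[3] - ab[3] * bc[2],
             ab[3] * bc[1] - ab[1] * bc[3],
             ab[1] * bc[2] - ab[2] * bc[1])
    nrm <- nrm / sqrt(sum(nrm^2))
    m <- c(nrm[2] * bc[3] - nrm[3] * bc[2],
           nrm[3] * bc[1] - nrm[1] * bc[3],
           nrm[1] * bc[2] - nrm[2] * bc[1])
    d2 <- c(-bond * cos(angle),
            bond * sin(angle) * cos(torsion),
            bond * sin(angle) * sin(torsion))
    c_ + d2[1] * bc + d2[2] * m + d2[3] * nrm
}

# Standard main-chain covalent geometry (Engh-Huber-like averages).
.BB <- list(
    b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
    b_ca_cb = 1.530,
    a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
    a_ca_c_o = 120.8, a_n_ca_cb = 110.4
)

# Build an ideal poly-peptide backbone with fixed (phi, psi, omega).
# Returns a data.frame of N/CA/C/O/CB atoms per residue.
.buildBackbone <- function(n, phi, psi, omega = 180,
                           resnames = rep("ALA", n)) {
    g <- .BB
    # bootstrap first three atoms in a plane
    N1 <- c(0, 0, 0)
    CA1 <- c(g$b_n_ca, 0, 0)
    th <- (180 - g$a_n_ca_c) * pi / 180
    C1 <- CA1 + g$b_ca_c * c(cos(th), sin(th), 0)
    pos <- list()
    pos[[1]] <- list(N = N1, CA = CA1, C = C1)
    for (i in 2:n) {
        p <- pos[[i - 1]]
        Ni <- .placeAtom(p$N, p$CA, p$C, g$b_c_n, g$a_ca_c_n, psi)
        CAi <- .placeAtom(p$CA, p$C, Ni, g$b_n_ca, g$a_c_n_ca, omega)
        Ci <- .placeAtom(p$C, Ni, CAi, g$b_ca_c, g$a_n_ca_c, phi)
        pos[[i]] <- list(N = Ni, CA = CAi, C = Ci)
    }
    rows <- list()
    for (i in seq_len(n)) {
        p <- pos[[i]]
        # carbonyl O: anti to the next N (or to psi+180 for the last residue)
        if (i < n) {
            nn <- pos[[i + 1]]$N
            O <- .placeAtom(nn, p$CA, p$C, g$b_c_o, g$a_ca_c_o, 180)
        } else {
            O <- .placeAtom(p$N, p$CA, p$C, g$b_c_o, g$a_ca_c_o, psi + 180)
        }
        res <- list(N = p$N, CA = p$CA, C = p$C, O = O)
        if (resnames[i] != "GLY") {
            res$CB <- .placeAtom(p$C, p$N, p$CA, g$b_ca_cb, g$a_n_ca_cb,
                                 -122.5)
        }
        for (nm in names(res)) {
            rows[[length(rows) + 1L]] <- data.frame(
                resno = i, resname = resnames[i], atom = nm,
                element = substr(nm, 1, 1),
                x = res[[nm]][1], y = res[[nm]][2], z = res[[nm]][3],
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows)
}

# Rigidly transform an AtomModel: x -> R x + t.
.transformModel <- function(model, R, t) {
    a <- model@atoms
    xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
    a$x <- xyz[, 1] + t[1]; a$y <- xyz[, 2] + t[2]; a$z <- xyz[, 3] + t[3]
    new("AtomModel", atoms = a)
}
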