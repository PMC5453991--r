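# C-alpha stage: learn log-likelihood (LLK) density targets around C-alpha
# positions of a reference map/model pair, extend C-alphas from the ends of
# placed secondary structures, merge the fragments, optionally assign the
# sequence, and evaluate against a ground-truth model.

# Offset lattice: integer-ish grid of `spacing` within `radius` of the
# origin, in the local C-alpha frame.
.llkOffsets <- function(radius = 4, spacing = 1) {
    ax <- seq(-radius, radius, by = spacing)
    g <- as.matrix(expand.grid(ax, ax, ax))
    dimnames(g) <- NULL
    g[sqrt(rowSums(g^2)) <= radius, , drop = FALSE]
}

# Orthonormal frame at Ca(i) from the triplet Ca(i-1), Ca(i), Ca(i+1):
# e1 = chain direction, e2 = bisector (the "bow" of the chain), e3 = normal.
# Returns a 3x3 matrix with the frame vectors as columns, or NULL when the
# triplet is degenerate.
.caFrame <- function(prev, cur, nxt) {
    u <- nxt - cur; v <- prev - cur
    e1 <- u - v
    n1 <- sqrt(sum(e1^2))
    if (n1 < 1e-8) return(NULL)
    e1 <- e1 / n1
    w <- u + v
    e2 <- w - sum(w * e1) * e1
    n2 <- sqrt(sum(e2^2))
    if (n2 < 1e-6) {  # nearly straight chain: pick any perpendicular
        a <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        e2 <- a - sum(a * e1) * e1
        e2 <- e2 / sqrt(sum(e2^2))
    } else e2 <- e2 / n2
    e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    cbind(e1, e2, e3)
}

# All interior-Ca frames of a model: list of (position, rotation, resname).
.modelFrames <- function(model) {
    a <- model@atoms
    ca <- a[trimws(a$atom) == "CA", , drop = FALSE]
    out <- list()
    for (ch in unique(ca$chain)) {
        c1 <- ca[ca$chain == ch, , drop = FALSE]
        n <- nrow(c1)
        if (n < 3) next
        xyz <- as.matrix(c1[, c("x", "y", "z")])
        for (i in 2:(n - 1)) {
            R <- .caFrame(xyz[i - 1, ], xyz[i, ], xyz[i + 1, ])
            if (is.null(R)) next
            out[[length(out) + 1L]] <- list(pos = xyz[i, ], rot = R,
                                            resname = c1$resname[i])
        }
    }
    out
}

#' Train C-alpha (and residue-type) log-likelihood targets
#'
#' For every interior C-alpha of the reference model, builds the canonical
#' local frame, samples the scaled reference map at a fixed offset lattice,
#' and accumulates per-offset means and variances. Per-residue-type targets
#' (used for side-chain/sequence assignment) are accumulated the same way
#' over a larger offset lattice that reaches the side-chain region.
#'
#' @param scaledReference reference \linkS4class{GridMap}, already on the
#'   working map's scale (see \code{\link{scaleReference}}).
#' @param referenceModel the reference \linkS4class{AtomModel}.
#' @param radius,spacing offset lattice for the generic C-alpha target
#'   (Angstrom).
#' @param typeRadius,typeSpacing offset lattice for residue-type targets.
#' @param withTypes also train per-residue-type targets.
#' @return list with \code{ca} (\linkS4class{LLKTarget}) and \code{types}
#'   (named list of \linkS4class{LLKTarget}s, possibly empty).
#' @export
trainLLKTarget <- function(scaledReference, referenceModel,
                           radius = 4, spacing = 1,
                           typeRadius = 6, typeSpacing = 1.25,
                           withTypes = TRUE) {
    frames <- .modelFrames(referenceModel)
    if (length(frames) < 10L)
        stop("fewer than 10 C-alpha triplets in the reference model")
    if (length(frames) < 100L)
        warning(sprintf("only %d C-alpha triplets; LLK statistics may be noisy",
                        length(frames)))
    interp <- .mapInterpolant(scaledReference)
    varFloor <- max(1e-6 * stats::var(as.vector(scaledReference@data)),
                    .Machine$double.eps)

    accumulate <- function(frames, offsets) {
        s <- numeric(nrow(offsets)); s2 <- numeric(nrow(offsets)); n <- 0L
        for (fr in frames) {
            pts <- offsets %*% t(fr$rot)
            pts <- sweep(pts, 2, fr$pos, "+")
            v <- .interpCubic(interp, pts)
            if (anyNA(v)) next
            s <- s + v; s2 <- s2 + v^2; n <- n + 1L
        }
        if (n < 2L) return(NULL)
        mu <- s / n
        sigma2 <- pmax(s2 / n - mu^2, varFloor)
        list(mu = mu, sigma2 = sigma2, n = n)
    }

    off <- .llkOffsets(radius, spacing)
    acc <- accumulate(frames, off)
    if (is.null(acc)) stop("no usable training triplets inside the map")
    ca <- new("LLKTarget", offsets = off, mu = acc$mu, sigma2 = acc$sigma2,
              kind = "ca", nTrain = acc$n)

    types <- list()
    if (withTypes) {
        offT <- .llkOffsets(typeRadius, typeSpacing)
        byType <- split(frames, vapply(frames, `[[`, character(1), "resname"))
        for (tn in names(byType)) {
            if (length(byType[[tn]]) < 3L) next
            a <- accumulate(byType[[tn]], offT)
            if (is.null(a)) next
            types[[tn]] <- new("LLKTarget", offsets = offT, mu = a$mu,
                               sigma2 = a$sigma2, kind = tn, nTrain = a$n)
        }
    }
    list(ca = ca, types = types)
}

# LLK score given a prepared interpolant (hot path). Out-of-map offsets
# count as zero density and are additionally penalised, so poses leaving
# the map score strongly negative but finite.
.llkScoreInterp <- function(interp, target, position, rotation) {
    pts <- target@offsets %*% t(rotation)
    pts <- sweep(pts, 2, position, "+")
    v <- .interpCubic(interp, pts)
    bad <- is.na(v)
    v[bad] <- 0
    s <- -sum((v - target@mu)^2 / (2 * target@sigma2) +
              0.5 * log(target@sigma2))
    s - 10 * sum(bad)
}

#' Log-likelihood score of a C-alpha pose
#'
#' \code{-sum_j ((rho_j - mu_j)^2 / (2 sigma2_j) + 0.5 log sigma2_j)} over
#' the target offsets transformed by the pose; higher is better. Poses
#' (partially) outside the map receive a strong finite penalty.
#'
#' @param map a \linkS4class{GridMap}.
#' @param target an \linkS4class{LLKTarget}.
#' @param position C-alpha position (Angstrom).
#' @param rotation 3x3 local frame (columns = frame vectors).
#' @return numeric score.
#' @export
llkScore <- function(map, target, position, rotation = diag(3)) {
    .llkScoreInterp(.mapInterpolant(map), target, position, rotation)
}

# Candidate-direction lattice for extension steps.
.extDirs <- function(n = 60L) .fibonacciSphere(n)

# Composite extension score for candidate c after chain ...,a,b:
# LLK at b with the completed (a,b,c) frame, plus a density bonus at c.
.candScore <- function(interp, target, a, b, cand, zfun, densityWeight) {
    R <- .caFrame(a, b, cand)
    if (is.null(R)) return(-Inf)
    .llkScoreInterp(interp, target, b, R) + densityWeight * zfun(cand)
}

#' Extend a C-alpha chain through the density
#'
#' From a seed of ordered C-alphas (a placed SSE segment or an existing
#' fragment), iteratively proposes next-C-alpha candidates on spherical
#' shells at 3.4/3.8/4.2 Angstrom obeying chain geometry
#' (Ca(i-1)-Ca(i+1) >= 4.5 Angstrom, no non-consecutive pair closer than
#' 3.0 Angstrom), scores each by the C-alpha LLK target plus a local
#' density bonus, and accepts the best candidate while it stays above an
#' adaptive threshold. Runs in both directions from the seed.
#'
#' @param map the working \linkS4class{GridMap}.
#' @param target the generic C-alpha \linkS4class{LLKTarget}.
#' @param seed matrix (>= 2 x 3) of ordered seed C-alpha positions, or a
#'   \linkS4class{ChainFragment}.
#' @param threshold acceptance threshold; \code{NULL} derives mean - 2 sd
#'   from the seed's interior scores.
#' @param maxSteps per-direction extension cap.
#' @param nDirections candidate directions per step.
#' @param radii candidate Ca-Ca step lengths (Angstrom).
#' @param densityWeight weight of the standardised-density bonus at the
#'   candidate position.
#' @param source fragment source label.
#' @return A \linkS4class{ChainFragment}.
#' @export
extendChain <- function(map, target, seed, threshold = NULL,
                        maxSteps = 50L, nDirections = 60L,
                        radii = c(3.4, 3.8, 4.2), densityWeight = 2,
                        source = "seed") {
    if (is(seed, "ChainFragment")) seed <- seed@ca
    seed <- as.matrix(seed)
    if (nrow(seed) < 2L) stop("a seed needs at least 2 ordered C-alphas")
    interp <- .mapInterpolant(map)
    mu <- mean(map@data); sdv <- stats::sd(as.vector(map@data))
    zfun <- function(p) {
        v <- .interpCubic(interp, matrix(p, 1, 3))
        if (is.na(v)) -5 else (v - mu) / sdv
    }
    dirs <- .extDirs(nDirections)

    seedScore <- function(cas) {
        n <- nrow(cas)
        if (n < 3L) return(numeric(0))
        vapply(2:(n - 1L), function(i) {
            .candScore(interp, target, cas[i - 1L, ], cas[i, ],
                       cas[i + 1L, ], zfun, densityWeight)
        }, numeric(1))
    }
    if (is.null(threshold)) {
        ss <- seedScore(seed)
        threshold <- if (length(ss) >= 2L) mean(ss) - 2 * stats::sd(ss)
                     else if (length(ss)) ss - abs(ss) * 0.5
                     else -Inf
    }

    extendOnce <- function(chain) {
        n <- nrow(chain)
        a <- chain[n - 1L, ]; b <- chain[n, ]
        # candidate positions on shells around b
        cand <- do.call(rbind, lapply(radii, function(r)
            sweep(dirs * r, 2, b, "+")))
        dPrev <- sqrt(rowSums(sweep(cand, 2, a)^2))
        ok <- dPrev >= 4.5
        if (nrow(chain) > 2L) {
            # collision with all non-neighbouring existing C-alphas
            for (j in seq_len(n - 1L)) {
                dj <- sqrt(rowSums(sweep(cand, 2, chain[j, ])^2))
                ok <- ok & dj >= 3.0
            }
        }
        cand <- cand[ok, , drop = FALSE]
        if (!nrow(cand)) return(NULL)
        sc <- vapply(seq_len(nrow(cand)), function(k)
            .candScore(interp, target, a, b, cand[k, ], zfun,
                       densityWeight), numeric(1))
        k <- which.max(sc)
        if (!is.finite(sc[k]) || sc[k] < threshold) return(NULL)
        list(pos = cand[k, ], score = sc[k])
    }

    grow <- function(chain) {
        scores <- numeric(0)
        for (s in seq_len(maxSteps)) {
            step <- extendOnce(chain)
            if (is.null(step)) break
            chain <- rbind(chain, step$pos)
            scores <- c(scores, step$score)
        }
        list(chain = chain, scores = scores)
    }

    # grow forward first, then backward against the full forward chain so
    # the two growth directions cannot collide with each other
    fwd <- grow(seed)
    bwd <- grow(fwd$chain[rev(seq_len(nrow(fwd$chain))), , drop = FALSE])
    ca <- bwd$chain[rev(seq_len(nrow(bwd$chain))), , drop = FALSE]
    llk <- c(rev(bwd$scores),
             rep(NA_real_, nrow(seed)), fwd$scores)
    # score the (now interior) seed positions too
    full <- ca
    for (i in seq_len(nrow(full))) {
        if (is.na(llk[i]) && i > 1L && i < nrow(full)) {
            llk[i] <- .candScore(interp, target, full[i - 1L, ], full[i, ],
                                 full[i + 1L, ], zfun, densityWeight)
        }
    }
    ChainFragment(ca, llk = llk, source = source)
}

.fragMeanLLK <- function(f) {
    v <- f@llk[is.finite(f@llk)]
    if (!length(v)) -Inf else mean(v)
}

# try joining two fragments end-to-end in the given order
.tryJoin <- function(f1, f2) {
    n1 <- nrow(f1@ca)
    gap <- sqrt(sum((f1@ca[n1, ] - f2@ca[1L, ])^2))
    if (gap < 3.0 || gap > 4.2) return(NULL)
    ca <- rbind(f1@ca, f2@ca)
    out <- tryCatch(
        ChainFragment(ca, llk = c(f1@llk, f2@llk),
                      source = paste(f1@source, f2@source, sep = "+"),
                      types = c(f1@types, f2@types)),
        error = function(e) NULL)
    out
}

.reverseFragment <- function(f) {
    idx <- rev(seq_len(nrow(f@ca)))
    ChainFragment(f@ca[idx, , drop = FALSE], llk = f@llk[idx],
                  source = f@source, types = f@types[idx])
}

#' Merge and deduplicate chain fragments
#'
#' Overlapping traces are deduplicated keeping the higher mean-LLK
#' fragment (overlap ends are trimmed; fragments mostly covered by better
#' ones are dropped), then fragments with compatible free ends
#' (3.0-4.2 Angstrom, consistent direction) are joined. The result
#' satisfies all chain-geometry invariants.
#'
#' @param fragments list of \linkS4class{ChainFragment}s.
#' @return list of merged \linkS4class{ChainFragment}s.
#' @export
mergeFragments <- function(fragments) {
    if (!length(fragments)) return(list())
    ord <- order(vapply(fragments, .fragMeanLLK, numeric(1)),
                 decreasing = TRUE)
    keptCA <- NULL
    kept <- list()
    for (i in ord) {
        f <- fragments[[i]]
        if (is.null(keptCA)) {
            kept <- list(f); keptCA <- f@ca; next
        }
        near <- vapply(seq_len(nrow(f@ca)), function(j)
            min(sqrt(rowSums(sweep(keptCA, 2, f@ca[j, ])^2))) < 3.0,
            logical(1))
        if (mean(near) > 0.5) next
        # trim overlapped runs off both ends
        keep <- !near
        first <- which(keep)[1L]
        last <- utils::tail(which(keep), 1L)
        if (is.na(first) || last - first + 1L < 2L) next
        if (any(near[first:last])) next  # interior overlap: drop whole
        idx <- first:last
        f2 <- tryCatch(
            ChainFragment(f@ca[idx, , drop = FALSE], llk = f@llk[idx],
                          source = f@source, types = f@types[idx]),
            error = function(e) NULL)
        if (is.null(f2)) next
        kept[[length(kept) + 1L]] <- f2
        keptCA <- rbind(keptCA, f2@ca)
    }
    # join pass: consider both orders and reversals until stable
    repeat {
        joined <- FALSE
        for (i in seq_along(kept)) {
            for (j in seq_along(kept)) {
                if (i == j) next
                f12 <- .tryJoin(kept[[i]], kept[[j]])
                if (is.null(f12))
                    f12 <- .tryJoin(kept[[i]], .reverseFragment(kept[[j]]))
                if (!is.null(f12)) {
                    kept[[i]] <- f12
                    kept[[j]] <- NULL
                    joined <- TRUE
                    break
                }
            }
            if (joined) break
        }
        if (!joined) break
    }
    kept
}

#' Assign a sequence to traced fragments
#'
#' Every alignment of the sequence onto each fragment (both directions) is
#' scored as the summed per-position residue-type LLK; the best alignment
#' is accepted only when it beats the second best by a stated margin.
#'
#' @param map the working \linkS4class{GridMap}.
#' @param fragments list of \linkS4class{ChainFragment}s.
#' @param sequence character: one-letter or three-letter residue sequence.
#' @param typeTargets named list of per-type \linkS4class{LLKTarget}s (from
#'   \code{trainLLKTarget}).
#' @param margin required relative gap between best and second-best
#'   alignment scores (fraction of |best|).
#' @return the fragments, with \code{types} filled in where an alignment
#'   was accepted.
#' @export
assignSequence <- function(map, fragments, sequence, typeTargets,
                           margin = 0.05) {
    seq3 <- if (length(sequence) == 1L && nchar(sequence[1]) > 1L &&
                all(strsplit(sequence, "")[[1]] %in% names(.AA13)))
        unname(.AA13[strsplit(sequence, "")[[1]]])
    else as.character(sequence)
    S <- length(seq3)
    interp <- .mapInterpolant(map)
    typeNames <- names(typeTargets)

    seq3rev <- rev(seq3)
    lapply(fragments, function(f) {
        L <- nrow(f@ca)
        if (L < 3L) return(f)
        if (L > S) {
            f@source <- paste0(f@source, ";seq-too-short")
            return(f)
        }
        # per-position, per-type LLK in the fragment's stored traversal;
        # the two direction hypotheses apply the sequence forward and
        # reversed against the same frames, so reversing the input
        # sequence exactly swaps the hypotheses
        M <- matrix(NA_real_, L, length(typeNames),
                    dimnames = list(NULL, typeNames))
        for (i in 2:(L - 1L)) {
            R <- .caFrame(f@ca[i - 1L, ], f@ca[i, ], f@ca[i + 1L, ])
            if (is.null(R)) next
            for (tn in typeNames)
                M[i, tn] <- .llkScoreInterp(interp, typeTargets[[tn]],
                                            f@ca[i, ], R)
        }
        alignScore <- function(sq, off) {
            tot <- 0; n <- 0L
            for (i in 2:(L - 1L)) {
                tn <- sq[off + i]
                if (!tn %in% typeNames || is.na(M[i, tn])) next
                tot <- tot + M[i, tn]; n <- n + 1L
            }
            if (n == 0L) -Inf else tot
        }
        offs <- 0:(S - L)
        scores <- c(vapply(offs, alignScore, numeric(1), sq = seq3),
                    vapply(offs, alignScore, numeric(1), sq = seq3rev))
        o <- order(scores, decreasing = TRUE)
        best <- scores[o[1L]]
        second <- if (length(scores) > 1L) scores[o[2L]] else -Inf
        if (!is.finite(best) || best - second <= margin * abs(best))
            return(f)  # ambiguous: no assignment
        k <- o[1L]
        rev <- k > length(offs)
        off <- offs[if (rev) k - length(offs) else k]
        f@types <- if (rev) seq3rev[off + seq_len(L)]
                   else seq3[off + seq_len(L)]
        f
    })
}

#' Convert fragments to a C-alpha model
#'
#' One chain per fragment; residues are ALA where untyped.
#'
#' @param fragments list of \linkS4class{ChainFragment}s.
#' @return An \linkS4class{AtomModel} of CA atoms.
#' @export
fragmentsToModel <- function(fragments) {
    chains <- c(LETTERS, letters, as.character(0:9))
    rows <- list()
    for (i in seq_along(fragments)) {
        f <- fragments[[i]]
        ch <- chains[((i - 1L) %% length(chains)) + 1L]
        for (j in seq_len(nrow(f@ca))) {
            rn <- f@types[j]
            rows[[length(rows) + 1L]] <- data.frame(
                chain = ch, resno = j,
                resname = if (is.na(rn)) "ALA" else rn,
                atom = "CA", element = "C",
                x = f@ca[j, 1], y = f@ca[j, 2], z = f@ca[j, 3],
                b = 20, weight = NA_real_, ss = "-",
                stringsAsFactors = FALSE)
        }
    }
    if (!length(rows)) stop("no fragments to convert")
    AtomModel(do.call(rbind, rows))
}

#' Evaluate a built model against ground truth
#'
#' For every built C-alpha, the distance to the nearest truth C-alpha;
#' reports the fractions within 1 and 2 Angstrom (completeness), the RMSD
#' over those nearest-neighbour distances, and the truth-side coverage
#' (fraction of true C-alphas with a built C-alpha within 1/2 Angstrom).
#'
#' @param built,truth \linkS4class{AtomModel}s (must contain CA atoms).
#' @return list with \code{within1}, \code{within2} (percent of built CAs),
#'   \code{rmsd} (Angstrom), \code{coverage1}, \code{coverage2} (percent of
#'   truth CAs), \code{nBuilt}, \code{nTruth}.
#' @export
evaluateModel <- function(built, truth) {
    cb <- caCoords(built); ct <- caCoords(truth)
    if (!nrow(cb) || !nrow(ct)) stop("both models must contain CA atoms")
    D2 <- outer(rowSums(cb^2), rep(1, nrow(ct))) +
        outer(rep(1, nrow(cb)), rowSums(ct^2)) - 2 * cb %*% t(ct)
    D2 <- pmax(D2, 0)
    dBuilt <- sqrt(apply(D2, 1L, min))
    dTruth <- sqrt(apply(D2, 2L, min))
    list(within1 = 100 * mean(dBuilt < 1),
         within2 = 100 * mean(dBuilt < 2),
         rmsd = sqrt(mean(dBuilt^2)),
         coverage1 = 100 * mean(dTruth < 1),
         coverage2 = 100 * mean(dTruth < 2),
         nBuilt = nrow(cb), nTruth = nrow(ct))
}
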