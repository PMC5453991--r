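# PDB coordinate I/O. Reading goes through bio3d (including HELIX/SHEET
# records); writing is done locally so secondary-structure records can be
# emitted alongside the ATOM records.

#' Read a PDB file into an AtomModel
#'
#' ATOM/HETATM records are read via \code{bio3d::read.pdb}; HELIX and SHEET
#' records, when present, are converted into per-residue secondary-structure
#' labels ("H"/"E"). Residues without a CA atom are kept but reported in a
#' warning, since they cannot be used for tracing.
#'
#' @param path path to a PDB file.
#' @return An \linkS4class{AtomModel}.
#' @export
readModel <- function(path) {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    a <- pdb$atom
    chain <- ifelse(is.na(a$chain), " ", a$chain)
    element <- trimws(ifelse(is.na(a$elesy) | trimws(a$elesy) == "",
                             substr(trimws(a$elety), 1L, 1L), a$elesy))
    atoms <- data.frame(
        chain = chain, resno = a$resno, resname = trimws(a$resid),
        atom = trimws(a$elety), element = element,
        x = a$x, y = a$y, z = a$z,
        b = ifelse(is.na(a$b), 0, a$b),
        weight = NA_real_, ss = "-",
        stringsAsFactors = FALSE)

    labelRange <- function(atoms, start, end, ch, lab) {
        sel <- atoms$chain == ch & atoms$resno >= start & atoms$resno <= end
        atoms$ss[sel] <- lab
        atoms
    }
    hx <- pdb$helix
    if (!is.null(hx) && length(hx$start))
        for (i in seq_along(hx$start))
            atoms <- labelRange(atoms, hx$start[i], hx$end[i],
                                hx$chain[i], "H")
    sh <- pdb$sheet
    if (!is.null(sh) && length(sh$start))
        for (i in seq_along(sh$start))
            atoms <- labelRange(atoms, sh$start[i], sh$end[i],
                                sh$chain[i], "E")

    resKey <- paste(atoms$chain, atoms$resno)
    hasCA <- resKey %in% resKey[atoms$atom == "CA"]
    if (any(!hasCA)) {
        missing <- unique(resKey[!hasCA])
        warning(sprintf("%d residue(s) without a CA atom (kept, flagged): %s",
                        length(missing),
                        paste(utils::head(missing, 5L), collapse = ", ")))
    }
    AtomModel(atoms)
}

# One fixed-width ATOM record.
.formatAtomLine <- function(serial, atom, resname, chain, resno, x, y, z,
                            b, element) {
    name <- if (nchar(atom) < 4L) sprintf(" %-3s", atom) else atom
    sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, resname, chain, resno, x, y, z, 1.00, b,
            sprintf("%2s", element))
}

# Contiguous same-label runs of a per-residue ss vector, per chain.
.ssRuns <- function(atoms) {
    ca <- atoms[atoms$atom == "CA", , drop = FALSE]
    out <- list()
    for (ch in unique(ca$chain)) {
        c1 <- ca[ca$chain == ch, , drop = FALSE]
        if (!nrow(c1)) next
        r <- rle(c1$ss)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (k in seq_along(r$values)) {
            if (r$values[k] %in% c("H", "E"))
                out[[length(out) + 1L]] <- list(
                    ss = r$values[k], chain = ch,
                    start = c1$resno[starts[k]], end = c1$resno[ends[k]],
                    startRes = c1$resname[starts[k]],
                    endRes = c1$resname[ends[k]])
        }
    }
    out
}

#' Write an AtomModel as a PDB file
#'
#' Emits HELIX/SHEET records derived from the per-residue secondary-structure
#' labels, followed by ATOM records (coordinates at the format's 3-decimal
#' precision) with TER/END.
#'
#' @param model an \linkS4class{AtomModel}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeModel <- function(model, path) {
    stopifnot(is(model, "AtomModel"))
    a <- model@atoms
    lines <- character(0)
    runs <- .ssRuns(a)
    nh <- 0L; ns <- 0L
    for (r in runs) {
        if (r$ss == "H") {
            nh <- nh + 1L
            lines <- c(lines, sprintf(
                "HELIX  %3d %3s %3s %1s %4d  %3s %1s %4d %2d%30s %5d",
                nh, sprintf("%3d", nh), r$startRes, r$chain, r$start,
                r$endRes, r$chain, r$end, 1L, "", r$end - r$start + 1L))
        } else {
            ns <- ns + 1L
            lines <- c(lines, sprintf(
                "SHEET  %3d %3s%2d %3s %1s%4d  %3s %1s%4d%2d",
                ns, sprintf("%3s", "S1"), 1L, r$startRes, r$chain, r$start,
                r$endRes, r$chain, r$end, 0L))
        }
    }
    serial <- 0L
    for (i in seq_len(nrow(a))) {
        serial <- serial + 1L
        lines <- c(lines, .formatAtomLine(
            serial, a$atom[i], a$resname[i], a$chain[i], a$resno[i],
            a$x[i], a$y[i], a$z[i], a$b[i], a$element[i]))
        last <- i == nrow(a) || a$chain[i + 1L] != a$chain[i]
        if (last) {
            serial <- serial + 1L
            lines <- c(lines, sprintf("TER   %5d      %-3s %1s%4d",
                                      serial, a$resname[i], a$chain[i],
                                      a$resno[i]))
        }
    }
    lines <- c(lines, "END")
    con <- tryCatch(file(path, "wb"),
                    error = function(e) stop("cannot open for writing: ", path))
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
    invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path path to a FASTA file of one-letter amino-acid sequences.
#' @return named character vector of sequences.
#' @export
readFasta <- function(path) {
    lines <- readLines(path)
    hdr <- grep("^>", lines)
    if (!length(hdr)) stop("no FASTA headers in ", path)
    starts <- hdr + 1L
    ends <- c(hdr[-1L] - 1L, length(lines))
    seqs <- vapply(seq_along(hdr), function(i) {
        paste(gsub("[^A-Za-z]", "", lines[starts[i]:ends[i]]), collapse = "")
    }, character(1))
    names(seqs) <- sub("^>\\s*", "", lines[hdr])
    toupper(seqs)
}
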