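## Tabular text I/O: snapshot tables (cell_id,x) and geometry tables
## (cell_id,L,z). Values are written with 17 significant digits so that
## write -> read -> write round-trips bit-exactly.

.fmt <- function(x) formatC(x, digits = 17, format = "g")

#' Write a snapshot set to tabular text files
#'
#' @param data a \linkS4class{SnapshotSet}
#' @param positionsFile output csv with header `cell_id,x`, one row per
#'   particle (cells with no particles contribute no rows)
#' @param geometryFile output csv with header `cell_id,L,z`, one row per
#'   cell
#' @return invisibly, the two file paths
#' @export
writeSnapshotSet <- function(data, positionsFile, geometryFile) {
    stopifnot(is(data, "SnapshotSet"))
    ids <- cellIds(data)
    n <- particleCounts(data)
    pos <- data.frame(cell_id = rep(ids, n),
                      x = .fmt(unlist(positions(data), use.names = FALSE)))
    if (sum(n) == 0) pos <- data.frame(cell_id = character(),
                                       x = character())
    write.table(pos, positionsFile, sep = ",", quote = FALSE,
                row.names = FALSE)
    geo <- data.frame(
        cell_id = ids,
        L = .fmt(vapply(geometry(data), domainLength, numeric(1))),
        z = .fmt(vapply(geometry(data), sourcePosition, numeric(1))))
    write.table(geo, geometryFile, sep = ",", quote = FALSE,
                row.names = FALSE)
    invisible(c(positionsFile, geometryFile))
}

.readHeadered <- function(file, expected) {
    hdr <- strsplit(readLines(file, n = 1L), ",", fixed = TRUE)[[1]]
    if (!identical(trimws(hdr), expected))
        stop("malformed header in '", file, "' (line 1): expected '",
             paste(expected, collapse = ","), "', found '",
             paste(hdr, collapse = ","), "'")
    read.table(file, header = TRUE, sep = ",",
               colClasses = c("character",
                              rep("numeric", length(expected) - 1L)))
}

#' Read a snapshot set from tabular text files
#'
#' Positions are validated to lie strictly inside their cell's domain;
#' offending rows are named in the error message. Every cell listed in the
#' geometry table yields a snapshot, including cells with zero particles.
#'
#' @param positionsFile csv with header `cell_id,x`
#' @param geometryFile csv with header `cell_id,L,z`
#' @return a \linkS4class{SnapshotSet}
#' @export
readSnapshotSet <- function(positionsFile, geometryFile) {
    geo <- .readHeadered(geometryFile, c("cell_id", "L", "z"))
    pos <- .readHeadered(positionsFile, c("cell_id", "x"))
    if (anyDuplicated(geo$cell_id))
        stop("duplicate cell ids in geometry table")
    unknown <- setdiff(pos$cell_id, geo$cell_id)
    if (length(unknown))
        stop("positions reference cells absent from the geometry table: ",
             paste(unique(unknown), collapse = ", "))
    Lof <- stats::setNames(geo$L, geo$cell_id)
    bad <- which(pos$x <= 0 | pos$x >= Lof[pos$cell_id])
    if (length(bad))
        stop("positions on or outside the absorbing boundary at data row",
             if (length(bad) > 1) "s" else "", " ",
             paste(bad + 1L, collapse = ", "),
             " of '", positionsFile, "'")
    snaps <- lapply(seq_len(nrow(geo)), function(i) {
        id <- geo$cell_id[i]
        Snapshot(id, CellGeometry(L = geo$L[i], z = geo$z[i]),
                 pos$x[pos$cell_id == id])
    })
    SnapshotSet(snaps)
}

#' Write posterior chains as tabular text
#'
#' @param chains a \linkS4class{PosteriorChains}
#' @param prior the \linkS4class{PriorSpec} used in fitting (for the
#'   log-posterior column)
#' @param file output csv with header `iter,lam,mu,logpost`
#' @return the file path, invisibly
#' @export
writeChains <- function(chains, prior, file) {
    stopifnot(is(chains, "PosteriorChains"))
    df <- data.frame(iter = seq_along(chains@lam),
                     lam = .fmt(chains@lam), mu = .fmt(chains@mu),
                     logpost = .fmt(.logPosterior(chains, prior)))
    write.table(df, file, sep = ",", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Write an HDPR polygon as a vertex list
#'
#' @param region an \linkS4class{HDPRegion}
#' @param file output csv with header `lam,mu`
#' @return the file path, invisibly
#' @export
writeHDPRegion <- function(region, file) {
    stopifnot(is(region, "HDPRegion"))
    v <- region@vertices
    df <- data.frame(lam = .fmt(v[, 1]), mu = .fmt(v[, 2]))
    write.table(df, file, sep = ",", quote = FALSE, row.names = FALSE)
    invisible(file)
}
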