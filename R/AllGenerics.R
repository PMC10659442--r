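## Accessors and show() methods. Slots are never accessed with @ from user
## code; these generics are the supported surface.

#' @name accessors
#' @title Accessors for snapBDD containers
#' @description Small generics exposing the slots of the package's S4
#'   containers: rates, geometry, positions, counts and MCMC metadata.
#' @param x an object of the documented class
#' @return the corresponding slot value (see each method)
NULL

#' @rdname accessors
#' @export
setGeneric("birthRate", function(x) standardGeneric("birthRate"))
#' @rdname accessors
#' @export
setGeneric("deathRate", function(x) standardGeneric("deathRate"))
#' @rdname accessors
#' @export
setMethod("birthRate", "NondimParams", function(x) x@lam)
#' @rdname accessors
#' @export
setMethod("deathRate", "NondimParams", function(x) x@mu)

#' @rdname accessors
#' @export
setGeneric("domainLength", function(x) standardGeneric("domainLength"))
#' @rdname accessors
#' @export
setGeneric("sourcePosition", function(x) standardGeneric("sourcePosition"))
#' @rdname accessors
#' @export
setMethod("domainLength", "CellGeometry", function(x) x@L)
#' @rdname accessors
#' @export
setMethod("sourcePosition", "CellGeometry", function(x) x@z)
#' @rdname accessors
#' @export
setMethod("domainLength", "Snapshot", function(x) x@geom@L)
#' @rdname accessors
#' @export
setMethod("sourcePosition", "Snapshot", function(x) x@geom@z)

#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname accessors
#' @export
setMethod("positions", "Snapshot", function(x) x@positions)
#' @rdname accessors
#' @export
setMethod("positions", "SnapshotSet",
    function(x) lapply(x@snapshots, positions))

#' @rdname accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))
#' @rdname accessors
#' @export
setMethod("geometry", "Snapshot", function(x) x@geom)
#' @rdname accessors
#' @export
setMethod("geometry", "SnapshotSet",
    function(x) lapply(x@snapshots, geometry))

#' @rdname accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))
#' @rdname accessors
#' @export
setMethod("cellIds", "SnapshotSet",
    function(x) vapply(x@snapshots, function(s) s@cellId, character(1)))

#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))
#' @rdname accessors
#' @export
setMethod("nCells", "SnapshotSet", function(x) length(x@snapshots))

#' @rdname accessors
#' @export
setGeneric("particleCounts", function(x) standardGeneric("particleCounts"))
#' @rdname accessors
#' @export
setMethod("particleCounts", "Snapshot", function(x) length(x@positions))
#' @rdname accessors
#' @export
setMethod("particleCounts", "SnapshotSet",
    function(x) vapply(x@snapshots, function(s) length(s@positions),
                       integer(1)))

#' @rdname accessors
#' @param i index
#' @export
setMethod("[[", "SnapshotSet", function(x, i) x@snapshots[[i]])

#' @rdname accessors
#' @export
setMethod("length", "SnapshotSet", function(x) length(x@snapshots))

#' @rdname accessors
#' @export
setGeneric("infoEntries", function(x) standardGeneric("infoEntries"))
#' @rdname accessors
#' @export
setMethod("infoEntries", "InfoMatrix", function(x) x@entries)

#' @rdname accessors
#' @export
setGeneric("lamSamples", function(x) standardGeneric("lamSamples"))
#' @rdname accessors
#' @export
setMethod("lamSamples", "PosteriorChains", function(x) x@lam)
#' @rdname accessors
#' @export
setGeneric("muSamples", function(x) standardGeneric("muSamples"))
#' @rdname accessors
#' @export
setMethod("muSamples", "PosteriorChains", function(x) x@mu)
#' @rdname accessors
#' @export
setGeneric("acceptanceRate", function(x) standardGeneric("acceptanceRate"))
#' @rdname accessors
#' @export
setMethod("acceptanceRate", "PosteriorChains", function(x) x@acceptanceRate)
#' @rdname accessors
#' @export
setGeneric("effectiveSize", function(x) standardGeneric("effectiveSize"))
#' @rdname accessors
#' @export
setMethod("effectiveSize", "PosteriorChains", function(x) x@ess)

#' @rdname accessors
#' @export
setGeneric("hdprArea", function(x) standardGeneric("hdprArea"))
#' @rdname accessors
#' @export
setMethod("hdprArea", "HDPRegion", function(x) x@area)
#' @rdname accessors
#' @export
setGeneric("hdprVertices", function(x) standardGeneric("hdprVertices"))
#' @rdname accessors
#' @export
setMethod("hdprVertices", "HDPRegion", function(x) x@vertices)

setMethod("show", "NondimParams", function(object) {
    cat(sprintf("NondimParams: lambda = %g, mu = %g\n",
                object@lam, object@mu))
})

setMethod("show", "CellGeometry", function(object) {
    cat(sprintf("CellGeometry: L = %g, z = %g\n", object@L, object@z))
})

setMethod("show", "Snapshot", function(object) {
    cat(sprintf("Snapshot '%s': %d particles in (0, %g), source at %g\n",
                object@cellId, length(object@positions), object@geom@L,
                object@geom@z))
})

setMethod("show", "SnapshotSet", function(object) {
    n <- particleCounts(object)
    cat(sprintf("SnapshotSet: %d cells, %d particles (mean %.2f per cell)\n",
                length(object@snapshots), sum(n),
                if (length(n)) mean(n) else 0))
})

setMethod("show", "InfoMatrix", function(object) {
    cat("InfoMatrix (Fisher information in (lambda, mu)):\n")
    print(object@entries)
    cat(sprintf("det = %g\n", det(object@entries)))
})

setMethod("show", "PosteriorChains", function(object) {
    cat(sprintf(
        "PosteriorChains: %d draws (%d chains), accept = %.2f\n",
        length(object@lam), length(unique(object@chain)),
        object@acceptanceRate))
    cat(sprintf("  mean lambda = %.4g, mean mu = %.4g; ESS = (%.0f, %.0f)\n",
                mean(object@lam), mean(object@mu),
                object@ess[["lam"]], object@ess[["mu"]]))
})

setMethod("show", "HDPRegion", function(object) {
    cat(sprintf("HDPRegion: level %.2f, %d vertices, area = %g\n",
                object@level, nrow(object@vertices), object@area))
})

setMethod("show", "HeterogeneityModel", function(object) {
    cat(sprintf("HeterogeneityModel: sigmaZ = %g, sigmaL = %g\n",
                object@sigmaZ, object@sigmaL))
})
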