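# Accessor generics: slots are never touched directly by user code.

#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))
#' @export
setGeneric("fieldTime", function(x) standardGeneric("fieldTime"))
#' @export
setGeneric("gridOf", function(x) standardGeneric("gridOf"))
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))
#' @export
setGeneric("lambdas", function(x) standardGeneric("lambdas"))
#' @export
setGeneric("stateTimes", function(x) standardGeneric("stateTimes"))
#' @export
setGeneric("nSolverSteps", function(x) standardGeneric("nSolverSteps"))
#' @export
setGeneric("stateAt", function(x, step) standardGeneric("stateAt"))
#' @export
setGeneric("observations", function(x) standardGeneric("observations"))
#' @export
setGeneric("obsTimes", function(x) standardGeneric("obsTimes"))
#' @export
setGeneric("obsMasses", function(x) standardGeneric("obsMasses"))
#' @export
setGeneric("controlValues", function(x) standardGeneric("controlValues"))
#' @export
setGeneric("supportMasks", function(x) standardGeneric("supportMasks"))
#' @export
setGeneric("objectiveHistory", function(x) standardGeneric("objectiveHistory"))
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))
#' @export
setGeneric("fittedControl", function(x) standardGeneric("fittedControl"))
#' @export
setGeneric("fittedTrajectory", function(x) standardGeneric("fittedTrajectory"))

#' @rdname PhaseField-class
#' @param x object.
#' @export
setMethod("fieldValues", "PhaseField", function(x) x@values)
#' @rdname PhaseField-class
#' @export
setMethod("fieldTime", "PhaseField", function(x) x@time)
#' @rdname PhaseField-class
#' @export
setMethod("gridOf", "PhaseField", function(x) x@grid)
#' @rdname GridSpec-class
#' @param x object.
#' @export
setMethod("nNodes", "GridSpec", function(x) x@n)
#' @rdname GridSpec-class
#' @export
setMethod("gridSpacing", "GridSpec", function(x) x@spacing)

#' @rdname StateTrajectory-class
#' @param x object.
#' @param step solver step index (0-based: 0 is the initial state).
#' @export
setMethod("lambdas", "StateTrajectory", function(x) x@lambdas)
#' @rdname StateTrajectory-class
#' @export
setMethod("stateTimes", "StateTrajectory", function(x) x@times)
#' @rdname StateTrajectory-class
#' @export
setMethod("nSolverSteps", "StateTrajectory", function(x) length(x@lambdas))
#' @rdname StateTrajectory-class
#' @export
setMethod("stateAt", "StateTrajectory", function(x, step)
  phaseField(x@states[[step + 1L]], x@grid, time = x@times[step + 1L]))
#' @rdname StateTrajectory-class
#' @export
setMethod("gridOf", "StateTrajectory", function(x) x@grid)

#' @rdname TargetSequence-class
#' @param x object.
#' @export
setMethod("observations", "TargetSequence", function(x) x@observations)
#' @rdname TargetSequence-class
#' @export
setMethod("obsTimes", "TargetSequence", function(x) x@times)
#' @rdname TargetSequence-class
#' @export
setMethod("obsMasses", "TargetSequence", function(x) x@masses)
#' @rdname TargetSequence-class
#' @export
setMethod("gridOf", "TargetSequence", function(x) x@grid)

#' @rdname ControlField-class
#' @param x object.
#' @export
setMethod("controlValues", "ControlField", function(x) x@values)
#' @rdname ControlField-class
#' @export
setMethod("supportMasks", "ControlField", function(x) x@masks)
#' @rdname ControlField-class
#' @export
setMethod("gridOf", "ControlField", function(x) x@grid)

#' @rdname PairResult-class
#' @param x object.
#' @export
setMethod("objectiveHistory", "PairResult", function(x) x@objectiveHistory)
#' @rdname PairResult-class
#' @export
setMethod("isConverged", "PairResult", function(x) x@converged)
#' @rdname PairResult-class
#' @export
setMethod("fittedControl", "PairResult", function(x) x@control)
#' @rdname PairResult-class
#' @export
setMethod("fittedTrajectory", "PairResult", function(x) x@trajectory)

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d nodes on [0,1]^2, spacing %.4g\n",
              object@n, object@n, object@spacing))
})

setMethod("show", "PhysicalParams", function(object) {
  cat("PhysicalParams\n")
  cat(sprintf("  surface tension delta : %g pN\n", object@delta))
  cat(sprintf("  friction tau          : %g pN s/um^2\n", object@tau))
  cat(sprintf("  membrane thickness eps: %g um\n", object@eps))
  cat(sprintf("  domain length L       : %g um\n", object@L))
  cat(sprintf("  duration T            : %g s (frame interval %g s)\n",
              object@T_total, object@TI))
  cat(sprintf("  characteristic force F: %g pN\n", object@F_char))
})

setMethod("show", "DimensionlessParams", function(object) {
  cat("DimensionlessParams\n")
  cat(sprintf("  eps_bar %.4g, tau_bar %.4g, delta_bar %.4g\n",
              object@eps_bar, object@tau_bar, object@delta_bar))
  cat(sprintf("  theta %.3g, RTS %d, substeps %s\n", object@theta, object@RTS,
              if (is.na(object@substeps)) "auto" else object@substeps))
})

setMethod("show", "PhaseField", function(object) {
  v <- object@values
  cat(sprintf("PhaseField: %d x %d, t = %.4g, range [%.3f, %.3f], mass %.4f\n",
              nrow(v), ncol(v), object@time, min(v), max(v),
              quadMean(v, object@grid)))
})

setMethod("show", "StateTrajectory", function(object) {
  cat(sprintf("StateTrajectory: %d steps on [%.4g, %.4g], dt = %.3g, grid %d^2\n",
              length(object@lambdas), object@times[1],
              object@times[length(object@times)], object@dt, object@grid@n))
})

setMethod("show", "TargetSequence", function(object) {
  cat(sprintf("TargetSequence: %d observations at t = %s on grid %d^2\n",
              length(object@observations),
              paste(signif(object@times, 4), collapse = ", "), object@grid@n))
})

setMethod("show", "PairResult", function(object) {
  nh <- length(object@objectiveHistory)
  cat(sprintf("PairResult %s: %s after %d iterations, J = %.4g (misfit %.4g)\n",
              object@label,
              if (object@converged) "converged" else "not converged",
              nh - 1L, object@objectiveHistory[nh], object@misfit))
})

setMethod("show", "SyntheticMovie", function(object) {
  cat(sprintf("SyntheticMovie '%s': %d frames of %d x %d px (seed %s)\n",
              object@meta$generator, length(object@frames),
              nrow(object@frames[[1]]@pixels), ncol(object@frames[[1]]@pixels),
              deparse(object@meta$seed)))
})
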