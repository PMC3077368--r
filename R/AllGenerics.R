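#' @rdname PhyloAlignment-class
#' @param x,object a `PhyloAlignment`
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))
#' @rdname PhyloAlignment-class
#' @export
setGeneric("alphabet", function(x) standardGeneric("alphabet"))
#' @rdname PhyloAlignment-class
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @rdname PhyloAlignment-class
#' @export
setGeneric("stateMatrix", function(x) standardGeneric("stateMatrix"))

#' @rdname AccelTestResult-class
#' @param object an `AccelTestResult`
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname AccelTestResult-class
#' @export
setGeneric("lrtStat", function(object) standardGeneric("lrtStat"))
#' @rdname AccelTestResult-class
#' @export
setGeneric("omegaHat", function(object) standardGeneric("omegaHat"))
#' @rdname AccelTestResult-class
#' @export
setGeneric("focalRate", function(object) standardGeneric("focalRate"))
#' @rdname AccelTestResult-class
#' @export
setGeneric("flags", function(object) standardGeneric("flags"))

setMethod("taxa", "PhyloAlignment", function(x) x@taxa)
setMethod("alphabet", "PhyloAlignment", function(x) x@alphabet)
setMethod("nSites", "PhyloAlignment", function(x) ncol(x@states))
setMethod("stateMatrix", "PhyloAlignment", function(x) x@states)

setMethod("pValue", "AccelTestResult", function(object) object@pValue)
setMethod("lrtStat", "AccelTestResult", function(object) object@lrt)
setMethod("omegaHat", "AccelTestResult", function(object) object@omegaHat)
setMethod("focalRate", "AccelTestResult", function(object) object@RHat)
setMethod("flags", "AccelTestResult", function(object) object@flags)

setMethod("show", "PhyloAlignment", function(object) {
  cat("PhyloAlignment:", length(object@taxa), "taxa x", ncol(object@states),
      object@alphabet, "sites\n")
  miss <- mean(is.na(object@states))
  cat("  taxa:", paste(utils::head(object@taxa, 7), collapse = ", "),
      if (length(object@taxa) > 7) "..." else "", "\n")
  cat(sprintf("  missing/masked: %.1f%%\n", 100 * miss))
})

setMethod("show", "SubstitutionModel", function(object) {
  cat("SubstitutionModel:", length(object@states), "states,",
      object@normalization, "normalization\n")
})

setMethod("show", "RegionalContext", function(object) {
  cat("RegionalContext over", length(object@branchIds), "branches,",
      length(object@neighborIds), "neighbor loci\n")
  cat(sprintf("  kappa = %.3f; dSr range [%.4g, %.4g]\n", object@kappa,
              min(object@dSr), max(object@dSr)))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "AccelTestResult", function(object) {
  cat("AccelTestResult [", object@focal, "]\n", sep = "")
  cat(sprintf("  lnL0 = %.4f  lnL1 = %.4f  LRT = %.4f  p = %.4g\n",
              object@lnL0, object@lnL1, object@lrt, object@pValue))
  cat(sprintf("  omega_hat = %.4g  R_hat = %.4g\n", object@omegaHat, object@RHat))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' @rdname GenotypeMatrix-class
#' @param x,object a `GenotypeMatrix`
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))
#' @rdname GenotypeMatrix-class
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))
#' @rdname GenotypeMatrix-class
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))
#' @rdname GenotypeMatrix-class
#' @export
setGeneric("qcLog", function(x) standardGeneric("qcLog"))

setMethod("dosage", "GenotypeMatrix", function(x) x@dosage)
setMethod("phenotypes", "GenotypeMatrix", function(x) x@pheno)
setMethod("snpInfo", "GenotypeMatrix", function(x) x@snpInfo)
setMethod("qcLog", "GenotypeMatrix", function(x) x@qcLog)

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@dosage), "individuals x",
      ncol(object@dosage), "SNPs\n")
  if ("status" %in% names(object@pheno))
    cat("  cases:", sum(object@pheno$status == 1, na.rm = TRUE),
        " controls:", sum(object@pheno$status == 0, na.rm = TRUE), "\n")
  if (nrow(object@qcLog)) cat("  QC removals logged:", nrow(object@qcLog), "\n")
})
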