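#' Construct a SpectralSet from a reflectance matrix and targets
#'
#' @param reflectance numeric matrix, N samples x L bands, ordered by
#'   wavelength. No missing values are allowed.
#' @param targets length-N vector: class labels (any atomic type) for
#'   classification, numeric response for regression.
#' @param task \code{"classification"} or \code{"regression"}.
#'
#' @details Classification labels are re-encoded to contiguous 0-based
#' integer codes in the sort order of the original labels; the mapping is
#' kept in the object and available via \code{\link{labelMap}}.
#'
#' @return a validated \linkS4class{SpectralSet}.
#' @examples
#' x <- matrix(runif(40), nrow = 4)
#' s <- spectralSet(x, c("corn", "wheat", "corn", "wheat"), "classification")
#' bandCount(s)   # 10
#' targets(s)     # 0 1 0 1
#' @export
spectralSet <- function(reflectance,
                        targets,
                        task = c("classification", "regression")) {
  task <- match.arg(task)
  reflectance <- as.matrix(reflectance)
  if (!is.numeric(reflectance))
    dataError("reflectance must be a numeric matrix")
  if (length(targets) != nrow(reflectance))
    dataError("targets must have one entry per sample (row)")
  if (anyNA(targets))
    dataError("targets contain missing values")

  if (task == "classification") {
    lv <- sort(unique(as.character(targets)))
    lmap <- stats::setNames(seq_along(lv) - 1L, lv)
    y <- unname(lmap[as.character(targets)])
  } else {
    if (!is.numeric(targets))
      dataError("regression targets must be numeric")
    lmap <- integer(0)
    y <- as.numeric(targets)
  }

  L <- ncol(reflectance)
  a <- t(reflectance)  # assay convention: bands x samples
  dimnames(a) <- list(paste0("band_", seq_len(L)),
                      paste0("sample_", seq_len(nrow(reflectance))))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(reflectance = a),
    colData = S4Vectors::DataFrame(target = y)
  )
  new("SpectralSet", se, task = task, labelMap = lmap)
}

#' @rdname accessors
#' @export
setMethod("reflectance", "SpectralSet", function(x) {
  t(SummarizedExperiment::assay(x, "reflectance"))
})

#' @rdname accessors
#' @export
setMethod("targets", "SpectralSet", function(x) {
  SummarizedExperiment::colData(x)$target
})

#' @rdname accessors
#' @export
setMethod("taskKind", "SpectralSet", function(x) x@task)

#' @rdname accessors
#' @export
setMethod("bandCount", "SpectralSet", function(x) nrow(x))

#' @rdname accessors
#' @export
setMethod("nClasses", "SpectralSet", function(x) {
  if (x@task != "classification") return(NA_integer_)
  length(unique(targets(x)))
})

#' @rdname accessors
#' @export
setMethod("labelMap", "SpectralSet", function(x) x@labelMap)

setMethod("show", "SpectralSet", function(object) {
  cat("SpectralSet:", ncol(object), "samples x", nrow(object), "bands,",
      object@task, "\n")
  if (object@task == "classification")
    cat("  classes:", nClasses(object), "\n")
})

#' Convert absorbance to reflectance
#'
#' Laboratory spectra (e.g. soil spectroscopy) are often recorded as
#' absorbance A; the selection algorithm operates on reflectance
#' R = 1 / 10^A, applied elementwise.
#'
#' @param a finite numeric vector or matrix of absorbance values.
#' @return reflectance of the same shape.
#' @examples
#' absorbanceToReflectance(c(0, 1, 2))  # 1, 0.1, 0.01
#' @export
absorbanceToReflectance <- function(a) {
  if (!is.numeric(a) || any(!is.finite(a)))
    dataError("absorbance values must be finite numbers")
  10^(-a)
}

#' Read a delimited spectral table into a SpectralSet
#'
#' Reads a CSV or TSV file (delimiter chosen by file extension) with a
#' header row: one row per sample, one numeric column per band ordered by
#' wavelength, plus the named target column.
#'
#' @param path path to the table.
#' @param targetColumn name of the target column.
#' @param task \code{"classification"} or \code{"regression"}.
#' @param absorbance logical; if TRUE, band values are absorbances and
#'   are converted to reflectance on load.
#' @param dropMissing logical; if TRUE rows with missing band values are
#'   dropped (with a warning reporting the count), otherwise they are an
#'   error.
#' @return a \linkS4class{SpectralSet}; band order is preserved exactly
#'   as in the file.
#' @seealso \code{\link{writeSpectra}} for the inverse operation.
#' @export
readSpectra <- function(path, targetColumn,
                        task = c("classification", "regression"),
                        absorbance = FALSE, dropMissing = TRUE) {
  task <- match.arg(task)
  if (!file.exists(path)) dataError(paste0("file not found: ", path))
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!targetColumn %in% names(df))
    configError(paste0("target column '", targetColumn, "' not found"))
  y <- df[[targetColumn]]
  bandCols <- setdiff(names(df), targetColumn)
  if (length(bandCols) < 2L)
    dataError("at least 2 band columns are required")
  for (cn in bandCols) {
    v <- df[[cn]]
    if (is.character(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(vn))
      if (length(bad))
        dataError(sprintf("non-numeric band value at row %d, column '%s'",
                          bad[1L], cn))
      vn[!is.na(v) & v == ""] <- NA_real_
      df[[cn]] <- vn
    }
  }
  m <- as.matrix(df[bandCols])
  storage.mode(m) <- "double"
  miss <- which(rowSums(is.na(m)) > 0L)
  if (length(miss)) {
    if (!dropMissing)
      dataError(sprintf("%d row(s) contain missing band values", length(miss)))
    warning(sprintf("dropped %d row(s) with missing band values",
                    length(miss)))
    m <- m[-miss, , drop = FALSE]
    y <- y[-miss]
  }
  if (absorbance) m <- absorbanceToReflectance(m)
  spectralSet(m, y, task)
}

#' Write a SpectralSet to a delimited table
#'
#' Writes one row per sample with band columns \code{band_1..band_L} and
#' the target column, at full double precision so that a
#' \code{\link{readSpectra}} round trip reproduces the data exactly.
#' For classification the stored 0-based integer codes are written.
#'
#' @param x a \linkS4class{SpectralSet}.
#' @param path output path (.csv or .tsv).
#' @param targetColumn name for the target column.
#' @return \code{path}, invisibly.
#' @export
writeSpectra <- function(x, path, targetColumn = "target") {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  m <- reflectance(x)
  df <- as.data.frame(lapply(seq_len(ncol(m)), function(j)
    format(m[, j], digits = 17L, trim = TRUE, scientific = FALSE)))
  names(df) <- paste0("band_", seq_len(ncol(m)))
  df[[targetColumn]] <- format(targets(x), digits = 17L, trim = TRUE,
                               scientific = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
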