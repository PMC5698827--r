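# Single-file JSON container for trained models. Plain text, full double
# precision, portable across platforms; readers reject unknown versions.

.MODEL_FORMAT_VERSION <- "1.0"

#' Write a trained DSN model to a JSON file
#'
#' The container stores the format version, training configuration, input
#' scaling, class labels and every module's `W`/`U` matrix at full double
#' precision. Identical models serialize to byte-identical files.
#'
#' @param model A [DsnModel-class] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeDsnModel <- function(model, path) {
  obj <- list(
    format = "MetaGeneDSN-dsn-model",
    version = .MODEL_FORMAT_VERSION,
    dRaw = model@dRaw,
    classes = model@classes,
    featureNames = model@featureNames,
    scalerCenter = model@scalerCenter,
    scalerScale = model@scalerScale,
    minmaxMin = model@minmaxMin,
    minmaxRange = model@minmaxRange,
    config = model@config,
    trainError = model@trainError,
    modules = lapply(model@modules, function(m) {
      list(W = unname(m$W), U = unname(m$U))
    })
  )
  # 17 significant digits round-trip IEEE doubles exactly
  json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                           pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' Read a trained DSN model from a JSON file
#'
#' @param path Path to a file written by [writeDsnModel()].
#' @return A [DsnModel-class] object.
#' @export
readDsnModel <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "MetaGeneDSN-dsn-model")) {
    stop("not a MetaGeneDSN model file: ", path)
  }
  if (!identical(obj$version, .MODEL_FORMAT_VERSION)) {
    stop("unsupported model format version '", obj$version,
         "' (this build reads version ", .MODEL_FORMAT_VERSION, ")")
  }
  modules <- if (is.data.frame(obj$modules)) {
    # jsonlite simplifies a list of homogeneous records to a data.frame
    lapply(seq_len(nrow(obj$modules)), function(i) {
      list(W = obj$modules$W[[i]], U = obj$modules$U[[i]])
    })
  } else {
    lapply(obj$modules, function(m) list(W = m$W, U = m$U))
  }
  methods::new("DsnModel",
               modules = modules,
               scalerCenter = obj$scalerCenter,
               scalerScale = obj$scalerScale,
               minmaxMin = obj$minmaxMin,
               minmaxRange = obj$minmaxRange,
               dRaw = as.integer(obj$dRaw),
               classes = obj$classes,
               featureNames = as.character(unlist(obj$featureNames)),
               config = obj$config,
               trainError = as.numeric(unlist(obj$trainError)),
               version = obj$version)
}
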