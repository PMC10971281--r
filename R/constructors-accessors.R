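#' Build an SVCallSet
#'
#' @param calls data.frame using the package call schema (see
#'   [SVCallSet-class]); missing optional columns are filled with defaults.
#' @param sample sample id; defaults to the one found in `calls`.
#' @param technology `"WGS"`, `"OGM"` or `"RNA"`.
#' @param metadata named list stored alongside the calls.
#' @return An [SVCallSet-class] object.
#' @examples
#' cs <- SVCallSet(data.frame(
#'   id = "d1", svtype = "DEL", chrom1 = "chr1", pos1 = 1000,
#'   chrom2 = "chr1", pos2 = 2000, length = 1000,
#'   support_sr = 5, support_pe = 4, source = "LUMPY", sample = "s1"))
#' svCalls(cs)
#' @export
SVCallSet <- function(calls = emptyCalls(), sample = NULL,
                      technology = "WGS", metadata = list()) {
  calls <- as.data.frame(calls)
  if (is.null(calls$strand1)) calls$strand1 <- rep("+", nrow(calls))
  if (is.null(calls$strand2)) calls$strand2 <- rep("-", nrow(calls))
  if (is.null(calls$length)) calls$length <- rep(NA_real_, nrow(calls))
  if (is.null(calls$support_sr)) calls$support_sr <- rep(0L, nrow(calls))
  if (is.null(calls$support_pe)) calls$support_pe <- rep(0L, nrow(calls))
  if (is.null(calls$support_mol)) calls$support_mol <- rep(0L, nrow(calls))
  if (is.null(calls$flags)) calls$flags <- rep("", nrow(calls))
  if (is.null(sample)) {
    sample <- if (nrow(calls)) calls$sample[1L] else NA_character_
  }
  if (nrow(calls)) calls$sample <- sample
  calls <- calls[, .CALL_COLUMNS, drop = FALSE]
  rownames(calls) <- NULL
  new("SVCallSet", sample = as.character(sample), technology = technology,
      calls = calls, metadata = metadata)
}

#' Empty call table with the package schema
#' @return A zero-row data.frame with all call columns.
#' @export
emptyCalls <- function() {
  data.frame(
    id = character(), svtype = character(), chrom1 = character(),
    pos1 = numeric(), strand1 = character(), chrom2 = character(),
    pos2 = numeric(), strand2 = character(), length = numeric(),
    support_sr = integer(), support_pe = integer(), support_mol = integer(),
    source = character(), sample = character(), flags = character(),
    stringsAsFactors = FALSE
  )
}

#' @describeIn SVCallSet calls table accessor.
#' @param x an `SVCallSet`.
#' @export
svCalls <- function(x) x@calls

#' @describeIn SVCallSet sample id accessor.
#' @export
sampleName <- function(x) x@sample

#' @describeIn SVCallSet technology accessor.
#' @export
technology <- function(x) x@technology

#' @rdname SVCallSet
#' @aliases metadata,SVCallSet-method
#' @importFrom S4Vectors metadata
#' @export
setMethod("metadata", "SVCallSet", function(x, ...) x@metadata)

#' Number of calls in a set
#' @param x an `SVCallSet`.
#' @rdname SVCallSet
#' @export
setMethod("length", "SVCallSet", function(x) nrow(x@calls))

#' @rdname SVCallSet
#' @param i logical/integer/character row selector over calls.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "SVCallSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@calls$id)
  initialize(x, calls = x@calls[i, , drop = FALSE])
})

setMethod("show", "SVCallSet", function(object) {
  cl <- object@calls
  cat(sprintf("SVCallSet: sample=%s technology=%s, %d calls\n",
              object@sample, object@technology, nrow(cl)))
  if (nrow(cl)) {
    tab <- table(factor(cl$svtype, levels = .SV_TYPES))
    cat(" ", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                   collapse = " "), "\n")
  }
  if (length(object@metadata)) {
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
  }
})

#' Replace the call table of an SVCallSet
#'
#' Keeps sample/technology/metadata, swaps in a new (typically filtered)
#' call table, revalidating the object.
#' @param x an `SVCallSet`.
#' @param calls replacement call data.frame.
#' @param metadata optional entries merged into the existing metadata.
#' @return An `SVCallSet`.
#' @export
setCalls <- function(x, calls, metadata = list()) {
  rownames(calls) <- NULL
  md <- x@metadata
  md[names(metadata)] <- metadata
  initialize(x, calls = calls[, .CALL_COLUMNS, drop = FALSE], metadata = md)
}

#' Construct the threshold set
#'
#' @param ... named overrides of individual thresholds (see
#'   [SVThresholds-class] for names and defaults).
#' @return An [SVThresholds-class] object.
#' @examples
#' th <- svThresholds()
#' th["del_ro"]
#' svThresholds(del_ro = 0.7)["del_ro"]
#' @export
svThresholds <- function(...) {
  over <- c(...)
  v <- .THRESHOLD_DEFAULTS
  if (length(over)) {
    bad <- setdiff(names(over), names(v))
    if (length(bad)) {
      stop("unknown threshold(s): ", paste(bad, collapse = ", "))
    }
    v[names(over)] <- over
  }
  new("SVThresholds", values = v)
}

#' @rdname svThresholds
#' @param x an `SVThresholds` object.
#' @param i threshold name.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "SVThresholds", function(x, i, j, ..., drop = TRUE) {
  unname(x@values[i])
})

setMethod("show", "SVThresholds", function(object) {
  cat("SVThresholds:\n")
  v <- object@values
  for (n in names(v)) cat(sprintf("  %-20s %g\n", n, v[n]))
})

#' Thresholds as a named list (for manifests and file headers)
#' @param th an `SVThresholds` object.
#' @return Named list of numeric thresholds.
#' @export
thresholdList <- function(th) as.list(th@values)
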