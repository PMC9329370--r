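#' Multi-channel modality time series
#'
#' Container for one modality's uniformly sampled, time-major observations of a
#' dynamical system, together with missing-data metadata.  This is the basic
#' unit every other function in the package consumes: the synthetic generator
#' produces lists of `modal_series`, the embedding and training pipeline read
#' them, and the restoration functions return them.
#'
#' @param values numeric vector (one channel) or T x C matrix, time in rows.
#' @param modality_id short identifier, e.g. `"hr"` or `"eda"`.
#' @param sample_rate sampling rate in Hz.
#' @param missing logical, either a scalar (whole modality missing) or one flag
#'   per time step.
#' @param sentinel the numeric marker used to encode missing values on disk and
#'   in masked training inputs (default `-1`).
#' @return an object of class `modal_series`.
#' @seealso [mask_modality()], [delay_embed()], [write_modalities()]
#' @export
modal_series <- function(values, modality_id, sample_rate = 1,
                         missing = FALSE, sentinel = -1) {
  if (is.null(dim(values))) values <- matrix(as.numeric(values), ncol = 1)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("'values' must have at least one row and one column")
  if (!is.character(modality_id) || length(modality_id) != 1L || !nzchar(modality_id))
    stop("'modality_id' must be a non-empty string")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("'sample_rate' must be > 0")
  if (length(missing) == 1L) missing <- rep(isTRUE(missing), nrow(values))
  if (length(missing) != nrow(values))
    stop("'missing' must be a scalar or one flag per time step")
  if (any(!is.finite(values[!missing, , drop = FALSE])))
    stop("non-finite values outside missing steps in modality '", modality_id, "'")
  structure(list(modality_id = modality_id,
                 sample_rate = as.numeric(sample_rate),
                 values = values,
                 missing = as.logical(missing),
                 sentinel = as.numeric(sentinel)),
            class = "modal_series")
}

#' @export
print.modal_series <- function(x, ...) {
  cat(sprintf("<modal_series '%s'>  T = %d, channels = %d, rate = %g Hz",
              x$modality_id, nrow(x$values), ncol(x$values), x$sample_rate))
  nm <- sum(x$missing)
  if (nm > 0L) cat(sprintf(", missing steps = %d (sentinel %g)", nm, x$sentinel))
  cat("\n")
  invisible(x)
}

#' @export
as.matrix.modal_series <- function(x, ...) x$values

# Accept either a modal_series or a plain matrix/vector; return T x C matrix.
.series_values <- function(x) {
  if (inherits(x, "modal_series")) return(x$values)
  if (is.null(dim(x))) return(matrix(as.numeric(x), ncol = 1))
  as.matrix(x)
}
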