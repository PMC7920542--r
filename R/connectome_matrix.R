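#' Construct a connectome matrix object
#'
#' A `connectome_matrix` couples an N x N numeric weight matrix with the
#' scale it is expressed on, a symmetry flag, and a logical mask of defined
#' entries. The diagonal is always undefined (within-parcel connectivity is
#' not modelled); further entries may be undefined for modalities with
#' incomplete sampling. All statistics in the package silently restrict to
#' defined entries and report the pair count they used.
#'
#' @param values Numeric N x N matrix.
#' @param scale One of `"raw_counts"`, `"fractional"`, `"log10_fractional"`,
#'   `"modality_raw"`.
#' @param symmetric Logical; `TRUE` when `values` equal their transpose on
#'   defined entries.
#' @param defined Optional logical N x N mask of defined entries; defaults to
#'   all off-diagonal entries with non-`NA` values. The diagonal is forced
#'   undefined.
#' @param parcels Optional character vector of parcel names (dimnames).
#' @return A `connectome_matrix` object.
#' @export
connectome_matrix <- function(values,
                              scale = c("raw_counts", "fractional",
                                        "log10_fractional", "modality_raw"),
                              symmetric = FALSE, defined = NULL,
                              parcels = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("connectome matrix must be square")
  n <- nrow(values)
  if (is.null(defined)) defined <- !is.na(values)
  defined <- defined & !is.na(values)
  diag(defined) <- FALSE
  if (scale == "raw_counts" && any(values[defined] < 0)) {
    stop("raw streamline counts must be non-negative")
  }
  if (scale == "fractional" &&
      any(values[defined] < 0 | values[defined] > 1)) {
    stop("fractional weights must lie in [0, 1]")
  }
  if (isTRUE(symmetric)) {
    both <- defined & t(defined)
    if (any(abs(values[both] - t(values)[both]) > 1e-12 * (1 + abs(values[both])))) {
      stop("matrix declared symmetric but values differ from their transpose")
    }
  }
  if (!is.null(parcels)) {
    if (length(parcels) != n) stop("parcels must have length ", n)
    dimnames(values) <- list(parcels, parcels)
    dimnames(defined) <- list(parcels, parcels)
  }
  structure(list(values = values, scale = scale, symmetric = isTRUE(symmetric),
                 defined = defined, n = n),
            class = "connectome_matrix")
}

#' @export
print.connectome_matrix <- function(x, ...) {
  cat(sprintf("connectome_matrix: %d x %d, scale=%s, symmetric=%s, %d defined pairs\n",
              x$n, x$n, x$scale, x$symmetric, sum(x$defined)))
  invisible(x)
}

#' Defined values of a connectome matrix
#'
#' @param x A `connectome_matrix`.
#' @param upper Use only the upper triangle (appropriate for symmetric
#'   matrices, to avoid double counting pairs).
#' @param mask Optional additional logical mask to intersect with.
#' @return Numeric vector of weights at defined (and masked) entries.
#' @export
cm_values <- function(x, upper = FALSE, mask = NULL) {
  keep <- x$defined
  if (!is.null(mask)) keep <- keep & mask
  if (upper) keep <- keep & upper.tri(keep)
  x$values[keep]
}

cm_like <- function(x, values, scale = x$scale, symmetric = x$symmetric,
                    defined = x$defined) {
  connectome_matrix(values, scale = scale, symmetric = symmetric,
                    defined = defined, parcels = rownames(x$values))
}

#' Construct a tract-length matrix
#'
#' @param lengths Numeric N x N matrix of fiber tract lengths in mm.
#' @param defined Optional logical mask; defaults to positive off-diagonal
#'   entries.
#' @param parcels Optional parcel names.
#' @return A `tract_lengths` object (list with `lengths`, `defined`).
#' @export
tract_lengths <- function(lengths, defined = NULL, parcels = NULL) {
  lengths <- as.matrix(lengths)
  if (nrow(lengths) != ncol(lengths)) stop("length matrix must be square")
  if (is.null(defined)) defined <- !is.na(lengths) & lengths > 0
  defined <- defined & !is.na(lengths)
  diag(defined) <- FALSE
  if (any(lengths[defined] <= 0)) stop("tract lengths must be positive where defined")
  asym <- abs(lengths - t(lengths))
  if (any(asym[defined & t(defined)] > 1e-9)) {
    lengths <- (lengths + t(lengths)) / 2  # symmetrize small numeric asymmetry
  }
  if (!is.null(parcels)) dimnames(lengths) <- list(parcels, parcels)
  structure(list(lengths = lengths, defined = defined, n = nrow(lengths)),
            class = "tract_lengths")
}

#' Construct a multi-subject stack of raw streamline counts
#'
#' @param counts Numeric S x N x N array of raw streamline counts.
#' @param subject_ids Optional character vector of length S.
#' @param motion_index Optional numeric length-S vector (integrated
#'   displacement over the scan, arbitrary units).
#' @return A `subject_stack` object.
#' @export
subject_stack <- function(counts, subject_ids = NULL, motion_index = NULL) {
  if (length(dim(counts)) != 3L) stop("counts must be an S x N x N array")
  if (dim(counts)[2] != dim(counts)[3]) stop("per-subject slices must be square")
  s <- dim(counts)[1]
  if (s < 1L) stop("need at least one subject")
  if (any(counts < 0, na.rm = TRUE)) stop("raw counts must be non-negative")
  if (is.null(subject_ids)) subject_ids <- sprintf("sub%03d", seq_len(s))
  if (length(subject_ids) != s) stop("subject_ids must have length ", s)
  if (!is.null(motion_index) && length(motion_index) != s) {
    stop("motion_index must have length ", s)
  }
  structure(list(counts = counts, subject_ids = subject_ids,
                 motion_index = motion_index,
                 n_subjects = s, n = dim(counts)[2]),
            class = "subject_stack")
}

#' @export
print.subject_stack <- function(x, ...) {
  cat(sprintf("subject_stack: %d subjects x %d x %d parcels\n",
              x$n_subjects, x$n, x$n))
  invisible(x)
}
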