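#' Read a connectivity matrix from delimited text
#'
#' Reads a square numeric matrix with parcel names as header row and first
#' column. Blank or non-numeric cells become undefined entries (the
#' convention used for modalities with incomplete sampling); the diagonal is
#' always undefined.
#'
#' @param path File path (CSV by default; the delimiter is sniffed from the
#'   header line).
#' @param scale Scale tag to attach, see [connectome_matrix()].
#' @param symmetric Whether the payload is to be validated as symmetric.
#' @param atlas Optional `parcel_atlas`; when given, parcel names must match
#'   the atlas and rows/columns are reordered to atlas order.
#' @return A `connectome_matrix`.
#' @export
read_matrix <- function(path, scale = "raw_counts", symmetric = FALSE,
                        atlas = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  rn <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- rn  # matrices, unlike data frames, allow duplicated names
  if (nrow(m) != ncol(m)) {
    stop("non-square payload: ", nrow(m), " x ", ncol(m))
  }
  if (!identical(rownames(m), colnames(m))) {
    stop("row and column parcel names disagree")
  }
  if (!is.null(atlas)) {
    key <- paste(atlas$name, substr(atlas$hemisphere, 1, 1), sep = "_")
    ord <- match(key, rownames(m))
    if (anyNA(ord)) ord <- match(atlas$name, rownames(m))
    if (anyNA(ord)) {
      stop("parcel names in file do not match atlas (",
           sum(is.na(ord)), " unmatched)")
    }
    m <- m[ord, ord, drop = FALSE]
  }
  connectome_matrix(m, scale = scale, symmetric = symmetric)
}

#' Write a connectivity matrix as delimited text
#'
#' Undefined entries are written as empty cells, so that
#' `read_matrix(write_matrix(x))` restores defined values bit-identically.
#'
#' @param x A `connectome_matrix`.
#' @param path Output path; `.tsv` extension selects tab delimiting.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  m <- x$values
  if (is.null(rownames(m))) {
    dimnames(m) <- list(sprintf("p%03d", seq_len(x$n)),
                        sprintf("p%03d", seq_len(x$n)))
  }
  out <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
  out[!x$defined] <- ""
  lines <- c(paste(c("", colnames(m)), collapse = sep),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], out[i, ]), collapse = sep),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a subject stack to a directory container
#'
#' The container is plain text: one delimited matrix per subject plus a JSON
#' sidecar carrying subject ids, motion indices and provenance. An optional
#' tract-length matrix is stored alongside.
#'
#' @param stack A `subject_stack`.
#' @param dir Output directory (created if needed).
#' @param lengths Optional `tract_lengths` to store with the stack.
#' @return `dir`, invisibly.
#' @export
write_subject_stack <- function(stack, dir, lengths = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in seq_len(stack$n_subjects)) {
    cm <- connectome_matrix(stack$counts[s, , ], scale = "raw_counts")
    write_matrix(cm, file.path(dir, paste0("counts_", stack$subject_ids[s], ".csv")))
  }
  if (!is.null(lengths)) {
    lm <- connectome_matrix(lengths$lengths, scale = "modality_raw",
                            defined = lengths$defined)
    write_matrix(lm, file.path(dir, "lengths.csv"))
  }
  meta <- list(subject_ids = stack$subject_ids,
               motion_index = stack$motion_index,
               n = stack$n, scale = "raw_counts")
  jsonlite::write_json(meta, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a subject stack from a directory container
#'
#' @param dir Directory written by [write_subject_stack()].
#' @return A list with elements `stack` (a `subject_stack`) and `lengths`
#'   (a `tract_lengths` or `NULL`).
#' @export
read_subject_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"), simplifyVector = TRUE)
  ids <- meta$subject_ids
  counts <- array(NA_real_, c(length(ids), meta$n, meta$n))
  for (s in seq_along(ids)) {
    cm <- read_matrix(file.path(dir, paste0("counts_", ids[s], ".csv")),
                      scale = "raw_counts")
    v <- cm$values
    v[!cm$defined] <- 0  # undefined raw entries are absent streamlines
    diag(v) <- 0
    counts[s, , ] <- v
  }
  lengths <- NULL
  lpath <- file.path(dir, "lengths.csv")
  if (file.exists(lpath)) {
    lm <- read_matrix(lpath, scale = "modality_raw")
    lengths <- tract_lengths(lm$values, defined = lm$defined)
  }
  motion <- meta$motion_index
  if (length(motion) == 0L) motion <- NULL
  list(stack = subject_stack(counts, ids, motion), lengths = lengths)
}

#' Group-average raw streamline counts
#'
#' Averaging raw counts across subjects precedes normalization in the group
#' pipeline: the group connectome is built from the entrywise mean of the
#' per-subject raw count matrices.
#'
#' @param stack A `subject_stack`.
#' @return A `connectome_matrix` on the `raw_counts` scale.
#' @export
group_average <- function(stack) {
  m <- apply(stack$counts, c(2, 3), mean)
  connectome_matrix(m, scale = "raw_counts")
}

#' Collapse a stack of per-subject tract lengths to a group matrix
#'
#' Per-pair lengths are combined by a streamline-count-weighted mean, so the
#' group length reflects the subjects that actually carried streamlines for
#' the pair.
#'
#' @param length_arr S x N x N array of per-subject tract lengths (0 or `NA`
#'   where a subject has no streamlines for the pair).
#' @param stack A `subject_stack` supplying the weights.
#' @return A `tract_lengths` object.
#' @export
group_lengths <- function(length_arr, stack) {
  if (!identical(dim(length_arr), dim(stack$counts))) {
    stop("length array and count stack dimensions disagree")
  }
  w <- stack$counts
  l <- length_arr
  l[is.na(l)] <- 0
  num <- apply(l * w, c(2, 3), sum)
  den <- apply(w * (l > 0), c(2, 3), sum)
  out <- ifelse(den > 0, num / den, NA_real_)
  tract_lengths(out, defined = den > 0 & row(out) != col(out))
}
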