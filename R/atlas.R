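#' Load and validate a cortical parcel atlas
#'
#' Reads the parcel table that anchors every analysis in the package: 360
#' parcels (180 per hemisphere) of the HCP-MMP1.0 multimodal parcellation,
#' each assigned to one of 10 functional networks per hemisphere. Left
#' hemisphere parcels carry ids 1..180 in display order; the homologous
#' right hemisphere parcel is obtained by adding 180.
#'
#' @param source Path to a delimited table with columns `parcel_id`, `name`,
#'   `hemisphere`, `network`, `display_order`, `original_index`. When `NULL`
#'   the packaged table is used.
#' @param myelination Optional two-column delimited file (name, value) giving
#'   a per-parcel T1w/T2w myelination index; values are keyed by parcel name
#'   and applied to both hemispheres unless the file lists 360 rows keyed by
#'   parcel id.
#' @param areas Optional two-column delimited file (name, mm^2) of parcel
#'   surface areas, keyed like `myelination`.
#' @return A `parcel_atlas`: a data frame with one row per parcel and columns
#'   `parcel_id`, `name`, `hemisphere`, `network`, `display_order`,
#'   `original_index`, `homolog_id` and, when supplied, `myelination` and
#'   `area_mm2`.
#' @export
load_atlas <- function(source = NULL, myelination = NULL, areas = NULL) {
  if (is.null(source)) {
    source <- system.file("extdata", "hcpmmp10_parcels.tsv", package = "cortconn",
                          mustWork = TRUE)
  }
  at <- utils::read.delim(source, stringsAsFactors = FALSE)
  at <- as_parcel_atlas(at)
  if (is.null(myelination) || is.character(myelination)) {
    at$myelination <- if (is.null(myelination)) NA_real_ else
      read_parcel_values(myelination, at)
  } else {
    at$myelination <- check_parcel_vector(myelination, at, "myelination")
  }
  if (!is.null(areas)) {
    a <- if (is.character(areas)) read_parcel_values(areas, at) else
      check_parcel_vector(areas, at, "area_mm2")
    if (any(!is.na(a) & a <= 0)) stop("parcel areas must be positive")
    at$area_mm2 <- a
  }
  at
}

#' Validate a parcel table and derive the homolog map
#'
#' Checks hemisphere balance, name uniqueness within hemisphere, network
#' completeness and the involution property of the name-based homolog
#' pairing, then attaches the `parcel_atlas` class.
#'
#' @param at Data frame with columns `parcel_id`, `name`, `hemisphere`,
#'   `network`, `display_order`, `original_index`.
#' @return A validated `parcel_atlas`.
#' @export
as_parcel_atlas <- function(at) {
  required <- c("parcel_id", "name", "hemisphere", "network",
                "display_order", "original_index")
  missing_cols <- setdiff(required, names(at))
  if (length(missing_cols)) {
    stop("atlas table lacks required column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("parcel_id", "display_order", "original_index")) {
    at[[col]] <- as.integer(at[[col]])
  }
  at <- at[order(at$parcel_id), , drop = FALSE]
  rownames(at) <- NULL
  n <- nrow(at)
  if (n %% 2L != 0L) stop("atlas must have an even parcel count, got ", n)
  half <- n %/% 2L
  per_hemi <- table(at$hemisphere)
  if (!setequal(names(per_hemi), c("left", "right")) ||
      any(per_hemi != half)) {
    stop("atlas must contain equal left/right hemispheres (", half,
         " each); got ", paste(names(per_hemi), per_hemi, collapse = ", "))
  }
  for (h in c("left", "right")) {
    nm <- at$name[at$hemisphere == h]
    if (anyDuplicated(nm)) {
      stop("duplicate parcel name(s) within ", h, " hemisphere: ",
           paste(unique(nm[duplicated(nm)]), collapse = ", "))
    }
  }
  if (any(is.na(at$network) | !nzchar(at$network))) {
    stop("missing network label(s) for parcel id(s): ",
         paste(at$parcel_id[is.na(at$network) | !nzchar(at$network)], collapse = ", "))
  }
  if (!identical(at$parcel_id, seq_len(n))) {
    stop("parcel_id must be 1..", n, " after ordering")
  }
  # homolog pairing: same name in the opposite hemisphere
  at$homolog_id <- NA_integer_
  left <- at[at$hemisphere == "left", ]
  right <- at[at$hemisphere == "right", ]
  m <- match(left$name, right$name)
  if (anyNA(m)) {
    stop("homolog map is not bijective; left parcel(s) without right homolog: ",
         paste(left$name[is.na(m)], collapse = ", "))
  }
  at$homolog_id[at$hemisphere == "left"] <- right$parcel_id[m]
  at$homolog_id[match(right$parcel_id[m], at$parcel_id)] <- left$parcel_id
  if (!identical(at$parcel_id, at$homolog_id[at$homolog_id])) {
    stop("homolog mapping is not an involution")
  }
  class(at) <- c("parcel_atlas", "data.frame")
  at
}

read_parcel_values <- function(path, atlas) {
  v <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(v) < 2L) stop("parcel value file needs two columns (key, value)")
  key <- v[[1L]]
  val <- as.numeric(v[[2L]])
  if (is.numeric(key) || !anyNA(suppressWarnings(as.integer(key)))) {
    out <- val[match(atlas$parcel_id, as.integer(key))]
  } else {
    out <- val[match(atlas$name, key)]
  }
  out
}

check_parcel_vector <- function(x, atlas, what) {
  x <- as.numeric(x)
  if (length(x) != nrow(atlas)) {
    stop(what, " vector must have length ", nrow(atlas))
  }
  x
}

#' @export
print.parcel_atlas <- function(x, ...) {
  cat("parcel_atlas:", nrow(x), "parcels,",
      length(unique(x$network)), "networks per hemisphere\n")
  invisible(x)
}

atlas_n <- function(atlas) nrow(atlas)

#' Indices of parcels in one hemisphere
#' @param atlas A `parcel_atlas`.
#' @param hemisphere `"left"`, `"right"`, or `"both"`.
#' @return Integer parcel ids.
#' @export
hemisphere_index <- function(atlas, hemisphere = c("left", "right", "both")) {
  hemisphere <- match.arg(hemisphere)
  if (hemisphere == "both") return(atlas$parcel_id)
  atlas$parcel_id[atlas$hemisphere == hemisphere]
}

#' Parcel set of the combined language and auditory networks
#'
#' The combined super-network used for the distance-binned laterality
#' profile; it is derived on demand and not stored in the atlas table.
#'
#' @param atlas A `parcel_atlas`.
#' @param hemisphere Which hemisphere's parcels to return.
#' @return Integer parcel ids.
#' @export
language_auditory_parcels <- function(atlas, hemisphere = c("both", "left", "right")) {
  hemisphere <- match.arg(hemisphere)
  sel <- atlas$network %in% c("Language", "Auditory")
  if (hemisphere != "both") sel <- sel & atlas$hemisphere == hemisphere
  atlas$parcel_id[sel]
}

#' Boolean mask of parcel pairs within one network
#'
#' @param atlas A `parcel_atlas`.
#' @param network A network label present in the atlas.
#' @param hemisphere `"left"`, `"right"` or `"both"`.
#' @return An N x N logical matrix, `TRUE` exactly where both parcels belong
#'   to the requested network (and hemisphere); diagonal `FALSE`.
#' @export
network_block_mask <- function(atlas, network, hemisphere = c("both", "left", "right")) {
  hemisphere <- match.arg(hemisphere)
  if (!network %in% atlas$network) stop("unknown network label: ", network)
  n <- atlas_n(atlas)
  sel <- atlas$network == network
  if (hemisphere != "both") sel <- sel & atlas$hemisphere == hemisphere
  mask <- outer(sel, sel, "&")
  diag(mask) <- FALSE
  dimnames(mask) <- list(atlas$name, atlas$name)
  mask
}

#' Boolean mask of homolog pairs
#'
#' @param atlas A `parcel_atlas`.
#' @return N x N logical matrix, `TRUE` where the column parcel is the row
#'   parcel's contralateral homolog.
#' @export
homolog_mask <- function(atlas) {
  n <- atlas_n(atlas)
  mask <- matrix(FALSE, n, n)
  mask[cbind(atlas$parcel_id, atlas$homolog_id)] <- TRUE
  dimnames(mask) <- list(atlas$name, atlas$name)
  mask
}

#' Hemisphere membership masks for parcel pairs
#'
#' @param atlas A `parcel_atlas`.
#' @param subset One of `"left"` (both parcels left), `"right"`, `"callosal"`
#'   (one parcel in each hemisphere) or `"all"`.
#' @return N x N logical matrix with diagonal `FALSE`.
#' @export
pair_subset_mask <- function(atlas, subset = c("all", "left", "right", "callosal")) {
  subset <- match.arg(subset)
  isL <- atlas$hemisphere == "left"
  mask <- switch(subset,
    all      = matrix(TRUE, atlas_n(atlas), atlas_n(atlas)),
    left     = outer(isL, isL, "&"),
    right    = outer(!isL, !isL, "&"),
    callosal = outer(isL, !isL, "&") | outer(!isL, isL, "&"))
  diag(mask) <- FALSE
  dimnames(mask) <- list(atlas$name, atlas$name)
  mask
}
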