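#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file (optionally gzip-compressed) into a
#' [scalar_volume()] or, for 4D files whose last dimension is 3, a
#' [vector_volume()] of per-voxel orientations (FSL dyads convention).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param expect_vector if `TRUE` the file must be 4D with last dimension
#'   3 and a `vector_volume` is returned; if `FALSE` the file must be 3D.
#' @return a `scalar_volume` or `vector_volume`.
#' @export
read_volume <- function(path, expect_vector = FALSE) {
  if (!file.exists(path)) stop("no such volume file: ", path)
  img <- tryCatch(
    RNifti::readNifti(path),
    error = function(e) stop("could not read '", path, "' as NIfTI: ",
                             conditionMessage(e))
  )
  dm <- dim(img)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  if (expect_vector) {
    if (length(dm) != 4L || dm[4] != 3L)
      stop("'", path, "': expected a 4D vector volume with last dimension 3")
    grid <- voxel_grid(dm[1:3], affine = aff)
    arr <- array(as.numeric(img), dim = c(grid$dims, 3L))
    m <- matrix(arr, ncol = 3)
    nrm <- sqrt(rowSums(m^2))
    fix <- nrm > 1e-12
    m[fix, ] <- m[fix, , drop = FALSE] / nrm[fix]
    vector_volume(array(m, dim = c(grid$dims, 3L)), grid)
  } else {
    if (length(dm) == 4L && dm[4] == 1L) dm <- dm[1:3]
    if (length(dm) != 3L)
      stop("'", path, "': expected a 3D scalar volume, found ",
           length(dim(img)), " dimensions")
    grid <- voxel_grid(dm, affine = aff)
    scalar_volume(array(as.numeric(img), dim = grid$dims), grid)
  }
}

#' Write a volume or mask to NIfTI
#'
#' @param vol a [scalar_volume()], [vector_volume()] or [roi_mask()]
#'   (masks are written as 0/1 integers; distance maps as integers).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param datatype passed to [RNifti::writeNifti()]; default `"double"`
#'   preserves values bit-exactly.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "double") {
  grid <- grid_of(vol)
  arr <- if (inherits(vol, "vector_volume")) {
    vol$vectors
  } else if (inherits(vol, "roi_mask")) {
    datatype <- "uint8"
    array(as.integer(vol$mask), dim = grid$dims)
  } else {
    vol$values
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid$voxel_size
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read an FSL-style gradient table
#'
#' Parses `bvec` (3 rows x M columns) and `bval` (1 row x M columns)
#' whitespace-separated text files. Zero-gradient (b = 0) entries are
#' excluded from the orientation matrix and reported as a count of b0
#' volumes; the remaining orientations are renormalised to unit length.
#'
#' @param bvec_path,bval_path paths to the two text files.
#' @return a `gradient_table`: list with `bvecs` (M x 3 unit row
#'   vectors), `bval` (shared b-value in s/mm^2), `n_b0` (count of
#'   excluded b = 0 volumes), and `dwi_index` (positions of the retained
#'   gradients in the original volume series).
#' @export
read_gradient_table <- function(bvec_path, bval_path) {
  bv <- as.matrix(utils::read.table(bvec_path))
  bl <- as.numeric(unlist(utils::read.table(bval_path)))
  if (nrow(bv) != 3L)
    stop("bvec file must have 3 rows (found ", nrow(bv), ")")
  if (ncol(bv) != length(bl))
    stop("bvec/bval column counts differ (", ncol(bv), " vs ", length(bl), ")")
  gradient_table(t(bv), bl)
}

#' @rdname read_gradient_table
#' @param bvecs M x 3 matrix of gradient orientations (rows may include
#'   zero rows for b = 0 volumes).
#' @param bvals length-M vector of b-values, or a single shared b-value.
#' @export
gradient_table <- function(bvecs, bvals) {
  bvecs <- as.matrix(bvecs)
  stopifnot(ncol(bvecs) == 3L)
  if (length(bvals) == 1L) bvals <- rep(bvals, nrow(bvecs))
  if (length(bvals) != nrow(bvecs))
    stop("bvals length does not match the number of gradient orientations")
  is_b0 <- bvals == 0 | sqrt(rowSums(bvecs^2)) < 1e-12
  dwi_index <- which(!is_b0)
  bvecs <- bvecs[!is_b0, , drop = FALSE]
  bvals <- bvals[!is_b0]
  if (length(unique(bvals)) > 1L)
    stop("multiple non-zero b-values found; single-shell data required")
  nrm <- sqrt(rowSums(bvecs^2))
  bvecs <- bvecs / nrm
  structure(
    list(bvecs = unname(bvecs), bval = bvals[1], n_b0 = sum(is_b0),
         dwi_index = dwi_index),
    class = "gradient_table"
  )
}

#' @export
print.gradient_table <- function(x, ...) {
  cat(sprintf("<gradient_table> %d directions at b = %g s/mm^2 (%d b0 volumes)\n",
              nrow(x$bvecs), x$bval, x$n_b0))
  invisible(x)
}

#' Read a cohort covariate table
#'
#' Reads a TSV with columns `participant_id`, `age` (years) and `sex`
#' (coded 1 = male, 2 = female) and validates it: unique ids, positive
#' ages, sex in \{1, 2\}.
#'
#' @param path path to the TSV file.
#' @return a `cohort_table` (a validated `data.frame`).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such cohort file: ", path)
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE),
    error = function(e) stop("could not read cohort table '", path, "': ",
                             conditionMessage(e))
  )
  cohort_table(df)
}

#' @rdname read_cohort
#' @param df a data.frame with the required columns.
#' @export
cohort_table <- function(df) {
  need <- c("participant_id", "age", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("cohort table has no rows")
  df$participant_id <- as.character(df$participant_id)
  df$age <- as.numeric(df$age)
  df$sex <- as.integer(df$sex)
  dup <- df$participant_id[duplicated(df$participant_id)]
  if (length(dup))
    stop("duplicate participant_id: ", paste(unique(dup), collapse = ", "))
  bad_age <- which(!is.finite(df$age) | df$age <= 0)
  if (length(bad_age))
    stop("non-positive or missing age in row(s): ",
         paste(bad_age, collapse = ", "))
  bad_sex <- which(!df$sex %in% c(1L, 2L))
  if (length(bad_sex))
    stop("sex must be coded 1 (male) or 2 (female); offending row(s): ",
         paste(bad_sex, collapse = ", "))
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' @rdname read_cohort
#' @param cohort a `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
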