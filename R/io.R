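#' Read and write vessel masks
#'
#' Masks round-trip through NIfTI (`.nii` / `.nii.gz`, via RNifti, voxel
#' spacing carried in pixdim) or MetaImage (`.mha`, uncompressed
#' MET_UCHAR with LOCAL data, written by a minimal reader/writer so that
#' spacing and offset round-trip). NIfTI masks are written with origin
#' (0, 0, 0); use MetaImage when a nonzero origin must be preserved.
#'
#' @param mask a [labeled_mask()].
#' @param path file path ending in `.nii`, `.nii.gz` or `.mha`.
#' @return `read_mask` returns a [labeled_mask()]; `write_mask` returns
#'   `path` invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "labeled_mask"))
  if (grepl("\\.mha$", path)) {
    write_mha(mask, path)
  } else if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(array(as.integer(mask$voxels),
                                 dim(mask$voxels)))
    RNifti::pixdim(img) <- mask$spacing
    RNifti::writeNifti(img, path)
  } else {
    stopf("unsupported mask format: %s", path)
  }
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (grepl("\\.mha$", path)) return(read_mha(path))
  if (!grepl("\\.nii(\\.gz)?$", path))
    stopf("unsupported mask format: %s", path)
  img <- RNifti::readNifti(path)
  labeled_mask(array(as.integer(img), dim(img)),
               spacing = as.numeric(RNifti::pixdim(img))[1:3])
}

write_mha <- function(mask, path) {
  d <- dim(mask$voxels)
  if (any(mask$voxels < 0) || any(mask$voxels > 255))
    stopf("MetaImage writer supports labels 0..255")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    "ObjectType = Image\n",
    "NDims = 3\n",
    "BinaryData = True\n",
    "BinaryDataByteOrderMSB = False\n",
    sprintf("DimSize = %d %d %d\n", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %g %g %g\n", mask$spacing[1],
            mask$spacing[2], mask$spacing[3]),
    sprintf("Offset = %g %g %g\n", mask$origin[1], mask$origin[2],
            mask$origin[3]),
    "ElementType = MET_UCHAR\n",
    "ElementDataFile = LOCAL\n")
  writeChar(hdr, con, eos = NULL)
  writeBin(as.raw(as.integer(mask$voxels)), con)
  invisible(path)
}

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_line <- function() {
    bytes <- raw(0)
    repeat {
      b <- readBin(con, "raw", n = 1)
      if (!length(b) || b == as.raw(10)) break
      bytes <- c(bytes, b)
    }
    rawToChar(bytes)
  }
  hdr <- list()
  repeat {
    line <- read_line()
    kv <- strsplit(line, " = ", fixed = TRUE)[[1]]
    hdr[[kv[1]]] <- kv[2]
    if (kv[1] == "ElementDataFile") break
  }
  if (!identical(hdr$ElementType, "MET_UCHAR") ||
      !identical(hdr$ElementDataFile, "LOCAL"))
    stopf("only uncompressed MET_UCHAR MetaImage with LOCAL data is supported")
  d <- as.integer(strsplit(hdr$DimSize, " ")[[1]])
  raw <- readBin(con, "raw", n = prod(d))
  labeled_mask(array(as.integer(raw), d),
               spacing = as.numeric(strsplit(hdr$ElementSpacing, " ")[[1]]),
               origin = as.numeric(strsplit(hdr$Offset, " ")[[1]]))
}

#' Read and write marker / cohort CSV tables
#'
#' Markers: columns `x_mm`, `y_mm`, `z_mm`, `branch`. Cohorts: columns
#' `subject_id`, `side`, `r_cca_mm`, `r_ica_mm`, `r_eca_mm` (extra
#' columns such as `ica_tortuosity`, `n`, `solve_status` pass through).
#'
#' @param markers,cohort data.frames to write.
#' @param path CSV path.
#' @return the data.frame (readers) or `path` invisibly (writers).
#' @export
write_markers <- function(markers, path) {
  need <- c("branch", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(markers)))
    stopf("markers need columns %s", paste(need, collapse = ", "))
  write.csv(markers[, union(need, names(markers))], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_markers
#' @export
read_markers <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("branch", "x_mm", "y_mm", "z_mm")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stopf("marker file %s is missing columns: %s", path,
          paste(miss, collapse = ", "))
  m
}

#' @rdname write_markers
#' @export
write_cohort <- function(cohort, path) {
  get_triples(cohort)  # validates radius columns
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_markers
#' @export
read_cohort <- function(path) {
  coh <- read.csv(path, stringsAsFactors = FALSE)
  tr <- get_triples(coh)
  bad <- which(!is.finite(as.matrix(tr)) | as.matrix(tr) <= 0,
               arr.ind = TRUE)
  if (nrow(bad))
    stopf("malformed cohort file %s: non-positive radius in row %d",
          path, bad[1, 1])
  coh
}
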