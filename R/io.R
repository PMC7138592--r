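#' Read a 3D NIfTI volume
#'
#' Thin wrapper over RNifti. Voxel sizes are taken from the file header;
#' data are returned in header order without any resampling (all inputs to
#' the pipeline are assumed pre-aligned on one grid).
#'
#' @param path path to a NIfTI-1 file (.nii or .nii.gz).
#' @param spaceTag space identifier to attach to the volume.
#' @return A \linkS4class{Volume}.
#' @export
readVolume <- function(path, spaceTag = "common") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3D image, got %dD: %s", length(d), path))
  Volume(array(as.numeric(img), d),
         voxelSize = RNifti::pixdim(img)[seq_len(3L)],
         spaceTag = spaceTag)
}

#' Write a Volume as NIfTI-1
#'
#' @param v a \linkS4class{Volume}.
#' @param path output path (.nii or .nii.gz); parent directory must exist.
#' @param datatype NIfTI datatype, e.g. "float" or "int16"; "auto" lets
#'   RNifti choose.
#' @return invisibly \code{path}.
#' @export
writeVolume <- function(v, path, datatype = "auto") {
  stopifnot(is(v, "Volume"))
  if (!dir.exists(dirname(path)))
    stop(sprintf("parent directory does not exist: %s", dirname(path)))
  img <- RNifti::asNifti(v@data)
  RNifti::pixdim(img) <- v@voxelSize
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a per-subject score table
#'
#' Delimited text (TSV or CSV by extension) with a header row; one row per
#' subject. The first column (or a column named \code{subject_id}) carries
#' subject identifiers; \code{age}, \code{sex}, \code{education} become
#' covariates; all remaining numeric columns are treated as
#' neuropsychological scores. Empty cells become NA (the subject is kept;
#' per-test analyses drop it for that test only).
#'
#' @param path path to the table.
#' @return data.frame with a \code{subject_id} column, covariate columns and
#'   one column per test; attribute \code{"score_columns"} names the tests.
#' @export
readScoreTable <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = c("", "NA"))
  idcol <- if ("subject_id" %in% names(df)) "subject_id" else names(df)[1L]
  ids <- as.character(df[[idcol]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicate subject_id in %s: %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  names(df)[names(df) == idcol] <- "subject_id"
  df$subject_id <- ids
  covar <- intersect(c("age", "sex", "education"), names(df))
  scorecols <- setdiff(names(df), c("subject_id", covar))
  scorecols <- scorecols[vapply(df[scorecols], is.numeric, logical(1))]
  attr(df, "score_columns") <- scorecols
  df
}

#' Write the score table of a cohort
#'
#' Inverse of \code{readScoreTable} for synthetic cohorts: one row per
#' subject with id, covariates and all score columns, tab separated.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param path output TSV path.
#' @return invisibly \code{path}.
#' @export
writeScoreTable <- function(cohort, path) {
  subs <- cohortSubjects(cohort)
  tests <- names(scores(subs[[1L]]))
  df <- data.frame(
    subject_id = vapply(subs, subjectId, character(1)),
    age = vapply(subs, function(s) covariates(s)$age, numeric(1)),
    sex = vapply(subs, function(s) covariates(s)$sex, character(1)),
    education = vapply(subs, function(s) covariates(s)$education, numeric(1)),
    check.names = FALSE)
  for (t in tests)
    df[[t]] <- vapply(subs, function(s) unname(scores(s)[t]), numeric(1))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @importFrom utils write.table
NULL

# Run an expression under a temporary, seeded RNG state, restoring the
# caller's stream afterwards. All stochastic operations in the package
# funnel through this for reproducibility.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
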