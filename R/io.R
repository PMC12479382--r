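#' Read a parcellated time-series TSV
#'
#' Expects a tab-separated file with a header row of parcel ids and one row
#' per frame. Validation errors (ragged rows, non-numeric cells, duplicate
#' ids) name the offending line or column.
#'
#' @param path File path.
#' @param tr_seconds Repetition time of the scan in seconds.
#' @param motion Optional frames x 6 motion matrix (or a confound TSV path
#'   read with [read_confounds()]).
#' @param fd Optional FD vector.
#' @return A [parcel_ts()].
#' @export
read_timeseries <- function(path, tr_seconds, motion = NULL, fd = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("time-series file has no data rows: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (anyDuplicated(header))
    stop("duplicate parcel id in header: ",
         header[duplicated(header)][1L])
  cells <- strsplit(lines[-1L], "\t", fixed = TRUE)
  width <- lengths(cells)
  if (any(width != length(header)))
    stop("ragged row at line ", which(width != length(header))[1L] + 1L,
         ": expected ", length(header), " cells, found ",
         width[width != length(header)][1L])
  mat <- matrix(suppressWarnings(as.numeric(unlist(cells))),
                nrow = length(cells), byrow = TRUE)
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell at line ", bad[["row"]] + 1L, ", column ",
         bad[["col"]])
  }
  colnames(mat) <- header
  parcel_ts(mat, tr_seconds, header, motion = motion, fd = fd)
}

#' Write a parcellated time-series TSV
#'
#' Plain tab-separated text with a parcel-id header row; values are written
#' with full (17-significant-digit) precision so a write/read round trip is
#' lossless.
#'
#' @param ts A [parcel_ts()].
#' @param path Output path.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "parcel_ts"))
  write_tsv_matrix(ts$data, path)
}

write_tsv_matrix <- function(mat, path, row_label = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  header <- colnames(mat)
  if (!is.null(row_label)) header <- c(row_label, header)
  writeLines(paste(header, collapse = "\t"), con)
  body <- apply(mat, 1L, function(r)
    paste(format_full(r), collapse = "\t"))
  if (!is.null(row_label))
    body <- paste(rownames(mat), body, sep = "\t")
  writeLines(body, con)
}

format_full <- function(x) formatC(x, digits = 17, format = "g")

#' Read a confound TSV (motion columns and FD)
#'
#' @param path TSV with labeled columns; six motion columns plus an FD
#'   column by default.
#' @param motion_cols Names of the motion columns.
#' @param fd_col Name of the FD column (or `NULL`).
#' @return List with `motion` (matrix or NULL) and `fd` (vector or NULL).
#' @export
read_confounds <- function(path,
                           motion_cols = c("trans_x", "trans_y", "trans_z",
                                           "rot_x", "rot_y", "rot_z"),
                           fd_col = "fd") {
  tab <- utils::read.delim(path, check.names = FALSE)
  motion <- NULL
  if (all(motion_cols %in% names(tab)))
    motion <- as.matrix(tab[motion_cols])
  fd <- if (!is.null(fd_col) && fd_col %in% names(tab))
    as.numeric(tab[[fd_col]]) else NULL
  list(motion = motion, fd = fd)
}

#' Read a parcel-to-network atlas TSV
#'
#' Columns `parcel_id` and `network_label` (extra columns are ignored).
#' Labels outside the six analyzed networks are routed to the excluded list
#' with a warning.
#'
#' @param path File path.
#' @return A [network_atlas()].
#' @export
read_atlas <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  need <- c("parcel_id", "network_label")
  if (!all(need %in% names(tab)))
    stop("atlas file must have columns parcel_id and network_label")
  network_atlas(tab$parcel_id, tab$network_label)
}

#' Write an atlas TSV
#' @param atlas A [network_atlas()].
#' @param path Output path.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "network_atlas"))
  all_parcels <- rbind(atlas$parcels, atlas$excluded)
  utils::write.table(
    data.frame(parcel_id = all_parcels$parcel_id,
               network_label = all_parcels$network),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a full synthetic cohort to disk
#'
#' Emits per-scan time-series and confound TSVs, the atlas TSV, the
#' questionnaire score table, and the planted-truth record as JSON.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (subj in names(cohort$scans)) {
    for (ses in names(cohort$scans[[subj]])) {
      ts <- cohort$scans[[subj]][[ses]]
      stem <- file.path(dir, paste0(subj, "_", ses))
      write_timeseries(ts, paste0(stem, "_ts.tsv"))
      conf <- cbind(ts$motion, fd = ts$fd)
      colnames(conf) <- c("trans_x", "trans_y", "trans_z",
                          "rot_x", "rot_y", "rot_z", "fd")
      write_tsv_matrix(conf, paste0(stem, "_confounds.tsv"))
    }
  }
  write_atlas(cohort$atlas, file.path(dir, "atlas.tsv"))
  utils::write.table(cohort$scores, file.path(dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
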