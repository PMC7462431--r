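#' Read a square labelled matrix from delimited text
#'
#' Comma- or tab-delimited, auto-detected. The first row must hold the N ROI
#' labels; N data rows of N fields follow. Labels keep ROI order explicit so
#' matrices, parcellations and epochs can never be silently misaligned.
#'
#' @param path file path.
#' @param expect_symmetric verify symmetry to a relative tolerance of 1e-9.
#' @return numeric N x N matrix with identical row/column names.
#' @export
read_conn_matrix <- function(path, expect_symmetric = FALSE) {
  sep <- detect_sep(path)
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  labels <- trimws(header)
  dt <- data.table::fread(path, sep = sep, skip = 1L, header = FALSE,
                          colClasses = "numeric", data.table = FALSE)
  if (ncol(dt) != length(labels) || nrow(dt) != length(labels))
    stop("matrix file is not square: ", length(labels), " labels but ",
         nrow(dt), " x ", ncol(dt), " cells", call. = FALSE)
  m <- as.matrix(dt)
  if (anyNA(m))   # Inf is legitimate (e.g. disconnected search information)
    stop("non-numeric or missing cell in matrix file ", path, call. = FALSE)
  dimnames(m) <- list(labels, labels)
  if (expect_symmetric) {
    fin <- m[is.finite(m)]
    tol <- 1e-9 * max(abs(fin), 1e-300)
    d <- abs(m - t(m))
    d[is.nan(d)] <- 0   # Inf on both sides (equal-sign) is symmetric
    if (max(d) > tol)
      stop("matrix expected symmetric but max |A - t(A)| = ",
           format(max(d)), call. = FALSE)
  }
  m
}

#' Write a square labelled matrix as delimited text
#'
#' @param m numeric square matrix; dimnames used as labels (generated if
#'   absent).
#' @param path output file path.
#' @param sep field separator, `","` or `"\t"`.
#' @export
write_conn_matrix <- function(m, path, sep = ",") {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  labels <- rownames(m)
  if (is.null(labels)) labels <- sprintf("roi%03d", seq_len(nrow(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(labels, collapse = sep), con)
  body <- apply(format(m, digits = 17, scientific = TRUE, trim = TRUE), 1L,
                paste, collapse = sep)
  writeLines(body, con)
  invisible(path)
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Construct a parcellation
#'
#' A parcellation holds, per ROI: a unique name, a hemisphere label (L/R), a
#' centroid in mm, and a size in voxels. Row order defines the ROI index
#' order used by every matrix and epoch in a run.
#'
#' @param roi_names character vector, unique.
#' @param hemisphere character vector in `{"L","R"}`.
#' @param centroid N x 3 numeric matrix of centroids (mm).
#' @param roi_size integer vector of ROI sizes (voxels), >= 1.
#' @return object of class `parcellation` (a data.frame with columns `name`,
#'   `hemisphere`, `x`, `y`, `z`, `size`).
#' @export
parcellation <- function(roi_names, hemisphere, centroid, roi_size) {
  centroid <- as.matrix(centroid)
  n <- length(roi_names)
  if (n < 2) stop("parcellation needs at least 2 ROIs", call. = FALSE)
  if (anyDuplicated(roi_names)) stop("duplicate ROI names", call. = FALSE)
  if (length(hemisphere) != n || nrow(centroid) != n || length(roi_size) != n)
    stop("parcellation fields have mismatched lengths", call. = FALSE)
  if (!all(hemisphere %in% c("L", "R")))
    stop("hemisphere labels must be 'L' or 'R'", call. = FALSE)
  if (!all(is.finite(centroid))) stop("non-finite centroid", call. = FALSE)
  if (any(roi_size < 1)) stop("roi_size must be >= 1", call. = FALSE)
  out <- data.frame(name = as.character(roi_names),
                    hemisphere = as.character(hemisphere),
                    x = centroid[, 1], y = centroid[, 2], z = centroid[, 3],
                    size = as.integer(round(roi_size)),
                    stringsAsFactors = FALSE)
  class(out) <- c("parcellation", "data.frame")
  out
}

#' Read a parcellation table
#'
#' Expects a delimited table (comma or tab, auto-detected) with header
#' columns `name, hemisphere, x, y, z, size`.
#'
#' @param path file path.
#' @return a [parcellation()].
#' @export
read_parcellation <- function(path) {
  sep <- detect_sep(path)
  df <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE)
  need <- c("name", "hemisphere", "x", "y", "z", "size")
  if (!all(need %in% names(df)))
    stop("parcellation table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  parcellation(df$name, df$hemisphere, as.matrix(df[, c("x", "y", "z")]),
               df$size)
}

#' Write a parcellation table
#' @param parc a [parcellation()].
#' @param path output file path.
#' @param sep field separator.
#' @export
write_parcellation <- function(parc, path, sep = ",") {
  utils::write.table(as.data.frame(parc), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Euclidean distances between ROI centroids
#' @param parc a [parcellation()].
#' @return symmetric N x N matrix of distances (mm), zero diagonal.
#' @export
roi_distances <- function(parc) {
  xyz <- as.matrix(as.data.frame(parc)[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  dimnames(d) <- list(parc$name, parc$name)
  d
}

#' Construct a source epoch
#'
#' One artifact-free interval of source-projected ROI time courses.
#'
#' @param data N x T numeric matrix (ROIs x samples); rownames are ROI names.
#' @param rate sampling rate, Hz.
#' @param subject subject identifier.
#' @param interval interval index within subject.
#' @param band band label, default `"broadband"`.
#' @return object of class `source_epoch`.
#' @export
source_epoch <- function(data, rate, subject = NA, interval = NA,
                         band = "broadband") {
  data <- as.matrix(data)
  if (ncol(data) < 2) stop("epoch needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(data))) stop("non-finite values in epoch", call. = FALSE)
  structure(list(data = data, rate = rate, subject = subject,
                 interval = interval, band = band,
                 duration_s = ncol(data) / rate),
            class = "source_epoch")
}

#' @export
print.source_epoch <- function(x, ...) {
  cat(sprintf("<source_epoch> subject=%s interval=%s %d ROIs x %d samples @ %g Hz (%.1f s)\n",
              x$subject, x$interval, nrow(x$data), ncol(x$data), x$rate,
              x$duration_s))
  invisible(x)
}

#' Read per-subject source epochs from a directory
#'
#' Each interval is one delimited file `<subject>_<interval>.csv` (or `.tsv`)
#' with the ROI labels in the first row and one row per time sample.
#' Empty files are skipped with a warning.
#'
#' @param dir directory containing epoch files.
#' @param rate sampling rate, Hz.
#' @param n_rois expected number of ROIs (from the parcellation); a mismatch
#'   raises before any computation.
#' @return list (by subject) of lists of [source_epoch()]s.
#' @export
read_epochs <- function(dir, rate, n_rois = NULL) {
  files <- sort(list.files(dir, pattern = "\\.(csv|tsv)$", full.names = TRUE))
  if (!length(files)) stop("no epoch files in ", dir, call. = FALSE)
  out <- list()
  for (f in files) {
    id <- sub("\\.(csv|tsv)$", "", basename(f))
    parts <- strsplit(id, "_")[[1]]
    subject <- paste(head(parts, -1L), collapse = "_")
    interval <- as.integer(parts[length(parts)])
    dt <- data.table::fread(f, header = TRUE, data.table = FALSE)
    if (!nrow(dt)) {
      warning("empty interval skipped: ", basename(f), call. = FALSE)
      next
    }
    x <- t(as.matrix(dt))   # stored samples x ROIs; epochs are ROIs x samples
    if (!is.null(n_rois) && nrow(x) != n_rois)
      stop("epoch ", basename(f), " has ", nrow(x),
           " ROIs, parcellation has ", n_rois, call. = FALSE)
    ep <- source_epoch(x, rate, subject = subject, interval = interval)
    out[[subject]] <- c(out[[subject]], list(ep))
  }
  out
}

#' Write per-subject source epochs to a directory
#' @param epochs list (by subject) of lists of [source_epoch()]s.
#' @param dir output directory, created if needed.
#' @export
write_epochs <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (subject in names(epochs)) {
    for (ep in epochs[[subject]]) {
      f <- file.path(dir, sprintf("%s_%03d.csv", subject, ep$interval))
      df <- as.data.frame(t(ep$data))
      names(df) <- rownames(ep$data)
      data.table::fwrite(df, f)
    }
  }
  invisible(dir)
}

#' Run configuration
#'
#' Defaults follow the standard resting-state EEG analysis conventions this
#' package is built around: alpha/beta/gamma bands, 0.5 Hz envelope cutoff,
#' 250 Hz working rate, filter weights G in \[0, 1000\], Louvain resolution
#' 0.9-1.3, 200 Louvain repetitions.
#'
#' @param bands named list of `c(low, high)` band edges in Hz.
#' @param envelope_cutoff envelope low-pass cutoff, Hz.
#' @param resample_rate working sampling rate, Hz.
#' @param G_grid nonnegative filter weights.
#' @param gamma_grid Louvain resolution parameters.
#' @param n_louvain_reps Louvain repetitions per condition.
#' @param seed integer RNG seed.
#' @param graph_normalization `"max1"` or `"none"`.
#' @param negative_weight_mode `"asym"` or `"zero"`.
#' @return object of class `run_config` (a named list).
#' @export
run_config <- function(bands = list(alpha = c(8, 13), beta = c(13, 30),
                                    gamma = c(30, 40)),
                       envelope_cutoff = 0.5,
                       resample_rate = 250,
                       G_grid = c(0, 0.02, 0.05, 0.1, 0.2, 0.5, 1, 2, 5,
                                  10, 100, 1000),
                       gamma_grid = seq(0.9, 1.3, by = 0.025),
                       n_louvain_reps = 200,
                       seed = 1L,
                       graph_normalization = c("max1", "none"),
                       negative_weight_mode = c("asym", "zero")) {
  graph_normalization <- match.arg(graph_normalization)
  negative_weight_mode <- match.arg(negative_weight_mode)
  for (b in names(bands)) {
    e <- bands[[b]]
    if (!(0 < e[1] && e[1] < e[2] && e[2] < resample_rate / 2))
      stop("band ", b, " edges must satisfy 0 < low < high < rate/2",
           call. = FALSE)
  }
  if (any(G_grid < 0) || any(G_grid > 1000))
    stop("G values must lie in [0, 1000]", call. = FALSE)
  if (any(gamma_grid <= 0)) stop("gamma must be positive", call. = FALSE)
  if (n_louvain_reps < 1) stop("n_louvain_reps must be >= 1", call. = FALSE)
  structure(list(bands = bands, envelope_cutoff = envelope_cutoff,
                 resample_rate = resample_rate, G_grid = G_grid,
                 gamma_grid = gamma_grid, n_louvain_reps = n_louvain_reps,
                 seed = as.integer(seed),
                 graph_normalization = graph_normalization,
                 negative_weight_mode = negative_weight_mode),
            class = "run_config")
}

#' Read / write run configuration as JSON
#' @param path file path.
#' @rdname run_config_io
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$bands)) raw$bands <- lapply(raw$bands, as.numeric)
  do.call(run_config, raw)
}

#' @param config a [run_config()].
#' @rdname run_config_io
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
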