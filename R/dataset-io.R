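#' Write a multimodal dataset to a portable text archive
#'
#' The archive is a directory of tab-separated matrices (one file per
#' named array: `x_1.tsv ... x_M.tsv`, and when ground truth is present
#' `truth_z.tsv`, `truth_eps.tsv`, `truth_eta_m.tsv`, `truth_A.tsv`,
#' `truth_order.tsv`) plus a JSON `meta.json` with the generating
#' specification and seeds. Values are written with 17 significant digits
#' so the round trip is bit-identical.
#'
#' @param ds an `mm_dataset`.
#' @param path directory to create (must not exist unless `overwrite`).
#' @param overwrite replace an existing archive.
#' @return `path`, invisibly.
#' @export
write_mmds <- function(ds, path, overwrite = FALSE) {
  stopifnot(inherits(ds, "mm_dataset"))
  if (dir.exists(path)) {
    if (!overwrite) stop("archive already exists: ", path)
    unlink(path, recursive = TRUE)
  }
  dir.create(path, recursive = TRUE)
  wm <- function(mat, file) .write_num_matrix(mat, file.path(path, file))
  for (m in seq_along(ds$x)) wm(ds$x[[m]], sprintf("x_%d.tsv", m))
  has_truth <- !is.null(ds$z)
  if (has_truth) {
    wm(ds$z, "truth_z.tsv")
    wm(ds$eps, "truth_eps.tsv")
    for (m in seq_along(ds$eta)) wm(ds$eta[[m]], sprintf("truth_eta_%d.tsv", m))
    wm(ds$A_true, "truth_A.tsv")
    writeLines(as.character(ds$order), file.path(path, "truth_order.tsv"))
  }
  meta <- ds$meta
  meta$M <- length(ds$x)
  meta$has_truth <- has_truth
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

.write_num_matrix <- function(mat, file) {
  lines <- apply(mat, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(lines, file)
}

.read_num_matrix <- function(file) {
  as.matrix(utils::read.table(file, sep = "\t", header = FALSE,
                              colClasses = "numeric"))
}

#' Read a multimodal dataset archive written by [write_mmds()]
#'
#' @param path archive directory.
#' @return an `mm_dataset` (without the generating `scm` object, which is
#'   not serialized).
#' @export
read_mmds <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  M <- meta$M
  x <- lapply(seq_len(M), function(m)
    unname(.read_num_matrix(file.path(path, sprintf("x_%d.tsv", m)))))
  out <- list(x = x, z = NULL, eps = NULL, eta = NULL, A_true = NULL,
              order = NULL, partition = NULL, scm = NULL, meta = meta)
  if (isTRUE(meta$has_truth)) {
    out$z <- unname(.read_num_matrix(file.path(path, "truth_z.tsv")))
    out$eps <- unname(.read_num_matrix(file.path(path, "truth_eps.tsv")))
    out$eta <- lapply(seq_len(M), function(m)
      unname(.read_num_matrix(file.path(path, sprintf("truth_eta_%d.tsv", m)))))
    A <- unname(.read_num_matrix(file.path(path, "truth_A.tsv")))
    storage.mode(A) <- "integer"
    out$A_true <- A
    out$order <- as.integer(readLines(file.path(path, "truth_order.tsv")))
  }
  if (!is.null(meta$spec$d_z)) {
    d_z <- meta$spec$d_z
    ends <- cumsum(d_z); starts <- c(1L, head(ends, -1L) + 1L)
    out$partition <- lapply(seq_along(d_z), function(m) seq.int(starts[m], ends[m]))
  }
  structure(out, class = "mm_dataset")
}
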