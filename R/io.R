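#' Read an undirected edge list
#'
#' TSV lines `u<TAB>v` with 0-based integer node ids; lines starting with
#' `#` and blank lines are ignored. Self-loops are dropped (with a warning)
#' and duplicates collapsed; the counts are kept in attributes
#' `n_self_loops` and `n_duplicates`.
#'
#' @param path file path.
#' @param one_based treat ids in the file as 1-based and shift to 0-based
#'   (brain-atlas ROI tables are commonly 1-based).
#' @return Canonical two-column integer edge matrix.
#' @export
read_edge_list <- function(path, one_based = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) return(canonical_edges(matrix(integer(), ncol = 2)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 2)
  if (length(bad))
    stop("line ", lineno[bad[1]], ": expected two tab-separated node ids")
  u <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1)))
  v <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2)))
  bad <- which(is.na(u) | is.na(v))
  if (length(bad))
    stop("line ", lineno[bad[1]], ": non-integer node id")
  if (one_based) { u <- u - 1L; v <- v - 1L }
  bad <- which(u < 0 | v < 0)
  if (length(bad))
    stop("line ", lineno[bad[1]], ": negative node id")
  canonical_edges(cbind(u, v))
}

#' Write an edge list as TSV
#'
#' @param edges two-column edge matrix.
#' @param path output path.
#' @param one_based write 1-based ids.
#' @export
write_edge_list <- function(edges, path, one_based = FALSE) {
  edges <- canonical_edges(as_edge_matrix(edges))
  off <- if (one_based) 1L else 0L
  writeLines(sprintf("%d\t%d", edges[, 1] + off, edges[, 2] + off), path)
  invisible(path)
}

#' Read a symmetric weight matrix from CSV
#'
#' Square numeric CSV (no row names; a header row is auto-detected).
#' Asymmetry up to `tol` is silently symmetrized as `(W + t(W)) / 2`;
#' larger asymmetry, non-square shape or missing values are errors.
#'
#' @param path file path.
#' @param tol absolute asymmetry tolerance.
#' @return Symmetric numeric matrix.
#' @export
read_weight_matrix <- function(path, tol = 1e-6) {
  first <- readLines(path, n = 1)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1]][1])))
  W <- as.matrix(read.table(path, sep = ",", header = has_header))
  dimnames(W) <- NULL
  if (nrow(W) != ncol(W)) stop("matrix is not square: ", nrow(W), "x", ncol(W))
  if (anyNA(W)) stop("matrix contains missing values")
  storage.mode(W) <- "double"
  asym <- max(abs(W - t(W)))
  if (asym > tol)
    stop("matrix asymmetry ", format(asym), " exceeds tolerance ", tol)
  (W + t(W)) / 2
}

#' Write a weight matrix as CSV
#'
#' @param W numeric matrix.
#' @param path output path.
#' @export
write_weight_matrix <- function(W, path) {
  write.table(format(W, digits = 15, trim = TRUE, scientific = FALSE),
              path, sep = ",", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Write a generation trace as TSV
#'
#' Columns: generation, psi, second_largest, n_clusters.
#'
#' @param trace a `generation_trace`.
#' @param path output path.
#' @export
write_trace <- function(trace, path) {
  write.table(as.data.frame(trace), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Plain key-value text recording what produced a result file: command,
#' parameters, master seed, input checksums and package version, so that a
#' rerun with the same manifest reproduces byte-identical outputs.
#'
#' @param path output path.
#' @param command command or function name.
#' @param params named list of parameters (seeds included).
#' @param inputs character vector of input file paths to checksum.
#' @export
write_manifest <- function(path, command, params = list(), inputs = character()) {
  kv <- c(command = command,
          package = as.character(utils::packageVersion("hdperc")),
          unlist(lapply(params, function(p) paste(format(p, digits = 15), collapse = ","))))
  if (length(inputs)) {
    sums <- vapply(inputs, function(f) {
      con <- file(f, "rb"); on.exit(close(con))
      # cheap content fingerprint: size + sum of bytes (no extra deps)
      bytes <- readBin(con, "raw", file.info(f)$size)
      sprintf("%d:%.0f", length(bytes), sum(as.integer(bytes)))
    }, "")
    names(sums) <- paste0("checksum.", basename(inputs))
    kv <- c(kv, sums)
  }
  writeLines(paste0(names(kv), " = ", kv), path)
  invisible(path)
}
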