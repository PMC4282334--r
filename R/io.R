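#' Read an adjacency-list file
#'
#' Format: one line per ego, `ego_id<TAB>alter_id,alter_id,...`; the alter
#' field may be empty (an ego nominating no one in sample).
#'
#' @param path file path.
#' @param ... passed to [parse_adjacency_list()] (`node_ids`, `unknown`).
#' @return a [directed_network()].
#' @export
read_adjacency_list <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  egos <- vapply(parts, `[`, "", 1L)
  alters <- lapply(parts, function(p) {
    if (length(p) < 2 || !nzchar(p[2])) character(0)
    else strsplit(p[2], ",", fixed = TRUE)[[1]]
  })
  names(alters) <- egos
  parse_adjacency_list(alters, ...)
}

#' Write an adjacency-list file
#'
#' @param net a [directed_network()].
#' @param path file path.
#' @export
write_adjacency_list <- function(net, path) {
  stopifnot(inherits(net, "directed_network"))
  lines <- vapply(net$node_ids, function(id) {
    paste0(id, "\t", paste(ego_alters(net, id), collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a weight matrix as sparse triplet CSV
#'
#' Columns `row,col,row_id,col_id,value`; a comment header records the
#' classification and scheme so files are self-describing.
#'
#' @param wm a `weight_matrix`.
#' @param path file path.
#' @export
write_weight_matrix_csv <- function(wm, path) {
  stopifnot(inherits(wm, "weight_matrix"))
  T3 <- methods::as(wm$W, "TsparseMatrix")
  rid <- if (!is.null(rownames(wm$W))) rownames(wm$W)[T3@i + 1L] else T3@i + 1L
  cid <- if (!is.null(colnames(wm$W))) colnames(wm$W)[T3@j + 1L] else T3@j + 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# classification=%s scheme=%s kind=%s nrow=%d ncol=%d",
                     wm$classification, wm$scheme, wm$kind,
                     nrow(wm$W), ncol(wm$W)), con)
  utils::write.csv(data.frame(row = T3@i + 1L, col = T3@j + 1L,
                              row_id = rid, col_id = cid, value = T3@x),
                   con, row.names = FALSE)
  invisible(path)
}

#' Read a sparse-triplet weight matrix CSV written by
#' [write_weight_matrix_csv()]
#'
#' @param path file path.
#' @return a `weight_matrix`.
#' @export
read_weight_matrix_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  meta <- regmatches(hdr, gregexpr("[a-z]+=[^ ]+", hdr))[[1]]
  meta <- stats::setNames(sub(".*=", "", meta), sub("=.*", "", meta))
  df <- utils::read.csv(path, comment.char = "#")
  nr <- as.integer(meta[["nrow"]]); nc <- as.integer(meta[["ncol"]])
  W <- Matrix::sparseMatrix(i = df$row, j = df$col, x = df$value,
                            dims = c(nr, nc))
  structure(list(W = W, classification = meta[["classification"]],
                 scheme = meta[["scheme"]], kind = meta[["kind"]]),
            class = "weight_matrix")
}

#' Export a weight matrix in Matrix Market format
#'
#' @param wm a `weight_matrix` (or bare matrix).
#' @param path file path (conventionally `.mtx`).
#' @export
write_weight_matrix_mtx <- function(wm, path) {
  Matrix::writeMM(wm_matrix(wm), path)
  invisible(path)
}
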