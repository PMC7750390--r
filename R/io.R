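#' Read and write positional records
#'
#' Positions travel as delimited text with one record per row:
#' `animal_id, day_index, timestamp, x_m, y_m` (timestamps in epoch-style
#' seconds; ISO-8601 timestamps are accepted on input and converted).
#'
#' @param path file path.
#' @return `load_positions()` returns a positions data.frame.
#' @export
load_positions <- function(path) {
  dt <- tryCatch(
    data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE),
    error = function(e) stop("failed to read positions from ", path, ": ",
                             conditionMessage(e)))
  if (nrow(dt) == 0) {
    warning("empty positions file: ", path)
    return(data.frame(animal_id = character(), day_index = integer(),
                      timestamp = numeric(), x_m = numeric(), y_m = numeric(),
                      stringsAsFactors = FALSE))
  }
  need <- c("animal_id", "day_index", "timestamp", "x_m", "y_m")
  if (!all(need %in% names(dt)))
    stop("positions file ", path, " must have columns: ",
         paste(need, collapse = ", "))
  if (inherits(dt$timestamp, "POSIXt"))
    dt$timestamp <- as.numeric(dt$timestamp)
  if (is.character(dt$timestamp)) {
    ts <- suppressWarnings(as.numeric(dt$timestamp))
    iso <- is.na(ts)
    if (any(iso))
      ts[iso] <- as.numeric(as.POSIXct(dt$timestamp[iso], tz = "UTC"))
    dt$timestamp <- ts
  }
  bad <- which(!is.finite(dt$x_m) | !is.finite(dt$y_m) |
                 !is.finite(dt$timestamp))
  if (length(bad))
    stop("malformed rows in ", path, " at line(s): ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  dt$animal_id <- as.character(dt$animal_id)
  dt$day_index <- as.integer(dt$day_index)
  dt[, need]
}

#' @rdname load_positions
#' @param positions positions data.frame.
#' @export
write_positions <- function(positions, path) {
  validate_positions(positions)
  data.table::fwrite(
    positions[c("animal_id", "day_index", "timestamp", "x_m", "y_m")], path)
  invisible(path)
}

#' Read and write interaction matrices
#'
#' Matrices are square delimited text with animal-id header row and
#' column; diagonal cells are empty (NA).
#'
#' @param matrix symmetric matrix with animal-id dimnames.
#' @param path file path.
#' @export
write_matrix <- function(matrix, path) {
  m <- as.matrix(matrix)
  df <- data.frame(animal_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, na = "")
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  dt <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE,
                          na.strings = "")
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (nrow(m) != ncol(m)) stop("matrix file ", path, " is not square")
  dimnames(m) <- list(ids, colnames(dt)[-1])
  storage.mode(m) <- "numeric"
  m
}

#' Long-format edge list for a set of interaction matrices
#'
#' @param matrices named list of matrices; names like `"day<k>_<zone>"`
#'   are parsed, otherwise supply `day_index`/`zone` attributes on each.
#' @return data.frame with columns `day_index`, `zone`, `id_a`, `id_b`,
#'   `count`.
#' @export
edge_list <- function(matrices) {
  rows <- lapply(matrices, function(m) {
    ids <- rownames(m)
    ut <- which(upper.tri(m), arr.ind = TRUE)
    data.frame(day_index = attr(m, "day_index"),
               zone = attr(m, "zone"),
               id_a = ids[ut[, 1]], id_b = ids[ut[, 2]],
               count = m[upper.tri(m)], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
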