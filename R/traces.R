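#' Write and read tabular protein traces
#'
#' Plain delimited text with a required header line and columns
#' `replica`, `frame`, `x`, `y`, `z`, `species`. `read_traces()`
#' validates the file and reports malformed lines with their line
#' numbers.
#'
#' @param traces a `protein_trace` or list of them.
#' @param path file path.
#' @param sep field separator.
#' @return `write_traces()` returns `path` invisibly; `read_traces()` a
#'   list of `protein_trace` objects keyed by replica id.
#' @export
write_traces <- function(traces, path, sep = "\t") {
  if (inherits(traces, "protein_trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(replica = attr(tr, "replica_id") %||% 1L,
               frame = tr$time, x = tr$x, y = tr$y, z = tr$z,
               species = "protein")))
  write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
              path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path, sep = "\t") {
  if (!file.exists(path)) stopf("trace file not found: %s", path)
  ln <- readLines(path)
  if (length(ln) < 2) stopf("trace file has no data rows: %s", path)
  hdr <- strsplit(ln[1], sep, fixed = TRUE)[[1]]
  need <- c("replica", "frame", "x", "y", "z", "species")
  if (!identical(tolower(hdr), need))
    stopf("bad header (line 1): expected '%s', got '%s'",
          paste(need, collapse = sep), ln[1])
  parts <- strsplit(ln[-1], sep, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6))
    stopf("wrong column count at line %d (%d fields, expected 6)",
          which(nf != 6)[1] + 1L, nf[nf != 6][1])
  m <- do.call(rbind, parts)
  num <- suppressWarnings(apply(m[, 2:5, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 4)
  if (any(is.na(num))) {
    bad <- which(rowSums(is.na(num)) > 0)[1]
    stopf("non-numeric value at line %d: '%s'", bad + 1L, ln[bad + 1])
  }
  if (any(!is.finite(num))) stopf("non-finite positions in %s", path)
  df <- data.frame(replica = m[, 1], frame = num[, 1], x = num[, 2],
                   y = num[, 3], z = num[, 4])
  lapply(split(df, df$replica), function(d) {
    d <- d[order(d$frame), ]
    if (any(diff(d$frame) <= 0))
      stopf("frame times not strictly increasing for replica %s",
            d$replica[1])
    rid <- suppressWarnings(as.integer(d$replica[1]))
    structure(data.frame(time = as.integer(d$frame), x = d$x, y = d$y,
                         z = d$z),
              replica_id = if (is.na(rid)) 1L else rid,
              class = c("protein_trace", "data.frame"))
  })
}

#' Read bead frames from GRO files
#'
#' @param paths one or more GRO file paths.
#' @return a list of [bead_frame()]s.
#' @export
read_frames <- function(paths) {
  lapply(paths, read_gro)
}
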