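#' Write a data frame as headered CSV with key-value comment lines
#'
#' Output starts with \code{# key: value} comment lines (the generating
#' seed, when the object carries one, is always recorded) followed by a
#' standard header row.  [read_seslt_csv()] reads the format back and
#' restores the comments as attributes.
#'
#' @param x data frame (mortality panel, SES index table, cohort, life
#'   table or survival curve).
#' @param path output file.
#' @param meta named character/numeric vector of extra header fields.
#' @return \code{path}, invisibly.
#' @export
write_seslt_csv <- function(x, path, meta = NULL) {
  hdr <- character(0)
  if (!is.null(attr(x, "seed")))
    hdr <- c(hdr, paste0("# seed: ", attr(x, "seed")))
  if (length(meta))
    hdr <- c(hdr, paste0("# ", names(meta), ": ", unlist(meta)))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(hdr)) writeLines(hdr, con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Read a headered CSV written by [write_seslt_csv()]
#'
#' @param path input file.
#' @return data frame; \code{# key: value} comment lines come back as
#'   attributes (numeric where possible).
#' @export
read_seslt_csv <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr <- grep("^# ", lines, value = TRUE)
  out <- utils::read.csv(path, comment.char = "#")
  for (h in hdr) {
    kv <- sub("^# ([^:]+): (.*)$", "\\1\r\\2", h)
    kv <- strsplit(kv, "\r", fixed = TRUE)[[1]]
    if (length(kv) == 2L) {
      val <- suppressWarnings(as.numeric(kv[2]))
      attr(out, kv[1]) <- if (is.na(val)) kv[2] else val
    }
  }
  out
}
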