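# STAR (RELION dialect) metadata reader/writer. Handles a single data block
# with one loop_ table, which is the layout the simulator emits and the
# trainer consumes.

#' Write a data frame as a STAR loop
#'
#' Columns become `_rln...`-style labels in order; the block is named
#' `data_particles`.
#'
#' @param df Data frame of per-particle metadata; column names are used as
#'   labels verbatim (prefix them with `_`, e.g. `_rlnAngleRot`, before
#'   calling, or plain names are prefixed with `_` automatically).
#' @param path Output path.
#' @param block Data block name (default "particles").
#' @return `path`, invisibly.
#' @export
write_star <- function(df, path, block = "particles") {
  labels <- colnames(df)
  labels <- ifelse(startsWith(labels, "_"), labels, paste0("_", labels))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", paste0("data_", block), "", "loop_"), con)
  writeLines(sprintf("%s #%d", labels, seq_along(labels)), con)
  body <- do.call(paste, c(lapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)  # round-trips doubles exactly
  }), sep = "  "))
  writeLines(body, con)
  invisible(path)
}

#' Read a STAR file's loop table
#'
#' Parses the first (or named) data block containing a `loop_` into a data
#' frame; numeric columns are converted automatically. Label names keep
#' their leading underscore stripped.
#'
#' @param path Input path.
#' @param block Optional block name to select (without the `data_` prefix).
#' @return Data frame.
#' @export
read_star <- function(path, block = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  starts <- grep("^data_", lines)
  if (length(starts) == 0) stop("no data block in STAR file")
  if (!is.null(block)) {
    starts <- starts[lines[starts] == paste0("data_", block)]
    if (length(starts) == 0) stop("block not found: ", block)
  }
  i <- starts[1] + 1
  while (i <= length(lines) && lines[i] != "loop_") i <- i + 1
  if (i > length(lines)) stop("no loop_ in data block")
  i <- i + 1
  labels <- character()
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    labels <- c(labels, sub("\\s*#\\d+$", "", lines[i]))
    i <- i + 1
  }
  rows <- list()
  while (i <= length(lines) && nzchar(lines[i]) &&
         !startsWith(lines[i], "data_")) {
    rows[[length(rows) + 1]] <- strsplit(lines[i], "\\s+")[[1]]
    i <- i + 1
  }
  if (length(rows) == 0) stop("empty loop in STAR file")
  m <- do.call(rbind, rows)
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  colnames(df) <- sub("^_", "", labels)
  for (j in seq_along(df)) {
    num <- suppressWarnings(as.numeric(df[[j]]))
    if (!anyNA(num)) df[[j]] <- num
  }
  df
}
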