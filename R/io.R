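# Readers/writers for the pipeline's standard text formats (GCT 1.2, GMT,
# TSV matrices, CSV annotations). All floats are serialized with 15
# significant digits so reruns are byte-comparable.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 15, format = "g"))
}

#' Write an expression matrix as GCT 1.2
#'
#' @param x an [expr_matrix()] or plain matrix.
#' @param path output file.
#' @param description optional per-gene description column (defaults to
#'   the gene id).
#' @export
write_gct <- function(x, path, description = NULL) {
  v <- as_values(x)
  desc <- description %||% rownames(v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(v), ncol(v), sep = "\t")), con)
  writeLines(paste(c("Name", "Description", colnames(v)), collapse = "\t"), con)
  body <- cbind(rownames(v), desc, apply(v, 2, fmt_num))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a GCT 1.2 expression file
#'
#' @param path GCT file.
#' @param unit unit tag for the returned [expr_matrix()] (default
#'   `"TPM"`).
#' @return An [expr_matrix()].
#' @export
read_gct <- function(path, unit = "TPM") {
  lines <- readLines(path)
  if (length(lines) < 3 || lines[1] != "#1.2")
    stopf("%s: malformed GCT header at line 1 (expected '#1.2')", path)
  dims <- suppressWarnings(as.integer(strsplit(lines[2], "\t")[[1]]))
  if (length(dims) != 2 || anyNA(dims))
    stopf("%s: malformed dimensions at line 2", path)
  tab <- read.delim(text = lines[-(1:2)], check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(tab) != dims[1] || ncol(tab) - 2 != dims[2])
    stopf("%s: dimensions line 2 says %d x %d but body is %d x %d",
          path, dims[1], dims[2], nrow(tab), ncol(tab) - 2)
  v <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(v) <- tab[[1]]
  expr_matrix(v, unit = unit)
}

#' Write gene sets as GMT
#'
#' One set per line: name, description, tab-separated members. A
#' [signature_set()] is written as two sets, `<name>_UP` and `<name>_DN`.
#'
#' @param sets named list of character vectors, or a [signature_set()].
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "signature_set"))
    sets <- setNames(list(sets$up, sets$down), paste0(sets$name, c("_UP", "_DN")))
  sets <- lapply(sets, function(s) if (is.list(s)) s$markers else s)
  empty <- !vapply(sets, length, integer(1))
  if (any(empty))
    stopf("cannot write empty gene set(s): %s",
          paste(names(sets)[empty], collapse = ", "))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Duplicate members within a set are removed with a warning.
#'
#' @param path GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stopf("%s: malformed GMT line %d (need name, description, members)", path, i)
    members <- parts[-(1:2)]
    if (anyDuplicated(members)) {
      warnf("%s: duplicate members in set '%s' deduplicated", path, parts[1])
      members <- unique(members)
    }
    out[[parts[1]]] <- members
  }
  out
}

#' Write a numeric matrix as TSV (row ids in first column)
#' @param m matrix; @param path output file; @param id_col name of the id
#'   column (default `"id"`).
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  m <- as_values(m)
  header <- paste(c(id_col, colnames(m)), collapse = "\t")
  body <- apply(cbind(rownames(m), apply(m, 2, fmt_num)), 1, paste, collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a TSV matrix written by [write_matrix_tsv()]
#' @param path TSV file.
#' @return Numeric matrix with row names from the first column.
#' @export
read_matrix_tsv <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(tab[, -1, drop = FALSE])
  rownames(v) <- tab[[1]]
  v
}

#' Read a sample annotation CSV
#'
#' @param path CSV with a `sample_id` column.
#' @return data.frame.
#' @export
read_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stopf("%s: missing 'sample_id' column", path)
  df
}

write_df_csv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
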