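# Standard-format I/O: expression as TSV (first column gene id, header =
# sample ids), clinical tables as TSV, gene sets as GMT (name TAB
# description TAB members...). Parsers validate schemas and report the
# offending line or identifier instead of coercing silently.

#' Read a genes x samples expression TSV
#'
#' @param path TSV file; first column gene ids, remaining columns samples.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file needs gene ids plus >= 1 sample")
  genes <- as.character(df[[1L]])
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicated gene ids: ", paste(unique(dup), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1L], is.numeric, TRUE))
    stop("non-numeric expression columns: ",
         paste(names(df)[-1L][bad], collapse = ", "))
  }
  if (anyNA(m)) {
    rows <- which(rowSums(is.na(m)) > 0)
    stop("missing expression values in genes: ",
         paste(genes[head(rows, 5L)], collapse = ", "),
         if (length(rows) > 5L) " ..." else "")
  }
  rownames(m) <- genes
  m
}

#' Write a genes x samples expression TSV
#'
#' @param expr numeric matrix with dimnames.
#' @param path output file.
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: one set per line, `name TAB description TAB
#'   member...`.
#' @return named list of character vectors; descriptions kept in the
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  desc <- character(length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("GMT parse error at line %d: expected >= 3 tab-separated fields",
                   i))
    nm[i] <- fields[1L]
    desc[i] <- fields[2L]
    sets[[i]] <- fields[-(1:2)]
  }
  dup <- nm[duplicated(nm)]
  if (length(dup))
    stop("duplicated gene-set names: ", paste(unique(dup), collapse = ", "))
  names(sets) <- nm
  names(desc) <- nm
  attr(sets, "description") <- desc
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description per-set description strings (recycled).
#' @export
write_gmt <- function(sets, path, description = "synthetic") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical TSV (sample, time_months, event, covariates)
#'
#' @param path TSV file.
#' @return validated data.frame.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  check_clinical(df)
  df
}

#' Write a clinical TSV
#'
#' @param clinical clinical data.frame.
#' @param path output file.
#' @export
write_clinical <- function(clinical, path) {
  check_clinical(clinical)
  write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
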