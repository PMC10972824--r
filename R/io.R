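# Readers/writers for the delimited formats the pipeline exchanges
# (DepMap-style matrices, GMT collections, plain gene lists) and the
# cell-line intersection that defines the analysis panel.

delim_for <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a delimited numeric matrix
#'
#' Reads a TSV/CSV matrix whose first column holds row identifiers and whose
#' header holds column identifiers. The delimiter is auto-detected from the
#' file extension (`.csv` = comma, otherwise tab) and can be overridden.
#' Empty fields and `"NA"` are recorded as missing, never as zero.
#'
#' @param path file path.
#' @param sep optional delimiter override.
#' @return numeric matrix with unique row and column names.
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(path, sep = NULL) {
  sep <- delim_for(path, sep)
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) < 2) stop("matrix file needs a header and at least one row: ", path)
  # sentinel keeps trailing empty fields (strsplit would drop them)
  fields <- lapply(strsplit(paste0(lines, sep, "\x01"), sep, fixed = TRUE),
                   function(f) f[-length(f)])
  header <- fields[[1]]
  ncol_expect <- length(header)
  cols <- header[-1]
  widths <- lengths(fields)
  ragged <- which(widths[-1] != ncol_expect) + 1L
  if (length(ragged) > 0) {
    stop("ragged row(s) at line(s) ", paste(ragged, collapse = ", "),
         " in ", path, " (expected ", ncol_expect, " fields)")
  }
  rows <- vapply(fields[-1], `[[`, character(1), 1L)
  dup_r <- unique(rows[duplicated(rows)])
  if (length(dup_r) > 0) {
    stop("duplicate row identifiers in ", path, ": ", paste(dup_r, collapse = ", "))
  }
  dup_c <- unique(cols[duplicated(cols)])
  if (length(dup_c) > 0) {
    stop("duplicate column identifiers in ", path, ": ", paste(dup_c, collapse = ", "))
  }
  vals <- vapply(fields[-1], function(f) {
    x <- f[-1]
    x[x == ""] <- NA_character_
    suppressWarnings(as.numeric(x))
  }, numeric(ncol_expect - 1L))
  mat <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = ncol_expect - 1L)
  dimnames(mat) <- list(rows, cols)
  mat
}

#' Write a delimited numeric matrix
#'
#' Inverse of [read_matrix()]: the first header cell is empty, rows carry
#' their identifiers, missing values are written as `NA`.
#'
#' @param mat numeric matrix with dimnames.
#' @param path destination; delimiter from extension unless `sep` given.
#' @param sep optional delimiter override.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path, sep = NULL) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  sep <- delim_for(path, sep)
  utils::write.table(mat, path, sep = sep, quote = FALSE, col.names = NA,
                     na = "NA")
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes inside a set are deduplicated with a warning; a line with fewer
#' than three fields is an error naming the line.
#'
#' @param path GMT file path.
#' @return named list of unique-gene character vectors, with a
#'   `descriptions` attribute.
#' @seealso [write_gmt()]
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stop("GMT line(s) with fewer than 3 fields at line(s) ",
         paste(short, collapse = ", "), " in ", path)
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate set names in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) {
    g <- f[-(1:2)]
    if (anyDuplicated(g)) {
      warning("duplicate genes within set '", f[[1]], "' deduplicated",
              call. = FALSE)
      g <- unique(g)
    }
    g
  })
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(desc, nm)
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of gene vectors; an optional `descriptions`
#'   attribute supplies the second column (default `"na"`).
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  desc <- attr(sets, "descriptions") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text gene list (one symbol per line)
#'
#' @param path file path.
#' @return character vector of unique symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}

#' Write a plain-text gene list
#'
#' @param genes character vector.
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Restrict panel components to their common cell lines
#'
#' The analysis operates on the cell lines for which drug response,
#' expression and (optionally) knockout-effect data all exist. Components
#' are restricted to that intersection and reordered to one shared,
#' sorted line list. The mutation table lists only lines that carry
#' variants, so it is filtered to the intersection but does not shrink it.
#'
#' @param expression genes x lines matrix (`log2(TPM+1)` scale).
#' @param responses lines x drugs AUC matrix (lower AUC = more sensitive).
#' @param mutations optional data frame with a `cell_line` column.
#' @param effects optional genes x lines knockout-effect matrix
#'   (more negative = more essential).
#' @param metadata optional data frame with a `cell_line` column.
#' @return an object of class `panel_bundle`: a list with elements
#'   `expression`, `responses`, `mutations`, `effects`, `metadata`,
#'   and `lines` (the ordered intersection).
#' @export
intersect_bundle <- function(expression, responses, mutations = NULL,
                             effects = NULL, metadata = NULL) {
  stopifnot(is.matrix(expression), is.matrix(responses))
  sets <- list(colnames(expression), rownames(responses))
  if (!is.null(effects)) sets <- c(sets, list(colnames(effects)))
  for (s in sets) {
    if (anyDuplicated(s)) stop("duplicate cell-line identifiers in a component")
  }
  lines <- sort(Reduce(intersect, sets))
  if (length(lines) == 0) stop("empty cell-line intersection across components")
  message("panel intersection: ", length(lines), " cell lines")
  bundle <- list(
    expression = expression[, lines, drop = FALSE],
    responses = responses[lines, , drop = FALSE],
    mutations = if (!is.null(mutations)) {
      mutations[mutations$cell_line %in% lines, , drop = FALSE]
    },
    effects = if (!is.null(effects)) effects[, lines, drop = FALSE],
    metadata = if (!is.null(metadata)) {
      metadata[match(lines, metadata$cell_line), , drop = FALSE]
    },
    lines = lines
  )
  structure(bundle, class = "panel_bundle")
}

#' @export
print.panel_bundle <- function(x, ...) {
  cat("panel_bundle:", length(x$lines), "cell lines\n")
  cat("  expression:", nrow(x$expression), "genes\n")
  cat("  responses :", ncol(x$responses), "drug(s)\n")
  if (!is.null(x$effects)) cat("  effects   :", nrow(x$effects), "genes\n")
  if (!is.null(x$mutations)) cat("  mutations :", nrow(x$mutations), "records\n")
  invisible(x)
}
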