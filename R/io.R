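#' Read a gene-by-sample expression matrix from TSV
#'
#' Parses a tab-delimited text file whose first row is a header of sample
#' identifiers and whose rows are genes (the common dialect for normalized
#' expression such as log2 FPKM or reporter-ion intensities). Duplicate gene
#' rows are collapsed by keeping the row with the highest mean value; blank
#' or `NA` cells are kept as missing; any other non-numeric cell outside the
#' gene column is an error, as is a repeated sample name in the header.
#'
#' @param path Path to a tab-delimited file.
#' @param gene_column Name or index of the gene-identifier column (default:
#'   first column).
#' @param duplicate_policy `"highest_mean"` (default) keeps, for each repeated
#'   gene identifier, the row with the largest mean; `"error"` refuses
#'   duplicated genes.
#' @param transpose Set `TRUE` when the file stores samples in rows and genes
#'   in the header (the matrix is transposed after parsing).
#' @return A tibble with a `gene` column followed by one numeric column per
#'   sample.
#' @export
read_expression <- function(path, gene_column = 1L,
                            duplicate_policy = c("highest_mean", "error"),
                            transpose = FALSE) {
  duplicate_policy <- match.arg(duplicate_policy)
  if (!file.exists(path) || file.size(path) == 0) {
    abort(sprintf("empty or missing expression file: %s", path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         name_repair = "minimal", progress = FALSE)
  if (nrow(raw) == 0L) abort("expression file has a header but no data rows")
  if (anyDuplicated(names(raw))) {
    abort(sprintf("duplicated sample name(s) in header: %s",
                  paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", ")))
  }
  if (is.numeric(gene_column)) gene_column <- names(raw)[gene_column]
  genes <- as.character(raw[[gene_column]])
  vals <- raw[setdiff(names(raw), gene_column)]
  num <- lapply(names(vals), function(nm) {
    v <- vals[[nm]]
    miss <- is.na(v) | v == "" | v == "NA"
    out <- suppressWarnings(as.numeric(v))
    bad <- !miss & is.na(out)
    if (any(bad)) {
      abort(sprintf("non-numeric value '%s' in column '%s'", v[bad][1], nm))
    }
    out
  })
  m <- matrix(unlist(num), nrow = nrow(raw),
              dimnames = list(NULL, names(vals)))
  if (transpose) {
    # file had samples in rows: first column holds sample ids, header holds genes
    sample_ids <- genes
    m <- t(m)
    genes <- rownames(m)
    colnames(m) <- sample_ids
  }
  rownames(m) <- NULL
  if (anyDuplicated(genes)) {
    if (duplicate_policy == "error") abort("duplicated gene identifiers")
    means <- rowMeans(m, na.rm = TRUE)
    keep <- unlist(lapply(split(seq_along(genes), genes), function(idx) {
      idx[which.max(means[idx])]
    }), use.names = FALSE)
    keep <- sort(keep)
    m <- m[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  rownames(m) <- genes
  as_expr_matrix(m) # validates invariants
  as_expr_tbl(m)
}

#' Read sample metadata (sample, group) from TSV
#'
#' Expects a header row and two tab-delimited columns: sample identifier
#' first, group label second (e.g. 6 `shRNA` knockdown vs 4 `scramble`
#' control samples). A sample listed twice with conflicting groups is an
#' error; exact duplicate rows are dropped.
#'
#' @param path Path to a tab-delimited file.
#' @return A tibble with columns `sample` and `group`.
#' @export
read_sample_meta <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 2L) abort("metadata file needs two columns: sample, group")
  meta <- dplyr::distinct(tibble(sample = as.character(raw[[1]]),
                                 group = as.character(raw[[2]])))
  if (anyDuplicated(meta$sample)) {
    abort("sample(s) listed with conflicting group labels")
  }
  meta
}

#' Read and write GMT gene-set collections
#'
#' `read_gmt()` parses the standard GMT dialect (set name, description, then
#' tab-separated members) into a long tibble with one row per set member.
#' Lines with fewer than three fields are skipped with a warning, or rejected
#' in strict mode. Duplicate members within a set are dropped; duplicate set
#' names are an error. `write_gmt()` writes the same representation back out;
#' a read of a written collection reproduces it up to member order.
#'
#' @param path File path.
#' @param strict If `TRUE`, malformed lines are an error instead of a warning.
#' @return `read_gmt()`: a tibble with columns `set`, `description`, `gene`.
#' @export
read_gmt <- function(path, strict = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("empty GMT file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3L
  if (any(short)) {
    msg <- sprintf("%d GMT line(s) with fewer than 3 fields", sum(short))
    if (strict) abort(msg) else warn(paste(msg, "- skipped"))
    parts <- parts[!short]
  }
  if (!length(parts)) abort("no valid gene sets in GMT file")
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) abort("duplicated gene-set names in GMT file")
  purrr::map_dfr(parts, function(p) {
    tibble(set = p[[1]], description = p[[2]], gene = unique(p[-(1:2)]))
  })
}

#' @rdname read_gmt
#' @param sets A gene-set collection: a tibble with columns `set`,
#'   (optionally) `description`, `gene`, or a named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lst <- as_gene_set_list(sets)
  desc <- attr(lst, "description")
  lines <- vapply(seq_along(lst), function(i) {
    paste(c(names(lst)[i], desc[[i]], lst[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# Normalize a collection (long tibble or named list) to a named list of
# unique member vectors, with a "description" attribute kept for writers.
as_gene_set_list <- function(sets) {
  if (is.data.frame(sets)) {
    if (!all(c("set", "gene") %in% names(sets))) {
      abort("gene-set table needs `set` and `gene` columns")
    }
    nm <- unique(sets$set)
    lst <- lapply(nm, function(s) unique(as.character(sets$gene[sets$set == s])))
    names(lst) <- nm
    if ("description" %in% names(sets)) {
      desc <- vapply(nm, function(s) as.character(sets$description[sets$set == s][1]), "")
    } else {
      desc <- rep("na", length(nm))
    }
  } else if (is.list(sets)) {
    if (is.null(names(sets)) || anyDuplicated(names(sets))) {
      abort("gene-set list must have unique names")
    }
    lst <- lapply(sets, function(g) unique(as.character(g)))
    desc <- rep("na", length(lst))
  } else {
    abort("`sets` must be a data frame or a named list")
  }
  if (any(lengths(lst) == 0L)) abort("empty gene set in collection")
  attr(lst, "description") <- desc
  lst
}

# Named list -> long tibble (inverse of as_gene_set_list)
gene_sets_tbl <- function(lst, description = NULL) {
  description <- description %||% attr(lst, "description") %||% rep("na", length(lst))
  purrr::map_dfr(seq_along(lst), function(i) {
    tibble(set = names(lst)[i], description = description[[i]], gene = lst[[i]])
  })
}
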