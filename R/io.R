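# Readers and writers for expression matrices, metadata and result tables.
#
# Matrix orientation is fixed as genes-in-rows, samples-in-columns (the GEO
# convention). Gene identifiers are opaque strings; no probe/symbol mapping
# is attempted.

#' Read a gene-by-sample expression matrix
#'
#' Supports plain tab-separated text (first column gene ids, header row of
#' sample ids) and the GEO series-matrix dialect (the table between
#' `!series_matrix_table_begin` and `!series_matrix_table_end`). Duplicate
#' gene ids are collapsed (mean by default) with a warning naming them;
#' genes containing any missing value are dropped with a message. An
#' optional `log2(x + 1)` transform is applied and recorded in the
#' `"transform"` attribute.
#'
#' @param path Path to the file.
#' @param format `"auto"` (detect the series-matrix marker), `"tsv"` or
#'   `"geo_series_matrix"`.
#' @param transform `"none"` or `"log2p1"`.
#' @param duplicates Collapse policy for repeated gene ids: `"mean"`
#'   (default), `"max"`, or `"first"`.
#' @return Numeric matrix (genes x samples) with attributes `"transform"`
#'   and `"source"`.
#' @export
read_expression <- function(path,
                            format = c("auto", "tsv", "geo_series_matrix"),
                            transform = c("none", "log2p1"),
                            duplicates = c("mean", "max", "first")) {
  format <- match.arg(format)
  transform <- match.arg(transform)
  duplicates <- match.arg(duplicates)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (format == "auto") {
    format <- if (any(startsWith(lines, "!series_matrix_table_begin")))
      "geo_series_matrix" else "tsv"
  }
  if (format == "geo_series_matrix") {
    beg <- which(startsWith(lines, "!series_matrix_table_begin"))
    end <- which(startsWith(lines, "!series_matrix_table_end"))
    if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L) {
      stop("malformed series-matrix table block in ", path, call. = FALSE)
    }
    lines <- lines[(beg + 1L):(end - 1L)]
    offset <- beg
  } else {
    offset <- 0L
  }
  if (length(lines) < 2L) stop("empty expression matrix in ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- length(fields[[1L]])
  ragged <- which(lengths(fields) != ncols)
  if (length(ragged)) {
    stop("ragged row(s) at line ", paste(ragged + offset, collapse = ", "),
         " of ", path, call. = FALSE)
  }
  strip <- function(x) gsub('^"|"$', "", x)
  header <- strip(fields[[1L]])
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids in header of ", path, call. = FALSE)
  }
  body <- fields[-1L]
  gene_ids <- strip(vapply(body, `[[`, character(1L), 1L))
  na_tokens <- c("", "NA", "na", "null", "NULL")
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(strip(f[-1L])),
           numeric(ncols - 1L)))
  vals <- if (ncols == 2L) matrix(vals, ncol = 1L) else t(vals)
  bad_cells <- which(vapply(body, function(f) {
    v <- strip(f[-1L])
    any(!v %in% na_tokens & is.na(suppressWarnings(as.numeric(v))))
  }, logical(1L)))
  if (length(bad_cells)) {
    stop("non-numeric cell(s) at line ",
         paste(utils::head(bad_cells, 5L) + 1L + offset, collapse = ", "),
         " of ", path, call. = FALSE)
  }
  rownames(vals) <- gene_ids
  colnames(vals) <- sample_ids

  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    warning("duplicate gene id(s) collapsed by '", duplicates, "': ",
            paste(utils::head(dup, 5L), collapse = ", "),
            if (length(dup) > 5L) ", ..." else "", call. = FALSE)
    keep <- !duplicated(gene_ids)
    if (duplicates == "first") {
      vals <- vals[keep, , drop = FALSE]
    } else {
      fun <- if (duplicates == "mean") colMeans else
        function(m) apply(m, 2L, max)
      collapsed <- vapply(dup, function(g) {
        fun(vals[gene_ids == g, , drop = FALSE])
      }, numeric(ncol(vals)))
      collapsed <- if (ncol(vals) == 1L)
        matrix(collapsed, nrow = 1L, dimnames = list(NULL, dup)) else collapsed
      vals <- vals[keep, , drop = FALSE]
      vals[dup, ] <- t(collapsed)
    }
  }
  n_na <- sum(rowSums(is.na(vals)) > 0)
  if (n_na > 0) {
    message(n_na, " gene(s) with missing values dropped")
    vals <- vals[rowSums(is.na(vals)) == 0, , drop = FALSE]
  }
  if (nrow(vals) == 0L) stop("no complete genes left in ", path, call. = FALSE)
  if (transform == "log2p1") vals <- log2(vals + 1)
  if (transform == "none" && any(vals < 0)) {
    warning("matrix contains negative values (log-scale data?); the [0,1] ",
            "range guarantee of the Pearson distance does not hold",
            call. = FALSE)
  }
  attr(vals, "transform") <- transform
  attr(vals, "source") <- path
  vals
}

#' Write an expression matrix as tab-separated text
#'
#' Inverse of [read_expression()]'s tsv path; values keep full precision so
#' a read/write round trip is lossless to numerical tolerance.
#'
#' @param matrix Genes-by-samples numeric matrix with dimnames.
#' @param path Output path.
#' @param id_column Name for the gene-id column (default `"gene_id"`).
#' @export
write_expression <- function(matrix, path, id_column = "gene_id") {
  df <- data.frame(rownames(matrix),
                   format(matrix, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_column, colnames(matrix))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Comma- or tab-separated text with a header containing at least
#' `sample_id` and `group`; `survival_days` is optional and blanks become
#' `NA`. Extra columns are passed through.
#'
#' @param path Path to the file.
#' @return Data frame with columns `sample_id`, `group`, `survival_days`
#'   (NA when absent), plus any extras.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("metadata lacks required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    dup <- unique(df$sample_id[duplicated(df$sample_id)])
    stop("duplicate sample id(s) in metadata: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(df$group) | df$group == "")) {
    stop("empty group label(s) in metadata", call. = FALSE)
  }
  if (!"survival_days" %in% names(df)) {
    df$survival_days <- NA_real_
  } else {
    df$survival_days <- as.numeric(df$survival_days)
  }
  df
}

#' Write a sample metadata table
#' @param metadata Data frame with at least `sample_id` and `group`.
#' @param path Output path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Merge expression matrices by shared genes
#'
#' Restricts each matrix to the (sorted) intersection of gene ids and
#' concatenates the samples. No cross-normalization is applied — the merged
#' values are the originals, relying on scale-invariant metrics (Pearson)
#' downstream; a notice is emitted to that effect. Per-sample provenance is
#' recorded in the `"source_of"` attribute.
#'
#' @param matrices List of at least two genes-by-samples matrices with gene
#'   ids as rownames.
#' @return Merged matrix over the shared genes.
#' @export
align_datasets <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 2L) {
    stop("need a list of at least 2 matrices", call. = FALSE)
  }
  gene_sets <- lapply(matrices, rownames)
  shared <- Reduce(intersect, gene_sets)
  if (length(shared) == 0L) {
    pairs <- utils::combn(length(matrices), 2L)
    counts <- apply(pairs, 2L, function(pr) {
      sprintf("%d-%d: %d", pr[1L], pr[2L],
              length(intersect(gene_sets[[pr[1L]]], gene_sets[[pr[2L]]])))
    })
    stop("no genes shared across all matrices; pairwise overlaps: ",
         paste(counts, collapse = "; "), call. = FALSE)
  }
  shared <- sort(shared)
  merged <- do.call(cbind, lapply(matrices, function(m) {
    m[shared, , drop = FALSE]
  }))
  if (anyDuplicated(colnames(merged))) {
    stop("duplicate sample ids across matrices: ",
         paste(unique(colnames(merged)[duplicated(colnames(merged))]),
               collapse = ", "), call. = FALSE)
  }
  message("merged ", length(matrices), " matrices over ", length(shared),
          " shared genes; no cross-normalization applied")
  src <- names(matrices)
  if (is.null(src)) src <- paste0("matrix", seq_along(matrices))
  attr(merged, "source_of") <-
    stats::setNames(rep(src, vapply(matrices, ncol, integer(1L))),
                    colnames(merged))
  merged
}

# shared formatter: 6 significant digits for result tables
.fmt6 <- function(df) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) signif(x, 6L))
  df
}

#' Write a distance-profile table
#'
#' Tab-separated with columns `sample_id`, `group` (if present),
#' `r_<label>`..., and classification columns when present. Floats are
#' written with 6 significant digits.
#'
#' @param profiles Profile data frame.
#' @param path Output path.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.table(.fmt6(profiles), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a barycentric-coordinate table
#'
#' Tab-separated with the `d_<label>` and `D_<label>` columns of
#' [to_barycentric()]; vertex labels appear in the header.
#'
#' @param bary Data frame from [to_barycentric()].
#' @param path Output path.
#' @export
write_barycentric <- function(bary, path) {
  keep <- grep("^(sample_id|group$|d_|D_)", names(bary), value = TRUE)
  utils::write.table(.fmt6(bary[keep]), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
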