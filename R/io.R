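#' @rdname read_fpkm_table
#' @export
TIMEPOINTS <- c("pre", "min3", "min10", "min30", "min60")

#' Construct a validated time-course FPKM matrix
#'
#' The central input container: a genes x 5 numeric matrix of FPKM values at
#' the pre-deflagellation baseline and 3, 10, 30 and 60 minutes into
#' ciliogenesis. Row names are gene identifiers (opaque strings), column
#' names are fixed to `pre, min3, min10, min30, min60`.
#'
#' @param values Numeric matrix (or data frame) with 5 columns in time order.
#' @param gene_ids Character vector of unique gene identifiers, one per row;
#'   defaults to `rownames(values)`.
#' @return A numeric matrix of class `time_course_matrix`.
#' @export
time_course_matrix <- function(values, gene_ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) != 5L) {
    stop("a time-course matrix needs exactly 5 time-point columns, got ",
         ncol(values))
  }
  if (nrow(values) < 1L) stop("time-course matrix has 0 genes")
  if (is.null(gene_ids)) stop("gene identifiers are required")
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("length of gene_ids does not match the number of rows")
  }
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup) > 0) {
    stop("duplicate gene identifiers: ", paste(dup, collapse = ", "))
  }
  if (any(!is.finite(values))) stop("FPKM values must all be finite")
  if (any(values < 0)) stop("FPKM values must be non-negative")
  dimnames(values) <- list(gene_ids, TIMEPOINTS)
  class(values) <- c("time_course_matrix", class(values))
  values
}

#' Read a tab-separated FPKM time-course table
#'
#' Expects a header row naming a gene-identifier column and the five
#' time-point columns. The default column names are
#' `gene_id, pre, min3, min10, min30, min60`; other layouts (e.g.
#' Cufflinks-style headers) are supported through `dialect`, a named
#' character vector mapping the canonical names to the names used in the
#' file. Column order in the file is irrelevant.
#'
#' Rows containing non-numeric expression values are dropped with a warning
#' naming the offending lines; missing columns, duplicated gene identifiers
#' and negative values are errors.
#'
#' @param path Path to a tab-separated text file.
#' @param dialect Optional named character vector, e.g.
#'   `c(gene_id = "tracking_id", pre = "T0", ...)`; names must be the
#'   canonical column names.
#' @return A [time_course_matrix()].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\tpre\tmin3\tmin10\tmin30\tmin60",
#'              "GLOD4\t3.55\t8.10\t12.50\t15.05\t11.58"), tf)
#' m <- read_fpkm_table(tf)
#' @export
read_fpkm_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  canonical <- c("gene_id", TIMEPOINTS)
  lookup <- setNames(canonical, canonical)
  if (!is.null(dialect)) {
    bad <- setdiff(names(dialect), canonical)
    if (length(bad) > 0) stop("unknown dialect keys: ", paste(bad, collapse = ", "))
    lookup[names(dialect)] <- dialect
  }
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", blank.lines.skip = TRUE)
  for (nm in canonical) {
    if (!lookup[[nm]] %in% names(df)) {
      stop("missing column '", lookup[[nm]], "' (", nm, ") in ", path)
    }
  }
  if (nrow(df) == 0L) stop("0 genes: ", path, " has a header but no data rows")
  ids <- trimws(df[[lookup[["gene_id"]]]])
  raw <- df[, lookup[TIMEPOINTS], drop = FALSE]
  num <- vapply(raw, function(col) suppressWarnings(as.numeric(trimws(col))),
                numeric(nrow(df)))
  num <- matrix(num, nrow = nrow(df))
  bad_rows <- which(apply(num, 1L, function(r) any(is.na(r))))
  if (length(bad_rows) > 0) {
    # +1 for the header line so the report matches the file
    warning("dropping ", length(bad_rows),
            " row(s) with non-numeric values at line(s): ",
            paste(bad_rows + 1L, collapse = ", "))
    num <- num[-bad_rows, , drop = FALSE]
    ids <- ids[-bad_rows]
  }
  if (nrow(num) == 0L) stop("0 genes: every data row of ", path, " was rejected")
  time_course_matrix(num, gene_ids = ids)
}

#' Read a gene set from a one-identifier-per-line text file
#'
#' Blank lines and lines starting with `#` are ignored; duplicated
#' identifiers are silently de-duplicated (the count is reported via
#' `message()`). Identifiers are whitespace-trimmed and matched exactly.
#'
#' @param path Path to the gene list file.
#' @param name Name of the set; defaults to the file name without extension.
#' @return An object of class `gene_set`: a list with elements `name` and
#'   `members` (character vector, unique, in first-seen order).
#' @export
read_gene_set <- function(path, name = NULL) {
  if (!file.exists(path)) stop("cannot read gene set file: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  ndup <- sum(duplicated(lines))
  if (ndup > 0) message(ndup, " duplicate identifier(s) removed from ", name)
  gene_set(name = name, members = unique(lines))
}

#' @rdname read_gene_set
#' @param members Character vector of gene identifiers.
#' @export
gene_set <- function(name, members) {
  name <- as.character(name)
  if (length(name) != 1L || !nzchar(name)) stop("gene set name must be non-empty")
  members <- unique(trimws(as.character(members)))
  members <- members[nzchar(members)]
  structure(list(name = name, members = members), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene set '", x$name, "': ", length(x$members), " identifier(s)\n",
      sep = "")
  invisible(x)
}

#' Write per-gene and per-cluster pipeline results as TSV
#'
#' Emits two tab-separated files into `dir`: `genes.tsv` with columns
#' `gene_id, status, max_fold_ratio, cluster_id, pattern_label` (cluster and
#' pattern are `NA` for genes that were not clustered; outliers carry
#' cluster_id `outlier`), and `clusters.tsv` with one row per final cluster:
#' `cluster_id, n_genes, mean_ratio_3, mean_ratio_10, mean_ratio_30,
#' mean_ratio_60, pattern_label, pattern_group`. Both files round-trip
#' through [read_gene_results()] / [read_cluster_results()] without loss.
#'
#' @param calls Regulation-call data frame from [classify_regulation()].
#' @param clusters `cluster_set` from [assign_genes()] (or `NULL` for a
#'   classification-only run).
#' @param labels Pattern-label data frame from [label_clusters()] (or `NULL`).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths of the written files.
#' @export
write_results <- function(calls, clusters = NULL, labels = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gene_cluster <- rep(NA_character_, nrow(calls))
  gene_pattern <- rep(NA_character_, nrow(calls))
  cl_rows <- NULL
  if (!is.null(clusters)) {
    idx <- setNames(seq_len(nrow(calls)), calls$gene_id)
    clustered <- c(unlist(lapply(clusters$clusters, `[[`, "members")),
                   clusters$outliers)
    missing <- setdiff(clustered, calls$gene_id)
    if (length(missing) > 0) {
      stop("clustered gene(s) missing from calls: ",
           paste(head(missing, 5L), collapse = ", "))
    }
    not_up <- clustered[calls$status[idx[clustered]] != "up"]
    if (length(not_up) > 0) {
      stop("clustered gene(s) not called up-regulated: ",
           paste(head(not_up, 5L), collapse = ", "))
    }
    for (cl in clusters$clusters) {
      gene_cluster[idx[cl$members]] <- cl$cluster_id
    }
    gene_cluster[idx[clusters$outliers]] <- "outlier"
    lab_of <- character(0)
    if (!is.null(labels)) {
      lab_of <- setNames(labels$principal, labels$cluster_id)
      for (cl in clusters$clusters) {
        gene_pattern[idx[cl$members]] <- lab_of[[cl$cluster_id]]
      }
      gene_pattern[idx[clusters$outliers]] <- "Unclassified"
    }
    cl_rows <- do.call(rbind, lapply(clusters$clusters, function(cl) {
      data.frame(cluster_id = cl$cluster_id,
                 n_genes = length(cl$members),
                 mean_ratio_3 = cl$mean_ratio_profile[1L],
                 mean_ratio_10 = cl$mean_ratio_profile[2L],
                 mean_ratio_30 = cl$mean_ratio_profile[3L],
                 mean_ratio_60 = cl$mean_ratio_profile[4L],
                 stringsAsFactors = FALSE)
    }))
    if (is.null(cl_rows)) {
      cl_rows <- data.frame(cluster_id = character(0), n_genes = integer(0),
                            mean_ratio_3 = numeric(0), mean_ratio_10 = numeric(0),
                            mean_ratio_30 = numeric(0), mean_ratio_60 = numeric(0))
    }
    if (!is.null(labels) && nrow(cl_rows) > 0) {
      cl_rows$pattern_label <- unname(lab_of[cl_rows$cluster_id])
      cl_rows$pattern_group <- pattern_group(cl_rows$pattern_label)
    } else {
      cl_rows$pattern_label <- character(nrow(cl_rows))
      cl_rows$pattern_group <- character(nrow(cl_rows))
    }
  } else {
    cl_rows <- data.frame(cluster_id = character(0), n_genes = integer(0),
                          mean_ratio_3 = numeric(0), mean_ratio_10 = numeric(0),
                          mean_ratio_30 = numeric(0), mean_ratio_60 = numeric(0),
                          pattern_label = character(0),
                          pattern_group = character(0))
  }
  genes <- data.frame(gene_id = calls$gene_id,
                      status = calls$status,
                      max_fold_ratio = calls$max_ratio,
                      cluster_id = gene_cluster,
                      pattern_label = gene_pattern,
                      stringsAsFactors = FALSE)
  gene_path <- file.path(dir, "genes.tsv")
  cluster_path <- file.path(dir, "clusters.tsv")
  write.table(genes, gene_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cl_rows, cluster_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(genes = gene_path, clusters = cluster_path))
}

#' @rdname write_results
#' @param path Path of a TSV written by [write_results()].
#' @export
read_gene_results <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c(gene_id = "character", status = "character",
                            max_fold_ratio = "numeric",
                            cluster_id = "character",
                            pattern_label = "character"))
}

#' @rdname write_results
#' @export
read_cluster_results <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c(cluster_id = "character", n_genes = "integer",
                            mean_ratio_3 = "numeric", mean_ratio_10 = "numeric",
                            mean_ratio_30 = "numeric", mean_ratio_60 = "numeric",
                            pattern_label = "character",
                            pattern_group = "character"))
}
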