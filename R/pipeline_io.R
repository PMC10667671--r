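# Readers and writers for the pipeline's on-disk formats, plus the generic
# distance-matrix concordance utility.

#' Read a community count table
#'
#' TSV tables are taxa rows x sample columns with the taxon id in the first
#' column; BIOM-style JSON follows the minimal BIOM 1.0 layout (`rows`,
#' `columns`, `matrix_type` dense or sparse, `data`).
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom-json"`.
#' @param sample_meta optional data.frame of sample metadata (`sample_id`
#'   column required) to attach.
#' @return a [community_table()].
#' @export
read_community <- function(path, format = c("tsv", "biom-json"), sample_meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("file not found: ", path)
  if (format == "tsv") {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop_input("TSV table needs a taxon column plus >= 1 sample")
    taxa <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2, as.numeric))), arr.ind = TRUE)
      stop_input(
        "non-numeric count near row ", bad[1, 1] + 1, ", column ", bad[1, 2] + 1
      )
    }
    counts <- t(m)
    colnames(counts) <- taxa
  } else {
    b <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    taxa <- if (is.data.frame(b$rows)) b$rows$id else vapply(b$rows, `[[`, "", "id")
    samples <- if (is.data.frame(b$columns)) b$columns$id else vapply(b$columns, `[[`, "", "id")
    mt <- b$matrix_type %||% "dense"
    if (mt == "dense") {
      m <- b$data
      if (is.list(m)) m <- do.call(rbind, lapply(m, as.numeric))
      m <- matrix(as.numeric(m), nrow = length(taxa))
    } else {
      m <- matrix(0, length(taxa), length(samples))
      d <- b$data
      if (is.list(d)) d <- do.call(rbind, d)
      m[cbind(d[, 1] + 1, d[, 2] + 1)] <- d[, 3]  # BIOM sparse triplets are 0-based
    }
    counts <- t(m)
    rownames(counts) <- samples
    colnames(counts) <- taxa
  }
  if (any(is.na(counts))) {
    bad <- which(is.na(counts), arr.ind = TRUE)[1, ]
    stop_input("missing count at sample ", bad[1], ", taxon ", bad[2])
  }
  if (!is.null(sample_meta)) {
    sample_meta <- sample_meta[match(rownames(counts), sample_meta$sample_id), , drop = FALSE]
    rownames(sample_meta) <- NULL
  }
  community_table(counts, sample_meta)
}

#' Write a community count table
#'
#' @param table a [community_table()].
#' @param path destination file.
#' @param format `"tsv"` (taxa rows x sample columns) or `"biom-json"`
#'   (minimal dense BIOM 1.0 layout).
#' @export
write_community <- function(table, path, format = c("tsv", "biom-json")) {
  stopifnot(inherits(table, "community_table"))
  format <- match.arg(format)
  m <- t(table$counts)  # taxa rows x sample columns on disk
  if (format == "tsv") {
    df <- data.frame(taxon_id = rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    obj <- list(
      id = "community", format = "Biological Observation Matrix 1.0.0",
      type = "OTU table", matrix_type = "dense",
      shape = dim(m),
      rows = data.frame(id = rownames(m), stringsAsFactors = FALSE),
      columns = data.frame(id = colnames(m), stringsAsFactors = FALSE),
      data = unname(m)
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read per-sample qPCR totals
#'
#' CSV with columns `sample_id`, `copies_per_ml`.
#' @param path file path.
#' @return data.frame.
#' @export
read_qpcr <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "copies_per_ml")
  if (!all(need %in% names(df))) {
    stop_input("qPCR CSV needs columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(df$copies_per_ml)) || any(df$copies_per_ml <= 0)) {
    stop_input("qPCR totals must be positive")
  }
  df
}

#' Read per-visit temperature profiles
#'
#' CSV with columns `visit_id`, `depth_m`, `temperature_C` (extra columns
#' such as `date` and `period` are carried along).
#' @param path file path.
#' @return data.frame.
#' @export
read_profiles <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("visit_id", "depth_m", "temperature_C")
  if (!all(need %in% names(df))) {
    stop_input("profile CSV needs columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Concordance between two dissimilarity matrices
#'
#' Pearson and Spearman correlation over the paired off-diagonal entries of
#' two dissimilarity matrices on the same samples (e.g. OTU- vs ASV-based
#' Bray-Curtis matrices).
#'
#' @param dm1,dm2 `dist` objects (or square matrices) on identical sample
#'   sets.
#' @return list with `pearson`, `spearman`, `n_pairs`.
#' @export
matrix_concordance <- function(dm1, dm2) {
  m1 <- as.matrix(dm1)
  m2 <- as.matrix(dm2)
  if (!is.null(rownames(m1)) && !is.null(rownames(m2))) {
    if (!setequal(rownames(m1), rownames(m2))) stop_input("sample sets differ")
    m2 <- m2[rownames(m1), rownames(m1)]
  } else if (!all(dim(m1) == dim(m2))) {
    stop_input("matrices must have the same dimensions")
  }
  v1 <- m1[lower.tri(m1)]
  v2 <- m2[lower.tri(m2)]
  list(
    pearson = cor(v1, v2),
    spearman = cor(v1, v2, method = "spearman"),
    n_pairs = length(v1)
  )
}
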