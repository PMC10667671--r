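# The sample x taxon count table and its metadata: the pipeline's central
# object. Counts are stored samples-in-rows; the on-disk TSV convention
# (taxa rows x sample columns) is handled by pipeline_io.

#' Construct a community table
#'
#' @param counts integer-like matrix, samples in rows, taxa in columns, with
#'   row names = sample ids and column names = taxon ids.
#' @param sample_meta data.frame with one row per sample, containing at least
#'   `sample_id`; typically also `depth` ("surface"/"bottom"), `date` and
#'   `period` ("before"/"mixing"/"after").
#' @return An object of class `community_table`: a list with elements
#'   `counts`, `sample_meta` and `taxon_ids`.
#' @export
community_table <- function(counts, sample_meta = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || (ncol(counts) > 0 && is.null(colnames(counts)))) {
    stop_input("counts must have sample row names and taxon column names")
  }
  if (anyDuplicated(rownames(counts))) stop_input("duplicate sample ids")
  if (anyDuplicated(colnames(counts))) stop_input("duplicate taxon ids")
  if (any(!is.finite(counts))) stop_input("counts must be finite")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop_input(
      "negative count at sample '", rownames(counts)[bad[1]],
      "', taxon '", colnames(counts)[bad[2]], "'"
    )
  }
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(sample_id = rownames(counts), stringsAsFactors = FALSE)
  }
  if (!"sample_id" %in% names(sample_meta)) stop_input("sample_meta needs a sample_id column")
  if (!identical(as.character(sample_meta$sample_id), rownames(counts))) {
    stop_input("sample_meta$sample_id must match count row names, in order")
  }
  structure(
    list(counts = counts, sample_meta = sample_meta, taxon_ids = colnames(counts)),
    class = "community_table"
  )
}

#' @export
print.community_table <- function(x, ...) {
  cat(
    "community_table:", nrow(x$counts), "samples x", ncol(x$counts), "taxa;",
    "total reads", format(sum(x$counts), big.mark = ","), "\n"
  )
  invisible(x)
}

#' @export
dim.community_table <- function(x) dim(x$counts)

# Internal: subset keeping metadata aligned.
subset_community <- function(table, samples = NULL, taxa = NULL) {
  counts <- table$counts
  meta <- table$sample_meta
  if (!is.null(samples)) {
    counts <- counts[samples, , drop = FALSE]
    meta <- meta[match(rownames(counts), meta$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  if (!is.null(taxa)) counts <- counts[, taxa, drop = FALSE]
  community_table(counts, meta)
}

#' Per-sample relative abundances
#'
#' @param table a [community_table()].
#' @return matrix of per-sample proportions (rows sum to 1).
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "community_table"))
  tot <- rowSums(table$counts)
  if (any(tot == 0)) {
    stop_input(
      "all-zero sample(s): ",
      paste(rownames(table$counts)[tot == 0], collapse = ", ")
    )
  }
  sweep(table$counts, 1, tot, "/")
}

#' Remove taxa with a low dataset-wide read total
#'
#' Drops taxa whose total count over all samples is below `min_total`
#' (default 10 reads), the usual guard against sequencing-error taxa.
#'
#' @param table a [community_table()].
#' @param min_total minimum dataset-wide total for a taxon to be retained.
#' @return filtered `community_table`; samples are unchanged.
#' @export
filter_low_count_taxa <- function(table, min_total = 10) {
  stopifnot(inherits(table, "community_table"))
  keep <- colSums(table$counts) >= min_total
  if (!any(keep)) warning("no taxa pass the min_total filter", call. = FALSE)
  subset_community(table, taxa = which(keep))
}

#' Rarefy a community table to even sequencing depth
#'
#' Subsamples each sample without replacement (multivariate hypergeometric,
#' via [vegan::rrarefy()]) down to `depth` reads. Samples whose total is
#' below `depth` are dropped with a warning.
#'
#' @param table a [community_table()].
#' @param depth target reads per sample; default = minimum sample total.
#' @param seed integer seed making the subsampling reproducible.
#' @return rarefied `community_table`; every remaining sample sums to `depth`.
#' @export
rarefy_table <- function(table, depth = NULL, seed = 1) {
  stopifnot(inherits(table, "community_table"))
  tot <- rowSums(table$counts)
  depth <- depth %||% min(tot)
  if (depth <= 0) stop_input("rarefaction depth must be positive")
  if (any(tot < depth)) {
    drop <- rownames(table$counts)[tot < depth]
    warning(
      "dropping ", length(drop), " sample(s) below rarefaction depth: ",
      paste(drop, collapse = ", "),
      call. = FALSE
    )
    table <- subset_community(table, samples = which(tot >= depth))
  }
  counts <- withr::with_seed(seed, withCallingHandlers(
    vegan::rrarefy(table$counts, depth),
    # vegan warns when the smallest count is large, a heuristic aimed at
    # catching non-count data; our inputs are counts by construction
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) invokeRestart("muffleWarning")
    }
  ))
  community_table(counts, table$sample_meta)
}

#' Partition taxa into occupancy classes and abundance categories
#'
#' Occupancy: `core` taxa occur in at least `core_min` (75%) of samples,
#' `satellite` taxa in less than `satellite_max` (50%), the rest are
#' `intermediate`. Abundance categories follow the six-way scheme for
#' abundant/rare taxonomies, from per-sample relative abundances:
#' AAT (>= `abundant_thr` in every sample), ART (< `rare_thr` in every
#' sample), MT (between thresholds in every sample), CAT (never rare,
#' sometimes abundant), CRT (never abundant, sometimes rare) and CRAT
#' (sometimes abundant and sometimes rare).
#'
#' Occupancy is meaningful per depth layer: pass one depth's (rarefied)
#' table at a time.
#'
#' @param table a [community_table()] for a single depth layer.
#' @param core_min minimum occurrence frequency for core taxa.
#' @param satellite_max occurrence frequency strictly below which a taxon is
#'   satellite.
#' @param abundant_thr relative abundance at or above which a taxon counts as
#'   abundant in a sample (default 1%).
#' @param rare_thr relative abundance strictly below which a taxon counts as
#'   rare in a sample (default 0.01%).
#' @return data.frame with one row per taxon: `taxon_id`,
#'   `occurrence_frequency`, `mean_relative_abundance`, `occupancy_class`,
#'   `abundance_class`.
#' @export
partition_taxa <- function(table, core_min = 0.75, satellite_max = 0.50,
                           abundant_thr = 0.01, rare_thr = 0.0001) {
  stopifnot(inherits(table, "community_table"))
  if (!(rare_thr < abundant_thr)) stop_input("rare_thr must be below abundant_thr")
  if (satellite_max > core_min) stop_input("satellite_max must not exceed core_min")
  rel <- relative_abundance(table)
  freq <- colMeans(table$counts > 0)
  occ <- ifelse(freq >= core_min, "core",
    ifelse(freq < satellite_max, "satellite", "intermediate")
  )
  has_ab <- apply(rel, 2, function(x) any(x >= abundant_thr))
  all_ab <- apply(rel, 2, function(x) all(x >= abundant_thr))
  has_ra <- apply(rel, 2, function(x) any(x < rare_thr))
  all_ra <- apply(rel, 2, function(x) all(x < rare_thr))
  abcl <- ifelse(all_ab, "AAT",
    ifelse(all_ra, "ART",
      ifelse(has_ab & has_ra, "CRAT",
        ifelse(has_ab, "CAT",
          ifelse(has_ra, "CRT", "MT")
        )
      )
    )
  )
  data.frame(
    taxon_id = colnames(table$counts),
    occurrence_frequency = unname(freq),
    mean_relative_abundance = unname(colMeans(rel)),
    occupancy_class = factor(unname(occ), levels = c("core", "intermediate", "satellite")),
    abundance_class = factor(unname(abcl), levels = c("AAT", "CAT", "MT", "CRT", "CRAT", "ART")),
    stringsAsFactors = FALSE
  )
}

#' qPCR-scaled absolute abundances
#'
#' Converts relative sequence abundances to absolute abundance (18S rRNA gene
#' copies per mL) by multiplying each sample's total qPCR copy number by the
#' relative abundance of each taxon, and sums the result over the entire,
#' core and satellite taxon sets.
#'
#' @param table a [community_table()].
#' @param qpcr_totals named numeric vector (or data.frame with `sample_id`
#'   and `copies_per_ml`) of total 18S copies per mL per sample.
#' @param partition output of [partition_taxa()] for the same table.
#' @return list with `per_taxon` (samples x taxa matrix of copies/mL) and
#'   `group_sums` (data.frame: sample_id, entire, core, satellite).
#' @export
absolute_abundance <- function(table, qpcr_totals, partition) {
  stopifnot(inherits(table, "community_table"))
  if (is.data.frame(qpcr_totals)) {
    qpcr_totals <- setNames(qpcr_totals$copies_per_ml, qpcr_totals$sample_id)
  }
  ids <- rownames(table$counts)
  missing <- ids[!ids %in% names(qpcr_totals)]
  if (length(missing) > 0) {
    stop_input("missing qPCR total for sample(s): ", paste(missing, collapse = ", "))
  }
  tot <- qpcr_totals[ids]
  if (any(!is.finite(tot)) || any(tot <= 0)) {
    stop_input("qPCR totals must be positive and finite")
  }
  rel <- relative_abundance(table)
  abs_tab <- sweep(rel, 1, tot, "*")
  core_set <- partition$taxon_id[partition$occupancy_class == "core"]
  sat_set <- partition$taxon_id[partition$occupancy_class == "satellite"]
  group_sums <- data.frame(
    sample_id = ids,
    entire = unname(rowSums(abs_tab)),
    core = unname(rowSums(abs_tab[, colnames(abs_tab) %in% core_set, drop = FALSE])),
    satellite = unname(rowSums(abs_tab[, colnames(abs_tab) %in% sat_set, drop = FALSE])),
    stringsAsFactors = FALSE
  )
  list(per_taxon = abs_tab, group_sums = group_sums)
}
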