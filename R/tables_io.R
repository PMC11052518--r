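#' Construct and validate an ASV count table
#'
#' An ASV table is the universal currency of the package: a non-negative
#' integer matrix with amplicon sequence variants (ASVs) as rows and samples
#' as columns, both uniquely labelled. All downstream stages (rarefaction,
#' diversity, ordination, networks) consume this object.
#'
#' @param counts numeric matrix of counts, ASVs x samples. Must be
#'   non-negative whole numbers with unique, non-empty row and column names.
#' @return the validated matrix with class `"asv_table"` prepended.
#' @examples
#' m <- matrix(c(1L, 2L, 3L, 4L), 2, 2,
#'             dimnames = list(c("asv1", "asv2"), c("s1", "s2")))
#' asv_table(m)
#' @export
asv_table <- function(counts) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have ASV row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate ASV ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (any(!nzchar(rownames(counts))) || any(!nzchar(colnames(counts))))
    stop("empty ASV or sample id")
  if (anyNA(counts)) stop("counts contain NA")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(counts != round(counts))) stop("counts must be whole numbers")
  storage.mode(counts) <- "integer"
  class(counts) <- c("asv_table", class(matrix()))
  counts
}

#' @export
print.asv_table <- function(x, ...) {
  cat("ASV table: ", nrow(x), " ASVs x ", ncol(x), " samples; ",
      "total reads ", sum(x), "\n", sep = "")
  invisible(x)
}

# strip class so plain matrix semantics apply internally
unclass_table <- function(x) {
  class(x) <- NULL
  x
}

#' Read an ASV count table from TSV
#'
#' Expects a tab-separated file whose first column holds ASV ids and whose
#' header row holds sample ids; cells are non-negative integers. Lines
#' starting with `#` are ignored. Row and column order are preserved.
#'
#' @param path file path.
#' @return an [asv_table()].
#' @export
read_asv_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("ASV table needs an id column and >= 1 sample")
  ids <- df[[1L]]
  num <- suppressWarnings(vapply(df[-1L], as.numeric, numeric(nrow(df))))
  num <- matrix(num, nrow = nrow(df),
                dimnames = list(ids, colnames(df)[-1L]))
  if (anyNA(num)) stop("non-numeric cell in ", path)
  if (any(num != round(num))) stop("non-integer cell in ", path)
  asv_table(num)
}

#' Write an ASV count table to TSV
#'
#' Canonical on-disk form: header `asv_id` plus sample ids, tab-separated,
#' one ASV per row. `write_asv_table(read_asv_table(f))` is byte-identical
#' to a canonicalised `f`.
#'
#' @param table an [asv_table()].
#' @param path output file path.
#' @export
write_asv_table <- function(table, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("asv_id", colnames(table)), collapse = "\t"), con)
  body <- apply(table, 1L, paste, collapse = "\t")
  writeLines(paste(rownames(table), body, sep = "\t"), con)
  invisible(path)
}

#' @rdname taxonomy_table
#' @export
taxonomy_ranks <- c("domain", "phylum", "class", "order", "family",
                    "genus", "species")

#' Construct, read or write a taxonomy table
#'
#' A taxonomy table maps each ASV id to a ranked lineage
#' (domain...species). Unresolved ranks carry the explicit sentinel
#' `"unclassified"`, never an empty string; this package treats
#' unclassified lineages as first-class named taxa because they are often
#' dominant in gut communities.
#'
#' @param df data.frame with column `asv_id` plus the seven rank columns.
#' @param path file path.
#' @return a validated data.frame of class `"taxonomy_table"`.
#' @export
taxonomy_table <- function(df) {
  need <- c("asv_id", taxonomy_ranks)
  if (!all(need %in% colnames(df)))
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "))
  df <- df[, need, drop = FALSE]
  if (anyDuplicated(df$asv_id)) stop("duplicate asv_id in taxonomy")
  for (r in taxonomy_ranks) {
    v <- as.character(df[[r]])
    if (anyNA(v) || any(!nzchar(v)))
      stop("empty lineage value at rank '", r,
           "'; use the sentinel \"unclassified\"")
    df[[r]] <- v
  }
  df$asv_id <- as.character(df$asv_id)
  rownames(df) <- NULL
  class(df) <- c("taxonomy_table", "data.frame")
  df
}

#' @rdname taxonomy_table
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  taxonomy_table(df)
}

#' @rdname taxonomy_table
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(tax, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct, read or write a sample metadata table
#'
#' Per-sample grouping factors: host `species` (free label), `season`
#' (spring/summer/autumn/winter) and `gut_part` (foregut/hindgut/whole;
#' "whole" covers small fish sampled as an entire intestinal tract).
#'
#' @param df data.frame with columns `sample_id`, `species`, `season`,
#'   `gut_part`.
#' @param path file path.
#' @return validated data.frame of class `"sample_metadata"`.
#' @export
sample_metadata <- function(df) {
  need <- c("sample_id", "species", "season", "gut_part")
  if (!all(need %in% colnames(df)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  df <- df[, need, drop = FALSE]
  for (v in need) df[[v]] <- as.character(df[[v]])
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  seasons <- c("spring", "summer", "autumn", "winter")
  parts <- c("foregut", "hindgut", "whole")
  if (!all(df$season %in% seasons))
    stop("season values must be one of: ", paste(seasons, collapse = ", "))
  if (!all(df$gut_part %in% parts))
    stop("gut_part values must be one of: ", paste(parts, collapse = ", "))
  if (any(!nzchar(df$species))) stop("empty species label")
  rownames(df) <- NULL
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' @rdname sample_metadata
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  sample_metadata(df)
}

#' @rdname sample_metadata
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Rarefy an ASV table to a common depth
#'
#' Randomly subsamples each sample's reads *without replacement* down to
#' `depth`, equalising sequencing effort before diversity estimation.
#' Samples whose total is below `depth` are dropped (never padded); the
#' dropped ids are reported in a message and recorded in the
#' `"dropped_samples"` attribute of the result. Every retained column sums
#' exactly to `depth`, and the result is reproducible for a fixed `seed`.
#'
#' The default depth of 17,248 reads matches a common refinement depth for
#' fish gut 16S surveys; override it for other datasets.
#'
#' @param table an [asv_table()].
#' @param depth target reads per sample (positive integer).
#' @param seed integer seed for the subsampling RNG.
#' @return rarefied [asv_table()] with attribute `dropped_samples`.
#' @export
rarefy <- function(table, depth = 17248L, seed = 1L) {
  stopifnot(depth >= 1, depth == round(depth))
  x <- unclass_table(asv_table(unclass_table(table)))
  totals <- colSums(x)
  keep <- totals >= depth
  if (!any(keep))
    stop("all samples have fewer than ", depth, " reads; nothing to rarefy")
  dropped <- colnames(x)[!keep]
  if (length(dropped))
    message("rarefy: dropped ", length(dropped),
            " sample(s) below depth ", depth, ": ",
            paste(dropped, collapse = ", "))
  x <- x[, keep, drop = FALSE]
  set.seed(seed)
  out <- apply(x, 2L, function(col) {
    tot <- sum(col)
    if (tot == depth) return(col)
    reads <- rep.int(seq_along(col), col)     # multiset of reads
    tabulate(sample(reads, depth), nbins = length(col))
  })
  out <- matrix(out, nrow = nrow(x), dimnames = dimnames(x))
  res <- asv_table(out)
  attr(res, "dropped_samples") <- dropped
  attr(res, "depth") <- as.integer(depth)
  res
}

# lineage key at `rank`: unclassified values are keyed by their most
# resolved classified parent, prefixed "unclassified_"
lineage_keys <- function(tax, rank) {
  ri <- match(rank, taxonomy_ranks)
  vals <- tax[[rank]]
  unk <- vals == "unclassified"
  if (any(unk)) {
    parent <- rep("root", sum(unk))
    if (ri > 1L) {
      up <- as.matrix(tax[unk, taxonomy_ranks[seq_len(ri - 1L)], drop = FALSE])
      for (i in seq_len(nrow(up))) {
        known <- which(up[i, ] != "unclassified")
        if (length(known)) parent[i] <- up[i, max(known)]
      }
    }
    vals[unk] <- paste0("unclassified_", parent)
  }
  vals
}

#' Aggregate an ASV table to a taxonomic rank as relative abundances
#'
#' Counts are summed over ASVs sharing the lineage value at `rank`, then
#' each sample column is normalised by its total so columns sum to 1.
#' ASVs unclassified at `rank` are kept as named pseudo-taxa
#' (`unclassified_<most resolved parent>`) rather than merged or dropped.
#'
#' @param table an [asv_table()].
#' @param tax a [taxonomy_table()] covering every ASV in `table`.
#' @param rank one of `r paste(taxonomy_ranks, collapse = ", ")`.
#' @return numeric matrix, taxa x samples, columns summing to 1; attribute
#'   `"counts"` holds the pre-normalisation aggregated counts.
#' @export
aggregate_by_taxon <- function(table, tax, rank = "phylum") {
  rank <- match.arg(rank, taxonomy_ranks)
  x <- unclass_table(table)
  miss <- setdiff(rownames(x), tax$asv_id)
  if (length(miss))
    stop("ASVs missing from taxonomy: ", paste(miss, collapse = ", "))
  tax <- tax[match(rownames(x), tax$asv_id), , drop = FALSE]
  keys <- lineage_keys(tax, rank)
  agg <- rowsum(x, group = keys)
  totals <- colSums(agg)
  if (any(totals == 0)) stop("sample with zero total cannot be normalised")
  rel <- sweep(agg, 2L, totals, "/")
  attr(rel, "counts") <- agg
  rel
}

#' Subset samples of an ASV table by metadata predicate
#'
#' Selects the sample columns whose metadata rows satisfy `expr`, an
#' unquoted logical expression over the metadata columns (evaluated as in
#' [base::subset()]).
#'
#' @param table an [asv_table()].
#' @param metadata a [sample_metadata()] covering the table's samples.
#' @param expr unquoted logical predicate, e.g. `species == "C. carpio" &
#'   season != "winter"`.
#' @param drop_empty_asvs if `TRUE`, drop ASVs that are all-zero in the
#'   selection.
#' @return the subsetted [asv_table()].
#' @export
subset_samples <- function(table, metadata, expr, drop_empty_asvs = FALSE) {
  x <- unclass_table(table)
  md <- metadata[match(colnames(x), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id))
    stop("metadata missing for samples: ",
         paste(colnames(x)[is.na(md$sample_id)], collapse = ", "))
  keep <- eval(substitute(expr), md, parent.frame())
  if (!is.logical(keep) || length(keep) != ncol(x))
    stop("predicate must evaluate to one logical per sample")
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stop("predicate selects no samples")
  out <- x[, keep, drop = FALSE]
  if (drop_empty_asvs) out <- out[rowSums(out) > 0, , drop = FALSE]
  asv_table(out)
}
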